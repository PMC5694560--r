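#' Check marker-order consistency between two genetic maps
#'
#' Shared markers (exact, case-sensitive name match) are compared
#' chromosome by chromosome. On each chromosome the retained set is a
#' maximum-cardinality subset of the shared markers whose order (by cM
#' position) is identical in both maps — the longest common monotone
#' subsequence of the shared-marker ranks. Every other shared marker is
#' flagged with reason `"order"`; markers assigned to different
#' chromosomes in the two maps are flagged with reason
#' `"chromosome_assignment"`.
#'
#' @param map_a,map_b `genetic_map` objects.
#' @return A `consistency_report`: a list with components
#'   \describe{
#'     \item{conflicts}{data.frame with columns `marker`, `map_a`, `map_b`,
#'       `chromosome_a`, `chromosome_b`, `reason`.}
#'     \item{retained}{data.frame of consistent shared markers with columns
#'       `marker`, `chromosome`, `position_a`, `position_b`.}
#'   }
#' @export
check_order_consistency <- function(map_a, map_b) {
  shared <- intersect(map_a$marker, map_b$marker)
  empty_conflicts <- data.frame(
    marker = character(), map_a = character(), map_b = character(),
    chromosome_a = character(), chromosome_b = character(),
    reason = character(), stringsAsFactors = FALSE)
  empty_retained <- data.frame(
    marker = character(), chromosome = character(),
    position_a = numeric(), position_b = numeric(), stringsAsFactors = FALSE)
  if (!length(shared)) {
    return(structure(list(conflicts = empty_conflicts, retained = empty_retained),
                     class = "consistency_report"))
  }
  ia <- match(shared, map_a$marker)
  ib <- match(shared, map_b$marker)
  chr_a <- map_a$chromosome[ia]
  chr_b <- map_b$chromosome[ib]
  pos_a <- map_a$position_cM[ia]
  pos_b <- map_b$position_cM[ib]

  mism <- chr_a != chr_b
  conflicts <- if (any(mism)) {
    data.frame(marker = shared[mism], map_a = map_id(map_a), map_b = map_id(map_b),
               chromosome_a = chr_a[mism], chromosome_b = chr_b[mism],
               reason = "chromosome_assignment", stringsAsFactors = FALSE)
  } else empty_conflicts

  retained <- empty_retained
  for (chr in unique(chr_a[!mism])) {
    sel <- which(!mism & chr_a == chr)
    # Order shared markers as in map_a; break a-position ties by b-position
    # (the most favourable resolution of an order ambiguous in map_a).
    ord <- order(pos_a[sel], pos_b[sel], method = "radix")
    sel <- sel[ord]
    keep <- longest_nondecreasing_subsequence(pos_b[sel])
    kept <- sel[keep]
    dropped <- setdiff(sel, kept)
    if (length(dropped)) {
      conflicts <- rbind(conflicts, data.frame(
        marker = shared[dropped], map_a = map_id(map_a), map_b = map_id(map_b),
        chromosome_a = chr_a[dropped], chromosome_b = chr_b[dropped],
        reason = "order", stringsAsFactors = FALSE))
    }
    retained <- rbind(retained, data.frame(
      marker = shared[kept], chromosome = chr,
      position_a = pos_a[kept], position_b = pos_b[kept],
      stringsAsFactors = FALSE))
  }
  rownames(conflicts) <- rownames(retained) <- NULL
  structure(list(conflicts = conflicts, retained = retained),
            class = "consistency_report")
}

# Indices of a longest non-decreasing subsequence of x (O(n^2) DP; map-pair
# chromosomes hold at most a few thousand shared markers). Ties in x are
# allowed because cM positions may coincide.
longest_nondecreasing_subsequence <- function(x) {
  n <- length(x)
  if (n <= 1L) return(seq_len(n))
  len <- rep(1L, n)
  prev <- rep(0L, n)
  for (i in 2:n) {
    for (j in 1:(i - 1L)) {
      if (x[j] <= x[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  i <- which.max(len)
  out <- integer(len[i])
  k <- len[i]
  while (i > 0L) {
    out[k] <- i
    k <- k - 1L
    i <- prev[i]
  }
  out
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("Consistency report: %d retained shared marker(s), %d conflict(s)\n",
              nrow(x$retained), nrow(x$conflicts)))
  if (nrow(x$conflicts)) print(utils::head(x$conflicts, 10L))
  invisible(x)
}

#' Write a consistency report to a tab-separated file
#'
#' One row per conflicted marker:
#' `marker<TAB>map_a<TAB>map_b<TAB>chromosome_a<TAB>chromosome_b<TAB>reason`.
#'
#' @param report a `consistency_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consistency_report <- function(report, path) {
  utils::write.table(report$conflicts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
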