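#' Read a BLAST tabular (outfmt 6) HSP file
#'
#' Twelve columns: `qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore`. Query coordinates are 1-based
#' inclusive.
#'
#' @param path path to the file (no header line).
#' @return data.frame with the twelve standard columns.
#' @export
read_hsp_table <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) != 12L) {
    stop("HSP file '", path, "' has ", ncol(tab),
         " columns; expected the 12-column BLAST tabular format")
  }
  names(tab) <- cols
  for (col in c("pident", "length", "qstart", "qend", "sstart", "send",
                "evalue", "bitscore")) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  if (any(tab$qstart > tab$qend)) {
    stop("HSP with qstart > qend in '", path, "'")
  }
  tab
}

#' Reduce the HSPs of one query-subject pair to a non-redundant set
#'
#' HSPs are accepted greedily in descending bitscore; an HSP whose query
#' span overlaps the already-accepted query coverage by more than
#' `max_overlap` of its own span is discarded. This keeps cumulative
#' statistics interpretable: uncontrolled summation over mutually
#' overlapping HSPs could push coverage past 100%.
#'
#' @param hsps data.frame of HSPs sharing `qseqid` and `sseqid` (columns
#'   as in [read_hsp_table()]).
#' @param max_overlap tolerated fractional overlap (default 0.05).
#' @return The retained subset of `hsps`.
#' @export
merge_hsps <- function(hsps, max_overlap = 0.05) {
  if (!nrow(hsps)) return(hsps)
  if (length(unique(hsps$qseqid)) > 1L || length(unique(hsps$sseqid)) > 1L) {
    stop("merge_hsps() expects HSPs of a single query-subject pair")
  }
  o <- order(-hsps$bitscore, hsps$qstart)
  covered <- matrix(numeric(0), ncol = 2L)  # accepted [start, end] intervals
  keep <- logical(nrow(hsps))
  for (i in o) {
    span <- hsps$qend[i] - hsps$qstart[i] + 1
    ov <- 0
    if (nrow(covered)) {
      lo <- pmax(covered[, 1L], hsps$qstart[i])
      hi <- pmin(covered[, 2L], hsps$qend[i])
      ov <- sum(pmax(0, hi - lo + 1))
    }
    if (ov <= max_overlap * span) {
      keep[i] <- TRUE
      covered <- rbind(covered, c(hsps$qstart[i], hsps$qend[i]))
    }
  }
  hsps[keep, , drop = FALSE]
}

#' Cumulative identity and alignment-length percentages of a hit
#'
#' Over the retained HSPs of one query-subject pair:
#' `CIP = 100 * sum(identities) / sum(alignment lengths)` where each
#' HSP contributes `pident/100 * length` identities, and
#' `CALP = 100 * sum(alignment lengths) / query_length`, capped at 100.
#' Together they favour the best alignment in the sense of the highest
#' cumulative identity over the longest cumulative length.
#'
#' @param hsps merged HSPs of one query-subject pair (see [merge_hsps()]).
#' @param query_length query sequence length in residues (> 0).
#' @return data.frame with one row: `qseqid`, `sseqid`, `cip`, `calp`,
#'   `n_hsps_used`; `NULL` for an empty HSP set (no hit is distinct from a
#'   zero-scoring hit).
#' @export
compute_cip_calp <- function(hsps, query_length) {
  stopifnot(query_length > 0)
  if (!nrow(hsps)) return(NULL)
  al <- sum(hsps$length)
  identities <- sum(hsps$pident / 100 * hsps$length)
  data.frame(qseqid = hsps$qseqid[1L], sseqid = hsps$sseqid[1L],
             cip = 100 * identities / al,
             calp = min(100, 100 * al / query_length),
             n_hsps_used = nrow(hsps), stringsAsFactors = FALSE)
}

#' Score all query-subject pairs of an HSP table
#'
#' Applies [merge_hsps()] then [compute_cip_calp()] to every pair.
#'
#' @param hsps data.frame as from [read_hsp_table()].
#' @param query_lengths named numeric vector (or data.frame with columns
#'   `qseqid`, `length`) of query lengths.
#' @inheritParams merge_hsps
#' @return data.frame of hits, one row per query-subject pair.
#' @export
score_hits <- function(hsps, query_lengths, max_overlap = 0.05) {
  if (is.data.frame(query_lengths)) {
    query_lengths <- stats::setNames(query_lengths$length, query_lengths$qseqid)
  }
  out <- list()
  for (piece in split(hsps, list(hsps$qseqid, hsps$sseqid), drop = TRUE)) {
    ql <- unname(query_lengths[piece$qseqid[1L]])
    if (length(ql) != 1L || is.na(ql)) {
      stop("no query length for '", piece$qseqid[1L], "'")
    }
    out[[length(out) + 1L]] <-
      compute_cip_calp(merge_hsps(piece, max_overlap), ql)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(qseqid = character(), sseqid = character(),
                      cip = numeric(), calp = numeric(),
                      n_hsps_used = integer(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Rank candidate hits and apply CIP/CALP thresholds
#'
#' Per query, hits are ordered by CIP (descending), then CALP
#' (descending), then subject id (ascending, a deterministic tie-break);
#' the best hit is reported with `pass = cip >= min_cip & calp >= min_calp`.
#'
#' @param hits data.frame of scored hits (see [score_hits()]).
#' @param min_cip,min_calp acceptance thresholds in percent (defaults 60
#'   and 70).
#' @return data.frame with the best hit per query and a logical `pass`
#'   column.
#' @export
rank_candidates <- function(hits, min_cip = 60, min_calp = 70) {
  stopifnot(min_cip >= 0, min_cip <= 100, min_calp >= 0, min_calp <= 100)
  if (!nrow(hits)) return(cbind(hits, data.frame(pass = logical())))
  hits <- hits[order(hits$qseqid, -hits$cip, -hits$calp, hits$sseqid,
                     method = "radix"), , drop = FALSE]
  best <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  best$pass <- best$cip >= min_cip & best$calp >= min_calp
  rownames(best) <- NULL
  best
}
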