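#' Summarize marker content of a genetic map
#'
#' Counts markers by the requested grouping. The wheat groupings assume
#' the hexaploid chromosome naming convention `<group><subgenome>` with
#' group 1–7 and subgenome A/B/D (e.g. `"5B"`); homoeologous group is the
#' digit, subgenome the letter.
#'
#' @param map a `genetic_map`.
#' @param by one of `"chromosome_type"` (chromosome x marker-type matrix
#'   with row/column totals), `"homoeologous_group"`, `"subgenome"`, or
#'   `"grand_total"`.
#' @return For `"grand_total"`, a single count; otherwise a data.frame of
#'   counts whose `n` column sums to the grand total.
#' @export
summarize_map <- function(map, by = c("chromosome_type", "homoeologous_group",
                                      "subgenome", "grand_total")) {
  by <- match.arg(by)
  counts <- marker_counts(map)
  summarize_marker_counts(counts, by)
}

#' Tally markers per chromosome and type
#'
#' @param map a `genetic_map`.
#' @return data.frame with columns `chromosome`, `marker_type`, `n`.
#' @export
marker_counts <- function(map) {
  if (!nrow(map)) {
    return(data.frame(chromosome = character(), marker_type = character(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  tab <- as.data.frame(table(chromosome = map$chromosome,
                             marker_type = map$marker_type),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "n"
  tab <- tab[tab$n > 0L, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Aggregate a marker count table
#'
#' Operates on per-chromosome, per-type counts (as produced by
#' [marker_counts()] or read from a published summary table), so that map
#' objects and printed marker tallies flow through the same aggregation.
#'
#' @param counts data.frame with columns `chromosome`, `marker_type`, `n`.
#' @inheritParams summarize_map
#' @return See [summarize_map()].
#' @export
summarize_marker_counts <- function(counts,
                                    by = c("chromosome_type",
                                           "homoeologous_group",
                                           "subgenome", "grand_total")) {
  by <- match.arg(by)
  stopifnot(all(c("chromosome", "marker_type", "n") %in% names(counts)))
  if (by == "grand_total") return(sum(counts$n))
  if (by == "chromosome_type") {
    out <- aggregate(n ~ chromosome + marker_type, counts, sum)
    return(out[order(out$chromosome, out$marker_type), , drop = FALSE])
  }
  chr <- unique(counts$chromosome)
  ok <- grepl("^[1-7][ABD]$", chr)
  if (!all(ok)) {
    stop("wheat grouping '", by, "' requires chromosome labels 1A..7D; found ",
         paste(utils::head(chr[!ok], 3L), collapse = ", "))
  }
  key <- if (by == "homoeologous_group") {
    substr(counts$chromosome, 1L, 1L)
  } else {
    substr(counts$chromosome, 2L, 2L)
  }
  out <- aggregate(list(n = counts$n), list(group = key), sum)
  names(out)[1L] <- if (by == "homoeologous_group") "homoeologous_group" else "subgenome"
  out[order(out[[1L]]), , drop = FALSE]
}
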