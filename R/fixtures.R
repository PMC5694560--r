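#' Packaged wheat summary tables
#'
#' Three small tab-separated tables transcribing the published wheat
#' integration summaries ship with the package: the consensus-map marker
#' tally per chromosome and marker type, the per-population QTL counts of
#' the 27 source studies, and the 32-meta-QTL summary (decimal commas
#' normalized to dots).
#'
#' @name wheat_tables
#' @return Each loader returns a data.frame.
NULL

fixture_path <- function(file) {
  system.file("extdata", file, package = "qtlmeta", mustWork = TRUE)
}

#' @describeIn wheat_tables marker counts in long format (`chromosome`,
#'   `marker_type`, `n`), ready for [summarize_marker_counts()].
#' @export
wheat_marker_counts <- function() {
  wide <- utils::read.delim(fixture_path("table1_markers.tsv"),
                            check.names = FALSE)
  types <- setdiff(names(wide), "chromosome")
  long <- data.frame(
    chromosome = rep(wide$chromosome, times = length(types)),
    marker_type = rep(types, each = nrow(wide)),
    n = unlist(wide[types], use.names = FALSE),
    stringsAsFactors = FALSE)
  long[long$n > 0, , drop = FALSE]
}

#' @describeIn wheat_tables per-population QTL counts by trait component;
#'   yield components `Th`..`GrW`, baking-quality components
#'   `Visco`..`OtherBQ`, and `GPC`.
#' @export
wheat_qtl_counts <- function() {
  utils::read.delim(fixture_path("table2_qtl_counts.tsv"), check.names = FALSE)
}

#' @describeIn wheat_tables the 32 meta-QTLs with CI bounds, printed
#'   widths, member counts and candidate genes.
#' @export
wheat_mqtl_table <- function() {
  utils::read.delim(fixture_path("table3_mqtl.tsv"), check.names = FALSE)
}

#' Expand a per-population QTL count table into QTL records
#'
#' Turns a counts-by-component table (as returned by [wheat_qtl_counts()])
#' into one record per counted QTL in the [read_qtl_table()] schema, so
#' the same validation and tally code paths apply to published counts as
#' to real QTL tables. Positions are placeholders (the published counts
#' carry no coordinates): peak 0, CI [0, 20], chromosome `"1A"`.
#'
#' @param counts data.frame of counts with population columns `parent1`,
#'   `parent2` and one column per trait component.
#' @return data.frame of QTL records with `trait_class` GY for yield
#'   components, BQ for baking-quality components and GPC.
#' @export
expand_qtl_counts <- function(counts) {
  comp_class <- c(Th = "GY", TKW = "GY", Tn = "GY", GrN = "GY", HI = "GY",
                  PH = "GY", SL = "GY", GrW = "GY",
                  Visco = "BQ", W = "BQ", Vol = "BQ", OtherBQ = "BQ",
                  GPC = "GPC")
  comps <- intersect(names(comp_class), names(counts))
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    pid <- sprintf("pop%02d_%s_x_%s", i, counts$parent1[i], counts$parent2[i])
    for (comp in comps) {
      k <- counts[[comp]][i]
      if (!k) next
      rows[[length(rows) + 1L]] <- data.frame(
        qtl_id = sprintf("p%02d_%s_%d", i, comp, seq_len(k)),
        population_id = pid,
        trait_class = comp_class[[comp]],
        trait_component = comp,
        chromosome = "1A", peak_cM = 0, ci_left_cM = 0, ci_right_cM = 20,
        lod = NA_real_, r2 = NA_real_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
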