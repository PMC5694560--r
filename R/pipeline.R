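#' Run the full integration pipeline
#'
#' Executes the stages in order: consensus-map construction
#' ([merge_maps()]), per-study QTL projection ([project_qtl_study()]),
#' meta-analysis ([run_meta_analysis()]) and, when a syntenome and
#' backbone are supplied, gene-repertoire extraction under the meta-QTL
#' intervals ([genes_under_mqtl()]) and CIP/CALP candidate scoring
#' ([score_hits()], [rank_candidates()]). Every exclusion (conflicted
#' marker, unprojectable QTL, unresolved cluster) is carried into the
#' returned audit trail, so every input QTL is accounted for exactly once
#' among meta-QTL members, unresolved clusters and exclusions.
#'
#' @param maps list of `genetic_map` objects (or paths readable by
#'   [read_map()]).
#' @param qtl_tables named list: one QTL data.frame (or path) per study;
#'   names must match `qtl_source_maps`.
#' @param qtl_source_maps named list mapping each QTL table name to its
#'   study `genetic_map` (or path). A study whose markers live on one of
#'   `maps` may reference that map directly.
#' @param merge_order `"by_size"` (default) or `"given"`.
#' @param criterion meta-analysis model-selection criterion.
#' @param syntenome,backbone optional syntenome and backbone data.frames
#'   (or paths) enabling the synteny stage.
#' @param hsps,query_lengths optional HSP table and query lengths enabling
#'   candidate scoring.
#' @param min_cip,min_calp candidate acceptance thresholds.
#' @param impute_ci_width CI width imputed for QTLs without published CIs.
#' @param out_dir optional directory; when given, every artifact is also
#'   written as a tab-separated file.
#' @return list with `consensus`, `conflicts`, `projected`, `excluded`,
#'   `mqtl`, `audit`, and (when enabled) `gene_repertoire`, `candidates`,
#'   plus `log` (per-stage counts).
#' @export
run_pipeline <- function(maps, qtl_tables, qtl_source_maps,
                         merge_order = c("by_size", "given"),
                         criterion = c("AWE", "AIC", "AICc", "BIC"),
                         syntenome = NULL, backbone = NULL,
                         hsps = NULL, query_lengths = NULL,
                         min_cip = 60, min_calp = 70,
                         impute_ci_width = 20, out_dir = NULL) {
  merge_order <- match.arg(merge_order)
  criterion <- match.arg(criterion)
  load_map <- function(m, id) if (inherits(m, "genetic_map")) m else read_map(m, id)
  load_tab <- function(x, reader) if (is.character(x)) reader(x) else x

  maps <- lapply(seq_along(maps), function(i)
    load_map(maps[[i]], paste0("map", i)))
  stopifnot(is.list(qtl_tables), is.list(qtl_source_maps),
            all(names(qtl_tables) %in% names(qtl_source_maps)))

  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- data.frame(stage = stage,
                                           detail = paste0(...),
                                           stringsAsFactors = FALSE)
  }

  consensus <- merge_maps(maps, order = merge_order)
  conflicts <- attr(consensus, "conflicts")
  note("maps", nrow(consensus), " consensus markers from ", length(maps),
       " maps; ", nrow(conflicts), " conflicted markers removed")

  projected <- list()
  excluded <- list()
  for (study in names(qtl_tables)) {
    qtls <- validate_qtl_records(load_tab(qtl_tables[[study]], read_qtl_table),
                                 impute_ci_width = impute_ci_width)
    src <- load_map(qtl_source_maps[[study]], study)
    res <- project_qtl_study(qtls, src, consensus)
    projected[[study]] <- res$projected
    if (nrow(res$excluded)) excluded[[study]] <- res$excluded
  }
  projected <- do.call(rbind, c(projected, list(make.row.names = FALSE)))
  excluded <- if (length(excluded)) {
    do.call(rbind, c(excluded, list(make.row.names = FALSE)))
  } else {
    data.frame(qtl_id = character(), chromosome = character(),
               reason = character(), stringsAsFactors = FALSE)
  }
  note("projection", nrow(projected), " QTLs projected, ",
       nrow(excluded), " excluded")

  meta <- run_meta_analysis(projected, criterion = criterion)
  note("metaqtl", nrow(meta$mqtl), " meta-QTLs, ",
       nrow(meta$audit), " unresolved clusters")

  out <- list(consensus = consensus, conflicts = conflicts,
              projected = projected, excluded = excluded,
              mqtl = meta$mqtl, audit = meta$audit)

  if (!is.null(syntenome) && !is.null(backbone)) {
    anchored <- anchor_syntenome(load_tab(syntenome, read_syntenome),
                                 load_tab(backbone, read_backbone))
    out$gene_repertoire <- genes_under_mqtl(meta$mqtl, anchored)
    note("synteny", nrow(out$gene_repertoire),
         " gene-by-MQTL repertoire rows")
  }
  if (!is.null(hsps) && !is.null(query_lengths)) {
    hits <- score_hits(load_tab(hsps, read_hsp_table), query_lengths)
    out$candidates <- rank_candidates(hits, min_cip = min_cip,
                                      min_calp = min_calp)
    note("candidates", sum(out$candidates$pass), " of ",
         nrow(out$candidates), " best hits pass CIP/CALP thresholds")
  }
  out$log <- do.call(rbind, log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_map(consensus, file.path(out_dir, "consensus.tsv"))
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(conflicts, "conflicts.tsv")
    wt(projected, "projected_qtl.tsv")
    wt(excluded, "excluded_qtl.tsv")
    write_mqtl_report(meta$mqtl, file.path(out_dir, "mqtl.tsv"))
    wt(meta$audit[, setdiff(names(meta$audit), "members")], "audit.tsv")
    if (!is.null(out$gene_repertoire)) wt(out$gene_repertoire, "gene_repertoire.tsv")
    if (!is.null(out$candidates)) wt(out$candidates, "candidates.tsv")
    wt(out$log, "run_log.tsv")
  }
  out
}

#' Write a meta-QTL report
#'
#' Tab-separated columns `mqtl_id`, `trait_class`, `chromosome`,
#' `position_cM`, `ci_left`, `ci_right`, `width_cM`, `n_qtls`,
#' `n_populations`, `components`, `member_qtl_ids`, paralleling the usual
#' printed meta-QTL summary tables. The width is `ci_right - ci_left`; all
#' cM values are rounded half-away-from-zero to two decimals at
#' serialization only.
#'
#' @param mqtls meta-QTL table from [run_meta_analysis()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mqtl_report <- function(mqtls, path) {
  out <- as.data.frame(mqtls)
  out$width_cM <- out$ci_right - out$ci_left
  for (col in c("position_cM", "ci_left", "ci_right", "width_cM")) {
    out[[col]] <- sprintf("%.2f", round_half_up(out[[col]], 2))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
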