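#' Read a QTL table
#'
#' Expects a tab-separated file with header columns `qtl_id`,
#' `population_id`, `trait_class`, `trait_component`, `chromosome`,
#' `peak_cM`, `ci_left_cM`, `ci_right_cM`, `lod`, `r2`. Trait classes are
#' restricted to the three studied families: `GY` (grain yield), `GPC`
#' (grain protein content) and `BQ` (baking quality). QTLs published
#' without a confidence interval get a default 95% CI of width
#' `impute_ci_width` centred on the peak, flagged in the `ci_imputed`
#' column.
#'
#' @param path path to the file.
#' @param impute_ci_width width (cM) of the CI imputed when `ci_left_cM`
#'   or `ci_right_cM` is missing.
#' @return data.frame of validated QTL records.
#' @export
read_qtl_table <- function(path, impute_ci_width = 20) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("qtl_id", "population_id", "trait_class", "trait_component",
                "chromosome", "peak_cM", "ci_left_cM", "ci_right_cM")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("QTL table '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(tab$lod)) tab$lod <- NA_real_
  if (is.null(tab$r2)) tab$r2 <- NA_real_
  validate_qtl_records(tab, impute_ci_width = impute_ci_width)
}

#' Validate (and CI-impute) QTL records
#'
#' @param qtls data.frame of QTL records (see [read_qtl_table()] for the
#'   columns).
#' @inheritParams read_qtl_table
#' @return The validated data.frame with a logical `ci_imputed` column.
#' @export
validate_qtl_records <- function(qtls, impute_ci_width = 20) {
  qtls <- as.data.frame(qtls, stringsAsFactors = FALSE)
  for (col in c("peak_cM", "ci_left_cM", "ci_right_cM", "lod", "r2")) {
    if (!is.null(qtls[[col]])) qtls[[col]] <- suppressWarnings(as.numeric(qtls[[col]]))
  }
  bad_class <- setdiff(unique(qtls$trait_class), c("GY", "GPC", "BQ"))
  if (length(bad_class)) {
    stop("unknown trait_class: ", paste(bad_class, collapse = ", "),
         " (expected GY, GPC or BQ)")
  }
  if (anyNA(qtls$peak_cM)) {
    stop("missing or non-numeric peak_cM (row ",
         which(is.na(qtls$peak_cM))[1L], ")")
  }
  miss <- is.na(qtls$ci_left_cM) | is.na(qtls$ci_right_cM)
  qtls$ci_imputed <- miss
  if (any(miss)) {
    qtls$ci_left_cM[miss] <- pmax(0, qtls$peak_cM[miss] - impute_ci_width / 2)
    qtls$ci_right_cM[miss] <- qtls$peak_cM[miss] + impute_ci_width / 2
  }
  bad <- which(qtls$ci_left_cM > qtls$peak_cM | qtls$peak_cM > qtls$ci_right_cM)
  if (length(bad)) {
    stop("QTL '", qtls$qtl_id[bad[1L]],
         "': peak lies outside its confidence interval")
  }
  if (!is.null(qtls$lod) && any(qtls$lod < 0, na.rm = TRUE)) {
    stop("negative LOD score")
  }
  if (!is.null(qtls$r2) && any(qtls$r2 < 0 | qtls$r2 > 1, na.rm = TRUE)) {
    stop("r2 outside [0, 1]")
  }
  qtls
}

#' Project QTLs onto consensus-map coordinates
#'
#' Each QTL's peak and CI bounds are projected through the homothetic
#' anchor frame of its chromosome ([project_position()]). Because the
#' projection is monotone, `ci_left <= peak <= ci_right` is preserved.
#' Flags record peaks or CI bounds beyond the terminal anchors
#' (`extrapolated_left` / `extrapolated_right`) and frames with fewer than
#' four anchors (`sparse_anchors`).
#'
#' @param qtls data.frame of QTL records on one chromosome (source-map
#'   coordinates).
#' @param frame [anchor_frame()] from source-map to consensus coordinates.
#' @param source_map identifier of the source map, copied to the output.
#' @return The records re-expressed in consensus coordinates, with columns
#'   `source_map` and `flags` (semicolon-joined) appended.
#' @export
project_qtl <- function(qtls, frame, source_map = "") {
  if (n_anchors(frame) < 2L) {
    stop("QTL projection requires at least 2 anchors on the chromosome")
  }
  out <- as.data.frame(qtls, stringsAsFactors = FALSE)
  lo <- frame$src[1L]
  hi <- frame$src[n_anchors(frame)]
  flags <- character(nrow(out))
  for (i in seq_len(nrow(out))) {
    f <- character()
    if (out$ci_left_cM[i] < lo) f <- c(f, "extrapolated_left")
    if (out$ci_right_cM[i] > hi) f <- c(f, "extrapolated_right")
    if (n_anchors(frame) < 4L) f <- c(f, "sparse_anchors")
    flags[i] <- paste(f, collapse = ";")
  }
  out$peak_cM <- project_position(out$peak_cM, frame)
  out$ci_left_cM <- project_position(out$ci_left_cM, frame)
  out$ci_right_cM <- project_position(out$ci_right_cM, frame)
  out$source_map <- source_map
  out$flags <- flags
  out
}

#' Project a whole QTL study onto the consensus map
#'
#' Builds, per chromosome, the anchor frame of consistent markers shared
#' between the study's own map and the consensus
#' ([check_order_consistency()]), then projects every QTL through it.
#' QTLs on chromosomes with fewer than two usable anchors (or absent from
#' the consensus) are excluded and reported.
#'
#' @param qtls data.frame of QTL records in `source_map` coordinates.
#' @param source_map the study's own `genetic_map`.
#' @param consensus the consensus `genetic_map`.
#' @return list with `projected` (data.frame of projected records) and
#'   `excluded` (data.frame with columns `qtl_id`, `chromosome`, `reason`).
#' @export
project_qtl_study <- function(qtls, source_map, consensus) {
  report <- check_order_consistency(consensus, source_map)
  projected <- list()
  excluded <- data.frame(qtl_id = character(), chromosome = character(),
                         reason = character(), stringsAsFactors = FALSE)
  for (chr in unique(qtls$chromosome)) {
    rows <- qtls[qtls$chromosome == chr, , drop = FALSE]
    if (!chr %in% consensus$chromosome) {
      excluded <- rbind(excluded, data.frame(
        qtl_id = rows$qtl_id, chromosome = chr,
        reason = "chromosome_absent_from_consensus", stringsAsFactors = FALSE))
      next
    }
    anchors <- report$retained[report$retained$chromosome == chr, , drop = FALSE]
    frame <- anchor_frame(anchors$position_b, anchors$position_a)
    if (n_anchors(frame) < 2L) {
      excluded <- rbind(excluded, data.frame(
        qtl_id = rows$qtl_id, chromosome = chr,
        reason = "fewer_than_2_anchors", stringsAsFactors = FALSE))
      next
    }
    projected[[chr]] <- project_qtl(rows, frame, source_map = map_id(source_map))
  }
  projected <- if (length(projected)) {
    do.call(rbind, projected)
  } else {
    cbind(qtls[0, , drop = FALSE],
          data.frame(source_map = character(), flags = character()))
  }
  rownames(projected) <- rownames(excluded) <- NULL
  list(projected = projected, excluded = excluded)
}
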