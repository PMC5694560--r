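#' Read an ordered gene list (syntenome)
#'
#' Tab-separated columns `chromosome`, `ordinal`, `gene_id`, and
#' optionally `orthologs` (semicolon-joined, may be empty) and `scaffold`.
#' Ordinals must be strictly increasing within a chromosome.
#'
#' @param path path to the file.
#' @return data.frame of genes sorted by (chromosome, ordinal).
#' @export
read_syntenome <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c("chromosome", "ordinal", "gene_id"), names(tab))
  if (length(missing_cols)) {
    stop("syntenome file '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab$ordinal <- as.numeric(tab$ordinal)
  if (is.null(tab$orthologs)) tab$orthologs <- ""
  if (is.null(tab$scaffold)) tab$scaffold <- ""
  tab <- tab[order(tab$chromosome, tab$ordinal), , drop = FALSE]
  dup <- unlist(tapply(tab$ordinal, tab$chromosome,
                       function(o) any(duplicated(o))))
  if (any(dup)) {
    stop("duplicated gene ordinal on chromosome ", names(dup)[dup][1L])
  }
  rownames(tab) <- NULL
  tab
}

#' Read backbone anchor markers for syntenome anchoring
#'
#' Tab-separated columns `chromosome`, `ordinal`, `marker`,
#' `consensus_cM`: markers shared between the consensus genetic map and
#' the ordered gene list, with their ordinal slot in the gene order and
#' their consensus map position.
#'
#' @param path path to the file.
#' @return data.frame sorted by (chromosome, ordinal).
#' @export
read_backbone <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c("chromosome", "ordinal", "marker", "consensus_cM"),
                          names(tab))
  if (length(missing_cols)) {
    stop("backbone file '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab$ordinal <- as.numeric(tab$ordinal)
  tab$consensus_cM <- as.numeric(tab$consensus_cM)
  tab <- tab[order(tab$chromosome, tab$ordinal), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Anchor a syntenome to consensus-map coordinates
#'
#' Each gene's map position (`anchored_cM`) is linearly interpolated by
#' ordinal between the flanking backbone markers; genes beyond the
#' terminal markers extend the terminal interval's cM-per-ordinal rate.
#' The interpolation is in ordinal rank, not physical distance: the gene
#' order carries rank information only. Chromosomes with fewer than two
#' backbone markers are left unanchored (`anchored_cM = NA`) with a
#' warning.
#'
#' @param genes syntenome data.frame (see [read_syntenome()]).
#' @param backbone backbone marker data.frame (see [read_backbone()]).
#' @return `genes` with an `anchored_cM` column appended.
#' @export
anchor_syntenome <- function(genes, backbone) {
  genes$anchored_cM <- NA_real_
  for (chr in unique(genes$chromosome)) {
    b <- backbone[backbone$chromosome == chr, , drop = FALSE]
    frame <- anchor_frame(b$ordinal, b$consensus_cM)
    sel <- genes$chromosome == chr
    if (n_anchors(frame) < 2L) {
      warning("chromosome ", chr, ": fewer than 2 backbone markers; ",
              sum(sel), " gene(s) left unanchored", call. = FALSE)
      next
    }
    genes$anchored_cM[sel] <- pmax(0, project_position(genes$ordinal[sel], frame))
  }
  genes
}

#' Genes under a map interval
#'
#' Returns the genes whose anchored position falls inside the closed
#' interval `[left, right]` on the given chromosome, in ordinal order —
#' the gene repertoire under a meta-QTL confidence interval.
#'
#' @param anchored anchored syntenome (see [anchor_syntenome()]).
#' @param chromosome chromosome label.
#' @param left,right interval bounds in cM, `left <= right`.
#' @return data.frame of genes (possibly empty).
#' @export
genes_in_interval <- function(anchored, chromosome, left, right) {
  stopifnot(left <= right)
  if (!chromosome %in% anchored$chromosome) {
    stop("unknown chromosome '", chromosome, "'")
  }
  sel <- anchored$chromosome == chromosome &
    !is.na(anchored$anchored_cM) &
    anchored$anchored_cM >= left & anchored$anchored_cM <= right
  out <- anchored[sel, , drop = FALSE]
  if (!nrow(out)) {
    warning("no genes anchored in [", left, ", ", right, "] on chromosome ",
            chromosome, call. = FALSE)
  }
  out <- out[order(out$ordinal), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene repertoires under a set of meta-QTL intervals
#'
#' @param mqtl meta-QTL table (see [run_meta_analysis()]).
#' @param anchored anchored syntenome.
#' @return data.frame pairing `mqtl_id` with each gene under its CI.
#' @export
genes_under_mqtl <- function(mqtl, anchored) {
  out <- list()
  for (i in seq_len(nrow(mqtl))) {
    if (!mqtl$chromosome[i] %in% anchored$chromosome) next
    g <- suppressWarnings(genes_in_interval(anchored, mqtl$chromosome[i],
                                            max(0, mqtl$ci_left[i]),
                                            mqtl$ci_right[i]))
    if (nrow(g)) {
      out[[length(out) + 1L]] <- cbind(mqtl_id = mqtl$mqtl_id[i], g)
    }
  }
  if (!length(out)) {
    return(cbind(data.frame(mqtl_id = integer()),
                 anchored[0, , drop = FALSE]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
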