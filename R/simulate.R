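# Run code under a fixed RNG seed, restoring the caller's RNG state after.
# Every generator is a pure function of (parameters, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate a true genetic map and distorted derived maps
#'
#' The true map places `markers_per_chrom` markers uniformly at random on
#' each chromosome. Each derived map samples a fraction `share_frac` of
#' the true markers (so maps overlap pairwise through the true set),
#' applies a per-chromosome monotone affine transform (scale drawn from
#' `scale_range`) plus Gaussian positional jitter (jitter that would break
#' marker order is redrawn), and reverses `n_inversions` random marker
#' runs, emulating genotype-specific inversions.
#'
#' @param n_maps number of derived maps.
#' @param chromosomes data.frame with columns `label` and `length_cM`.
#' @param markers_per_chrom markers per chromosome on the true map (>= 2).
#' @param share_frac fraction of true markers carried by each derived map,
#'   in (0, 1].
#' @param distortion_sd standard deviation (cM) of the positional jitter.
#' @param n_inversions number of marker-run inversions injected per
#'   derived map.
#' @param scale_range range of the per-chromosome affine scale factor.
#' @param seed integer seed.
#' @return list with `true_map` (a `genetic_map`), `derived` (list of
#'   `genetic_map`s) and `truth` (distortion and inversion logs).
#' @export
simulate_maps <- function(n_maps, chromosomes, markers_per_chrom,
                          share_frac = 0.5, distortion_sd = 0,
                          n_inversions = 0L, scale_range = c(0.8, 1.2),
                          seed = 1L) {
  stopifnot(markers_per_chrom >= 2L, share_frac > 0, share_frac <= 1,
            distortion_sd >= 0)
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(chromosomes))) {
      lab <- chromosomes$label[i]
      pos <- sort(stats::runif(markers_per_chrom, 0, chromosomes$length_cM[i]))
      rows[[i]] <- data.frame(
        chromosome = lab,
        marker = sprintf("%s_m%03d", lab, seq_len(markers_per_chrom)),
        position_cM = pos,
        marker_type = sample(c("SNP", "SSR", "RFLP", "DarT", "Gene"),
                             markers_per_chrom, replace = TRUE,
                             prob = c(0.85, 0.07, 0.04, 0.03, 0.01)),
        stringsAsFactors = FALSE)
    }
    true_map <- genetic_map(do.call(rbind, rows), "true")

    derived <- list()
    distortions <- list()
    inversions <- list()
    for (m in seq_len(n_maps)) {
      mid <- sprintf("map%02d", m)
      pieces <- list()
      for (i in seq_len(nrow(chromosomes))) {
        lab <- chromosomes$label[i]
        chr <- true_map[true_map$chromosome == lab, , drop = FALSE]
        n_take <- max(2L, round(share_frac * nrow(chr)))
        take <- sort(sample(nrow(chr), n_take))
        chr <- chr[take, , drop = FALSE]
        scale <- stats::runif(1, scale_range[1L], scale_range[2L])
        pos <- chr$position_cM * scale
        if (distortion_sd > 0) {
          prev <- -Inf
          for (k in seq_along(pos)) {
            for (try in 1:25) {
              cand <- pos[k] + stats::rnorm(1, 0, distortion_sd)
              if (cand > prev) break
            }
            if (cand <= prev) cand <- prev + 1e-3
            pos[k] <- cand
            prev <- cand
          }
          pos <- pos - min(0, min(pos))  # keep positions non-negative
        }
        chr$position_cM <- pos
        pieces[[lab]] <- chr
        distortions[[length(distortions) + 1L]] <- data.frame(
          map = mid, chromosome = lab, scale = scale, stringsAsFactors = FALSE)
      }
      dm <- do.call(rbind, pieces)
      for (v in seq_len(n_inversions)) {
        chr_lab <- sample(chromosomes$label, 1L)
        idx <- which(dm$chromosome == chr_lab)
        idx <- idx[order(dm$position_cM[idx])]
        if (length(idx) < 2L) next
        run <- min(sample(2:5, 1L), length(idx))
        start <- sample(length(idx) - run + 1L, 1L)
        span <- idx[start:(start + run - 1L)]
        dm$position_cM[span] <- rev(dm$position_cM[span])
        inversions[[length(inversions) + 1L]] <- data.frame(
          map = mid, chromosome = chr_lab,
          markers = paste(dm$marker[span], collapse = ","),
          stringsAsFactors = FALSE)
      }
      derived[[mid]] <- genetic_map(dm, mid)
    }
    list(true_map = true_map, derived = derived,
         truth = list(
           distortions = do.call(rbind, distortions),
           inversions = if (length(inversions)) do.call(rbind, inversions)
                        else data.frame(map = character(),
                                        chromosome = character(),
                                        markers = character())))
  })
}

#' Simulate multi-population QTL studies around known meta-QTL positions
#'
#' Each population detects each true meta-QTL with probability
#' `detection_prob`, contributing `qtls_per_mqtl` QTLs whose peaks are
#' drawn from `Normal(true position, scatter_sd^2)` truncated to the
#' chromosome, with CI widths drawn uniformly from `ci_width_range`,
#' centred on the peak and clipped to the chromosome. LOD scores
#' (Uniform(3, 15)) and R-squared values (Uniform(0.03, 0.25)) are
#' plausible dressing, not used by the meta-analysis.
#'
#' @param true_mqtls data.frame with columns `chromosome`, `trait_class`,
#'   `position_cM` and optionally `components` (comma-joined trait
#'   components, default `"TKW"`).
#' @param chromosomes data.frame with columns `label`, `length_cM`.
#' @param n_populations number of mapping populations.
#' @param qtls_per_mqtl QTLs contributed per detected meta-QTL per
#'   population.
#' @param scatter_sd standard deviation (cM) of peak scatter around the
#'   true position.
#' @param ci_width_range range (cM) of CI widths.
#' @param detection_prob per-population detection probability.
#' @param seed integer seed.
#' @return list with `qtls` (one data.frame per population, in the
#'   [read_qtl_table()] schema) and `truth` (the input `true_mqtls`).
#' @export
simulate_qtl_studies <- function(true_mqtls, chromosomes, n_populations,
                                 qtls_per_mqtl = 1L, scatter_sd = 0,
                                 ci_width_range = c(8, 20),
                                 detection_prob = 1, seed = 1L) {
  stopifnot(scatter_sd >= 0, all(ci_width_range > 0),
            detection_prob >= 0, detection_prob <= 1)
  if (is.null(true_mqtls$components)) true_mqtls$components <- "TKW"
  with_seed(seed, {
    tables <- list()
    for (p in seq_len(n_populations)) {
      pid <- sprintf("pop%02d", p)
      rows <- list()
      for (i in seq_len(nrow(true_mqtls))) {
        L <- chromosomes$length_cM[match(true_mqtls$chromosome[i],
                                         chromosomes$label)]
        comps <- strsplit(true_mqtls$components[i], ",")[[1L]]
        for (q in seq_len(qtls_per_mqtl)) {
          if (stats::runif(1) > detection_prob) next
          peak <- true_mqtls$position_cM[i]
          if (scatter_sd > 0) {
            repeat {
              cand <- stats::rnorm(1, peak, scatter_sd)
              if (cand >= 0 && cand <= L) break
            }
            peak <- cand
          }
          w <- stats::runif(1, ci_width_range[1L], ci_width_range[2L])
          rows[[length(rows) + 1L]] <- data.frame(
            qtl_id = sprintf("%s_q%03d", pid, length(rows) + 1L),
            population_id = pid,
            trait_class = true_mqtls$trait_class[i],
            trait_component = sample(comps, 1L),
            chromosome = true_mqtls$chromosome[i],
            peak_cM = peak,
            ci_left_cM = max(0, peak - w / 2),
            ci_right_cM = min(L, peak + w / 2),
            lod = stats::runif(1, 3, 15),
            r2 = stats::runif(1, 0.03, 0.25),
            stringsAsFactors = FALSE)
        }
      }
      tables[[pid]] <- if (length(rows)) do.call(rbind, rows) else
        data.frame(qtl_id = character(), population_id = character(),
                   trait_class = character(), trait_component = character(),
                   chromosome = character(), peak_cM = numeric(),
                   ci_left_cM = numeric(), ci_right_cM = numeric(),
                   lod = numeric(), r2 = numeric(), stringsAsFactors = FALSE)
    }
    list(qtls = tables, truth = true_mqtls)
  })
}

#' Simulate an ordered gene list interleaved with map markers
#'
#' Places `genes_per_interval` genes between each pair of consecutive
#' markers of the true map. Gene ordinals run 1..G sequentially along the
#' chromosome; the marker closing interval j sits at ordinal slot
#' `j * genes_per_interval + 0.5`, so markers interleave the gene order.
#' Every `anchor_step`-th marker is emitted as a backbone anchor with its
#' map position. Each gene carries a synthetic rice-style ortholog label.
#'
#' @param true_map a `genetic_map`.
#' @param genes_per_interval genes between consecutive markers.
#' @param anchor_step emit every `anchor_step`-th marker as an anchor.
#' @param seed integer seed.
#' @return list with `genes` (syntenome data.frame) and `backbone`
#'   (anchor data.frame), in the [read_syntenome()] / [read_backbone()]
#'   schemas.
#' @export
simulate_syntenome <- function(true_map, genes_per_interval = 2L,
                               anchor_step = 1L, seed = 1L) {
  with_seed(seed, {
    genes <- list()
    backbone <- list()
    for (chr in unique(true_map$chromosome)) {
      m <- true_map[true_map$chromosome == chr, , drop = FALSE]
      n_m <- nrow(m)
      backbone[[chr]] <- data.frame(
        chromosome = chr,
        ordinal = (seq_len(n_m) - 1L) * genes_per_interval + 0.5,
        marker = m$marker, consensus_cM = m$position_cM,
        stringsAsFactors = FALSE)[seq(1L, n_m, by = anchor_step), , drop = FALSE]
      if (n_m < 2L) next
      g_ord <- seq_len((n_m - 1L) * genes_per_interval)
      genes[[chr]] <- data.frame(
        chromosome = chr, ordinal = g_ord,
        gene_id = sprintf("%s_g%04d", chr, g_ord),
        orthologs = sprintf("Os%02dg%07d", sample(1:12, length(g_ord), TRUE),
                            sample(1e6, length(g_ord))),
        scaffold = sprintf("scaffold_%05d", sample(99999L, length(g_ord))),
        stringsAsFactors = FALSE)
    }
    list(genes = do.call(rbind, c(genes, list(make.row.names = FALSE))),
         backbone = do.call(rbind, c(backbone, list(make.row.names = FALSE))))
  })
}

#' Simulate BLAST-tabular HSP sets with planted best hits
#'
#' For each query, one planted subject receives an alignment whose merged
#' CIP and CALP equal the planted values up to the rounding of integer
#' alignment-column counts (at most 0.5 points for query lengths >= 100),
#' plus `decoys_per_query` decoy subjects with strictly lower identity.
#'
#' @param query_lengths named numeric vector of query lengths (residues).
#' @param planted_identity planted CIP, percent in (0, 100].
#' @param planted_coverage planted CALP, percent in (0, 100].
#' @param decoys_per_query decoy subjects per query.
#' @param seed integer seed.
#' @return list with `hsps` (12-column BLAST tabular data.frame) and
#'   `truth` (data.frame `qseqid`, `planted_subject`).
#' @export
simulate_hsps <- function(query_lengths, planted_identity = 90,
                          planted_coverage = 80, decoys_per_query = 2L,
                          seed = 1L) {
  stopifnot(planted_identity > 0, planted_identity <= 100,
            planted_coverage > 0, planted_coverage <= 100)
  with_seed(seed, {
    rows <- list()
    truth <- list()
    hsp_row <- function(q, s, qstart, qend, pident) {
      len <- qend - qstart + 1L
      data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
                 mismatch = round((1 - pident / 100) * len), gapopen = 0L,
                 qstart = qstart, qend = qend, sstart = 1L, send = len,
                 evalue = 1e-30, bitscore = round(2 * len * pident / 100, 1),
                 stringsAsFactors = FALSE)
    }
    for (q in names(query_lengths)) {
      L <- query_lengths[[q]]
      subject <- paste0(q, "_ortho")
      al <- max(1L, round(planted_coverage / 100 * L))
      # split the planted alignment into two disjoint HSPs when long enough
      if (al >= 40L) {
        cut <- al %/% 2L
        gap <- max(0L, L - al)
        rows[[length(rows) + 1L]] <- hsp_row(q, subject, 1L, cut, planted_identity)
        rows[[length(rows) + 1L]] <- hsp_row(q, subject, cut + gap + 1L,
                                             al + gap, planted_identity)
      } else {
        rows[[length(rows) + 1L]] <- hsp_row(q, subject, 1L, al, planted_identity)
      }
      for (d in seq_len(decoys_per_query)) {
        ident <- max(1, planted_identity - stats::runif(1, 5, 25))
        dlen <- max(1L, round(stats::runif(1, 0.2, 0.9) * L))
        rows[[length(rows) + 1L]] <-
          hsp_row(q, sprintf("%s_decoy%02d", q, d), 1L, dlen, ident)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        qseqid = q, planted_subject = subject, stringsAsFactors = FALSE)
    }
    list(hsps = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}
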