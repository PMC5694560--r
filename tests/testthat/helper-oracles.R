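# Small builders and brute-force oracles used across test files.

make_map <- function(id, chromosome, markers, positions,
                     types = rep("SNP", length(markers))) {
  genetic_map(data.frame(chromosome = chromosome, marker = markers,
                         position_cM = positions, marker_type = types,
                         stringsAsFactors = FALSE), id)
}

# Brute force: size of the largest subset of shared markers whose order is
# identical in both maps (enumerates all 2^n subsets; n <= 12 or so).
bf_max_common_monotone <- function(pos_a, pos_b) {
  n <- length(pos_a)
  best <- 0L
  for (mask in 0:(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) <= best) next
    oa <- order(pos_a[idx], pos_b[idx])
    pb <- pos_b[idx][oa]
    if (all(diff(pb) >= 0)) best <- length(idx)
  }
  best
}

# Brute force: maximum weighted-Gaussian log-likelihood over all contiguous
# partitions of sorted observations into K blocks.
bf_best_partition_logL <- function(x, s, K) {
  o <- order(x)
  x <- x[o]; s <- s[o]
  w <- 1 / s^2
  n <- length(x)
  block_logL <- function(idx) {
    mu <- sum(w[idx] * x[idx]) / sum(w[idx])
    sum(-0.5 * ((x[idx] - mu) / s[idx])^2 - log(s[idx]) - 0.5 * log(2 * pi))
  }
  if (K == 1L) return(block_logL(seq_len(n)))
  cuts <- utils::combn(n - 1L, K - 1L)
  best <- -Inf
  for (j in seq_len(ncol(cuts))) {
    bounds <- c(0L, cuts[, j], n)
    ll <- sum(vapply(seq_len(K), function(k) {
      block_logL((bounds[k] + 1L):bounds[k + 1L])
    }, numeric(1L)))
    if (ll > best) best <- ll
  }
  best
}

# Random projected-QTL table for property tests.
random_projected_qtls <- function(n, chromosome = "1A", trait = "GY") {
  peak <- runif(n, 0, 150)
  w <- runif(n, 4, 16)
  data.frame(
    qtl_id = sprintf("q%03d", seq_len(n)),
    population_id = sprintf("pop%02d", sample(5L, n, replace = TRUE)),
    trait_class = trait, trait_component = "TKW",
    chromosome = chromosome, peak_cM = peak,
    ci_left_cM = peak - w / 2, ci_right_cM = peak + w / 2,
    stringsAsFactors = FALSE)
}
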