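#' Convert a 95% confidence interval to a position standard deviation
#'
#' Under the Gaussian observation model a 95% CI spans 2 x 1.96 standard
#' deviations, so `s = (ci_right - ci_left) / 3.92`.
#'
#' @param ci_left,ci_right CI bounds in cM.
#' @return Standard deviation(s) in cM.
#' @export
std_from_ci <- function(ci_left, ci_right) {
  w <- ci_right - ci_left
  if (any(w <= 0)) stop("confidence interval must have positive width")
  w / 3.92
}

# Weighted-SSE cost matrix: cost[i, j] = sum_{l in i..j} w_l (x_l - mu_ij)^2
# with mu_ij the weighted mean of block i..j. x must be sorted.
block_cost_matrix <- function(x, w) {
  n <- length(x)
  cw <- cumsum(w); cwx <- cumsum(w * x); cwx2 <- cumsum(w * x^2)
  cw0 <- c(0, cw); cwx0 <- c(0, cwx); cwx20 <- c(0, cwx2)
  cost <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    j <- i:n
    W <- cw0[j + 1L] - cw0[i]
    S <- cwx0[j + 1L] - cwx0[i]
    cost[i, j] <- pmax(0, (cwx20[j + 1L] - cwx20[i]) - S^2 / W)
  }
  cost
}

#' Fit the best contiguous K-cluster model to ordered QTL observations
#'
#' Observations are QTL peak positions `x` with known standard deviations
#' `s` (from [std_from_ci()]); weights are `w = 1/s^2`. The model places K
#' meta-QTL positions `mu_1 < ... < mu_K` and assigns each observation to
#' one of them, with assignments contiguous in x-order. The fit maximizes
#' the Gaussian log-likelihood
#' `sum_i [-(x_i - mu_k(i))^2 / (2 s_i^2) - log(s_i sqrt(2 pi))]`
#' over all contiguous partitions, by dynamic programming over breakpoints
#' (O(n^2 K)); each cluster's ML position is its weighted mean.
#'
#' @param x numeric vector of projected peak positions (cM), any order.
#' @param s positive numeric vector of position standard deviations (cM).
#' @param K number of clusters, `1 <= K <= length(x)`.
#' @return A `cluster_model`: list with `K`, `assignment` (cluster index
#'   per observation, in the order of the input `x`), `mu`, `cluster_var`
#'   (pooled variance `1 / sum(w)` per cluster), `logL`.
#' @export
fit_k_clusters <- function(x, s, K) {
  n <- length(x)
  stopifnot(length(s) == n, all(s > 0))
  if (K < 1L || K > n) stop("K must be between 1 and the number of observations")
  o <- order(x)
  xs <- x[o]; ss <- s[o]; w <- 1 / ss^2
  cost <- block_cost_matrix(xs, w)

  # dp[k, j]: min total weighted SSE for observations 1..j in k blocks
  dp <- matrix(Inf, K, n)
  back <- matrix(0L, K, n)
  dp[1L, ] <- cost[1L, ]
  back[1L, ] <- 1L
  if (K > 1L) {
    for (k in 2:K) {
      for (j in k:n) {
        starts <- k:j
        v <- dp[k - 1L, starts - 1L] + cost[cbind(starts, j)]
        b <- which.min(v)
        dp[k, j] <- v[b]
        back[k, j] <- starts[b]
      }
    }
  }
  # trace back block starts
  assign_sorted <- integer(n)
  j <- n
  for (k in K:1) {
    i <- back[k, j]
    assign_sorted[i:j] <- k
    j <- i - 1L
  }
  mu <- vapply(seq_len(K), function(k) {
    idx <- assign_sorted == k
    sum(w[idx] * xs[idx]) / sum(w[idx])
  }, numeric(1L))
  cluster_var <- vapply(seq_len(K), function(k) 1 / sum(w[assign_sorted == k]),
                        numeric(1L))
  logL <- -0.5 * dp[K, n] - sum(log(ss)) - n * 0.5 * log(2 * pi)
  assignment <- integer(n)
  assignment[o] <- assign_sorted
  structure(list(K = K, assignment = assignment, mu = mu,
                 cluster_var = cluster_var, logL = logL),
            class = "cluster_model")
}

#' Information criteria for contiguous cluster models
#'
#' Computes the criterion value for a fitted K-cluster model with n
#' observations. `"AWE"` (default) is a selection-adjusted criterion in
#' the style of Banfield & Raftery's approximate weight of evidence for
#' classification likelihoods: the model's parameter count is `2K - 1`
#' (K cluster positions plus K-1 partition breakpoints) and each parameter
#' costs `2 * (3/2 + log n)`. The adjustment matters because the
#' likelihood is maximized over the partition as well as the positions, so
#' unadjusted AIC (`-2 logL + 2K`) systematically prefers K+1 clusters.
#' `"AIC"`, `"AICc"` and `"BIC"` use the conventional formulas with K
#' position parameters.
#'
#' @param logL maximized log-likelihood.
#' @param K number of clusters.
#' @param n number of observations.
#' @param criterion one of `"AWE"`, `"AIC"`, `"AICc"`, `"BIC"`.
#' @return Criterion value (smaller is better).
#' @export
model_criterion <- function(logL, K, n, criterion = c("AWE", "AIC", "AICc", "BIC")) {
  criterion <- match.arg(criterion)
  switch(criterion,
    AWE  = -2 * logL + 2 * (2 * K - 1) * (1.5 + log(n)),
    AIC  = -2 * logL + 2 * K,
    AICc = -2 * logL + 2 * K +
      ifelse(n - K - 1 > 0, 2 * K * (K + 1) / (n - K - 1), Inf),
    BIC  = -2 * logL + K * log(n))
}

#' Select the number of meta-QTLs on a chromosome region
#'
#' Fits the contiguous-cluster models with K in {1, 2, 3, 4} (bounded by
#' n) plus the n-model in which every QTL is its own meta-QTL
#' (`mu_i = x_i`, so its log-likelihood is the Gaussian constant
#' `-sum(log(s_i sqrt(2 pi)))`), evaluates the information criterion for
#' each, and returns the best model; ties are broken toward smaller K.
#'
#' @inheritParams fit_k_clusters
#' @param criterion see [model_criterion()].
#' @param k_max largest explicit cluster number tried (default 4, the
#'   upstream method's limit before falling back to the n-model).
#' @return The winning `cluster_model`, with a `criteria` attribute: a
#'   data.frame of K, logL and criterion value for every candidate model.
#' @export
select_model <- function(x, s, criterion = c("AWE", "AIC", "AICc", "BIC"),
                         k_max = 4L) {
  criterion <- match.arg(criterion)
  n <- length(x)
  if (!n) stop("select_model() needs at least one observation")
  stopifnot(length(s) == n, all(s > 0))
  ks <- seq_len(min(k_max, n))
  fits <- lapply(ks, function(K) fit_k_clusters(x, s, K))
  if (n > k_max) {
    o <- order(x)
    nmodel <- structure(list(
      K = n, assignment = {a <- integer(n); a[o] <- seq_len(n); a},
      mu = sort(x), cluster_var = (s^2)[o],
      logL = -sum(log(s)) - n * 0.5 * log(2 * pi)), class = "cluster_model")
    fits <- c(fits, list(nmodel))
  }
  crit <- vapply(fits, function(f) model_criterion(f$logL, f$K, n, criterion),
                 numeric(1L))
  tab <- data.frame(K = vapply(fits, `[[`, numeric(1L), "K"),
                    logL = vapply(fits, `[[`, numeric(1L), "logL"),
                    criterion = crit)
  best <- fits[[which.min(crit)]]  # which.min takes the first (smallest K) on ties
  attr(best, "criteria") <- tab
  attr(best, "criterion_used") <- criterion
  best
}

#' Split a chromosome into QTL-covered segments
#'
#' Segments are the connected components of the union of the observations'
#' confidence intervals; regions covered by no CI separate segments.
#' Intervals that merely touch (shared endpoint) belong to one segment —
#' a QTL-free region must have positive length to split.
#'
#' @param ci_left,ci_right numeric vectors of CI bounds (cM).
#' @return data.frame with one row per segment: `left`, `right`,
#'   `n_obs`, and a `members` list-column of observation indices.
#' @export
split_segments <- function(ci_left, ci_right) {
  n <- length(ci_left)
  stopifnot(length(ci_right) == n, all(ci_right >= ci_left))
  if (!n) {
    return(data.frame(left = numeric(), right = numeric(), n_obs = integer()))
  }
  o <- order(ci_left, ci_right)
  seg_id <- integer(n)
  cur <- 1L
  right <- ci_right[o[1L]]
  seg_id[o[1L]] <- 1L
  for (k in seq_len(n)[-1L]) {
    i <- o[k]
    if (ci_left[i] > right) {        # strict: touching intervals merge
      cur <- cur + 1L
      right <- ci_right[i]
    } else {
      right <- max(right, ci_right[i])
    }
    seg_id[i] <- cur
  }
  out <- data.frame(
    left = as.numeric(tapply(ci_left, seg_id, min)),
    right = as.numeric(tapply(ci_right, seg_id, max)),
    n_obs = as.integer(tabulate(seg_id)))
  out$members <- split(seq_len(n), seg_id)
  out
}

#' Pooled consensus position and 95% confidence interval of a cluster
#'
#' The consensus variance is `1 / sum(w_i)` with `w_i = 1/s_i^2`, so the
#' pooled CI strictly shrinks as members are added; the consensus position
#' is the weighted mean.
#'
#' @param x member positions (cM).
#' @param s member standard deviations (cM).
#' @return list with `mu`, `var`, `ci95` (length-2 numeric).
#' @export
consensus_interval <- function(x, s) {
  stopifnot(length(x) >= 1L, length(s) == length(x), all(s > 0))
  w <- 1 / s^2
  mu <- sum(w * x) / sum(w)
  v <- 1 / sum(w)
  list(mu = mu, var = v, ci95 = c(mu - 1.96 * sqrt(v), mu + 1.96 * sqrt(v)))
}

#' Meta-analysis of projected QTLs into meta-QTLs
#'
#' Projected QTLs are grouped by trait class and chromosome. Within each
#' group, peak positions and CI-derived standard deviations form the
#' observations; [select_model()] picks the number of clusters. When the
#' n-model wins (more than `k_max` underlying loci) or a group exceeds
#' `max_group_size` observations, the chromosome is split at QTL-free gaps
#' ([split_segments()]) and each segment re-analyzed independently
#' (recursion depth capped at `max_depth`). Clusters supported by at least
#' two member QTLs from at least two distinct populations become meta-QTLs
#' with pooled positions and 95% CIs ([consensus_interval()]); all other
#' clusters are reported as unresolved in the audit table, never dropped.
#'
#' @param projected data.frame of projected QTLs with columns `qtl_id`,
#'   `population_id`, `trait_class`, `trait_component`, `chromosome`,
#'   `peak_cM`, `ci_left_cM`, `ci_right_cM`.
#' @param criterion model-selection criterion, see [model_criterion()].
#' @param max_group_size groups larger than this are segment-split before
#'   model selection.
#' @param max_depth recursion-depth cap for segment splitting.
#' @return list with components
#'   \describe{
#'     \item{mqtl}{data.frame: `mqtl_id`, `trait_class`, `chromosome`,
#'       `position_cM`, `ci_left`, `ci_right`, `width_cM`, `n_qtls`,
#'       `n_populations`, `components`, `member_qtl_ids`.}
#'     \item{audit}{data.frame of unresolved clusters with a `reason`
#'       column (`single_member` or `single_population`).}
#'   }
#' @export
run_meta_analysis <- function(projected, criterion = c("AWE", "AIC", "AICc", "BIC"),
                              max_group_size = 25L, max_depth = 3L) {
  criterion <- match.arg(criterion)
  needed <- c("qtl_id", "population_id", "trait_class", "trait_component",
              "chromosome", "peak_cM", "ci_left_cM", "ci_right_cM")
  stopifnot(all(needed %in% names(projected)))

  clusters <- list()
  groups <- split(seq_len(nrow(projected)),
                  list(projected$trait_class, projected$chromosome), drop = TRUE)
  for (idx in groups) {
    clusters <- c(clusters,
                  analyze_group(projected[idx, , drop = FALSE], criterion,
                                max_group_size, max_depth, depth = 0L))
  }

  mqtl_rows <- list()
  audit_rows <- list()
  for (cl in clusters) {
    g <- cl$members
    npop <- length(unique(g$population_id))
    ci <- consensus_interval(g$peak_cM, g$s)
    row <- data.frame(
      trait_class = g$trait_class[1L], chromosome = g$chromosome[1L],
      position_cM = ci$mu, ci_left = ci$ci95[1L], ci_right = ci$ci95[2L],
      width_cM = ci$ci95[2L] - ci$ci95[1L],
      n_qtls = nrow(g), n_populations = npop,
      components = paste(sort(unique(g$trait_component)), collapse = ","),
      member_qtl_ids = paste(g$qtl_id, collapse = ","),
      stringsAsFactors = FALSE)
    if (nrow(g) >= 2L && npop >= 2L) {
      mqtl_rows[[length(mqtl_rows) + 1L]] <- row
    } else {
      row$reason <- if (nrow(g) < 2L) "single_member" else "single_population"
      audit_rows[[length(audit_rows) + 1L]] <- row
    }
  }
  bind_sorted <- function(rows) {
    if (!length(rows)) return(NULL)
    out <- do.call(rbind, rows)
    out <- out[order(factor(out$trait_class, levels = c("GY", "GPC", "BQ")),
                     out$chromosome, out$position_cM), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  mqtl <- bind_sorted(mqtl_rows)
  if (is.null(mqtl)) {
    mqtl <- data.frame(mqtl_id = integer(), trait_class = character(),
                       chromosome = character(), position_cM = numeric(),
                       ci_left = numeric(), ci_right = numeric(),
                       width_cM = numeric(), n_qtls = integer(),
                       n_populations = integer(), components = character(),
                       member_qtl_ids = character(), stringsAsFactors = FALSE)
  } else {
    mqtl <- cbind(mqtl_id = seq_len(nrow(mqtl)), mqtl)
  }
  audit <- bind_sorted(audit_rows)
  if (is.null(audit)) {
    audit <- cbind(mqtl[0, -1L, drop = FALSE], data.frame(reason = character()))
  }
  list(mqtl = mqtl, audit = audit)
}

# Recursive per-group analysis; returns a list of clusters, each a list
# with a `members` data.frame (group rows + s column).
analyze_group <- function(g, criterion, max_group_size, max_depth, depth) {
  if (!nrow(g)) return(list())
  g$s <- std_from_ci(g$ci_left_cM, g$ci_right_cM)
  n <- nrow(g)

  recurse_segments <- function(reason) {
    segs <- split_segments(g$ci_left_cM, g$ci_right_cM)
    if (nrow(segs) == 1L || depth >= max_depth) {
      if (depth >= max_depth) {
        warning("segment recursion depth cap reached on chromosome ",
                g$chromosome[1L], " (", reason, "); accepting current model",
                call. = FALSE)
      }
      return(NULL)
    }
    out <- list()
    for (k in seq_len(nrow(segs))) {
      sub <- g[segs$members[[k]], , drop = FALSE]
      sub$s <- NULL
      out <- c(out, analyze_group(sub, criterion, max_group_size, max_depth,
                                  depth + 1L))
    }
    out
  }

  if (n > max_group_size) {
    res <- recurse_segments("group size")
    if (!is.null(res)) return(res)
  }
  model <- select_model(g$peak_cM, g$s, criterion = criterion)
  if (model$K == n && n > 4L) {
    res <- recurse_segments("n-model selected")
    if (!is.null(res)) return(res)
  }
  lapply(seq_len(model$K), function(k) {
    list(members = g[model$assignment == k, , drop = FALSE])
  })
}
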