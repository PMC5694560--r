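test_that("CI-to-sd conversion uses the 95% Gaussian convention", {
  expect_equal(std_from_ci(8.04, 11.96), 1)
  expect_equal(std_from_ci(0, 7.84), 2)
  expect_error(std_from_ci(5, 5), "positive width")
})

test_that("fit_k_clusters maximizes the weighted likelihood", {
  m1 <- fit_k_clusters(c(10, 20), c(1, 1), 1)
  expect_equal(m1$mu, 15)

  # weighted mean: (0*1 + 10*(1/9)) / (1 + 1/9) = 1
  m2 <- fit_k_clusters(c(0, 10), c(1, 3), 1)
  expect_equal(m2$mu, 1)
  expect_equal(m2$cluster_var, 1 / (1 + 1 / 9))

  m3 <- fit_k_clusters(c(10, 10.5, 50, 50.5), rep(1, 4), 2)
  expect_equal(m3$assignment, c(1L, 1L, 2L, 2L))
  expect_equal(m3$mu, c(10.25, 50.25))

  expect_error(fit_k_clusters(c(1, 2), c(1, 1), 3), "between 1")
  expect_error(fit_k_clusters(c(1, 2), c(1, 1), 0), "between 1")
})

test_that("DP log-likelihood equals exhaustive partition enumeration", {
  set.seed(405)
  for (i in 1:30) {
    n <- sample(3:10, 1L)
    x <- runif(n, 0, 100)
    s <- runif(n, 0.5, 4)
    for (K in 1:min(n, 5L)) {
      expect_equal(fit_k_clusters(x, s, K)$logL,
                   bf_best_partition_logL(x, s, K), tolerance = 1e-9)
    }
  }
})

test_that("logL is non-decreasing in K and mu strictly increasing", {
  set.seed(406)
  for (i in 1:20) {
    n <- sample(4:12, 1L)
    x <- runif(n, 0, 100)
    s <- runif(n, 0.5, 3)
    fits <- lapply(seq_len(n), function(K) fit_k_clusters(x, s, K))
    ll <- vapply(fits, `[[`, numeric(1L), "logL")
    expect_true(all(diff(ll) >= -1e-9))
    for (f in fits) expect_true(all(diff(f$mu) > 0))
  }
})

test_that("model selection picks the visually obvious K and breaks ties small", {
  one <- select_model(42, 3)
  expect_equal(one$K, 1L)
  expect_equal(one$mu, 42)

  expect_equal(select_model(c(10, 10.2, 10.4), rep(1, 3))$K, 1L)
  expect_equal(select_model(c(10, 10.5, 50, 50.5), rep(1, 4))$K, 2L)
  # same answers under the unadjusted criteria for these clear-cut cases
  expect_equal(select_model(c(10, 10.2, 10.4), rep(1, 3), criterion = "AIC")$K, 1L)
  expect_equal(select_model(c(10, 10.5, 50, 50.5), rep(1, 4), criterion = "AIC")$K, 2L)

  expect_error(select_model(numeric(0), numeric(0)), "at least one")

  tab <- attr(select_model(c(0, 30, 60, 90, 120), rep(1, 5)), "criteria")
  expect_equal(nrow(tab), 5L)  # K = 1..4 plus the n-model
  expect_equal(tab$K, c(1, 2, 3, 4, 5))
})

test_that("selection is invariant to input permutation", {
  set.seed(407)
  x <- rnorm(12, rep(c(20, 70), each = 6), 2)
  s <- runif(12, 1, 2)
  ref <- select_model(x, s)
  for (i in 1:10) {
    p <- sample(12)
    got <- select_model(x[p], s[p])
    expect_equal(got$K, ref$K)
    expect_equal(got$mu, ref$mu)
    expect_equal(got$assignment, ref$assignment[p])
  }
})

test_that("segments are the connected components of the CI union", {
  seg <- split_segments(c(0, 5, 40), c(10, 15, 50))
  expect_equal(seg$left, c(0, 40))
  expect_equal(seg$right, c(15, 50))
  expect_equal(seg$n_obs, c(2L, 1L))

  touching <- split_segments(c(0, 10), c(10, 20))
  expect_equal(nrow(touching), 1L)
  expect_equal(c(touching$left, touching$right), c(0, 20))

  expect_equal(nrow(split_segments(numeric(0), numeric(0))), 0L)
})

test_that("consensus intervals pool precision", {
  single <- consensus_interval(10, 2)
  expect_equal(diff(single$ci95) / 2, 3.92)

  two <- consensus_interval(c(10, 10), c(1, 1))
  expect_equal(diff(two$ci95) / 2, 1.96 / sqrt(2))

  dom <- consensus_interval(c(10, 10), c(1, 1000))
  expect_equal(diff(dom$ci95) / 2, 1.96 * sqrt(1 / (1 + 1e-6)))

  set.seed(408)
  for (i in 1:20) {
    n <- sample(2:8, 1L)
    s <- runif(n, 0.5, 5)
    expect_lt(consensus_interval(runif(n, 0, 10), s)$var, min(s^2))
  }
})

test_that("meta-analysis recovers two planted meta-QTLs and applies rules", {
  set.seed(409)
  qtls <- do.call(rbind, lapply(1:4, function(p) {
    peaks <- rnorm(2, c(20, 60), 1)
    data.frame(qtl_id = sprintf("p%d_q%d", p, 1:2),
               population_id = sprintf("pop%d", p),
               trait_class = "GY", trait_component = "TKW",
               chromosome = "2D", peak_cM = peaks,
               ci_left_cM = peaks - 3.92, ci_right_cM = peaks + 3.92,
               stringsAsFactors = FALSE)
  }))
  res <- run_meta_analysis(qtls)
  expect_equal(nrow(res$mqtl), 2L)
  expect_equal(res$mqtl$position_cM, c(20, 60), tolerance = 2)
  expect_equal(res$mqtl$n_populations, c(4L, 4L))
  expect_true(all(res$mqtl$ci_left < res$mqtl$position_cM &
                  res$mqtl$position_cM < res$mqtl$ci_right))

  # three co-located QTLs from ONE population: audit, not an MQTL
  solo <- qtls[1:3, ]
  solo$population_id <- "pop1"
  solo$peak_cM <- c(30, 30.5, 31)
  solo$ci_left_cM <- solo$peak_cM - 4
  solo$ci_right_cM <- solo$peak_cM + 4
  solo$qtl_id <- c("a", "b", "c")
  res2 <- run_meta_analysis(solo)
  expect_equal(nrow(res2$mqtl), 0L)
  expect_equal(nrow(res2$audit), 1L)
  expect_equal(res2$audit$reason, "single_population")
})

test_that("every input QTL lands in exactly one MQTL or audit cluster", {
  set.seed(410)
  for (i in 1:5) {
    qtls <- random_projected_qtls(sample(8:30, 1L))
    res <- run_meta_analysis(qtls)
    ids <- c(unlist(strsplit(res$mqtl$member_qtl_ids, ",")),
             unlist(strsplit(res$audit$member_qtl_ids, ",")))
    expect_setequal(ids, qtls$qtl_id)
    expect_equal(length(ids), nrow(qtls))
  }
})

test_that("oversized groups are segment-split before model selection", {
  set.seed(411)
  # 30 observations in two well-separated blocks forces the >25 path
  peaks <- c(rnorm(15, 30, 1.5), rnorm(15, 120, 1.5))
  qtls <- data.frame(
    qtl_id = sprintf("q%02d", 1:30),
    population_id = sprintf("pop%d", rep(1:5, 6)),
    trait_class = "GY", trait_component = "Th", chromosome = "3B",
    peak_cM = peaks, ci_left_cM = peaks - 5, ci_right_cM = peaks + 5,
    stringsAsFactors = FALSE)
  res <- run_meta_analysis(qtls)
  expect_equal(nrow(res$mqtl), 2L)
  expect_equal(sort(res$mqtl$position_cM), c(30, 120), tolerance = 2)
})
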