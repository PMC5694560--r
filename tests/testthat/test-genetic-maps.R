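test_that("read_map parses well-formed files and rejects bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chromosome\tmarker\tposition_cM\tmarker_type",
               "1A\tmA\t0.0\tSNP",
               "1A\tmB\t12.5\tSSR",
               "2B\tmC\t3.1\tDarT"), path)
  m <- read_map(path, "toy")
  expect_s3_class(m, "genetic_map")
  expect_equal(nrow(m), 3L)
  expect_equal(map_id(m), "toy")
  expect_setequal(m$chromosome, c("1A", "2B"))

  writeLines("chromosome\tmarker\tposition_cM\tmarker_type", path)
  expect_equal(nrow(read_map(path, "empty")), 0L)

  writeLines(c("chromosome\tmarker\tposition_cM\tmarker_type",
               "1A\tmA\t-5.0\tSNP"), path)
  expect_error(read_map(path, "neg"), "line 2")

  writeLines(c("chromosome\tmarker\tposition_cM", "1A\tmA\t1.0"), path)
  expect_error(read_map(path, "short"), "missing column")
})

test_that("map round-trips through write_map and duplicates are rejected", {
  m <- make_map("a", "1A", c("m1", "m2", "m3"), c(0, 5.125, 10))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_map(m, path)
  back <- read_map(path, "a")
  expect_equal(back$marker, m$marker)
  expect_equal(back$position_cM, qtlmeta:::round_half_up(m$position_cM, 2),
               tolerance = 1e-9)
  expect_error(make_map("d", "1A", c("m1", "m1"), c(0, 1)), "duplicated")
})

test_that("order consistency retains identical orders and flags swaps", {
  a <- make_map("a", "1A", paste0("m", 1:10), 1:10)
  b <- make_map("b", "1A", paste0("m", 1:10), 2 * (1:10))
  rep0 <- check_order_consistency(a, b)
  expect_equal(nrow(rep0$conflicts), 0L)
  expect_equal(nrow(rep0$retained), 10L)

  # A B C D E vs A B D C E: exactly one of C/D dropped, 4 retained
  a2 <- make_map("a", "1A", LETTERS[1:5], 1:5)
  b2 <- make_map("b", "1A", c("A", "B", "D", "C", "E"), 1:5)
  rep2 <- check_order_consistency(a2, b2)
  expect_equal(nrow(rep2$retained), 4L)
  expect_equal(nrow(rep2$conflicts), 1L)
  expect_true(rep2$conflicts$marker %in% c("C", "D"))
  expect_equal(rep2$conflicts$reason, "order")
})

test_that("chromosome reassignment is flagged regardless of positions", {
  a <- make_map("a", c("1A", "1A"), c("mA", "mB"), c(0, 5))
  b <- make_map("b", c("1B", "1A"), c("mA", "mB"), c(0, 5))
  rep <- check_order_consistency(a, b)
  expect_equal(rep$conflicts$marker, "mA")
  expect_equal(rep$conflicts$reason, "chromosome_assignment")
  expect_equal(rep$retained$marker, "mB")
})

test_that("retained set matches the brute-force maximum (oracle)", {
  set.seed(401)
  for (rep_i in 1:40) {
    n <- sample(4:10, 1L)
    pos_a <- sort(runif(n, 0, 100))
    pos_b <- sample(pos_a)  # random permutation of the order
    a <- make_map("a", "1A", paste0("m", 1:n), pos_a)
    b <- make_map("b", "1A", paste0("m", 1:n), pos_b)
    got <- nrow(check_order_consistency(a, b)$retained)
    expect_equal(got, bf_max_common_monotone(pos_a, pos_b))
  }
})

test_that("projection follows the homothetic formula and its edge rules", {
  expect_equal(project_position(4, anchor_frame(c(0, 10), c(0, 10))), 4)
  expect_equal(project_position(5, anchor_frame(c(0, 10), c(0, 20))), 10)
  fr <- anchor_frame(c(0, 10, 30), c(0, 15, 30))
  expect_equal(project_position(20, fr), 22.5)
  # anchor fixpoints
  expect_equal(project_position(fr$src, fr), fr$dst)
  # extrapolation extends the terminal interval's scale
  expect_equal(project_position(40, fr), 30 + 10 * 0.75)
  expect_equal(project_position(-2, fr), -3)
  # tied source anchors collapse to the mean destination
  fr2 <- anchor_frame(c(0, 5, 5, 10), c(0, 4, 6, 10))
  expect_equal(n_anchors(fr2), 3L)
  expect_equal(project_position(5, fr2), 5)
  expect_error(project_position(1, anchor_frame(3, 7)), "2 anchors")
})

test_that("projection is monotone with fixpoints on random frames", {
  set.seed(402)
  for (i in 1:200) {
    k <- sample(2:8, 1L)
    fr <- anchor_frame(sort(runif(k, 0, 100)) + cumsum(rep(0.5, k)),
                       sort(runif(k, 0, 120)))
    p <- sort(runif(25, -20, 140))
    out <- project_position(p, fr)
    expect_true(all(diff(out) >= -1e-12))
    expect_equal(project_position(fr$src, fr), fr$dst, tolerance = 1e-12)
  }
})

test_that("merging is idempotent and projects unique markers homothetically", {
  m <- make_map("m", rep(c("1A", "2B"), each = 3),
                paste0("m", 1:6), c(0, 10, 20, 0, 4, 8))
  twice <- merge_maps(list(m, m), order = "given")
  expect_equal(twice$marker, m$marker)
  expect_equal(twice$position_cM, m$position_cM)

  backbone <- make_map("bb", "1A", c("a", "b", "c"), c(0, 10, 20))
  second <- make_map("s2", "1A", c("a", "b", "c", "u"), c(0, 5, 10, 7.5))
  cons <- merge_maps(list(backbone, second), order = "given")
  expect_equal(cons$position_cM[cons$marker == "u"], 15)
  expect_equal(nrow(cons), 4L)

  # single shared marker on a chromosome: nothing projected, warning
  third <- make_map("s3", "1A", c("a", "v"), c(0, 3))
  expect_warning(cons3 <- merge_maps(list(backbone, third), order = "given"),
                 "fewer than 2")
  expect_false("v" %in% cons3$marker)
})

test_that("merge conserves counts and removes conflicts from incoming only", {
  set.seed(403)
  backbone <- make_map("bb", "1A", paste0("m", 1:12), sort(runif(12, 0, 100)))
  extra <- make_map("ex", "1A", c(paste0("m", 1:6), paste0("u", 1:4)),
                    c(sort(runif(6, 0, 50)), sort(runif(4, 50, 100))))
  cons <- merge_maps(list(backbone, extra), order = "given")
  log <- attr(cons, "merge_log")
  expect_equal(nrow(cons),
               nrow(backbone) + log$n_projected[2L])
  # a conflicted shared marker stays at its backbone position
  swapped <- make_map("sw", "1A", c("m1", "m2", "m3", "m4"), c(1, 3, 2, 4) * 10)
  bb2 <- make_map("bb2", "1A", c("m1", "m2", "m3", "m4"), c(10, 20, 30, 40))
  cons2 <- merge_maps(list(bb2, swapped), order = "given")
  expect_equal(cons2$position_cM, bb2$position_cM)
  expect_gte(nrow(attr(cons2, "conflicts")), 1L)
})

test_that("by-size ordering picks the densest map as backbone", {
  small <- make_map("small", "1A", c("a", "b"), c(0, 50))
  dense <- make_map("dense", "1A", c("a", "b", "x", "y"), c(0, 100, 25, 75))
  cons <- merge_maps(list(small, dense), order = "by_size")
  # dense is backbone: its coordinates (0..100) survive
  expect_equal(max(cons$position_cM), 100)
})

test_that("map summaries aggregate and conserve the grand total", {
  m <- make_map("m", rep(c("1A", "1B", "2D"), each = 2), paste0("m", 1:6),
                rep(c(0, 10), 3), types = c("SNP", "SSR", "SNP", "SNP", "DarT", "SNP"))
  expect_equal(summarize_map(m, "grand_total"), 6L)
  grp <- summarize_map(m, "homoeologous_group")
  expect_equal(grp$n[grp$homoeologous_group == "1"], 4L)
  sub <- summarize_map(m, "subgenome")
  expect_equal(sum(sub$n), 6L)
  expect_equal(sum(summarize_map(m, "chromosome_type")$n), 6L)

  empty <- genetic_map(data.frame(chromosome = character(), marker = character(),
                                  position_cM = numeric()), "e")
  expect_equal(summarize_map(empty, "grand_total"), 0L)

  weird <- make_map("w", "chrX", "m1", 0)
  expect_error(summarize_map(weird, "subgenome"), "1A\\.\\.7D")
})
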