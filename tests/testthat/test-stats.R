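test_that("identical cores are not significant; permutation p is 1 for zero effect", {
  a <- rep(c(1L, 1L, 2L, 2L), 50)
  res <- compare_paired_cores(a, a, n_perm = 500, seed = 2)
  expect_equal(res$permutation_p, 1)
  expect_false(res$significant)
})

test_that("disjoint class distributions are strongly significant", {
  res <- compare_paired_cores(rep(1L, 200), rep(9L, 200),
                              n_perm = 2000, seed = 3)
  expect_lt(res$wilcoxon_p, 0.01)
  expect_lt(res$permutation_p, 0.01)
  expect_true(res$significant)
})

test_that("degenerate inputs are handled as contracted", {
  expect_error(compare_paired_cores(integer(0), 1:3), "non-empty")
  # constant pooled vector: both p-values are 1
  res <- compare_paired_cores(rep(5L, 30), rep(5L, 40), n_perm = 100,
                              seed = 1)
  expect_equal(res$wilcoxon_p, 1)
  expect_equal(res$permutation_p, 1)
})

test_that("permutation p-values are reproducible bit-for-bit given a seed", {
  set.seed(99)
  a <- sample(1:16, 300, replace = TRUE)
  b <- sample(1:16, 250, replace = TRUE)
  r1 <- compare_paired_cores(a, b, n_perm = 1000, seed = 42)
  r2 <- compare_paired_cores(a, b, n_perm = 1000, seed = 42)
  expect_identical(r1$permutation_p, r2$permutation_p)
  r3 <- compare_paired_cores(a, b, n_perm = 1000, seed = 43)
  expect_false(identical(r3$permutation_p, r2$permutation_p))
})

test_that("swapping equally sized cores leaves the permutation p unchanged", {
  set.seed(7)
  a <- sample(1:16, 200, replace = TRUE, prob = c(rep(2, 8), rep(1, 8)))
  b <- sample(1:16, 200, replace = TRUE)
  r_ab <- compare_paired_cores(a, b, n_perm = 2000, seed = 5)
  r_ba <- compare_paired_cores(b, a, n_perm = 2000, seed = 5)
  expect_identical(r_ab$permutation_p, r_ba$permutation_p)
})

test_that("conjunction of both tests keeps type-I error at or below alpha", {
  set.seed(21)
  f <- subtype_class_fractions("LumB")
  n_sig <- 0L
  n_rep <- 100
  for (i in 1:n_rep) {
    a <- sample.int(16, 200, replace = TRUE, prob = f)
    b <- sample.int(16, 200, replace = TRUE, prob = f)
    r <- compare_paired_cores(a, b, alpha = 0.01, n_perm = 500,
                              seed = 1000 + i)
    n_sig <- n_sig + r$significant
  }
  # alpha = 0.01 plus two binomial standard errors at 100 replicates
  expect_lte(n_sig / n_rep, 0.01 + 2 * sqrt(0.01 * 0.99 / n_rep))
})

test_that("chi-squared alternative agrees on extreme cases", {
  expect_lt(compare_paired_cores_chisq(rep(1L, 200), rep(9L, 200)), 0.01)
  expect_equal(compare_paired_cores_chisq(rep(1L, 50), rep(1L, 50)), 1)
})

test_that("paired screen tests exactly the two-core cases and tallies subtypes", {
  cells <- rbind(
    transform(make_cells(100, core_id = "s1"), eph_ki67_class = 1L),
    transform(make_cells(100, core_id = "s2"), eph_ki67_class = 1L),
    transform(make_cells(100, core_id = "s3"), eph_ki67_class = 1L),
    transform(make_cells(100, core_id = "s4"), eph_ki67_class = 9L),
    transform(make_cells(100, core_id = "s5"), eph_ki67_class = 5L))
  meta <- rbind(make_meta("s1", "case1", subtype = "LumA"),
                make_meta("s2", "case1", subtype = "LumA"),
                make_meta("s3", "case2", subtype = "TNBC"),
                make_meta("s4", "case2", subtype = "TNBC"),
                make_meta("s5", "case3", subtype = "LumB"))  # unpaired
  scr <- run_paired_core_screen(cells, meta, n_perm = 500, seed = 4)
  expect_equal(nrow(scr$results), 2)  # only paired cases
  expect_false(scr$results$significant[scr$results$case_id == "case1"])
  expect_true(scr$results$significant[scr$results$case_id == "case2"])
  bt <- scr$by_subtype
  expect_equal(bt$n_cases[bt$subtype == "LumA"], 1)
  expect_equal(bt$n_significant[bt$subtype == "TNBC"], 1)
  expect_equal(bt$n_cases[bt$subtype == "LumB"], 0)
})

test_that("discordant-subtype cases are tallied under both subtypes", {
  cells <- rbind(
    transform(make_cells(80, core_id = "s1"), eph_ki67_class = 1L),
    transform(make_cells(80, core_id = "s2"), eph_ki67_class = 9L))
  meta <- rbind(make_meta("s1", "case1", subtype = "LumA"),
                make_meta("s2", "case1", subtype = "LumB"))
  scr <- run_paired_core_screen(cells, meta, n_perm = 500, seed = 8)
  bt <- scr$by_subtype
  expect_equal(bt$n_cases[bt$subtype == "LumA"], 1)
  expect_equal(bt$n_cases[bt$subtype == "LumB"], 1)
})

test_that("planted composition shifts are detected with high power", {
  set.seed(31)
  f <- subtype_class_fractions("LumA")
  g <- shift_class_fractions(f, 0.3)
  hits <- 0L
  n_rep <- 40
  for (i in 1:n_rep) {
    a <- sample.int(16, 1000, replace = TRUE, prob = f)
    b <- sample.int(16, 1000, replace = TRUE, prob = g)
    r <- compare_paired_cores(a, b, n_perm = 500, seed = 2000 + i)
    hits <- hits + r$significant
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("one-way ANOVA and Tukey HSD behave as textbook expectations", {
  # two identical groups: F ~ 0, p ~ 1
  r0 <- compare_groups_anova(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_lt(r0$f, 1e-20)
  expect_gt(r0$p, 0.999)

  # planted separation: every Tukey contrast with group c significant
  set.seed(17)
  v <- c(rnorm(10, 0, 0.01), rnorm(10, 0, 0.01), rnorm(10, 10, 0.01))
  g <- rep(c("a", "b", "c"), each = 10)
  r1 <- compare_groups_anova(v, g)
  expect_lt(r1$p, 1e-10)
  with_c <- grepl("c", r1$tukey$comparison)
  expect_true(all(r1$tukey$p_adj[with_c] < 0.01))
  expect_true(all(r1$tukey$p_adj[!with_c] > 0.1))
})

test_that("ANOVA F on a 3x4 table matches the hand-computed statistic", {
  # worked example: groups with means 2, 4, 6 and within-group SS known
  vals <- c(1, 2, 3, 2, 3, 4, 5, 4, 5, 6, 7, 6)
  grp <- rep(c("g1", "g2", "g3"), each = 4)
  means <- tapply(vals, grp, mean)
  grand <- mean(vals)
  ss_b <- sum(4 * (means - grand)^2)
  ss_w <- sum((vals - means[grp])^2)
  f_hand <- (ss_b / 2) / (ss_w / 9)
  r <- compare_groups_anova(vals, grp)
  expect_equal(r$f, f_hand, tolerance = 1e-12)
})

test_that("two-group ANOVA equals the squared pooled t statistic", {
  set.seed(23)
  x <- rnorm(15); y <- rnorm(20, 0.5)
  r <- compare_groups_anova(c(x, y), rep(c("x", "y"), c(15, 20)))
  t2 <- stats::t.test(x, y, var.equal = TRUE)$statistic^2
  expect_equal(r$f, unname(t2), tolerance = 1e-9)
})

test_that("immune densities are percent positive of all segmented cells", {
  cells <- make_cells(100)
  cells$pos_cd8 <- c(rep(TRUE, 10), rep(FALSE, 90))
  cells$pos_cd20 <- FALSE
  d <- immune_density(cells)
  expect_equal(d$cd8_pct, 10)
  expect_equal(d$cd20_pct, 0)

  # threshold route: 0.2 strict on normalized signals
  cells2 <- make_cells(4)
  cells2$norm_cd8 <- c(0.19, 0.2, 0.21, 5)
  cells2$norm_cd20 <- 0
  d2 <- immune_density(cells2)
  expect_equal(d2$cd8_pct, 50)
})
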