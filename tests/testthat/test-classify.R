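# independent truth table: group from (er_high, pr, her2) per the fixed
# eight-row mapping, class = 2*(group-1) + 1 + ki67
eph_truth <- data.frame(
  er = c(F, F, F, F, T, T, T, T),
  pr = c(F, F, T, T, F, F, T, T),
  her2 = c(F, T, F, T, F, T, F, T),
  group = 1:8)

test_that("positivity is strict at every printed cut-point", {
  thr <- marker_thresholds()
  eps <- 1e-6
  # every marker at threshold and just above
  at <- make_cells(1)
  for (m in names(thr)) at[[paste0("norm_", m)]] <- unname(thr[m])
  above <- at
  for (m in names(thr)) above[[paste0("norm_", m)]] <- unname(thr[m]) + eps
  pos_at <- call_positivity(at, thr)
  pos_above <- call_positivity(above, thr)
  for (m in names(thr)) {
    expect_false(pos_at[[paste0("pos_", m)]], info = m)
    expect_true(pos_above[[paste0("pos_", m)]], info = m)
  }
})

test_that("P53 is positive for any nonzero normalized signal", {
  cells <- make_cells(2)
  for (m in mxif_markers()[mxif_markers() != "pck"]) {
    cells[[paste0("norm_", m)]] <- 0
  }
  cells$norm_p53 <- c(0, 0.01)
  out <- call_positivity(cells)
  expect_equal(out$pos_p53, c(FALSE, TRUE))
})

test_that("missing normalized values raise an error naming cell and marker", {
  cells <- make_cells(1)
  expect_error(call_positivity(cells), "norm_er|marker 'er'")
  for (m in mxif_markers()[mxif_markers() != "pck"]) {
    cells[[paste0("norm_", m)]] <- 0
  }
  cells$norm_ki67 <- NA_real_
  expect_error(call_positivity(cells), "c001.*ki67")
})

test_that("exhaustive corner grid around all cut-points matches the truth table", {
  thr <- marker_thresholds()
  markers <- c("er", "pr", "her2", "ki67", "p53", "p16", "p21", "cd8", "cd20")
  eps <- 1e-4
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(markers)))
  names(grid) <- markers
  cells <- make_cells(nrow(grid))
  for (m in markers) {
    lo <- if (thr[m] == 0) 0 else unname(thr[m]) - eps
    cells[[paste0("norm_", m)]] <- ifelse(grid[[m]], unname(thr[m]) + eps, lo)
  }
  out <- assign_eph(call_positivity(cells, thr))
  for (m in markers) {
    expect_identical(out[[paste0("pos_", m)]], grid[[m]], info = m)
  }
  key <- paste(grid$er, grid$pr, grid$her2)
  expected_group <- eph_truth$group[match(key, with(eph_truth,
                                                   paste(er, pr, her2)))]
  expect_identical(out$eph_group, as.integer(expected_group))
  expect_identical(out$eph_ki67_class,
                   as.integer(2 * (expected_group - 1) + 1 + grid$ki67))
})

test_that("the sixteen-class mapping is a bijection over (group, Ki67)", {
  combos <- expand.grid(er = c(F, T), pr = c(F, T), her2 = c(F, T),
                        ki67 = c(F, T))
  cells <- data.frame(pos_er = combos$er, pos_pr = combos$pr,
                      pos_her2 = combos$her2, pos_ki67 = combos$ki67)
  out <- assign_eph(cells)
  expect_setequal(out$eph_ki67_class, 1:16)
  expect_equal(out$eph_group, (out$eph_ki67_class - 1) %/% 2 + 1)
  # Ki67-negative class of each group is odd
  expect_true(all((out$eph_ki67_class %% 2 == 1) == !out$pos_ki67))
})

test_that("documented example cells land in the expected groups", {
  cells <- make_cells(2)
  vals <- list(c(er = 5.0, pr = 3.0, her2 = 1.0, ki67 = 0.1),
               c(er = 0.3, pr = 0.5, her2 = 2.0, ki67 = 0.5))
  for (m in mxif_markers()[mxif_markers() != "pck"]) {
    cells[[paste0("norm_", m)]] <- c(vals[[1]][m], vals[[2]][m])
    cells[[paste0("norm_", m)]][is.na(cells[[paste0("norm_", m)]])] <- 0
  }
  out <- assign_eph(call_positivity(cells))
  expect_equal(out$eph_group, c(7L, 1L))
  expect_equal(out$eph_ki67_class, c(13L, 2L))
})

test_that("raising ER can never demote a cell from ER-high groups", {
  set.seed(11)
  for (i in 1:200) {
    v <- runif(4, 0, 15)
    cells <- make_cells(2)
    for (m in mxif_markers()[mxif_markers() != "pck"]) {
      cells[[paste0("norm_", m)]] <- 0
    }
    cells$norm_er <- c(v[1], v[1] + runif(1, 0, 15 - v[1]))
    cells$norm_pr <- v[2]; cells$norm_her2 <- v[3]; cells$norm_ki67 <- v[4]
    out <- assign_eph(call_positivity(cells))
    expect_true(out$eph_group[2] >= out$eph_group[1])
  }
})

test_that("surrogate subtyping follows the consensus rule set", {
  cases <- list(
    list(make_meta(er = 90, pr = 80, her2 = "0", ki67 = 10), "LumA"),
    list(make_meta(er = 90, pr = 10, her2 = "0", ki67 = 10), "LumB"),
    list(make_meta(er = 90, pr = 80, her2 = "0", ki67 = 30), "LumB"),
    list(make_meta(er = 50, pr = 30, her2 = "3+", ki67 = 10), "LumB_HER2pos"),
    list(make_meta(er = 0, pr = 0, her2 = "3+", ki67 = 40), "HER2"),
    list(make_meta(er = 0, pr = 0, her2 = "0", ki67 = 40), "TNBC"),
    list(make_meta(er = 0, pr = 0, her2 = "2+", fish = "amplified"), "HER2"),
    list(make_meta(er = 0, pr = 0, her2 = "2+", fish = "not_amplified"),
         "TNBC"),
    list(make_meta(er = 1, pr = 0, her2 = "0", ki67 = 10), "LumB"))
  for (cs in cases) {
    expect_equal(assign_surrogate_subtype(cs[[1]])$subtype, cs[[2]])
  }
})

test_that("unresolved equivocal HER2 and rule-gap profiles are errors", {
  bad <- make_meta(her2 = "2+", fish = NA_character_)
  expect_error(assign_surrogate_subtype(bad), "FISH")
  gap <- make_meta(er = 0, pr = 50, her2 = "0")
  expect_error(assign_surrogate_subtype(gap), "outside the surrogate rule")
})

test_that("core summaries count classes and fractions sum to one", {
  cells <- make_cells(4)
  cells$eph_ki67_class <- c(1L, 1L, 2L, 13L)
  s <- summarize_core(cells)
  expect_equal(s$frac_class_1, 0.5)
  expect_equal(s$frac_class_2, 0.25)
  expect_equal(s$frac_class_13, 0.25)
  expect_equal(sum(unlist(s[paste0("frac_class_", 1:16)])), 1,
               tolerance = 1e-12)

  ten <- make_cells(10)
  ten$eph_ki67_class <- 1L
  s10 <- summarize_core(ten)
  expect_equal(s10$frac_class_1, 1)
  expect_equal(sum(unlist(s10[paste0("frac_class_", 2:16)])), 0)
})

test_that("empty cores are flagged with undefined (not zero) fractions", {
  empty <- make_cells(1)[0, ]
  empty$eph_ki67_class <- integer(0)
  s <- summarize_core(empty, all_cells = NULL)
  expect_true(s$empty)
  expect_true(all(is.na(unlist(s[paste0("frac_class_", 1:16)]))))
})

test_that("recovered fractions at n = 2000 sit within binomial tolerance", {
  set.seed(3)
  n <- 2000
  cls <- sample(c(9L, 13L), n, replace = TRUE, prob = c(0.6, 0.4))
  cells <- make_cells(n)
  cells$eph_ki67_class <- cls
  s <- summarize_core(cells)
  for (k in c(9, 13)) {
    p <- c(`9` = 0.6, `13` = 0.4)[[as.character(k)]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(s[[paste0("frac_class_", k)]] - p), 3 * se)
  }
})
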