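test_that("generation is fully deterministic given the seed", {
  spec <- core_spec("s1", subtype = "LumB", n_cells = 400, seed = 11)
  g1 <- generate_core(spec)
  g2 <- generate_core(spec)
  expect_identical(g1$cells, g2$cells)
  expect_identical(g1$meta, g2$meta)
  expect_identical(g1$truth$class_counts, g2$truth$class_counts)
  g3 <- generate_core(core_spec("s1", subtype = "LumB", n_cells = 400,
                                seed = 12))
  expect_false(identical(g1$cells$centroid_x, g3$cells$centroid_x))
})

test_that("manifest counts equal realized cell counts and never leak labels", {
  g <- generate_core(core_spec("s1", subtype = "HER2", n_cells = 500,
                               seed = 2))
  tr <- g$truth
  expect_equal(tr$n_cancer + tr$n_cd8 + tr$n_cd20 + tr$n_stroma, tr$n_cells)
  expect_equal(nrow(g$cells),
               tr$n_cells + tr$n_benign + tr$n_qcfail + 2L)  # + artifacts
  expect_equal(sum(tr$class_counts), tr$n_cancer)
  expect_equal(as.vector(table(factor(tr$cells$intended_class, levels = 1:16))),
               unname(tr$class_counts))
  # the observable table carries no ground-truth columns
  expect_false(any(c("population_label", "eph_group", "eph_ki67_class",
                     "intended_class") %in% names(g$cells)))
})

test_that("realized class fractions converge to the spec at n = 10^4", {
  f <- subtype_class_fractions("LumB")
  g <- generate_core(core_spec("s1", subtype = "LumB", n_cells = 10000,
                               class_fractions = f, stroma_frac = 0,
                               immune = list(cd8_frac = 0, cd20_frac = 0,
                                             pattern = "scattered"),
                               benign_frac = 0, qc_fail_frac = 0, seed = 5))
  realized <- g$truth$class_counts / g$truth$n_cancer
  for (k in 1:16) {
    se <- sqrt(f[k] * (1 - f[k]) / g$truth$n_cancer)
    expect_lt(abs(realized[k] - f[k]), 4 * se + 1e-12)
  }
})

test_that("all centroids lie inside the core disc; uniform model passes a quadrat test", {
  spec <- core_spec("s1", subtype = "LumA", n_cells = 10000,
                    stroma_frac = 0,
                    immune = list(cd8_frac = 0, cd20_frac = 0,
                                  pattern = "scattered"),
                    benign_frac = 0, qc_fail_frac = 0, seed = 6)
  g <- generate_core(spec)
  R <- 0.5 * spec$core_diameter_um / spec$pixel_size_um
  r2 <- (g$cells$centroid_x - R)^2 + (g$cells$centroid_y - R)^2
  expect_true(all(r2 <= R^2 * (1 + 1e-12)))

  # equal-area quadrats: uniformity on (r^2, theta)
  tissue <- g$cells[g$cells$perimeter_px > 90, ]  # cancer cells only
  u <- ((tissue$centroid_x - R)^2 + (tissue$centroid_y - R)^2) / R^2
  th <- atan2(tissue$centroid_y - R, tissue$centroid_x - R)
  counts <- table(cut(u, seq(0, 1, by = 0.25)),
                  cut(th, seq(-pi, pi, length.out = 9)))
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.001)
})

test_that("a single-class core survives the full pipeline unchanged", {
  f <- numeric(16); f[1] <- 1
  b <- generate_tma(list(core_spec("s1", subtype = "TNBC", n_cells = 100,
                                   class_fractions = f)), seed = 3)
  res <- run_mxif_pipeline(b, mxif_config(n_perm = 50))
  expect_equal(nrow(res$cancer), b$truth$s1$n_cancer)
  expect_true(all(res$cancer$eph_ki67_class == 1L))
})

test_that("planted immune densities are recovered within binomial tolerance", {
  b <- generate_tma(list(core_spec(
    "s1", subtype = "LumA", n_cells = 2000,
    immune = list(cd8_frac = 0.05, cd20_frac = 0.02,
                  pattern = "scattered"))), seed = 9)
  res <- run_mxif_pipeline(b, mxif_config(n_perm = 50))
  d <- res$immune_density
  # the saturated artifact cell reads CD8+ and CD20+; truth accounts for it
  expect_equal(d$cd8_pct / 100 * d$n_cells, b$truth$s1$n_cd8_pos_all)
  expect_lt(abs(d$cd8_pct - 5), 1)
  expect_lt(abs(d$cd20_pct - 2), 1)
})

test_that("infeasible intensity models are rejected", {
  im_bad <- intensity_model()
  im_bad$margin <- -0.2
  expect_error(validate_intensity_model(im_bad), "infeasible")
  expect_error(core_spec("s1", im = im_bad), "infeasible")
  expect_error(core_spec("s1", class_fractions = rep(1 / 8, 16)),
               "summing to 1")
  expect_error(core_spec("s1", n_cells = 0), "n_cells")
})

test_that("class-pure Thomas clustering enriches same-class neighborhoods", {
  f <- numeric(16); f[c(1, 9)] <- c(0.5, 0.5)
  spec <- core_spec("s1", subtype = "LumB", n_cells = 1500,
                    class_fractions = f, stroma_frac = 0,
                    immune = list(cd8_frac = 0, cd20_frac = 0,
                                  pattern = "scattered"),
                    benign_frac = 0, qc_fail_frac = 0,
                    spatial_model = list(type = "thomas_cluster",
                                         parent_rate = 30,
                                         cluster_sd_px = 40,
                                         offspring_mean = 50),
                    cluster_by_class = TRUE, seed = 14)
  g <- generate_core(spec)
  cancer <- g$truth$cells$population == "cancer"
  cls <- g$truth$cells$intended_class[cancer]
  x <- g$cells$centroid_x[cancer]; y <- g$cells$centroid_y[cancer]
  nb <- find_neighbors(x, y, 100)
  within <- vapply(seq_along(nb), function(i) {
    if (!length(nb[[i]])) return(NA_real_)
    mean(cls[nb[[i]]] == cls[i])
  }, numeric(1))
  for (k in c(1, 9)) {
    glob <- mean(cls == k)
    expect_gt(mean(within[cls == k], na.rm = TRUE), glob + 0.1)
  }
})

test_that("paired null cores are rarely flagged significant", {
  set.seed(41)
  hits <- 0L
  n_rep <- 25
  for (i in 1:n_rep) {
    f <- subtype_class_fractions("LumB")
    a <- sample.int(16, 1000, replace = TRUE, prob = f)
    b <- sample.int(16, 1000, replace = TRUE, prob = f)
    hits <- hits + compare_paired_cores(a, b, n_perm = 400,
                                        seed = 500 + i)$significant
  }
  expect_lte(hits / n_rep, 0.02 + 2 * sqrt(0.02 * 0.98 / n_rep))
})

test_that("TMA bundles assemble all cores with per-core manifests", {
  specs <- list(core_spec("s1", "case1", subtype = "LumA", n_cells = 150),
                core_spec("s2", "case1", subtype = "LumA", n_cells = 150),
                core_spec("s3", "case2", subtype = "TNBC", n_cells = 150))
  b <- generate_tma(specs, seed = 77)
  expect_equal(nrow(b$meta), 3)
  expect_setequal(names(b$truth), c("s1", "s2", "s3"))
  expect_equal(length(unique(b$cells$core_id)), 3)
  counts <- table(b$cells$core_id)
  for (s in names(b$truth)) {
    tr <- b$truth[[s]]
    expect_equal(unname(counts[s]),
                 tr$n_cells + tr$n_benign + tr$n_qcfail + 2L)
  }
})

test_that("bundles round-trip through the on-disk layout", {
  b <- generate_tma(list(core_spec("s1", subtype = "TNBC", n_cells = 120)),
                    seed = 19)
  dir <- withr::local_tempdir()
  write_tma_bundle(b, dir)
  expect_true(all(file.exists(file.path(dir, c("cells.csv", "cores.csv",
                                               "regions.geojson",
                                               "truth.json")))))
  cells <- read_cell_table(file.path(dir, "cells.csv"))
  expect_equal(cells$raw_er, b$cells$raw_er)
  meta <- read_core_metadata(file.path(dir, "cores.csv"))
  expect_equal(meta$ihc_her2, b$meta$ihc_her2)
  regs <- read_annotations(file.path(dir, "regions.geojson"))
  expect_equal(length(regs), length(b$regions))
})
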