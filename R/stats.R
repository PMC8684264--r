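#' Paired-core heterogeneity test
#'
#' Compares the EPH x Ki67 class composition of two cores from the same
#' specimen, with each core represented as the vector of per-cell class
#' indices 1-16. Two tests are run: a two-sample Wilcoxon rank-sum test on
#' the class-index vectors (normal approximation with tie correction; exact
#' enumeration when the combined sample is below 50 without ties) and a
#' label-permutation test on the absolute difference of mean class indices,
#' with the add-one estimator `p = (1 + #(T_perm >= T_obs)) / (1 + n_perm)`.
#' The pair is declared significantly different when both p-values fall
#' below `alpha`. Treating the nominal class index as an ordinal score
#' follows the group-major class ordering and is a deliberate, documented
#' simplification; [compare_paired_cores_chisq()] offers a contingency
#' alternative.
#'
#' @param classes_a,classes_b Integer vectors of per-cell classes (1-16) of
#'   the two cores; both non-empty.
#' @param alpha Significance level applied to both tests (default 0.01).
#' @param n_perm Number of label permutations.
#' @param seed Integer seed making the permutation p-value reproducible.
#' @return Object of class `paired_core_test`: `wilcoxon_p`,
#'   `permutation_p`, `significant`, the observed statistic, sizes and
#'   parameters.
#' @examples
#' a <- rep(1:2, 100); b <- rep(9L, 200)
#' compare_paired_cores(a, b, n_perm = 999, seed = 1)
#' @export
compare_paired_cores <- function(classes_a, classes_b, alpha = 0.01,
                                 n_perm = 10000, seed = 1L) {
  if (!length(classes_a) || !length(classes_b)) {
    stop("both class vectors must be non-empty")
  }
  a <- as.numeric(classes_a); b <- as.numeric(classes_b)
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    wp <- 1; pp <- 1; t_obs <- 0
  } else {
    wp <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    t_obs <- abs(mean(a) - mean(b))
    # permuting the sorted pooled vector makes the p-value a function of the
    # pooled multiset and (n_a, n_b) only: exchangeable under label swap
    pooled <- sort(pooled)
    s_tot <- sum(pooled); n_tot <- na + nb
    pp <- withr::with_seed(as.integer(seed), {
      hits <- 0L
      for (k in seq_len(n_perm)) {
        sa <- sum(pooled[sample.int(n_tot, na)])
        t_perm <- abs(sa / na - (s_tot - sa) / nb)
        if (t_perm >= t_obs - 1e-12) hits <- hits + 1L
      }
      (1 + hits) / (1 + n_perm)
    })
  }
  structure(list(wilcoxon_p = wp, permutation_p = pp,
                 significant = max(wp, pp) < alpha,
                 statistic = t_obs, n_a = na, n_b = nb,
                 alpha = alpha, n_perm = n_perm, seed = as.integer(seed)),
            class = "paired_core_test")
}

#' @export
print.paired_core_test <- function(x, ...) {
  cat("Paired-core heterogeneity test (16-class composition)\n")
  cat(sprintf("  n = %d vs %d cells; |mean class diff| = %.4f\n",
              x$n_a, x$n_b, x$statistic))
  cat(sprintf("  Wilcoxon p = %.4g; permutation p = %.4g (n_perm = %d, seed = %d)\n",
              x$wilcoxon_p, x$permutation_p, x$n_perm, x$seed))
  cat(sprintf("  significant at alpha = %g (both tests): %s\n",
              x$alpha, x$significant))
  invisible(x)
}

#' Chi-squared alternative to the paired-core rank test
#'
#' Pearson chi-squared test on the 2 x 16 contingency table of class counts
#' (simulated p-value when expected counts are small). Provided as a
#' nominal-scale cross-check of [compare_paired_cores()]; not the default.
#'
#' @inheritParams compare_paired_cores
#' @param n_sim Monte-Carlo replicates when expected counts are sparse.
#' @return p-value.
#' @export
compare_paired_cores_chisq <- function(classes_a, classes_b, n_sim = 2000) {
  if (!length(classes_a) || !length(classes_b)) {
    stop("both class vectors must be non-empty")
  }
  tab <- rbind(tabulate(classes_a, 16), tabulate(classes_b, 16))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L) return(1)
  exp_min <- min(outer(rowSums(tab), colSums(tab)) / sum(tab))
  if (exp_min < 5) {
    stats::chisq.test(tab, simulate.p.value = TRUE, B = n_sim)$p.value
  } else {
    stats::chisq.test(tab)$p.value
  }
}

#' Paired-core heterogeneity screen over a whole TMA
#'
#' Runs [compare_paired_cores()] for every case contributing exactly two
#' cores, using the EPH x Ki67 classes of each core's cancer cells, and
#' tallies significant cases per subtype. A case whose two cores carry
#' discordant subtypes is tallied under both subtypes.
#'
#' @param cells Classified cancer cells (`core_id`, `eph_ki67_class`).
#' @param meta Core metadata with `case_id` and `subtype`.
#' @param alpha Significance level for both tests.
#' @param n_perm Permutations per test.
#' @param seed Base seed; case `i` uses `seed + i`.
#' @return List of class `paired_core_screen`: `results` (one row per
#'   paired case) and `by_subtype` (significant / total tallies).
#' @export
run_paired_core_screen <- function(cells, meta, alpha = 0.01,
                                   n_perm = 10000, seed = 1L) {
  if (!"subtype" %in% names(meta)) stop("meta must carry subtype")
  cases <- split(meta$core_id, meta$case_id)
  cases <- cases[vapply(cases, length, integer(1)) == 2L]
  rows <- list()
  i <- 0L
  for (case_id in names(cases)) {
    i <- i + 1L
    cid <- cases[[case_id]]
    a <- cells$eph_ki67_class[cells$core_id == cid[1L]]
    b <- cells$eph_ki67_class[cells$core_id == cid[2L]]
    if (!length(a) || !length(b)) next  # empty core: no test possible
    tst <- compare_paired_cores(a, b, alpha = alpha, n_perm = n_perm,
                                seed = as.integer(seed) + i)
    rows[[case_id]] <- data.frame(
      case_id = case_id, core_a = cid[1L], core_b = cid[2L],
      subtype_a = meta$subtype[match(cid[1L], meta$core_id)],
      subtype_b = meta$subtype[match(cid[2L], meta$core_id)],
      n_a = tst$n_a, n_b = tst$n_b,
      wilcoxon_p = tst$wilcoxon_p, permutation_p = tst$permutation_p,
      significant = tst$significant, stringsAsFactors = FALSE)
  }
  results <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  if (is.null(results) || !nrow(results)) {
    results <- data.frame(case_id = character(0), core_a = character(0),
                          core_b = character(0), subtype_a = character(0),
                          subtype_b = character(0), n_a = integer(0),
                          n_b = integer(0), wilcoxon_p = numeric(0),
                          permutation_p = numeric(0),
                          significant = logical(0))
  }
  tallies <- list()
  for (st in subtype_levels()) {
    hit <- results$subtype_a == st | results$subtype_b == st
    tallies[[st]] <- data.frame(subtype = st, n_cases = sum(hit),
                                n_significant = sum(results$significant[hit]),
                                stringsAsFactors = FALSE)
  }
  by_subtype <- do.call(rbind, c(tallies, list(make.row.names = FALSE)))
  by_subtype$frac_significant <-
    ifelse(by_subtype$n_cases > 0,
           by_subtype$n_significant / by_subtype$n_cases, NA_real_)
  structure(list(results = results, by_subtype = by_subtype,
                 alpha = alpha, n_perm = n_perm, seed = as.integer(seed)),
            class = "paired_core_screen")
}

#' @export
print.paired_core_screen <- function(x, ...) {
  cat(sprintf("Paired-core screen: %d cases, alpha = %g, n_perm = %d\n",
              nrow(x$results), x$alpha, x$n_perm))
  cat(sprintf("  significant: %d / %d\n", sum(x$results$significant),
              nrow(x$results)))
  print(x$by_subtype, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Standard one-way analysis of variance of `values` across `group`,
#' followed by Tukey's honest-significant-difference pairwise table. Used
#' for comparing per-core EPH-group fractions across subtypes and Shannon
#' equitability across central classes.
#'
#' @param values Numeric response.
#' @param group Grouping factor (>= 2 levels with data).
#' @return List of class `group_anova`: `f`, `p`, `df`, and `tukey`
#'   (`data.frame` with `comparison`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
compare_groups_anova <- function(values, group) {
  group <- factor(group)
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]; group <- droplevels(group[keep])
  if (nlevels(group) < 2L) stop("need >= 2 groups with data")
  fit <- stats::aov(values ~ group)
  av <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(f = av[["F value"]][1L], p = av[["Pr(>F)"]][1L],
                 df = av[["Df"]], tukey = tukey),
            class = "group_anova")
}

#' @export
print.group_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g (df %d, %d), p = %.4g\n",
              x$f, x$df[1L], x$df[2L], x$p))
  print(x$tukey, row.names = FALSE)
  invisible(x)
}

#' Per-core immune-cell densities
#'
#' CD8 and CD20 densities as percent of all QC-passing segmented cells of
#' each core, using positivity at the normalized cut-point 0.2 (strict `>`).
#'
#' @param all_cells All QC-passing segmented cells with either `pos_cd8` /
#'   `pos_cd20` or `norm_cd8` / `norm_cd20` columns.
#' @param thresholds A [marker_thresholds()] (used when positivity columns
#'   are absent).
#' @return `data.frame` with `core_id`, `n_cells`, `cd8_pct`, `cd20_pct`.
#' @export
immune_density <- function(all_cells, thresholds = marker_thresholds()) {
  for (m in c("cd8", "cd20")) {
    if (!paste0("pos_", m) %in% names(all_cells)) {
      all_cells[[paste0("pos_", m)]] <-
        all_cells[[paste0("norm_", m)]] > unname(thresholds[m])
    }
  }
  res <- lapply(split(all_cells, all_cells$core_id), function(cc) {
    data.frame(core_id = cc$core_id[1L], n_cells = nrow(cc),
               cd8_pct = 100 * mean(cc$pos_cd8),
               cd20_pct = 100 * mean(cc$pos_cd20),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out[order(out$core_id), , drop = FALSE]
}
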