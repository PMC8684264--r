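#' Call marker positivity from normalized signals
#'
#' A cell is positive for a marker when its normalized 0-15 value is
#' strictly greater than the marker's cut-point (so P53, with cut-point 0,
#' is positive for any nonzero signal, and a value exactly at a cut-point is
#' negative). Adds one `pos_<marker>` logical column per thresholded marker.
#'
#' @param cells Cell `data.frame` with `norm_<marker>` columns.
#' @param thresholds A [marker_thresholds()] vector.
#' @return `cells` with `pos_<marker>` columns.
#' @export
call_positivity <- function(cells, thresholds = marker_thresholds()) {
  for (m in names(thresholds)) {
    col <- paste0("norm_", m)
    if (!col %in% names(cells)) {
      stop(sprintf("missing normalized signal for marker '%s' (column %s)", m, col))
    }
    v <- cells[[col]]
    if (anyNA(v)) {
      stop(sprintf("cell '%s': missing normalized value for marker '%s'",
                   cells$cell_id[which(is.na(v))[1L]], m))
    }
    cells[[paste0("pos_", m)]] <- v > unname(thresholds[m])
  }
  cells
}

#' EPH group from ER/PR/HER2 positivity
#'
#' The fixed bijection from the three binary calls to groups 1-8:
#' \tabular{lllll}{
#' group \tab ER \tab PR \tab HER2 \cr
#' 1 \tab w/neg \tab - \tab - \cr 2 \tab w/neg \tab - \tab + \cr
#' 3 \tab w/neg \tab + \tab - \cr 4 \tab w/neg \tab + \tab + \cr
#' 5 \tab m/s \tab - \tab - \cr 6 \tab m/s \tab - \tab + \cr
#' 7 \tab m/s \tab + \tab - \cr 8 \tab m/s \tab + \tab +
#' }
#'
#' @param er_high,pr_pos,her2_pos Logical vectors.
#' @return Integer vector of groups 1-8.
#' @export
eph_group_from_calls <- function(er_high, pr_pos, her2_pos) {
  1L + 4L * as.integer(er_high) + 2L * as.integer(pr_pos) +
    as.integer(her2_pos)
}

#' Assign EPH groups and EPH x Ki67 classes
#'
#' Cells are assigned to one of eight EPH co-expression groups from their
#' ER ("ER-high", moderate/strong), PR and HER2 positivity, then split by
#' Ki67 into sixteen classes with the fixed group-major ordering
#' `class = 2 * (group - 1) + 1 + ki67_pos`, i.e. the Ki67-negative class of
#' a group precedes its Ki67-positive class.
#'
#' @param cells Cell `data.frame` carrying `pos_er`, `pos_pr`, `pos_her2`,
#'   `pos_ki67` (from [call_positivity()]).
#' @return `cells` with integer columns `eph_group` (1-8) and
#'   `eph_ki67_class` (1-16).
#' @examples
#' x <- data.frame(pos_er = TRUE, pos_pr = TRUE,
#'                 pos_her2 = FALSE, pos_ki67 = FALSE)
#' assign_eph(x)$eph_group        # 7
#' assign_eph(x)$eph_ki67_class   # 13
#' @export
assign_eph <- function(cells) {
  need <- c("pos_er", "pos_pr", "pos_her2", "pos_ki67")
  miss <- setdiff(need, names(cells))
  if (length(miss)) {
    stop(sprintf("missing positivity column(s): %s (run call_positivity first)",
                 paste(miss, collapse = ", ")))
  }
  cells$eph_group <- eph_group_from_calls(cells$pos_er, cells$pos_pr,
                                          cells$pos_her2)
  cells$eph_ki67_class <- 2L * (cells$eph_group - 1L) + 1L +
    as.integer(cells$pos_ki67)
  cells
}

.assign_subtype_one <- function(er_pct, pr_pct, her2, fish, ki67_pct, rules) {
  if (her2 == "2+" && !isTRUE(fish %in% c("amplified", "not_amplified"))) {
    stop("HER2 IHC 2+ (equivocal) unresolved by FISH")
  }
  her2_pos <- her2 == "3+" || (her2 == "2+" && fish == "amplified")
  er_pos <- er_pct >= rules$erpr_pos_cut
  pr_pos <- pr_pct >= rules$erpr_pos_cut
  if (er_pos) {
    if (her2_pos) return("LumB_HER2pos")
    if (ki67_pct < rules$ki67_cut && pr_pct >= rules$pr_cut) return("LumA")
    return("LumB")
  }
  if (!pr_pos) return(if (her2_pos) "HER2" else "TNBC")
  stop(sprintf("ER-negative, PR-positive IHC profile (ER %g%%, PR %g%%) is outside the surrogate rule table",
               er_pct, pr_pct))
}

#' St. Gallen IHC-surrogate subtype of each core
#'
#' Classifies cores from their clinical IHC scores: HER2-positive means IHC
#' 3+ or FISH-amplified 2+; receptor positivity means >= 1% positive cells
#' (configurable). ER+/HER2- cores are Luminal A-like when Ki67 is below the
#' Ki67 cut (default 20%) and PR is at or above the PR cut (default 20%),
#' otherwise Luminal B-like; ER+/HER2+ is Luminal B-like (HER2+);
#' ER-/PR-/HER2+ is HER2+ (non-luminal); ER-/PR-/HER2- is TNBC.
#'
#' @param meta Core metadata (see [read_core_metadata()]).
#' @param rules A [subtype_rules()].
#' @return `meta` with the `subtype` column filled.
#' @export
assign_surrogate_subtype <- function(meta, rules = subtype_rules()) {
  validate_core_metadata(meta)
  meta$subtype <- vapply(seq_len(nrow(meta)), function(i) {
    tryCatch(.assign_subtype_one(meta$ihc_er_percent[i], meta$ihc_pr_percent[i],
                                 meta$ihc_her2[i], meta$fish_result[i],
                                 meta$ihc_ki67_percent[i], rules),
             error = function(e) stop(sprintf("core '%s': %s", meta$core_id[i],
                                              conditionMessage(e)), call. = FALSE))
  }, character(1))
  meta
}

#' Per-core composition and marker summary
#'
#' Summarizes one core: fractions of the sixteen EPH x Ki67 classes over its
#' cancer cells (summing to 1), positive fractions of Ki67/P53/P16/P21 over
#' cancer cells, CD8/CD20 densities as percent of all QC-passing segmented
#' cells, quantiles (25/50/75/99th percentile) of normalized P53/P16/P21
#' over cancer cells, and, when neighborhood profiles are supplied, the mean
#' Shannon equitability per central EPH group.
#'
#' @param cancer_cells Classified cancer cells of one core (`eph_ki67_class`
#'   and `pos_*` columns present).
#' @param all_cells All QC-passing segmented cells of the same core (for
#'   immune densities); `NULL` to skip.
#' @param profiles Optional [neighborhood_composition()] output for the
#'   core's cancer cells under the `EPH8` scheme.
#' @return One-row `data.frame`. For a core with zero cancer cells `empty`
#'   is `TRUE` and the cancer-based summaries are `NA` (undefined, not 0).
#' @export
summarize_core <- function(cancer_cells, all_cells = NULL, profiles = NULL) {
  core_id <- unique(c(cancer_cells$core_id,
                      if (!is.null(all_cells)) all_cells$core_id))
  core_id <- core_id[!is.na(core_id)]
  if (length(core_id) > 1L) stop("summarize_core expects cells of a single core")
  if (!length(core_id)) core_id <- NA_character_
  n <- nrow(cancer_cells)
  out <- data.frame(core_id = core_id, n_cancer_cells = n, empty = n == 0L,
                    stringsAsFactors = FALSE)
  if (n > 0L) {
    cls <- factor(cancer_cells$eph_ki67_class, levels = 1:16)
    frac <- as.numeric(table(cls)) / n
  } else {
    frac <- rep(NA_real_, 16L)
  }
  out[paste0("frac_class_", 1:16)] <- as.list(frac)
  for (m in c("ki67", "p53", "p16", "p21")) {
    col <- paste0("pos_", m)
    out[[paste0("pos_frac_", m)]] <-
      if (n > 0L && col %in% names(cancer_cells)) mean(cancer_cells[[col]])
      else NA_real_
  }
  for (m in c("p53", "p16", "p21")) {
    col <- paste0("norm_", m)
    q <- if (n > 0L && col %in% names(cancer_cells)) {
      stats::quantile(cancer_cells[[col]], c(0.25, 0.5, 0.75, 0.99),
                      names = FALSE)
    } else rep(NA_real_, 4L)
    out[paste0(m, c("_q25", "_q50", "_q75", "_q99"))] <- as.list(q)
  }
  if (!is.null(all_cells) && nrow(all_cells)) {
    out$cd8_pct <- 100 * mean(all_cells$pos_cd8)
    out$cd20_pct <- 100 * mean(all_cells$pos_cd20)
  } else {
    out$cd8_pct <- NA_real_
    out$cd20_pct <- NA_real_
  }
  eh <- rep(NA_real_, 8L)
  if (!is.null(profiles)) {
    agg <- aggregate_equitability(profiles)
    idx <- match(seq_len(8L), as.integer(as.character(agg$central_class)))
    eh <- agg$mean_eh[idx]
  }
  out[paste0("eh_eph", 1:8)] <- as.list(eh)
  out
}
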