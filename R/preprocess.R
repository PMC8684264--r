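#' Min-max normalize raw marker signals to the 0-15 scale
#'
#' Each marker is rescaled independently by `15 * (x - min) / (max - min)`,
#' with the minimum and maximum taken over all QC-passing segmented cells of
#' the whole dataset (before any cancer gating), so that thresholds defined
#' on the normalized scale are comparable across the cancer and immune
#' analyses. Per-core normalization is available as an option. The fitted
#' min/max per marker is recorded for reproducibility; a degenerate marker
#' (max equal to min) normalizes to all zeros with a warning.
#'
#' Renormalizing an already normalized table is refused unless `force =
#' TRUE`, since the 0-15 scale is not idempotent under a second fit.
#'
#' @param cells Cell `data.frame` with `raw_<marker>` columns.
#' @param markers Markers to normalize.
#' @param spec Optional previously fitted specification (as returned in the
#'   `norm_spec` attribute) to apply instead of fitting; values are clamped
#'   to \[0, 15\].
#' @param per_core Fit min/max within each core instead of globally.
#' @param force Allow renormalization of a table that already carries
#'   normalized columns.
#' @return `cells` with `norm_<marker>` columns added and the fitted
#'   specification in `attr(., "norm_spec")` (a list with `out_min`,
#'   `out_max` and a per-marker `range` matrix).
#' @examples
#' cells <- data.frame(core_id = "c1", cell_id = as.character(1:3),
#'                     raw_er = c(100, 600, 1100), qc_pass = TRUE)
#' normalize_markers(cells, markers = "er")$norm_er  # 0, 7.5, 15
#' @export
normalize_markers <- function(cells, markers = mxif_markers(), spec = NULL,
                              per_core = FALSE, force = FALSE) {
  if (!force && any(paste0("norm_", markers) %in% names(cells))) {
    stop("cells already carry normalized columns; renormalization is not allowed (use force = TRUE to override)")
  }
  if (!"qc_pass" %in% names(cells)) cells$qc_pass <- TRUE
  miss <- setdiff(paste0("raw_", markers), names(cells))
  if (length(miss)) {
    stop(sprintf("missing raw signal column(s): %s", paste(miss, collapse = ", ")))
  }
  out_min <- 0; out_max <- 15

  apply_range <- function(x, lo, hi) {
    if (hi == lo) return(rep(0, length(x)))
    pmin(out_max, pmax(out_min, out_max * (x - lo) / (hi - lo)))
  }

  if (!is.null(spec)) {
    for (m in markers) {
      r <- spec$range[, m]
      cells[[paste0("norm_", m)]] <-
        apply_range(cells[[paste0("raw_", m)]], r[1L], r[2L])
    }
    attr(cells, "norm_spec") <- spec
    return(cells)
  }

  fit_one <- function(idx) {
    rng <- sapply(markers, function(m) {
      x <- cells[[paste0("raw_", m)]][idx]
      x <- x[cells$qc_pass[idx] & is.finite(x)]
      if (!length(x)) stop(sprintf("no QC-passing values to fit marker '%s'", m))
      range(x)
    })
    rownames(rng) <- c("min", "max")
    rng
  }

  if (per_core) {
    for (m in markers) cells[[paste0("norm_", m)]] <- NA_real_
    ranges <- list()
    for (cid in unique(cells$core_id)) {
      idx <- which(cells$core_id == cid)
      rng <- fit_one(idx)
      ranges[[cid]] <- rng
      for (m in markers) {
        if (rng["max", m] == rng["min", m]) {
          warning(sprintf("marker '%s' degenerate (constant) in core %s; normalized to 0", m, cid))
        }
        cells[[paste0("norm_", m)]][idx] <-
          apply_range(cells[[paste0("raw_", m)]][idx], rng["min", m], rng["max", m])
      }
    }
    spec <- list(out_min = out_min, out_max = out_max, per_core = TRUE,
                 range = ranges)
  } else {
    rng <- fit_one(seq_len(nrow(cells)))
    for (m in markers) {
      if (rng["max", m] == rng["min", m]) {
        warning(sprintf("marker '%s' is degenerate (constant raw signal); normalized to 0", m))
      }
      cells[[paste0("norm_", m)]] <-
        apply_range(cells[[paste0("raw_", m)]], rng["min", m], rng["max", m])
    }
    spec <- list(out_min = out_min, out_max = out_max, per_core = FALSE,
                 range = rng)
  }
  attr(cells, "norm_spec") <- spec
  cells
}

#' Fitted normalization specification of a cell table
#' @param cells A cell table returned by [normalize_markers()].
#' @return The fitted specification, or `NULL`.
#' @export
normalization_spec <- function(cells) attr(cells, "norm_spec")

#' QC and size gating of segmented cells
#'
#' A cell is kept when it passes upstream QC and exceeds all three
#' morphology gates strictly: perimeter > 90 px, cell area > 400 px^2,
#' nuclear area > 10 px^2 (defaults; see [gating_config()]). Cells at a
#' boundary value are rejected. The reject log names the first failed rule
#' per cell, in the order qc, perimeter, cell_area, nuclear_area.
#'
#' @param cells Cell `data.frame` with morphology columns.
#' @param gating A [gating_config()].
#' @return List with `kept` (cells passing all gates) and `rejects`
#'   (`core_id`, `cell_id`, `reason`); `nrow(kept) + nrow(rejects)` always
#'   equals `nrow(cells)`.
#' @export
qc_and_size_gate <- function(cells, gating = gating_config()) {
  if (!"qc_pass" %in% names(cells)) cells$qc_pass <- TRUE
  reason <- rep(NA_character_, nrow(cells))
  reason[!(cells$nuclear_area_px > gating$min_nuclear_area_px)] <- "nuclear_area"
  reason[!(cells$cell_area_px > gating$min_cell_area_px)] <- "cell_area"
  reason[!(cells$perimeter_px > gating$min_perimeter_px)] <- "perimeter"
  reason[!cells$qc_pass] <- "qc"
  keep <- is.na(reason)
  list(kept = cells[keep, , drop = FALSE],
       rejects = data.frame(core_id = cells$core_id[!keep],
                            cell_id = cells$cell_id[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE))
}

#' Select the cancer-cell population of each core
#'
#' Applies the QC/size gate first, then the subtype-specific cancer gate:
#' cores of PCK-gated subtypes (luminal and HER2+) keep cells with raw
#' pan-cytokeratin signal at or above 1500 that do not fall inside any
#' `exclude_benign` annotation; cores of annotation-gated subtypes (TNBC,
#' where PCK is too weak to threshold) keep cells inside an `include_tumor`
#' annotation (benign exclusions still apply). Membership is decided by the
#' cell centroid; polygon boundaries count as inside.
#'
#' @param cells Cell `data.frame` (QC flags and morphology present).
#' @param core_meta Core metadata with a `subtype` column set for every core
#'   appearing in `cells`.
#' @param regions Optional `region_set` of annotations.
#' @param gating A [gating_config()].
#' @return The selected cells with `population_label` set to `"cancer"`; the
#'   per-core in/out counts are attached as `attr(., "gate_log")`.
#' @export
select_cancer_population <- function(cells, core_meta, regions = NULL,
                                     gating = gating_config()) {
  if (!"subtype" %in% names(core_meta) || any(is.na(core_meta$subtype))) {
    stop("core metadata must carry a subtype for every core (run assign_surrogate_subtype first)")
  }
  sized <- qc_and_size_gate(cells, gating)$kept
  kept_list <- list()
  log <- list()
  for (cid in unique(cells$core_id)) {
    sub <- core_meta$subtype[match(cid, core_meta$core_id)]
    if (is.na(sub)) stop(sprintf("core '%s' missing from core metadata", cid))
    cc <- sized[sized$core_id == cid, , drop = FALSE]
    excl <- regions_for_core(regions, cid, "exclude_benign")
    in_excl <- rep(FALSE, nrow(cc))
    for (r in excl) {
      in_excl <- in_excl | point_in_polygon(cc$centroid_x, cc$centroid_y,
                                            r$vertices)
    }
    if (sub %in% gating$pck_gated_subtypes) {
      keep <- cc$raw_pck >= gating$pck_raw_min & !in_excl
    } else if (sub %in% gating$annotation_gated_subtypes) {
      incl <- regions_for_core(regions, cid, "include_tumor")
      if (!length(incl)) {
        stop(sprintf("core '%s' (subtype %s) requires include_tumor annotation regions but none were provided",
                     cid, sub))
      }
      in_incl <- rep(FALSE, nrow(cc))
      for (r in incl) {
        in_incl <- in_incl | point_in_polygon(cc$centroid_x, cc$centroid_y,
                                              r$vertices)
      }
      keep <- in_incl & !in_excl
    } else {
      stop(sprintf("subtype '%s' of core '%s' is in neither gating path", sub, cid))
    }
    sel <- cc[keep, , drop = FALSE]
    if (nrow(sel)) sel$population_label <- "cancer"
    kept_list[[cid]] <- sel
    log[[cid]] <- data.frame(core_id = cid, subtype = sub,
                             n_in = sum(cells$core_id == cid),
                             n_sized = nrow(cc), n_cancer = nrow(sel),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, kept_list)
  rownames(out) <- NULL
  attr(out, "gate_log") <- do.call(rbind, c(log, list(make.row.names = FALSE)))
  out
}

#' All segmented cells for immune analysis
#'
#' The immune (CD8/CD20) analysis runs on every QC-passing segmented cell,
#' cancer and stromal alike; no size, PCK or region gating is applied.
#'
#' @param cells Cell `data.frame`.
#' @return QC-passing subset of `cells`.
#' @export
select_all_cells_for_immune <- function(cells) {
  if (!"qc_pass" %in% names(cells)) return(cells)
  cells[cells$qc_pass, , drop = FALSE]
}
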