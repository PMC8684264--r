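#' mxifhet: single-cell heterogeneity analysis of MxIF breast-cancer TMAs
#'
#' Tools to take a table of segmented single cells from multiplexed
#' immunofluorescence (MxIF) imaging of a breast-cancer tissue microarray
#' (TMA), together with per-core clinical IHC scores and optional region
#' annotations, through marker normalization, positivity thresholding,
#' ER/PR/HER2 ("EPH") co-expression classification, IHC-surrogate subtyping,
#' spatial neighborhood and diversity analysis, immune profiling, and
#' paired-core heterogeneity statistics. A synthetic TMA generator with a
#' recorded ground-truth manifest supports validation end to end.
#'
#' @keywords internal
"_PACKAGE"

#' Marker panel measured per cell
#'
#' The ten protein markers quantified per segmented cell, each extracted
#' upstream from its reported subcellular compartment (ER, PR, Ki67, P21, P16
#' nuclear; HER2 and PCK membranous; P53 nuclear+cytosol; CD8, CD20 whole
#' cell). Raw signal columns in a cell table are named `raw_<marker>`,
#' normalized columns `norm_<marker>`, positivity columns `pos_<marker>`.
#'
#' @return Character vector of marker names.
#' @export
mxif_markers <- function() {
  c("er", "pr", "her2", "ki67", "p53", "p21", "p16", "pck", "cd8", "cd20")
}

#' Positivity cut-points on the normalized 0-15 scale
#'
#' Default cut-points calibrated against clinical IHC scoring of the same
#' cores: ER 0.4 (separates negative/weak from moderate/strong, "ER-high"),
#' PR 1.6, HER2 5.0, Ki67 0.2, P53 0 (any signal), P16 2, P21 1, and 0.2 for
#' the immune markers CD8 and CD20. A cell is positive when its normalized
#' value is strictly greater than the cut-point.
#'
#' @param er,pr,her2,ki67,p53,p16,p21,cd8,cd20 Cut-points on the normalized
#'   0-15 scale.
#' @return Named numeric vector of class `marker_thresholds`.
#' @examples
#' marker_thresholds()
#' marker_thresholds(ki67 = 0.3)
#' @export
marker_thresholds <- function(er = 0.4, pr = 1.6, her2 = 5.0, ki67 = 0.2,
                              p53 = 0, p16 = 2, p21 = 1,
                              cd8 = 0.2, cd20 = 0.2) {
  thr <- c(er = er, pr = pr, her2 = her2, ki67 = ki67, p53 = p53,
           p16 = p16, p21 = p21, cd8 = cd8, cd20 = cd20)
  if (any(!is.finite(thr)) || any(thr < 0) || any(thr > 15)) {
    stop("all thresholds must be finite and within [0, 15]")
  }
  class(thr) <- "marker_thresholds"
  thr
}

#' Cancer-cell gating configuration
#'
#' Morphology gates are strict inequalities (a cell passes with perimeter
#' > 90 px, cell area > 400 px^2 and nuclear area > 10 px^2); the
#' pan-cytokeratin (PCK) gate on raw signal is inclusive (>= 1500). Luminal
#' and HER2+ cores are gated by PCK and benign-duct exclusion regions; TNBC
#' cores, whose cells express PCK too weakly to threshold, are gated by
#' manually annotated tumor-inclusion regions instead.
#'
#' @param min_perimeter_px,min_cell_area_px,min_nuclear_area_px Morphology
#'   gates in pixels / square pixels (strict `>`).
#' @param pck_raw_min PCK raw-signal gate (inclusive `>=`).
#' @param pck_gated_subtypes Subtypes whose cancer population is PCK-gated.
#' @param annotation_gated_subtypes Subtypes gated by `include_tumor` regions.
#' @return A list of class `gating_config`.
#' @export
gating_config <- function(min_perimeter_px = 90, min_cell_area_px = 400,
                          min_nuclear_area_px = 10, pck_raw_min = 1500,
                          pck_gated_subtypes = c("LumA", "LumB",
                                                 "LumB_HER2pos", "HER2"),
                          annotation_gated_subtypes = "TNBC") {
  thr <- c(min_perimeter_px, min_cell_area_px, min_nuclear_area_px,
           pck_raw_min)
  if (any(!is.finite(thr)) || any(thr <= 0)) {
    stop("all gating thresholds must be positive")
  }
  structure(list(min_perimeter_px = min_perimeter_px,
                 min_cell_area_px = min_cell_area_px,
                 min_nuclear_area_px = min_nuclear_area_px,
                 pck_raw_min = pck_raw_min,
                 pck_gated_subtypes = pck_gated_subtypes,
                 annotation_gated_subtypes = annotation_gated_subtypes),
            class = "gating_config")
}

#' IHC-surrogate subtype rule parameters
#'
#' Parameters of the St. Gallen surrogate classification applied to per-core
#' IHC scores. HER2 positivity is IHC 3+ or FISH amplification of an
#' equivocal 2+; ER/PR receptor positivity is percent positive cells >=
#' `erpr_pos_cut` (clinical 1% convention). Among ER+/HER2- cores, Luminal
#' A-like requires Ki67 below `ki67_cut` and PR at or above `pr_cut`;
#' otherwise Luminal B-like.
#'
#' @param ki67_cut Ki67 percent cut between Luminal A-like and B-like.
#' @param pr_cut PR percent required for Luminal A-like.
#' @param erpr_pos_cut Percent positive cells defining ER/PR receptor
#'   positivity.
#' @return A list of class `subtype_rules`.
#' @export
subtype_rules <- function(ki67_cut = 20, pr_cut = 20, erpr_pos_cut = 1) {
  stopifnot(ki67_cut > 0, ki67_cut <= 100, pr_cut >= 0, pr_cut <= 100,
            erpr_pos_cut >= 0, erpr_pos_cut <= 100)
  structure(list(ki67_cut = ki67_cut, pr_cut = pr_cut,
                 erpr_pos_cut = erpr_pos_cut),
            class = "subtype_rules")
}

#' Subtype labels used throughout the package
#' @return Character vector of the five IHC-surrogate subtype labels.
#' @export
subtype_levels <- function() {
  c("LumA", "LumB", "LumB_HER2pos", "HER2", "TNBC")
}

#' Convert micrometres to pixels
#'
#' Distances are Euclidean in pixel units throughout; the imaging pixel size
#' defaults to 0.293 um/px. With the default pixel size the two standard
#' neighborhood radii, 30 um and 100 um, map to the conventional 100 px and
#' 341 px.
#'
#' @param um Distance in micrometres.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param round_standard Snap 30 um / 100 um to 100 / 341 px when the pixel
#'   size is the default 0.293 (the conventional rounded values).
#' @return Distance in pixels.
#' @examples
#' um_to_px(30)   # 100 px (snapped)
#' um_to_px(100)  # 341 px
#' @export
um_to_px <- function(um, pixel_size_um = 0.293, round_standard = TRUE) {
  px <- um / pixel_size_um
  if (round_standard && identical(pixel_size_um, 0.293)) {
    px[um == 30] <- 100
    px[um == 100] <- 341
  }
  px
}
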