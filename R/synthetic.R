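#' Default EPH group composition of a subtype
#'
#' Typical eight-group compositions by IHC-surrogate subtype: Luminal A-like
#' cores are dominated by ER-moderate/strong, PR+ group 7 with groups 3 and
#' 5 present; Luminal B-like (HER2-) by PR-negative groups 1 and 5; Luminal
#' B-like (HER2+) by groups 1 and 2 (with 3/4 admixture); HER2+ non-luminal
#' by groups 1 and 2 only; TNBC almost entirely by group 1. Proliferative
#' (Ki67+) rates rise from Luminal A to TNBC.
#'
#' @param subtype One of [subtype_levels()].
#' @param ki67_rate Optional override of the subtype's Ki67+ rate.
#' @return Named numeric vector of length 16 (classes `1:16`) summing to 1.
#' @export
subtype_class_fractions <- function(subtype, ki67_rate = NULL) {
  groups <- switch(subtype,
    LumA = c("1" = 0.15, "3" = 0.15, "5" = 0.25, "7" = 0.45),
    LumB = c("1" = 0.35, "3" = 0.10, "5" = 0.45, "7" = 0.10),
    LumB_HER2pos = c("1" = 0.35, "2" = 0.35, "3" = 0.15, "4" = 0.15),
    HER2 = c("1" = 0.45, "2" = 0.55),
    TNBC = c("1" = 0.90, "2" = 0.03, "3" = 0.04, "5" = 0.03),
    stop(sprintf("unknown subtype '%s'", subtype)))
  if (is.null(ki67_rate)) {
    ki67_rate <- switch(subtype, LumA = 0.08, LumB = 0.30,
                        LumB_HER2pos = 0.30, HER2 = 0.40, TNBC = 0.50)
  }
  f <- numeric(16)
  names(f) <- as.character(1:16)
  for (g in names(groups)) {
    gi <- as.integer(g)
    f[2L * (gi - 1L) + 1L] <- groups[[g]] * (1 - ki67_rate)
    f[2L * gi] <- groups[[g]] * ki67_rate
  }
  f
}

#' Shift probability mass between classes
#'
#' Moves `mass` of total probability from the heaviest class into a target
#' class (by default the Ki67-matched class two groups away), producing the
#' planted between-core composition shift used in power studies.
#'
#' @param fractions Length-16 fractions summing to 1.
#' @param mass Total mass to move (capped at the source class's mass).
#' @param from,to Optional explicit class indices.
#' @return Shifted fractions (still summing to 1).
#' @export
shift_class_fractions <- function(fractions, mass = 0.3,
                                  from = NULL, to = NULL) {
  if (is.null(from)) from <- which.max(fractions)
  if (is.null(to)) to <- ((from - 1L + 4L) %% 16L) + 1L
  moved <- min(mass, fractions[from])
  fractions[from] <- fractions[from] - moved
  fractions[to] <- fractions[to] + moved
  fractions
}

#' Class-conditional marker intensity model
#'
#' Parameters of the synthetic raw-signal model on the normalized-target
#' scale: cells planted negative for a marker draw below the cut-point
#' (scaled Beta, or exactly 0 for P53 whose cut-point is 0), positive cells
#' draw above it (cut-point plus Gamma, capped at 15), both with a guard
#' margin `margin * cut-point` around the threshold. Targets map to raw
#' units via per-marker `scale`. P53 has two positive modes: the low
#' 0-to-1 signal of occasional cells in IHC-normal cores and the high-level
#' mode of overexpressing cores. Per-core positivity rates for P53/P16
#' depend on the core's IHC status; P21 uses a flat rate.
#'
#' @param thresholds A [marker_thresholds()].
#' @param margin Relative guard margin around each cut-point (must be in
#'   `[0, 1)`; a negative margin would place planted-negative cells above
#'   their threshold and is rejected as infeasible).
#' @param scale Raw units per normalized unit (recycled over markers).
#' @return List of class `intensity_model`.
#' @export
intensity_model <- function(thresholds = marker_thresholds(), margin = 0.05,
                            scale = 250) {
  mk <- names(thresholds)
  scale <- stats::setNames(rep_len(scale, length(mk) + 1L), c(mk, "pck"))
  spread <- c(er = 1.5, pr = 1.2, her2 = 1.5, ki67 = 1.0, p53 = 1.5,
              p16 = 1.2, p21 = 0.8, cd8 = 1.2, cd20 = 1.2)[mk]
  im <- structure(list(thresholds = thresholds, margin = margin,
                       scale = scale, spread = spread,
                       neg_beta = c(1.2, 3),
                       p53_oe = list(lo = 1, shape = 2, scale = 2),
                       rates = list(p53_OE = 0.6, p53_normal = 0.15,
                                    p53_null = 0, p16_OE = 0.6,
                                    p16_normal = 0.1, p21 = 0.2)),
                  class = "intensity_model")
  validate_intensity_model(im)
  im
}

#' @rdname intensity_model
#' @param im An `intensity_model`.
#' @export
validate_intensity_model <- function(im) {
  if (!is.finite(im$margin) || im$margin >= 1) stop("margin must be < 1")
  if (im$margin < 0) {
    stop("infeasible intensity model: negative class located above its threshold")
  }
  if (any(im$scale <= 0) || any(im$spread <= 0)) {
    stop("intensity model scale and spread must be positive")
  }
  invisible(im)
}

# normalized-scale targets for one marker
.draw_targets <- function(m, positive, n, im, p53_mode = "OE") {
  thr <- unname(im$thresholds[m])
  if (!positive) {
    if (thr == 0) return(rep(0, n))
    return(stats::rbeta(n, im$neg_beta[1], im$neg_beta[2]) *
             (1 - im$margin) * thr)
  }
  if (m == "p53") {
    if (p53_mode == "normal") return(stats::runif(n, 0.05, 1))
    return(pmin(15, im$p53_oe$lo +
                  stats::rgamma(n, im$p53_oe$shape, scale = im$p53_oe$scale)))
  }
  pmin(15, (1 + im$margin) * thr +
         stats::rgamma(n, 2, scale = unname(im$spread[m])))
}

#' Specification of one synthetic TMA core
#'
#' Describes a 1.1 mm core: its subtype and metadata linkage, total
#' QC-passing cell count, sixteen-class cancer composition, spatial point
#' model (uniform on the core disc, or a Thomas cluster process whose
#' clusters can be class-pure), immune content and pattern, and nuisance
#' fractions (stroma, benign epithelium inside an exclusion annotation,
#' QC failures).
#'
#' @param core_id,case_id,pair_id Identifiers (pair = the two cores cut from
#'   one specimen).
#' @param subtype IHC-surrogate subtype driving metadata and defaults.
#' @param n_cells Total QC-passing segmented cells (cancer + immune +
#'   stroma).
#' @param class_fractions Length-16 fractions over EPH x Ki67 classes
#'   (default: [subtype_class_fractions()]).
#' @param spatial_model `list(type = "uniform_disc")` or
#'   `list(type = "thomas_cluster", parent_rate = , cluster_sd_px = ,
#'   offspring_mean = )`.
#' @param cluster_by_class Should Thomas clusters be class-pure?
#' @param immune `list(cd8_frac, cd20_frac, pattern)` with pattern
#'   `"scattered"` or `"aggregated"`.
#' @param stroma_frac Fraction of `n_cells` that is stromal.
#' @param benign_frac Benign epithelial cells (inside an `exclude_benign`
#'   region) added on top of `n_cells`; only emitted for PCK-gated subtypes.
#' @param qc_fail_frac QC-failing cells added on top of `n_cells`.
#' @param leak_rate Probability that a cancer cell's ER/PR/HER2/Ki67 signal
#'   is drawn on the wrong side of its cut-point (default 0: the planted
#'   classes are recovered exactly).
#' @param im An [intensity_model()].
#' @param core_diameter_um,pixel_size_um Core geometry.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return List of class `core_spec`.
#' @export
core_spec <- function(core_id, case_id = core_id, pair_id = case_id,
                      subtype = "LumA", n_cells = 1000,
                      class_fractions = NULL,
                      spatial_model = list(type = "uniform_disc"),
                      cluster_by_class = FALSE,
                      immune = list(cd8_frac = 0.03, cd20_frac = 0.02,
                                    pattern = "scattered"),
                      stroma_frac = 0.2, benign_frac = 0.02,
                      qc_fail_frac = 0.02, leak_rate = 0,
                      im = intensity_model(),
                      core_diameter_um = 1100, pixel_size_um = 0.293,
                      seed = 1L) {
  if (is.null(class_fractions)) {
    class_fractions <- subtype_class_fractions(subtype)
  }
  if (length(class_fractions) != 16L ||
      abs(sum(class_fractions) - 1) > 1e-9 || any(class_fractions < 0)) {
    stop("class_fractions must be 16 nonnegative values summing to 1")
  }
  if (n_cells <= 0) stop("n_cells must be > 0")
  if (immune$cd8_frac + immune$cd20_frac + stroma_frac >= 1) {
    stop("immune and stroma fractions must leave room for cancer cells")
  }
  validate_intensity_model(im)
  structure(list(core_id = core_id, case_id = case_id, pair_id = pair_id,
                 subtype = subtype, n_cells = as.integer(n_cells),
                 class_fractions = unname(class_fractions),
                 spatial_model = spatial_model,
                 cluster_by_class = isTRUE(cluster_by_class),
                 immune = immune, stroma_frac = stroma_frac,
                 benign_frac = benign_frac, qc_fail_frac = qc_fail_frac,
                 leak_rate = leak_rate, im = im,
                 core_diameter_um = core_diameter_um,
                 pixel_size_um = pixel_size_um, seed = as.integer(seed)),
            class = "core_spec")
}

# rejection sampler for points uniform on the unit disc scaled to radius R,
# centred at (R, R), subject to an acceptance predicate
.sample_uniform <- function(n, R, accept) {
  out <- matrix(NA_real_, n, 2L)
  got <- 0L
  while (got < n) {
    m <- max(16L, 2L * (n - got))
    r <- R * sqrt(stats::runif(m))
    th <- stats::runif(m, 0, 2 * pi)
    x <- R + r * cos(th); y <- R + r * sin(th)
    ok <- accept(x, y)
    take <- min(sum(ok), n - got)
    if (take > 0L) {
      idx <- which(ok)[seq_len(take)]
      out[got + seq_len(take), ] <- cbind(x[idx], y[idx])
      got <- got + take
    }
  }
  out
}

# Thomas process conditioned on n points: Poisson number of uniformly placed
# parents, offspring Gaussian around an assigned parent, clipped by rejection
.sample_thomas <- function(n, R, accept, parent_rate, sd_px,
                           group = rep(1L, n)) {
  n_parents <- max(2L, stats::rpois(1L, parent_rate))
  parents <- .sample_uniform(n_parents, R * 0.95 + 0.05 * R, accept)
  groups <- sort(unique(group))
  # partition parents among groups (class-pure clusters)
  gsize <- tabulate(match(group, groups))
  alloc <- pmax(1L, round(n_parents * gsize / sum(gsize)))
  parent_group <- rep(seq_along(groups), alloc)[seq_len(max(n_parents, sum(alloc)))]
  parent_group <- parent_group[!is.na(parent_group)]
  if (length(parent_group) > n_parents) {
    extra <- length(parent_group) - n_parents
    parents <- rbind(parents, .sample_uniform(extra, R * 0.95, accept))
  }
  out <- matrix(NA_real_, n, 2L)
  cluster <- integer(n)
  for (i in seq_len(n)) {
    cand <- which(parent_group == match(group[i], groups))
    p <- cand[sample.int(length(cand), 1L)]
    cluster[i] <- p
    for (try in 1:50) {
      xy <- parents[p, ] + stats::rnorm(2L, 0, sd_px)
      if (accept(xy[1L], xy[2L])) break
      xy <- parents[p, ]
    }
    out[i, ] <- xy
  }
  list(xy = out, cluster = cluster)
}

.meta_for_subtype <- function(subtype, core_id, case_id, pair_id) {
  pick <- function(x, p) x[sample.int(length(x), 1L, prob = p)]
  m <- switch(subtype,
    LumA = list(er = stats::runif(1, 70, 95), eri = "strong",
                pr = stats::runif(1, 30, 90), pri = pick(c("moderate", "strong"), c(.5, .5)),
                her2 = pick(c("0", "1+"), c(.5, .5)), fish = NA_character_,
                ki67 = stats::runif(1, 5, 15),
                p53 = pick(c("normal", "null", "OE"), c(.9, .05, .05)),
                p16 = pick(c("normal", "OE"), c(.9, .1))),
    LumB = list(er = stats::runif(1, 40, 90), eri = pick(c("moderate", "strong"), c(.5, .5)),
                pr = stats::runif(1, 0, 15),
                pri = pick(c("neg", "weak"), c(.5, .5)),
                her2 = pick(c("0", "1+"), c(.5, .5)), fish = NA_character_,
                ki67 = stats::runif(1, 25, 50),
                p53 = pick(c("normal", "null", "OE"), c(.7, .1, .2)),
                p16 = pick(c("normal", "OE"), c(.8, .2))),
    LumB_HER2pos = {
      h <- pick(c("3+", "2+"), c(.7, .3))
      list(er = stats::runif(1, 30, 90), eri = "moderate",
           pr = stats::runif(1, 0, 60), pri = "weak",
           her2 = h, fish = if (h == "2+") "amplified" else NA_character_,
           ki67 = stats::runif(1, 15, 40),
           p53 = pick(c("normal", "null", "OE"), c(.6, .1, .3)),
           p16 = pick(c("normal", "OE"), c(.7, .3)))
    },
    HER2 = {
      h <- pick(c("3+", "2+"), c(.7, .3))
      list(er = 0, eri = "neg", pr = 0, pri = "neg",
           her2 = h, fish = if (h == "2+") "amplified" else NA_character_,
           ki67 = stats::runif(1, 30, 60),
           p53 = pick(c("normal", "null", "OE"), c(.3, .2, .5)),
           p16 = pick(c("normal", "OE"), c(.6, .4)))
    },
    TNBC = {
      h <- pick(c("0", "1+", "2+"), c(.6, .3, .1))
      list(er = 0, eri = "neg", pr = 0, pri = "neg",
           her2 = h, fish = if (h == "2+") "not_amplified" else NA_character_,
           ki67 = stats::runif(1, 30, 70),
           p53 = pick(c("normal", "null", "OE"), c(.2, .3, .5)),
           p16 = pick(c("normal", "OE"), c(.4, .6)))
    },
    stop(sprintf("unknown subtype '%s'", subtype)))
  data.frame(core_id = core_id, case_id = case_id, pair_id = pair_id,
             ihc_er_percent = m$er, ihc_er_intensity = m$eri,
             ihc_pr_percent = m$pr, ihc_pr_intensity = m$pri,
             ihc_her2 = m$her2, fish_result = m$fish,
             ihc_ki67_percent = m$ki67, ihc_p53 = m$p53, ihc_p16 = m$p16,
             stringsAsFactors = FALSE)
}

# planted positivity flags of an EPH x Ki67 class
.class_flags <- function(cls) {
  g <- (cls - 1L) %/% 2L + 1L
  list(er = g >= 5L, pr = ((g - 1L) %/% 2L) %% 2L == 1L,
       her2 = (g - 1L) %% 2L == 1L, ki67 = cls %% 2L == 0L)
}

#' Generate one synthetic TMA core
#'
#' Draws cell positions from the spec's spatial model (clipped to the 1.1 mm
#' core disc), class labels from the multinomial composition, and raw marker
#' signals from the class-conditional intensity model, such that running the
#' full pipeline (global min-max normalization, size/PCK/annotation gating,
#' thresholding) recovers the planted labels exactly under the default
#' zero-leak model. Each core carries two tiny QC-passing artifact cells
#' (one blank, one saturated on all markers, emulating debris/hot pixels)
#' that pin the dataset-wide dynamic range of every marker. Ground truth is
#' returned in a separate manifest and never written into the cell table.
#'
#' @param spec A [core_spec()].
#' @return List with `cells` (observable columns only), `meta` (one row),
#'   `regions` (a `region_set`, possibly empty) and `truth` (manifest:
#'   populations, intended classes, cluster ids, planted positives).
#' @export
generate_core <- function(spec) {
  stopifnot(inherits(spec, "core_spec"))
  withr::with_seed(spec$seed, .generate_core_impl(spec))
}

.generate_core_impl <- function(spec) {
  im <- spec$im
  mk <- names(im$thresholds)
  R <- 0.5 * spec$core_diameter_um / spec$pixel_size_um
  meta <- .meta_for_subtype(spec$subtype, spec$core_id, spec$case_id,
                            spec$pair_id)

  # population sizes
  p_imm <- c(spec$immune$cd8_frac, spec$immune$cd20_frac)
  p_cancer <- 1 - sum(p_imm) - spec$stroma_frac
  counts <- as.vector(stats::rmultinom(1L, spec$n_cells,
                                       c(p_cancer, p_imm, spec$stroma_frac)))
  n_cancer <- counts[1L]; n_cd8 <- counts[2L]; n_cd20 <- counts[3L]
  n_stroma <- counts[4L]
  pck_gated <- spec$subtype %in% gating_config()$pck_gated_subtypes
  n_benign <- if (pck_gated) round(spec$benign_frac * spec$n_cells) else 0L
  n_qcfail <- round(spec$qc_fail_frac * spec$n_cells)

  # regions: benign-duct exclusion square for PCK-gated cores, tumor
  # inclusion square for annotation-gated (TNBC) cores
  regions <- list()
  benign_poly <- NULL
  if (n_benign > 0L) {
    cx <- R + 0.6 * R; w <- 0.14 * R
    benign_poly <- cbind(c(cx - w, cx + w, cx + w, cx - w),
                         c(R - w, R - w, R + w, R + w))
    regions[[length(regions) + 1L]] <-
      list(label = "exclude_benign", core_id = spec$core_id,
           vertices = benign_poly)
  }
  tumor_poly <- NULL
  if (!pck_gated) {
    w <- 0.6 * R
    tumor_poly <- cbind(c(R - w, R + w, R + w, R - w),
                        c(R - w, R - w, R + w, R + w))
    regions[[length(regions) + 1L]] <-
      list(label = "include_tumor", core_id = spec$core_id,
           vertices = tumor_poly)
  }
  in_disc <- function(x, y) (x - R)^2 + (y - R)^2 <= R^2
  in_benign <- function(x, y) {
    if (is.null(benign_poly)) rep(FALSE, length(x))
    else point_in_polygon(x, y, benign_poly)
  }
  accept_tissue <- function(x, y) in_disc(x, y) & !in_benign(x, y)
  accept_cancer <- if (is.null(tumor_poly)) accept_tissue else {
    function(x, y) accept_tissue(x, y) & point_in_polygon(x, y, tumor_poly)
  }

  # cancer classes and positions
  cls_counts <- as.vector(stats::rmultinom(1L, n_cancer, spec$class_fractions))
  classes <- rep.int(1:16, cls_counts)
  if (length(classes)) classes <- sample(classes)  # shuffle row order
  cluster_id <- rep(NA_integer_, n_cancer)
  if (spec$spatial_model$type == "thomas_cluster" && n_cancer > 0L) {
    sm <- spec$spatial_model
    grp <- if (spec$cluster_by_class) classes else rep(1L, n_cancer)
    th <- .sample_thomas(n_cancer, R, accept_cancer,
                         parent_rate = sm$parent_rate %||% 30,
                         sd_px = sm$cluster_sd_px %||% 60, group = grp)
    xy_cancer <- th$xy; cluster_id <- th$cluster
  } else if (spec$spatial_model$type == "uniform_disc") {
    xy_cancer <- .sample_uniform(n_cancer, R, accept_cancer)
  } else {
    stop(sprintf("unknown spatial model '%s'", spec$spatial_model$type))
  }

  # immune positions
  imm_xy <- function(n) {
    if (n == 0L) return(matrix(numeric(0), 0L, 2L))
    if (identical(spec$immune$pattern, "aggregated")) {
      .sample_thomas(n, R, accept_tissue, parent_rate = 2, sd_px = 40)$xy
    } else {
      .sample_uniform(n, R, accept_tissue)
    }
  }
  xy_cd8 <- imm_xy(n_cd8); xy_cd20 <- imm_xy(n_cd20)
  xy_stroma <- .sample_uniform(n_stroma, R, accept_tissue)
  xy_benign <- if (n_benign > 0L) {
    cbind(stats::runif(n_benign, min(benign_poly[, 1]), max(benign_poly[, 1])),
          stats::runif(n_benign, min(benign_poly[, 2]), max(benign_poly[, 2])))
  } else matrix(numeric(0), 0L, 2L)
  xy_qcfail <- .sample_uniform(n_qcfail, R, accept_tissue)
  xy_art <- matrix(R, 2L, 2L) + cbind(c(-2, 2), c(0, 0))

  population <- c(rep("cancer", n_cancer), rep("CD8", n_cd8),
                  rep("CD20", n_cd20), rep("stroma", n_stroma),
                  rep("benign", n_benign), rep("qcfail", n_qcfail),
                  "artifact_blank", "artifact_saturated")
  xy <- rbind(xy_cancer, xy_cd8, xy_cd20, xy_stroma, xy_benign, xy_qcfail,
              xy_art)
  n_tot <- length(population)

  # planted positivity flags
  pos <- matrix(FALSE, n_tot, length(mk), dimnames = list(NULL, mk))
  is_cancer <- population == "cancer"
  if (n_cancer > 0L) {
    fl <- .class_flags(classes)
    pos[is_cancer, "er"] <- fl$er
    pos[is_cancer, "pr"] <- fl$pr
    pos[is_cancer, "her2"] <- fl$her2
    pos[is_cancer, "ki67"] <- fl$ki67
    p53_rate <- switch(meta$ihc_p53, OE = im$rates$p53_OE,
                       normal = im$rates$p53_normal, null = im$rates$p53_null)
    p16_rate <- switch(meta$ihc_p16, OE = im$rates$p16_OE,
                       normal = im$rates$p16_normal)
    pos[is_cancer, "p53"] <- stats::runif(n_cancer) < p53_rate
    pos[is_cancer, "p16"] <- stats::runif(n_cancer) < p16_rate
    pos[is_cancer, "p21"] <- stats::runif(n_cancer) < im$rates$p21
  }
  pos[population == "CD8", "cd8"] <- TRUE
  pos[population == "CD20", "cd20"] <- TRUE
  pos[population == "benign", c("er", "pr")] <- TRUE
  leaked <- rep(FALSE, n_tot)
  if (spec$leak_rate > 0 && n_cancer > 0L) {
    for (m in c("er", "pr", "her2", "ki67")) {
      flip <- is_cancer & stats::runif(n_tot) < spec$leak_rate
      pos[flip, m] <- !pos[flip, m]
      leaked <- leaked | flip
    }
  }

  # normalized-scale targets -> raw signals
  raw <- matrix(NA_real_, n_tot, length(mk) + 1L,
                dimnames = list(NULL, paste0("raw_", c(mk, "pck"))))
  p53_mode <- if (meta$ihc_p53 == "normal") "normal" else "OE"
  for (m in mk) {
    t <- numeric(n_tot)
    for (v in c(TRUE, FALSE)) {
      idx <- which(pos[, m] == v)
      if (length(idx)) {
        t[idx] <- .draw_targets(m, v, length(idx), im, p53_mode = p53_mode)
      }
    }
    t[population == "artifact_blank"] <- 0
    t[population == "artifact_saturated"] <- 15
    raw[, paste0("raw_", m)] <- t * unname(im$scale[m])
  }
  # PCK gating operates on raw signal: epithelial cells of PCK-gated
  # subtypes sit at or above 1500; TNBC cancer expresses PCK weakly
  pck_raw <- stats::runif(n_tot, 0, 1300)
  epith <- population %in% c("benign") | (is_cancer & pck_gated)
  pck_raw[epith] <- 1500 + stats::rgamma(sum(epith), 2, scale = 800)
  pck_raw[is_cancer & !pck_gated] <- stats::runif(sum(is_cancer & !pck_gated),
                                                  50, 1200)
  pck_raw[population == "artifact_blank"] <- 0
  pck_raw[population == "artifact_saturated"] <- 15 * unname(im$scale["pck"])
  raw[, "raw_pck"] <- pck_raw

  # morphology: cancer-sized cells clear all gates strictly; immune, stroma
  # and artifacts are small and fail the size gate
  big <- population %in% c("cancer", "benign", "qcfail")
  perim <- stats::runif(n_tot, 40, 88)
  area <- stats::runif(n_tot, 150, 395)
  nuc <- stats::runif(n_tot, 3, 9.5)
  nb <- sum(big)
  perim[big] <- 91 + stats::rgamma(nb, 2, scale = 30)
  area[big] <- 401 + stats::rgamma(nb, 2, scale = 150)
  nuc[big] <- 11 + stats::rgamma(nb, 2, scale = 35)
  art <- population %in% c("artifact_blank", "artifact_saturated")
  perim[art] <- 5; area[art] <- 10; nuc[art] <- 1

  cell_id <- sprintf("%s_c%05d", spec$core_id, seq_len(n_tot))
  cells <- data.frame(core_id = spec$core_id, cell_id = cell_id,
                      centroid_x = xy[, 1L], centroid_y = xy[, 2L],
                      perimeter_px = perim, cell_area_px = area,
                      nuclear_area_px = nuc,
                      qc_pass = population != "qcfail",
                      stringsAsFactors = FALSE)
  cells <- cbind(cells, as.data.frame(raw))

  intended_class <- rep(NA_integer_, n_tot)
  intended_class[is_cancer] <- classes
  truth <- list(
    core_id = spec$core_id, subtype = spec$subtype,
    n_cells = spec$n_cells, class_fractions = spec$class_fractions,
    n_cancer = n_cancer, n_cd8 = n_cd8, n_cd20 = n_cd20,
    n_stroma = n_stroma, n_benign = n_benign, n_qcfail = n_qcfail,
    class_counts = stats::setNames(tabulate(classes, 16L),
                                   as.character(1:16)),
    # the saturated artifact cell reads positive on every marker
    n_cd8_pos_all = n_cd8 + 1L, n_cd20_pos_all = n_cd20 + 1L,
    n_all_qc_pass = sum(population != "qcfail"),
    pos_counts = colSums(pos[is_cancer, , drop = FALSE]),
    seed = spec$seed,
    cells = data.frame(cell_id = cell_id, population = population,
                       intended_class = intended_class,
                       cluster = c(cluster_id,
                                   rep(NA_integer_, n_tot - n_cancer)),
                       leaked = leaked, stringsAsFactors = FALSE))
  list(cells = cells, meta = meta,
       regions = structure(regions, class = "region_set"), truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a full synthetic TMA bundle
#'
#' Generates every core of a list of [core_spec()]s and concatenates the
#' cell tables, metadata, annotations and ground-truth manifests. When
#' `seed` is given, each spec's seed is re-derived deterministically from it
#' (keeping derived seeds below 2^31).
#'
#' @param specs List of [core_spec()]s.
#' @param seed Optional integer base seed overriding the specs' seeds.
#' @return List of class `tma_bundle` with `cells`, `meta`, `regions`,
#'   `truth` (per-core manifests plus realized totals).
#' @export
generate_tma <- function(specs, seed = NULL) {
  if (!length(specs)) stop("specs must be a non-empty list of core_spec")
  if (!is.null(seed)) {
    for (i in seq_along(specs)) {
      specs[[i]]$seed <- as.integer((as.numeric(seed) + 104729 * i) %%
                                      2147483647)
    }
  }
  gens <- lapply(specs, generate_core)
  cells <- do.call(rbind, c(lapply(gens, `[[`, "cells"),
                            list(make.row.names = FALSE)))
  meta <- do.call(rbind, c(lapply(gens, `[[`, "meta"),
                           list(make.row.names = FALSE)))
  regions <- do.call(c, lapply(gens, function(g) unclass(g$regions)))
  truth <- lapply(gens, `[[`, "truth")
  names(truth) <- vapply(truth, `[[`, character(1), "core_id")
  structure(list(cells = cells, meta = meta,
                 regions = structure(regions, class = "region_set"),
                 truth = truth),
            class = "tma_bundle")
}

#' @export
print.tma_bundle <- function(x, ...) {
  cat(sprintf("Synthetic TMA bundle: %d cores, %d cases, %d cells\n",
              nrow(x$meta), length(unique(x$meta$case_id)), nrow(x$cells)))
  print(table(vapply(x$truth, `[[`, character(1), "subtype")))
  invisible(x)
}

#' Write a TMA bundle to disk
#'
#' Emits `cells.csv`, `cores.csv`, `regions.geojson` and `truth.json`
#' (ground-truth manifest) into a directory.
#'
#' @param bundle A `tma_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tma_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cell_table(bundle$cells, file.path(dir, "cells.csv"))
  write_core_metadata(bundle$meta, file.path(dir, "cores.csv"))
  write_annotations(bundle$regions, file.path(dir, "regions.geojson"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Standard synthetic TMA scenarios
#'
#' Builds the core specs of three study designs and generates the bundle:
#' \describe{
#' \item{default}{Paired cores per case with the study's paired-case mix
#'   (10 LumA, 15 LumB, 2 LumB-HER2+, 4 HER2+, 10 TNBC cases). A fixed
#'   per-subtype share of cases (6/10, 9/15, 1/2, 4/4, 2/10) carries a
#'   planted 30% composition shift between its two cores (intra-tumoral
#'   heterogeneity); one LumA case is discordant, its second core built
#'   from a LumB spec. Luminal cores use class-pure Thomas clustering;
#'   HER2+ cores are immune-rich with aggregated lymphocytes.}
#' \item{null_pairs}{Every pair shares one composition (no planted shift),
#'   uniform spatial model.}
#' \item{clustered}{All cores Thomas-clustered with class-pure clusters.}
#' }
#'
#' @param name Scenario name.
#' @param seed Integer base seed.
#' @param n_cells Cells per core.
#' @param case_mix Named integer vector of paired cases per subtype.
#' @return A `tma_bundle`.
#' @export
tma_scenario <- function(name = c("default", "null_pairs", "clustered"),
                         seed = 1L, n_cells = 600,
                         case_mix = c(LumA = 10, LumB = 15, LumB_HER2pos = 2,
                                      HER2 = 4, TNBC = 10)) {
  name <- match.arg(name)
  shifted_share <- c(LumA = 6 / 10, LumB = 9 / 15, LumB_HER2pos = 1 / 2,
                     HER2 = 4 / 4, TNBC = 2 / 10)
  specs <- list()
  spot <- 0L
  case_n <- 0L
  for (st in names(case_mix)) {
    n_cases <- case_mix[[st]]
    if (n_cases == 0) next
    n_shift <- if (name == "default") round(shifted_share[[st]] * n_cases) else 0L
    for (k in seq_len(n_cases)) {
      case_n <- case_n + 1L
      case_id <- sprintf("case_%03d", case_n)
      fr <- subtype_class_fractions(st)
      shifted <- name == "default" && k <= n_shift
      discordant <- name == "default" && st == "LumA" && k == n_cases
      clustered <- name == "clustered" ||
        (name == "default" && st %in% c("LumA", "LumB"))
      spatial <- if (clustered) {
        list(type = "thomas_cluster", parent_rate = 40, cluster_sd_px = 50,
             offspring_mean = n_cells / 40)
      } else list(type = "uniform_disc")
      immune <- if (st == "HER2") {
        list(cd8_frac = 0.08, cd20_frac = 0.06,
             pattern = if (k %% 2L == 0L) "aggregated" else "scattered")
      } else list(cd8_frac = 0.03, cd20_frac = 0.02, pattern = "scattered")
      for (side in 1:2) {
        spot <- spot + 1L
        st_side <- if (discordant && side == 2L) "LumB" else st
        fr_side <- if (discordant && side == 2L) subtype_class_fractions("LumB")
          else if (shifted && side == 2L) shift_class_fractions(fr, 0.3)
          else fr
        specs[[spot]] <- core_spec(
          core_id = sprintf("spot_%03d", spot), case_id = case_id,
          pair_id = case_id, subtype = st_side, n_cells = n_cells,
          class_fractions = fr_side, spatial_model = spatial,
          cluster_by_class = clustered, immune = immune)
      }
    }
  }
  generate_tma(specs, seed = seed)
}
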