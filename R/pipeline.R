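#' Pipeline run configuration
#'
#' Bundles every tunable of the analysis: pixel size, marker thresholds,
#' gating, subtype rules, neighborhood radii, diversity species scope, test
#' parameters and the seed. The configuration is serialized into the
#' provenance record of every pipeline run.
#'
#' @param pixel_size_um Pixel size (µm/px).
#' @param thresholds [marker_thresholds()].
#' @param gating [gating_config()].
#' @param rules [subtype_rules()].
#' @param radii_um Neighborhood radii in micrometres.
#' @param species_scope Species scope for equitability (see
#'   [neighborhood_composition()]).
#' @param alpha,n_perm,seed Paired-core test parameters.
#' @return List of class `mxif_config`.
#' @export
mxif_config <- function(pixel_size_um = 0.293,
                        thresholds = marker_thresholds(),
                        gating = gating_config(),
                        rules = subtype_rules(),
                        radii_um = c(30, 100),
                        species_scope = "present_in_core",
                        alpha = 0.01, n_perm = 10000, seed = 1L) {
  stopifnot(pixel_size_um > 0, all(radii_um > 0), alpha > 0, alpha < 1,
            n_perm >= 1)
  structure(list(pixel_size_um = pixel_size_um, thresholds = thresholds,
                 gating = gating, rules = rules, radii_um = radii_um,
                 species_scope = species_scope, alpha = alpha,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "mxif_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields (`pixel_size_um`, `radii_um`, `species_scope`, `alpha`,
#' `n_perm`, `seed`) and the named members of `thresholds`, `gating` and
#' `subtype_rules` override the defaults of [mxif_config()].
#'
#' @param path YAML file.
#' @return An `mxif_config`.
#' @export
mxif_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- do.call(marker_thresholds, as.list(y$thresholds %||% list()))
  gat <- do.call(gating_config, as.list(y$gating %||% list()))
  rul <- do.call(subtype_rules, as.list(y$subtype_rules %||% list()))
  mxif_config(pixel_size_um = y$pixel_size_um %||% 0.293,
              thresholds = thr, gating = gat, rules = rul,
              radii_um = unlist(y$radii_um %||% c(30, 100)),
              species_scope = y$species_scope %||% "present_in_core",
              alpha = y$alpha %||% 0.01, n_perm = y$n_perm %||% 10000,
              seed = y$seed %||% 1L)
}

#' Run the full single-cell heterogeneity analysis
#'
#' Orchestrates the stages on one dataset: surrogate subtyping of cores from
#' IHC scores, global min-max normalization, marker positivity and EPH/Ki67
#' classification, cancer-population gating (size, PCK or annotations),
#' per-core composition summaries, spatial neighborhood and equitability
#' profiles at the configured radii, immune densities and immune
#' neighborhoods (100 µm), the paired-core heterogeneity screen, and the
#' across-subtype / across-central-class ANOVAs. The run is deterministic
#' given the inputs and configuration.
#'
#' @param input A `tma_bundle` (from [generate_tma()] / [tma_scenario()]),
#'   or a named list of file paths `list(cells =, meta =, regions =)`
#'   (regions optional).
#' @param config An [mxif_config()].
#' @param out_dir Optional directory; when given, gated cells, classified
#'   cancer cells, core summaries, profiles, paired-screen results and a
#'   JSON provenance record are written there.
#' @return Object of class `mxif_analysis`.
#' @export
run_mxif_pipeline <- function(input, config = mxif_config(), out_dir = NULL) {
  if (inherits(input, "tma_bundle")) {
    cells <- input$cells; meta <- input$meta; regions <- input$regions
  } else if (is.list(input)) {
    for (p in c(input$cells, input$meta, input$regions)) {
      if (!file.exists(p)) stop(sprintf("input path does not exist: %s", p))
    }
    cells <- read_cell_table(input$cells, schema_config = input$schema_config)
    meta <- read_core_metadata(input$meta)
    regions <- if (!is.null(input$regions)) read_annotations(input$regions)
  } else stop("input must be a tma_bundle or a list of paths")

  log <- list(n_cells_in = nrow(cells), n_cores = nrow(meta))

  if (!"subtype" %in% names(meta) || anyNA(meta$subtype)) {
    meta <- assign_surrogate_subtype(meta, config$rules)
  }
  cells <- normalize_markers(cells)
  cells <- call_positivity(cells, config$thresholds)
  cells$population_label <- ifelse(cells$pos_cd8, "CD8",
                             ifelse(cells$pos_cd20, "CD20", "other"))

  all_cells <- select_all_cells_for_immune(cells)
  cancer <- select_cancer_population(cells, meta, regions, config$gating)
  cancer <- assign_eph(cancer)
  log$gate_log <- attr(cancer, "gate_log")
  log$n_cancer <- nrow(cancer)

  radii_px <- um_to_px(config$radii_um, config$pixel_size_um)
  profiles <- lapply(radii_px, function(r) {
    neighborhood_composition(cancer, "EPH8", radius_px = r,
                             species_scope = config$species_scope)
  })
  names(profiles) <- paste0("r", config$radii_um, "um")

  summaries <- do.call(rbind, c(lapply(meta$core_id, function(cid) {
    s <- summarize_core(cancer[cancer$core_id == cid, , drop = FALSE],
                        all_cells[all_cells$core_id == cid, , drop = FALSE],
                        profiles[[1L]][profiles[[1L]]$core_id == cid, ,
                                       drop = FALSE])
    s$core_id <- cid
    s
  }), list(make.row.names = FALSE)))
  summaries$subtype <- meta$subtype[match(summaries$core_id, meta$core_id)]

  dens <- immune_density(all_cells, config$thresholds)
  imm_prof <- immune_neighborhood(all_cells,
                                  radius_px = um_to_px(100,
                                                       config$pixel_size_um))
  screen <- run_paired_core_screen(cancer, meta, alpha = config$alpha,
                                   n_perm = config$n_perm,
                                   seed = config$seed)

  # class fractions across subtypes, one ANOVA per EPH x Ki67 class
  anova_cls <- do.call(rbind, lapply(1:16, function(k) {
    v <- summaries[[paste0("frac_class_", k)]]
    ok <- is.finite(v)
    if (length(unique(summaries$subtype[ok])) < 2L) {
      return(data.frame(class = k, f = NA_real_, p = NA_real_))
    }
    a <- compare_groups_anova(v[ok], summaries$subtype[ok])
    data.frame(class = k, f = a$f, p = a$p)
  }))
  eh <- profiles[[1L]]
  eh_ok <- !is.na(eh$equitability)
  anova_eh <- if (length(unique(eh$central_class[eh_ok])) >= 2L) {
    compare_groups_anova(eh$equitability[eh_ok], eh$central_class[eh_ok])
  }

  res <- structure(list(meta = meta, all_cells = all_cells, cancer = cancer,
                        summaries = summaries, profiles = profiles,
                        immune_density = dens, immune_profiles = imm_prof,
                        paired_screen = screen,
                        anova_class_fractions = anova_cls,
                        anova_equitability = anova_eh,
                        config = config, log = log),
                   class = "mxif_analysis")
  if (!is.null(out_dir)) write_mxif_analysis(res, out_dir)
  res
}

#' Write pipeline artifacts to a directory
#' @param x An `mxif_analysis`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_mxif_analysis <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cell_table(x$cancer, file.path(dir, "classified_cancer_cells.csv"))
  write_core_summaries(x$summaries, file.path(dir, "core_summaries.csv"))
  for (nm in names(x$profiles)) {
    utils::write.csv(x$profiles[[nm]],
                     file.path(dir, sprintf("profiles_%s.csv", nm)),
                     row.names = FALSE)
  }
  utils::write.csv(x$paired_screen$results, file.path(dir, "paired_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(x$immune_density, file.path(dir, "immune_density.csv"),
                   row.names = FALSE)
  prov <- list(config = unclass_rec(x$config), log = x$log[c("n_cells_in",
                                                             "n_cores",
                                                             "n_cancer")])
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

unclass_rec <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_rec) else unclass(x)
}

#' @export
print.mxif_analysis <- function(x, ...) {
  cat("MxIF single-cell heterogeneity analysis\n")
  cat(sprintf("  cores: %d (%d cases); cells in: %d; cancer cells: %d\n",
              nrow(x$meta), length(unique(x$meta$case_id)),
              x$log$n_cells_in, x$log$n_cancer))
  cat("  subtypes: ")
  print(table(x$meta$subtype))
  cat(sprintf("  paired-core screen: %d/%d cases significant (alpha = %g)\n",
              sum(x$paired_screen$results$significant),
              nrow(x$paired_screen$results), x$config$alpha))
  invisible(x)
}

#' @export
summary.mxif_analysis <- function(object, ...) {
  cat("Per-subtype paired-core heterogeneity:\n")
  print(object$paired_screen$by_subtype, row.names = FALSE)
  cat("\nImmune densities (% of all cells) by subtype:\n")
  d <- object$immune_density
  d$subtype <- object$meta$subtype[match(d$core_id, object$meta$core_id)]
  print(stats::aggregate(cbind(cd8_pct, cd20_pct) ~ subtype, d, mean))
  if (!is.null(object$anova_equitability)) {
    cat(sprintf("\nEquitability across central EPH groups (30 um): F = %.3g, p = %.3g\n",
                object$anova_equitability$f, object$anova_equitability$p))
  }
  invisible(object)
}

#' Stacked per-core class composition plot
#'
#' Barplot of the sixteen EPH x Ki67 class fractions per core, cores
#' grouped by subtype (base graphics).
#'
#' @param x An `mxif_analysis`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.mxif_analysis <- function(x, ...) {
  s <- x$summaries[!x$summaries$empty, , drop = FALSE]
  s <- s[order(s$subtype, s$core_id), , drop = FALSE]
  m <- t(as.matrix(s[, paste0("frac_class_", 1:16)]))
  colnames(m) <- s$core_id
  graphics::barplot(m, col = grDevices::hcl.colors(16, "Spectral"),
                    las = 2, cex.names = 0.5,
                    ylab = "fraction of cancer cells", ...)
  invisible(x)
}
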