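#' @name mxif_io
#' @title Reading and writing MxIF single-cell analysis tables
#'
#' @description
#' Cell tables and core metadata travel as UTF-8 CSV with a header row;
#' region annotations as GeoJSON polygons in pixel coordinates (y increasing
#' downward, image convention). Because deposited cell tables name their
#' columns freely, `read_cell_table()` resolves required columns through a
#' `schema_config` map from canonical names to actual file headers.
#'
#' Canonical cell-table columns: `core_id`, `cell_id`, `centroid_x`,
#' `centroid_y`, `perimeter_px`, `cell_area_px`, `nuclear_area_px`,
#' `raw_<marker>` for every marker in the panel, and optionally `qc_pass`,
#' `norm_<marker>`, `pos_<marker>`, `eph_group`, `eph_ki67_class`,
#' `population_label`.
NULL

.cell_required_cols <- function(markers) {
  c("core_id", "cell_id", "centroid_x", "centroid_y",
    "perimeter_px", "cell_area_px", "nuclear_area_px",
    paste0("raw_", markers))
}

.cell_numeric_cols <- function(cols) {
  grepl("^(centroid_|perimeter_|cell_area_|nuclear_area_|raw_|norm_)", cols) |
    cols %in% c("eph_group", "eph_ki67_class")
}

# strict numeric coercion: a non-missing field that fails to parse is an
# error, never a silent NA
.coerce_numeric <- function(x, col) {
  if (is.numeric(x)) return(x)
  xc <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(xc))
  bad <- which(is.na(out) & !is.na(xc) & nzchar(xc) & toupper(xc) != "NA")
  if (length(bad)) {
    stop(sprintf("column '%s': unparseable numeric value '%s' at row %d",
                 col, xc[bad[1L]], bad[1L]))
  }
  out
}

.coerce_logical <- function(x, col) {
  if (is.logical(x)) return(x)
  xc <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(xc))
  out[xc %in% c("TRUE", "T", "1")] <- TRUE
  out[xc %in% c("FALSE", "F", "0")] <- FALSE
  bad <- which(is.na(out) & !is.na(xc) & nzchar(xc) & xc != "NA")
  if (length(bad)) {
    stop(sprintf("column '%s': unparseable logical value at row %d",
                 col, bad[1L]))
  }
  out
}

#' Read a segmented single-cell table
#'
#' One row per segmented cell. Row order is preserved; unparseable numeric
#' fields raise an error rather than becoming `NA`; a duplicated `cell_id`
#' within a core is an integrity error.
#'
#' @param path CSV file path.
#' @param schema_config Named character vector or list mapping canonical
#'   column names (see [mxif_io]) to the file's actual headers; canonical
#'   names absent from the map are looked up verbatim.
#' @param markers Marker panel expected in the file (`raw_<marker>` columns
#'   required for each).
#' @return A `data.frame` of cells with canonical column names; `qc_pass`
#'   defaults to `TRUE` when the file has no such column.
#' @export
read_cell_table <- function(path, schema_config = NULL,
                            markers = mxif_markers()) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  schema_config <- unlist(schema_config)
  resolve <- function(canon) {
    actual <- if (!is.null(schema_config) && canon %in% names(schema_config))
      schema_config[[canon]] else canon
    if (!actual %in% names(raw)) return(NA_character_)
    actual
  }
  required <- .cell_required_cols(markers)
  optional <- c("qc_pass", paste0("norm_", markers), paste0("pos_", markers),
                "eph_group", "eph_ki67_class", "population_label")
  out <- list()
  for (canon in required) {
    actual <- resolve(canon)
    if (is.na(actual)) {
      stop(sprintf("cell table schema error: required column '%s' not found in '%s'",
                   canon, path))
    }
    out[[canon]] <- raw[[actual]]
  }
  for (canon in optional) {
    actual <- resolve(canon)
    if (!is.na(actual)) out[[canon]] <- raw[[actual]]
  }
  cells <- as.data.frame(out, check.names = FALSE,
                         stringsAsFactors = FALSE)
  for (col in names(cells)) {
    if (.cell_numeric_cols(col)) {
      cells[[col]] <- .coerce_numeric(cells[[col]], col)
    } else if (col == "qc_pass" || grepl("^pos_", col)) {
      cells[[col]] <- .coerce_logical(cells[[col]], col)
    } else {
      cells[[col]] <- as.character(cells[[col]])
    }
  }
  if (!"qc_pass" %in% names(cells)) cells$qc_pass <- TRUE
  key <- paste(cells$core_id, cells$cell_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop(sprintf("cell table integrity error: duplicate cell_id within core (%s)",
                 sub("\r", " / ", d, fixed = TRUE)))
  }
  bad_raw <- vapply(markers, function(m) any(cells[[paste0("raw_", m)]] < 0,
                                             na.rm = TRUE), logical(1))
  if (any(bad_raw)) {
    stop(sprintf("negative raw signal for marker(s): %s",
                 paste(markers[bad_raw], collapse = ", ")))
  }
  rownames(cells) <- NULL
  cells
}

#' Write a cell table to CSV
#'
#' @param cells Cell `data.frame` (canonical columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, na = "NA")
  invisible(path)
}

.her2_levels <- c("0", "1+", "2+", "3+")
.intensity_levels <- c("neg", "weak", "moderate", "strong")

#' Validate core metadata consistency
#'
#' Checks percents within \[0, 100\], categorical fields within their
#' vocabularies, and that every HER2 IHC 2+ (equivocal) core carries a FISH
#' result (equivocal cases are resolved by fluorescence in situ
#' hybridization before subtyping).
#'
#' @param meta Core metadata `data.frame`.
#' @return `meta`, invisibly, or an error.
#' @export
validate_core_metadata <- function(meta) {
  req <- c("core_id", "case_id", "pair_id",
           "ihc_er_percent", "ihc_er_intensity",
           "ihc_pr_percent", "ihc_pr_intensity",
           "ihc_her2", "fish_result", "ihc_ki67_percent",
           "ihc_p53", "ihc_p16")
  missing <- setdiff(req, names(meta))
  if (length(missing)) {
    stop(sprintf("core metadata schema error: required column '%s' not found",
                 missing[1L]))
  }
  if (anyDuplicated(meta$core_id)) stop("duplicate core_id in core metadata")
  chk_pct <- function(col) {
    v <- meta[[col]]
    if (any(!is.finite(v) | v < 0 | v > 100)) {
      stop(sprintf("column '%s': percent outside [0, 100]", col))
    }
  }
  chk_pct("ihc_er_percent"); chk_pct("ihc_pr_percent")
  chk_pct("ihc_ki67_percent")
  chk_cat <- function(col, levels) {
    bad <- !meta[[col]] %in% levels
    if (any(bad)) {
      stop(sprintf("column '%s': value '%s' not one of {%s}", col,
                   meta[[col]][bad][1L], paste(levels, collapse = ", ")))
    }
  }
  chk_cat("ihc_her2", .her2_levels)
  chk_cat("ihc_er_intensity", .intensity_levels)
  chk_cat("ihc_pr_intensity", .intensity_levels)
  chk_cat("ihc_p53", c("normal", "null", "OE"))
  chk_cat("ihc_p16", c("normal", "OE"))
  chk_cat("fish_result", c("amplified", "not_amplified", NA))
  unresolved <- meta$ihc_her2 == "2+" &
    (is.na(meta$fish_result) | !meta$fish_result %in% c("amplified", "not_amplified"))
  if (any(unresolved)) {
    stop(sprintf("core '%s': HER2 IHC 2+ (equivocal) requires a FISH result",
                 meta$core_id[unresolved][1L]))
  }
  invisible(meta)
}

#' Read per-core IHC metadata
#'
#' One row per TMA core: case/pair linkage, ER/PR percent and intensity
#' category, HER2 0/1+/2+/3+ with FISH resolution of equivocal 2+ cases,
#' Ki67 percent, P53 status (normal/null/OE), P16 status (normal/OE), and
#' optionally a pre-assigned `subtype`.
#'
#' @param path CSV file path.
#' @return Validated core metadata `data.frame`.
#' @export
read_core_metadata <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (col in c("ihc_er_percent", "ihc_pr_percent", "ihc_ki67_percent")) {
    if (col %in% names(meta)) meta[[col]] <- .coerce_numeric(meta[[col]], col)
  }
  if ("fish_result" %in% names(meta)) {
    meta$fish_result[meta$fish_result %in% c("", "NA")] <- NA_character_
  }
  if ("subtype" %in% names(meta)) {
    meta$subtype[meta$subtype %in% c("", "NA")] <- NA_character_
  }
  validate_core_metadata(meta)
  rownames(meta) <- NULL
  meta
}

#' Write core metadata to CSV
#' @param meta Core metadata `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_core_metadata <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, na = "NA")
  invisible(path)
}

.region_labels <- c("exclude_benign", "include_tumor")

#' Read region annotations from GeoJSON
#'
#' Expects a `FeatureCollection` of `Polygon` features in pixel coordinates,
#' each with a `label` property (`exclude_benign` for benign ducts to drop,
#' `include_tumor` for annotated TNBC tumor regions) and a `core_id`
#' property tying the region to its TMA core. Rings must be explicitly
#' closed and simple; only the outer ring is used.
#'
#' @param path GeoJSON file path.
#' @return A `region_set`: list of regions, each with `label`, `core_id`
#'   and a two-column `vertices` matrix (closing vertex removed).
#' @export
read_annotations <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("annotation file must be a GeoJSON FeatureCollection")
  }
  regions <- lapply(gj$features, function(f) {
    label <- f$properties$label
    if (is.null(label) || !label %in% .region_labels) {
      stop(sprintf("unknown annotation label '%s'; allowed labels: %s",
                   if (is.null(label)) "<missing>" else label,
                   paste(.region_labels, collapse = ", ")))
    }
    core_id <- f$properties$core_id
    if (is.null(core_id)) core_id <- NA_character_
    if (is.null(f$geometry$type) || f$geometry$type != "Polygon") {
      stop("annotation features must have Polygon geometry")
    }
    ring <- f$geometry$coordinates[[1L]]
    verts <- do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
    n <- nrow(verts)
    if (n < 4L || !all(verts[1L, ] == verts[n, ])) {
      stop("annotation polygon ring is open (first and last vertex must coincide)")
    }
    verts <- verts[-n, , drop = FALSE]
    if (nrow(verts) < 3L) stop("annotation polygon must have >= 3 vertices")
    if (!polygon_is_simple(verts)) {
      stop("annotation polygon is self-intersecting")
    }
    list(label = label, core_id = as.character(core_id), vertices = verts)
  })
  structure(regions, class = "region_set")
}

#' Write region annotations to GeoJSON
#' @param regions A `region_set` (see [read_annotations()]).
#' @param path Output GeoJSON path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(regions, path) {
  features <- lapply(regions, function(r) {
    ring <- rbind(r$vertices, r$vertices[1L, , drop = FALSE])
    list(type = "Feature",
         properties = list(label = r$label, core_id = r$core_id),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Subset a region set by core and label
#' @param regions A `region_set` or `NULL`.
#' @param core_id Core to keep.
#' @param label Optional label filter.
#' @return List of matching regions (possibly empty).
#' @export
regions_for_core <- function(regions, core_id, label = NULL) {
  if (is.null(regions)) return(list())
  keep <- vapply(regions, function(r) {
    (is.na(r$core_id) || r$core_id == core_id) &&
      (is.null(label) || r$label == label)
  }, logical(1))
  regions[keep]
}

#' Write per-core summaries to CSV
#'
#' Deterministic column order: identifiers and subtype, the sixteen
#' EPH x Ki67 class fractions, positive fractions of Ki67/P53/P16/P21,
#' CD8/CD20 densities, normalized P53/P16/P21 quantiles, then mean Shannon
#' equitability per central EPH group.
#'
#' @param summaries `data.frame` as assembled from [summarize_core()] rows.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_core_summaries <- function(summaries, path) {
  lead <- intersect(c("core_id", "subtype", "n_cancer_cells", "empty"),
                    names(summaries))
  frac <- grep("^frac_class_", names(summaries), value = TRUE)
  frac <- frac[order(as.integer(sub("frac_class_", "", frac)))]
  pos <- intersect(paste0("pos_frac_", c("ki67", "p53", "p16", "p21")),
                   names(summaries))
  dens <- intersect(c("cd8_pct", "cd20_pct"), names(summaries))
  quant <- grep("^(p53|p16|p21)_q", names(summaries), value = TRUE)
  eh <- grep("^eh_eph", names(summaries), value = TRUE)
  rest <- setdiff(names(summaries), c(lead, frac, pos, dens, quant, eh))
  utils::write.csv(summaries[, c(lead, frac, pos, dens, quant, eh, rest)],
                   path, row.names = FALSE, na = "NA")
  invisible(path)
}
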