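#' Radius neighbors of every cell
#'
#' For each cell, the indices of all other cells whose centroid lies within
#' `radius_px` (Euclidean, inclusive: a pair at exactly the radius are
#' neighbors). The cell itself is excluded. Implemented with a grid-bucket
#' spatial index (bucket width = radius, 3 x 3 bucket sweep), which is exact
#' and equivalent to the quadratic all-pairs scan.
#'
#' @param x,y Numeric centroid coordinates in pixels.
#' @param radius_px Search radius in pixels (> 0).
#' @return List of length `length(x)`; element `i` is the sorted integer
#'   vector of neighbor indices of cell `i`.
#' @examples
#' nb <- find_neighbors(c(0, 50, 200), c(0, 0, 0), 100)
#' nb[[1]]  # 2
#' nb[[3]]  # integer(0)
#' @export
find_neighbors <- function(x, y, radius_px) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (!is.finite(radius_px) || radius_px <= 0) stop("radius_px must be > 0")
  out <- rep(list(integer(0)), n)
  if (n < 2L) return(out)
  r2 <- radius_px * radius_px
  ix <- floor(x / radius_px)
  iy <- floor(y / radius_px)
  key <- paste(ix, iy, sep = ",")
  bins <- split(seq_len(n), key)
  for (b in bins) {
    bx <- ix[b[1L]]; by <- iy[b[1L]]
    cand <- integer(0)
    for (dx in -1L:1L) {
      for (dy in -1L:1L) {
        nb <- bins[[paste(bx + dx, by + dy, sep = ",")]]
        if (!is.null(nb)) cand <- c(cand, nb)
      }
    }
    cx <- x[cand]; cy <- y[cand]
    for (i in b) {
      d2 <- (cx - x[i])^2 + (cy - y[i])^2
      hit <- cand[d2 <= r2]
      out[[i]] <- sort(hit[hit != i])
    }
  }
  out
}

#' Shannon equitability index
#'
#' Shannon diversity `H = -sum(p_i * log(p_i))` over classes with positive
#' count, divided by the maximum diversity `log(s)` for `s` species. The
#' index lies in \[0, 1\]: 1 when all `s` species are present in equal
#' abundance, 0 for a single species (the `s = 1` case is defined as 0,
#' since a one-species neighborhood has no diversity).
#'
#' @param counts Nonnegative numeric vector of per-class counts; at least
#'   one must be positive.
#' @param s Number of species defining maximum diversity; defaults to the
#'   number of classes with positive count.
#' @return The equitability index in \[0, 1\].
#' @examples
#' shannon_equitability(c(5, 5, 5, 5))        # 1
#' shannon_equitability(10)                   # 0
#' shannon_equitability(c(3, 1))              # ~0.8113
#' @export
shannon_equitability <- function(counts, s = sum(counts > 0)) {
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and nonnegative")
  }
  tot <- sum(counts)
  if (tot <= 0) stop("all-zero counts: equitability undefined")
  if (s < 1) stop("s must be >= 1")
  if (s == 1) return(0)
  p <- counts[counts > 0] / tot
  h <- -sum(p * log(p))
  min(1, h / log(s))
}

.scheme_classes <- function(cells, class_scheme) {
  switch(class_scheme,
    EPH8 = list(cls = as.character(cells$eph_group),
                levels = as.character(1:8)),
    EPHKi67_16 = list(cls = as.character(cells$eph_ki67_class),
                      levels = as.character(1:16)),
    immune3 = {
      lab <- cells$population_label
      cls <- ifelse(lab %in% c("CD8", "CD20"), lab, "cancer")
      list(cls = cls, levels = c("cancer", "CD8", "CD20"))
    },
    stop(sprintf("unknown class scheme '%s'", class_scheme))
  )
}

#' Neighborhood composition and diversity per cell
#'
#' For each cell of each core, counts its neighbors within `radius_px` by
#' class under the chosen scheme (`EPH8` groups, `EPHKi67_16` classes, or
#' `immune3` = cancer/CD8/CD20 with every non-immune cell counted as
#' cancer), derives the class fractions, and computes the Shannon
#' equitability of the neighborhood. Cells with no neighbors get an
#' undefined (NA) profile. The species count for equitability defaults to
#' the classes present in the core, making the index comparable across
#' central classes within a core; alternatives are the classes present in
#' the neighborhood itself or the full fixed panel.
#'
#' @param cells Classified cell `data.frame` (one or more cores).
#' @param class_scheme `"EPH8"`, `"EPHKi67_16"` or `"immune3"`.
#' @param radius_px Neighborhood radius in pixels (conventionally 100 px =
#'   30 um or 341 px = 100 um).
#' @param species_scope `"present_in_core"` (default),
#'   `"present_in_neighborhood"` or `"fixed_panel"`.
#' @return `data.frame` with one row per cell: `core_id`, `cell_id`,
#'   `central_class`, `radius_px`, `n_neighbors`, `count_<class>` and
#'   `frac_<class>` per scheme class, and `equitability`.
#' @export
neighborhood_composition <- function(cells, class_scheme = "EPH8",
                                     radius_px = 100,
                                     species_scope = c("present_in_core",
                                                       "present_in_neighborhood",
                                                       "fixed_panel")) {
  species_scope <- match.arg(species_scope)
  res <- lapply(split(seq_len(nrow(cells)), cells$core_id), function(idx) {
    cc <- cells[idx, , drop = FALSE]
    sc <- .scheme_classes(cc, class_scheme)
    cls <- factor(sc$cls, levels = sc$levels)
    if (anyNA(cls)) stop("cells carry class labels outside the chosen scheme")
    nb <- find_neighbors(cc$centroid_x, cc$centroid_y, radius_px)
    counts <- t(vapply(nb, function(j) tabulate(cls[j], nbins = length(sc$levels)),
                       integer(length(sc$levels))))
    colnames(counts) <- sc$levels
    nn <- rowSums(counts)
    fr <- counts / ifelse(nn > 0, nn, NA_real_)
    s_core <- sum(tabulate(cls, nbins = length(sc$levels)) > 0)
    eh <- vapply(seq_len(nrow(cc)), function(i) {
      if (nn[i] == 0) return(NA_real_)
      s <- switch(species_scope,
                  present_in_core = s_core,
                  present_in_neighborhood = sum(counts[i, ] > 0),
                  fixed_panel = length(sc$levels))
      shannon_equitability(counts[i, ], s = s)
    }, numeric(1))
    out <- data.frame(core_id = cc$core_id, cell_id = cc$cell_id,
                      central_class = as.character(cls),
                      radius_px = radius_px, n_neighbors = nn,
                      stringsAsFactors = FALSE)
    out[paste0("count_", sc$levels)] <- as.data.frame(counts)
    out[paste0("frac_", sc$levels)] <- as.data.frame(fr)
    out$equitability <- eh
    out
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  attr(out, "class_scheme") <- class_scheme
  out
}

#' Mean and spread of equitability per central class
#'
#' Aggregates [neighborhood_composition()] profiles by central class,
#' excluding undefined (neighborless) profiles.
#'
#' @param profiles Output of [neighborhood_composition()].
#' @return `data.frame` with `central_class`, `n` (defined profiles),
#'   `mean_eh`, `sd_eh` (`NA` when `n < 2`).
#' @export
aggregate_equitability <- function(profiles) {
  def <- profiles[!is.na(profiles$equitability), , drop = FALSE]
  classes <- unique(profiles$central_class)
  out <- do.call(rbind, lapply(classes, function(cl) {
    v <- def$equitability[def$central_class == cl]
    data.frame(central_class = cl, n = length(v),
               mean_eh = if (length(v)) mean(v) else NA_real_,
               sd_eh = if (length(v) >= 2L) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cumulative neighborhood profile across cores
#'
#' Pools neighbor counts over all cells of each central class across the
#' supplied profiles (typically several cores of one subtype) and
#' row-normalizes, giving the overall proportion of each neighbor class
#' around each central class.
#'
#' @param profiles Output of [neighborhood_composition()] (one or more
#'   cores, same scheme).
#' @return Square matrix, central class x neighbor class; each row with any
#'   neighbors sums to 1, rows without neighbors are `NA`.
#' @export
cumulative_neighborhood_profile <- function(profiles) {
  cnt_cols <- grep("^count_", names(profiles), value = TRUE)
  levels <- sub("^count_", "", cnt_cols)
  mat <- matrix(0, length(levels), length(levels),
                dimnames = list(central = levels, neighbor = levels))
  for (cl in levels) {
    rows <- profiles$central_class == cl
    mat[cl, ] <- colSums(profiles[rows, cnt_cols, drop = FALSE])
  }
  tot <- rowSums(mat)
  sweep_na <- mat / ifelse(tot > 0, tot, NA_real_)
  sweep_na
}

#' Immune-cell neighborhood composition
#'
#' Classifies every cell as cancer, CD8 or CD20 (`immune3` scheme) and
#' returns, for each central CD8 or CD20 lymphocyte, the composition of its
#' neighborhood within `radius_px` (default 341 px = 100 um). Isolated
#' immune cells have an undefined profile.
#'
#' @param cells All QC-passing segmented cells with `population_label` set
#'   (`"CD8"`, `"CD20"`, anything else counts as cancer).
#' @param radius_px Neighborhood radius in pixels.
#' @return [neighborhood_composition()] rows restricted to immune central
#'   cells.
#' @export
immune_neighborhood <- function(cells, radius_px = 341) {
  prof <- neighborhood_composition(cells, class_scheme = "immune3",
                                   radius_px = radius_px)
  prof[prof$central_class %in% c("CD8", "CD20"), , drop = FALSE]
}
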