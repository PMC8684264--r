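#' Point-in-polygon test (inclusive boundary)
#'
#' Even-odd (ray casting) containment test in image pixel coordinates
#' (y increasing downward; the test is orientation-agnostic). Points lying
#' exactly on a polygon edge or vertex count as inside, so that inclusion
#' gating is deterministic and conservative.
#'
#' @param x,y Numeric vectors of point coordinates (pixels).
#' @param polygon Two-column numeric matrix of vertices. A closing vertex
#'   equal to the first may be present but is not required.
#' @return Logical vector, `TRUE` where the point is inside or on the
#'   boundary.
#' @export
point_in_polygon <- function(x, y, polygon) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L) {
    stop("polygon must be a matrix of >= 3 vertices with 2 columns")
  }
  # drop explicit closing vertex
  n <- nrow(polygon)
  if (all(polygon[1L, ] == polygon[n, ])) polygon <- polygon[-n, , drop = FALSE]
  n <- nrow(polygon)
  if (n < 3L) stop("polygon must have >= 3 distinct vertices")
  px <- polygon[, 1L]; py <- polygon[, 2L]
  qx <- c(px[-1L], px[1L]); qy <- c(py[-1L], py[1L])

  m <- length(x)
  inside <- logical(m)
  on_edge <- logical(m)
  for (e in seq_len(n)) {
    x1 <- px[e]; y1 <- py[e]; x2 <- qx[e]; y2 <- qy[e]
    # boundary: collinear and within the segment's bounding box
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    onb <- cross == 0 &
      x >= pmin(x1, x2) & x <= pmax(x1, x2) &
      y >= pmin(y1, y2) & y <= pmax(y1, y2)
    on_edge <- on_edge | onb
    # even-odd crossing with the half-open rule on y
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

# orientation of ordered triple (a, b, c): >0 counter-clockwise in math axes
.orient <- function(ax, ay, bx, by, cx, cy) {
  sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
}

# do closed segments p1-p2 and p3-p4 intersect?
.segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- .orient(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- .orient(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- .orient(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- .orient(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  if (d1 != d2 && d3 != d4) return(TRUE)
  on_seg <- function(p, a, b) {
    .orient(a[1], a[2], b[1], b[2], p[1], p[2]) == 0 &&
      p[1] >= min(a[1], b[1]) && p[1] <= max(a[1], b[1]) &&
      p[2] >= min(a[2], b[2]) && p[2] <= max(a[2], b[2])
  }
  on_seg(p1, p3, p4) || on_seg(p2, p3, p4) ||
    on_seg(p3, p1, p2) || on_seg(p4, p1, p2)
}

#' Is a polygon simple (non-self-intersecting)?
#'
#' Checks every pair of non-adjacent edges for intersection (O(m^2), fine
#' for hand-drawn annotation polygons).
#'
#' @param polygon Two-column vertex matrix, closing vertex optional.
#' @return `TRUE` for a simple polygon, `FALSE` e.g. for a bowtie.
#' @export
polygon_is_simple <- function(polygon) {
  polygon <- as.matrix(polygon)
  n <- nrow(polygon)
  if (n >= 2L && all(polygon[1L, ] == polygon[n, ])) {
    polygon <- polygon[-n, , drop = FALSE]
  }
  n <- nrow(polygon)
  if (n < 3L) return(FALSE)
  edges <- cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      # adjacent edges (sharing a vertex) legitimately touch
      shared <- length(intersect(edges[i, ], edges[j, ])) > 0L
      if (shared) next
      if (.segments_intersect(polygon[edges[i, 1L], ], polygon[edges[i, 2L], ],
                              polygon[edges[j, 1L], ], polygon[edges[j, 2L], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}
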