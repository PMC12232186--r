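# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Point-in-polygon, boundary inclusive (even-odd rule with an explicit
# on-segment check). `points` is an n x 2 matrix, `poly` an m x 2 matrix of
# vertices (closed implicitly). Returns a logical vector.
point_in_polygon <- function(points, poly, eps = 1e-9) {
  stopifnot(is.matrix(points), ncol(points) == 2L,
            is.matrix(poly), ncol(poly) == 2L, nrow(poly) >= 3L)
  px <- points[, 1L]; py <- points[, 2L]
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    x1 <- poly[j, 1L]; y1 <- poly[j, 2L]
    x2 <- poly[i, 1L]; y2 <- poly[i, 2L]
    # on-segment: collinear and within bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    collin <- abs(cross) <= eps * max(1, sqrt(seg_len2))
    within <- px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    on_edge <- on_edge | (collin & within)
    # ray casting (horizontal ray to +x)
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xint))
    }
  }
  inside | on_edge
}

# Shoelace area of a simple polygon (absolute value).
polygon_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Convert an internal [y, x] matrix to an EBImage Image (x, y) and back.
as_ebimage <- function(m) EBImage::Image(t(m))
from_ebimage <- function(img) t(EBImage::imageData(img))

# Clamp helper
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Angle (degrees) between two vectors
vector_angle_deg <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(clamp(ca, -1, 1)) * 180 / pi
}
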