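# Internal planar geometry: point-to-polyline/polygon distances, rim normals,
# point-in-polygon. Coordinates are n x 2 matrices in micrometres throughout.

as_xy_matrix <- function(x, arg = "coordinates") {
  if (is.data.frame(x)) {
    cols <- intersect(c("x_um", "y_um"), names(x))
    if (length(cols) == 2L) x <- as.matrix(x[, cols]) else x <- as.matrix(x[, c("x", "y")])
  }
  x <- matrix(as.numeric(x), ncol = 2L)
  if (!all(is.finite(x))) stop(arg, " must contain finite coordinates")
  x
}

# Distances from points (n x 2) to one segment a-b; returns list(dist, t)
# with t the clamped projection parameter.
.seg_dist <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    d <- sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2)
    return(list(dist = d, t = rep(0, nrow(pts))))
  }
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  fx <- a[1] + t * ab[1]
  fy <- a[2] + t * ab[2]
  list(dist = sqrt((pts[, 1] - fx)^2 + (pts[, 2] - fy)^2), t = t)
}

# Minimum distance from each point to a polyline (closed = polygon boundary).
dist_to_boundary <- function(points, vertices, closed = FALSE) {
  pts <- as_xy_matrix(points)
  v <- as_xy_matrix(vertices, "vertices")
  n <- nrow(v)
  if (n < 2L) stop("boundary needs at least 2 vertices")
  idx_from <- if (closed) seq_len(n) else seq_len(n - 1L)
  idx_to <- if (closed) c(seq_len(n)[-1L], 1L) else seq_len(n)[-1L]
  d <- rep(Inf, nrow(pts))
  for (k in seq_along(idx_from)) {
    d <- pmin(d, .seg_dist(pts, v[idx_from[k], ], v[idx_to[k], ])$dist)
  }
  d
}

# Nearest point on an open polyline to a single point, with the local unit
# normal. On a vertex shared by two segments the angle-bisector normal of the
# adjacent segments is used, so the normal field is continuous along the rim.
nearest_rim_point <- function(point, vertices) {
  p <- as.numeric(point)
  v <- as_xy_matrix(vertices, "rim")
  n <- nrow(v)
  best <- list(dist = Inf, foot = NULL, seg = NA_integer_, t = NA_real_)
  pm <- matrix(p, 1L, 2L)
  for (k in seq_len(n - 1L)) {
    s <- .seg_dist(pm, v[k, ], v[k + 1L, ])
    if (s$dist < best$dist) {
      ab <- v[k + 1L, ] - v[k, ]
      best <- list(dist = s$dist, foot = v[k, ] + s$t * ab, seg = k, t = s$t)
    }
  }
  seg_normal <- function(k) {
    ab <- v[k + 1L, ] - v[k, ]
    nrm <- c(-ab[2], ab[1])
    nrm / sqrt(sum(nrm^2))
  }
  tol <- 1e-12
  k <- best$seg
  at_start <- best$t < tol
  at_end <- best$t > 1 - tol
  if (at_start && k > 1L) {
    nrm <- seg_normal(k - 1L) + seg_normal(k)
  } else if (at_end && k < n - 1L) {
    nrm <- seg_normal(k) + seg_normal(k + 1L)
  } else {
    nrm <- seg_normal(k)
  }
  len <- sqrt(sum(nrm^2))
  if (len < tol) nrm <- seg_normal(k) else nrm <- nrm / len
  list(foot = as.numeric(best$foot), normal = nrm, dist = best$dist)
}

# Unit rim normal at the rim point nearest to `point`, oriented so that it
# points toward the wound side.
rim_normal_toward <- function(point, vertices, wound_side_point) {
  nr <- nearest_rim_point(point, vertices)
  w <- as.numeric(wound_side_point) - nr$foot
  if (sum(w^2) == 0) stop("wound_side_point lies on the rim")
  if (sum(nr$normal * w) < 0) nr$normal <- -nr$normal
  nr
}

# Signed angle in degrees from vector u to vector v, in (-180, 180].
signed_angle_deg <- function(u, v) {
  ang <- atan2(u[1] * v[2] - u[2] * v[1], u[1] * v[1] + u[2] * v[2]) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Even-odd ray casting; boundary points may fall on either side but the rim
# itself has measure zero for the point patterns handled here.
point_in_polygon <- function(points, vertices) {
  pts <- as_xy_matrix(points)
  v <- as_xy_matrix(vertices, "polygon")
  n <- nrow(v)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

polygon_area <- function(vertices) {
  v <- as_xy_matrix(vertices, "polygon")
  n <- nrow(v)
  j <- c(seq_len(n)[-1L], 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

# Regular polygon used as the default injection-site rim.
regular_polygon <- function(radius, n_vertices = 64L, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(x_um = center[1] + radius * cos(th), y_um = center[2] + radius * sin(th))
}
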