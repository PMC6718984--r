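# Independent brute-force oracles used across tests. These deliberately use
# naive enumeration rather than the package's own code paths.

# Exact perinuclear band by pairwise pixel distances (O(n^2), small images).
brute_force_band <- function(mask, pixel_size, band_um) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (nrow(idx) == 0) return(out)
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j]) next
      dmin <- sqrt(min((idx[, 1] - i)^2 + (idx[, 2] - j)^2)) * pixel_size
      out[i, j] <- dmin <= band_um
    }
  }
  out
}

# Bin assignment by explicit comparison against bin edges (right-closed
# intervals, except bin 1 which also contains 0).
brute_force_bins <- function(d, D, n_bins) {
  edges <- seq(0, D, length.out = n_bins + 1)
  vapply(d, function(x) {
    for (b in seq_len(n_bins)) {
      if ((x > edges[b] || (b == 1 && x == 0)) && x <= edges[b + 1]) return(b)
    }
    NA_integer_
  }, integer(1))
}

# 2x2 rigid transform applied to an n x 2 coordinate matrix.
rigid_transform <- function(xy, angle_deg, shift) {
  a <- angle_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  sweep(as.matrix(xy) %*% t(R), 2, -shift)
}

# Apply a rigid transform to every geometric element of a scratch field.
transform_field <- function(field, angle_deg, shift) {
  tf <- function(m) {
    out <- rigid_transform(as_mat(m), angle_deg, shift)
    data.frame(id = seq_len(nrow(out)), x_um = out[, 1], y_um = out[, 2])
  }
  as_mat <- function(m) {
    if (is.data.frame(m)) as.matrix(m[, c("x_um", "y_um")]) else as.matrix(m)
  }
  field$nuclei <- tf(field$nuclei)
  field$golgi <- tf(field$golgi)
  field$rim <- rigid_transform(as_mat(field$rim), angle_deg, shift)
  field$wound_side_point <- drop(rigid_transform(matrix(field$wound_side_point, 1),
                                                 angle_deg, shift))
  field
}
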