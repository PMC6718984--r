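#' Pair Golgi centroids with their nearest nuclei
#'
#' Each Golgi centroid is assigned to the nucleus whose centroid is nearest
#' in Euclidean distance. When two Golgi map to the same nucleus only the
#' nearer pair is kept and the other Golgi is flagged; nuclei that receive no
#' Golgi are excluded from polarity scoring and counted (cells without a
#' visible Golgi do not enter the analysis).
#'
#' @param nuclei,golgi Data frames with columns `x_um`, `y_um` (an `id`
#'   column is used if present, otherwise row order).
#' @return List with `pairs` (data frame `nucleus_id`, `golgi_id`,
#'   `separation_um`), `unmatched_nuclei` (ids), and `flagged_golgi` (ids of
#'   Golgi displaced by a nearer competitor).
#' @examples
#' assign_golgi(data.frame(x_um = 0, y_um = 0), data.frame(x_um = 3, y_um = 4))
#' @export
assign_golgi <- function(nuclei, golgi) {
  if (is.null(nuclei) || nrow(as.data.frame(nuclei)) == 0) stop("empty nuclei list")
  nuclei <- as.data.frame(nuclei)
  golgi <- as.data.frame(golgi)
  nid <- if ("id" %in% names(nuclei)) nuclei$id else seq_len(nrow(nuclei))
  gid <- if ("id" %in% names(golgi)) golgi$id else seq_len(nrow(golgi))
  if (nrow(golgi) == 0) {
    return(list(pairs = data.frame(nucleus_id = integer(), golgi_id = integer(),
                                   separation_um = numeric()),
                unmatched_nuclei = nid, flagged_golgi = gid[0]))
  }
  nx <- as_xy_matrix(nuclei)
  gx <- as_xy_matrix(golgi)
  d2 <- outer(gx[, 1], nx[, 1], "-")^2 + outer(gx[, 2], nx[, 2], "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  sep <- sqrt(d2[cbind(seq_len(nrow(gx)), nearest)])
  keep <- rep(TRUE, nrow(gx))
  for (n in unique(nearest)) {
    grp <- which(nearest == n)
    if (length(grp) > 1L) keep[grp[-which.min(sep[grp])]] <- FALSE
  }
  pairs <- data.frame(nucleus_id = nid[nearest[keep]], golgi_id = gid[keep],
                      separation_um = sep[keep])
  list(pairs = pairs,
       unmatched_nuclei = setdiff(nid, pairs$nucleus_id),
       flagged_golgi = gid[!keep])
}

#' Polarity angle of a nucleus-Golgi axis relative to the scratch
#'
#' The migration direction of a cell is taken as the vector from the nucleus
#' centroid to its Golgi centroid. The angle is measured against the rim
#' normal at the rim point nearest to the nucleus, oriented toward the wound
#' side: 0 degrees means the cell points straight at the scratch.
#'
#' @param nucleus,golgi Numeric length-2 points (um).
#' @param rim Rim polyline, two-column matrix of ordered vertices (um).
#' @param wound_side_point A point on the wound side of the rim.
#' @return Signed angle in degrees in `(-180, 180]`, or `NA` with a
#'   `"zero_length_axis"` attribute when the Golgi coincides with the nucleus
#'   (such cells are excluded with a reason code by [polarity_analysis()]).
#' @examples
#' rim <- cbind(c(0, 0), c(-50, 50))
#' polarity_angle(c(-10, 0), c(-5, 0), rim, wound_side_point = c(10, 0)) # 0
#' @export
polarity_angle <- function(nucleus, golgi, rim, wound_side_point) {
  v <- as.numeric(golgi) - as.numeric(nucleus)
  if (sqrt(sum(v^2)) < .Machine$double.eps) {
    return(structure(NA_real_, reason = "zero_length_axis"))
  }
  nr <- rim_normal_toward(nucleus, rim, wound_side_point)
  signed_angle_deg(nr$normal, v)
}

#' Classify polarized cells and test against the uniform sector null
#'
#' A cell is polarized when its angle lies within the wound-facing sector
#' (`|theta| <= sector_halfwidth`, boundary inclusive). Under uniform
#' directions the sector captures `2 * sector_halfwidth / 360` of cells --
#' one third for the default 60-degree half-width -- so the test is a
#' two-class chi-squared goodness of fit against expected counts `n/3`
#' (polarized) and `2n/3` (not polarized), df = 1, upper-tail p, no
#' continuity correction by default.
#'
#' @param angles Numeric vector of polarity angles in degrees; `NA` entries
#'   are dropped (excluded cells).
#' @param sector_halfwidth Sector half-width in degrees (default 60).
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return A `polarity_result` list: `n_total`, `n_polarized`,
#'   `expected_polarized`, `chi2`, `p_value`, `excluded`.
#' @examples
#' classify_and_test(c(0, 30, -45, 120, 170, -100))
#' @export
classify_and_test <- function(angles, sector_halfwidth = 60, correct = FALSE) {
  excluded <- sum(is.na(angles))
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n == 0) stop("no angles to classify")
  p0 <- 2 * sector_halfwidth / 360
  n_pol <- sum(abs(angles) <= sector_halfwidth)
  exp_pol <- n * p0
  obs <- c(n_pol, n - n_pol)
  expd <- c(exp_pol, n - exp_pol)
  dev <- abs(obs - expd)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expd)
  structure(list(
    n_total = n, n_polarized = n_pol, expected_polarized = exp_pol,
    chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    excluded = excluded, sector_halfwidth = sector_halfwidth, correct = correct
  ), class = "polarity_result")
}

#' @export
print.polarity_result <- function(x, ...) {
  cat(sprintf("Polarity test: %d / %d polarized (expected %.1f under null)\n",
              x$n_polarized, x$n_total, x$expected_polarized))
  cat(sprintf("  chi-squared = %.3f, df = 1, p = %.4g\n", x$chi2, x$p_value))
  if (x$excluded > 0) cat(sprintf("  excluded cells: %d\n", x$excluded))
  invisible(x)
}

#' Power of the two-class sector chi-squared test
#'
#' Analytic power of the df = 1 goodness-of-fit test at Cohen's effect size
#' w: the test statistic is asymptotically noncentral chi-squared with
#' noncentrality `n * w^2`, so power is
#' `P(chisq_1(ncp = n w^2) > chisq_{1, 1-alpha})`. The Monte-Carlo mode
#' simulates the actual two-class test under an alternative of effect size
#' w. Cohen's w fixes only the magnitude of the deviation from the null,
#' not its direction; with two classes there are exactly two alternatives of
#' size w (polarized excess or deficit) whose exact powers straddle the
#' direction-free analytic value, so each replicate draws the direction at
#' random. The two modes agree within Monte-Carlo error.
#'
#' @param n Sample size (cells analysed); vectorized.
#' @param effect_size_w Cohen's w (>= 0); vectorized.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param method `"analytic"` (default) or `"montecarlo"`.
#' @param n_sim Replicates for the Monte-Carlo mode.
#' @param null_probs Null class probabilities (default `c(1/3, 2/3)`).
#' @param seed Optional seed for the Monte-Carlo mode.
#' @return Power in `[0, 1]`; equals `alpha` at `w = 0`.
#' @examples
#' sector_power(787, 0.1)            # > 0.80
#' sector_power(787, 0)              # = alpha
#' @export
sector_power <- function(n, effect_size_w, alpha = 0.05,
                         method = c("analytic", "montecarlo"),
                         n_sim = 1e5, null_probs = c(1 / 3, 2 / 3), seed = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (any(n < 1)) stop("n must be >= 1")
  if (any(effect_size_w < 0)) stop("effect_size_w must be >= 0")
  method <- match.arg(method)
  crit <- stats::qchisq(1 - alpha, df = 1)
  if (method == "analytic") {
    return(stats::pchisq(crit, df = 1, ncp = n * effect_size_w^2, lower.tail = FALSE))
  }
  if (length(n) != 1L || length(effect_size_w) != 1L) {
    stop("montecarlo mode takes scalar n and effect_size_w")
  }
  # Alternative with Cohen's w relative to the null: shift delta on class 1,
  # w^2 = delta^2 / p1 + delta^2 / p2  =>  delta = w / sqrt(1/p1 + 1/p2);
  # the sign of the shift is drawn at random per replicate (see Details).
  delta <- effect_size_w / sqrt(1 / null_probs[1] + 1 / null_probs[2])
  if (any(null_probs + c(delta, -delta) < 0 | null_probs + c(delta, -delta) > 1) ||
      any(null_probs - c(delta, -delta) < 0)) {
    stop("effect size too large for the null probabilities")
  }
  if (!is.null(seed)) set.seed(seed)
  sgn <- sample(c(-1, 1), n_sim, replace = TRUE)
  o1 <- stats::rbinom(n_sim, n, null_probs[1] + sgn * delta)
  e1 <- n * null_probs[1]
  chi2 <- (o1 - e1)^2 / e1 + ((n - o1) - (n - e1))^2 / (n - e1)
  mean(chi2 > crit)
}

#' Extract object centroids from a single-channel image
#'
#' Global threshold (Otsu by default), connected-component labelling, an
#' area filter, then intensity-weighted centroids in physical units. Pixel
#' `(i, j)` has its centre at `((i - 0.5) * pixel_size, (j - 0.5) * pixel_size)`.
#'
#' @param image Numeric matrix (2D intensity image).
#' @param pixel_size um per pixel.
#' @param threshold `"otsu"` or `"fixed"` (then give `threshold_value`).
#' @param threshold_value Threshold intensity for `threshold = "fixed"`.
#' @param min_area,max_area Connected-component area filter in pixels;
#'   components outside the range are dropped and counted in the
#'   `"excluded"` attribute.
#' @return Data frame `id`, `x_um`, `y_um`, `area_px`; attribute `excluded`
#'   gives the number of area-filtered components. Empty (with a warning)
#'   when no objects survive.
#' @export
extract_centroids <- function(image, pixel_size = 1,
                              threshold = c("otsu", "fixed"),
                              threshold_value = NULL,
                              min_area = 1, max_area = Inf) {
  threshold <- match.arg(threshold)
  img <- as.matrix(image)
  rng <- range(img)
  if (threshold == "otsu") {
    if (diff(rng) == 0) {
      bw <- matrix(FALSE, nrow(img), ncol(img))
    } else {
      scaled <- (img - rng[1]) / diff(rng)
      bw <- scaled > EBImage::otsu(EBImage::Image(scaled))
    }
  } else {
    if (is.null(threshold_value)) stop("threshold_value required for fixed threshold")
    bw <- img > threshold_value
  }
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  labm <- as.matrix(EBImage::imageData(lab))
  nlab <- max(labm)
  if (nlab == 0) {
    warning("no objects found")
    out <- data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                      area_px = integer())
    attr(out, "excluded") <- 0L
    return(out)
  }
  idx <- which(labm > 0, arr.ind = TRUE)
  l <- labm[labm > 0]
  w <- img[labm > 0]
  w[w < 0] <- 0
  area <- tabulate(l, nlab)
  wsum <- rowsum(w, l)[, 1]
  wsum[wsum == 0] <- 1  # fall back to unweighted centroid of zero-signal blob
  cx <- rowsum(w * idx[, 1], l)[, 1] / wsum
  cy <- rowsum(w * idx[, 2], l)[, 1] / wsum
  ok <- area >= min_area & area <= max_area
  out <- data.frame(id = seq_len(nlab)[ok],
                    x_um = (cx[ok] - 0.5) * pixel_size,
                    y_um = (cy[ok] - 0.5) * pixel_size,
                    area_px = area[ok])
  rownames(out) <- NULL
  attr(out, "excluded") <- sum(!ok)
  if (nrow(out) == 0) warning("all objects removed by the area filter")
  out
}

#' Bin polarity angles into sectors for a polar histogram
#'
#' @param angles Angles in degrees in `(-180, 180]`.
#' @param n_sectors Number of equal sectors; must divide 360. For
#'   `n_sectors` in 6, 12, 18, 36 the +/-60 degree sector boundary falls on
#'   bin edges, so the polarized sector is a union of whole bins.
#' @return Data frame `sector`, `lower`, `upper`, `mid`, `count`; counts sum
#'   to `length(angles)`.
#' @examples
#' polar_histogram(c(-10, 5, 100), n_sectors = 12)
#' @export
polar_histogram <- function(angles, n_sectors = 12) {
  if (n_sectors < 1 || 360 %% n_sectors != 0) stop("n_sectors must divide 360")
  angles <- angles[!is.na(angles)]
  width <- 360 / n_sectors
  bin <- ceiling((angles + 180) / width)
  bin[bin < 1] <- 1  # angle exactly -180 (excluded by convention, guard anyway)
  lower <- -180 + (seq_len(n_sectors) - 1) * width
  data.frame(sector = seq_len(n_sectors), lower = lower, upper = lower + width,
             mid = lower + width / 2,
             count = tabulate(bin, n_sectors))
}

#' Full scratch-field polarity analysis
#'
#' Runs the whole polarity pipeline on a field: Golgi-to-nucleus pairing,
#' restriction to cells adjacent to the scratch (nucleus within `band_um` of
#' the rim), per-cell polarity angles, sector classification and the
#' chi-squared test, plus the power of the test at the configured effect
#' size.
#'
#' @param field A `scratch_field` (from [gen_scratch_field()] or built from
#'   coordinate tables via [read_scratch_field()]).
#' @param band_um Only cells whose nucleus lies within this distance of the
#'   rim are analysed (default 100 um).
#' @param sector_halfwidth Polarized-sector half-width in degrees.
#' @param alpha,effect_size_w Parameters of the reported power.
#' @param correct Yates continuity correction for the chi-squared test.
#' @return A `polarity_result` with additional elements `cells` (per-cell
#'   data frame: ids, angle, polarized flag, exclusion reason), `power`,
#'   `band_um`, `field_id`.
#' @examples
#' f <- gen_scratch_field(500, polarized_weight = 0.8, seed = 7)
#' polarity_analysis(f)
#' @export
polarity_analysis <- function(field, band_um = 100, sector_halfwidth = 60,
                              alpha = 0.05, effect_size_w = 0.1, correct = FALSE) {
  stopifnot(is.list(field), !is.null(field$nuclei), !is.null(field$rim))
  asg <- assign_golgi(field$nuclei, field$golgi)
  nuc <- as.data.frame(field$nuclei)
  gol <- as.data.frame(field$golgi)
  nid <- if ("id" %in% names(nuc)) nuc$id else seq_len(nrow(nuc))
  gid <- if ("id" %in% names(gol)) gol$id else seq_len(nrow(gol))
  rimd <- dist_to_boundary(nuc, field$rim)
  cells <- asg$pairs
  cells$rim_distance_um <- rimd[match(cells$nucleus_id, nid)]
  cells$angle <- NA_real_
  cells$exclusion_reason <- ifelse(cells$rim_distance_um > band_um,
                                   "outside_band", NA_character_)
  for (i in seq_len(nrow(cells))) {
    if (!is.na(cells$exclusion_reason[i])) next
    ni <- match(cells$nucleus_id[i], nid)
    gi <- match(cells$golgi_id[i], gid)
    th <- polarity_angle(c(nuc$x_um[ni], nuc$y_um[ni]),
                         c(gol$x_um[gi], gol$y_um[gi]),
                         field$rim, field$wound_side_point)
    if (is.na(th)) {
      cells$exclusion_reason[i] <- attr(th, "reason")
    } else {
      cells$angle[i] <- th
    }
  }
  used <- cells$angle[is.na(cells$exclusion_reason)]
  res <- classify_and_test(used, sector_halfwidth = sector_halfwidth, correct = correct)
  cells$polarized <- !is.na(cells$angle) & abs(cells$angle) <= sector_halfwidth
  res$excluded_no_golgi <- length(asg$unmatched_nuclei)
  res$flagged_golgi <- length(asg$flagged_golgi)
  res$cells <- cells
  res$power <- sector_power(res$n_total, effect_size_w, alpha)
  res$alpha <- alpha
  res$effect_size_w <- effect_size_w
  res$band_um <- band_um
  res$field_id <- field$field_id
  res
}
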