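vertical_rim <- cbind(c(0, 0), c(-50, 50))
wound <- c(10, 0)  # wound side is x > 0

test_that("golgi are paired to the nearest nucleus with duplicates flagged", {
  p <- assign_golgi(data.frame(x_um = 0, y_um = 0), data.frame(x_um = 3, y_um = 4))
  expect_equal(p$pairs$separation_um, 5)

  p <- assign_golgi(data.frame(x_um = c(0, 10), y_um = c(0, 0)),
                    data.frame(x_um = 2, y_um = 0))
  expect_equal(p$pairs$nucleus_id, 1)
  expect_equal(p$unmatched_nuclei, 2)

  # two golgi competing for one nucleus: nearer kept, farther flagged
  p <- assign_golgi(data.frame(x_um = 0, y_um = 0),
                    data.frame(id = c(1, 2), x_um = c(7, 2), y_um = c(0, 0)))
  expect_equal(p$pairs$golgi_id, 2)
  expect_equal(p$flagged_golgi, 1)

  expect_error(assign_golgi(data.frame(x_um = numeric(), y_um = numeric()),
                            data.frame(x_um = 1, y_um = 1)), "empty")
})

test_that("polarity angle follows the wound-directed rim normal", {
  expect_equal(polarity_angle(c(-10, 0), c(-5, 0), vertical_rim, wound), 0)
  expect_equal(abs(polarity_angle(c(-10, 0), c(-15, 0), vertical_rim, wound)), 180)
  expect_equal(abs(polarity_angle(c(-10, 0), c(-10, 5), vertical_rim, wound)), 90)
  # intermediate angle: vector at 45 degrees from the normal
  expect_equal(abs(polarity_angle(c(-10, 0), c(-10 + 1, 1), vertical_rim, wound)), 45)
  # coincident centroids are excluded with a reason code
  th <- polarity_angle(c(-10, 0), c(-10, 0), vertical_rim, wound)
  expect_true(is.na(th))
  expect_equal(attr(th, "reason"), "zero_length_axis")
})

test_that("polarity angle is invariant under joint rigid transforms", {
  f <- gen_scratch_field(40, 0.5, seed = 21)
  base <- polarity_analysis(f, band_um = 1e6)$cells$angle
  for (ang in c(30, 117, -64)) {
    g <- transform_field(f, ang, shift = c(13.7, -42.1))
    rot <- polarity_analysis(g, band_um = 1e6)$cells$angle
    expect_equal(rot, base, tolerance = 1e-9)
  }
})

test_that("sector classification and chi-squared match the hand formula", {
  # 200/300 polarized: chi2 = (200-100)^2/100 + (100-200)^2/200 = 150
  angles <- c(runif(200, -60, 60), runif(100, 61, 179))
  res <- classify_and_test(angles)
  expect_equal(res$n_polarized, 200)
  expect_equal(res$chi2, 150)
  expect_equal(res$p_value, pchisq(150, 1, lower.tail = FALSE))
  # cross-check against the stock goodness-of-fit test
  ref <- chisq.test(c(200, 100), p = c(1 / 3, 2 / 3))
  expect_equal(res$chi2, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)

  # observed equals expected: chi2 = 0, p = 1
  angles <- c(runif(100, -59, 59), runif(200, 61, 179))
  res <- classify_and_test(angles)
  expect_equal(res$chi2, 0)
  expect_equal(res$p_value, 1)

  # boundary is inclusive
  expect_equal(classify_and_test(c(60, -60, 120))$n_polarized, 2)
  expect_error(classify_and_test(numeric()), "no angles")
})

test_that("type-I error of the sector test is near alpha", {
  set.seed(31)
  reject <- replicate(1000, {
    th <- runif(787, -180, 180)
    classify_and_test(th)$p_value < 0.05
  })
  expect_gt(mean(reject), 0.03)
  expect_lt(mean(reject), 0.07)
})

test_that("analytic power matches an independent simulation and is monotone", {
  expect_equal(sector_power(787, 0), 0.05)
  expect_gt(sector_power(787, 0.1), 0.80)
  # independent oracle: simulate the two-class test under a random-direction
  # alternative of size w with rbinom + the explicit statistic, not via the
  # package's own Monte-Carlo mode
  set.seed(41)
  delta <- 0.1 / sqrt(3 + 1.5)
  p1 <- 1 / 3 + sample(c(-1, 1), 20000, replace = TRUE) * delta
  o1 <- rbinom(20000, 787, p1)
  pvals <- pchisq((o1 - 787 / 3)^2 / (787 / 3) +
                    (787 - o1 - 2 * 787 / 3)^2 / (2 * 787 / 3),
                  1, lower.tail = FALSE)
  expect_lt(abs(mean(pvals < 0.05) - sector_power(787, 0.1)), 0.01)
  # the exact one-directional powers straddle the direction-free analytic
  # value: excess of polarized cells is detected slightly more often than
  # the analytic power, a deficit slightly less often
  exact_dir <- vapply(c(delta, -delta), function(dl) {
    k <- 0:787
    chi2 <- (k - 787 / 3)^2 / (787 / 3) + (787 - k - 2 * 787 / 3)^2 / (2 * 787 / 3)
    sum(dbinom(k, 787, 1 / 3 + dl) * (chi2 > qchisq(0.95, 1)))
  }, numeric(1))
  expect_lt(min(exact_dir), sector_power(787, 0.1))
  expect_gt(max(exact_dir), sector_power(787, 0.1))
  # package's own Monte-Carlo mode agrees with the analytic value
  expect_lt(abs(sector_power(787, 0.1, method = "montecarlo", n_sim = 5e4,
                             seed = 42) - sector_power(787, 0.1)), 0.01)
  # monotone in n and in w
  expect_true(all(diff(sector_power(c(100, 400, 787, 2000), 0.1)) > 0))
  expect_true(all(diff(sector_power(787, c(0, 0.05, 0.1, 0.2))) > 0))
  expect_error(sector_power(100, 0.1, alpha = 1.2), "alpha")
})

test_that("polar histogram conserves counts and aligns the sector boundary", {
  h <- polar_histogram(rep(0, 25), n_sectors = 12)
  expect_equal(sum(h$count), 25)
  # bins are right-closed, so angle 0 sits in the (-30, 0] sector
  expect_equal(h$count[h$upper == 0], 25)
  set.seed(51)
  th <- runif(3000, -180, 180)
  for (ns in c(6, 12, 18, 36)) {
    h <- polar_histogram(th, n_sectors = ns)
    expect_equal(sum(h$count), 3000)
    expect_true(any(h$lower == -60) && any(h$upper == 60))
  }
  expect_error(polar_histogram(th, n_sectors = 7), "divide")
})

test_that("centroid extraction recovers disk centres", {
  img <- matrix(0, 60, 60)
  centers <- rbind(c(15, 15), c(40, 20), c(25, 48))
  for (k in 1:3) {
    for (i in 1:60) for (j in 1:60) {
      if ((i - centers[k, 1])^2 + (j - centers[k, 2])^2 <= 16) img[i, j] <- 1
    }
  }
  cent <- extract_centroids(img, pixel_size = 1)
  expect_equal(nrow(cent), 3)
  got <- cent[order(cent$x_um), c("x_um", "y_um")] + 0.5
  want <- centers[order(centers[, 1]), ]
  expect_true(all(abs(as.matrix(got) - want) <= 1))
  # blank image: empty with a warning
  expect_warning(out <- extract_centroids(matrix(0, 10, 10)), "no objects")
  expect_equal(nrow(out), 0)
  # merged blob removed by the area filter is reported
  two <- matrix(0, 30, 30)
  two[10:20, 10:20] <- 1
  expect_warning(out <- extract_centroids(two, max_area = 50), "area filter")
  expect_equal(attr(out, "excluded"), 1L)
})

test_that("full pipeline recovers the mixture polarized fraction", {
  for (rho in c(0, 0.5, 1)) {
    f <- gen_scratch_field(800, rho, seed = 60 + round(10 * rho))
    res <- polarity_analysis(f, band_um = 150)
    p_exp <- rho + (1 - rho) / 3
    se <- sqrt(max(p_exp * (1 - p_exp), 1e-4) / 800)
    expect_lt(abs(res$n_polarized / res$n_total - p_exp), 3 * se + 1e-9)
    expect_equal(res$excluded_no_golgi, 0)
  }
})
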