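unit_square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))

make_section <- function(cells, rim = unit_square, excl = NULL) {
  structure(list(section_id = "S1", cells = cells, rim_polygon = rim,
                 exclusion_region = if (is.null(excl)) rim else excl,
                 day_post_injection = NA, tumor_id = "T1"),
            class = "section_pattern")
}

test_that("distances from the rim handle edges, corners and exclusion", {
  cells <- data.frame(cell_id = 1:4,
                      x_um = c(2, 1, 2, 0.5), y_um = c(0.5, 0.5, 2, 0.5),
                      population = rep("control", 4))
  d <- cell_distances(make_section(cells))
  expect_equal(d$distance_um[1], 1)        # axis-aligned offset
  expect_equal(d$distance_um[2], 0)        # on the boundary
  expect_equal(d$distance_um[3], sqrt(2))  # nearest feature is corner (1,1)
  expect_true(d$excluded[4])               # inside the needle-track region
  expect_false(any(d$excluded[1:3]))
  all_in <- data.frame(cell_id = 1, x_um = 0.5, y_um = 0.5, population = "control")
  expect_warning(cell_distances(make_section(all_in)), "all cells")
})

test_that("bin assignment matches the ceiling rule and a brute-force oracle", {
  expect_equal(bin_distances(c(55, 100), n_bins = 10)[1], 6L)  # D = 100, d = 55
  expect_equal(bin_distances(c(0, 100))[1], 1L)                 # d = 0 -> bin 1
  expect_equal(bin_distances(c(50, 100))[2], 10L)               # d = D -> last bin
  set.seed(71)
  d <- c(runif(1e4, 0, 300), 300)  # pin the maximum
  expect_identical(bin_distances(d, 10), brute_force_bins(d, 300, 10))
  expect_warning(b <- bin_distances(c(0, 0)), "rim")
  expect_identical(b, c(1L, 1L))
  expect_error(bin_distances(numeric()), "no included")
})

test_that("bin assignment is scale invariant", {
  set.seed(72)
  d <- runif(500, 0, 120)
  expect_identical(bin_distances(d), bin_distances(d * 7.3))
  expect_identical(bin_distances(d), bin_distances(d * 0.002))
})

test_that("enrichment profile pools counts, conserves cells, flags 0/0 bins", {
  secs <- lapply(1:3, function(i)
    gen_section(400, 300, 0.02, 0.005, seed = 80 + i,
                section_id = paste0("S", i)))
  e <- enrichment_profile(secs)
  expect_s3_class(e, "bin_enrichment")
  expect_equal(sum(e$counts_silenced) + e$excluded[["silenced"]], 3 * 400)
  expect_equal(sum(e$counts_control) + e$excluded[["control"]], 3 * 300)
  expect_equal(e$ratio[e$defined],
               (e$counts_silenced / e$counts_control)[e$defined])
  # order of sections does not matter
  e2 <- enrichment_profile(rev(secs))
  expect_equal(e2$counts_silenced, e$counts_silenced)
  expect_equal(e2$pearson_r, e$pearson_r)
})

test_that("enrichment is invariant to per-section rigid transforms", {
  s <- gen_section(300, 250, 0.02, 0.005, seed = 85)
  rot <- s
  a <- 73 * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  xy <- as.matrix(s$cells[, c("x_um", "y_um")]) %*% t(R)
  rot$cells$x_um <- xy[, 1] + 11
  rot$cells$y_um <- xy[, 2] - 5
  rp <- s$rim_polygon %*% t(R)
  rot$rim_polygon <- cbind(rp[, 1] + 11, rp[, 2] - 5)
  rot$exclusion_region <- rot$rim_polygon
  e1 <- enrichment_profile(s)
  e2 <- enrichment_profile(rot)
  expect_equal(e2$counts_silenced, e1$counts_silenced)
  expect_equal(e2$pearson_r, e1$pearson_r, tolerance = 1e-9)
})

test_that("known ratios and degenerate profiles are handled", {
  # hand-built two-bin example via direct counts: ratios 2.0 and 1.0
  cells <- data.frame(
    cell_id = 1:25,
    x_um = 1 + c(rep(0.05, 10), rep(1.0, 5), rep(0.05, 5), rep(1.0, 5)),
    y_um = 0.5,
    population = rep(c("silenced", "control"), c(15, 10))
  )
  e <- suppressWarnings(enrichment_profile(make_section(cells), n_bins = 2))
  expect_equal(e$counts_silenced, c(10L, 5L))
  expect_equal(e$counts_control, c(5L, 5L))
  expect_equal(e$ratio, c(2, 1))

  # constant ratio: r undefined, p = 1 by convention
  cells <- data.frame(cell_id = 1:40,
                      x_um = 1 + rep(seq(0.1, 1, length.out = 10), 4),
                      y_um = 0.5,
                      population = rep(c("silenced", "control"), each = 20))
  e <- enrichment_profile(make_section(cells), n_bins = 10)
  expect_true(all(e$ratio[e$defined] == 1))
  expect_true(is.na(e$pearson_r))
  expect_equal(e$p_value, 1)

  # empty control population: ratios undefined, correlation not computed
  s0 <- suppressWarnings(gen_section(100, 0, 0.02, 0.005, seed = 86))
  expect_warning(e0 <- enrichment_profile(s0), "defined ratio")
  expect_true(all(!e0$defined | is.nan(e0$ratio)))
  expect_true(is.na(e0$pearson_r))
})

test_that("depletion of the silenced population yields a negative trend", {
  secs <- lapply(1:4, function(i)
    gen_section(970, 350, 0.02, 0.005, seed = 90 + i,
                section_id = paste0("S", i)))
  e <- enrichment_profile(secs)
  expect_lt(e$pearson_r, 0)
  expect_lt(e$p_value, 0.01)
})

test_that("composition timecourse recovers the schedule and its trend", {
  sched <- data.frame(day = c(18, 89, 179), fraction = c(0.67, 0.33, 0.08))
  tc <- gen_timecourse(sched, cells_per_section = 500, sections_per_tumor = 3,
                       seed = 95)
  res <- composition_timecourse(tc)
  expect_equal(res$timepoints$day, sched$day)
  se <- sqrt(sched$fraction * (1 - sched$fraction) / (3 * 500))
  expect_true(all(abs(res$timepoints$fraction_silenced_mean - sched$fraction)
                  <= 3 * se))
  expect_lt(res$pearson_r, 0)
  # paper-style summary triple, single sections
  single <- data.frame(tumor_id = c("A", "B", "C"), day = c(18, 89, 179),
                       n_silenced = c(67, 33, 8), n_control = c(33, 67, 92))
  expect_lt(composition_timecourse(single)$pearson_r, 0)
  # constant fractions: no trend
  const <- data.frame(tumor_id = c("A", "B", "C"), day = c(1, 10, 20),
                      n_silenced = 50, n_control = 50)
  res <- composition_timecourse(const)
  expect_equal(res$p_value, 1)
  # per-section mode uses all sections
  res_sec <- composition_timecourse(tc, level = "section")
  expect_lt(res_sec$pearson_r, 0)
  expect_lt(res_sec$p_value, 0.01)
  expect_error(composition_timecourse(
    data.frame(tumor_id = "A", day = 1, n_silenced = 0, n_control = 0)),
    "zero total")
})
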