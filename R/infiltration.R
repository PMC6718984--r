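#' Distances of section cells from the injection-site rim
#'
#' Minimum Euclidean distance from each cell to the rim polygon boundary.
#' Cells strictly inside the exclusion region (by default the rim polygon
#' itself, standing for the needle track) are excluded from the analysis and
#' reported; a cell sitting exactly on the rim has distance 0 and is kept.
#'
#' @param section A `section_pattern` (see [gen_section()]) or a list with
#'   `cells` (`x_um`, `y_um`, `population`), `rim_polygon` and optionally
#'   `exclusion_region`.
#' @return Data frame `cell_id`, `population`, `distance_um`, `excluded`.
#'   Warns when every cell is excluded.
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' s <- list(cells = data.frame(cell_id = 1, x_um = 2, y_um = 0.5,
#'                              population = "control"),
#'           rim_polygon = sq)
#' cell_distances(s)$distance_um  # 1
#' @export
cell_distances <- function(section) {
  stopifnot(is.list(section), !is.null(section$cells), !is.null(section$rim_polygon))
  cells <- as.data.frame(section$cells)
  rim <- as_xy_matrix(section$rim_polygon, "rim_polygon")
  if (abs(polygon_area(rim)) < .Machine$double.eps) stop("degenerate rim polygon")
  excl_poly <- if (is.null(section$exclusion_region)) rim else
    as_xy_matrix(section$exclusion_region, "exclusion_region")
  pts <- as_xy_matrix(cells)
  d <- dist_to_boundary(pts, rim, closed = TRUE)
  inside <- point_in_polygon(pts, excl_poly)
  out <- data.frame(
    cell_id = if ("cell_id" %in% names(cells)) cells$cell_id else seq_len(nrow(cells)),
    population = cells$population,
    distance_um = d, excluded = inside
  )
  if (all(out$excluded) && nrow(out) > 0) warning("all cells fall inside the exclusion region")
  out
}

#' Assign per-section distance bins
#'
#' Normalizes a section by its own maximum cell distance `D` (over both
#' populations pooled) and splits `[0, D]` into `n_bins` equal bins:
#' `bin(d) = ceiling(n_bins * d / D)`, with `d = 0` mapped to bin 1 and
#' `d = D` to bin `n_bins`. This makes sections with very different spreads
#' comparable.
#'
#' @param distances Distances (um) of the section's included cells.
#' @param n_bins Number of bins (default 10).
#' @return Integer bin indices in `1..n_bins`. If all distances are 0 every
#'   cell lands in bin 1 with a warning.
#' @examples
#' bin_distances(c(0, 55, 100)) # 1, 6, 10
#' @export
bin_distances <- function(distances, n_bins = 10) {
  if (length(distances) == 0) stop("no included cells in the section")
  if (any(distances < 0)) stop("distances must be >= 0")
  D <- max(distances)
  if (D == 0) {
    warning("all cells lie on the rim; every cell assigned to bin 1")
    return(rep(1L, length(distances)))
  }
  # clamp both ends: d = 0 belongs to bin 1, and floating-point round-up at
  # d = D must not spill past the last bin
  pmin(as.integer(n_bins), pmax(1L, as.integer(ceiling(n_bins * distances / D))))
}

#' Pooled distance-bin enrichment profile of silenced vs control cells
#'
#' For each section, distances from the rim are binned with the per-section
#' maximum-distance normalization; counts are then pooled across sections per
#' bin and population. The enrichment ratio per bin is silenced/control, and
#' the association between ratio and bin index is tested with Pearson's
#' correlation (two-sided t-test on `#defined bins - 2` df). Bins with zero
#' control count have an undefined ratio and are excluded from the
#' correlation unless a pseudocount is supplied.
#'
#' @param sections List of `section_pattern` objects (or a single one).
#' @param n_bins Bins per section (default 10).
#' @param pseudocount Added to both population counts in every bin before
#'   forming ratios (default 0, i.e. undefined bins are dropped).
#' @return A `bin_enrichment` list: `n_bins`, `counts_silenced`,
#'   `counts_control`, `ratio`, `defined`, `pearson_r`, `abs_r`, `p_value`,
#'   `sections_used`, `cells_used`, `excluded`, `max_distance_per_section`.
#'   With fewer than 3 defined bins the correlation is `NA` and a warning is
#'   raised; a constant ratio yields `pearson_r = NA`, `p_value = 1`.
#' @examples
#' secs <- lapply(1:2, function(i)
#'   gen_section(400, 400, 0.02, 0.005, seed = i, section_id = paste0("S", i)))
#' enrichment_profile(secs)
#' @export
enrichment_profile <- function(sections, n_bins = 10, pseudocount = 0) {
  if (inherits(sections, "section_pattern")) sections <- list(sections)
  if (length(sections) == 0) stop("no sections supplied")
  cs <- integer(n_bins)
  cc <- integer(n_bins)
  excluded <- c(silenced = 0L, control = 0L)
  used <- c(silenced = 0L, control = 0L)
  Dmax <- numeric(length(sections))
  for (k in seq_along(sections)) {
    dd <- cell_distances(sections[[k]])
    excl <- dd$excluded
    excluded["silenced"] <- excluded["silenced"] + sum(excl & dd$population == "silenced")
    excluded["control"] <- excluded["control"] + sum(excl & dd$population == "control")
    dd <- dd[!excl, , drop = FALSE]
    if (nrow(dd) == 0) { Dmax[k] <- NA_real_; next }
    Dmax[k] <- max(dd$distance_um)
    b <- bin_distances(dd$distance_um, n_bins)
    cs <- cs + tabulate(b[dd$population == "silenced"], n_bins)
    cc <- cc + tabulate(b[dd$population == "control"], n_bins)
    used["silenced"] <- used["silenced"] + sum(dd$population == "silenced")
    used["control"] <- used["control"] + sum(dd$population == "control")
  }
  ratio <- (cs + pseudocount) / (cc + pseudocount)
  defined <- is.finite(ratio)
  r <- NA_real_; p <- NA_real_
  if (sum(defined) < 3) {
    warning("fewer than 3 bins with a defined ratio; correlation not computed")
  } else if (stats::sd(ratio[defined]) == 0) {
    # Constant ratio: no association; report r undefined, p = 1 by convention.
    p <- 1
  } else {
    ct <- stats::cor.test(seq_len(n_bins)[defined], ratio[defined],
                          method = "pearson", alternative = "two.sided")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(
    n_bins = n_bins, counts_silenced = cs, counts_control = cc,
    ratio = ratio, defined = defined,
    pearson_r = r, abs_r = abs(r), p_value = p,
    sections_used = length(sections), cells_used = used, excluded = excluded,
    max_distance_per_section = Dmax, pseudocount = pseudocount
  ), class = "bin_enrichment")
}

#' @export
print.bin_enrichment <- function(x, ...) {
  cat(sprintf("Bin enrichment over %d sections (%d silenced, %d control cells)\n",
              x$sections_used, x$cells_used["silenced"], x$cells_used["control"]))
  cat("  ratio per bin:", paste(sprintf("%.3g", x$ratio), collapse = " "), "\n")
  cat(sprintf("  Pearson r = %.3f (|r| = %.3f), p = %.4g over %d defined bins\n",
              x$pearson_r, x$abs_r, x$p_value, sum(x$defined)))
  invisible(x)
}

#' Tumor composition over time and its trend test
#'
#' Per-section silenced fraction `silenced / (silenced + control)`, averaged
#' per tumor with the SEM across sections as intra-tumoral variability, then
#' a Pearson correlation of mean fraction against day post injection
#' (two-sided). The trend is tested at the tumor level by default; a
#' per-section mode correlates every section's fraction with its day, which
#' uses more points but treats sections of one tumor as independent.
#'
#' @param counts Data frame with one row per section: `tumor_id`, `day`,
#'   `n_silenced`, `n_control` (as produced by [gen_timecourse()]).
#' @param level `"tumor"` (default) or `"section"`: observations entering
#'   the correlation.
#' @return List with `timepoints` (data frame `tumor_id`, `day`,
#'   `fraction_silenced_mean`, `fraction_silenced_sem`, `n_sections`),
#'   `pearson_r`, `p_value` (NA with fewer than 3 observations), `level`.
#' @examples
#' tc <- gen_timecourse(data.frame(day = c(18, 89, 179),
#'                                 fraction = c(0.67, 0.33, 0.08)), seed = 1)
#' composition_timecourse(tc)
#' @export
composition_timecourse <- function(counts, level = c("tumor", "section")) {
  level <- match.arg(level)
  stopifnot(all(c("tumor_id", "day", "n_silenced", "n_control") %in% names(counts)))
  tot <- counts$n_silenced + counts$n_control
  if (any(tot == 0)) stop("a section has zero total cells")
  counts$fraction <- counts$n_silenced / tot
  sp <- split(counts, counts$tumor_id)
  tp <- do.call(rbind, lapply(sp, function(d) {
    m <- mean(d$fraction)
    sem <- if (nrow(d) > 1) stats::sd(d$fraction) / sqrt(nrow(d)) else 0
    data.frame(tumor_id = d$tumor_id[1], day = d$day[1],
               fraction_silenced_mean = m, fraction_silenced_sem = sem,
               n_sections = nrow(d))
  }))
  tp <- tp[order(tp$day), ]
  rownames(tp) <- NULL
  xs <- if (level == "tumor") tp$day else counts$day
  ys <- if (level == "tumor") tp$fraction_silenced_mean else counts$fraction
  r <- NA_real_; p <- NA_real_
  if (length(ys) >= 3 && length(unique(xs)) >= 2 && stats::sd(ys) > 0) {
    ct <- stats::cor.test(xs, ys, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  } else if (length(ys) >= 3) {
    p <- 1  # constant composition: no trend by convention
  }
  list(timepoints = tp, pearson_r = r, p_value = p, level = level)
}
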