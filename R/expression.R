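#' Relative expression by the delta-delta-Ct method
#'
#' Replicate Ct values are averaged per sample and target, the gene of
#' interest is normalized to the housekeeping gene (delta Ct), and fold
#' change relative to the reference sample is `efficiency^-ddCt` with
#' amplification efficiency fixed at 2 by default. The SEM is propagated
#' from replicate Ct variance by the delta method:
#' `sem = rel * log(eff) * sqrt(se_goi^2 + se_hk^2)`.
#'
#' @param ct_table Data frame with columns `sample_id`, `target` (values
#'   `"gene_of_interest"` and `"housekeeping"`), `ct` (> 0), and optionally
#'   `replicate`.
#' @param reference_sample Sample whose relative expression is defined as 1.
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @return Data frame `sample_id`, `rel_expr`, `sem`; the reference row has
#'   `rel_expr` exactly 1.
#' @examples
#' ct <- data.frame(sample_id = rep(c("A", "ref"), each = 2),
#'                  target = rep(c("gene_of_interest", "housekeeping"), 2),
#'                  ct = c(22, 20, 20, 20))
#' ddct(ct, "ref")   # A: 0.25
#' @export
ddct <- function(ct_table, reference_sample, efficiency = 2) {
  stopifnot(all(c("sample_id", "target", "ct") %in% names(ct_table)))
  if (any(ct_table$ct <= 0)) stop("Ct values must be positive")
  if (!reference_sample %in% ct_table$sample_id) stop("reference sample not in table")
  if (efficiency <= 1) stop("efficiency must exceed 1")
  ag <- stats::aggregate(ct ~ sample_id + target, ct_table, mean)
  vg <- stats::aggregate(ct ~ sample_id + target, ct_table,
                         function(x) stats::var(x) / length(x))
  names(vg)[3] <- "se2"
  vg$se2[is.na(vg$se2)] <- 0
  samples <- unique(ct_table$sample_id)
  get_ct <- function(s, tg) {
    v <- ag$ct[ag$sample_id == s & ag$target == tg]
    if (length(v) == 0) stop("missing ", tg, " Ct for sample ", s)
    v
  }
  get_se2 <- function(s, tg) {
    v <- vg$se2[vg$sample_id == s & vg$target == tg]
    if (length(v) == 0) 0 else v
  }
  dct_ref <- get_ct(reference_sample, "gene_of_interest") -
    get_ct(reference_sample, "housekeeping")
  out <- do.call(rbind, lapply(samples, function(s) {
    dct <- get_ct(s, "gene_of_interest") - get_ct(s, "housekeeping")
    rel <- efficiency^(-(dct - dct_ref))
    se_dct <- sqrt(get_se2(s, "gene_of_interest") + get_se2(s, "housekeeping"))
    data.frame(sample_id = s, rel_expr = rel,
               sem = rel * log(efficiency) * se_dct)
  }))
  rownames(out) <- NULL
  out
}

#' Normalize western-blot band densities to a loading control
#'
#' Each sample's target-band density is divided by its loading-control
#' density (alpha-tubulin in the usual design) and expressed relative to the
#' reference sample.
#'
#' @param densities Data frame with columns `sample_id`, `target_intensity`,
#'   `loading_intensity` (all positive).
#' @param reference_sample Sample mapped to 1.
#' @return Data frame `sample_id`, `rel_level`.
#' @examples
#' d <- data.frame(sample_id = c("ref", "s1"),
#'                 target_intensity = c(50, 30), loading_intensity = c(50, 60))
#' blot_normalize(d, "ref")  # s1: 0.5
#' @export
blot_normalize <- function(densities, reference_sample) {
  stopifnot(all(c("sample_id", "target_intensity", "loading_intensity")
                %in% names(densities)))
  if (any(densities$loading_intensity <= 0)) stop("zero or negative loading-control intensity")
  if (any(densities$target_intensity < 0)) stop("negative target intensity")
  if (!reference_sample %in% densities$sample_id) stop("reference sample not in table")
  norm <- densities$target_intensity / densities$loading_intensity
  ref <- norm[densities$sample_id == reference_sample][1]
  data.frame(sample_id = densities$sample_id, rel_level = norm / ref)
}

#' Compare relative expression between two groups
#'
#' Two-sample comparison of relative expression values between groups (for
#' instance foci-forming vs contact-inhibited cultures). By default the
#' test is a Welch t-test on log-transformed values, appropriate for
#' fold-change data spanning orders of magnitude; a rank-sum alternative and
#' an untransformed mode are available. The result is invariant to swapping
#' group labels (up to the sign of the effect).
#'
#' @param rel_expr Positive expression values.
#' @param group Two-level group labels, same length.
#' @param log_transform Test on `log(rel_expr)` (default `TRUE`).
#' @param test `"welch"` or `"wilcoxon"`.
#' @return List: `effect` (difference of group means on the analysis scale,
#'   second level minus first), `statistic`, `p_value`, `test`, `groups`.
#' @export
group_expression_test <- function(rel_expr, group, log_transform = TRUE,
                                  test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  lev <- unique(as.character(group))
  if (length(lev) != 2) stop("exactly two groups required")
  if (any(table(group) < 2)) stop("need at least 2 samples per group")
  x <- if (log_transform) {
    if (any(rel_expr <= 0)) stop("log transform needs positive values")
    log(rel_expr)
  } else rel_expr
  a <- x[group == lev[1]]
  b <- x[group == lev[2]]
  ht <- if (test == "welch") stats::t.test(b, a) else
    stats::wilcox.test(b, a, exact = FALSE)
  list(effect = mean(b) - mean(a), statistic = unname(ht$statistic),
       p_value = ht$p.value, test = test,
       log_transform = log_transform, groups = lev)
}
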