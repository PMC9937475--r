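# Descriptive volumetry: left/right asymmetry, AD-vs-NC volume
# reductions, and paired left-right correlations.

#' Percent difference relative to the midpoint mean
#'
#' Returns 100 |a - b| / ((a + b) / 2): the absolute difference
#' expressed relative to the mean of the two values. This symmetric
#' convention is used for both hemispheric asymmetry (left vs right
#' group means) and group reduction (NC vs AD group means); it is the
#' convention under which the hippocampal asymmetry of AD cohorts comes
#' out near 3.3% and the AD-vs-NC hippocampal reduction near 19%.
#'
#' @param a,b Strictly positive volumes (mm^3); vectorized.
#' @return Percent difference(s) in \[0, 200).
#' @examples
#' percent_difference(2933.4, 3030.7)  # ~3.26
#' @export
percent_difference <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0))
    stop("percent_difference requires strictly positive volumes",
         call. = FALSE)
  100 * abs(a - b) / ((a + b) / 2)
}

#' @rdname percent_difference
#' @param nc_mean,ad_mean Group mean volumes; `group_reduction()` is
#'   the same midpoint-mean percent difference, named for the AD-vs-NC
#'   atrophy use.
#' @export
group_reduction <- function(nc_mean, ad_mean)
  percent_difference(nc_mean, ad_mean)

#' Pearson correlation of paired left/right volumes
#'
#' Product-moment correlation with the two-sided t-test p-value, via
#' [stats::cor.test()].
#'
#' @param left,right Equal-length numeric vectors (>= 3 subjects),
#'   paired by subject.
#' @return Named numeric `c(r, p_value)`.
#' @export
paired_correlation <- function(left, right) {
  if (length(left) != length(right))
    stop("left and right must be paired per subject (equal length)",
         call. = FALSE)
  if (length(left) < 3L)
    stop("need at least 3 subjects", call. = FALSE)
  if (stats::sd(left) == 0 || stats::sd(right) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(left, right)
  c(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Per-group left/right asymmetry summary for one region
#'
#' For each diagnostic group: hemispheric mean volumes, the mean and SD
#' of the per-subject signed (left - right) differences, the percent
#' asymmetry of the group means (midpoint-mean convention,
#' [percent_difference()]), and the paired left-right Pearson
#' correlation.
#'
#' @param cohort A [cohort_table()]; every subject must have both
#'   hemispheres of `region`.
#' @param region One of the four MTL regions.
#' @return A data frame with one row per group present (AD, NC):
#'   columns `group`, `n`, `mean_left`, `mean_right`, `mean_diff`,
#'   `sd_diff`, `percent_asymmetry`, `pearson_r`, `p_value`. Signed
#'   differences are left minus right (negative when left is the
#'   smaller); `percent_asymmetry` is the magnitude.
#' @export
asymmetry_summary <- function(cohort, region = "hippocampus") {
  stopifnot(inherits(cohort, "cohort_table"))
  region <- normalize_region(region)
  if (is.na(region)) stop("unknown region", call. = FALSE)
  rows <- lapply(intersect(GROUPS, unique(cohort$group)), function(g) {
    sub <- cohort[cohort$group == g & cohort$region == region, , drop = FALSE]
    ids <- unique(sub$subject_id)
    l <- sub$volume_mm3[match(paste(ids, "left"),
                              paste(sub$subject_id, sub$hemisphere))]
    r <- sub$volume_mm3[match(paste(ids, "right"),
                              paste(sub$subject_id, sub$hemisphere))]
    if (anyNA(l) || anyNA(r))
      stop("group ", g, ": subject(s) missing a hemisphere for region '",
           region, "': ",
           paste(ids[is.na(l) | is.na(r)], collapse = ", "), call. = FALSE)
    d <- l - r
    corr <- if (length(ids) >= 3L && stats::sd(l) > 0 && stats::sd(r) > 0)
      paired_correlation(l, r) else c(r = NA_real_, p_value = NA_real_)
    data.frame(group = g, n = length(ids),
               mean_left = mean(l), mean_right = mean(r),
               mean_diff = mean(d),
               sd_diff = if (length(d) > 1L) stats::sd(d) else 0,
               percent_asymmetry = if (mean(d) == 0) 0 else
                 percent_difference(mean(l), mean(r)),
               pearson_r = corr[["r"]], p_value = corr[["p_value"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average asymmetry across groups
#'
#' The arithmetic mean of the per-group percent asymmetries (as
#' reported, i.e. already-rounded percentages average to the figure a
#' table reader would quote).
#'
#' @param percentages Numeric vector of per-group asymmetry
#'   percentages.
#' @return Their mean.
#' @export
average_asymmetry <- function(percentages) mean(percentages)

#' Format a p-value for display
#'
#' Three decimals, floored at "< 0.001".
#' @param p A p-value.
#' @return Character scalar.
#' @export
format_p_value <- function(p) {
  ifelse(p < 0.001, "< 0.001", sprintf("%.3f", p))
}
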