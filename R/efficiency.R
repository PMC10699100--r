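#' Fit the relative binding efficiency by linear regression
#'
#' Ordinary least-squares fit of the anti-tag mean gray value (response) on
#' the reference-channel mean gray value (predictor) over ROI measurements,
#' with an intercept. The intercept absorbs shared background; the slope is
#' the relative efficiency with which the anti-tag antibody detects the
#' tagged protein, in units of the reference antibody's signal.
#'
#' @param measurements Data frame with columns `mean_ref` and `mean_tag`
#'   (see [measure_regions()]); measurements from several pictures of the
#'   same condition are typically pooled into one fit.
#' @param antibody_id,experiment_id Labels carried into the result.
#' @return One-row data frame: `antibody_id`, `experiment_id`, `slope`,
#'   `intercept`, `r_squared`, `n_points`.
#' @export
fit_efficiency <- function(measurements, antibody_id = NA_character_,
                           experiment_id = NA_character_) {
  stopifnot(all(c("mean_ref", "mean_tag") %in% names(measurements)))
  n <- nrow(measurements)
  if (n < 3L)
    stop("insufficient data: need >= 3 ROI measurements, got ", n, call. = FALSE)
  x <- measurements$mean_ref; y <- measurements$mean_tag
  if (stats::sd(x) == 0)
    stop("degenerate design: zero variance in mean_ref", call. = FALSE)
  fit <- stats::lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(stats::residuals(fit)^2) / tss
  data.frame(antibody_id = antibody_id, experiment_id = experiment_id,
             slope = unname(stats::coef(fit)[2L]),
             intercept = unname(stats::coef(fit)[1L]),
             r_squared = r2, n_points = n)
}

#' Normalize efficiencies to the reference antibody (set to 100)
#'
#' Within each experiment, every slope is expressed relative to the slope
#' of the reference antibody included in that experiment:
#' `value = 100 * slope / slope(reference)`. Normalization is strictly
#' within-experiment, which is what makes independent experiments
#' comparable; the reference antibody scores exactly 100 everywhere.
#'
#' @param fits Data frame of regression fits with columns `antibody_id`,
#'   `experiment_id`, `slope` (see [fit_efficiency()]).
#' @param reference_id The reference antibody's `antibody_id`.
#' @return `fits` with an added `normalized_value` column.
#' @export
normalize_to_reference <- function(fits, reference_id) {
  stopifnot(all(c("antibody_id", "experiment_id", "slope") %in% names(fits)))
  out <- fits
  out$normalized_value <- NA_real_
  for (exp_id in unique(fits$experiment_id)) {
    in_exp <- fits$experiment_id == exp_id
    ref_row <- in_exp & fits$antibody_id == reference_id
    if (!any(ref_row))
      stop("missing reference '", reference_id, "' in experiment '", exp_id,
           "'", call. = FALSE)
    ref_slope <- fits$slope[ref_row][1L]
    if (ref_slope <= 0)
      stop("degenerate reference: slope ", ref_slope, " in experiment '",
           exp_id, "'", call. = FALSE)
    out$normalized_value[in_exp] <- 100 * (fits$slope[in_exp] / ref_slope)
  }
  out
}

#' Aggregate normalized efficiencies across independent experiments
#'
#' @param values Numeric vector of normalized efficiencies for one antibody,
#'   one per independent experiment.
#' @return A list with `mean` (arithmetic mean), `sem` (sample standard
#'   deviation over `sqrt(n)`; 0 when `n = 1`, with a caveat message), and
#'   `n` (number of experiments).
#' @export
summarize_replicates <- function(values) {
  if (length(values) == 0L)
    stop("insufficient data: no replicate values", call. = FALSE)
  n <- length(values)
  if (n == 1L) {
    message("single experiment: SEM reported as 0")
    sem <- 0
  } else {
    sem <- stats::sd(values) / sqrt(n)
  }
  list(mean = mean(values), sem = sem, n = n)
}

#' Specificity relative to an irrelevant-antibody control
#'
#' An antibody is specific when its signal is at least twice the signal of
#' the irrelevant control in the same condition (boundary inclusive). The
#' control value is floored at 1 on the 0-100 normalized scale to guard the
#' division when the control slope is near zero.
#'
#' @param value Normalized efficiency of the antibody under test.
#' @param control_value Normalized efficiency of the irrelevant control in
#'   the same condition.
#' @param floor Numeric floor applied to the control value.
#' @return A list with `ratio` and `is_specific` (`ratio >= 2`).
#' @export
specificity_ratio <- function(value, control_value, floor = 1) {
  if (!is.numeric(value) || value < 0)
    stop("'value' must be a non-negative number", call. = FALSE)
  if (control_value < floor) {
    warning("control value ", signif(control_value, 3), " below floor ",
            floor, "; using the floor", call. = FALSE)
    control_value <- floor
  }
  ratio <- value / control_value
  list(ratio = ratio, is_specific = ratio >= 2)
}

#' Classify an antibody as good, fair, mediocre or nonspecific
#'
#' Classes follow the signal hierarchy observed across high- and
#' low-concentration staining: an antibody that is not specific at high
#' concentration (5000 ng/mL) is `nonspecific`; a specific antibody with a
#' normalized signal at or below 50 is `mediocre` (weak even at high
#' concentration); otherwise it is `good` if it remains specific at low
#' concentration (50 ng/mL) and `fair` if it does not. When the
#' low-concentration assay was not run, the good/fair split is
#' undetermined and the antibody is conservatively reported `fair` with
#' attribute `undetermined = TRUE`.
#'
#' @param high_value Normalized efficiency at high concentration.
#' @param low_value Normalized efficiency at low concentration, or `NA`.
#' @param specific_high Logical: specific (>= 2x control) at high
#'   concentration.
#' @param specific_low Logical: specific at low concentration, or `NA` when
#'   not assayed.
#' @return Character scalar label in
#'   `c("nonspecific", "mediocre", "fair", "good")`, with attribute
#'   `undetermined` when the good/fair split could not be made.
#' @export
classify_antibody <- function(high_value, low_value = NA_real_,
                              specific_high, specific_low = NA) {
  if (!is.numeric(high_value) || is.na(high_value) || high_value < 0)
    stop("'high_value' must be a non-negative number", call. = FALSE)
  if (!is.na(low_value) && low_value < 0)
    stop("'low_value' must be non-negative", call. = FALSE)
  if (!isTRUE(specific_high) && !isFALSE(specific_high))
    stop("'specific_high' must be TRUE or FALSE", call. = FALSE)
  if (!specific_high) return("nonspecific")
  if (high_value <= 50) return("mediocre")
  if (is.na(specific_low))
    return(structure("fair", undetermined = TRUE))
  if (specific_low) "good" else "fair"
}

# Ordering used by monotonicity checks: worse < better.
class_rank <- function(label) {
  match(label, c("nonspecific", "mediocre", "fair", "good"))
}
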