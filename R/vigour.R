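# Amplitude-duration fits and vigour scoring.

#' Fit the amplitude-duration relationship
#'
#' Self-paced reach durations grow approximately affinely with amplitude,
#' `T = slope * A + intercept`. Vigour is defined downstream as the inverse
#' of the slope. The `fitts_like` variant adds a log regressor,
#' `T = slope * A + intercept + c * log2(A / W + 1)`, with W the target
#' width.
#'
#' @param amplitude Stimulus amplitudes, deg.
#' @param duration Movement durations, s.
#' @param variant `"affine"` (default) or `"fitts_like"`.
#' @param target_width Target width W for the log regressor, deg. Default 2.
#' @return An object of class `ampdur_fit` with `slope` (s/deg),
#'   `intercept` (s), `log_coef` (NA for affine), `r2`, and `n`.
#' @export
#' @examples
#' A <- seq(5, 95, 10)
#' fit_amplitude_duration(A, 0.008 * A + 0.63)
fit_amplitude_duration <- function(amplitude, duration,
                                   variant = c("affine", "fitts_like"),
                                   target_width = 2) {
  variant <- match.arg(variant)
  keep <- is.finite(amplitude) & is.finite(duration)
  amplitude <- amplitude[keep]; duration <- duration[keep]
  n_amp <- length(unique(amplitude))
  if (variant == "affine" && n_amp < 2)
    stop("affine fit needs at least 2 distinct amplitudes")
  if (variant == "fitts_like" && n_amp < 3)
    stop("fitts_like fit needs at least 3 distinct amplitudes")
  fit <- if (variant == "affine") {
    stats::lm(duration ~ amplitude)
  } else {
    lg <- log2(amplitude / target_width + 1)
    stats::lm(duration ~ amplitude + lg)
  }
  cf <- stats::coef(fit)
  sst <- sum((duration - mean(duration))^2)
  r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else 1
  structure(
    list(slope = unname(cf["amplitude"]), intercept = unname(cf[1]),
         log_coef = if (variant == "fitts_like") unname(cf["lg"]) else NA_real_,
         r2 = r2, n = length(duration),
         variant = variant, target_width = target_width),
    class = "ampdur_fit")
}

#' @export
print.ampdur_fit <- function(x, ...) {
  cat(sprintf("Amplitude-duration fit (%s): T = %.4g * A + %.4g", x$variant,
              x$slope, x$intercept))
  if (!is.na(x$log_coef)) cat(sprintf(" + %.4g log2(A/W+1)", x$log_coef))
  cat(sprintf("  [R2 = %.3f, n = %d]\n", x$r2, x$n))
  invisible(x)
}

#' Vigour scores from amplitude-duration slopes
#'
#' Vigour is the inverse of the amplitude-duration slope (deg/s); relative
#' vigour normalizes by the cohort mean so the cohort average is 1.
#'
#' @param slopes Named or unnamed vector of per-participant slopes, s/deg
#'   (or a list of [fit_amplitude_duration()] objects).
#' @return Data frame with `vigour` (deg/s) and `relative_vigour`.
#' @export
vigour_scores <- function(slopes) {
  if (is.list(slopes) && all(vapply(slopes, inherits, logical(1), "ampdur_fit")))
    slopes <- vapply(slopes, `[[`, numeric(1), "slope")
  if (any(!is.finite(slopes)) || any(slopes <= 0))
    stop("invalid vigour: all amplitude-duration slopes must be positive")
  v <- 1 / slopes
  data.frame(vigour = v, relative_vigour = v / mean(v),
             row.names = names(slopes))
}

#' Fitting-free vigour scores from peak velocities
#'
#' For each participant, the mean peak velocity at each stimulus amplitude is
#' divided by the cohort mean peak velocity at that amplitude; the
#' participant's score is the average of those ratios over amplitudes. This
#' reproduces the peak-velocity-based relative vigour used for saccades and
#' serves as a fitting-free cross-check of the slope-based score.
#'
#' @param segments Data frame with columns `participant_id`,
#'   `stimulus_amplitude_deg` and `peak_speed_deg_s` (one row per movement).
#' @return Data frame with `participant_id` and `pv_relative_vigour`.
#' @export
peak_velocity_vigour <- function(segments) {
  req <- c("participant_id", "stimulus_amplitude_deg", "peak_speed_deg_s")
  if (!all(req %in% names(segments)))
    stop("segments must contain: ", paste(req, collapse = ", "))
  seg <- segments[is.finite(segments$peak_speed_deg_s), ]
  # participant x amplitude mean peaks
  pm <- stats::aggregate(peak_speed_deg_s ~ participant_id + stimulus_amplitude_deg,
                         data = seg, FUN = mean)
  cm <- stats::aggregate(peak_speed_deg_s ~ stimulus_amplitude_deg,
                         data = pm, FUN = mean)
  names(cm)[2] <- "cohort_peak"
  if (any(cm$cohort_peak <= 0)) stop("amplitude bin with no cohort data")
  pm <- merge(pm, cm, by = "stimulus_amplitude_deg")
  pm$ratio <- pm$peak_speed_deg_s / pm$cohort_peak
  out <- stats::aggregate(ratio ~ participant_id, data = pm, FUN = mean)
  names(out)[2] <- "pv_relative_vigour"
  out[order(out$participant_id), ]
}
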