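# Trial-level kinematics: zero-phase filtering, numerical differentiation,
# minimum-jerk template fitting, and movement segment metrics.

#' Zero-phase low-pass filter
#'
#' Fifth-order Butterworth low-pass applied forward and backward
#' (zero phase lag, DC gain 1), the standard preprocessing for motion
#' capture signals.
#'
#' @param x Uniformly sampled signal.
#' @param fs Sampling frequency, Hz. Default 250.
#' @param cutoff Cutoff frequency, Hz. Default 10.
#' @param order Filter order. Default 5.
#' @return The filtered signal, same length as `x`.
#' @export
lowpass_filter <- function(x, fs = 250, cutoff = 10, order = 5) {
  if (length(x) < 3 * (order + 1) * 3)
    stop("signal too short for zero-phase filtering (needs ~", 9 * (order + 1),
         " samples, got ", length(x), ")")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # detrend to the endpoint chord and odd-reflect-pad before the
  # forward-backward pass: suppresses the zero-state transients filtfilt
  # otherwise leaves at both ends (and makes the DC gain exactly 1)
  n <- length(x)
  trend <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / (n - 1)
  r <- x - trend
  np <- min(n - 1, ceiling(6 * fs / cutoff))
  front <- 2 * r[1] - r[(np + 1):2]
  back <- 2 * r[n] - r[(n - 1):(n - np)]
  y <- as.numeric(signal::filtfilt(bf, c(front, r, back)))
  y[(np + 1):(np + n)] + trend
}

# Central-difference derivative (one-sided at the ends).
finite_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Minimum-jerk velocity template
#'
#' Evaluates the three-parameter bell-shaped velocity profile
#' \deqn{v(t) = a\left[\frac{60 (t-t_0)^3}{(t_f-t_0)^4}
#'   - \frac{30 (t-t_0)^4}{(t_f-t_0)^5}
#'   - \frac{30 (t-t_0)^2}{(t_f-t_0)^3}\right]}
#' with v = 0 outside `[t0, tf]`. Note the sign convention of this
#' parameterization: the bracket is the negative of the usual unit bell, so
#' the integral of v over the movement equals `-a`; a movement of positive
#' displacement d corresponds to `a = -d`. Peak |v| is `1.875 |a| / (tf - t0)`
#' at the midpoint and the peak-to-mean speed ratio is exactly 1.875.
#'
#' @param t Time(s) at which to evaluate, s.
#' @param a Signed scale parameter (minus the displacement), rad.
#' @param t0,tf Movement onset and offset, s (`t0 < tf`).
#' @return Angular velocity at `t`, rad/s.
#' @export
#' @examples
#' minjerk_velocity(0.5, a = 1, t0 = 0, tf = 1) # -1.875
minjerk_velocity <- function(t, a, t0, tf) {
  if (!(t0 < tf)) stop("'t0' must be strictly smaller than 'tf'")
  d <- tf - t0
  s <- t - t0
  v <- a * (60 * s^3 / d^4 - 30 * s^4 / d^5 - 30 * s^2 / d^3)
  v[t < t0 | t > tf] <- 0
  v
}

#' Peak-to-mean speed ratio of a velocity profile
#'
#' @param velocity Sampled velocity over the movement, any angular unit.
#' @param time Optional sample times (only uniform sampling is assumed
#'   otherwise; the ratio is invariant to the time scale).
#' @return `max(|v|) / mean(|v|)`; 1.875 for a minimum-jerk bell, 1 for a
#'   constant profile, 2 for a triangular profile.
#' @export
velocity_ratio <- function(velocity, time = NULL) {
  av <- abs(velocity)
  m <- if (is.null(time)) mean(av) else {
    # trapezoid average for non-uniform sampling
    sum(diff(time) * (av[-1] + av[-length(av)]) / 2) / diff(range(time))
  }
  if (m <= 0) stop("mean speed is zero: empty or degenerate segment")
  max(av) / m
}

#' Shoulder angle from marker positions
#'
#' Angle between the shoulder-to-finger vector and a fixed reference
#' direction, via the arccosine of the dot product of unit vectors.
#'
#' @param shoulder,finger 3D positions (numeric length-3, or matrices with
#'   one row per sample).
#' @param reference 3D reference direction (need not be normalized).
#' @return Angle(s) in radians, in `[0, pi]`.
#' @export
angle_from_markers <- function(shoulder, finger, reference) {
  if (is.null(dim(shoulder))) shoulder <- matrix(shoulder, nrow = 1)
  if (is.null(dim(finger))) finger <- matrix(finger, nrow = 1)
  v <- finger - shoulder
  nv <- sqrt(rowSums(v^2))
  nr <- sqrt(sum(reference^2))
  if (any(nv == 0) || nr == 0) stop("zero-length vector")
  cosang <- (v %*% reference) / (nv * nr)
  ang <- acos(pmin(1, pmax(-1, cosang)))
  if (length(ang) == 1L) as.numeric(ang) else as.numeric(ang)
}

#' Fit a minimum-jerk template to a trial and extract the movement segment
#'
#' Least-squares fit of the three-parameter minimum-jerk velocity profile to
#' the trial's angular velocity over the inter-stimulus window, identifying
#' movement onset, offset and hence duration. The search runs bounded
#' Nelder-Mead local optimizations from a deterministic multi-start grid of
#' (t0, tf) candidates (default 16 starts seeded around the velocity support)
#' with the scale initialized from the observed displacement, and keeps the
#' lowest sum of squared errors.
#'
#' @param time Sample times, s (uniform).
#' @param angle Shoulder angle, rad (will be low-pass filtered unless
#'   `filter = FALSE`).
#' @param fs Sampling rate, Hz. Default 250.
#' @param filter Apply [lowpass_filter()] before differentiating? Default TRUE.
#' @param n_starts Number of multi-start local searches. Default 16.
#' @param motion_threshold Minimal peak speed, rad/s, below which the trial
#'   is flagged as containing no movement. Default 0.05.
#' @param r2_floor Fits with R^2 below this value are flagged. Default 0.5.
#' @return A list with `params` (a, t0, tf), `segment` (a one-row data frame
#'   with duration_s, amplitude_deg, peak_speed_deg_s, mean_speed_deg_s,
#'   fit_r2), and `flag` (`"ok"`, `"no_movement"` or `"poor_fit"`).
#' @export
fit_movement <- function(time, angle, fs = 250, filter = TRUE,
                         n_starts = 16, motion_threshold = 0.05,
                         r2_floor = 0.5) {
  stopifnot(length(time) == length(angle), length(time) > 20)
  dt <- time[2] - time[1]
  ang <- if (filter) lowpass_filter(angle, fs = fs) else angle
  vel <- finite_diff(ang, dt)

  if (max(abs(vel)) < motion_threshold) {
    seg <- data.frame(duration_s = NA_real_, amplitude_deg = NA_real_,
                      peak_speed_deg_s = NA_real_, mean_speed_deg_s = NA_real_,
                      fit_r2 = NA_real_)
    return(list(params = NULL, segment = seg, flag = "no_movement"))
  }

  # seed (t0, tf) around the observed velocity support and crop the data
  # to a window around it: the template is zero outside its own support, so
  # far-away samples only add a constant to the objective
  ipk <- which.max(abs(vel))
  above <- abs(vel) > 0.1 * abs(vel[ipk])
  i0 <- which(above)[1]
  i1 <- utils::tail(which(above), 1)
  t_on <- time[i0]; t_off <- time[i1]
  span <- max(t_off - t_on, 10 * dt)
  crop <- time >= t_on - 0.75 * span & time <= t_off + 0.75 * span
  tw <- time[crop]; vw <- vel[crop]

  sse_of <- function(par) {
    if (par[3] - par[2] < 4 * dt) return(Inf)
    sum((vw - minjerk_velocity(tw, par[1], par[2], par[3]))^2)
  }

  k <- max(2L, floor(sqrt(n_starts)))
  t0_grid <- t_on + span * seq(-0.25, 0.25, length.out = k)
  tf_grid <- t_off + span * seq(-0.25, 0.25, length.out = k)
  a0 <- -(ang[i1] - ang[i0])

  best <- NULL
  for (t0c in t0_grid) for (tfc in tf_grid) {
    if (tfc - t0c < 4 * dt) next
    fit <- stats::optim(c(a0, t0c, tfc), sse_of, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best <- stats::optim(best$par, sse_of, method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-12))
  par <- best$par
  if (par[3] < par[2]) par[2:3] <- par[3:2]
  t0 <- max(par[2], time[1]); tf <- min(par[3], time[length(time)])

  sst <- sum((vw - mean(vw))^2)
  r2 <- if (sst > 0) 1 - best$value / sst else NA_real_
  r2 <- min(max(r2, 0), 1)

  inwin <- time >= t0 & time <= tf
  vwin <- vel[inwin]
  a_start <- stats::approx(time, ang, t0)$y
  a_end <- stats::approx(time, ang, tf)$y
  seg <- data.frame(
    duration_s = tf - t0,
    amplitude_deg = abs(a_end - a_start) * 180 / pi,
    peak_speed_deg_s = max(abs(vwin)) * 180 / pi,
    mean_speed_deg_s = mean(abs(vwin)) * 180 / pi,
    fit_r2 = r2)
  flag <- if (!is.na(r2) && r2 < r2_floor) "poor_fit" else "ok"
  list(params = list(a = par[1], t0 = t0, tf = tf), segment = seg, flag = flag)
}

#' Segment every trial of a long-format recording table
#'
#' Applies [fit_movement()] to each trial of a trials table (as produced by
#' [simulate_session()] or [read_trials()]) and returns one row per movement.
#'
#' @param trials Long-format data frame with columns `participant_id`,
#'   `session_id`, `block_id`, `trial_index`, `stimulus_amplitude_deg`,
#'   `direction`, `t_s`, `angle_rad`.
#' @param fs Sampling rate, Hz.
#' @param ... Passed to [fit_movement()].
#' @return Data frame with the trial metadata, the fitted segment metrics
#'   and the fit flag.
#' @export
segment_trials <- function(trials, fs = 250, ...) {
  req <- c("participant_id", "session_id", "block_id", "trial_index",
           "stimulus_amplitude_deg", "direction", "t_s", "angle_rad")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("trials table is missing columns: ",
                         paste(miss, collapse = ", "))
  key <- interaction(trials$participant_id, trials$session_id,
                     trials$block_id, trials$trial_index, drop = TRUE)
  out <- lapply(split(trials, key), function(tr) {
    tr <- tr[order(tr$t_s), ]
    fm <- fit_movement(tr$t_s, tr$angle_rad, fs = fs, ...)
    cbind(tr[1, c("participant_id", "session_id", "block_id", "trial_index",
                  "stimulus_amplitude_deg", "direction")],
          fm$segment, flag = fm$flag, row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$participant_id, out$session_id, out$block_id,
            out$trial_index), ]
}
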