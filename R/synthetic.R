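# Synthetic cohorts and trial recordings with the statistical structure the
# analysis assumes: participants differ in anthropometry, traits and
# ground-truth cost-of-time parameters; trial durations follow the free-time
# optimal control model perturbed by multiplicative session/block/trial
# noise; recordings are sampled shoulder-angle traces with measurement noise.

#' Configuration of a synthetic cohort
#'
#' Defaults mirror the study design the package is built around: 38
#' participants, 5 blocks of 20 trials per session (2 trials for each of 10
#' amplitudes from 5 to 95 deg, one leftward and one rightward), repeated
#' sessions for a subset of participants, inter-stimulus intervals growing
#' from 3.6 s (5 deg) to 4.2 s (95 deg), sampling at 250 Hz.
#'
#' Participants are generated behaviour-first: each draws an affine
#' amplitude-duration relationship (log-normal slope around 0.008 s/deg,
#' normal intercept around 0.63 s, slope-intercept correlation 0.81) with
#' boredom proneness loading on the vigour latent, and the participant's
#' ground-truth cost-of-time parameters are then identified by exact
#' inversion of the optimal control model (sample the time-cost density g
#' along the affine line, fit the sigmoid density). This guarantees every
#' participant exhibits an interior time/effort trade-off in the reported
#' kinematic regime, and lets the co-variations among log(alpha), beta,
#' delta and inertia emerge from the model instead of being imposed. The
#' boredom loading default is calibrated so that the induced beta ~ boredom
#' effect has an expected R^2 near `beta_trait_r2`.
#'
#' Duration noise is multiplicative log-normal at the session, block and
#' trial levels; the session/block defaults are calibrated (see
#' [calibrate_duration_noise()]) so that the block-level vigour variance
#' splits roughly 72/11/17 percent across participants/sessions/blocks.
#'
#' @param n_participants Number of participants.
#' @param sessions_per_participant Integer vector of session counts,
#'   recycled/truncated to `n_participants`. The default assigns 21
#'   participants one session, 2 two, 7 three, 1 four and 7 five.
#' @param blocks_per_session Blocks per session.
#' @param amplitudes_deg Stimulus amplitudes, deg.
#' @param mass_mean,mass_sd Body mass distribution, kg.
#' @param arm_length_mean,arm_length_sd Extended arm length, m.
#' @param trait_correlation Correlation between boredom and impulsivity.
#' @param boredom_mean,boredom_sd,boredom_range Boredom proneness score
#'   distribution and plausible bounds.
#' @param impulsivity_mean,impulsivity_sd,impulsivity_range Impulsivity
#'   score distribution and plausible bounds.
#' @param slope_median,slope_sdlog Log-normal distribution of the affine
#'   amplitude-duration slope, s/deg.
#' @param intercept_mean,intercept_sd,intercept_min Normal distribution of
#'   the amplitude-duration intercept, s, truncated below at
#'   `intercept_min`.
#' @param slope_intercept_cor Correlation between the (log) slope and the
#'   intercept.
#' @param beta_trait_r2 Target share of ground-truth beta variance explained
#'   by boredom proneness (realized through the boredom loading on the
#'   vigour latent).
#' @param cot_fit_amplitudes Amplitude grid (deg) used when identifying each
#'   participant's ground-truth cost-of-time parameters.
#' @param friction,epsilon,effort_mode Arm/effort settings, see [arm_model()].
#' @param session_noise_sd,block_noise_sd,trial_noise_sd Standard deviations
#'   of the log-normal duration multipliers at each level.
#' @param angle_noise_sd Additive measurement noise on the recorded angle,
#'   rad.
#' @param reaction_mean,reaction_sd Movement onset latency after stimulus, s.
#' @param fs Sampling rate, Hz.
#' @param t_min,t_max Free-time search bracket, s.
#' @param seed Master seed; all draws derive deterministically from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 38,
                          sessions_per_participant =
                            c(rep(1L, 21), rep(2L, 2), rep(3L, 7), 4L, rep(5L, 7)),
                          blocks_per_session = 5,
                          amplitudes_deg = seq(5, 95, by = 10),
                          mass_mean = 68.7, mass_sd = 12.7,
                          arm_length_mean = 0.721, arm_length_sd = 0.048,
                          trait_correlation = 0.55,
                          boredom_mean = 10, boredom_sd = 4.5,
                          boredom_range = c(0, 28),
                          impulsivity_mean = 60, impulsivity_sd = 10,
                          impulsivity_range = c(34, 136),
                          slope_median = 0.0075, slope_sdlog = 0.45,
                          intercept_mean = 0.63, intercept_sd = 0.15,
                          intercept_min = 0.35,
                          slope_intercept_cor = 0.81,
                          beta_trait_r2 = 0.24,
                          cot_fit_amplitudes = seq(5, 125, length.out = 15),
                          friction = 0.8, epsilon = 0.005,
                          effort_mode = "torque_jerk",
                          session_noise_sd = 0.17,
                          block_noise_sd = 0.20,
                          trial_noise_sd = 0.06,
                          angle_noise_sd = 0.002,
                          reaction_mean = 0.3, reaction_sd = 0.04,
                          fs = 250, t_min = 0.2, t_max = 5,
                          seed = 1L) {
  cfg <- as.list(environment())
  cfg$sessions_per_participant <-
    rep_len(as.integer(sessions_per_participant), n_participants)
  if (any(cfg$amplitudes_deg <= 0)) stop("amplitudes must be positive")
  sds <- c(mass_sd, arm_length_sd, boredom_sd, impulsivity_sd, slope_sdlog,
           intercept_sd, session_noise_sd, block_noise_sd,
           trial_noise_sd, angle_noise_sd, reaction_sd)
  if (any(sds < 0)) stop("all standard deviations must be >= 0")
  if (abs(trait_correlation) >= 1) stop("infeasible trait correlation")
  if (abs(slope_intercept_cor) > 1) stop("infeasible slope-intercept correlation")
  if (beta_trait_r2 < 0 || beta_trait_r2 >= 1) stop("beta_trait_r2 must be in [0, 1)")
  if (epsilon <= 0 && effort_mode == "torque_jerk")
    stop("epsilon must be > 0 for the torque_jerk effort mode")
  structure(cfg, class = "cohort_config")
}

# deterministic per-entity seed (kept below 2^31)
.derive_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in ids) s <- (s * 69069 + as.double(k) * 6619 + 1) %% 2147483647
  as.integer(s)
}

.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  tries <- 0
  while (length(bad) && tries < 1000) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
    tries <- tries + 1
  }
  pmin(pmax(x, lower), upper)
}

# empirical correlation between the identified ground-truth beta and the
# (negated) slope latent of the behaviour draw, measured on large default
# cohorts; converts the target beta ~ boredom R^2 into the boredom loading
# on the vigour latent.
.BETA_VIGOUR_COR <- 0.80

#' Generate a synthetic cohort
#'
#' Draws per-participant anthropometry (truncated normal), correlated trait
#' scores and affine amplitude-duration behaviour (see [cohort_config()]),
#' then identifies each participant's ground-truth cost-of-time parameters
#' by inverting the optimal control model: the time-cost density g is
#' sampled along the participant's affine amplitude-duration line and the
#' sigmoid density is fitted to those samples.
#'
#' @param config A [cohort_config()].
#' @param identify_cot Identify ground-truth cost-of-time parameters for
#'   each participant (the expensive step)? Set FALSE when only
#'   anthropometry, traits and behaviour targets are needed.
#' @return Data frame with one row per participant: ids, anthropometry,
#'   inertia, traits, `n_sessions`, target behaviour (`target_slope`,
#'   `target_intercept`), and (when `identify_cot`) ground-truth `alpha`,
#'   `beta`, `delta` and the identification quality `cot_fit_r2`.
#' @export
generate_cohort <- function(config, identify_cot = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  set.seed(.derive_seed(config$seed, 101))

  mass <- .rtruncnorm(n, config$mass_mean, config$mass_sd,
                      max(config$mass_mean - 3 * config$mass_sd, 30),
                      config$mass_mean + 3 * config$mass_sd)
  arml <- .rtruncnorm(n, config$arm_length_mean, config$arm_length_sd,
                      max(config$arm_length_mean - 3 * config$arm_length_sd, 0.4),
                      config$arm_length_mean + 3 * config$arm_length_sd)

  rho <- config$trait_correlation
  z_bor <- stats::rnorm(n)
  z_imp <- rho * z_bor + sqrt(1 - rho^2) * stats::rnorm(n)
  boredom <- pmin(pmax(config$boredom_mean + config$boredom_sd * z_bor,
                       config$boredom_range[1]), config$boredom_range[2])
  impulsivity <- pmin(pmax(config$impulsivity_mean + config$impulsivity_sd * z_imp,
                           config$impulsivity_range[1]),
                      config$impulsivity_range[2])

  # behaviour draw: boredom loads on the vigour latent (more prone to
  # boredom -> more vigorous -> smaller slope); the loading w is sized so
  # the induced ground-truth beta ~ boredom R^2 is close to beta_trait_r2
  w <- min(1, sqrt(config$beta_trait_r2) / .BETA_VIGOUR_COR)
  z_s <- -(w * z_bor + sqrt(1 - w^2) * stats::rnorm(n))
  slope <- config$slope_median * exp(config$slope_sdlog * z_s)
  ric <- config$slope_intercept_cor
  intercept <- pmax(config$intercept_mean +
                      config$intercept_sd * (ric * z_s +
                                             sqrt(1 - ric^2) * stats::rnorm(n)),
                    config$intercept_min)

  cohort <- data.frame(
    participant_id = seq_len(n),
    body_mass_kg = mass, arm_length_m = arml,
    inertia = estimate_inertia(mass, arml),
    boredom = boredom, impulsivity = impulsivity,
    n_sessions = config$sessions_per_participant,
    target_slope = slope, target_intercept = intercept)

  if (identify_cot) {
    cp <- lapply(seq_len(n), function(i) {
      arm <- .participant_arm(cohort[i, ], config)
      sc <- sample_cot(arm, list(slope = slope[i], intercept = intercept[i]),
                       amplitudes = config$cot_fit_amplitudes)
      fit <- fit_sigmoid(sc$duration_s, sc$g_value)
      c(alpha = fit$alpha, beta = unname(fit$beta), delta = unname(fit$delta),
        cot_fit_r2 = fit$r2)
    })
    cp <- do.call(rbind, cp)
    cohort <- cbind(cohort, as.data.frame(cp))
  }
  cohort
}

# arm model of one cohort row
.participant_arm <- function(p, config) {
  arm_model(p$inertia, friction = config$friction, epsilon = config$epsilon,
            effort_mode = config$effort_mode)
}

#' Model-predicted durations for one participant
#'
#' Free-time optimal durations at each stimulus amplitude under the
#' participant's ground-truth cost of time, i.e. the noiseless nominal
#' behaviour of the generator.
#'
#' @param participant One row of [generate_cohort()] output.
#' @param config The [cohort_config()].
#' @param amplitudes_deg Amplitudes, deg; defaults to the config's stimuli.
#' @return Named numeric vector of durations, s.
#' @export
participant_durations <- function(participant, config,
                                  amplitudes_deg = config$amplitudes_deg) {
  arm <- .participant_arm(participant, config)
  cot <- cot_params(participant$alpha, participant$beta, participant$delta)
  boundary <- logical(length(amplitudes_deg))
  dur <- vapply(seq_along(amplitudes_deg), function(i) {
    ft <- withCallingHandlers(
      solve_free_time(arm, amplitudes_deg[i] * pi / 180, cot,
                      t_min = config$t_min, t_max = config$t_max),
      warning = function(w) invokeRestart("muffleWarning"))
    boundary[i] <<- ft$boundary
    ft$duration
  }, numeric(1))
  structure(stats::setNames(dur, amplitudes_deg), boundary = boundary)
}

.isi_of <- function(amp_deg, amplitudes) {
  lo <- min(amplitudes); hi <- max(amplitudes)
  3.6 + (amp_deg - lo) / (hi - lo) * 0.6
}

#' Simulate one session of recordings
#'
#' Each block presents a randomized sequence of two trials per amplitude
#' (one leftward, one rightward, paired). The nominal duration at each
#' amplitude comes from the free-time model; it is perturbed by the
#' session-, block- and trial-level multiplicative noise, the trajectory is
#' re-solved at the perturbed duration, sampled at `fs` over the
#' inter-stimulus window (movement onset after a reaction latency), and
#' measurement noise is added to the angle.
#'
#' @inheritParams participant_durations
#' @param session_id Session number.
#' @param nominal_durations Optional precomputed [participant_durations()]
#'   (avoids re-solving the free-time problem for repeated sessions).
#' @return Long-format trials data frame (one row per sample) with columns
#'   `participant_id`, `session_id`, `block_id`, `trial_index`,
#'   `stimulus_amplitude_deg`, `direction`, `t_s`, `angle_rad`.
#' @export
simulate_session <- function(participant, session_id, config,
                             nominal_durations = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(nominal_durations))
    nominal_durations <- participant_durations(participant, config)
  bnd <- attr(nominal_durations, "boundary")
  if (!is.null(bnd) && any(bnd))
    warning("participant ", participant$participant_id,
            ": free-time solution at the bracket edge for amplitude(s) ",
            paste(names(nominal_durations)[bnd], collapse = ", "),
            " deg; affected trials use the bracket-edge duration")
  arm <- .participant_arm(participant, config)
  amps <- config$amplitudes_deg
  pid <- participant$participant_id
  set.seed(.derive_seed(config$seed, 300, pid, session_id))
  m_sess <- exp(stats::rnorm(1, 0, config$session_noise_sd))
  out <- vector("list", config$blocks_per_session)

  for (b in seq_len(config$blocks_per_session)) {
    m_block <- exp(stats::rnorm(1, 0, config$block_noise_sd))
    seqc <- data.frame(amp = rep(amps, each = 2),
                       dir = rep(c("left", "right"), length(amps)))
    seqc <- seqc[sample.int(nrow(seqc)), ]
    btr <- vector("list", nrow(seqc))
    for (i in seq_len(nrow(seqc))) {
      A <- seqc$amp[i]
      sgn <- if (seqc$dir[i] == "left") -1 else 1
      isi <- .isi_of(A, amps)
      react <- .rtruncnorm(1, config$reaction_mean, config$reaction_sd,
                           0.1, config$reaction_mean + 3 * config$reaction_sd)
      m_trial <- exp(stats::rnorm(1, 0, config$trial_noise_sd))
      Tn <- nominal_durations[[as.character(A)]]
      Tt <- min(max(Tn * m_sess * m_block * m_trial, 0.15),
                isi - react - 0.15)
      sol <- solve_fixed_time(lq_problem(arm, A * pi / 180, Tt),
                              n_grid = max(51, ceiling(Tt * config$fs)))
      tg <- seq(0, isi - 1 / config$fs, by = 1 / config$fs)
      ang <- stats::approx(sol$time + react, sol$angle, xout = tg,
                           yleft = 0, yright = sol$angle[length(sol$angle)])$y
      ang <- sgn * ang + stats::rnorm(length(tg), 0, config$angle_noise_sd)
      btr[[i]] <- data.frame(
        participant_id = pid, session_id = session_id, block_id = b,
        trial_index = i, stimulus_amplitude_deg = A,
        direction = seqc$dir[i], t_s = tg, angle_rad = ang)
    }
    out[[b]] <- do.call(rbind, btr)
  }
  do.call(rbind, out)
}

#' Simulate all sessions of a cohort
#'
#' @param cohort Output of [generate_cohort()].
#' @param config The matching [cohort_config()].
#' @return Long-format trials data frame covering every participant,
#'   session and block.
#' @export
simulate_cohort_trials <- function(cohort, config) {
  out <- list()
  for (i in seq_len(nrow(cohort))) {
    p <- cohort[i, ]
    nd <- participant_durations(p, config)
    for (s in seq_len(p$n_sessions))
      out[[length(out) + 1L]] <- simulate_session(p, s, config,
                                                  nominal_durations = nd)
  }
  do.call(rbind, out)
}

#' Draw block-level vigour scores directly from the three-level model
#'
#' Simulates `y = beta0 + u_k + v_jk + e_ijk` on a given design without any
#' kinematic forward model: the reference generator for validating the
#' variance decomposition.
#'
#' @param grand_mean beta0.
#' @param variances Length-3 vector `c(omega_e, omega_v, omega_u)` of
#'   block/session/participant variances.
#' @param sessions_per_participant Session counts (one per participant).
#' @param blocks_per_session Blocks per session.
#' @return Data frame with `participant`, `session`, `block`, `score`.
#' @export
simulate_vigour_scores <- function(grand_mean, variances,
                                   sessions_per_participant,
                                   blocks_per_session = 5) {
  stopifnot(length(variances) == 3, all(variances >= 0))
  rows <- list()
  for (k in seq_along(sessions_per_participant)) {
    u <- stats::rnorm(1, 0, sqrt(variances[3]))
    for (j in seq_len(sessions_per_participant[k])) {
      v <- stats::rnorm(1, 0, sqrt(variances[2]))
      e <- stats::rnorm(blocks_per_session, 0, sqrt(variances[1]))
      rows[[length(rows) + 1L]] <- data.frame(
        participant = k, session = j, block = seq_len(blocks_per_session),
        score = grand_mean + u + v + e)
    }
  }
  do.call(rbind, rows)
}

#' Calibrate session/block duration-noise levels
#'
#' The participant-level spread of (log) vigour emerges from the cohort's
#' cost-of-time parameter distribution; the session- and block-level noise
#' standard deviations that produce a desired variance split are therefore
#' obtained by measuring that spread on a noiseless cohort and scaling.
#' Because durations are perturbed multiplicatively, a session multiplier
#' `exp(N(0, s^2))` shifts log-vigour by `N(0, s^2)` exactly.
#'
#' @param config A [cohort_config()].
#' @param target Proportions `c(block, session, participant)` of vigour
#'   variance; default `c(0.17, 0.11, 0.72)`.
#' @return List with the measured participant-level log-vigour SD and the
#'   implied `session_noise_sd` and `block_noise_sd`.
#' @export
calibrate_duration_noise <- function(config, target = c(0.17, 0.11, 0.72)) {
  stopifnot(abs(sum(target) - 1) < 1e-8)
  cohort <- generate_cohort(config)
  lv <- vapply(seq_len(nrow(cohort)), function(i) {
    d <- participant_durations(cohort[i, ], config)
    f <- fit_amplitude_duration(config$amplitudes_deg, d)
    -log(f$slope)
  }, numeric(1))
  s_u <- stats::sd(lv)
  list(log_vigour_sd = s_u,
       session_noise_sd = s_u * sqrt(target[2] / target[3]),
       block_noise_sd = s_u * sqrt(target[1] / target[3]))
}

#' Write / read trials tables
#'
#' Plain-CSV round trip of long-format trial recordings; numeric values are
#' kept to 9 significant digits.
#'
#' @param trials Trials data frame (see [simulate_session()]).
#' @param path File path.
#' @return `read_trials` returns the trials data frame.
#' @export
write_trials <- function(trials, path) {
  req <- c("participant_id", "session_id", "block_id", "trial_index",
           "stimulus_amplitude_deg", "direction", "t_s", "angle_rad")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("trials table is missing columns: ",
                         paste(miss, collapse = ", "))
  out <- trials[, req]
  for (cn in c("stimulus_amplitude_deg", "t_s", "angle_rad"))
    out[[cn]] <- signif(out[[cn]], 9)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant_id", "session_id", "block_id", "trial_index",
           "stimulus_amplitude_deg", "direction", "t_s", "angle_rad")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("malformed trials file: missing columns ",
                         paste(miss, collapse = ", "))
  num <- setdiff(req, "direction")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) | is.na(df[[cn]]))
    if (length(bad)) stop("malformed trials file: non-numeric '", cn,
                          "' at data line ", bad[1])
    df[[cn]] <- v
  }
  df
}
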