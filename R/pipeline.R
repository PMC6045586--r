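# Pipeline orchestration: simulate -> segment -> vigour -> infer_cot ->
# decompose -> regress -> report, with CSV/JSON artifacts in an output
# directory and a JSON run manifest. Each stage reads only the artifacts of
# its upstream stages, so the pipeline can be resumed stage by stage.

.PIPELINE_STAGES <- c("simulate", "segment", "vigour", "infer_cot",
                      "decompose", "regress", "report")

#' Load a pipeline configuration from YAML
#'
#' The YAML file holds any subset of [cohort_config()] arguments; missing
#' entries take the documented defaults. Validation happens before any
#' stage runs.
#'
#' @param path Path to a YAML file.
#' @return A [cohort_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown configuration fields: ",
                            paste(unknown, collapse = ", "))
  do.call(cohort_config, raw)
}

.artifact <- function(outdir, name) file.path(outdir, name)

.need <- function(path, stage_hint) {
  if (!file.exists(path))
    stop("missing upstream artifact '", basename(path),
         "': run the '", stage_hint, "' stage first")
  path
}

#' Run the cost-of-time analysis pipeline
#'
#' Executes the requested stages in dependency order:
#' \describe{
#'   \item{simulate}{generate the synthetic cohort and trial recordings
#'     (`cohort.csv`, `trials.csv`);}
#'   \item{segment}{minimum-jerk segmentation of every trial
#'     (`segments.csv`);}
#'   \item{vigour}{block-level and participant-level amplitude-duration
#'     fits and vigour scores (`vigour_blocks.csv`,
#'     `vigour_participants.csv`);}
#'   \item{infer_cot}{per-participant time-cost sampling and sigmoid
#'     identification (`cot.csv`);}
#'   \item{decompose}{three-level variance decomposition of block-level
#'     relative vigour (`variance.json`);}
#'   \item{regress}{trait regressions for relative vigour, log(alpha) and
#'     beta (`regressions.csv`);}
#'   \item{report}{summary report (`report.json`).}
#' }
#'
#' @param config A [cohort_config()] or a path to a YAML file for
#'   [load_config()].
#' @param outdir Output directory (created if needed).
#' @param stages Character vector of stages to run, or `"all"`.
#' @param seed Optional override of the config's master seed.
#' @param hlm_nboot Bootstrap draws for the variance-proportion CIs.
#' @return The run manifest (also written to `run_manifest.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config = cohort_config(), outdir, stages = "all",
                         seed = NULL, hlm_nboot = 200) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (identical(stages, "all")) stages <- .PIPELINE_STAGES
  bad <- setdiff(stages, .PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  timings <- list()
  tic <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    message("[cotreach] stage: ", stage)
    force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }

  if ("simulate" %in% stages) tic("simulate", {
    cohort <- generate_cohort(config)
    utils::write.csv(cohort, .artifact(outdir, "cohort.csv"),
                     row.names = FALSE)
    write_trials(simulate_cohort_trials(cohort, config),
                 .artifact(outdir, "trials.csv"))
  })

  if ("segment" %in% stages) tic("segment", {
    trials <- read_trials(.need(.artifact(outdir, "trials.csv"), "simulate"))
    seg <- segment_trials(trials, fs = config$fs)
    utils::write.csv(seg, .artifact(outdir, "segments.csv"),
                     row.names = FALSE)
  })

  if ("vigour" %in% stages) tic("vigour", {
    seg <- utils::read.csv(.need(.artifact(outdir, "segments.csv"),
                                 "segment"))
    seg <- seg[seg$flag == "ok" & is.finite(seg$duration_s), ]
    fit_rows <- function(d) {
      f <- fit_amplitude_duration(d$stimulus_amplitude_deg, d$duration_s)
      data.frame(slope = f$slope, intercept = f$intercept, r2 = f$r2,
                 n = f$n)
    }
    # participant-level pooled fits
    pf <- do.call(rbind, lapply(split(seg, seg$participant_id), fit_rows))
    pf <- cbind(participant_id = as.integer(rownames(pf)), pf)
    vs <- vigour_scores(stats::setNames(pf$slope, pf$participant_id))
    pf$vigour <- vs$vigour
    pf$relative_vigour <- vs$relative_vigour
    cohort_mean_vigour <- mean(pf$vigour)
    utils::write.csv(pf, .artifact(outdir, "vigour_participants.csv"),
                     row.names = FALSE)
    # block-level fits, normalized by the cohort mean participant vigour
    key <- interaction(seg$participant_id, seg$session_id, seg$block_id,
                       drop = TRUE)
    bf <- do.call(rbind, lapply(split(seg, key), function(d) {
      cbind(d[1, c("participant_id", "session_id", "block_id")],
            fit_rows(d), row.names = NULL)
    }))
    bf <- bf[bf$slope > 0, ]
    bf$vigour <- 1 / bf$slope
    bf$relative_vigour <- bf$vigour / cohort_mean_vigour
    rownames(bf) <- NULL
    utils::write.csv(bf, .artifact(outdir, "vigour_blocks.csv"),
                     row.names = FALSE)
  })

  if ("infer_cot" %in% stages) tic("infer_cot", {
    cohort <- utils::read.csv(.need(.artifact(outdir, "cohort.csv"),
                                    "simulate"))
    pf <- utils::read.csv(.need(.artifact(outdir, "vigour_participants.csv"),
                                "vigour"))
    rows <- lapply(seq_len(nrow(pf)), function(i) {
      p <- cohort[cohort$participant_id == pf$participant_id[i], ]
      arm <- .participant_arm(p, config)
      sc <- sample_cot(arm, list(slope = pf$slope[i],
                                 intercept = pf$intercept[i]))
      fit <- fit_sigmoid(sc$duration_s, sc$g_value)
      data.frame(participant_id = pf$participant_id[i],
                 variant = fit$variant,
                 alpha = fit$alpha, beta = fit$beta, delta = fit$delta,
                 alpha_lo = fit$ci["alpha", 1], alpha_hi = fit$ci["alpha", 2],
                 beta_lo = fit$ci["beta", 1], beta_hi = fit$ci["beta", 2],
                 delta_lo = fit$ci["delta", 1], delta_hi = fit$ci["delta", 2],
                 r2 = fit$r2, flag = fit$flag)
    })
    utils::write.csv(do.call(rbind, rows), .artifact(outdir, "cot.csv"),
                     row.names = FALSE)
  })

  if ("decompose" %in% stages) tic("decompose", {
    bf <- utils::read.csv(.need(.artifact(outdir, "vigour_blocks.csv"),
                                "vigour"))
    hl <- fit_empty_hlm(bf$relative_vigour, bf$participant_id,
                        bf$session_id, bf$block_id, nboot = hlm_nboot)
    res <- list(
      grand_mean = hl$grand_mean,
      omega_e = hl$omega_e, omega_v = hl$omega_v, omega_u = hl$omega_u,
      proportions = as.list(hl$proportions), n = hl$n)
    if (!is.null(hl$ci))
      res$proportion_ci <- apply(hl$ci, 1, as.list, simplify = FALSE)
    jsonlite::write_json(res, .artifact(outdir, "variance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  if ("regress" %in% stages) tic("regress", {
    cohort <- utils::read.csv(.need(.artifact(outdir, "cohort.csv"),
                                    "simulate"))
    pf <- utils::read.csv(.need(.artifact(outdir, "vigour_participants.csv"),
                                "vigour"))
    ct <- utils::read.csv(.need(.artifact(outdir, "cot.csv"), "infer_cot"))
    d <- merge(merge(cohort, pf, by = "participant_id"),
               ct[, c("participant_id", "alpha", "beta", "delta")],
               by = "participant_id", suffixes = c("_true", ""))
    d$log_alpha <- log(d$alpha)
    preds <- c("inertia", "boredom", "impulsivity")
    outs <- c("relative_vigour", "log_alpha", "beta")
    tab <- do.call(rbind, lapply(outs, function(o)
      do.call(rbind, lapply(preds, function(p)
        cbind(predictor = p, outcome = o, ols_regress(d[[p]], d[[o]]))))))
    utils::write.csv(tab, .artifact(outdir, "regressions.csv"),
                     row.names = FALSE)
  })

  if ("report" %in% stages) tic("report", make_report(outdir))

  manifest <- list(
    package_version = as.character(utils::packageVersion("cotreach")),
    seed = config$seed,
    stages = stages,
    config = unclass(config),
    artifacts = as.list(stats::setNames(
      file.path(outdir, c("cohort.csv", "trials.csv", "segments.csv",
                          "vigour_blocks.csv", "vigour_participants.csv",
                          "cot.csv", "variance.json", "regressions.csv",
                          "report.json")),
      c("cohort", "trials", "segments", "vigour_blocks",
        "vigour_participants", "cot", "variance", "regressions", "report"))),
    timings_s = timings)
  jsonlite::write_json(manifest, .artifact(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Summarize pipeline artifacts into a report
#'
#' Collects the vigour distribution, amplitude-duration fit quality,
#' cost-of-time parameters with confidence intervals, variance proportions
#' and the trait regression table into one JSON report.
#'
#' @param outdir Directory holding the pipeline artifacts.
#' @return The report list, invisibly; written to `report.json`.
#' @export
make_report <- function(outdir) {
  pf <- utils::read.csv(.need(.artifact(outdir, "vigour_participants.csv"),
                              "vigour"))
  if (nrow(pf) == 0) stop("empty cohort: no participant-level vigour rows")
  ct <- utils::read.csv(.need(.artifact(outdir, "cot.csv"), "infer_cot"))
  var_json <- jsonlite::read_json(.need(.artifact(outdir, "variance.json"),
                                        "decompose"))
  reg <- utils::read.csv(.need(.artifact(outdir, "regressions.csv"),
                               "regress"))
  report <- list(
    n_participants = nrow(pf),
    vigour = list(
      mean = mean(pf$vigour), sd = stats::sd(pf$vigour),
      range = range(pf$vigour),
      mean_slope = mean(pf$slope), mean_intercept = mean(pf$intercept),
      mean_fit_r2 = mean(pf$r2)),
    cot = list(
      per_participant = ct,
      alpha_mean = mean(ct$alpha), beta_mean = mean(ct$beta),
      delta_mean = mean(ct$delta), mean_fit_r2 = mean(ct$r2, na.rm = TRUE)),
    variance_decomposition = var_json,
    regressions = reg)
  jsonlite::write_json(report, .artifact(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
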