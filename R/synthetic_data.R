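#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: 27 patients; coded
#' sessions every other session over 1-10 and every fourth over 11-34 with
#' baseline (1) and posttreatment (34) always coded; two coders per session
#' with noise calibrated to good agreement (ICC near 0.8); per-patient,
#' phase-dependent flickering between a negative-dominant and a
#' positive-dominant attractor state; and outcomes linearly coupled to
#' phase-2 destabilization and peak processing through planted standardized
#' coefficients mirroring the published effect sizes.
#'
#' @param n_patients Number of patients, default 27.
#' @param coded_sessions Sessions in the coding schedule; baseline and the
#'   last session are always kept, the rest are independently missed with
#'   probability `miss_prob` (at least one kept per phase).
#' @param seed Integer seed; the same seed and config regenerate the cohort
#'   bit-identically. A per-patient seed sequence derived from it keeps each
#'   patient's data stable under changes of `n_patients`.
#' @param switch_range_phase1,switch_range_phase2 Ranges from which each
#'   patient's per-phase attractor switching probability is drawn uniformly.
#' @param emission_means 2 x 2 matrix of per-variable emission means on the
#'   0-3 scale: rows = latent state (`neg_state`, `pos_state`), columns =
#'   variable valence (`neg`, `pos`).
#' @param emission_sd Session-level emission SD around the state mean.
#' @param coder_sd Independent per-coder noise SD before re-discretization;
#'   the default targets an inter-rater ICC of about 0.8.
#' @param miss_prob Probability that a non-anchor scheduled session is
#'   uncoded, default 0.18 (matching roughly 82% tape coverage).
#' @param processing Parameters of the processing trajectory: `base1`,
#'   `base2` (phase baselines), `noise_sd`, `peak_mean`, `peak_sd` (patient
#'   peak levels), `peak_session_mean`, `peak_session_sd`, `width` (Gaussian
#'   bump around the patient's peak session).
#' @param outcome_scid Planted standardized coefficients of the SCID-II
#'   posttreatment model on (scid_pre, dispersion2, peak_processing2).
#' @param outcome_positive Planted standardized coefficients of the positive
#'   pattern strength posttreatment model on (pos_strength_pre, dispersion2,
#'   peak_processing2).
#' @param scid_pre_mean,scid_pre_sd,scid_post_mean,scid_post_sd,pos_post_mean,pos_post_sd
#'   Location/scale used to map the standardized outcome models to score
#'   units. The positive-pattern posttreatment scale is chosen so that the
#'   0-12 strength floor censors almost no mass (a scale pinned to a mean of
#'   about 2 would clip a fifth of the distribution and distort the planted
#'   linear coupling).
#' @param realization_var_adjust Named variance deductions (`scid`,
#'   `positive`) applied to the outcome residual so the planted coefficients
#'   are standardized with respect to the *realized* (discretized) outcome,
#'   whose measurement noise would otherwise shrink them.
#' @param exact_planting If `TRUE` (default), the outcome noise is
#'   residualized against the predictor directions that carry a nonzero
#'   planted coefficient and rescaled to unit sample variance, so the
#'   cohort's sample coefficients equal the planted values exactly (up to
#'   discretization of the realized outcome). Directions with a planted zero
#'   are left stochastic, so null-effect cohorts retain calibrated
#'   R-squared-change test behavior.
#' @param min_resid_var Floor on the standardized residual variance of the
#'   outcome models.
#' @return Object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(
    n_patients = 27,
    coded_sessions = c(1, 2, 4, 6, 8, 10, 14, 18, 22, 26, 30, 34),
    seed = 1,
    switch_range_phase1 = c(0.15, 0.45),
    switch_range_phase2 = c(0.05, 0.30),
    emission_means = matrix(c(2.1, 0.9, 0.7, 2.0), 2, 2,
      dimnames = list(c("neg_state", "pos_state"), c("neg", "pos"))),
    emission_sd = 0.3,
    coder_sd = 0.2,
    miss_prob = 0.18,
    processing = list(
      base1 = 1.1, base2 = 1.2, noise_sd = 0.4,
      peak_mean = 2.3, peak_sd = 0.5,
      peak_session_mean = 15, peak_session_sd = 4, width = 6
    ),
    outcome_scid = c(pre = 0.24, dispersion2 = -0.35, processing2 = -0.45),
    outcome_positive = c(pre = 0.25, dispersion2 = 0.39, processing2 = 0.46),
    scid_pre_mean = 10.82, scid_pre_sd = 2.18,
    scid_post_mean = 6.5, scid_post_sd = 3.35,
    pos_post_mean = 4.5, pos_post_sd = 2.0,
    realization_var_adjust = c(scid = 0.01, positive = 0.10),
    exact_planting = TRUE,
    min_resid_var = 0.1) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    coded_sessions = sort(unique(as.integer(coded_sessions))),
    seed = as.integer(seed),
    switch_range_phase1 = switch_range_phase1,
    switch_range_phase2 = switch_range_phase2,
    emission_means = emission_means,
    emission_sd = emission_sd,
    coder_sd = coder_sd,
    miss_prob = miss_prob,
    processing = processing,
    outcome_scid = outcome_scid,
    outcome_positive = outcome_positive,
    scid_pre_mean = scid_pre_mean, scid_pre_sd = scid_pre_sd,
    scid_post_mean = scid_post_mean, scid_post_sd = scid_post_sd,
    pos_post_mean = pos_post_mean, pos_post_sd = pos_post_sd,
    realization_var_adjust = realization_var_adjust,
    exact_planting = isTRUE(exact_planting),
    min_resid_var = min_resid_var
  )
  if (cfg$n_patients < 1L) {
    stop("n_patients must be >= 1", call. = FALSE)
  }
  for (r in list(switch_range_phase1, switch_range_phase2)) {
    if (length(r) != 2L || any(r < 0) || any(r > 1) || r[1] > r[2]) {
      stop("switching-rate ranges must be ordered probabilities in [0, 1]",
        call. = FALSE)
    }
  }
  if (any(emission_means < 0) || any(emission_means > 3)) {
    stop("emission means must lie on the 0-3 rating scale", call. = FALSE)
  }
  if (emission_sd < 0 || coder_sd < 0) {
    stop("emission and coder SDs must be non-negative", call. = FALSE)
  }
  if (miss_prob < 0 || miss_prob >= 1) {
    stop("miss_prob must be in [0, 1)", call. = FALSE)
  }
  if (length(cfg$coded_sessions) < 4L || cfg$coded_sessions[1] != 1L) {
    stop("coding schedule must start at session 1 and cover both phases",
      call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort config: %d patients, %d scheduled sessions (%s), seed %d\n",
    x$n_patients, length(x$coded_sessions),
    paste(x$coded_sessions, collapse = ","), x$seed
  ))
  cat(sprintf(
    "  switching p1 U(%.2f, %.2f), p2 U(%.2f, %.2f); emission SD %.2f; coder SD %.2f\n",
    x$switch_range_phase1[1], x$switch_range_phase1[2],
    x$switch_range_phase2[1], x$switch_range_phase2[2],
    x$emission_sd, x$coder_sd
  ))
  cat(sprintf(
    "  planted SCID-II betas (%s); positive-pattern betas (%s)\n",
    paste(sprintf("%.2f", x$outcome_scid), collapse = ", "),
    paste(sprintf("%.2f", x$outcome_positive), collapse = ", ")
  ))
  invisible(x)
}

.patient_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 1000003) * 2011 + i)
}

.discretize <- function(x) {
  pmin(pmax(round(x), 0L), 3L)
}

# per-patient raw material, drawn in a fixed order inside the patient's
# RNG substream so cohorts are reproducible under n_patients changes
.draw_patient <- function(cfg, i, schedule) {
  set.seed(.patient_seed(cfg$seed, i))
  ns <- length(cfg$coded_sessions)
  sess <- cfg$coded_sessions
  anchors <- sess %in% c(sess[1], sess[ns])
  in_p2 <- sess >= schedule$phase2[1]

  s1 <- stats::runif(1, cfg$switch_range_phase1[1], cfg$switch_range_phase1[2])
  s2 <- stats::runif(1, cfg$switch_range_phase2[1], cfg$switch_range_phase2[2])

  keep_u <- stats::runif(ns)
  keep <- anchors | keep_u >= cfg$miss_prob
  # coverage guarantee: at least one non-anchor session per phase
  for (ph in list(!in_p2 & !anchors, in_p2 & !anchors)) {
    if (any(ph) && !any(keep & ph)) {
      keep[which(ph)[which.max(keep_u[ph])]] <- TRUE
    }
  }

  switch_u <- stats::runif(ns - 1)
  state <- integer(ns) # 1 = negative-dominant, 2 = positive-dominant
  state[1] <- 1L
  for (j in 2:ns) {
    p_switch <- if (in_p2[j]) s2 else s1
    state[j] <- if (switch_u[j - 1] < p_switch) 3L - state[j - 1] else state[j - 1]
  }

  emis <- matrix(stats::rnorm(ns * 12, sd = cfg$emission_sd), ns, 12)
  pr <- cfg$processing
  peak_target <- stats::rnorm(1, pr$peak_mean, pr$peak_sd)
  peak_sess <- round(stats::rnorm(1, pr$peak_session_mean, pr$peak_session_sd))
  peak_sess <- min(max(peak_sess, schedule$phase2[1]),
    schedule$post_target - 2L)
  proc_noise <- stats::rnorm(ns, sd = pr$noise_sd)
  coder_noise <- array(stats::rnorm(ns * 13 * 2, sd = cfg$coder_sd),
    dim = c(ns, 13, 2))

  scid_pre <- max(0L, as.integer(round(stats::rnorm(1, cfg$scid_pre_mean,
    cfg$scid_pre_sd))))
  e_scid <- stats::rnorm(1)
  e_pos <- stats::rnorm(1)
  post_emis <- stats::rnorm(6, sd = 0.2)
  post_coder <- matrix(stats::rnorm(12, sd = cfg$coder_sd), 6, 2)

  list(
    s1 = s1, s2 = s2, keep = keep, state = state, emis = emis,
    peak_target = peak_target, peak_sess = peak_sess,
    proc_noise = proc_noise, coder_noise = coder_noise,
    scid_pre = scid_pre, e_scid = e_scid, e_pos = e_pos,
    post_emis = post_emis, post_coder = post_coder
  )
}

#' Generate a synthetic coded-session cohort
#'
#' Simulates the full data layout the analysis pipeline consumes. Each
#' patient carries a latent two-state chain per phase — a negative-dominant
#' (pathological) and a positive-dominant (adaptive) attractor — whose
#' switching probability is drawn from the config's per-phase range
#' ("flickering"). Each coded session emits the 12 pattern variables by
#' adding Gaussian noise around the active state's valence means and the
#' processing variable from a rising phase-2 trajectory peaking at a
#' patient-specific session; two coders re-observe every emission with
#' independent noise, and all ratings are discretized to the 0-3 scale.
#' SCID-II and positive-pattern posttreatment scores are produced by the
#' planted standardized linear models on the *realized* phase-2 dispersion
#' and peak processing (computed with the same pipeline rules the analysis
#' applies), rescaled to score units, discretized, and floored at their
#' scale minimum; the positive-pattern outcome is realized physically by
#' regenerating the posttreatment session's positive ratings around the
#' model's target strength.
#'
#' @param config A [synthetic_config()].
#' @param schedule A [phase_schedule()] (defines phase membership and the
#'   post-assessment target).
#' @return Object of class `"synthetic_cohort"`: list with `codings` (long
#'   per-coder table as read by [read_codings()]), `outcomes` (per-patient
#'   SCID-II table), `truth` (per-patient latent parameters and planted
#'   coefficients; diagnostics only, never an analysis input), and `config`.
#' @export
generate_cohort <- function(config = synthetic_config(),
                            schedule = phase_schedule()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_patients
  sess <- config$coded_sessions
  ns <- length(sess)
  ids <- sprintf("P%03d", seq_len(n))
  vars <- change_variables()
  neg_cols <- change_variables("negative")
  pos_cols <- change_variables("positive")
  in_p2 <- sess >= schedule$phase2[1]
  pr <- config$processing

  draws <- lapply(seq_len(n), function(i) .draw_patient(config, i, schedule))

  coding_rows <- vector("list", n)
  for (i in seq_len(n)) {
    d <- draws[[i]]
    mu_neg <- config$emission_means[d$state, "neg"]
    mu_pos <- config$emission_means[d$state, "pos"]
    latent <- cbind(
      matrix(mu_pos, ns, 6) + d$emis[, 1:6],
      matrix(mu_neg, ns, 6) + d$emis[, 7:12]
    )
    amp <- max(0, d$peak_target - pr$base2)
    proc_mu <- ifelse(in_p2,
      pr$base2 + amp * exp(-((sess - d$peak_sess) / pr$width)^2),
      pr$base1
    )
    latent <- cbind(latent, proc_mu + d$proc_noise)

    per_coder <- lapply(1:2, function(cd) {
      r <- .discretize(latent + d$coder_noise[, , cd])
      df <- data.frame(
        patient_id = ids[i], session_number = sess,
        coder_id = paste0("C", cd), stringsAsFactors = FALSE
      )
      df[vars] <- as.data.frame(r)
      df[d$keep, , drop = FALSE]
    })
    coding_rows[[i]] <- rbind(per_coder[[1]], per_coder[[2]])
  }
  codings <- do.call(rbind, coding_rows)
  codings <- codings[order(codings$patient_id, codings$session_number,
    codings$coder_id), , drop = FALSE]
  rownames(codings) <- NULL

  # realized process measures, computed with the analysis pipeline's own rules
  proc_sum <- build_summaries(codings, outcomes = NULL, schedule = schedule)

  m <- match(ids, proc_sum$patient_id)
  disp2 <- proc_sum$dispersion2[m]
  proc2 <- proc_sum$peak_processing2[m]
  pos_pre <- proc_sum$pos_strength_pre[m]
  scid_pre <- vapply(draws, `[[`, numeric(1), "scid_pre")

  zs <- function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x, na.rm = TRUE)) / s
  }
  planted_y <- function(Z, a, e_raw, adjust) {
    C <- suppressWarnings(stats::cor(Z, use = "pairwise.complete.obs"))
    C[!is.finite(C)] <- 0
    diag(C) <- 1
    expl <- drop(crossprod(a, C %*% a))
    sigma <- sqrt(max(config$min_resid_var, 1 - expl - adjust))
    e <- e_raw
    active <- which(a != 0)
    if (config$exact_planting && length(active) &&
      length(e) >= length(active) + 3L) {
      X <- cbind(1, Z[, active, drop = FALSE])
      e <- stats::residuals(stats::lm.fit(X, e_raw))
      s <- stats::sd(e)
      if (is.finite(s) && s > 0) e <- e / s
    }
    drop(Z %*% a) + sigma * e
  }

  Z_scid <- cbind(zs(scid_pre), zs(disp2), zs(proc2))
  y_scid <- planted_y(Z_scid, config$outcome_scid,
    vapply(draws, `[[`, numeric(1), "e_scid"),
    config$realization_var_adjust[["scid"]])
  scid_post <- pmax(0L, as.integer(round(config$scid_post_mean +
    config$scid_post_sd * y_scid)))

  Z_pos <- cbind(zs(pos_pre), zs(disp2), zs(proc2))
  y_pos <- planted_y(Z_pos, config$outcome_positive,
    vapply(draws, `[[`, numeric(1), "e_pos"),
    config$realization_var_adjust[["positive"]])
  pos_target <- pmin(12, pmax(0, config$pos_post_mean +
    config$pos_post_sd * y_pos))

  # realize the positive-pattern outcome in the posttreatment session itself:
  # regenerate its six positive ratings around target/4 per node
  post_sess <- sess[ns]
  for (i in seq_len(n)) {
    if (is.na(pos_target[i])) next
    d <- draws[[i]]
    node <- pos_target[i] / 4 + d$post_emis
    for (cd in 1:2) {
      rows <- codings$patient_id == ids[i] &
        codings$session_number == post_sess &
        codings$coder_id == paste0("C", cd)
      if (!any(rows)) next
      codings[rows, pos_cols] <-
        as.list(.discretize(node + d$post_coder[, cd]))
    }
  }

  outcomes <- data.frame(
    patient_id = ids,
    scid_pre = as.integer(scid_pre),
    scid_post = scid_post,
    assessment_session = post_sess,
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    patient_id = ids,
    switch_rate_phase1 = vapply(draws, `[[`, numeric(1), "s1"),
    switch_rate_phase2 = vapply(draws, `[[`, numeric(1), "s2"),
    peak_target = vapply(draws, `[[`, numeric(1), "peak_target"),
    peak_session = vapply(draws, `[[`, numeric(1), "peak_sess"),
    realized_dispersion2 = disp2,
    realized_processing2 = proc2,
    pos_post_target = pos_target,
    states = vapply(draws, function(d) paste(d$state, collapse = ""),
      character(1)),
    stringsAsFactors = FALSE
  )
  attr(truth, "outcome_scid") <- config$outcome_scid
  attr(truth, "outcome_positive") <- config$outcome_positive

  structure(
    list(codings = codings, outcomes = outcomes, truth = truth,
      config = config, schedule = schedule),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d patients, %d coding rows (%d coders/session), seed %d\n",
    x$config$n_patients, nrow(x$codings), 2L, x$config$seed
  ))
  invisible(x)
}

#' Mean dispersion as a function of the attractor switching rate
#'
#' Generates one cohort per switching rate (both phase ranges pinned to the
#' rate) and reports the cohort mean of phase-2 dispersion. Destabilization
#' operationalized as dispersion should grow with the flickering rate; a
#' rate of 0 keeps every patient in one attractor for the whole phase.
#'
#' @param config Base [synthetic_config()] (its seed feeds each run).
#' @param rates Numeric vector of switching probabilities in [0, 1].
#' @param schedule A [phase_schedule()].
#' @return `data.frame` with `rate` and `mean_dispersion2`, sorted by rate.
#' @export
sweep_switching_rate <- function(config = synthetic_config(), rates,
                                 schedule = phase_schedule()) {
  stopifnot(all(rates >= 0), all(rates <= 1))
  rates <- sort(rates)
  out <- vapply(rates, function(r) {
    cfg <- config
    cfg$switch_range_phase1 <- c(r, r)
    cfg$switch_range_phase2 <- c(r, r)
    co <- generate_cohort(cfg, schedule)
    s <- build_summaries(co$codings, co$outcomes, schedule)
    mean(s$dispersion2, na.rm = TRUE)
  }, numeric(1))
  data.frame(rate = rates, mean_dispersion2 = out)
}
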