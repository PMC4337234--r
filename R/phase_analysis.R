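#' Treatment phase schedule
#'
#' Encodes the two-phase structure of the therapy protocol: a symptom-
#' reduction phase (sessions 1-10) followed by a schema-focused phase
#' (sessions 11-34). Session 1 is the baseline measurement and the coded
#' session closest to the post-assessment target (default session 34) is the
#' posttreatment measurement; both are excluded from their phases'
#' dispersion sets.
#'
#' @param phase1 Integer range `c(first, last)` of the symptom-reduction
#'   phase, default `c(1, 10)`.
#' @param phase2 Integer range of the schema-focused phase, default
#'   `c(11, 34)`.
#' @param baseline Baseline session number, default 1; must fall in `phase1`.
#' @param post_target Target session of the post assessment, default 34;
#'   must exceed the end of `phase1`.
#' @return Object of class `"phase_schedule"`.
#' @export
phase_schedule <- function(phase1 = c(1, 10), phase2 = c(11, 34),
                           baseline = 1, post_target = 34) {
  stopifnot(
    length(phase1) == 2L, length(phase2) == 2L,
    phase1[1] <= phase1[2], phase2[1] <= phase2[2]
  )
  if (phase1[2] >= phase2[1]) {
    stop("phase ranges must be disjoint and ordered", call. = FALSE)
  }
  if (baseline < phase1[1] || baseline > phase1[2]) {
    stop("baseline session must fall in the phase-1 range", call. = FALSE)
  }
  if (post_target <= phase1[2]) {
    stop("post-assessment target must follow phase 1", call. = FALSE)
  }
  structure(
    list(
      phase1 = as.integer(phase1), phase2 = as.integer(phase2),
      baseline = as.integer(baseline), post_target = as.integer(post_target)
    ),
    class = "phase_schedule"
  )
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat(sprintf(
    "Phase schedule: baseline %d | phase 1: %d-%d | phase 2: %d-%d | post target %d\n",
    x$baseline, x$phase1[1], x$phase1[2], x$phase2[1], x$phase2[2],
    x$post_target
  ))
  invisible(x)
}

#' Identify a patient's post-assessment session
#'
#' The posttreatment measurement uses the coded session closest to the
#' schedule's target (session 34); among equidistant candidates the earlier
#' session is chosen. Only sessions at or after the phase-2 start qualify.
#'
#' @param sessions Integer vector of a patient's coded session numbers.
#' @param schedule A [phase_schedule()].
#' @return The post session number, or `NA` if the patient has no coded
#'   session at or after the phase-2 start.
#' @export
post_session <- function(sessions, schedule = phase_schedule()) {
  cand <- sessions[sessions >= schedule$phase2[1]]
  if (!length(cand)) {
    return(NA_integer_)
  }
  d <- abs(cand - schedule$post_target)
  cand <- cand[d == min(d)]
  as.integer(min(cand))
}

#' Assign coded sessions to analysis phases
#'
#' @param session Integer vector of session numbers (>= 1).
#' @param schedule A [phase_schedule()].
#' @param post_session The patient's identified post-assessment session (see
#'   [post_session()]), or `NA` when unknown; needed to separate the post
#'   measurement from the phase-2 dispersion set.
#' @return Character vector with levels `baseline`, `phase1`, `phase2`,
#'   `post`, `outside`. The baseline and post sessions are labelled as such,
#'   not as members of their phases, so no session contributes to both a
#'   phase's dispersion set and an endpoint measurement.
#' @export
#' @examples
#' assign_phase(c(1, 7, 15, 40), phase_schedule(), post_session = 34)
assign_phase <- function(session, schedule = phase_schedule(),
                         post_session = NA) {
  stopifnot(all(session >= 1))
  out <- rep("outside", length(session))
  in1 <- session >= schedule$phase1[1] & session <= schedule$phase1[2]
  in2 <- session >= schedule$phase2[1] & session <= schedule$phase2[2]
  out[in1] <- "phase1"
  out[in2] <- "phase2"
  out[session == schedule$baseline] <- "baseline"
  if (!is.na(post_session)) {
    out[session == post_session] <- "post"
  }
  out
}

#' Peak emotional processing in a set of sessions
#'
#' Emotional processing often rises and then falls within a phase, so the
#' highest level achieved (the peak) detects a shift in meaning and affect
#' more reliably than the phase mean. Returns the maximum averaged
#' processing rating and the earliest session attaining it.
#'
#' @param processing Numeric vector of averaged processing ratings.
#' @param session Matching session numbers.
#' @return List with `peak` (numeric, `NA` for an empty phase) and `session`
#'   (session of the peak, earliest on ties).
#' @export
peak_processing <- function(processing, session) {
  keep <- !is.na(processing)
  processing <- processing[keep]
  session <- session[keep]
  if (!length(processing)) {
    return(list(peak = NA_real_, session = NA_integer_))
  }
  peak <- max(processing)
  list(peak = peak, session = as.integer(min(session[processing == peak])))
}

#' Baseline and posttreatment pattern strengths for one patient
#'
#' Pattern strength (0-12) is measured at the baseline session and at the
#' coded session closest to the post-assessment target (earlier session on
#' ties), for each valence.
#'
#' @param profiles [session_profiles()] rows for one patient.
#' @param schedule A [phase_schedule()].
#' @return List with `post_session` and per-valence `pre` / `post`
#'   strengths (`NA` and a `missing` reason when baseline or post coding is
#'   absent).
#' @export
endpoint_strengths <- function(profiles, schedule = phase_schedule()) {
  sessions <- sort(unique(profiles$session_number))
  post <- post_session(sessions, schedule)
  get <- function(valence, sess) {
    if (is.na(sess)) {
      return(NA_real_)
    }
    row <- profiles[profiles$valence == valence &
      profiles$session_number == sess, , drop = FALSE]
    if (nrow(row) == 0L) NA_real_ else row$strength[1]
  }
  base <- if (schedule$baseline %in% sessions) schedule$baseline else NA_integer_
  list(
    post_session = post,
    neg_pre = get("negative", base), neg_post = get("negative", post),
    pos_pre = get("positive", base), pos_post = get("positive", post),
    missing = c(
      if (is.na(base)) "no baseline coding",
      if (is.na(post)) "no posttreatment coding"
    )
  )
}

#' Build the per-patient analysis table
#'
#' Runs the full per-patient reduction: coder averaging, pattern profiles,
#' phase assignment, per-phase state-space grids and dispersion, per-phase
#' peak processing, endpoint pattern strengths, and the merge with the
#' SCID-II outcome table. One row per patient passing the coverage rules;
#' patients failing them are dropped with a reason recorded in the
#' `"dropped"` attribute.
#'
#' Phase-1 dispersion uses the phase-1 sessions excluding baseline; phase-2
#' dispersion uses the phase-2 sessions excluding the post-assessment
#' session. Peak processing for phase 1 covers the phase-1 range including
#' baseline; for phase 2 it covers phase-2 sessions before the post
#' assessment, so the peak always precedes the posttreatment measurement.
#'
#' @param codings Raw coding `data.frame` (per coder; see [read_codings()]).
#' @param outcomes Outcome `data.frame` (see [read_outcomes()]), or `NULL`
#'   to produce process columns only.
#' @param schedule A [phase_schedule()].
#' @param threshold Activation threshold, default 2.
#' @param cognitive_activation Passed to [session_profiles()].
#' @return `data.frame` of class `"patient_summaries"`, one row per patient:
#'   `patient_id`, `dispersion1`, `dispersion2`, `peak_processing1`,
#'   `peak_processing2`, `peak_session1`, `peak_session2`,
#'   `neg_strength_pre`, `neg_strength_post`, `pos_strength_pre`,
#'   `pos_strength_post`, `post_session`, `scid_pre`, `scid_post`.
#'   Attributes: `dropped` (`data.frame` patient/reason), `grids` (named
#'   list of per-patient phase grids for plotting/export).
#' @export
build_summaries <- function(codings, outcomes = NULL,
                            schedule = phase_schedule(), threshold = 2,
                            cognitive_activation = "node-mean") {
  averaged <- average_coders(codings)
  profiles <- session_profiles(averaged, threshold, cognitive_activation)
  points <- activation_points(profiles)

  patients <- unique(averaged$patient_id)
  rows <- vector("list", length(patients))
  dropped <- list()
  grids <- list()

  for (i in seq_along(patients)) {
    p <- patients[i]
    pp <- points[points$patient_id == p, , drop = FALSE]
    prof <- profiles[profiles$patient_id == p, , drop = FALSE]
    post <- post_session(pp$session_number, schedule)
    lab <- assign_phase(pp$session_number, schedule, post_session = post)

    reason <- NULL
    if (!(schedule$baseline %in% pp$session_number)) {
      reason <- "no baseline coding"
    } else if (is.na(post)) {
      reason <- "no posttreatment coding"
    } else if (!any(lab == "phase1")) {
      reason <- "no phase-1 session beyond baseline"
    } else if (!any(lab == "phase2")) {
      reason <- "no phase-2 session beyond the post-assessment session"
    }
    if (!is.null(reason)) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        patient_id = p, reason = reason, stringsAsFactors = FALSE
      )
      next
    }

    ph1 <- pp[lab == "phase1", , drop = FALSE]
    ph2 <- pp[lab == "phase2", , drop = FALSE]
    ok1 <- !is.na(ph1$x) & !is.na(ph1$y)
    ok2 <- !is.na(ph2$x) & !is.na(ph2$y)
    g1 <- build_grid(ph1$x[ok1], ph1$y[ok1])
    g2 <- build_grid(ph2$x[ok2], ph2$y[ok2])
    grids[[p]] <- list(phase1 = g1, phase2 = g2)

    in_p1_peak <- lab %in% c("baseline", "phase1")
    # peak window for phase 2: schema-phase sessions preceding the post
    # measurement (the post session itself is the outcome, not process)
    pk1 <- peak_processing(pp$processing[in_p1_peak],
      pp$session_number[in_p1_peak])
    pk2 <- peak_processing(pp$processing[lab == "phase2"],
      pp$session_number[lab == "phase2"])

    ep <- endpoint_strengths(prof, schedule)

    rows[[i]] <- data.frame(
      patient_id = p,
      dispersion1 = as.numeric(dispersion(g1)),
      dispersion2 = as.numeric(dispersion(g2)),
      peak_processing1 = pk1$peak,
      peak_processing2 = pk2$peak,
      peak_session1 = pk1$session,
      peak_session2 = pk2$session,
      neg_strength_pre = ep$neg_pre,
      neg_strength_post = ep$neg_post,
      pos_strength_pre = ep$pos_pre,
      pos_strength_post = ep$pos_post,
      post_session = ep$post_session,
      stringsAsFactors = FALSE
    )
  }

  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    stop("no patient passed the coverage rules", call. = FALSE)
  }
  if (!is.null(outcomes)) {
    m <- match(out$patient_id, outcomes$patient_id)
    out$scid_pre <- outcomes$scid_pre[m]
    out$scid_post <- outcomes$scid_post[m]
  } else {
    out$scid_pre <- NA_integer_
    out$scid_post <- NA_integer_
  }
  rownames(out) <- NULL
  dropped <- if (length(dropped)) {
    do.call(rbind, dropped)
  } else {
    data.frame(patient_id = character(), reason = character(),
      stringsAsFactors = FALSE)
  }
  structure(out,
    dropped = dropped, grids = grids,
    class = c("patient_summaries", "data.frame")
  )
}
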