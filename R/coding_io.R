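#' CHANGE variable keys
#'
#' The 13 per-session rating variables of the CHANGE observational coding
#' system as used throughout this package: six positively valenced and six
#' negatively valenced pattern variables (View of Self, Hope, Relationships,
#' Emotion, Behavior, Somatic functioning) plus Emotional Processing. Every
#' variable is rated on the ordinal 0-3 scale (0 = not present / very low,
#' 3 = high).
#'
#' @param valence Optional filter: `"positive"`, `"negative"`, or
#'   `"processing"`. Default returns all 13 keys.
#' @return Character vector of column names.
#' @export
#' @examples
#' change_variables()
#' change_variables("negative")
change_variables <- function(valence = c("all", "positive", "negative", "processing")) {
  valence <- match.arg(valence)
  base <- c("view_self", "hope", "relationships", "emotion", "behavior", "somatic")
  pos <- paste0("pos_", base)
  neg <- paste0("neg_", base)
  switch(valence,
    all = c(pos, neg, "processing"),
    positive = pos,
    negative = neg,
    processing = "processing"
  )
}

.coding_id_cols <- c("patient_id", "session_number", "coder_id")

#' Read a coded-session table
#'
#' Reads a long-format CSV of per-session, per-coder CHANGE ratings: one row
#' per (patient, session, coder), with the 13 rating columns named as in
#' [change_variables()]. Ratings must be in \{0, 1, 2, 3\}; missing single
#' ratings are the explicit `NA` sentinel (empty cell or `NA`), never an
#' absent column.
#'
#' @param path Path to a CSV file with header.
#' @return A `data.frame` with columns `patient_id` (character),
#'   `session_number` (integer), `coder_id` (character) and the 13 rating
#'   columns (integer, `NA` allowed). Row order is preserved.
#' @seealso [write_codings()], [average_coders()], [validate_dataset()]
#' @export
read_codings <- function(path) {
  if (!file.exists(path)) {
    stop("codings file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c(.coding_id_cols, change_variables())
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("codings file is missing required column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  df <- df[required]
  df$patient_id <- as.character(df$patient_id)
  df$coder_id <- as.character(df$coder_id)
  sn <- suppressWarnings(as.integer(df$session_number))
  if (anyNA(sn) || any(sn < 1)) {
    bad <- which(is.na(sn) | sn < 1)[1]
    stop("invalid session_number at data row ", bad, call. = FALSE)
  }
  df$session_number <- sn
  for (v in change_variables()) {
    raw <- df[[v]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & !(raw %in% c("", "NA")) & is.na(val))
    if (length(bad)) {
      stop("non-numeric rating in column '", v, "' at data row ", bad[1],
        call. = FALSE
      )
    }
    off <- which(!is.na(val) & !(val %in% 0:3))
    if (length(off)) {
      stop("rating outside {0,1,2,3} in column '", v, "' at data row ", off[1],
        call. = FALSE
      )
    }
    df[[v]] <- as.integer(val)
  }
  key <- do.call(paste, c(df[.coding_id_cols], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate (patient_id, session_number, coder_id) rows in ", path,
      call. = FALSE
    )
  }
  rownames(df) <- NULL
  df
}

#' Write a coded-session table
#'
#' Inverse of [read_codings()]: writes the long CSV dialect this package
#' reads (UTF-8, `.` decimal point, `NA` for missing ratings).
#'
#' @param codings Coding `data.frame` as returned by [read_codings()] or
#'   [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_codings <- function(codings, path) {
  required <- c(.coding_id_cols, change_variables())
  missing <- setdiff(required, names(codings))
  if (length(missing)) {
    stop("codings are missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  utils::write.csv(codings[required], path, row.names = FALSE, quote = FALSE,
    na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a patient outcome table
#'
#' Reads the per-patient outcome CSV: SCID-II dimensional symptom sums at
#' pretreatment and posttreatment plus the session number of the post
#' assessment.
#'
#' @param path Path to a CSV with columns `patient_id`, `scid_pre`,
#'   `scid_post`, `assessment_session`.
#' @return `data.frame` with those columns; SCID sums are non-negative
#'   integers.
#' @export
read_outcomes <- function(path) {
  if (!file.exists(path)) {
    stop("outcomes file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "scid_pre", "scid_post", "assessment_session")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("outcomes file is missing required column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  df <- df[required]
  df$patient_id <- as.character(df$patient_id)
  for (v in c("scid_pre", "scid_post", "assessment_session")) {
    val <- suppressWarnings(as.integer(df[[v]]))
    if (any(!is.na(df[[v]]) & is.na(val))) {
      stop("non-integer value in outcomes column '", v, "'", call. = FALSE)
    }
    df[[v]] <- val
  }
  if (any(df$scid_pre < 0, na.rm = TRUE) || any(df$scid_post < 0, na.rm = TRUE)) {
    stop("SCID-II dimensional scores must be non-negative", call. = FALSE)
  }
  if (any(df$assessment_session < 1, na.rm = TRUE)) {
    stop("assessment_session must be >= 1", call. = FALSE)
  }
  if (anyDuplicated(df$patient_id)) {
    stop("duplicate patient_id in outcomes table", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Write a patient outcome table
#'
#' @param outcomes Outcome `data.frame` (see [read_outcomes()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  utils::write.csv(
    outcomes[c("patient_id", "scid_pre", "scid_post", "assessment_session")],
    path,
    row.names = FALSE, quote = FALSE, na = "NA", fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Average ratings across coders
#'
#' Collapses per-coder rows to one row per (patient, session) by taking the
#' per-variable arithmetic mean across coders. With the usual two coders the
#' averaged ratings lie on the half-point grid \{0, 0.5, 1, ..., 3\}. Sessions
#' coded by a single coder pass through unchanged. Averaged ratings are the
#' input to all downstream scoring.
#'
#' Missing ratings (`NA`) are dropped from the per-variable mean; a variable
#' missing for every coder stays `NA` and propagates as a missing node rather
#' than being imputed.
#'
#' @param codings Coding `data.frame` (see [read_codings()]).
#' @return `data.frame` with columns `patient_id`, `session_number`,
#'   `n_coders`, and the 13 rating columns (numeric). Ordered by patient then
#'   session.
#' @export
average_coders <- function(codings) {
  vars <- change_variables()
  key <- paste(codings$patient_id, codings$session_number, sep = "\r")
  ckey <- paste(key, codings$coder_id, sep = "\r")
  if (anyDuplicated(ckey)) {
    dup <- ckey[duplicated(ckey)][1]
    stop("conflicting duplicate coder rows for (patient, session, coder): ",
      gsub("\r", ", ", dup),
      call. = FALSE
    )
  }
  grp <- factor(key, levels = unique(key))
  out <- data.frame(
    patient_id = tapply(codings$patient_id, grp, `[`, 1),
    session_number = as.integer(tapply(codings$session_number, grp, `[`, 1)),
    n_coders = as.integer(tapply(codings$coder_id, grp, length)),
    stringsAsFactors = FALSE
  )
  for (v in vars) {
    out[[v]] <- as.numeric(tapply(codings[[v]], grp, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) NA_real_ else mean(x)
    }))
  }
  out <- out[order(out$patient_id, out$session_number), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate a coded-session dataset against the analysis coverage rules
#'
#' Produces a report (never an error) listing out-of-range ratings, duplicate
#' coder rows, per-patient session coverage by treatment phase, and patients
#' that cannot enter the analysis: a patient is analyzable only with a coded
#' baseline session, at least one phase-1 session beyond baseline, at least
#' one phase-2 session beyond the post-assessment session, a coded session at
#' or after the phase-2 start (the posttreatment measurement), and pre/post
#' outcome values.
#'
#' @param codings Coding `data.frame`.
#' @param outcomes Outcome `data.frame`, or `NULL` to skip outcome checks.
#' @param schedule A [phase_schedule()].
#' @return Object of class `"change_validation"`: list with `ok` (logical),
#'   `violations` (`data.frame` of patient/check/detail), and `coverage`
#'   (per-patient counts of coded sessions by phase). Input data are never
#'   modified.
#' @export
validate_dataset <- function(codings, outcomes = NULL, schedule = phase_schedule()) {
  violations <- list()
  flag <- function(patient, check, detail) {
    violations[[length(violations) + 1L]] <<- data.frame(
      patient_id = patient, check = check, detail = detail,
      stringsAsFactors = FALSE
    )
  }

  vars <- change_variables()
  for (v in intersect(vars, names(codings))) {
    off <- which(!is.na(codings[[v]]) & !(codings[[v]] %in% 0:3))
    for (i in off) {
      flag(codings$patient_id[i], "out_of_range",
        sprintf("%s = %s at session %d", v, codings[[v]][i],
          codings$session_number[i]))
    }
  }
  ckey <- paste(codings$patient_id, codings$session_number, codings$coder_id,
    sep = "\r")
  for (d in unique(ckey[duplicated(ckey)])) {
    parts <- strsplit(d, "\r", fixed = TRUE)[[1]]
    flag(parts[1], "duplicate_row",
      sprintf("session %s coder %s coded twice", parts[2], parts[3]))
  }

  patients <- unique(codings$patient_id)
  cov <- data.frame(
    patient_id = patients,
    n_baseline = 0L, n_phase1 = 0L, n_phase2 = 0L, n_post = 0L,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(patients)) {
    p <- patients[i]
    sess <- sort(unique(codings$session_number[codings$patient_id == p]))
    post <- post_session(sess, schedule)
    lab <- assign_phase(sess, schedule, post_session = post)
    cov$n_baseline[i] <- sum(lab == "baseline")
    cov$n_phase1[i] <- sum(lab == "phase1")
    cov$n_phase2[i] <- sum(lab == "phase2")
    cov$n_post[i] <- sum(lab == "post")
    if (cov$n_baseline[i] == 0L) {
      flag(p, "missing_baseline", "no coded baseline session")
    }
    if (cov$n_phase1[i] == 0L) {
      flag(p, "insufficient_phase_coverage",
        "no phase-1 session beyond baseline")
    }
    if (cov$n_post[i] == 0L) {
      flag(p, "missing_post", "no coded session at or after phase-2 start")
    }
    if (cov$n_phase2[i] == 0L) {
      flag(p, "insufficient_phase_coverage",
        "no phase-2 session beyond the post-assessment session")
    }
    if (!is.null(outcomes)) {
      row <- outcomes[outcomes$patient_id == p, , drop = FALSE]
      if (nrow(row) == 0L || is.na(row$scid_pre[1]) || is.na(row$scid_post[1])) {
        flag(p, "missing_outcome", "no pre/post SCID-II record")
      }
    }
  }

  violations <- if (length(violations)) {
    do.call(rbind, violations)
  } else {
    data.frame(patient_id = character(), check = character(),
      detail = character(), stringsAsFactors = FALSE)
  }
  structure(
    list(ok = nrow(violations) == 0L, violations = violations, coverage = cov),
    class = "change_validation"
  )
}

#' @export
print.change_validation <- function(x, ...) {
  cat("CHANGE dataset validation:",
    if (x$ok) "OK" else sprintf("%d violation(s)", nrow(x$violations)), "\n")
  cat(sprintf("  %d patient(s); coded sessions per patient: baseline %s, phase1 %s, phase2 %s, post %s\n",
    nrow(x$coverage),
    paste(range(x$coverage$n_baseline), collapse = "-"),
    paste(range(x$coverage$n_phase1), collapse = "-"),
    paste(range(x$coverage$n_phase2), collapse = "-"),
    paste(range(x$coverage$n_post), collapse = "-")))
  if (!x$ok) {
    print(utils::head(x$violations, 20), row.names = FALSE)
    if (nrow(x$violations) > 20) cat("  ...\n")
  }
  invisible(x)
}

#' Export activation trajectories in a GridWare-style dialect
#'
#' Writes per-patient-phase activation trajectories as a tab-delimited file
#' with an onset column and one column per grid dimension, the layout the
#' GridWare trajectory importer expects. Each coded session is one unit of
#' duration; onsets are consecutive integers within a trajectory.
#'
#' @param points `data.frame` with columns `patient_id`, `phase`, `x`
#'   (positive activation) and `y` (negative activation), in trajectory
#'   order; `x`, `y` must be integers in 0..4. An optional `onset` column
#'   overrides the default consecutive onsets.
#' @param path Output file path.
#' @return `path`, invisibly. An empty `points` writes the header only, with
#'   a warning.
#' @export
export_trajectories <- function(points, path) {
  required <- c("patient_id", "phase", "x", "y")
  missing <- setdiff(required, names(points))
  if (length(missing)) {
    stop("trajectory points are missing column(s): ",
      paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(points)) {
    bad <- which(!(points$x %in% 0:4) | !(points$y %in% 0:4))
    if (length(bad)) {
      stop(sprintf(
        "activation coordinates outside 0..4 at row %d: (%s, %s)",
        bad[1], points$x[bad[1]], points$y[bad[1]]
      ), call. = FALSE)
    }
  }
  if (!"onset" %in% names(points)) {
    points$onset <- stats::ave(
      rep(1L, nrow(points)),
      paste(points$patient_id, points$phase, sep = "\r"),
      FUN = seq_along
    )
  }
  out <- points[c("patient_id", "phase", "onset", "x", "y")]
  names(out) <- c("patient_id", "phase", "Onset", "pos_activation",
    "neg_activation")
  utils::write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  if (nrow(points) == 0L) {
    warning("no trajectory points: wrote header only", call. = FALSE)
  }
  invisible(path)
}

#' Read a trajectory file written by [export_trajectories()]
#'
#' @param path Tab-delimited trajectory file.
#' @return `data.frame` with columns `patient_id`, `phase`, `onset`, `x`, `y`.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- c("patient_id", "phase", "onset", "x", "y")
  df$patient_id <- as.character(df$patient_id)
  df$phase <- as.character(df$phase)
  df
}
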