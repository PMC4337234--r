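#' Fit the full pattern-destabilization analysis
#'
#' The package's front door: runs the whole pipeline from per-coder session
#' codings and a patient outcome table to the study-level statistics.
#' Stages: coder averaging; node, strength (0-12) and activation (0-4)
#' scoring per valence; per-patient per-phase 5x5 state-space grids and
#' dispersion; peak emotional processing per phase; baseline/posttreatment
#' pattern strengths; then the outcome layer — pairwise correlation matrix
#' of the ten analysis variables, paired pre/post t-tests with Cohen's d,
#' and hierarchical regressions (Step 1: pretreatment score; Step 2: that
#' phase's dispersion and peak processing) for each of the three outcomes
#' and each phase.
#'
#' @param codings Coding `data.frame` (see [read_codings()]).
#' @param outcomes Outcome `data.frame` (see [read_outcomes()]).
#' @param schedule A [phase_schedule()].
#' @param threshold Activation threshold on node scores, default 2.
#' @param cognitive_activation `"node-mean"` (default) or `"per-variable"`;
#'   see [session_profiles()].
#' @return Object of class `"pattern_analysis"`: list with `summaries` (the
#'   per-patient table), `correlations` (`"cor_matrix"`), `paired_tests`
#'   (named list of `"paired_t"`), `regressions` (nested list
#'   `phase1`/`phase2` by outcome of `"hier_reg"`), `dropped`, `schedule`,
#'   and the scoring options.
#' @export
#' @examples
#' co <- generate_cohort(synthetic_config(seed = 7))
#' fit <- pattern_analysis(co$codings, co$outcomes)
#' fit
pattern_analysis <- function(codings, outcomes,
                             schedule = phase_schedule(), threshold = 2,
                             cognitive_activation = "node-mean") {
  summaries <- build_summaries(codings, outcomes, schedule, threshold,
    cognitive_activation)

  table1_vars <- c(
    "dispersion1", "dispersion2", "peak_processing1", "peak_processing2",
    "scid_pre", "scid_post", "neg_strength_pre", "neg_strength_post",
    "pos_strength_pre", "pos_strength_post"
  )
  correlations <- correlation_matrix(summaries, table1_vars)

  paired_tests <- list(
    negative_strength = paired_t(summaries$neg_strength_pre,
      summaries$neg_strength_post),
    positive_strength = paired_t(summaries$pos_strength_pre,
      summaries$pos_strength_post),
    processing = paired_t(summaries$peak_processing1,
      summaries$peak_processing2),
    dispersion = paired_t(summaries$dispersion1, summaries$dispersion2),
    scid = paired_t(summaries$scid_pre, summaries$scid_post)
  )

  spec_for <- list(
    scid = c(out = "scid_post", pre = "scid_pre"),
    negative_pattern = c(out = "neg_strength_post", pre = "neg_strength_pre"),
    positive_pattern = c(out = "pos_strength_post", pre = "pos_strength_pre")
  )
  regressions <- lapply(c(phase1 = 1L, phase2 = 2L), function(ph) {
    proc_vars <- paste0(c("dispersion", "peak_processing"), ph)
    lapply(spec_for, function(sp) {
      hierarchical_regression(summaries, sp[["out"]],
        list(sp[["pre"]], proc_vars))
    })
  })

  structure(
    list(
      summaries = summaries,
      correlations = correlations,
      paired_tests = paired_tests,
      regressions = regressions,
      dropped = attr(summaries, "dropped"),
      schedule = schedule,
      threshold = threshold,
      cognitive_activation = cognitive_activation
    ),
    class = "pattern_analysis"
  )
}

#' @export
print.pattern_analysis <- function(x, ...) {
  cat(sprintf(
    "Pattern-destabilization analysis: %d patient(s) analyzed, %d dropped\n",
    nrow(x$summaries), nrow(x$dropped)
  ))
  print(x$schedule)
  s <- x$summaries
  cat(sprintf(
    "  dispersion: phase 1 mean %.2f (SD %.2f), phase 2 mean %.2f (SD %.2f)\n",
    mean(s$dispersion1, na.rm = TRUE), stats::sd(s$dispersion1, na.rm = TRUE),
    mean(s$dispersion2, na.rm = TRUE), stats::sd(s$dispersion2, na.rm = TRUE)
  ))
  cat(sprintf(
    "  peak processing: phase 1 mean %.2f, phase 2 mean %.2f\n",
    mean(s$peak_processing1, na.rm = TRUE),
    mean(s$peak_processing2, na.rm = TRUE)
  ))
  cat("Use summary() for paired tests and regressions.\n")
  invisible(x)
}

#' @export
summary.pattern_analysis <- function(object, digits = 2, ...) {
  structure(list(fit = object, digits = digits),
    class = "summary.pattern_analysis")
}

#' @export
print.summary.pattern_analysis <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nPaired pre/post tests:\n")
  for (nm in names(fit$paired_tests)) {
    cat(sprintf("  %-18s ", nm))
    print(fit$paired_tests[[nm]])
  }
  cat("\nIntercorrelations:\n")
  print(fit$correlations, digits = x$digits)
  for (ph in names(fit$regressions)) {
    cat(sprintf("\n== Regressions, %s process variables ==\n", ph))
    for (nm in names(fit$regressions[[ph]])) {
      cat(sprintf("\n-- outcome: %s --\n", nm))
      print(fit$regressions[[ph]][[nm]], digits = x$digits)
    }
  }
  invisible(x)
}

#' @export
coef.pattern_analysis <- function(object, phase = c("phase2", "phase1"), ...) {
  phase <- match.arg(phase)
  regs <- object$regressions[[phase]]
  do.call(rbind, lapply(names(regs), function(nm) {
    st <- regs[[nm]]$steps[[length(regs[[nm]]$steps)]]
    cbind(outcome = nm, st$coefficients)
  }))
}

#' Plot a patient's state-space grids
#'
#' Draws the phase-1 and phase-2 occupancy grids for one patient: positive
#' activation on the x-axis, negative activation on the y-axis, point size
#' proportional to the number of sessions in the cell, with the phase
#' dispersion in the panel title.
#'
#' @param x A `"pattern_analysis"` object.
#' @param patient Patient id; default the first analyzed patient.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.pattern_analysis <- function(x, patient = NULL, ...) {
  grids <- attr(x$summaries, "grids")
  if (is.null(patient)) {
    patient <- names(grids)[1]
  }
  if (!patient %in% names(grids)) {
    stop("no grids for patient ", patient, call. = FALSE)
  }
  old <- graphics::par(mfrow = c(1, 2), pty = "s")
  on.exit(graphics::par(old))
  for (ph in c("phase1", "phase2")) {
    g <- grids[[patient]][[ph]]
    occ <- which(g$counts > 0, arr.ind = TRUE)
    graphics::plot(NA,
      xlim = c(-0.5, 4.5), ylim = c(-0.5, 4.5),
      xlab = "positive activation", ylab = "negative activation",
      main = sprintf("%s %s: dispersion %.2f", patient, ph,
        as.numeric(dispersion(g))),
      xaxs = "i", yaxs = "i", xaxt = "n", yaxt = "n"
    )
    graphics::axis(1, at = 0:4)
    graphics::axis(2, at = 0:4)
    graphics::abline(h = seq(-0.5, 4.5), v = seq(-0.5, 4.5), col = "grey80")
    if (nrow(occ)) {
      graphics::points(occ[, 2L] - 1, occ[, 1L] - 1,
        cex = 1 + 1.5 * g$counts[occ] / max(g$counts[occ]), pch = 16
      )
    }
  }
  invisible(x)
}
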