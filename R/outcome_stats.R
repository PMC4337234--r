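#' Paired t-test with Cohen's d
#'
#' Classical paired-samples t-test on pre/post values with the effect size
#' conventional for within-subject contrasts: Cohen's d = mean difference /
#' SD of the difference scores. The identity |t| = |d| * sqrt(n) links the
#' two exactly.
#'
#' @param pre,post Equal-length numeric vectors of paired values (pairs with
#'   a missing member are dropped). The difference is `pre - post`.
#' @param conf_level Confidence level of the mean-difference CI, default 0.95.
#' @return Object of class `"paired_t"`: list with `mean_diff`, `sd_diff`,
#'   `n`, `df`, `t`, `p` (two-tailed), `ci` (length 2), `cohen_d`.
#' @export
#' @examples
#' pt <- paired_t(c(5, 7, 9, 4), c(3, 6, 5, 4))
#' pt$t
paired_t <- function(pre, post, conf_level = 0.95) {
  if (length(pre) != length(post)) {
    stop("pre and post must have equal length", call. = FALSE)
  }
  keep <- !is.na(pre) & !is.na(post)
  d <- pre[keep] - post[keep]
  n <- length(d)
  if (n < 2L) {
    stop("paired t-test needs at least 2 complete pairs", call. = FALSE)
  }
  sd_diff <- stats::sd(d)
  if (sd_diff == 0) {
    if (mean(d) != 0) {
      stop("constant nonzero differences: t is unbounded", call. = FALSE)
    }
    # identical pre/post: no effect, by convention t = d = 0
    return(structure(
      list(
        mean_diff = 0, sd_diff = 0, n = n, df = n - 1L, t = 0, p = 1,
        ci = c(0, 0), cohen_d = 0, conf_level = conf_level
      ),
      class = "paired_t"
    ))
  }
  paired_t_stats(mean(d), sd_diff, n, conf_level)
}

#' Paired t-test from summary statistics
#'
#' Same result object as [paired_t()], computed from the mean and SD of the
#' difference scores — the form in which published tables report paired
#' contrasts.
#'
#' @param mean_diff Mean of the difference scores.
#' @param sd_diff SD of the difference scores (> 0).
#' @param n Number of pairs (>= 2).
#' @param conf_level Confidence level, default 0.95.
#' @return Object of class `"paired_t"` (see [paired_t()]).
#' @export
#' @examples
#' paired_t_stats(1.06, 1.87, 27)$t # ~2.94
paired_t_stats <- function(mean_diff, sd_diff, n, conf_level = 0.95) {
  stopifnot(n >= 2, sd_diff > 0)
  df <- n - 1L
  se <- sd_diff / sqrt(n)
  t <- mean_diff / se
  p <- 2 * stats::pt(-abs(t), df)
  crit <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(
    list(
      mean_diff = mean_diff, sd_diff = sd_diff, n = as.integer(n),
      df = as.integer(df), t = t, p = p,
      ci = c(mean_diff - crit * se, mean_diff + crit * se),
      cohen_d = mean_diff / sd_diff, conf_level = conf_level
    ),
    class = "paired_t"
  )
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf(
    "Paired t-test: mean diff = %.2f (SD = %.2f), t(%d) = %.2f, p = %.4g\n  %g%% CI [%.2f, %.2f], Cohen's d = %.2f\n",
    x$mean_diff, x$sd_diff, x$df, x$t, x$p, 100 * x$conf_level,
    x$ci[1], x$ci[2], x$cohen_d
  ))
  invisible(x)
}

#' Pairwise-complete Pearson correlation matrix
#'
#' Correlation matrix over the analysis variables with pairwise deletion:
#' each cell uses all patients with both variables observed, with the
#' per-pair n and two-tailed p value recorded alongside r.
#'
#' @param data `data.frame` (e.g. [build_summaries()] output).
#' @param variables Character vector of column names; default all numeric
#'   columns.
#' @return Object of class `"cor_matrix"`: list of square matrices `r`, `n`,
#'   `p` plus per-variable `mean` and `sd`. Constant variables yield `NA`
#'   correlations and are named in `degenerate`.
#' @export
correlation_matrix <- function(data, variables = NULL) {
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  m <- as.matrix(data[variables])
  k <- length(variables)
  r <- n <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      nij <- sum(ok)
      n[i, j] <- nij
      if (i == j) {
        r[i, j] <- 1
        p[i, j] <- 0
        next
      }
      if (nij < 3 || stats::sd(m[ok, i]) == 0 || stats::sd(m[ok, j]) == 0) {
        next
      }
      ct <- stats::cor.test(m[ok, i], m[ok, j])
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  degenerate <- variables[apply(m, 2, function(x) {
    stats::sd(x, na.rm = TRUE) == 0 || sum(!is.na(x)) < 3
  })]
  structure(
    list(
      r = r, n = n, p = p,
      mean = colMeans(m, na.rm = TRUE),
      sd = apply(m, 2, stats::sd, na.rm = TRUE),
      degenerate = degenerate
    ),
    class = "cor_matrix"
  )
}

#' @export
print.cor_matrix <- function(x, digits = 2, ...) {
  cat("Pairwise Pearson correlations (n varies by pair):\n")
  print(round(x$r, digits))
  cat("\nMeans:\n")
  print(round(x$mean, digits))
  cat("SDs:\n")
  print(round(x$sd, digits))
  invisible(x)
}

.standardized_betas <- function(fit, data, outcome) {
  b <- stats::coef(fit)
  preds <- names(b)[names(b) != "(Intercept)"]
  sds <- vapply(data[preds], stats::sd, numeric(1))
  b[preds] * sds / stats::sd(data[[outcome]])
}

#' Hierarchical (stepwise-entry) multiple regression
#'
#' Ordinary least squares in successive steps, each adding predictors to the
#' previous step's model, as used to test whether process variables
#' (dispersion, peak processing) explain outcome variance beyond the
#' pretreatment score. For each step the per-predictor B, SE, standardized
#' beta, t and p are reported together with R-squared, the R-squared change
#' from the previous step, and the change-F test
#' \deqn{\Delta F = \frac{\Delta R^2 / q}{(1 - R^2_{full}) / (n - k_{full} - 1)}}
#' with q predictors added and k_full predictors in the current step
#' (equivalently, the model-comparison F from [stats::anova()]).
#'
#' Rows with a missing value in the outcome or any predictor of any step are
#' dropped listwise for the whole analysis.
#'
#' @param data `data.frame` of analysis rows.
#' @param outcome Outcome column name.
#' @param steps List of character vectors: predictors *added* at each step.
#' @return Object of class `"hier_reg"`: list with `outcome`, `n`, and
#'   `steps`, each step holding `predictors`, `coefficients` (B, SE, beta,
#'   t, p), `r2`, `dr2`, `dF`, `df_dF` and `p_dF`.
#' @export
hierarchical_regression <- function(data, outcome, steps) {
  all_preds <- unique(unlist(steps))
  use <- stats::complete.cases(data[c(outcome, all_preds)])
  d <- data[use, c(outcome, all_preds), drop = FALSE]
  n <- nrow(d)
  if (n < length(all_preds) + 2L) {
    stop("too few listwise-complete rows for the full model", call. = FALSE)
  }
  qr_full <- qr(as.matrix(cbind(1, d[all_preds])))
  if (qr_full$rank < length(all_preds) + 1L) {
    stop("singular design: collinear predictors among ",
      paste(all_preds, collapse = ", "),
      call. = FALSE
    )
  }

  out_steps <- vector("list", length(steps))
  prev_fit <- NULL
  prev_r2 <- 0
  preds <- character()
  for (s in seq_along(steps)) {
    preds <- c(preds, steps[[s]])
    fml <- stats::reformulate(preds, response = outcome)
    fit <- stats::lm(fml, data = d)
    sm <- summary(fit)
    r2 <- sm$r.squared
    if (is.null(prev_fit)) {
      an <- stats::anova(fit)
      dF <- sm$fstatistic[["value"]]
      df_dF <- c(sm$fstatistic[["numdf"]], sm$fstatistic[["dendf"]])
      p_dF <- stats::pf(dF, df_dF[1], df_dF[2], lower.tail = FALSE)
    } else {
      an <- stats::anova(prev_fit, fit)
      dF <- an$F[2]
      df_dF <- c(an$Df[2], an$Res.Df[2])
      p_dF <- an$`Pr(>F)`[2]
    }
    ct <- sm$coefficients[preds, , drop = FALSE]
    out_steps[[s]] <- list(
      predictors = preds,
      coefficients = data.frame(
        predictor = preds,
        B = ct[, "Estimate"],
        SE = ct[, "Std. Error"],
        beta = unname(.standardized_betas(fit, d, outcome)[preds]),
        t = ct[, "t value"],
        p = ct[, "Pr(>|t|)"],
        row.names = NULL, stringsAsFactors = FALSE
      ),
      r2 = r2, dr2 = r2 - prev_r2,
      dF = dF, df_dF = df_dF, p_dF = p_dF
    )
    prev_fit <- fit
    prev_r2 <- r2
  }
  structure(
    list(outcome = outcome, n = n, steps = out_steps),
    class = "hier_reg"
  )
}

#' @export
print.hier_reg <- function(x, digits = 2, ...) {
  cat(sprintf("Hierarchical regression of %s (n = %d)\n", x$outcome, x$n))
  for (s in seq_along(x$steps)) {
    st <- x$steps[[s]]
    cat(sprintf(
      "Step %d: R2 = %.*f, dR2 = %.*f, dF(%d, %d) = %.*f, p = %.4g\n",
      s, digits, st$r2, digits, st$dr2, st$df_dF[1], st$df_dF[2],
      digits, st$dF, st$p_dF
    ))
    ct <- st$coefficients
    ct[-1] <- lapply(ct[-1], round, digits + 1)
    print(ct, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.hier_reg <- function(object, step = length(object$steps), ...) {
  ct <- object$steps[[step]]$coefficients
  stats::setNames(ct$B, ct$predictor)
}

#' Standardized regression from a correlation matrix
#'
#' Reconstructs the standardized solution of a (hierarchical) regression
#' from a printed correlation matrix alone: beta = R^-1 r, R-squared =
#' beta' r, where R is the predictor intercorrelation submatrix and r the
#' predictor-outcome correlations. Useful to audit a published regression
#' table against its published correlation table; no unstandardized
#' quantities are available on this route.
#'
#' @param R Predictor correlation matrix (named, symmetric, positive
#'   definite).
#' @param r Named vector of predictor-outcome correlations (same order as
#'   `R`).
#' @param steps List of character vectors: predictors added at each step.
#' @return Object of class `"std_reg"`: list of steps with `beta` (named),
#'   `r2` and `dr2`.
#' @export
#' @examples
#' regression_from_correlations(matrix(1, 1, 1, dimnames = list("x", "x")),
#'   c(x = 0.5), list("x"))
regression_from_correlations <- function(R, r, steps) {
  R <- as.matrix(R)
  if (is.null(rownames(R))) {
    rownames(R) <- colnames(R) <- names(r)
  }
  stopifnot(nrow(R) == ncol(R), length(r) == nrow(R))
  if (max(abs(R - t(R))) > 1e-8) {
    stop("predictor correlation matrix must be symmetric", call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("predictor correlation matrix is not positive definite", call. = FALSE)
  }
  out_steps <- vector("list", length(steps))
  prev_r2 <- 0
  preds <- character()
  for (s in seq_along(steps)) {
    preds <- c(preds, steps[[s]])
    Rs <- R[preds, preds, drop = FALSE]
    rs <- r[preds]
    beta <- drop(solve(Rs, rs))
    names(beta) <- preds
    r2 <- drop(crossprod(beta, rs))
    out_steps[[s]] <- list(beta = beta, r2 = r2, dr2 = r2 - prev_r2)
    prev_r2 <- r2
  }
  structure(list(steps = out_steps), class = "std_reg")
}

#' @export
print.std_reg <- function(x, digits = 2, ...) {
  for (s in seq_along(x$steps)) {
    st <- x$steps[[s]]
    cat(sprintf("Step %d: R2 = %.*f (dR2 = %.*f)\n", s, digits, st$r2,
      digits, st$dr2))
    print(round(st$beta, digits))
  }
  invisible(x)
}

#' Inter-rater agreement ICC(A,1)
#'
#' Single-rater, absolute-agreement intraclass correlation from the two-way
#' random-effects model (ICC(A,1) in the McGraw & Wong taxonomy): sessions
#' (targets) and coders are both treated as random, and coder mean
#' differences count against agreement. Computed from the two-way ANOVA mean
#' squares
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with n targets and k raters.
#'
#' @param coder1,coder2 Equal-length numeric ratings of the same targets by
#'   two coders (pairs with missing values dropped).
#' @return Object of class `"icc"`: list with `value`, `n`, `k`, `form`
#'   (`"ICC(A,1)"`), the mean squares, and `degenerate` (TRUE when between-
#'   target variance is zero, leaving the coefficient uninformative).
#' @export
icc_agreement <- function(coder1, coder2) {
  if (length(coder1) != length(coder2)) {
    stop("coder rating vectors must have equal length", call. = FALSE)
  }
  keep <- !is.na(coder1) & !is.na(coder2)
  x <- cbind(coder1[keep], coder2[keep])
  n <- nrow(x)
  k <- ncol(x)
  if (n < 3L) {
    stop("ICC needs at least 3 paired ratings", call. = FALSE)
  }
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  degenerate <- msr <= mse
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  value <- if (denom == 0) 1 else (msr - mse) / denom
  structure(
    list(
      value = value, n = n, k = k, form = "ICC(A,1)",
      ms = c(rows = msr, cols = msc, error = mse),
      degenerate = degenerate
    ),
    class = "icc"
  )
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("%s = %.3f (n = %d targets, k = %d raters)%s\n",
    x$form, x$value, x$n, x$k,
    if (x$degenerate) " [degenerate: no between-target variance]" else ""))
  invisible(x)
}
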