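#' Fit the person-specific inverse movement-to-RMSSD model
#'
#' Fits, by ordinary least squares, the calibration model
#' \deqn{E[\mathrm{RMSSD}_j] = B_0 + B_1 / \mathrm{Acceleration}_j}
#' over the valid epochs of a scripted calibration session. The model is
#' linear in the transformed predictor `1/max(acceleration, accel_floor)`;
#' the floor (default 0.005 g) keeps the predictor bounded at near-zero
#' movement. `b0` is the RMSSD expected with no movement, `b1` the change in
#' RMSSD attributable to movement.
#'
#' The detection threshold scale `se` is, by default, the standard error of
#' the mean of the raw calibration RMSSD values (`sd/sqrt(n)`). Because that
#' quantity shrinks with session length, `error_quantity` can instead select
#' the calibration RMSSD standard deviation (`"sd"`) or the regression
#' residual standard error (`"residual_se"`) for sensitivity analyses.
#'
#' The fit-quality exclusion gate ([quality_gate()]) is applied before
#' returning, and resting RMSSD (mean RMSSD over the rest phase) is
#' attached.
#'
#' @param session A [calibration_session()].
#' @param accel_floor Acceleration floor in g before inversion
#'   (default 0.005).
#' @param error_quantity One of `"sem"` (default), `"sd"`, `"residual_se"`.
#' @param k Threshold multiplier stored in the model (default 2).
#' @param min_run Minimum episode length in epochs stored in the model
#'   (default 15, i.e. 7.5 min of 30-s epochs).
#' @return A `person_model`: list with `person_id`, `b0`, `b1`, `se`, `r2`,
#'   `b1_pvalue`, `resting_rmssd`, `n_epochs`, `status`, `k`, `min_run`,
#'   `accel_floor`, `error_quantity`.
#' @seealso [quality_gate()], [expected_rmssd()], [threshold()]
#' @export
fit_inverse_model <- function(session, accel_floor = 0.005,
                              error_quantity = c("sem", "sd", "residual_se"),
                              k = 2, min_run = 15) {
  stopifnot(inherits(session, "calibration_session"))
  error_quantity <- match.arg(error_quantity)
  ep <- session$epochs
  use <- ep$valid
  y <- ep$rmssd_ms[use]
  a <- ep$accel_g[use]
  n <- length(y)
  model <- structure(list(
    person_id = session$person_id,
    b0 = NA_real_, b1 = NA_real_, se = NA_real_, r2 = NA_real_,
    b1_pvalue = NA_real_, resting_rmssd = NA_real_, n_epochs = n,
    status = "excluded_insufficient_data", k = k,
    min_run = as.integer(min_run), accel_floor = accel_floor,
    error_quantity = error_quantity), class = "person_model")
  model$resting_rmssd <- resting_rmssd(session)
  if (n < 6) {
    return(model)
  }
  x <- 1 / pmax(a, accel_floor)
  degenerate <- stats::var(x) < 1e-12
  flat <- stats::sd(y) <= 1e-10 * max(1, abs(mean(y)))
  if (flat && !degenerate) {
    # a perfectly flat response defeats lm numerically (a "perfect fit" of
    # floating-point noise); report the no-relation outcome directly
    model$b0 <- mean(y)
    model$b1 <- 0
    model$r2 <- NA_real_
    model$b1_pvalue <- NA_real_
    model$se <- 0
    model$status <- "excluded_nonsignificant"
    return(model)
  }
  if (!degenerate) {
    fit <- stats::lm(y ~ x)
    # noiseless sessions trip summary.lm's "essentially perfect fit" warning
    sm <- suppressWarnings(summary(fit))
    model$b0 <- unname(stats::coef(fit)[1])
    model$b1 <- unname(stats::coef(fit)[2])
    model$r2 <- sm$r.squared
    model$b1_pvalue <- sm$coefficients["x", "Pr(>|t|)"]
    resid_se <- sm$sigma
  } else {
    resid_se <- stats::sd(y)
  }
  model$se <- switch(error_quantity,
                     sem = stats::sd(y) / sqrt(n),
                     sd = stats::sd(y),
                     residual_se = resid_se)
  model$status <- quality_gate(model, degenerate = degenerate)
  model
}

#' Fit-quality exclusion gate
#'
#' A calibration fit is usable only when the inverse model explains enough
#' RMSSD variance, the movement--RMSSD relation is significant, and the curve
#' is actually inverse (positive slope on 1/acceleration). Gates are checked
#' in order:
#' * `excluded_low_r2` -- explained variance below `min_r2` (default 0.25);
#' * `excluded_nonsignificant` -- two-sided p-value of `b1` at or above
#'   `alpha` (default 0.05);
#' * `excluded_no_inverse_fit` -- `b1 <= 0`, or the transformed regression is
#'   degenerate (no variance in 1/acceleration);
#' * otherwise `ok`.
#'
#' An exclusion is a data property, not an error: excluded models are valid
#' outputs that downstream detection refuses to use.
#'
#' @param model A `person_model` (fitted; `status` ignored).
#' @param min_r2 Minimum explained variance (default 0.25).
#' @param alpha Significance level for the slope t-test (default 0.05).
#' @param degenerate Set by [fit_inverse_model()] when 1/acceleration has no
#'   variance.
#' @return The status string.
#' @export
quality_gate <- function(model, min_r2 = 0.25, alpha = 0.05,
                         degenerate = FALSE) {
  if (degenerate || is.na(model$b1)) return("excluded_no_inverse_fit")
  # a perfectly flat response leaves r2 and the slope p-value undefined
  # (0/0); that is a no-relation outcome, not a low-variance one
  if (!is.na(model$r2) && model$r2 < min_r2) return("excluded_low_r2")
  if (is.na(model$b1_pvalue) || model$b1_pvalue >= alpha) {
    return("excluded_nonsignificant")
  }
  if (model$b1 <= 0) return("excluded_no_inverse_fit")
  "ok"
}

#' Resting RMSSD from the calibration rest phase
#'
#' Arithmetic mean of the valid epoch RMSSD values whose windows start inside
#' the session's rest (sitting) phase.
#'
#' @param session A [calibration_session()].
#' @return Resting RMSSD in ms.
#' @export
resting_rmssd <- function(session) {
  stopifnot(inherits(session, "calibration_session"))
  ph <- session$phases
  rest <- ph[ph$label == "rest", , drop = FALSE]
  if (nrow(rest) == 0) {
    stop("resting_rmssd: session has no rest phase", call. = FALSE)
  }
  ep <- session$epochs
  lab <- phase_of(ep$start_s, rest)
  use <- !is.na(lab) & ep$valid
  if (!any(use)) {
    stop("resting_rmssd: rest phase contains no valid epoch", call. = FALSE)
  }
  mean(ep$rmssd_ms[use])
}

#' @export
print.person_model <- function(x, ...) {
  cat(sprintf("<person_model> %s: status=%s\n", x$person_id, x$status))
  if (!is.na(x$b0)) {
    cat(sprintf("  Expected RMSSD = %.2f + %.3f / accel  (R2=%.2f, p=%.3g)\n",
                x$b0, x$b1, x$r2, x$b1_pvalue))
    cat(sprintf("  se=%.3f ms (%s), resting RMSSD=%.1f ms, k=%g, min_run=%d\n",
                x$se, x$error_quantity, x$resting_rmssd, x$k, x$min_run))
  }
  invisible(x)
}
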