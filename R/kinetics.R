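#' Time-activity curve for one source region
#'
#' Holds timestamped fractions of injected activity (activity in the
#' region divided by injected activity, physical decay *not* removed, so
#' fitted half-lives are effective half-lives) for one region of one
#' subject.
#'
#' @param subject_id,region_id Labels.
#' @param time_h Sample times in hours post-injection (strictly
#'   increasing, >= 0).
#' @param fraction_id Fractions of injected activity at `time_h`
#'   (0 <= fraction <= 1 within numerical tolerance).
#' @return A data frame of class `time_activity_curve` with columns
#'   `subject_id`, `region_id`, `time_h`, `fraction_id`.
#' @examples
#' time_activity_curve("P1", "kidneys", c(1, 2, 4), c(0.013, 0.009, 0.0044))
#' @export
time_activity_curve <- function(subject_id, region_id, time_h, fraction_id) {
  stopifnot(length(time_h) == length(fraction_id))
  if (any(!is.finite(time_h)) || any(!is.finite(fraction_id)))
    stop("time_h and fraction_id must be finite")
  if (any(time_h < 0)) stop("time_h must be >= 0")
  if (any(fraction_id < 0)) stop("fraction_id must be >= 0")
  if (any(fraction_id > 1 + 1e-6))
    stop("fraction_id exceeds 1 for a single region")
  o <- order(time_h)
  time_h <- time_h[o]; fraction_id <- fraction_id[o]
  if (anyDuplicated(time_h))
    stop("duplicate time points in time-activity curve")
  structure(
    data.frame(subject_id = subject_id, region_id = region_id,
               time_h = time_h, fraction_id = fraction_id,
               stringsAsFactors = FALSE),
    class = c("time_activity_curve", "data.frame")
  )
}

#' @export
print.time_activity_curve <- function(x, ...) {
  cat(sprintf("Time-activity curve: %s / %s (%d samples)\n",
              x$subject_id[1], x$region_id[1], nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

new_monoexp_fit <- function(A0, t_eff, residual_norm, n, method) {
  A0 <- unname(A0); t_eff <- unname(t_eff)
  stopifnot(A0 > 0, t_eff > 0)
  structure(
    list(amplitude_A0 = A0, half_life_eff_h = t_eff,
         lambda_eff_per_h = log(2) / t_eff,
         residual_norm = residual_norm, n = n, method = method),
    class = "monoexp_fit"
  )
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf(
    "Mono-exponential fit (%s): A0 = %.5g, T_eff = %.4g h, ||r|| = %.3g\n",
    x$method, x$amplitude_A0, x$half_life_eff_h, x$residual_norm))
  invisible(x)
}

#' Fit a mono-exponential model to a time-activity curve
#'
#' Least-squares fit of `A(t) = A0 * exp(-lambda_eff * t)` in linear
#' activity space. Two-point curves are solved in closed form. Longer
#' curves are fitted by Levenberg-Marquardt ([minpack.lm::nls.lm()]),
#' initialised from a log-linear regression on the positive samples (with
#' a coarse grid search over the effective half-life as fallback when
#' samples are non-positive or the regression yields a non-decaying
#' slope).
#'
#' @param curve A [time_activity_curve()] with at least 2 samples.
#' @param weighting `"uniform"` (unweighted residuals, default) or
#'   `"relative"` (residuals divided by the model value, weighting all
#'   samples equally on a relative scale).
#' @return A `monoexp_fit` object with elements `amplitude_A0`
#'   (fraction of injected activity back-extrapolated to t = 0),
#'   `half_life_eff_h`, `lambda_eff_per_h` and `residual_norm`.
#' @examples
#' tac <- time_activity_curve("S", "r", c(1, 2, 4), c(0.5, 0.25, 0.0625))
#' fit_monoexponential(tac)
#' @export
fit_monoexponential <- function(curve, weighting = c("uniform", "relative")) {
  weighting <- match.arg(weighting)
  t <- curve$time_h; y <- curve$fraction_id
  if (length(unique(t)) < 2L)
    stop("mono-exponential fit needs >= 2 samples with distinct times")

  if (length(t) == 2L) {
    # closed form through two points
    if (any(y <= 0)) stop("two-point fit requires positive activities")
    lam <- log(y[1] / y[2]) / (t[2] - t[1])
    if (lam <= 0) stop("two-point curve is not decaying; no positive T_eff")
    A0 <- y[1] * exp(lam * t[1])
    return(new_monoexp_fit(A0, log(2) / lam, 0, 2L, "closed-form"))
  }

  start <- .monoexp_start(t, y)
  resid_fun <- function(p) {
    m <- exp(p[1]) * exp(-exp(p[2]) * t)
    r <- y - m
    if (weighting == "relative") r <- r / m
    r
  }
  fit <- minpack.lm::nls.lm(
    par = c(log(start$A0), log(start$lambda)), fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (fit$info == 0 || !all(is.finite(fit$par))) {
    stop("mono-exponential fit failed to converge; residuals: ",
         paste(signif(fit$fvec, 3), collapse = ", "))
  }
  new_monoexp_fit(exp(fit$par[1]), log(2) / exp(fit$par[2]),
                  sqrt(sum(resid_fun(fit$par)^2)), length(t),
                  paste0("nls.lm/", weighting))
}

# initial values: log-linear regression on positive samples, grid fallback
.monoexp_start <- function(t, y) {
  pos <- y > 0
  if (sum(pos) >= 2L) {
    co <- stats::coef(stats::lm(log(y[pos]) ~ t[pos]))
    if (is.finite(co[2]) && co[2] < 0) {
      return(list(A0 = exp(co[1]), lambda = -co[2]))
    }
  }
  # coarse grid over T_eff in [0.1, 20] h, A0 by linear least squares
  grid <- exp(seq(log(0.1), log(20), length.out = 120))
  best <- NULL; best_ss <- Inf
  for (T in grid) {
    e <- exp(-(log(2) / T) * t)
    A0 <- sum(y * e) / sum(e^2)
    if (A0 <= 0) next
    ss <- sum((y - A0 * e)^2)
    if (ss < best_ss) { best_ss <- ss; best <- list(A0 = A0, lambda = log(2) / T) }
  }
  if (is.null(best)) stop("no admissible starting values for mono-exponential fit")
  best
}

#' Time-integrated activity coefficient from a fit
#'
#' Integrates the fitted mono-exponential analytically over `[0, Inf)`:
#' `tiac = A0 / lambda_eff = A0 * T_eff / ln 2`, in hours (MBq.h/MBq).
#'
#' @param fit A `monoexp_fit`.
#' @return TIAC in hours.
#' @examples
#' tiac_from_fit(fit_monoexponential(
#'   time_activity_curve("S", "r", c(1, 2, 4), c(0.5, 0.25, 0.0625))))
#' @export
tiac_from_fit <- function(fit) {
  stopifnot(inherits(fit, "monoexp_fit"))
  fit$amplitude_A0 / fit$lambda_eff_per_h
}

#' Back-extrapolate a single measured fraction to t = 0
#'
#' `A0 = f(t) * exp(ln 2 * t / T_eff)`; used to form single-time-point
#' TIACs when only one reliable sample and an effective half-life are
#' available.
#'
#' @param fraction_at_t Fraction of injected activity measured at `t_h`.
#' @param t_h Measurement time in hours (>= 0).
#' @param half_life_eff_h Effective half-life in hours (> 0).
#' @return Amplitude at t = 0.
#' @export
back_extrapolate <- function(fraction_at_t, t_h, half_life_eff_h) {
  stopifnot(fraction_at_t > 0, t_h >= 0)
  if (half_life_eff_h <= 0) stop("half-life must be positive")
  fraction_at_t * exp(log(2) * t_h / half_life_eff_h)
}

#' Biological half-life from an effective half-life
#'
#' Decomposes `1/T_eff = 1/T_phys + 1/T_bio`, i.e.
#' `T_bio = 1 / (1/T_eff - 1/T_phys)`.
#'
#' @param half_life_eff_h Effective half-life in hours; must be shorter
#'   than the physical half-life (otherwise no positive biological
#'   clearance exists).
#' @param constants A [decay_constants()] object.
#' @return Biological half-life in hours.
#' @export
biological_half_life <- function(half_life_eff_h,
                                 constants = decay_constants()) {
  stopifnot(half_life_eff_h > 0)
  if (half_life_eff_h >= constants$t_phys_h)
    stop("effective half-life >= physical half-life: ",
         "no positive biological clearance")
  1 / (1 / half_life_eff_h - 1 / constants$t_phys_h)
}

#' Read time-activity curves from CSV
#'
#' Expects columns `subject_id`, `region_id`, `time_h`, `fraction_id`
#' (header required, '.' decimal separator). Returns one
#' [time_activity_curve()] per subject/region pair.
#'
#' @param path Path to the CSV file.
#' @return Named list of `time_activity_curve` objects
#'   (`"subject|region"` keys).
#' @export
read_tac_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("subject_id", "region_id", "time_h", "fraction_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("TAC file missing column(s): ",
                         paste(miss, collapse = ", "))
  split_df <- split(df, paste(df$subject_id, df$region_id, sep = "|"))
  lapply(split_df, function(d)
    time_activity_curve(d$subject_id[1], d$region_id[1], d$time_h,
                        d$fraction_id))
}
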