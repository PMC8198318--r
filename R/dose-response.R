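# Dose-response and growth model fitting: four-parameter log-logistic (LL4)
# and three-parameter exponential decay (EXD3) by nonlinear least squares,
# AIC model selection, ED50 with asymptotic 95% CI, and log2-linear
# doubling-time estimation.

#' Four-parameter log-logistic model
#'
#' `f(x) = c + (d - c) / (1 + exp(b * (ln x - ln e)))`. At `x = e` the
#' response is the midpoint `(c + d) / 2`, so `e` is the ED50.
#'
#' @param x dose (> 0).
#' @param b slope; `c`, `d` lower/upper asymptotes; `e` ED50.
#' @param c,d,e model parameters.
#' @return response value(s).
#' @export
ll4 <- function(x, b, c, d, e) {
  if (any(x <= 0)) stop2("ll4 is defined for x > 0")
  c + (d - c) / (1 + exp(b * (log(x) - log(e))))
}

#' Three-parameter exponential decay model
#'
#' `f(x) = c + (d - c) * exp(-x / e)`; `f(0) = d`, `f(Inf) = c`.
#'
#' @param x dose (>= 0).
#' @param c lower asymptote; `d` intercept; `e` decay scale.
#' @param d,e model parameters.
#' @return response value(s).
#' @export
exd3 <- function(x, c, d, e) {
  if (any(x < 0)) stop2("exd3 is defined for x >= 0")
  c + (d - c) * exp(-x / e)
}

#' Gaussian least-squares AIC
#'
#' `AIC = n * ln(RSS / n) + 2 * (k + 1)`: the error variance counts as one
#' estimated parameter on top of the `k` model parameters.
#'
#' @param rss residual sum of squares.
#' @param n number of observations (>= 2).
#' @param k number of model parameters.
#' @return AIC value (`-Inf` for an exact fit).
#' @export
aic_gaussian <- function(rss, n, k) {
  if (n < 2) stop2("AIC undefined for n < 2")
  n * log(rss / n) + 2 * (k + 1)
}

check_dr_table <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("dose_uM", "viability") %in% names(data)))
  if (any(data$dose_uM <= 0)) stop2("doses must be positive")
  data
}

#' Fit a dose-response model
#'
#' Nonlinear least squares with the documented initialization
#' (`c0 = min viability`, `d0 = max viability`, `e0` = geometric mean dose,
#' `b0 = 1`) and `e` constrained positive. Replicates enter as individual
#' observations. The 95% CI for the ED50 is asymptotic (Wald, t-quantile on
#' `n - k` df).
#'
#' @param data data.frame with `dose_uM`, `viability` (>= 4 distinct doses
#'   for LL4).
#' @param family `"LL4"` or `"EXD3"`.
#' @return object of class `fit_result`: list with `family`, `coef`, `rss`,
#'   `n`, `aic`, `ed50`, `ed50_ci`, `converged`, `note`. For EXD3 the ED50
#'   is `e * ln 2` (the dose halving the decay term).
#' @export
fit_dose_response <- function(data, family = c("LL4", "EXD3")) {
  family <- match.arg(family)
  check_dr_table(data)
  n_doses <- length(unique(data$dose_uM))
  if (family == "LL4" && n_doses < 4)
    stop2("LL4 fitting needs >= 4 distinct doses")
  if (family == "EXD3" && n_doses < 3)
    stop2("EXD3 fitting needs >= 3 distinct doses")
  x <- data$dose_uM
  y <- data$viability
  c0 <- min(y); d0 <- max(y); e0 <- exp(mean(log(x)))
  n <- length(y)
  failed <- function(note) {
    structure(list(family = family, coef = NULL, rss = NA_real_, n = n,
                   aic = NA_real_, ed50 = NA_real_,
                   ed50_ci = c(NA_real_, NA_real_),
                   converged = FALSE, note = note),
              class = "fit_result")
  }
  fit <- tryCatch({
    if (family == "LL4") {
      minpack.lm::nlsLM(
        y ~ c + (d - c) / (1 + exp(b * (log(x) - log(e)))),
        start = list(b = 1, c = c0, d = d0, e = e0),
        lower = c(b = -Inf, c = -Inf, d = -Inf, e = 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        y ~ c + (d - c) * exp(-x / e),
        start = list(c = c0, d = d0, e = e0),
        lower = c(c = -Inf, d = -Inf, e = 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(failed("nonlinear least squares did not converge"))
  cf <- coef(fit)
  rss <- sum(residuals(fit)^2)
  k <- length(cf)
  ed50 <- if (family == "LL4") cf[["e"]] else cf[["e"]] * log(2)
  ci <- c(NA_real_, NA_real_)
  se_e <- tryCatch(sqrt(vcov(fit)["e", "e"]), error = function(e) NA_real_)
  if (is.finite(se_e) && n > k) {
    mult <- if (family == "EXD3") log(2) else 1
    ci <- ed50 + c(-1, 1) * qt(0.975, n - k) * se_e * mult
  } else if (n > k) {
    ci <- c(ed50, ed50)  # exact fit: degenerate interval at the estimate
  }
  structure(list(family = family, coef = as.list(cf), rss = rss, n = n,
                 aic = aic_gaussian(max(rss, 0), n, k), ed50 = ed50,
                 ed50_ci = ci, converged = TRUE, note = ""),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result [", x$family, "] converged:", x$converged, "\n")
  if (x$converged) {
    cat("  coef:", paste(names(x$coef),
                         signif(unlist(x$coef), 4), sep = "=",
                         collapse = ", "), "\n")
    cat(sprintf("  RSS = %.4g, n = %d, AIC = %.3f\n", x$rss, x$n, x$aic))
    cat(sprintf("  ED50 = %.4g [%.4g, %.4g]\n", x$ed50,
                x$ed50_ci[1], x$ed50_ci[2]))
  } else cat("  ", x$note, "\n")
  invisible(x)
}

#' Select the dose-response model by AIC
#'
#' Fits LL4 and EXD3 and returns the converged fit with the lower AIC
#' (ties go to LL4). If only one family converges it is returned with a
#' note.
#'
#' @param data data.frame with `dose_uM`, `viability`.
#' @return the winning `fit_result`.
#' @export
select_model <- function(data) {
  f_ll4 <- tryCatch(fit_dose_response(data, "LL4"),
                    error = function(e) NULL)
  f_exd <- tryCatch(fit_dose_response(data, "EXD3"),
                    error = function(e) NULL)
  ok_l <- !is.null(f_ll4) && f_ll4$converged
  ok_e <- !is.null(f_exd) && f_exd$converged
  if (!ok_l && !ok_e) stop2("neither LL4 nor EXD3 converged")
  if (ok_l && !ok_e) {
    f_ll4$note <- "EXD3 did not converge"
    return(f_ll4)
  }
  if (ok_e && !ok_l) {
    f_exd$note <- "LL4 did not converge"
    return(f_exd)
  }
  if (f_ll4$aic <= f_exd$aic) f_ll4 else f_exd
}

#' Survival fraction relative to untreated control
#'
#' @param treated,control vectors of signals; control mean must be > 0.
#' @return `mean(treated) / mean(control)`.
#' @export
survival_fraction <- function(treated, control) {
  if (!(mean(control) > 0)) stop2("control mean must be > 0")
  mean(treated) / mean(control)
}

#' Doubling time from exponential growth data
#'
#' Ordinary least squares of `log2(signal)` on time; the doubling time is
#' `1 / slope` with a CI obtained from the slope CI. Requires >= 3 distinct
#' time points and positive signals.
#'
#' @param series data.frame with `time_h` and `count` (or `signal`).
#' @return object of class `growth_fit`: `doubling_time_h`, `slope`
#'   (doublings per hour), `r_squared`, `ci` (95% for the doubling time),
#'   `defined` flag (FALSE when the slope is <= 0).
#' @export
fit_doubling_time <- function(series) {
  stopifnot(is.data.frame(series), "time_h" %in% names(series))
  sig_col <- intersect(c("count", "signal"), names(series))[1]
  if (is.na(sig_col)) stop2("series needs a 'count' or 'signal' column")
  y <- series[[sig_col]]
  t <- series$time_h
  if (length(unique(t)) < 3) stop2("need >= 3 distinct time points")
  if (any(y <= 0)) stop2("signals must be > 0")
  fit <- lm(log2(y) ~ t)
  slope <- unname(coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(slope) || slope <= 0) {
    return(structure(list(doubling_time_h = NA_real_, slope = slope,
                          r_squared = r2, ci = c(NA_real_, NA_real_),
                          defined = FALSE),
                     class = "growth_fit"))
  }
  ci_slope <- tryCatch(suppressWarnings(confint(fit)[2, ]),
                       error = function(e) c(NA_real_, NA_real_))
  ci <- if (all(is.finite(ci_slope)) && all(ci_slope > 0))
    sort(1 / ci_slope) else c(NA_real_, NA_real_)
  structure(list(doubling_time_h = 1 / slope, slope = slope,
                 r_squared = r2, ci = unname(ci), defined = TRUE),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (x$defined)
    cat(sprintf("growth_fit: doubling time %.2f h [%.2f, %.2f], R^2 = %.4f\n",
                x$doubling_time_h, x$ci[1], x$ci[2], x$r_squared))
  else cat("growth_fit: doubling time undefined (slope <= 0)\n")
  invisible(x)
}
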