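#' Cortical amplitude time series as a sum of Gaussians
#'
#' Represents the cortical flow amplitude \eqn{V(t) = \sum_i a_i
#' \exp[-(t - b_i)^2 / 2 c_i^2]} (\eqn{\mu m\,s^{-1}}; \eqn{t} in s) —
#' the functional form used to model the contraction peaks of successive
#' cell cycles.
#'
#' @param a Peak amplitudes, \eqn{\mu m\,s^{-1}}.
#' @param b Peak times, s.
#' @param c Peak widths (Gaussian sigmas), s.
#' @return An object of class `amplitude_series` (callable via
#'   [amplitude_value()]).
#' @export
amplitude_gaussians <- function(a, b, c) {
  stopifnot(length(a) == length(b), length(b) == length(c),
            all(c > 0), all(a >= 0))
  structure(list(a = a, b = b, c = c), class = "amplitude_series")
}

#' @export
print.amplitude_series <- function(x, ...) {
  cat(sprintf("<amplitude_series> %d Gaussian peak(s), total chi = %.1f um\n",
              length(x$a), chi_total(x)))
  invisible(x)
}

#' Evaluate a cortical amplitude series
#'
#' @param amplitude An `amplitude_series`.
#' @param t Times, s.
#' @return \eqn{V(t)}, \eqn{\mu m\,s^{-1}}.
#' @export
amplitude_value <- function(amplitude, t) {
  stopifnot(inherits(amplitude, "amplitude_series"))
  v <- rep(0, length(t))
  for (i in seq_along(amplitude$a)) {
    v <- v + amplitude$a[i] *
      exp(-(t - amplitude$b[i])^2 / (2 * amplitude$c[i]^2))
  }
  v
}

#' Rescaled time from a cortical amplitude history
#'
#' \eqn{\chi(t) = \int_0^t V(t')\,dt'}: the integral measure of cortical
#' contractions that fully parameterizes Stokes-flow transport. Accepts a
#' Gaussian-sum [amplitude_gaussians()] (integrated analytically via the
#' error function) or a tabulated series (trapezoidal rule).
#'
#' @param amplitude An `amplitude_series`, or a data frame with columns
#'   `t` and `v`.
#' @param t Upper integration limit(s), s; `Inf` gives the total.
#' @return \eqn{\chi} values, \eqn{\mu m}.
#' @export
chi_from_amplitude <- function(amplitude, t) {
  if (inherits(amplitude, "amplitude_series")) {
    vapply(t, function(tt) {
      s <- 0
      for (i in seq_along(amplitude$a)) {
        ai <- amplitude$a[i]; bi <- amplitude$b[i]; ci <- amplitude$c[i]
        upper <- if (is.infinite(tt)) 1 else pracma::erf((tt - bi) / (ci * sqrt(2)))
        lower <- pracma::erf((0 - bi) / (ci * sqrt(2)))
        s <- s + ai * ci * sqrt(pi / 2) * (upper - lower)
      }
      s
    }, numeric(1))
  } else {
    stopifnot(all(c("t", "v") %in% names(amplitude)))
    if (any(amplitude$v < -1e-12)) {
      warning("negative amplitude samples; chi is defined for V >= 0.",
              call. = FALSE)
    }
    vapply(t, function(tt) {
      keep <- amplitude$t <= tt
      tv <- amplitude$t[keep]; vv <- amplitude$v[keep]
      if (length(tv) < 2) return(0)
      sum(diff(tv) * (vv[-1] + vv[-length(vv)]) / 2)
    }, numeric(1))
  }
}

# total chi of a Gaussian sum over all time: sum a_i c_i sqrt(2 pi)
chi_total <- function(amplitude) {
  sum(amplitude$a * amplitude$c) * sqrt(2 * pi)
}

#' Fit a sum of Gaussians to a cortical amplitude time series
#'
#' Nonlinear least-squares fit of \eqn{V(t) = \sum_{i=1}^{k} a_i
#' \exp[-(t - b_i)^2/2 c_i^2]} to sampled amplitudes, initialized by peak
#' detection (local maxima above half the global maximum, or equally
#' spaced fallbacks). Optionally rescales the fitted series so that its
#' largest peak attains a prescribed cortical amplitude (e.g. 0.3
#' \eqn{\mu m\,s^{-1}} at the cell-cycle-6 contraction peak, the
#' calibration used to convert relative flow measurements into cortical
#' amplitudes).
#'
#' @param data Data frame with columns `t` (s) and `v`
#'   (\eqn{\mu m\,s^{-1}} or relative units).
#' @param n_peaks Number of Gaussians \eqn{k}.
#' @param peak_value Optional calibration: after fitting, amplitudes are
#'   scaled so the tallest fitted peak equals this value.
#' @return An object of class `amplitude_fit`: the fitted
#'   `amplitude_series` plus the `nls` object, parameter table with 95\%
#'   confidence intervals, and the total \eqn{\chi} with its propagated
#'   95\% range.
#' @export
fit_amplitude_gaussians <- function(data, n_peaks = 3, peak_value = NULL) {
  stopifnot(all(c("t", "v") %in% names(data)), n_peaks >= 1)
  t <- data$t; v <- data$v
  ord <- order(t); t <- t[ord]; v <- v[ord]
  # peak detection for initial values
  loc <- which(diff(sign(diff(v))) == -2) + 1L
  loc <- loc[v[loc] > max(v) / 2]
  if (length(loc) < n_peaks) {
    extra <- round(seq(1, length(t), length.out = n_peaks + 2))[2:(n_peaks + 1)]
    loc <- unique(c(loc, extra))[seq_len(n_peaks)]
  } else {
    loc <- loc[order(v[loc], decreasing = TRUE)][seq_len(n_peaks)]
  }
  span <- diff(range(t))
  start <- list(a = v[loc], b = t[loc],
                c = rep(span / (6 * n_peaks), n_peaks))
  model <- function(par, t) {
    k <- length(par) / 3
    a <- par[seq_len(k)]; b <- par[k + seq_len(k)]; cc <- par[2 * k + seq_len(k)]
    rowSums(vapply(seq_len(k), function(i) {
      a[i] * exp(-(t - b[i])^2 / (2 * cc[i]^2))
    }, numeric(length(t))))
  }
  par0 <- c(start$a, start$b, start$c)
  names(par0) <- c(paste0("a", seq_len(n_peaks)), paste0("b", seq_len(n_peaks)),
                   paste0("c", seq_len(n_peaks)))
  fit <- minpack.lm::nls.lm(
    par = par0,
    fn = function(p) v - model(p, t),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (fit$info == 0) {
    stop(sprintf("Gaussian-sum fit failed to converge (residual %.3g).",
                 sqrt(sum(fit$fvec^2))), call. = FALSE)
  }
  p <- fit$par
  k <- n_peaks
  a <- abs(p[seq_len(k)]); b <- p[k + seq_len(k)]; cc <- abs(p[2 * k + seq_len(k)])
  scale <- 1
  if (!is.null(peak_value)) {
    scale <- peak_value / max(a)
    a <- a * scale
  }
  series <- amplitude_gaussians(unname(a), unname(b), unname(cc))
  # 95% intervals from the parameter covariance (delta method for chi)
  cov <- tryCatch(vcov(fit), error = function(e) NULL)
  se <- if (!is.null(cov)) sqrt(pmax(0, diag(cov))) else rep(NA_real_, 3 * k)
  params <- tibble::tibble(
    term = names(par0),
    estimate = c(a, b, cc),
    std_error = c(se[seq_len(k)] * scale, se[k + seq_len(k)],
                  se[2 * k + seq_len(k)]),
    conf_low = c(a, b, cc) - 1.96 * c(se[seq_len(k)] * scale,
                                      se[k + seq_len(k)], se[2 * k + seq_len(k)]),
    conf_high = c(a, b, cc) + 1.96 * c(se[seq_len(k)] * scale,
                                       se[k + seq_len(k)], se[2 * k + seq_len(k)])
  )
  chi_tot <- chi_total(series)
  chi_se <- if (!is.null(cov)) {
    # d chi / d a_i = c_i sqrt(2 pi) * scale ; d chi / d c_i = a_i sqrt(2 pi)
    grad <- c(cc * sqrt(2 * pi) * scale, rep(0, k), a * sqrt(2 * pi))
    sqrt(max(0, drop(t(grad) %*% cov %*% grad)))
  } else NA_real_
  structure(
    list(series = series, params = params, fit = fit,
         chi_total = chi_tot,
         chi_conf = c(chi_tot - 1.96 * chi_se, chi_tot + 1.96 * chi_se),
         residual_rms = sqrt(mean(fit$fvec^2)) * scale),
    class = "amplitude_fit"
  )
}

#' @export
print.amplitude_fit <- function(x, ...) {
  cat(sprintf(
    "<amplitude_fit> %d peaks, total chi = %.1f um (95%% CI %.1f-%.1f), RMS %.3g\n",
    length(x$series$a), x$chi_total, x$chi_conf[1], x$chi_conf[2],
    x$residual_rms
  ))
  invisible(x)
}
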