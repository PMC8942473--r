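# Nonlinear least-squares fits of the analysis suite. All fits go through
# minpack.lm's Levenberg-Marquardt with box constraints and a small
# multistart (data-driven start plus seed-jittered replicates), so results
# are deterministic given the data and seed.

.fit_cost_tol <- 1e-10

# Run nls.lm from several starts, return the best converged fit.
.lm_multistart <- function(residual_fn, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    fit <- try(minpack.lm::nls.lm(
      par = st, fn = residual_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(ftol = .fit_cost_tol,
                                           ptol = .fit_cost_tol,
                                           maxiter = 500)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15)
      best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)
  best
}

.jitter_starts <- function(start, n, seed, spread = 0.5) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      start * exp(stats::runif(length(start), -spread, spread)) *
        sign(start + (start == 0))
    })
  })
}

#' Fit a Boltzmann activation curve to displacement-response data
#'
#' Least-squares fit of the open-probability-vs-displacement relation with
#' one component, `p_o(X) = 1/(1 + exp(-s (X - X_0.5)))`, or two,
#' `p_o(X) = w1 B1(X) + (1 - w1) B2(X)` (a weighted sum of two
#' single-Boltzmann terms). The gating force `z = s * kB * T * 1e6` (N) is
#' reported using the configured temperature.
#'
#' @param data Data frame or list with displacement (um) in the first
#'   column (or `$x`) and open probability in the second (or `$y`),
#'   `p_o` values within `[0, 1.05]`.
#' @param n_components 1 or 2.
#' @param temperature Temperature in K for the gating-force conversion.
#' @param seed Multistart jitter seed.
#' @return Object of class `boltzmann_fit`: `x_half`, `slope_s`, `z`,
#'   `components` (two-component case), `rss`, `n_points`.
#' @export
fit_boltzmann <- function(data, n_components = 1, temperature = 295,
                          seed = 1) {
  xy <- .as_xy(data)
  x <- xy$x; y <- xy$y
  if (any(y < -0.05 | y > 1.05))
    stop("open probabilities must lie in [0, 1.05]", call. = FALSE)
  n_min <- if (n_components == 1) 4L else 7L
  if (length(x) < n_min)
    stop("need at least ", n_min, " points for ", n_components,
         "-component fit", call. = FALSE)
  span <- diff(range(x))
  if (span <= 0) stop("displacement values are degenerate", call. = FALSE)

  if (n_components == 1) {
    x_half0 <- stats::approx(y, x, xout = 0.5, ties = mean, rule = 2)$y
    start <- c(x_half = x_half0, slope = 4 / span)
    lower <- c(min(x) - span, 1e-3 / span)
    upper <- c(max(x) + span, 1e4 / span)
    resid <- function(p) y - boltzmann_po(x, p[1L], p[2L])
    starts <- c(list(start), .jitter_starts(start, 7, seed))
    best <- .lm_multistart(resid, starts, lower, upper)
    p <- best$par
    out <- list(x_half = unname(p[1L]), slope_s = unname(p[2L]),
                z = unname(p[2L]) * .kB * temperature * 1e6,
                components = NULL, rss = best$rss,
                n_points = length(x), n_components = 1L,
                temperature = temperature)
  } else if (n_components == 2) {
    q <- stats::quantile(x, c(0.3, 0.7), names = FALSE)
    start <- c(x_half1 = q[1L], slope1 = 6 / span,
               x_half2 = q[2L], slope2 = 6 / span, w1 = 0.5)
    lower <- c(min(x) - span, 1e-3 / span, min(x) - span, 1e-3 / span, 0)
    upper <- c(max(x) + span, 1e4 / span, max(x) + span, 1e4 / span, 1)
    resid <- function(p) y - .boltzmann2_po(x, p[1L], p[2L], p[3L], p[4L], p[5L])
    starts <- c(list(start), .jitter_starts(start, 11, seed))
    best <- .lm_multistart(resid, starts, lower, upper)
    p <- best$par
    # order components by midpoint
    ord <- order(c(p[1L], p[3L]))
    comps <- list(
      list(x_half = unname(p[1L]), slope = unname(p[2L]), weight = unname(p[5L])),
      list(x_half = unname(p[3L]), slope = unname(p[4L]), weight = 1 - unname(p[5L])))
    comps <- comps[ord]
    dominant <- which.max(c(comps[[1L]]$weight, comps[[2L]]$weight))
    out <- list(x_half = comps[[dominant]]$x_half,
                slope_s = comps[[dominant]]$slope,
                z = comps[[dominant]]$slope * .kB * temperature * 1e6,
                components = comps, rss = best$rss,
                n_points = length(x), n_components = 2L,
                temperature = temperature)
  } else stop("n_components must be 1 or 2", call. = FALSE)
  structure(out, class = "boltzmann_fit")
}

#' @export
predict.boltzmann_fit <- function(object, newdata, ...) {
  x <- if (is.list(newdata) && !is.null(newdata$x)) newdata$x else newdata
  if (object$n_components == 1L) {
    boltzmann_po(x, object$x_half, object$slope_s)
  } else {
    c1 <- object$components[[1L]]; c2 <- object$components[[2L]]
    c1$weight * boltzmann_po(x, c1$x_half, c1$slope) +
      c2$weight * boltzmann_po(x, c2$x_half, c2$slope)
  }
}

#' Fit a logistic (Hill) dose-response curve
#'
#' Least-squares fit of `I(C) = (I_i - I_f)/(1 + (C/c_half)^p) + I_f`
#' to current amplitude versus blocker concentration; `c_half` is the
#' IC50 and `p` the Hill coefficient.
#'
#' @param data Two-column data (concentration uM, current pA), as for
#'   [fit_boltzmann()]. At least 4 distinct concentrations.
#' @param seed Multistart jitter seed.
#' @return Object of class `dose_response_fit`: `i_initial`, `i_final`,
#'   `c_half`, `hill_p`, `rss`, `n_points`.
#' @export
fit_dose_response <- function(data, seed = 1) {
  xy <- .as_xy(data)
  conc <- xy$x; y <- xy$y
  if (length(unique(conc)) < 4L)
    stop("need at least 4 distinct concentrations", call. = FALSE)
  if (any(conc < 0)) stop("negative concentration", call. = FALSE)
  if (stats::sd(y) == 0) stop("all responses equal; nothing to fit",
                              call. = FALSE)
  ord <- order(conc)
  i_i0 <- y[ord][1L]; i_f0 <- y[ord][length(y)]
  cpos <- conc[conc > 0]
  c0 <- exp(mean(log(cpos)))
  start <- c(i_initial = i_i0, i_final = i_f0, c_half = c0, hill_p = 1)
  span_y <- diff(range(y))
  lower <- c(min(y) - 2 * span_y, min(y) - 2 * span_y,
             max(min(cpos) * 1e-3, 1e-9), 0.05)
  upper <- c(max(y) + 2 * span_y, max(y) + 2 * span_y,
             max(conc) * 1e3, 20)
  resid <- function(p) y - hill_current(conc, p[1L], p[2L], p[3L], p[4L])
  starts <- c(list(start), .jitter_starts(start, 7, seed))
  best <- .lm_multistart(resid, starts, lower, upper)
  p <- best$par
  structure(list(i_initial = unname(p[1L]), i_final = unname(p[2L]),
                 c_half = unname(p[3L]), hill_p = unname(p[4L]),
                 rss = best$rss, n_points = length(conc)),
            class = "dose_response_fit")
}

#' @export
predict.dose_response_fit <- function(object, newdata, ...) {
  x <- if (is.list(newdata) && !is.null(newdata$x)) newdata$x else newdata
  hill_current(x, object$i_initial, object$i_final, object$c_half,
               object$hill_p)
}

#' Fit a bi-exponential decay to a current trace
#'
#' Fits `y(t) = A1 exp(-t/tau1) + A2 exp(-t/tau2) + A_ss` to the decay
#' phase of a mechanically activated current, with `t` measured from the
#' start of the fit window. Components are returned with `tau1 < tau2`.
#' When the two time constants collapse (`tau2/tau1 < 1.5`) the fit is
#' repeated with a single exponential and flagged.
#'
#' @param trace A current [trace()], or a two-column table (t ms, I pA).
#' @param fit_window `(start, end)` in ms selecting the decay phase
#'   (ignored for tabular input); must contain at least 20 samples.
#' @param seed Multistart jitter seed.
#' @return Object of class `biexp_fit`: `a1`, `tau1`, `a2`, `tau2`,
#'   `a_ss`, `rss`, `n_points`, `single_exponential` flag.
#' @export
fit_biexp <- function(trace, fit_window = NULL, seed = 1) {
  if (inherits(trace, "trace")) {
    if (trace$kind != "current")
      stop("fit_biexp expects a current trace", call. = FALSE)
    tt <- trace_times(trace)
    if (is.null(fit_window)) fit_window <- range(tt)
    sel <- tt >= fit_window[1L] & tt <= fit_window[2L]
    t <- tt[sel] - fit_window[1L]
    y <- trace$samples[sel]
  } else {
    xy <- .as_xy(trace)
    t <- xy$x - min(xy$x); y <- xy$y
  }
  if (length(t) < 20L) stop("need at least 20 samples in the fit window",
                            call. = FALSE)
  span <- max(t)
  if (stats::sd(y) < 1e-12 * max(1, abs(mean(y)))) {
    return(structure(list(a1 = 0, tau1 = NA_real_, a2 = 0, tau2 = NA_real_,
                          a_ss = mean(y), rss = sum((y - mean(y))^2),
                          n_points = length(t), single_exponential = FALSE),
                     class = "biexp_fit"))
  }
  amp0 <- y[1L] - y[length(y)]
  ass0 <- y[length(y)]
  lower <- c(-Inf, span * 1e-4, -Inf, span * 1e-4, -Inf)
  upper <- c(Inf, span * 100, Inf, span * 100, Inf)
  resid <- function(p) y - biexp_current(t, p[1L], p[2L], p[3L], p[4L], p[5L])
  # log-spaced tau pairs spanning the window
  taus <- exp(seq(log(span / 100), log(span), length.out = 4))
  starts <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    starts[[length(starts) + 1L]] <-
      c(a1 = amp0 / 2, tau1 = taus[i], a2 = amp0 / 2, tau2 = taus[j],
        a_ss = ass0)
  }
  starts <- c(starts, .jitter_starts(starts[[2L]], 4, seed))
  best <- .lm_multistart(resid, starts, lower, upper)
  p <- unname(best$par)
  if (p[2L] > p[4L]) p <- p[c(3L, 4L, 1L, 2L, 5L)]
  single <- FALSE
  if (p[4L] / p[2L] < 1.5) {
    warning("bi-exponential time constants collapsed; refitting single exponential",
            call. = FALSE)
    resid1 <- function(q) y - (q[1L] * exp(-t / q[2L]) + q[3L])
    st1 <- list(c(a = amp0, tau = mean(p[c(2L, 4L)]), a_ss = ass0))
    b1 <- .lm_multistart(resid1, c(st1, .jitter_starts(st1[[1L]], 3, seed)),
                         c(-Inf, span * 1e-4, -Inf), c(Inf, span * 100, Inf))
    q <- unname(b1$par)
    p <- c(q[1L], q[2L], 0, NA_real_, q[3L])
    best$rss <- b1$rss
    single <- TRUE
  }
  structure(list(a1 = p[1L], tau1 = p[2L], a2 = p[3L], tau2 = p[4L],
                 a_ss = p[5L], rss = best$rss, n_points = length(t),
                 single_exponential = single),
            class = "biexp_fit")
}

#' @export
predict.biexp_fit <- function(object, newdata, ...) {
  t <- if (is.list(newdata) && !is.null(newdata$x)) newdata$x else newdata
  if (object$single_exponential || is.na(object$tau2))
    object$a1 * exp(-t / object$tau1) + object$a_ss
  else biexp_current(t, object$a1, object$tau1, object$a2, object$tau2,
                     object$a_ss)
}

#' Fit a linear I-V relation
#'
#' Ordinary least-squares line `I = g (V - E_rev)`; the slope is the
#' whole-cell conductance in nS (pA/mV) and the reversal potential is
#' where the regression line crosses zero current.
#'
#' @param data Two-column data (V mV, I pA) with at least 3 distinct
#'   voltages.
#' @return Object of class `iv_fit`: `conductance` (nS), `e_rev` (mV),
#'   `r_squared`, and the underlying `intercept` (pA).
#' @export
fit_iv <- function(data) {
  xy <- .as_xy(data)
  v <- xy$x; i <- xy$y
  if (length(unique(v)) < 3L)
    stop("need at least 3 distinct voltages", call. = FALSE)
  fit <- stats::lm(i ~ v)
  co <- stats::coef(fit)
  g <- unname(co[2L]); b <- unname(co[1L])
  e_rev <- if (abs(g) < 1e-12) NA_real_ else -b / g
  tss <- sum((i - mean(i))^2)
  r2 <- if (tss == 0) 1 else max(0, min(1, 1 - sum(stats::resid(fit)^2) / tss))
  structure(list(conductance = g, e_rev = e_rev, intercept = b,
                 r_squared = r2, n_points = length(v),
                 slope_defined = abs(g) >= 1e-12),
            class = "iv_fit")
}

#' @export
predict.iv_fit <- function(object, newdata, ...) {
  v <- if (is.list(newdata) && !is.null(newdata$x)) newdata$x else newdata
  object$conductance * v + object$intercept
}

# Coerce two-column tabular input (data.frame, matrix, or list with x/y).
.as_xy <- function(data) {
  if (is.list(data) && !is.null(data$x) && !is.null(data$y))
    return(list(x = as.numeric(data$x), y = as.numeric(data$y)))
  if (is.matrix(data)) data <- as.data.frame(data)
  if (is.data.frame(data)) {
    if (ncol(data) < 2L) stop("need two columns", call. = FALSE)
    return(list(x = as.numeric(data[[1L]]), y = as.numeric(data[[2L]])))
  }
  stop("unsupported tabular input", call. = FALSE)
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> %d component(s): X_0.5 = %.4g um, slope = %.4g /um, z = %.3g N (RSS %.3g, n = %d)\n",
              x$n_components, x$x_half, x$slope_s, x$z, x$rss, x$n_points))
  invisible(x)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> IC50 = %.4g uM, Hill p = %.3g, I_i = %.4g pA, I_f = %.4g pA (RSS %.3g, n = %d)\n",
              x$c_half, x$hill_p, x$i_initial, x$i_final, x$rss, x$n_points))
  invisible(x)
}

#' @export
print.biexp_fit <- function(x, ...) {
  if (x$single_exponential)
    cat(sprintf("<biexp_fit> collapsed to single exponential: A = %.4g pA, tau = %.4g ms, A_ss = %.4g pA\n",
                x$a1, x$tau1, x$a_ss))
  else
    cat(sprintf("<biexp_fit> A1 = %.4g pA (tau1 = %.4g ms), A2 = %.4g pA (tau2 = %.4g ms), A_ss = %.4g pA (RSS %.3g)\n",
                x$a1, x$tau1, x$a2, x$tau2, x$a_ss, x$rss))
  invisible(x)
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf("<iv_fit> g = %.4g nS, E_rev = %.4g mV, R^2 = %.4f (n = %d)\n",
              x$conductance, x$e_rev, x$r_squared, x$n_points))
  invisible(x)
}
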