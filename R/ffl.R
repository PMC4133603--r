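#' Parameters of the normalized incoherent feed-forward loop
#'
#' The I1-FFL (master activator -> intermediate repressor -> jointly
#' regulated target) is written in normalized fold-change variables: basal
#' steady states are scaled to 1, so a step stimulus is fully described by
#' the input fold change `fold` (F), the repressor relaxation rate
#' `alpha_r` and the target relaxation rate `alpha_z` (per hour). With
#' `repression = "strong"` the target production term is `F / r` (the
#' fold-sensor limit that confers exact adaptation); `"hill"` uses a Hill
#' repression function with threshold `K` and coefficient `h`, normalized
#' so the basal state stays stationary.
#'
#' @param fold Input fold change F >= 1 (F = 1 means no stimulus).
#' @param alpha_r Repressor relaxation rate, 1/h, > 0.
#' @param alpha_z Target relaxation rate, 1/h, > 0.
#' @param repression `"strong"` (default) or `"hill"`.
#' @param K,h Hill repression threshold (fold units, > 0) and coefficient
#'   (>= 1); required iff `repression = "hill"`.
#' @param amplitude Optional output scale applied to the target (default 1).
#' @return An `ffl_params` list.
#' @export
ffl_params <- function(fold, alpha_r, alpha_z,
                       repression = c("strong", "hill"),
                       K = NULL, h = NULL, amplitude = 1) {
  repression <- match.arg(repression)
  assert_scalar_number(fold, "fold", lower = 1)
  assert_scalar_number(alpha_r, "alpha_r")
  assert_scalar_number(alpha_z, "alpha_z")
  if (alpha_r <= 0 || alpha_z <= 0) stop("relaxation rates must be > 0")
  if (repression == "hill") {
    if (is.null(K) || is.null(h)) stop("hill repression requires K and h")
    assert_scalar_number(K, "K")
    assert_scalar_number(h, "h", lower = 1)
    if (K <= 0) stop("K must be > 0")
  } else if (!is.null(K) || !is.null(h)) {
    stop("K and h are only meaningful with repression = 'hill'")
  }
  assert_scalar_number(amplitude, "amplitude")
  structure(list(fold = fold, alpha_r = alpha_r, alpha_z = alpha_z,
                 repression = repression, K = K, h = h,
                 amplitude = amplitude),
            class = "ffl_params")
}

#' @export
print.ffl_params <- function(x, ...) {
  cat(sprintf("I1-FFL parameters: F = %.4g, alpha_r = %.4g /h, alpha_z = %.4g /h (%s repression)\n",
              x$fold, x$alpha_r, x$alpha_z, x$repression))
  invisible(x)
}

ffl_trajectory <- function(time, r, z) {
  structure(data.frame(time = time, r = r, z = z),
            class = c("ffl_trajectory", "data.frame"))
}

#' Simulate the I1-FFL by numerical integration
#'
#' Integrates, in normalized fold-change variables with `r(0) = z(0) = 1`:
#' `dr/dt = alpha_r (F - r)` and, for strong repression,
#' `dz/dt = alpha_z (F / r - z)`; for Hill repression,
#' `dz/dt = alpha_z (F (1 + (1/K)^h) / (1 + (r/K)^h) - z)`
#' (the normalizing factor keeps the basal state stationary before the
#' stimulus). Uses an adaptive-step stiff-capable integrator (lsoda) with
#' relative tolerance 1e-10.
#'
#' @param params [ffl_params()] object.
#' @param times Non-negative time grid (hours).
#' @return An `ffl_trajectory` data frame with columns `time`, `r`, `z`.
#' @examples
#' p <- ffl_params(fold = 10, alpha_r = 1, alpha_z = 1)
#' simulate_i1ffl(p, times = c(0, 1))$z[2]  # ~ 1.960
#' @export
simulate_i1ffl <- function(params, times) {
  stopifnot(inherits(params, "ffl_params"))
  if (any(times < 0)) stop("times must be >= 0")
  tt <- sort(unique(c(0, times)))
  F <- params$fold
  production <- if (params$repression == "strong") {
    function(r) F / r
  } else {
    K <- params$K; h <- params$h
    norm <- 1 + (1 / K)^h
    function(r) F * norm / (1 + (r / K)^h)
  }
  rhs <- function(t, y, parms) {
    list(c(params$alpha_r * (F - y[1L]),
           params$alpha_z * (production(y[1L]) - y[2L])))
  }
  sol <- deSolve::ode(y = c(r = 1, z = 1), times = tt, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  if (any(!is.finite(sol[, c("r", "z")]))) {
    stop(sprintf("non-finite state during integration (F = %g, alpha_r = %g, alpha_z = %g)",
                 F, params$alpha_r, params$alpha_z))
  }
  idx <- match(times, tt)
  ffl_trajectory(times, sol[idx, "r"],
                 1 + params$amplitude * (sol[idx, "z"] - 1))
}

#' Analytic I1-FFL solution for equal relaxation rates
#'
#' With equal repressor and target rates (`alpha_r = alpha_z = alpha`) and
#' strong repression, the system solves in closed form:
#' `r(t) = F + (1 - F) exp(-alpha t)` and
#' `z(t) = 1 + ((F - 1)/F) exp(-alpha t) ln(1 - F + F exp(alpha t))`.
#' The logarithm is evaluated in the numerically stable form
#' `alpha t + ln F + log1p((1 - F) exp(-alpha t) / F)`, which is exact for
#' large `alpha t`. The closed form was verified by substitution into the
#' governing equations.
#'
#' @param fold Input fold change F >= 1.
#' @param alpha Shared relaxation rate (1/h), > 0.
#' @param times Non-negative time grid (hours).
#' @return An `ffl_trajectory` data frame.
#' @export
analytic_i1ffl_equal_rates <- function(fold, alpha, times) {
  assert_scalar_number(fold, "fold", lower = 1)
  assert_scalar_number(alpha, "alpha")
  if (alpha <= 0) stop("alpha must be > 0")
  if (any(times < 0)) stop("times must be >= 0")
  at <- alpha * times
  r <- fold + (1 - fold) * exp(-at)
  if (fold == 1) {
    z <- rep(1, length(times))
  } else {
    lg <- at + log(fold) + log1p((1 - fold) * exp(-at) / fold)
    z <- 1 + (fold - 1) / fold * exp(-at) * lg
  }
  ffl_trajectory(times, r, z)
}

#' Simulate the uncoupled (repressor-clamped) target
#'
#' Clamping the intermediate repressor at its basal level (r = 1), as in a
#' repressor knockout, collapses the I1-FFL pulse to simple monotone
#' activation: `z(t) = F + (1 - F) exp(-alpha_z t)`, saturating at the
#' plateau F.
#'
#' @inheritParams simulate_i1ffl
#' @return An `ffl_trajectory` data frame (with `r` identically 1).
#' @export
simulate_uncoupled <- function(params, times) {
  stopifnot(inherits(params, "ffl_params"))
  if (any(times < 0)) stop("times must be >= 0")
  F <- params$fold
  z <- F + (1 - F) * exp(-params$alpha_z * times)
  ffl_trajectory(times, rep(1, length(times)),
                 1 + params$amplitude * (z - 1))
}

#' Simulate a coherent FFL with an AND gate (delayed activation)
#'
#' The intermediate activator relaxes toward the input
#' (`y(t) = F + (1 - F) exp(-alpha_y t)` for basal level 1, or
#' `y(t) = F (1 - exp(-alpha_y t))` for the zero-basal variant) and target
#' production switches on only while `y >= K`, producing an onset delay
#' `T = ln((F - 1)/(F - K)) / alpha_y` (basal 1) or
#' `T = ln(F/(F - K)) / alpha_y` (basal 0). After the gate opens the target
#' relaxes monotonically to F. This is the delay-element behaviour typical
#' of genes with a lag before robust sustained induction.
#'
#' @param fold Input fold change F.
#' @param alpha_y,alpha_z Intermediate and target relaxation rates (1/h).
#' @param K Activation threshold; needs `1 < K < F` (basal 1) or
#'   `0 < K < F` (basal 0). `K >= F` is an error: the gate never opens.
#' @param times Non-negative time grid (hours).
#' @param basal `"one"` (normalized fold-change variables, default) or
#'   `"zero"` (intermediate starts at zero).
#' @return An `ffl_trajectory` data frame (`r` holds the intermediate
#'   activator) with attribute `onset_delay` (hours).
#' @export
simulate_cffl_and <- function(fold, alpha_y, alpha_z, K, times,
                              basal = c("one", "zero")) {
  basal <- match.arg(basal)
  assert_scalar_number(fold, "fold")
  assert_scalar_number(alpha_y, "alpha_y")
  assert_scalar_number(alpha_z, "alpha_z")
  assert_scalar_number(K, "K")
  if (alpha_y <= 0 || alpha_z <= 0) stop("rates must be > 0")
  if (K >= fold) stop("K >= F: the AND gate never opens")
  if (any(times < 0)) stop("times must be >= 0")
  if (basal == "one") {
    if (K <= 1) stop("basal-1 variant needs K > 1")
    y <- fold + (1 - fold) * exp(-alpha_y * times)
    delay <- log((fold - 1) / (fold - K)) / alpha_y
  } else {
    if (K <= 0) stop("K must be > 0")
    y <- fold * (1 - exp(-alpha_y * times))
    delay <- log(fold / (fold - K)) / alpha_y
  }
  z <- ifelse(times < delay, 1,
              fold + (1 - fold) * exp(-alpha_z * (times - delay)))
  out <- ffl_trajectory(times, y, z)
  attr(out, "onset_delay") <- delay
  out
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SSres / SStot` of a fitted curve against observations.
#'
#' @param observed,fitted Equal-length numeric vectors (>= 2 values);
#'   `observed` must not be constant.
#' @return R-squared (<= 1; negative when the fit is worse than the mean).
#' @export
r_squared <- function(observed, fitted) {
  if (length(observed) != length(fitted) || length(observed) < 2L) {
    stop("observed and fitted must have equal length >= 2")
  }
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0) stop("R-squared undefined: observed values are constant")
  1 - sum((observed - fitted)^2) / sstot
}

# normalize the time-course argument accepted by fit_i1ffl /
# predict_repressor: either the gen_ffl_timecourse() list or a data frame
# with a time column and a value/mean column
as_time_course <- function(tc) {
  if (is.list(tc) && !is.data.frame(tc) && all(c("time", "mean") %in% names(tc))) {
    return(data.frame(time = tc$time, value = tc$mean))
  }
  if (is.data.frame(tc) && "time" %in% names(tc)) {
    vcol <- intersect(c("value", "mean", "z"), names(tc))[1L]
    if (!is.na(vcol)) return(data.frame(time = tc$time, value = tc[[vcol]]))
  }
  stop("time course must be a gen_ffl_timecourse() result or a data frame ",
       "with columns time and value/mean")
}

# penalized objective in log-parameter space; returns Inf outside bounds
fit_bounds <- list(fold = c(1 + 1e-9, 1e3), rate = c(1e-2, 1e2))

#' Fit the I1-FFL to a fold-change time course
#'
#' Two-stage global least squares. Stage 1 fits the analytic equal-rates
#' solution ([analytic_i1ffl_equal_rates()]) over (F, alpha); stage 2 fits
#' the full numerical model ([simulate_i1ffl()], strong repression) over
#' (F, alpha_r, alpha_z), initialized from stage 1. Both stages minimize
#' the sum of squared residuals by derivative-free Nelder-Mead search in
#' log-parameter space from multiple seeded starts, with bounds
#' F in [1, 1e3] and rates in [1e-2, 1e2] per hour enforced by penalty.
#'
#' @param tc Time course: result of [gen_ffl_timecourse()] or a data frame
#'   with columns `time` and `value` (fold change, basal = 1). At least 4
#'   points must fall inside the fit window and all values must be > 0.
#' @param window_hours Optional fit window; only points with
#'   `time <= window_hours` are used (e.g. 4 to weight the early response).
#' @param seed Integer seed fixing the multi-start perturbations.
#' @param n_starts Number of starts per stage (>= 1).
#' @return An `ffl_fit` list with elements `stage1` and `stage2`, each a
#'   `ffl_fit_result` carrying `params` ([ffl_params()]), `sse`,
#'   `r_squared`, `fit_window` and `stage`.
#' @export
fit_i1ffl <- function(tc, window_hours = NULL, seed = 1, n_starts = 6) {
  df <- as_time_course(tc)
  if (!is.null(window_hours)) df <- df[df$time <= window_hours, , drop = FALSE]
  if (nrow(df) < 4L) stop("need at least 4 time points in the fit window")
  if (any(df$value <= 0)) stop("fold-change values must be > 0")
  tm <- df$time
  obs <- df$value
  sstot <- sum((obs - mean(obs))^2)
  if (sstot == 0) stop("observed values are constant; nothing to fit")
  window <- if (is.null(window_hours)) max(tm) else window_hours

  penalize <- function(F, rates) {
    F < fit_bounds$fold[1L] || F > fit_bounds$fold[2L] ||
      any(rates < fit_bounds$rate[1L]) || any(rates > fit_bounds$rate[2L])
  }
  obj1 <- function(par) {
    F <- 1 + exp(par[1L]); a <- exp(par[2L])
    if (penalize(F, a)) return(1e12)
    z <- analytic_i1ffl_equal_rates(F, a, tm)$z
    sum((obs - z)^2)
  }
  obj2 <- function(par) {
    F <- 1 + exp(par[1L]); ar <- exp(par[2L]); az <- exp(par[3L])
    if (penalize(F, c(ar, az))) return(1e12)
    p <- ffl_params(F, ar, az)
    z <- tryCatch(simulate_i1ffl(p, tm)$z, error = function(e) NULL)
    if (is.null(z) || any(!is.finite(z))) return(1e12)
    sum((obs - z)^2)
  }
  polish <- function(obj, par) {
    for (i in 1:2) {
      res <- stats::optim(par, obj, method = "Nelder-Mead",
                          control = list(reltol = 1e-14, maxit = 5000L))
      par <- res$par
    }
    res
  }
  run_stage <- function(obj, starts) {
    best <- NULL
    for (s in starts) {
      res <- tryCatch(polish(obj, s), error = function(e) NULL)
      if (!is.null(res) && is.finite(res$value) &&
          (is.null(best) || res$value < best$value)) {
        best <- res
      }
    }
    if (is.null(best)) stop("no fit start converged")
    best
  }

  # heuristics: the peak height bounds F from below; its time sets the scale
  zmax <- max(obs)
  tpk <- max(tm[which.max(obs)], min(tm[tm > 0]))
  f0 <- log(pmax(c(zmax, 3 * zmax, 10 * zmax) - 1, 0.2))
  a0 <- log(c(0.5, 1, 2) / tpk)
  base1 <- lapply(seq_along(f0), function(i) c(f0[i], a0[i]))
  starts1 <- withr::with_seed(seed, {
    extra <- lapply(seq_len(max(0L, n_starts - length(base1))), function(i) {
      base1[[1L + (i - 1L) %% length(base1)]] + stats::rnorm(2L, 0, 0.7)
    })
    c(base1, extra)[seq_len(max(n_starts, length(base1)))]
  })
  best1 <- run_stage(obj1, starts1)
  p1 <- ffl_params(1 + exp(best1$par[1L]), exp(best1$par[2L]),
                   exp(best1$par[2L]))
  fit1 <- structure(list(params = p1, sse = best1$value,
                         r_squared = 1 - best1$value / sstot,
                         fit_window = window,
                         stage = "analytic_equal_rates"),
                    class = "ffl_fit_result")

  s2_center <- c(best1$par[1L], best1$par[2L], best1$par[2L])
  starts2 <- withr::with_seed(seed + 1L, {
    extra <- lapply(seq_len(max(0L, n_starts - 1L)), function(i) {
      s2_center + stats::rnorm(3L, 0, 0.5)
    })
    c(list(s2_center), extra)
  })
  best2 <- run_stage(obj2, starts2)
  p2 <- ffl_params(1 + exp(best2$par[1L]), exp(best2$par[2L]),
                   exp(best2$par[3L]))
  fit2 <- structure(list(params = p2, sse = best2$value,
                         r_squared = 1 - best2$value / sstot,
                         fit_window = window,
                         stage = "numeric_free_rates"),
                    class = "ffl_fit_result")
  structure(list(stage1 = fit1, stage2 = fit2), class = "ffl_fit")
}

#' @export
print.ffl_fit_result <- function(x, ...) {
  cat(sprintf("[%s] F = %.4g, alpha_r = %.4g, alpha_z = %.4g | SSE = %.3g, R^2 = %.4f (window %g h)\n",
              x$stage, x$params$fold, x$params$alpha_r, x$params$alpha_z,
              x$sse, x$r_squared, x$fit_window))
  invisible(x)
}

#' @export
print.ffl_fit <- function(x, ...) {
  print(x$stage1)
  print(x$stage2)
  invisible(x)
}

#' Predicted intermediate-repressor dynamics
#'
#' Under the fitted I1-FFL parameters the repressor follows
#' `r(t) = F + (1 - F) exp(-alpha_r t)`: a monotone rise from 1 to F. The
#' prediction can be overlaid against a candidate repressor's measured
#' time course to ask whether that gene could be the intermediate node;
#' when a candidate is supplied, the comparison R-squared of candidate
#' values against the prediction at the candidate's time points is
#' returned.
#'
#' @param fit An `ffl_fit` (stage-2 parameters are used) or a single
#'   `ffl_fit_result`.
#' @param times Time grid for the predicted trajectory (hours).
#' @param candidate Optional measured time course of a candidate repressor
#'   (data frame with `time` and `value`/`mean`, or a
#'   [gen_ffl_timecourse()] result).
#' @return List: `trajectory` (data frame `time`, `r`) and
#'   `comparison_r_squared` (`NULL` without a candidate).
#' @export
predict_repressor <- function(fit, times, candidate = NULL) {
  res <- if (inherits(fit, "ffl_fit")) fit$stage2 else fit
  stopifnot(inherits(res, "ffl_fit_result"))
  p <- res$params
  rfun <- function(t) p$fold + (1 - p$fold) * exp(-p$alpha_r * t)
  out <- list(trajectory = data.frame(time = times, r = rfun(times)),
              comparison_r_squared = NULL)
  if (!is.null(candidate)) {
    cd <- as_time_course(candidate)
    out$comparison_r_squared <- r_squared(cd$value, rfun(cd$time))
  }
  out
}
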