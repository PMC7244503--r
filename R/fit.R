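#' Fluorescence trace
#'
#' A trace is a tibble with a strictly increasing `time_s` column and one
#' or more signal columns (arbitrary fluorescence units). Optional labelled
#' segments record the acquisition protocol (baseline, post-substrate,
#' post-invader additions).
#'
#' @param time_s time in seconds, strictly increasing
#' @param signal fluorescence signal (a.u.)
#' @param segments optional tibble with columns `segment`, `start_s`,
#'   `end_s`
#' @param ... further signal columns (e.g. `cy3`, `cy5`)
#' @return tibble of class `tmsd_trace`
#' @export
tmsd_trace <- function(time_s, signal = NULL, segments = NULL, ...) {
  extra <- list(...)
  if (any(!is.finite(time_s)) ||
      any(vapply(c(list(signal), extra), function(v)
        !is.null(v) && any(!is.finite(v)), logical(1)))) {
    stop("trace contains NaN or non-finite values", call. = FALSE)
  }
  if (any(diff(time_s) <= 0)) {
    stop("trace time must be strictly increasing", call. = FALSE)
  }
  cols <- c(list(time_s = time_s),
            if (!is.null(signal)) list(signal = signal), extra)
  out <- tibble::as_tibble(cols)
  class(out) <- c("tmsd_trace", class(out))
  attr(out, "segments") <- segments
  out
}

#' Fractional fluorescence recovery
#'
#' Normalizes a trace to `(F(t) - Fmin) / (Fmax - Fmin)`, where `Fmin` and
#' `Fmax` are the mean signal over a baseline window and a maximum window.
#' The result is invariant under affine transformations of the raw signal.
#'
#' @param trace a [tmsd_trace()] (column `signal`)
#' @param baseline_window,max_window length-2 numeric time windows
#'   `c(start_s, end_s)` over which `Fmin` / `Fmax` are averaged
#' @return normalized trace of class `tmsd_trace`
#' @export
normalize_trace <- function(trace, baseline_window, max_window) {
  stopifnot(length(baseline_window) == 2, length(max_window) == 2)
  in_win <- function(w) trace$time_s >= w[1] & trace$time_s <= w[2]
  i_min <- in_win(baseline_window)
  i_max <- in_win(max_window)
  if (!any(i_min) || !any(i_max)) {
    stop("normalization window contains no samples", call. = FALSE)
  }
  f_min <- mean(trace$signal[i_min])
  f_max <- mean(trace$signal[i_max])
  if (f_max == f_min) {
    stop("degenerate trace: Fmax equals Fmin, cannot normalize",
         call. = FALSE)
  }
  out <- trace
  out$signal <- (trace$signal - f_min) / (f_max - f_min)
  out
}

#' Fit rate constants of an ODE model to a trace
#'
#' Nonlinear least squares of a mass-action model against a fluorescence
#' trace. `model_builder` receives a named list of rate constants (the
#' free parameters merged over `known`) and must return a
#' [reaction_network()] with a signal definition; the model signal at the
#' trace times is compared with `trace$signal`. Optimisation runs in
#' log10-parameter space (which enforces positivity) with a trust-region
#' Levenberg-Marquardt solver and `multi_start` log-spaced restarts per
#' free constant; the best converged solution by residual sum of squares
#' is returned. Standard errors come from the Jacobian at the optimum.
#' The result is deterministic for identical inputs.
#'
#' @param trace a [tmsd_trace()] with columns `time_s`, `signal`
#' @param model_builder function(named list of constants) ->
#'   [reaction_network()]
#' @param free_parameters named numeric vector of initial guesses for the
#'   free rate constants
#' @param known named list of fixed parameters passed to `model_builder`
#' @param lower,upper bounds on the free constants (natural scale)
#' @param multi_start number of log-spaced starting points
#' @param model_id optional identifier recorded in the result
#' @return object of class `tmsd_fit`
#' @export
fit_rate_constant <- function(trace, model_builder, free_parameters,
                              known = list(), lower = NULL, upper = NULL,
                              multi_start = 5, model_id = NULL) {
  stopifnot(is.numeric(free_parameters), !is.null(names(free_parameters)),
            all(free_parameters > 0))
  n_free <- length(free_parameters)
  if (nrow(trace) < n_free + 2) {
    stop("need at least as many data points as free parameters + 2",
         call. = FALSE)
  }
  if (is.null(lower)) lower <- free_parameters / 1e4
  if (is.null(upper)) upper <- free_parameters * 1e4
  times <- trace$time_s
  obs <- trace$signal

  resid_fun <- function(log_par) {
    pars <- as.list(stats::setNames(10^log_par, names(free_parameters)))
    net <- do.call(model_builder, c(pars, known))
    sim <- simulate_network(net, times)
    sim$signal - obs
  }

  offsets <- if (multi_start > 1) {
    seq(-1, 1, length.out = multi_start)
  } else 0
  best <- NULL
  for (off in offsets) {
    start <- log10(free_parameters) + off
    start <- pmin(pmax(start, log10(lower)), log10(upper))
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, fn = resid_fun,
        lower = log10(lower), upper = log10(upper),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }

  if (is.null(best)) {
    return(structure(
      list(estimates = tibble::tibble(term = names(free_parameters),
                                      estimate = NA_real_,
                                      std.error = NA_real_),
           rss = NA_real_, converged = FALSE, n_obs = length(obs),
           model_id = model_id %||% "unknown"),
      class = "tmsd_fit"
    ))
  }

  fit <- best$fit
  converged <- fit$info %in% 1:4
  est_log <- fit$par
  est <- 10^est_log
  dof <- max(length(obs) - n_free, 1)
  sigma2 <- best$rss / dof
  se <- rep(NA_real_, n_free)
  cov_log <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  if (!is.null(cov_log)) {
    d <- diag(cov_log)
    se <- ifelse(d >= 0, sqrt(d) * log(10) * est, NA_real_)
  }
  structure(
    list(
      estimates = tibble::tibble(term = names(free_parameters),
                                 estimate = unname(est),
                                 std.error = unname(se)),
      rss = best$rss, converged = converged, n_obs = length(obs),
      model_id = model_id %||% "model", info = fit$info,
      message = fit$message
    ),
    class = "tmsd_fit"
  )
}

#' @export
print.tmsd_fit <- function(x, ...) {
  cat("<tmsd_fit>", x$model_id,
      if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  print(x$estimates)
  cat(sprintf("  RSS = %.4g over %d points\n", x$rss, x$n_obs))
  invisible(x)
}

#' Tidy a displacement-kinetics fit
#'
#' @param x a [fit_rate_constant()] result
#' @param ... unused
#' @return tibble with columns `term`, `estimate`, `std.error`
#' @importFrom generics tidy
#' @method tidy tmsd_fit
#' @export
tidy.tmsd_fit <- function(x, ...) x$estimates

#' One-row summary of a displacement-kinetics fit
#'
#' @param x a [fit_rate_constant()] result
#' @param ... unused
#' @return tibble with columns `rss`, `converged`, `n_obs`, `model_id`
#' @importFrom generics glance
#' @method glance tmsd_fit
#' @export
glance.tmsd_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged, n_obs = x$n_obs,
                 model_id = x$model_id)
}

#' @export
generics::tidy

#' @export
generics::glance

`%||%` <- function(a, b) if (is.null(a)) b else a
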