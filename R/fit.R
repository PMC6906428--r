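#' Fit the logistic seed-filling curve to one dry-weight trajectory
#'
#' Nonlinear least squares for `w(t) = k / (1 + a exp(-b t))` by
#' Levenberg-Marquardt (via [minpack.lm::nlsLM()]).  Starting values are
#' self-generated unless supplied: `k0 = 1.05 * max(w)`, then the logit
#' transform `log(k0 / w - 1)` is regressed on `t`, giving `b0 = -slope` and
#' `a0 = exp(intercept)` — robust for S-shaped data.
#'
#' @param times Days after pollination; strictly increasing, length >= 4.
#' @param weights 50-seed dry weights (g); non-negative, same length.
#' @param init Optional named numeric vector/list with starting `k`, `a`, `b`.
#' @param max_iter Maximum optimizer iterations (default 200).
#' @return An object of class `filling_fit`: a list with elements
#'   `k`, `a`, `b`, `r_squared`, `n_obs`, `converged`, plus the data and
#'   fitted values.  On non-convergence the parameter estimates from the last
#'   iterate are returned with `converged = FALSE` — never silent garbage.
#' @export
#' @examples
#' t <- c(10, 15, 20, 25, 30, 35, 40, 43, 46, 49, 52, 55, 58, 61)
#' w <- logistic_weight(t, k = 15, a = 36, b = 0.12)
#' fit <- fit_logistic(t, w)
#' glance(fit)
fit_logistic <- function(times, weights, init = NULL, max_iter = 200) {
  stopifnot(is.numeric(times), is.numeric(weights))
  if (length(times) != length(weights)) {
    abort("`times` and `weights` must have equal length.")
  }
  if (length(times) < 4) {
    abort("Need at least 4 time points to fit 3 logistic parameters.")
  }
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  if (any(weights < 0)) abort("`weights` must be non-negative (g).")
  if (sd(weights) == 0) {
    abort("Degenerate input: all dry weights are equal; no filling signal to fit.")
  }

  if (is.null(init)) init <- logistic_start(times, weights)
  init <- as.list(init)[c("k", "a", "b")]
  if (anyNA(names(init)) || any(vapply(init, is.null, logical(1)))) {
    abort("`init` must supply named starting values k, a, b.")
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      weights ~ k / (1 + a * exp(-b * times)),
      start = init,
      lower = c(k = .Machine$double.eps, a = .Machine$double.eps,
                b = .Machine$double.eps),
      control = minpack.lm::nls.lm.control(
        maxiter = max_iter, ftol = 1e-12, ptol = 1e-12
      )
    ),
    error = function(e) e
  )

  if (inherits(fit, "error")) {
    res <- list(
      k = unname(init$k), a = unname(init$a), b = unname(init$b),
      r_squared = NA_real_, n_obs = length(times), converged = FALSE,
      times = times, weights = weights, fitted = rep(NA_real_, length(times)),
      message = conditionMessage(fit)
    )
    class(res) <- "filling_fit"
    return(res)
  }

  est <- coef(fit)
  info <- fit$convInfo
  converged <- isTRUE(info$isConv) ||
    # nls.lm reports convergence codes 1:3 as success
    (!is.null(info$stopCode) && info$stopCode %in% 1:3)
  fitted_w <- as.numeric(stats::fitted(fit))
  res <- list(
    k = unname(est["k"]), a = unname(est["a"]), b = unname(est["b"]),
    r_squared = r_squared(weights, fitted_w),
    n_obs = length(times), converged = converged,
    times = times, weights = weights, fitted = fitted_w,
    message = NULL
  )
  class(res) <- "filling_fit"
  res
}

logistic_start <- function(times, weights) {
  k0 <- 1.05 * max(weights)
  ok <- weights > 0 & weights < k0
  if (sum(ok) < 2) abort("Degenerate input: too few informative weights to initialize.")
  z <- log(k0 / weights[ok] - 1)
  sl <- coef(lm(z ~ times[ok]))
  b0 <- max(-unname(sl[2]), 1e-4)
  a0 <- max(exp(unname(sl[1])), 1e-4)
  list(k = k0, a = a0, b = b0)
}

r_squared <- function(observed, fitted) {
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) abort("Degenerate input: zero total variance; R^2 undefined.")
  1 - sum((observed - fitted)^2) / ss_tot
}

#' Coefficient of determination of a filling fit
#'
#' `R^2 = 1 - SS_res / SS_tot` of a fitted logistic curve against a
#' trajectory.  May be negative for a curve unrelated to the data; such
#' values are reported as computed, with a warning.
#'
#' @param fit A `filling_fit` object.
#' @param times,weights Optional trajectory to score against; defaults to the
#'   data the curve was fitted to.
#' @return A single numeric R-squared.
#' @export
goodness_of_fit <- function(fit, times = fit$times, weights = fit$weights) {
  stopifnot(inherits(fit, "filling_fit"))
  pred <- logistic_weight(times, fit$k, fit$a, fit$b)
  r2 <- r_squared(weights, pred)
  if (r2 < 0) warn("R^2 is negative: the curve fits worse than the mean.")
  r2
}

#' @export
print.filling_fit <- function(x, ...) {
  cat("Logistic seed-filling fit (", x$n_obs, " points)\n", sep = "")
  cat(sprintf("  k = %.4g g   a = %.4g   b = %.4g /DAP\n", x$k, x$a, x$b))
  cat(sprintf("  R^2 = %.4f   converged: %s\n",
              x$r_squared, x$converged))
  invisible(x)
}

#' @rdname fit_logistic
#' @param x A `filling_fit` object.
#' @param ... Unused.
#' @export
tidy.filling_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k", "a", "b"),
    estimate = c(x$k, x$a, x$b)
  )
}

#' @rdname fit_logistic
#' @export
glance.filling_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, nobs = x$n_obs, converged = x$converged
  )
}

#' @rdname fit_logistic
#' @export
augment.filling_fit <- function(x, ...) {
  tibble::tibble(
    dap = x$times, weight_g = x$weights,
    .fitted = x$fitted, .resid = x$weights - x$fitted
  )
}

#' Fit one logistic curve per line and environment
#'
#' Data-frame-first wrapper around [fit_logistic()]: one filling curve is
#' fitted for each inbred line in each environment.
#'
#' @param data Long-format data frame with columns `line_id`, `environment`,
#'   `dap` and `weight_g` (see [read_weight_table()]).
#' @param min_points Minimum observations required per curve (default 4);
#'   shorter trajectories are dropped with a warning.
#' @param init,max_iter Passed to [fit_logistic()].
#' @return Tibble with one row per line x environment: `line_id`,
#'   `environment`, `k`, `a`, `b`, `r_squared`, `n_obs`, `converged`.
#' @export
fit_filling <- function(data, min_points = 4, init = NULL, max_iter = 200) {
  data <- validate_weight_table(data)
  grp <- dplyr::group_by(data, .data$line_id, .data$environment)
  sizes <- dplyr::summarise(grp, n = dplyr::n(), .groups = "drop")
  if (any(sizes$n < min_points)) {
    warn(sprintf("%d line x environment series have fewer than %d points and were dropped.",
                 sum(sizes$n < min_points), min_points))
  }
  keep <- dplyr::semi_join(data, dplyr::filter(sizes, .data$n >= min_points),
                           by = c("line_id", "environment"))
  res <- keep |>
    dplyr::arrange(.data$line_id, .data$environment, .data$dap) |>
    dplyr::group_by(.data$line_id, .data$environment) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_logistic(d$dap, d$weight_g, init = init, max_iter = max_iter)
      tibble::tibble(k = f$k, a = f$a, b = f$b, r_squared = f$r_squared,
                     n_obs = f$n_obs, converged = f$converged)
    }) |>
    dplyr::ungroup()
  res
}

validate_weight_table <- function(data) {
  stopifnot(is.data.frame(data))
  need <- setdiff(c("line_id", "environment", "dap", "weight_g"), names(data))
  if (length(need)) {
    abort(paste0("Weight table lacks column(s): ", paste(need, collapse = ", ")))
  }
  if (any(data$weight_g < 0)) {
    bad <- which(data$weight_g < 0)
    abort(paste0("Negative dry weight in row(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  key <- paste(data$line_id, data$environment, data$dap, sep = "\r")
  if (anyDuplicated(key)) {
    d <- data[duplicated(key), , drop = FALSE][1, ]
    abort(sprintf("Duplicate observation for line '%s', environment '%s', dap %s.",
                  d$line_id, d$environment, format(d$dap)))
  }
  tibble::as_tibble(data)
}
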