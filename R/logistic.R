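#' Logistic seed-filling curve
#'
#' Dry weight of the developing seed at time `t` under the three-parameter
#' logistic model `w(t) = k / (1 + a * exp(-b * t))`, where `k` is the
#' asymptotic final dry weight (g), `a` is a dimensionless shape parameter
#' locating the curve in time, and `b` (per day after pollination, DAP) is the
#' relative filling rate.  The curve has its inflexion at `t = log(a)/b`,
#' where `w = k/2` and the instantaneous filling rate is maximal.
#'
#' @param t Time in days after pollination (DAP); any real value, vectorised.
#' @param k Final (asymptotic) seed dry weight in grams; must be positive.
#' @param a Shape parameter; must be positive.
#' @param b Relative filling rate per DAP; must be positive.
#' @return Numeric vector of dry weights (g), strictly increasing in `t` and
#'   bounded in `(0, k)`.
#' @seealso [filling_rate()], [fit_logistic()], [derive_parameters()]
#' @export
#' @examples
#' logistic_weight(log(50) / 0.2, k = 1, a = 50, b = 0.2)  # k/2 at inflexion
logistic_weight <- function(t, k, a, b) {
  check_logistic_params(k, a, b)
  k / (1 + a * exp(-b * t))
}

#' Instantaneous seed-filling rate
#'
#' First derivative of [logistic_weight()]:
#' `v(t) = k a b exp(-b t) / (1 + a exp(-b t))^2` (g/DAP).  The rate is
#' positive everywhere, symmetric about the inflexion `t = log(a)/b`, and
#' attains its maximum `k b / 4` there.
#'
#' @inheritParams logistic_weight
#' @return Numeric vector of filling rates (g/DAP).
#' @export
filling_rate <- function(t, k, a, b) {
  check_logistic_params(k, a, b)
  # k*b*p*(1-p) with p = w/k: algebraically k*a*b*exp(-bt)/(1+a*exp(-bt))^2,
  # but stable for arbitrarily large |t|
  p <- 1 / (1 + a * exp(-b * t))
  k * b * p * (1 - p)
}

check_logistic_params <- function(k, a, b) {
  if (any(!is.finite(k)) || any(k <= 0)) {
    abort("`k` must be a positive finite final dry weight (g).")
  }
  if (any(!is.finite(a)) || any(a <= 0)) {
    abort("`a` must be a positive finite shape parameter.")
  }
  if (any(!is.finite(b)) || any(b <= 0)) {
    abort("`b` must be a positive finite relative filling rate (per DAP).")
  }
  invisible(TRUE)
}

#' Derive the twelve seed-filling traits from logistic parameters
#'
#' Given fitted logistic parameters, computes the full set of closed-form
#' seed-filling traits: the two inflexion times of the rate curve (`t1`, `t2`)
#' delimiting the fast growth phase, the completion time `t3` at which the
#' seed reaches a `completion` fraction of its final weight, the dry matter
#' accumulated in each of the three phases (`w1`, `w2`, `w3`), the time to
#' half the final weight (`t_mid = log(a)/b`), the average filling rate
#' `v_bar = k b / 6`, the active filling period `T = 6 / b`, and the maximum
#' filling rate `v_max = k b / 4`.
#'
#' Closed forms (with `completion = c`):
#' \deqn{t_1 = -\log((2+\sqrt3)/a)/b, \quad t_2 = -\log((2-\sqrt3)/a)/b,
#'       \quad t_3 = \log(a c/(1-c))/b}
#' \deqn{w_1 = k/(3+\sqrt3), \quad w_2 = (\sqrt3/3) k,
#'       \quad w_3 = (c - 1/2 - \sqrt3/6) k}
#' so that `w1 + w2 + w3 = c * k` exactly, `v_max = 1.5 * v_bar`, and
#' `T * v_bar = k`.  At the default `completion = 0.99`,
#' `t3 = log(99 a)/b` and `w3 = (49/100 - sqrt(3)/6) k`; the three phases
#' contribute about 21%, 58% and 20% of the final dry weight for every
#' parameter combination.
#'
#' @param fits A data frame with numeric columns `k`, `a`, `b` (one row per
#'   fitted curve; other columns are carried through), or a single
#'   `filling_fit` object from [fit_logistic()].
#' @param completion Fraction of the final dry weight at which filling is
#'   considered complete (default 0.99); must be in (0.5, 1).
#' @return A tibble with the input identifier columns plus
#'   `k, b, t_mid, t1, t2, t3, w1, w2, w3, v_bar, t_active, v_max` and a
#'   logical `pre_pollination_inflexion` flag, set when `a <= 2 + sqrt(3)`
#'   so that the first inflexion falls at or before pollination (`t1 <= 0`).
#' @export
#' @examples
#' derive_parameters(data.frame(k = 1, a = 50, b = 0.2))
derive_parameters <- function(fits, completion = 0.99) {
  if (inherits(fits, "filling_fit")) {
    fits <- tibble::tibble(k = fits$k, a = fits$a, b = fits$b)
  }
  stopifnot(is.data.frame(fits))
  need <- setdiff(c("k", "a", "b"), names(fits))
  if (length(need)) {
    abort(paste0("`fits` lacks column(s): ", paste(need, collapse = ", ")))
  }
  if (completion <= 0.5 || completion >= 1) {
    abort("`completion` must lie in (0.5, 1).")
  }
  k <- fits$k; a <- fits$a; b <- fits$b
  check_logistic_params(k, a, b)
  s3 <- sqrt(3)
  flag <- a <= 2 + s3
  if (any(flag)) {
    warn("Some fits have a <= 2 + sqrt(3): first inflexion precedes pollination (t1 <= 0).")
  }
  out <- tibble::as_tibble(fits[setdiff(names(fits), c("k", "a", "b"))])
  dplyr::bind_cols(
    out,
    tibble::tibble(
      k = k,
      b = b,
      t_mid = log(a) / b,
      t1 = -log((2 + s3) / a) / b,
      t2 = -log((2 - s3) / a) / b,
      t3 = log(a * completion / (1 - completion)) / b,
      w1 = k / (3 + s3),
      w2 = (s3 / 3) * k,
      w3 = (completion - 0.5 - s3 / 6) * k,
      v_bar = k * b / 6,
      t_active = 6 / b,
      v_max = k * b / 4,
      pre_pollination_inflexion = flag
    )
  )
}
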