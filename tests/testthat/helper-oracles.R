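# Independent numerical oracles used to check closed-form results.

# Second derivative of the filling-rate curve by a five-point (4th-order)
# central difference, Richardson-extrapolated to 6th order; the step scales
# with 1/b so accuracy is invariant to the curve's time scale.
rate_second_deriv <- function(t, k, a, b, h) {
  v <- function(x) filling_rate(x, k, a, b)
  d2 <- function(hh) {
    (-v(t - 2 * hh) + 16 * v(t - hh) - 30 * v(t) + 16 * v(t + hh) -
       v(t + 2 * hh)) / (12 * hh^2)
  }
  (16 * d2(h / 2) - d2(h)) / 15
}

# Numeric inflexion times of the rate curve: sign-change roots of its second
# derivative on either side of the rate maximum log(a)/b.
numeric_inflexions <- function(k, a, b) {
  h <- 0.004 / b
  tm <- log(a) / b
  span <- 3 / b
  f <- function(t) rate_second_deriv(t, k, a, b, h)
  c(
    uniroot(f, c(tm - span, tm - 1e-9), tol = 1e-12)$root,
    uniroot(f, c(tm + 1e-9, tm + span), tol = 1e-12)$root
  )
}

# Numeric completion time: root of w(t) - completion * k.
numeric_t3 <- function(k, a, b, completion = 0.99) {
  f <- function(t) logistic_weight(t, k, a, b) - completion * k
  uniroot(f, c(log(a) / b, log(a) / b + 20 / b), tol = 1e-14,
          extendInt = "upX")$root
}

# Two-sided Fisher p by brute-force enumeration over all tables sharing the
# observed margins: sum hypergeometric probabilities <= the observed one.
fisher_enum_p <- function(ref_high, alt_high, ref_low, alt_low) {
  r1 <- ref_high + alt_high
  c1 <- ref_high + ref_low
  N <- r1 + ref_low + alt_low
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  pr <- dhyper(xs, c1, N - c1, r1)
  obs <- dhyper(ref_high, c1, N - c1, r1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# NB exact-test p by direct summation, written independently of the package
# implementation (linear-scale mass function, no normalization shortcut).
nb_enum_p <- function(y_high, y_low, dispersion = 0.04) {
  n <- y_high + y_low
  if (n == 0) return(1)
  size <- 1 / dispersion
  mass <- dnbinom(0:n, size = size, mu = n / 2) *
    dnbinom(n:0, size = size, mu = n / 2)
  mass <- mass / sum(mass)
  min(sum(mass[mass <= mass[y_high + 1] * (1 + 1e-10)]), 1)
}

dap_schedule <- c(10, 15, 20, 25, 30, 35, 40, 43, 46, 49, 52, 55, 58, 61)

# Long-format weight table for a set of generating parameters.
make_weight_table <- function(params, dap = dap_schedule, noise_sd = 0) {
  purrr::pmap_dfr(params, function(line_id, environment, k, a, b) {
    w <- logistic_weight(dap, k, a, b)
    if (noise_sd > 0) w <- pmax(w + rnorm(length(dap), 0, noise_sd), 0)
    tibble::tibble(line_id = line_id, environment = environment,
                   dap = dap, weight_g = w)
  })
}

# Balanced line x environment trait table with known variance components.
make_trait_table <- function(n_lines, n_env, sigma2_g, sigma2_resid,
                             env_effects = rnorm(n_env, 0, 1), mu = 10) {
  gval <- rnorm(n_lines, 0, sqrt(sigma2_g))
  tidyr::expand_grid(line = seq_len(n_lines), env = seq_len(n_env)) |>
    dplyr::mutate(
      line_id = sprintf("L%04d", line),
      environment = paste0("env", env),
      y = mu + gval[line] + env_effects[env] +
        rnorm(dplyr::n(), 0, sqrt(sigma2_resid))
    ) |>
    dplyr::select(line_id, environment, y)
}
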