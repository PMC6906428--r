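test_that("variance components respond correctly to degenerate structure", {
  # no genetic variance: every line identical within environment
  d <- tidyr::expand_grid(line_id = sprintf("L%02d", 1:30),
                          environment = c("e1", "e2", "e3")) |>
    dplyr::mutate(y = dplyr::case_match(environment, "e1" ~ 1, "e2" ~ 2, "e3" ~ 3))
  vc <- suppressWarnings(variance_components(d, "y"))
  expect_equal(vc$sigma2_g, 0)
  expect_equal(vc$sigma2_resid, 0)
  expect_gt(vc$sigma2_env, 0)

  # a constant environment shift changes only the environment component
  set.seed(2)
  base <- make_trait_table(80, 2, sigma2_g = 2, sigma2_resid = 1,
                           env_effects = c(0, 0))
  shifted <- dplyr::mutate(base, y = y + ifelse(environment == "env2", 7, 0))
  v1 <- suppressWarnings(variance_components(base, "y"))
  v2 <- suppressWarnings(variance_components(shifted, "y"))
  expect_equal(v2$sigma2_g, v1$sigma2_g, tolerance = 1e-10)
  expect_equal(v2$sigma2_resid, v1$sigma2_resid, tolerance = 1e-10)
  expect_gt(v2$sigma2_env, v1$sigma2_env)

  expect_error(variance_components(dplyr::filter(d, environment == "e1"), "y"),
               "single environment")
})

test_that("method-of-moments recovers generating variance components", {
  set.seed(3)
  ests <- t(vapply(1:10, function(i) {
    d <- make_trait_table(500, 3, sigma2_g = 3, sigma2_resid = 1)
    vc <- variance_components(d, "y")
    c(vc$sigma2_g, vc$sigma2_resid)
  }, numeric(2)))
  expect_equal(mean(ests[, 1]), 3, tolerance = 0.1)
  expect_equal(mean(ests[, 2]), 1, tolerance = 0.1)
})

test_that("heritability follows its defining ratio and stays in [0, 1]", {
  vc <- tibble::tibble(sigma2_g = 3, sigma2_resid = 3, n_env = 3)
  expect_equal(heritability(vc), 0.75)
  expect_equal(heritability(tibble::tibble(sigma2_g = 2, sigma2_resid = 0, n_env = 2)), 1)
  expect_warning(
    h <- heritability(tibble::tibble(sigma2_g = 0, sigma2_resid = 0, n_env = 2)),
    "undefined")
  expect_true(is.na(h))
  # monotone in the number of environments
  hs <- vapply(2:8, function(e) {
    heritability(tibble::tibble(sigma2_g = 1, sigma2_resid = 2, n_env = e))
  }, numeric(1))
  expect_true(all(diff(hs) > 0))
  expect_true(all(hs >= 0 & hs <= 1))
})

test_that("coefficient of variation is exact and scale-invariant", {
  expect_equal(cv_percent(rep(4, 10)), 0)
  expect_equal(cv_percent(c(1, 2, 3)), 50)
  x <- rlnorm(50)
  expect_equal(cv_percent(7.3 * x), cv_percent(x), tolerance = 1e-12)
  expect_error(cv_percent(c(-1, 1)), "mean is zero")
})

test_that("correlation matrix is symmetric PSD with exact special cases", {
  set.seed(4)
  fits <- tibble::tibble(k = runif(60, 10, 20), a = runif(60, 30, 120),
                         b = runif(60, 0.1, 0.2))
  p <- derive_parameters(fits)
  cm <- correlation_matrix(p, c("k", "b", "v_bar", "v_max", "t3"))
  self <- dplyr::filter(cm, trait_x == trait_y)
  expect_true(all(self$r == 1) && all(self$p == 0))
  # v_max and v_bar are both proportional to k*b
  expect_equal(dplyr::filter(cm, trait_x == "v_bar", trait_y == "v_max")$r, 1,
               tolerance = 1e-12)
  # assemble the full matrix; check symmetry and positive semidefiniteness
  traits <- c("k", "b", "v_bar", "v_max", "t3")
  m <- matrix(NA_real_, 5, 5, dimnames = list(traits, traits))
  for (i in seq_len(nrow(cm))) {
    m[cm$trait_x[i], cm$trait_y[i]] <- cm$r[i]
    m[cm$trait_y[i], cm$trait_x[i]] <- cm$r[i]
  }
  expect_true(all(eigen(m, symmetric = TRUE, only.values = TRUE)$values > -1e-8))
  # zero-variance column flagged
  p$flat <- 1
  expect_warning(cm2 <- correlation_matrix(p, c("k", "flat")), "Zero-variance")
  expect_true(is.na(dplyr::filter(cm2, trait_x == "k", trait_y == "flat")$r))
})

test_that("t3 and k are positively correlated when generated with shared QTL", {
  study <- simulate_study(sim_config(), seed = 101)
  fits <- suppressWarnings(fit_filling(study$weights))
  p <- derive_parameters(fits)
  cm <- correlation_matrix(p, c("k", "t3"))
  r <- dplyr::filter(cm, trait_x == "k", trait_y == "t3")$r
  expect_gt(r, 0)
})

test_that("BLUP shrinks line means toward the grand mean, never past it", {
  set.seed(6)
  d <- make_trait_table(100, 3, sigma2_g = 1, sigma2_resid = 2)
  bl <- blup(d, "y")
  mu <- mean(d$y)  # balanced design: grand mean survives environment centring
  expect_true(all(abs(bl$blup - mu) <= abs(bl$mean - mu) + 1e-12))
  # zero genetic variance: every BLUP collapses to the grand mean
  d0 <- tidyr::expand_grid(line_id = sprintf("L%02d", 1:40),
                           environment = c("e1", "e2")) |>
    dplyr::mutate(y = ifelse(environment == "e1", 0, 1))
  bl0 <- suppressWarnings(blup(d0, "y"))
  expect_equal(bl0$blup, rep(0.5, 40), tolerance = 1e-10)
})

test_that("BLUP outranks raw means in accuracy at low heritability", {
  set.seed(7)
  gain <- vapply(1:10, function(i) {
    g <- rnorm(200, 0, sqrt(0.3))
    d <- tidyr::expand_grid(line = 1:200, env = 1:3) |>
      dplyr::mutate(line_id = sprintf("L%03d", line), environment = paste0("e", env),
                    y = g[line] + rnorm(dplyr::n(), 0, sqrt(2.1)))
    bl <- suppressWarnings(blup(d, "y"))
    truth <- g[as.integer(sub("L", "", bl$line_id))]
    cor(bl$blup, truth) - cor(bl$mean, truth)
  }, numeric(1))
  # balanced design: BLUP is a monotone shrinkage of the mean, so accuracy
  # is equal up to numerical noise; it must never be worse
  expect_true(all(gain > -1e-10))
})

test_that("Welch pool comparison reproduces hand-computed results", {
  expect_equal(pool_t_test(c(1, 2, 3), c(1, 2, 3))$p, 1, tolerance = 1e-12)
  tt <- pool_t_test(1:5, 3:7)
  expect_equal(tt$t, -2, tolerance = 1e-12)
  expect_equal(tt$df, 8, tolerance = 1e-12)
  expect_equal(tt$p, 2 * pt(-2, 8), tolerance = 1e-12)
  set.seed(8)
  sep <- pool_t_test(rnorm(13, 0, 1e-4), 1 + rnorm(13, 0, 1e-4))
  expect_lt(sep$p, 1e-10)
  const <- pool_t_test(rep(2, 5), rep(2, 6))
  expect_equal(const$t, 0)
  expect_equal(const$p, 1)
})

test_that("trait summary aggregates mean, CV, components and heritability", {
  set.seed(9)
  d <- make_trait_table(120, 3, sigma2_g = 2, sigma2_resid = 1)
  names(d)[3] <- "k"
  ts <- trait_summary(d, "k")
  expect_equal(ts$h2, heritability(variance_components(d, "k")))
  expect_gt(ts$h2, 0.5)
  expect_equal(ts$mean, mean(d$k))
})

test_that("closed-form balanced mean squares match the linear-model route", {
  set.seed(10)
  d <- make_trait_table(40, 3, sigma2_g = 1.5, sigma2_resid = 0.8)
  vc <- variance_components(d, "y")
  fit <- lm(y ~ factor(environment) + factor(line_id), data = d)
  tab <- anova(fit)
  e <- 3
  expect_equal(vc$sigma2_resid, tab["Residuals", "Mean Sq"], tolerance = 1e-10)
  expect_equal(vc$sigma2_g,
               (tab["factor(line_id)", "Mean Sq"] - tab["Residuals", "Mean Sq"]) / e,
               tolerance = 1e-10)
  # a missing cell falls back to the model route without error
  d2 <- d[-5, ]
  vc2 <- variance_components(d2, "y")
  expect_gt(vc2$sigma2_g, 0)
})
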