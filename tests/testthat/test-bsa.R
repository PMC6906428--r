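test_that("pool selection takes clean extremes with deterministic ties", {
  set.seed(41)
  v <- setNames(sample(seq(0.40, 0.50, length.out = 208)), sprintf("L%03d", 1:208))
  pools <- select_pools(v, n_per_pool = 13)
  expect_equal(table(pools$pool)[["high"]], 13)
  expect_equal(table(pools$pool)[["low"]], 13)
  expect_lt(max(pools$value[pools$pool == "low"]),
            min(pools$value[pools$pool == "high"]))
  # boundary ties break by line id, reproducibly
  vt <- setNames(c(rep(1, 5), rep(2, 20), rep(3, 5)), sprintf("L%02d", 1:30))
  p1 <- select_pools(vt, n_per_pool = 10)
  p2 <- select_pools(vt[sample(30)], n_per_pool = 10)
  expect_equal(dplyr::arrange(p1, line_id), dplyr::arrange(p2, line_id))
  expect_error(select_pools(setNames(rep(1, 30), paste0("L", 1:30)), 10),
               "equal")
  expect_error(select_pools(v, 120), "eligible")
})

test_that("the filling-midpoint filter restricts pool eligibility", {
  v <- setNames(seq_len(60) / 100, sprintf("L%02d", 1:60))
  tm <- setNames(c(rep(30, 40), rep(45, 20)), names(v))
  pools <- select_pools(v, n_per_pool = 5, t_mid = tm, t_mid_tolerance = 3)
  expect_true(all(tm[pools$line_id] == 30))
  expect_error(select_pools(v, n_per_pool = 25, t_mid = tm, t_mid_tolerance = 3),
               "eligible")
})

test_that("SNP indices and delta follow their definitions", {
  sites <- tibble::tibble(ref_high = c(0, 10, 0), alt_high = c(20, 10, 0),
                          ref_low = c(10, 10, 5), alt_low = c(10, 10, 5))
  si <- snp_index(sites)
  expect_equal(si$index_high[1:2], c(1, 0.5))
  expect_equal(si$delta_index[1:2], c(0.5, 0))
  expect_false(si$testable[3])
  expect_true(is.na(si$index_high[3]))
})

test_that("delta SNP index is centred at zero under the null", {
  set.seed(43)
  n <- 10000
  alt_h <- rbinom(n, 40, 0.5); alt_l <- rbinom(n, 40, 0.5)
  si <- snp_index(tibble::tibble(ref_high = 40 - alt_h, alt_high = alt_h,
                                 ref_low = 40 - alt_l, alt_low = alt_l))
  expect_lt(abs(mean(si$delta_index)), 0.01)
})

test_that("G statistic matches the hand-worked table and chi-square asymptotics", {
  ind <- g_statistic(tibble::tibble(ref_high = 20, alt_high = 10,
                                    ref_low = 20, alt_low = 10))
  expect_equal(ind$g_stat, 0, tolerance = 1e-12)
  worked <- g_statistic(tibble::tibble(ref_high = 20, alt_high = 0,
                                       ref_low = 10, alt_low = 10))
  expect_equal(worked$g_stat,
               2 * (20 * log(20 / 15) + 10 * log(10 / 15) + 10 * log(10 / 5)),
               tolerance = 1e-12)
  expect_equal(worked$g_stat, 17.26, tolerance = 1e-3)
  # zero margin: G = 0 by convention, flagged
  degen <- g_statistic(tibble::tibble(ref_high = 0, alt_high = 0,
                                      ref_low = 10, alt_low = 10))
  expect_equal(degen$g_stat, 0)
  expect_true(degen$g_degenerate)
  # G tracks Pearson chi-square when expected counts are large
  set.seed(44)
  tabs <- tibble::tibble(
    ref_high = rbinom(200, 200, 0.5), alt_high = rbinom(200, 200, 0.5),
    ref_low = rbinom(200, 200, 0.5), alt_low = rbinom(200, 200, 0.5)
  )
  g <- g_statistic(tabs)$g_stat
  x2 <- purrr::pmap_dbl(tabs, function(ref_high, alt_high, ref_low, alt_low) {
    suppressWarnings(chisq.test(matrix(c(ref_high, alt_high, ref_low, alt_low),
                                       2, byrow = TRUE), correct = FALSE)$statistic)
  })
  big <- x2 > 1  # avoid ratio blow-ups at ~0
  expect_lt(max(abs(g[big] - x2[big]) / x2[big]), 0.10)
})

test_that("Fisher p-values agree exactly with hypergeometric enumeration", {
  bal <- fisher_per_snp(tibble::tibble(ref_high = 10, alt_high = 10,
                                       ref_low = 10, alt_low = 10))
  expect_equal(bal$fisher_p, 1, tolerance = 1e-12)
  extreme <- fisher_per_snp(tibble::tibble(ref_high = 20, alt_high = 0,
                                           ref_low = 0, alt_low = 20))
  expect_equal(extreme$fisher_p, 2 / choose(40, 20), tolerance = 1e-12)
  set.seed(45)
  tabs <- tibble::tibble(
    ref_high = rpois(100, 15), alt_high = rpois(100, 8),
    ref_low = rpois(100, 10), alt_low = rpois(100, 12)
  )
  got <- fisher_per_snp(tabs)$fisher_p
  want <- purrr::pmap_dbl(tabs, fisher_enum_p)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("G and Fisher order sites concordantly on deep tables", {
  set.seed(46)
  f <- runif(300, 0.2, 0.8)
  shift <- runif(300, -0.15, 0.15)
  tabs <- tibble::tibble(
    alt_high = rbinom(300, 400, pmin(pmax(f + shift, 0.05), 0.95)),
    alt_low = rbinom(300, 400, f)
  ) |>
    dplyr::mutate(ref_high = 400 - alt_high, ref_low = 400 - alt_low)
  st <- bsa_site_stats(tabs)
  rho <- cor(st$g_stat, -log10(st$fisher_p), method = "spearman")
  expect_gt(rho, 0.99)
})

test_that("FDR adjustment reproduces the step-up arithmetic", {
  expect_equal(fdr_adjust(0.037), 0.037)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(47)
  p <- runif(200)^2
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  qh <- fdr_adjust(p, method = "hochberg")
  expect_true(all(qh >= q - 1e-12))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})
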