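test_that("TMM factors are 1 for pure depth differences and geometric-mean 1", {
  set.seed(51)
  base <- rnbinom(800, mu = 100, size = 10)
  ident <- cbind(s1 = base, s2 = base)
  f <- tmm_factors(ident)
  expect_equal(f$tmm_factor, c(1, 1), tolerance = 1e-12)
  doubled <- cbind(s1 = base, s2 = 2L * base)
  f2 <- tmm_factors(doubled)
  expect_equal(f2$tmm_factor, c(1, 1), tolerance = 1e-9)
  # geometric mean 1 and invariance to a global scalar
  three <- cbind(a = rnbinom(800, mu = 80, size = 10) + 1L,
                 b = rnbinom(800, mu = 120, size = 10) + 1L,
                 c = rnbinom(800, mu = 100, size = 10) + 1L)
  f3 <- tmm_factors(three)
  expect_equal(exp(mean(log(f3$tmm_factor))), 1, tolerance = 1e-12)
  f3s <- tmm_factors(3L * three)
  expect_equal(f3s$tmm_factor, f3$tmm_factor, tolerance = 1e-9)
})

test_that("composition bias pulls the amplified sample's factor below 1", {
  set.seed(52)
  a <- rnbinom(2000, mu = 200, size = 20) + 1L
  b <- a
  amp <- sample(2000, 100)
  b[amp] <- 16L * b[amp]
  f <- tmm_factors(cbind(a = a, b = b))
  fb <- f$tmm_factor[f$sample == "b"] / f$tmm_factor[f$sample == "a"]
  expect_lt(fb, 1)
  # brute-force recomputation of the trimmed weighted mean for b vs a
  na_ <- sum(a); nb <- sum(b)
  m <- log2((b / nb) / (a / na_))
  aval <- 0.5 * log2((b / nb) * (a / na_))
  w <- (nb - b) / (nb * b) + (na_ - a) / (na_ * a)
  n <- length(m)
  lo_m <- floor(n * 0.30) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * 0.05) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m & rank(aval) >= lo_a & rank(aval) <= hi_a
  f_oracle <- 2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
  expect_equal(fb, f_oracle, tolerance = 1e-10)
})

test_that("TMM factors agree with the established reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(53)
  y <- cbind(a = rnbinom(3000, mu = 150, size = 8),
             b = rnbinom(3000, mu = 150, size = 8),
             c = rnbinom(3000, mu = 150, size = 8))
  y[1:150, "b"] <- 12L * y[1:150, "b"]
  ours <- tmm_factors(y)$tmm_factor
  ref <- edgeR::calcNormFactors(y, method = "TMM")
  expect_equal(ours, unname(ref), tolerance = 1e-6)
})

test_that("exact-test p-values match the split-enumeration oracle to 1e-10", {
  set.seed(54)
  yh <- c(rnbinom(46, mu = 60, size = 25), 1000L, 0L, 0L, 30L)
  yl <- c(rnbinom(46, mu = 60, size = 25), 0L, 1000L, 0L, 30L)
  res <- nb_exact_test(yh, yl, lib_high = 1, lib_low = 1)
  want <- purrr::map2_dbl(yh, yl, nb_enum_p)
  expect_equal(res$p, want, tolerance = 1e-10)
  # symmetric split: maximal p; extreme split: vanishing p
  expect_gte(res$p[50], 0.99)
  expect_lt(res$p[47], 1e-6)
  # zero-count gene flagged untested with p = 1 and log2FC = 0
  expect_false(res$tested[49])
  expect_equal(res$p[49], 1)
  expect_equal(res$log2fc[49], 0)
})

test_that("swapping bulk labels flips the fold change and keeps p", {
  set.seed(55)
  yh <- rnbinom(200, mu = 80, size = 25)
  yl <- rnbinom(200, mu = 80, size = 25)
  fwd <- nb_exact_test(yh, yl, lib_high = 1e6, lib_low = 1e6)
  rev_ <- nb_exact_test(yl, yh, lib_high = 1e6, lib_low = 1e6)
  expect_equal(fwd$p, rev_$p, tolerance = 1e-12)
  expect_equal(fwd$log2fc, -rev_$log2fc, tolerance = 1e-12)
})

test_that("exact test ranks genes like the reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(56)
  yh <- rnbinom(400, mu = 120, size = 25)
  yl <- as.integer(round(rnbinom(400, mu = 120, size = 25) *
                           rep(c(1, 4), each = 200)))
  ours <- nb_exact_test(yh, yl, lib_high = sum(yh), lib_low = sum(yl))
  dge <- edgeR::DGEList(counts = cbind(h = yh, l = yl), group = c("h", "l"))
  dge$samples$norm.factors <- c(1, 1)
  ref <- edgeR::exactTest(dge, pair = c("l", "h"), dispersion = 0.04)$table
  keep <- ours$p > 0 & ref$PValue > 0
  expect_gt(cor(log(ours$p[keep]), log(ref$PValue[keep]), method = "spearman"),
            0.99)
})

test_that("the DEG rule applies Bonferroni and the fold-change gate", {
  tests <- tibble::tibble(
    gene = paste0("g", 1:10),
    p = c(0.04, 0.001 / 10, rep(0.5, 8)),
    log2fc = c(3, 1.5, rep(0, 8)),
    tested = TRUE
  )
  out <- deg_filter(tests)
  # raw 0.04 over 10 genes -> adjusted 0.4: not a DEG
  expect_equal(out$padj[1], 0.4)
  expect_false(out$deg[1])
  # significant adjusted p but |log2FC| <= 2: not a DEG
  expect_lt(out$padj[2], 0.05)
  expect_false(out$deg[2])
  expect_equal(sum(out$deg), 0)
})

test_that("planted DE genes are recovered with no false positives", {
  set.seed(57)
  cfg <- sim_config()
  expr <- simulate_expression(cfg, seed = 57)
  tmm <- tmm_factors(expr$counts)
  res <- nb_exact_test(expr$counts[, "high"], expr$counts[, "low"],
                       lib_high = tmm$effective_lib_size[1],
                       lib_low = tmm$effective_lib_size[2])
  out <- deg_filter(res)
  truth <- expr$truth
  found <- out$gene[out$deg]
  expect_gte(length(intersect(found, truth$gene[truth$is_de])), 27)
  expect_equal(length(setdiff(found, truth$gene[truth$is_de])), 0)
})
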