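#' TMM normalization factors
#'
#' Trimmed mean of M-values composition factors for a gene x sample count
#' table.  The reference is the sample whose upper-quartile/library-size
#' ratio is closest to the mean of those ratios.  For each sample, gene-wise
#' log2 expression ratios against the reference (M values) and average log2
#' abundances (A values) are computed over genes expressed in both samples,
#' doubly trimmed (`trim_m` of the M distribution and `trim_a` of the A
#' distribution from each tail), and combined as a weighted mean with inverse
#' asymptotic-binomial-variance weights; the factor is `2^` that mean.
#' Factors are rescaled to have geometric mean 1.
#'
#' @param counts Non-negative integer matrix or data frame, genes x samples.
#' @param trim_m Two-sided trim fraction on M values (default 0.30).
#' @param trim_a Two-sided trim fraction on A values (default 0.05).
#' @param lib_size Optional per-sample library sizes; default column sums.
#' @return Tibble with `sample`, `lib_size`, `tmm_factor` and
#'   `effective_lib_size = lib_size * tmm_factor`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05, lib_size = NULL) {
  y <- as.matrix(counts)
  if (any(y < 0)) abort("Counts must be non-negative.")
  if (ncol(y) < 2) abort("TMM needs at least 2 samples.")
  if (is.null(lib_size)) lib_size <- colSums(y)
  if (any(lib_size <= 0)) abort("Library sizes must be positive.")

  f75 <- vapply(seq_len(ncol(y)), function(j) {
    quantile(y[, j], 0.75, names = FALSE) / lib_size[j]
  }, numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))

  logf <- vapply(seq_len(ncol(y)), function(j) {
    if (j == ref) return(0)
    single_tmm(y[, j], y[, ref], lib_size[j], lib_size[ref],
               trim_m = trim_m, trim_a = trim_a)
  }, numeric(1))
  f <- 2^logf
  f <- f / exp(mean(log(f)))
  tibble::tibble(
    sample = colnames(y) %||% paste0("sample", seq_len(ncol(y))),
    lib_size = unname(lib_size),
    tmm_factor = unname(f),
    effective_lib_size = unname(lib_size * f)
  )
}

single_tmm <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) abort("Sample shares no expressed genes with the TMM reference.")
  o <- obs[keep]; r <- ref[keep]
  m <- log2((o / n_obs) / (r / n_ref))
  a <- 0.5 * log2((o / n_obs) * (r / n_ref))
  w <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)
  fin <- is.finite(m) & is.finite(a) & is.finite(w)
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  n <- length(m)
  if (!n) return(0)
  if (max(abs(m)) < 1e-6) return(0)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) return(0)
  sum(m[keep2] / w[keep2]) / sum(1 / w[keep2])
}

#' Negative-binomial exact test between two bulks
#'
#' Genewise exact test for a difference between two pooled RNA samples
#' (one library per bulk), with a fixed negative-binomial dispersion
#' `BCV^2` (default `0.2^2 = 0.04`).  Counts are first rescaled to a common
#' effective library size — the geometric mean of the TMM-adjusted sizes —
#' and rounded to the nearest integer.  Conditional on each gene's rescaled
#' total `n`, the probability of every split `(j, n - j)` between bulks is
#' evaluated under equal means (`mu = n/2` per bulk); the two-sided p-value
#' sums the probabilities of all splits no more probable than the observed
#' one (capped at 1).  The log2 fold change (high vs low) uses a
#' `prior_count` offset per bulk to avoid infinities.
#'
#' @param counts_high,counts_low Integer count vectors (one per gene).
#' @param lib_high,lib_low Effective library sizes of the two bulks (library
#'   size times TMM factor); default the column sums.
#' @param dispersion Negative-binomial dispersion (default 0.04).
#' @param prior_count Offset added to each bulk's normalized count for the
#'   fold change (default 0.125).
#' @param gene Optional gene ids.
#' @return Tibble with `gene`, `p`, `log2fc`, `logcpm` and logical `tested`
#'   (`FALSE`, with `p = 1` and `log2fc = 0`, for genes with zero total).
#' @export
nb_exact_test <- function(counts_high, counts_low,
                          lib_high = sum(counts_high),
                          lib_low = sum(counts_low),
                          dispersion = 0.04, prior_count = 0.125,
                          gene = NULL) {
  stopifnot(length(counts_high) == length(counts_low))
  if (any(c(counts_high, counts_low) < 0)) abort("Counts must be non-negative.")
  if (dispersion <= 0) abort("`dispersion` must be positive.")
  if (is.null(gene)) {
    gene <- names(counts_high) %||% paste0("gene", seq_along(counts_high))
  }
  common <- sqrt(lib_high * lib_low)
  yh <- round(counts_high * common / lib_high)
  yl <- round(counts_low * common / lib_low)
  size <- 1 / dispersion

  res <- purrr::map2_dfr(yh, yl, function(h, l) {
    n <- h + l
    if (n == 0) {
      return(tibble::tibble(p = 1, tested = FALSE))
    }
    j <- 0:n
    logpr <- dnbinom(j, size = size, mu = n / 2, log = TRUE) +
      dnbinom(n - j, size = size, mu = n / 2, log = TRUE)
    pr <- exp(logpr - max(logpr))
    pr <- pr / sum(pr)
    obs <- pr[h + 1]
    tibble::tibble(p = min(sum(pr[pr <= obs * (1 + 1e-10)]), 1), tested = TRUE)
  })

  tibble::tibble(
    gene = gene,
    p = res$p,
    log2fc = log2((yh + prior_count) / (yl + prior_count)),
    logcpm = log2(((yh + yl) / 2 + prior_count) / common * 1e6),
    tested = res$tested
  ) |>
    dplyr::mutate(log2fc = ifelse(res$tested, .data$log2fc, 0))
}

#' Call differentially expressed genes
#'
#' Bonferroni-adjusts the exact-test p-values over the tested genes (p times
#' the number of tested genes, capped at 1) and flags a gene as a DEG when
#' the adjusted p-value is below `alpha` AND the absolute log2 fold change
#' exceeds `min_abs_lfc`.
#'
#' @param tests Tibble from [nb_exact_test()] (columns `gene`, `p`, `log2fc`,
#'   `tested`).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param min_abs_lfc Fold-change threshold on `|log2fc|` (default 2).
#' @return Input tibble with `padj`, logical `deg` and `direction`
#'   (`"up"` = higher in the high pool, `"down"`, or `NA`); the up/down DEG
#'   counts are attached as attribute `"deg_counts"`.
#' @export
deg_filter <- function(tests, alpha = 0.05, min_abs_lfc = 2) {
  stopifnot(all(c("gene", "p", "log2fc", "tested") %in% names(tests)))
  m <- sum(tests$tested)
  out <- tests |>
    dplyr::mutate(
      padj = ifelse(.data$tested, pmin(.data$p * m, 1), 1),
      deg = .data$padj < alpha & abs(.data$log2fc) > min_abs_lfc,
      direction = dplyr::case_when(
        .data$deg & .data$log2fc > 0 ~ "up",
        .data$deg & .data$log2fc < 0 ~ "down",
        TRUE ~ NA_character_
      )
    )
  attr(out, "deg_counts") <- c(
    up = sum(out$direction == "up", na.rm = TRUE),
    down = sum(out$direction == "down", na.rm = TRUE)
  )
  out
}
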