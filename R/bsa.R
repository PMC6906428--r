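#' Select extreme phenotype pools
#'
#' Ranks lines by a (typically BLUP) trait value and takes the top and bottom
#' `n_per_pool` lines as the high and low bulks.  When a vector of filling
#' midpoints (`t_mid`, the time at which the maximum filling rate is reached)
#' is supplied, lines are first restricted to those whose `t_mid` lies within
#' `t_mid_tolerance` of the population median, so that the two pools reach
#' their maximum rate at a similar time.  Ties at a pool boundary are broken
#' deterministically by line id.
#'
#' @param values Data frame with `line_id` and the ranking column named in
#'   `trait` (default `"blup"`), or a numeric vector named by line id.
#' @param n_per_pool Lines per pool (default 13).
#' @param trait Ranking column when `values` is a data frame.
#' @param t_mid Optional numeric vector of filling midpoints, named by line
#'   id or aligned with `values`.
#' @param t_mid_tolerance Half-width (DAP) of the eligibility band around the
#'   median `t_mid`; required when `t_mid` is supplied.
#' @return Tibble with `line_id`, `value` and `pool` (`"high"` / `"low"`),
#'   `2 * n_per_pool` rows.
#' @export
select_pools <- function(values, n_per_pool = 13, trait = "blup",
                         t_mid = NULL, t_mid_tolerance = NULL) {
  if (is.data.frame(values)) {
    stopifnot("line_id" %in% names(values), trait %in% names(values))
    d <- tibble::tibble(line_id = as.character(values$line_id),
                        value = values[[trait]])
  } else {
    if (is.null(names(values))) abort("A numeric `values` vector must be named by line id.")
    d <- tibble::tibble(line_id = names(values), value = as.numeric(values))
  }
  d <- d[!is.na(d$value), ]
  if (!is.null(t_mid)) {
    if (is.null(t_mid_tolerance)) abort("Supply `t_mid_tolerance` with `t_mid`.")
    tm <- if (!is.null(names(t_mid))) t_mid[d$line_id] else t_mid
    ok <- !is.na(tm) & abs(tm - median(tm, na.rm = TRUE)) <= t_mid_tolerance
    d <- d[ok, ]
  }
  if (nrow(d) < 2 * n_per_pool) {
    abort(sprintf("Only %d eligible lines; need %d for two pools of %d.",
                  nrow(d), 2 * n_per_pool, n_per_pool))
  }
  if (sd(d$value) == 0) abort("All trait values are equal; no contrast to pool on.")
  d <- dplyr::arrange(d, .data$value, .data$line_id)
  low <- d[seq_len(n_per_pool), ]
  high <- d[seq(nrow(d) - n_per_pool + 1, nrow(d)), ]
  dplyr::bind_rows(
    dplyr::mutate(high, pool = "high"),
    dplyr::mutate(low, pool = "low")
  )
}

validate_sites <- function(sites) {
  stopifnot(is.data.frame(sites))
  need <- setdiff(c("ref_high", "alt_high", "ref_low", "alt_low"), names(sites))
  if (length(need)) {
    abort(paste0("Bulk site table lacks column(s): ", paste(need, collapse = ", ")))
  }
  cnt <- as.matrix(sites[c("ref_high", "alt_high", "ref_low", "alt_low")])
  if (any(cnt < 0, na.rm = TRUE)) abort("Allele depths must be non-negative.")
  tibble::as_tibble(sites)
}

#' SNP index per bulk and the delta SNP index
#'
#' The SNP index of a bulk is the alternate-allele read fraction
#' `alt / (ref + alt)`; the delta SNP index is `index_high - index_low`,
#' bounded in `[-1, 1]`.  Sites with zero depth in either bulk are flagged
#' untestable (`NA` indices).
#'
#' @param sites Data frame with columns `ref_high`, `alt_high`, `ref_low`,
#'   `alt_low` (other columns carried through).
#' @return The input tibble with `index_high`, `index_low`, `delta_index` and
#'   logical `testable` appended.
#' @export
snp_index <- function(sites) {
  sites <- validate_sites(sites)
  nh <- sites$ref_high + sites$alt_high
  nl <- sites$ref_low + sites$alt_low
  testable <- nh > 0 & nl > 0
  dplyr::mutate(
    sites,
    index_high = ifelse(nh > 0, .data$alt_high / nh, NA_real_),
    index_low = ifelse(nl > 0, .data$alt_low / nl, NA_real_),
    delta_index = .data$index_high - .data$index_low,
    testable = testable
  )
}

#' G statistic per SNP site
#'
#' Likelihood-ratio statistic on the 2x2 bulk-by-allele count table:
#' `G = 2 * sum(n * log(n / e))` over the four cells, with expected counts
#' `e = row_total * col_total / N` and the convention `0 * log(0/e) = 0`.
#' Tables with a zero row or column margin return `G = 0` and are flagged.
#'
#' @inheritParams snp_index
#' @return Input tibble with `g_stat` and logical `g_degenerate` appended.
#' @export
g_statistic <- function(sites) {
  sites <- validate_sites(sites)
  g <- purrr::pmap_dbl(
    sites[c("ref_high", "alt_high", "ref_low", "alt_low")],
    function(ref_high, alt_high, ref_low, alt_low) {
      obs <- matrix(c(ref_high, alt_high, ref_low, alt_low), 2, byrow = TRUE)
      if (any(rowSums(obs) == 0) || any(colSums(obs) == 0)) return(0)
      e <- outer(rowSums(obs), colSums(obs)) / sum(obs)
      terms <- ifelse(obs == 0, 0, obs * log(obs / e))
      2 * sum(terms)
    }
  )
  degenerate <- with(sites, ref_high + alt_high == 0 | ref_low + alt_low == 0 |
                       ref_high + ref_low == 0 | alt_high + alt_low == 0)
  dplyr::mutate(sites, g_stat = g, g_degenerate = degenerate)
}

#' Fisher's exact test per SNP site
#'
#' Two-sided exact test of allele-count independence between the two bulks:
#' the p-value sums the hypergeometric probabilities of all tables with the
#' observed margins whose probability does not exceed the observed table's.
#' Degenerate margins give `p = 1`.
#'
#' @inheritParams snp_index
#' @return Input tibble with `fisher_p` appended.
#' @export
fisher_per_snp <- function(sites) {
  sites <- validate_sites(sites)
  p <- purrr::pmap_dbl(
    sites[c("ref_high", "alt_high", "ref_low", "alt_low")],
    function(ref_high, alt_high, ref_low, alt_low) {
      tab <- matrix(c(ref_high, alt_high, ref_low, alt_low), 2, byrow = TRUE)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
      fisher.test(tab)$p.value
    }
  )
  dplyr::mutate(sites, fisher_p = p)
}

#' False-discovery-rate adjustment of per-site p-values
#'
#' Benjamini-Hochberg step-up by default (monotone q-values), with the
#' Hochberg step-up family-wise procedure available as an alternative.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"hochberg"`.
#' @return Numeric vector of adjusted p-values (q-values).
#' @export
fdr_adjust <- function(p, method = c("BH", "hochberg")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = method)
}

#' Per-site bulked-segregant statistics
#'
#' Convenience wrapper computing, for every SNP site, the two bulk SNP
#' indices and their difference, the G statistic, the two-sided Fisher exact
#' p-value, its FDR adjustment and the significance call at `alpha`.
#'
#' @inheritParams snp_index
#' @param alpha FDR significance threshold (default 0.05).
#' @param method Adjustment method for [fdr_adjust()].
#' @return Tibble with all per-site statistics and logical `significant`.
#' @export
bsa_site_stats <- function(sites, alpha = 0.05, method = c("BH", "hochberg")) {
  sites |>
    snp_index() |>
    g_statistic() |>
    fisher_per_snp() |>
    dplyr::mutate(
      q = fdr_adjust(.data$fisher_p, method = method),
      significant = .data$q < alpha
    )
}
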