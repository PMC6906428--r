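#' Effective number of markers and genome-wide LOD threshold
#'
#' Li-Ji correction for multiple testing over correlated markers: the
#' eigenvalues `lambda_i` of the marker-marker correlation matrix are mapped
#' through `f(lambda) = I(lambda >= 1) + (lambda - floor(lambda))` and summed
#' to give the effective number of independent tests `Meff`; the genome-wide
#' significance threshold on the LOD scale is `-log10(alpha / Meff)`.
#'
#' @param geno Lines x markers matrix coded `"A"`/`"B"`/`NA` (or numeric);
#'   constant or all-missing markers are dropped before the decomposition.
#' @param alpha Genome-wide type-I rate (default 0.05).
#' @param chr Optional per-marker chromosome vector; when supplied, Meff is
#'   computed per chromosome and summed (by default the decomposition is
#'   genome-wide).
#' @return One-row tibble: `meff`, `n_markers`, `alpha`, `threshold`.
#' @export
#' @examples
#' # 35 effective markers at alpha 0.05 give a LOD threshold of 2.8
#' -log10(0.05 / 35)
meff_threshold <- function(geno, alpha = 0.05, chr = NULL) {
  s <- if (is.character(geno)) geno_to_score(geno) else as.matrix(geno)
  keep <- apply(s, 2, function(x) sum(!is.na(x)) >= 2 && sd(x, na.rm = TRUE) > 0)
  if (sum(keep) < 2) abort("Need at least 2 variable markers for Meff.")
  s <- s[, keep, drop = FALSE]
  groups <- if (is.null(chr)) rep(1L, ncol(s)) else chr[keep]
  meff <- sum(vapply(split(seq_len(ncol(s)), groups), function(idx) {
    if (length(idx) == 1) return(1)
    cc <- suppressWarnings(cor(s[, idx], use = "pairwise.complete.obs"))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    lam <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
    lam <- pmax(lam, 0)
    sum(as.numeric(lam >= 1) + (lam - floor(lam)))
  }, numeric(1)))
  tibble::tibble(
    meff = meff, n_markers = ncol(s), alpha = alpha,
    threshold = -log10(alpha / meff)
  )
}

# Expected +/-1 genotype score at arbitrary cM positions, from flanking bins,
# with RIL-by-selfing transition probabilities on the observed scale.
expected_scores <- function(s, map, positions_cm, chr_markers_cm) {
  # s: lines x markers (+/-1, NA already filled) for ONE chromosome, ordered
  p <- chr_markers_cm
  n <- nrow(s)
  out <- matrix(NA_real_, n, length(positions_cm))
  for (j in seq_along(positions_cm)) {
    pos <- positions_cm[j]
    iL <- findInterval(pos, p)
    iR <- iL + 1
    if (iL == 0) {                       # before first marker
      R <- ril_observed(kosambi_r(p[1] - pos))
      out[, j] <- s[, 1] * (1 - 2 * R)
    } else if (iR > length(p)) {         # after last marker
      R <- ril_observed(kosambi_r(pos - p[length(p)]))
      out[, j] <- s[, length(p)] * (1 - 2 * R)
    } else {
      RL <- ril_observed(kosambi_r(pos - p[iL]))
      RR <- ril_observed(kosambi_r(p[iR] - pos))
      sL <- s[, iL]; sR <- s[, iR]
      same <- sL == sR
      p_same <- (1 - RL) * (1 - RR) / ((1 - RL) * (1 - RR) + RL * RR)
      p_left <- (1 - RL) * RR / ((1 - RL) * RR + RL * (1 - RR))
      out[, j] <- ifelse(same, sL * (2 * p_same - 1), sL * (2 * p_left - 1))
    }
  }
  out
}

fill_scores <- function(s) {
  # impute missing marker scores from the column mean (cofactor use only)
  for (j in seq_len(ncol(s))) {
    nas <- is.na(s[, j])
    if (any(nas)) s[nas, j] <- mean(s[, j], na.rm = TRUE)
  }
  s
}

# Forward stepwise marker-cofactor selection: add the marker with the
# smallest partial-F p-value while its selection-adjusted p-value
# (Bonferroni over the candidates screened at that step) is below entry_p,
# up to max_cofactors.  Adjusting for the best-of-m selection keeps the
# background model from soaking up chance variance under the null.
select_cofactors <- function(s, y, entry_p = 0.01, max_cofactors = 5) {
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n))
  chosen <- integer(0)
  repeat {
    if (length(chosen) >= max_cofactors) break
    qr_X <- qr(X)
    ry <- qr.resid(qr_X, y)
    cand <- setdiff(seq_len(ncol(s)), chosen)
    rM <- qr.resid(qr_X, s[, cand, drop = FALSE])
    ss <- colSums(rM^2)
    ok <- ss > 1e-10
    if (!any(ok)) break
    rho2 <- rep(0, length(cand))
    rho2[ok] <- (as.numeric(crossprod(rM[, ok, drop = FALSE], ry)))^2 /
      (ss[ok] * sum(ry^2))
    df2 <- n - ncol(X) - 1
    if (df2 < 2) break
    Fs <- df2 * rho2 / pmax(1 - rho2, .Machine$double.eps)
    pv <- pf(Fs, 1, df2, lower.tail = FALSE)
    best <- which.min(pv)
    if (pv[best] * length(cand) >= entry_p) break
    chosen <- c(chosen, cand[best])
    X <- cbind(X, s[, cand[best]])
  }
  chosen
}

#' Composite interval mapping scan
#'
#' Haley-Knott-style composite interval mapping for a RIL population.
#' Background markers are first chosen by forward stepwise regression
#' (entry p < `entry_p`, at most `max_cofactors`).  The genome is then walked
#' in `step`-cM increments; at each position the expected genotype score is
#' computed from the flanking bins via Kosambi-based RIL conditional
#' probabilities, and the position is tested by comparing residual sums of
#' squares of the models with and without the position term, always excluding
#' cofactors within `window/2` cM of the tested position:
#' `LOD = (n/2) * log10(RSS0 / RSS1)`.  The additive effect is half the
#' difference between the parent-2 and parent-1 homozygote means, and
#' `PVE = 100 * (1 - RSS1 / RSS0)` (relative to the cofactor-only model).
#'
#' @param geno Lines x markers matrix, coded `"A"`/`"B"`/`NA` or numeric
#'   -1/+1; rownames are line ids.
#' @param map Tibble with `marker`, `chr`, `cm` matching the columns of
#'   `geno` (positions non-decreasing within chromosome).
#' @param pheno Either a numeric vector named by line id, or a data frame
#'   with a `line_id` column and the trait column named in `trait`.
#' @param trait Trait column name when `pheno` is a data frame.
#' @param window Cofactor exclusion window in cM (default 10).
#' @param step Scan step in cM (default 1).
#' @param max_cofactors Maximum background markers (default 5).
#' @param entry_p Stepwise entry p-value (default 0.01).
#' @return A tibble of class `qtl_scan`: `chr`, `cm`, `lod`, `effect`, `pve`,
#'   `n_cofactors`, with the selected cofactor markers in attribute
#'   `"cofactors"` and the threshold-free scan metadata in attributes.
#' @export
cim_scan <- function(geno, map, pheno, trait = NULL, window = 10, step = 1,
                     max_cofactors = 5, entry_p = 0.01) {
  stopifnot(is.data.frame(map), all(c("marker", "chr", "cm") %in% names(map)))
  s_all <- if (is.character(geno)) geno_to_score(geno) else as.matrix(geno)
  if (ncol(s_all) != nrow(map)) abort("`geno` columns and `map` rows must match.")

  if (is.data.frame(pheno)) {
    if (is.null(trait)) abort("Supply `trait` when `pheno` is a data frame.")
    y <- setNames(pheno[[trait]], pheno$line_id)
  } else {
    y <- pheno
  }
  if (!is.null(names(y)) && !is.null(rownames(s_all))) {
    shared <- intersect(rownames(s_all), names(y)[!is.na(y)])
    if (length(shared) < 10) abort("Fewer than 10 lines shared between genotypes and phenotype.")
    s_all <- s_all[shared, , drop = FALSE]
    y <- as.numeric(y[shared])
  } else {
    if (length(y) != nrow(s_all)) abort("Unnamed phenotype must match genotype rows.")
    keep <- !is.na(y)
    s_all <- s_all[keep, , drop = FALSE]
    y <- as.numeric(y[keep])
  }
  n <- length(y)

  variable <- apply(s_all, 2, function(x) sd(x, na.rm = TRUE) > 0 && !all(is.na(x)))
  s_imp <- fill_scores(s_all[, variable, drop = FALSE])
  map_var <- map[variable, , drop = FALSE]
  cof_idx <- select_cofactors(s_imp, y, entry_p = entry_p,
                              max_cofactors = max_cofactors)
  cof_map <- map_var[cof_idx, , drop = FALSE]

  res <- purrr::map_dfr(unique(map$chr), function(ch) {
    on_chr <- which(map_var$chr == ch)
    if (!length(on_chr)) {
      warn(sprintf("No polymorphic markers on chromosome %s; skipped.", ch))
      return(tibble::tibble())
    }
    pcm <- map_var$cm[on_chr]
    positions <- unique(c(seq(min(pcm), max(pcm), by = step), max(pcm)))
    es <- expected_scores(s_imp[, on_chr, drop = FALSE], map_var, positions, pcm)
    np <- length(positions)
    lod <- eff <- pve <- numeric(np)
    ncof <- integer(np)
    rss0_cache <- list()
    one <- rep(1, n)
    for (j in seq_len(np)) {
      pos <- positions[j]
      keep_cof <- !(cof_map$chr == ch & abs(cof_map$cm - pos) <= window / 2)
      key <- paste(c("c", which(keep_cof)), collapse = ",")
      X0 <- cbind(one, s_imp[, cof_idx[keep_cof], drop = FALSE])
      if (is.null(rss0_cache[[key]])) {
        rss0_cache[[key]] <- sum(.lm.fit(X0, y)$residuals^2)
      }
      rss0 <- rss0_cache[[key]]
      f1 <- .lm.fit(cbind(X0, es[, j]), y)
      rss1 <- sum(f1$residuals^2)
      lod[j] <- (n / 2) * log10(max(rss0 / rss1, 1))
      eff[j] <- f1$coefficients[ncol(X0) + 1]
      pve[j] <- 100 * max(1 - rss1 / rss0, 0)
      ncof[j] <- sum(keep_cof)
    }
    tibble::tibble(chr = ch, cm = positions, lod = lod, effect = eff,
                   pve = pve, n_cofactors = ncof)
  })
  attr(res, "cofactors") <- cof_map$marker
  attr(res, "n_lines") <- n
  class(res) <- c("qtl_scan", class(res))
  res
}

#' Call QTL from a scan and collapse them into nonredundant loci
#'
#' Contiguous runs of scan positions with LOD at or above `threshold` become
#' one QTL with its peak at the maximum-LOD position and a 1.5-LOD support
#' interval.  Peaks from different traits, environments or overlapping runs
#' that lie within `merge_cm` of each other on the same chromosome are
#' assigned one nonredundant locus id (single-linkage clustering of peak
#' positions).
#'
#' @param scan A `qtl_scan` tibble (possibly row-bound across traits and
#'   environments; any extra identifier columns such as `trait` or
#'   `environment` are preserved and used to separate scans).
#' @param threshold LOD threshold, e.g. from [meff_threshold()].
#' @param merge_cm Merge radius in cM for nonredundant loci (default 10).
#' @param drop_lod Support-interval drop from the peak (default 1.5).
#' @return Tibble with one row per QTL: identifier columns, `chr`, `peak_cm`,
#'   `lod`, `effect`, `pve`, `ci_lo`, `ci_hi`, `locus` (nonredundant id).
#' @export
call_qtl <- function(scan, threshold, merge_cm = 10, drop_lod = 1.5) {
  stopifnot(is.data.frame(scan),
            all(c("chr", "cm", "lod", "effect", "pve") %in% names(scan)))
  if (!nrow(scan)) return(tibble::tibble())
  ids <- intersect(c("trait", "environment"), names(scan))
  scan <- dplyr::ungroup(tibble::as_tibble(scan))
  groups <- if (length(ids)) {
    split(scan, interaction(scan[ids], drop = TRUE, sep = "\r"))
  } else list(scan)

  qtl <- purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(split(g, g$chr), function(gc) {
      gc <- dplyr::arrange(gc, .data$cm)
      above <- gc$lod >= threshold
      if (!any(above)) return(tibble::tibble())
      runs <- rle(above)
      ends <- cumsum(runs$lengths)
      starts <- c(1, utils::head(ends, -1) + 1)
      seg <- which(runs$values)
      purrr::map_dfr(seg, function(u) {
        idx <- starts[u]:ends[u]
        pk <- idx[which.max(gc$lod[idx])]
        lim <- gc$lod[pk] - drop_lod
        lo <- pk; while (lo > 1 && gc$lod[lo - 1] >= lim &&
                           gc$chr[lo - 1] == gc$chr[pk]) lo <- lo - 1
        hi <- pk; while (hi < nrow(gc) && gc$lod[hi + 1] >= lim &&
                           gc$chr[hi + 1] == gc$chr[pk]) hi <- hi + 1
        dplyr::bind_cols(
          gc[pk, ids, drop = FALSE],
          tibble::tibble(
            chr = gc$chr[pk], peak_cm = gc$cm[pk], lod = gc$lod[pk],
            effect = gc$effect[pk], pve = gc$pve[pk],
            ci_lo = gc$cm[lo], ci_hi = gc$cm[hi]
          )
        )
      })
    })
  })
  if (!nrow(qtl)) return(qtl)
  # nonredundant loci: single-linkage clusters of peaks within merge_cm
  qtl <- dplyr::arrange(qtl, .data$chr, .data$peak_cm)
  new_locus <- c(TRUE, qtl$chr[-1] != qtl$chr[-nrow(qtl)] |
                   diff(qtl$peak_cm) > merge_cm)
  qtl$locus <- cumsum(new_locus)
  qtl
}
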