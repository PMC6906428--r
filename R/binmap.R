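# Genotype matrices are lines x markers, coded "A" (parent-1 homozygote),
# "B" (parent-2 homozygote) or NA.  RILs carry no heterozygote class;
# residual "H" calls are recoded NA at load time (see read_genotypes()).

geno_to_score <- function(geno) {
  g <- as.matrix(geno)
  s <- matrix(NA_real_, nrow(g), ncol(g), dimnames = dimnames(g))
  s[g == "A"] <- -1
  s[g == "B"] <- 1
  bad <- !is.na(g) & !(g %in% c("A", "B"))
  if (any(bad)) {
    abort(paste0("Unknown genotype code(s): ",
                 paste(unique(g[bad]), collapse = ", ")))
  }
  s
}

#' Filter markers for segregation distortion
#'
#' Per-marker chi-square goodness-of-fit test of the non-missing calls
#' against the 1:1 A:B ratio expected in a biparental RIL population
#' (1 degree of freedom).  Markers with `p < alpha` are removed; markers with
#' fewer than `min_calls` informative calls are not tested and are flagged.
#'
#' @param geno Character matrix (lines x markers) coded `"A"`/`"B"`/`NA`.
#' @param alpha Removal threshold on the chi-square p-value (default 0.001).
#' @param min_calls Minimum informative calls for a marker to be tested
#'   (default 20).
#' @return List with `geno` (retained columns) and `report`, a tibble with
#'   one row per input marker: `marker`, `n_a`, `n_b`, `chisq`, `p`, `status`
#'   (`"retained"`, `"removed"`, or `"untested"`).
#' @export
segregation_filter <- function(geno, alpha = 0.001, min_calls = 20) {
  g <- as.matrix(geno)
  n_a <- colSums(g == "A", na.rm = TRUE)
  n_b <- colSums(g == "B", na.rm = TRUE)
  n <- n_a + n_b
  chisq <- ifelse(n > 0, (n_a - n / 2)^2 / (n / 2) + (n_b - n / 2)^2 / (n / 2), NA_real_)
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  status <- dplyr::case_when(
    n < min_calls ~ "untested",
    p < alpha ~ "removed",
    TRUE ~ "retained"
  )
  report <- tibble::tibble(
    marker = colnames(g) %||% as.character(seq_len(ncol(g))),
    n_a = unname(n_a), n_b = unname(n_b),
    chisq = ifelse(status == "untested", NA_real_, unname(chisq)),
    p = ifelse(status == "untested", NA_real_, unname(p)),
    status = status
  )
  list(geno = g[, status != "removed", drop = FALSE], report = report)
}

#' Sliding-window bin map construction
#'
#' Collapses a dense, physically ordered SNP matrix into bin markers.  Per
#' line and chromosome, a window of `window` consecutive SNPs slides one SNP
#' at a time; the window is called A (or B) when at least `min_call`
#' informative SNPs agree, otherwise it is ambiguous.  Runs of identical
#' window calls define the line's genotype blocks, with breakpoints placed at
#' the SNP midway between the centres of the flanking discordant windows.
#' Finally, consecutive SNP columns identical across all lines collapse into
#' one bin.
#'
#' @param geno Character matrix (lines x SNPs) coded `"A"`/`"B"`/`NA`, with
#'   SNPs in physical order within chromosome.
#' @param marker_info Tibble with columns `marker` and `chr` matching the SNP
#'   columns of `geno`, in column order.
#' @param window Window size in SNPs (default 15).
#' @param min_call Calls required for a window genotype (default 11).
#' @return List with `geno` — the lines x bins matrix — and `bins`, a tibble
#'   (`bin`, `chr`, `n_snps`, `first_marker`, `last_marker`).
#' @export
bin_map <- function(geno, marker_info, window = 15, min_call = 11) {
  g <- as.matrix(geno)
  stopifnot(is.data.frame(marker_info),
            all(c("marker", "chr") %in% names(marker_info)),
            nrow(marker_info) == ncol(g))
  if (min_call > window) abort("`min_call` cannot exceed `window`.")
  smoothed <- g
  for (ch in unique(marker_info$chr)) {
    idx <- which(marker_info$chr == ch)
    if (length(idx) < window) {
      warn(sprintf("Chromosome %s has fewer than %d SNPs; single-bin fallback.",
                   ch, window))
      sub <- g[, idx, drop = FALSE]
      maj <- apply(sub, 1, function(row) {
        na_ <- sum(row == "A", na.rm = TRUE); nb <- sum(row == "B", na.rm = TRUE)
        if (na_ == nb) NA_character_ else if (na_ > nb) "A" else "B"
      })
      smoothed[, idx] <- matrix(maj, nrow(g), length(idx))
      next
    }
    smoothed[, idx] <- t(apply(g[, idx, drop = FALSE], 1, smooth_line,
                               window = window, min_call = min_call))
  }
  # collapse adjacent identical columns (within chromosome) into bins
  col_key <- apply(smoothed, 2, function(col) paste(ifelse(is.na(col), ".", col), collapse = ""))
  new_bin <- c(TRUE, col_key[-1] != col_key[-length(col_key)] |
                 marker_info$chr[-1] != marker_info$chr[-nrow(marker_info)])
  bin_id <- cumsum(new_bin)
  first <- which(new_bin)
  last <- c(first[-1] - 1, ncol(smoothed))
  bins <- tibble::tibble(
    bin = paste0("bin", sprintf("%04d", seq_along(first))),
    chr = marker_info$chr[first],
    n_snps = last - first + 1,
    first_marker = marker_info$marker[first],
    last_marker = marker_info$marker[last]
  )
  bg <- smoothed[, first, drop = FALSE]
  colnames(bg) <- bins$bin
  list(geno = bg, bins = bins)
}

smooth_line <- function(calls, window, min_call) {
  m <- length(calls)
  n_win <- m - window + 1
  isA <- as.integer(!is.na(calls) & calls == "A")
  isB <- as.integer(!is.na(calls) & calls == "B")
  ca <- cumsum(isA); cb <- cumsum(isB)
  winA <- ca[window:m] - c(0, ca)[1:n_win]
  winB <- cb[window:m] - c(0, cb)[1:n_win]
  win_call <- rep(NA_character_, n_win)
  win_call[winA >= min_call] <- "A"
  win_call[winB >= min_call] <- "B"
  informative <- which(!is.na(win_call))
  if (!length(informative)) return(rep(NA_character_, m))
  # run-length over informative window calls; breakpoints at midpoints
  # between centres of flanking discordant windows
  runs <- rle(win_call[informative])
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  centre <- informative + (window - 1) / 2
  out <- rep(NA_character_, m)
  seg_start_snp <- 1
  for (u in seq_along(runs$values)) {
    if (u < length(runs$values)) {
      c1 <- centre[ends[u]]
      c2 <- centre[starts[u + 1]]
      seg_end_snp <- floor((c1 + c2) / 2)
    } else {
      seg_end_snp <- m
    }
    out[seg_start_snp:seg_end_snp] <- runs$values[u]
    seg_start_snp <- seg_end_snp + 1
  }
  out
}

#' Genetic map from adjacent-bin recombination estimates
#'
#' Estimates the meiotic recombination fraction between adjacent bins from
#' the observed discordance `R` (fraction of lines whose calls differ),
#' inverting the RIL-by-selfing accumulation `R = 2r/(1+2r)` as
#' `r = R / (2(1-R))`, then accumulates Kosambi distances along each
#' chromosome.
#'
#' @param bin_geno Lines x bins character matrix from [bin_map()] (or any
#'   ordered `"A"`/`"B"`/`NA` matrix).
#' @param bins Tibble with columns `bin` and `chr` matching `bin_geno`.
#' @param max_R Observed discordance at which an interval is declared
#'   unlinked and capped, with a warning (default 0.49 on the meiotic scale,
#'   i.e. `R` capped just below `ril_observed(0.5)`).
#' @return Tibble genetic map: `marker`, `chr`, `cm`, plus the interval
#'   estimates `R_obs` and `r_hat` (NA for the first bin of each chromosome).
#' @export
estimate_recomb <- function(bin_geno, bins, max_R = ril_observed(0.49)) {
  g <- as.matrix(bin_geno)
  stopifnot(nrow(bins) == ncol(g), all(c("bin", "chr") %in% names(bins)))
  purrr::map_dfr(split(seq_len(nrow(bins)), factor(bins$chr, unique(bins$chr))),
    function(idx) {
      R <- rep(NA_real_, length(idx))
      if (length(idx) > 1) {
        for (j in 2:length(idx)) {
          a <- g[, idx[j - 1]]; b <- g[, idx[j]]
          ok <- !is.na(a) & !is.na(b)
          R[j] <- if (any(ok)) mean(a[ok] != b[ok]) else NA_real_
        }
      }
      capped <- !is.na(R) & R > max_R
      if (any(capped)) {
        warn(sprintf("%d adjacent-bin interval(s) look unlinked (R > %.3f); capped.",
                     sum(capped), max_R))
        R[capped] <- max_R
      }
      r_hat <- ril_r(R)
      d <- kosambi_cm(ifelse(is.na(r_hat), 0, r_hat))
      tibble::tibble(
        marker = bins$bin[idx], chr = bins$chr[idx],
        cm = cumsum(d), R_obs = R, r_hat = r_hat
      )
    })
}
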