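#' Variance components for one trait across environments
#'
#' Method-of-moments decomposition of a line x environment trait table with
#' one observation per cell (the entry-mean design).  With `g` lines and `e`
#' environments, the genotype, environment and interaction mean squares give
#' \deqn{\hat\sigma^2_g = (MS_G - MS_{GxE})/e, \quad
#'       \hat\sigma^2 = MS_{GxE}, \quad
#'       \hat\sigma^2_{env} = (MS_E - MS_{GxE})/g.}
#' With a single observation per cell the genotype-by-environment mean square
#' is the error term, so the "error" variance here is the G-by-E-confounded
#' residual — the standard convention for entry-mean heritability.
#' Negative moment estimates are truncated to zero and flagged.
#'
#' @param data Data frame with columns `line_id`, `environment` and the trait.
#' @param trait Name of the trait column (string).
#' @return One-row tibble of class `variance_components`: `trait`, `sigma2_g`,
#'   `sigma2_resid`, `sigma2_env`, `n_env`, `n_lines`, `grand_mean`,
#'   `truncated`.
#' @export
variance_components <- function(data, trait) {
  stopifnot(is.data.frame(data), is.character(trait), length(trait) == 1)
  need <- setdiff(c("line_id", "environment", trait), names(data))
  if (length(need)) {
    abort(paste0("Trait table lacks column(s): ", paste(need, collapse = ", ")))
  }
  d <- tibble::tibble(
    line = factor(data$line_id),
    env = factor(data$environment),
    y = data[[trait]]
  )
  d <- d[complete.cases(d), ]
  if (anyDuplicated(paste(d$line, d$env, sep = "\r"))) {
    abort("Duplicated line within an environment; one observation per cell expected.")
  }
  e <- nlevels(droplevels(d$env))
  g <- nlevels(droplevels(d$line))
  if (e < 2) abort("Heritability is undefined with a single environment.")
  missing_frac <- 1 - nrow(d) / (e * g)
  if (missing_frac > 0.20) {
    abort(sprintf("%.0f%% of line x environment cells are missing (> 20%%).",
                  100 * missing_frac))
  }

  if (nrow(d) == e * g) {
    # balanced layout: mean squares in closed form (much faster than lm for
    # hundreds of line levels, identical by construction)
    ybar <- mean(d$y)
    line_m <- tapply(d$y, d$line, mean)
    env_m <- tapply(d$y, d$env, mean)
    ms_line <- e * sum((line_m - ybar)^2) / (g - 1)
    ms_env <- g * sum((env_m - ybar)^2) / (e - 1)
    resid2 <- (d$y - line_m[d$line] - env_m[d$env] + ybar)^2
    ms_resid <- sum(resid2) / ((g - 1) * (e - 1))
  } else {
    fit <- lm(y ~ env + line, data = d)
    tab <- anova(fit)
    ms_env <- tab["env", "Mean Sq"]
    ms_line <- tab["line", "Mean Sq"]
    ms_resid <- tab["Residuals", "Mean Sq"]
  }
  if (is.na(ms_resid)) abort("Residual degrees of freedom exhausted; cannot separate components.")

  s2g <- (ms_line - ms_resid) / e
  s2env <- (ms_env - ms_resid) / g
  truncated <- s2g < 0 || s2env < 0
  if (truncated) {
    warn(sprintf("Negative moment estimate truncated to 0 for trait '%s'.", trait))
  }
  out <- tibble::tibble(
    trait = trait,
    sigma2_g = max(s2g, 0),
    sigma2_resid = ms_resid,
    sigma2_env = max(s2env, 0),
    n_env = e, n_lines = g,
    grand_mean = mean(d$y),
    truncated = truncated
  )
  class(out) <- c("variance_components", class(out))
  out
}

#' Broad-sense heritability on an entry-mean basis
#'
#' `H^2 = sigma2_g / (sigma2_g + sigma2_resid / e)`, the fraction of variance
#' among line means across `e` environments attributable to genetic variance.
#'
#' @param vc A `variance_components` row from [variance_components()].
#' @return Heritability in `[0, 1]`; `NA` with a warning when both components
#'   are zero.
#' @export
heritability <- function(vc) {
  stopifnot(all(c("sigma2_g", "sigma2_resid", "n_env") %in% names(vc)))
  if (vc$n_env < 2) abort("Heritability requires at least two environments.")
  denom <- vc$sigma2_g + vc$sigma2_resid / vc$n_env
  if (denom == 0) {
    warn("Both variance components are zero; heritability undefined.")
    return(NA_real_)
  }
  vc$sigma2_g / denom
}

#' Coefficient of variation in percent
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation.
#'
#' @param values Numeric vector with non-zero mean.
#' @return CV as a percentage.
#' @export
cv_percent <- function(values) {
  values <- values[!is.na(values)]
  m <- mean(values)
  if (m == 0) abort("CV undefined: mean is zero.")
  100 * sd(values) / m
}

#' Pairwise Pearson correlations among traits
#'
#' Pearson `r` for every pair of trait columns, with two-sided p-values from
#' the t-distribution transform `t = r * sqrt((n-2)/(1-r^2))` on `n - 2`
#' degrees of freedom, and significance stars at the 0.05 / 0.01 levels.
#'
#' @param data Data frame containing the trait columns.
#' @param traits Character vector of trait column names; defaults to all
#'   numeric columns.
#' @return Long tibble with `trait_x`, `trait_y`, `n`, `r`, `p`, `stars`
#'   covering each unordered pair once plus the unit diagonal.  Zero-variance
#'   columns yield `NA` entries with a warning.
#' @export
correlation_matrix <- function(data, traits = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(traits)) {
    traits <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  miss <- setdiff(traits, names(data))
  if (length(miss)) abort(paste0("Unknown trait column(s): ", paste(miss, collapse = ", ")))
  x <- as.matrix(data[traits])
  const <- apply(x, 2, function(v) sd(v, na.rm = TRUE) == 0)
  if (any(const)) {
    warn(paste0("Zero-variance column(s): ", paste(traits[const], collapse = ", "),
                "; correlations set to NA."))
  }
  pairs <- tidyr::expand_grid(
    trait_x = factor(traits, levels = traits),
    trait_y = factor(traits, levels = traits)
  )
  pairs <- pairs[as.integer(pairs$trait_x) <= as.integer(pairs$trait_y), ]
  res <- purrr::pmap_dfr(pairs, function(trait_x, trait_y) {
    i <- as.character(trait_x); j <- as.character(trait_y)
    ok <- complete.cases(x[, c(i, j), drop = FALSE])
    n <- sum(ok)
    if (n < 3 || const[i] || const[j]) {
      return(tibble::tibble(trait_x = i, trait_y = j, n = n,
                            r = NA_real_, p = NA_real_))
    }
    if (i == j) {
      return(tibble::tibble(trait_x = i, trait_y = j, n = n, r = 1, p = 0))
    }
    r <- cor(x[ok, i], x[ok, j])
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    tibble::tibble(trait_x = i, trait_y = j, n = n, r = r,
                   p = 2 * pt(-abs(tstat), df = n - 2))
  })
  res$stars <- dplyr::case_when(
    is.na(res$p) ~ "",
    res$p < 0.01 ~ "**",
    res$p < 0.05 ~ "*",
    TRUE ~ ""
  )
  res
}

#' Best linear unbiased prediction of line values
#'
#' Closed-form shrinkage BLUP on the (near-)balanced line x environment
#' layout: after removing environment means, each line mean is shrunk toward
#' the grand mean by
#' `lambda_i = sigma2_g / (sigma2_g + sigma2_resid / e_i)`, where `e_i` is the
#' number of environments observed for line `i`.  Under balance this equals
#' the genotype-random-intercept mixed-model predictor; it never moves a line
#' further from the grand mean than its raw mean.
#'
#' @inheritParams variance_components
#' @return Tibble with `line_id`, `n_env`, `mean` (environment-centred line
#'   mean plus grand mean) and `blup`.
#' @export
blup <- function(data, trait) {
  vc <- variance_components(data, trait)
  d <- tibble::tibble(
    line_id = data$line_id,
    env = data$environment,
    y = data[[trait]]
  )
  d <- d[complete.cases(d), ]
  mu <- mean(d$y)
  env_eff <- d |>
    dplyr::group_by(.data$env) |>
    dplyr::summarise(env_mean = mean(.data$y), .groups = "drop")
  d <- dplyr::left_join(d, env_eff, by = "env")
  d$y_centred <- d$y - d$env_mean + mu
  d |>
    dplyr::group_by(.data$line_id) |>
    dplyr::summarise(
      n_env = dplyr::n(),
      mean = mean(.data$y_centred),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      denom = vc$sigma2_g + vc$sigma2_resid / .data$n_env,
      lambda = ifelse(.data$denom > 0, vc$sigma2_g / .data$denom, 0),
      blup = mu + .data$lambda * (.data$mean - mu)
    ) |>
    dplyr::select("line_id", "n_env", "mean", "blup")
}

#' Welch two-sample t-test between phenotype pools
#'
#' Two-sided unequal-variance (Welch) t-test comparing a trait between two
#' pools of lines.
#'
#' @param values_pool1,values_pool2 Numeric vectors, each of length >= 2.
#' @return Tibble with `t`, `df`, `p`, and the two pool means.
#' @export
pool_t_test <- function(values_pool1, values_pool2) {
  x <- values_pool1[!is.na(values_pool1)]
  y <- values_pool2[!is.na(values_pool2)]
  if (length(x) < 2 || length(y) < 2) abort("Each pool needs at least 2 values.")
  if (sd(x) == 0 && sd(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(tibble::tibble(
      t = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
      df = length(x) + length(y) - 2,
      p = if (same) 1 else 0,
      mean_pool1 = mean(x), mean_pool2 = mean(y)
    ))
  }
  ht <- t.test(x, y)
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, mean_pool1 = mean(x), mean_pool2 = mean(y)
  )
}

#' Per-trait summary across a multi-environment trial
#'
#' Convenience wrapper producing, for each trait column, the grand mean, the
#' coefficient of variation among line means, the variance components and the
#' broad-sense heritability.
#'
#' @inheritParams variance_components
#' @param traits Character vector of trait columns; defaults to all numeric
#'   columns other than identifiers.
#' @return Tibble with one row per trait: `trait`, `mean`, `cv_percent`,
#'   `sigma2_g`, `sigma2_resid`, `h2`.
#' @export
trait_summary <- function(data, traits = NULL) {
  if (is.null(traits)) {
    traits <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                      c("line_id", "environment"))
  }
  purrr::map_dfr(traits, function(tr) {
    vc <- variance_components(data, tr)
    line_means <- data |>
      dplyr::group_by(.data$line_id) |>
      dplyr::summarise(m = mean(.data[[tr]], na.rm = TRUE), .groups = "drop")
    tibble::tibble(
      trait = tr,
      mean = vc$grand_mean,
      cv_percent = cv_percent(line_means$m),
      sigma2_g = vc$sigma2_g,
      sigma2_resid = vc$sigma2_resid,
      h2 = heritability(vc)
    )
  })
}
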