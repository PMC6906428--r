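#' Configuration for the synthetic RIL seed-filling study
#'
#' Builds the parameter set controlling the synthetic data generator, which
#' emulates a biparental maize RIL study end to end: 208 recombinant inbred
#' lines genotyped on a 10-chromosome map, phenotyped for 50-seed dry weight
#' at 14 days-after-pollination time points across 3 environments, with QTL
#' acting additively on the logistic parameters (k, a, b), environment and
#' genotype-by-environment effects, Gaussian weighing noise, binomial bulk
#' allele depths and negative-binomial expression counts.
#'
#' Defaults are chosen to resemble a real maize filling trial: parents with
#' contrasting dynamics (a small fast-filling parent against a large
#' slow-filling one, both reaching their maximum rate near 30 DAP, so that
#' midparent `v_max = k b / 4` falls around 0.45 g/DAP), a weighing noise of
#' 0.9 g on 50-seed weights giving fit R-squared near 0.95, and QTL plus
#' G-by-E magnitudes giving broad-sense heritabilities around 0.6-0.85.  One
#' QTL (chromosome 7 at 40 cM) is pleiotropic on all three parameters so the
#' derived traits inherit correlated effects.
#'
#' @param n_lines Number of RILs (default 208).
#' @param n_env Number of environments (default 3).
#' @param n_chr,chr_length_cm,markers_per_chr Map geometry: default 10
#'   chromosomes of 160 cM with 33 evenly spaced bin markers each.
#' @param parent1,parent2 Named vectors `c(k=, a=, b=)` of parental logistic
#'   parameters (g, -, per DAP).
#' @param qtl Named list with elements `k`, `a`, `b`, each a tibble
#'   `(chr, cm, effect)`; the additive effect is half the difference between
#'   the parent-2 and parent-1 homozygote, in the parameter's units.
#' @param env_sd,gxe_sd Named vectors `c(k=, a=, b=)`: SDs of the environment
#'   main effects and of the line-by-environment deviations.
#' @param noise_sd Gaussian measurement noise SD on dry weights (g);
#'   negative noisy weights are truncated at zero.
#' @param proportional_noise If `TRUE`, noise SD scales with the expected
#'   weight (heteroscedastic alternative; default `FALSE`).
#' @param dap Sampling schedule in days after pollination.
#' @param geno_error_rate,geno_missing_rate Per-call genotyping error /
#'   missingness rates (defaults 0).
#' @param depth Bulk sequencing depth per SNP site (reads; default 40).
#' @param n_genes,n_de,fold_change,lib_size,dispersion Expression simulation:
#'   gene count, number of DE genes, their fold change (high over low bulk),
#'   nominal library size and NB dispersion (`BCV^2`).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 208, n_env = 3,
                       n_chr = 10, chr_length_cm = 160, markers_per_chr = 33,
                       parent1 = c(k = 13, a = 121.5, b = 0.16),
                       parent2 = c(k = 17, a = 36.6, b = 0.12),
                       qtl = default_qtl(),
                       env_sd = c(k = 0.8, a = 5, b = 0.006),
                       gxe_sd = c(k = 1.2, a = 6, b = 0.005),
                       noise_sd = 0.5, proportional_noise = FALSE,
                       dap = c(10, 15, 20, 25, 30, 35, 40, 43, 46, 49,
                               52, 55, 58, 61),
                       geno_error_rate = 0, geno_missing_rate = 0,
                       depth = 40,
                       n_genes = 1030, n_de = 30, fold_change = 8,
                       lib_size = 2e6, dispersion = 0.04) {
  cfg <- as.list(environment())
  for (nm in c("parent1", "parent2", "env_sd", "gxe_sd")) {
    if (!all(c("k", "a", "b") %in% names(cfg[[nm]]))) {
      abort(sprintf("`%s` must name k, a and b.", nm))
    }
  }
  if (any(c(env_sd, gxe_sd, noise_sd, geno_error_rate, geno_missing_rate) < 0)) {
    abort("Rates and standard deviations must be non-negative.")
  }
  if (any(parent1[c("k", "a", "b")] <= 0) || any(parent2[c("k", "a", "b")] <= 0)) {
    abort("Parental logistic parameters must be positive.")
  }
  stopifnot(is.list(qtl), all(names(qtl) %in% c("k", "a", "b")))
  class(cfg) <- "sim_config"
  cfg
}

default_qtl <- function() {
  list(
    k = tibble::tibble(chr = c("chr1", "chr5", "chr7"), cm = c(50, 80, 40),
                       effect = c(0.9, 0.7, 0.55)),
    a = tibble::tibble(chr = c("chr3", "chr7"), cm = c(30, 40),
                       effect = c(25, 17)),
    b = tibble::tibble(chr = c("chr2", "chr7"), cm = c(60, 40),
                       effect = c(0.012, 0.008))
  )
}

#' Simulate RIL genotypes along a genetic map
#'
#' Generates homozygous recombinant-inbred genotypes directly at the
#' F-infinity expectation: along each chromosome the parental origin follows
#' a two-state Markov chain whose transition probability between adjacent
#' markers is the observed RIL discordance `R = 2r/(1+2r)`, with the meiotic
#' `r` obtained from the inverse Kosambi transform of the inter-marker cM
#' gap.  Optional per-call error and missingness are applied afterwards.
#'
#' @param config A [sim_config()] object.
#' @param map Optional custom map tibble (`marker`, `chr`, `cm`); by default
#'   an evenly spaced map is built from the config geometry.
#' @param seed Optional integer seed for reproducibility.
#' @return List with `geno` (lines x markers character matrix, `"A"`/`"B"`)
#'   and `map`.
#' @export
simulate_ril_genotypes <- function(config = sim_config(), map = NULL,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(map)) {
    map <- purrr::map_dfr(seq_len(config$n_chr), function(ci) {
      tibble::tibble(
        marker = sprintf("chr%d_m%02d", ci, seq_len(config$markers_per_chr)),
        chr = paste0("chr", ci),
        cm = seq(0, config$chr_length_cm, length.out = config$markers_per_chr)
      )
    })
  }
  if (any(unlist(tapply(map$cm, map$chr, diff)) < 0)) {
    abort("Map positions must be non-decreasing within chromosome.")
  }
  n <- config$n_lines
  g <- matrix(NA_integer_, n, nrow(map))
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    g[, idx[1]] <- rbinom(n, 1, 0.5)
    if (length(idx) > 1) {
      for (j in 2:length(idx)) {
        gap <- map$cm[idx[j]] - map$cm[idx[j - 1]]
        R <- ril_observed(kosambi_r(gap))
        flip <- rbinom(n, 1, R)
        g[, idx[j]] <- ifelse(flip == 1, 1 - g[, idx[j - 1]], g[, idx[j - 1]])
      }
    }
  }
  out <- matrix(ifelse(g == 1, "B", "A"), n, nrow(map))
  if (config$geno_error_rate > 0) {
    err <- matrix(runif(length(out)) < config$geno_error_rate, n)
    out[err] <- ifelse(out[err] == "A", "B", "A")
  }
  if (config$geno_missing_rate > 0) {
    out[matrix(runif(length(out)) < config$geno_missing_rate, n)] <- NA_character_
  }
  dimnames(out) <- list(sprintf("RIL%03d", seq_len(n)), map$marker)
  list(geno = out, map = map)
}

qtl_marker_index <- function(qtl_tbl, map) {
  vapply(seq_len(nrow(qtl_tbl)), function(i) {
    on_chr <- which(map$chr == qtl_tbl$chr[i])
    if (!length(on_chr)) abort(sprintf("QTL chromosome %s not on the map.", qtl_tbl$chr[i]))
    on_chr[which.min(abs(map$cm[on_chr] - qtl_tbl$cm[i]))]
  }, integer(1))
}

#' Simulate seed-filling phenotypes on simulated genotypes
#'
#' Each line's genetic value for every logistic parameter is the midparent
#' plus the sum of its QTL allele scores (+1 for the parent-2 homozygote, -1
#' for parent-1) times the additive effects, each QTL being anchored at the
#' map marker nearest its configured position.  Per environment, an
#' environment main effect and a line-by-environment (G-by-E) deviate are
#' added; dry weights are then generated from the logistic curve at the DAP
#' schedule plus Gaussian measurement noise (truncated at zero).  Parameter
#' draws that come out non-positive are resampled (with a warning), up to 20
#' attempts.
#'
#' @param sim Output of [simulate_ril_genotypes()].
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return List with `weights` (long tibble `line_id`, `environment`, `dap`,
#'   `weight_g`), `truth_line` (per-line genetic `k`, `a`, `b` and derived
#'   `v_max`), `truth_env` (realized per line x environment parameters) and
#'   `qtl` (the QTL spec with anchored markers).
#' @export
simulate_filling_phenotypes <- function(sim, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geno <- sim$geno; map <- sim$map
  n <- nrow(geno)
  lines <- rownames(geno)
  s <- geno_to_score(geno)
  s[is.na(s)] <- 0

  mid <- (config$parent1[c("k", "a", "b")] + config$parent2[c("k", "a", "b")]) / 2
  gvals <- sapply(c("k", "a", "b"), function(par) {
    v <- rep(mid[[par]], n)
    q <- config$qtl[[par]]
    if (!is.null(q) && nrow(q)) {
      idx <- qtl_marker_index(q, map)
      v <- v + as.numeric(s[, idx, drop = FALSE] %*% q$effect)
    }
    v
  })
  if (any(gvals <= 0)) abort("Config error: genetic values non-positive; shrink QTL effects.")

  qtl_anno <- purrr::imap_dfr(config$qtl, function(q, par) {
    if (is.null(q) || !nrow(q)) return(tibble::tibble())
    dplyr::mutate(q, parameter = par, marker = map$marker[qtl_marker_index(q, map)])
  })

  envs <- paste0("env", seq_len(config$n_env))
  env_eff <- matrix(
    sapply(c("k", "a", "b"), function(p) rnorm(config$n_env, 0, config$env_sd[[p]])),
    nrow = config$n_env, dimnames = list(NULL, c("k", "a", "b"))
  )

  truth_env <- purrr::map_dfr(seq_len(config$n_env), function(e) {
    draw <- function(p) {
      v <- gvals[, p] + env_eff[e, p] + rnorm(n, 0, config$gxe_sd[[p]])
      tries <- 0
      while (any(v <= 0) && tries < 20) {
        bad <- v <= 0
        v[bad] <- gvals[bad, p] + env_eff[e, p] + rnorm(sum(bad), 0, config$gxe_sd[[p]])
        tries <- tries + 1
      }
      if (any(v <= 0)) abort("Config error: cannot draw positive parameters.")
      if (tries > 0) warn(sprintf("Resampled %s deviates to keep parameters positive.", p))
      v
    }
    tibble::tibble(line_id = lines, environment = envs[e],
                   k = draw("k"), a = draw("a"), b = draw("b"))
  })

  weights <- truth_env |>
    tidyr::expand_grid(dap = config$dap) |>
    dplyr::mutate(
      mu = logistic_weight(.data$dap, .data$k, .data$a, .data$b),
      sd_w = if (config$proportional_noise) {
        config$noise_sd * .data$mu / mean(.data$mu)
      } else config$noise_sd,
      weight_g = pmax(.data$mu + rnorm(dplyr::n(), 0, .data$sd_w), 0)
    ) |>
    dplyr::select("line_id", "environment", "dap", "weight_g")

  truth_line <- tibble::tibble(
    line_id = lines,
    k = gvals[, "k"], a = gvals[, "a"], b = gvals[, "b"],
    v_max = gvals[, "k"] * gvals[, "b"] / 4,
    t_mid = log(gvals[, "a"]) / gvals[, "b"]
  )
  list(weights = weights, truth_line = truth_line, truth_env = truth_env,
       qtl = qtl_anno)
}

#' Simulate bulk allele depths at every marker site
#'
#' For each site, each bulk's alternate (parent-2) allele frequency is the
#' fraction of its pool lines carrying the parent-2 allele; read counts are
#' drawn independently per bulk as `alt ~ Binomial(depth, freq)`,
#' `ref = depth - alt`.  Physical positions are assigned at 1 Mb per cM (a
#' desk-scale caricature used consistently across the simulated study).
#'
#' @param sim Output of [simulate_ril_genotypes()].
#' @param pools Tibble from [select_pools()] (`line_id`, `pool`).
#' @param depth Read depth per site and bulk.
#' @param seed Optional integer seed.
#' @return Tibble: `site`, `chr`, `cm`, `pos_bp`, `ref_high`, `alt_high`,
#'   `ref_low`, `alt_low`.
#' @export
simulate_bulk_counts <- function(sim, pools, depth = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hi <- pools$line_id[pools$pool == "high"]
  lo <- pools$line_id[pools$pool == "low"]
  if (!length(hi) || !length(lo)) abort("Both pools must be non-empty.")
  if (length(intersect(hi, lo))) abort("Pools must be disjoint line sets.")
  g <- sim$geno
  freq_hi <- colMeans(g[hi, , drop = FALSE] == "B", na.rm = TRUE)
  freq_lo <- colMeans(g[lo, , drop = FALSE] == "B", na.rm = TRUE)
  m <- ncol(g)
  alt_hi <- rbinom(m, depth, freq_hi)
  alt_lo <- rbinom(m, depth, freq_lo)
  tibble::tibble(
    site = colnames(g), chr = sim$map$chr, cm = sim$map$cm,
    pos_bp = round(sim$map$cm * 1e6) + 1,
    ref_high = depth - alt_hi, alt_high = alt_hi,
    ref_low = depth - alt_lo, alt_low = alt_lo
  )
}

#' Simulate bulk expression counts with designated DE genes
#'
#' Draws one RNA library per bulk.  Gene abundances follow a log-normal
#' baseline; the configured number of DE genes have their abundance in the
#' high bulk multiplied by the fold change (chosen at random among genes, or
#' per an explicit `de_spec`).  Counts are negative binomial with the
#' configured dispersion around library-size-scaled proportions, with
#' per-sample library sizes jittered around the nominal size.
#'
#' @param config A [sim_config()].
#' @param de_spec Optional tibble (`gene`, `fold_change`) overriding the
#'   random DE assignment; fold changes must be positive.
#' @param gene_pos Optional tibble (`gene`, `chr`, `start_bp`, `end_bp`)
#'   giving gene coordinates; by default genes are placed uniformly along the
#'   simulated chromosomes (1 Mb per cM).
#' @param seed Optional integer seed.
#' @return List with `counts` (genes x 2 matrix: columns `high`, `low`),
#'   `truth` (tibble `gene`, `is_de`, `fold_change`) and `gene_coords`.
#' @export
simulate_expression <- function(config = sim_config(), de_spec = NULL,
                                gene_pos = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ng <- config$n_genes
  genes <- sprintf("gene%04d", seq_len(ng))
  lambda <- stats::rlnorm(ng, meanlog = log(50), sdlog = 1.5)
  if (is.null(de_spec)) {
    de_idx <- sample.int(ng, config$n_de)
    fold <- rep(1, ng); fold[de_idx] <- config$fold_change
  } else {
    if (any(de_spec$fold_change <= 0)) abort("Config error: fold changes must be positive.")
    fold <- rep(1, ng)
    fold[match(de_spec$gene, genes)] <- de_spec$fold_change
  }
  lam_hi <- lambda * fold
  lib <- config$lib_size * runif(2, 0.85, 1.15)
  mu_hi <- lam_hi / sum(lam_hi) * lib[1]
  mu_lo <- lambda / sum(lambda) * lib[2]
  size <- 1 / config$dispersion
  counts <- cbind(
    high = rnbinom(ng, size = size, mu = mu_hi),
    low = rnbinom(ng, size = size, mu = mu_lo)
  )
  rownames(counts) <- genes
  if (is.null(gene_pos)) {
    chr <- sample(paste0("chr", seq_len(config$n_chr)), ng, replace = TRUE)
    start <- round(runif(ng, 1, config$chr_length_cm * 1e6))
    gene_pos <- tibble::tibble(gene = genes, chr = chr, start_bp = start,
                               end_bp = start + 4999)
  }
  list(
    counts = counts,
    truth = tibble::tibble(gene = genes, is_de = fold != 1, fold_change = fold),
    gene_coords = gene_pos
  )
}

#' Simulate the complete synthetic study
#'
#' Generates every input the pipeline consumes: RIL genotypes and map,
#' dry-weight trajectories with their generating truth, truth-defined extreme
#' pools on the genetic `v_max`, bulk allele depths and bulk expression
#' counts.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the whole study is reproducible from it.
#' @param n_per_pool Lines per extreme pool (default 13).
#' @return Named list: `config`, `geno`, `map`, `weights`, `truth_line`,
#'   `truth_env`, `qtl`, `pools`, `bulk_sites`, `expression`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1, n_per_pool = 13) {
  set.seed(seed)
  sim <- simulate_ril_genotypes(config)
  phen <- simulate_filling_phenotypes(sim, config)
  pools <- select_pools(
    setNames(phen$truth_line$v_max, phen$truth_line$line_id),
    n_per_pool = n_per_pool
  )
  bulk <- simulate_bulk_counts(sim, pools, depth = config$depth)
  expr <- simulate_expression(config)
  c(list(config = config), sim,
    phen[c("weights", "truth_line", "truth_env", "qtl")],
    list(pools = pools, bulk_sites = bulk, expression = expr))
}
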