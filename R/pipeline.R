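#' Pipeline configuration
#'
#' Assembles and validates the options controlling [run_pipeline()].  Unknown
#' option names are rejected.  Every run writes a resolved copy of this
#' configuration (`pipeline_config.yaml`) next to its outputs when `outdir`
#' is set.
#'
#' @param seed Integer seed governing all randomness in a simulated run.
#' @param sim A [sim_config()] for the synthetic study.
#' @param outdir Optional output directory; created if needed.  When `NULL`,
#'   nothing is written and results are only returned.
#' @param completion Filling-completion fraction for [derive_parameters()].
#' @param min_points Minimum trajectory points per fitted curve.
#' @param cim_window,cim_step CIM cofactor window and scan step (cM).
#' @param alpha Genome-wide type-I rate for the Meff threshold.
#' @param merge_cm Nonredundant-locus merge radius (cM).
#' @param n_per_pool Lines per extreme pool.
#' @param t_mid_tolerance Optional DAP band on the filling midpoint when
#'   selecting pools.
#' @param dispersion NB dispersion for the expression exact test.
#' @param deg_alpha,deg_min_lfc DEG rule: Bonferroni-adjusted p and |log2FC|
#'   thresholds.
#' @param fdr_alpha FDR threshold for significant SNP sites.
#' @param scan_traits Trait columns to scan for QTL (default `v_max` and `k`;
#'   scanning all 12 is supported but slower).
#' @param stages Character vector of stages to run, a subset of
#'   `c("fit", "stats", "qtl", "bsa", "deg")`.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, sim = sim_config(), outdir = NULL,
                            completion = 0.99, min_points = 4,
                            cim_window = 10, cim_step = 1, alpha = 0.05,
                            merge_cm = 10, n_per_pool = 13,
                            t_mid_tolerance = NULL, dispersion = 0.04,
                            deg_alpha = 0.05, deg_min_lfc = 2,
                            fdr_alpha = 0.05,
                            scan_traits = c("v_max", "k"),
                            stages = c("fit", "stats", "qtl", "bsa", "deg")) {
  cfg <- as.list(environment())
  stopifnot(inherits(sim, "sim_config"))
  bad <- setdiff(stages, c("fit", "stats", "qtl", "bsa", "deg"))
  if (length(bad)) abort(paste0("Unknown stage(s): ", paste(bad, collapse = ", ")))
  if (!"fit" %in% stages) abort("The `fit` stage is required by all others.")
  class(cfg) <- "pipeline_config"
  cfg
}

persist <- function(outdir, name, x) {
  if (is.null(outdir)) return(invisible(NULL))
  if (is.matrix(x)) {
    if (is.character(x)) write_genotypes(x, file.path(outdir, paste0(name, ".tsv")))
    else write_counts(x, file.path(outdir, paste0(name, ".tsv")))
  } else {
    flat <- x
    for (j in names(flat)) if (is.list(flat[[j]])) {
      flat[[j]] <- vapply(flat[[j]], paste, "", collapse = ";")
    }
    write_delim_auto(flat, file.path(outdir, paste0(name, ".tsv")))
  }
  invisible(NULL)
}

#' Run the full synthetic-study pipeline
#'
#' Executes, on a freshly simulated study: curve fitting and trait
#' derivation, multi-environment trait statistics and BLUP of the maximum
#' filling rate, the Meff-thresholded composite-interval QTL scans and
#' nonredundant QTL calls, extreme-pool construction, bulked-segregant SNP
#' statistics, and the expression exact test with the DEG rule and candidate
#' gene intersection.  Every stage's table is returned (and persisted as
#' delimited text when `outdir` is set), together with a run log of the seed
#' and parameters.  Reruns with the same configuration and seed are
#' reproducible.
#'
#' @param config A [pipeline_config()].
#' @return Named list of stage outputs (`fits`, `traits`, `summary`,
#'   `correlations`, `blup_vmax`, `map`, `threshold`, `scans`, `qtl`,
#'   `pools`, `site_stats`, `deg`, `candidates`, `log`); stages toggled off
#'   are absent.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  if (!is.null(outdir)) {
    resolved <- config
    resolved$sim <- unclass(resolved$sim)
    resolved$sim$qtl <- lapply(resolved$sim$qtl, as.data.frame)
    yaml::write_yaml(
      lapply(unclass(resolved), function(x) if (is.null(x)) "NULL" else x),
      file.path(outdir, "pipeline_config.yaml")
    )
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  out <- list(log = list(seed = config$seed,
                         package_version = as.character(utils::packageVersion("seedfillr")),
                         stages = config$stages))

  study <- run_stage("simulate", simulate_study(config$sim, seed = config$seed,
                                                n_per_pool = config$n_per_pool))
  out$study <- study
  persist(outdir, "genotypes", study$geno)
  persist(outdir, "map_true", study$map)
  persist(outdir, "weights", study$weights)

  fits <- run_stage("fit", fit_filling(study$weights, min_points = config$min_points))
  traits <- run_stage("fit", derive_parameters(fits, completion = config$completion))
  out$fits <- fits
  out$traits <- traits
  persist(outdir, "fits", fits)
  persist(outdir, "traits", traits)

  trait_cols <- c("k", "b", "t_mid", "t1", "t2", "t3", "w1", "w2", "w3",
                  "v_bar", "t_active", "v_max")
  if ("stats" %in% config$stages) {
    out$summary <- run_stage("stats", trait_summary(traits, trait_cols))
    out$correlations <- run_stage("stats", correlation_matrix(traits, trait_cols))
    out$blup_vmax <- run_stage("stats", blup(traits, "v_max"))
    persist(outdir, "trait_summary", out$summary)
    persist(outdir, "correlations", out$correlations)
    persist(outdir, "blup_vmax", out$blup_vmax)
  }

  if ("qtl" %in% config$stages) {
    thr <- run_stage("qtl", meff_threshold(study$geno, alpha = config$alpha))
    line_means <- traits |>
      dplyr::group_by(.data$line_id) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(config$scan_traits), mean),
                       .groups = "drop")
    scans <- purrr::map_dfr(config$scan_traits, function(tr) {
      sc <- run_stage("qtl", cim_scan(
        study$geno, study$map, line_means, trait = tr,
        window = config$cim_window, step = config$cim_step
      ))
      dplyr::mutate(sc, trait = tr)
    })
    out$threshold <- thr
    out$scans <- scans
    out$qtl <- run_stage("qtl", call_qtl(scans, thr$threshold,
                                         merge_cm = config$merge_cm))
    persist(outdir, "scan", scans)
    if (nrow(out$qtl)) persist(outdir, "qtl", out$qtl)
  }

  if (any(c("bsa", "deg") %in% config$stages)) {
    ranking <- if (!is.null(out$blup_vmax)) {
      setNames(out$blup_vmax$blup, out$blup_vmax$line_id)
    } else {
      lm_ <- traits |>
        dplyr::group_by(.data$line_id) |>
        dplyr::summarise(v = mean(.data$v_max), .groups = "drop")
      setNames(lm_$v, lm_$line_id)
    }
    tmids <- traits |>
      dplyr::group_by(.data$line_id) |>
      dplyr::summarise(tm = mean(.data$t_mid), .groups = "drop")
    out$pools <- run_stage("pools", select_pools(
      ranking, n_per_pool = config$n_per_pool,
      t_mid = setNames(tmids$tm, tmids$line_id),
      t_mid_tolerance = config$t_mid_tolerance %||% Inf
    ))
    persist(outdir, "pools", out$pools)
  }

  if ("bsa" %in% config$stages) {
    bulk <- run_stage("bsa", simulate_bulk_counts(study, out$pools,
                                                  depth = config$sim$depth))
    out$bulk_sites <- bulk
    out$site_stats <- run_stage("bsa", bsa_site_stats(bulk, alpha = config$fdr_alpha))
    persist(outdir, "site_stats", out$site_stats)
  }

  if ("deg" %in% config$stages) {
    expr <- study$expression
    tmm <- run_stage("deg", tmm_factors(expr$counts))
    tests <- run_stage("deg", nb_exact_test(
      expr$counts[, "high"], expr$counts[, "low"],
      lib_high = tmm$effective_lib_size[tmm$sample == "high"],
      lib_low = tmm$effective_lib_size[tmm$sample == "low"],
      dispersion = config$dispersion
    ))
    out$tmm <- tmm
    out$deg <- run_stage("deg", deg_filter(tests, alpha = config$deg_alpha,
                                           min_abs_lfc = config$deg_min_lfc))
    persist(outdir, "deg", out$deg)
    if (all(c("bsa", "qtl") %in% config$stages) && nrow(out$qtl)) {
      lookup <- dplyr::distinct(out$bulk_sites, .data$chr, .data$cm, .data$pos_bp)
      qtl_phys <- qtl_to_physical(out$qtl, lookup)
      out$candidates <- run_stage("candidates", candidate_genes(
        out$deg, qtl_phys, out$site_stats, expr$gene_coords
      ))
      persist(outdir, "candidates", out$candidates)
    }
  }
  out
}
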