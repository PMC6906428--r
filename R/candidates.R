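#' Project QTL support intervals from genetic to physical coordinates
#'
#' Linearly interpolates bin positions (cM) against their physical anchors to
#' express QTL support intervals in base pairs.  All physical coordinates in
#' this package are 1-based inclusive.
#'
#' @param qtl Tibble from [call_qtl()] (`chr`, `ci_lo`, `ci_hi` in cM).
#' @param bin_lookup Tibble with `chr`, `cm`, `pos_bp`: the physical anchor of
#'   each bin marker.
#' @return `qtl` with `start_bp` and `end_bp` appended.
#' @export
qtl_to_physical <- function(qtl, bin_lookup) {
  stopifnot(all(c("chr", "ci_lo", "ci_hi") %in% names(qtl)),
            all(c("chr", "cm", "pos_bp") %in% names(bin_lookup)))
  project <- function(chr, cm) {
    lk <- bin_lookup[bin_lookup$chr == chr, ]
    if (nrow(lk) < 2) abort(sprintf("Need >= 2 anchors on chromosome %s.", chr))
    stats::approx(lk$cm, lk$pos_bp, xout = cm, rule = 2)$y
  }
  qtl |>
    dplyr::mutate(
      start_bp = round(purrr::map2_dbl(.data$chr, .data$ci_lo, project)),
      end_bp = round(purrr::map2_dbl(.data$chr, .data$ci_hi, project))
    )
}

#' Intersect DEGs, QTL intervals and significant SNPs into candidate genes
#'
#' A gene is a candidate when (i) it is a DEG, (ii) its body overlaps a QTL
#' support interval, (iii) it carries at least one FDR-significant SNP, and
#' (iv) — if an externally supplied enrichment list is given — it appears in
#' that list.  Provenance (which locus, which SNP sites) is recorded per
#' candidate.  All coordinates must be physical, 1-based inclusive; passing
#' genetic (cM) intervals is an error — project them first with
#' [qtl_to_physical()].
#'
#' @param degs Tibble from [deg_filter()] (`gene`, `deg`).
#' @param qtl_intervals Tibble with `chr`, `start_bp`, `end_bp` and
#'   optionally `locus`.
#' @param snp_sites Tibble from [bsa_site_stats()] with `chr`, `pos_bp` and
#'   `significant` (or a `site` id column).
#' @param gene_coords Tibble with `gene`, `chr`, `start_bp`, `end_bp`.
#' @param enriched Optional character vector of gene ids from an external
#'   GO/KEGG enrichment.
#' @return Tibble with one row per candidate: `gene`, `chr`, `start_bp`,
#'   `end_bp`, `locus` (list of overlapping loci), `n_significant_snps`,
#'   `snp_sites` (list column).
#' @export
candidate_genes <- function(degs, qtl_intervals, snp_sites, gene_coords,
                            enriched = NULL) {
  if (!all(c("start_bp", "end_bp") %in% names(qtl_intervals))) {
    if (all(c("ci_lo", "ci_hi") %in% names(qtl_intervals))) {
      abort(paste0("`qtl_intervals` carries genetic (cM) bounds; project to ",
                   "physical coordinates with qtl_to_physical() first."))
    }
    abort("`qtl_intervals` needs physical `start_bp`/`end_bp` columns.")
  }
  stopifnot(all(c("gene", "deg") %in% names(degs)),
            all(c("gene", "chr", "start_bp", "end_bp") %in% names(gene_coords)),
            all(c("chr", "pos_bp") %in% names(snp_sites)))
  if (!"significant" %in% names(snp_sites)) {
    abort("`snp_sites` needs a `significant` column (see bsa_site_stats()).")
  }
  if (!"locus" %in% names(qtl_intervals)) {
    qtl_intervals$locus <- seq_len(nrow(qtl_intervals))
  }
  sig <- snp_sites[snp_sites$significant & !is.na(snp_sites$significant), ]
  deg_ids <- degs$gene[degs$deg]
  if (!is.null(enriched)) deg_ids <- intersect(deg_ids, enriched)
  g <- gene_coords[gene_coords$gene %in% deg_ids, ]
  if (!nrow(g) || !nrow(sig)) return(empty_candidates())

  purrr::pmap_dfr(g, function(gene, chr, start_bp, end_bp, ...) {
    loci <- qtl_intervals$locus[qtl_intervals$chr == chr &
                                  qtl_intervals$start_bp <= end_bp &
                                  qtl_intervals$end_bp >= start_bp]
    if (!length(loci)) return(empty_candidates())
    hits <- sig[sig$chr == chr & sig$pos_bp >= start_bp & sig$pos_bp <= end_bp, ]
    if (!nrow(hits)) return(empty_candidates())
    tibble::tibble(
      gene = gene, chr = chr, start_bp = start_bp, end_bp = end_bp,
      locus = list(unique(loci)),
      n_significant_snps = nrow(hits),
      snp_sites = list(if ("site" %in% names(hits)) hits$site else hits$pos_bp)
    )
  })
}

empty_candidates <- function() {
  tibble::tibble(
    gene = character(), chr = character(),
    start_bp = numeric(), end_bp = numeric(),
    locus = list(), n_significant_snps = integer(), snp_sites = list()
  )
}
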