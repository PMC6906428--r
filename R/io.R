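# Delimited-text readers/writers.  Delimiter follows the file extension
# (.csv -> comma, anything else -> tab); readers validate rather than coerce.

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

write_delim_auto <- function(x, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(x, path, delim = delim)
  invisible(path)
}

#' Read a long-format dry-weight table
#'
#' Expects columns `line_id`, `environment`, `dap`, `weight_g` (comma- or
#' tab-delimited, chosen by extension).  Duplicate (line, environment, dap)
#' rows and negative weights are errors, named in the message.
#'
#' @param path File path.
#' @return Validated tibble.
#' @export
read_weight_table <- function(path) {
  validate_weight_table(read_delim_auto(path))
}

#' @rdname read_weight_table
#' @param data Weight table to write.
#' @export
write_weight_table <- function(data, path) {
  write_delim_auto(validate_weight_table(data), path)
}

#' Read a RIL genotype matrix
#'
#' First column `line_id`, remaining columns markers, values coded `"A"`
#' (parent-1 homozygote), `"B"` (parent-2 homozygote) or missing (`NA`,
#' empty, `"-"` or `"."`).  Residual heterozygote calls (`"H"`) are recoded
#' to `NA` with a reported count — RILs carry no heterozygote class.  Any
#' other symbol is an error listing the offending codes.
#'
#' @param path File path.
#' @return Character matrix lines x markers with an attribute
#'   `n_het_recoded`.
#' @export
read_genotypes <- function(path) {
  d <- read_delim_auto(path)
  if (names(d)[1] != "line_id") abort("Genotype file must start with a `line_id` column.")
  g <- as.matrix(d[-1])
  mode(g) <- "character"
  g[g %in% c("", "-", ".", "NA")] <- NA_character_
  n_het <- sum(g == "H", na.rm = TRUE)
  if (n_het > 0) {
    warn(sprintf("%d heterozygote call(s) recoded to NA.", n_het))
    g[!is.na(g) & g == "H"] <- NA_character_
  }
  bad <- unique(g[!is.na(g) & !(g %in% c("A", "B"))])
  if (length(bad)) {
    abort(paste0("Unknown genotype code(s): ", paste(bad, collapse = ", ")))
  }
  rownames(g) <- d$line_id
  attr(g, "n_het_recoded") <- n_het
  g
}

#' @rdname read_genotypes
#' @param geno Genotype matrix to write (rownames are line ids).
#' @export
write_genotypes <- function(geno, path) {
  d <- dplyr::bind_cols(
    tibble::tibble(line_id = rownames(geno)),
    tibble::as_tibble(geno)
  )
  write_delim_auto(d, path)
}

#' Read a genetic map
#'
#' Columns `marker`, `chr`, `cm`; marker ids must be unique and positions
#' non-decreasing within chromosome.
#'
#' @param path File path.
#' @return Tibble map.
#' @export
read_map <- function(path) {
  d <- read_delim_auto(path)
  need <- setdiff(c("marker", "chr", "cm"), names(d))
  if (length(need)) abort(paste0("Map lacks column(s): ", paste(need, collapse = ", ")))
  if (anyDuplicated(d$marker)) abort("Map marker ids must be unique.")
  if (any(d$cm < 0)) abort("Map positions must be non-negative cM.")
  if (any(unlist(tapply(d$cm, d$chr, diff)) < 0)) {
    abort("Map positions must be non-decreasing within chromosome.")
  }
  d
}

#' @rdname read_map
#' @param map Map tibble to write.
#' @export
write_map <- function(map, path) write_delim_auto(map, path)

#' Read a gene x sample count table
#'
#' First column `gene`, remaining columns samples; all counts must be
#' non-negative integers.
#'
#' @param path File path.
#' @return Integer matrix genes x samples.
#' @export
read_counts <- function(path) {
  d <- read_delim_auto(path)
  if (names(d)[1] != "gene") abort("Count table must start with a `gene` column.")
  m <- as.matrix(d[-1])
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    abort("Counts must be non-negative integers with no missing values.")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- d$gene
  m
}

#' @rdname read_counts
#' @param counts Count matrix to write (rownames are gene ids).
#' @export
write_counts <- function(counts, path) {
  d <- dplyr::bind_cols(tibble::tibble(gene = rownames(counts)),
                        tibble::as_tibble(counts))
  write_delim_auto(d, path)
}

#' Read per-site bulk allele depths from a delimited table
#'
#' Columns `chr`, `pos_bp`, `ref_high`, `alt_high`, `ref_low`, `alt_low`
#' (optional `site`).  Positions are 1-based.
#'
#' @param path File path.
#' @return Validated tibble of bulk site counts.
#' @export
read_bulk_sites <- function(path) {
  d <- read_delim_auto(path)
  need <- setdiff(c("chr", "pos_bp"), names(d))
  if (length(need)) abort(paste0("Bulk site table lacks column(s): ",
                                 paste(need, collapse = ", ")))
  validate_sites(d)
}

#' @rdname read_bulk_sites
#' @param sites Site table to write.
#' @export
write_bulk_sites <- function(sites, path) write_delim_auto(sites, path)

#' Read bulk allele depths from a two-sample VCF
#'
#' Extracts per-site reference/alternate read depths from the `AD` FORMAT
#' subfield of the two bulk sample columns.  Only biallelic SNP records with
#' an `AD` field are used; multi-allelic and AD-less records are skipped,
#' with counts reported.  VCF positions are 1-based per the standard and are
#' kept as such.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @param bulk_high,bulk_low Sample names of the high and low bulks; default
#'   the first and second sample columns.
#' @return Tibble `site`, `chr`, `pos_bp`, `ref_high`, `alt_high`,
#'   `ref_low`, `alt_low`, with attributes `n_skipped_multiallelic` and
#'   `n_skipped_no_ad`.
#' @export
read_bulk_vcf <- function(path, bulk_high = NULL, bulk_low = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  if (length(samples) < 2) abort("VCF must contain two bulk sample columns.")
  bulk_high <- bulk_high %||% samples[1]
  bulk_low <- bulk_low %||% samples[2]
  if (!all(c(bulk_high, bulk_low) %in% samples)) {
    abort("Bulk sample name(s) not present in the VCF.")
  }
  fix <- tibble::as_tibble(vcfR::getFIX(v))
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | fix$ALT == ""
  ad <- vcfR::extract.gt(v, element = "AD")
  no_ad <- is.na(ad[, bulk_high]) | is.na(ad[, bulk_low])
  keep <- !multi & !no_ad
  split_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    list(ref = as.integer(vapply(parts, `[`, "", 1)),
         alt = as.integer(vapply(parts, function(p) p[2] %||% NA_character_, "")))
  }
  hi <- split_ad(ad[keep, bulk_high])
  lo <- split_ad(ad[keep, bulk_low])
  out <- tibble::tibble(
    site = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
                  paste0(fix$CHROM[keep], ":", fix$POS[keep]), fix$ID[keep]),
    chr = fix$CHROM[keep],
    pos_bp = as.integer(fix$POS[keep]),
    ref_high = hi$ref, alt_high = hi$alt,
    ref_low = lo$ref, alt_low = lo$alt
  )
  attr(out, "n_skipped_multiallelic") <- sum(multi)
  attr(out, "n_skipped_no_ad") <- sum(no_ad & !multi)
  validate_sites(out)
}
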