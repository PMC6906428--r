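#' Kosambi map function and its inverse
#'
#' Converts a meiotic recombination fraction `r` into genetic distance
#' `d = 25 * log((1 + 2r) / (1 - 2r))` centimorgans, allowing for crossover
#' interference, and back via `r = (exp(d/25) - 1) / (2 * (exp(d/25) + 1))`
#' (equivalently `r = tanh(d/50) / 2`).
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param d Genetic distance(s) in cM, `>= 0`.
#' @return `kosambi_cm()`: distance in cM; `kosambi_r()`: recombination
#'   fraction.
#' @export
#' @examples
#' kosambi_cm(0.2)        # 21.18 cM
#' kosambi_r(kosambi_cm(0.2))
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) {
    abort("Recombination fraction must lie in [0, 0.5) for a finite Kosambi distance.")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @export
kosambi_r <- function(d) {
  if (any(d < 0)) abort("Genetic distance must be non-negative.")
  tanh(d / 50) / 2
}

#' Observed recombination between RIL genotypes
#'
#' In a recombinant inbred line produced by repeated selfing, recombination
#' accumulates over generations: a meiotic recombination fraction `r` between
#' two loci is observed as a discordance `R = 2r / (1 + 2r)` between the
#' fixed genotypes.  `ril_observed()` maps meiotic to observed; `ril_r()`
#' inverts it, `r = R / (2 * (1 - R))`.
#'
#' @param r Meiotic recombination fraction in `[0, 0.5)`.
#' @param R Observed RIL discordance fraction in `[0, 0.5)` (values at or
#'   above 2/3, the unlinked expectation, have no finite preimage).
#' @return The transformed fraction.
#' @export
ril_observed <- function(r) 2 * r / (1 + 2 * r)

#' @rdname ril_observed
#' @export
ril_r <- function(R) R / (2 * (1 - R))
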