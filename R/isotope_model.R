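#' @title Peptide isotopomer forward model
#' @description Elemental compositions of tryptic peptides, their natural
#'   mass-isotopomer distributions, and the distribution after metabolic
#'   deuterium incorporation at a given body-water enrichment.  This forward
#'   model underlies both the synthetic-data generator and the physical
#'   interpretation of the total-labeling plateau.
#' @name isotope_model
NULL

#' Elemental composition of a peptide from its sequence
#'
#' Standard peptide condensation: the sum of residue formulas plus one water
#' for the termini.
#'
#' @param sequence Non-empty string of standard one-letter residue codes.
#' @param residues Residue table from [residue_table()].
#' @return Named numeric vector of atom counts (C, H, N, O, S) for the
#'   neutral molecule.
#' @examples
#' composition_from_sequence("GG")  # C4 H8 N2 O3
#' @export
composition_from_sequence <- function(sequence, residues = residue_table()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty peptide sequence")
  aa <- strsplit(sequence, "")[[1]]
  idx <- match(aa, residues$residue)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("unknown residue '", aa[bad], "' at position ", bad,
         " in sequence ", sequence)
  }
  comp <- colSums(residues[idx, .elements, drop = FALSE])
  comp["H"] <- comp["H"] + 2  # terminal H2O
  comp["O"] <- comp["O"] + 1
  comp
}

# Truncated convolution: first n coefficients of the product of two
# truncated probability-generating vectors.  Truncation is exact for the
# retained coefficients (dropped entries only feed higher masses).
conv_trunc <- function(a, b, n) {
  la <- min(length(a), n)
  out <- numeric(n)
  for (i in seq_len(la)) {
    if (a[i] == 0) next
    lb <- min(length(b), n - i + 1L)
    if (lb < 1L) break
    j <- seq_len(lb)
    out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
  }
  out
}

# pmf of the summed mass offset of `count` atoms of one element, truncated
# to offsets 0..n-1, by binary-exponentiation of the single-atom pmf.
element_pmf <- function(single, count, n) {
  out <- c(1, numeric(n - 1L))
  base <- conv_trunc(single, c(1, numeric(n - 1L)), n)
  while (count > 0) {
    if (count %% 2 == 1) out <- conv_trunc(out, base, n)
    base <- conv_trunc(base, base, n)
    count <- count %/% 2
  }
  out
}

#' Natural mass-isotopomer distribution of a composition
#'
#' Abundances of the M+0 .. M+(n_iso-1) nominal-mass isotopologues under
#' natural isotope abundances, obtained by convolving per-element
#' distributions.  The vector is deliberately not renormalised: the mass
#' lost beyond M+(n_iso-1) is reported in the `truncation` attribute.
#'
#' @param comp Named atom-count vector as from [composition_from_sequence()],
#'   or a formula string.
#' @param n_iso Number of isotopomers to retain (default 6, i.e. M+0..M+5);
#'   must be at least 2.
#' @param abundances Isotope-abundance set, see [natural_abundances()].
#' @return Numeric vector `m0..m(n_iso-1)` with attribute `truncation`
#'   (the probability mass beyond the last retained isotopomer).
#' @examples
#' natural_distribution(c(C = 1, H = 0, N = 0, O = 0, S = 0))
#' natural_distribution("C4H8N2O3")  # di-glycine
#' @export
natural_distribution <- function(comp, n_iso = 6L,
                                 abundances = natural_abundances()) {
  if (is.character(comp)) comp <- parse_formula(comp)
  if (n_iso < 2) stop("n_iso must be >= 2")
  if (any(comp < 0)) stop("negative atom counts")
  comp <- comp[.elements]
  comp[is.na(comp)] <- 0
  out <- c(1, numeric(n_iso - 1L))
  for (el in .elements) {
    if (comp[[el]] > 0) {
      out <- conv_trunc(out, element_pmf(abundances[[el]], comp[[el]], n_iso),
                        n_iso)
    }
  }
  names(out) <- paste0("m", seq_len(n_iso) - 1L)
  attr(out, "truncation") <- max(0, 1 - sum(out))
  out
}

#' Exchangeable hydrogens of a peptide
#'
#' Sum over residues of the mean number of C-bound hydrogens that
#' equilibrate with body water; this finite site count is what makes the
#' labeling plateau physically interpretable.
#'
#' @inheritParams composition_from_sequence
#' @return Non-negative numeric count (residue-table values are averages,
#'   so the sum is generally non-integer).
#' @examples
#' exchangeable_hydrogens("GG")  # 2 * 2.06
#' @export
exchangeable_hydrogens <- function(sequence, residues = residue_table()) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  aa <- strsplit(sequence, "")[[1]]
  idx <- match(aa, residues$residue)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("residue '", aa[bad], "' at position ", bad,
         " missing from exchangeable-hydrogen table")
  }
  sum(residues$exchangeable_H[idx])
}

# Deuterium-incorporation pmf for a possibly non-integer site count:
# binomial pmfs at the two bracketing integers, linearly interpolated by
# the fractional part (site-count tables are residue averages).
label_pmf <- function(n_eh, p_w, n_iso) {
  lo <- floor(n_eh)
  hi <- ceiling(n_eh)
  w <- n_eh - lo
  k <- seq_len(n_iso) - 1L
  pmf <- (1 - w) * stats::dbinom(k, size = lo, prob = p_w)
  if (w > 0) pmf <- pmf + w * stats::dbinom(k, size = hi, prob = p_w)
  pmf
}

#' Isotopomer distribution after metabolic deuterium labeling
#'
#' Convolves the natural distribution with a binomial deuterium-incorporation
#' distribution over the peptide's exchangeable sites, each site labeled
#' independently at the body-water enrichment (single-compartment precursor
#' assumption, no isotope-effect correction).  Reduces exactly to the
#' natural distribution when `p_w = 0` or `n_eh = 0`.
#'
#' @inheritParams natural_distribution
#' @param n_eh Exchangeable-hydrogen count (>= 0, may be non-integer; the
#'   two bracketing binomials are interpolated by the fractional part).
#' @param p_w Body-water deuterium enrichment as a fraction in `[0, 0.5)`.
#' @return As [natural_distribution()].
#' @export
labeled_distribution <- function(comp, n_eh, p_w, n_iso = 6L,
                                 abundances = natural_abundances()) {
  if (!is.numeric(p_w) || length(p_w) != 1L || p_w < 0 || p_w >= 0.5) {
    stop("p_w must be a single fraction in [0, 0.5)")
  }
  if (n_eh < 0) stop("n_eh must be >= 0")
  nat <- natural_distribution(comp, n_iso = n_iso, abundances = abundances)
  if (p_w == 0 || n_eh == 0) return(nat)
  out <- conv_trunc(nat, label_pmf(n_eh, p_w, n_iso), n_iso)
  names(out) <- names(nat)
  attr(out, "truncation") <- max(0, 1 - sum(out))
  out
}

#' Asymptotic (plateau) total labeling of a peptide
#'
#' The total labeling `I = 1 - M0 / sum(Mj)` of the fully labeled
#' distribution: the plateau a peptide's enrichment curve approaches once
#' the whole protein pool has turned over at body-water enrichment `p_w`.
#' At `p_w = 0` it equals the natural-abundance baseline exactly.
#'
#' @inheritParams labeled_distribution
#' @return Fraction in `[0, 1)`.
#' @export
asymptotic_labeling <- function(comp, n_eh, p_w, n_iso = 6L,
                                abundances = natural_abundances()) {
  d <- labeled_distribution(comp, n_eh, p_w, n_iso = n_iso,
                            abundances = abundances)
  total_labeling(d)
}
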