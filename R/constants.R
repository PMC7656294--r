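#' Natural isotope abundances used throughout the package
#'
#' One fixed, published standard-abundance set (IUPAC 2013 representative
#' values) so that every isotopomer computation in the package is
#' bit-reproducible.  Each element maps to a numeric vector of isotopologue
#' probabilities indexed by nominal-mass offset (position 1 = offset 0).
#' Offsets with no stable isotope (e.g. 35S) carry probability 0.
#'
#' @return Named list with elements `C`, `H`, `N`, `O`, `S`.
#' @examples
#' natural_abundances()$C  # 12C, 13C
#' @export
natural_abundances <- function() {
  list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
  )
}

.elements <- c("C", "H", "N", "O", "S")

#' Residue composition and exchangeable-hydrogen table
#'
#' Reads the packaged per-residue table: elemental formula of each amino-acid
#' residue (amino acid minus one water) and the mean number of C-bound
#' hydrogens that equilibrate with body water during amino-acid metabolism
#' (the values commonly used in heavy-water proteomics, e.g. Ala 4.00,
#' Gly 2.06, Leu 0.60).  The exchangeable counts are literature-style
#' averages, not measurements from any one study; they can be overridden by
#' supplying a file with the same three columns.
#'
#' @param path Optional path to a replacement TSV with columns
#'   `residue`, `formula`, `exchangeable_H`.
#' @return data.frame with columns `residue`, `formula`, `exchangeable_H`
#'   plus parsed atom counts `C`, `H`, `N`, `O`, `S`.
#' @export
residue_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "residue_composition.tsv",
                        package = "proturn", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "formula", "exchangeable_H")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("residue table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(nchar(tab$residue) == 1L)) {
    stop("residue codes must be single letters")
  }
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  miss_res <- setdiff(std, tab$residue)
  if (length(miss_res)) {
    stop("residue table must cover all 20 standard residues; missing: ",
         paste(miss_res, collapse = ", "))
  }
  if (any(tab$exchangeable_H < 0)) stop("exchangeable_H values must be >= 0")
  counts <- t(vapply(tab$formula, parse_formula, numeric(length(.elements))))
  rownames(counts) <- NULL
  cbind(tab, as.data.frame(counts))
}

#' Parse a Hill-style elemental formula
#'
#' @param formula String such as `"C6H11NO"`; element symbols restricted to
#'   C, H, N, O, S; an omitted count means 1.
#' @return Named numeric vector of atom counts over C, H, N, O, S.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  out <- stats::setNames(numeric(length(.elements)), .elements)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    if (!el %in% .elements) {
      stop("unsupported element '", el, "' in formula ", formula)
    }
    out[el] <- out[el] + if (nzchar(n)) as.numeric(n) else 1
  }
  out
}
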