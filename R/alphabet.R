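#' Sequence alphabets
#'
#' An alphabet is an ordered set of single-character symbols plus a gap
#' symbol and one or more named orderings (permutations of the symbols)
#' used to arrange the y-axis of a sequence bundle, e.g. by hydrophobicity.
#'
#' @param name Alphabet name.
#' @param symbols Character vector of distinct single characters.
#' @param gap_symbol Gap character; must not be one of `symbols`.
#' @param orderings Named list of permutations of `symbols`. An
#'   "alphabetical" ordering is added automatically if absent.
#' @return An object of class `bk_alphabet`.
#' @export
alphabet <- function(name, symbols, gap_symbol = "-", orderings = list()) {
  symbols <- as.character(symbols)
  if (any(nchar(symbols) != 1L))
    bk_stop("alphabet_error", "alphabet symbols must be single characters")
  if (anyDuplicated(symbols))
    bk_stop("alphabet_error", "alphabet symbols must be unique")
  if (nchar(gap_symbol) != 1L || gap_symbol %in% symbols)
    bk_stop("alphabet_error",
            "gap symbol must be a single character outside the alphabet")
  if (!("alphabetical" %in% names(orderings)))
    orderings$alphabetical <- sort(symbols)
  for (nm in names(orderings)) {
    ord <- as.character(orderings[[nm]])
    if (!setequal(ord, symbols) || length(ord) != length(symbols))
      bk_stop("alphabet_error", sprintf(
        "ordering '%s' is not a permutation of the alphabet", nm))
    orderings[[nm]] <- ord
  }
  structure(list(name = name, symbols = symbols, gap_symbol = gap_symbol,
                 orderings = orderings),
            class = "bk_alphabet")
}

#' @export
print.bk_alphabet <- function(x, ...) {
  cat(sprintf("Alphabet '%s': %d symbols [%s], gap '%s'\n", x$name,
              length(x$symbols), paste(x$symbols, collapse = ""),
              x$gap_symbol))
  cat("orderings:", paste(names(x$orderings), collapse = ", "), "\n")
  invisible(x)
}

# Kyte-Doolittle hydropathy, ties broken alphabetically.
kyte_doolittle <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
  H = -3.2, D = -3.5, E = -3.5, N = -3.5, Q = -3.5, K = -3.9, R = -4.5)

#' Built-in alphabets
#'
#' Provides the standard "dna", "rna" and "protein" alphabets. The protein
#' alphabet carries three orderings: "alphabetical", "hydrophobicity"
#' (Kyte-Doolittle scale, most hydrophobic first) and "chemical-class"
#' (hydrophobic, aromatic, polar, positive, negative residues grouped).
#'
#' @return Named list of `bk_alphabet` objects.
#' @export
builtin_alphabets <- function() {
  aa <- names(kyte_doolittle)
  hydro <- aa[order(-kyte_doolittle, aa)]
  chem <- c("A", "V", "L", "I", "M", "P", "G",      # hydrophobic
            "F", "W", "Y",                          # aromatic
            "S", "T", "C", "N", "Q",                # polar
            "K", "R", "H",                          # positive
            "D", "E")                               # negative
  list(
    dna = alphabet("dna", c("A", "C", "G", "T")),
    rna = alphabet("rna", c("A", "C", "G", "U")),
    protein = alphabet("protein", sort(aa), orderings = list(
      hydrophobicity = hydro, `chemical-class` = chem))
  )
}
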