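#' Genetic code with configurable start codons
#'
#' Builds the codon translation table for an NCBI genetic-code table number
#' (default 11, bacterial/archaeal) together with the start- and stop-codon
#' sets used by the ORF finder.  The default start set is
#' `{ATG, GTG, TTG, CTG}`: methionine plus the common bacterial valine and
#' leucine alternative initiators.  Pass `full_alt_starts = TRUE` to admit
#' every valine (GTN) and leucine (TTA/TTG/CTN) codon as a start.
#'
#' Codons containing `N` are opaque: they never match a start or stop codon
#' and translate to `X`.
#'
#' @param table NCBI genetic-code table number (character or integer).
#' @param start_codons character vector of start codons; overrides the default.
#' @param full_alt_starts logical; use the full Val/Leu codon sets as starts.
#' @return an object of class `genetic_code`: a list with elements
#'   `translation` (named character vector codon -> amino acid),
#'   `start_codons` and `stop_codons`.
#' @examples
#' code <- genetic_code()
#' code$stop_codons
#' @export
genetic_code <- function(table = 11, start_codons = NULL, full_alt_starts = FALSE) {
  tr <- Biostrings::getGeneticCode(as.character(table))
  stops <- names(tr)[tr == "*"]
  if (is.null(start_codons)) {
    start_codons <- if (full_alt_starts) {
      c("ATG", "GTT", "GTC", "GTA", "GTG", "TTA", "TTG", "CTT", "CTC", "CTA", "CTG")
    } else {
      c("ATG", "GTG", "TTG", "CTG")
    }
  }
  start_codons <- toupper(start_codons)
  bad <- setdiff(start_codons, names(tr))
  if (length(bad)) stop_domain("invalid start codon(s): %s", paste(bad, collapse = ", "))
  start_codons <- setdiff(start_codons, stops)
  structure(
    list(translation = tr, start_codons = start_codons, stop_codons = stops),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code:", length(x$translation), "codons\n")
  cat("  start codons:", paste(x$start_codons, collapse = " "), "\n")
  cat("  stop codons: ", paste(x$stop_codons, collapse = " "), "\n")
  invisible(x)
}

# translate a vector of codons; N-containing/unknown codons -> X
translate_codons <- function(codons, code) {
  aa <- unname(code$translation[codons])
  aa[is.na(aa)] <- "X"
  aa
}
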