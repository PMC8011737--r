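# Six-frame ORF delimitation.
#
# A single pass per frame over the codon stream implements the finite state
# machine: outside any ORF, the first start codon (Met or an alternative
# Val/Leu initiator) opens a candidate; the next in-frame stop codon closes
# it.  Within each stop-terminated segment at most one ORF is reported
# (alternative starts are revisited later by the resize step).  Candidates
# opening at a Val/Leu codon are moved to the first in-frame methionine when
# the Met-to-stop span still satisfies the minimum length.

# adjust the opening codon index j of the segment (j .. stop_idx) to the
# first in-frame ATG when that keeps the ORF at least min_len_nt long
met_adjust <- function(codons, j, stop_idx, min_len_nt) {
  if (codons[j] == "ATG" || stop_idx - j < 2L) return(j)
  rel <- which(codons[(j + 1L):(stop_idx - 1L)] == "ATG")
  if (length(rel) == 0L) return(j)
  m <- j + rel[1L]
  if ((stop_idx - m + 1L) * 3L >= min_len_nt) m else j
}

#' Find candidate ORFs in all six frames
#'
#' Scans the contig once per frame on each strand.  Every maximal
#' start-to-stop span is reported at most once; the ORF opens at the first
#' methionine, valine or leucine start codon of its stop-terminated segment
#' and closes at (and includes) the next in-frame stop codon.  ORFs whose
#' span from the (possibly methionine-adjusted) start through the stop codon
#' is shorter than `min_len_nt` are discarded.  Codons containing `N` never
#' match a start or stop codon.
#'
#' @param genome a `genome_record`.
#' @param code a `genetic_code`.
#' @param min_len_nt minimum ORF length in nucleotides, stop included
#'   (default 60).
#' @return list of `orf` objects sorted by start coordinate.
#' @examples
#' g <- genome_record("c1", paste0("ATG", strrep("AAA", 20), "TAA"))
#' find_orfs(g, genetic_code())
#' @export
find_orfs <- function(genome, code, min_len_nt = 60L) {
  stopifnot(inherits(genome, "genome_record"), inherits(code, "genetic_code"))
  min_len_nt <- as.integer(min_len_nt)
  L <- nchar(genome$sequence)
  out <- list()
  if (L < 6L) return(out)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome$sequence else revcomp(genome$sequence)
    for (f in 0:2) {
      codons <- codon_vector(s, f + 1L)
      nc <- length(codons)
      if (nc == 0L) next
      is_stop <- codons %in% code$stop_codons
      is_start <- codons %in% code$start_codons
      prev <- 0L
      for (si in which(is_stop)) {
        seg <- which(is_start[(prev + 1L):si])
        if (length(seg)) {
          j <- prev + seg[1L]
          j <- met_adjust(codons, j, si, min_len_nt)
          if ((si - j + 1L) * 3L >= min_len_nt) {
            st_s <- f + (j - 1L) * 3L
            en_s <- f + si * 3L
            if (strand == "+") {
              start <- st_s; end <- en_s
            } else {
              start <- L - en_s; end <- L - st_s
            }
            out[[length(out) + 1L]] <-
              new_orf(genome$id, start, end, strand, f)
          }
        }
        prev <- si
      }
    }
  }
  out[order(vapply(out, `[[`, 0L, "start"), vapply(out, `[[`, 0L, "end"))]
}

#' Move a Val/Leu-initiated ORF to its first in-frame methionine
#'
#' If the ORF opens at an alternative (valine/leucine) start codon and an
#' in-frame ATG lies between start and stop such that the ATG-to-stop span
#' (stop codon included) is at least `min_len_nt`, the start is moved to that
#' first ATG.  Otherwise the ORF is returned unchanged.  Idempotent.
#'
#' @inheritParams find_orfs
#' @param orf a candidate `orf`.
#' @return the (possibly adjusted) `orf`.
#' @export
apply_met_preference <- function(orf, genome, code, min_len_nt = 60L) {
  codons <- orf_codons(orf, genome)
  j <- met_adjust(codons, 1L, length(codons), as.integer(min_len_nt))
  if (j > 1L) move_start(orf, j - 1L) else orf
}

#' Translate an ORF to its amino-acid sequence
#'
#' Translates all codons except the terminal stop, per the codon table
#' (alternative start codons are not forced to methionine).  Codons
#' containing `N` translate to `X`.
#'
#' @inheritParams apply_met_preference
#' @return single amino-acid string of length `(end - start)/3 - 1`.
#' @export
translate_orf <- function(orf, genome, code) {
  codons <- orf_codons(orf, genome)
  n <- length(codons)
  if (n < 2L) stop_domain("ORF too short to translate")
  aa <- translate_codons(codons[-n], code)
  if (any(aa == "*"))
    stop_domain("internal stop codon in ORF %s:[%d,%d)%s",
                orf$contig_id, orf$start, orf$end, orf$strand)
  paste(aa, collapse = "")
}
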