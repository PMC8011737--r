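#' Composite annotation accuracy
#'
#' Scores how well a database subject and an ORF query fit together,
#' combining alignment identity with the mutual coverage of subject and
#' query:
#'
#' \deqn{ACC = ID \cdot \frac{ML}{SL} \cdot \frac{ML}{OL}}
#'
#' where `ID` is the identity fraction, `ML` the aligned (match) length,
#' `SL` the subject length and `OL` the ORF length, all lengths in amino
#' acids.  When the query and subject match over their whole length
#' (`ML = SL = OL`) the accuracy equals the identity.  The value is always
#' in `[0, ID]`.
#'
#' @param identity identity fraction in `[0,1]`.
#' @param match_len_aa aligned length `ML` (aa), `0 < ML <= min(SL, OL)`.
#' @param subject_len_aa subject length `SL` (aa).
#' @param orf_len_aa ORF length `OL` (aa, stop codon excluded).
#' @return the accuracy fraction.
#' @examples
#' accuracy(0.97, 200, 200, 200)  # full-length match: ACC = ID
#' accuracy(0.90, 90, 100, 120)
#' @export
accuracy <- function(identity, match_len_aa, subject_len_aa, orf_len_aa) {
  if (any(subject_len_aa <= 0) || any(orf_len_aa <= 0))
    stop_domain("subject and ORF lengths must be positive")
  if (any(match_len_aa <= 0)) stop_domain("match length must be positive")
  if (any(identity < 0 | identity > 1)) stop_domain("identity must be in [0,1]")
  identity * (match_len_aa / subject_len_aa) * (match_len_aa / orf_len_aa)
}

# Levenshtein edit distance, two-row dynamic programme.
levenshtein <- function(a, b) {
  u <- utf8ToInt(a); v <- utf8ToInt(b)
  n <- length(u); m <- length(v)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    cost <- as.integer(u[i] != v)
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L, prev[j] + cost[j])
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Similarity score between two equal-length sequences
#'
#' \deqn{S = (L - D) / L}
#'
#' where `D` is the Levenshtein edit distance (substitutions, insertions,
#' deletions) and `L` the common string length.  Only equal-length strings
#' are compared; the score is 1 exactly when the strings are identical.
#' Used as the gate that validates start-site extension without a second
#' similarity search.
#'
#' @param a,b equal-length, non-empty strings (amino-acid sequences).
#' @return similarity fraction in `[0,1]`.
#' @examples
#' similarity_score("MKLV", "MKIV")  # one substitution: 0.75
#' @export
similarity_score <- function(a, b) {
  if (!is_string(a) || !is_string(b)) stop_domain("similarity_score expects two strings")
  L <- nchar(a)
  if (L == 0L) stop_domain("similarity_score is undefined for empty strings")
  if (nchar(b) != L) stop_domain("similarity_score compares only strings of equal length")
  (L - levenshtein(a, b)) / L
}

#' ORF length in amino acids
#'
#' The number of codons excluding the stop codon: the unit in which the
#' accuracy metric compares the ORF with subject and match lengths.
#'
#' @param orf an `orf`.
#' @return integer length in amino acids.
#' @examples
#' \dontrun{orf_len_aa(orf)  # a 66 nt ORF gives 21}
#' @export
orf_len_aa <- function(orf) (orf$end - orf$start) %/% 3L - 1L
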