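# Automatic start-site refinement against the best subject.
#
# Two cases: the query is longer than a fully-matched subject (shrink to an
# alternative downstream start), or shorter than a subject that fully covers
# the query (extend to an upstream start).  Extension is validated without a
# second similarity search: the upstream extension must translate to a tail
# at least `tail_similarity_min` similar to the corresponding subject region
# and must not contain an in-frame stop.  The stop codon, strand and frame
# are never changed; stop disagreements are only flagged.

#' Shrink an ORF towards the subject length
#'
#' When the subject matches over its entire length (`ML = SL`) but the ORF is
#' longer, moves the start to the in-frame alternative start codon (Met, Val
#' or Leu initiator) that brings the ORF length closest to the subject
#' length.  The move is applied only if it shortens the ORF, keeps it at
#' least `min_orf_nt` long, and does not cut into the aligned query span;
#' otherwise the ORF is returned unchanged.  Ties between equidistant
#' candidates keep the longer ORF.  Idempotent; never touches strand, frame
#' or stop.
#'
#' @param orf an `orf`.
#' @param entry the [hit_entry] whose subject guides the resize.
#' @param genome the `genome_record` the ORF lies on.
#' @param code a `genetic_code`.
#' @param thr a [thresholds] object.
#' @return the (possibly resized) `orf`.
#' @export
shrink_to_subject <- function(orf, entry, genome, code, thr = thresholds()) {
  ol <- orf_len_aa(orf)
  if (!(entry$match_len == entry$subject_len && ol > entry$subject_len)) return(orf)
  codons <- orf_codons(orf, genome)
  n <- length(codons)
  # the aligned query span is anchored on the coordinates the ORF had when it
  # was searched; start shifts applied since then consume part of the margin
  consumed <- if (orf$strand == "+") (orf$start - orf$orig_start) %/% 3L
              else (orf$orig_end - orf$end) %/% 3L
  kmax <- entry$start_query - consumed           # keep the aligned span intact
  if (kmax < 1L) return(orf)
  ks <- which(codons[2:(n - 1L)] %in% code$start_codons)  # shift by k keeps codon k+1
  ks <- ks[ks <= kmax & (n - ks) * 3L >= thr$min_orf_nt]
  if (!length(ks)) return(orf)
  dist <- abs((ol - ks) - entry$subject_len)
  if (min(dist) >= abs(ol - entry$subject_len)) return(orf)  # must move closer
  best <- ks[order(dist, ks)][1L]   # tie: smaller shift = longer ORF
  move_start(orf, best)
}

#' Extend an ORF towards the subject length
#'
#' When the query is fully covered by a longer subject (`ML = OL < SL`),
#' searches upstream in-frame start codons (within `SL - OL` plus a 10-codon
#' slack).  A candidate is accepted only if the new length is closer to the
#' subject length, the extension region contains no in-frame stop, and its
#' translation is at least `tail_similarity_min` similar (Levenshtein
#' similarity) to the subject region of equal length immediately upstream of
#' the matched span.  Otherwise the ORF is unchanged.
#'
#' @inheritParams shrink_to_subject
#' @param slack_codons extra upstream codons searched beyond `SL - OL`
#'   (default 10).
#' @param region `"adjacent"` compares the extension with the subject region
#'   immediately upstream of the match; `"prefix"` with the subject's first
#'   residues.  The two coincide when the query aligns to the subject's
#'   suffix.
#' @return the (possibly extended) `orf`.
#' @export
extend_to_subject <- function(orf, entry, genome, code, thr = thresholds(),
                              slack_codons = 10L, region = c("adjacent", "prefix")) {
  region <- match.arg(region)
  ol <- orf_len_aa(orf)
  sl <- entry$subject_len
  if (!(entry$match_len == ol && ol < sl)) return(orf)
  L <- nchar(genome$sequence)
  kmax <- min(sl - ol + as.integer(slack_codons),
              entry$start_match,                       # need a subject region to compare
              2L * (sl - ol))                          # must end up closer to SL
  if (orf$strand == "+") kmax <- min(kmax, orf$start %/% 3L)
  else kmax <- min(kmax, (L - orf$end) %/% 3L)
  if (kmax < 1L) return(orf)
  ext_nt <- if (orf$strand == "+") {
    substr(genome$sequence, orf$start - 3L * kmax + 1L, orf$start)
  } else {
    revcomp(substr(genome$sequence, orf$end + 1L, orf$end + 3L * kmax))
  }
  ext_codons <- codon_vector(ext_nt)   # kmax codons, last is adjacent to current start
  best <- NULL; best_dist <- Inf
  for (k in seq_len(kmax)) {
    cods <- ext_codons[(kmax - k + 1L):kmax]
    if (!(cods[1L] %in% code$start_codons)) next
    if (any(cods %in% code$stop_codons)) next
    sub_region <- if (region == "adjacent") {
      substr(entry$subject_seq, entry$start_match - k + 1L, entry$start_match)
    } else {
      substr(entry$subject_seq, 1L, k)
    }
    if (nchar(sub_region) != k) next
    tail_aa <- paste(translate_codons(cods, code), collapse = "")
    if (similarity_score(tail_aa, sub_region) < thr$tail_similarity_min) next
    d <- abs((ol + k) - sl)
    if (d < best_dist || (d == best_dist && !is.null(best) && k > best)) {
      best <- k; best_dist <- d
    }
  }
  if (is.null(best) || best_dist >= abs(ol - sl)) return(orf)
  extend_start(orf, best)
}

#' Flag a stop-site disagreement between query and subject
#'
#' TRUE when the aligned ends do not reach both the query end and the
#' subject end, i.e. the database product predicts a stop ahead of (or
#' beyond) the ORF stop.  Nothing is changed automatically: stop-site
#' alteration is out of scope, the disagreement is only recorded.
#'
#' @param orf an `orf`.
#' @param entry the scored [hit_entry].
#' @return logical.
#' @export
flag_unmatched_stop <- function(orf, entry) {
  !(entry$end_query == orf_len_aa(orf) && entry$end_match == entry$subject_len)
}
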