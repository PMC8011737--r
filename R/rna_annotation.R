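# tRNA/rRNA annotation by similarity to reference sequence sets.
#
# Plain Smith-Waterman matching of each reference against both strands with
# identity and coverage gates; covariance-model search is explicitly out of
# scope.  RNA features never enter CDS overlap cleaning — they are appended
# to the final EMBL.

dna_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3, baseOnly = FALSE)
    cache
  }
})

#' Annotate tRNA and rRNA features from reference sequences
#'
#' Aligns each reference locally against both strands of the contig.  Hits
#' with identity at least `min_identity` over at least `min_cov` of the
#' reference length become [feature_record]s (kind from the reference,
#' product from the reference id).  After each accepted hit the matched
#' region is masked and the search repeated, so multiple copies of a
#' reference are recovered; overlapping hits from the same reference keep
#' the best identity.
#'
#' @param genome a `genome_record`.
#' @param refs list of lists with `id`, `kind` (`"tRNA"`/`"rRNA"`) and
#'   `sequence` (DNA), e.g. from [read_rna_refs()].
#' @param min_identity minimum identity fraction (default 0.9).
#' @param min_cov minimum reference coverage fraction (default 0.9).
#' @return list of [feature_record] objects sorted by start.
#' @export
annotate_rna <- function(genome, refs, min_identity = 0.9, min_cov = 0.9) {
  if (!length(refs)) {
    warning("no RNA reference sequences supplied; nothing annotated")
    return(list())
  }
  L <- nchar(genome$sequence)
  feats <- list()
  for (ref in refs) {
    rlen <- nchar(ref$sequence)
    for (strand in c("+", "-")) {
      target <- if (strand == "+") genome$sequence else revcomp(genome$sequence)
      for (iter in seq_len(16L)) {
        pa <- Biostrings::pairwiseAlignment(
          pattern = Biostrings::DNAString(ref$sequence),
          subject = Biostrings::DNAString(target),
          type = "local", substitutionMatrix = dna_submat(),
          gapOpening = 5, gapExtension = 2)
        cols <- Biostrings::nchar(pa)
        if (cols == 0L) break
        ident <- Biostrings::nmatch(pa) / cols
        cov <- (BiocGenerics::end(Biostrings::pattern(pa)) -
                  BiocGenerics::start(Biostrings::pattern(pa)) + 1L) / rlen
        if (ident < min_identity || cov < min_cov) break
        s0 <- BiocGenerics::start(Biostrings::subject(pa)) - 1L
        e0 <- BiocGenerics::end(Biostrings::subject(pa))
        if (strand == "-") { tmp <- s0; s0 <- L - e0; e0 <- L - tmp }
        feats[[length(feats) + 1L]] <- feature_record(
          ref$kind, genome$id, s0, e0, strand,
          qualifiers = list(product = ref$id,
                            note = sprintf("identity=%.2f%%; coverage=%.2f%%",
                                           100 * ident, 100 * cov)))
        # mask the matched span and look for further copies
        ms <- BiocGenerics::start(Biostrings::subject(pa))
        me <- BiocGenerics::end(Biostrings::subject(pa))
        substr(target, ms, me) <- strrep("N", me - ms + 1L)
      }
    }
  }
  # deduplicate overlapping hits from the same reference, keeping best identity
  if (length(feats) > 1L) {
    keep <- rep(TRUE, length(feats))
    idn <- function(f) as.numeric(sub(".*identity=([0-9.]+)%.*", "\\1", f$qualifiers$note))
    for (i in seq_along(feats)) for (j in seq_along(feats)) {
      if (i == j || !keep[i] || !keep[j]) next
      a <- feats[[i]]; b <- feats[[j]]
      if (a$qualifiers$product == b$qualifiers$product &&
          a$contig_id == b$contig_id &&
          interval_overlap(a$start, a$end, b$start, b$end) > 0L &&
          idn(a) >= idn(b)) keep[j] <- FALSE
    }
    feats <- feats[keep]
  }
  feats[order(vapply(feats, `[[`, 0L, "start"))]
}
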