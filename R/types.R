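# Value objects shared across the package.  All genomic coordinates are
# 0-based half-open on the forward strand, whatever the feature strand;
# the EMBL 1-based inclusive + complement() convention is serialization only.

#' Construct a genome record
#'
#' @param id contig identifier (non-empty string).
#' @param sequence DNA sequence over `{A,C,G,T,N}`; lower case is folded up.
#' @param topology `"linear"` or `"circular"`.  Circular contigs are accepted
#'   but treated as linear: origin-spanning features are not modelled.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!is_string(id) || !nzchar(id)) stop_domain("contig id must be a non-empty string")
  sequence <- toupper(sequence)
  if (!is_string(sequence) || nchar(sequence) < 1L)
    stop_domain("contig '%s': sequence must be non-empty", id)
  if (grepl("[^ACGTN]", sequence))
    stop_domain("contig '%s': sequence contains characters outside {A,C,G,T,N}", id)
  structure(list(id = id, sequence = sequence, topology = topology),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %s\n", x$id, nchar(x$sequence), x$topology))
  invisible(x)
}

#' Construct a reference protein database entry
#'
#' Carries the annotation payload transferred onto a confirmed ORF: product
#' name, optional gene acronym, organism, and GO/EC/KEGG cross references.
#'
#' @param entry_id unique database accession.
#' @param product_name product description (e.g. `"DNA gyrase subunit A"`,
#'   or `"hypothetical protein"`).
#' @param sequence amino-acid sequence (20 standard residues plus `X`).
#' @param gene_name optional gene acronym (e.g. `"gyrA"`), `NULL` if absent.
#' @param organism source organism.
#' @param go_terms character vector of GO identifiers.
#' @param ec_numbers character vector of EC numbers.
#' @param kegg_pathways character vector of KEGG pathway identifiers.
#' @return an object of class `reference_protein`.
#' @export
reference_protein <- function(entry_id, product_name, sequence, gene_name = NULL,
                              organism = "unknown organism",
                              go_terms = character(0), ec_numbers = character(0),
                              kegg_pathways = character(0)) {
  if (!is_string(entry_id) || !nzchar(entry_id)) stop_domain("entry_id must be non-empty")
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop_domain("entry '%s': empty protein sequence", entry_id)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence))
    stop_domain("entry '%s': sequence outside the 20 standard amino acids + X", entry_id)
  if (!is.null(gene_name) && !nzchar(gene_name)) gene_name <- NULL
  structure(list(entry_id = entry_id, product_name = product_name,
                 gene_name = gene_name, organism = organism, sequence = sequence,
                 go_terms = as.character(go_terms), ec_numbers = as.character(ec_numbers),
                 kegg_pathways = as.character(kegg_pathways)),
            class = "reference_protein")
}

#' Construct a feature record
#'
#' The flat-file-facing representation of an annotated interval (CDS, tRNA or
#' rRNA).  Coordinates are 0-based half-open on the forward strand.
#'
#' @param kind `"CDS"`, `"tRNA"` or `"rRNA"`.
#' @param contig_id contig the feature lies on.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @param qualifiers named list (`product`, `gene`, `note`, `db_xref`,
#'   `EC_number`, `accuracy`, ...).
#' @return an object of class `feature_record`.
#' @export
feature_record <- function(kind, contig_id, start, end, strand,
                           qualifiers = list()) {
  kind <- match.arg(kind, c("CDS", "tRNA", "rRNA"))
  strand <- match.arg(strand, c("+", "-"))
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0L || end <= start) stop_domain("invalid interval [%d, %d)", start, end)
  structure(list(kind = kind, contig_id = contig_id, start = start, end = end,
                 strand = strand, qualifiers = qualifiers),
            class = "feature_record")
}

#' @export
print.feature_record <- function(x, ...) {
  cat(sprintf("<feature_record> %s %s:[%d,%d)%s %s\n", x$kind, x$contig_id,
              x$start, x$end, x$strand, x$qualifiers$product %||% ""))
  invisible(x)
}

#' Construct a similarity-search hit entry
#'
#' One similarity-search result for a translated ORF query against a
#' reference protein (the subject), with the alignment geometry needed by the
#' accuracy metric.  Amino-acid coordinates are 0-based half-open;
#' `match_len` is the alignment column count (equal to the aligned span on
#' both sides for gapless alignments; for gapped alignments both spans are at
#' most `match_len`).
#'
#' @param entry_id subject accession.
#' @param product_name subject product name.
#' @param subject_seq subject amino-acid sequence.
#' @param identity fraction of identical alignment columns, in `[0,1]`.
#' @param start_query,end_query aligned span on the query (aa, 0-based half-open).
#' @param start_match,end_match aligned span on the subject.
#' @param match_len alignment column count; defaults to the query span.
#' @param product_id,gene_name,organism,go_terms,kegg_pathways,ec_numbers
#'   annotation payload carried from the reference entry.
#' @param accuracy optional precomputed composite accuracy.
#' @return an object of class `hit_entry`.
#' @export
hit_entry <- function(entry_id, product_name, subject_seq, identity,
                      start_query, end_query, start_match, end_match,
                      match_len = NULL, product_id = entry_id, gene_name = NULL,
                      organism = "unknown organism", go_terms = character(0),
                      kegg_pathways = character(0), ec_numbers = character(0),
                      accuracy = NA_real_) {
  subject_seq <- toupper(subject_seq)
  sl <- nchar(subject_seq)
  if (sl < 1L) stop_domain("hit '%s': empty subject sequence", entry_id)
  if (is.na(identity) || identity < 0 || identity > 1)
    stop_domain("hit '%s': identity must be in [0,1]", entry_id)
  start_query <- as.integer(start_query); end_query <- as.integer(end_query)
  start_match <- as.integer(start_match); end_match <- as.integer(end_match)
  if (start_query < 0L || end_query <= start_query)
    stop_domain("hit '%s': invalid query span", entry_id)
  if (start_match < 0L || end_match <= start_match || end_match > sl)
    stop_domain("hit '%s': invalid subject span", entry_id)
  if (is.null(match_len)) match_len <- end_query - start_query
  match_len <- as.integer(match_len)
  if ((end_query - start_query) > match_len || (end_match - start_match) > match_len)
    stop_domain("hit '%s': aligned spans exceed the alignment column count", entry_id)
  if (match_len > sl)
    stop_domain("hit '%s': match length exceeds subject length", entry_id)
  if (!is.null(gene_name) && !nzchar(gene_name)) gene_name <- NULL
  structure(list(entry_id = entry_id, product_name = product_name,
                 product_id = product_id, gene_name = gene_name,
                 subject_seq = subject_seq, subject_len = sl,
                 start_query = start_query, end_query = end_query,
                 start_match = start_match, end_match = end_match,
                 match_len = match_len, identity = identity,
                 organism = organism, go_terms = as.character(go_terms),
                 kegg_pathways = as.character(kegg_pathways),
                 ec_numbers = as.character(ec_numbers), accuracy = accuracy),
            class = "hit_entry")
}

#' @export
print.hit_entry <- function(x, ...) {
  cat(sprintf("<hit_entry> %s '%s'%s id=%.3f ML=%d SL=%d acc=%s\n",
              x$entry_id, x$product_name,
              if (!is.null(x$gene_name)) sprintf(" (%s)", x$gene_name) else "",
              x$identity, x$match_len, x$subject_len,
              if (is.na(x$accuracy)) "NA" else sprintf("%.3f", x$accuracy)))
  invisible(x)
}

#' Is a hit entry a hypothetical/uncharacterized product?
#'
#' Product names containing "hypothetical" or "uncharacterized"
#' (case-insensitively) are demoted in every ranking rule.
#' @param entry a `hit_entry` (or anything with a `product_name`).
#' @return logical.
#' @export
is_hypothetical <- function(entry) {
  if (is.null(entry)) return(TRUE)
  grepl("hypothetical|uncharacterized", entry$product_name, ignore.case = TRUE)
}

has_gene <- function(entry) !is.null(entry) && !is.null(entry$gene_name) && nzchar(entry$gene_name)

#' Decision thresholds
#'
#' The tunable gates used throughout annotation and pre-curation, stored as
#' fractions in `[0,1]` (rendered as percentages only in reports).
#'
#' @param tolerance accuracy band below the best hit within which entries are
#'   considered equivalent (default 0.02).
#' @param borf_min_accuracy minimum accuracy for a blasted ORF to trigger
#'   overlap cleaning (default 0.90).
#' @param oorf_remove_accuracy blasted overlapping ORFs below this accuracy
#'   are removed during cleaning (default 0.80).
#' @param tail_similarity_min minimum tail similarity for start-site
#'   extension (default 0.90).
#' @param overlap_fraction_max overlap fraction of the other ORF's length
#'   above which it is removed (default 0.50).
#' @param low_accuracy_cutoff pre-curation low-accuracy filter cutoff
#'   (default 0.80).
#' @param min_orf_nt minimum ORF length in nucleotides, stop codon included
#'   (default 60).
#' @param min_overlap_nt overlaps shorter than this are ignored as
#'   biologically routine stop/start sharing (default 4).
#' @return an object of class `thresholds`.
#' @export
thresholds <- function(tolerance = 0.02, borf_min_accuracy = 0.90,
                       oorf_remove_accuracy = 0.80, tail_similarity_min = 0.90,
                       overlap_fraction_max = 0.50, low_accuracy_cutoff = 0.80,
                       min_orf_nt = 60L, min_overlap_nt = 4L) {
  fr <- c(tolerance = tolerance, borf_min_accuracy = borf_min_accuracy,
          oorf_remove_accuracy = oorf_remove_accuracy,
          tail_similarity_min = tail_similarity_min,
          overlap_fraction_max = overlap_fraction_max,
          low_accuracy_cutoff = low_accuracy_cutoff)
  if (any(fr < 0 | fr > 1))
    stop_domain("threshold fractions must lie in [0,1]")
  structure(list(tolerance = tolerance, borf_min_accuracy = borf_min_accuracy,
                 oorf_remove_accuracy = oorf_remove_accuracy,
                 tail_similarity_min = tail_similarity_min,
                 overlap_fraction_max = overlap_fraction_max,
                 low_accuracy_cutoff = low_accuracy_cutoff,
                 min_orf_nt = as.integer(min_orf_nt),
                 min_overlap_nt = as.integer(min_overlap_nt)),
            class = "thresholds")
}

#' @export
print.thresholds <- function(x, ...) {
  cat("Annotation thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# ---- ORF object ------------------------------------------------------------

new_orf <- function(contig_id, start, end, strand, frame,
                    status = "candidate", selected_entry = NULL,
                    candidates = list(), qualifiers = list(),
                    orig_start = NULL, orig_end = NULL) {
  structure(list(contig_id = contig_id, start = as.integer(start),
                 end = as.integer(end), strand = strand, frame = as.integer(frame),
                 status = status, selected_entry = selected_entry,
                 candidates = candidates, qualifiers = qualifiers,
                 # reference coordinates the hit-entry alignment spans refer to
                 orig_start = as.integer(orig_start %||% start),
                 orig_end = as.integer(orig_end %||% end)),
            class = "orf")
}

#' @export
print.orf <- function(x, ...) {
  cat(sprintf("<orf> %s:[%d,%d)%s frame=%d %s", x$contig_id, x$start, x$end,
              x$strand, x$frame, x$status))
  if (!is.null(x$selected_entry))
    cat(sprintf(" -> %s (acc %.3f)", x$selected_entry$entry_id,
                x$selected_entry$accuracy))
  cat("\n")
  invisible(x)
}

#' ORF length in nucleotides (stop codon included)
#' @param orf an `orf`.
#' @return integer length in nt.
#' @export
orf_nt_len <- function(orf) orf$end - orf$start

# accuracy of the selected entry, 0 when the ORF has no hit
orf_accuracy <- function(orf) {
  if (is.null(orf$selected_entry)) return(0)
  acc <- orf$selected_entry$accuracy
  if (is.na(acc)) 0 else acc
}

# validate structural ORF invariants against the genome
validate_orf <- function(orf, genome, code) {
  stopifnot(inherits(orf, "orf"))
  L <- nchar(genome$sequence)
  if (orf$start < 0L || orf$end > L) stop_domain("ORF outside contig bounds")
  if ((orf$end - orf$start) %% 3L != 0L) stop_domain("ORF length not divisible by 3")
  cods <- orf_codons(orf, genome)
  n <- length(cods)
  if (!(cods[n] %in% code$stop_codons)) stop_domain("ORF does not end in a stop codon")
  if (any(cods[-n] %in% code$stop_codons)) stop_domain("ORF contains an internal stop codon")
  invisible(TRUE)
}

# nucleotide sequence of the ORF read on its own strand
orf_strand_seq <- function(orf, genome) {
  s <- substr(genome$sequence, orf$start + 1L, orf$end)
  if (orf$strand == "-") revcomp(s) else s
}

# codons of the ORF on its own strand (last one is the stop)
orf_codons <- function(orf, genome) codon_vector(orf_strand_seq(orf, genome))

# move the ORF start k codons downstream on its own strand (k > 0 shrinks)
move_start <- function(orf, k) {
  if (orf$strand == "+") orf$start <- orf$start + 3L * k
  else orf$end <- orf$end - 3L * k
  orf
}

# grow the ORF start k codons upstream on its own strand
extend_start <- function(orf, k) move_start(orf, -k)
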