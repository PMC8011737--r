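# Independent oracles and small generators used across the suite.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

random_aa <- function(n) paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I",
                                        "K", "L", "M", "N", "P", "Q", "R", "S",
                                        "T", "V", "W", "Y"), n, replace = TRUE),
                               collapse = "")

rc <- function(x) chartr("ACGTN", "TGCAN",
                         paste(rev(strsplit(x, "")[[1]]), collapse = ""))

# Brute-force six-frame ORF scan by regular expression over a codon-spaced
# string: an entirely different route from the package's state machine.
oracle_find_orfs <- function(seq, min_len = 60L,
                             starts = c("ATG", "GTG", "TTG", "CTG")) {
  stops <- c("TAA", "TAG", "TGA")
  pat <- sprintf("(?<![ACGTN])(?:%s)(?: (?!%s)[ACGTN]{3})* (?:%s)",
                 paste(starts, collapse = "|"),
                 paste(stops, collapse = "|"),
                 paste(stops, collapse = "|"))
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc(seq)
    for (f in 0:2) {
      ncod <- (L - f) %/% 3L
      if (ncod < 2L) next
      cods <- substring(s, f + seq_len(ncod) * 3L - 2L, f + seq_len(ncod) * 3L)
      spaced <- paste(cods, collapse = " ")
      m <- gregexpr(pat, spaced, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      for (k in seq_along(m)) {
        j <- (m[k] - 1L) %/% 4L + 1L                    # first codon index
        q <- j + (attr(m, "match.length")[k] + 1L) %/% 4L - 1L  # stop codon index
        span <- cods[j:q]
        if (span[1] != "ATG") {
          mi <- which(span[-c(1L, length(span))] == "ATG")
          if (length(mi) && (length(span) - mi[1]) * 3L >= min_len)
            j <- j + mi[1]
        }
        if ((q - j + 1L) * 3L < min_len) next
        st_s <- f + (j - 1L) * 3L
        en_s <- f + q * 3L
        if (strand == "+") out[[length(out) + 1L]] <- c(st_s, en_s, 1L)
        else out[[length(out) + 1L]] <- c(L - en_s, L - st_s, -1L)
      }
    }
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, function(x) sprintf("%d:%d:%s", x[1], x[2],
                                       if (x[3] == 1L) "+" else "-"), ""))
}

orf_keys <- function(orfs) {
  sort(vapply(orfs, function(o) sprintf("%d:%d:%s", o$start, o$end, o$strand), ""))
}

# hit entry whose subject is matched over its entire length (ML = SL)
entry_full_subject <- function(subject_seq, id = "E1",
                               product = "ATP synthase subunit alpha",
                               gene = NULL, identity = 1, start_query = 0L,
                               accuracy = NA_real_) {
  sl <- nchar(subject_seq)
  hit_entry(id, product, subject_seq, identity,
            start_query = start_query, end_query = start_query + sl,
            start_match = 0L, end_match = sl,
            gene_name = gene, accuracy = accuracy)
}

# hit entry whose query is covered over its entire length (ML = OL < SL)
entry_full_query <- function(subject_seq, ol, start_match, id = "E1",
                             product = "ATP synthase subunit alpha",
                             gene = NULL, identity = 1, accuracy = NA_real_) {
  hit_entry(id, product, subject_seq, identity,
            start_query = 0L, end_query = ol,
            start_match = start_match, end_match = start_match + ol,
            gene_name = gene, accuracy = accuracy)
}

# build a genome string from codon blocks
cods <- function(...) paste(c(...), collapse = "")

# a confirmed orf with a selected entry, as the pre-curation passes see it
confirmed_orf <- function(contig, start, end, strand, entry,
                          candidates = list(entry), frame = NULL) {
  frame <- frame %||% (start %% 3L)
  o <- orfannot:::new_orf(contig, start, end, strand, frame, status = "confirmed",
                          orig_start = start, orig_end = end)
  o$selected_entry <- entry
  o$candidates <- candidates
  o
}

`%||%` <- function(a, b) if (is.null(a)) b else a
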