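# Similarity-search providers.
#
# A provider is a function taking a translated ORF (amino-acid string) and
# returning a list of hit_entry objects sorted by descending identity.  The
# built-in local provider aligns the query against every protein of a local
# reference database with Smith-Waterman (BLOSUM62, affine gaps); the
# fixture provider replays a scripted lookup table so engine behaviour can be
# tested deterministically.

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Search a query protein against a local reference database
#'
#' Smith-Waterman local alignment of the translated ORF against each
#' database protein (BLOSUM62, affine gap penalties in BLAST convention).
#' The best local alignment per protein becomes a [hit_entry] with
#' identity = identical columns / alignment columns and the aligned spans on
#' query and subject; the composite accuracy is computed against the query
#' length.  Entries below `min_identity` are dropped; ties are broken by
#' identity (descending), subject length (ascending), then entry id.
#'
#' @param query_aa translated ORF (amino-acid string, no stop).
#' @param db list of [reference_protein] objects.
#' @param max_hits maximum entries returned (default 10).
#' @param min_identity minimum identity fraction (default 0.3).
#' @param gap_open,gap_ext affine gap opening/extension penalties.
#' @return list of [hit_entry] objects sorted by descending identity.
#' @export
local_search <- function(query_aa, db, max_hits = 10L, min_identity = 0.3,
                         gap_open = 11, gap_ext = 1) {
  if (!is_string(query_aa) || !nzchar(query_aa)) stop_domain("empty query")
  if (length(db) == 0L) stop_domain("empty reference database")
  subjects <- Biostrings::AAStringSet(vapply(db, `[[`, "", "sequence"))
  pa <- Biostrings::pairwiseAlignment(
    pattern = subjects, subject = Biostrings::AAString(query_aa),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_ext)
  cols <- Biostrings::nchar(pa)
  nm <- Biostrings::nmatch(pa)
  ol <- nchar(query_aa)
  hits <- list()
  for (i in seq_along(db)) {
    if (cols[i] == 0L) next
    ident <- nm[i] / cols[i]
    if (ident < min_identity) next
    p <- db[[i]]
    # pattern = subject protein, subject = query in this call
    sm <- BiocGenerics::start(Biostrings::pattern(pa))[i] - 1L
    em <- BiocGenerics::end(Biostrings::pattern(pa))[i]
    sq <- BiocGenerics::start(Biostrings::subject(pa))[i] - 1L
    eq <- BiocGenerics::end(Biostrings::subject(pa))[i]
    h <- hit_entry(entry_id = p$entry_id, product_name = p$product_name,
                   subject_seq = p$sequence, identity = ident,
                   start_query = sq, end_query = eq,
                   start_match = sm, end_match = em,
                   match_len = cols[i], gene_name = p$gene_name,
                   organism = p$organism, go_terms = p$go_terms,
                   kegg_pathways = p$kegg_pathways, ec_numbers = p$ec_numbers)
    h$accuracy <- accuracy(ident, h$match_len, h$subject_len, ol)
    hits[[length(hits) + 1L]] <- h
  }
  if (!length(hits)) return(list())
  ord <- order(-vapply(hits, `[[`, 0, "identity"),
               vapply(hits, `[[`, 0L, "subject_len"),
               vapply(hits, `[[`, "", "entry_id"))
  utils::head(hits[ord], max_hits)
}

#' Scripted similarity search for deterministic tests
#'
#' Exact lookup of the query in a prebuilt table; misses return an empty
#' list.  Entries are validated at table construction time (see
#' [fixture_table()]).
#'
#' @param query_aa amino-acid query string.
#' @param table a named list mapping query strings to lists of [hit_entry].
#' @return the scripted list of [hit_entry], or `list()` on a miss.
#' @export
fixture_search <- function(query_aa, table) {
  table[[query_aa]] %||% list()
}

#' Build a validated fixture lookup table
#'
#' @param ... named arguments: `query string = list of hit_entry`.
#' @return the validated table, usable with [fixture_search()].
#' @export
fixture_table <- function(...) {
  table <- list(...)
  if (length(table) && (is.null(names(table)) || any(!nzchar(names(table)))))
    stop_domain("fixture table entries must be named by query string")
  for (entries in table) {
    for (e in entries) {
      if (!inherits(e, "hit_entry"))
        stop_domain("fixture table values must be lists of hit_entry objects")
    }
  }
  table
}

#' Search provider constructors
#'
#' A search provider is a function `query_aa -> list of hit_entry`.
#' `local_provider()` wraps [local_search()] over a fixed database;
#' `fixture_provider()` wraps [fixture_search()] over a scripted table.
#'
#' @param db list of [reference_protein] objects.
#' @param ... passed on to [local_search()].
#' @return a provider function.
#' @export
local_provider <- function(db, ...) {
  force(db)
  function(query_aa) local_search(query_aa, db, ...)
}

#' @rdname local_provider
#' @param table validated fixture table (see [fixture_table()]).
#' @export
fixture_provider <- function(table) {
  force(table)
  function(query_aa) fixture_search(query_aa, table)
}
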