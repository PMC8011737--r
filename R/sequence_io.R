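# Sequence and flat-file input/output.
#
# Internal coordinates are 0-based half-open on the forward strand; the EMBL
# 1-based inclusive convention with complement() for the minus strand exists
# only at (de)serialization time.

#' Read a genome FASTA file
#'
#' @param path FASTA file; one record per contig.
#' @return list of [genome_record] objects (id = first header token).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: %s", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop_domain("not a readable FASTA file: %s", path))
  if (length(set) == 0L) stop_domain("empty FASTA file: %s", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop_domain("duplicate contig id(s): %s", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lapply(seq_along(set), function(i) genome_record(ids[i], as.character(set[[i]])))
}

#' Read a structured protein reference database FASTA
#'
#' Header dialect:
#' `>entry_id|product name|gene=...|org=...|go=GO:...;GO:...|ec=...|kegg=...`
#' with empty optional fields allowed, so the full annotation payload
#' (product, gene acronym, organism, GO/EC/KEGG cross references) travels in
#' plain FASTA.
#'
#' @param path protein FASTA file.
#' @return list of [reference_protein] objects.
#' @export
read_protein_db <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: %s", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop_domain("not a readable FASTA file: %s", path))
  if (length(set) == 0L) stop_domain("empty protein database: %s", path)
  out <- lapply(seq_along(set), function(i) {
    fields <- strsplit(names(set)[i], "|", fixed = TRUE)[[1]]
    if (length(fields) < 2L)
      stop_domain("malformed protein header (need at least 'id|product'): %s", names(set)[i])
    kv <- list()
    if (length(fields) > 2L) {
      for (f in fields[-(1:2)]) {
        m <- regmatches(f, regexec("^([a-z]+)=(.*)$", f))[[1]]
        if (length(m) == 3L) kv[[m[2]]] <- m[3]
      }
    }
    split_tags <- function(x) if (is.null(x) || !nzchar(x)) character(0)
                              else strsplit(x, ";", fixed = TRUE)[[1]]
    reference_protein(
      entry_id = trimws(fields[1]), product_name = trimws(fields[2]),
      sequence = as.character(set[[i]]),
      gene_name = if (!is.null(kv$gene) && nzchar(kv$gene)) kv$gene else NULL,
      organism = kv$org %||% "unknown organism",
      go_terms = split_tags(kv$go), ec_numbers = split_tags(kv$ec),
      kegg_pathways = split_tags(kv$kegg))
  })
  ids <- vapply(out, `[[`, "", "entry_id")
  if (anyDuplicated(ids))
    stop_domain("duplicate entry id(s) in protein database: %s",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out
}

#' Write a protein reference database FASTA
#'
#' Inverse of [read_protein_db()].
#' @param db list of [reference_protein] objects.
#' @param path output file.
#' @export
write_protein_db <- function(db, path) {
  lines <- unlist(lapply(db, function(p) {
    hdr <- sprintf(">%s|%s|gene=%s|org=%s|go=%s|ec=%s|kegg=%s",
                   p$entry_id, p$product_name, p$gene_name %||% "",
                   p$organism, paste(p$go_terms, collapse = ";"),
                   paste(p$ec_numbers, collapse = ";"),
                   paste(p$kegg_pathways, collapse = ";"))
    c(hdr, p$sequence)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read tRNA/rRNA reference sequences
#'
#' FASTA with a `kind=tRNA` or `kind=rRNA` tag in each header
#' (e.g. `>tRNA-Ala kind=tRNA`); records without a tag default to tRNA.
#'
#' @param path FASTA file of RNA reference sequences (DNA alphabet).
#' @return list of lists with elements `id`, `kind`, `sequence`.
#' @export
read_rna_refs <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(set), function(i) {
    hdr <- names(set)[i]
    id <- strsplit(hdr, "\\s+")[[1]][1]
    kind <- if (grepl("kind=rRNA", hdr)) "rRNA" else "tRNA"
    list(id = id, kind = kind, sequence = toupper(as.character(set[[i]])))
  })
}

# ---- flat-file reading -----------------------------------------------------

parse_location <- function(loc, contig_len, what) {
  loc <- gsub("[<>]", "", trimws(loc))
  if (grepl("join|order", loc))
    stop_domain("unsupported multi-exon location '%s' (%s)", loc, what)
  strand <- "+"
  m <- regmatches(loc, regexec("^complement\\((.*)\\)$", loc))[[1]]
  if (length(m) == 2L) { strand <- "-"; loc <- m[2] }
  m <- regmatches(loc, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc))[[1]]
  if (length(m) != 3L) stop_domain("cannot parse location '%s' (%s)", loc, what)
  a <- as.integer(m[2]); b <- as.integer(m[3])
  if (a < 1L || b < a || b > contig_len)
    stop_domain("location '%s' outside contig bounds (%d bp)", loc, contig_len)
  list(start = a - 1L, end = b, strand = strand)
}

# parse one feature-table block (lines already stripped of FT/leading blanks)
parse_feature_block <- function(kind, loc, quals, contig_id, contig_len) {
  pos <- parse_location(loc, contig_len, kind)
  q <- list()
  for (ql in quals) {
    m <- regmatches(ql, regexec('^/([A-Za-z_]+)(?:=(?:"(.*)"|(.*)))?$', ql))[[1]]
    if (length(m) < 2L) next
    key <- m[2]
    val <- if (nzchar(m[3])) m[3] else m[4]
    if (key == "db_xref") q$db_xref <- c(q$db_xref, val)
    else if (key == "EC_number") q$EC_number <- c(q$EC_number, val)
    else q[[key]] <- val
  }
  feature_record(kind, contig_id, pos$start, pos$end, pos$strand, q)
}

#' Read an EMBL or GenBank flat file
#'
#' Parses contig sequences plus CDS/tRNA/rRNA features, converting the
#' file's 1-based inclusive coordinates (with `complement()` on the minus
#' strand) to the internal 0-based half-open forward convention.  `join()`
#' locations are rejected: the prokaryotic CDS model here is single-exon and
#' explicit failure beats silent corruption.
#'
#' @param path flat file.
#' @param dialect `"embl"` or `"genbank"`; guessed from the extension when
#'   missing (`.gb`/`.gbk`/`.genbank` read as GenBank, anything else EMBL).
#' @param skip_unsupported skip features with unparseable locations with a
#'   warning instead of failing (used by re-annotation).
#' @return list with elements `genome` (list of [genome_record]) and
#'   `features` (list of [feature_record]).
#' @export
read_flatfile <- function(path, dialect = NULL, skip_unsupported = FALSE) {
  if (!file.exists(path)) stop_domain("file not found: %s", path)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.(gb|gbk|gbff|genbank)$", path, ignore.case = TRUE))
      "genbank" else "embl"
  }
  dialect <- match.arg(dialect, c("embl", "genbank"))
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(0L, utils::head(lines, -1L) == "//")))
  genome <- list(); features <- list()
  for (rl in recs) {
    rl <- rl[rl != "//"]
    if (!length(rl) || !any(nzchar(rl))) next
    parsed <- if (dialect == "embl") parse_embl_record(rl, skip_unsupported)
              else parse_genbank_record(rl, skip_unsupported)
    if (is.null(parsed)) next
    genome[[length(genome) + 1L]] <- parsed$genome
    features <- c(features, parsed$features)
  }
  if (!length(genome)) stop_domain("no records found in %s", path)
  list(genome = genome, features = features)
}

# collect (kind, location, qualifier-lines) triples from feature-table lines
collect_features <- function(ftlines, contig_id, contig_len, skip_unsupported = FALSE) {
  keep <- c("CDS", "tRNA", "rRNA")
  feats <- list()
  cur <- NULL
  flush <- function(cur, feats) {
    if (!is.null(cur) && cur$kind %in% keep) {
      f <- if (skip_unsupported) {
        tryCatch(parse_feature_block(cur$kind, cur$loc, cur$quals,
                                     contig_id, contig_len),
                 error = function(e) {
                   warning(sprintf("skipping feature: %s", conditionMessage(e)),
                           call. = FALSE)
                   NULL
                 })
      } else {
        parse_feature_block(cur$kind, cur$loc, cur$quals, contig_id, contig_len)
      }
      if (!is.null(f)) feats[[length(feats) + 1L]] <- f
    }
    feats
  }
  for (ln in ftlines) {
    key <- trimws(substr(ln, 1L, 16L))
    body <- trimws(substring(ln, 17L))
    if (nzchar(key)) {
      feats <- flush(cur, feats)
      cur <- list(kind = key, loc = body, quals = character(0))
    } else if (!is.null(cur)) {
      if (startsWith(body, "/")) cur$quals <- c(cur$quals, body)
      else if (length(cur$quals)) {
        # continuation of a wrapped qualifier value
        n <- length(cur$quals)
        cur$quals[n] <- paste0(sub('"$', "", cur$quals[n]), " ", body)
      } else cur$loc <- paste0(cur$loc, body)
    }
  }
  flush(cur, feats)
}

parse_embl_record <- function(rl, skip_unsupported = FALSE) {
  idl <- grep("^ID   ", rl, value = TRUE)
  if (!length(idl)) return(NULL)
  contig_id <- trimws(strsplit(sub("^ID   ", "", idl[1]), ";")[[1]][1])
  topology <- if (grepl("circular", idl[1])) "circular" else "linear"
  sq_at <- grep("^SQ", rl)
  if (!length(sq_at)) stop_domain("EMBL record '%s' lacks a sequence block", contig_id)
  seq_lines <- rl[(sq_at[1] + 1L):length(rl)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  g <- genome_record(contig_id, sequence, topology)
  ft <- grep("^FT   ", rl, value = TRUE)
  ft <- substring(ft, 6L)  # drop "FT   ", leaving the 16-col key field
  feats <- collect_features(sprintf("%-17s", ft), contig_id, nchar(sequence),
                            skip_unsupported)
  list(genome = g, features = feats)
}

parse_genbank_record <- function(rl, skip_unsupported = FALSE) {
  locus <- grep("^LOCUS", rl, value = TRUE)
  if (!length(locus)) return(NULL)
  contig_id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
  topology <- if (grepl("circular", locus[1])) "circular" else "linear"
  ori_at <- grep("^ORIGIN", rl)
  if (!length(ori_at)) stop_domain("GenBank record '%s' lacks an ORIGIN block", contig_id)
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(rl[(ori_at[1] + 1L):length(rl)], collapse = "")))
  g <- genome_record(contig_id, sequence, topology)
  feat_at <- grep("^FEATURES", rl)
  feats <- list()
  if (length(feat_at)) {
    ftlines <- rl[(feat_at[1] + 1L):(ori_at[1] - 1L)]
    ftlines <- ftlines[grepl("^ {5}", ftlines)]
    # GenBank indents the key at col 6 and qualifiers at col 22
    ftlines <- substring(ftlines, 6L)
    feats <- collect_features(sprintf("%-17s", ftlines), contig_id, nchar(sequence),
                              skip_unsupported)
  }
  list(genome = g, features = feats)
}

# ---- EMBL writing ----------------------------------------------------------

format_location <- function(f) {
  loc <- sprintf("%d..%d", f$start + 1L, f$end)
  if (f$strand == "-") sprintf("complement(%s)", loc) else loc
}

embl_feature_lines <- function(f) {
  out <- sprintf("FT   %-16s%s", f$kind, format_location(f))
  qline <- function(txt) sprintf("FT   %-16s%s", "", txt)
  q <- f$qualifiers
  add <- character(0)
  if (!is.null(q$product)) add <- c(add, sprintf('/product="%s"', q$product))
  if (!is.null(q$gene)) add <- c(add, sprintf('/gene="%s"', q$gene))
  for (ec in q$EC_number) add <- c(add, sprintf('/EC_number="%s"', ec))
  for (dx in q$db_xref) add <- c(add, sprintf('/db_xref="%s"', dx))
  if (!is.null(q$note)) add <- c(add, sprintf('/note="%s"', q$note))
  c(out, vapply(add, qline, ""))
}

embl_sequence_lines <- function(sequence) {
  n <- nchar(sequence)
  counts <- vapply(c("A", "C", "G", "T"), function(b)
    sum(strsplit(sequence, "")[[1]] == b), 0L)
  other <- n - sum(counts)
  hdr <- sprintf("SQ   Sequence %d BP; %d A; %d C; %d G; %d T; %d other;",
                 n, counts["A"], counts["C"], counts["G"], counts["T"], other)
  seq <- tolower(sequence)
  starts <- seq.int(1L, n, by = 60L)
  body <- vapply(starts, function(s) {
    chunk <- substr(seq, s, min(s + 59L, n))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    sprintf("     %-66s%9d", paste(groups, collapse = " "), min(s + 59L, n))
  }, "")
  c(hdr, body)
}

# coerce an annotated orf to a feature_record for export
as_feature_record <- function(x) {
  if (inherits(x, "feature_record")) return(x)
  stopifnot(inherits(x, "orf"))
  q <- list()
  e <- x$selected_entry
  if (!is.null(e)) {
    q$product <- e$product_name
    if (has_gene(e)) q$gene <- e$gene_name
    if (length(e$ec_numbers)) q$EC_number <- e$ec_numbers
    dx <- c(e$go_terms,
            if (length(e$kegg_pathways)) paste0("KEGG:", e$kegg_pathways))
    if (length(dx)) q$db_xref <- dx
    q$note <- sprintf("accuracy=%.2f%%; entry=%s", 100 * e$accuracy, e$entry_id)
  } else {
    q$product <- "hypothetical protein"
    q$note <- "no database hit"
  }
  if (isTRUE(x$qualifiers$unmatched_stop))
    q$note <- paste0(q$note, "; unmatched stop")
  feature_record("CDS", x$contig_id, x$start, x$end, x$strand, q)
}

#' Write an EMBL flat file
#'
#' Emits one EMBL record per contig with CDS/tRNA/rRNA features sorted by
#' contig then start.  CDS qualifiers carry `/product`, `/gene` (when
#' present), `/EC_number`, `/db_xref` for GO and KEGG, and a `/note` with the
#' accuracy and the source database entry.  Identical duplicate features are
#' deduplicated with a warning.
#'
#' @param genome list of [genome_record] objects (or a single one).
#' @param features list of [feature_record] and/or annotated `orf` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_embl <- function(genome, features, path) {
  if (inherits(genome, "genome_record")) genome <- list(genome)
  features <- lapply(features, as_feature_record)
  keys <- vapply(features, function(f)
    paste(f$contig_id, f$kind, f$start, f$end, f$strand), "")
  if (anyDuplicated(keys)) {
    warning("duplicate features deduplicated on export")
    features <- features[!duplicated(keys)]
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genome) {
    L <- nchar(g$sequence)
    feats <- features[vapply(features, `[[`, "", "contig_id") == g$id]
    feats <- feats[order(vapply(feats, `[[`, 0L, "start"),
                         vapply(feats, `[[`, 0L, "end"))]
    for (f in feats) if (f$end > L)
      stop_domain("feature [%d,%d) exceeds contig %s bounds", f$start, f$end, g$id)
    writeLines(sprintf("ID   %s; SV 1; %s; genomic DNA; STD; PRO; %d BP.",
                       g$id, g$topology, L), con)
    writeLines("XX", con)
    writeLines("FH   Key             Location/Qualifiers", con)
    writeLines("FH", con)
    writeLines(sprintf("FT   %-16s%s", "source", sprintf("1..%d", L)), con)
    for (f in feats) writeLines(embl_feature_lines(f), con)
    writeLines("XX", con)
    writeLines(embl_sequence_lines(g$sequence), con)
    writeLines("//", con)
  }
  invisible(path)
}
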