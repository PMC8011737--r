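# Deterministic synthetic protein databases and genomes with planted,
# ground-truthed genes, so the whole annotation stack is testable without
# any download.
#
# Each planted CDS back-translates a database protein exactly (uniform
# random synonymous codons).  Genes are sandwiched between 9 nt "stop
# walls" (TAA repeats in the gene frame), which pin the finite-state-machine
# start to the true ATG, and spacers are scrubbed of accidental long ORFs by
# writing in-frame stop codons at spacer positions, so the ground truth is
# unambiguous for recovery tests.  Codon-usage and GC-content realism is a
# non-goal.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

codon_inverse <- function(code) {
  inv <- split(names(code$translation), unname(code$translation))
  inv[["*"]] <- NULL
  inv
}

back_translate <- function(aa, code, inv = codon_inverse(code)) {
  res <- strsplit(aa, "", fixed = TRUE)[[1]]
  cods <- vapply(res, function(a) {
    opts <- inv[[a]]
    if (is.null(opts)) stop_domain("cannot back-translate residue '%s'", a)
    opts[sample.int(length(opts), 1L)]
  }, "")
  # a synthetic CDS must open the reading frame with a canonical start
  if (res[1L] == "M") cods[1L] <- "ATG"
  paste0(paste(cods, collapse = ""),
         code$stop_codons[sample.int(length(code$stop_codons), 1L)])
}

#' Generate a synthetic protein reference database
#'
#' `n` random proteins starting with methionine; a fraction carry gene
#' acronyms, a fraction are named "hypothetical protein".  Deterministic
#' for a fixed seed.
#'
#' @param n number of entries.
#' @param len_range integer range of protein lengths (aa).
#' @param gene_fraction fraction of entries carrying a gene acronym.
#' @param hypothetical_fraction fraction named "hypothetical protein".
#' @param seed RNG seed.
#' @return list of [reference_protein] objects.
#' @export
synth_protein_db <- function(n, len_range = c(80L, 200L), gene_fraction = 0.5,
                             hypothetical_fraction = 0.2, seed = 1L) {
  if (n < 1L) stop_domain("n must be at least 1")
  if (gene_fraction < 0 || gene_fraction > 1 ||
      hypothetical_fraction < 0 || hypothetical_fraction > 1)
    stop_domain("fractions must lie in [0,1]")
  vocab <- c("DNA polymerase III subunit", "ATP synthase subunit",
             "50S ribosomal protein", "elongation factor",
             "ABC transporter permease", "two-component histidine kinase",
             "acyl carrier protein", "cell division protein",
             "RNA polymerase sigma factor", "peptide chain release factor",
             "outer membrane porin", "glycosyltransferase")
  sample_range <- function(rng) {
    v <- seq.int(rng[1], rng[2])
    v[sample.int(length(v), 1L)]
  }
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      len <- sample_range(len_range)
      seq <- paste(c("M", sample(AA20, len - 1L, replace = TRUE)), collapse = "")
      hyp <- stats::runif(1) < hypothetical_fraction
      gene <- if (stats::runif(1) < gene_fraction)
        paste0(paste(sample(letters, 3L, replace = TRUE), collapse = ""),
               sample(LETTERS, 1L))
      product <- if (hyp) "hypothetical protein"
                 else sprintf("%s %d", sample(vocab, 1L), i)
      reference_protein(
        entry_id = sprintf("SYN%04d", i), product_name = product,
        sequence = seq, gene_name = gene,
        organism = "synthetic organism",
        go_terms = if (stats::runif(1) < 0.6)
          sprintf("GO:%07d", sample.int(999999L, sample(1:3, 1L))),
        ec_numbers = if (stats::runif(1) < 0.3)
          paste(sample(1:6, 1L), sample(1:20, 1L), sample(1:20, 1L),
                sample(1:200, 1L), sep = "."),
        kegg_pathways = if (stats::runif(1) < 0.4)
          sprintf("ko%05d", sample.int(99999L, 1L)))
    })
  })
}

# write an in-frame stop codon into a spurious ORF using editable positions
scrub_orf <- function(seqvec, orf, editable, code) {
  # candidate codon start positions (forward coords) in the ORF's frame,
  # strictly inside the coding span (never its own stop codon)
  if (orf$strand == "+") {
    starts <- seq.int(orf$start, orf$end - 6L, by = 3L)
    stopc <- c("T", "A", "A")
  } else {
    starts <- seq.int(orf$start + 3L, orf$end - 3L, by = 3L)
    stopc <- c("T", "T", "A")   # reverse-complement of TAA
  }
  for (p in rev(starts)) {      # prefer downstream edits, away from gene starts
    idx <- (p + 1L):(p + 3L)
    if (all(editable[idx])) {
      seqvec[idx] <- stopc
      return(list(seq = seqvec, done = TRUE))
    }
  }
  list(seq = seqvec, done = FALSE)
}

#' Generate a synthetic genome with planted, ground-truthed genes
#'
#' Back-translates the first `n_genes` database proteins with uniform
#' random synonymous codons, places them on random strands separated by
#' random spacers, and records the exact coordinates as ground truth.
#' `mutation_rate` introduces nonsynonymous point changes (per residue) in
#' the genomic copies only, for identity-gradient tests.  `overlap_spec`
#' plants decoy ORFs overlapping chosen genes in a shifted reading frame.
#'
#' @param db protein database from [synth_protein_db()].
#' @param n_genes number of planted genes (at most `length(db)`).
#' @param spacer_range integer range of intergenic spacer lengths (nt).
#' @param overlap_spec optional list of specs
#'   `list(gene =, frame_shift = 1|2, min_overlap_nt =)` planting a decoy
#'   ORF overlapping that gene's 3' end on the forward strand; impossible
#'   geometries raise an error.
#' @param mutation_rate per-residue nonsynonymous mutation probability.
#' @param seed RNG seed.
#' @return an object of class `planted_truth`: list with `genome` (one
#'   contig), `db`, `features` (ground-truth CDS [feature_record]s),
#'   `decoys` (planted decoy intervals) and `seed`.
#' @export
synth_genome <- function(db, n_genes, spacer_range = c(60L, 150L),
                         overlap_spec = NULL, mutation_rate = 0, seed = 1L) {
  if (n_genes > length(db)) stop_domain("n_genes exceeds database size")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop_domain("mutation_rate must lie in [0,1]")
  code <- genetic_code()
  inv <- codon_inverse(code)
  wall_l <- "TAATAATAA"; wall_r <- "TTATTATTA"
  spec_by_gene <- list()
  for (sp in overlap_spec %||% list()) {
    if (is.null(sp$gene) || sp$gene < 1L || sp$gene > n_genes)
      stop_domain("overlap_spec refers to a gene outside 1..n_genes")
    spec_by_gene[[as.character(sp$gene)]] <- sp
  }
  with_seed(seed, {
    blocks <- character(0)
    editable_blocks <- logical(0)   # per block: may the scrubber edit it?
    feats <- list(); decoys <- list()
    pos <- 0L
    push <- function(blk, edit) {
      blocks <<- c(blocks, blk)
      editable_blocks <<- c(editable_blocks, edit)
      pos <<- pos + nchar(blk)
    }
    spacer <- function() {
      v <- seq.int(spacer_range[1], spacer_range[2])
      paste(sample(c("A", "C", "G", "T"), v[sample.int(length(v), 1L)],
                   replace = TRUE), collapse = "")
    }
    push(spacer(), TRUE)
    for (i in seq_len(n_genes)) {
      p <- db[[i]]
      aa <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
      if (mutation_rate > 0 && length(aa) > 1L) {
        hit <- which(stats::runif(length(aa) - 1L) < mutation_rate) + 1L
        for (h in hit) aa[h] <- sample(setdiff(AA20, aa[h]), 1L)
      }
      sp <- spec_by_gene[[as.character(i)]]
      strand <- if (!is.null(sp)) "+" else sample(c("+", "-"), 1L)
      gene_nt <- NULL; decoy <- NULL
      for (try in seq_len(200L)) {
        cand_nt <- back_translate(paste(aa, collapse = ""), code, inv)
        if (is.null(sp)) { gene_nt <- cand_nt; break }
        d <- plant_decoy(cand_nt, sp, code)
        if (!is.null(d)) { gene_nt <- cand_nt; decoy <- d; break }
      }
      if (is.null(gene_nt))
        stop_domain("impossible overlap_spec geometry for gene %d", i)
      push(wall_l, FALSE)
      gene_start <- pos
      push(if (strand == "+") gene_nt else revcomp(gene_nt), FALSE)
      feats[[length(feats) + 1L]] <- feature_record(
        "CDS", "ctg1", gene_start, pos, strand,
        qualifiers = list(product = p$product_name, gene = p$gene_name,
                          note = sprintf("entry=%s", p$entry_id)))
      if (!is.null(decoy)) {
        # decoy tail continues into the downstream spacer region
        push(decoy$tail, FALSE)
        decoys[[length(decoys) + 1L]] <-
          list(start = gene_start + decoy$offset, end = pos,
               strand = "+", gene = i)
      } else {
        push(wall_r, FALSE)
      }
      push(spacer(), TRUE)
    }
    seqvec <- strsplit(paste(blocks, collapse = ""), "", fixed = TRUE)[[1]]
    editable <- rep(editable_blocks, times = nchar(blocks))
    truth_key <- vapply(feats, function(f) paste(f$start, f$end, f$strand), "")
    decoy_ok <- function(o) {
      any(vapply(decoys, function(d)
        o$strand == d$strand && o$end == d$end, TRUE))
    }
    for (iter in seq_len(60L)) {
      g <- genome_record("ctg1", paste(seqvec, collapse = ""))
      found <- find_orfs(g, code)
      spurious <- Filter(function(o) {
        !(paste(o$start, o$end, o$strand) %in% truth_key) && !decoy_ok(o)
      }, found)
      edited <- FALSE
      for (o in spurious) {
        r <- scrub_orf(seqvec, o, editable, code)
        if (r$done) { seqvec <- r$seq; edited <- TRUE }
      }
      if (!edited) break
    }
    structure(list(genome = list(genome_record("ctg1", paste(seqvec, collapse = ""))),
                   db = db, features = feats, decoys = decoys, seed = seed),
              class = "planted_truth")
  })
}

# find a decoy reading frame inside the gene tail: a start codon at offset
# `off` (0-based, off %% 3 == frame_shift) in the shifted frame, no stop
# between it and the gene end, and a stop-terminated tail written into the
# downstream spacer in the decoy's own frame.  NULL when this sampling of
# synonymous codons does not admit the geometry.
plant_decoy <- function(gene_nt, sp, code) {
  shift <- sp$frame_shift %||% 1L
  if (!shift %in% c(1L, 2L)) stop_domain("overlap_spec frame_shift must be 1 or 2")
  min_ov <- sp$min_overlap_nt %||% 60L
  L <- nchar(gene_nt)
  offs <- seq.int(shift, L - 3L, by = 3L)
  offs <- offs[L - offs >= min_ov]
  if (!length(offs)) stop_domain("overlap_spec min_overlap_nt exceeds the gene length")
  for (off in offs) {
    whole <- (L - off) %/% 3L             # complete decoy codons inside the gene
    cods <- codon_vector(substr(gene_nt, off + 1L, off + 3L * whole))
    if (!(cods[1L] %in% code$start_codons)) next
    if (any(cods %in% code$stop_codons)) next
    rem <- (L - off) %% 3L                # gene bases of the straddling codon
    completion <- if (rem == 0L) "" else if (rem == 1L) "GC" else "C"
    n_filler <- max(1L, (63L - (L - off) - nchar(completion) - 3L + 2L) %/% 3L)
    tail <- paste0(completion, strrep("GCA", n_filler), "TAA")
    return(list(offset = off, tail = tail))
  }
  NULL
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("<planted_truth> %d contig(s), %d planted genes, %d decoys (seed %d)\n",
              length(x$genome), length(x$features), length(x$decoys), x$seed))
  invisible(x)
}
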