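# The optimized blasting strategy.
#
# Candidate ORFs wait in a queue ordered by decreasing nucleotide length.
# The head is searched against the reference database, every entry is scored
# with its eventual resized length, and the best entry is selected by the
# ranking criteria.  If the resize shortened the ORF below the next queue
# head it is reinserted by its new length (already blasted; on return it
# goes straight to overlap cleaning).  A characterized, high-accuracy head
# cleans the ORFs overlapping it: blasted low-accuracy ones are removed,
# unblasted ones are truncated to an alternative start clearing the overlap
# or removed.  Hypothetical or low-accuracy heads clean nothing, so the ORFs
# overlapping them are still searched later.

orf_desc_order <- function(orfs) {
  order(-(vapply(orfs, `[[`, 0L, "end") - vapply(orfs, `[[`, 0L, "start")),
        vapply(orfs, `[[`, 0L, "start"))
}

#' Create an annotation engine state
#'
#' @param orfs candidate `orf` list (from [find_orfs()] or re-annotation
#'   import).
#' @param provider a search provider function (see [local_provider()]).
#' @param thr a [thresholds] object.
#' @return an object of class `annotation_state` with fields `queue`
#'   (ordered by decreasing length), `done`, `removed`.
#' @export
annotation_state <- function(orfs, provider, thr = thresholds()) {
  structure(list(queue = orfs[orf_desc_order(orfs)], done = list(),
                 removed = list(), thresholds = thr, provider = provider),
            class = "annotation_state")
}

#' @export
print.annotation_state <- function(x, ...) {
  cat(sprintf("<annotation_state> queued %d | done %d | removed %d\n",
              length(x$queue), length(x$done), length(x$removed)))
  invisible(x)
}

queue_insert <- function(queue, orf) {
  queue[[length(queue) + 1L]] <- orf
  queue[orf_desc_order(queue)]
}

# score one entry against the ORF, applying the prospective resize.  A
# validated extension counts its tail as aligned (that is what the
# tail-similarity gate establishes without a second search), so the match
# span grows with the ORF; the identity is carried over unchanged.
evaluate_entry <- function(orf, entry, genome, code, thr) {
  ol <- orf_len_aa(orf)
  r <- orf
  if (entry$match_len == entry$subject_len && ol > entry$subject_len) {
    r <- shrink_to_subject(orf, entry, genome, code, thr)
  } else if (entry$match_len == ol && ol < entry$subject_len) {
    r <- extend_to_subject(orf, entry, genome, code, thr)
    k <- orf_len_aa(r) - ol
    if (k > 0L) {
      entry$start_match <- entry$start_match - k
      entry$end_query <- entry$end_query + k
      entry$match_len <- entry$match_len + k
    }
  }
  entry$accuracy <- accuracy(entry$identity, entry$match_len,
                             entry$subject_len, orf_len_aa(r))
  list(orf = r, entry = entry)
}

select_best_index <- function(entries, thr) {
  if (!length(entries)) stop_domain("cannot select from an empty entry list")
  acc <- vapply(entries, `[[`, 0, "accuracy")
  if (anyNA(acc)) stop_domain("entries must be scored before selection")
  keep <- which(acc >= max(acc) - thr$tolerance)
  gene <- vapply(entries, has_gene, TRUE)[keep]
  hypo <- vapply(entries, is_hypothetical, TRUE)[keep]
  ml <- vapply(entries, `[[`, 0L, "match_len")[keep]
  keep[order(-gene, hypo, -acc[keep], ml, seq_along(keep))][1L]
}

#' Select the best database entry for an ORF
#'
#' Applies the ranking criteria in order: entries within `tolerance` of the
#' maximal accuracy survive; gene-bearing entries beat gene-less ones;
#' characterized products beat hypothetical ones; then higher accuracy wins;
#' equal accuracy prefers the shorter matching sequence; a full tie keeps
#' the first entry in input order.
#'
#' @param entries non-empty list of scored [hit_entry] objects (accuracies
#'   computed with the eventual resized ORF lengths).
#' @param thr a [thresholds] object.
#' @return the selected [hit_entry].
#' @export
select_best_entry <- function(entries, thr = thresholds()) {
  entries[[select_best_index(entries, thr)]]
}

# first shift k >= 1 whose start codon clears the overlap with borf;
# returns the truncated orf, or NULL when impossible/too short
truncate_past <- function(oorf, borf, genome, code, thr) {
  codons <- orf_codons(oorf, genome)
  n <- length(codons)
  ks <- which(codons[2:(n - 1L)] %in% code$start_codons)
  for (k in ks) {
    cand <- move_start(oorf, k)
    if ((cand$end - cand$start) < thr$min_orf_nt) return(NULL)
    if (interval_overlap(cand$start, cand$end, borf$start, borf$end) == 0L)
      return(cand)
  }
  NULL
}

# does the Fig-8-style geometry admit a truncation for this pair?
overlap_case <- function(borf, oorf) {
  if (borf$strand == oorf$strand) {
    if (borf$strand == "+" && borf$end < oorf$end) return("trunc")
    if (borf$strand == "-" && oorf$start < borf$start) return("trunc")
  } else if (borf$strand == "+" && oorf$strand == "-") {
    if (oorf$start < borf$start) return("trunc")
  } else {
    if (oorf$start > borf$start) return("trunc")
  }
  "fraction"
}

#' Clean ORFs overlapping a confirmed high-accuracy ORF
#'
#' For every ORF overlapping `borf` by at least `min_overlap_nt`:
#' already-blasted ORFs with accuracy below `oorf_remove_accuracy` are
#' removed; never-blasted ORFs are truncated to the first alternative start
#' codon clearing the overlap when the pair geometry allows it (same-strand
#' stop ordering, or opposite strands with the other ORF's stop outside
#' `borf`), and removed when no such start exists or the remainder falls
#' below `min_orf_nt`; otherwise, when the overlap exceeds
#' `overlap_fraction_max` of the other ORF's length, the other ORF is
#' removed.
#'
#' @param borf the confirmed, characterized, high-accuracy `orf`.
#' @param state an `annotation_state`.
#' @param genome,code genome record and genetic code.
#' @return the updated `annotation_state`.
#' @export
clean_overlaps <- function(borf, state, genome, code) {
  thr <- state$thresholds
  ov_nt <- function(o) {
    if (o$contig_id != borf$contig_id) return(0L)
    interval_overlap(o$start, o$end, borf$start, borf$end)
  }

  # blasted ORFs (finished or reinserted) with low accuracy are removed
  drop_blasted <- function(pool) {
    keep <- list(); removed <- list()
    for (o in pool) {
      if (o$status %in% c("blasted", "confirmed") &&
          ov_nt(o) >= thr$min_overlap_nt &&
          orf_accuracy(o) < thr$oorf_remove_accuracy) {
        o$status <- "removed"
        removed[[length(removed) + 1L]] <- o
      } else keep[[length(keep) + 1L]] <- o
    }
    list(keep = keep, removed = removed)
  }
  d <- drop_blasted(state$done)
  state$done <- d$keep
  state$removed <- c(state$removed, d$removed)

  queue <- list()
  for (o in state$queue) {
    ov <- ov_nt(o)
    if (ov < thr$min_overlap_nt) { queue[[length(queue) + 1L]] <- o; next }
    if (o$status != "candidate") {  # reinserted, already blasted
      if (orf_accuracy(o) < thr$oorf_remove_accuracy) {
        o$status <- "removed"
        state$removed[[length(state$removed) + 1L]] <- o
      } else queue[[length(queue) + 1L]] <- o
      next
    }
    if (overlap_case(borf, o) == "trunc") {
      cand <- truncate_past(o, borf, genome, code, thr)
      if (is.null(cand)) {
        o$status <- "removed"
        state$removed[[length(state$removed) + 1L]] <- o
      } else queue[[length(queue) + 1L]] <- cand
    } else if (ov / (o$end - o$start) > thr$overlap_fraction_max) {
      o$status <- "removed"
      state$removed[[length(state$removed) + 1L]] <- o
    } else {
      queue[[length(queue) + 1L]] <- o
    }
  }
  state$queue <- queue[orf_desc_order(queue)]
  state
}

#' Run the length-prioritized annotation queue to completion
#'
#' Pops the longest waiting ORF, searches it, scores and selects the best
#' entry (with prospective resize), reinserts resized ORFs that dropped
#' below the next queue head, and triggers overlap cleaning for
#' characterized heads with accuracy at least `borf_min_accuracy`.
#' Terminates when the queue is empty; every ORF ends confirmed or removed.
#'
#' @param state an `annotation_state`.
#' @param genome the `genome_record` (single contig) the ORFs lie on, or a
#'   named list of genome records for multi-contig runs.
#' @param code a `genetic_code`.
#' @return the final `annotation_state` (empty queue).
#' @export
process_queue <- function(state, genome, code) {
  thr <- state$thresholds
  contigs <- if (inherits(genome, "genome_record")) {
    stats::setNames(list(genome), genome$id)
  } else {
    stats::setNames(genome, vapply(genome, `[[`, "", "id"))
  }
  while (length(state$queue)) {
    orf <- state$queue[[1L]]
    state$queue <- state$queue[-1L]
    g <- contigs[[orf$contig_id]]
    if (orf$status == "candidate") {
      orf$orig_start <- orf$start; orf$orig_end <- orf$end
      query <- tryCatch(translate_orf(orf, g, code), error = function(e) NULL)
      hits <- if (is.null(query)) list()
              else tryCatch(state$provider(query), error = function(e) NULL)
      if (is.null(hits)) {          # provider failure: keep the ORF, move on
        orf$status <- "confirmed"
        orf$qualifiers$unresolved <- TRUE
        state$done[[length(state$done) + 1L]] <- orf
        next
      }
      if (!length(hits)) {
        orf$status <- "confirmed"
        orf$qualifiers$no_hit <- TRUE
        state$done[[length(state$done) + 1L]] <- orf
        next
      }
      ev <- lapply(hits, function(h) evaluate_entry(orf, h, g, code, thr))
      i <- select_best_index(lapply(ev, `[[`, "entry"), thr)
      new <- ev[[i]]$orf
      new$selected_entry <- ev[[i]]$entry
      new$candidates <- lapply(ev, `[[`, "entry")
      new$qualifiers$unmatched_stop <- flag_unmatched_stop(new, ev[[i]]$entry)
      new$status <- "blasted"
      if (length(state$queue) &&
          orf_nt_len(new) < orf_nt_len(state$queue[[1L]])) {
        state$queue <- queue_insert(state$queue, new)
        next
      }
      orf <- new
    }
    # cleaning stage: orf is blasted
    e <- orf$selected_entry
    clean <- !is.null(e) && !is_hypothetical(e) &&
      orf_accuracy(orf) >= thr$borf_min_accuracy
    if (clean) state <- clean_overlaps(orf, state, g, code)
    orf$status <- "confirmed"
    state$done[[length(state$done) + 1L]] <- orf
  }
  state$done <- state$done[orf_desc_order(state$done)]
  state
}
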