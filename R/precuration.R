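# Pre-curation: three automated passes applied before human review, in fixed
# order — low-accuracy filter, two-step overlap filter, intergenic-region
# reduction.  Features here are confirmed ORFs that retain their candidate
# entry lists, so the overlap and intergenic passes can swap a feature to an
# alternative database entry and re-run the start-site resize.

contig_table <- function(genome) {
  if (inherits(genome, "genome_record")) genome <- list(genome)
  stats::setNames(genome, vapply(genome, `[[`, "", "id"))
}

# re-anchor the feature on its original blast-time coordinates, attach the
# given entry, and re-run the prospective resize + accuracy computation
attach_entry <- function(f, entry, genome, code, thr) {
  g <- contig_table(genome)[[f$contig_id]]
  f$start <- f$orig_start %||% f$start
  f$end <- f$orig_end %||% f$end
  ev <- evaluate_entry(f, entry, g, code, thr)
  out <- ev$orf
  out$selected_entry <- ev$entry
  out$qualifiers$unmatched_stop <- flag_unmatched_stop(out, ev$entry)
  out
}

#' Count overlapping feature pairs
#'
#' @param features list of `orf`/`feature_record` objects.
#' @param min_overlap_nt overlaps shorter than this are ignored.
#' @return integer number of overlapping pairs.
#' @export
count_overlaps <- function(features, min_overlap_nt = 4L) {
  n <- length(features)
  if (n < 2L) return(0L)
  cnt <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- features[[i]]; b <- features[[j]]
    if (a$contig_id == b$contig_id &&
        interval_overlap(a$start, a$end, b$start, b$end) >= min_overlap_nt)
      cnt <- cnt + 1L
  }
  cnt
}

#' Total intergenic length
#'
#' Nucleotides of each contig not covered by any feature.
#' @param features list of `orf`/`feature_record` objects.
#' @param genome a `genome_record` or list of them.
#' @return integer total intergenic length in nt.
#' @export
total_intergenic <- function(features, genome) {
  tot <- 0L
  for (g in contig_table(genome)) {
    cov <- logical(nchar(g$sequence))
    for (f in features) {
      if (f$contig_id == g$id && f$end > f$start)
        cov[(f$start + 1L):f$end] <- TRUE
    }
    tot <- tot + sum(!cov)
  }
  tot
}

#' Low-accuracy filter
#'
#' Removes every feature whose selected-entry accuracy falls below the
#' cutoff (features without a hit count as accuracy 0).  Order is preserved.
#'
#' @param features list of confirmed annotated `orf` objects.
#' @param cutoff accuracy cutoff fraction (default 0.80).
#' @return list with elements `kept` and `removed`.
#' @export
low_accuracy_filter <- function(features, cutoff = 0.80) {
  keep <- vapply(features, orf_accuracy, 0) >= cutoff
  list(kept = features[keep], removed = features[!keep])
}

feature_class <- function(f) {
  e <- f$selected_entry
  c(gene = has_gene(e), characterized = !is_hypothetical(e))
}

#' Two-step overlap filter
#'
#' Step 1 tries to dissolve each overlapping pair by swapping one member to
#' an alternative entry — accuracy within `tolerance` of its best candidate,
#' shorter subject — whose re-resize removes the overlap.  Step 2, when the
#' swap fails, removes one member by ordered criteria: accuracy difference
#' beyond `tolerance` removes the less accurate; a gene-acronym member is
#' kept over a gene-less one; a characterized member over an
#' uncharacterized one; an uncharacterized feature bridging two others is
#' removed.  Unresolved overlaps are flagged
#' (`qualifiers$overlap_unresolved`), never silently hidden.
#'
#' @param features list of confirmed annotated `orf` objects.
#' @param thr a [thresholds] object.
#' @param genome a `genome_record` or list of them.
#' @param code a `genetic_code`.
#' @return list with elements `kept` and `removed`.
#' @export
overlap_filter <- function(features, thr, genome, code) {
  removed <- list()
  repeat {
    changed <- FALSE
    n <- length(features)
    pair <- NULL
    for (i in seq_len(max(0L, n - 1L))) {
      for (j in (i + 1L):n) {
        a <- features[[i]]; b <- features[[j]]
        if (a$contig_id == b$contig_id &&
            interval_overlap(a$start, a$end, b$start, b$end) >= thr$min_overlap_nt &&
            !(isTRUE(a$qualifiers$overlap_unresolved) &&
              isTRUE(b$qualifiers$overlap_unresolved))) {
          pair <- c(i, j); break
        }
      }
      if (!is.null(pair)) break
    }
    if (is.null(pair)) break
    i <- pair[1L]; j <- pair[2L]

    # -- step 1: alternative-entry swap with shorter subject
    swapped <- FALSE
    for (m in pair) {
      f <- features[[m]]
      other <- features[[setdiff(pair, m)]]
      if (is.null(f$selected_entry) || length(f$candidates) < 2L) next
      accs <- vapply(f$candidates, `[[`, 0, "accuracy")
      best <- max(accs)
      for (ci in order(vapply(f$candidates, `[[`, 0L, "subject_len"))) {
        alt <- f$candidates[[ci]]
        if (alt$entry_id == f$selected_entry$entry_id) next
        if (alt$subject_len >= f$selected_entry$subject_len) next
        if (accs[ci] < best - thr$tolerance) next
        cand <- attach_entry(f, alt, genome, code, thr)
        widened <- any(vapply(features[-m], function(o) {
          o$contig_id == cand$contig_id &&
            interval_overlap(cand$start, cand$end, o$start, o$end) >
              interval_overlap(f$start, f$end, o$start, o$end)
        }, TRUE))
        if (!widened &&
            interval_overlap(cand$start, cand$end, other$start, other$end) <
            thr$min_overlap_nt) {
          cand$candidates <- f$candidates
          features[[m]] <- cand
          swapped <- TRUE
          break
        }
      }
      if (swapped) break
    }
    if (swapped) { changed <- TRUE; next }

    # -- step 2: remove one member by ordered criteria
    a <- features[[i]]; b <- features[[j]]
    acc_a <- orf_accuracy(a); acc_b <- orf_accuracy(b)
    cls_a <- feature_class(a); cls_b <- feature_class(b)
    drop <- NULL
    if (abs(acc_a - acc_b) > thr$tolerance) {
      drop <- if (acc_a < acc_b) i else j
    } else if (cls_a["gene"] != cls_b["gene"]) {
      drop <- if (cls_a["gene"]) j else i
    } else if (cls_a["characterized"] != cls_b["characterized"]) {
      drop <- if (cls_a["characterized"]) j else i
    } else {
      # an uncharacterized feature causing overlap with two others
      for (m in pair) {
        f <- features[[m]]
        if (feature_class(f)["characterized"]) next
        n_ov <- sum(vapply(seq_along(features), function(k) {
          if (k == m) return(FALSE)
          o <- features[[k]]
          o$contig_id == f$contig_id &&
            interval_overlap(f$start, f$end, o$start, o$end) >= thr$min_overlap_nt
        }, TRUE))
        if (n_ov >= 2L) { drop <- m; break }
      }
    }
    if (is.null(drop)) {
      features[[i]]$qualifiers$overlap_unresolved <- TRUE
      features[[j]]$qualifiers$overlap_unresolved <- TRUE
      changed <- TRUE
    } else {
      f <- features[[drop]]
      f$status <- "removed"
      removed[[length(removed) + 1L]] <- f
      features <- features[-drop]
      changed <- TRUE
    }
    if (!changed) break
  }
  list(kept = features, removed = removed)
}

#' Intergenic-region reduction
#'
#' For each feature flanked by intergenic gaps, considers alternative
#' entries of equivalent characteristics (same gene/characterized class,
#' accuracy within `tolerance`) with a longer subject.  When the re-resize
#' (start-site extension) shrinks the flanking gap without creating any
#' overlap, the feature is swapped to that entry.  Total intergenic length
#' is non-increasing and the overlap count is unchanged.
#'
#' @inheritParams overlap_filter
#' @return the updated feature list.
#' @export
reduce_intergenic <- function(features, thr, genome, code) {
  if (length(features) < 1L) return(features)
  for (m in seq_along(features)) {
    f <- features[[m]]
    e <- f$selected_entry
    if (is.null(e) || length(f$candidates) < 2L) next
    cls <- feature_class(f)
    others <- features[-m]
    gap_for <- function(x) {
      gl <- Inf; gr <- Inf
      for (o in others) {
        if (o$contig_id != x$contig_id) next
        if (o$end <= x$start) gl <- min(gl, x$start - o$end)
        if (o$start >= x$end) gr <- min(gr, o$start - x$end)
      }
      g <- contig_table(genome)[[x$contig_id]]
      gl <- min(gl, x$start)
      gr <- min(gr, nchar(g$sequence) - x$end)
      gl + gr
    }
    cur_gap <- gap_for(f)
    alts <- which(vapply(seq_along(f$candidates), function(ci) {
      alt <- f$candidates[[ci]]
      alt$entry_id != e$entry_id &&
        alt$subject_len > e$subject_len &&
        abs(alt$accuracy - e$accuracy) <= thr$tolerance &&
        identical(unname(feature_class(list(selected_entry = alt))), unname(cls))
    }, TRUE))
    for (ci in alts[order(-vapply(f$candidates[alts], `[[`, 0L, "subject_len"))]) {
      cand <- attach_entry(f, f$candidates[[ci]], genome, code, thr)
      if (cand$start == f$start && cand$end == f$end) next   # no extension happened
      new_overlap <- any(vapply(others, function(o) {
        o$contig_id == cand$contig_id &&
          interval_overlap(cand$start, cand$end, o$start, o$end) >=
            max(1L, interval_overlap(f$start, f$end, o$start, o$end) + 1L)
      }, TRUE))
      if (new_overlap) next
      if (gap_for(cand) >= cur_gap) next
      best_acc <- max(vapply(f$candidates, `[[`, 0, "accuracy"))
      if (orf_accuracy(cand) < best_acc - thr$tolerance) next
      cand$candidates <- f$candidates
      features[[m]] <- cand
      break
    }
  }
  features
}
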