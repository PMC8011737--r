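# End-to-end workflows: annotate a genome FASTA from scratch, or re-annotate
# an existing EMBL/GenBank feature table, then filter and report.  A run
# leaves a project directory behind: the exported EMBL, a config snapshot,
# and the per-ORF hit lists, so filtering and reporting can be re-applied
# without re-running the search.

#' Default pipeline configuration
#'
#' @return nested named list of configuration defaults: genetic code table
#'   and start codons, decision thresholds, search provider settings, RNA
#'   matching gates, filter toggles and the RNG seed.
#' @export
default_config <- function() {
  list(
    genetic_code = 11,
    start_codons = c("ATG", "GTG", "TTG", "CTG"),
    thresholds = list(tolerance = 0.02, borf_min_accuracy = 0.90,
                      oorf_remove_accuracy = 0.80, tail_similarity_min = 0.90,
                      overlap_fraction_max = 0.50, low_accuracy_cutoff = 0.80,
                      min_orf_nt = 60L, min_overlap_nt = 4L),
    search = list(provider = "local", max_hits = 10L, min_identity = 0.3,
                  gap_open = 11, gap_ext = 1),
    rna = list(min_identity = 0.9, min_cov = 0.9),
    filters = list(low_accuracy = TRUE, overlaps = TRUE, intergenic = TRUE),
    seed = 1L
  )
}

merge_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  utils::modifyList(default_config(), config)
}

# ---- project serialization -------------------------------------------------

entry_to_list <- function(e) unclass(e)

list_to_entry <- function(x) {
  hit_entry(entry_id = x$entry_id, product_name = x$product_name,
            subject_seq = x$subject_seq, identity = x$identity,
            start_query = x$start_query, end_query = x$end_query,
            start_match = x$start_match, end_match = x$end_match,
            match_len = x$match_len, product_id = x$product_id,
            gene_name = x$gene_name, organism = x$organism,
            go_terms = unlist(x$go_terms), kegg_pathways = unlist(x$kegg_pathways),
            ec_numbers = unlist(x$ec_numbers), accuracy = x$accuracy %||% NA_real_)
}

orf_to_list <- function(o) {
  x <- unclass(o)
  x$selected_entry <- if (!is.null(o$selected_entry)) entry_to_list(o$selected_entry)
  x$candidates <- lapply(o$candidates, entry_to_list)
  x
}

list_to_orf <- function(x) {
  o <- new_orf(x$contig_id, x$start, x$end, x$strand, x$frame,
               status = x$status, qualifiers = as.list(x$qualifiers),
               orig_start = x$orig_start, orig_end = x$orig_end)
  if (!is.null(x$selected_entry)) o$selected_entry <- list_to_entry(x$selected_entry)
  o$candidates <- lapply(x$candidates, list_to_entry)
  o
}

save_project <- function(project, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hits_dir <- file.path(out_dir, "orfs")
  dir.create(hits_dir, showWarnings = FALSE)
  for (f in c(project$features, project$removed)) {
    nm <- sprintf("%s_%d_%d%s.json", f$contig_id, f$start, f$end,
                  if (f$strand == "+") "fwd" else "rev")
    jsonlite::write_json(orf_to_list(f), file.path(hits_dir, nm),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  jsonlite::write_json(list(features = lapply(project$features, orf_to_list),
                            removed = lapply(project$removed, orf_to_list),
                            rna = lapply(project$rna, unclass)),
                       file.path(out_dir, "project.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  yaml::write_yaml(project$config, file.path(out_dir, "config.yaml"))
  writeLines(unlist(lapply(project$genome, function(g)
    c(paste0(">", g$id), g$sequence))), file.path(out_dir, "genome.fa"))
  invisible(out_dir)
}

#' Load a saved annotation project
#'
#' @param dir project directory produced by [run_annotate()] or
#'   [run_reannotate()].
#' @return an `annotation_project` object.
#' @export
load_project <- function(dir) {
  pj <- jsonlite::read_json(file.path(dir, "project.json"))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  rna <- lapply(pj$rna, function(x)
    feature_record(x$kind, x$contig_id, x$start, x$end, x$strand,
                   qualifiers = as.list(x$qualifiers)))
  genome <- if (file.exists(file.path(dir, "genome.fa")))
    read_fasta(file.path(dir, "genome.fa"))
  structure(list(dir = dir, genome = genome,
                 features = lapply(pj$features, list_to_orf),
                 removed = lapply(pj$removed, list_to_orf),
                 rna = rna, config = cfg),
            class = "annotation_project")
}

#' Apply pre-curation passes to a saved project
#'
#' Re-runs any subset of the three pre-curation passes on a project's
#' confirmed features and re-exports the EMBL file.
#'
#' @param project an `annotation_project` or project directory path.
#' @param passes character subset of
#'   `c("low_accuracy", "overlaps", "intergenic")`.
#' @param cutoff optional override of the low-accuracy cutoff.
#' @return the updated `annotation_project`, invisibly.
#' @export
filter_project <- function(project,
                           passes = c("low_accuracy", "overlaps", "intergenic"),
                           cutoff = NULL) {
  if (is.character(project)) project <- load_project(project)
  passes <- match.arg(passes, several.ok = TRUE)
  cfg <- merge_config(project$config)
  thr <- do.call(thresholds, cfg$thresholds)
  code <- genetic_code(cfg$genetic_code, cfg$start_codons)
  features <- project$features
  removed <- project$removed
  if ("low_accuracy" %in% passes) {
    la <- low_accuracy_filter(features, cutoff %||% thr$low_accuracy_cutoff)
    features <- la$kept; removed <- c(removed, la$removed)
  }
  if ("overlaps" %in% passes) {
    of <- overlap_filter(features, thr, project$genome, code)
    features <- of$kept; removed <- c(removed, of$removed)
  }
  if ("intergenic" %in% passes) {
    features <- reduce_intergenic(features, thr, project$genome, code)
  }
  project$features <- features
  project$removed <- removed
  if (!is.null(project$dir)) {
    save_project(project, project$dir)
    write_embl(project$genome, c(features, project$rna),
               file.path(project$dir, "annotation.embl"))
  }
  invisible(project)
}

#' @export
print.annotation_project <- function(x, ...) {
  cat(sprintf("<annotation_project> %d CDS, %d RNA, %d removed%s\n",
              length(x$features), length(x$rna), length(x$removed),
              if (!is.null(x$dir)) paste0(" @ ", x$dir) else ""))
  invisible(x)
}

# shared back half of both workflows: queue processing, filters, export
annotate_core <- function(genome, db, orfs, cfg, out_dir, rna_feats = list()) {
  code <- genetic_code(cfg$genetic_code, cfg$start_codons)
  thr <- do.call(thresholds, cfg$thresholds)
  provider <- local_provider(db, max_hits = cfg$search$max_hits,
                             min_identity = cfg$search$min_identity,
                             gap_open = cfg$search$gap_open,
                             gap_ext = cfg$search$gap_ext)
  state <- annotation_state(orfs, provider, thr)
  state <- process_queue(state, genome, code)
  features <- state$done
  removed <- state$removed
  if (isTRUE(cfg$filters$low_accuracy)) {
    la <- low_accuracy_filter(features, thr$low_accuracy_cutoff)
    features <- la$kept; removed <- c(removed, la$removed)
  }
  if (isTRUE(cfg$filters$overlaps)) {
    of <- overlap_filter(features, thr, genome, code)
    features <- of$kept; removed <- c(removed, of$removed)
  }
  if (isTRUE(cfg$filters$intergenic)) {
    features <- reduce_intergenic(features, thr, genome, code)
  }
  ord <- order(vapply(features, `[[`, "", "contig_id"),
               vapply(features, `[[`, 0L, "start"))
  features <- features[ord]
  project <- structure(list(dir = out_dir, genome = genome, features = features,
                            removed = removed, rna = rna_feats, config = cfg),
                       class = "annotation_project")
  if (!is.null(out_dir)) {
    save_project(project, out_dir)
    write_embl(genome, c(features, rna_feats), file.path(out_dir, "annotation.embl"))
  }
  project
}

#' Annotate a genome FASTA from scratch
#'
#' Runs the full workflow: six-frame ORF prediction, length-prioritized
#' similarity search with start-site resize and overlap cleaning, the three
#' pre-curation filters (as enabled in the config), tRNA/rRNA reference
#' matching, and EMBL export.  The project directory keeps the EMBL file,
#' the per-ORF hit lists and a config snapshot.
#'
#' @param genome_path genome FASTA.
#' @param db_path protein reference database FASTA (see [read_protein_db()]).
#' @param out_dir project directory to create (`NULL` for none).
#' @param config named list overriding [default_config()], or the path of a
#'   YAML file with such overrides.
#' @param rna_refs_path optional FASTA of tRNA/rRNA reference sequences.
#' @return an `annotation_project` object, invisibly.
#' @export
run_annotate <- function(genome_path, db_path, out_dir = NULL, config = list(),
                         rna_refs_path = NULL) {
  cfg <- merge_config(config)
  genome <- read_fasta(genome_path)
  db <- read_protein_db(db_path)
  code <- genetic_code(cfg$genetic_code, cfg$start_codons)
  orfs <- unlist(lapply(genome, function(g)
    find_orfs(g, code, cfg$thresholds$min_orf_nt)), recursive = FALSE)
  rna_feats <- list()
  if (!is.null(rna_refs_path)) {
    refs <- read_rna_refs(rna_refs_path)
    rna_feats <- unlist(lapply(genome, function(g)
      annotate_rna(g, refs, cfg$rna$min_identity, cfg$rna$min_cov)),
      recursive = FALSE)
  }
  invisible(annotate_core(genome, db, orfs, cfg, out_dir, rna_feats))
}

#' Re-annotate an existing EMBL or GenBank annotation
#'
#' Imports CDS coordinates from the flat file (prediction is skipped, the
#' coordinates are kept; start-site resize remains permitted), re-runs the
#' similarity search and entry selection on them, applies the configured
#' filters and exports EMBL.  tRNA/rRNA features of the input are carried
#' through.  Unsupported (multi-exon) locations are listed and skipped with
#' a warning.
#'
#' @param flatfile_path EMBL or GenBank file.
#' @param db_path protein reference database FASTA.
#' @param out_dir project directory to create (`NULL` for none).
#' @param config named list or YAML path overriding [default_config()].
#' @param dialect `"embl"` or `"genbank"`; guessed from the extension when
#'   missing.
#' @return an `annotation_project` object, invisibly.
#' @export
run_reannotate <- function(flatfile_path, db_path, out_dir = NULL,
                           config = list(), dialect = NULL) {
  cfg <- merge_config(config)
  ff <- read_flatfile(flatfile_path, dialect, skip_unsupported = TRUE)
  genome <- ff$genome
  db <- read_protein_db(db_path)
  lens <- stats::setNames(vapply(genome, function(g) nchar(g$sequence), 0L),
                          vapply(genome, `[[`, "", "id"))
  cds <- Filter(function(f) f$kind == "CDS", ff$features)
  orfs <- lapply(cds, function(f) {
    frame <- if (f$strand == "+") f$start %% 3L
             else (lens[[f$contig_id]] - f$end) %% 3L
    new_orf(f$contig_id, f$start, f$end, f$strand, frame,
            qualifiers = list(imported = TRUE))
  })
  rna_feats <- Filter(function(f) f$kind != "CDS", ff$features)
  invisible(annotate_core(genome, db, orfs, cfg, out_dir, rna_feats))
}

#' Summary report of an annotation project
#'
#' Feature counts (CDS/tRNA/rRNA), gene-acronym and hypothetical counts,
#' and the mean accuracy of the annotated CDS as a percentage with two
#' decimals.
#'
#' @param project an `annotation_project` or a project directory path.
#' @return an object of class `annotation_report`.
#' @export
report <- function(project) {
  if (is.character(project)) project <- load_project(project)
  feats <- project$features
  rna <- project$rna
  accs <- vapply(feats, orf_accuracy, 0)
  hyp <- vapply(feats, function(f)
    is.null(f$selected_entry) || is_hypothetical(f$selected_entry), TRUE)
  structure(list(
    n_cds = length(feats),
    n_trna = sum(vapply(rna, `[[`, "", "kind") == "tRNA"),
    n_rrna = sum(vapply(rna, `[[`, "", "kind") == "rRNA"),
    n_gene = sum(vapply(feats, function(f) has_gene(f$selected_entry), TRUE)),
    n_hypothetical = sum(hyp),
    mean_accuracy_pct = if (length(feats)) round(100 * mean(accs), 2) else 0
  ), class = "annotation_report")
}

#' @export
print.annotation_report <- function(x, ...) {
  cat("Annotation report\n")
  cat(sprintf("  CDS features:        %d\n", x$n_cds))
  cat(sprintf("  tRNA features:       %d\n", x$n_trna))
  cat(sprintf("  rRNA features:       %d\n", x$n_rrna))
  cat(sprintf("  with gene acronym:   %d\n", x$n_gene))
  cat(sprintf("  hypothetical:        %d\n", x$n_hypothetical))
  cat(sprintf("  mean accuracy:       %.2f%%\n", x$mean_accuracy_pct))
  invisible(x)
}
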