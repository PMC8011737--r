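code <- genetic_code()
thr <- thresholds()

cand <- function(acc, id, product = "ABC transporter permease", gene = NULL,
                 ml = 60L) {
  e <- entry_full_subject(random_aa(ml), id = id, product = product, gene = gene)
  e$accuracy <- acc
  e
}

test_that("the low-accuracy filter keeps exactly the features at or above the cutoff", {
  g <- genome_record("c1", strrep("ACGT", 100))
  f1 <- confirmed_orf("c1", 0L, 63L, "+", cand(0.95, "A"))
  f2 <- confirmed_orf("c1", 100L, 163L, "+", cand(0.60, "B"))
  out <- low_accuracy_filter(list(f1, f2), 0.80)
  expect_length(out$kept, 1)
  expect_length(out$removed, 1)
  expect_equal(out$kept[[1]]$selected_entry$entry_id, "A")

  expect_equal(low_accuracy_filter(list(), 0.8), list(kept = list(), removed = list()))
  all_good <- low_accuracy_filter(list(f1), 0.8)
  expect_length(all_good$removed, 0)
  # a feature with no hit counts as accuracy zero
  nohit <- orfannot:::new_orf("c1", 200L, 263L, "+", 2L, status = "confirmed")
  expect_length(low_accuracy_filter(list(nohit), 0.8)$kept, 0)
})

test_that("the overlap filter first tries an alternative entry with a shorter subject", {
  set.seed(61)
  body <- rep("AAC", 120L); body[1L] <- "ATG"; body[21L] <- "GTG"
  g <- genome_record("c1", paste0(strrep("C", 30), cods(body, "TAA"), strrep("C", 30)))
  e_long <- cand(1.0, "LONG", ml = 120L)
  e_short <- entry_full_subject(random_aa(100), id = "SHORT", start_query = 20L)
  e_short$accuracy <- 0.99
  a <- confirmed_orf("c1", 30L, 393L, "+", e_long, candidates = list(e_long, e_short))
  b <- confirmed_orf("c1", 0L, 60L, "+", cand(1.0, "NB", gene = "nbrA"))
  out <- overlap_filter(list(a, b), thr, g, code)
  expect_length(out$kept, 2)
  expect_length(out$removed, 0)
  a2 <- out$kept[[1]]
  expect_equal(a2$selected_entry$entry_id, "SHORT")
  expect_equal(a2$start, 90L)              # re-resized to the GTG
  expect_equal(a2$end, 393L)
  expect_equal(count_overlaps(out$kept, thr$min_overlap_nt), 0L)
  # idempotent
  again <- overlap_filter(out$kept, thr, g, code)
  expect_equal(orf_keys(again$kept), orf_keys(out$kept))
})

test_that("unresolved overlaps fall through the ordered removal criteria", {
  g <- genome_record("c1", strrep("ACGT", 200))
  # (a) accuracy difference beyond the tolerance: the weaker member goes
  a <- confirmed_orf("c1", 0L, 120L, "+", cand(1.0, "STRONG"))
  b <- confirmed_orf("c1", 60L, 210L, "+", cand(0.90, "WEAK"))
  out <- overlap_filter(list(a, b), thr, g, code)
  expect_equal(vapply(out$removed, function(f) f$selected_entry$entry_id, ""), "WEAK")

  # (b) the gene-acronym member is kept
  h <- confirmed_orf("c1", 0L, 120L, "+", cand(1.0, "HYP", product = "hypothetical protein"))
  gn <- confirmed_orf("c1", 60L, 210L, "+", cand(1.0, "GEN", gene = "yacG"))
  out <- overlap_filter(list(h, gn), thr, g, code)
  expect_equal(out$removed[[1]]$selected_entry$entry_id, "HYP")

  # (c) the characterized member is kept
  h2 <- confirmed_orf("c1", 0L, 120L, "+", cand(1.0, "HYP2", product = "uncharacterized protein"))
  c2 <- confirmed_orf("c1", 60L, 210L, "+", cand(1.0, "CHR2"))
  out <- overlap_filter(list(h2, c2), thr, g, code)
  expect_equal(out$removed[[1]]$selected_entry$entry_id, "HYP2")

  # (d) an uncharacterized bridge overlapping two others is removed
  left <- confirmed_orf("c1", 0L, 120L, "+", cand(1.0, "L", product = "hypothetical protein"))
  mid <- confirmed_orf("c1", 100L, 220L, "+", cand(1.0, "M", product = "hypothetical protein"))
  right <- confirmed_orf("c1", 200L, 320L, "+", cand(1.0, "R", product = "hypothetical protein"))
  out <- overlap_filter(list(left, mid, right), thr, g, code)
  expect_equal(out$removed[[1]]$selected_entry$entry_id, "M")
  expect_length(out$kept, 2)

  # a genuinely tied pair is flagged, never silently hidden
  t1 <- confirmed_orf("c1", 0L, 120L, "+", cand(1.0, "T1", gene = "aaaA"))
  t2 <- confirmed_orf("c1", 60L, 210L, "+", cand(1.0, "T2", gene = "bbbB"))
  out <- overlap_filter(list(t1, t2), thr, g, code)
  expect_length(out$kept, 2)
  expect_true(all(vapply(out$kept, function(f)
    isTRUE(f$qualifiers$overlap_unresolved), TRUE)))
  # and the pass never increases the number of overlapping pairs
  expect_lte(count_overlaps(out$kept, thr$min_overlap_nt),
             count_overlaps(list(t1, t2), thr$min_overlap_nt))
})

intergenic_fixture <- function(neighbor_end = 24L) {
  ext <- c("ATG", rep("GAT", 9L))
  body <- rep("AAC", 100L); body[1L] <- "ATG"
  s <- paste0(strrep("C", 30), cods(ext), cods(body, "TAA"), strrep("C", 12))
  g <- genome_record("c1", s)
  f <- orfannot:::new_orf("c1", 60L, 363L, "+", 0L, status = "confirmed")
  q <- translate_orf(f, g, code)
  e1 <- entry_full_subject(q, id = "EX1", accuracy = 1.0)
  e2 <- entry_full_query(paste0("M", strrep("D", 9), q), ol = 100L,
                         start_match = 10L, id = "EX2", accuracy = 1.0)
  f$selected_entry <- e1
  f$candidates <- list(e1, e2)
  u <- confirmed_orf("c1", 0L, neighbor_end, "+", cand(1.0, "U", gene = "upsA"))
  list(g = g, f = f, u = u)
}

test_that("intergenic reduction swaps to a longer equivalent entry when safe", {
  fx <- intergenic_fixture(neighbor_end = 24L)
  before <- total_intergenic(list(fx$u, fx$f), fx$g)
  out <- reduce_intergenic(list(fx$u, fx$f), thr, fx$g, code)
  f2 <- out[[2]]
  expect_equal(f2$selected_entry$entry_id, "EX2")
  expect_equal(f2$start, 30L)              # extended by ten codons
  expect_equal(orfannot:::orf_accuracy(f2), 1.0)
  expect_lt(total_intergenic(out, fx$g), before)
  expect_equal(count_overlaps(out, thr$min_overlap_nt), 0L)
  # idempotent: nothing further to improve
  out2 <- reduce_intergenic(out, thr, fx$g, code)
  expect_equal(orf_keys(out2), orf_keys(out))
})

test_that("intergenic reduction never creates a new overlap", {
  fx <- intergenic_fixture(neighbor_end = 45L)   # extension would collide
  out <- reduce_intergenic(list(fx$u, fx$f), thr, fx$g, code)
  expect_equal(out[[2]]$selected_entry$entry_id, "EX1")
  expect_equal(out[[2]]$start, 60L)
  # and with no alternative entries it is a no-op
  solo <- fx$f; solo$candidates <- list(solo$selected_entry)
  out2 <- reduce_intergenic(list(fx$u, solo), thr, fx$g, code)
  expect_equal(out2[[2]]$start, 60L)
})
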