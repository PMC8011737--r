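code <- genetic_code()
thr <- thresholds()

scored <- function(acc, gene = NULL, product = "ATP synthase subunit", ml = 50L,
                   id = sprintf("E%02d", sample.int(99, 1))) {
  e <- entry_full_subject(random_aa(ml), id = id, product = product, gene = gene,
                          identity = 1)
  e$accuracy <- acc
  e
}

test_that("entry selection follows the ordered ranking criteria", {
  set.seed(51)
  # a gene-bearing entry beats a slightly more accurate gene-less one
  a <- scored(0.955, id = "A"); b <- scored(0.950, gene = "dnaA", id = "B")
  expect_equal(select_best_entry(list(a, b), thr)$entry_id, "B")
  # outside the tolerance band the accuracy decides
  a2 <- scored(0.99, id = "A2"); b2 <- scored(0.95, gene = "dnaA", id = "B2")
  expect_equal(select_best_entry(list(a2, b2), thr)$entry_id, "A2")
  # characterized beats hypothetical at similar accuracy
  h <- scored(0.96, product = "hypothetical protein", id = "H")
  c1 <- scored(0.95, id = "C1")
  expect_equal(select_best_entry(list(h, c1), thr)$entry_id, "C1")
  # equal accuracy: shorter matching sequence wins
  long <- scored(0.95, gene = "x", ml = 80L, id = "L")
  short <- scored(0.95, gene = "y", ml = 70L, id = "S")
  expect_equal(select_best_entry(list(long, short), thr)$entry_id, "S")
  # degenerate input and the error contract
  only <- scored(0.5, id = "O")
  expect_equal(select_best_entry(list(only), thr)$entry_id, "O")
  expect_error(select_best_entry(list(), thr), "empty")
})

# three well-separated genes with distinct translations
three_gene_fixture <- function() {
  blocks <- list(c("ATG", rep("AAA", 19), "TAA"),
                 c("ATG", rep("GAA", 19), "TAA"),
                 c("ATG", rep("CCA", 19), "TAA"))
  pad <- strrep("C", 12)
  s <- pad
  orfs <- list()
  for (b in blocks) {
    start <- nchar(s)
    s <- paste0(s, cods(b))
    orfs[[length(orfs) + 1L]] <-
      orfannot:::new_orf("c1", start, nchar(s), "+", start %% 3L)
    s <- paste0(s, pad)
  }
  g <- genome_record("c1", s)
  queries <- vapply(orfs, translate_orf, "", g, code)
  list(g = g, orfs = orfs, queries = queries)
}

test_that("non-overlapping planted genes are all confirmed with their hits", {
  fx <- three_gene_fixture()
  tab <- do.call(fixture_table, stats::setNames(
    lapply(seq_along(fx$queries), function(i)
      list(entry_full_subject(fx$queries[i], id = sprintf("P%d", i)))),
    fx$queries))
  st <- annotation_state(fx$orfs, fixture_provider(tab), thr)
  st <- process_queue(st, fx$g, code)
  expect_length(st$queue, 0)
  expect_length(st$removed, 0)
  expect_length(st$done, 3)
  for (o in st$done) {
    expect_equal(o$status, "confirmed")
    expect_equal(orfannot:::orf_accuracy(o), 1.0)
  }
  # re-running overlap cleaning changes nothing (idempotence)
  st2 <- clean_overlaps(st$done[[1]], st, fx$g, code)
  expect_length(st2$removed, 0)
  expect_length(st2$done, 3)
})

# two overlapping same-strand ORFs in shifted frames, built codon by codon
overlap_pair_fixture <- function() {
  a_body <- c(rep("AAC", 19), "ACT", rep("GAA", 18))
  s <- paste0(cods("ATG", a_body, "TAA"),               # A = [0, 120)+
              strrep("GAA", 20), "G", "TAA",
              strrep("C", 20))
  g <- genome_record("c1", s)
  a <- orfannot:::new_orf("c1", 0L, 120L, "+", 0L)
  b <- orfannot:::new_orf("c1", 64L, 184L, "+", 1L)      # opens at the CTG
  list(g = g, a = a, b = b,
       qa = translate_orf(a, g, code), qb = translate_orf(b, g, code))
}

test_that("a hypothetical head cleans nothing, so overlapped ORFs still get searched", {
  fx <- overlap_pair_fixture()
  ea <- entry_full_subject(fx$qa, id = "HYP", product = "hypothetical protein",
                           identity = 0.95)
  eb <- entry_full_subject(fx$qb, id = "CHR", gene = "abcZ")
  tab <- do.call(fixture_table, stats::setNames(list(list(ea), list(eb)),
                                                c(fx$qa, fx$qb)))
  st <- annotation_state(list(fx$a, fx$b), fixture_provider(tab), thr)
  st <- process_queue(st, fx$g, code)
  expect_length(st$done, 2)
  expect_length(st$removed, 0)
  ids <- vapply(st$done, function(o) o$selected_entry$entry_id, "")
  expect_setequal(ids, c("HYP", "CHR"))   # both were searched and kept
})

test_that("a blasted low-accuracy ORF overlapping a confirmed head is removed", {
  fx <- overlap_pair_fixture()
  ea <- entry_full_subject(fx$qa, id = "LOW", product = "hypothetical protein",
                           identity = 0.5)
  eb <- entry_full_subject(fx$qb, id = "CHR", gene = "abcZ")
  tab <- do.call(fixture_table, stats::setNames(list(list(ea), list(eb)),
                                                c(fx$qa, fx$qb)))
  st <- annotation_state(list(fx$a, fx$b), fixture_provider(tab), thr)
  st <- process_queue(st, fx$g, code)
  expect_length(st$done, 1)
  expect_equal(st$done[[1]]$selected_entry$entry_id, "CHR")
  expect_length(st$removed, 1)
  expect_equal(st$removed[[1]]$selected_entry$entry_id, "LOW")
  expect_equal(st$removed[[1]]$status, "removed")
})

test_that("an ORF resized below the next head is reinserted, not re-searched", {
  # A: 121 codons with a GTG at codon 20; its perfect hit spans codons 20..119
  a_body <- rep("AAC", 120L); a_body[1L] <- "ATG"; a_body[21L] <- "GTG"
  b_body <- c("ATG", rep("GGA", 108L))
  s <- paste0(cods(a_body, "TAA"), strrep("C", 9), cods(b_body, "TAA"))
  g <- genome_record("c1", s)
  a <- orfannot:::new_orf("c1", 0L, 363L, "+", 0L)
  b <- orfannot:::new_orf("c1", 372L, 702L, "+", 0L)
  qa <- translate_orf(a, g, code); qb <- translate_orf(b, g, code)
  searched <- character(0)
  base <- fixture_provider(do.call(fixture_table, stats::setNames(
    list(list(entry_full_subject(substr(qa, 21, 120), id = "SHORT",
                                 start_query = 20L)),
         list(entry_full_subject(qb, id = "BFULL"))), c(qa, qb))))
  counting <- function(q) { searched <<- c(searched, q); base(q) }
  st <- annotation_state(list(a, b), counting, thr)
  st <- process_queue(st, g, code)
  expect_length(st$done, 2)
  shrunk <- st$done[[which(vapply(st$done, function(o)
    o$selected_entry$entry_id, "") == "SHORT")]]
  expect_equal(shrunk$start, 60L)          # moved to the GTG
  expect_equal(shrunk$end, 363L)
  expect_equal(orf_len_aa(shrunk), 100L)
  # each ORF searched exactly once despite the reinsertion
  expect_equal(sort(searched), sort(c(qa, qb)))
})

# ---- hand-traced overlap-cleaning geometries ------------------------------

mk_state <- function(oorfs, thr. = thr) {
  annotation_state(oorfs, fixture_provider(fixture_table()), thr.)
}

borf_at <- function(start, end, strand) {
  o <- orfannot:::new_orf("c1", start, end, strand, start %% 3L, status = "confirmed")
  o$selected_entry <- scored(1.0, gene = "bor", id = "BORF")
  o
}

seq_with <- function(len, ...) {
  v <- rep("A", len)
  for (p in list(...)) {
    chars <- strsplit(p[[2]], "")[[1]]
    v[(as.integer(p[[1]]) + 1L):(as.integer(p[[1]]) + length(chars))] <- chars
  }
  genome_record("c1", paste(v, collapse = ""))
}

test_that("same-strand overlap truncates the other ORF past the head's stop", {
  g <- seq_with(300L, list(180L, "GTG"), list(237L, "TAA"))
  oorf <- orfannot:::new_orf("c1", 120L, 240L, "+", 0L)
  st <- clean_overlaps(borf_at(60L, 180L, "+"), mk_state(list(oorf)), g, code)
  expect_length(st$queue, 1)
  expect_equal(st$queue[[1]]$start, 180L)
  expect_equal(st$queue[[1]]$end, 240L)
  expect_length(st$removed, 0)
})

test_that("truncation without a usable start codon removes the other ORF", {
  # no start codon at all past the head
  g <- seq_with(300L, list(237L, "TAA"))
  oorf <- orfannot:::new_orf("c1", 120L, 240L, "+", 0L)
  st <- clean_overlaps(borf_at(60L, 180L, "+"), mk_state(list(oorf)), g, code)
  expect_length(st$queue, 0)
  expect_length(st$removed, 1)
  # a start exists but the remainder would fall below the minimum length
  g2 <- seq_with(300L, list(183L, "GTG"), list(237L, "TAA"))
  st2 <- clean_overlaps(borf_at(60L, 180L, "+"), mk_state(list(oorf)), g2, code)
  expect_length(st2$removed, 1)
})

test_that("a reverse ORF poking into a forward head is re-anchored before it", {
  g <- seq_with(300L, list(147L, "CAC"), list(60L, "TTA"))
  oorf <- orfannot:::new_orf("c1", 60L, 210L, "-", 0L)
  st <- clean_overlaps(borf_at(150L, 270L, "+"), mk_state(list(oorf)), g, code)
  expect_length(st$queue, 1)
  expect_equal(st$queue[[1]]$start, 60L)
  expect_equal(st$queue[[1]]$end, 150L)
  expect_equal(st$queue[[1]]$strand, "-")
})

test_that("a forward ORF starting inside a reverse head is re-anchored after it", {
  g <- seq_with(300L, list(180L, "ATG"), list(267L, "TAA"))
  oorf <- orfannot:::new_orf("c1", 120L, 270L, "+", 0L)
  st <- clean_overlaps(borf_at(60L, 180L, "-"), mk_state(list(oorf)), g, code)
  expect_length(st$queue, 1)
  expect_equal(st$queue[[1]]$start, 180L)
  expect_equal(st$queue[[1]]$end, 270L)
})

test_that("heavy overlaps without a truncation geometry remove the other ORF", {
  g <- seq_with(400L)
  inside <- orfannot:::new_orf("c1", 90L, 162L, "+", 0L)   # 100% inside the head
  st <- clean_overlaps(borf_at(60L, 240L, "+"), mk_state(list(inside)), g, code)
  expect_length(st$removed, 1)
  # a modest tail overlap on the opposite strand survives
  mild <- orfannot:::new_orf("c1", 200L, 320L, "-", 2L)    # 40/120 = 33% overlap
  st2 <- clean_overlaps(borf_at(60L, 240L, "+"), mk_state(list(mild)), g, code)
  expect_length(st2$removed, 0)
  expect_length(st2$queue, 1)
})

test_that("tiny stop/start-sharing overlaps are left alone", {
  g <- seq_with(400L)
  touch <- orfannot:::new_orf("c1", 237L, 357L, "+", 0L)   # 3 nt shared
  st <- clean_overlaps(borf_at(60L, 240L, "+"), mk_state(list(touch)), g, code)
  expect_length(st$queue, 1)
  expect_equal(st$queue[[1]]$start, 237L)
})
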