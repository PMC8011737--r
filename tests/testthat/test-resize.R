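code <- genetic_code()
thr <- thresholds()

# ORF of 121 codons (OL = 120 aa) with alternative GTG starts at the given
# 0-based codon indices; all other codons are non-start, non-stop
orf_with_alt_starts <- function(alt_at = integer(0), n_codons = 121L, pad = 30L) {
  body <- rep("AAA", n_codons - 1L)
  body[1L] <- "ATG"
  for (a in alt_at) body[a + 1L] <- "GTG"
  s <- paste0(strrep("C", pad), cods(body, "TAA"), strrep("C", pad))
  g <- genome_record("c1", s)
  o <- orfannot:::new_orf("c1", pad, pad + 3L * n_codons, "+", pad %% 3L)
  list(g = g, o = o)
}

test_that("shrink moves the start to the codon closest to the subject length", {
  set.seed(41)
  fx <- orf_with_alt_starts(alt_at = 20L)
  e <- entry_full_subject(random_aa(100), start_query = 20L)
  r <- shrink_to_subject(fx$o, e, fx$g, code, thr)
  expect_equal(orf_len_aa(r), 100L)
  expect_equal(r$start, fx$o$start + 60L)
  expect_equal(r$end, fx$o$end)
  # idempotent: the shrunk ORF no longer satisfies OL > SL
  expect_identical(shrink_to_subject(r, e, fx$g, code, thr), r)
})

test_that("equidistant shrink candidates keep the longer ORF", {
  set.seed(42)
  fx <- orf_with_alt_starts(alt_at = c(18L, 22L))
  e <- entry_full_subject(random_aa(100), start_query = 30L)
  r <- shrink_to_subject(fx$o, e, fx$g, code, thr)
  expect_equal(orf_len_aa(r), 102L)         # codon 18, not codon 22
})

test_that("shrink is a no-op without a usable alternative start", {
  set.seed(43)
  fx <- orf_with_alt_starts()               # no alternative start at all
  e <- entry_full_subject(random_aa(100), start_query = 20L)
  expect_identical(shrink_to_subject(fx$o, e, fx$g, code, thr), fx$o)
  # the only start would cut into the aligned query span
  fx2 <- orf_with_alt_starts(alt_at = 20L)
  e2 <- entry_full_subject(random_aa(100), start_query = 10L)
  expect_identical(shrink_to_subject(fx2$o, e2, fx2$g, code, thr), fx2$o)
  # and a subject longer than the ORF never triggers a shrink
  e3 <- entry_full_subject(random_aa(150), start_query = 0L)
  expect_identical(shrink_to_subject(fx2$o, e3, fx2$g, code, thr), fx2$o)
})

# extension fixture: 10 upstream codons (led by ATG) encode the subject
# residues immediately before the matched span
extension_fixture <- function(ext_codons, n_codons = 101L) {
  body <- rep("AAA", n_codons - 1L)
  body[1L] <- "ATG"
  s <- paste0(strrep("C", 30L), cods(ext_codons), cods(body, "TAA"), strrep("C", 12L))
  g <- genome_record("c1", s)
  start <- 30L + 3L * length(ext_codons)
  o <- orfannot:::new_orf("c1", start, start + 3L * n_codons, "+", start %% 3L)
  list(g = g, o = o)
}

test_that("extension restores the subject length when the tails agree", {
  ext <- c("ATG", rep("GAT", 9L))           # translates to M DDDDDDDDD
  fx <- extension_fixture(ext)
  q <- translate_orf(fx$o, fx$g, code)
  subject <- paste0("M", strrep("D", 9), q)
  e <- entry_full_query(subject, ol = 100L, start_match = 10L)
  r <- extend_to_subject(fx$o, e, fx$g, code, thr)
  expect_equal(orf_len_aa(r), 110L)
  expect_equal(r$start, fx$o$start - 30L)
  expect_equal(r$end, fx$o$end)
})

test_that("extension is rejected on an in-frame stop or a dissimilar tail", {
  # stop codon inside the extension region
  ext_stop <- c("ATG", rep("GAT", 4L), "TAA", rep("GAT", 4L))
  fx <- extension_fixture(ext_stop)
  q <- translate_orf(fx$o, fx$g, code)
  subject <- paste0("M", strrep("D", 9), q)
  e <- entry_full_query(subject, ol = 100L, start_match = 10L)
  expect_identical(extend_to_subject(fx$o, e, fx$g, code, thr), fx$o)

  # tail similarity 0.80 < 0.90: two mismatches over ten residues
  ext <- c("ATG", rep("GAT", 9L))
  fx2 <- extension_fixture(ext)
  q2 <- translate_orf(fx2$o, fx2$g, code)
  subject2 <- paste0("M", "WW", strrep("D", 7), q2)
  e2 <- entry_full_query(subject2, ol = 100L, start_match = 10L)
  expect_identical(extend_to_subject(fx2$o, e2, fx2$g, code, thr), fx2$o)
  # but it passes with a permissive gate
  lax <- thresholds(tail_similarity_min = 0.75)
  expect_equal(orf_len_aa(extend_to_subject(fx2$o, e2, fx2$g, code, lax)), 110L)
})

test_that("stop-site disagreements are flagged, never fixed", {
  set.seed(44)
  o <- orfannot:::new_orf("c1", 0L, 303L, "+", 0L)       # OL = 100
  full <- entry_full_subject(random_aa(100), start_query = 0L)
  expect_false(flag_unmatched_stop(o, full))
  early <- hit_entry("E", "p", random_aa(100), 0.9,
                     start_query = 0L, end_query = 70L,
                     start_match = 30L, end_match = 100L)
  expect_true(flag_unmatched_stop(o, early))              # subject stops early
  covered <- entry_full_query(random_aa(110), ol = 100L, start_match = 0L)
  expect_true(flag_unmatched_stop(o, covered))            # query ends inside subject
})

test_that("resize never changes strand, frame or stop, and is idempotent", {
  set.seed(45)
  n_checked <- 0L
  for (i in 1:120) {
    n_cod <- sample(25:60, 1)
    alt <- sample(setdiff(seq_len(n_cod - 3L), 1L), sample(0:3, 1))
    body <- rep(sample(c("AAA", "GAA", "CCA", "GGA"), n_cod - 1L, TRUE))
    body[1L] <- "ATG"
    for (a in alt) body[a + 1L] <- "GTG"
    pad <- sample(c(30L, 60L), 1)
    strand <- sample(c("+", "-"), 1)
    block <- cods(body, "TAA")
    s <- paste0(random_dna(pad), if (strand == "+") block else rc(block),
                random_dna(pad))
    g <- genome_record("c1", s)
    o <- orfannot:::new_orf("c1", pad, pad + 3L * n_cod, strand,
                            if (strand == "+") pad %% 3L
                            else (nchar(s) - pad - 3L * n_cod) %% 3L)
    ol <- orf_len_aa(o)
    if (runif(1) < 0.5) {
      sl <- max(20L, ol - sample(1:12, 1))
      e <- entry_full_subject(random_aa(sl), start_query = ol - sl)
      f <- function(x) shrink_to_subject(x, e, g, code, thr)
    } else {
      sl <- ol + sample(1:8, 1)
      e <- entry_full_query(random_aa(sl), ol = ol, start_match = sl - ol)
      f <- function(x) extend_to_subject(x, e, g, code, thr)
    }
    r <- f(o)
    expect_equal(r$strand, o$strand)
    if (o$strand == "+") expect_equal(r$end, o$end) else expect_equal(r$start, o$start)
    expect_equal((r$end - r$start) %% 3L, 0L)
    expect_gte(r$end - r$start, thr$min_orf_nt)
    cods_r <- orfannot:::orf_codons(r, g)
    expect_true(cods_r[length(cods_r)] %in% code$stop_codons)
    expect_false(any(cods_r[-length(cods_r)] %in% code$stop_codons))
    expect_identical(f(r), r)
    if (r$start != o$start || r$end != o$end) n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 10L)   # the loop genuinely exercises applied resizes
})
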