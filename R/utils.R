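#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement over the alphabet `{A,C,G,T,N}`.
#' @param x a single DNA string.
#' @return the reverse complement string.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

# split a DNA string into consecutive codons starting at 1-based offset
codon_vector <- function(seq, offset = 1L) {
  n <- nchar(seq)
  starts <- seq.int(offset, n - 2L, by = 3L)
  if (length(starts) == 0L || starts[1] > n - 2L) return(character(0))
  substring(seq, starts, starts + 2L)
}

# overlap in nucleotides of two half-open intervals on the same contig
interval_overlap <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2))
}

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so deterministic generators do not
#' disturb the caller's RNG stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_domain <- function(...) stop(sprintf(...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
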