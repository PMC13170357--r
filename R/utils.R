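#' Run code with a temporarily seeded RNG
#'
#' Saves and restores `.Random.seed` so simulation functions are pure in
#' `(inputs, seed)` without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA string(s) with a given GC content
#' @noRd
random_dna <- function(n, length, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

#' Reverse complement of character DNA sequences
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Hamming distance between two equal-length strings
#' @noRd
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  if (length(ra) != length(rb)) {
    abort("hamming(): sequences must have equal length")
  }
  sum(ra != rb)
}

#' Substitute bases independently at a fixed per-base rate
#'
#' Each hit position is replaced by one of the three other bases, so the
#' realized mismatch rate equals `rate` exactly in expectation.
#' @noRd
mutate_bases <- function(seqs, rate) {
  if (rate == 0) {
    return(seqs)
  }
  vapply(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- stats::runif(length(chars)) < rate
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(b) {
        sample(setdiff(DNA_BASES, b), 1)
      }, character(1))
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' All Hamming-1 neighbours of a barcode
#' @noRd
hamming1_neighbours <- function(barcode) {
  chars <- strsplit(barcode, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(3L * n)
  idx <- 0L
  for (i in seq_len(n)) {
    for (b in setdiff(DNA_BASES, chars[i])) {
      idx <- idx + 1L
      tmp <- chars
      tmp[i] <- b
      out[idx] <- paste(tmp, collapse = "")
    }
  }
  out
}

#' Check a DNA alphabet (A/C/G/T only)
#' @noRd
assert_dna <- function(x, what = "sequence") {
  if (any(grepl("[^ACGT]", x))) {
    abort(paste0(what, " must contain only A/C/G/T"))
  }
  invisible(x)
}
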