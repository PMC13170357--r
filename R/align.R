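#' Ungapped local alignment of junction flanks to a genome
#'
#' A dependency-free seed-and-extend aligner tailored to short junction
#' flanks: exact k-mer seeds (default k = 12) locate candidate diagonals on
#' both strands, each diagonal is scored ungapped with match +1 / mismatch -2,
#' and the maximal-scoring contiguous segment on the diagonal (Kadane scan) is
#' reported. Scores are converted to bitscores and E-values with the
#' Karlin-Altschul formulation, `bits = (lambda * S - ln K) / ln 2` and
#' `E = m * n * 2^(-bits)`, using lambda = 1.28 and K = 0.46 for this scoring
#' scheme; `m` is the flank length and `n` the total genome length. Hits are
#' filtered at `min_identity` (percent identity over the aligned segment) and
#' `max_evalue`, and returned sorted by bitscore, descending.
#'
#' Each hit also reports `insertion_pos`: the reference coordinate aligned to
#' the first flank base, i.e. the genomic base adjacent to the T-DNA right
#' arm under the package's position convention (`+` hits: segment diagonal
#' start; `-` hits: diagonal end).
#'
#' @param flank Flank sequence (single string) for [align_flank()]; a
#'   character vector for [align_flanks()].
#' @param genome An [annotated_genome] (or any object with a `chromosomes`
#'   named character vector).
#' @param min_identity Minimum percent identity of retained hits.
#' @param max_evalue Maximum E-value of retained hits.
#' @param k Seed k-mer length.
#' @param min_flank Minimum flank length; shorter queries error
#'   ([align_flank()]) or are skipped ([align_flanks()]).
#' @param lambda,karlin_k Karlin-Altschul parameters for the +1/-2 scheme.
#' @return [align_flank()]: tibble of hits (`chromosome`, `start`, `end`,
#'   `strand`, `length`, `identity`, `score`, `bitscore`, `evalue`,
#'   `insertion_pos`). [align_flanks()]: the same with a leading `flank`
#'   column covering all queries.
#' @export
align_flank <- function(flank, genome, min_identity = 95, max_evalue = 0.1,
                        k = 12, min_flank = 20, lambda = 1.28,
                        karlin_k = 0.46) {
  stopifnot(length(flank) == 1)
  if (nchar(flank) < min_flank) {
    abort(sprintf("flank shorter than the configured minimum (%d nt)", min_flank))
  }
  hits <- align_flanks(flank, genome,
    min_identity = min_identity, max_evalue = max_evalue, k = k,
    min_flank = min_flank, lambda = lambda, karlin_k = karlin_k
  )
  dplyr::select(hits, -"flank")
}

#' @rdname align_flank
#' @export
align_flanks <- function(flank, genome, min_identity = 95, max_evalue = 0.1,
                         k = 12, min_flank = 20, lambda = 1.28,
                         karlin_k = 0.46) {
  chroms <- genome$chromosomes
  stopifnot(is.character(chroms), !is.null(names(chroms)))
  n_db <- sum(nchar(chroms))
  empty <- tibble::tibble(
    flank = character(), chromosome = character(), start = integer(),
    end = integer(), strand = character(), length = integer(),
    identity = double(), score = double(), bitscore = double(),
    evalue = double(), insertion_pos = integer()
  )
  flanks <- unique(flank[nchar(flank) >= min_flank & nchar(flank) >= k])
  if (length(flanks) == 0) {
    return(empty)
  }

  # seed table: one row per (query, strand, offset) k-mer; the "-" strand is
  # searched by seeding the reverse complement of the flank
  seed_rows <- list()
  for (i in seq_along(flanks)) {
    f <- flanks[i]
    L <- nchar(f)
    offs <- unique(c(seq(1L, L - k + 1L, by = k), L - k + 1L))
    for (strand in c("+", "-")) {
      q <- if (strand == "+") f else revcomp(f)
      seed_rows[[length(seed_rows) + 1]] <- tibble::tibble(
        qidx = i, strand = strand, offset = offs,
        seed = substring(q, offs, offs + k - 1L)
      )
    }
  }
  seeds <- dplyr::bind_rows(seed_rows)
  useeds <- unique(seeds$seed)
  seed_index <- split(seq_len(nrow(seeds)), seeds$seed)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(useeds))

  # candidate diagonals: (query, strand, chromosome, window start)
  cand <- list()
  for (cn in names(chroms)) {
    m <- Biostrings::matchPDict(pd, Biostrings::DNAString(chroms[[cn]]))
    st <- Biostrings::startIndex(m)
    hit_seed <- which(lengths(st) > 0)
    if (length(hit_seed) == 0) next
    si_vec <- rep(hit_seed, lengths(st[hit_seed]))
    p_vec <- unlist(st[hit_seed], use.names = FALSE)
    rows <- seed_index[useeds[si_vec]]
    idx <- unlist(rows, use.names = FALSE)
    p_rep <- rep(p_vec, lengths(rows))
    cand[[length(cand) + 1]] <- tibble::tibble(
      qidx = seeds$qidx[idx], strand = seeds$strand[idx],
      chromosome = cn, diag = p_rep - seeds$offset[idx] + 1L
    )
  }
  if (length(cand) == 0) {
    return(empty)
  }
  cand <- dplyr::distinct(dplyr::bind_rows(cand))

  out <- vector("list", nrow(cand))
  for (r in seq_len(nrow(cand))) {
    f <- flanks[cand$qidx[r]]
    L <- nchar(f)
    q <- if (cand$strand[r] == "+") f else revcomp(f)
    cn <- cand$chromosome[r]
    clen <- nchar(chroms[[cn]])
    d <- cand$diag[r]
    lo <- max(1L, d)
    hi <- min(clen, d + L - 1L)
    if (hi - lo + 1L < k) next
    ref <- substr(chroms[[cn]], lo, hi)
    qseg <- substr(q, lo - d + 1L, hi - d + 1L)
    match_vec <- charToRaw(qseg) == charToRaw(ref)
    seg <- max_subarray(ifelse(match_vec, 1, -2))
    if (seg$score <= 0) next
    alen <- seg$to - seg$from + 1L
    matches <- sum(match_vec[seg$from:seg$to])
    identity <- 100 * matches / alen
    bits <- (lambda * seg$score - log(karlin_k)) / log(2)
    evalue <- nchar(f) * n_db * 2^(-bits)
    if (identity < min_identity || evalue > max_evalue) next
    ref_start <- lo + seg$from - 1L
    ref_end <- lo + seg$to - 1L
    # reference base aligned to flank base 1 (unclipped diagonal end)
    ipos <- if (cand$strand[r] == "+") d else d + L - 1L
    if (ipos < 1L || ipos > clen) next
    out[[r]] <- tibble::tibble(
      flank = f, chromosome = cn, start = ref_start, end = ref_end,
      strand = cand$strand[r], length = alen, identity = identity,
      score = seg$score, bitscore = bits, evalue = evalue,
      insertion_pos = as.integer(ipos)
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(empty)
  }
  # a diagonal can be seeded from several k-mers; keep one record each
  res <- dplyr::distinct(res)
  dplyr::arrange(res, .data$flank, dplyr::desc(.data$bitscore), .data$evalue)
}

# maximal-scoring contiguous subarray (Kadane), 1-based from/to
max_subarray <- function(v) {
  best <- 0
  best_from <- 0L
  best_to <- -1L
  cur <- 0
  cur_from <- 1L
  for (i in seq_along(v)) {
    if (cur <= 0) {
      cur <- v[i]
      cur_from <- i
    } else {
      cur <- cur + v[i]
    }
    if (cur > best) {
      best <- cur
      best_from <- cur_from
      best_to <- i
    }
  }
  list(score = best, from = best_from, to = best_to)
}

#' Resolve mapping uniqueness from a hit list
#'
#' A flank maps uniquely when it has exactly one retained hit, or when the
#' best bitscore exceeds the second best by at least `min_bit_gap` (default
#' 10 bits). Anything else with hits is multi-locus; an empty hit list is
#' "unaligned" (distinct from multi-locus).
#'
#' @param hits Tibble of hits as returned by [align_flank()].
#' @param min_bit_gap Required bitscore gap between best and second-best hit.
#' @return List with `status` (`"unique"`, `"multi-locus"` or `"unaligned"`)
#'   and `best` (one-row tibble, or `NULL` when unaligned).
#' @export
resolve_uniqueness <- function(hits, min_bit_gap = 10) {
  if (is.null(hits) || nrow(hits) == 0) {
    return(list(status = "unaligned", best = NULL))
  }
  hits <- dplyr::arrange(hits, dplyr::desc(.data$bitscore))
  if (nrow(hits) == 1 ||
    hits$bitscore[1] - hits$bitscore[2] >= min_bit_gap) {
    list(status = "unique", best = hits[1, ])
  } else {
    list(status = "multi-locus", best = NULL)
  }
}
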