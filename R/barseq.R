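#' Extract barcodes from BarSeq amplicon reads
#'
#' Finds the constant left priming flank (first occurrence, up to
#' `max_flank_mismatch` substitutions), takes the following
#' `barcode_length`-nt window as the barcode, and requires the constant right
#' flank to follow immediately (again up to `max_flank_mismatch`
#' substitutions). Reads failing any anchor, or too short to contain the full
#' window, yield `NA`.
#'
#' @param reads Character vector of read sequences.
#' @param left_flank,right_flank Constant priming-site sequences flanking the
#'   barcode.
#' @param barcode_length Barcode length in nt (default 20).
#' @param max_flank_mismatch Substitutions tolerated per flank (default 1).
#' @return Character vector of barcodes (`NA` for unparseable reads).
#' @export
extract_barcode <- function(reads, left_flank, right_flank,
                            barcode_length = 20, max_flank_mismatch = 1) {
  if (!nzchar(left_flank) || !nzchar(right_flank)) {
    abort("flanks must be non-empty")
  }
  n <- length(reads)
  out <- rep(NA_character_, n)
  if (n == 0) {
    return(out)
  }
  llen <- nchar(left_flank)
  rlen <- nchar(right_flank)
  m <- Biostrings::vmatchPattern(left_flank, Biostrings::DNAStringSet(reads),
    max.mismatch = max_flank_mismatch
  )
  starts <- Biostrings::startIndex(m)
  for (i in seq_len(n)) {
    st <- starts[[i]]
    if (is.null(st)) next
    st <- st[st >= 1 & st <= nchar(reads[i]) - llen + 1]
    if (length(st) == 0) next
    lstart <- min(st)
    bc_start <- lstart + llen
    r_start <- bc_start + barcode_length
    if (r_start + rlen - 1 > nchar(reads[i])) next
    rf <- substr(reads[i], r_start, r_start + rlen - 1)
    if (hamming(rf, right_flank) > max_flank_mismatch) next
    out[i] <- substr(reads[i], bc_start, bc_start + barcode_length - 1)
  }
  out
}

#' Count extracted barcodes and link them to the insertion pool
#'
#' Observed barcodes are assigned to pool barcodes by exact match (optionally
#' rescuing barcodes at Hamming distance 1 from exactly one pool barcode);
#' everything else is tallied per sample as unassigned. The returned table
#' has one row per pool barcode (zero-filled) so columns line up across
#' samples; `assigned + unassigned = extracted` per sample.
#'
#' @param extracted Tibble (`sample_id`, `barcode`) of extracted barcodes,
#'   `NA` barcodes allowed (counted as unparsed).
#' @param pool A `tn_pool` (or tibble with `barcode` and `classification`).
#' @param meta Sample metadata tibble (`sample_id`, `temperature`,
#'   `replicate`, `batch`).
#' @param rescue_hamming1 Rescue observed barcodes at Hamming distance 1 from
#'   a unique pool barcode (default `FALSE`).
#' @return A raw [bc_counts] table with attribute `run_log`: per-sample
#'   tibble (`sample_id`, `extracted`, `assigned`, `unassigned`).
#' @export
count_and_link <- function(extracted, pool, meta, rescue_hamming1 = FALSE) {
  extracted <- tibble::as_tibble(extracted)
  stopifnot(all(c("sample_id", "barcode") %in% names(extracted)))
  pool_bc <- unique(pool$barcode)
  obs <- extracted[!is.na(extracted$barcode), ]
  if (rescue_hamming1 && nrow(obs) > 0) {
    unknown <- setdiff(unique(obs$barcode), pool_bc)
    if (length(unknown) > 0) {
      rescue <- vapply(unknown, function(b) {
        cand <- intersect(hamming1_neighbours(b), pool_bc)
        if (length(cand) == 1) cand else NA_character_
      }, character(1))
      hit <- match(obs$barcode, names(rescue))
      ok <- !is.na(hit) & !is.na(rescue[hit])
      obs$barcode[ok] <- rescue[hit[ok]]
    }
  }
  obs$assigned <- obs$barcode %in% pool_bc
  counts_long <- obs %>%
    dplyr::filter(.data$assigned) %>%
    dplyr::count(.data$sample_id, .data$barcode, name = "count")
  wide <- tidyr::expand_grid(barcode = pool_bc, sample_id = meta$sample_id) %>%
    dplyr::left_join(counts_long, by = c("barcode", "sample_id")) %>%
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count")
  run_log <- extracted %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(
      reads = dplyr::n(),
      extracted = sum(!is.na(.data$barcode)),
      .groups = "drop"
    ) %>%
    dplyr::left_join(
      obs %>% dplyr::group_by(.data$sample_id) %>%
        dplyr::summarise(assigned = sum(.data$assigned), .groups = "drop"),
      by = "sample_id"
    ) %>%
    dplyr::mutate(
      assigned = dplyr::coalesce(.data$assigned, 0L),
      unassigned = .data$extracted - .data$assigned
    )
  out <- bc_counts(wide, meta = meta, normalized = FALSE)
  attr(out, "run_log") <- run_log
  out
}
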