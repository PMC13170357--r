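#' Locate the T-DNA right-arm junction in reads
#'
#' Scans every window of each read for the junction sequence, tolerating up to
#' `max_mismatches` substitutions (default 2). The reported match is the
#' window with the fewest mismatches; ties go to the lowest offset. Reads with
#' no qualifying window are dropped from the result.
#'
#' Offsets are 0-based: the sequence before the junction (the first `offset`
#' bases) is the barcode region, the sequence after it the genomic flank.
#'
#' @param reads Character vector of read sequences, or a tibble with
#'   `read_id` and `sequence` columns.
#' @param junction Junction nucleotide sequence.
#' @param max_mismatches Maximum Hamming distance of the matched window.
#' @return Tibble (`read_id`, `offset`, `mismatches`, `flank`), one row per
#'   read with a junction match.
#' @export
find_junction <- function(reads, junction, max_mismatches = 2) {
  if (is.character(reads)) {
    reads <- tibble::tibble(
      read_id = sprintf("read_%06d", seq_along(reads)),
      sequence = reads
    )
  }
  if (!nzchar(junction)) abort("empty junction sequence")
  if (nrow(reads) == 0) {
    return(tibble::tibble(
      read_id = character(), offset = integer(),
      mismatches = integer(), flank = character()
    ))
  }
  if (any(!nzchar(reads$sequence))) abort("empty read sequence")
  if (any(nchar(reads$sequence) < nchar(junction))) {
    abort("junction longer than some reads")
  }
  subj <- Biostrings::DNAStringSet(reads$sequence)
  jlen <- nchar(junction)
  remaining <- seq_len(nrow(reads))
  res <- vector("list", max_mismatches + 1)
  # escalate the mismatch budget: the first level at which a read matches is
  # its minimal Hamming distance, and all its hits at that level attain it
  for (mm in 0:max_mismatches) {
    if (length(remaining) == 0) break
    m <- Biostrings::vmatchPattern(junction, subj[remaining], max.mismatch = mm)
    starts <- Biostrings::startIndex(m)
    # drop windows hanging off either read end (edge positions count as
    # mismatches in Biostrings but are not legal junction windows here)
    maxs <- nchar(reads$sequence[remaining]) - jlen + 1L
    starts <- lapply(seq_along(starts), function(i) {
      st <- starts[[i]]
      st[st >= 1L & st <= maxs[i]]
    })
    hit <- lengths(starts) > 0
    if (any(hit)) {
      ridx <- remaining[hit]
      first <- vapply(starts[hit], min, integer(1))
      res[[mm + 1]] <- tibble::tibble(
        read_id = reads$read_id[ridx],
        offset = first - 1L,
        mismatches = mm,
        flank = substr(reads$sequence[ridx], first + jlen,
          nchar(reads$sequence[ridx])
        )
      )
      remaining <- remaining[!hit]
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      read_id = character(), offset = integer(),
      mismatches = integer(), flank = character()
    ))
  }
  dplyr::arrange(out, match(.data$read_id, reads$read_id))
}
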