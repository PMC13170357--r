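#' Simulate TnSeq junction reads from an insertion truth set
#'
#' Each read is `barcode + junction + genomic flank`: the mutant's barcode,
#' the T-DNA right-arm junction sequence, then `flank_length` bases of genomic
#' sequence read outward from the insertion point on the recorded strand
#' (reverse complement for `-` strand insertions). Substitution errors are
#' applied independently per base over the whole read. Read names are opaque
#' serial numbers so no truth coordinate can be recovered by parsing them.
#'
#' Insertions too close to a chromosome end yield truncated flanks; they are
#' emitted (real libraries contain them) and recorded in the simulation log
#' (`attr(reads, "sim_log")`) so tests can exclude them.
#'
#' @param truth An `insertion_truth` from [simulate_insertions()].
#' @param genome The [annotated_genome] the truth was drawn from.
#' @param junction T-DNA right-arm junction sequence (nucleotide string).
#' @param flank_length Genomic flank length in bp.
#' @param substitution_rate Per-base substitution error rate, `< 0.25`.
#' @param reads_per_insertion Reads per insertion (constant integer; default
#'   10, the order of junction-library coverage in real barcoded T-DNA pools).
#' @param seed Integer RNG seed.
#' @return Tibble (`read_id`, `sequence`) with attribute `sim_log`
#'   (tibble of truncated-flank reads).
#' @export
simulate_tnseq_reads <- function(truth, genome, junction,
                                 flank_length = 60, substitution_rate = 0,
                                 reads_per_insertion = 10, seed = 1) {
  stopifnot(
    inherits(truth, "insertion_truth"),
    inherits(genome, "annotated_genome"),
    reads_per_insertion >= 1
  )
  assert_dna(junction, "junction")
  if (substitution_rate < 0 || substitution_rate >= 0.25) {
    abort("substitution_rate must be in [0, 0.25)")
  }
  lens <- chrom_lengths(genome)
  if (flank_length > min(lens)) {
    abort("flank_length exceeds the shortest chromosome")
  }

  ins <- truth$insertions
  flanks <- extract_flanks(genome, ins$chromosome, ins$position, ins$strand,
    flank_length
  )
  truncated <- nchar(flanks) < flank_length

  with_seed(seed, {
    idx <- rep(seq_len(nrow(ins)), each = reads_per_insertion)
    seqs <- paste0(ins$barcode[idx], junction, flanks[idx])
    seqs <- mutate_bases(seqs, substitution_rate)
    reads <- tibble::tibble(
      read_id = sprintf("read_%06d", seq_along(seqs)),
      sequence = seqs
    )
    log <- tibble::tibble(
      read_id = reads$read_id[truncated[idx]],
      reason = "truncated_flank",
      flank_length = nchar(flanks)[idx][truncated[idx]]
    )
    attr(reads, "sim_log") <- log
    reads
  })
}

# genomic flank read outward from the insertion base along `strand`
extract_flanks <- function(genome, chromosome, position, strand, flank_length) {
  lens <- chrom_lengths(genome)
  n <- length(position)
  out <- character(n)
  for (i in seq_len(n)) {
    L <- lens[[chromosome[i]]]
    if (strand[i] == "+") {
      to <- min(position[i] + flank_length - 1L, L)
      out[i] <- substr(genome$chromosomes[[chromosome[i]]], position[i], to)
    } else {
      from <- max(position[i] - flank_length + 1L, 1L)
      out[i] <- revcomp(
        substr(genome$chromosomes[[chromosome[i]]], from, position[i])
      )
    }
  }
  out
}

#' Write reads as FASTQ (Phred+33 placeholder qualities)
#'
#' @param reads Tibble with `read_id` and `sequence` columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(reads$sequence, reads$read_id))
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ path.
#' @return Tibble (`read_id`, `sequence`).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(x)),
    sequence = as.character(x)
  )
}
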