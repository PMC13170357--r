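#' Assign insertions to genes by coordinate intersection
#'
#' Each single-locus insertion gets the `gene_id` of the gene whose 1-based
#' inclusive `[start, end]` interval contains its position, or `"intergenic"`
#' when none does. Positions falling in two or more overlapping annotation
#' features are flagged `multi_feature` (their `gene_id` lists all features,
#' `;`-separated); such barcodes are excluded later from gene-level fitness.
#'
#' @param records Tibble with `chromosome` and `position` columns (rows with
#'   `NA` position pass through as `NA`/intergenic-free).
#' @param genome An [annotated_genome].
#' @return `records` with `gene_id` and `multi_feature` columns added.
#' @export
annotate_insertions <- function(records, genome) {
  records <- tibble::as_tibble(records)
  stopifnot(
    inherits(genome, "annotated_genome"),
    all(c("chromosome", "position") %in% names(records))
  )
  lens <- chrom_lengths(genome)
  has_pos <- !is.na(records$position)
  if (any(has_pos & (!records$chromosome %in% names(lens)))) {
    abort("record on unknown chromosome")
  }
  if (any(has_pos &
    (records$position < 1 | records$position > lens[records$chromosome]))) {
    abort("insertion position outside chromosome bounds")
  }
  records$gene_id <- NA_character_
  records$multi_feature <- FALSE
  if (!any(has_pos)) {
    return(records)
  }
  g <- genome$genes
  if (nrow(g) == 0) {
    records$gene_id[has_pos] <- "intergenic"
    return(records)
  }
  q <- GenomicRanges::GRanges(
    records$chromosome[has_pos],
    IRanges::IRanges(records$position[has_pos], records$position[has_pos])
  )
  s <- GenomicRanges::GRanges(g$chromosome, IRanges::IRanges(g$start, g$end))
  ov <- GenomicRanges::findOverlaps(q, s)
  qh <- S4Vectors::queryHits(ov)
  ids <- vapply(seq_len(sum(has_pos)), function(i) {
    hits <- g$gene_id[S4Vectors::subjectHits(ov)[qh == i]]
    if (length(hits) == 0) "intergenic" else paste(sort(hits), collapse = ";")
  }, character(1))
  nhits <- tabulate(qh, nbins = sum(has_pos))
  records$gene_id[has_pos] <- ids
  records$multi_feature[has_pos] <- nhits >= 2
  records
}

#' Genome-wide insertion density in fixed-size bins
#'
#' Tiles each chromosome with 1-based bins `[k * bin + 1, (k + 1) * bin]`
#' (the last bin truncated at the chromosome end) and counts single-locus
#' insertions per bin. Bin counts sum to the number of counted insertions.
#'
#' @param records Tibble of insertion records; only rows with
#'   `classification == "single"` (when the column exists) and a position are
#'   counted.
#' @param genome An [annotated_genome].
#' @param bin_size Bin width in bp (default 50 kb).
#' @return Tibble (`chromosome`, `bin_start`, `bin_end`, `insertion_count`)
#'   covering every bin of every chromosome.
#' @export
bin_density <- function(records, genome, bin_size = 50000) {
  stopifnot(inherits(genome, "annotated_genome"), bin_size >= 1)
  records <- tibble::as_tibble(records)
  if ("classification" %in% names(records)) {
    records <- records[records$classification == "single", ]
  }
  records <- records[!is.na(records$position), ]
  lens <- chrom_lengths(genome)
  bins <- purrr::map_dfr(names(lens), function(cn) {
    n_bins <- ceiling(lens[[cn]] / bin_size)
    tibble::tibble(
      chromosome = cn,
      bin_start = (seq_len(n_bins) - 1L) * as.integer(bin_size) + 1L,
      bin_end = pmin(seq_len(n_bins) * as.integer(bin_size), lens[[cn]])
    )
  })
  if (nrow(records) > 0) {
    hits <- records %>%
      dplyr::mutate(
        bin_start = (ceiling(.data$position / bin_size) - 1L) *
          as.integer(bin_size) + 1L
      ) %>%
      dplyr::count(.data$chromosome, .data$bin_start, name = "insertion_count")
    bins <- dplyr::left_join(bins, hits, by = c("chromosome", "bin_start"))
    bins$insertion_count[is.na(bins$insertion_count)] <- 0L
  } else {
    bins$insertion_count <- 0L
  }
  bins
}
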