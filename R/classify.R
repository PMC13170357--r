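#' Classify a barcode's insertion from its read-level mapping evidence
#'
#' Aggregates the per-read locus calls of one barcode into the pool-file
#' classification:
#'
#' * `concatameric` — insert-derived: a strict majority of the barcode's
#'   aligned reads match the T-DNA/vector sequence better than the genome;
#' * `ambiguous` — two or more resolved unique genomic loci conflict
#'   (different chromosome or strand, or >= 10 bp apart after near-position
#'   resolution);
#' * `multi-locus` — no read passes the bitscore-gap uniqueness test but at
#'   least one aligns to multiple genomic loci;
#' * `single` — exactly one resolved unique locus; its position is the most
#'   abundantly supported locus among reads < 10 bp apart, and `read_support`
#'   is the number of uniquely mapped reads behind it.
#'
#' @param evidence Tibble with one row per read of the barcode: `status`
#'   (`"unique"`, `"multi-locus"`, `"insert"`, `"unaligned"`) and, for unique
#'   reads, `chromosome`, `position`, `strand`.
#' @param min_dist Near-position merge radius in bp (default 10).
#' @return One-row tibble (`classification`, `chromosome`, `position`,
#'   `strand`, `read_support`). Non-single classifications carry `NA`
#'   coordinates; `read_support` is the barcode's total informative reads.
#' @export
classify_insertion <- function(evidence, min_dist = 10) {
  evidence <- tibble::as_tibble(evidence)
  stopifnot("status" %in% names(evidence))
  n_insert <- sum(evidence$status == "insert")
  n_unique <- sum(evidence$status == "unique")
  n_multi <- sum(evidence$status == "multi-locus")
  n_aligned <- n_insert + n_unique + n_multi

  non_single <- function(class, support) {
    tibble::tibble(
      classification = class, chromosome = NA_character_,
      position = NA_integer_, strand = NA_character_,
      read_support = as.integer(support)
    )
  }
  if (n_aligned == 0) {
    return(non_single("unaligned", 0))
  }
  if (n_insert > n_aligned / 2) {
    return(non_single("concatameric", n_aligned))
  }
  if (n_unique == 0) {
    return(non_single("multi-locus", n_aligned))
  }
  uq <- evidence[evidence$status == "unique", ]
  loci <- uq %>%
    dplyr::count(.data$chromosome, .data$strand, .data$position,
      name = "count"
    ) %>%
    resolve_near_positions(min_dist = min_dist)
  if (nrow(loci) > 1) {
    return(non_single("ambiguous", n_aligned))
  }
  tibble::tibble(
    classification = "single",
    chromosome = loci$chromosome[1],
    position = as.integer(loci$position[1]),
    strand = loci$strand[1],
    read_support = as.integer(loci$count[1])
  )
}
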