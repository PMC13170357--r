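#' Simulate a ground-truth set of barcoded insertions
#'
#' Insertion positions are uniform over the genome, optionally with one
#' rectangular hotspot window whose per-base insertion density is multiplied
#' by an enrichment factor (emulating the transcription-driven insertion peaks
#' seen in real T-DNA pools). Each insertion carries a distinct random barcode
#' and a lognormal baseline abundance for downstream BarSeq simulation.
#'
#' The stored position is the first genomic base adjacent to the T-DNA right
#' arm; `strand` records the direction in which the genomic flank reads into
#' the genome from that base.
#'
#' @param genome An [annotated_genome].
#' @param n Number of insertions (>= 1).
#' @param hotspot Optional list with `chromosome`, `start`, `end`,
#'   `enrichment` (fold increase in per-base density inside the window).
#' @param barcode_length Barcode length in nt (default 20).
#' @param baseline_sdlog Lognormal sigma of baseline mutant abundances
#'   (default 0.4, moderate clone-abundance dispersion; see the package
#'   vignette for how dispersion interacts with gene-mean baseline
#'   normalization).
#' @param gene_effects Optional named numeric vector, `gene_id` -> true
#'   log2(50C/37C) effect planted on every mutant of that gene.
#' @param seed Integer RNG seed.
#' @return An `insertion_truth` object: list with `insertions` (tibble:
#'   `barcode`, `chromosome`, `position`, `strand`, `gene_id`,
#'   `baseline_abundance`), `gene_effects`, `hotspot`.
#' @export
simulate_insertions <- function(genome, n, hotspot = NULL, barcode_length = 20,
                                baseline_sdlog = 0.4, gene_effects = NULL,
                                seed = 1) {
  stopifnot(inherits(genome, "annotated_genome"), n >= 1, barcode_length >= 4)
  lens <- chrom_lengths(genome)
  if (!is.null(hotspot)) {
    req <- c("chromosome", "start", "end", "enrichment")
    if (!all(req %in% names(hotspot))) {
      abort("hotspot needs fields: chromosome, start, end, enrichment")
    }
    if (!hotspot$chromosome %in% names(lens) ||
      hotspot$start < 1 || hotspot$end > lens[[hotspot$chromosome]] ||
      hotspot$start > hotspot$end) {
      abort("hotspot interval outside genome")
    }
    if (hotspot$enrichment <= 0) abort("hotspot enrichment must be positive")
  }
  gene_effects <- gene_effects %||% stats::setNames(numeric(0), character(0))
  if (length(gene_effects) > 0 &&
    !all(names(gene_effects) %in% genome$genes$gene_id)) {
    abort("gene_effects names must be gene ids of the genome")
  }

  with_seed(seed, {
    # per-base sampling weights: 1 outside the hotspot, `enrichment` inside
    total <- sum(lens)
    if (is.null(hotspot)) {
      gpos <- sample.int(total, n, replace = TRUE)
    } else {
      hs_len <- hotspot$end - hotspot$start + 1
      w_hs <- hs_len * hotspot$enrichment
      in_hs <- stats::runif(n) < w_hs / (w_hs + (total - hs_len))
      offset <- cumsum(c(0, lens))[match(hotspot$chromosome, names(lens))]
      gpos <- integer(n)
      n_in <- sum(in_hs)
      gpos[in_hs] <- offset + hotspot$start - 1L +
        sample.int(hs_len, n_in, replace = TRUE)
      # rejection-free background draw over the complement
      bg <- sample.int(total - hs_len, n - n_in, replace = TRUE)
      hs_lo <- offset + hotspot$start - 1L
      bg <- ifelse(bg > hs_lo, bg + hs_len, bg)
      gpos[!in_hs] <- bg
    }
    cum <- cumsum(lens)
    chrom_idx <- findInterval(gpos - 1L, c(0L, cum), rightmost.closed = FALSE)
    chrom <- names(lens)[chrom_idx]
    position <- gpos - c(0L, cum)[chrom_idx]

    barcodes <- unique(random_dna(n, barcode_length))
    while (length(barcodes) < n) {
      barcodes <- unique(c(barcodes, random_dna(n - length(barcodes), barcode_length)))
    }
    ins <- tibble::tibble(
      barcode = barcodes[seq_len(n)],
      chromosome = chrom,
      position = as.integer(position),
      strand = sample(c("+", "-"), n, replace = TRUE),
      baseline_abundance = stats::rlnorm(n, meanlog = 0, sdlog = baseline_sdlog)
    )
    ins$gene_id <- gene_at_positions(genome, ins$chromosome, ins$position)
    structure(
      list(insertions = ins, gene_effects = gene_effects, hotspot = hotspot),
      class = "insertion_truth"
    )
  })
}

#' @export
print.insertion_truth <- function(x, ...) {
  cat(sprintf(
    "<insertion_truth> %d insertion(s), %d genic, %d gene(s) with planted effects\n",
    nrow(x$insertions), sum(x$insertions$gene_id != "intergenic"),
    length(x$gene_effects)
  ))
  invisible(x)
}

# first containing gene per position ("intergenic" when none); generator-side
# convenience, independent of the mapping module's multi-feature handling
gene_at_positions <- function(genome, chromosome, position) {
  g <- genome$genes
  if (nrow(g) == 0) {
    return(rep("intergenic", length(position)))
  }
  q <- GenomicRanges::GRanges(chromosome, IRanges::IRanges(position, position))
  s <- GenomicRanges::GRanges(g$chromosome, IRanges::IRanges(g$start, g$end))
  ov <- GenomicRanges::findOverlaps(q, s, select = "first")
  out <- rep("intergenic", length(position))
  hit <- !is.na(ov)
  out[hit] <- g$gene_id[ov[hit]]
  out
}

#' Simulate a truth set with a fixed number of barcodes per gene
#'
#' Calibration-study variant of [simulate_insertions()]: places exactly
#' `barcodes_per_gene` insertions uniformly inside every annotated gene, so
#' gene-level statistics see a balanced design (e.g. 200 genes x 5 barcodes).
#'
#' @inheritParams simulate_insertions
#' @param barcodes_per_gene Insertions planted in each gene.
#' @return An `insertion_truth` object (see [simulate_insertions()]).
#' @export
simulate_gene_pool_truth <- function(genome, barcodes_per_gene = 5,
                                     barcode_length = 20, baseline_sdlog = 0.4,
                                     gene_effects = NULL, seed = 1) {
  stopifnot(inherits(genome, "annotated_genome"), barcodes_per_gene >= 1)
  g <- genome$genes
  if (nrow(g) == 0) abort("genome has no annotated genes")
  gene_effects <- gene_effects %||% stats::setNames(numeric(0), character(0))
  with_seed(seed, {
    idx <- rep(seq_len(nrow(g)), each = barcodes_per_gene)
    position <- g$start[idx] +
      vapply(g$end[idx] - g$start[idx] + 1L, sample.int, integer(1), size = 1) - 1L
    n <- length(idx)
    barcodes <- unique(random_dna(n, barcode_length))
    while (length(barcodes) < n) {
      barcodes <- unique(c(barcodes, random_dna(n - length(barcodes), barcode_length)))
    }
    ins <- tibble::tibble(
      barcode = barcodes[seq_len(n)],
      chromosome = g$chromosome[idx],
      position = as.integer(position),
      strand = sample(c("+", "-"), n, replace = TRUE),
      baseline_abundance = stats::rlnorm(n, 0, baseline_sdlog),
      gene_id = g$gene_id[idx]
    )
    structure(
      list(insertions = ins, gene_effects = gene_effects, hotspot = NULL),
      class = "insertion_truth"
    )
  })
}

#' Plant log2 temperature effects on a set of genes
#'
#' Convenience for simulation studies: selects genes that carry at least
#' `min_barcodes` insertions in the truth set and assigns them the given
#' log2(50C/37C) effect.
#'
#' @param truth An `insertion_truth`.
#' @param n_genes Number of genes to affect.
#' @param effect Planted log2 effect (scalar or length `n_genes`).
#' @param min_barcodes Minimum insertions a gene must carry to be eligible.
#' @param seed Integer RNG seed.
#' @return The truth object with `gene_effects` replaced.
#' @export
plant_gene_effects <- function(truth, n_genes, effect, min_barcodes = 1,
                               seed = 1) {
  stopifnot(inherits(truth, "insertion_truth"))
  tab <- table(truth$insertions$gene_id)
  tab <- tab[names(tab) != "intergenic" & tab >= min_barcodes]
  if (length(tab) < n_genes) {
    abort(sprintf(
      "only %d gene(s) carry >= %d barcodes; cannot plant %d effects",
      length(tab), min_barcodes, n_genes
    ))
  }
  with_seed(seed, {
    chosen <- sample(names(tab), n_genes)
    truth$gene_effects <- stats::setNames(rep_len(effect, n_genes), chosen)
    truth
  })
}
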