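#' Annotated genome: chromosome sequences plus gene intervals
#'
#' The coordinate frame for all insertion mapping. Chromosome sequences are
#' stored as a named character vector; genes as a tibble of 1-based inclusive
#' intervals, the GFF convention used throughout the package.
#'
#' @param chromosomes Named character vector of A/C/G/T sequences.
#' @param genes Tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(chromosomes, genes) {
  stopifnot(is.character(chromosomes), !is.null(names(chromosomes)))
  assert_dna(chromosomes, "chromosome sequence")
  genes <- tibble::as_tibble(genes)
  req <- c("gene_id", "chromosome", "start", "end", "strand")
  if (!all(req %in% names(genes))) {
    abort(paste0("genes must have columns: ", paste(req, collapse = ", ")))
  }
  if (any(!genes$chromosome %in% names(chromosomes))) {
    abort("gene on unknown chromosome")
  }
  if (any(genes$start > genes$end)) {
    abort("gene start must be <= end")
  }
  lens <- nchar(chromosomes)[genes$chromosome]
  if (any(genes$start < 1L) || any(genes$end > lens)) {
    abort("gene interval outside chromosome bounds")
  }
  structure(
    list(chromosomes = chromosomes, genes = genes),
    class = "annotated_genome"
  )
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf(
    "<annotated_genome> %d chromosome(s), %s bp total, %d gene(s)\n",
    length(x$chromosomes), format(sum(nchar(x$chromosomes)), big.mark = ","),
    nrow(x$genes)
  ))
  invisible(x)
}

#' Chromosome lengths of an annotated genome
#' @param genome An `annotated_genome`.
#' @return Named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  vapply(genome$chromosomes, nchar, integer(1))
}

#' Simulate a small annotated genome
#'
#' Draws i.i.d. bases at the requested GC content and places non-overlapping
#' genes uniformly along each chromosome. Genes are allocated to chromosomes
#' proportionally to length (largest-remainder rounding); within a chromosome
#' the inter-gene gaps are drawn from a symmetric multinomial so placement is
#' uniform given the gene lengths. Identical arguments and seed give
#' byte-identical output.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_lengths Integer vector of lengths (bp); recycled to
#'   `n_chromosomes`.
#' @param n_genes Total number of genes to place.
#' @param gene_length_range Length-2 integer vector, min/max gene length (bp).
#' @param gc_content GC fraction in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return An [annotated_genome].
#' @examples
#' g <- simulate_genome(1, 10000, n_genes = 5, gene_length_range = c(500, 500), seed = 7)
#' g$genes
#' @export
simulate_genome <- function(n_chromosomes, chromosome_lengths, n_genes,
                            gene_length_range = c(800, 2000),
                            gc_content = 0.5, seed = 1) {
  stopifnot(
    n_chromosomes >= 1, n_genes >= 0,
    gc_content >= 0, gc_content <= 1,
    length(gene_length_range) == 2,
    gene_length_range[1] <= gene_length_range[2],
    gene_length_range[1] >= 1
  )
  lens <- as.integer(rep_len(chromosome_lengths, n_chromosomes))
  if (any(lens < 1L)) abort("chromosome lengths must be positive")

  with_seed(seed, {
    chrom_names <- sprintf("chr%d", seq_len(n_chromosomes))
    chroms <- stats::setNames(vapply(lens, function(L) {
      random_dna(1, L, gc_content)
    }, character(1)), chrom_names)

    # allocate gene counts per chromosome, proportional to length
    alloc <- largest_remainder(lens / sum(lens) * n_genes)
    gene_rows <- vector("list", n_chromosomes)
    gid <- 0L
    for (i in seq_len(n_chromosomes)) {
      k <- alloc[i]
      if (k == 0L) next
      len_choices <- seq(gene_length_range[1], gene_length_range[2])
      glens <- len_choices[sample.int(length(len_choices), k, replace = TRUE)]
      free <- lens[i] - sum(glens)
      if (free < 0L) {
        abort(sprintf(
          "cannot place %d genes (%d bp) on chromosome of %d bp",
          k, sum(glens), lens[i]
        ))
      }
      # uniform composition of the free space into k + 1 gaps
      gaps <- as.vector(stats::rmultinom(1, free, rep(1, k + 1)))
      starts <- integer(k)
      pos <- 1L + gaps[1]
      for (j in seq_len(k)) {
        starts[j] <- pos
        pos <- pos + glens[j] + gaps[j + 1]
      }
      gene_rows[[i]] <- tibble::tibble(
        gene_id = sprintf("gene_%04d", gid + seq_len(k)),
        chromosome = chrom_names[i],
        start = starts,
        end = starts + glens - 1L,
        strand = sample(c("+", "-"), k, replace = TRUE)
      )
      gid <- gid + k
    }
    genes <- dplyr::bind_rows(gene_rows)
    if (nrow(genes) == 0) {
      genes <- tibble::tibble(
        gene_id = character(), chromosome = character(),
        start = integer(), end = integer(), strand = character()
      )
    }
    annotated_genome(chroms, genes)
  })
}

# integer allocation summing to round(sum(x)) by largest remainder
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    bump <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[bump] <- fl[bump] + 1
  }
  as.integer(fl)
}

#' Write an annotated genome as FASTA + GFF3
#'
#' @param genome An [annotated_genome].
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, the genome.
#' @export
write_genome <- function(genome, fasta_path, gff_path) {
  stopifnot(inherits(genome, "annotated_genome"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$chromosomes), fasta_path
  )
  g <- genome$genes
  lines <- c(
    "##gff-version 3",
    sprintf(
      "%s\ttnbarseq\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      g$chromosome, g$start, g$end, g$strand, g$gene_id
    )
  )
  writeLines(lines, gff_path)
  invisible(genome)
}

#' Read an annotated genome from FASTA + GFF3
#'
#' Uses `Biostrings` for the FASTA and `rtracklayer` for the GFF3; features of
#' type `gene` with an `ID` attribute become the gene table.
#'
#' @param fasta_path,gff_path Input paths.
#' @return An [annotated_genome].
#' @export
read_genome <- function(fasta_path, gff_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  chroms <- stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_genome() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  genes <- tibble::tibble(
    gene_id = as.character(gr$ID),
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  annotated_genome(chroms, genes)
}
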