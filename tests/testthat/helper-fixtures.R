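# Shared small fixtures, built in code at test time.

JX <- "CGGTCTGACAATCGCTAGGC" # arbitrary fixed right-arm junction for tests

tiny_genome <- function(seed = 7) {
  simulate_genome(2, c(30000, 20000),
    n_genes = 12, gene_length_range = c(600, 1000), seed = seed
  )
}

# truth-derived pool (bypasses mapping) for fitness tests
truth_pool <- function(truth) {
  ins <- truth$insertions
  structure(
    tibble::tibble(
      barcode = ins$barcode, chromosome = ins$chromosome,
      position = ins$position, strand = ins$strand,
      classification = "single", read_support = 10L,
      gene_id = ins$gene_id, multi_feature = FALSE, batch = "b1"
    ),
    class = c("tn_pool", class(tibble::tibble()))
  )
}

# minimal raw count table for hand-built fitness cases
manual_counts <- function(mat, temperatures, replicates) {
  meta <- tibble::tibble(
    sample_id = colnames(mat),
    temperature = temperatures,
    replicate = replicates,
    batch = "b1"
  )
  bc_counts(tibble::as_tibble(mat, rownames = "barcode"), meta = meta)
}
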