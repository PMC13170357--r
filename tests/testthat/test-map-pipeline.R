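# End-to-end junction-read mapping against simulated truth.

test_that("error-free reads with unique flanks are recovered exactly", {
  g <- simulate_genome(3, c(60000, 50000, 40000), n_genes = 30, seed = 11)
  tr <- simulate_insertions(g, 60, seed = 12)
  reads <- simulate_tnseq_reads(tr, g, JX,
    flank_length = 60,
    reads_per_insertion = 3, seed = 13
  )
  pool <- map_tnseq(reads, g, junction = JX)
  expect_s3_class(pool, "tn_pool")
  truth <- tr$insertions
  got <- pool[match(truth$barcode, pool$barcode), ]
  expect_true(all(got$classification == "single"))
  expect_equal(got$position, truth$position)
  expect_equal(got$chromosome, truth$chromosome)
  expect_equal(got$strand, truth$strand)
  expect_true(all(got$read_support >= 1))
  # gene assignment agrees with the generator's interval annotation
  expect_equal(
    sub(";.*$", "", got$gene_id)[!got$multi_feature],
    truth$gene_id[!got$multi_feature]
  )
})

test_that("a concatameric barcode (flank inside the T-DNA) is excluded as insert-derived", {
  g <- simulate_genome(1, 50000, n_genes = 0, seed = 14)
  tdna <- simulate_genome(1, 3000, n_genes = 0, seed = 15)$chromosomes[[1]]
  # one genuine genomic insertion, one barcode whose flank is T-DNA sequence
  tr <- simulate_insertions(g, 1, seed = 16)
  genomic <- simulate_tnseq_reads(tr, g, JX,
    flank_length = 50,
    reads_per_insertion = 2, seed = 17
  )
  bc2 <- strrep("AC", 10)
  concat <- tibble::tibble(
    read_id = c("read_900001", "read_900002"),
    sequence = paste0(bc2, JX, substr(tdna, 501, 550))
  )
  reads <- dplyr::bind_rows(genomic, concat)
  pool <- map_tnseq(reads, g,
    junction = JX,
    insert_seq = paste0(tdna, JX)
  )
  expect_equal(
    pool$classification[pool$barcode == bc2], "concatameric"
  )
  expect_equal(
    pool$classification[pool$barcode == tr$insertions$barcode], "single"
  )
})

test_that("a flank duplicated at two loci is classified multi-locus", {
  base <- simulate_genome(1, 40000, n_genes = 0, seed = 18)$chromosomes[[1]]
  seg <- substr(base, 2001, 2060)
  chrom <- paste0(base, strrep("A", 40), seg)
  g <- annotated_genome(
    c(chr1 = chrom),
    tibble::tibble(
      gene_id = character(), chromosome = character(),
      start = integer(), end = integer(), strand = character()
    )
  )
  bc <- strrep("GT", 10)
  reads <- tibble::tibble(
    read_id = "read_000001",
    sequence = paste0(bc, JX, seg)
  )
  pool <- map_tnseq(reads, g, junction = JX)
  expect_equal(pool$classification[pool$barcode == bc], "multi-locus")
  expect_true(is.na(pool$position[pool$barcode == bc]))
})

test_that("batches are merged before collapsing with provenance retained", {
  g <- simulate_genome(1, 50000, n_genes = 5, seed = 19)
  tr <- simulate_insertions(g, 10, seed = 20)
  r1 <- simulate_tnseq_reads(tr, g, JX, reads_per_insertion = 2, seed = 21)
  r2 <- simulate_tnseq_reads(tr, g, JX, reads_per_insertion = 2, seed = 22)
  pool <- map_tnseq(list(batch1 = r1, batch2 = r2), g, junction = JX)
  expect_true(all(pool$batch == "batch1;batch2"))
  expect_true(all(pool$read_support == 4))
})

test_that("pool files round-trip through TSV", {
  g <- simulate_genome(1, 50000, n_genes = 5, seed = 23)
  tr <- simulate_insertions(g, 8, seed = 24)
  reads <- simulate_tnseq_reads(tr, g, JX, reads_per_insertion = 2, seed = 25)
  pool <- map_tnseq(reads, g, junction = JX)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pool(pool, path)
  back <- read_pool(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(pool)[TRUE, ],
    ignore_attr = TRUE
  )
})

test_that("the run log accounts for every read", {
  g <- simulate_genome(1, 50000, n_genes = 5, seed = 26)
  tr <- simulate_insertions(g, 10, seed = 27)
  reads <- simulate_tnseq_reads(tr, g, JX, reads_per_insertion = 3, seed = 28)
  # append a junk read with no junction
  reads <- dplyr::bind_rows(
    reads,
    tibble::tibble(read_id = "read_999999", sequence = strrep("ACGT", 40))
  )
  pool <- map_tnseq(reads, g, junction = JX)
  log <- attr(pool, "run_log")
  expect_equal(log$reads_in, 31)
  expect_equal(log$junction_found, 30)
  expect_equal(log$usable_reads, 30)
  expect_equal(log$single, 10L)
})
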