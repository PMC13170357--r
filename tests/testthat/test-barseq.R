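LF <- "GATGTCCACGAGGTCTCT" # constant priming sites used across tests
RF <- "CGTACGCTGCAGGTCGAC"

test_that("barcode extraction honors flanks, lengths and mismatch tolerance", {
  bc <- strrep("ACGT", 5)
  expect_equal(extract_barcode(paste0("TT", LF, bc, RF, "AA"), LF, RF), bc)
  # missing right flank
  expect_true(is.na(extract_barcode(paste0("TT", LF, bc, "AAAAAAAAAAAAAAAAAAAA"), LF, RF)))
  # one substitution in the left flank still anchors
  lf1 <- paste0("C", substr(LF, 2, nchar(LF)))
  expect_equal(extract_barcode(paste0(lf1, bc, RF), LF, RF), bc)
  # two substitutions exceed the default tolerance
  lf2 <- paste0("CC", substr(LF, 3, nchar(LF)))
  expect_true(is.na(extract_barcode(paste0(lf2, bc, RF), LF, RF)))
  # read too short to hold the barcode window
  expect_true(is.na(extract_barcode(paste0(LF, substr(bc, 1, 10)), LF, RF)))
  expect_error(extract_barcode("ACGT", "", RF), "non-empty")
})

test_that("extraction with a mismatched anchor matches an exhaustive scan", {
  set.seed(91)
  for (i in 1:25) {
    bc <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
    pre <- paste(sample(c("A", "C", "G", "T"), sample(0:6, 1), replace = TRUE),
      collapse = ""
    )
    read <- paste0(pre, LF, bc, RF, "GG")
    # exhaustive reference: try every offset for the left flank
    offs <- 1:(nchar(read) - nchar(LF) + 1)
    mm <- vapply(offs, function(o) {
      sum(strsplit(substr(read, o, o + nchar(LF) - 1), "")[[1]] !=
        strsplit(LF, "")[[1]])
    }, numeric(1))
    stopifnot(any(mm <= 1))
    expect_equal(extract_barcode(read, LF, RF), bc)
  }
})

test_that("counting links to the pool and tallies unassigned reads", {
  pool <- tibble::tibble(
    barcode = c(strrep("A", 20), strrep("C", 20)),
    classification = c("single", "multi-locus")
  )
  meta <- tibble::tibble(
    sample_id = "37_1", temperature = 37, replicate = 1L, batch = "b1"
  )
  ext <- tibble::tibble(
    sample_id = "37_1",
    barcode = c(pool$barcode[1], pool$barcode[1], pool$barcode[2], strrep("G", 20), NA)
  )
  cts <- count_and_link(ext, pool, meta)
  m <- tibble::as_tibble(cts)
  expect_equal(m[["37_1"]][m$barcode == pool$barcode[1]], 2L)
  expect_equal(m[["37_1"]][m$barcode == pool$barcode[2]], 1L)
  log <- attr(cts, "run_log")
  expect_equal(log$reads, 5L)
  expect_equal(log$extracted, 4L)
  expect_equal(log$assigned, 3L)
  expect_equal(log$unassigned, 1L)
  # conservation: assigned + unassigned = extracted
  expect_equal(log$assigned + log$unassigned, log$extracted)
})

test_that("Hamming-1 rescue assigns near-miss barcodes only when unambiguous", {
  b1 <- strrep("A", 20)
  pool <- tibble::tibble(barcode = b1, classification = "single")
  meta <- tibble::tibble(
    sample_id = "37_1", temperature = 37, replicate = 1L, batch = "b1"
  )
  miss <- paste0("C", strrep("A", 19))
  ext <- tibble::tibble(sample_id = "37_1", barcode = miss)
  off <- count_and_link(ext, pool, meta)
  expect_equal(attr(off, "run_log")$assigned, 0L)
  on <- count_and_link(ext, pool, meta, rescue_hamming1 = TRUE)
  expect_equal(attr(on, "run_log")$assigned, 1L)
  expect_equal(tibble::as_tibble(on)[["37_1"]], 1L)
})

test_that("normalization scales columns to the target and is scale-invariant", {
  mat <- matrix(c(10, 90, 20, 180), nrow = 2,
    dimnames = list(c("b1", "b2"), c("37_1", "37_2"))
  )
  cts <- manual_counts(mat, c(37, 37), c(1L, 2L))
  norm <- normalize_total(cts)
  m <- tibble::as_tibble(norm)
  expect_equal(m[["37_1"]], c(1e5, 9e5))
  expect_true(all(abs(colSums(as.matrix(m[, -1])) - 1e6) < 1e-6))
  # scale invariance: doubling a raw column leaves its normalized column unchanged
  mat2 <- mat
  mat2[, 1] <- mat2[, 1] * 7
  norm2 <- normalize_total(manual_counts(mat2, c(37, 37), c(1L, 2L)))
  expect_equal(tibble::as_tibble(norm2)[["37_1"]], m[["37_1"]])
  # zero-total sample errors by name
  mat3 <- mat
  mat3[, 2] <- 0
  expect_error(
    normalize_total(manual_counts(mat3, c(37, 37), c(1L, 2L))), "37_2"
  )
})

test_that("replicate concordance reports r, R^2 and handles degenerate columns", {
  mat <- matrix(c(1, 2, 3, 4, 1, 2, 3, 4, 4, 3, 2, 1), nrow = 4,
    dimnames = list(paste0("b", 1:4), c("37_1", "37_2", "37_3"))
  )
  cts <- manual_counts(mat, c(37, 37, 37), 1:3)
  cc <- replicate_concordance(cts)
  dup <- cc[cc$sample_a == "37_1" & cc$sample_b == "37_2", ]
  expect_equal(dup$pearson_r, 1)
  expect_equal(dup$r_squared, 1)
  anti <- cc[cc$sample_a == "37_1" & cc$sample_b == "37_3", ]
  expect_equal(anti$pearson_r, -1)
  # constant column: undefined, reported NA rather than 0
  mat2 <- cbind(mat[, 1, drop = FALSE], `37_2` = rep(5, 4))
  cc2 <- replicate_concordance(manual_counts(mat2, c(37, 37), 1:2))
  expect_true(is.na(cc2$pearson_r))
})

test_that("independent random columns are uncorrelated under the null", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    a <- stats::rpois(1000, 50)
    b <- stats::rpois(1000, 50)
    abs(stats::cor(a, b)) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
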