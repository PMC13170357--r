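#' Map TnSeq junction reads into an annotated insertion pool file
#'
#' The full junction-read pipeline: detect the T-DNA right-arm junction in
#' each read (<= `max_mismatches` substitutions), split the read into barcode
#' (the bases before the junction) and genomic flank (the bases after it),
#' collapse Hamming-1 barcode sequencing errors, align each distinct flank to
#' the genome (and, when `insert_seq` is given, to the insert sequence) with
#' the internal seed-and-extend aligner, resolve per-read uniqueness by the
#' bitscore-gap rule, classify each barcode (single / multi-locus /
#' concatameric / ambiguous), resolve near-identical positions (< 10 bp), and
#' assign genes by coordinate intersection.
#'
#' Reads whose pre-junction prefix is not exactly `barcode_length` nt, or
#' whose flank is shorter than `min_flank`, are dropped and tallied in the
#' run log. Multiple sequencing batches are concatenated before collapsing;
#' per-batch read support is kept in the `batch` column.
#'
#' @param reads Tibble (`read_id`, `sequence`), or a named list of such
#'   tibbles (names become batches).
#' @param genome An [annotated_genome].
#' @param junction T-DNA right-arm junction sequence.
#' @param insert_seq Optional full T-DNA/vector sequence for the
#'   insert-derived (concatameric) test; `NULL` disables it.
#' @param barcode_length Expected barcode length in nt (default 20).
#' @param max_mismatches Junction-window mismatch tolerance (default 2).
#' @param min_identity,max_evalue Alignment retention thresholds (95, 0.1).
#' @param min_bit_gap Uniqueness bitscore gap (default 10).
#' @param min_flank Minimum usable flank length in nt (default 20).
#' @param min_dist Near-position merge radius in bp (default 10).
#' @param k Aligner seed length.
#' @return A `tn_pool`: tibble with one row per barcode (`barcode`,
#'   `chromosome`, `position`, `strand`, `classification`, `read_support`,
#'   `gene_id`, `multi_feature`, `batch`), with a `run_log` attribute.
#' @export
map_tnseq <- function(reads, genome, junction, insert_seq = NULL,
                      barcode_length = 20, max_mismatches = 2,
                      min_identity = 95, max_evalue = 0.1, min_bit_gap = 10,
                      min_flank = 20, min_dist = 10, k = 12) {
  stopifnot(inherits(genome, "annotated_genome"))
  assert_dna(junction, "junction")
  if (is.data.frame(reads)) reads <- list(batch1 = reads)
  if (is.null(names(reads))) {
    names(reads) <- sprintf("batch%d", seq_along(reads))
  }
  reads <- dplyr::bind_rows(reads, .id = "batch")
  # read ids may repeat across batches; qualify them for internal joins
  reads$read_id <- paste(reads$batch, reads$read_id, sep = ":")
  n_reads <- nrow(reads)

  jm <- find_junction(reads, junction, max_mismatches = max_mismatches)
  jm <- dplyr::left_join(jm, reads[c("read_id", "batch")], by = "read_id")
  n_junction <- nrow(jm)
  jm$barcode <- substr(
    reads$sequence[match(jm$read_id, reads$read_id)], 1, jm$offset
  )
  ok_bc <- jm$offset == barcode_length
  ok_fl <- nchar(jm$flank) >= min_flank
  usable <- jm[ok_bc & ok_fl, ]

  # Hamming-1 barcode error collapsing on read counts (batches pooled)
  if (nrow(usable) > 0) {
    collapsed <- collapse_barcode_errors(
      dplyr::count(usable, .data$barcode, name = "count")
    )
    absorbed <- attr(collapsed, "absorbed")
    if (nrow(absorbed) > 0) {
      hit <- match(usable$barcode, absorbed$barcode)
      usable$barcode[!is.na(hit)] <- absorbed$into[hit[!is.na(hit)]]
    }
  }

  run_log <- tibble::tibble(
    reads_in = n_reads,
    junction_found = n_junction,
    bad_barcode = sum(!ok_bc),
    short_flank = sum(ok_bc & !ok_fl),
    usable_reads = nrow(usable)
  )

  empty_pool <- tibble::tibble(
    barcode = character(), chromosome = character(), position = integer(),
    strand = character(), classification = character(),
    read_support = integer(), gene_id = character(),
    multi_feature = logical(), batch = character()
  )
  if (nrow(usable) == 0) {
    return(structure(empty_pool,
      run_log = run_log,
      class = c("tn_pool", class(tibble::tibble()))
    ))
  }

  # align distinct flanks once; per-read status via the uniqueness rule
  genome_hits <- align_flanks(usable$flank, genome,
    min_identity = min_identity, max_evalue = max_evalue, k = k,
    min_flank = min_flank
  )
  insert_best <- NULL
  if (!is.null(insert_seq)) {
    ins_hits <- align_flanks(
      usable$flank,
      list(chromosomes = c(insert = insert_seq)),
      min_identity = min_identity, max_evalue = max_evalue, k = k,
      min_flank = min_flank
    )
    insert_best <- ins_hits %>%
      dplyr::group_by(.data$flank) %>%
      dplyr::summarise(insert_bits = max(.data$bitscore), .groups = "drop")
  }

  flank_status <- purrr::map_dfr(unique(usable$flank), function(f) {
    hits <- genome_hits[genome_hits$flank == f, ]
    res <- resolve_uniqueness(hits, min_bit_gap = min_bit_gap)
    best_bits <- if (nrow(hits) > 0) max(hits$bitscore) else -Inf
    ins_bits <- if (!is.null(insert_best) && f %in% insert_best$flank) {
      insert_best$insert_bits[insert_best$flank == f]
    } else {
      -Inf
    }
    if (ins_bits > best_bits) {
      return(tibble::tibble(
        flank = f, status = "insert", chromosome = NA_character_,
        position = NA_integer_, strand = NA_character_
      ))
    }
    if (res$status == "unique") {
      tibble::tibble(
        flank = f, status = "unique",
        chromosome = res$best$chromosome,
        position = res$best$insertion_pos,
        strand = res$best$strand
      )
    } else {
      tibble::tibble(
        flank = f, status = res$status, chromosome = NA_character_,
        position = NA_integer_, strand = NA_character_
      )
    }
  })
  evidence <- dplyr::left_join(usable, flank_status, by = "flank")

  pool <- evidence %>%
    dplyr::group_by(.data$barcode) %>%
    dplyr::group_modify(function(df, key) {
      cls <- classify_insertion(
        df[c("status", "chromosome", "position", "strand")],
        min_dist = min_dist
      )
      cls$batch <- paste(sort(unique(df$batch)), collapse = ";")
      cls
    }) %>%
    dplyr::ungroup()

  n_unaligned <- sum(pool$classification == "unaligned")
  pool <- pool[pool$classification != "unaligned", ]
  pool <- annotate_insertions(pool, genome)
  pool <- dplyr::select(
    pool, "barcode", "chromosome", "position", "strand",
    "classification", "read_support", "gene_id", "multi_feature", "batch"
  )
  run_log$unaligned_barcodes <- n_unaligned
  run_log <- dplyr::bind_cols(
    run_log,
    tibble::as_tibble(as.list(table(
      factor(pool$classification,
        levels = c("single", "multi-locus", "concatameric", "ambiguous")
      )
    )))
  )
  structure(dplyr::arrange(pool, .data$chromosome, .data$position),
    run_log = run_log,
    class = c("tn_pool", class(tibble::tibble()))
  )
}

#' @export
print.tn_pool <- function(x, ...) {
  cat(sprintf(
    "<tn_pool> %d barcode(s): %d single, %d multi-locus, %d concatameric, %d ambiguous\n",
    nrow(x), sum(x$classification == "single"),
    sum(x$classification == "multi-locus"),
    sum(x$classification == "concatameric"),
    sum(x$classification == "ambiguous")
  ))
  NextMethod()
}

#' Write / read a pool file (TSV)
#'
#' Columns: `barcode`, `chromosome`, `position`, `strand`, `classification`,
#' `read_support`, `gene_id`, `multi_feature`, `batch`. Write-then-read
#' round-trips to identical records.
#'
#' @param pool A `tn_pool` (or compatible tibble).
#' @param path TSV path.
#' @return Invisibly `path`; [read_pool()] returns the pool tibble.
#' @export
write_pool <- function(pool, path) {
  readr::write_tsv(tibble::as_tibble(pool), path)
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  pool <- readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols(
    barcode = "c", chromosome = "c", position = "i", strand = "c",
    classification = "c", read_support = "i", gene_id = "c",
    multi_feature = "l", batch = "c"
  ))
  structure(pool, class = c("tn_pool", class(tibble::tibble())))
}
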