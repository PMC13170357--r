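#' Barcode-by-sample count table with sample metadata
#'
#' A thin tibble subclass: first column `barcode`, one numeric column per
#' sample. Sample metadata (`sample_id`, `temperature`, `replicate`, `batch`)
#' travels in the `meta` attribute; `normalized` records whether columns are
#' raw counts or total-count-scaled abundances.
#'
#' @param counts Tibble/data frame, column `barcode` plus one column per sample.
#' @param meta Tibble with columns `sample_id`, `temperature`, `replicate`,
#'   `batch`; `sample_id` must match the count columns.
#' @param normalized Logical flag.
#' @return A `bc_counts` tibble.
#' @export
bc_counts <- function(counts, meta, normalized = FALSE) {
  counts <- tibble::as_tibble(counts)
  if (names(counts)[1] != "barcode") {
    abort("first column of a count table must be 'barcode'")
  }
  meta <- tibble::as_tibble(meta)
  req <- c("sample_id", "temperature", "replicate", "batch")
  if (!all(req %in% names(meta))) {
    abort(paste0("meta must have columns: ", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(meta[c("temperature", "replicate", "batch")])) {
    abort("(temperature, replicate, batch) triples must be unique")
  }
  if (!setequal(meta$sample_id, setdiff(names(counts), "barcode"))) {
    abort("sample_id in meta must match count table columns")
  }
  if (anyDuplicated(counts$barcode)) abort("duplicate barcodes in count table")
  structure(counts,
    meta = meta, normalized = normalized,
    class = c("bc_counts", class(tibble::tibble()))
  )
}

#' @export
print.bc_counts <- function(x, ...) {
  cat(sprintf(
    "<bc_counts> %d barcode(s) x %d sample(s) [%s]\n",
    nrow(x), ncol(x) - 1,
    if (isTRUE(attr(x, "normalized"))) "normalized" else "raw counts"
  ))
  NextMethod()
}

#' Sample metadata of a count table
#' @param counts A [bc_counts] table.
#' @return The metadata tibble.
#' @export
sample_meta <- function(counts) {
  attr(counts, "meta")
}

sample_cols <- function(counts) setdiff(names(counts), "barcode")

#' Total-count normalization (counts per `target`)
#'
#' Scales every sample column by `target / column total`, the package's
#' "total-count scaling". With the default target of one million the values
#' are counts per million (CPM); any positive rescaling of a raw column
#' leaves its normalized column unchanged.
#'
#' @param counts A raw [bc_counts] table.
#' @param target Common column total after scaling (default `1e6`).
#' @return A normalized [bc_counts] table.
#' @export
normalize_total <- function(counts, target = 1e6) {
  stopifnot(inherits(counts, "bc_counts"))
  sc <- sample_cols(counts)
  totals <- vapply(counts[sc], sum, numeric(1))
  if (any(totals <= 0)) {
    abort(paste0(
      "sample(s) with zero total count: ",
      paste(sc[totals <= 0], collapse = ", ")
    ))
  }
  out <- counts
  for (s in sc) out[[s]] <- counts[[s]] * (target / totals[[s]])
  bc_counts(out, meta = sample_meta(counts), normalized = TRUE)
}

#' Pairwise replicate concordance at each temperature
#'
#' For every same-temperature sample pair, Pearson r and the coefficient of
#' determination (R^2) of the ordinary least-squares fit of one replicate on
#' the other. A constant column yields `NA` (undefined), never 0.
#'
#' @param counts A (typically normalized) [bc_counts] table.
#' @return Tibble (`temperature`, `sample_a`, `sample_b`, `pearson_r`,
#'   `r_squared`, `n_barcodes`).
#' @export
replicate_concordance <- function(counts) {
  stopifnot(inherits(counts, "bc_counts"))
  meta <- sample_meta(counts)
  out <- list()
  for (tp in unique(meta$temperature)) {
    ids <- meta$sample_id[meta$temperature == tp]
    if (length(ids) < 2) next
    prs <- utils::combn(ids, 2)
    for (q in seq_len(ncol(prs))) {
      a <- counts[[prs[1, q]]]
      b <- counts[[prs[2, q]]]
      r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        NA_real_
      } else {
        stats::cor(a, b)
      }
      out[[length(out) + 1]] <- tibble::tibble(
        temperature = tp, sample_a = prs[1, q], sample_b = prs[2, q],
        pearson_r = r, r_squared = r^2, n_barcodes = nrow(counts)
      )
    }
  }
  if (length(out) == 0) {
    abort("replicate_concordance() needs >= 2 samples at some temperature")
  }
  dplyr::bind_rows(out)
}

#' Write / read a count table as TSV
#'
#' Layout: header `barcode` then one column per sample named `<temp>_<rep>`
#' (the metadata `sample_id`). Metadata is written alongside as
#' `<path>.meta.tsv` unless `meta_path` is given.
#'
#' @param counts A [bc_counts] table.
#' @param path Count TSV path.
#' @param meta_path Metadata TSV path (default `<path>.meta.tsv`).
#' @return Invisibly, `path`.
#' @export
write_counts_tsv <- function(counts, path, meta_path = paste0(path, ".meta.tsv")) {
  stopifnot(inherits(counts, "bc_counts"))
  readr::write_tsv(tibble::as_tibble(counts), path)
  readr::write_tsv(sample_meta(counts), meta_path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param normalized Whether the stored table holds normalized abundances.
#' @export
read_counts_tsv <- function(path, meta_path = paste0(path, ".meta.tsv"),
                            normalized = FALSE) {
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  bc_counts(counts, meta = meta, normalized = normalized)
}
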