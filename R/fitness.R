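#' One-sample Wilcoxon signed-rank test on log2 ratios
#'
#' Two-sided test of whether the median of the ratios differs from zero.
#' Zero ratios are discarded (the signed-rank convention); the null
#' distribution is enumerated exactly for n <= `exact_max` without ties, and
#' a tie-corrected normal approximation is used above that. Fewer than 3
#' non-zero ratios are reported untestable (`NA` with a flag); all-zero input
#' gives p = 1 with a degenerate-data flag.
#'
#' @param ratios Numeric vector of log2(50C/37C) ratios.
#' @param exact_max Largest n for the exact null distribution (default 25).
#' @return List: `p_value`, `statistic` (W, the positive-rank sum), `n_used`,
#'   `flag` (`"ok"`, `"untestable"` or `"degenerate"`).
#' @export
wilcoxon_one_sample <- function(ratios, exact_max = 25) {
  ratios <- ratios[is.finite(ratios)]
  nz <- ratios[ratios != 0]
  if (length(ratios) > 0 && length(nz) == 0) {
    return(list(p_value = 1, statistic = NA_real_, n_used = 0L,
      flag = "degenerate"
    ))
  }
  if (length(nz) < 3) {
    return(list(p_value = NA_real_, statistic = NA_real_,
      n_used = length(nz), flag = "untestable"
    ))
  }
  exact <- length(nz) <= exact_max && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(
    stats::wilcox.test(nz, mu = 0, exact = exact, correct = !exact)
  )
  list(
    p_value = min(1, unname(wt$p.value)),
    statistic = unname(wt$statistic),
    n_used = length(nz), flag = "ok"
  )
}

#' Mann-Whitney U test between two abundance distributions
#'
#' Two-sided comparison of barcode abundances at 37C vs 50C; exact null for
#' combined n <= `exact_max` without ties, tie-corrected normal approximation
#' otherwise.
#'
#' @param abund_37,abund_50 Numeric vectors of (normalized) abundances.
#' @param exact_max Largest combined n for the exact null (default 20).
#' @return List: `p_value`, `statistic` (U for the first sample), `n_37`,
#'   `n_50`.
#' @export
mann_whitney <- function(abund_37, abund_50, exact_max = 20) {
  stopifnot(length(abund_37) > 0, length(abund_50) > 0)
  exact <- (length(abund_37) + length(abund_50)) <= exact_max &&
    !any(duplicated(c(abund_37, abund_50)))
  wt <- suppressWarnings(
    stats::wilcox.test(abund_37, abund_50, exact = exact, correct = !exact)
  )
  list(
    p_value = min(1, unname(wt$p.value)),
    statistic = unname(wt$statistic),
    n_37 = length(abund_37), n_50 = length(abund_50)
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up procedure with monotone enforcement; output order matches
#' input order and every adjusted value is >= its raw p-value.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Numeric vector of FDR-adjusted values.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.na(p_values) & (p_values <= 0 | p_values > 1))) {
    abort("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Sample SD and coefficient of variation of replicate log2 ratios
#'
#' @param ratios Numeric vector (>= 2 values for a defined SD).
#' @return List: `sd` (n-1 denominator), `cv_percent`
#'   (`100 * sd / |mean|`; `NA` with `cv_defined = FALSE` at mean 0).
#' @export
dispersion <- function(ratios) {
  ratios <- ratios[is.finite(ratios)]
  s <- if (length(ratios) >= 2) stats::sd(ratios) else NA_real_
  m <- mean(ratios)
  if (is.na(m) || m == 0) {
    list(sd = s, cv_percent = NA_real_, cv_defined = FALSE)
  } else {
    list(sd = s, cv_percent = 100 * s / abs(m), cv_defined = TRUE)
  }
}

#' Filter barcodes and genes ahead of fitness testing
#'
#' Drops barcodes that are not single-locus, barcodes flagged multi-feature
#' (insertion position intersecting several annotated features), intergenic
#' barcodes, and every gene whose raw read count is below `min_reads` for all
#' of its barcodes in all samples.
#'
#' @param raw A raw [bc_counts] table.
#' @param pool An annotated `tn_pool`.
#' @param min_reads Gene-retention threshold: a gene is kept iff some
#'   (barcode, sample) raw count is >= this (default 5).
#' @return Tibble (`barcode`, `gene_id`, one column per sample) of retained
#'   barcodes, with attribute `removed` summarising exclusions.
#' @export
filter_barcodes_and_genes <- function(raw, pool, min_reads = 5) {
  stopifnot(inherits(raw, "bc_counts"))
  if (isTRUE(attr(raw, "normalized"))) {
    abort("filtering uses raw read counts; pass the unnormalized table")
  }
  sc <- sample_cols(raw)
  keep_pool <- pool[
    pool$classification == "single" &
      !pool$multi_feature &
      pool$gene_id != "intergenic",
  ]
  df <- dplyr::inner_join(
    tibble::as_tibble(raw),
    keep_pool[c("barcode", "gene_id")],
    by = "barcode"
  )
  gene_max <- df %>%
    tidyr::pivot_longer(dplyr::all_of(sc),
      names_to = "sample_id", values_to = "count"
    ) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(mx = max(.data$count), .groups = "drop")
  low <- gene_max$gene_id[gene_max$mx < min_reads]
  out <- df[!df$gene_id %in% low, c("barcode", "gene_id", sc)]
  attr(out, "removed") <- tibble::tibble(
    barcodes_not_single = sum(!raw$barcode %in% pool$barcode[pool$classification == "single"]),
    barcodes_multi_feature = sum(raw$barcode %in% pool$barcode[pool$multi_feature]),
    genes_low_count = length(low)
  )
  out
}

#' Per-gene baseline-normalized log2 ratios
#'
#' The gene's baseline is the mean normalized abundance over all of its
#' barcodes across all 37C replicates. Each (barcode, 50C replicate)
#' normalized abundance is divided by this baseline and log2-transformed,
#' giving one ratio per mutant per 50C replicate. Zero abundances at 50C are
#' dropped by default (log undefined) and tallied; with `pseudocount` set,
#' `log2((value + pseudocount) / baseline)` is used instead.
#'
#' @param filtered Output of [filter_barcodes_and_genes()] joined to
#'   normalized abundances, i.e. a tibble with `barcode`, `gene_id` and one
#'   column per sample of normalized abundance.
#' @param meta Sample metadata (`sample_id`, `temperature`, ...).
#' @param gene Gene identifier.
#' @param pseudocount Optional pseudocount for zero 50C abundances
#'   (`NULL` = drop them).
#' @return List: `gene_id`, `baseline_37`, `log2_ratios`, `n_barcodes`,
#'   `n_zero_dropped`.
#' @export
gene_log2fc <- function(filtered, meta, gene, pseudocount = NULL) {
  df <- filtered[filtered$gene_id == gene, ]
  if (nrow(df) == 0) abort(sprintf("gene '%s' not in filtered table", gene))
  s37 <- meta$sample_id[meta$temperature == 37]
  s50 <- meta$sample_id[meta$temperature == 50]
  if (length(s37) == 0 || length(s50) == 0) {
    abort("need samples at both 37 and 50")
  }
  baseline <- mean(as.matrix(df[s37]))
  if (!is.finite(baseline) || baseline <= 0) {
    return(list(
      gene_id = gene, baseline_37 = baseline, log2_ratios = numeric(0),
      n_barcodes = nrow(df), n_zero_dropped = 0L, untestable = TRUE
    ))
  }
  vals <- as.vector(as.matrix(df[s50]))
  if (is.null(pseudocount)) {
    n_zero <- sum(vals == 0)
    vals <- vals[vals > 0]
  } else {
    n_zero <- 0L
    vals <- vals + pseudocount
  }
  list(
    gene_id = gene, baseline_37 = baseline,
    log2_ratios = log2(vals / baseline),
    n_barcodes = nrow(df), n_zero_dropped = as.integer(n_zero),
    untestable = FALSE
  )
}

#' Gene-level temperature fitness from barcode counts
#'
#' The whole per-gene analysis: filter barcodes and genes
#' ([filter_barcodes_and_genes()]), total-count normalize
#' ([normalize_total()]), compute baseline-normalized log2(50C/37C) ratios
#' per mutant and 50C replicate ([gene_log2fc()]), test each gene with <=
#' `max_barcodes` barcodes (one-sample Wilcoxon signed-rank by default, or
#' Mann-Whitney U between raw temperature groups), adjust p-values with
#' Benjamini-Hochberg, and call hits at `|mean log2FC| >= lfc_threshold` and
#' `FDR < fdr_threshold`.
#'
#' @param raw A raw [bc_counts] table.
#' @param pool An annotated `tn_pool`.
#' @param min_reads Gene-retention raw-count threshold (default 5).
#' @param max_barcodes Genes with more uniquely mapped barcodes than this are
#'   excluded from testing and flagged (default 15).
#' @param lfc_threshold Hit threshold on `|mean_log2fc|` (default 1).
#' @param fdr_threshold Hit threshold on FDR (default 0.05).
#' @param test `"wilcoxon"` (baseline-normalized, default) or
#'   `"mannwhitney"` (abundance distributions between temperatures).
#' @param pseudocount Optional pseudocount for zero 50C abundances.
#' @param norm_target Total-count scaling target (default 1e6 = CPM).
#' @return A `gene_fitness` object; see [tidy.gene_fitness()] for the
#'   per-gene result table and [glance.gene_fitness()] for the run summary.
#' @export
gene_fitness <- function(raw, pool, min_reads = 5, max_barcodes = 15,
                         lfc_threshold = 1, fdr_threshold = 0.05,
                         test = c("wilcoxon", "mannwhitney"),
                         pseudocount = NULL, norm_target = 1e6) {
  test <- match.arg(test)
  stopifnot(inherits(raw, "bc_counts"))
  meta <- sample_meta(raw)
  filtered_raw <- filter_barcodes_and_genes(raw, pool, min_reads = min_reads)
  norm <- normalize_total(raw, target = norm_target)
  sc <- sample_cols(norm)
  filtered <- dplyr::inner_join(
    filtered_raw[c("barcode", "gene_id")],
    tibble::as_tibble(norm),
    by = "barcode"
  )
  genes <- unique(filtered$gene_id)
  n_bc <- table(filtered$gene_id)

  tested <- genes[n_bc[genes] <= max_barcodes]
  excluded <- tibble::tibble(
    gene_id = genes[n_bc[genes] > max_barcodes],
    n_barcodes = as.integer(n_bc[genes[n_bc[genes] > max_barcodes]]),
    reason = "more_than_max_barcodes"
  )

  s37 <- meta$sample_id[meta$temperature == 37]
  s50 <- meta$sample_id[meta$temperature == 50]
  rows <- purrr::map(tested, function(g) {
    fc <- gene_log2fc(filtered, meta, g, pseudocount = pseudocount)
    ratios <- fc$log2_ratios
    disp <- dispersion(ratios)
    p <- if (test == "wilcoxon") {
      wilcoxon_one_sample(ratios)$p_value
    } else {
      df <- filtered[filtered$gene_id == g, ]
      mann_whitney(
        as.vector(as.matrix(df[s37])),
        as.vector(as.matrix(df[s50]))
      )$p_value
    }
    tibble::tibble(
      gene_id = g,
      n_barcodes = fc$n_barcodes,
      n_ratios = length(ratios),
      n_zero_dropped = fc$n_zero_dropped,
      baseline_37 = fc$baseline_37,
      mean_log2fc = if (length(ratios) > 0) mean(ratios) else NA_real_,
      sd = disp$sd,
      cv_percent = disp$cv_percent,
      p_value = p
    )
  })
  results <- dplyr::bind_rows(rows)
  if (nrow(results) == 0) {
    abort("no testable genes after filtering")
  }
  results$fdr <- NA_real_
  ok <- !is.na(results$p_value)
  results$fdr[ok] <- bh_adjust(results$p_value[ok])
  results$is_hit <- !is.na(results$fdr) & !is.na(results$mean_log2fc) &
    abs(results$mean_log2fc) >= lfc_threshold & results$fdr < fdr_threshold
  results$direction <- dplyr::if_else(results$mean_log2fc > 0,
    "favors-50", "favors-37"
  )
  structure(
    list(
      results = dplyr::arrange(results, .data$fdr, dplyr::desc(abs(.data$mean_log2fc))),
      excluded = excluded,
      params = list(
        min_reads = min_reads, max_barcodes = max_barcodes,
        lfc_threshold = lfc_threshold, fdr_threshold = fdr_threshold,
        test = test, pseudocount = pseudocount, norm_target = norm_target
      ),
      meta = meta
    ),
    class = "gene_fitness"
  )
}

#' @export
print.gene_fitness <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<gene_fitness> %d gene(s) tested (%s), %d hit(s): %d favors-50, %d favors-37; %d excluded (> %d barcodes)\n",
    g$genes_tested, x$params$test, g$n_hits, g$hits_favor_50,
    g$hits_favor_37, nrow(x$excluded), x$params$max_barcodes
  ))
  invisible(x)
}

#' Tidy the per-gene fitness results
#'
#' @param x A `gene_fitness` object.
#' @param ... Unused.
#' @return Tibble with one row per tested gene: `gene_id`, `n_barcodes`,
#'   `mean_log2fc`, `sd`, `cv_percent`, `p_value`, `fdr`, `is_hit`,
#'   `direction` (plus ratio bookkeeping columns).
#' @export
tidy.gene_fitness <- function(x, ...) {
  x$results
}

#' One-row summary of a fitness analysis
#'
#' @param x A `gene_fitness` object.
#' @param ... Unused.
#' @return One-row tibble: `genes_tested`, `genes_excluded`, `n_hits`,
#'   `hits_favor_50`, `hits_favor_37`.
#' @export
glance.gene_fitness <- function(x, ...) {
  r <- x$results
  tibble::tibble(
    genes_tested = nrow(r),
    genes_excluded = nrow(x$excluded),
    n_hits = sum(r$is_hit),
    hits_favor_50 = sum(r$is_hit & r$direction == "favors-50"),
    hits_favor_37 = sum(r$is_hit & r$direction == "favors-37")
  )
}

#' Volcano-style output table
#'
#' One row per tested gene with `-log10(FDR)`, sorted by FDR ascending then
#' `|mean_log2fc|` descending; genes excluded from testing are absent here
#' and listed in the fit's `excluded` table.
#'
#' @param fit A `gene_fitness` object.
#' @return Tibble (`gene_id`, `mean_log2fc`, `neg_log10_fdr`, `is_hit`).
#' @export
volcano_table <- function(fit) {
  stopifnot(inherits(fit, "gene_fitness"))
  r <- fit$results[!is.na(fit$results$fdr), ]
  tibble::tibble(
    gene_id = r$gene_id,
    mean_log2fc = r$mean_log2fc,
    neg_log10_fdr = -log10(r$fdr),
    is_hit = r$is_hit
  )
}

#' Apply hit thresholds to an external differential-abundance table
#'
#' Recomputes hit calls (effect-size and FDR thresholds, direction split)
#' from any per-gene table of mean log2(50C/37C) and adjusted p-values, e.g.
#' a published screen's gene-level results.
#'
#' @param table Data frame with the two columns named below.
#' @param lfc_col,fdr_col Column names (default `mean_log2fc`, `fdr`).
#' @param lfc_threshold,fdr_threshold Hit thresholds (1 and 0.05).
#' @return One-row tibble: `n_genes`, `n_hits`, `hits_favor_50`,
#'   `hits_favor_37`.
#' @export
hit_calls_from_table <- function(table, lfc_col = "mean_log2fc",
                                 fdr_col = "fdr", lfc_threshold = 1,
                                 fdr_threshold = 0.05) {
  lfc <- table[[lfc_col]]
  fdr <- table[[fdr_col]]
  if (is.null(lfc) || is.null(fdr)) abort("columns not found in table")
  hit <- !is.na(lfc) & !is.na(fdr) &
    abs(lfc) >= lfc_threshold & fdr < fdr_threshold
  tibble::tibble(
    n_genes = sum(!is.na(lfc) & !is.na(fdr)),
    n_hits = sum(hit),
    hits_favor_50 = sum(hit & lfc > 0),
    hits_favor_37 = sum(hit & lfc < 0)
  )
}
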