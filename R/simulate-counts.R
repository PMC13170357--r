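#' Simulate a BarSeq barcode count table with planted temperature effects
#'
#' For each sample the expected barcode proportions are the truth's lognormal
#' baseline abundances, scaled for 50C samples by `2^effect` of the gene each
#' barcode sits in (barcodes in genes without a planted effect, and intergenic
#' barcodes, scale by 1). Per-replicate biological noise is a lognormal
#' multiplier with sigma `abundance_noise`; sequencing is multinomial sampling
#' of `sequencing_depth` reads over the renormalized proportions, so each
#' sample's counts sum exactly to the depth. A negative-binomial per-barcode
#' option models extra count overdispersion instead (totals then vary around
#' the depth).
#'
#' @param truth An `insertion_truth` (with `baseline_abundance` and optional
#'   `gene_effects`).
#' @param temperatures Numeric vector of conditions (default `c(37, 50)`);
#'   effects apply to samples at 50.
#' @param replicates_per_temperature Biological replicates per temperature.
#' @param sequencing_depth Total reads per sample.
#' @param abundance_noise Lognormal sigma of the per-replicate, per-barcode
#'   biological noise multiplier (0 = none).
#' @param sampling `"multinomial"` (default) or `"negbin"`.
#' @param negbin_size Dispersion (size) for the negative-binomial option.
#' @param seed Integer RNG seed.
#' @return A [bc_counts] table (barcode x sample, samples named
#'   `<temp>_<rep>`) with sample metadata attached; attribute
#'   `true_proportions` holds the per-sample expected proportions.
#' @export
simulate_barseq_counts <- function(truth,
                                   temperatures = c(37, 50),
                                   replicates_per_temperature = 3,
                                   sequencing_depth = 1e6,
                                   abundance_noise = 0,
                                   sampling = c("multinomial", "negbin"),
                                   negbin_size = 20,
                                   seed = 1) {
  stopifnot(
    inherits(truth, "insertion_truth"),
    replicates_per_temperature >= 1, sequencing_depth >= 1,
    abundance_noise >= 0
  )
  sampling <- match.arg(sampling)
  ins <- truth$insertions
  if (is.null(ins$baseline_abundance) || any(ins$baseline_abundance <= 0)) {
    abort("every barcode in the truth set needs a positive baseline abundance")
  }
  effects <- truth$gene_effects
  bc_effect <- ifelse(ins$gene_id %in% names(effects),
    unname(effects[ins$gene_id]), 0
  )
  bc_effect[is.na(bc_effect)] <- 0

  meta <- tidyr::expand_grid(
    temperature = temperatures,
    replicate = seq_len(replicates_per_temperature)
  ) %>%
    dplyr::mutate(
      sample_id = sprintf("%g_%d", .data$temperature, .data$replicate),
      batch = "sim"
    ) %>%
    dplyr::select("sample_id", "temperature", "replicate", "batch")

  n_bc <- nrow(ins)
  with_seed(seed, {
    counts <- matrix(0, nrow = n_bc, ncol = nrow(meta),
      dimnames = list(ins$barcode, meta$sample_id)
    )
    true_prop <- counts
    for (j in seq_len(nrow(meta))) {
      scale <- if (meta$temperature[j] == 50) 2^bc_effect else rep(1, n_bc)
      w <- ins$baseline_abundance * scale
      if (abundance_noise > 0) {
        w <- w * stats::rlnorm(n_bc, meanlog = 0, sdlog = abundance_noise)
      }
      p <- w / sum(w)
      true_prop[, j] <- p
      counts[, j] <- switch(sampling,
        multinomial = as.vector(stats::rmultinom(1, sequencing_depth, p)),
        negbin = stats::rnbinom(n_bc, mu = sequencing_depth * p,
          size = negbin_size
        )
      )
    }
    out <- bc_counts(
      tibble::as_tibble(counts, rownames = "barcode"),
      meta = meta, normalized = FALSE
    )
    attr(out, "true_proportions") <-
      tibble::as_tibble(true_prop, rownames = "barcode")
    out
  })
}
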