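#' Collapse single-base barcode sequencing errors
#'
#' Barcodes at Hamming distance 1 from a strictly higher-count barcode are
#' absorbed into it (read counts summed). Absorption is greedy by descending
#' recipient count and iterates to a fixed point, so chains of errors funnel
#' into the dominant barcode; when a donor has several candidate recipients
#' the highest-count one wins, ties going to the lexicographically smaller
#' recipient. Total read count is conserved and the operation is idempotent.
#'
#' @param counts Tibble with `barcode` and `count` columns, or a named
#'   numeric vector.
#' @return Tibble (`barcode`, `count`) of surviving barcodes (sorted by
#'   descending count then barcode), with attribute `absorbed`: a tibble
#'   mapping each absorbed `barcode` to its `into` recipient.
#' @export
collapse_barcode_errors <- function(counts) {
  if (is.numeric(counts) && !is.null(names(counts))) {
    counts <- tibble::tibble(barcode = names(counts), count = unname(counts))
  }
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("barcode", "count") %in% names(counts)))
  if (anyDuplicated(counts$barcode)) abort("duplicate barcodes in input")
  if (nrow(counts) > 1 && length(unique(nchar(counts$barcode))) != 1) {
    abort("barcodes must have uniform length")
  }
  cnt <- stats::setNames(counts$count, counts$barcode)
  absorbed_from <- character(0)
  absorbed_into <- character(0)

  repeat {
    changed <- FALSE
    ord <- order(-cnt, names(cnt))
    for (rec in names(cnt)[ord]) {
      if (!rec %in% names(cnt)) next # absorbed earlier this pass
      nb <- hamming1_neighbours(rec)
      donors <- nb[nb %in% names(cnt)]
      donors <- donors[cnt[donors] < cnt[[rec]]]
      if (length(donors) > 0) {
        cnt[[rec]] <- cnt[[rec]] + sum(cnt[donors])
        absorbed_from <- c(absorbed_from, donors)
        absorbed_into <- c(absorbed_into, rep(rec, length(donors)))
        cnt <- cnt[setdiff(names(cnt), donors)]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # resolve absorption chains (donor -> intermediate -> final survivor)
  if (length(absorbed_from) > 0) {
    map <- stats::setNames(absorbed_into, absorbed_from)
    final <- vapply(absorbed_from, function(b) {
      while (b %in% names(map)) b <- map[[b]]
      b
    }, character(1))
    absorbed <- tibble::tibble(barcode = absorbed_from, into = unname(final))
  } else {
    absorbed <- tibble::tibble(barcode = character(), into = character())
  }
  out <- tibble::tibble(barcode = names(cnt), count = unname(cnt))
  out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$barcode)
  attr(out, "absorbed") <- absorbed
  out
}

#' Resolve near-identical insertion positions (< 10 bp apart)
#'
#' Within each `(barcode, chromosome, strand)` group, positions closer than
#' `min_dist` bp to a better-supported position are absorbed into it: the
#' highest-count position (ties to the smaller coordinate) is retained, all
#' positions strictly within `min_dist` of it are merged in (counts summed),
#' and the rule repeats on the remainder. Positions `>= min_dist` apart stay
#' distinct.
#'
#' @param positions Tibble with columns `position` and `count`, plus optional
#'   grouping columns `barcode`, `chromosome`, `strand`.
#' @param min_dist Positions closer than this are merged (default 10 bp).
#' @return Tibble with the same grouping columns and resolved
#'   (`position`, `count`) rows.
#' @export
resolve_near_positions <- function(positions, min_dist = 10) {
  positions <- tibble::as_tibble(positions)
  stopifnot(all(c("position", "count") %in% names(positions)))
  grp <- intersect(c("barcode", "chromosome", "strand"), names(positions))
  resolve_one <- function(df) {
    pos <- df$position
    cnt <- df$count
    keep_pos <- integer(0)
    keep_cnt <- numeric(0)
    while (length(pos) > 0) {
      i <- which(cnt == max(cnt))
      i <- i[which.min(pos[i])]
      near <- abs(pos - pos[i]) < min_dist
      keep_pos <- c(keep_pos, pos[i])
      keep_cnt <- c(keep_cnt, sum(cnt[near]))
      pos <- pos[!near]
      cnt <- cnt[!near]
    }
    tibble::tibble(position = keep_pos, count = keep_cnt)
  }
  if (length(grp) == 0) {
    return(dplyr::arrange(resolve_one(positions), .data$position))
  }
  positions %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
    dplyr::group_modify(~ resolve_one(.x)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grp, "position"))))
}
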