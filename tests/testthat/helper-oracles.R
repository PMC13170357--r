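# Brute-force reference implementations, deliberately naive and independent
# of the package's code paths. Used to pin down the rule-level contracts.

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# exhaustive junction scan: minimal mismatches, ties to the lowest offset
oracle_find_junction <- function(read, junction, max_mismatches = 2) {
  jlen <- nchar(junction)
  offs <- 0:(nchar(read) - jlen)
  mm <- vapply(offs, function(o) {
    oracle_hamming(substr(read, o + 1, o + jlen), junction)
  }, numeric(1))
  ok <- mm <= max_mismatches
  if (!any(ok)) {
    return(NULL)
  }
  best <- min(mm[ok])
  o <- min(offs[ok & mm == best])
  list(
    offset = o, mismatches = best,
    flank = substr(read, o + jlen + 1, nchar(read))
  )
}

# all-pairs Hamming matrix + greedy absorption by descending recipient count
# (strictly smaller donors only, recipient ties to the lexicographically
# smaller barcode), iterated to a fixed point
oracle_collapse <- function(counts) {
  cnt <- counts
  repeat {
    changed <- FALSE
    ord <- order(-cnt, names(cnt))
    for (rec in names(cnt)[ord]) {
      if (!rec %in% names(cnt)) next
      d <- vapply(names(cnt), oracle_hamming, numeric(1), b = rec)
      donors <- names(cnt)[d == 1 & cnt < cnt[[rec]]]
      if (length(donors) > 0) {
        cnt[[rec]] <- cnt[[rec]] + sum(cnt[donors])
        cnt <- cnt[setdiff(names(cnt), donors)]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  cnt[order(-cnt, names(cnt))]
}

# greedy near-position merging: best-supported position (ties -> smaller
# coordinate) absorbs everything strictly within min_dist, repeat
oracle_resolve_positions <- function(pos, cnt, min_dist = 10) {
  keep <- list()
  while (length(pos) > 0) {
    cand <- which(cnt == max(cnt))
    i <- cand[which.min(pos[cand])]
    near <- abs(pos - pos[i]) < min_dist
    keep[[length(keep) + 1]] <- c(position = pos[i], count = sum(cnt[near]))
    pos <- pos[!near]
    cnt <- cnt[!near]
  }
  out <- do.call(rbind, keep)
  out[order(out[, "position"]), , drop = FALSE]
}

# exact one-sample signed-rank p by enumerating all 2^n sign assignments
oracle_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  mu <- n * (n + 1) / 4
  min(1, mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12))
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mann_whitney_p <- function(x, y) {
  nx <- length(x)
  all_v <- c(x, y)
  n <- length(all_v)
  combs <- utils::combn(n, nx)
  u_of <- function(idx) {
    xs <- all_v[idx]
    ys <- all_v[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(nx))
  mu <- nx * (n - nx) / 2
  u_all <- apply(combs, 2, u_of)
  min(1, mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12))
}

# BH step-up by hand
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

random_barcodes <- function(n, len, seed) {
  set.seed(seed)
  replicate(n, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
    collapse = ""
  ))
}
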