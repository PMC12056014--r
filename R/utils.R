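# internal helpers shared across modules

# Nearest-rank upper quantile: the value x_(n - ceil(q*n) + 1) of the sorted
# sample, so that at most ceil(q*n) observations are >= the returned value.
upper_quantile_nearest_rank <- function(x, q) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) abort("no non-missing values to take a quantile of")
  m <- ceiling(q * n)
  m <- max(min(m, n), 1L)
  x[n - m + 1L]
}

# Equal-width frequency bins on [0, 1]; freq == 1 goes into the last bin.
freq_bin_index <- function(freq, bin_width) {
  n_bins <- as.integer(round(1 / bin_width))
  idx <- pmin(floor(freq / bin_width), n_bins - 1L) + 1L
  as.integer(idx)
}

# Merge undersized bins into their nearest neighbour (by bin-centre
# distance, ties towards the lower bin). `bin` are integer bin indices,
# `ok` marks the observations that count towards bin size. Returns a
# vector of merged-group labels aligned with `bin`.
merge_small_bins <- function(bin, ok, centers, min_size) {
  groups <- sort(unique(bin))
  # group membership: named list bin index -> current group label
  lab <- setNames(groups, groups)
  repeat {
    glabs <- unique(lab)
    if (length(glabs) <= 1L) break
    sizes <- vapply(glabs, function(g) sum(ok & lab[as.character(bin)] == g), integer(1))
    gcent <- vapply(glabs, function(g) mean(centers[as.integer(names(lab)[lab == g])]), numeric(1))
    small <- glabs[sizes < min_size]
    if (length(small) == 0L) break
    # merge the smallest offender first (ties -> lowest centre)
    o <- order(sizes[match(small, glabs)], gcent[match(small, glabs)])
    g0 <- small[o[1L]]
    others <- glabs[glabs != g0]
    d <- abs(gcent[match(others, glabs)] - gcent[match(g0, glabs)])
    tgt <- others[order(d, gcent[match(others, glabs)])][1L]
    lab[lab == g0] <- tgt
  }
  unname(lab[as.character(bin)])
}

stop_if_not_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("%s must lie in [0, 1]", what))
  }
  invisible(x)
}
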