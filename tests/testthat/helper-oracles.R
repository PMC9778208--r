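# Independent brute-force oracles and tiny fixtures used across tests.

tiny_genome <- function() genome_build(c("chrA", "chrB"), c(1000, 730))

# random binned track on a genome (uniform values, fixed by the caller's seed)
random_track <- function(genome, bin_width = 50, max_value = 10) {
  tr <- empty_track(genome, bin_width)
  tr$value <- round(stats::runif(nrow(tr), 0, max_value), 3)
  tr
}

# per-bp accumulation, then per-bin mean over the bin's true width
oracle_bin_bedgraph <- function(records, genome, bin_width) {
  out <- empty_track(genome, bin_width)
  for (ci in seq_len(nrow(genome))) {
    ch <- genome$chrom[ci]; len <- genome$length[ci]
    perbp <- numeric(len)
    recs <- records[records$chrom == ch, ]
    for (i in seq_len(nrow(recs))) {
      idx <- (recs$start[i] + 1):recs$end[i]
      perbp[idx] <- perbp[idx] + recs$value[i]
    }
    rows <- which(out$chrom == ch)
    for (b in rows) {
      bp <- (out$start[b] + 1):out$end[b]
      out$value[b] <- sum(perbp[bp]) / length(bp)
    }
  }
  out
}

# truncated-window sliding median
oracle_sliding_median <- function(x, k) {
  h <- (k - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# bp-weighted window mean by per-bp expansion
oracle_window_mean <- function(track, chrom, lo, hi) {
  ch <- track[track$chrom == chrom, ]
  bp_vals <- unlist(lapply(seq_len(nrow(ch)), function(b) {
    rep(ch$value[b], ch$end[b] - ch$start[b])
  }))
  mean(bp_vals[(lo + 1):hi])
}

# five-number summary by explicit sort-and-interpolate (type-7 quartiles)
oracle_fivenum <- function(x) {
  s <- sort(x); n <- length(s)
  qt <- function(p) {
    hpos <- (n - 1) * p + 1
    lo <- floor(hpos); hi <- ceiling(hpos)
    s[lo] + (hpos - lo) * (s[hi] - s[lo])
  }
  c(min = s[1], q1 = qt(0.25), median = qt(0.5), q3 = qt(0.75), max = s[n])
}

# closed-form Welch t statistic, Welch-Satterthwaite df, two-sided p
oracle_welch <- function(a, b) {
  n <- length(a); m <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / n + vb / m
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / n)^2 / (n - 1) + (vb / m)^2 / (m - 1))
  c(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# closed-form OLS via the normal equations
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x),
    r = sxy / sqrt(sxx * sum((y - mean(y))^2)))
}

# exact inclusion probabilities of weighted sampling without replacement
# (successive draws), by enumeration of ordered draw sequences
oracle_inclusion_probs <- function(w, k) {
  n <- length(w)
  probs <- numeric(n)
  rec <- function(remaining, chosen, p) {
    if (length(chosen) == k) {
      probs[chosen] <<- probs[chosen] + p
      return(invisible())
    }
    for (i in remaining) {
      rec(setdiff(remaining, i), c(chosen, i), p * w[i] / sum(w[remaining]))
    }
  }
  rec(seq_len(n), integer(0), 1)
  probs
}

# small simulated panel shared by slower tests
small_sim_config <- function(n_chrom = 4, n_cells = 300, ...) {
  sim_config(n_chrom = n_chrom, n_cells = n_cells, ...)
}
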