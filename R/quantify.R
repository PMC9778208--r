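#' Mean signal in windows centered on features
#'
#' For each feature, takes the bp-overlap-weighted mean of bin values over
#' the window `[midpoint - width/2, midpoint + width/2)`, clipped to the
#' chromosome; clipped windows average over the clipped extent only and
#' are flagged.
#'
#' @param profile A binned track tibble, optionally with a `strain`
#'   column (the computation is then done per strain).
#' @param features A tibble of features with `chrom`, `start`, `end` and
#'   `name` columns (e.g. an origin set, or centromeres via their
#'   intervals).
#' @param width_bp Window width in bp (default 500); must be at least the
#'   bin width.
#' @return A tibble with columns `strain` (if present in `profile`),
#'   `name`, `chrom`, `midpoint`, `signal`, `clipped`.
#' @export
window_signal <- function(profile, features, width_bp = 500) {
  bw <- track_bin_width(profile)
  if (width_bp < bw) abort("window narrower than one bin")
  if (!"name" %in% names(features)) abort("features need a name column")
  if ("strain" %in% names(profile)) {
    out <- purrr::map(split_strains(profile), function(tr) {
      res <- window_signal_one(tr, features, width_bp)
      res$strain <- tr$strain[1]
      res
    })
    return(dplyr::relocate(dplyr::bind_rows(out), "strain"))
  }
  window_signal_one(profile, features, width_bp)
}

split_strains <- function(profile) {
  split(profile, factor(profile$strain, levels = unique(profile$strain)))
}

window_signal_one <- function(track, features, width_bp) {
  genome <- track_genome(track)
  unknown <- setdiff(unique(features$chrom), genome$chrom)
  if (length(unknown)) {
    abort(paste0("feature on unknown chromosome: ", paste(unknown, collapse = ", ")))
  }
  bw <- track_bin_width(track)
  by_chrom <- track_split(track)
  chrom_len <- setNames(genome$length, genome$chrom)
  mids <- if ("midpoint" %in% names(features)) features$midpoint else
    feature_midpoint(features)
  half <- width_bp / 2
  n <- nrow(features)
  signal <- numeric(n); clipped <- logical(n)
  for (i in seq_len(n)) {
    ch <- features$chrom[i]
    lo <- mids[i] - floor(half); hi <- mids[i] + ceiling(half)
    lo_c <- max(0, lo); hi_c <- min(chrom_len[[ch]], hi)
    clipped[i] <- lo_c != lo || hi_c != hi
    signal[i] <- span_weighted_mean(by_chrom[[ch]], lo_c, hi_c, bw)
  }
  tibble::tibble(name = features$name, chrom = features$chrom,
                 midpoint = mids, signal = signal, clipped = clipped)
}

# bp-overlap-weighted mean of bin values over [lo, hi)
span_weighted_mean <- function(ch_track, lo, hi, bw) {
  if (hi <= lo) return(NA_real_)
  b0 <- floor(lo / bw) + 1L
  b1 <- floor((hi - 1) / bw) + 1L
  b1 <- min(b1, length(ch_track$value))
  idx <- b0:b1
  ov <- pmin(ch_track$end[idx], hi) - pmax(ch_track$start[idx], lo)
  sum(ch_track$value[idx] * ov) / sum(ov)
}

#' Per-origin signal difference between two strains
#'
#' The per-origin difference `reference - test` in window signal; positive
#' values mean activity lost in the test strain.  Antisymmetric under
#' swapping reference and test.
#'
#' @param windows A long window-signal tibble (from [window_signal()] on a
#'   multi-strain profile) containing both strains.
#' @param reference,test Strain labels.
#' @return A tibble with columns `name`, `chrom`, `signal_reference`,
#'   `signal_test`, `delta`; the labels are kept in attributes
#'   `reference` and `test`.
#' @export
delta_signal <- function(windows, reference, test) {
  pick <- function(s) {
    w <- dplyr::filter(windows, .data$strain == s)
    if (nrow(w) == 0) abort(paste0("strain not present in windows: ", s))
    w
  }
  a <- pick(reference); b <- pick(test)
  if (!setequal(a$name, b$name) || nrow(a) != nrow(b)) {
    abort("reference and test strains cover different origin rows")
  }
  b <- b[match(a$name, b$name), ]
  out <- tibble::tibble(name = a$name, chrom = a$chrom,
                        signal_reference = a$signal, signal_test = b$signal,
                        delta = a$signal - b$signal)
  attr(out, "reference") <- reference
  attr(out, "test") <- test
  out
}

# five-number summary with type-7 (linear interpolation) quartiles
fivenum_stats <- function(x) {
  if (length(x) == 0) {
    return(tibble::tibble(n = 0L, min = NA_real_, q1 = NA_real_,
                          median = NA_real_, q3 = NA_real_, max = NA_real_))
  }
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  tibble::tibble(n = length(x), min = min(x), q1 = q[1], median = q[2],
                 q3 = q[3], max = max(x))
}

#' Boxplot statistics of window signal by origin group
#'
#' Five-number summaries (min, Q1, median, Q3, max; quartiles by linear
#' interpolation) of per-origin window signal, per strain and origin
#' group.
#'
#' @param windows A window-signal tibble (see [window_signal()]).
#' @param origins An origin set tibble.
#' @param groups Origin groups to summarize (see [origin_group_long()]).
#' @return A tibble with columns `strain` (if present), `group`, `n`,
#'   `min`, `q1`, `median`, `q3`, `max`.  Empty groups are reported with
#'   `n = 0` and NA summaries.
#' @export
group_boxplot_stats <- function(windows, origins,
                                groups = c("confirmed", "fkh_activated",
                                           "cen_proximal")) {
  long <- origin_group_long(origins, groups)
  strains <- if ("strain" %in% names(windows)) unique(windows$strain) else NA_character_
  res <- purrr::map(strains, function(s) {
    w <- if (is.na(s)) windows else windows[windows$strain == s, ]
    sub <- purrr::map(groups, function(g) {
      vals <- w$signal[w$name %in% long$name[long$group == g]]
      st <- fivenum_stats(vals)
      st$group <- g
      st
    })
    out <- dplyr::bind_rows(sub)
    if (!is.na(s)) out$strain <- s
    out
  })
  out <- dplyr::bind_rows(res)
  dplyr::relocate(out, dplyr::any_of(c("strain", "group")))
}

#' Welch two-sided t-test
#'
#' Unequal-variance (Welch) t statistic with Welch-Satterthwaite degrees
#' of freedom and a two-sided p-value.  When both samples have zero
#' variance and equal means, returns t = 0, p = 1 by convention; when both
#' are constant with unequal means, t is signed infinity with p = 0.
#'
#' @param a,b Numeric samples with at least 2 finite values each.
#' @return A one-row tibble with columns `t`, `df`, `p`, `mean_a`,
#'   `mean_b`.
#' @export
two_sided_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("need at least 2 values per sample")
  if (any(!is.finite(a)) || any(!is.finite(b))) abort("samples must be finite")
  va <- var(a); vb <- var(b)
  n <- length(a); m <- length(b)
  se2 <- va / n + vb / m
  if (se2 == 0) {
    d <- mean(a) - mean(b)
    t <- if (d == 0) 0 else sign(d) * Inf
    return(tibble::tibble(t = t, df = n + m - 2,
                          p = if (d == 0) 1 else 0,
                          mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Per-group Welch t-tests between two strains
#'
#' For each origin group, compares the two strains' per-origin window
#' values with [two_sided_ttest()].  Raw p-values are primary;
#' Benjamini-Hochberg q-values are appended as a clearly secondary
#' convenience column.
#'
#' @param windows A multi-strain window-signal tibble.
#' @param origins An origin set tibble.
#' @param strain_a,strain_b Strain labels to compare.
#' @param groups Origin groups to test.
#' @return A tibble with columns `group`, `n_a`, `n_b`, `t`, `df`, `p`,
#'   `q_bh`.
#' @export
group_ttests <- function(windows, origins, strain_a, strain_b,
                         groups = c("confirmed", "fkh_activated",
                                    "cen_proximal")) {
  long <- origin_group_long(origins, groups)
  rows <- purrr::map(groups, function(g) {
    nm <- long$name[long$group == g]
    a <- windows$signal[windows$strain == strain_a & windows$name %in% nm]
    b <- windows$signal[windows$strain == strain_b & windows$name %in% nm]
    if (length(a) < 2 || length(b) < 2) {
      return(tibble::tibble(group = g, n_a = length(a), n_b = length(b),
                            t = NA_real_, df = NA_real_, p = NA_real_))
    }
    tt <- two_sided_ttest(a, b)
    tibble::tibble(group = g, n_a = length(a), n_b = length(b),
                   t = tt$t, df = tt$df, p = tt$p)
  })
  out <- dplyr::bind_rows(rows)
  out$q_bh <- stats::p.adjust(out$p, method = "BH")
  attr(out, "strains") <- c(a = strain_a, b = strain_b)
  out
}

#' Peak width at half maximum around features
#'
#' Width of the signal peak around each feature midpoint at half of
#' (peak height - local baseline), where the baseline is the minimum
#' within the search span and crossings are located by linear
#' interpolation between bin centers.  Peak width is a proxy for fork
#' travel distance: genome-wide, it varies inversely with how many
#' origins fire.
#'
#' @param profile A single-strain binned track tibble.
#' @param features A feature tibble with `chrom`, `start`, `end`, `name`.
#' @param search_bp Search span centered on the feature midpoint (default
#'   10000 bp).
#' @return A tibble with columns `name`, `fwhm` (bp; NA when undefined),
#'   `peak_height`, `baseline` and `status` (`"ok"`, `"flat"` for a
#'   constant span, `"censored"` when a half-height crossing was not
#'   reached inside the span).
#' @export
peak_width_fwhm <- function(profile, features, search_bp = 10000) {
  if ("strain" %in% names(profile) && length(unique(profile$strain)) > 1) {
    abort("peak_width_fwhm expects a single-strain profile")
  }
  genome <- track_genome(profile)
  chrom_len <- setNames(genome$length, genome$chrom)
  by_chrom <- track_split(profile)
  bw <- track_bin_width(profile)
  mids <- if ("midpoint" %in% names(features)) features$midpoint else
    feature_midpoint(features)
  rows <- purrr::map(seq_len(nrow(features)), function(i) {
    ch <- features$chrom[i]
    tr <- by_chrom[[ch]]
    if (is.null(tr)) abort(paste0("feature on unknown chromosome: ", ch))
    lo <- max(0, mids[i] - search_bp / 2)
    hi <- min(chrom_len[[ch]], mids[i] + search_bp / 2)
    b0 <- floor(lo / bw) + 1L
    b1 <- min(floor((hi - 1) / bw) + 1L, length(tr$value))
    v <- tr$value[b0:b1]
    x <- (tr$start[b0:b1] + tr$end[b0:b1]) / 2
    fwhm_one(x, v, name = features$name[i])
  })
  dplyr::bind_rows(rows)
}

fwhm_one <- function(x, v, name) {
  out <- tibble::tibble(name = name, fwhm = NA_real_,
                        peak_height = max(v), baseline = min(v),
                        status = "ok")
  if (max(v) == min(v)) {
    out$status <- "flat"
    return(out)
  }
  p <- which.max(v)
  half <- min(v) + (max(v) - min(v)) / 2
  cross <- function(side) {
    if (p == 1 && side == "left") return(NA_real_)
    if (p == length(v) && side == "right") return(NA_real_)
    idx <- if (side == "left") rev(seq_len(p - 1)) else seq.int(p + 1, length(v))
    for (j in idx) {
      if (v[j] <= half) {
        k <- if (side == "left") j + 1L else j - 1L
        return(x[j] + (x[k] - x[j]) * (half - v[j]) / (v[k] - v[j]))
      }
    }
    NA_real_
  }
  left <- cross("left"); right <- cross("right")
  if (is.na(left) || is.na(right)) {
    out$status <- "censored"
    return(out)
  }
  out$fwhm <- right - left
  out
}

#' Feature-centered signal matrix for heatmaps
#'
#' One row per feature, one column per bin offset spanning `span_bp`
#' centered on the feature midpoint.  Cell (f, j) holds the bin value at
#' offset `(j - n/2) * bin_width` from the midpoint of feature f;
#' offsets falling outside the chromosome are NA.
#'
#' @param profile A single-strain binned track tibble.
#' @param features A feature tibble with `chrom`, `start`, `end`, `name`.
#' @param span_bp Span in bp (default 10000); must be a multiple of the
#'   bin width.
#' @param sort_rows If TRUE, order rows by decreasing row mean (flagged in
#'   the `sorted` attribute); default keeps input feature order.
#' @return A numeric matrix of class `heatmap_matrix` with feature names
#'   as rownames and the bin-start offsets (bp) in `attr(, "offsets")`.
#' @export
heatmap_matrix <- function(profile, features, span_bp = 10000,
                           sort_rows = FALSE) {
  bw <- track_bin_width(profile)
  if (span_bp %% bw != 0) abort("span_bp must be a multiple of the bin width")
  genome <- track_genome(profile)
  unknown <- setdiff(unique(features$chrom), genome$chrom)
  if (length(unknown)) {
    abort(paste0("feature on unknown chromosome: ", paste(unknown, collapse = ", ")))
  }
  chrom_len <- setNames(genome$length, genome$chrom)
  by_chrom <- track_split(profile)
  ncol <- span_bp / bw
  offsets <- (seq_len(ncol) - 1 - ncol / 2) * bw
  mids <- if ("midpoint" %in% names(features)) features$midpoint else
    feature_midpoint(features)
  m <- matrix(NA_real_, nrow = nrow(features), ncol = ncol,
              dimnames = list(features$name, NULL))
  for (i in seq_len(nrow(features))) {
    ch <- features$chrom[i]
    pos <- mids[i] + offsets
    ok <- pos >= 0 & pos < chrom_len[[ch]]
    bins <- floor(pos[ok] / bw) + 1L
    m[i, ok] <- by_chrom[[ch]]$value[bins]
  }
  if (sort_rows) m <- m[order(-rowMeans(m, na.rm = TRUE)), , drop = FALSE]
  structure(m, offsets = offsets, span_bp = span_bp, bin_width = bw,
            sorted = sort_rows, class = c("heatmap_matrix", "matrix", "array"))
}

#' Tidy a heatmap matrix into long form
#'
#' @param x A `heatmap_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `name`, `offset`, `value`.
#' @export
#' @method tidy heatmap_matrix
tidy.heatmap_matrix <- function(x, ...) {
  tibble::tibble(name = rep(rownames(x), times = ncol(x)),
                 offset = rep(attr(x, "offsets"), each = nrow(x)),
                 value = as.vector(unclass(x)))
}

#' Per-group ordinary least-squares fits
#'
#' Fits `y ~ x` by OLS within each group and reports slope, intercept and
#' Pearson r — the "line of best fit" companion to a two-strain scatter
#' plot of per-feature signal.
#'
#' @param data A data frame of per-feature values.
#' @param x,y Column names (strings) of the predictor and response.
#' @param group Optional column name defining sub-groups; NULL fits all
#'   rows as one group.
#' @return An object of class `scatter_fit`: a tibble with columns
#'   `group`, `n`, `slope`, `intercept`, `r` (attribute `data` keeps the
#'   input for plotting).
#' @export
scatter_fit <- function(data, x, y, group = NULL) {
  stopifnot(x %in% names(data), y %in% names(data))
  grp <- if (is.null(group)) rep("all", nrow(data)) else as.character(data[[group]])
  rows <- purrr::map(unique(grp), function(g) {
    xs <- data[[x]][grp == g]; ys <- data[[y]][grp == g]
    if (length(xs) < 2) abort(paste0("group ", g, ": need at least 2 points"))
    if (var(xs) == 0) abort(paste0("group ", g, ": constant x, fit undefined"))
    fit <- stats::lm(ys ~ xs)
    tibble::tibble(group = g, n = length(xs),
                   slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   r = cor(xs, ys))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "data") <- tibble::tibble(x = data[[x]], y = data[[y]], group = grp)
  attr(out, "vars") <- c(x = x, y = y)
  class(out) <- c("scatter_fit", class(out))
  out
}
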