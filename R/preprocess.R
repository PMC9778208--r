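#' Median-smooth a binned track
#'
#' Sliding-window median per chromosome.  The window is expressed in bp and
#' converted to bins; an even bin count is rounded up to the next odd count
#' so the window is symmetric (1000 bp at 50 bp bins becomes 21 bins,
#' an effective 1050 bp).  At chromosome ends the window is truncated
#' (shrinks) rather than padded.
#'
#' @param track A binned track tibble, optionally with a `strain` column
#'   (smoothing is then applied per strain).
#' @param window_bp Window width in bp (default 1000).
#' @return The smoothed track, same shape as the input.
#' @export
median_smooth <- function(track, window_bp = 1000) {
  bw <- track_bin_width(track)
  if (window_bp < bw) abort("smoothing window smaller than one bin")
  k <- ceiling(window_bp / bw)
  if (k %% 2 == 0) k <- k + 1L
  group_cols <- intersect(c("strain", "replicate", "chrom"), names(track))
  out <- dplyr::mutate(dplyr::group_by(track, dplyr::across(dplyr::all_of(group_cols))),
                       value = sliding_median(.data$value, k))
  out <- dplyr::ungroup(out)
  keep_provenance(out, track,
                  sprintf("median_smooth: window_bp=%g (%d bins)", window_bp, k))
}

# Exact sliding median with truncated (shrinking) centered windows.
sliding_median <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 1L) return(x)
  h <- (k - 1L) %/% 2L
  if (n >= k) {
    y <- as.vector(stats::runmed(x, k, endrule = "keep"))
  } else {
    y <- x
  }
  edge <- unique(c(seq_len(min(h, n)), seq.int(max(1L, n - h + 1L), n)))
  for (i in edge) {
    y[i] <- median(x[max(1L, i - h):min(n, i + h)])
  }
  y
}

#' Genome-wide Pearson correlation between two tracks
#'
#' @param a,b Binned track tibbles with identical bin scaffolds.
#' @return Pearson r over all concatenated bins.
#' @export
replicate_correlation <- function(a, b) {
  check_same_bins(a, b)
  if (nrow(a) < 2) abort("need at least 2 bins")
  if (sd(a$value) == 0 || sd(b$value) == 0) {
    abort("zero variance track: correlation undefined")
  }
  cor(a$value, b$value)
}

check_same_bins <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !identical(a$chrom, b$chrom) ||
      !identical(a$start, b$start) ||
      !identical(a$end, b$end)) {
    abort("tracks have different bin scaffolds")
  }
  invisible(TRUE)
}

#' Average replicate tracks into a strain profile
#'
#' Element-wise arithmetic mean of one or more replicate tracks.  The
#' result carries a `strain` column and a provenance attribute recording
#' the replicate count and all pairwise Pearson correlations.
#'
#' @param tracks A list of binned track tibbles on identical scaffolds, or
#'   a single long tibble with a `replicate` column.
#' @param strain Strain (genotype) label for the profile.
#' @return A strain profile: a binned track tibble with a leading `strain`
#'   column, provenance in `attr(, "provenance")` and pairwise replicate
#'   correlations in `attr(, "replicate_correlations")`.
#' @export
average_replicates <- function(tracks, strain = "strain") {
  if (is.data.frame(tracks)) {
    stopifnot("replicate" %in% names(tracks))
    tracks <- purrr::map(split(tracks, tracks$replicate),
                         function(df) df[, c("chrom", "start", "end", "value")])
  }
  if (length(tracks) < 1) abort("need at least one replicate track")
  base <- tracks[[1]]
  for (t in tracks[-1]) check_same_bins(base, t)
  vals <- vapply(tracks, function(t) t$value, numeric(nrow(base)))
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = length(tracks))
  out <- tibble::tibble(strain = strain, chrom = base$chrom,
                        start = base$start, end = base$end,
                        value = rowMeans(vals))
  cors <- tibble::tibble(strain = character(), rep_i = integer(),
                         rep_j = integer(), pearson_r = double())
  if (length(tracks) >= 2) {
    pairs <- utils::combn(length(tracks), 2)
    cors <- tibble::tibble(
      strain = strain,
      rep_i = pairs[1, ], rep_j = pairs[2, ],
      pearson_r = apply(pairs, 2, function(p) {
        replicate_correlation(tracks[[p[1]]], tracks[[p[2]]])
      }))
  }
  attr(out, "replicate_correlations") <- cors
  attr(out, "provenance") <- c(
    sprintf("average_replicates: strain=%s n=%d", strain, length(tracks)),
    if (nrow(cors)) sprintf("replicate_correlation: r(%d,%d)=%.6f",
                            cors$rep_i, cors$rep_j, cors$pearson_r))
  out
}

keep_provenance <- function(out, input, step) {
  attr(out, "replicate_correlations") <- attr(input, "replicate_correlations")
  attr(out, "provenance") <- c(attr(input, "provenance"), step)
  out
}

#' Provenance of a processed profile
#'
#' @param x A track or profile produced by the preprocessing chain.
#' @return Character vector of applied operations with parameters.
#' @export
provenance <- function(x) attr(x, "provenance") %||% character()

#' Scale-normalize profiles across strains
#'
#' Multiplies each strain's track by one scalar so that every strain's
#' genome-wide total signal equals `target_total` (by default the mean of
#' the input totals).  Within-strain signal shape — every ratio of bin
#' values — is preserved exactly.
#'
#' @param profiles A long tibble of strain profiles (columns `strain`,
#'   `chrom`, `start`, `end`, `value`), or a list of such profiles to be
#'   row-bound.
#' @param target_total Total signal after normalization; default: mean of
#'   the per-strain input totals.
#' @return The normalized long tibble; per-strain scale factors are in
#'   `attr(, "scale_factors")`.
#' @export
scale_normalize <- function(profiles, target_total = NULL) {
  prov <- if (is.data.frame(profiles)) attr(profiles, "provenance") else
    unlist(purrr::map(profiles, provenance))
  if (!is.data.frame(profiles)) profiles <- dplyr::bind_rows(profiles)
  stopifnot("strain" %in% names(profiles))
  totals <- dplyr::summarise(dplyr::group_by(profiles, .data$strain),
                             total = sum(.data$value), .groups = "drop")
  if (nrow(totals) < 2) abort("scale_normalize needs at least two strains")
  if (any(totals$total <= 0)) {
    abort(paste0("zero-total profile: ",
                 paste(totals$strain[totals$total <= 0], collapse = ", ")))
  }
  target_total <- target_total %||% mean(totals$total)
  totals$scale <- target_total / totals$total
  out <- dplyr::mutate(
    dplyr::left_join(profiles, totals[, c("strain", "scale")], by = "strain"),
    value = .data$value * .data$scale)
  out$scale <- NULL
  attr(out, "scale_factors") <- totals
  attr(out, "provenance") <- c(prov,
    sprintf("scale_normalize: target_total=%.6g", target_total))
  out
}
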