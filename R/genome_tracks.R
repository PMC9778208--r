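#' Construct a genome build table
#'
#' A genome build is the coordinate frame for all tracks and annotations:
#' an ordered table of chromosome names and lengths.  All coordinates in
#' the package are 0-based, half-open (BED convention).
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Positive integer vector of chromosome lengths in bp.
#' @return A tibble with columns `chrom` and `length`, rows in the order
#'   given.
#' @examples
#' genome_build(c("chrI", "chrII"), c(230218, 813184))
#' @export
genome_build <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) abort("no chromosomes")
  if (anyDuplicated(chrom)) {
    abort(paste0("duplicate chromosome name: ",
                 paste(unique(chrom[duplicated(chrom)]), collapse = ", ")))
  }
  if (any(!is.finite(length)) || any(length <= 0) || any(length != floor(length))) {
    abort("chromosome lengths must be positive integers")
  }
  tibble::tibble(chrom = chrom, length = length)
}

#' Read a UCSC-style chrom.sizes file
#'
#' @param path Path to a two-column whitespace-delimited file: chromosome
#'   name, then length in bp.
#' @return A genome build tibble (see [genome_build()]) with rows in file
#'   order.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort("no chromosomes")
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) abort(paste0("malformed line ", bad[1], " in ", path))
  chrom <- vapply(parts, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(len)) abort(paste0("malformed length on line ", which(is.na(len))[1]))
  genome_build(chrom, len)
}

#' Write a chrom.sizes file
#'
#' @param genome A genome build tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  readr::write_lines(sprintf("%s\t%d", genome$chrom, as.integer(genome$length)), path)
  invisible(path)
}

# One row per fixed-width bin covering the genome; the last bin of each
# chromosome is truncated at the chromosome end.
bin_scaffold <- function(genome, bin_width) {
  stopifnot(is.numeric(bin_width), bin_width >= 1)
  pieces <- purrr::map2(genome$chrom, genome$length, function(ch, len) {
    starts <- seq(0, len - 1, by = bin_width)
    tibble::tibble(chrom = ch, start = starts, end = pmin(starts + bin_width, len))
  })
  dplyr::bind_rows(pieces)
}

#' Create an all-zero binned track
#'
#' A binned track is a tibble with one row per fixed-width genomic bin and
#' columns `chrom`, `start`, `end`, `value`.  Bin `i` of a chromosome covers
#' `[i * w, (i + 1) * w)`; the final bin is truncated at the chromosome end.
#'
#' @param genome A genome build tibble.
#' @param bin_width Bin width in bp (default 50).
#' @return A binned track tibble with all values 0.
#' @export
empty_track <- function(genome, bin_width = 50) {
  sc <- bin_scaffold(genome, bin_width)
  sc$value <- 0
  sc
}

#' Recover the genome build from a binned track
#'
#' @param track A binned track tibble.
#' @return A genome build tibble (chromosome lengths are the final bin ends).
#' @export
track_genome <- function(track) {
  g <- dplyr::summarise(dplyr::group_by(track, .data$chrom),
                        length = max(.data$end), .groups = "drop")
  # preserve first-appearance order
  g[match(unique(track$chrom), g$chrom), ]
}

#' Bin width of a binned track
#'
#' @param track A binned track tibble.
#' @return The bin width in bp (largest bin extent; the final bin of a
#'   chromosome may be narrower).
#' @export
track_bin_width <- function(track) {
  max(track$end - track$start)
}

# Split a (single-strain) track into per-chromosome value vectors plus widths.
track_split <- function(track) {
  idx <- split(seq_len(nrow(track)), factor(track$chrom, levels = unique(track$chrom)))
  purrr::map(idx, function(i) {
    list(start = track$start[i], end = track$end[i], value = track$value[i])
  })
}

parse_table_lines <- function(path, min_cols, what) {
  lines <- readr::read_lines(path)
  keep <- nzchar(trimws(lines)) &
    !startsWith(lines, "track") & !startsWith(lines, "browser") &
    !startsWith(lines, "#")
  lines <- lines[keep]
  if (length(lines) == 0L) abort(paste0("no records in ", what, " file ", path))
  parts <- strsplit(trimws(lines), "[ \t]+")
  ncols <- vapply(parts, length, 1L)
  if (any(ncols < min_cols)) {
    abort(paste0("malformed ", what, " line (fewer than ", min_cols,
                 " fields): line ", which(ncols < min_cols)[1]))
  }
  parts
}

#' Read a bedGraph file onto fixed-width bins
#'
#' Each record's value is spread over the bins it overlaps, weighted by the
#' number of base pairs of overlap; the value of a bin is the per-bp mean
#' over the bin (uncovered base pairs count as zero).  A bin entirely
#' covered by a single record therefore carries that record's value
#' exactly.  Binning conserves mass: `sum(value * bin_bp)` equals
#' `sum(record_value * record_bp)` up to float rounding.
#'
#' @param path Path to a bedGraph file (chrom, start, end, value; 0-based
#'   half-open).  `track`/`browser`/`#` lines are skipped.
#' @param genome A genome build tibble; records on chromosomes absent from
#'   it are an error.
#' @param bin_width Bin width in bp (default 50).
#' @return A binned track tibble.
#' @export
read_bedgraph <- function(path, genome, bin_width = 50) {
  parts <- parse_table_lines(path, 4L, "bedGraph")
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.numeric(vapply(parts, `[[`, "", 2L))
  end <- as.numeric(vapply(parts, `[[`, "", 3L))
  value <- as.numeric(vapply(parts, `[[`, "", 4L))
  if (anyNA(start) || anyNA(end) || anyNA(value)) abort("malformed bedGraph record")
  bedgraph_to_track(tibble::tibble(chrom = chrom, start = start, end = end,
                                   value = value),
                    genome, bin_width)
}

#' Bin an in-memory set of coverage records
#'
#' @param records A tibble with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open, non-negative values).
#' @inheritParams read_bedgraph
#' @return A binned track tibble.
#' @export
bedgraph_to_track <- function(records, genome, bin_width = 50) {
  unknown <- setdiff(unique(records$chrom), genome$chrom)
  if (length(unknown)) {
    abort(paste0("unknown chromosome in bedGraph: ", paste(unknown, collapse = ", ")))
  }
  if (any(records$value < 0)) abort("negative coverage value in bedGraph")
  if (any(!is.finite(records$value))) abort("non-finite coverage value in bedGraph")
  chrom_len <- setNames(genome$length, genome$chrom)
  if (any(records$start < 0) || any(records$start >= records$end)) {
    abort("invalid bedGraph interval (need 0 <= start < end)")
  }
  if (any(records$end > chrom_len[records$chrom])) {
    abort("bedGraph interval exceeds chromosome length")
  }

  out <- empty_track(genome, bin_width)
  bw <- bin_width
  values <- split(seq_len(nrow(records)),
                  factor(records$chrom, levels = genome$chrom))
  offsets <- c(0, cumsum(ceiling(genome$length / bw)))[seq_along(genome$chrom)]
  names(offsets) <- genome$chrom
  val <- out$value
  width <- out$end - out$start

  for (ch in genome$chrom) {
    ri <- values[[ch]]
    if (length(ri) == 0L) next
    s <- records$start[ri]; e <- records$end[ri]; v <- records$value[ri]
    nb <- ceiling(chrom_len[[ch]] / bw)
    off <- offsets[[ch]]
    w_ch <- width[off + seq_len(nb)]
    b0 <- floor(s / bw); b1 <- floor((e - 1) / bw)
    contrib <- numeric(nb)
    add_at <- function(idx, x) {
      if (length(idx) == 0L) return()
      agg <- rowsum(x, idx)
      contrib[as.numeric(rownames(agg))] <<- contrib[as.numeric(rownames(agg))] + agg[, 1]
    }
    single <- b0 == b1
    if (any(single)) {
      i <- which(single)
      add_at(b0[i] + 1, v[i] * ((e[i] - s[i]) / w_ch[b0[i] + 1]))
    }
    multi <- which(!single)
    if (length(multi)) {
      i <- multi
      # first (possibly partial) bin
      add_at(b0[i] + 1, v[i] * (((b0[i] + 1) * bw - s[i]) / w_ch[b0[i] + 1]))
      # last (possibly partial) bin
      add_at(b1[i] + 1, v[i] * ((e[i] - b1[i] * bw) / w_ch[b1[i] + 1]))
      # interior bins fully covered: per-bp mean contribution is exactly v
      interior <- i[b1[i] - b0[i] >= 2]
      if (length(interior)) {
        d <- numeric(nb + 1)
        agg <- rowsum(c(v[interior], -v[interior]),
                      c(b0[interior] + 2, b1[interior] + 1))
        d[as.numeric(rownames(agg))] <- agg[, 1]
        contrib <- contrib + cumsum(d[seq_len(nb)])
      }
    }
    val[off + seq_len(nb)] <- val[off + seq_len(nb)] + contrib
  }
  out$value <- val
  out
}

#' Write a binned track as bedGraph
#'
#' Adjacent equal-valued bins are collapsed into one record (run-length
#' encoding); zero-valued runs are written explicitly, so
#' `read_bedgraph(write_bedgraph(t))` reproduces `t` bit-exactly.
#'
#' @param track A binned track tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  recs <- dplyr::group_modify(
    dplyr::group_by(track, .data$chrom),
    function(df, key) {
      r <- rle(df$value)
      ends_idx <- cumsum(r$lengths)
      starts_idx <- ends_idx - r$lengths + 1L
      tibble::tibble(start = df$start[starts_idx], end = df$end[ends_idx],
                     value = r$values)
    })
  recs <- dplyr::ungroup(recs)
  # restore original chromosome order
  recs <- recs[order(match(recs$chrom, unique(track$chrom))), ]
  readr::write_lines(sprintf("%s\t%d\t%d\t%.17g", recs$chrom,
                             as.integer(recs$start), as.integer(recs$end),
                             recs$value),
                     path)
  invisible(path)
}

#' Read a BED3+ feature file
#'
#' @param path Path to a BED file with at least chrom/start/end; column 4,
#'   if present, is taken as the feature name, and any further columns are
#'   kept as `extra1`, `extra2`, ... character columns.
#' @param genome A genome build tibble used to validate coordinates.
#' @return A tibble of validated intervals in file order with columns
#'   `chrom`, `start`, `end`, `name` (NA when absent) and any extras.
#' @export
read_bed_features <- function(path, genome) {
  parts <- parse_table_lines(path, 3L, "BED")
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.numeric(vapply(parts, `[[`, "", 2L))
  end <- as.numeric(vapply(parts, `[[`, "", 3L))
  if (anyNA(start) || anyNA(end)) abort("malformed BED coordinates")
  name <- vapply(parts, function(p) if (length(p) >= 4L) p[[4L]] else NA_character_, "")
  out <- tibble::tibble(chrom = chrom, start = start, end = end, name = name)
  maxc <- max(vapply(parts, length, 1L))
  if (maxc > 4L) {
    for (j in 5:maxc) {
      out[[paste0("extra", j - 4L)]] <-
        vapply(parts, function(p) if (length(p) >= j) p[[j]] else NA_character_, "")
    }
  }
  validate_intervals(out, genome)
  out
}

validate_intervals <- function(x, genome) {
  unknown <- setdiff(unique(x$chrom), genome$chrom)
  if (length(unknown)) {
    abort(paste0("unknown chromosome: ", paste(unknown, collapse = ", ")))
  }
  if (any(x$start < 0) || any(x$start >= x$end)) {
    abort("invalid interval: need 0 <= start < end (half-open)")
  }
  chrom_len <- setNames(genome$length, genome$chrom)
  if (any(x$end > chrom_len[x$chrom])) {
    abort("interval end exceeds chromosome length")
  }
  invisible(x)
}

#' Feature midpoints
#'
#' @param features A tibble with `start` and `end` columns.
#' @return Integer midpoints, `floor((start + end) / 2)`.
#' @export
feature_midpoint <- function(features) {
  floor((features$start + features$end) / 2)
}
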