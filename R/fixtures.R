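sc_chrom_lengths <- c(
  chrI = 230218, chrII = 813184, chrIII = 316620, chrIV = 1531933,
  chrV = 576874, chrVI = 270161, chrVII = 1090940, chrVIII = 562643,
  chrIX = 439888, chrX = 745751, chrXI = 666816, chrXII = 1078177,
  chrXIII = 924431, chrXIV = 784333, chrXV = 1091291, chrXVI = 948066)

sc_cen_positions <- c(
  chrI = 151465, chrII = 238207, chrIII = 114385, chrIV = 449711,
  chrV = 151987, chrVI = 148510, chrVII = 496920, chrVIII = 105586,
  chrIX = 355629, chrX = 436307, chrXI = 440129, chrXII = 150828,
  chrXIII = 268031, chrXIV = 628758, chrXV = 326584, chrXVI = 555957)

#' The 16-chromosome budding-yeast genome build
#'
#' Nuclear chromosome lengths of the sacCer3 reference assembly.
#'
#' @return A genome build tibble.
#' @export
sc_genome <- function() {
  genome_build(names(sc_chrom_lengths), unname(sc_chrom_lengths))
}

#' Budding-yeast centromere positions
#'
#' Approximate centromere midpoints on the sacCer3 assembly.
#'
#' @return A centromere tibble (`chrom`, `position`, `name`).
#' @export
sc_centromeres <- function() {
  tibble::tibble(chrom = names(sc_cen_positions),
                 position = unname(sc_cen_positions),
                 name = sprintf("CEN%d", seq_along(sc_cen_positions)))
}

#' Synthetic genome-scale origin annotation fixture
#'
#' A deterministic, synthetic stand-in for the yeast origin annotation at
#' its published scale: 410 confirmed origins spread over the 16
#' chromosomes in proportion to length, 95 flagged Fkh-activated with a
#' 35-origin Fkh1-sensitive subset, and 2 rDNA-flagged origins placed at
#' the rDNA locus on chromosome XII.  Origin coordinates are evenly
#' spaced, not real; only the counts, name style and genomic frame mimic
#' the published annotation.
#'
#' @param n_confirmed,n_fkh,n_fkh1,n_rdna Group sizes.
#' @return A list with `genome`, `origins` (CEN-proximal classified) and
#'   `centromeres`.
#' @export
synthetic_origin_fixture <- function(n_confirmed = 410, n_fkh = 95,
                                     n_fkh1 = 35, n_rdna = 2) {
  genome <- sc_genome()
  cens <- sc_centromeres()
  frac <- genome$length / sum(genome$length)
  n_per <- floor(frac * n_confirmed)
  # distribute the remainder to the largest fractional parts
  rem <- n_confirmed - sum(n_per)
  extra <- order(frac * n_confirmed - n_per, decreasing = TRUE)[seq_len(rem)]
  n_per[extra] <- n_per[extra] + 1
  rows <- purrr::map(seq_len(nrow(genome)), function(ci) {
    n <- n_per[ci]
    mids <- round(genome$length[ci] * (seq_len(n) - 0.5) / n)
    tibble::tibble(chrom = genome$chrom[ci],
                   start = mids - 150, end = mids + 150,
                   name = sprintf("ARS%02d%02d", ci, seq_len(n)))
  })
  bed <- dplyr::bind_rows(rows)
  # rDNA origins: the two origins nearest the chrXII rDNA locus (~460 kb)
  x12 <- which(bed$chrom == "chrXII")
  rdna_idx <- x12[order(abs(feature_midpoint(bed[x12, ]) - 460000))][seq_len(n_rdna)]
  rdna <- integer(nrow(bed)); rdna[rdna_idx] <- 1L
  # Fkh-activated: every k-th non-rDNA origin until n_fkh are flagged
  candidates <- setdiff(seq_len(nrow(bed)), rdna_idx)
  fkh_idx <- candidates[round(seq(1, length(candidates), length.out = n_fkh))]
  fkh <- integer(nrow(bed)); fkh[fkh_idx] <- 1L
  fkh1_idx <- fkh_idx[round(seq(1, n_fkh, length.out = n_fkh1))]
  fkh1 <- integer(nrow(bed)); fkh1[fkh1_idx] <- 1L
  flags <- tibble::tibble(name = bed$name, confirmed = 1L,
                          fkh_activated = fkh, fkh1_sensitive = fkh1,
                          rdna = rdna)
  origins <- origin_set(bed, flags)
  origins <- classify_cen_proximal(origins, cens)
  list(genome = genome, origins = origins, centromeres = cens)
}

#' Write an annotation fixture to standard-format files
#'
#' @param fixture A list with `genome`, `origins`, `centromeres` (as from
#'   [synthetic_origin_fixture()] or [sim_fixture()]).
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix (default "synthetic").
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_files <- function(fixture, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    chrom_sizes = file.path(dir, paste0(prefix, ".chrom.sizes")),
    origins_bed = file.path(dir, paste0(prefix, "_origins.bed")),
    flags_tsv = file.path(dir, paste0(prefix, "_origin_flags.tsv")),
    centromeres_bed = file.path(dir, paste0(prefix, "_centromeres.bed")))
  write_chrom_sizes(fixture$genome, paths[["chrom_sizes"]])
  o <- fixture$origins
  readr::write_lines(sprintf("%s\t%d\t%d\t%s", o$chrom, as.integer(o$start),
                             as.integer(o$end), o$name),
                     paths[["origins_bed"]])
  flags <- tibble::tibble(name = o$name,
                          confirmed = as.integer(o$confirmed),
                          fkh_activated = as.integer(o$fkh_activated),
                          fkh1_sensitive = as.integer(o$fkh1_sensitive),
                          rdna = as.integer(o$rdna))
  readr::write_tsv(flags, paths[["flags_tsv"]])
  cen <- fixture$centromeres
  readr::write_lines(sprintf("%s\t%d\t%d\t%s", cen$chrom,
                             as.integer(cen$position - 60),
                             as.integer(cen$position + 60), cen$name),
                     paths[["centromeres_bed"]])
  invisible(paths)
}
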