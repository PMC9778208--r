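#' Load an annotated origin set
#'
#' Combines a BED file of origin intervals with a TSV of per-origin group
#' flags into one origin table.  Flags mimic the usual annotation layers
#' for budding yeast origins: the OriDB-style "confirmed" list, the
#' Fkh-activated list, its Fkh1-sensitive subset, and rDNA-locus origins.
#'
#' @param bed_path BED4 file of origin intervals (name in column 4).
#' @param flags_path TSV with header `name confirmed fkh_activated
#'   fkh1_sensitive rdna` and 0/1 values.  Origins absent from the file
#'   default to confirmed with all other flags off.
#' @param genome A genome build tibble.
#' @return An origin set: a tibble with columns `chrom`, `start`, `end`,
#'   `name`, `midpoint`, logical flags `confirmed`, `fkh_activated`,
#'   `fkh1_sensitive`, `rdna`, `cen_proximal` (FALSE until
#'   [classify_cen_proximal()] is run) and `dist_to_cen` (NA until
#'   computed).
#' @export
load_origin_set <- function(bed_path, flags_path, genome) {
  bed <- read_bed_features(bed_path, genome)
  if (anyNA(bed$name)) abort("origin BED must carry names in column 4")
  flags <- readr::read_tsv(flags_path, show_col_types = FALSE, comment = "#")
  origin_set(bed, flags)
}

#' Build an origin set from in-memory tables
#'
#' @param bed A tibble with `chrom`, `start`, `end`, `name`.
#' @param flags A tibble with `name` plus 0/1 or logical columns
#'   `confirmed`, `fkh_activated`, `fkh1_sensitive`, `rdna` (missing
#'   columns default to confirmed = TRUE, others FALSE).
#' @return An origin set tibble; see [load_origin_set()].
#' @export
origin_set <- function(bed, flags = NULL) {
  if (anyDuplicated(bed$name)) {
    abort(paste0("duplicate origin name: ",
                 paste(unique(bed$name[duplicated(bed$name)]), collapse = ", ")))
  }
  out <- tibble::tibble(chrom = bed$chrom, start = bed$start, end = bed$end,
                        name = bed$name, midpoint = feature_midpoint(bed))
  flag_cols <- c("confirmed", "fkh_activated", "fkh1_sensitive", "rdna")
  defaults <- c(confirmed = TRUE, fkh_activated = FALSE,
                fkh1_sensitive = FALSE, rdna = FALSE)
  if (!is.null(flags)) {
    if (anyDuplicated(flags$name)) abort("duplicate origin name in flags")
    missing <- setdiff(flags$name, out$name)
    if (length(missing)) {
      abort(paste0("flag for unknown origin name: ", paste(missing, collapse = ", ")))
    }
  }
  for (fc in flag_cols) {
    v <- rep(unname(defaults[fc]), nrow(out))
    if (!is.null(flags) && fc %in% names(flags)) {
      i <- match(flags$name, out$name)
      v[i] <- as.logical(as.numeric(flags[[fc]]))
    }
    out[[fc]] <- v
  }
  out$cen_proximal <- FALSE
  out$dist_to_cen <- NA_real_
  out
}

#' Read centromere positions from a BED file
#'
#' @param path BED4 file of centromere intervals (CEN1-style names in
#'   column 4).  The point position used downstream is the interval
#'   midpoint.
#' @param genome A genome build tibble.
#' @return A tibble with columns `chrom`, `position`, `name`.
#' @export
read_centromeres <- function(path, genome) {
  bed <- read_bed_features(path, genome)
  tibble::tibble(chrom = bed$chrom, position = feature_midpoint(bed),
                 name = bed$name)
}

#' Remove rDNA-flagged origins
#'
#' Origins inside the rDNA repeat locus behave anomalously in
#' coverage-based assays and are conventionally dropped before
#' feature-centered analyses.  Removal is idempotent, and a removed origin
#' leaves every group it belonged to.
#'
#' @param origins An origin set tibble.
#' @return The origin set without rdna-flagged rows.
#' @export
exclude_rdna <- function(origins) {
  dplyr::filter(origins, !.data$rdna)
}

#' Distance from each origin to its nearest centromere
#'
#' @param origins An origin set tibble.
#' @param centromeres A centromere tibble (`chrom`, `position`, `name`).
#' @return `origins` with `dist_to_cen` filled: the minimum over
#'   same-chromosome centromeres of |midpoint - position|, or `Inf` for
#'   origins on a chromosome without a centromere.
#' @export
distance_to_nearest_cen <- function(origins, centromeres) {
  cen_by_chrom <- split(centromeres$position, centromeres$chrom)
  origins$dist_to_cen <- purrr::map2_dbl(origins$chrom, origins$midpoint,
    function(ch, m) {
      pos <- cen_by_chrom[[ch]]
      if (is.null(pos)) Inf else min(abs(m - pos))
    })
  origins
}

#' Classify CEN-proximal origins by the nearest-flanking rule
#'
#' For each centromere, the closest confirmed origin with midpoint left of
#' the centromere position and the closest with midpoint right of it are
#' selected; the union over centromeres forms the CEN-proximal group.  A
#' 16-centromere genome with confirmed origins flanking every centromere
#' therefore yields 32 CEN-proximal origins.  Selection runs on the
#' rDNA-excluded confirmed set; equidistant candidates on one side are
#' broken by lexicographically smaller name, and an origin whose midpoint
#' coincides with the centromere counts as left-flanking.
#'
#' @param origins An origin set tibble.
#' @param centromeres A centromere tibble (`chrom`, `position`, `name`).
#' @return `origins` with the `cen_proximal` flag set and `dist_to_cen`
#'   filled for every origin.
#' @export
classify_cen_proximal <- function(origins, centromeres) {
  origins <- distance_to_nearest_cen(origins, centromeres)
  origins$cen_proximal <- FALSE
  eligible <- which(origins$confirmed & !origins$rdna)
  for (i in seq_len(nrow(centromeres))) {
    ch <- centromeres$chrom[i]; pos <- centromeres$position[i]
    cand <- eligible[origins$chrom[eligible] == ch]
    if (length(cand) == 0L) {
      warn(paste0("centromere ", centromeres$name[i],
                  " has no confirmed origins on its chromosome"))
      next
    }
    mid <- origins$midpoint[cand]
    for (side in c("left", "right")) {
      sel <- if (side == "left") cand[mid <= pos] else cand[mid > pos]
      if (length(sel) == 0L) next
      d <- abs(origins$midpoint[sel] - pos)
      best <- sel[d == min(d)]
      if (length(best) > 1L) best <- best[order(origins$name[best])][1L]
      origins$cen_proximal[best] <- TRUE
    }
  }
  origins
}

#' Named origin groups of an origin set
#'
#' @param origins An origin set tibble.
#' @param groups Character vector of group names to report; any of
#'   `"confirmed"`, `"fkh_activated"`, `"fkh1_sensitive"`,
#'   `"cen_proximal"`, `"rdna"`.
#' @return A long tibble with columns `group` and `name`, one row per
#'   origin-group membership.
#' @export
origin_group_long <- function(origins,
                              groups = c("confirmed", "fkh_activated",
                                         "cen_proximal")) {
  bad <- setdiff(groups, c("confirmed", "fkh_activated", "fkh1_sensitive",
                           "cen_proximal", "rdna"))
  if (length(bad)) abort(paste0("unknown origin group: ", paste(bad, collapse = ", ")))
  dplyr::bind_rows(purrr::map(groups, function(g) {
    tibble::tibble(group = g, name = origins$name[origins[[g]]])
  }))
}

#' Group size summary of an origin set
#'
#' @inheritParams origin_group_long
#' @return A tibble with columns `group` and `n`.
#' @export
origin_group_sizes <- function(origins,
                               groups = c("confirmed", "fkh_activated",
                                          "fkh1_sensitive", "cen_proximal",
                                          "rdna")) {
  long <- origin_group_long(origins, groups)
  counts <- dplyr::count(long, .data$group, name = "n")
  out <- tibble::tibble(group = groups)
  out$n <- dplyr::coalesce(counts$n[match(groups, counts$group)], 0L)
  out
}
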