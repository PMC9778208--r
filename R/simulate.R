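#' Simulator configuration
#'
#' Parameters of the stochastic origin-firing simulator.  The model: in a
#' hydroxyurea-arrested early S phase, licensed origins compete for a
#' limiting pool of initiation kinase (DDK); per cell, at most
#' `pool_size` origins fire, drawn without replacement with probability
#' proportional to their recruitment weight.  Weights combine a base
#' efficiency with two pathway boosts — a Forkhead (Fkh1/2) boost on
#' Fkh-activated origins and a kinetochore (Ctf19) boost decaying
#' linearly with distance from the centromere — and a genotype-wide
#' multiplier for hypomorphic *DBF4* alleles.  Forks from fired origins
#' progress slowly and share a per-cell synthesis capacity (the dNTP
#' budget under hydroxyurea), so the fewer origins fire, the farther each
#' fork travels.
#'
#' @param n_chrom,chrom_length,origin_spacing,origin_width Toy genome
#'   layout: number of chromosomes, their common length (bp), regular
#'   origin spacing (bp) and origin interval width (bp).  The default 16
#'   chromosomes of 300 kb with origins every 30 kb mimic the yeast
#'   genome's layout at desk scale.
#' @param bin_width Track bin width in bp.
#' @param base_efficiency Baseline recruitment weight of every origin,
#'   in (0, 1].
#' @param fkh_boost Multiplier (>= 1) on Fkh-activated origins when the
#'   Forkhead pathway is functional.
#' @param cen_boost Maximal kinetochore-pathway multiplier at distance 0
#'   from the centromere; decays linearly to 1 at `cen_range`.
#' @param cen_range Distance (bp) out to which the kinetochore pathway
#'   stimulates origins (default 25000).
#' @param pool_size Maximal number of origins firing per cell (the
#'   limiting DDK pool).
#' @param fork_speed Fork speed under hydroxyurea, bp/min.
#' @param duration Arrest duration in minutes (default 60);
#'   `duration_dC` (default 90) is used for the dC allele.
#' @param capacity_origins Per-cell synthesis capacity expressed as the
#'   number of origins that could replicate a full `2 * fork_speed *
#'   duration` extent; forks share this budget, so the per-fork extent is
#'   `min(fork_speed * duration, fork_speed * duration *
#'   capacity_origins / n_fired)`.
#' @param n_cells Cells per simulated experiment.
#' @param read_depth Expected coverage counts for a bin replicated in
#'   every cell; bin counts are Poisson around `read_depth * fraction`.
#' @param overdispersion Extra-Poisson noise; 0 (default) gives Poisson
#'   counts, values > 0 give negative binomial with size
#'   `1/overdispersion`.
#' @param firing_times `"arrest"` (default): all fired origins fire at
#'   t = 0, the single-snapshot approximation of an HU arrest;
#'   `"exponential"`: waiting times are exponential with rate
#'   proportional to weight, and forks only run for the remaining time.
#' @param firing_rate_scale Rate per minute per unit weight for the
#'   exponential firing-time option.
#' @param global_multiplier Named genotype-wide weight multipliers for
#'   the *DBF4* alleles (WT, Zn*, dC).  A hypomorphic allele also shrinks
#'   the effective pool: `pool_eff = max(1, round(pool_size *
#'   multiplier))`.
#' @param duration_dC Arrest duration (min) for the dC allele.
#' @param chip_background,chip_cen_amplitude,chip_cenprox_amplitude,chip_origin_amplitude
#'   Poisson means of the Dbf4 occupancy (ChIP-like) track: flat
#'   background plus Gaussian peaks at centromeres, CEN-proximal origins
#'   and remaining origins.
#' @param chip_cen_sd,chip_origin_sd Gaussian peak standard deviations
#'   (bp).
#' @param zn_cen_factor,zn_cenprox_factor Suppression factors (< 1)
#'   applied to CEN and CEN-proximal ChIP peaks by the Zn* allele.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 16, chrom_length = 3e5,
                       origin_spacing = 3e4, origin_width = 300,
                       bin_width = 50,
                       base_efficiency = 0.4,
                       fkh_boost = 3, cen_boost = 4, cen_range = 25000,
                       pool_size = 20,
                       fork_speed = 50, duration = 60,
                       capacity_origins = 5,
                       n_cells = 2000, read_depth = 100, overdispersion = 0,
                       firing_times = c("arrest", "exponential"),
                       firing_rate_scale = 0.1,
                       global_multiplier = c("WT" = 1, "Zn*" = 0.8, "dC" = 0.4),
                       duration_dC = 90,
                       chip_background = 5, chip_cen_amplitude = 60,
                       chip_cenprox_amplitude = 12, chip_origin_amplitude = 1,
                       chip_cen_sd = 500, chip_origin_sd = 300,
                       zn_cen_factor = 0.3, zn_cenprox_factor = 0.6) {
  firing_times <- match.arg(firing_times)
  cfg <- as.list(environment())
  stopifnot(cfg$base_efficiency > 0, cfg$base_efficiency <= 1,
            cfg$fkh_boost >= 1, cfg$cen_boost >= 1, cfg$cen_range > 0,
            cfg$pool_size >= 0, cfg$fork_speed >= 0, cfg$duration > 0,
            cfg$capacity_origins > 0, cfg$n_cells >= 1,
            cfg$read_depth > 0, cfg$overdispersion >= 0,
            all(cfg$global_multiplier >= 0),
            all(c("WT", "Zn*", "dC") %in% names(cfg$global_multiplier)))
  structure(cfg, class = "sim_config")
}

#' Genotype of a simulated strain
#'
#' Pathway switches for a simulated genotype.  The `Zn*` and `dC`
#' *DBF4* alleles force the kinetochore (CEN) recruitment pathway off —
#' their defining defect — and additionally apply their genotype-wide
#' multiplier (mild for Zn*, strong for the dC hypomorph).
#'
#' @param fkh1,fkh2 Is the respective Forkhead factor functional?
#'   (`fkh2 = FALSE` models the fkh2-dsm allele, which lacks only origin
#'   regulation.)
#' @param ctf19 Is the Ctf19 kinetochore pathway functional?
#' @param dbf4_allele One of `"WT"`, `"Zn*"`, `"dC"`.
#' @param label Strain label; a default is composed from the switches.
#' @return A list of class `sim_genotype`.
#' @export
sim_genotype <- function(fkh1 = TRUE, fkh2 = TRUE, ctf19 = TRUE,
                         dbf4_allele = c("WT", "Zn*", "dC"), label = NULL) {
  dbf4_allele <- match.arg(dbf4_allele)
  cen_pathway <- ctf19 && dbf4_allele == "WT"
  if (is.null(label)) {
    bits <- c(if (!fkh1) "fkh1d", if (!fkh2) "fkh2dsm", if (!ctf19) "ctf19d",
              if (dbf4_allele == "Zn*") "dbf4-Zn", if (dbf4_allele == "dC") "dbf4-dC")
    label <- if (length(bits)) paste(bits, collapse = "-") else "WT"
  }
  structure(list(fkh1 = fkh1, fkh2 = fkh2, ctf19 = ctf19,
                 dbf4_allele = dbf4_allele, cen_pathway = cen_pathway,
                 label = label),
            class = "sim_genotype")
}

#' The default genotype panel
#'
#' The five strains whose contrasts span the two recruitment pathways:
#' wild type, `ctf19d` (kinetochore pathway off), `dbf4-Zn` (kinetochore
#' pathway off plus a mild global defect), `dbf4-dC` (kinetochore pathway
#' off plus a strong global defect), and `fkh1d-fkh2dsm` (Forkhead
#' pathway off).  `fkh1d` alone is included as an optional sixth strain.
#'
#' @param include_fkh1d Include the single `fkh1d` genotype (default
#'   FALSE).
#' @return A named list of `sim_genotype` objects.
#' @export
genotype_panel <- function(include_fkh1d = FALSE) {
  panel <- list(
    "WT" = sim_genotype(),
    "ctf19d" = sim_genotype(ctf19 = FALSE, label = "ctf19d"),
    "dbf4-Zn" = sim_genotype(dbf4_allele = "Zn*", label = "dbf4-Zn"),
    "dbf4-dC" = sim_genotype(dbf4_allele = "dC", label = "dbf4-dC"),
    "fkh1d-fkh2dsm" = sim_genotype(fkh1 = FALSE, fkh2 = FALSE,
                                   label = "fkh1d-fkh2dsm"))
  if (include_fkh1d) {
    panel[["fkh1d"]] <- sim_genotype(fkh1 = FALSE, label = "fkh1d")
  }
  panel
}

#' Toy genome of the simulator
#'
#' @param config A `sim_config`.
#' @return A genome build tibble (`chr01` ... style names).
#' @export
sim_genome <- function(config) {
  genome_build(sprintf("chr%02d", seq_len(config$n_chrom)),
               rep(config$chrom_length, config$n_chrom))
}

#' Deterministic annotation fixture of the simulator
#'
#' Builds the toy genome, a regular grid of origins and one mid-chromosome
#' centromere per chromosome, with group flags laid out to mirror the
#' proportions of the yeast annotation: roughly a quarter of origins
#' Fkh-activated, a subset of those Fkh1-sensitive, two rDNA-flagged
#' origins on chromosome 12, and two CEN-flanking origins per chromosome.
#'
#' @param config A `sim_config`.
#' @return A list with `genome`, `origins` (CEN-proximal already
#'   classified) and `centromeres`.
#' @export
sim_fixture <- function(config) {
  genome <- sim_genome(config)
  n_per <- floor((config$chrom_length - config$origin_spacing / 2) /
                   config$origin_spacing) + 1
  rows <- purrr::map(seq_len(config$n_chrom), function(ci) {
    mids <- config$origin_spacing / 2 + config$origin_spacing * (seq_len(n_per) - 1)
    tibble::tibble(chrom = sprintf("chr%02d", ci),
                   start = mids - config$origin_width / 2,
                   end = mids + config$origin_width / 2,
                   name = sprintf("ORI%02d%02d", ci, seq_len(n_per)),
                   idx = seq_len(n_per), chrom_idx = ci)
  })
  bed <- dplyr::bind_rows(rows)
  flags <- tibble::tibble(
    name = bed$name,
    confirmed = 1L,
    fkh_activated = as.integer(bed$idx %in% c(2, 7) |
                                 (bed$idx == 4 & bed$chrom_idx <= 5)),
    fkh1_sensitive = as.integer(bed$idx == 2 & bed$chrom_idx <= 14),
    rdna = as.integer(bed$chrom_idx == 12 & bed$idx %in% c(n_per - 1, n_per)))
  origins <- origin_set(bed[, c("chrom", "start", "end", "name")], flags)
  centromeres <- tibble::tibble(
    chrom = sprintf("chr%02d", seq_len(config$n_chrom)),
    position = floor(config$chrom_length / 2),
    name = sprintf("CEN%02d", seq_len(config$n_chrom)))
  origins <- classify_cen_proximal(origins, centromeres)
  list(genome = genome, origins = origins, centromeres = centromeres)
}

#' Per-origin firing weights under a genotype
#'
#' The recruitment weight of each origin:
#' `base_efficiency * fkh_factor * cen_factor * global_multiplier`.
#' The Fkh boost applies to Fkh-activated origins when the Forkhead
#' pathway serves them (Fkh1-sensitive origins require Fkh1 itself;
#' others are served by either Fkh1 or Fkh2).  The kinetochore factor
#' `cen_boost(d) = cen_boost - (cen_boost - 1) * d / cen_range` applies
#' to origins within `cen_range` of a centromere when the CEN pathway is
#' intact (Ctf19 present and a wild-type *DBF4* allele).
#'
#' @param origins An origin set tibble.
#' @param centromeres A centromere tibble.
#' @param genotype A `sim_genotype`.
#' @param config A `sim_config`.
#' @return A tibble with columns `name`, `chrom`, `midpoint`, `weight`.
#' @export
assign_firing_weights <- function(origins, centromeres, genotype, config) {
  origins <- distance_to_nearest_cen(origins, centromeres)
  fkh_served <- ifelse(origins$fkh1_sensitive, genotype$fkh1,
                       genotype$fkh1 | genotype$fkh2)
  fkh_factor <- ifelse(origins$fkh_activated & fkh_served, config$fkh_boost, 1)
  cen_factor <- rep(1, nrow(origins))
  if (genotype$cen_pathway) {
    d <- origins$dist_to_cen
    in_range <- is.finite(d) & d <= config$cen_range
    cen_factor[in_range] <- config$cen_boost -
      (config$cen_boost - 1) * d[in_range] / config$cen_range
  }
  gm <- config$global_multiplier[[genotype$dbf4_allele]]
  tibble::tibble(name = origins$name, chrom = origins$chrom,
                 midpoint = origins$midpoint,
                 weight = config$base_efficiency * fkh_factor * cen_factor * gm)
}

#' Effective firing pool under a genotype
#'
#' The limiting-pool size scaled by the genotype's global multiplier:
#' a hypomorphic kinase supports fewer simultaneous initiations.
#'
#' @param genotype A `sim_genotype`.
#' @param config A `sim_config`.
#' @return Integer pool size, at least 1 (0 only if `pool_size` is 0).
#' @export
effective_pool_size <- function(genotype, config) {
  if (config$pool_size == 0) return(0L)
  gm <- config$global_multiplier[[genotype$dbf4_allele]]
  max(1L, as.integer(round(config$pool_size * gm)))
}

genotype_duration <- function(genotype, config) {
  if (genotype$dbf4_allele == "dC") config$duration_dC else config$duration
}

fork_extent <- function(n_fired, config, duration) {
  if (n_fired == 0) return(0)
  full <- config$fork_speed * duration
  min(full, full * config$capacity_origins / n_fired)
}

#' Simulate origin firing and replication in one cell
#'
#' Draws up to `pool_size` origins without replacement with probability
#' proportional to weight; each fired origin replicates an interval
#' `[midpoint - L, midpoint + L)` clipped to its chromosome, where the
#' fork extent `L` shares the per-cell synthesis capacity among fired
#' forks (see [sim_config()]).
#'
#' @param weights A weight tibble from [assign_firing_weights()].
#' @param config A `sim_config`.
#' @param pool_size Pool size for this cell; default
#'   `config$pool_size`.
#' @param duration Arrest duration (min); default `config$duration`.
#' @param genome Genome build for clipping; default [sim_genome()] of the
#'   config.
#' @return A list with `fired` (tibble: `name`, `chrom`, `midpoint`,
#'   `time`, `extent`) and `intervals` (tibble of merged replicated
#'   intervals: `chrom`, `start`, `end`).
#' @export
simulate_cell <- function(weights, config, pool_size = config$pool_size,
                          duration = config$duration, genome = NULL) {
  if (any(weights$weight <= 0)) abort("firing weights must be positive")
  genome <- genome %||% sim_genome(config)
  n <- min(pool_size, nrow(weights))
  if (n == 0) {
    return(list(fired = tibble::tibble(name = character(), chrom = character(),
                                       midpoint = double(), time = double(),
                                       extent = double()),
                intervals = tibble::tibble(chrom = character(),
                                           start = double(), end = double())))
  }
  idx <- sample.int(nrow(weights), n, prob = weights$weight)
  if (config$firing_times == "exponential") {
    t_fire <- rexp(n, rate = config$firing_rate_scale * weights$weight[idx])
    run <- pmax(0, duration - t_fire)
    budget <- fork_extent(n, config, duration)
    extent <- pmin(config$fork_speed * run, budget)
  } else {
    t_fire <- rep(0, n)
    extent <- rep(fork_extent(n, config, duration), n)
  }
  chrom_len <- setNames(genome$length, genome$chrom)
  fired <- tibble::new_tibble(
    list(name = weights$name[idx], chrom = weights$chrom[idx],
         midpoint = weights$midpoint[idx], time = t_fire, extent = extent),
    nrow = n)
  s <- pmax(0, fired$midpoint - extent)
  e <- unname(pmin(chrom_len[fired$chrom], fired$midpoint + extent))
  keep <- e > s
  iv <- tibble::new_tibble(list(chrom = fired$chrom[keep], start = s[keep],
                                end = e[keep]), nrow = sum(keep))
  list(fired = fired, intervals = merge_intervals(iv))
}

merge_intervals <- function(iv) {
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv$chrom, iv$start), ]
  keep_start <- numeric(0); keep_end <- numeric(0); keep_chrom <- character(0)
  cur_chrom <- NA_character_; cur_s <- NA_real_; cur_e <- NA_real_
  for (i in seq_len(nrow(iv))) {
    if (!identical(iv$chrom[i], cur_chrom) || iv$start[i] > cur_e) {
      if (!is.na(cur_chrom)) {
        keep_chrom <- c(keep_chrom, cur_chrom)
        keep_start <- c(keep_start, cur_s); keep_end <- c(keep_end, cur_e)
      }
      cur_chrom <- iv$chrom[i]; cur_s <- iv$start[i]; cur_e <- iv$end[i]
    } else {
      cur_e <- max(cur_e, iv$end[i])
    }
  }
  keep_chrom <- c(keep_chrom, cur_chrom)
  keep_start <- c(keep_start, cur_s); keep_end <- c(keep_end, cur_e)
  tibble::new_tibble(list(chrom = keep_chrom, start = keep_start,
                          end = keep_end), nrow = length(keep_chrom))
}

# Fraction of cells in which each bin is replicated (bp-weighted), from a
# list of per-cell merged interval tables.
replicated_fraction <- function(interval_list, genome, bin_width) {
  all_iv <- dplyr::bind_rows(interval_list)
  n_cells <- length(interval_list)
  if (nrow(all_iv) == 0) return(empty_track(genome, bin_width))
  all_iv$value <- 1
  frac <- bedgraph_to_track(all_iv, genome, bin_width)
  frac$value <- frac$value / n_cells
  frac
}

#' Synthetic BrdU incorporation (QBU-like) track
#'
#' Converts per-cell replication outcomes into a coverage-like track: the
#' per-bin replicated-cell fraction `f` is observed as Poisson counts
#' with mean `read_depth * f` (negative binomial when `overdispersion >
#' 0`).
#'
#' @param outcomes A list of outcomes from [simulate_cell()].
#' @param genome A genome build tibble.
#' @param config A `sim_config`.
#' @return A binned track tibble of noisy counts.
#' @export
brdu_track <- function(outcomes, genome, config) {
  if (length(outcomes) == 0) abort("need at least one cell")
  frac <- replicated_fraction(purrr::map(outcomes, "intervals"),
                              genome, config$bin_width)
  frac$value <- add_read_noise(config$read_depth * frac$value, config)
  frac
}

add_read_noise <- function(mu, config) {
  if (config$overdispersion > 0) {
    as.double(rnbinom(length(mu), mu = mu, size = 1 / config$overdispersion))
  } else {
    as.double(rpois(length(mu), lambda = mu))
  }
}

#' Synthetic Dbf4 occupancy (ChIP-like) track
#'
#' Flat Poisson background plus Gaussian-shaped enrichment peaks: strong
#' at centromeres, weak at CEN-proximal origins, minimal at other
#' confirmed origins.  The Zn* allele suppresses the CEN peaks by
#' `zn_cen_factor` and CEN-proximal origin peaks by `zn_cenprox_factor`;
#' other origin peaks are unchanged.
#'
#' @param origins An origin set tibble with `cen_proximal` classified.
#' @param centromeres A centromere tibble.
#' @param genotype A `sim_genotype`.
#' @param config A `sim_config`.
#' @param genome Genome build; default [sim_genome()] of the config.
#' @return A binned track tibble of noisy counts.
#' @export
dbf4_chip_track <- function(origins, centromeres, genotype, config,
                            genome = NULL) {
  genome <- genome %||% sim_genome(config)
  mu_track <- empty_track(genome, config$bin_width)
  mu <- rep(config$chip_background, nrow(mu_track))
  centers <- (mu_track$start + mu_track$end) / 2
  chrom_index <- split(seq_len(nrow(mu_track)), mu_track$chrom)
  zn <- genotype$dbf4_allele == "Zn*"
  add_peak <- function(chrom, pos, amp, sd) {
    if (amp <= 0) return()
    i <- chrom_index[[chrom]]
    x <- centers[i] - pos
    near <- abs(x) <= 4 * sd
    mu[i[near]] <<- mu[i[near]] + amp * exp(-x[near]^2 / (2 * sd^2))
  }
  for (i in seq_len(nrow(centromeres))) {
    add_peak(centromeres$chrom[i], centromeres$position[i],
             config$chip_cen_amplitude * if (zn) config$zn_cen_factor else 1,
             config$chip_cen_sd)
  }
  conf <- origins[origins$confirmed & !origins$rdna, ]
  for (i in seq_len(nrow(conf))) {
    amp <- if (conf$cen_proximal[i]) {
      config$chip_cenprox_amplitude * if (zn) config$zn_cenprox_factor else 1
    } else {
      config$chip_origin_amplitude
    }
    add_peak(conf$chrom[i], conf$midpoint[i], amp, config$chip_origin_sd)
  }
  mu_track$value <- add_read_noise(mu, config)
  mu_track
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Fast path for the arrest model: per-cell fired sets only, accumulated
# into per-origin fired counts plus the replicated-fraction track.
simulate_tracks_fast <- function(weights, genome, config, pool_size,
                                 duration, n_cells) {
  n_origin <- nrow(weights)
  n <- min(pool_size, n_origin)
  counts <- integer(n_origin)
  if (n > 0) {
    for (cell in seq_len(n_cells)) {
      idx <- sample.int(n_origin, n, prob = weights$weight)
      counts[idx] <- counts[idx] + 1L
    }
  }
  extent <- fork_extent(n, config, duration)
  chrom_len <- setNames(genome$length, genome$chrom)
  fired <- counts > 0 & extent > 0
  frac <- empty_track(genome, config$bin_width)
  if (any(fired)) {
    recs <- tibble::tibble(
      chrom = weights$chrom[fired],
      start = pmax(0, weights$midpoint[fired] - extent),
      end = unname(pmin(chrom_len[weights$chrom[fired]],
                        weights$midpoint[fired] + extent)),
      value = counts[fired] / n_cells)
    # valid only when fork extents never overlap between adjacent origins;
    # enforced by the caller
    frac <- bedgraph_to_track(recs, genome, config$bin_width)
  }
  list(frac = frac, counts = counts, extent = extent)
}

min_origin_gap <- function(weights) {
  gaps <- unlist(purrr::map(split(weights$midpoint, weights$chrom),
                            function(m) if (length(m) > 1) diff(sort(m)) else Inf))
  min(c(gaps, Inf))
}

#' Simulate a full multi-strain QBU experiment
#'
#' For each genotype, simulates `replicates` independent experiments of
#' `n_cells` cells each and emits noisy BrdU-like tracks plus a truth
#' table of per-origin firing frequencies.  Fixed seed gives bit-identical
#' output.
#'
#' @param config A `sim_config`.
#' @param genotypes A named list of `sim_genotype` objects (default
#'   [genotype_panel()]).
#' @param replicates Replicates per genotype (default 2).
#' @param seed Integer seed (required for reproducibility).
#' @return A list with `genome`, `origins`, `centromeres`, `tracks` (long
#'   tibble: `strain`, `replicate`, `chrom`, `start`, `end`, `value`) and
#'   `truth` (tibble: `strain`, `replicate`, `name`, `weight`,
#'   `fired_freq`).
#' @export
simulate_experiment <- function(config, genotypes = genotype_panel(),
                                replicates = 2, seed = 1) {
  fixture <- sim_fixture(config)
  with_seed(seed, {
    track_rows <- list(); truth_rows <- list()
    for (g in genotypes) {
      weights <- assign_firing_weights(fixture$origins, fixture$centromeres,
                                       g, config)
      pool <- effective_pool_size(g, config)
      dur <- genotype_duration(g, config)
      use_fast <- config$firing_times == "arrest" &&
        2 * fork_extent(min(pool, nrow(weights)), config, dur) <=
          min_origin_gap(weights)
      for (r in seq_len(replicates)) {
        if (use_fast) {
          sim <- simulate_tracks_fast(weights, fixture$genome, config,
                                      pool, dur, config$n_cells)
          frac <- sim$frac
          counts <- sim$counts
        } else {
          outcomes <- purrr::map(seq_len(config$n_cells), function(i) {
            simulate_cell(weights, config, pool_size = pool,
                          duration = dur, genome = fixture$genome)
          })
          frac <- replicated_fraction(purrr::map(outcomes, "intervals"),
                                      fixture$genome, config$bin_width)
          fired_names <- unlist(purrr::map(outcomes, function(o) o$fired$name))
          counts <- as.integer(table(factor(fired_names,
                                            levels = weights$name)))
        }
        track <- frac
        track$value <- add_read_noise(config$read_depth * track$value, config)
        track_rows[[length(track_rows) + 1]] <- tibble::tibble(
          strain = g$label, replicate = r, chrom = track$chrom,
          start = track$start, end = track$end, value = track$value)
        truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
          strain = g$label, replicate = r, name = weights$name,
          weight = weights$weight, fired_freq = counts / config$n_cells)
      }
    }
    list(genome = fixture$genome, origins = fixture$origins,
         centromeres = fixture$centromeres,
         tracks = dplyr::bind_rows(track_rows),
         truth = dplyr::bind_rows(truth_rows))
  })
}
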