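test_that("firing weights multiply base efficiency by pathway boosts", {
  cfg <- sim_config()
  fx <- sim_fixture(cfg)
  # neutral parameters: weights equal base efficiencies
  cfg0 <- sim_config(fkh_boost = 1, cen_boost = 1)
  w0 <- assign_firing_weights(fx$origins, fx$centromeres, sim_genotype(), cfg0)
  expect_equal(w0$weight, rep(cfg0$base_efficiency, nrow(w0)))

  # hand-set 4-origin toy: bases 0.5, one fkh boost 2, one cen boost 3 at d=0
  g <- genome_build("c1", 200000)
  bed <- tibble::tibble(chrom = "c1", start = c(1, 30000, 60000, 90000) - 1,
                        end = c(1, 30000, 60000, 90000) + 299,
                        name = paste0("O", 1:4))
  flags <- tibble::tibble(name = "O2", confirmed = 1, fkh_activated = 1,
                          fkh1_sensitive = 0, rdna = 0)
  os <- origin_set(bed, flags)
  cens <- tibble::tibble(chrom = "c1", position = os$midpoint[3], name = "CEN")
  os <- classify_cen_proximal(os, cens)
  toy_cfg <- sim_config(base_efficiency = 0.5, fkh_boost = 2, cen_boost = 3)
  w <- assign_firing_weights(os, cens, sim_genotype(), toy_cfg)
  expect_equal(w$weight, c(0.5, 1.0, 1.5, 0.5))

  # ctf19 off strips exactly the cen factor
  w_ctf <- assign_firing_weights(os, cens, sim_genotype(ctf19 = FALSE), toy_cfg)
  expect_equal(w_ctf$weight, c(0.5, 1.0, 0.5, 0.5))
})

test_that("single cells respect pool size and fork-extent geometry", {
  cfg <- sim_config(pool_size = 0)
  fx <- sim_fixture(cfg)
  w <- assign_firing_weights(fx$origins, fx$centromeres, sim_genotype(), cfg)
  out <- simulate_cell(w, cfg)
  expect_equal(nrow(out$intervals), 0)

  # single origin: replicated interval has length 2 v T (unclipped)
  g <- genome_build("c1", 1e6)
  bed <- tibble::tibble(chrom = "c1", start = 499850, end = 500150, name = "O1")
  os <- origin_set(bed, NULL)
  cfg1 <- sim_config(fork_speed = 1000, duration = 60, pool_size = 1,
                     capacity_origins = 5)
  w1 <- assign_firing_weights(os, tibble::tibble(chrom = character(),
                                                 position = double(),
                                                 name = character()),
                              sim_genotype(), cfg1)
  set.seed(1)
  out1 <- simulate_cell(w1, cfg1, genome = g)
  expect_equal(out1$intervals$end - out1$intervals$start, 120000)

  # capacity sharing: per-fork extent shrinks as 1/n_fired beyond capacity
  cfg2 <- sim_config()
  fx2 <- sim_fixture(cfg2)
  w2 <- assign_firing_weights(fx2$origins, fx2$centromeres, sim_genotype(), cfg2)
  set.seed(2)
  out2 <- simulate_cell(w2, cfg2)
  expect_equal(nrow(out2$fired), cfg2$pool_size)
  expect_equal(unique(out2$fired$extent),
               cfg2$fork_speed * cfg2$duration * cfg2$capacity_origins /
                 cfg2$pool_size)
  total_bp <- sum(out2$intervals$end - out2$intervals$start)
  expect_lte(total_bp,
             2 * cfg2$fork_speed * cfg2$duration * nrow(out2$fired) + 1e-9)
})

test_that("K = 1 firing frequencies follow weight proportions (chi-square)", {
  set.seed(123)
  w <- tibble::tibble(name = paste0("O", 1:6), chrom = "c1",
                      midpoint = (1:6) * 10000,
                      weight = c(0.1, 0.5, 1, 2, 0.25, 0.8))
  g <- genome_build("c1", 100000)
  cfg <- sim_config(pool_size = 1)
  counts <- integer(6)
  for (i in 1:10000) {
    out <- simulate_cell(w, cfg, genome = g)
    j <- match(out$fired$name, w$name)
    counts[j] <- counts[j] + 1L
  }
  gt <- stats::chisq.test(counts, p = w$weight / sum(w$weight))
  expect_gt(gt$p.value, 0.001)
})

test_that("sampler inclusion probabilities match the enumeration oracle", {
  set.seed(321)
  w <- c(0.3, 1.2, 0.7, 2.0, 0.5, 1.0)
  want <- oracle_inclusion_probs(w, 2)
  n_draw <- 40000
  counts <- integer(6)
  for (i in seq_len(n_draw)) {
    idx <- sample.int(6, 2, prob = w)
    counts[idx] <- counts[idx] + 1L
  }
  expect_equal(counts / n_draw, want, tolerance = 0.02)
  expect_equal(sum(want), 2, tolerance = 1e-12)
})

test_that("raising one origin's weight weakly depresses all competitors", {
  w <- rep(1, 10)
  base <- oracle_inclusion_probs(w, 3)
  w2 <- w; w2[1] <- 3
  up <- oracle_inclusion_probs(w2, 3)
  expect_gt(up[1], base[1])
  expect_true(all(up[-1] <= base[-1] + 1e-12))

  # and the expected window signal never decreases with the origin's weight
  cfg <- small_sim_config(n_cells = 800)
  fx <- sim_fixture(cfg)
  w_lo <- assign_firing_weights(fx$origins, fx$centromeres, sim_genotype(), cfg)
  w_hi <- w_lo
  target <- w_hi$name[1]
  w_hi$weight[1] <- w_hi$weight[1] * 2
  freq <- function(wt, seed) {
    set.seed(seed)
    hits <- 0
    for (i in seq_len(cfg$n_cells)) {
      out <- simulate_cell(wt, cfg, genome = fx$genome)
      hits <- hits + (target %in% out$fired$name)
    }
    hits / cfg$n_cells
  }
  wins <- vapply(1:5, function(s) freq(w_hi, s) >= freq(w_lo, s), logical(1))
  expect_true(all(wins))
})

test_that("BrdU tracks are Poisson around depth times replicated fraction", {
  g <- genome_build("c1", 50000)
  cfg <- sim_config(read_depth = 100)
  # every cell replicates the whole chromosome
  outcomes <- purrr::map(1:50, function(i) {
    list(intervals = tibble::tibble(chrom = "c1", start = 0, end = 50000))
  })
  set.seed(10)
  tr <- brdu_track(outcomes, g, cfg)
  expect_lt(abs(mean(tr$value) - 100), 3 * sqrt(100 / nrow(tr)))

  # a bin replicated in no cell is always exactly 0
  outcomes0 <- purrr::map(1:20, function(i) {
    list(intervals = tibble::tibble(chrom = "c1", start = 0, end = 1000))
  })
  tr0 <- brdu_track(outcomes0, g, cfg)
  expect_true(all(tr0$value[tr0$start >= 1000] == 0))
})

test_that("fast-path replicated fractions agree with per-cell interval unions", {
  cfg <- small_sim_config(n_cells = 40)
  fx <- sim_fixture(cfg)
  w <- assign_firing_weights(fx$origins, fx$centromeres, sim_genotype(), cfg)
  set.seed(6)
  outcomes <- purrr::map(seq_len(cfg$n_cells), function(i) {
    simulate_cell(w, cfg, genome = fx$genome)
  })
  frac_slow <- repliquant:::replicated_fraction(
    purrr::map(outcomes, "intervals"), fx$genome, cfg$bin_width)
  # reconstruct the same fraction from fired counts (forks never overlap at
  # default spacing)
  fired <- table(factor(unlist(purrr::map(outcomes, function(o) o$fired$name)),
                        levels = w$name))
  extent <- cfg$fork_speed * cfg$duration * cfg$capacity_origins /
    cfg$pool_size
  recs <- tibble::tibble(chrom = w$chrom, start = pmax(0, w$midpoint - extent),
                         end = pmin(cfg$chrom_length, w$midpoint + extent),
                         value = as.numeric(fired) / cfg$n_cells)
  recs <- recs[recs$value > 0, ]
  frac_fast <- bedgraph_to_track(recs, fx$genome, cfg$bin_width)
  expect_equal(frac_slow$value, frac_fast$value, tolerance = 1e-12)
})

test_that("ChIP tracks show CEN enrichment suppressed by the Zn* allele", {
  cfg <- sim_config()
  fx <- sim_fixture(cfg)
  set.seed(40)
  wt <- dbf4_chip_track(fx$origins, fx$centromeres, sim_genotype(), cfg)
  zn <- dbf4_chip_track(fx$origins, fx$centromeres,
                        sim_genotype(dbf4_allele = "Zn*"), cfg)
  cen_feats <- tibble::tibble(chrom = fx$centromeres$chrom,
                              start = fx$centromeres$position,
                              end = fx$centromeres$position + 1,
                              name = fx$centromeres$name)
  w_wt <- window_signal(wt, cen_feats, 500)$signal
  w_zn <- window_signal(zn, cen_feats, 500)$signal
  expect_lt(two_sided_ttest(w_wt, w_zn)$p, 0.01)
  expect_gt(mean(w_wt), mean(w_zn))

  # amplitude 0 gives a flat background track
  cfg0 <- sim_config(chip_cen_amplitude = 0, chip_cenprox_amplitude = 0,
                     chip_origin_amplitude = 0)
  flat <- dbf4_chip_track(fx$origins, fx$centromeres, sim_genotype(), cfg0)
  expect_lt(abs(mean(flat$value) - cfg0$chip_background),
            3 * sqrt(cfg0$chip_background / nrow(flat)))
})

test_that("experiments are seed-deterministic with correlated replicates", {
  cfg <- small_sim_config()
  s1 <- simulate_experiment(cfg, genotype_panel()["WT"], replicates = 2,
                            seed = 99)
  s2 <- simulate_experiment(cfg, genotype_panel()["WT"], replicates = 2,
                            seed = 99)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$truth, s2$truth)

  r1 <- s1$tracks[s1$tracks$replicate == 1, c("chrom", "start", "end", "value")]
  r2 <- s1$tracks[s1$tracks$replicate == 2, c("chrom", "start", "end", "value")]
  expect_gt(replicate_correlation(r1, r2), 0.9)
})

test_that("losing Fkh1 shifts firing toward CEN-proximal origins", {
  cfg <- small_sim_config(n_cells = 500)
  fx <- sim_fixture(cfg)
  cen_names <- fx$origins$name[fx$origins$cen_proximal]
  shifts <- vapply(1:8, function(s) {
    sim <- simulate_experiment(cfg, genotype_panel(include_fkh1d = TRUE)
                               [c("WT", "fkh1d")],
                               replicates = 1, seed = 1000 + s)
    m <- tapply(sim$truth$fired_freq[sim$truth$name %in% cen_names],
                sim$truth$strain[sim$truth$name %in% cen_names], mean)
    m[["fkh1d"]] - m[["WT"]]
  }, numeric(1))
  expect_gt(mean(shifts > 0), 0.8)
})
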