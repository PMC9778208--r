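make_features <- function(chrom, mids, width = 300) {
  tibble::tibble(chrom = chrom, start = mids - width / 2,
                 end = mids + width / 2, name = paste0("F", seq_along(mids)))
}

test_that("window signal equals the per-bp oracle, including clipping", {
  g <- tiny_genome()
  const <- empty_track(g, 50)
  const$value <- 2.5
  feats <- make_features("chrA", c(250, 500, 900))
  w <- window_signal(const, feats, 500)
  expect_equal(w$signal, rep(2.5, 3))

  set.seed(33)
  for (rep in 1:20) {
    tr <- random_track(g)
    mids <- c(sample(0:999, 3), 40, 980)  # interior + both edges
    feats <- make_features("chrA", mids)
    got <- window_signal(tr, feats, 500)
    for (i in seq_along(mids)) {
      lo <- max(0, mids[i] - 250); hi <- min(1000, mids[i] + 250)
      expect_equal(got$signal[i], oracle_window_mean(tr, "chrA", lo, hi),
                   tolerance = 1e-12)
    }
    expect_true(all(got$clipped[mids - 250 < 0 | mids + 250 > 1000]))
  }
  expect_error(window_signal(random_track(g),
                             make_features("chrZ", 100), 500),
               "unknown chromosome")
})

test_that("delta tables are antisymmetric and zero on identical strains", {
  g <- tiny_genome()
  set.seed(4)
  tr <- random_track(g)
  prof <- dplyr::bind_rows(tibble::tibble(strain = "WT", tr),
                           tibble::tibble(strain = "mut", tr))
  prof$value[prof$strain == "mut"] <-
    prof$value[prof$strain == "mut"] + runif(nrow(tr))
  feats <- make_features("chrA", c(250, 500, 750))
  w <- window_signal(prof, feats, 500)
  d1 <- delta_signal(w, "WT", "mut")
  d2 <- delta_signal(w, "mut", "WT")
  expect_equal(d1$delta, -d2$delta)
  expect_equal(delta_signal(w, "WT", "WT")$delta, rep(0, 3))
  expect_error(delta_signal(w, "WT", "absent"), "not present")
})

test_that("boxplot statistics use linear-interpolation quartiles", {
  g <- genome_build("c", 10000)
  os <- origin_set(tibble::tibble(chrom = "c", start = (1:5) * 1000,
                                  end = (1:5) * 1000 + 300,
                                  name = paste0("O", 1:5)), NULL)
  w <- tibble::tibble(name = paste0("O", 1:5), signal = c(1, 2, 3, 4, 5))
  st <- group_boxplot_stats(w, os, "confirmed")
  expect_equal(st$q1, 2)
  expect_equal(st$median, 3)
  expect_equal(st$q3, 4)

  # singleton group degenerates to five equal numbers
  one <- origin_set(tibble::tibble(chrom = "c", start = 100, end = 400,
                                   name = "O1"), NULL)
  st1 <- group_boxplot_stats(w[1, ], one, "confirmed")
  expect_equal(unlist(st1[, c("min", "q1", "median", "q3", "max")]),
               rep(1, 5), ignore_attr = TRUE)

  # random groups match the sort-and-interpolate oracle
  set.seed(55)
  for (rep in 1:30) {
    n <- sample(2:40, 1)
    vals <- round(runif(n, 0, 100), 2)
    osn <- origin_set(tibble::tibble(chrom = "c", start = (1:n) * 10,
                                     end = (1:n) * 10 + 5,
                                     name = paste0("O", 1:n)), NULL)
    wn <- tibble::tibble(name = paste0("O", 1:n), signal = vals)
    st <- group_boxplot_stats(wn, osn, "confirmed")
    want <- oracle_fivenum(vals)
    expect_equal(unlist(st[, c("min", "q1", "median", "q3", "max")]), want,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }

  # empty group is reported with n = 0 and NA summaries
  os$fkh_activated <- FALSE
  ste <- group_boxplot_stats(w, os, c("confirmed", "fkh_activated"))
  expect_equal(ste$n[ste$group == "fkh_activated"], 0L)
  expect_true(is.na(ste$median[ste$group == "fkh_activated"]))
})

test_that("Welch t-test matches the closed-form and handles degenerate input", {
  tt <- two_sided_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)

  a <- c(1, 2, 3); b <- a + 10
  got <- two_sided_ttest(a, b)
  want <- oracle_welch(a, b)
  expect_equal(got$t, unname(want["t"]), tolerance = 1e-12)
  expect_equal(got$df, unname(want["df"]), tolerance = 1e-12)
  expect_equal(got$p, unname(want["p"]), tolerance = 1e-12)

  set.seed(66)
  for (rep in 1:100) {
    a <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    got <- two_sided_ttest(a, b)
    want <- oracle_welch(a, b)
    expect_equal(c(got$t, got$df, got$p), unname(want), tolerance = 1e-9)
  }

  # both samples constant: convention
  expect_equal(two_sided_ttest(c(2, 2), c(2, 2))$p, 1)
  expect_equal(two_sided_ttest(c(3, 3), c(2, 2))$t, Inf)
  expect_equal(two_sided_ttest(c(1, 1), c(2, 2))$p, 0)
})

test_that("Welch p agrees with a permutation test within Monte-Carlo error", {
  set.seed(101)
  a <- rnorm(30, 0, 1); b <- rnorm(30, 0.45, 1)
  got <- two_sided_ttest(a, b)$p
  pool <- c(a, b); n <- length(a)
  obs <- abs(mean(a) - mean(b))
  perm <- replicate(20000, {
    idx <- sample.int(length(pool), n)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  p_perm <- (1 + sum(perm >= obs)) / (1 + length(perm))
  expect_lt(abs(got - p_perm), 0.03)
})

test_that("FWHM recovers triangle and Gaussian peak widths", {
  # symmetric triangle of base W over zero baseline: FWHM = W/2
  # (apex placed on a bin center so the sampled maximum is the true apex)
  g <- genome_build("c", 20000)
  tr <- empty_track(g, 50)
  centers <- (tr$start + tr$end) / 2
  W <- 4000; apex <- 10025
  tr$value <- pmax(0, 1 - abs(centers - apex) / (W / 2))
  feats <- make_features("c", apex)
  got <- peak_width_fwhm(tr, feats, 10000)
  expect_equal(got$status, "ok")
  expect_equal(got$fwhm, W / 2, tolerance = 1e-9)

  # Gaussian peak: FWHM = 2 sqrt(2 ln 2) sigma, within one bin
  sigma <- 1000
  tr$value <- exp(-(centers - apex)^2 / (2 * sigma^2))
  got <- peak_width_fwhm(tr, feats, 10000)
  expect_lt(abs(got$fwhm - 2 * sqrt(2 * log(2)) * sigma), 50)

  # flat span is flagged; a peak sitting on the span edge is censored
  tr$value <- rep(1, nrow(tr))
  expect_equal(peak_width_fwhm(tr, feats, 10000)$status, "flat")
  tr$value <- centers / 1000
  expect_equal(peak_width_fwhm(tr, feats, 4000)$status, "censored")
})

test_that("heatmap matrices sample offsets around midpoints", {
  g <- tiny_genome()
  const <- empty_track(g, 50)
  const$value <- 1.25
  feats <- make_features("chrA", c(500, 250))
  hm <- heatmap_matrix(const, feats, 500)
  expect_equal(ncol(hm), 10)
  expect_true(all(unclass(hm) == 1.25))

  # 10 kb span at 50 bp bins = 200 columns; edges give NA
  g2 <- genome_build("c", 50000)
  tr <- random_track(g2)
  feats2 <- make_features("c", c(25000, 2000))
  hm2 <- heatmap_matrix(tr, feats2, 10000)
  expect_equal(ncol(hm2), 200)
  expect_true(anyNA(hm2[2, ]))
  expect_false(anyNA(hm2[1, ]))

  # center column equals the bin containing the midpoint; consistent with
  # a one-bin window at bin-center midpoints
  feats3 <- make_features("c", c(25025, 10075))  # bin centers
  hm3 <- heatmap_matrix(tr, feats3, 10000)
  w <- window_signal(tr, feats3, 50)
  expect_equal(unname(hm3[, 101]), w$signal, tolerance = 1e-12)
  expect_error(heatmap_matrix(tr, feats3, 130), "multiple")
})

test_that("scatter fits match the closed-form normal equations", {
  x <- 1:10
  df <- tibble::tibble(a = x, b = 2 * x + 1)
  fit <- scatter_fit(df, "a", "b")
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)

  set.seed(88)
  for (rep in 1:30) {
    n <- sample(3:30, 1)
    d <- tibble::tibble(a = rnorm(n), b = rnorm(n))
    got <- scatter_fit(d, "a", "b")
    want <- oracle_ols(d$a, d$b)
    expect_equal(c(got$slope, got$intercept, got$r), unname(want),
                 tolerance = 1e-9)
  }

  # grouped fit returns one row per group
  d <- tibble::tibble(a = rep(1:5, 2), b = c(1:5 * 2, 1:5 * -1),
                      grp = rep(c("u", "v"), each = 5))
  fit2 <- scatter_fit(d, "a", "b", "grp")
  expect_equal(fit2$slope, c(2, -1), tolerance = 1e-12)
  expect_error(scatter_fit(tibble::tibble(a = c(1, 1), b = 1:2), "a", "b"),
               "constant x")

  # independent y: slope within 3 standard errors of zero
  set.seed(202)
  d3 <- tibble::tibble(a = rnorm(1000), b = rnorm(1000))
  fit3 <- scatter_fit(d3, "a", "b")
  se <- summary(stats::lm(b ~ a, data = d3))$coefficients[2, 2]
  expect_lt(abs(fit3$slope), 3 * se)
})

test_that("window signal scales linearly with normalization", {
  g <- tiny_genome()
  set.seed(71)
  tr <- random_track(g)
  feats <- make_features("chrA", c(300, 600))
  w1 <- window_signal(tr, feats, 500)
  tr2 <- tr; tr2$value <- tr$value * 3.7
  w2 <- window_signal(tr2, feats, 500)
  expect_equal(w2$signal, 3.7 * w1$signal, tolerance = 1e-12)
})

test_that("tidy and glance methods expose comparison and fit results", {
  g <- tiny_genome()
  set.seed(12)
  tr <- random_track(g)
  prof <- dplyr::bind_rows(tibble::tibble(strain = "WT", tr),
                           tibble::tibble(strain = "mut", tr))
  os <- origin_set(tibble::tibble(chrom = "chrA", start = c(200, 600),
                                  end = c(500, 900), name = c("O1", "O2")),
                   NULL)
  w <- window_signal(prof, os, 300)
  gc <- group_comparison(w, os, groups = "confirmed")
  expect_s3_class(tidy(gc), "tbl_df")
  expect_equal(glance(gc)$n_strains, 2)
  expect_s3_class(autoplot(gc), "ggplot")

  d <- tibble::tibble(a = 1:6, b = (1:6) * 2 + rnorm(6, 0, 0.1))
  fit <- scatter_fit(d, "a", "b")
  td <- tidy(fit)
  expect_setequal(td$term, c("slope", "intercept"))
  expect_equal(glance(fit)$n, 6)
  expect_s3_class(autoplot(fit), "ggplot")
})
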