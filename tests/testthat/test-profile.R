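make_profile <- function(x, y, frac = rep(1L, length(x))) {
  polytrans:::new_polysome_profile(x, y, frac)
}

test_that("profiles round-trip through TSV and bad files are rejected", {
  sim <- simulate_profile(gradient_model(), seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(sim$profile, path)
  back <- read_profile(path)
  expect_equal(back$position, sim$profile$position)
  expect_equal(back$absorbance, sim$profile$absorbance)
  expect_equal(back$fraction_index, sim$profile$fraction_index)

  df <- tibble::tibble(position = c(1, 3, 2, 4), absorbance = 0, fraction_index = 1L)
  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(df, bad)
  expect_error(read_profile(bad), "row 3")

  noc <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(a = 1), noc)
  expect_error(read_profile(noc), "missing required column")
})

test_that("baseline correction removes offsets and ramps exactly", {
  x <- seq(0, 100, length.out = 200)
  flat <- make_profile(x, rep(0.3, 200))
  expect_equal(correct_baseline(flat)$absorbance, rep(0, 200))
  ramp <- make_profile(x, 0.1 + 0.02 * x)
  expect_equal(correct_baseline(ramp)$absorbance, rep(0, 200))
  expect_error(correct_baseline(make_profile(1:5, 1:5)), ">= 10")
  expect_error(correct_baseline(flat, anchors = list(c(-10, -5), c(90, 100))),
               "outside")
})

test_that("baseline-corrected integration recovers closed-form areas", {
  # well-separated peaks: valley truncation loses negligible Gaussian mass
  m <- gradient_model(peak_widths = c(1.5, 1, 1, 1.2, 1.2, 1.2, 1.2, 1.2),
                      noise_sd = 0, n_points = 4000,
                      baseline_offset = 0.2, baseline_slope = 0.004)
  sim <- simulate_profile(m, seed = 1)
  p <- correct_baseline(sim$profile)
  seg <- segment_peaks(p)
  areas <- integrate_regions(p, seg)
  truth <- sim$truth$region_areas
  for (reg in c("80S", "POLYSOMES")) {
    est <- areas$area[areas$region == reg]
    expect_lt(abs(est - truth[[reg]]) / truth[[reg]], 0.01)
  }
})

test_that("valley segmentation places the 80S/polysome boundary at the true minimum", {
  m <- gradient_model(noise_sd = 0)
  sim <- simulate_profile(m, seed = 1)
  p <- correct_baseline(sim$profile)
  seg <- segment_peaks(p)
  expect_equal(seg$region, c("RNP", "40S", "60S", "80S", "POLYSOMES"))
  expect_true(all(diff(c(seg$start[1], seg$end)) >= 0))
  # oracle: grid-search minimum of the generating function between the 80S
  # and first polysome centers
  grid <- seq(42, 55, by = 0.001)
  f <- polytrans:::gradient_signal(m, grid) -
    (m$baseline_offset + m$baseline_slope * grid)
  oracle_valley <- grid[which.min(f)]
  boundary <- seg$start[seg$region == "POLYSOMES"]
  expect_lt(abs(boundary - oracle_valley), m$peak_widths[4])
})

test_that("segmentation handles single-species and flat traces", {
  x <- seq(0, 100, length.out = 500)
  one <- make_profile(x, exp(-(x - 50)^2 / 50))
  seg <- segment_peaks(one, expected_species = "80S")
  expect_equal(seg$region, c("80S", "POLYSOMES"))
  poly <- seg[seg$region == "POLYSOMES", ]
  expect_equal(poly$end - poly$start, 0)
  expect_true("no_polysome_peaks" %in% attr(seg, "qc_flags"))
  expect_error(segment_peaks(make_profile(x, rep(0, 500))), "no peaks")
  expect_error(segment_peaks(one), "detected only")
})

test_that("region integration is trapezoidal with negative-area clamping", {
  # unit-height rectangle of width 2 -> area 2
  x <- seq(0, 10, by = 0.01)
  y <- ifelse(x >= 4 & x <= 6, 1, 0)
  p <- make_profile(x, y)
  seg <- tibble::tibble(region = "80S", start = 3, end = 7)
  # one-sample trapezoids at the two step edges bound the error by dx
  expect_equal(integrate_regions(p, seg)$area, 2, tolerance = 0.011)
  # all-negative region clamps to 0 and flags
  pneg <- make_profile(x, rep(-1, length(x)))
  res <- integrate_regions(pneg, tibble::tibble(region = "80S", start = 1, end = 2))
  expect_equal(res$area, 0)
  expect_true(res$clamped)
  expect_error(
    integrate_regions(p, tibble::tibble(region = "80S", start = -5, end = 2)),
    "outside")
})

test_that("FRP is the polysome share of polysome + 80S area", {
  mk <- function(a80, apoly) {
    tibble::tibble(region = c("RNP", "40S", "60S", "80S", "POLYSOMES"),
                   area = c(9, 9, 9, a80, apoly), clamped = FALSE)
  }
  expect_equal(compute_frp(mk(5, 0))$frp, 0)
  expect_equal(compute_frp(mk(3, 3))$frp, 0.5)
  expect_error(compute_frp(mk(0, 0)), "undefined")
  expect_equal(polysome_monosome_ratio(mk(2, 6)), 3)
  # RNP/40S/60S areas are excluded from the denominator by definition
  expect_equal(compute_frp(mk(1, 3))$frp, 0.75)
})

test_that("FRP estimates track ground truth and respect invariance properties", {
  sim <- simulate_profile(gradient_model(noise_sd = 0), seed = 9)
  r <- profile_frp(sim$profile)
  expect_lt(abs(r$frp - sim$truth$frp), 0.005)
  expect_gte(r$frp, 0); expect_lte(r$frp, 1)
  # scale invariance: scaling absorbance scales areas, leaves FRP unchanged
  scaled <- polytrans:::new_polysome_profile(
    sim$profile$position, sim$profile$absorbance * 7,
    sim$profile$fraction_index)
  r7 <- profile_frp(scaled)
  expect_equal(r7$frp, r$frp, tolerance = 1e-9)
  expect_equal(r7$area_polysomes, 7 * r$area_polysomes, tolerance = 1e-9)
  # monotonicity: adding polysomal mass strictly increases FRP
  heavier <- gradient_model()
  heavier$peak_amplitudes[5:8] <- heavier$peak_amplitudes[5:8] * 1.5
  heavier$noise_sd <- 0
  r_h <- profile_frp(simulate_profile(heavier, seed = 9)$profile)
  expect_gt(r_h$frp, r$frp)
})

test_that("FRP group comparison matches the reference t test and handles degeneracy", {
  a <- c(0.81, 0.77, 0.74, 0.79)
  b <- c(0.55, 0.61, 0.50, 0.58)
  res <- compare_frp(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-8)
  expect_lt(compare_frp(c(0.8, 0.801, 0.799), c(0.4, 0.401, 0.399))$p_value, 1e-3)
  # identical groups carry no evidence
  expect_gte(compare_frp(a, a)$p_value, 0.99)
  degen <- compare_frp(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(degen$p_value, 1)
  expect_equal(degen$flag, "zero_variance")
  expect_error(compare_frp(0.5, c(0.1, 0.2)), ">= 2")
  expect_equal(tidy(res)$p_value, res$p_value)
})

test_that("one-tailed testing must be requested explicitly and halves the p", {
  a <- c(0.81, 0.77, 0.74, 0.79)
  b <- c(0.55, 0.61, 0.50, 0.58)
  two <- compare_frp(a, b)
  one <- compare_frp(a, b, alternative = "greater")
  expect_equal(two$alternative, "two.sided")
  expect_equal(one$p_value, two$p_value / 2, tolerance = 1e-12)
})

test_that("phenotype correlation reports Pearson and Spearman with tests", {
  d <- tibble::tibble(frp = c(0.4, 0.5, 0.6, 0.7, 0.8))
  d$lin <- 2 * d$frp + 1
  d$mono <- exp(3 * d$frp)
  res <- correlate_phenotype(d, frp, lin)
  expect_equal(res$estimate[res$method == "pearson"], 1)
  res2 <- correlate_phenotype(d, frp, mono)
  expect_equal(res2$estimate[res2$method == "spearman"], 1)
  expect_lt(res2$estimate[res2$method == "pearson"], 1)
  ref <- cor.test(d$frp, d$mono)
  expect_equal(res2$p_value[res2$method == "pearson"], ref$p.value, tolerance = 1e-8)
  expect_error(correlate_phenotype(d[1:3, ], frp, lin), ">= 4")
  d$const <- 1
  expect_error(correlate_phenotype(d, frp, const), "constant")
})

test_that("negative FRP-righting coupling is recovered across seeds", {
  rs <- sapply(1:30, function(s) {
    co <- simulate_cohort(n_per_group = c(control = 10, SMA = 10), seed = s)
    frp <- purrr::map_dfr(co$profiles, profile_frp)
    m <- dplyr::left_join(co$phenotypes,
                          dplyr::rename(frp, mouse_id = "sample"),
                          by = "mouse_id")
    correlate_phenotype(m, frp, righting_s, method = "pearson")$estimate
  })
  expect_gte(mean(rs < 0), 0.95)
})

test_that("relative phenotypes are scaled to stage-matched control means", {
  rec <- tibble::tibble(
    mouse_id = sprintf("m%d", 1:5),
    genotype = c("control", "control", "SMA", "SMA", "control"),
    stage = c("early", "early", "early", "late", "late"),
    weight_g = c(4, 6, 3, 2, 5),
    righting_s = c(10, 20, 30, 30, 8)
  )
  out <- relative_phenotype(rec)
  # hand-computed: early control mean weight 5, righting 15; late: 5 and 8
  expect_equal(out$relative_weight, c(4/5, 6/5, 3/5, 2/5, 1))
  expect_equal(out$relative_righting, c(10/15, 20/15, 2, 30/8, 1))
  # control at exactly the control mean -> 1.0
  expect_equal(out$relative_weight[out$mouse_id == "m5"], 1)
  rec$stage[5] <- "late"; rec$genotype[5] <- "SMA"
  expect_error(relative_phenotype(rec), "no control records.*late")
  allsame <- tibble::tibble(mouse_id = c("a", "b"), genotype = c("control", "SMA"),
                            stage = "early", weight_g = 3, righting_s = 12)
  expect_equal(relative_phenotype(allsame)$relative_weight, c(1, 1))
})

test_that("Ward clustering equals the exhaustive Lance-Williams oracle on 6 points", {
  set.seed(42)
  for (rep in 1:5) {
    z <- matrix(rnorm(18), nrow = 6,
                dimnames = list(sprintf("m%d", 1:6), c("a", "b", "c")))
    d <- tibble::tibble(mouse_id = rownames(z), frp = z[, 1],
                        relative_weight = z[, 2], relative_righting = z[, 3])
    cl <- cluster_mice(d)
    zs <- scale(z)
    oracle <- ward_oracle(zs)
    expect_equal(cl$hclust$height, oracle$heights, tolerance = 1e-10)
    expect_equal(hclust_merge_sets(cl$hclust), oracle$merges)
    expect_true(all(diff(cl$hclust$height) >= -1e-12))
  }
})

test_that("clustering is invariant to pre-standardisation rescaling and separates groups", {
  set.seed(7)
  d <- tibble::tibble(
    mouse_id = sprintf("m%d", 1:10),
    frp = c(rnorm(5, 0.8, 0.02), rnorm(5, 0.4, 0.02)),
    relative_weight = c(rnorm(5, 1, 0.02), rnorm(5, 0.5, 0.02)),
    relative_righting = c(rnorm(5, 1, 0.05), rnorm(5, 3, 0.05))
  )
  cl <- cluster_mice(d)
  d2 <- dplyr::mutate(d, relative_weight = relative_weight * 1000)
  cl2 <- cluster_mice(d2)
  expect_equal(cl$hclust$height, cl2$hclust$height, tolerance = 1e-10)
  expect_equal(cl$hclust$merge, cl2$hclust$merge)
  # >= 6 sd separation in every variable: the 2-cut matches the groups
  truth <- rep(1:2, each = 5)
  lab <- tidy(cl)$cluster
  expect_true(all(table(lab, truth) %in% c(0, 5)))
  d$frp[3] <- NA
  expect_error(cluster_mice(d), "m3")
})
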