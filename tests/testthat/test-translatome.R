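toy_pair <- function(pol, tot, groups) {
  structure(list(pol = pol, tot = tot,
                 samples = tibble::tibble(sample = colnames(pol), group = groups)),
            class = "count_matrix_pair")
}

test_that("cpm normalisation matches manual computation and is scale invariant", {
  m <- matrix(c(10, 20, 70, 5, 15, 80), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  pair <- toy_pair(m, m, c("control", "case"))
  norm <- normalize_expression(pair)
  expect_equal(norm$pol[, "s1"], c(g1 = 1e5, g2 = 2e5, g3 = 7e5))
  expect_equal(norm$pol[, "s2"], c(g1 = 5e4, g2 = 1.5e5, g3 = 8e5))
  # doubling one sample's counts leaves its normalised profile unchanged
  m2 <- m; m2[, 1] <- m2[, 1] * 2
  norm2 <- normalize_expression(toy_pair(m2, m2, c("control", "case")))
  expect_equal(norm2$pol[, "s1"], norm$pol[, "s1"])
  # length scaling divides by kilobases
  lens <- c(g1 = 1000, g2 = 2000, g3 = 500)
  nl <- normalize_expression(pair, "length_scaled", gene_lengths = lens)
  expect_equal(nl$pol[, "s1"], c(g1 = 1e5, g2 = 1e5, g3 = 14e5))
  expect_error(normalize_expression(pair, "length_scaled"), "gene_lengths")
  zero <- m; zero[, 1] <- 0
  expect_error(normalize_expression(toy_pair(zero, m, c("a", "b"))), "> 0")
})

test_that("log2TE is the pseudo-counted polysomal/total log ratio", {
  m <- matrix(1:6, nrow = 3)
  te0 <- compute_te(m, m, pseudo = 0.5)
  expect_true(all(te0$log2te == 0))
  te1 <- compute_te(2 * m, m, pseudo = 1e-12)
  expect_equal(te1$log2te, matrix(1, 3, 2), tolerance = 1e-9)
  expect_error(compute_te(-m, m), ">= 0")
  # library-size invariance through cpm: scaling raw counts is a no-op
  cp <- simulate_counts(n_genes = 30, n_samples_per_group = 3, seed = 2)
  te_a <- compute_te(normalize_expression(cp))
  cp$pol[, 2] <- cp$pol[, 2] * 3L
  te_b <- compute_te(normalize_expression(cp))
  expect_equal(te_a$log2te, te_b$log2te)
})

test_that("exhaustive permutation p-values equal the enumeration oracle", {
  set.seed(5)
  x <- matrix(rnorm(30), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  groups <- rep(c("case", "control"), each = 3)
  res <- test_delta_te(x, groups)  # choose(6,3)=20 -> exhaustive
  for (i in 1:5) {
    expect_equal(res$p_value[res$gene == paste0("g", i)],
                 perm_p_oracle(x[i, ], groups == "case"))
  }
  cp <- simulate_counts(n_genes = 40, n_samples_per_group = 4, seed = 3)
  te <- compute_te(normalize_expression(cp))
  ex <- test_delta_te(te)  # choose(8,4)=70 exhaustive
  expect_true(all(ex$p_value >= 2 / 70 - 1e-12))
  expect_equal(ex$fdr, p.adjust(ex$p_value, "BH"))
  # BH is monotone in p rank
  o <- order(ex$p_value)
  expect_true(all(diff(ex$fdr[o]) >= -1e-12))
})

test_that("sampled permutations approximate the exhaustive p-value", {
  set.seed(21)
  x <- matrix(rnorm(36), nrow = 2,
              dimnames = list(c("g1", "g2"), paste0("s", 1:18)))
  groups <- rep(c("case", "control"), each = 9)  # choose(18,9) > 10000 -> sampled
  res <- test_delta_te(x, groups, n_permutations = 5000, seed = 9)
  for (g in c("g1", "g2")) {
    exact <- perm_p_oracle(x[rownames(x) == g, ], groups == "case")
    est <- res$p_value[res$gene == g]
    expect_lt(abs(est - exact), 3 * sqrt(exact * (1 - exact) / 5000) + 1e-3)
  }
})

test_that("planted strong shifts reach the enumeration floor; direction is right", {
  shift <- setNames(c(2, -2), c("gene0001", "gene0002"))
  cp <- simulate_counts(n_genes = 100, n_samples_per_group = 4,
                        dispersion = 0.01, te_shift_spec = shift, seed = 4)
  res <- test_delta_te(compute_te(normalize_expression(cp)))
  hit <- res[res$gene %in% names(shift), ]
  expect_equal(hit$p_value, rep(2 / 70, 2))  # floor of the 4v4 enumeration
  expect_equal(hit$direction[hit$gene == "gene0001"], "up")
  expect_equal(hit$direction[hit$gene == "gene0002"], "down")
  expect_true(all(hit$significant))
})

test_that("permutation p-values are valid under the null", {
  cp <- simulate_counts(n_genes = 400, n_samples_per_group = 6, seed = 10)
  res <- test_delta_te(compute_te(normalize_expression(cp)))
  for (alpha in c(0.01, 0.05, 0.1, 0.2)) {
    expect_lte(mean(res$p_value <= alpha), alpha + 0.035)
  }
  expect_warning(test_delta_te(compute_te(normalize_expression(cp)),
                               n_permutations = 50), "100 permutations")
})

test_that("delta-delta-Ct fold changes follow the two-reference pathway", {
  base <- tidyr::expand_grid(
    gene = c("Smn", "Actb", "Ppia"),
    sample = c("c1", "c2", "k1", "k2"),
    compartment = "POL",
    technical_replicate = 1:2
  )
  base$group <- ifelse(startsWith(base$sample, "c"), "control", "case")
  base$ct <- 20
  # all Cts equal -> FC 1
  expect_equal(qpcr_fold_change(base, "Smn")$fold_change, 1)
  # target one cycle lower in case -> FC 2
  d <- base
  d$ct[d$gene == "Smn" & d$group == "case"] <- 19
  expect_equal(qpcr_fold_change(d, "Smn")$fold_change, 2)
  # references shifted +1 and +3 cycles in case, target unchanged:
  # mean reference Ct rises 2 cycles -> ddCt = -2 -> FC 4 (hand-computed)
  r <- base
  r$ct[r$gene == "Actb" & r$group == "case"] <- 21
  r$ct[r$gene == "Ppia" & r$group == "case"] <- 23
  expect_equal(qpcr_fold_change(r, "Smn")$fold_change, 4)
  # technical replicates are averaged before biological aggregation
  t2 <- d
  t2$ct[t2$gene == "Smn" & t2$sample == "k1" & t2$technical_replicate == 1] <- 18
  t2$ct[t2$gene == "Smn" & t2$sample == "k1" & t2$technical_replicate == 2] <- 20
  expect_equal(qpcr_fold_change(t2, "Smn")$fold_change, 2)
  # missing reference in one sample is rejected by name
  miss <- base[!(base$gene == "Ppia" & base$sample == "k2"), ]
  expect_error(qpcr_fold_change(miss, "Smn"), "k2")
})

test_that("qPCR delta-TE composes fold changes exactly", {
  expect_equal(qpcr_delta_te(2, 2), 0)
  expect_equal(qpcr_delta_te(2, 1), 1)
  expect_equal(qpcr_delta_te(2, 1, scale = "raw"), 1)
  expect_equal(qpcr_delta_te(1, 2, scale = "raw"), -1)
  expect_error(qpcr_delta_te(0, 1), "> 0")
  # noiseless generator round trip: planted log2 delta-TE of -0.5 exactly
  fc <- tibble::tibble(gene = "Smn", compartment = c("POL", "TOT"),
                       fc = c(2^(-0.5) * 1.3, 1.3))
  ct <- simulate_qpcr(fc, ct_noise_sd = 0, seed = 2)
  fp <- qpcr_fold_change(ct, "Smn", compartment = "POL")$fold_change
  ft <- qpcr_fold_change(ct, "Smn", compartment = "TOT")$fold_change
  expect_equal(qpcr_delta_te(fp, ft), -0.5, tolerance = 1e-12)
})

test_that("noisy qPCR fold-change recovery is nearly unbiased", {
  fcs <- sapply(1:60, function(s) {
    ct <- simulate_qpcr(tibble::tibble(gene = "g", compartment = "POL", fc = 2),
                        ct_noise_sd = 0.2, n_bio = 4, seed = s)
    qpcr_fold_change(ct, "g", compartment = "POL")$fold_change
  })
  expect_lt(abs(mean(fcs) / 2 - 1), 0.05)
})

test_that("DEG overlap summaries count shared and level-specific genes", {
  a <- paste0("g", 1:10)
  same <- classify_degs(a, a)
  expect_equal(same$summary$pct_of_a, 100)
  disj <- classify_degs(paste0("g", 1:5), paste0("h", 1:5))
  expect_equal(disj$summary$n_shared, 0)
  expect_equal(disj$summary$pct_of_a, 0)
  # planted 30% overlap
  transcriptome <- paste0("g", 1:100)
  translatome <- c(paste0("g", 1:30), paste0("x", 1:40))
  res <- classify_degs(transcriptome, translatome)
  expect_equal(res$summary$pct_of_a, 30)
  expect_equal(res$sets$specific$transcriptome, paste0("g", 31:100))
  expect_error(classify_degs(c("g1", "zz"), "g1", universe = paste0("g", 1:5)),
               "outside")
  # tibble inputs with significance flags
  tb <- tibble::tibble(gene = paste0("g", 1:4),
                       significant = c(TRUE, TRUE, FALSE, FALSE))
  res2 <- classify_degs(tb, tb)
  expect_equal(res2$summary$n_shared, 2)
})
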