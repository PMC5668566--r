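#' Parametric model of an A254 sucrose-gradient absorbance trace
#'
#' Describes a polysome profile as a sum of Gaussian peaks over a linear
#' baseline: one peak each for the free-RNP pool, the 40S and 60S ribosomal
#' subunits and the 80S monosome, followed by two or more polysome peaks in
#' the heavy part of the gradient. Peak areas have the closed form
#' amplitude * sigma * sqrt(2*pi), which is what every downstream ground
#' truth is computed from.
#'
#' @param peak_centers Positions of the peak maxima in gradient coordinates
#'   (arbitrary units, strictly increasing). One per species: RNP, 40S, 60S,
#'   80S, then at least two polysome peaks.
#' @param peak_widths Gaussian sigma per peak, same units as position (> 0).
#' @param peak_amplitudes Peak heights in absorbance units (>= 0).
#' @param baseline_offset,baseline_slope Linear baseline in absorbance units
#'   (slope per position unit).
#' @param noise_sd Additive Gaussian noise on the trace, absorbance units.
#' @param n_points Number of equally spaced sampling positions.
#' @param span Numeric length-2, the position range of the trace.
#' @param fraction_count Number of equal-width collected fractions (>= 4);
#'   default 12, emulating ~1 mL fractions of a 15\%--50\% gradient run.
#' @param tail_skew Optional exponential-tail modification (0 = symmetric
#'   Gaussians, the default; > 0 skews each peak toward the heavy side).
#'
#' @return An object of class `gradient_model`.
#' @export
gradient_model <- function(peak_centers = c(8, 20, 30, 42, 55, 64, 72, 80),
                           peak_widths = c(2.5, 1.6, 1.8, 2.2, 2.4, 2.6, 2.8, 3.0),
                           peak_amplitudes = c(0.9, 0.25, 0.4, 1.0, 0.65, 0.5, 0.35, 0.22),
                           baseline_offset = 0.05,
                           baseline_slope = 0.002,
                           noise_sd = 0.005,
                           n_points = 1000,
                           span = c(0, 100),
                           fraction_count = 12,
                           tail_skew = 0) {
  k <- length(peak_centers)
  if (k < 6) {
    abort("gradient_model needs >= 6 peaks: RNP, 40S, 60S, 80S and >= 2 polysome peaks")
  }
  if (length(peak_widths) != k || length(peak_amplitudes) != k) {
    abort("peak_centers, peak_widths and peak_amplitudes must have equal length")
  }
  if (any(diff(peak_centers) <= 0)) abort("peak_centers must be strictly increasing")
  if (any(peak_widths <= 0)) abort("peak_widths must be > 0")
  if (any(peak_amplitudes < 0)) abort("peak_amplitudes must be >= 0")
  if (fraction_count < 4) abort("fraction_count must be >= 4")
  if (n_points < 10) abort("n_points must be >= 10")
  if (noise_sd < 0) abort("noise_sd must be >= 0")

  species <- c("RNP", "40S", "60S", "80S",
               paste0("POLY", seq_len(k - 4)))
  overlap_warn <- any(diff(peak_centers) < head(peak_widths, -1) + tail(peak_widths, -1))

  structure(
    list(peak_centers = peak_centers, peak_widths = peak_widths,
         peak_amplitudes = peak_amplitudes, species = species,
         baseline_offset = baseline_offset, baseline_slope = baseline_slope,
         noise_sd = noise_sd, n_points = n_points, span = span,
         fraction_count = fraction_count, tail_skew = tail_skew,
         overlap_warning = overlap_warn),
    class = "gradient_model"
  )
}

# noiseless generating function of a model, vectorised over position
gradient_signal <- function(model, x) {
  y <- model$baseline_offset + model$baseline_slope * x
  for (i in seq_along(model$peak_centers)) {
    g <- model$peak_amplitudes[i] *
      exp(-((x - model$peak_centers[i])^2) / (2 * model$peak_widths[i]^2))
    if (model$tail_skew > 0) {
      # exponentially modified tail toward the heavy (right) side
      g <- g * (1 + model$tail_skew * stats::pnorm(x, model$peak_centers[i],
                                                   model$peak_widths[i]))
      g <- g / (1 + model$tail_skew / 2)
    }
    y <- y + g
  }
  y
}

new_polysome_profile <- function(positions, absorbance, fraction_index,
                                 meta = list(), baseline = NULL) {
  out <- tibble(position = positions, absorbance = absorbance,
                fraction_index = as.integer(fraction_index))
  attr(out, "meta") <- meta
  attr(out, "baseline") <- baseline
  class(out) <- c("polysome_profile", class(out))
  out
}

#' Simulate a polysome profile with analytically known ground truth
#'
#' Samples the model's generating function (baseline + Gaussian peaks) on a
#' regular grid, adds Gaussian noise, and assigns each point to one of
#' `fraction_count` equal-width fractions. Ground-truth peak and region areas
#' are the closed-form Gaussian integrals, and the ground-truth FRP is
#' polysome area / (polysome area + 80S area) -- the 40S/60S/RNP regions are
#' excluded from the denominator by definition.
#'
#' @param model A [gradient_model()].
#' @param seed Integer seed; identical seeds give identical profiles.
#' @param meta Named list of sample metadata attached to the profile.
#'
#' @return A list with elements `profile` (a `polysome_profile` tibble:
#'   position, absorbance, fraction_index) and `truth` (peak areas, region
#'   areas, `frp`, baseline parameters, qc flags).
#' @export
simulate_profile <- function(model, seed = 1, meta = list()) {
  if (!inherits(model, "gradient_model")) abort("`model` must be a gradient_model")
  set.seed(seed)

  x <- seq(model$span[1], model$span[2], length.out = model$n_points)
  y <- gradient_signal(model, x)
  if (model$noise_sd > 0) y <- y + rnorm(length(x), 0, model$noise_sd)

  breaks <- seq(model$span[1], model$span[2], length.out = model$fraction_count + 1)
  frac <- pmin(findInterval(x, breaks, rightmost.closed = TRUE), model$fraction_count)

  peak_areas <- setNames(
    model$peak_amplitudes * model$peak_widths * sqrt(2 * pi),
    model$species
  )
  poly <- sum(peak_areas[startsWith(names(peak_areas), "POLY")])
  region_areas <- c(
    RNP = unname(peak_areas["RNP"]), `40S` = unname(peak_areas["40S"]),
    `60S` = unname(peak_areas["60S"]), `80S` = unname(peak_areas["80S"]),
    POLYSOMES = poly
  )
  denom <- poly + region_areas[["80S"]]
  flags <- character()
  if (model$overlap_warning) flags <- c(flags, "overlapping_peaks")
  if (denom == 0) flags <- c(flags, "frp_undefined")
  frp <- if (denom > 0) poly / denom else NA_real_

  list(
    profile = new_polysome_profile(x, y, frac, meta = meta),
    truth = list(peak_areas = peak_areas, region_areas = region_areas,
                 frp = frp, qc_flags = flags,
                 baseline = c(offset = model$baseline_offset,
                              slope = model$baseline_slope))
  )
}

# build a gradient model whose ground-truth FRP equals `frp`, by rescaling
# the default polysome amplitudes against a fixed 80S peak
model_for_frp <- function(frp, base = gradient_model(), noise_sd = base$noise_sd) {
  stopifnot(frp > 0, frp < 1)
  amp <- base$peak_amplitudes
  is_poly <- startsWith(base$species, "POLY")
  a80 <- amp[base$species == "80S"] * base$peak_widths[base$species == "80S"] *
    sqrt(2 * pi)
  poly_area_now <- sum(amp[is_poly] * base$peak_widths[is_poly] * sqrt(2 * pi))
  target_poly <- a80 * frp / (1 - frp)
  amp[is_poly] <- amp[is_poly] * target_poly / poly_area_now
  base$peak_amplitudes <- amp
  base$noise_sd <- noise_sd
  base
}

#' Simulate a mouse cohort: profiles plus coupled phenotypes
#'
#' Draws one true FRP per mouse from its group's distribution (truncated to
#' (0, 1)), realises a polysome profile with that ground-truth FRP, and
#' generates body weight and righting-reflex time as linear functions of the
#' true FRP plus Gaussian noise. Righting time is capped at 30 s after noise,
#' matching the assay termination rule, and floored at 1 s.
#'
#' @param group_specs A data frame with one row per group and columns
#'   `group`, `frp_mean`, `frp_sd`, `weight_intercept`, `weight_slope`,
#'   `weight_sd`, `righting_intercept`, `righting_slope`, `righting_sd`.
#'   Slopes are the coupling coefficients of phenotype on FRP; set them to 0
#'   for phenotypes independent of translation state. The default emulates a
#'   heterozygous-control group (high FRP) and an SMA group (reduced FRP)
#'   with heavier weight and faster righting at higher FRP.
#' @param n_per_group Named integer vector of mice per group. Defaults to 6,
#'   within the study's replicate range (min 3 -- max 9).
#' @param stage,treatment Labels copied into every record.
#' @param seed Integer seed.
#' @param profile_noise_sd Trace noise for the realised profiles.
#'
#' @return A list: `profiles` (named list of `polysome_profile`),
#'   `phenotypes` (tibble: mouse_id, genotype, stage, treatment, weight_g,
#'   righting_s), `truth` (tibble of per-mouse true FRP plus the group specs).
#' @export
simulate_cohort <- function(group_specs = default_group_specs(),
                            n_per_group = c(control = 6, SMA = 6),
                            stage = "early", treatment = "none",
                            seed = 1, profile_noise_sd = 0.005) {
  group_specs <- as_tibble(group_specs)
  check_columns(group_specs, c("group", "frp_mean", "frp_sd",
                               "weight_intercept", "weight_slope", "weight_sd",
                               "righting_intercept", "righting_slope", "righting_sd"),
                "group_specs")
  if (any(n_per_group <= 0)) abort("n_per_group must be positive")
  if (is.null(names(n_per_group))) names(n_per_group) <- group_specs$group
  set.seed(seed)

  records <- list(); profiles <- list(); truths <- list()
  for (g in group_specs$group) {
    spec <- group_specs[group_specs$group == g, ]
    n <- n_per_group[[g]]
    # rejection sampling into (0,1); profile realisation needs frp < 1
    frp <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        f <- rnorm(1, spec$frp_mean, spec$frp_sd)
        if (f > 0.005 && f < 0.995) break
      }
      frp[i] <- f
    }
    weight <- spec$weight_intercept + spec$weight_slope * frp +
      rnorm(n, 0, spec$weight_sd)
    righting <- spec$righting_intercept + spec$righting_slope * frp +
      rnorm(n, 0, spec$righting_sd)
    righting <- pmin(pmax(righting, 1), 30)  # assay cap applied after noise
    ids <- sprintf("%s_%02d", g, seq_len(n))
    records[[g]] <- tibble(mouse_id = ids, genotype = g, stage = stage,
                           treatment = treatment,
                           weight_g = pmax(weight, 0.5), righting_s = righting)
    truths[[g]] <- tibble(mouse_id = ids, genotype = g, true_frp = frp)
    for (i in seq_len(n)) {
      m <- model_for_frp(frp[i], noise_sd = profile_noise_sd)
      sim <- simulate_profile(m, seed = seed + 7919L * match(g, group_specs$group) + i,
                              meta = list(sample = ids[i], genotype = g,
                                          stage = stage, treatment = treatment))
      profiles[[ids[i]]] <- sim$profile
    }
  }
  list(profiles = profiles,
       phenotypes = bind_rows(records),
       truth = list(mice = bind_rows(truths), group_specs = group_specs))
}

#' @rdname simulate_cohort
#' @export
default_group_specs <- function() {
  tibble(
    group = c("control", "SMA"),
    frp_mean = c(0.75, 0.55), frp_sd = c(0.03, 0.05),
    weight_intercept = 2.0, weight_slope = 6.0, weight_sd = 0.3,
    righting_intercept = 32, righting_slope = -30, righting_sd = 1.5
  )
}

#' Default mapping of 12 gradient fractions to sedimentation regions
#'
#' Light fractions hold free RNPs, then the 40S and 60S subunits, the 80S
#' monosome, and the heavy half of the gradient holds polysomes.
#'
#' @param fraction_count Number of fractions (default 12).
#' @return Tibble with columns `fraction_index`, `region`.
#' @export
default_fraction_regions <- function(fraction_count = 12) {
  if (fraction_count < 5) abort("need >= 5 fractions to cover all regions")
  # proportions roughly matching where the default gradient model's peaks sit
  cuts <- round(fraction_count * c(0.17, 0.25, 0.33, 0.5))
  region <- character(fraction_count)
  region[seq_len(cuts[1])] <- "RNP"
  region[(cuts[1] + 1):cuts[2]] <- "40S"
  region[(cuts[2] + 1):cuts[3]] <- "60S"
  region[(cuts[3] + 1):cuts[4]] <- "80S"
  region[(cuts[4] + 1):fraction_count] <- "POLYSOMES"
  tibble(fraction_index = seq_len(fraction_count), region = region)
}

#' Simulate per-fraction immunoblot densitometry (co-sedimentation) tables
#'
#' Distributes each protein's total signal over gradient fractions according
#' to its per-region shares (spread uniformly within a region's fractions)
#' and multiplies each band intensity by multiplicative lognormal lane noise,
#' keeping intensities positive as densitometry values are.
#'
#' @param region_distribution Named list, one element per protein, each a
#'   named numeric vector of signal shares over regions (RNP, 40S, 60S, 80S,
#'   POLYSOMES). Shares must be nonnegative and not all zero; they are
#'   normalised to sum to 1.
#' @param lane_noise_cv Coefficient of variation of the lognormal band noise.
#' @param fraction_count Number of fractions.
#' @param fraction_regions Fraction-to-region map; defaults to
#'   [default_fraction_regions()].
#' @param total_signal Total densitometry signal per lane (arbitrary units).
#' @param sample Sample label for the lane.
#' @param seed Integer seed.
#'
#' @return A tibble (protein, sample, fraction_index, intensity) with the
#'   fraction-region map attached as attribute `fraction_regions`.
#' @export
simulate_cosed <- function(region_distribution,
                           lane_noise_cv = 0, fraction_count = 12,
                           fraction_regions = NULL, total_signal = 100,
                           sample = "sample1", seed = 1) {
  if (is.null(fraction_regions)) {
    fraction_regions <- default_fraction_regions(fraction_count)
  }
  set.seed(seed)
  rows <- purrr::imap(region_distribution, function(shares, protein) {
    if (any(shares < 0)) abort(sprintf("negative share for protein %s", protein))
    if (sum(shares) == 0) abort(sprintf("all-zero shares for protein %s", protein))
    shares <- shares / sum(shares)
    per_frac <- numeric(fraction_count)
    for (reg in names(shares)) {
      idx <- fraction_regions$fraction_index[fraction_regions$region == reg]
      if (length(idx) == 0 && shares[[reg]] > 0) {
        abort(sprintf("region %s has no fractions in the map", reg))
      }
      per_frac[idx] <- per_frac[idx] + shares[[reg]] / length(idx)
    }
    intensity <- per_frac * total_signal
    if (lane_noise_cv > 0) {
      intensity <- intensity * rlnorm_mean_cv(fraction_count, 1, lane_noise_cv)
    }
    tibble(protein = protein, sample = sample,
           fraction_index = seq_len(fraction_count), intensity = intensity)
  })
  out <- bind_rows(rows)
  attr(out, "fraction_regions") <- fraction_regions
  out
}

#' Simulate paired polysomal/total count matrices with planted TE shifts
#'
#' Negative-binomial counts with shared dispersion. Total-RNA (TOT) means are
#' shared across groups; polysomal (POL) means equal the total means except
#' for the genes in `te_shift_spec`, whose polysomal mean in the case group
#' is scaled by 2^log2dTE. Per-sample library-size factors are drawn
#' uniformly from `library_size_range`.
#'
#' @param n_genes Number of genes.
#' @param n_samples_per_group Samples per group and compartment (control and
#'   case, POL and TOT each).
#' @param baseline_log_mean_range Range of per-gene natural-log mean counts.
#' @param dispersion NB dispersion (1/size); values below 1e-8 fall back to
#'   Poisson sampling.
#' @param te_shift_spec Named numeric vector of planted log2 delta-TE values
#'   (names are gene ids present in the gene set), or NULL for a global null.
#' @param library_size_range Range of per-sample library-size factors (> 0).
#' @param seed Integer seed.
#'
#' @return A list of class `count_matrix_pair`: integer matrices `pol` and
#'   `tot` (genes x samples), `samples` (tibble: sample, group) and `truth`
#'   (tibble: gene, log2dte).
#' @export
simulate_counts <- function(n_genes = 1000, n_samples_per_group = 4,
                            baseline_log_mean_range = log(c(20, 2000)),
                            dispersion = 0.1, te_shift_spec = NULL,
                            library_size_range = c(0.8, 1.2), seed = 1) {
  if (dispersion < 0) abort("dispersion must be >= 0")
  if (any(library_size_range <= 0)) abort("library sizes must be > 0")
  set.seed(seed)

  genes <- sprintf("gene%04d", seq_len(n_genes))
  shift <- setNames(rep(0, n_genes), genes)
  if (!is.null(te_shift_spec)) {
    if (!all(names(te_shift_spec) %in% genes)) {
      abort("te_shift_spec names must be a subset of the simulated gene set")
    }
    shift[names(te_shift_spec)] <- te_shift_spec
  }

  n <- 2L * n_samples_per_group
  group <- rep(c("control", "case"), each = n_samples_per_group)
  samples <- sprintf("%s_%d", group, c(seq_len(n_samples_per_group),
                                       seq_len(n_samples_per_group)))
  base_mu <- exp(runif(n_genes, baseline_log_mean_range[1], baseline_log_mean_range[2]))
  size_tot <- runif(n, library_size_range[1], library_size_range[2])
  size_pol <- runif(n, library_size_range[1], library_size_range[2])

  mu_tot <- outer(base_mu, size_tot)
  mu_pol <- outer(base_mu, size_pol)
  case_cols <- group == "case"
  mu_pol[, case_cols] <- mu_pol[, case_cols] * 2^shift

  draw <- function(mu) {
    cnt <- if (dispersion < 1e-8) rpois(length(mu), mu) else
      rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    matrix(cnt, nrow = n_genes, dimnames = list(genes, samples))
  }
  structure(
    list(pol = draw(mu_pol), tot = draw(mu_tot),
         samples = tibble(sample = samples, group = group),
         truth = tibble(gene = genes, log2dte = unname(shift))),
    class = "count_matrix_pair"
  )
}

#' Simulate qPCR Ct tables with planted fold changes
#'
#' Ct values follow base_ct - log2(relative expression) + noise, so one
#' cycle corresponds to a two-fold expression difference. Reference genes
#' have fold change 1 in every compartment by construction; case-group
#' targets carry the planted fold change of their compartment.
#'
#' @param true_fold_changes Tibble (gene, compartment, fc) of planted
#'   case-vs-control fold changes per compartment (POL, TOT), or a named
#'   list `list(gene = c(POL = fc, TOT = fc))`.
#' @param ct_noise_sd Gaussian noise on Ct, in cycles.
#' @param reference_genes Two reference-gene names (fold change forced to 1).
#' @param n_bio Biological replicates per group (>= 1).
#' @param n_tech Technical replicates per reaction (>= 1).
#' @param base_ct Mean Ct of an unchanged gene; per-gene offsets are drawn
#'   once so genes differ in expression level.
#' @param seed Integer seed.
#'
#' @return A long tibble (gene, sample, group, compartment, biological_replicate,
#'   technical_replicate, ct).
#' @export
simulate_qpcr <- function(true_fold_changes, ct_noise_sd = 0,
                          reference_genes = c("Actb", "Ppia"),
                          n_bio = 4, n_tech = 2, base_ct = 22, seed = 1) {
  if (n_bio < 1 || n_tech < 1) abort("need >= 1 biological and technical replicate")
  if (length(reference_genes) != 2) abort("exactly two reference genes are required")
  fc_tbl <- if (is.data.frame(true_fold_changes)) {
    as_tibble(true_fold_changes)
  } else {
    bind_rows(purrr::imap(true_fold_changes, function(v, g) {
      tibble(gene = g, compartment = names(v), fc = unname(v))
    }))
  }
  check_columns(fc_tbl, c("gene", "compartment", "fc"), "true_fold_changes")
  if (any(fc_tbl$gene %in% reference_genes & fc_tbl$fc != 1)) {
    abort("reference genes must have fold change 1")
  }
  set.seed(seed)

  genes <- unique(c(fc_tbl$gene, reference_genes))
  gene_offset <- setNames(runif(length(genes), -2, 2), genes)
  grid <- tidyr::expand_grid(
    gene = genes, compartment = c("POL", "TOT"),
    group = c("control", "case"),
    biological_replicate = seq_len(n_bio),
    technical_replicate = seq_len(n_tech)
  )
  grid <- left_join(grid, fc_tbl, by = c("gene", "compartment"))
  grid$fc[is.na(grid$fc)] <- 1
  rel_expr <- ifelse(grid$group == "case", grid$fc, 1)
  grid$ct <- base_ct + gene_offset[grid$gene] - log2(rel_expr) +
    rnorm(nrow(grid), 0, ct_noise_sd)
  grid$sample <- sprintf("%s_%d", grid$group, grid$biological_replicate)
  select(grid, "gene", "sample", "group", "compartment",
         "biological_replicate", "technical_replicate", "ct")
}

#' Simulate per-cell fluorescence intensities (AHA labelling)
#'
#' Per-cell mean intensities are lognormal with a common coefficient of
#' variation; the case-group mean is the control mean scaled by
#' (1 - percent_decrease/100). Replicates emulate independent neuronal
#' preparations, each with its own cell count.
#'
#' @param percent_decrease True percent decrease of the case mean, in
#'   `[0, 100)`.
#' @param n_per_replicate_ctrl,n_per_replicate_case Integer vectors of cells
#'   per replicate preparation (equal length not required).
#' @param lognormal_cv Per-cell coefficient of variation.
#' @param control_mean Control-group mean intensity (arbitrary units).
#' @param seed Integer seed.
#'
#' @return Tibble (replicate_id, genotype, cell_id, mean_intensity).
#' @export
simulate_cell_intensities <- function(percent_decrease,
                                      n_per_replicate_ctrl,
                                      n_per_replicate_case,
                                      lognormal_cv = 0.4,
                                      control_mean = 100, seed = 1) {
  if (percent_decrease < 0 || percent_decrease >= 100) {
    abort("percent_decrease must be in [0, 100)")
  }
  if (length(n_per_replicate_ctrl) == 0 || length(n_per_replicate_case) == 0) {
    abort("replicate cell-count lists must be nonempty")
  }
  set.seed(seed)
  gen <- function(ns, genotype, mean) {
    bind_rows(purrr::imap(as.list(ns), function(n, r) {
      tibble(replicate_id = sprintf("%s_rep%d", genotype, as.integer(r)),
             genotype = genotype, cell_id = seq_len(n),
             mean_intensity = rlnorm_mean_cv(n, mean, lognormal_cv))
    }))
  }
  bind_rows(
    gen(n_per_replicate_ctrl, "control", control_mean),
    gen(n_per_replicate_case, "SMA", control_mean * (1 - percent_decrease / 100))
  )
}

#' Simulate axonal ribosome counts over electron-micrograph profiles
#'
#' Per-axon ribosome counts are Poisson with rate density x area; axon areas
#' are lognormal. The case-group density is the control density scaled by
#' (1 - percent_decrease/100). Axons are attributed to 3 mice per genotype.
#'
#' @param control_density Control ribosome density (ribosomes per unit area, > 0).
#' @param percent_decrease True percent density deficit in the case group.
#' @param area_mean,area_cv Lognormal axon-area distribution (mean in the
#'   same unit area the density refers to).
#' @param n_axons_per_group Axon profiles per genotype.
#' @param n_mice Mice per genotype the axons are attributed to.
#' @param seed Integer seed.
#'
#' @return Tibble (mouse_id, genotype, axon_id, ribosome_count, axon_area).
#' @export
simulate_axon_counts <- function(control_density = 50, percent_decrease = 0,
                                 area_mean = 1, area_cv = 0.3,
                                 n_axons_per_group = 30, n_mice = 3, seed = 1) {
  if (control_density <= 0) abort("control_density must be > 0")
  if (area_mean <= 0) abort("axon areas must be positive")
  if (percent_decrease < 0 || percent_decrease >= 100) {
    abort("percent_decrease must be in [0, 100)")
  }
  set.seed(seed)
  gen <- function(genotype, density) {
    area <- rlnorm_mean_cv(n_axons_per_group, area_mean, area_cv)
    tibble(
      mouse_id = sprintf("%s_m%d", genotype,
                         rep_len(seq_len(n_mice), n_axons_per_group)),
      genotype = genotype, axon_id = seq_len(n_axons_per_group),
      ribosome_count = rpois(n_axons_per_group, density * area),
      axon_area = area
    )
  }
  bind_rows(gen("control", control_density),
            gen("SMA", control_density * (1 - percent_decrease / 100)))
}
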