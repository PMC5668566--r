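#' Percent decrease of the case-group mean relative to control
#'
#' 100 * (1 - mean(case) / mean(ctrl)), on arithmetic means of the raw
#' values. Invariant to common rescaling of both groups.
#'
#' @param ctrl_values,case_values Numeric vectors.
#' @return Percent decrease (negative values mean an increase).
#' @export
percent_decrease <- function(ctrl_values, case_values) {
  if (length(ctrl_values) == 0 || length(case_values) == 0) {
    abort("both groups must be nonempty")
  }
  m <- mean(ctrl_values)
  if (m <= 0) abort("control mean must be > 0")
  100 * (1 - mean(case_values) / m)
}

effect_row <- function(contrast, ctrl, case, pooling) {
  est <- percent_decrease(ctrl, case)
  if (sd(ctrl) == 0 && sd(case) == 0) {
    # degenerate lanes carry no within-group variance; keep the estimate,
    # report the no-evidence / complete-separation convention
    equal <- mean(ctrl) == mean(case)
    tt <- list(statistic = if (equal) 0 else sign(mean(case) - mean(ctrl)) * Inf,
               parameter = length(ctrl) + length(case) - 2,
               p.value = if (equal) 1 else 0,
               conf.int = c(NA_real_, NA_real_))
  } else {
    tt <- t.test(case, ctrl, var.equal = TRUE)
  }
  # CI of the mean difference, expressed as percent of the control mean
  ci <- sort(100 * -tt$conf.int / mean(ctrl), na.last = TRUE)
  tibble(contrast = contrast, pooling = pooling,
         estimate_pct = est, ci_low = ci[1], ci_high = ci[2],
         t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value,
         mean_control = mean(ctrl), mean_case = mean(case),
         n_control = length(ctrl), n_case = length(case))
}

#' Compare per-cell fluorescence intensity between genotypes
#'
#' Estimates the percent decrease in mean intensity (case vs control) with a
#' two-sample Student's t test, at two units of analysis: cells pooled
#' across replicate preparations (the default reading of per-cell n), and
#' replicate means (robust to pseudo-replication). Both are always reported.
#' Per-replicate summaries include SEM = sd / sqrt(n).
#'
#' @param table Tibble (replicate_id, genotype, cell_id, mean_intensity).
#' @param control,case Genotype labels.
#' @return Tibble with one row per pooling mode (contrast, pooling,
#'   estimate_pct, ci, t, df, p_value, ...); per-replicate summaries in
#'   attribute `replicates`.
#' @export
compare_intensities <- function(table, control = "control", case = "SMA") {
  check_columns(table, c("replicate_id", "genotype", "mean_intensity"), "table")
  ctrl <- table$mean_intensity[table$genotype == control]
  cse <- table$mean_intensity[table$genotype == case]
  if (length(ctrl) < 2 || length(cse) < 2) {
    abort("need >= 2 cells per genotype")
  }
  contrast <- sprintf("%s_vs_%s", case, control)
  rep_means <- summarise(group_by(table, .data$genotype, .data$replicate_id),
                         sem = sd(.data$mean_intensity) / sqrt(dplyr::n()),
                         n_cells = dplyr::n(),
                         mean_intensity = mean(.data$mean_intensity),
                         .groups = "drop")
  out <- bind_rows(
    effect_row(contrast, ctrl, cse, "pooled_cells"),
    if (sum(rep_means$genotype == control) >= 2 &&
        sum(rep_means$genotype == case) >= 2) {
      effect_row(contrast,
                 rep_means$mean_intensity[rep_means$genotype == control],
                 rep_means$mean_intensity[rep_means$genotype == case],
                 "replicate_means")
    }
  )
  attr(out, "replicates") <- rep_means
  out
}

#' Axonal ribosome density: per-axon estimates and group effect
#'
#' Density is ribosome count divided by axon area, per axon profile. The
#' group effect is the percent decrease of the case-group mean density with
#' a two-tailed Student's t test on per-axon densities.
#'
#' @param table Tibble (mouse_id, genotype, axon_id, ribosome_count,
#'   axon_area); areas must be > 0.
#' @param control,case Genotype labels.
#' @return One-row effect tibble (as [compare_intensities()]); per-axon
#'   densities in attribute `densities`.
#' @export
ribosome_density <- function(table, control = "control", case = "SMA") {
  check_columns(table, c("genotype", "ribosome_count", "axon_area"), "table")
  if (any(table$axon_area <= 0)) abort("axon areas must be > 0")
  if (any(table$ribosome_count < 0)) abort("ribosome counts must be >= 0")
  dens <- mutate(table, density = .data$ribosome_count / .data$axon_area)
  ctrl <- dens$density[dens$genotype == control]
  cse <- dens$density[dens$genotype == case]
  if (length(ctrl) < 2 || length(cse) < 2) abort("need >= 2 axons per genotype")
  out <- effect_row(sprintf("%s_vs_%s", case, control), ctrl, cse, "per_axon")
  attr(out, "densities") <- dens
  out
}

#' Is a treated signal indistinguishable from background?
#'
#' Flags whether a treated intensity distribution cannot be told apart from
#' a background distribution (no-label or translation-inhibitor wells) by a
#' two-sample t test at level `alpha` -- the control used to confirm that
#' labelling reports de novo synthesis.
#'
#' @param treated,background Numeric intensity vectors.
#' @param alpha Test level.
#' @return List: `indistinguishable` (logical), `p_value`, `mean_treated`,
#'   `mean_background`.
#' @export
background_control <- function(treated, background, alpha = 0.05) {
  if (length(background) == 0) abort("background set must be nonempty")
  if (length(treated) < 2 || length(background) < 2) {
    abort("need >= 2 observations per group")
  }
  tt <- t.test(treated, background)
  list(indistinguishable = tt$p.value >= alpha, p_value = tt$p.value,
       mean_treated = mean(treated), mean_background = mean(background))
}
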