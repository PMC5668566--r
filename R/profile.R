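#' Read a polysome profile from a delimited file
#'
#' Expects columns `position`, `absorbance`, `fraction_index` (the layout
#' [write_profile()] emits). Positions must be strictly increasing and
#' fraction indices nondecreasing; violations are rejected with the first
#' offending row number.
#'
#' @param path File path.
#' @param dialect "tsv" (default) or "csv".
#' @param meta Named list of sample metadata to attach.
#' @return A `polysome_profile` tibble.
#' @export
read_profile <- function(path, dialect = c("tsv", "csv"), meta = list()) {
  dialect <- match.arg(dialect)
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("position", "absorbance", "fraction_index"),
                sprintf("profile file '%s'", path))
  validate_profile_frame(df, path)
  new_polysome_profile(df$position, df$absorbance, df$fraction_index, meta = meta)
}

validate_profile_frame <- function(df, what = "profile") {
  bad <- which(diff(df$position) <= 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: positions not strictly increasing, first offence at row %d",
                  what, bad[1] + 1L))
  }
  badf <- which(diff(df$fraction_index) < 0)
  if (length(badf) > 0) {
    abort(sprintf("%s: fraction_index decreases at row %d", what, badf[1] + 1L))
  }
  invisible(df)
}

#' Write a polysome profile as a 3-column TSV
#'
#' @param profile A `polysome_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(as_tibble(profile)[, c("position", "absorbance", "fraction_index")],
                   path, progress = FALSE)
  invisible(path)
}

#' Subtract a linear baseline from an absorbance trace
#'
#' Fits a straight line through the median (position, absorbance) of two
#' anchor windows -- by default the first and last 2\% of the trace, where no
#' ribosomal species sediment -- and subtracts it. Negative residuals are
#' preserved; clamping is deferred to region integration.
#'
#' @param profile A `polysome_profile` with >= 10 points.
#' @param anchors Optional list of two numeric length-2 position windows;
#'   windows must lie inside the trace.
#' @param anchor_frac Fraction of the trace used for each default anchor
#'   window.
#' @return The baseline-corrected `polysome_profile`; the fitted baseline
#'   (intercept, slope) is stored in attribute `baseline`.
#' @export
correct_baseline <- function(profile, anchors = NULL, anchor_frac = 0.02) {
  if (nrow(profile) < 10) abort("trace must have >= 10 points")
  x <- profile$position; y <- profile$absorbance
  if (is.null(anchors)) {
    k <- max(2L, ceiling(anchor_frac * length(x)))
    anchors <- list(range(head(x, k)), range(tail(x, k)))
  }
  med <- purrr::map(anchors, function(w) {
    if (w[1] < min(x) - 1e-9 || w[2] > max(x) + 1e-9) {
      abort("baseline anchor window lies outside the trace")
    }
    sel <- x >= w[1] & x <= w[2]
    if (!any(sel)) abort("baseline anchor window contains no points")
    c(median(x[sel]), median(y[sel]))
  })
  slope <- (med[[2]][2] - med[[1]][2]) / (med[[2]][1] - med[[1]][1])
  intercept <- med[[1]][2] - slope * med[[1]][1]
  out <- new_polysome_profile(x, y - (intercept + slope * x),
                              profile$fraction_index,
                              meta = attr(profile, "meta"),
                              baseline = c(intercept = intercept, slope = slope))
  out
}

# prominence of each local maximum: height above the higher of the two
# deepest valleys separating it from taller terrain (standard definition)
peak_prominences <- function(y, peaks) {
  vapply(peaks, function(p) {
    left <- y[seq_len(p)]
    higher_l <- which(left > y[p])
    base_l <- if (length(higher_l) == 0) min(left) else
      min(left[seq(max(higher_l), p)])
    right <- y[seq(p, length(y))]
    higher_r <- which(right > y[p])
    base_r <- if (length(higher_r) == 0) min(right) else
      min(right[seq_len(min(higher_r))])
    y[p] - max(base_l, base_r)
  }, numeric(1))
}

#' Segment a profile into sedimentation regions at inter-peak valleys
#'
#' Detects local maxima, keeps those with prominence at least
#' `min_prominence`, assigns the first detected peaks (in position order) to
#' the expected species, and places region boundaries at the valley minima
#' between adjacent assigned peaks. Everything after the valley following
#' the 80S peak is the POLYSOMES region -- the remaining heavy peaks of the
#' profile. If no peak is detected beyond the last expected species, the
#' POLYSOMES region has zero width at the trace end.
#'
#' Peak detection runs on a Savitzky-Golay-smoothed copy of the trace so
#' that detector noise does not spawn spurious low-prominence maxima; region
#' boundaries are read off the smoothed trace, while integration
#' ([integrate_regions()]) always uses the raw absorbance values.
#'
#' @param profile A baseline-corrected `polysome_profile`.
#' @param expected_species Ordered species labels, light to heavy; default
#'   RNP, 40S, 60S, 80S.
#' @param min_prominence Minimum peak prominence, absorbance units.
#' @param smooth_window Width (points) of the Savitzky-Golay filter used for
#'   detection; even values are rounded up to odd, 0 disables smoothing.
#'   Default: 2\% of the trace length.
#' @return A `peak_segmentation`: tibble (region, start, end) with detected
#'   peak positions in attribute `detected_peaks` and per-boundary ambiguity
#'   flags (valley depth below `min_prominence`) in attribute `qc_flags`.
#' @export
segment_peaks <- function(profile, expected_species = c("RNP", "40S", "60S", "80S"),
                          min_prominence = 0.05,
                          smooth_window = ceiling(0.02 * nrow(profile))) {
  x <- profile$position; y_raw <- profile$absorbance
  y <- y_raw
  if (smooth_window > 0 && length(y) > 11) {
    fl <- min(smooth_window, floor((length(y) - 1) / 2))
    if (fl %% 2 == 0) fl <- fl + 1
    if (fl >= 5) y <- pracma::savgol(y_raw, fl = fl, forder = 3)
  }
  pk <- pracma::findpeaks(y)
  if (is.null(pk)) abort("no peaks detected")
  idx <- sort(pk[, 2])
  prom <- peak_prominences(y, idx)
  idx <- idx[prom >= min_prominence]
  if (length(idx) < length(expected_species)) {
    abort(sprintf(
      "expected %d species but detected only %d peak(s) at position(s): %s",
      length(expected_species), length(idx),
      paste(signif(x[idx], 4), collapse = ", ")))
  }
  assigned <- idx[seq_along(expected_species)]
  extra <- idx[-seq_along(expected_species)]

  valley_between <- function(i, j) {
    seg <- seq(i, j)
    seg[which.min(y[seg])]
  }
  n_sp <- length(expected_species)
  # internal boundaries between consecutive assigned species
  bounds <- integer(0); flags <- character(0)
  if (n_sp > 1) {
    for (s in seq_len(n_sp - 1)) {
      v <- valley_between(assigned[s], assigned[s + 1])
      depth <- min(y[assigned[s]], y[assigned[s + 1]]) - y[v]
      if (depth < min_prominence) {
        flags <- c(flags, sprintf("shallow_valley_%s_%s",
                                  expected_species[s], expected_species[s + 1]))
      }
      bounds <- c(bounds, v)
    }
  }
  # boundary between the last expected species (80S) and the polysomes
  if (length(extra) > 0) {
    v80 <- valley_between(assigned[n_sp], extra[1])
    depth <- min(y[assigned[n_sp]], y[extra[1]]) - y[v80]
    if (depth < min_prominence) flags <- c(flags, "shallow_valley_80S_POLYSOMES")
    poly <- c(x[v80], x[length(x)])
  } else {
    # no polysomal peak: close the last species region at the minimum after
    # its peak and leave POLYSOMES empty at the trace end
    after <- seq(assigned[n_sp], length(y))
    v80 <- after[which.min(y[after])]
    poly <- c(x[length(x)], x[length(x)])
    flags <- c(flags, "no_polysome_peaks")
  }

  starts <- x[c(1, bounds)]
  ends <- x[c(bounds, v80)]
  regions <- tibble(
    region = c(expected_species, "POLYSOMES"),
    start = c(starts, poly[1]),
    end = c(ends, poly[2])
  )
  attr(regions, "detected_peaks") <- tibble(position = x[idx], height = y[idx])
  attr(regions, "qc_flags") <- flags
  class(regions) <- c("peak_segmentation", class(regions))
  regions
}

#' Integrate baseline-corrected absorbance over segmented regions
#'
#' Trapezoidal integration of the trace within each region's position
#' window. Negative net areas (noise dipping below the baseline) are clamped
#' to zero and flagged rather than rejected.
#'
#' @param profile A `polysome_profile` (baseline-corrected).
#' @param segmentation A `peak_segmentation` over the same trace.
#' @return A `region_areas` tibble (region, area, clamped); the baseline
#'   parameters used, if any, travel in attribute `baseline_model`.
#' @export
integrate_regions <- function(profile, segmentation) {
  x <- profile$position; y <- profile$absorbance
  lo <- min(x) - 1e-9; hi <- max(x) + 1e-9
  res <- purrr::pmap(segmentation[, c("region", "start", "end")],
                     function(region, start, end) {
    if (start < lo || end > hi) {
      abort(sprintf("region %s [%g, %g] lies outside the trace", region, start, end))
    }
    sel <- x >= start & x <= end
    a <- if (sum(sel) < 2) 0 else pracma::trapz(x[sel], y[sel])
    tibble(region = region, area = max(a, 0), clamped = a < 0)
  })
  out <- bind_rows(res)
  attr(out, "baseline_model") <- attr(profile, "baseline")
  class(out) <- c("region_areas", class(out))
  out
}

#' Fraction of ribosomes in polysomes (FRP)
#'
#' FRP = polysome area / (polysome area + 80S area). The RNP, 40S and 60S
#' areas are excluded from the denominator by definition: the statistic
#' reads the share of assembled ribosomes engaged in translation on
#' polysomes versus idling as 80S monosomes.
#'
#' @param areas A `region_areas` with 80S and POLYSOMES rows.
#' @param meta Optional named list of sample metadata carried into the result.
#' @return One-row tibble (frp, area_polysomes, area_80s, qc) of class
#'   `frp_result`.
#' @export
compute_frp <- function(areas, meta = list()) {
  check_columns(areas, c("region", "area"), "areas")
  a80 <- areas$area[areas$region == "80S"]
  apoly <- areas$area[areas$region == "POLYSOMES"]
  if (length(a80) != 1 || length(apoly) != 1) {
    abort("areas must contain exactly one 80S and one POLYSOMES region")
  }
  if (a80 + apoly == 0) abort("FRP undefined: 80S and polysome areas are both zero")
  qc <- if (any(areas$clamped %||% FALSE)) "clamped_area" else ""
  out <- tibble(frp = apoly / (apoly + a80),
                area_polysomes = apoly, area_80s = a80, qc = qc)
  for (nm in names(meta)) out[[nm]] <- meta[[nm]]
  class(out) <- c("frp_result", class(out))
  out
}

#' Polysome-to-monosome area ratio (P/M), an FRP variant
#'
#' @inheritParams compute_frp
#' @return Polysome area divided by 80S area.
#' @export
polysome_monosome_ratio <- function(areas) {
  a80 <- areas$area[areas$region == "80S"]
  apoly <- areas$area[areas$region == "POLYSOMES"]
  if (a80 == 0) abort("P/M ratio undefined: 80S area is zero")
  apoly / a80
}

#' One-call FRP from a raw trace
#'
#' Runs baseline correction, valley segmentation, region integration and the
#' FRP ratio with the given settings.
#'
#' @inheritParams segment_peaks
#' @param baseline Subtract the linear baseline first (default TRUE).
#' @param ... Passed to [segment_peaks()].
#' @return One-row `frp_result` tibble, carrying the profile's metadata.
#' @export
profile_frp <- function(profile, baseline = TRUE, ...) {
  meta <- attr(profile, "meta") %||% list()
  p <- if (baseline) correct_baseline(profile) else profile
  seg <- segment_peaks(p, ...)
  areas <- integrate_regions(p, seg)
  compute_frp(areas, meta = meta)
}

#' Compare FRP between two groups with Student's t test
#'
#' @param group_a,group_b Numeric FRP vectors, or `frp_result` tibbles.
#' @param alternative "two.sided" (default), "less" or "greater", the
#'   alternative for mean(a) - mean(b). One-tailed testing must be requested
#'   explicitly.
#' @return A `frp_test` object (list: statistic, df, p_value, estimate,
#'   alternative, flag); `tidy()`/`glance()` return it as a tibble.
#' @export
compare_frp <- function(group_a, group_b,
                        alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  a <- if (is.data.frame(group_a)) group_a$frp else group_a
  b <- if (is.data.frame(group_b)) group_b$frp else group_b
  if (length(a) < 2 || length(b) < 2) abort("each group needs >= 2 FRP values")
  flag <- ""
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      # degenerate: identical constants carry no evidence either way
      res <- list(statistic = 0, parameter = length(a) + length(b) - 2,
                  p.value = 1, estimate = c(mean(a), mean(b)))
      flag <- "zero_variance"
    } else {
      res <- list(statistic = sign(mean(a) - mean(b)) * Inf,
                  parameter = length(a) + length(b) - 2, p.value = 0,
                  estimate = c(mean(a), mean(b)))
      flag <- "zero_variance"
    }
  } else {
    res <- t.test(a, b, alternative = alternative, var.equal = TRUE)
  }
  structure(
    list(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value, mean_a = mean(a), mean_b = mean(b),
         alternative = alternative, flag = flag),
    class = "frp_test"
  )
}

#' Correlate per-mouse FRP with a phenotype
#'
#' Reports Pearson and/or Spearman coefficients with correlation-test
#' p-values, as used to relate translation state to body weight and
#' righting-reflex time.
#'
#' @param data Data frame with one row per mouse.
#' @param frp,phenotype Columns (unquoted) holding FRP and the phenotype.
#' @param method "both" (default), "pearson" or "spearman".
#' @return Tibble (method, estimate, p_value, n).
#' @export
correlate_phenotype <- function(data, frp, phenotype,
                                method = c("both", "pearson", "spearman")) {
  method <- match.arg(method)
  x <- eval_tidy(enquo(frp), data)
  y <- eval_tidy(enquo(phenotype), data)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) abort("need >= 4 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("correlation undefined for a constant vector")
  methods <- if (method == "both") c("pearson", "spearman") else method
  bind_rows(lapply(methods, function(m) {
    ct <- suppressWarnings(cor.test(x, y, method = m))
    tibble(method = m, estimate = unname(ct$estimate),
           p_value = ct$p.value, n = length(x))
  }))
}

#' Express phenotypes relative to stage-matched control means
#'
#' Divides each mouse's weight and righting time by the mean of the control
#' animals at the same disease stage, yielding the dimensionless relative
#' phenotypes used for clustering.
#'
#' @param records Phenotype tibble with columns mouse_id, genotype, stage,
#'   weight_g, righting_s.
#' @param control Genotype label of the control group.
#' @return `records` with `relative_weight` and `relative_righting` added.
#' @export
relative_phenotype <- function(records, control = "control") {
  check_columns(records, c("mouse_id", "genotype", "stage",
                           "weight_g", "righting_s"), "records")
  ctrl <- records[records$genotype == control, ]
  empty <- setdiff(unique(records$stage), unique(ctrl$stage))
  if (length(empty) > 0) {
    abort(sprintf("no control records for stage(s): %s",
                  paste(empty, collapse = ", ")))
  }
  ref <- summarise(group_by(ctrl, .data$stage),
                   .w = mean(.data$weight_g), .r = mean(.data$righting_s))
  out <- left_join(records, ref, by = "stage")
  out <- mutate(out,
                relative_weight = .data$weight_g / .data$.w,
                relative_righting = .data$righting_s / .data$.r)
  select(out, -".w", -".r")
}

#' Ward hierarchical clustering of mice on translation and phenotype
#'
#' Standardises each variable to a common mean and standard deviation,
#' computes Euclidean distances, and agglomerates with the Ward.D update
#' rule (i.e., on unsquared input distances, as the named method does).
#'
#' @param data One row per mouse; must be complete in `vars`.
#' @param vars Character vector of clustering variables.
#' @param id_col Column with mouse identifiers.
#' @param k Number of flat clusters to cut (default 2).
#' @return A `mouse_clustering` object: list(hclust, labels tibble, k, vars).
#' @export
cluster_mice <- function(data, vars = c("frp", "relative_weight", "relative_righting"),
                         id_col = "mouse_id", k = 2) {
  check_columns(data, c(id_col, vars), "data")
  if (nrow(data) < 3) abort("need >= 3 mice to cluster")
  m <- as.matrix(data[, vars])
  bad <- data[[id_col]][!stats::complete.cases(m)]
  if (length(bad) > 0) {
    abort(sprintf("missing values for mice: %s", paste(bad, collapse = ", ")))
  }
  z <- scale(m)
  # a constant column carries no information; scale() gives NaN there
  z[, apply(m, 2, sd) == 0] <- 0
  rownames(z) <- data[[id_col]]
  hc <- hclust(dist(z, method = "euclidean"), method = "ward.D")
  labels <- tibble(!!id_col := data[[id_col]],
                   cluster = unname(cutree(hc, k = k)))
  structure(list(hclust = hc, labels = labels, k = k, vars = vars),
            class = "mouse_clustering")
}

#' @export
print.frp_test <- function(x, ...) {
  cat(sprintf("Student's t test on FRP (%s)\n", x$alternative))
  cat(sprintf("  t = %.4g, df = %g, p = %.4g\n", x$statistic, x$df, x$p_value))
  cat(sprintf("  mean A = %.4f, mean B = %.4f\n", x$mean_a, x$mean_b))
  if (nzchar(x$flag)) cat(sprintf("  flag: %s\n", x$flag))
  invisible(x)
}

#' @export
print.mouse_clustering <- function(x, ...) {
  cat(sprintf("Ward.D/Euclidean clustering of %d mice on %s; k = %d\n",
              nrow(x$labels), paste(x$vars, collapse = ", "), x$k))
  print(table(x$labels$cluster))
  invisible(x)
}

#' @export
plot.mouse_clustering <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "", main = "Ward.D clustering of mice", ...)
  invisible(x)
}
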