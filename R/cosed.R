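#' Normalise a co-sedimentation table to per-lane signal shares
#'
#' Western-blot exposures differ between blots, so each lane (one protein in
#' one sample) is normalised to its own total signal; all cross-protein
#' comparisons are made on the resulting shares, which sum to 1 across
#' fractions.
#'
#' @param table Long tibble (protein, sample, fraction_index, intensity);
#'   intensities must be >= 0.
#' @return The table with a `share` column added; the `fraction_regions`
#'   attribute, if present, is preserved.
#' @export
normalize_distribution <- function(table) {
  check_columns(table, c("protein", "sample", "fraction_index", "intensity"),
                "co-sedimentation table")
  if (any(table$intensity < 0)) abort("intensities must be >= 0")
  regions <- attr(table, "fraction_regions")
  out <- table |>
    group_by(.data$protein, .data$sample) |>
    mutate(.total = sum(.data$intensity)) |>
    ungroup()
  zero <- distinct(filter(out, .data$.total == 0),
                   .data$protein, .data$sample)
  if (nrow(zero) > 0) {
    abort(sprintf("all-zero lane(s): %s",
                  paste(sprintf("%s/%s", zero$protein, zero$sample),
                        collapse = ", ")))
  }
  out <- select(mutate(out, share = .data$intensity / .data$.total), -".total")
  attr(out, "fraction_regions") <- regions
  out
}

resolve_regions <- function(shares, regions) {
  regions <- regions %||% attr(shares, "fraction_regions")
  if (is.null(regions)) {
    abort("no fraction-to-region map: pass `regions` or use a table carrying one")
  }
  check_columns(regions, c("fraction_index", "region"), "regions")
  regions
}

#' Polysome-association index of a protein
#'
#' The summed signal share over the fractions of the target region(s):
#' by default the polysomal fractions, optionally 80S plus polysomes.
#' Bounded in `[0, 1]`; the index over a region set and its complement sum
#' to 1 (mass conservation).
#'
#' @param shares Normalised table from [normalize_distribution()].
#' @param regions Fraction-to-region map (tibble fraction_index, region);
#'   taken from the table's attribute when omitted.
#' @param target Region name(s) counted as associated, e.g. "POLYSOMES" or
#'   `c("80S", "POLYSOMES")`.
#' @return Tibble (protein, sample, target, association_index).
#' @export
association_index <- function(shares, regions = NULL, target = "POLYSOMES") {
  check_columns(shares, c("protein", "sample", "fraction_index", "share"),
                "shares")
  regions <- resolve_regions(shares, regions)
  target_frac <- regions$fraction_index[regions$region %in% target]
  if (length(target_frac) == 0) {
    abort(sprintf("target region(s) %s cover no fractions",
                  paste(target, collapse = ", ")))
  }
  shares |>
    group_by(.data$protein, .data$sample) |>
    summarise(association_index =
                sum(.data$share[.data$fraction_index %in% target_frac]),
              .groups = "drop") |>
    mutate(target = paste(target, collapse = "+"), .before = "association_index")
}

#' Shift of a sedimentation distribution between two conditions
#'
#' Signed summary of how a protein's signal redistributes across the
#' gradient: the change in polysome-association index and the change in the
#' signal's centre of mass, in fraction-index units. A negative
#' centre-of-mass shift means movement toward lighter fractions (as seen
#' when ribosomes are dissociated with EDTA). Antisymmetric:
#' shift(a, b) = -shift(b, a).
#'
#' @param shares_a,shares_b Single-lane normalised tables (or tibbles with
#'   `fraction_index` and `share`) on the same fraction grid; `a` is the
#'   reference condition.
#' @param regions Optional fraction-to-region map for the index component.
#' @param target Region(s) for the association index.
#' @return One-row tibble (delta_association_index, delta_center_of_mass).
#' @export
sedimentation_shift <- function(shares_a, shares_b, regions = NULL,
                                target = "POLYSOMES") {
  check_columns(shares_a, c("fraction_index", "share"), "shares_a")
  check_columns(shares_b, c("fraction_index", "share"), "shares_b")
  a <- arrange(shares_a, .data$fraction_index)
  b <- arrange(shares_b, .data$fraction_index)
  if (!identical(a$fraction_index, b$fraction_index)) {
    abort("the two distributions are on different fraction grids")
  }
  com_a <- sum(a$fraction_index * a$share)
  com_b <- sum(b$fraction_index * b$share)
  regions <- regions %||% attr(shares_a, "fraction_regions") %||%
    attr(shares_b, "fraction_regions")
  d_idx <- NA_real_
  if (!is.null(regions)) {
    tf <- regions$fraction_index[regions$region %in% target]
    d_idx <- sum(b$share[b$fraction_index %in% tf]) -
      sum(a$share[a$fraction_index %in% tf])
  }
  tibble(delta_association_index = d_idx,
         delta_center_of_mass = com_b - com_a)
}
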