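#' Normalise paired polysomal/total count matrices
#'
#' Counts-per-million scaling per sample; with gene lengths supplied,
#' length-scaled normalisation (CPM further divided by kilobases, an
#' FPKM-style quantity).
#'
#' @param pair A `count_matrix_pair` (see [simulate_counts()]), or any list
#'   with matrices `pol` and `tot` and a `samples` tibble.
#' @param method "cpm" (default) or "length_scaled".
#' @param gene_lengths Named numeric vector of gene lengths in bases,
#'   required for `length_scaled`.
#' @return The pair with normalised numeric matrices and attribute
#'   `normalization` recording the method.
#' @export
normalize_expression <- function(pair, method = c("cpm", "length_scaled"),
                                 gene_lengths = NULL) {
  method <- match.arg(method)
  norm_one <- function(m) {
    lib <- colSums(m)
    if (any(lib <= 0)) abort("library sizes must be > 0")
    out <- sweep(m, 2, lib, "/") * 1e6
    if (method == "length_scaled") {
      if (is.null(gene_lengths)) {
        abort("length_scaled normalisation requires gene_lengths")
      }
      len <- gene_lengths[rownames(m)]
      if (anyNA(len)) abort("gene_lengths missing for some genes")
      out <- out / (len / 1e3)
    }
    out
  }
  pair$pol <- norm_one(pair$pol)
  pair$tot <- norm_one(pair$tot)
  attr(pair, "normalization") <- method
  pair
}

#' Per-gene, per-sample log2 translation efficiency
#'
#' TE is the polysomal-to-total abundance ratio of a transcript:
#' log2((pol + pseudo) / (tot + pseudo)) on normalised expression. The
#' pseudo-count keeps log-ratios finite at zero counts with minimal bias at
#' moderate depth.
#'
#' @param pol,tot Normalised matrices (genes x samples, matched columns), or
#'   pass a normalised pair as `pol` and leave `tot` missing.
#' @param pseudo Pseudo-count in normalised units (default 0.5).
#' @param samples Optional sample-metadata tibble (sample, group); taken
#'   from the pair when one is passed.
#' @return A `te_matrix`: list(log2te = genes x samples matrix, samples).
#' @export
compute_te <- function(pol, tot = NULL, pseudo = 0.5, samples = NULL) {
  if (is.null(tot) && is.list(pol) && !is.null(pol$pol)) {
    samples <- samples %||% pol$samples
    tot <- pol$tot; pol <- pol$pol
  }
  if (any(pol < 0) || any(tot < 0)) abort("expression values must be >= 0")
  if (!identical(dim(pol), dim(tot))) abort("pol and tot must have matched dimensions")
  structure(list(log2te = log2((pol + pseudo) / (tot + pseudo)),
                 samples = samples),
            class = "te_matrix")
}

# all case/control label assignments as a weight matrix: column j has
# +1/n_case on that assignment's case samples and -1/n_ctrl elsewhere, so
# X %*% W gives the difference of group means under every assignment
assignment_weights <- function(n, n_case, n_permutations, exhaustive) {
  if (exhaustive) {
    sets <- combn(n, n_case)
  } else {
    sets <- replicate(n_permutations, sample.int(n, n_case))
  }
  w <- matrix(-1 / (n - n_case), nrow = n, ncol = ncol(sets))
  for (j in seq_len(ncol(sets))) w[sets[, j], j] <- 1 / n_case
  w
}

#' Permutation test for differential translation efficiency
#'
#' The field's dedicated tools for differential TE are external packages;
#' this function is a deliberately simple, fully documented stand-in: the
#' statistic is the difference of group-mean log2TE (case minus control),
#' and its null distribution comes from permuting sample labels once per
#' permutation, applied jointly to the polysomal and total compartments so
#' the POL/TOT pairing is preserved. Results are comparable to dedicated
#' tools in direction and ranking, not in exact p-values.
#'
#' When the number of distinct case/control label assignments is at most
#' 10,000 the null is enumerated exhaustively and the p-value is exact;
#' otherwise `n_permutations` random assignments are drawn and the two-sided
#' p-value uses the add-one correction. FDR is Benjamini-Hochberg across
#' genes; `significant` applies the raw p < `alpha` selection.
#'
#' @param te A `te_matrix` from [compute_te()], or a genes x samples log2TE
#'   matrix.
#' @param groups Character/factor of group labels per sample; taken from the
#'   te_matrix metadata when omitted.
#' @param case,control Labels of the two groups (contrast is case - control).
#' @param n_permutations Random permutations when enumeration is infeasible.
#' @param alpha Raw-p significance threshold (default 0.05).
#' @param seed Integer seed for the sampled-permutation branch.
#' @return A `te_result` tibble: gene, log2te_control, log2te_case, log2dte,
#'   p_value, fdr, direction, significant.
#' @export
test_delta_te <- function(te, groups = NULL, case = "case", control = "control",
                          n_permutations = 10000, alpha = 0.05, seed = 1) {
  if (inherits(te, "te_matrix")) {
    groups <- groups %||% te$samples$group
    te <- te$log2te
  }
  if (is.null(groups)) abort("`groups` is required")
  if (length(groups) != ncol(te)) abort("one group label per sample is required")
  if (!all(c(case, control) %in% groups)) {
    abort(sprintf("groups must contain both '%s' and '%s'", case, control))
  }
  if (n_permutations < 100) warn("fewer than 100 permutations: p-values will be coarse")

  keep <- groups %in% c(case, control)
  te <- te[, keep, drop = FALSE]
  groups <- groups[keep]
  n <- length(groups); n_case <- sum(groups == case)
  if (n_case < 2 || n - n_case < 2) warn("fewer than 2 samples in a group")

  # put case columns first so assignment 1..n_case is the observed labelling
  ord <- order(groups != case)
  te <- te[, ord, drop = FALSE]

  exhaustive <- choose(n, n_case) <= 10000
  if (!exhaustive) set.seed(seed)
  w <- assignment_weights(n, n_case, n_permutations, exhaustive)
  stat <- te %*% w
  obs <- te %*% c(rep(1 / n_case, n_case), rep(-1 / (n - n_case), n - n_case))

  tol <- 1e-12
  if (exhaustive) {
    p <- rowMeans(abs(stat) >= abs(as.vector(obs)) - tol)
  } else {
    p <- (1 + rowSums(abs(stat) >= abs(as.vector(obs)) - tol)) /
      (ncol(w) + 1)
  }

  mean_case <- rowMeans(te[, seq_len(n_case), drop = FALSE])
  mean_ctrl <- rowMeans(te[, -seq_len(n_case), drop = FALSE])
  out <- tibble(
    gene = rownames(te) %||% as.character(seq_len(nrow(te))),
    log2te_control = unname(mean_ctrl), log2te_case = unname(mean_case),
    log2dte = as.vector(obs),
    p_value = unname(p), fdr = unname(p.adjust(p, "BH")),
    direction = ifelse(as.vector(obs) >= 0, "up", "down"),
    significant = p < alpha
  )
  class(out) <- c("te_result", class(out))
  out
}

#' qPCR fold change by the delta-delta-Ct method
#'
#' Technical replicates are averaged first, per reaction. Per sample,
#' delta-Ct is the target Ct minus the arithmetic mean of the two
#' reference-gene Cts -- which on the expression scale normalises to the
#' geometric mean of the references (e.g. actin and cyclophilin A).
#' delta-delta-Ct is the mean delta-Ct of the case group minus the mean
#' delta-Ct of the control group, and the fold change is 2^(-ddCt).
#'
#' @param ct Long tibble (gene, sample, group, compartment,
#'   biological_replicate, technical_replicate, ct). A missing
#'   `technical_replicate` column is treated as a single technical replicate.
#' @param target_gene Target gene name(s).
#' @param reference_genes Two reference genes, required in every sample.
#' @param compartment "POL" or "TOT".
#' @param case,control Group labels.
#' @return Tibble (gene, compartment, fold_change, delta_delta_ct, n_case,
#'   n_control).
#' @export
qpcr_fold_change <- function(ct, target_gene,
                             reference_genes = c("Actb", "Ppia"),
                             compartment = c("POL", "TOT"),
                             case = "case", control = "control") {
  compartment <- match.arg(compartment)
  check_columns(ct, c("gene", "sample", "group", "compartment", "ct"), "ct table")
  if (any(ct$ct <= 0)) abort("Ct values must be > 0")
  d <- filter(ct, .data$compartment == !!compartment,
              .data$group %in% c(case, control))
  # technical replicates averaged before any biological aggregation
  d <- summarise(group_by(d, .data$gene, .data$sample, .data$group),
                 ct = mean(.data$ct), .groups = "drop")
  ref <- filter(d, .data$gene %in% reference_genes)
  ref_n <- summarise(group_by(ref, .data$sample), k = dplyr::n_distinct(.data$gene),
                     .groups = "drop")
  bad <- ref_n$sample[ref_n$k < length(reference_genes)]
  missing_all <- setdiff(unique(d$sample), ref_n$sample)
  bad <- c(bad, missing_all)
  if (length(bad) > 0) {
    abort(sprintf("reference gene(s) missing in sample(s): %s",
                  paste(unique(bad), collapse = ", ")))
  }
  ref_mean <- summarise(group_by(ref, .data$sample), ref_ct = mean(.data$ct),
                        .groups = "drop")
  purrr::map_dfr(target_gene, function(g) {
    tg <- filter(d, .data$gene == g)
    if (nrow(tg) == 0) abort(sprintf("target gene %s absent from the table", g))
    tg <- left_join(tg, ref_mean, by = "sample")
    tg <- mutate(tg, dct = .data$ct - .data$ref_ct)
    ddct <- mean(tg$dct[tg$group == case]) - mean(tg$dct[tg$group == control])
    tibble(gene = g, compartment = compartment,
           fold_change = 2^(-ddct), delta_delta_ct = ddct,
           n_case = sum(tg$group == case), n_control = sum(tg$group == control))
  })
}

#' log2 delta-TE from polysomal and total fold changes
#'
#' The change in translation efficiency measured by qPCR: the difference
#' between the fold change at the polysomal level and at the total level,
#' on the log2 scale (primary) or as a raw fold-change difference.
#'
#' @param fc_pol,fc_tot Positive fold changes (vectors recycle elementwise).
#' @param scale "log2" (default): log2(fc_pol) - log2(fc_tot); "raw":
#'   fc_pol - fc_tot.
#' @return Numeric delta-TE.
#' @export
qpcr_delta_te <- function(fc_pol, fc_tot, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  if (any(fc_pol <= 0) || any(fc_tot <= 0)) abort("fold changes must be > 0")
  if (scale == "log2") log2(fc_pol) - log2(fc_tot) else fc_pol - fc_tot
}

#' Overlap of differentially expressed gene sets across expression levels
#'
#' Summarises how transcriptome-level and translatome-level DEG calls (and
#' optionally differential-TE calls) intersect: shared genes, level-specific
#' genes, and overlap percentages relative to each list and as Jaccard.
#'
#' @param transcriptome,translatome Character vectors of significant genes,
#'   or tibbles with `gene` and logical `significant` columns.
#' @param te Optional third set (differential-TE genes), same forms.
#' @param universe Optional character vector; all sets must lie within it.
#' @return List: `sets` (shared / specific gene vectors) and `summary`
#'   (tibble of pairwise overlap counts and percentages).
#' @export
classify_degs <- function(transcriptome, translatome, te = NULL,
                          universe = NULL) {
  as_set <- function(x, what) {
    if (is.data.frame(x)) {
      check_columns(x, c("gene", "significant"), what)
      x$gene[x$significant]
    } else as.character(x)
  }
  sets <- list(transcriptome = as_set(transcriptome, "transcriptome"),
               translatome = as_set(translatome, "translatome"))
  if (!is.null(te)) sets$te <- as_set(te, "te")
  if (!is.null(universe)) {
    for (nm in names(sets)) {
      out_of <- setdiff(sets[[nm]], universe)
      if (length(out_of) > 0) {
        abort(sprintf("%s genes outside the shared universe: %s", nm,
                      paste(head(out_of, 5), collapse = ", ")))
      }
    }
  }
  pairs <- combn(names(sets), 2, simplify = FALSE)
  summary <- bind_rows(lapply(pairs, function(p) {
    a <- sets[[p[1]]]; b <- sets[[p[2]]]
    shared <- intersect(a, b)
    tibble(set_a = p[1], set_b = p[2],
           n_a = length(a), n_b = length(b), n_shared = length(shared),
           pct_of_a = if (length(a)) 100 * length(shared) / length(a) else NA_real_,
           pct_of_b = if (length(b)) 100 * length(shared) / length(b) else NA_real_,
           jaccard = if (length(union(a, b)))
             length(shared) / length(union(a, b)) else NA_real_)
  }))
  list(
    sets = list(shared = Reduce(intersect, sets),
                specific = purrr::imap(sets, function(s, nm) {
                  setdiff(s, unlist(sets[names(sets) != nm]))
                })),
    summary = summary
  )
}
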