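# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Greedy Ward agglomeration on unsquared distances, written directly from
# the Lance-Williams update: d(k, i+j) =
#   ((n_i+n_k) d(ik) + (n_j+n_k) d(jk) - n_k d(ij)) / (n_i+n_j+n_k)
# Returns the sequence of merge heights and the member sets at each merge.
ward_oracle <- function(z) {
  d <- as.matrix(dist(z))
  n <- nrow(d)
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  heights <- numeric(0)
  merges <- list()
  dd <- d
  diag(dd) <- Inf
  repeat {
    k <- length(active)
    if (k == 1) break
    ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    heights <- c(heights, dd[i, j])
    merges[[length(merges) + 1]] <- sort(c(active[[i]], active[[j]]))
    ni <- sizes[i]; nj <- sizes[j]
    new_d <- sapply(seq_len(k), function(m) {
      if (m == i || m == j) return(Inf)
      nm <- sizes[m]
      ((ni + nm) * dd[i, m] + (nj + nm) * dd[j, m] - nm * dd[i, j]) /
        (ni + nj + nm)
    })
    active[[i]] <- c(active[[i]], active[[j]])
    sizes[i] <- ni + nj
    dd[i, ] <- new_d; dd[, i] <- new_d
    dd <- dd[-j, -j, drop = FALSE]
    active <- active[-j]
    sizes <- sizes[-j]
    diag(dd) <- Inf
  }
  list(heights = heights, merges = merges)
}

# member sets at every merge of an hclust tree, sorted for comparison
hclust_merge_sets <- function(hc) {
  sets <- list()
  for (s in seq_len(nrow(hc$merge))) {
    members <- function(node) {
      if (node < 0) return(-node)
      sort(unlist(lapply(hc$merge[node, ], members)))
    }
    sets[[s]] <- sort(c(members(hc$merge[s, 1]), members(hc$merge[s, 2])))
  }
  sets
}

# numerical quadrature of a model's peak signal (baseline removed), split at
# inter-peak midpoints so narrow peaks are never missed by the integrator
quadrature_peak_area <- function(model) {
  f <- function(x) {
    polytrans:::gradient_signal(model, x) -
      (model$baseline_offset + model$baseline_slope * x)
  }
  ctr <- model$peak_centers
  cuts <- c(min(ctr) - 50, (head(ctr, -1) + tail(ctr, -1)) / 2, max(ctr) + 50)
  sum(vapply(seq_len(length(cuts) - 1), function(i) {
    stats::integrate(f, cuts[i], cuts[i + 1], subdivisions = 2000L,
                     rel.tol = 1e-10)$value
  }, numeric(1)))
}

# exhaustive two-sided permutation p for a difference of group means on a
# single gene, enumerating every case/control labelling
perm_p_oracle <- function(values, is_case) {
  n <- length(values)
  nc <- sum(is_case)
  obs <- mean(values[is_case]) - mean(values[!is_case])
  sets <- combn(n, nc)
  stats <- apply(sets, 2, function(s) {
    mean(values[s]) - mean(values[-s])
  })
  mean(abs(stats) >= abs(obs) - 1e-12)
}
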