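#' Tidy an FRP group-comparison test
#'
#' @param x A `frp_test` from [compare_frp()].
#' @param ... Unused.
#' @return One-row tibble (statistic, df, p_value, mean_a, mean_b,
#'   alternative, flag).
#' @export
tidy.frp_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         mean_a = x$mean_a, mean_b = x$mean_b,
         alternative = x$alternative, flag = x$flag)
}

#' @rdname tidy.frp_test
#' @export
glance.frp_test <- function(x, ...) tidy(x, ...)

#' Tidy a mouse clustering: one row per mouse with its flat cluster
#'
#' @param x A `mouse_clustering` from [cluster_mice()].
#' @param ... Unused.
#' @export
tidy.mouse_clustering <- function(x, ...) x$labels

#' @rdname tidy.mouse_clustering
#' @return For `glance()`: one row with n, k, and the final merge heights.
#' @export
glance.mouse_clustering <- function(x, ...) {
  h <- x$hclust$height
  tibble(n = nrow(x$labels), k = x$k,
         height_last = h[length(h)],
         height_ratio = if (length(h) >= 2) h[length(h)] / h[length(h) - 1]
         else NA_real_)
}
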