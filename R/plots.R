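#' Plot a cluster permutation test
#'
#' Draws the pointwise t statistic over time with the cluster-forming
#' threshold and shades significant clusters.
#'
#' @param object A `cluster_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_test <- function(object, ...) {
  df <- tibble(time_s = object$time_s, t = object$tstat)
  sig <- object$clusters[object$clusters$significant, , drop = FALSE]
  p <- ggplot(df, aes(x = .data$time_s, y = .data$t)) +
    geom_hline(yintercept = c(-object$threshold, object$threshold),
               linetype = "dashed", colour = "grey50") +
    geom_line() +
    labs(x = "time (s)", y = "t statistic",
         title = "Cluster permutation test")
  if (nrow(sig)) {
    p <- p + geom_rect(
      data = as_tibble(sig),
      aes(xmin = .data$start_s, xmax = .data$end_s),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "firebrick",
      inherit.aes = FALSE)
  }
  p
}

#' Plot per-contact or searchlight decoding results
#'
#' Mean NMCC per contact grouped by structure, colored by significance, with
#' the 0.5 chance level marked.
#'
#' @param results Tibble with `structure`, `mean_nmcc`, `significant`
#'   (output of [evaluate_contacts()] or [run_searchlight()]).
#' @return A ggplot.
#' @export
plot_decoding_results <- function(results) {
  ggplot(results, aes(x = .data$structure, y = .data$mean_nmcc,
                      colour = .data$significant)) +
    geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    geom_jitter(width = 0.15, height = 0) +
    coord_flip() +
    facet_wrap(~hemisphere) +
    labs(x = NULL, y = "mean NMCC", colour = "significant")
}

#' Plot pairwise method agreement
#'
#' @param agreement A `method_agreement` tibble from [compare_methods()].
#' @param ... Unused.
#' @return A ggplot bar chart of Jaccard indices per pair and hemisphere.
#' @export
autoplot.method_agreement <- function(agreement, ...) {
  ggplot(agreement, aes(x = .data$pair, y = .data$jaccard,
                        fill = .data$hemisphere)) +
    geom_col(position = "dodge") +
    ylim(0, 1) +
    labs(x = NULL, y = "Jaccard index", fill = NULL,
         title = "Agreement between contrast-detection methods")
}
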