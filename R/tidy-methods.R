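#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cluster model
#'
#' One row per SNV: assignment and distance to each centroid.
#' @param x An `mx_cluster_model`.
#' @param ... Unused.
#' @return A tibble: snv, cluster, dist_cluster_* columns.
#' @export
tidy.mx_cluster_model <- function(x, ...) {
  d <- x$distances
  colnames(d) <- paste0("dist_cluster_", seq_len(x$k))
  tibble::tibble(
    snv = names(x$assignment) %||% as.character(seq_along(x$assignment)),
    cluster = unname(x$assignment)
  ) %>%
    dplyr::bind_cols(tibble::as_tibble(d))
}

#' @rdname tidy.mx_cluster_model
#' @export
glance.mx_cluster_model <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_snvs = length(x$assignment),
    n_missing = x$n_missing,
    tot_withinss = x$tot_withinss,
    min_cluster_size = min(tabulate(x$assignment, x$k))
  )
}

#' Tidy a Firth logistic fit
#'
#' @param x An `mx_firth_fit`.
#' @param ... Unused.
#' @return A tibble: term, estimate, std.error, statistic, p.value.
#' @export
tidy.mx_firth_fit <- function(x, ...) {
  z <- x$coef / x$se
  tibble::tibble(
    term = names(x$coef),
    estimate = unname(x$coef),
    std.error = unname(x$se),
    statistic = unname(z),
    p.value = 2 * pnorm(-abs(unname(z)))
  )
}

#' @rdname tidy.mx_firth_fit
#' @export
glance.mx_firth_fit <- function(x, ...) {
  tibble::tibble(
    logLik_penalized = x$loglik_penalized,
    iter = x$iter,
    converged = x$converged
  )
}

#' Heat-map of cluster-phenotype temperatures
#'
#' Tiles of `sign(gamma) * (-log10 P)` per (cluster, phenotype).
#' @param object An `mx_cluster_profile` from
#'   [cluster_phenotype_association()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mx_cluster_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$cluster), y = .data$phenotype,
                               fill = .data$temperature)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "cluster", y = NULL,
                  fill = expression(sign(gamma) %.% -log[10] * P)) +
    ggplot2::theme_minimal()
}

#' Plot axes of genetic variation
#'
#' Scatter of study coordinates on two axes, coloured by ancestry when a
#' study-metadata tibble is supplied.
#' @param axes An `mx_axes` tibble from [compute_axes()].
#' @param study_meta Optional tibble (study, ancestry).
#' @param dims Axis pair to display (default 1:2).
#' @return A ggplot object.
#' @export
plot_axes <- function(axes, study_meta = NULL, dims = 1:2) {
  df <- axes
  if (!is.null(study_meta)) {
    df <- dplyr::left_join(df, study_meta[, c("study", "ancestry")], by = "study")
  }
  xcol <- paste0("axis", dims[1])
  ycol <- paste0("axis", dims[2])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[xcol]], y = .data[[ycol]]))
  p <- if ("ancestry" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$ancestry), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = xcol, y = ycol) + ggplot2::theme_minimal()
}

#' Quantile-quantile plot of association P values
#'
#' Observed versus expected -log10 P with the genomic-control lambda in
#' the subtitle.
#' @param pvalues Numeric vector of P values.
#' @return A ggplot object.
#' @export
plot_qq <- function(pvalues) {
  n <- length(pvalues)
  df <- tibble::tibble(
    expected = -log10(stats::ppoints(n)),
    observed = -log10(sort(pvalues))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10] * P),
                  y = expression(Observed ~ -log[10] * P),
                  subtitle = sprintf("lambda[GC] = %.3f",
                                     genomic_control_lambda(pvalues))) +
    ggplot2::theme_minimal()
}

#' Bar plot of partitioned-score outcome associations
#'
#' Effect (log-OR or years) per SD of each score with 95% confidence bars.
#' @param ps_results Tibble from [associate_outcome()] (optionally several
#'   outcomes bound together).
#' @return A ggplot object.
#' @export
plot_ps_results <- function(ps_results) {
  ggplot2::ggplot(ps_results,
                  ggplot2::aes(x = .data$score, y = .data$estimate)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - 1.96 * .data$se,
                                        ymax = .data$estimate + 1.96 * .data$se),
                           width = 0.25) +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(x = NULL, y = "effect per SD of score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
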