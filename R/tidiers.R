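# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy an AMOVA result
#'
#' @param x `ssr_amova` object.
#' @param ... ignored.
#' @return the variance-partition table as a tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.ssr_amova <- function(x, ...) x$table

#' One-row AMOVA summary
#'
#' @param x `ssr_amova` object.
#' @param ... ignored.
#' @return tibble with the three F-statistics and their p-values.
#' @export
#' @exportS3Method generics::glance
glance.ssr_amova <- function(x, ...) {
  tibble::tibble(f_ct = x$f_ct, f_sc = x$f_sc, f_st = x$f_st,
                 p_ct = x$table$p[1], p_sc = x$table$p[2],
                 p_st = x$table$p[3], n_perm = x$n_perm)
}

#' @export
#' @exportS3Method generics::tidy
tidy.ssr_outlier_chain <- function(x, ...) {
  tibble::tibble(locus = rep(x$loci, each = nrow(x$alpha)),
                 state = rep(seq_len(nrow(x$alpha)), length(x$loci)),
                 alpha = as.vector(x$alpha),
                 included = as.vector(x$included) == 1)
}

#' @export
#' @exportS3Method generics::tidy
tidy.ssr_structure <- function(x, ...) {
  tidyr::pivot_longer(x$q_table, dplyr::starts_with("cluster"),
                      names_to = "cluster", values_to = "q")
}

#' @export
#' @exportS3Method generics::glance
glance.ssr_structure <- function(x, ...) {
  tibble::tibble(k = x$K, lnp = x$lnP, mean_loglik = x$mean_loglik,
                 var_loglik = x$var_loglik, alpha = x$alpha)
}

#' @export
#' @exportS3Method generics::tidy
tidy.ssr_dapc <- function(x, ...) {
  dplyr::bind_cols(x$individuals, x$pc_scores, x$ld_scores,
                   tibble::tibble(assigned = x$assigned))
}

#' @export
#' @exportS3Method generics::glance
glance.ssr_dapc <- function(x, ...) {
  tibble::tibble(n_pcs = x$n_pcs,
                 n_axes = ncol(x$ld_scores),
                 accuracy = mean(x$assigned == x$groups))
}

#' @export
#' @exportS3Method generics::tidy
tidy.ssr_abc <- function(x, ...) x$table

#' @export
#' @exportS3Method generics::glance
glance.ssr_abc <- function(x, ...) {
  best <- which.max(x$table$marginal_density)
  second <- order(x$table$marginal_density, decreasing = TRUE)[2]
  tibble::tibble(best = x$best,
                 relative_density = x$table$relative_density[best],
                 bayes_factor_vs_next =
                   x$table$marginal_density[best] /
                   x$table$marginal_density[second])
}

#' @export
#' @exportS3Method generics::tidy
tidy.ssr_dbrda <- function(x, ...) x$tests

#' @export
#' @exportS3Method generics::glance
glance.ssr_dbrda <- function(x, ...) {
  tibble::tibble(total_inertia = x$total_inertia,
                 constrained_prop = x$constrained_prop,
                 adj_r2 = x$adj_r2, r2 = x$r2, n_perm = x$n_perm)
}

#' Membership barplot of a clustering run
#'
#' @param object `ssr_structure` result.
#' @param ... ignored.
#' @return ggplot object (stacked per-individual memberships, grouped
#'   by population).
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.ssr_structure <- function(object, ...) {
  d <- tidy(object)
  d$individual <- factor(d$individual, levels = unique(d$individual))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$individual, y = .data$q,
                                  fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(~population, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "membership") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing = ggplot2::unit(0.1, "lines"))
}

#' Evanno delta-K profile
#'
#' @param object `ssr_deltak` table.
#' @param ... ignored.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.ssr_deltak <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$delta_k)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "K", y = expression(Delta * K)) +
    ggplot2::theme_minimal()
}

#' DAPC scatter of the discriminant axes
#'
#' @param object `ssr_dapc` result.
#' @param ... ignored.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.ssr_dapc <- function(object, ...) {
  d <- tidy(object)
  if ("LD2" %in% names(d)) {
    ggplot2::ggplot(d, ggplot2::aes(.data$LD1, .data$LD2,
                                    colour = .data$population)) +
      ggplot2::geom_point() + ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(.data$LD1, fill = .data$population)) +
      ggplot2::geom_histogram(bins = 30, position = "identity",
                              alpha = 0.6) +
      ggplot2::theme_minimal()
  }
}

#' Relative-density barplot of an ABC model comparison
#'
#' @param object `ssr_abc` result.
#' @param ... ignored.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.ssr_abc <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$model,
                               y = .data$relative_density)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "scenario", y = "relative density (%)") +
    ggplot2::theme_minimal()
}

#' Outlier-scan decision plot (posterior odds vs locus effect)
#'
#' @param object `ssr_outlier` report.
#' @param po_threshold decision threshold drawn as a reference line.
#' @param ... ignored.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.ssr_outlier <- function(object, po_threshold = 10, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$alpha,
                                       y = log10(.data$po + 1e-3),
                                       colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = log10(po_threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = "posterior mean alpha", y = "log10 posterior odds") +
    ggplot2::theme_minimal()
}

#' Site scores of a constrained ordination
#'
#' @param object `ssr_dbrda` result.
#' @param groups optional vector of group labels for colouring.
#' @param ... ignored.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.ssr_dbrda <- function(object, groups = NULL, ...) {
  d <- object$site_scores
  if (is.null(d)) stop("no site scores stored", call. = FALSE)
  names(d)[1:2] <- c("axis1", "axis2")
  if (!is.null(groups)) d$group <- groups
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$axis1, .data$axis2)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "dbRDA axis 1", y = "dbRDA axis 2")
  if (is.null(groups)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}
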