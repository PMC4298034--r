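# ggplot2 methods for the result objects.

#' Plot a multilocus prediction table
#'
#' Monte Carlo estimates (points with 95% CI bars) and exact analytic values
#' (lines) for each family and twin cell, against the number of loci.
#'
#' @param object A `dc_table2` from [reproduce_table2()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dc_table2 <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat$cell <- factor(dat$cell, levels = c(PARENT_LABELS, PAIR_LABELS))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$n_loci)) +
    ggplot2::geom_line(ggplot2::aes(y = 100 * .data$analytic), colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$cell), scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Number of loci", y = "Percent",
                  title = "Family and MZ twin predictions by number of loci")
  if ("estimate" %in% names(dat)) {
    p <- p +
      ggplot2::geom_pointrange(ggplot2::aes(
        y = 100 * .data$estimate,
        ymin = 100 * (.data$estimate - .data$ci_halfwidth),
        ymax = 100 * (.data$estimate + .data$ci_halfwidth)
      ), size = 0.2)
  }
  p
}

#' Plot Monte Carlo GWAS power
#'
#' Per-locus power with 95% CI bars and the any-locus power as a dashed
#' reference line.
#'
#' @param object A `dc_power` from [gwas_power_mc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dc_power <- function(object, ...) {
  dat <- object$per_locus
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$locus), y = .data$power)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data$power - .data$ci_halfwidth),
      ymax = pmin(1, .data$power + .data$ci_halfwidth)
    )) +
    ggplot2::geom_hline(yintercept = object$any_locus_power, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Locus", y = "Power",
      title = sprintf("GWAS power, %d cases / %d controls, alpha = %g",
                      object$design$n_cases, object$design$n_controls,
                      object$design$alpha),
      subtitle = sprintf("Dashed line: any-locus power %.4f", object$any_locus_power)
    )
}

#' Plot simulated family or twin estimates
#'
#' @param object A `dc_family_sim` or `dc_twin_sim` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dc_family_sim <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$parents, y = 100 * .data$p_left)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = 100 * (.data$p_left - .data$ci_halfwidth),
      ymax = 100 * (.data$p_left + .data$ci_halfwidth)
    ), width = 0.2) +
    ggplot2::labs(x = "Parental phenotypes", y = "Percent left-handed offspring")
}

#' @rdname autoplot.dc_family_sim
#' @export
autoplot.dc_twin_sim <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pair, y = 100 * .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = 100 * (.data$proportion - .data$ci_halfwidth),
      ymax = 100 * (.data$proportion + .data$ci_halfwidth)
    ), width = 0.2) +
    ggplot2::labs(x = "Twin pair", y = "Percent of pairs",
                  title = sprintf("%s twin pairs", dat$zygosity[[1]]))
}

#' Plot model predictions against observed proportions
#'
#' @param comparison A tibble from [compare_observed()].
#' @return A ggplot with predicted and observed proportions side by side;
#'   observed values carry binomial standard-error bars where the published
#'   denominator is known.
#' @export
plot_model_vs_observed <- function(comparison) {
  dat <- tidyr::pivot_longer(
    comparison, c("predicted", "observed"),
    names_to = "kind", values_to = "proportion"
  )
  dat$se <- ifelse(dat$kind == "observed", dat$observed_se, NA_real_)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$measure, y = 100 * .data$proportion,
                                    fill = .data$kind)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = 100 * (.data$proportion - 1.96 * .data$se),
      ymax = 100 * (.data$proportion + 1.96 * .data$se)
    ), position = ggplot2::position_dodge(width = 0.8), width = 0.2, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "Percent", fill = NULL,
                  title = "Model predictions vs observed proportions")
}
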