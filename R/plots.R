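#' Plot a potential-of-mean-force curve
#'
#' @param object An `iface_pmf`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot iface_pmf
#' @export
autoplot.iface_pmf <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            cols = c("dF_cumulant", "dF_exponential"),
                            names_to = "estimator", values_to = "dF")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda_A, y = .data$dF,
                                   colour = .data$estimator)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pulled distance (Å)",
                  y = expression(Delta * F ~ "(kcal/mol)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-contact MSFD profile across conditions
#'
#' One point per interface contact (ordered by region then residue number),
#' coloured by condition label — the standard way to eyeball which interface
#' regions gain flexibility between conditions.
#'
#' @param tables A list of `iface_msfd_table`s over one contact universe.
#' @return A ggplot.
#' @export
plot_msfd <- function(tables) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  df <- dplyr::bind_rows(lapply(tables, as_tibble)) |>
    dplyr::arrange(.data$region, .data$resno_b, .data$resno_a) |>
    dplyr::mutate(contact = paste0(.data$resno_a, "-", .data$resno_b))
  df$contact <- factor(df$contact, levels = unique(df$contact))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contact, y = .data$msfd,
                                   colour = .data$label,
                                   group = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_grid(. ~ region, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "interface contact", y = "MSFD (Å²)",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Averaged force-distance profile plot
#'
#' @param profiles Named list of force-distance tibbles
#'   (from [force_distance_profile()]), one per condition.
#' @return A ggplot.
#' @export
plot_force_distance <- function(profiles) {
  if (inherits(profiles, "data.frame")) profiles <- list(profile = profiles)
  df <- dplyr::bind_rows(profiles, .id = "label")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_A,
                                   y = .data$force_kcal_mol_A,
                                   colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "midpoint displacement (Å)",
                  y = "mean trap force (kcal/mol/Å)", colour = NULL) +
    ggplot2::theme_minimal()
}
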