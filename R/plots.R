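# ggplot2 quick-look graphics for the main result types.

#' Plot concentration time courses
#'
#' @param traj a `pbpk_trajectory` or `coupled_trajectory`.
#' @param species species to show (default all).
#' @param compartments compartments to show (default venous blood and
#'   liver).
#' @param every thinning of time points.
#' @return a ggplot.
#' @export
plot_trajectory <- function(traj, species = NULL,
                            compartments = c("venous_blood", "liver"),
                            every = 1L) {
  tb <- trajectory_tbl(traj, every = every)
  if (!is.null(species)) tb <- tb[tb$species %in% species, ]
  tb <- tb[tb$compartment %in% compartments, ]
  ggplot2::ggplot(tb, ggplot2::aes(
    x = .data$time_min / 60, y = .data$concentration_uM,
    colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time [h]", y = "concentration [µM]",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.pbpk_trajectory <- function(object, ...) {
  plot_trajectory(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot exchange-flux time courses of a coupled run
#'
#' @param traj a `coupled_trajectory`.
#' @param reactions reaction ids (default: the exchange reactions).
#' @return a ggplot.
#' @export
plot_flux_series <- function(traj, reactions = NULL) {
  stopifnot(inherits(traj, "coupled_trajectory"))
  fl <- traj$fluxes[!is.na(traj$fluxes$flux), ]
  if (is.null(reactions)) {
    rx <- traj$multiscale$network$reactions
    reactions <- rx$id[rx$is_exchange]
  }
  fl <- fl[fl$reaction %in% reactions, ]
  ggplot2::ggplot(fl, ggplot2::aes(x = .data$time_min / 60,
                                   y = .data$flux,
                                   colour = .data$reaction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [h]", y = "flux [µmol/L/min]",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an objective-panel robustness report
#'
#' Bars show the relative decrease of each affected objective; facets
#' over time points when the report carries them.
#'
#' @param report a `panel_report` (possibly stacked over time points).
#' @param affected_only show only affected objectives (default TRUE).
#' @return a ggplot.
#' @export
plot_panel_report <- function(report, affected_only = TRUE) {
  df <- tibble::as_tibble(report)
  if (affected_only) df <- df[df$affected, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$objective,
                                        y = .data$decrease)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "relative decrease of optimum") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if ("time_point" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~time_point)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.panel_report <- function(object, ...) {
  plot_panel_report(object, ...)
}

#' Plot cohort biomarker distributions
#'
#' Empirical distributions of the healthy and diseased steady-state
#' endpoints of a virtual population.
#'
#' @param cohort tibble from [run_cohort()].
#' @return a ggplot.
#' @export
plot_cohort <- function(cohort) {
  long <- tidyr::pivot_longer(cohort, c("healthy_uM", "diseased_uM"),
                              names_to = "state", values_to = "uM")
  long$state <- sub("_uM$", "", long$state)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$uM, fill = .data$state)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity",
                            bins = 20) +
    ggplot2::labs(x = "venous ammonia [µM]", y = "individuals",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
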