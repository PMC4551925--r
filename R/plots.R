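# ggplot2 views of trajectories and knot traces.

#' Plot the observables of a trajectory
#'
#' Panels for the potential-energy terms and for the twist/writhe balance
#' against time (tau).
#'
#' @param traj an `sc_trajectory`.
#' @param terms which energy terms to draw.
#' @return a ggplot object.
#' @export
plot_observables <- function(traj, terms = c("E_pot", "E_kin")) {
  obs <- traj$observables
  long <- do.call(rbind, lapply(intersect(terms, names(obs)), function(tm)
    data.frame(time = obs$time, value = obs[[tm]], series = tm)))
  topol <- do.call(rbind, lapply(intersect(c("Tw1", "Wr1", "Lk12"),
                                           names(obs)), function(tm)
    data.frame(time = obs$time, value = obs[[tm]], series = tm)))
  long$panel <- "energy (eps)"
  topol$panel <- "topology (turns)"
  d <- rbind(long, topol)
  ggplot2::ggplot(d, ggplot2::aes(x = time, y = value, colour = series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (tau)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a knot-position trace
#'
#' Contour distance of the knot core to the nick/gap site against time, with
#' the core length as a secondary series.
#'
#' @param trace output of [knot_position_trace()].
#' @return a ggplot object.
#' @export
plot_knot_trace <- function(trace) {
  d <- rbind(data.frame(time = trace$time, value = trace$distance,
                        series = "distance to site (units)"),
             data.frame(time = trace$time, value = trace$core_length,
                        series = "knot core length (units)"))
  ggplot2::ggplot(d, ggplot2::aes(x = time, y = value, colour = series)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (tau)", y = "repeat units", colour = NULL) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("time", "value", "series"))
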