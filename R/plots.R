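# ggplot2 autoplot methods for the main result types.

#' Plot an MSD profile
#'
#' MSD against lag time, with a ribbon of +/- 1 block SEM where available.
#'
#' @param object An `"msd_profile"` from [compute_msd()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msd_profile
#' @export
autoplot.msd_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_ns, y = .data$msd))
  if (any(is.finite(object$sem))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$msd - .data$sem, ymax = .data$msd + .data$sem),
      alpha = 0.25
    )
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ns)", y = expression(MSD ~ (ring(A)^2)))
}

#' Plot a radial distribution function
#'
#' @param object An `"rdf_profile"` from [compute_rdf()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rdf_profile
#' @export
autoplot.rdf_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = expression(r ~ (ring(A))), y = "g(r)")
}

#' Plot a time series
#'
#' @param object A `"time_series"` tibble (RMSD, Rg, distances, counts).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot time_series
#' @export
autoplot.time_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ns, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (ns)",
      y = paste0(attr(object, "label") %||% "value",
                 if (nzchar(attr(object, "units") %||% "")) {
                   paste0(" (", attr(object, "units"), ")")
                 } else "")
    )
}

#' Plot per-residue RMSF
#'
#' @param object An `"rmsf_profile"` from [compute_rmsf()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rmsf_profile
#' @export
autoplot.rmsf_profile <- function(object, ...) {
  xvar <- if ("resid" %in% names(object)) "resid" else "index"
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[xvar]], y = .data$rmsf)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xvar, y = expression(RMSF ~ (ring(A))))
}

#' Plot per-frame contact counts
#'
#' @param object A `"contact_counts"` tibble from [count_contacts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contact_counts
#' @export
autoplot.contact_counts <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object), c("hbond", "saltbridge", "vdw", "total"),
    names_to = "class", values_to = "count"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ns, y = .data$count,
                                     colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = "contacts")
}

#' Plot a binding-energy series
#'
#' @param object An `"energy_series"` from [binding_energy_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot energy_series
#' @export
autoplot.energy_series <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object), c("E_coulomb", "E_lj", "G_gb", "G_np", "total"),
    names_to = "component", values_to = "energy"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ns, y = .data$energy,
                                     colour = .data$component)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time (ns)", y = "energy (kcal/mol)")
}
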