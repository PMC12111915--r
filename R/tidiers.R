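# broom-style tidiers for fitted/result objects.

#' Tidy a diffusion fit
#'
#' @param x A `"diffusion_fit"` from [fit_diffusion()].
#' @param ... Unused.
#' @return One-row tibble: `D`, `fit_slope`, `fit_intercept`, the fit
#'   window, dimensionality and fit diagnostics.
#' @method tidy diffusion_fit
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble(
    D = x$D, fit_slope = x$fit_slope, fit_intercept = x$fit_intercept,
    fit_from_ns = x$fit_range_ns[1], fit_to_ns = x$fit_range_ns[2],
    d = x$d, n_points = x$n_points, negative_fit = x$negative_fit,
    r_squared = x$r_squared
  )
}

#' @rdname tidy.diffusion_fit
#' @method glance diffusion_fit
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble(D = x$D, r_squared = x$r_squared, n_points = x$n_points,
         negative_fit = x$negative_fit)
}

#' Tidy a group comparison
#'
#' @param x A `"group_comparison"` from [compare_groups()].
#' @param ... Unused.
#' @return `tidy()`: per-group tibble (n, mean, sd, normality p).
#'   `glance()`: one row with the omnibus test, statistic, p-value and
#'   stars.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$per_group

#' @rdname tidy.group_comparison
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(test_used = x$test_used, statistic = x$statistic,
         p_value = x$p_value, stars = x$stars,
         n_groups = nrow(x$per_group))
}

#' Tidy a superposition result
#'
#' @param x A `"superposition"` from [kabsch_superpose()].
#' @param ... Unused.
#' @return One-row tibble with the rmsd, rotation determinant and
#'   translation components.
#' @method tidy superposition
#' @export
tidy.superposition <- function(x, ...) {
  tibble(
    rmsd = x$rmsd, det_rotation = det(x$rotation),
    t_x = x$translation[1], t_y = x$translation[2], t_z = x$translation[3]
  )
}

#' Summarise a time series or energy series
#'
#' @param x A `"time_series"` or `"energy_series"` tibble.
#' @param n_blocks Blocks for the SEM.
#' @param ... Unused.
#' @return One-row tibble with block-averaged mean and SEM (per component
#'   for an energy series).
#' @method glance time_series
#' @export
glance.time_series <- function(x, n_blocks = 5L, ...) {
  s <- block_average(x$value, n_blocks = min(n_blocks, nrow(x)))
  tibble(mean = s$mean, sem = s$sem, n = s$n,
         label = attr(x, "label") %||% "", units = attr(x, "units") %||% "")
}

#' @rdname glance.time_series
#' @method glance energy_series
#' @export
glance.energy_series <- function(x, n_blocks = 5L, ...) {
  nb <- max(2L, min(n_blocks, nrow(x)))
  comp <- c("E_coulomb", "E_lj", "G_gb", "G_np", "total")
  out <- lapply(comp, function(cl) {
    if (nrow(x) >= nb) {
      s <- block_average(x[[cl]], n_blocks = nb)
      tibble(component = cl, mean = s$mean, sem = s$sem)
    } else {
      tibble(component = cl, mean = mean(x[[cl]]), sem = NA_real_)
    }
  })
  bind_rows(out)
}
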