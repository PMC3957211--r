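#' Tidy a trained network into a module table
#'
#' @param x A `polysnn_net`.
#' @param ... Unused.
#' @return Tibble with one row per configured delay path: `module`,
#'   `pattern`, `input`, `path`, `output`, `delay_ms`, `target_ms`.
#' @export
tidy.polysnn_net <- function(x, ...) {
  n <- x$n_configured
  idx <- rep(seq_len(n), each = 4L)
  path <- rep(1:4, n)
  keep <- path <= x$nout[idx]
  tibble(
    module = idx[keep],
    pattern = x$module_pattern[idx[keep]],
    input = x$input[idx[keep]],
    path = path[keep],
    output = as.integer(t(x$out))[keep],
    delay_ms = as.numeric(t(x$delay))[keep],
    target_ms = as.numeric(t(x$target))[keep]
  )
}

#' One-row summary of a trained network
#'
#' @param x A `polysnn_net`.
#' @param ... Unused.
#' @return Tibble with the network dimensions, configured module count and
#'   remaining pattern capacity.
#' @export
glance.polysnn_net <- function(x, ...) {
  tibble(
    backend = x$config$backend,
    n_neurons = x$config$n_neurons,
    n_axon_modules = x$config$n_axon_modules,
    n_configured = x$n_configured,
    n_patterns = x$n_patterns,
    mode = x$mode,
    modules_free = x$config$n_axon_modules - x$n_configured
  )
}

#' Tidy a recall run into its emitted spike train
#'
#' @param x A `polysnn_recall`.
#' @param ... Unused.
#' @return Tibble `time_ms`, `neuron`.
#' @export
tidy.polysnn_recall <- function(x, ...) x$spikes

#' One-row summary of a recall run
#'
#' @param x A `polysnn_recall`.
#' @param ... Unused.
#' @export
glance.polysnn_recall <- function(x, ...) {
  tibble(n_emitted = nrow(x$spikes), all_firing = x$all_firing,
         n_events = x$n_events, n_dropped = x$n_dropped,
         t0 = x$t0, initiation = x$initiation, engine = x$engine)
}

#' Plot a size-sweep result
#'
#' Bar chart of mean recall percentage per neuron-array size with standard
#' -error bars.
#'
#' @param object A [run_size_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polysnn_size_sweep <- function(object, ...) {
  s <- object |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(mean = mean(.data$pct_recalled),
                     se = stats::sd(.data$pct_recalled) / sqrt(dplyr::n()))
  ggplot2::ggplot(s, ggplot2::aes(factor(.data$size), .data$mean)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      width = 0.2) +
    ggplot2::labs(x = "neuron array size", y = "% patterns recalled") +
    ggplot2::ylim(0, 100)
}

#' Plot a capacity-experiment result
#'
#' @param object A [run_capacity_experiment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polysnn_capacity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(factor(.data$run),
                                       .data$pct_recalled)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "run", y = "% patterns recalled") +
    ggplot2::ylim(0, 100)
}

#' Plot a noise-sweep result
#'
#' @param object A [run_noise_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polysnn_noise_sweep <- function(object, ...) {
  s <- object |>
    dplyr::group_by(.data$rate) |>
    dplyr::summarise(mean = mean(.data$pct_recalled),
                     se = stats::sd(.data$pct_recalled) / sqrt(dplyr::n()))
  ggplot2::ggplot(s, ggplot2::aes(factor(.data$rate), .data$mean)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      width = 0.2) +
    ggplot2::labs(x = "noise rate (spikes/s, whole network)",
                  y = "% patterns recalled") +
    ggplot2::ylim(0, 100)
}

#' Plot an imperfection-experiment result
#'
#' Per-pattern recalled spike fractions by pattern length and training
#' mode.
#'
#' @param object A [run_axon_imperfection_experiment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polysnn_imperfection <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(factor(.data$length),
                                       100 * .data$fraction,
                                       fill = .data$mode)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "pattern length (spikes)", y = "% spikes recalled",
                  fill = "training")
}
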