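#' Neuron-array size sweep at full axon capacity
#'
#' Trains a full complement of random patterns (by default 82 patterns of
#' 51 spikes, one axon module per spike) into networks of increasing
#' virtual-neuron count and recalls every pattern from its first
#' `initiation` spikes.  Small arrays suffer catastrophic cross-talk (the
#' all-firing state); larger arrays dilute the per-neuron connection load
#' and approach perfect recall.
#'
#' @param sizes Neuron-array sizes to test.
#' @param n_patterns,pattern_length Pattern set dimensions.
#' @param n_runs Independent seeded runs per size.
#' @param mode Training mode, `"programming"` or `"adaptation"`.
#' @param seed Master seed; per-run seeds are derived from it.
#' @param ... Further arguments to [network_config()].
#' @return Tibble (`polysnn_size_sweep`) with one row per (size, run):
#'   `pct_recalled`, `pct_all_firing`, `mean_fraction`.
#' @export
run_size_sweep <- function(sizes = c(128, 256, 512, 1024),
                           n_patterns = 82, pattern_length = 51,
                           n_runs = 10, mode = "programming", seed = 1,
                           ...) {
  grid <- tidyr::expand_grid(size = sizes, run = seq_len(n_runs))
  seeds <- withr::with_seed(seed,
    matrix(sample.int(2^30, length(sizes) * n_runs), nrow = length(sizes)))
  out <- purrr::pmap(grid, function(size, run) {
    s <- seeds[match(size, sizes), run]
    pats <- generate_patterns(n_patterns, pattern_length, size, seed = s)
    cfg <- network_config(n_neurons = size,
                          n_axon_modules = n_patterns * pattern_length, ...)
    net <- train(cfg, pats, mode = mode, seed = s + 1L)
    sc <- recall_patterns(net, pats, seed = s + 2L)
    tibble(size = size, run = run,
           pct_recalled = 100 * mean(sc$success),
           pct_all_firing = 100 * mean(sc$all_firing),
           mean_fraction = mean(sc$fraction))
  })
  structure(dplyr::bind_rows(out),
            class = c("polysnn_size_sweep", class(tibble())))
}

#' Storage-capacity experiment
#'
#' Trains a large pattern load (by default 1200 patterns of 51 spikes on a
#' 4k-neuron, 80k-module configuration) and reports the percentage of
#' patterns successfully recalled per run.
#'
#' @param n_patterns Number of stored patterns.
#' @param pattern_length Spikes per pattern.
#' @param n_neurons,n_modules Network dimensions.
#' @param n_runs Independent seeded runs.
#' @param mode Training mode.
#' @param seed Master seed.
#' @param ... Further arguments to [network_config()].
#' @return Tibble (`polysnn_capacity`) with `run`, `pct_recalled`,
#'   `pct_all_firing`, `mean_fraction`.
#' @export
run_capacity_experiment <- function(n_patterns = 1200, pattern_length = 51,
                                    n_neurons = 4096, n_modules = 81920,
                                    n_runs = 3, mode = "programming",
                                    seed = 1, ...) {
  seeds <- withr::with_seed(seed, sample.int(2^30, n_runs))
  out <- purrr::map(seq_len(n_runs), function(run) {
    s <- seeds[run]
    pats <- generate_patterns(n_patterns, pattern_length, n_neurons, seed = s)
    cfg <- network_config(n_neurons = n_neurons, n_axon_modules = n_modules,
                          ...)
    net <- train(cfg, pats, mode = mode, seed = s + 1L)
    sc <- recall_patterns(net, pats, seed = s + 2L)
    tibble(run = run, pct_recalled = 100 * mean(sc$success),
           pct_all_firing = 100 * mean(sc$all_firing),
           mean_fraction = mean(sc$fraction))
  })
  structure(dplyr::bind_rows(out),
            class = c("polysnn_capacity", class(tibble())))
}

#' Noise-robustness sweep
#'
#' Recalls a trained pattern set while injecting a network-level Poisson
#' noise train (extra spikes on random neurons and synapse lines) at rates
#' from a few to over a hundred spikes per second — for comparison, a
#' stored pattern itself runs at about 100 spikes per second.
#'
#' @param rates Poisson rates, spikes per second over the whole network.
#' @param n_patterns,pattern_length Pattern set dimensions.
#' @param n_neurons Network size.
#' @param n_runs Seeded runs per rate.
#' @param mode Training mode.
#' @param seed Master seed.
#' @param ... Further arguments to [network_config()].
#' @return Tibble (`polysnn_noise_sweep`) with `rate`, `run`,
#'   `pct_recalled`, `mean_fraction`.
#' @export
run_noise_sweep <- function(rates = c(2, 8, 32, 128),
                            n_patterns = 82, pattern_length = 51,
                            n_neurons = 4096, n_runs = 3,
                            mode = "programming", seed = 1, ...) {
  grid <- tidyr::expand_grid(rate = rates, run = seq_len(n_runs))
  seeds <- withr::with_seed(seed, sample.int(2^30, nrow(grid)))
  out <- purrr::pmap(cbind(grid, s = seeds), function(rate, run, s) {
    pats <- generate_patterns(n_patterns, pattern_length, n_neurons, seed = s)
    cfg <- network_config(n_neurons = n_neurons,
                          n_axon_modules = n_patterns * pattern_length, ...)
    net <- train(cfg, pats, mode = mode, seed = s + 1L)
    dur <- max(pats$time_ms) + 200
    noise <- generate_noise(rate, dur, n_neurons, seed = s + 2L)
    sc <- recall_patterns(net, pats, noise = noise, seed = s + 3L)
    tibble(rate = rate, run = run,
           pct_recalled = 100 * mean(sc$success),
           mean_fraction = mean(sc$fraction))
  })
  structure(dplyr::bind_rows(out),
            class = c("polysnn_noise_sweep", class(tibble())))
}

#' Analog-axon imperfection experiment
#'
#' Reproduces the analog-axon test protocol: a 100-module axon array and
#' digital neurons, loaded to capacity with disjoint (zero-overlap) random
#' patterns of a given length.  In programming mode each stored delay
#' carries the relative programming error; in adaptation mode the
#' programming pass is followed by fixed-step STDDP iterations, leaving the
#' residual emission jitter as the dominant error.  Reported per pattern is
#' the fraction of its spikes recalled within the scoring tolerance.
#'
#' @param lengths Pattern lengths to test.
#' @param modes Training modes to compare.
#' @param n_modules Axon-array size.
#' @param n_neurons Neuron-array size (the 4-of-9 bus addresses 126).
#' @param n_runs Seeded runs per (mode, length).
#' @param adapt_iterations Fixed-step iterations in adaptation mode.
#' @param adapt_step Fixed adaptation step, ms.
#' @param imperfection The [imperfection_model()] to emulate.
#' @param seed Master seed.
#' @return Tibble (`polysnn_imperfection`) with one row per recalled
#'   pattern: `mode`, `length`, `run`, `pattern`, `fraction`.
#' @export
run_axon_imperfection_experiment <- function(lengths = c(20, 25, 33, 50),
                                             modes = c("programming",
                                                       "adaptation"),
                                             n_modules = 100, n_neurons = 126,
                                             n_runs = 40,
                                             adapt_iterations = 20,
                                             adapt_step = 0.1,
                                             imperfection = imperfection_model(),
                                             seed = 1) {
  grid <- tidyr::expand_grid(mode = modes, length = lengths,
                             run = seq_len(n_runs))
  seeds <- withr::with_seed(seed, sample.int(2^30, nrow(grid)))
  out <- purrr::pmap(cbind(grid, s = seeds), function(mode, length, run, s) {
    n_pat <- axon_capacity(n_modules, length)
    pats <- generate_patterns(n_pat, length, n_neurons, disjoint = TRUE,
                              seed = s)
    cfg <- network_config(
      n_neurons = n_neurons, n_axon_modules = n_modules,
      imperfection = imperfection,
      policy = adaptation_policy("fixed_step", step = adapt_step))
    net <- train(cfg, pats, mode = mode,
                 presentations = adapt_iterations, init = "programming",
                 seed = s + 1L)
    sc <- recall_patterns(net, pats, seed = s + 2L)
    tibble(mode = mode, length = length, run = run, pattern = sc$pattern,
           fraction = sc$fraction)
  })
  structure(dplyr::bind_rows(out),
            class = c("polysnn_imperfection", class(tibble())))
}
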