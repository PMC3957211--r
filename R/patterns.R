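#' Generate random spatio-temporal spike patterns
#'
#' Each pattern is an ordered list of (neuron, time) pairs with strictly
#' increasing times: neuron addresses are drawn uniformly over the network
#' (with no neuron repeated within any 5 consecutive spikes, so the four
#' delay paths of a module always target distinct neurons), and inter-spike
#' intervals are i.i.d. uniform on `[isi_min, isi_max]` (defaults 5–15 ms,
#' so a 51-spike pattern spans about 500 ms).  In disjoint mode the neuron
#' sets of different patterns do not overlap (no cross-talk by
#' construction), which requires `n_patterns * pattern_length <= n_neurons`.
#'
#' @param n_patterns Number of patterns.
#' @param pattern_length Spikes per pattern (S).
#' @param n_neurons Network size; addresses are 0-based in
#'   `[0, n_neurons)`.
#' @param isi_min,isi_max Inter-spike-interval bounds, ms.
#' @param disjoint If `TRUE`, partition neurons across patterns.
#' @param seed Optional seed for reproducible pattern sets.
#' @return Tibble with columns `pattern` (1-based id), `spike` (1-based
#'   position), `neuron` (0-based address), `time_ms` (first spike at 0).
#' @export
generate_patterns <- function(n_patterns, pattern_length, n_neurons,
                              isi_min = 5, isi_max = 15, disjoint = FALSE,
                              seed = NULL) {
  stopifnot(n_patterns >= 1, pattern_length >= 1, n_neurons >= 1,
            isi_min > 0, isi_max >= isi_min)
  if (disjoint && n_patterns * pattern_length > n_neurons) {
    abort(sprintf(
      "disjoint mode infeasible: %d patterns x %d spikes > %d neurons",
      n_patterns, pattern_length, n_neurons),
      class = "polysnn_spec_error")
  }
  if (!disjoint && n_neurons < 5 && pattern_length > n_neurons) {
    abort("cannot avoid neuron repeats within 5 consecutive spikes",
          class = "polysnn_spec_error")
  }
  gen <- function() {
    if (disjoint) {
      pool <- sample.int(n_neurons) - 1L
      ids <- matrix(pool[seq_len(n_patterns * pattern_length)],
                    nrow = n_patterns, byrow = TRUE)
    } else {
      ids <- matrix(
        sample.int(n_neurons, n_patterns * pattern_length, replace = TRUE) - 1L,
        nrow = n_patterns, ncol = pattern_length)
      for (k in seq_len(pattern_length)[-1]) {
        lo <- max(1L, k - 4L)
        repeat {
          prev <- ids[, lo:(k - 1L), drop = FALSE]
          bad <- rowSums(prev == ids[, k]) > 0
          if (!any(bad)) break
          ids[bad, k] <- sample.int(n_neurons, sum(bad), replace = TRUE) - 1L
        }
      }
    }
    isi <- matrix(runif(n_patterns * (pattern_length - 1L), isi_min, isi_max),
                  nrow = n_patterns)
    times <- cbind(0, t(apply(isi, 1L, cumsum)))
    if (pattern_length == 1L) times <- matrix(0, n_patterns, 1L)
    tibble(
      pattern = rep(seq_len(n_patterns), each = pattern_length),
      spike = rep(seq_len(pattern_length), n_patterns),
      neuron = as.integer(t(ids)),
      time_ms = as.numeric(t(times))
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a Poisson noise spike train
#'
#' Homogeneous Poisson process at the network level: the number of noise
#' spikes over `duration_ms` is Poisson with mean
#' `rate_hz * duration_ms / 1000`, and each spike is assigned a uniformly
#' random neuron and synapse line.  The rate counts extra spikes presented
#' to the whole network per second, not per-neuron firing rates.
#'
#' @param rate_hz Network-level Poisson rate, spikes per second.
#' @param duration_ms Duration of the noise train, ms.
#' @param n_neurons Network size (0-based addresses).
#' @param n_lines Number of synapse lines.
#' @param seed Optional seed.
#' @return Tibble with `time_ms`, `neuron`, `line`, time-sorted.
#' @export
generate_noise <- function(rate_hz, duration_ms, n_neurons, n_lines = 4,
                           seed = NULL) {
  stopifnot(rate_hz >= 0, duration_ms >= 0, n_neurons >= 1)
  gen <- function() {
    n <- rpois(1, rate_hz * duration_ms / 1000)
    tibble(
      time_ms = sort(runif(n, 0, duration_ms)),
      neuron = sample.int(n_neurons, n, replace = TRUE) - 1L,
      line = sample.int(n_lines, n, replace = TRUE) - 1L
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Score a recall run against the stored pattern
#'
#' An expected spike `(n, t)` counts as recalled iff some emitted spike has
#' the same neuron address and `|time - (t + t0)| <= tolerance`, using
#' greedy one-to-one matching in time order.  The initiation spikes
#' presented to start the recall are excluded from the denominator.  A
#' pattern counts as successfully recalled iff the recalled fraction reaches
#' `success_threshold` and the run did not enter the all-firing state.
#'
#' @param expected Tibble of the stored pattern (`neuron`, `time_ms`).
#' @param emitted A [recall()] result, or a tibble of emitted spikes
#'   (`neuron`, `time_ms`).
#' @param t0 Recall start offset used for the run, ms.
#' @param tolerance Matching tolerance, ms (default 1, the coincidence
#'   window).
#' @param success_threshold Minimum recalled fraction for success.
#' @param initiation Number of initiation spikes excluded from scoring.
#' @param all_firing Logical; taken from `emitted` when it is a recall
#'   result.
#' @return One-row tibble: `n_expected`, `n_scored`, `n_recalled`,
#'   `fraction`, `all_firing`, `success`.
#' @export
score_recall <- function(expected, emitted, t0 = 0, tolerance = 1,
                         success_threshold = 0.95, initiation = 3,
                         all_firing = FALSE) {
  if (inherits(emitted, "polysnn_recall")) {
    all_firing <- emitted$all_firing
    t0 <- emitted$t0
    initiation <- emitted$initiation
    emitted <- emitted$spikes
  }
  expected <- dplyr::arrange(as_tibble(expected), .data$time_ms)
  n_exp <- nrow(expected)
  scored <- expected[seq_len(n_exp) > initiation, , drop = FALSE]
  n_scored <- nrow(scored)
  n_rec <- 0L
  if (n_scored > 0 && nrow(emitted) > 0) {
    em_by_n <- split(emitted$time_ms, emitted$neuron)
    used <- lapply(em_by_n, function(v) rep(FALSE, length(v)))
    for (i in seq_len(n_scored)) {
      key <- as.character(scored$neuron[i])
      tv <- em_by_n[[key]]
      if (is.null(tv)) next
      ok <- which(!used[[key]] &
                    abs(tv - (scored$time_ms[i] + t0)) <= tolerance)
      if (length(ok)) {
        used[[key]][ok[1L]] <- TRUE
        n_rec <- n_rec + 1L
      }
    }
  }
  frac <- if (n_scored > 0) n_rec / n_scored else 1
  tibble(
    n_expected = n_exp, n_scored = n_scored, n_recalled = n_rec,
    fraction = frac, all_firing = isTRUE(all_firing),
    success = frac >= success_threshold && !isTRUE(all_firing)
  )
}

#' Read and write spike trains as CSV
#'
#' The package spike CSV dialect has columns `time_ms`, `neuron_id` and
#' `line`.
#'
#' @param spikes Tibble with `time_ms`, `neuron` and optionally `line`.
#' @param path File path.
#' @return `write_spikes()` returns `path` invisibly; `read_spikes()`
#'   returns a tibble with `time_ms`, `neuron`, `line`.
#' @export
write_spikes <- function(spikes, path) {
  readr::write_csv(
    tibble(time_ms = spikes$time_ms, neuron_id = spikes$neuron,
           line = if ("line" %in% names(spikes)) spikes$line else 0L),
    path
  )
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(
    time_ms = readr::col_double(),
    neuron_id = readr::col_integer(),
    line = readr::col_integer()
  ))
  tibble(time_ms = d$time_ms, neuron = d$neuron_id, line = d$line)
}
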