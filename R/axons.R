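#' Analog-imperfection model for axon modules
#'
#' Captures the behavioural imperfections of the analog axon circuit:
#' a relative error on each programmed delay (charge injection plus ramp
#' inaccuracy, about 10%), a residual timing jitter on every emission
#' (bounded by roughly 0.3 ms after delay adaptation), and an optional
#' probability of a spurious emission on a neighbouring delay path caused by
#' parasitic coupling.
#'
#' @param sigma Relative programming error: a programmed delay is multiplied
#'   by `1 + e`, `e ~ Normal(0, sigma)`.
#' @param residual Half-range of the additive uniform jitter applied to each
#'   emission time, ms.
#' @param spurious_p Probability, per emission, of an extra spurious
#'   emission on a random path of the same module.
#' @param seed Optional seed recorded with the model.
#' @return A `polysnn_imperfection_model`.
#' @export
imperfection_model <- function(sigma = 0.10, residual = 0.3, spurious_p = 0,
                               seed = NULL) {
  stopifnot(sigma >= 0, residual >= 0, spurious_p >= 0, spurious_p <= 1)
  structure(list(sigma = sigma, residual = residual, spurious_p = spurious_p,
                 seed = seed),
            class = "polysnn_imperfection_model")
}

#' Delay-adaptation policy (STDDP update rule)
#'
#' Spike-timing-dependent delay plasticity decreases an axonal delay when the
#' destination neuron fires before the pre-synaptic spike arrives and
#' increases it in the opposite case.  Three update strategies exist: exact
#' one-step correction of the timing error (equivalent to delay programming),
#' a fixed step per presentation, and a correction proportional to the error
#' (default coefficient 0.5, which halves the error each presentation).
#'
#' @param strategy `"exact"`, `"fixed_step"` or `"proportional"`.
#' @param step Fixed step size, ms (fixed_step strategy).
#' @param coefficient Proportional coefficient in (0, 1].
#' @return A `polysnn_adaptation_policy`.
#' @export
adaptation_policy <- function(strategy = c("proportional", "exact",
                                           "fixed_step"),
                              step = 0.1, coefficient = 0.5) {
  strategy <- match.arg(strategy)
  stopifnot(step > 0, coefficient > 0, coefficient <= 1)
  structure(list(strategy = strategy, step = step, coefficient = coefficient),
            class = "polysnn_adaptation_policy")
}

#' Apply one STDDP update to a delay
#'
#' The timing error is `delta = t_pre_arrival - t_post_fire`; the updated
#' delay is `delay - delta` (exact), `delay - step * sign(delta)`
#' (fixed_step) or `delay - coefficient * delta` (proportional), clamped to
#' `(0, max_delay]`.  All arguments are vectorised.
#'
#' @param delay Current delay(s), ms.
#' @param t_pre_arrival Arrival time of the pre-synaptic spike at the
#'   destination synapse, ms.
#' @param t_post_fire Firing time of the destination neuron in the same
#'   presentation, ms.
#' @param policy An [adaptation_policy()].
#' @param max_delay Upper clamp, ms.
#' @return Updated delay(s), ms.
#' @examples
#' # proportional updates halve the error each presentation
#' d <- 18; target <- 10
#' for (i in 1:5) d <- adapt_delay(d, 100 + d, 100 + target)
#' d - target  # 8 / 2^5 = 0.25
#' @export
adapt_delay <- function(delay, t_pre_arrival, t_post_fire,
                        policy = adaptation_policy(), max_delay = 100) {
  stopifnot(inherits(policy, "polysnn_adaptation_policy"))
  delta <- t_pre_arrival - t_post_fire
  new <- switch(policy$strategy,
    exact = delay - delta,
    fixed_step = delay - policy$step * sign(delta),
    proportional = delay - policy$coefficient * delta
  )
  pmin(pmax(new, 1e-9), max_delay)
}

#' Create an empty axon array
#'
#' An axon module holds one input address register, four output address
#' registers, four programmable delay paths and a shared ramp generator.
#' Modules are allocated to training spikes strictly in physical order.
#'
#' @param n_modules Number of axon modules.
#' @param max_delay Ramp range: largest programmable delay, ms.
#' @param quantization Optional delay quantisation step, ms (e.g. 0.1 to
#'   emulate a digital delay counter); `NULL` keeps delays continuous.
#' @return A `polysnn_axon_array`.
#' @export
axon_array <- function(n_modules, max_delay = 100, quantization = NULL) {
  stopifnot(n_modules >= 1, max_delay > 0)
  structure(
    list(n_modules = as.integer(n_modules),
         input = rep(NA_integer_, n_modules),
         input_t = rep(NA_real_, n_modules),
         out = matrix(NA_integer_, n_modules, 4),
         delay = matrix(NA_real_, n_modules, 4),
         nout = integer(n_modules),
         next_free = 1L,
         open = integer(0),      # input-configured modules of the current
                                 # pattern still collecting outputs
         max_delay = max_delay, quantization = quantization),
    class = "polysnn_axon_array"
  )
}

#' @export
print.polysnn_axon_array <- function(x, ...) {
  cat(sprintf("<polysnn_axon_array> %d modules, %d input-configured, max delay %g ms\n",
              x$n_modules, x$next_free - 1L, x$max_delay))
  invisible(x)
}

#' Mark a pattern boundary during sequential training
#'
#' Closes the modules still collecting output addresses so that the next
#' pattern's spikes do not leak into them (trailing modules of a pattern
#' keep fewer than four configured outputs).
#'
#' @param array A [axon_array()].
#' @return The updated array.
#' @export
begin_pattern <- function(array) {
  array$open <- integer(0)
  array
}

.quantize <- function(d, q) if (is.null(q)) d else round(d / q) * q

#' Feed one training spike through the allocation state machine
#'
#' The lowest enabled-but-unconfigured module latches the spike's address as
#' its input (enabling the next module), and every previously
#' input-configured module of the current pattern that still has fewer than
#' four outputs latches the address as its next output and programs the
#' corresponding delay path with the interval since its own input spike.
#'
#' @param array A [axon_array()].
#' @param neuron Virtual neuron address of the training spike.
#' @param t Spike time, ms.
#' @param imperfection Optional [imperfection_model()] applied when
#'   programming delays.
#' @return The updated array.  Raises a capacity error when all modules are
#'   consumed.
#' @export
allocate_on_training_spike <- function(array, neuron, t, imperfection = NULL) {
  stopifnot(inherits(array, "polysnn_axon_array"))
  neuron <- as.integer(neuron)
  # configure the next output of every open module first: the new module
  # never takes its own spike as an output
  still_open <- logical(length(array$open))
  for (i in seq_along(array$open)) {
    mm <- array$open[i]
    j <- array$nout[mm] + 1L
    array <- program_delay(array, mm, j, array$input_t[mm], t, imperfection)
    array$out[mm, j] <- neuron
    array$nout[mm] <- j
    still_open[i] <- j < 4L
  }
  array$open <- array$open[still_open]
  m0 <- array$next_free
  if (m0 > array$n_modules) {
    abort("axon array capacity exhausted: no free module for training spike",
          class = "polysnn_capacity_error")
  }
  array$input[m0] <- neuron
  array$input_t[m0] <- t
  array$next_free <- m0 + 1L
  array$open <- c(array$open, m0)
  array
}

#' Program one delay path of an axon module
#'
#' Stores `t_output_spike - t_input` on path `path`, multiplied by
#' `(1 + e)`, `e ~ Normal(0, sigma)`, when an imperfection model emulating
#' the analog memory is given.
#'
#' @param array A [axon_array()].
#' @param module 1-based module index.
#' @param path 1-based delay-path index (1..4).
#' @param t_input Time of the module's input spike, ms.
#' @param t_output_spike Time of the training spike being stored, ms.
#' @param imperfection Optional [imperfection_model()].
#' @return The updated array.  Non-positive or over-range delays raise a
#'   programming error.
#' @export
program_delay <- function(array, module, path, t_input, t_output_spike,
                          imperfection = NULL) {
  d <- t_output_spike - t_input
  if (!is.finite(d) || d <= 0 || d > array$max_delay) {
    abort(sprintf("cannot program delay of %g ms on module %d path %d (range (0, %g])",
                  d, module, path, array$max_delay),
          class = "polysnn_programming_error")
  }
  if (!is.null(imperfection) && imperfection$sigma > 0) {
    d <- d * (1 + rnorm(1, 0, imperfection$sigma))
    d <- min(max(d, 1e-9), array$max_delay)
  }
  array$delay[module, path] <- .quantize(d, array$quantization)
  array
}

#' Pre-synaptic emissions triggered by a post-synaptic spike
#'
#' Every module whose input address matches the spike's address restarts its
#' ramp at `t` and schedules one pre-synaptic spike per configured path at
#' `t + delay[j]`, addressed to output `j` on active line `j - 1`.  With an
#' imperfection model, each emission gets additive uniform jitter within the
#' residual bound and, with probability `spurious_p`, an extra spurious
#' emission on a random path of the same module.  (Ramp-restart cancellation
#' of pending emissions is handled by the network event loop.)
#'
#' @param array A [axon_array()].
#' @param neuron Address of the post-synaptic spike.
#' @param t Spike time, ms.
#' @param imperfection Optional [imperfection_model()].
#' @return Tibble of scheduled emissions: `time_ms`, `neuron`, `line`,
#'   `module`, `spurious`, sorted by time.
#' @export
on_postsyn_spike <- function(array, neuron, t, imperfection = NULL) {
  stopifnot(inherits(array, "polysnn_axon_array"))
  mods <- which(!is.na(array$input) & array$input == neuron)
  rows <- list()
  for (mm in mods) {
    no <- array$nout[mm]
    if (no == 0L) next
    d <- array$delay[mm, seq_len(no)]
    te <- t + d
    spur <- rep(FALSE, no)
    if (!is.null(imperfection)) {
      if (imperfection$residual > 0) {
        te <- te + runif(no, -imperfection$residual, imperfection$residual)
      }
      if (imperfection$spurious_p > 0) {
        extra <- which(runif(no) < imperfection$spurious_p)
        if (length(extra)) {
          j2 <- sample.int(no, length(extra), replace = TRUE)
          te2 <- t + array$delay[mm, j2] +
            if (imperfection$residual > 0) {
              runif(length(j2), -imperfection$residual, imperfection$residual)
            } else 0
          rows[[length(rows) + 1L]] <- tibble(
            time_ms = te2, neuron = array$out[mm, j2], line = j2 - 1L,
            module = mm, spurious = TRUE)
        }
      }
    }
    rows[[length(rows) + 1L]] <- tibble(
      time_ms = te, neuron = array$out[mm, seq_len(no)],
      line = seq_len(no) - 1L, module = mm, spurious = spur)
  }
  if (!length(rows)) {
    return(tibble(time_ms = numeric(), neuron = integer(), line = integer(),
                  module = integer(), spurious = logical()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$time_ms)
}

#' Pattern capacity of an axon array
#'
#' Each spike of a pattern consumes one axon module (its four delay paths
#' store the intervals to the next four spikes), so an array of `n_modules`
#' modules stores `floor(n_modules / pattern_length)` patterns.
#'
#' @param n_modules Number of axon modules.
#' @param pattern_length Spikes per pattern.
#' @return Integer number of storable patterns.
#' @examples
#' axon_capacity(100, c(20, 25, 33, 50))  # 5 4 3 2
#' @export
axon_capacity <- function(n_modules, pattern_length) {
  as.integer(n_modules %/% pattern_length)
}

#' Serialise a trained axon array to JSON
#'
#' Writes the configured modules (index, input address, output addresses,
#' delays) together with the array geometry, so a trained network can be
#' re-loaded for reproducible recall runs.
#'
#' @param array A [axon_array()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_axon_array <- function(array, path) {
  conf <- which(!is.na(array$input))
  doc <- list(
    n_modules = array$n_modules,
    max_delay = array$max_delay,
    quantization = array$quantization,
    modules = lapply(conf, function(mm) {
      no <- array$nout[mm]
      list(module = mm, input = array$input[mm], input_t = array$input_t[mm],
           outputs = if (no) as.integer(array$out[mm, seq_len(no)]) else integer(),
           delays = if (no) as.numeric(array$delay[mm, seq_len(no)]) else numeric())
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_axon_array
#' @export
read_axon_array <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  array <- axon_array(doc$n_modules, doc$max_delay,
                      quantization = doc$quantization)
  for (entry in doc$modules) {
    mm <- entry$module
    array$input[mm] <- as.integer(entry$input)
    array$input_t[mm] <- as.numeric(entry$input_t)
    no <- length(entry$outputs)
    array$nout[mm] <- no
    if (no) {
      array$out[mm, seq_len(no)] <- as.integer(unlist(entry$outputs))
      array$delay[mm, seq_len(no)] <- as.numeric(unlist(entry$delays))
    }
  }
  conf <- which(!is.na(array$input))
  array$next_free <- if (length(conf)) max(conf) + 1L else 1L
  array
}
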