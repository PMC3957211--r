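#' Digital coincidence-detector neuron
#'
#' The digital neuron is a coincidence detector built from one timer per
#' synapse line and a comparator: a pre-synaptic spike on line `l` at time
#' `t` loads that line's timer with `t + window`; the neuron fires when at
#' least `threshold` lines hold unexpired timers and the neuron is outside
#' its refractory period.  Firing clears all timers.  Defaults follow the
#' 4-input, threshold-3, 1 ms-window detector used to limit cross-talk
#' between stored patterns.
#'
#' @param n_lines Number of synapse lines (input timers).
#' @param threshold Number of coincident lines required to fire (K).
#' @param window Coincidence window W in ms.
#' @param refractory Refractory period in ms.
#' @return A `polysnn_digital_neuron` state object.
#' @examples
#' nrn <- digital_neuron()
#' s <- digital_on_presyn(nrn, 0, 0)
#' s <- digital_on_presyn(s$neuron, 0.4, 1)
#' s <- digital_on_presyn(s$neuron, 0.9, 2)
#' s$fired  # TRUE: three lines within 1 ms
#' @export
digital_neuron <- function(n_lines = 4, threshold = 3, window = 1,
                           refractory = 2) {
  stopifnot(threshold >= 1, threshold <= n_lines, window > 0, refractory >= 0)
  structure(
    list(n_lines = as.integer(n_lines), threshold = as.integer(threshold),
         window = window, refractory = refractory,
         timers = rep(-Inf, n_lines), refractory_until = -Inf, t_last = -Inf),
    class = "polysnn_digital_neuron"
  )
}

#' Deliver a pre-synaptic spike to a digital neuron
#'
#' Events must be presented in non-decreasing time order; an out-of-order
#' event raises a sequencing error.
#'
#' @param neuron A [digital_neuron()] state.
#' @param t Event time, ms.
#' @param line 0-based synapse line.
#' @return List with the updated `neuron` and `fired` (logical).
#' @export
digital_on_presyn <- function(neuron, t, line) {
  stopifnot(inherits(neuron, "polysnn_digital_neuron"))
  if (t < neuron$t_last) {
    abort("events must be presented in non-decreasing time order",
          class = "polysnn_sequencing_error")
  }
  line <- as.integer(line)
  if (line < 0L || line >= neuron$n_lines) {
    abort("synapse line out of range", class = "polysnn_sequencing_error")
  }
  neuron$t_last <- t
  neuron$timers[line + 1L] <- t + neuron$window
  fired <- FALSE
  if (t >= neuron$refractory_until &&
      sum(neuron$timers > t) >= neuron$threshold) {
    fired <- TRUE
    neuron$timers <- rep(-Inf, neuron$n_lines)
    neuron$refractory_until <- t + neuron$refractory
  }
  list(neuron = neuron, fired = fired)
}

#' Run a digital neuron over an event stream
#'
#' Convenience wrapper: feeds a time-sorted stream of `(time_ms, line)`
#' events through [digital_on_presyn()] and returns the firing times.
#'
#' @param events Data frame with `time_ms` and `line`.
#' @param neuron A [digital_neuron()]; default parameters if omitted.
#' @return Numeric vector of firing times.
#' @export
digital_run <- function(events, neuron = digital_neuron()) {
  fires <- numeric(0)
  for (i in seq_len(nrow(events))) {
    st <- digital_on_presyn(neuron, events$time_ms[i], events$line[i])
    neuron <- st$neuron
    if (st$fired) fires <- c(fires, events$time_ms[i])
  }
  fires
}
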