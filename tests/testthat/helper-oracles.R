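# Independent oracles used to cross-check the implementation.

# O(n^2) sliding-window check of the coincidence rule: an event fires the
# neuron iff at least K distinct lines carry a spike in the trailing window
# (t - W, t], counting only events since the last firing, outside the
# refractory period.  Deliberately structured as a backward window scan,
# not as timers.
oracle_digital_fires <- function(events, K = 3, n_lines = 4, W = 1,
                                 refractory = 2) {
  fires <- numeric(0)
  refr_until <- -Inf
  since <- 1L  # first event index after the last firing
  n <- nrow(events)
  for (i in seq_len(n)) {
    t <- events$time_ms[i]
    if (t < refr_until) next
    lines <- unique(events$line[seq(since, i)][
      events$time_ms[seq(since, i)] > t - W])
    if (length(lines) >= K) {
      fires <- c(fires, t)
      refr_until <- t + refractory
      since <- i + 1L
    }
  }
  fires
}

# dense-grid Euler integration of the synapse/membrane system, independent
# of the closed-form update; returns TRUE iff the neuron crosses threshold
oracle_analog_fires <- function(events, tau_syn, tau_mem, amplitude,
                                threshold, t_end, dt = 2e-4) {
  i_syn <- rep(0, 4)
  i_out <- 0
  ev <- events[order(events$time_ms), ]
  k <- 1L
  for (t in seq(0, t_end, by = dt)) {
    while (k <= nrow(ev) && ev$time_ms[k] <= t) {
      i_syn[ev$line[k] + 1L] <- amplitude
      k <- k + 1L
    }
    i_out <- i_out + dt * (sum(i_syn) - i_out) / tau_mem
    if (i_out >= threshold) return(TRUE)
    i_syn <- i_syn - dt * i_syn / tau_syn
  }
  FALSE
}

# reference map-with-expiry for the multiplexing controller
oracle_controller_replay <- function(spikes, pool_size = 50, lease = 1) {
  assigned <- data.frame(address = integer(), expiry = numeric(),
                         phys = integer())
  free <- seq_len(pool_size)
  out <- integer(nrow(spikes))
  for (i in seq_len(nrow(spikes))) {
    t <- spikes$time_ms[i]
    gone <- assigned$expiry <= t
    free <- sort(c(free, assigned$phys[gone]))
    assigned <- assigned[!gone, ]
    hit <- match(spikes$address[i], assigned$address)
    if (!is.na(hit)) {
      out[i] <- assigned$phys[hit]
    } else if (length(free)) {
      p <- free[1L]
      free <- free[-1L]
      assigned <- rbind(assigned,
                        data.frame(address = spikes$address[i],
                                   expiry = t + lease, phys = p))
      out[i] <- p
    } else {
      out[i] <- NA_integer_
    }
  }
  out
}

# small random pattern set + trained digital net for engine cross-checks
make_small_net <- function(seed, n_neurons = 64, n_patterns = 6,
                           pattern_length = 12, ...) {
  pats <- generate_patterns(n_patterns, pattern_length, n_neurons,
                            seed = seed)
  cfg <- network_config(n_neurons = n_neurons,
                        n_axon_modules = n_patterns * pattern_length, ...)
  list(patterns = pats, net = train(cfg, pats, "programming", seed = seed + 1))
}
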