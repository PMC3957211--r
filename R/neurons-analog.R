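#' Behavioural analog LIF neuron
#'
#' Behavioural model of the analog leaky integrate-and-fire coincidence
#' detector.  Each of the four synapse lines holds a post-synaptic current
#' that a pre-synaptic spike resets to full amplitude and that then decays
#' exponentially with `tau_syn`.  The summed synapse current drives a
#' first-order low-pass membrane filter,
#' `tau_mem * dI_out/dt + I_out = sum(I_syn)`, and the neuron fires when
#' `I_out` crosses `threshold` outside the refractory period; firing zeroes
#' `I_out` (no integration happens during the refractory period).
#'
#' `tau_mem` defaults to the device value `n * U_T * C_mem / I_t` with
#' n = 1.5, U_T = 25.6 mV, C_mem = 0.6 pF, I_t = 1 nA (about 0.023 ms), so
#' the membrane essentially tracks the summed synapse current.  `tau_syn`
#' defaults to 1.6 ms, a value at which the tuning criterion — three spikes
#' anywhere within 1 ms cross threshold while any two do not — is satisfiable;
#' `threshold = NULL` requests bisection calibration against that criterion.
#' The analog neuron remains a less precise coincidence detector than the
#' digital timer model (there is no hard window edge).
#'
#' @param n_lines Number of synapse lines.
#' @param tau_syn Synapse decay constant, ms.
#' @param tau_mem Membrane time constant, ms.
#' @param amplitude Synapse current amplitude immediately after a spike
#'   (normalised units).
#' @param threshold Firing threshold on `I_out`; `NULL` = auto-calibrate via
#'   [calibrate_analog_threshold()].
#' @param refractory Refractory period, ms.
#' @param pulse_width Output spike pulse width, ms (bookkeeping only).
#' @return A `polysnn_analog_neuron` state object.
#' @export
analog_neuron <- function(n_lines = 4, tau_syn = 1.6, tau_mem = 0.023,
                          amplitude = 1, threshold = NULL, refractory = 2,
                          pulse_width = 0.1) {
  stopifnot(tau_syn > 0, tau_mem > 0, amplitude > 0, refractory >= 0)
  params <- list(n_lines = as.integer(n_lines), tau_syn = tau_syn,
                 tau_mem = tau_mem, amplitude = amplitude,
                 refractory = refractory, pulse_width = pulse_width)
  if (is.null(threshold)) {
    threshold <- calibrate_analog_threshold(params)
  }
  structure(
    c(params, list(threshold = threshold,
                   i_syn = rep(0, n_lines), i_out = 0,
                   t_now = 0, refractory_until = -Inf)),
    class = "polysnn_analog_neuron"
  )
}

# closed-form update of the two-exponential system over dt >= 0:
# synapse currents decay with tau_syn; I_out follows the first-order filter
# driven by sum(i_syn) * exp(-t/tau_syn).
.analog_advance <- function(i_syn, i_out, dt, tau_syn, tau_mem) {
  if (dt <= 0) return(list(i_syn = i_syn, i_out = i_out))
  s0 <- sum(i_syn)
  es <- exp(-dt / tau_syn)
  em <- exp(-dt / tau_mem)
  if (abs(tau_syn - tau_mem) < 1e-12) {
    i_out2 <- i_out * em + s0 * (dt / tau_mem) * em
  } else {
    a <- s0 * tau_syn / (tau_syn - tau_mem)
    i_out2 <- (i_out - a) * em + a * es
  }
  list(i_syn = i_syn * es, i_out = i_out2)
}

# first time in (0, dt] at which I_out reaches thres given no further input;
# Inf if it never does.  The trajectory has at most one interior maximum.
.analog_crossing <- function(i_syn, i_out, thres, dt, tau_syn, tau_mem) {
  if (i_out >= thres) return(0)
  s0 <- sum(i_syn)
  if (s0 <= 0) return(Inf)
  f <- function(u) .analog_advance(i_syn, i_out, u, tau_syn, tau_mem)$i_out - thres
  # analytic stationary point of the two-exponential trajectory
  if (abs(tau_syn - tau_mem) < 1e-12) {
    u_star <- tau_syn * (s0 - i_out) / s0
  } else {
    a <- s0 * tau_syn / (tau_syn - tau_mem)
    ratio <- (a * tau_mem) / ((a - i_out) * tau_syn)
    u_star <- if (ratio > 0) {
      log(ratio) / (1 / tau_syn - 1 / tau_mem)
    } else {
      -1
    }
  }
  if (!is.finite(u_star) || u_star <= 0) return(Inf)  # decaying from the start
  u_star <- min(u_star, dt)
  if (f(u_star) < 0) return(Inf)
  uniroot(f, c(0, u_star), tol = 1e-12)$root
}

#' Advance an analog neuron to a later time
#'
#' Applies the closed-form two-exponential update between events (no
#' fixed-step integration), including threshold crossing and refractory
#' handling.  A negative time step raises a sequencing error.
#'
#' @param neuron A [analog_neuron()] state.
#' @param t Target time, ms.
#' @return List with updated `neuron`, `fired` (logical) and `t_fire`
#'   (crossing time or `NA`).
#' @export
analog_step <- function(neuron, t) {
  stopifnot(inherits(neuron, "polysnn_analog_neuron"))
  if (t < neuron$t_now) {
    abort("negative time step", class = "polysnn_sequencing_error")
  }
  fired <- FALSE
  t_fire <- NA_real_
  t0 <- neuron$t_now
  # no integration during the refractory period: I_out pinned at 0 while the
  # synapse currents keep decaying
  if (t0 < neuron$refractory_until) {
    t_hold <- min(t, neuron$refractory_until)
    neuron$i_syn <- neuron$i_syn * exp(-(t_hold - t0) / neuron$tau_syn)
    neuron$i_out <- 0
    t0 <- t_hold
  }
  if (t > t0) {
    tc <- .analog_crossing(neuron$i_syn, neuron$i_out, neuron$threshold,
                           t - t0, neuron$tau_syn, neuron$tau_mem)
    if (is.finite(tc)) {
      adv <- .analog_advance(neuron$i_syn, neuron$i_out, tc,
                             neuron$tau_syn, neuron$tau_mem)
      fired <- TRUE
      t_fire <- t0 + tc
      neuron$i_syn <- adv$i_syn * exp(-(t - t_fire) / neuron$tau_syn)
      neuron$i_out <- 0
      neuron$refractory_until <- t_fire + neuron$refractory
    } else {
      adv <- .analog_advance(neuron$i_syn, neuron$i_out, t - t0,
                             neuron$tau_syn, neuron$tau_mem)
      neuron$i_syn <- adv$i_syn
      neuron$i_out <- adv$i_out
    }
  }
  neuron$t_now <- t
  list(neuron = neuron, fired = fired, t_fire = t_fire)
}

#' Deliver a pre-synaptic spike to an analog neuron
#'
#' Advances the state to `t`, then resets line `line`'s synapse current to
#' full amplitude (the spike pulls the synapse capacitor to ground, i.e.
#' maximal current).
#'
#' @inheritParams analog_step
#' @param line 0-based synapse line.
#' @return List with updated `neuron`, `fired`, `t_fire` (a crossing during
#'   the advance to `t`, if any).
#' @export
analog_on_presyn <- function(neuron, t, line) {
  st <- analog_step(neuron, t)
  line <- as.integer(line)
  stopifnot(line >= 0L, line < st$neuron$n_lines)
  st$neuron$i_syn[line + 1L] <- st$neuron$amplitude
  st
}

#' Run an analog neuron over an event stream and report firing times
#'
#' Feeds `(time_ms, line)` events through [analog_on_presyn()], checking for
#' threshold crossings between events and over `settle_ms` after the last
#' event.
#'
#' @param events Data frame with `time_ms`, `line`.
#' @param neuron An [analog_neuron()].
#' @param settle_ms Extra time simulated after the last event.
#' @return Numeric vector of firing times.
#' @export
analog_run <- function(events, neuron = analog_neuron(), settle_ms = 5) {
  fires <- numeric(0)
  for (i in seq_len(nrow(events))) {
    st <- analog_on_presyn(neuron, events$time_ms[i], events$line[i])
    neuron <- st$neuron
    if (st$fired) fires <- c(fires, st$t_fire)
  }
  if (nrow(events)) {
    st <- analog_step(neuron, max(events$time_ms) + settle_ms)
    if (st$fired) fires <- c(fires, st$t_fire)
  }
  fires
}

#' Calibrate the analog firing threshold by bisection
#'
#' Finds the largest threshold fired by the worst-case coincident triple
#' (three spikes evenly spread over the 1 ms window, the hardest pattern the
#' detector must accept) and the largest response reachable by any pair of
#' spikes (two simultaneous spikes on distinct lines, the hardest pattern it
#' must reject), then returns their midpoint.  Errors if the two overlap —
#' i.e. if the time constants cannot realise the 3-but-not-2 criterion.
#'
#' @param params List with `n_lines`, `tau_syn`, `tau_mem`, `amplitude`,
#'   `refractory` (as built by [analog_neuron()]).
#' @param window Coincidence window the criterion refers to, ms.
#' @param tol Bisection tolerance on the threshold.
#' @return Calibrated threshold (numeric).
#' @export
calibrate_analog_threshold <- function(params, window = 1, tol = 1e-4) {
  peak_for <- function(times, lines, thres) {
    # does the input pattern cross `thres`?
    nrn <- structure(
      c(params, list(threshold = thres, i_syn = rep(0, params$n_lines),
                     i_out = 0, t_now = 0, refractory_until = -Inf)),
      class = "polysnn_analog_neuron"
    )
    length(analog_run(tibble(time_ms = times, line = lines), nrn)) > 0
  }
  sup_thres <- function(times, lines) {
    lo <- 0
    hi <- params$n_lines * params$amplitude
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (peak_for(times, lines, mid)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  r3 <- sup_thres(c(0, window / 2, window), c(0, 1, 2))
  r2 <- sup_thres(c(0, 1e-9), c(0, 1))
  if (r3 <= r2) {
    abort(paste0("cannot tune analog neuron: worst-case triple response (",
                 signif(r3, 4), ") does not exceed pair response (",
                 signif(r2, 4), "); increase tau_syn"),
          class = "polysnn_tuning_error")
  }
  (r2 + r3) / 2
}
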