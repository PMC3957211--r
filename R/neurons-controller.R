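#' Virtual-neuron multiplexing controller
#'
#' A small pool of physical neurons serves a much larger virtual address
#' space: a pre-synaptic spike to an unassigned virtual address leases a free
#' physical neuron, latches the address into its register and starts a
#' 1 ms expiry timer (the lease is not renewed by further spikes — it covers
#' the coincidence window).  Spikes to an already-assigned, unexpired address
#' are routed to the leased neuron.  When the pool is exhausted the spike is
#' dropped and counted.  With the defaults (4096 virtual addresses on 50
#' physical neurons) the virtual/physical ratio is about 80.
#'
#' @param pool_size Number of physical neurons.
#' @param lease_ms Lease duration, ms.
#' @return A `polysnn_controller` state object.
#' @export
controller_state <- function(pool_size = 50, lease_ms = 1) {
  stopifnot(pool_size >= 1, lease_ms > 0)
  structure(
    list(pool_size = as.integer(pool_size), lease_ms = lease_ms,
         address = rep(NA_integer_, pool_size),   # latched virtual address
         expiry = rep(-Inf, pool_size),
         n_assigned = 0L, n_expired_reused = 0L, n_dropped = 0L),
    class = "polysnn_controller"
  )
}

#' Route a pre-synaptic spike through the controller
#'
#' @param ctrl A [controller_state()].
#' @param address Virtual neuron address of the incoming spike.
#' @param t Event time, ms.
#' @return List with updated `ctrl`, `physical` (1-based physical index, or
#'   `NA` if dropped), `newly_assigned` and `dropped` (logicals).
#' @export
controller_on_presyn <- function(ctrl, address, t) {
  stopifnot(inherits(ctrl, "polysnn_controller"))
  hit <- which(!is.na(ctrl$address) & ctrl$address == address &
                 ctrl$expiry > t)
  if (length(hit)) {
    return(list(ctrl = ctrl, physical = hit[1L], newly_assigned = FALSE,
                dropped = FALSE))
  }
  free <- which(ctrl$expiry <= t)
  if (!length(free)) {
    ctrl$n_dropped <- ctrl$n_dropped + 1L
    warn(sprintf("neuron pool exhausted at t = %g ms; spike to address %d dropped",
                 t, address), class = "polysnn_pool_exhausted")
    return(list(ctrl = ctrl, physical = NA_integer_, newly_assigned = FALSE,
                dropped = TRUE))
  }
  p <- free[1L]
  ctrl$address[p] <- as.integer(address)
  ctrl$expiry[p] <- t + ctrl$lease_ms
  ctrl$n_assigned <- ctrl$n_assigned + 1L
  list(ctrl = ctrl, physical = p, newly_assigned = TRUE, dropped = FALSE)
}

#' Translate a physical neuron's firing into a virtual post-synaptic spike
#'
#' @param ctrl A [controller_state()].
#' @param physical 1-based physical neuron index.
#' @param t Firing time, ms.
#' @return The latched virtual address; an internal-state error if the
#'   neuron holds no live lease at `t`.
#' @export
controller_on_fire <- function(ctrl, physical, t) {
  stopifnot(inherits(ctrl, "polysnn_controller"))
  if (physical < 1L || physical > ctrl$pool_size ||
      is.na(ctrl$address[physical]) || ctrl$expiry[physical] <= t) {
    abort("fire from unassigned or expired physical neuron",
          class = "polysnn_internal_state_error")
  }
  ctrl$address[physical]
}

#' Number of live leases at a time point
#'
#' @inheritParams controller_on_fire
#' @return Integer count of unexpired assignments.
#' @export
controller_n_leased <- function(ctrl, t) {
  sum(!is.na(ctrl$address) & ctrl$expiry > t)
}
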