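# Reference event-driven engine.
#
# Same event semantics as the compiled engine — events processed in
# (time, sequence) order, axon ramp restarts cancel pending emissions via
# per-module generation counters — but written in plain R and supporting
# all three neuron backends.  The digital path is deliberately independent
# of the C++ implementation so the two can be cross-checked.
#
# Event kinds: 0 = post-synaptic spike (triggers matching axon modules),
# 1 = pre-synaptic arrival, 2 = predicted analog threshold crossing.

.r_recall <- function(net, init_t, init_n, noise, t_end, max_emitted,
                      jitter, spurious_p) {
  cfg <- net$config
  n_neurons <- cfg$n_neurons
  n_lines <- cfg$n_lines
  backend <- cfg$backend

  # routing: configured modules by input address (1-based R views)
  mods_by_addr <- vector("list", n_neurons)
  for (a in which(diff(net$addr_ptr) > 0)) {
    mods_by_addr[[a]] <- net$addr_mod[(net$addr_ptr[a] + 1L):
                                        net$addr_ptr[a + 1L]] + 1L
  }
  mod_gen <- numeric(length(net$nout))

  # growable event queue
  cap <- 4096L
  qt <- numeric(cap); qs <- numeric(cap); qk <- integer(cap)
  qn <- integer(cap); ql <- integer(cap); qm <- integer(cap); qg <- numeric(cap)
  alive <- logical(cap)
  n_used <- 0L; seq_ctr <- 0
  push <- function(t, kind, neuron, line, module, gen) {
    n_used <<- n_used + 1L
    if (n_used > cap) {
      cap <<- cap * 2L
      length(qt) <<- cap; length(qs) <<- cap; length(qk) <<- cap
      length(qn) <<- cap; length(ql) <<- cap; length(qm) <<- cap
      length(qg) <<- cap; length(alive) <<- cap
    }
    seq_ctr <<- seq_ctr + 1
    qt[n_used] <<- t; qs[n_used] <<- seq_ctr; qk[n_used] <<- kind
    qn[n_used] <<- neuron; ql[n_used] <<- line; qm[n_used] <<- module
    qg[n_used] <<- gen; alive[n_used] <<- TRUE
  }

  for (i in seq_along(init_t)) push(init_t[i], 0L, init_n[i], -1L, 0L, -1)
  for (i in seq_len(nrow(noise))) {
    push(noise$time_ms[i], 1L, noise$neuron[i], noise$line[i], 0L, -1)
  }

  em_t <- numeric(0); em_n <- integer(0)
  all_firing <- FALSE; n_events <- 0; n_dropped <- 0L
  n_expired_fires <- 0L

  trigger <- function(addr, t) {
    for (mm in mods_by_addr[[addr + 1L]]) {
      mod_gen[mm] <<- mod_gen[mm] + 1
      g <- mod_gen[mm]
      no <- net$nout[mm]
      if (no == 0L) next
      for (j in seq_len(no)) {
        te <- t + net$delay[mm, j]
        if (jitter > 0) te <- te + runif(1, -jitter, jitter)
        push(te, 1L, net$out[mm, j], j - 1L, mm, g)
        if (spurious_p > 0 && runif(1) < spurious_p) {
          j2 <- sample.int(no, 1L)
          te2 <- t + net$delay[mm, j2]
          if (jitter > 0) te2 <- te2 + runif(1, -jitter, jitter)
          push(te2, 1L, net$out[mm, j2], j2 - 1L, mm, g)
        }
      }
    }
  }

  # ---- neuron state -------------------------------------------------------
  digital_like <- backend == "digital" ||
    (backend == "multiplexed" && cfg$pool_backend == "digital")
  analog_like <- backend == "analog" ||
    (backend == "multiplexed" && cfg$pool_backend == "analog")
  n_states <- if (backend == "multiplexed") cfg$pool_size else n_neurons

  timers <- matrix(-Inf, n_states, n_lines)
  refr <- rep(-Inf, n_states)
  if (analog_like) {
    ap <- cfg$analog
    isyn <- matrix(0, n_states, n_lines)
    iout <- rep(0, n_states)
    tlast <- rep(0, n_states)
    ngen <- numeric(n_states)
  }
  if (backend == "multiplexed") {
    cl_addr <- rep(NA_integer_, cfg$pool_size)
    cl_exp <- rep(-Inf, cfg$pool_size)
  }

  fire <- function(state_idx, addr, t) {
    em_t[length(em_t) + 1L] <<- t
    em_n[length(em_n) + 1L] <<- addr
    refr[state_idx] <<- t + cfg$refractory
    if (length(em_t) > max_emitted) {
      all_firing <<- TRUE
      return(FALSE)
    }
    trigger(addr, t)
    TRUE
  }

  # analog helpers operating on row `i` of the state matrices
  an_advance <- function(i, t) {
    # advance to t assuming no crossing occurs (guaranteed by the predicted
    # crossing events); refractory pins i_out at 0
    t0 <- tlast[i]
    if (t0 < refr[i]) {
      th <- min(t, refr[i])
      isyn[i, ] <<- isyn[i, ] * exp(-(th - t0) / ap$tau_syn)
      iout[i] <<- 0
      t0 <- th
    }
    if (t > t0) {
      adv <- .analog_advance(isyn[i, ], iout[i], t - t0, ap$tau_syn, ap$tau_mem)
      isyn[i, ] <<- adv$i_syn
      iout[i] <<- adv$i_out
    }
    tlast[i] <<- t
  }
  an_schedule <- function(i) {
    # predicted crossing from the current state (post-refractory if needed)
    ngen[i] <<- ngen[i] + 1
    t0 <- tlast[i]
    is0 <- isyn[i, ]; io0 <- iout[i]
    if (t0 < refr[i]) {
      is0 <- is0 * exp(-(refr[i] - t0) / ap$tau_syn)
      io0 <- 0
      t0 <- refr[i]
    }
    tc <- .analog_crossing(is0, io0, ap$threshold, t_end - t0,
                           ap$tau_syn, ap$tau_mem)
    if (is.finite(tc)) push(t0 + tc, 2L, i, -1L, 0L, ngen[i])
  }

  deliver_digital <- function(i, addr, line, t) {
    timers[i, line + 1L] <<- t + cfg$window
    if (t >= refr[i] && sum(timers[i, ] > t) >= cfg$threshold) {
      timers[i, ] <<- -Inf
      return(fire(i, addr, t))
    }
    TRUE
  }

  deliver_analog <- function(i, line, t) {
    an_advance(i, t)
    isyn[i, line + 1L] <<- ap$amplitude
    an_schedule(i)
    TRUE
  }

  # ---- main loop ----------------------------------------------------------
  repeat {
    live <- which(alive[seq_len(n_used)])
    if (!length(live)) break
    j <- live[which.min(qt[live])]
    alive[j] <- FALSE
    t <- qt[j]
    if (t > t_end) break
    n_events <- n_events + 1
    kind <- qk[j]

    if (kind == 0L) {
      trigger(qn[j], t)
    } else if (kind == 1L) {
      mm <- qm[j]
      if (qg[j] >= 0 && mod_gen[mm] != qg[j]) next  # ramp restarted
      v <- qn[j]; line <- ql[j]
      if (backend == "digital") {
        if (!deliver_digital(v + 1L, v, line, t)) break
      } else if (backend == "analog") {
        if (!deliver_analog(v + 1L, line, t)) break
      } else {
        # controller: route the virtual address to a physical neuron
        hit <- which(!is.na(cl_addr) & cl_addr == v & cl_exp > t)
        if (length(hit)) {
          p <- hit[1L]
        } else {
          free <- which(cl_exp <= t)
          if (!length(free)) {
            n_dropped <- n_dropped + 1L
            next
          }
          p <- free[1L]
          cl_addr[p] <- v
          cl_exp[p] <- t + cfg$lease_ms
          timers[p, ] <- -Inf
          if (analog_like) {
            isyn[p, ] <- 0; iout[p] <- 0; tlast[p] <- t
            ngen[p] <- ngen[p] + 1  # cancel stale predictions
          }
        }
        if (digital_like) {
          if (!deliver_digital(p, v, line, t)) break
        } else {
          if (!deliver_analog(p, line, t)) break
        }
      }
    } else {
      # predicted analog crossing
      i <- qn[j]
      if (ngen[i] != qg[j]) next
      if (t < refr[i]) next
      addr <- i - 1L
      if (backend == "multiplexed") {
        if (is.na(cl_addr[i]) || cl_exp[i] <= t) {
          n_expired_fires <- n_expired_fires + 1L
          next
        }
        addr <- cl_addr[i]
      }
      # land exactly on the crossing: advance synapses to t, zero i_out
      isyn[i, ] <- isyn[i, ] * exp(-(t - tlast[i]) / ap$tau_syn)
      iout[i] <- 0
      tlast[i] <- t
      ngen[i] <- ngen[i] + 1
      if (!fire(i, addr, t)) break
      an_schedule(i)
    }
  }

  list(spikes = tibble(time_ms = em_t, neuron = em_n),
       all_firing = all_firing, n_events = n_events,
       n_dropped = n_dropped, n_expired_fires = n_expired_fires)
}
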