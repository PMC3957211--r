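#' Skew/glitch model for the asynchronous AER bus
#'
#' Behavioural model of the analog-side bus imperfections: a fixed per-wire
#' timing skew (current-to-voltage conversion spread plus board propagation),
#' per-pulse width jitter, and brief glitch pulses caused by coupling
#' capacitance.  Glitches occur while a valid address is held on the bus and
#' briefly raise an additional (currently LOW) address wire, making the
#' address momentarily invalid before it returns — the mechanism that causes
#' duplicate sampling.
#'
#' @param skew_max Bound on the per-wire skew offset, microseconds.  Offsets
#'   are drawn uniformly in `[-skew_max, skew_max]` from `seed`.
#' @param glitch_rate Expected glitches per microsecond of address plateau.
#' @param glitch_width Length-2 numeric, min/max glitch width in
#'   microseconds (tens of nanoseconds scale).
#' @param width_jitter Half-range of per-pulse width jitter, microseconds.
#' @param seed Integer seed; the model is reproducible from it.
#' @return A `polysnn_skew_glitch_model`.
#' @export
skew_glitch_model <- function(skew_max = 0.2, glitch_rate = 0.05,
                              glitch_width = c(0.005, 0.05),
                              width_jitter = 0.05, seed = 1L) {
  stopifnot(skew_max >= 0, glitch_rate >= 0, width_jitter >= 0,
            length(glitch_width) == 2L, all(glitch_width >= 0),
            glitch_width[1] <= glitch_width[2])
  structure(
    list(skew_max = skew_max, glitch_rate = glitch_rate,
         glitch_width = as.numeric(glitch_width),
         width_jitter = width_jitter, seed = as.integer(seed)),
    class = "polysnn_skew_glitch_model"
  )
}

#' Synthesise a bus waveform from spike events
#'
#' Turns a time-sorted list of address events into per-wire pulse trains on
#' the M address wires plus the active line(s), applying the skew/glitch
#' model if given.  Wire numbering: wires `1..M` are address bits (wire 1 is
#' the most significant bit of the codeword integer), wires `M+1..M+L` are
#' the active lines (wire `M+1+line` carries synapse line `line`).
#'
#' @param events Data frame with columns `time_us`, `address`
#'   (codebook index) and optionally `line` (0-based active line, default 0).
#' @param book Codebook from [build_codebook()].
#' @param pulse_width Nominal pulse width, microseconds.
#' @param model Optional [skew_glitch_model()]; `NULL` means an ideal bus.
#' @param n_active_lines Number of active-line wires L (1 for the
#'   post-synaptic bus, 4 for the pre-synaptic bus).
#' @return A tibble (`polysnn_bus_waveform`) with columns `wire`, `t_on`,
#'   `t_off`, time-sorted, non-overlapping per wire.
#' @export
synthesize_bus_waveform <- function(events, book, pulse_width = 1,
                                    model = NULL, n_active_lines = 1) {
  stopifnot(inherits(book, "polysnn_codebook"), pulse_width > 0)
  events <- as_tibble(events)
  if (!"line" %in% names(events)) events$line <- 0L
  stopifnot(all(c("time_us", "address") %in% names(events)))
  if (is.unsorted(events$time_us)) {
    abort("events must be time-sorted", class = "polysnn_bus_overlap")
  }
  if (any(events$line < 0L | events$line >= n_active_lines)) {
    abort("active line out of range", class = "polysnn_bus_overlap")
  }
  m <- book$spec$width
  nn <- book$spec$weight
  n_wires <- m + n_active_lines
  n_ev <- nrow(events)

  min_gap <- pulse_width +
    if (is.null(model)) 0 else model$width_jitter + 2 * model$skew_max
  if (n_ev > 1 && any(diff(events$time_us) <= min_gap)) {
    abort("events too close to separate on the bus",
          class = "polysnn_bus_overlap")
  }

  # wires touched by each event: N address wires + 1 active wire
  wires_of <- lapply(book$words, .word_wires, m = m)
  wire_mat <- matrix(unlist(wires_of[events$address + 1L]), nrow = nn)
  wire_mat <- rbind(wire_mat, m + 1L + events$line)
  wire_vec <- as.integer(wire_mat)
  ev_of <- rep(seq_len(n_ev), each = nn + 1L)
  t_ev <- events$time_us[ev_of]

  build <- function(skew, jit_fun) {
    rise <- t_ev + skew[wire_vec]
    fall <- rise + pmax(pulse_width + jit_fun(length(rise)), 1e-4)
    out <- tibble(wire = wire_vec, t_on = rise, t_off = fall, glitch = FALSE)
    if (!is.null(model) && model$glitch_rate > 0) {
      # per-event plateau over which all N address wires are simultaneously
      # HIGH; glitches are brief extra pulses on LOW address wires inside it
      addr_rows <- seq_len(nn)
      rise_m <- matrix(rise, nrow = nn + 1L)
      fall_m <- matrix(fall, nrow = nn + 1L)
      p_lo <- apply(rise_m[addr_rows, , drop = FALSE], 2, max)
      p_hi <- apply(fall_m[addr_rows, , drop = FALSE], 2, min)
      span <- p_hi - p_lo - model$glitch_width[2]
      n_g <- ifelse(span > 0, rpois(n_ev, model$glitch_rate * (p_hi - p_lo)), 0L)
      if (sum(n_g) > 0) {
        g_ev <- rep(seq_len(n_ev), n_g)
        g_wire <- vapply(g_ev, function(k) {
          sample(setdiff(seq_len(m), wire_mat[addr_rows, k]), 1L)
        }, integer(1))
        g_on <- p_lo[g_ev] + runif(length(g_ev)) * span[g_ev]
        g_w <- runif(length(g_ev), model$glitch_width[1], model$glitch_width[2])
        g <- tibble(wire = g_wire, t_on = g_on, t_off = g_on + g_w,
                    glitch = TRUE)
        # two glitches landing on the same wire may overlap; keep the first
        g <- dplyr::arrange(g, .data$wire, .data$t_on)
        prev_end <- stats::ave(g$t_off, g$wire, FUN = function(v) {
          cummax(c(-Inf, head(v, -1)))
        })
        out <- dplyr::bind_rows(out, g[g$t_on >= prev_end, ])
      }
    }
    out
  }

  wave <- if (is.null(model)) {
    build(rep(0, n_wires), function(n) rep(0, n))
  } else {
    stopifnot(inherits(model, "polysnn_skew_glitch_model"))
    withr::with_seed(model$seed, {
      skew <- runif(n_wires, -model$skew_max, model$skew_max)
      build(skew, function(n) runif(n, -model$width_jitter, model$width_jitter))
    })
  }

  wave <- dplyr::arrange(wave, .data$wire, .data$t_on)
  same_wire <- diff(wave$wire) == 0L
  if (any(same_wire & head(wave$t_off, -1) > tail(wave$t_on, -1))) {
    abort("overlapping pulses on a wire", class = "polysnn_bus_overlap")
  }
  wave <- dplyr::arrange(wave, .data$t_on)
  structure(wave, class = c("polysnn_bus_waveform", class(wave)),
            n_wires = n_wires, pulse_width = pulse_width,
            m = m, n_active_lines = n_active_lines)
}

# popcount lookup for sampler words (<= 16 address bits)
.pc_table <- local({
  tab <- NULL
  function(nbits) {
    need <- 2L^nbits
    if (is.null(tab) || length(tab) < need) tab <<- .popcount(0:(need - 1L))
    tab
  }
})

#' Sample an asynchronous bus waveform with the three-step interface circuit
#'
#' Behavioural model of the clocked synchronisation interface: (1) each wire
#' goes through a two-register synchroniser (two clock periods of delay);
#' (2) a popcount counter watches the synchronised address and latches it
#' into a FIFO when it *becomes* valid (condition 1), when one valid address
#' is replaced by a different one (condition 2), or — on a multi-active-line
#' bus — when the same valid address reappears with different active lines
#' (condition 3); a valid address merely held on the bus is ignored;
#' (3) the FIFO is drained into fixed-width output spikes, one every four
#' clock cycles.
#'
#' @param wave A [synthesize_bus_waveform()] result (or any tibble with
#'   `wire`, `t_on`, `t_off` columns in microseconds).
#' @param book Codebook used to decode sampled words.
#' @param clock_hz Sampling clock (default 50 MHz).
#' @param fifo_depth FIFO depth (default 32 entries).
#' @param n_active_lines Number of active-line wires.
#' @param dedup_us Optional dedup timer: if set, a re-latch of the same
#'   address within this window is suppressed.  Off by default.
#' @return Tibble (`polysnn_sampled_spikes`) with `tick` (latch clock tick),
#'   `time_us`, `out_tick` (FIFO drain tick), `address` (decoded index) and
#'   `active_lines` (bitmask over L lines).
#' @export
sample_bus <- function(wave, book, clock_hz = 50e6, fifo_depth = 32,
                       n_active_lines = attr(wave, "n_active_lines") %||% 1,
                       dedup_us = NULL) {
  stopifnot(inherits(book, "polysnn_codebook"), clock_hz > 0, fifo_depth > 0)
  m <- book$spec$width
  t_us <- 1e6 / clock_hz

  if (nrow(wave) == 0) return(.empty_samples())

  # raw wire w is HIGH at tick k iff some pulse covers k * t_us; after the
  # two-register synchroniser the value is seen two ticks later
  k_on <- ceiling(wave$t_on / t_us) + 2
  k_off <- ceiling(wave$t_off / t_us) + 2  # first tick back LOW
  keep <- k_off > k_on                     # pulses too short to ever be sampled
  k_on <- k_on[keep]; k_off <- k_off[keep]
  wires <- wave$wire[keep]
  if (!length(k_on)) return(.empty_samples())

  brk <- sort(unique(c(k_on, k_off)))
  seg_start <- brk[-length(brk)]
  n_seg <- length(seg_start)
  addr_word <- numeric(n_seg)
  act_word <- numeric(n_seg)
  for (w in unique(wires)) {
    iv <- which(wires == w)
    o <- order(k_on[iv])
    s <- k_on[iv][o]; e <- k_off[iv][o]
    idx <- findInterval(seg_start, s)
    on <- idx >= 1L & seg_start < e[pmax(idx, 1L)]
    if (w <= m) {
      addr_word <- addr_word + 2^(m - w) * on
    } else {
      act_word <- act_word + 2^(w - m - 1L) * on
    }
  }
  cnt <- .pc_table(m)[addr_word + 1L]
  valid <- cnt == book$spec$weight

  p_addr <- c(0, addr_word[-n_seg])
  p_act <- c(0, act_word[-n_seg])
  p_valid <- c(FALSE, valid[-n_seg])

  c1 <- valid & !p_valid
  c2 <- valid & p_valid & addr_word != p_addr
  c3 <- (n_active_lines > 1) & valid & p_valid & addr_word == p_addr &
    act_word != p_act & act_word != 0
  latch <- which(c1 | c2 | c3)
  if (!length(latch)) return(.empty_samples())

  # active lines of a sample: OR of the active bits over the plateau during
  # which the latched address stays valid (active wires can lag by skew);
  # the scan stops at the next latch so condition-3 samples stay separate
  is_latch <- logical(n_seg)
  is_latch[latch] <- TRUE
  act_out <- integer(length(latch))
  for (i in seq_along(latch)) {
    s <- latch[i]
    acc <- act_word[s]
    j <- s + 1
    while (j <= n_seg && !is_latch[j] && valid[j] &&
           addr_word[j] == addr_word[s]) {
      acc <- bitwOr(as.integer(acc), as.integer(act_word[j]))
      j <- j + 1
    }
    act_out[i] <- acc
  }

  ticks <- seg_start[latch]
  addr <- book$index_of[addr_word[latch] + 1L]

  if (!is.null(dedup_us)) {
    keep <- rep(TRUE, length(ticks))
    last_t <- -Inf; last_a <- -1L
    for (i in seq_along(ticks)) {
      if (addr[i] == last_a && (ticks[i] - last_t) * t_us <= dedup_us) {
        keep[i] <- FALSE
      } else {
        last_t <- ticks[i]; last_a <- addr[i]
      }
    }
    ticks <- ticks[keep]; addr <- addr[keep]; act_out <- act_out[keep]
  }

  # FIFO drain: one fixed-width output spike per 4 clock cycles; occupancy
  # above fifo_depth is an overflow
  out_tick <- numeric(length(ticks))
  dropped <- 0L
  prev_out <- -Inf
  pending <- numeric(0)
  for (i in seq_along(ticks)) {
    pending <- pending[pending > ticks[i]]
    if (length(pending) >= fifo_depth) {
      dropped <- dropped + 1L
      out_tick[i] <- NA_real_
      next
    }
    out_tick[i] <- max(ticks[i], prev_out + 4)
    prev_out <- out_tick[i]
    pending <- c(pending, out_tick[i])
  }
  if (dropped > 0L) {
    abort(sprintf("FIFO overflow: %d entries dropped", dropped),
          class = "polysnn_fifo_overflow", n_dropped = dropped)
  }

  out <- tibble(tick = ticks, time_us = ticks * t_us, out_tick = out_tick,
                address = as.integer(addr), active_lines = as.integer(act_out))
  structure(out, class = c("polysnn_sampled_spikes", class(out)))
}

.empty_samples <- function() {
  out <- tibble(tick = numeric(), time_us = numeric(), out_tick = numeric(),
                address = integer(), active_lines = integer())
  structure(out, class = c("polysnn_sampled_spikes", class(out)))
}

#' Write/read sampled spikes as CSV
#'
#' Serialises sampled bus spikes to the package spike CSV dialect
#' (`tick`, `address_index`, `active_lines`).
#'
#' @param samples A [sample_bus()] result.
#' @param path File path.
#' @return `write_sampled_spikes()` returns `path` invisibly;
#'   `read_sampled_spikes()` returns a tibble.
#' @export
write_sampled_spikes <- function(samples, path) {
  readr::write_csv(
    tibble(tick = samples$tick, address_index = samples$address,
           active_lines = samples$active_lines),
    path
  )
  invisible(path)
}

#' @rdname write_sampled_spikes
#' @export
read_sampled_spikes <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    tick = readr::col_double(),
    address_index = readr::col_integer(),
    active_lines = readr::col_integer()
  ))
}
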