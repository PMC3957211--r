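#' Network configuration
#'
#' Describes a polychronous network: the virtual neuron array size, the
#' axon array size, the neuron backend and its coincidence parameters, the
#' delay-adaptation policy and the optional analog-imperfection model.
#'
#' @param n_neurons Number of virtual neurons (0-based addresses).
#' @param n_axon_modules Number of axon modules (each with 4 delay paths).
#' @param backend `"digital"` (timer coincidence detectors), `"analog"`
#'   (behavioural LIF neurons) or `"multiplexed"` (a pool of `pool_size`
#'   physical neurons leased to virtual addresses).
#' @param n_lines Synapse lines per neuron.
#' @param threshold Coincidence threshold K.
#' @param window Coincidence window W, ms.
#' @param refractory Refractory period, ms.
#' @param analog Optional [analog_neuron()] template for the
#'   analog/multiplexed backends (built with defaults when `NULL`).
#' @param pool_size Physical pool size for the multiplexed backend.
#' @param pool_backend Physical neuron model behind the controller,
#'   `"analog"` or `"digital"`.
#' @param lease_ms Controller lease duration, ms.
#' @param max_delay Axonal ramp range, ms.
#' @param quantization Optional delay quantisation step, ms.
#' @param initiation Number of pattern spikes presented to start a recall;
#'   must be at least `threshold` so the first unseen spike receives K
#'   coincident arrivals.
#' @param policy [adaptation_policy()] used in adaptation-mode training.
#' @param imperfection Optional [imperfection_model()] emulating analog
#'   axons.
#' @param all_firing_factor A recall run is flagged as being in the
#'   all-firing state when it emits more than this multiple of the stored
#'   pattern's spikes.
#' @return A `polysnn_config`.
#' @export
network_config <- function(n_neurons, n_axon_modules,
                           backend = c("digital", "analog", "multiplexed"),
                           n_lines = 4, threshold = 3, window = 1,
                           refractory = 2, analog = NULL,
                           pool_size = 50, pool_backend = c("analog", "digital"),
                           lease_ms = 1,
                           max_delay = 100, quantization = NULL,
                           initiation = 3,
                           policy = adaptation_policy(),
                           imperfection = NULL,
                           all_firing_factor = 5) {
  backend <- match.arg(backend)
  pool_backend <- match.arg(pool_backend)
  stopifnot(n_neurons >= 1, n_axon_modules >= 1,
            threshold >= 1, threshold <= n_lines, window > 0,
            refractory >= 0, max_delay > 0, all_firing_factor > 0)
  if (initiation < threshold) {
    abort("initiation spike count must be at least the coincidence threshold",
          class = "polysnn_invalid_spec")
  }
  if (backend %in% c("analog", "multiplexed") && is.null(analog)) {
    analog <- analog_neuron(n_lines = n_lines, refractory = refractory)
  }
  structure(
    list(n_neurons = as.integer(n_neurons),
         n_axon_modules = as.integer(n_axon_modules),
         backend = backend, n_lines = as.integer(n_lines),
         threshold = as.integer(threshold), window = window,
         refractory = refractory, analog = analog,
         pool_size = as.integer(pool_size), pool_backend = pool_backend,
         lease_ms = lease_ms,
         max_delay = max_delay, quantization = quantization,
         initiation = as.integer(initiation), policy = policy,
         imperfection = imperfection,
         all_firing_factor = all_firing_factor),
    class = "polysnn_config"
  )
}

#' @export
print.polysnn_config <- function(x, ...) {
  cat(sprintf("<polysnn_config> %d neurons, %d axon modules, %s backend (K=%d/%d, W=%g ms)\n",
              x$n_neurons, x$n_axon_modules, x$backend, x$threshold,
              x$n_lines, x$window))
  invisible(x)
}

#' Train a network on a set of patterns
#'
#' Allocates axon modules to pattern spikes in sequential order (spike `k`
#' of a pattern becomes module `k`'s input; the next four spikes become its
#' outputs) and configures the delay paths.  In `programming` mode the
#' observed inter-spike intervals are stored in a single presentation
#' (multiplied by the relative programming error when an imperfection model
#' is active).  In `adaptation` mode delays start from random values (or
#' from a noisy programming pass, see `init`) and are refined by `presentations`
#' supervised replays of the pattern under the configured STDDP policy; each
#' replay pairs every delay path's pre-synaptic arrival with its own target
#' spike.
#'
#' @param config A [network_config()].
#' @param patterns Tibble with `pattern`, `neuron`, `time_ms` (as produced
#'   by [generate_patterns()]).
#' @param mode `"programming"` or `"adaptation"`.
#' @param presentations Number of training presentations in adaptation mode.
#' @param init Initial delays for adaptation mode: `"random"` (uniform over
#'   the ramp range) or `"programming"` (a programming pass first, then
#'   adaptation iterations — the analog axon's schedule).  `"auto"` picks
#'   `"programming"` when an imperfection model is active, else `"random"`.
#' @param seed Optional seed for the random components of training.
#' @return A trained `polysnn_net`.
#' @export
train <- function(config, patterns, mode = c("programming", "adaptation"),
                  presentations = 5, init = c("auto", "random", "programming"),
                  seed = NULL) {
  mode <- match.arg(mode)
  init <- match.arg(init)
  stopifnot(inherits(config, "polysnn_config"))
  patterns <- as_tibble(patterns)
  if (!"pattern" %in% names(patterns)) patterns$pattern <- 1L
  patterns <- dplyr::arrange(patterns, .data$pattern, .data$time_ms)
  if (any(patterns$neuron < 0L | patterns$neuron >= config$n_neurons)) {
    abort("pattern neuron id outside the virtual address space",
          class = "polysnn_invalid_spec")
  }
  incr <- patterns |>
    dplyr::group_by(.data$pattern) |>
    dplyr::summarise(ok = all(diff(.data$time_ms) > 0) || dplyr::n() == 1L)
  if (!all(incr$ok)) {
    abort("pattern times must be strictly increasing",
          class = "polysnn_invalid_spec")
  }
  sizes <- patterns |> dplyr::count(.data$pattern)
  over <- which(cumsum(sizes$n) > config$n_axon_modules)
  if (length(over)) {
    abort(sprintf(
      "axon array capacity exhausted while training pattern %s (%d modules available, %d needed)",
      sizes$pattern[over[1L]], config$n_axon_modules, sum(sizes$n)),
      class = "polysnn_capacity_error")
  }

  run <- function() {
    df <- patterns |>
      dplyr::group_by(.data$pattern) |>
      dplyr::mutate(
        o1 = dplyr::lead(.data$neuron, 1), o2 = dplyr::lead(.data$neuron, 2),
        o3 = dplyr::lead(.data$neuron, 3), o4 = dplyr::lead(.data$neuron, 4),
        d1 = dplyr::lead(.data$time_ms, 1) - .data$time_ms,
        d2 = dplyr::lead(.data$time_ms, 2) - .data$time_ms,
        d3 = dplyr::lead(.data$time_ms, 3) - .data$time_ms,
        d4 = dplyr::lead(.data$time_ms, 4) - .data$time_ms
      ) |>
      dplyr::ungroup()
    n_used <- nrow(df)
    out <- cbind(df$o1, df$o2, df$o3, df$o4)
    target <- cbind(df$d1, df$d2, df$d3, df$d4)
    if (any(target > config$max_delay, na.rm = TRUE)) {
      abort("inter-spike interval exceeds the ramp range (max_delay)",
            class = "polysnn_programming_error")
    }
    nout <- rowSums(!is.na(out))
    imp <- config$imperfection
    set <- !is.na(target)

    delay <- target
    if (mode == "programming" || init == "programming" ||
        (init == "auto" && mode == "adaptation" && !is.null(imp))) {
      if (!is.null(imp) && imp$sigma > 0) {
        delay[set] <- target[set] * (1 + rnorm(sum(set), 0, imp$sigma))
        delay[set] <- pmin(pmax(delay[set], 1e-9), config$max_delay)
      }
    } else if (mode == "adaptation") {
      delay[set] <- runif(sum(set), 1e-9, config$max_delay)
    }
    if (mode == "adaptation") {
      jit <- if (!is.null(imp)) imp$residual else 0
      for (p in seq_len(presentations)) {
        arr <- delay[set] + if (jit > 0) runif(sum(set), -jit, jit) else 0
        delay[set] <- adapt_delay(delay[set], arr, target[set],
                                  policy = config$policy,
                                  max_delay = config$max_delay)
      }
    }
    if (!is.null(config$quantization)) {
      delay[set] <- .quantize(delay[set], config$quantization)
    }

    input <- df$neuron
    # routing index: configured modules grouped by input address (CSR form)
    ord <- order(input)
    counts <- tabulate(input + 1L, nbins = config$n_neurons)
    list(input = as.integer(input),
         input_t = df$time_ms,
         out = matrix(as.integer(out), n_used, 4),
         delay = delay, nout = as.integer(nout),
         target = target,
         module_pattern = df$pattern,
         addr_ptr = c(0L, cumsum(counts)),
         addr_mod = as.integer(ord - 1L),
         n_configured = n_used)
  }
  core <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  structure(
    c(list(config = config, mode = mode,
           n_patterns = length(unique(patterns$pattern))), core),
    class = "polysnn_net"
  )
}

#' @export
print.polysnn_net <- function(x, ...) {
  cat(sprintf("<polysnn_net> %s backend; %d/%d modules configured (%d patterns, %s mode)\n",
              x$config$backend, x$n_configured, x$config$n_axon_modules,
              x$n_patterns, x$mode))
  invisible(x)
}

#' Recall a stored pattern
#'
#' Presents the first `initiation` spikes of the pattern as post-synaptic
#' spikes at their original relative times (offset by `t0`), merges the
#' optional noise train as pre-synaptic arrivals, and runs the event loop
#' until quiescence or the time cap
#' `t0 + pattern duration + 10 * max_delay`.  A run that emits more than
#' `all_firing_factor` times the stored spike count is cut off and flagged
#' as all-firing.
#'
#' @param net A trained [train()] network.
#' @param pattern Tibble with `neuron`, `time_ms` for one pattern.
#' @param t0 Start offset of the recall, ms.
#' @param noise Optional tibble `time_ms`, `neuron`, `line` of noise spikes
#'   (absolute times).
#' @param initiation Number of initiation spikes (default from the config;
#'   0 returns an empty train).
#' @param engine `"cpp"` (compiled event loop, digital backend),
#'   `"r"` (reference event loop, any backend) or `"auto"`.
#' @param seed Seed for emission jitter / spurious draws; drawn from the
#'   session RNG when `NULL`.
#' @return A `polysnn_recall`: list with `spikes` (tibble `time_ms`,
#'   `neuron`), `all_firing`, `n_events`, `n_dropped`, `t0`, `initiation`.
#' @export
recall <- function(net, pattern, t0 = 0, noise = NULL, initiation = NULL,
                   engine = c("auto", "cpp", "r"), seed = NULL) {
  stopifnot(inherits(net, "polysnn_net"))
  engine <- match.arg(engine)
  cfg <- net$config
  pattern <- dplyr::arrange(as_tibble(pattern), .data$time_ms)
  if ("pattern" %in% names(pattern) &&
      length(unique(pattern$pattern)) > 1L) {
    abort("recall() takes a single pattern; see recall_patterns()",
          class = "polysnn_invalid_spec")
  }
  initiation <- as.integer(initiation %||% cfg$initiation)
  if (initiation <= 0L) {
    return(structure(list(spikes = tibble(time_ms = numeric(),
                                          neuron = integer()),
                          all_firing = FALSE, n_events = 0, n_dropped = 0L,
                          t0 = t0, initiation = 0L, engine = "none"),
                     class = "polysnn_recall"))
  }
  initiation <- min(initiation, nrow(pattern))
  init_t <- pattern$time_ms[seq_len(initiation)] + t0
  init_n <- pattern$neuron[seq_len(initiation)]
  t_end <- t0 + max(pattern$time_ms) + 10 * cfg$max_delay
  max_emitted <- ceiling(cfg$all_firing_factor * nrow(pattern))
  imp <- cfg$imperfection
  jitter <- if (!is.null(imp)) imp$residual else 0
  spurious_p <- if (!is.null(imp)) imp$spurious_p else 0
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  if (is.null(noise)) {
    noise <- tibble(time_ms = numeric(), neuron = integer(), line = integer())
  }

  if (engine == "auto") engine <- if (cfg$backend == "digital") "cpp" else "r"
  if (engine == "cpp" && cfg$backend != "digital") {
    abort("the compiled engine only supports the digital backend",
          class = "polysnn_invalid_spec")
  }

  if (engine == "cpp") {
    res <- cpp_recall_digital(
      net$nout, net$out, net$delay, net$addr_ptr, net$addr_mod,
      cfg$n_neurons, cfg$n_lines, cfg$threshold, cfg$window, cfg$refractory,
      init_t, as.integer(init_n),
      noise$time_ms, as.integer(noise$neuron), as.integer(noise$line),
      t_end, as.integer(max_emitted), jitter, spurious_p, as.integer(seed))
    out <- list(spikes = tibble(time_ms = res$time_ms,
                                neuron = as.integer(res$neuron)),
                all_firing = res$all_firing, n_events = res$n_events,
                n_dropped = 0L, t0 = t0, initiation = initiation,
                engine = "cpp")
  } else {
    res <- withr::with_seed(seed, .r_recall(
      net, init_t, init_n, noise, t_end, max_emitted, jitter, spurious_p))
    out <- c(res, list(t0 = t0, initiation = initiation, engine = "r"))
  }
  structure(out, class = "polysnn_recall")
}

#' @export
print.polysnn_recall <- function(x, ...) {
  cat(sprintf("<polysnn_recall> %d emitted spikes (%s engine)%s\n",
              nrow(x$spikes), x$engine,
              if (x$all_firing) " [ALL-FIRING]" else ""))
  invisible(x)
}

#' Recall and score every stored pattern
#'
#' @param net A trained network.
#' @param patterns The training pattern set (`pattern`, `neuron`,
#'   `time_ms`).
#' @param t0 Recall offset, ms.
#' @param noise Optional noise train shared across recalls.
#' @param tolerance,success_threshold Scoring parameters, see
#'   [score_recall()].
#' @param seed Optional seed; per-pattern engine seeds are derived from it.
#' @param ... Passed on to [recall()].
#' @return Tibble with one row per pattern: scoring columns from
#'   [score_recall()] plus `pattern`.
#' @export
recall_patterns <- function(net, patterns, t0 = 0, noise = NULL,
                            tolerance = 1, success_threshold = 0.95,
                            seed = NULL, ...) {
  patterns <- as_tibble(patterns)
  ids <- unique(patterns$pattern)
  seeds <- if (is.null(seed)) {
    sample.int(.Machine$integer.max - 1L, length(ids))
  } else {
    withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, length(ids)))
  }
  purrr::map2(ids, seeds, function(id, s) {
    pat <- patterns[patterns$pattern == id, ]
    run <- recall(net, pat, t0 = t0, noise = noise, seed = s, ...)
    sc <- score_recall(pat, run, tolerance = tolerance,
                       success_threshold = success_threshold)
    sc$pattern <- id
    sc
  }) |>
    dplyr::bind_rows() |>
    dplyr::relocate("pattern")
}

#' Router lookup tables
#'
#' The router remaps spike addresses between the binary address space used
#' internally and the physical k-of-n bus encodings: binary index `i` maps
#' to the `i`-th codeword in lexicographic order.  Four conversions exist
#' (to/from the 3-of-8 neuron bus and the 4-of-9 axon bus).
#'
#' @param neuron_spec,axon_spec [code_spec()]s of the two buses.
#' @return A `polysnn_router` holding the two codebooks.
#' @export
router_tables <- function(neuron_spec = code_spec(8, 3),
                          axon_spec = code_spec(9, 4)) {
  structure(list(neuron = build_codebook(neuron_spec),
                 axon = build_codebook(axon_spec)),
            class = "polysnn_router")
}

#' Remap event addresses through the router
#'
#' Rewrites the `address` column of an event table between binary indices
#' and bus codewords; times and lines are preserved.  An address outside
#' the table's domain (e.g. a virtual address beyond the physical bus
#' limit) raises a routing error.
#'
#' @param tables A [router_tables()].
#' @param events Tibble with an `address` column.
#' @param direction One of `"neuron_to_bus"`, `"bus_to_neuron"`,
#'   `"axon_to_bus"`, `"bus_to_axon"`.
#' @return The events with `address` rewritten.
#' @export
remap <- function(tables, events,
                  direction = c("neuron_to_bus", "bus_to_neuron",
                                "axon_to_bus", "bus_to_axon")) {
  stopifnot(inherits(tables, "polysnn_router"))
  direction <- match.arg(direction)
  book <- if (grepl("neuron", direction)) tables$neuron else tables$axon
  to_bus <- direction %in% c("neuron_to_bus", "axon_to_bus")
  events <- as_tibble(events)
  new <- tryCatch(
    if (to_bus) aer_encode(book, events$address)
    else aer_decode(book, events$address),
    error = function(e) {
      abort(paste0("unmapped address: ", conditionMessage(e)),
            class = "polysnn_routing_error")
    }
  )
  events$address <- new
  events
}

#' Write/read a network configuration
#'
#' Serialises a [network_config()] to YAML (`.yml`/`.yaml`) or JSON.
#'
#' @param config A [network_config()].
#' @param path File path.
#' @return `path` invisibly / the reconstructed config.
#' @export
write_config <- function(config, path) {
  doc <- config[c("n_neurons", "n_axon_modules", "backend", "n_lines",
                  "threshold", "window", "refractory", "pool_size",
                  "pool_backend", "lease_ms", "max_delay", "quantization",
                  "initiation", "all_firing_factor")]
  doc$policy <- unclass(config$policy)
  doc$imperfection <- if (!is.null(config$imperfection)) {
    unclass(config$imperfection)
  }
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  network_config(
    n_neurons = doc$n_neurons, n_axon_modules = doc$n_axon_modules,
    backend = doc$backend, n_lines = doc$n_lines, threshold = doc$threshold,
    window = as.numeric(doc$window), refractory = as.numeric(doc$refractory),
    pool_size = doc$pool_size, pool_backend = doc$pool_backend,
    lease_ms = as.numeric(doc$lease_ms), max_delay = as.numeric(doc$max_delay),
    quantization = doc$quantization, initiation = doc$initiation,
    policy = do.call(adaptation_policy, doc$policy),
    imperfection = if (!is.null(doc$imperfection)) {
      do.call(imperfection_model, doc$imperfection)
    },
    all_firing_factor = as.numeric(doc$all_firing_factor)
  )
}

#' Serialise a trained network to JSON
#'
#' Writes the configuration and every configured axon module (input,
#' outputs, delays, pattern provenance) so a recall session can be
#' reproduced later or on another machine.
#'
#' @param net A trained [train()] network.
#' @param path Output file path.
#' @return `path` invisibly / the reconstructed network.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "polysnn_net"))
  cfg_path <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_path))
  write_config(net$config, cfg_path)
  doc <- list(
    config = jsonlite::read_json(cfg_path, simplifyVector = TRUE),
    mode = net$mode,
    n_patterns = net$n_patterns,
    input = net$input,
    input_t = net$input_t,
    out = net$out,
    delay = net$delay,
    nout = net$nout,
    target = net$target,
    module_pattern = net$module_pattern
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg_path <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_path))
  jsonlite::write_json(doc$config, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  config <- read_config(cfg_path)
  as_int_mat <- function(m) matrix(as.integer(m), nrow(m), ncol(m))
  input <- as.integer(doc$input)
  counts <- tabulate(input + 1L, nbins = config$n_neurons)
  structure(
    list(config = config, mode = doc$mode, n_patterns = doc$n_patterns,
         input = input, input_t = as.numeric(doc$input_t),
         out = as_int_mat(doc$out), delay = doc$delay,
         nout = as.integer(doc$nout), target = doc$target,
         module_pattern = doc$module_pattern,
         addr_ptr = c(0L, cumsum(counts)),
         addr_mod = as.integer(order(input) - 1L),
         n_configured = length(input)),
    class = "polysnn_net"
  )
}
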