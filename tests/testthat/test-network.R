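test_that("a five-neuron, threshold-2 chain completes from two spikes", {
  # neurons 1 and 5 fire asynchronously; their spikes arrive at neuron 3
  # together, which fires and (with neuron 5) drives neuron 2, and so on
  t1 <- 3; t2 <- 5; t3 <- 4
  pat <- data.frame(neuron = c(1L, 5L, 3L, 2L),
                    time_ms = c(0, t1, t1 + t2, t1 + t2 + t3))
  cfg <- network_config(n_neurons = 6, n_axon_modules = 4,
                        threshold = 2, initiation = 2)
  net <- train(cfg, pat, "programming")
  r <- recall(net, pat, t0 = 0, seed = 1)
  expect_identical(r$spikes$neuron, c(3L, 2L))
  expect_equal(r$spikes$time_ms, c(t1 + t2, t1 + t2 + t3))
})

test_that("noiseless programming recall reproduces stored times exactly", {
  fx <- make_small_net(11, n_neurons = 126, n_patterns = 5,
                       pattern_length = 20)
  for (p in 1:5) {
    pat <- fx$patterns[fx$patterns$pattern == p, ]
    r <- recall(fx$net, pat, t0 = 50, seed = p)
    expect_false(r$all_firing)
    got <- r$spikes[order(r$spikes$time_ms), ]
    exp <- pat[-(1:3), ]
    # cross-talk can add spikes; every stored spike must appear exactly
    hit <- vapply(seq_len(nrow(exp)), function(i) {
      any(got$neuron == exp$neuron[i] &
            abs(got$time_ms - (exp$time_ms[i] + 50)) < 1e-9)
    }, logical(1))
    expect_true(all(hit))
  }
})

test_that("mid-pattern entry recalls the tail of the pattern", {
  fx <- make_small_net(13, n_neurons = 200, n_patterns = 3,
                       pattern_length = 15)
  pat <- fx$patterns[fx$patterns$pattern == 2, ]
  tail_pat <- pat[6:15, ]
  r <- recall(fx$net, tail_pat, t0 = 0, seed = 4)
  sc <- score_recall(tail_pat, r)
  expect_identical(sc$fraction, 1)
})

test_that("recall with zero initiation spikes returns an empty train", {
  fx <- make_small_net(17)
  pat <- fx$patterns[fx$patterns$pattern == 1, ]
  r <- recall(fx$net, pat, initiation = 0)
  expect_identical(nrow(r$spikes), 0L)
})

test_that("identical config and seeds give identical spike trains", {
  fx <- make_small_net(19)
  pat <- fx$patterns[fx$patterns$pattern == 1, ]
  noise <- generate_noise(64, 300, 64, seed = 2)
  a <- recall(fx$net, pat, noise = noise, seed = 5)
  b <- recall(fx$net, pat, noise = noise, seed = 5)
  expect_identical(a$spikes, b$spikes)
})

test_that("every emitted spike respects causality", {
  fx <- make_small_net(23)
  pat <- fx$patterns[fx$patterns$pattern == 3, ]
  r <- recall(fx$net, pat, t0 = 100, seed = 6)
  expect_true(all(r$spikes$time_ms >= 100))
})

test_that("the compiled and reference engines emit identical trains", {
  for (seed in c(101, 202, 303)) {
    fx <- make_small_net(seed, n_neurons = 48, n_patterns = 8,
                         pattern_length = 10)
    for (p in c(1, 4, 8)) {
      pat <- fx$patterns[fx$patterns$pattern == p, ]
      noise <- generate_noise(100, 200, 48, seed = seed + p)
      a <- recall(fx$net, pat, noise = noise, engine = "cpp", seed = 9)
      b <- recall(fx$net, pat, noise = noise, engine = "r", seed = 9)
      expect_identical(a$spikes, b$spikes)
      expect_identical(a$all_firing, b$all_firing)
    }
  }
})

test_that("adaptation with the exact strategy equals delay programming", {
  pats <- generate_patterns(3, 10, 60, seed = 41)
  cfg <- network_config(n_neurons = 60, n_axon_modules = 30,
                        policy = adaptation_policy("exact"))
  prog <- train(cfg, pats, "programming")
  adap <- train(cfg, pats, "adaptation", presentations = 1, init = "random",
                seed = 77)
  expect_equal(adap$delay, prog$delay, tolerance = 1e-12)
})

test_that("training past the axon capacity raises a capacity error", {
  pats <- generate_patterns(6, 20, 126, disjoint = FALSE, seed = 43)
  cfg <- network_config(n_neurons = 126, n_axon_modules = 100)
  expect_error(train(cfg, pats), class = "polysnn_capacity_error")
  expect_error(train(cfg, pats), "pattern 6")
})

test_that("analog and multiplexed backends complete disjoint patterns", {
  pats <- generate_patterns(2, 10, 126, disjoint = TRUE, seed = 47)
  for (backend in c("analog", "multiplexed")) {
    cfg <- network_config(n_neurons = 126, n_axon_modules = 20,
                          backend = backend)
    net <- train(cfg, pats, "programming")
    for (p in 1:2) {
      pat <- pats[pats$pattern == p, ]
      sc <- score_recall(pat, recall(net, pat, seed = p))
      expect_gte(sc$fraction, 0.9)
    }
  }
})

test_that("router remapping is invertible and rejects unmapped addresses", {
  rt <- router_tables()
  ev <- tibble::tibble(address = c(0L, 10L, 55L), time_ms = 1:3, line = 0L)
  bus <- remap(rt, ev, "neuron_to_bus")
  expect_identical(bus$address[1], build_codebook(code_spec(8, 3))$words[1])
  back <- remap(rt, bus, "bus_to_neuron")
  expect_identical(back, ev)
  expect_error(remap(rt, tibble::tibble(address = 56L), "neuron_to_bus"),
               class = "polysnn_routing_error")
  expect_error(remap(rt, tibble::tibble(address = 1L), "bus_to_neuron"),
               class = "polysnn_routing_error")
})

test_that("configs survive YAML and JSON round trips", {
  cfg <- network_config(128, 4096, imperfection = imperfection_model(),
                        policy = adaptation_policy("fixed_step", step = 0.2))
  for (ext in c(".yml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_config(cfg, path)
    back <- read_config(path)
    expect_identical(back$n_neurons, cfg$n_neurons)
    expect_identical(back$policy, cfg$policy)
    expect_identical(back$imperfection$sigma, cfg$imperfection$sigma)
  }
})

test_that("tidy and glance expose the trained delay structure", {
  fx <- make_small_net(53, n_patterns = 2, pattern_length = 6)
  td <- tidy(fx$net)
  expect_identical(nrow(td), sum(fx$net$nout))
  expect_true(all(td$delay_ms == td$target_ms))  # noiseless programming
  g <- glance(fx$net)
  expect_identical(g$n_configured, 12L)
})
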