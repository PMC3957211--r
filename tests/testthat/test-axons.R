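pat3 <- data.frame(neuron = c(10L, 20L, 30L, 40L, 50L, 60L),
                   time_ms = c(0, 3, 8, 11, 20, 26))

feed_pattern <- function(array, pat) {
  array <- begin_pattern(array)
  for (i in seq_len(nrow(pat))) {
    array <- allocate_on_training_spike(array, pat$neuron[i], pat$time_ms[i])
  }
  array
}

test_that("sequential allocation wires each spike to the next four", {
  arr <- feed_pattern(axon_array(10), pat3)
  expect_identical(arr$input[1:6], pat3$neuron)
  expect_identical(arr$out[1, ], pat3$neuron[2:5])
  expect_identical(arr$delay[1, ], pat3$time_ms[2:5] - pat3$time_ms[1])
  expect_identical(arr$out[3, 1:3], pat3$neuron[4:6])
  expect_identical(arr$nout, c(4L, 4L, 3L, 2L, 1L, 0L, 0L, 0L, 0L, 0L))
})

test_that("a 2-spike pattern leaves trailing modules partly configured", {
  arr <- feed_pattern(axon_array(4), data.frame(neuron = c(1L, 2L),
                                                time_ms = c(0, 5)))
  expect_identical(arr$nout[1:2], c(1L, 0L))
  expect_true(is.na(arr$input[3]))
})

test_that("pattern boundaries stop output configuration leaking", {
  arr <- axon_array(10)
  arr <- feed_pattern(arr, pat3[1:3, ])
  arr <- feed_pattern(arr, data.frame(neuron = 99L, time_ms = 0))
  # module 2 (input 20) must not have latched the next pattern's spike
  expect_identical(arr$nout[2], 1L)
  expect_identical(arr$input[4], 99L)
})

test_that("a pattern of S spikes consumes exactly S modules", {
  arr <- axon_array(100)
  for (p in 1:5) {
    arr <- feed_pattern(arr, data.frame(neuron = sample(0:99, 20),
                                        time_ms = cumsum(runif(20, 5, 15))))
  }
  expect_identical(arr$next_free, 101L)
  expect_error(allocate_on_training_spike(begin_pattern(arr), 1L, 0),
               class = "polysnn_capacity_error")
})

test_that("pattern capacity follows floor(modules / length)", {
  expect_identical(axon_capacity(100, c(20, 25, 33, 50)), c(5L, 4L, 3L, 2L))
  expect_identical(axon_capacity(4096, 51), 80L)
})

test_that("digital delay programming stores the interval exactly", {
  arr <- axon_array(4)
  arr <- begin_pattern(arr)
  arr <- allocate_on_training_spike(arr, 0L, 100)
  arr <- allocate_on_training_spike(arr, 1L, 112.5)
  expect_identical(arr$delay[1, 1], 12.5)
})

test_that("analog programming errors stay within 3 sigma almost surely", {
  withr::with_seed(8, {
    imp <- imperfection_model(sigma = 0.10)
    arr <- axon_array(3000)
    target <- 10
    for (i in 1:3000) {
      arr <- begin_pattern(arr)
      arr <- allocate_on_training_spike(arr, 0L, 0)
      arr <- program_delay(arr, i, 1, 0, target, imp)
    }
    rel <- abs(arr$delay[, 1] - target) / target
    expect_gt(mean(rel <= 0.30), 0.99)
  })
})

test_that("zero or out-of-range delays raise programming errors", {
  arr <- axon_array(2)
  expect_error(program_delay(arr, 1, 1, 5, 5),
               class = "polysnn_programming_error")
  expect_error(program_delay(arr, 1, 1, 5, 4),
               class = "polysnn_programming_error")
  expect_error(program_delay(arr, 1, 1, 0, 200),
               class = "polysnn_programming_error")
})

test_that("a matching post-synaptic spike emits on every configured path", {
  arr <- feed_pattern(axon_array(10), pat3)
  em <- on_postsyn_spike(arr, 10L, t = 100)
  expect_identical(em$time_ms, 100 + c(3, 8, 11, 20))
  expect_identical(em$neuron, c(20L, 30L, 40L, 50L))
  expect_identical(em$line, 0:3)
  expect_identical(nrow(on_postsyn_spike(arr, 77L, t = 100)), 0L)
})

test_that("modules sharing an input address all fire", {
  arr <- axon_array(4)
  for (p in 1:2) {
    arr <- feed_pattern(arr, data.frame(neuron = c(5L, 6L + p),
                                        time_ms = c(0, 4 + p)))
  }
  em <- on_postsyn_spike(arr, 5L, t = 0)
  expect_identical(sort(em$neuron), c(7L, 8L))
})

test_that("STDDP strategies leave a zero error untouched and contract", {
  pol_e <- adaptation_policy("exact")
  pol_f <- adaptation_policy("fixed_step", step = 0.1)
  pol_p <- adaptation_policy("proportional", coefficient = 0.5)
  for (pol in list(pol_e, pol_f, pol_p)) {
    expect_equal(adapt_delay(10, 105, 105, pol), 10)
  }
  # proportional halving: error 8 -> 4, 2, 1, 0.5, 0.25
  d <- 18
  errs <- numeric(5)
  for (i in 1:5) {
    d <- adapt_delay(d, 100 + d, 110, pol_p)
    errs[i] <- d - 10
  }
  expect_equal(errs, c(4, 2, 1, 0.5, 0.25))
  # exact correction reproduces delay programming in one step
  expect_equal(adapt_delay(37, 100 + 37, 100 + 12.5, pol_e), 12.5)
  # fixed step moves toward the target by exactly `step`
  expect_equal(adapt_delay(10, 105, 104, pol_f), 9.9)
})

test_that("proportional contraction follows (1 - c)^n in the noiseless case", {
  for (c0 in c(0.25, 0.5, 1)) {
    pol <- adaptation_policy("proportional", coefficient = c0)
    d <- 30; target <- 12
    for (n in 1:6) {
      d <- adapt_delay(d, d, target, pol)
      expect_equal(abs(d - target), (1 - c0)^n * 18, tolerance = 1e-9)
    }
  }
})

test_that("trained axon arrays survive a JSON round trip", {
  arr <- feed_pattern(axon_array(10), pat3)
  path <- withr::local_tempfile(fileext = ".json")
  write_axon_array(arr, path)
  back <- read_axon_array(path)
  expect_identical(back$input, arr$input)
  expect_identical(back$out, arr$out)
  expect_equal(back$delay, arr$delay)
  expect_identical(back$nout, arr$nout)
})

test_that("single-spike allocation agrees with the vectorised trainer", {
  withr::with_seed(31, {
    pats <- generate_patterns(4, 9, 40, seed = 3)
    cfg <- network_config(n_neurons = 40, n_axon_modules = 36)
    net <- train(cfg, pats, "programming")
    arr <- axon_array(36)
    for (p in unique(pats$pattern)) {
      arr <- feed_pattern(arr, pats[pats$pattern == p, c("neuron", "time_ms")])
    }
    expect_identical(arr$input[1:36], net$input)
    expect_identical(arr$out[1:36, ], net$out)
    expect_equal(arr$delay[1:36, ], net$delay)
  })
})
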