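test_that("generated patterns respect ISI bounds and expected duration", {
  pats <- generate_patterns(20, 51, 512, seed = 1)
  by_pat <- split(pats, pats$pattern)
  isis <- unlist(lapply(by_pat, function(p) diff(p$time_ms)))
  expect_true(all(isis >= 5 & isis <= 15))
  # 50 intervals with mean 10 ms: about 500 ms per pattern
  durs <- vapply(by_pat, function(p) max(p$time_ms), numeric(1))
  expect_equal(mean(durs), 500, tolerance = 0.05)
})

test_that("no neuron repeats within any five consecutive spikes", {
  pats <- generate_patterns(30, 51, 128, seed = 2)
  ok <- vapply(split(pats$neuron, pats$pattern), function(v) {
    all(vapply(seq_len(length(v) - 4), function(i) {
      !anyDuplicated(v[i:(i + 4)])
    }, logical(1)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("disjoint mode partitions the neuron space", {
  pats <- generate_patterns(5, 20, 126, disjoint = TRUE, seed = 3)
  sets <- split(pats$neuron, pats$pattern)
  expect_false(anyDuplicated(unlist(sets)) > 0)
  expect_error(generate_patterns(5, 30, 126, disjoint = TRUE),
               class = "polysnn_spec_error")
})

test_that("pattern generation is reproducible from the seed", {
  expect_identical(generate_patterns(4, 10, 64, seed = 9),
                   generate_patterns(4, 10, 64, seed = 9))
})

test_that("noise generation follows Poisson statistics", {
  expect_identical(nrow(generate_noise(0, 1000, 128)), 0L)
  n <- nrow(generate_noise(128, 1000, 128, seed = 4))
  expect_lt(abs(n - 128), 3 * sqrt(128))
  tr <- generate_noise(50, 500, 64, seed = 5)
  expect_true(all(tr$neuron >= 0 & tr$neuron < 64))
  expect_true(all(tr$line %in% 0:3))
  expect_false(is.unsorted(tr$time_ms))
})

test_that("scoring matches jitter against the tolerance edge", {
  pat <- data.frame(neuron = 0:4, time_ms = c(0, 10, 20, 30, 40))
  hit <- data.frame(neuron = 3:4, time_ms = c(30.29, 40.29))
  miss <- data.frame(neuron = 3:4, time_ms = c(30.31, 40.31))
  expect_identical(
    score_recall(pat, hit, tolerance = 0.3, initiation = 3)$fraction, 1)
  expect_identical(
    score_recall(pat, miss, tolerance = 0.3, initiation = 3)$fraction, 0)
})

test_that("an all-firing run never counts as success", {
  pat <- data.frame(neuron = 0:4, time_ms = c(0, 10, 20, 30, 40))
  em <- data.frame(neuron = 3:4, time_ms = c(30, 40))
  sc <- score_recall(pat, em, all_firing = TRUE)
  expect_identical(sc$fraction, 1)
  expect_false(sc$success)
})

test_that("scoring is monotone in correct and spurious spikes", {
  withr::with_seed(6, {
    pat <- data.frame(neuron = sample(0:20, 10), time_ms = cumsum(runif(10, 5, 15)))
    part <- pat[c(4:7), ]
    base <- score_recall(pat, part)$fraction
    more <- score_recall(pat, pat[4:10, ])$fraction
    expect_gte(more, base)
    spur <- rbind(part, data.frame(neuron = 19L, time_ms = 999))
    expect_lte(score_recall(pat, spur)$fraction, base)
  })
})

test_that("spike trains round-trip through the CSV dialect", {
  tr <- generate_noise(40, 200, 32, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spikes(tr, path)
  back <- read_spikes(path)
  expect_equal(back$time_ms, tr$time_ms)
  expect_identical(back$neuron, tr$neuron)
  expect_identical(back$line, tr$line)
})
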