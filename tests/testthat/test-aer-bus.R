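book38 <- build_codebook(code_spec(8, 3))
book49 <- build_codebook(code_spec(9, 4))

test_that("an ideal bus waveform aligns pulses exactly with event times", {
  ev <- tibble::tibble(time_us = c(0, 10, 20), address = c(0L, 5L, 55L))
  w <- synthesize_bus_waveform(ev, book38, pulse_width = 1)
  expect_true(all(w$t_on %in% ev$time_us))
  expect_true(all(w$t_off - w$t_on == 1))
  # each event touches exactly 3 address wires + 1 active wire
  per_event <- split(w$wire, findInterval(w$t_on, c(-1, 5, 15, 25)))
  expect_true(all(lengths(per_event) == 4L))
  expect_true(all(vapply(per_event, function(v) sum(v <= 8), 0L) == 3L))
})

test_that("waveform synthesis is reproducible from the model seed", {
  ev <- tibble::tibble(time_us = seq(0, 90, by = 10), address = 0:9)
  mdl <- skew_glitch_model(seed = 7)
  w1 <- synthesize_bus_waveform(ev, book38, model = mdl)
  w2 <- synthesize_bus_waveform(ev, book38, model = mdl)
  expect_identical(as.data.frame(w1), as.data.frame(w2))
})

test_that("events closer than the pulse width are rejected", {
  ev <- tibble::tibble(time_us = c(0, 0.5), address = c(0L, 1L))
  expect_error(synthesize_bus_waveform(ev, book38, pulse_width = 1),
               class = "polysnn_bus_overlap")
})

test_that("a clean waveform samples once per event with correct addresses", {
  ev <- tibble::tibble(time_us = seq(0, 40, by = 10),
                       address = c(5L, 17L, 5L, 42L, 0L))
  s <- sample_bus(synthesize_bus_waveform(ev, book38), book38)
  expect_identical(nrow(s), 5L)
  expect_identical(s$address, ev$address)
  expect_true(all(s$active_lines == 1L))
})

test_that("a stable valid address is latched once, not repeatedly", {
  # address held HIGH for 1000 ticks: condition 1 fires once at the rise
  wires <- polysnn:::.word_wires(aer_encode(book38, 12L), 8)
  w <- tibble::tibble(wire = c(wires, 9L), t_on = 0, t_off = 20)
  s <- sample_bus(w, book38)
  expect_identical(nrow(s), 1L)
  expect_identical(s$address, 12L)
})

test_that("condition 2 latches a valid address replacing a different one", {
  w1 <- polysnn:::.word_wires(aer_encode(book38, 3L), 8)
  w2 <- polysnn:::.word_wires(aer_encode(book38, 40L), 8)
  # back-to-back pulses: the bus goes directly from one valid word to
  # another on the shared tick boundary
  w <- tibble::tibble(
    wire = c(w1, 9L, w2, 9L),
    t_on = rep(c(0, 5), each = 4),
    t_off = rep(c(5, 10), each = 4)
  )
  s <- sample_bus(w, book38)
  expect_identical(s$address, c(3L, 40L))
})

test_that("condition 3 latches same address re-sent on a different line", {
  wires <- polysnn:::.word_wires(aer_encode(book49, 100L), 9)
  w <- tibble::tibble(
    wire = c(wires, 10L, 12L),          # active lines 0 and 2
    t_on = c(rep(0, 4), 0, 2),
    t_off = c(rep(4, 4), 1, 3)
  )
  s <- sample_bus(w, book49, n_active_lines = 4)
  expect_identical(nrow(s), 2L)
  expect_identical(s$address, c(100L, 100L))
  expect_identical(s$active_lines, c(1L, 4L))
})

test_that("skewed/glitched waveforms never produce wrong addresses", {
  mdl <- skew_glitch_model(skew_max = 0.2, glitch_rate = 0.1, seed = 3)
  ev <- tibble::tibble(time_us = (0:199) * 50,
                       address = rep(0:49, 4))
  s <- sample_bus(synthesize_bus_waveform(ev, book38, model = mdl), book38)
  # collapse immediate duplicate re-samples of the same address
  keep <- c(TRUE, !(diff(s$address) == 0 & diff(s$time_us) <= 2))
  expect_identical(s$address[keep], ev$address)
  # duplicates only repeat the immediately preceding address within 1 us
  dup <- which(!keep)
  expect_true(all(s$address[dup] == s$address[dup - 1L]))
  expect_true(all(s$time_us[dup] - s$time_us[dup - 1L] < 1))
})

test_that("the optional dedup timer suppresses duplicate samples", {
  mdl <- skew_glitch_model(skew_max = 0.2, glitch_rate = 0.3, seed = 11)
  ev <- tibble::tibble(time_us = (0:99) * 50, address = rep(0:49, 2))
  w <- synthesize_bus_waveform(ev, book38, model = mdl)
  s_raw <- sample_bus(w, book38)
  s_dedup <- sample_bus(w, book38, dedup_us = 1)
  expect_gte(nrow(s_raw), nrow(s_dedup))
  expect_identical(nrow(s_dedup), nrow(ev))
})

test_that("sampling latency stays within synchroniser + skew + drain", {
  t_us <- 1e6 / 50e6
  mdl <- skew_glitch_model(skew_max = 0.2, glitch_rate = 0, seed = 5)
  ev <- tibble::tibble(time_us = (0:49) * 50, address = 0:49)
  s <- sample_bus(synthesize_bus_waveform(ev, book38, model = mdl), book38)
  lat <- s$out_tick * t_us - ev$time_us
  expect_true(all(abs(lat) <= 0.2 + 3 * t_us + 4 * t_us))
})

test_that("FIFO overflow raises an error carrying the dropped count", {
  # 60 distinct valid addresses changing every tick: latches outrun the
  # 4-cycle drain and overflow the 32-deep FIFO
  t_us <- 1e6 / 50e6
  rows <- lapply(0:59, function(i) {
    tibble::tibble(wire = polysnn:::.word_wires(book49$words[i + 1], 9),
                   t_on = i * t_us, t_off = (i + 1) * t_us)
  })
  w <- dplyr::bind_rows(rows)
  err <- tryCatch(sample_bus(w, book49, n_active_lines = 1),
                  polysnn_fifo_overflow = function(e) e)
  expect_s3_class(err, "polysnn_fifo_overflow")
  expect_gt(err$n_dropped, 0)
})

test_that("sampled spikes round-trip through the spike CSV", {
  ev <- tibble::tibble(time_us = seq(0, 40, by = 10), address = 0:4)
  s <- sample_bus(synthesize_bus_waveform(ev, book38), book38)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sampled_spikes(s, path)
  back <- read_sampled_spikes(path)
  expect_identical(back$address_index, s$address)
  expect_identical(back$tick, s$tick)
})
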