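test_that("spikes to the same address within the lease share one neuron", {
  ctrl <- controller_state()
  a <- controller_on_presyn(ctrl, 1234L, t = 0)
  b <- controller_on_presyn(a$ctrl, 1234L, t = 0.5)
  expect_true(a$newly_assigned)
  expect_false(b$newly_assigned)
  expect_identical(a$physical, b$physical)
})

test_that("an expired lease forces a fresh assignment", {
  ctrl <- controller_state()
  a <- controller_on_presyn(ctrl, 7L, t = 0)
  b <- controller_on_presyn(a$ctrl, 7L, t = 2)
  expect_true(b$newly_assigned)
})

test_that("the lease is not renewed by later spikes to the same address", {
  ctrl <- controller_state()
  a <- controller_on_presyn(ctrl, 7L, t = 0)
  b <- controller_on_presyn(a$ctrl, 7L, t = 0.9)   # hit, no renewal
  c <- controller_on_presyn(b$ctrl, 7L, t = 1.05)  # original lease expired
  expect_false(b$newly_assigned)
  expect_true(c$newly_assigned)
})

test_that("51 distinct addresses within 1 ms on a 50-neuron pool drop one", {
  ctrl <- controller_state(pool_size = 50)
  dropped <- 0L
  for (i in 0:50) {
    r <- suppressWarnings(controller_on_presyn(ctrl, i, t = i * 0.01))
    ctrl <- r$ctrl
    dropped <- dropped + r$dropped
  }
  expect_identical(dropped, 1L)
  expect_identical(ctrl$n_dropped, 1L)
})

test_that("a firing neuron emits the latched virtual address", {
  ctrl <- controller_state()
  r <- controller_on_presyn(ctrl, 1234L, t = 0)
  expect_identical(controller_on_fire(r$ctrl, r$physical, t = 0.4), 1234L)
  expect_error(controller_on_fire(r$ctrl, r$physical, t = 1.5),
               class = "polysnn_internal_state_error")
  expect_error(controller_on_fire(r$ctrl, 50L, t = 0.4),
               class = "polysnn_internal_state_error")
})

test_that("the controller serves the full 4k virtual address space", {
  ctrl <- controller_state()
  addrs <- c(0L, 511L, 4095L)
  for (i in seq_along(addrs)) {
    r <- controller_on_presyn(ctrl, addrs[i], t = (i - 1) * 5)
    expect_identical(controller_on_fire(r$ctrl, r$physical, (i - 1) * 5 + 0.1),
                     addrs[i])
    ctrl <- r$ctrl
  }
  expect_gte(4096 / ctrl$pool_size, 80)
})

test_that("controller routing matches the reference map-with-expiry replay", {
  withr::with_seed(21, {
    spikes <- data.frame(time_ms = sort(runif(500, 0, 20)),
                         address = sample(0:79, 500, replace = TRUE))
    ctrl <- controller_state(pool_size = 20)
    got <- integer(500)
    for (i in seq_len(500)) {
      r <- suppressWarnings(controller_on_presyn(ctrl, spikes$address[i],
                                                 spikes$time_ms[i]))
      ctrl <- r$ctrl
      got[i] <- r$physical
    }
    expect_identical(got, oracle_controller_replay(spikes, 20, 1))
  })
})

test_that("lease conservation holds at every instant", {
  withr::with_seed(5, {
    ctrl <- controller_state(pool_size = 10)
    ts <- sort(runif(300, 0, 10))
    for (i in seq_along(ts)) {
      r <- suppressWarnings(
        controller_on_presyn(ctrl, sample(0:29, 1), ts[i]))
      ctrl <- r$ctrl
      leased <- controller_n_leased(ctrl, ts[i])
      expect_lte(leased, ctrl$pool_size)
      expect_gte(leased, 0L)
    }
  })
})
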