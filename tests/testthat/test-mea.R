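test_that("detectSpikes finds injected peaks and scales with amplitude", {
  fs <- 12500
  n <- fs * 2
  trace <- withr::with_seed(15, rnorm(n, 0, 1))
  peaks <- seq(0.1, 1.9, length.out = 10)
  idx <- round(peaks * fs) + 1
  trace[idx] <- 8  # 8-SD peaks on unit white noise
  ts <- detectSpikes(trace, fs)
  expect_equal(length(ts), 10L)
  expect_equal(ts, (idx - 1) / fs, tolerance = 1e-9)
  # scale invariance: doubling the trace leaves detections unchanged
  expect_equal(detectSpikes(trace * 2, fs), ts)
  # flat and empty traces
  expect_equal(detectSpikes(rep(1, 1000), fs), numeric(0))
  expect_equal(detectSpikes(numeric(0), fs), numeric(0))
})

test_that("filterActive applies the strict >5 spikes/min rule", {
  win <- c(0, 420)  # 7 minutes
  st <- SpikeTrains(list(a = seq_len(35) * 10, b = seq_len(36) * 10,
                         c = numeric(0)),
                    window = win)
  out <- filterActive(st)
  expect_equal(names(out), "b")  # 35/7min = exactly 5 -> removed
  expect_error(filterActive(SpikeTrains(list(a = numeric(0)),
                                        window = c(5, 5))), "zero-length")
})

test_that("burst detection matches the published thresholds", {
  five <- SpikeTrains(list(n1 = 1 + (0:4) * 0.05))
  expect_equal(nrow(detectBursts(five)), 1L)
  four <- SpikeTrains(list(n1 = 1 + (0:3) * 0.05))
  expect_equal(nrow(detectBursts(four)), 0L)
  # ISI exactly 100 ms is within a burst; 101 ms splits it
  atLimit <- SpikeTrains(list(n1 = 1 + (0:4) * 0.100))
  expect_equal(nrow(detectBursts(atLimit)), 1L)
  over <- SpikeTrains(list(n1 = c(1 + (0:3) * 0.05, 1.15 + 0.101)))
  expect_equal(nrow(detectBursts(over)), 0L)
})

test_that("burst sets equal the sliding-scan oracle on random trains", {
  withr::with_seed(99, {
    for (i in 1:300) {
      n <- sample(5:60, 1)
      ts <- sort(runif(n, 0, 30))
      st <- SpikeTrains(list(x = ts), window = c(0, 30))
      mine <- detectBursts(st, minSpikes = 5, maxIsi = 0.5)
      orc <- oracleBursts(spikeTimes(st)$x, 5, 0.5)
      expect_equal(nrow(mine), nrow(orc))
      if (nrow(orc)) {
        expect_equal(mine$start, orc$start)
        expect_equal(mine$end, orc$end)
        expect_equal(mine$n_spikes, orc$n_spikes)
      }
    }
  })
})

test_that("bursts are disjoint and degenerate thresholds cover all spikes", {
  ts <- withr::with_seed(7, sort(runif(200, 0, 60)))
  st <- SpikeTrains(list(x = ts), window = c(0, 60))
  b <- detectBursts(st, minSpikes = 5, maxIsi = 0.2)
  if (nrow(b) > 1) {
    expect_true(all(b$start[-1] > b$end[-nrow(b)]))
  }
  whole <- detectBursts(st, minSpikes = 1, maxIsi = Inf)
  expect_equal(nrow(whole), 1L)
  expect_equal(whole$n_spikes, 200L)
  expect_equal(c(whole$start, whole$end), range(ts))
})

test_that("network events pool neurons and match the pooled oracle", {
  mk <- function(nNeurons, isi, nSpikes, start = 5) {
    ts <- start + (seq_len(nSpikes) - 1) * isi
    trains <- split(ts, rep_len(seq_len(nNeurons), nSpikes))
    names(trains) <- sprintf("n%d", seq_len(nNeurons))
    SpikeTrains(trains, window = c(0, 60))
  }
  ev <- detectNetworkEvents(mk(10, 0.02, 50))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_spikes, 50L)
  expect_equal(nrow(detectNetworkEvents(mk(10, 0.02, 49))), 0L)
  # random multi-neuron configs against the pooled brute-force oracle
  withr::with_seed(41, {
    for (i in 1:100) {
      k <- sample(2:6, 1)
      trains <- lapply(seq_len(k), function(j) sort(runif(30, 0, 20)))
      names(trains) <- sprintf("n%d", seq_len(k))
      st <- SpikeTrains(trains, window = c(0, 20))
      mine <- detectNetworkEvents(st, minSpikes = 10, maxIsi = 0.1)
      pooled <- sort(unlist(spikeTimes(st)))
      orc <- oracleBursts(pooled, 10, 0.1)
      expect_equal(nrow(mine), nrow(orc))
      if (nrow(orc)) expect_equal(mine$n_spikes, orc$n_spikes)
    }
  })
})

test_that("single-neuron network detection reduces to burst detection", {
  ts <- withr::with_seed(13, sort(runif(120, 0, 40)))
  st <- SpikeTrains(list(only = ts), window = c(0, 40))
  b <- detectBursts(st, minSpikes = 5, maxIsi = 0.1)
  ev <- detectNetworkEvents(st, minSpikes = 5, maxIsi = 0.1)
  expect_equal(nrow(ev), nrow(b))
  expect_equal(ev$start, b$start)
  expect_equal(ev$n_spikes, b$n_spikes)
})

test_that("time rescaling rescales event boundaries identically", {
  ts <- withr::with_seed(17, sort(runif(80, 0, 30)))
  st1 <- SpikeTrains(list(x = ts), window = c(0, 30))
  st2 <- SpikeTrains(list(x = ts * 3), window = c(0, 90))
  b1 <- detectBursts(st1, minSpikes = 4, maxIsi = 0.3)
  b2 <- detectBursts(st2, minSpikes = 4, maxIsi = 0.9)
  expect_equal(b2$start, b1$start * 3)
  expect_equal(b2$end, b1$end * 3)
  expect_equal(b2$n_spikes, b1$n_spikes)
})

test_that("population vector matches a hand-computed toy", {
  st <- SpikeTrains(list(a = c(0.05, 1.25), b = c(0.15), c = c(1.21)),
                    window = c(0, 2))
  # frame 0.1 s: frames 1 (a) and 2 (b) get 1; frame 13 has a+c -> 2
  pv <- populationVector(st, frame = 0.1, window = 0.1)  # no smoothing
  expect_equal(sum(pv$value), 4)
  expect_equal(pv$value[1:2], c(1, 1))
  expect_equal(pv$value[13], 2)
  # no spikes -> all-zero vector
  empty <- SpikeTrains(list(a = numeric(0)), window = c(0, 2))
  expect_true(all(populationVector(empty, 0.1)$value == 0))
  # smoothing spreads a unit impulse over the window, conserving mass
  one <- SpikeTrains(list(a = 0.55), window = c(0, 2))
  pv2 <- populationVector(one, frame = 0.1, window = 0.5)
  expect_equal(sum(pv2$value), 1, tolerance = 1e-12)
  expect_equal(sum(pv2$value > 0), 5L)
})

test_that("treatment AUC is the trapezoid rule with optional smoothing", {
  t <- c(0, 1, 2, 3)
  expect_equal(treatmentAUC(t, rep(4, 4), 0, 3), 12)   # v * T
  v <- c(1, 3, 2, 5)
  expect_equal(treatmentAUC(t, v, 0, 3), 2 + 2.5 + 3.5)
  # time reversal preserves the trapezoid sum
  expect_equal(treatmentAUC(t, rev(v), 0, 3), treatmentAUC(t, v, 0, 3))
  # two-point moving average first
  sm <- c(1, 2, 2.5, 3.5)
  expect_equal(treatmentAUC(t, v, 0, 3, smooth = TRUE),
               sum(diff(t) * (head(sm, -1) + tail(sm, -1)) / 2))
  expect_error(treatmentAUC(t, v, 2.5, 2.6), "2 timepoints")
})

test_that("normalized percent change supports both conventions", {
  vals <- rbind(treated = c(10, 12, 8),
                ctrl1 = c(10, 11, 10),
                ctrl2 = c(10, 9, 10))
  npc <- normalizedPercentChange(vals, baselineIndex = 1,
                                 controlWells = c("ctrl1", "ctrl2"))
  # hand: ctrl mean rel = (1.1 + 0.9)/2 = 1.0 at t2 -> treated rel 1.2
  expect_equal(unname(npc["treated", ]), c(0, 20, -20))
  sub <- normalizedPercentChange(vals, 1, c("ctrl1", "ctrl2"),
                                 mode = "subtract")
  expect_equal(unname(sub["treated", ]), c(0, 20, -20))
  # treated identical to control -> 0 everywhere
  same <- rbind(a = c(5, 6), ctrl = c(5, 6))
  expect_equal(unname(normalizedPercentChange(same, 1, "ctrl")["a", ]),
               c(0, 0))
  # a single control well is exactly 0 against itself
  expect_equal(unname(normalizedPercentChange(same, 1, "ctrl")["ctrl", ]),
               c(0, 0))
  # zero baseline reported missing
  z <- rbind(a = c(0, 5), ctrl = c(5, 6))
  expect_true(all(is.na(normalizedPercentChange(z, 1, "ctrl")["a", ])))
})
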