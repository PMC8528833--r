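# small shared fixtures: fs 200, 1 s records keep the suite fast
coh_fs <- 200
coh_ws <- build_scales(coh_fs, 1)

noise_pair_epochs <- function(n_epochs, seed, n = coh_fs) {
  withr::with_seed(seed, {
    epoch_array(array(rnorm(n_epochs * 2 * n), c(n_epochs, 2, n)),
                coh_fs, 1L, c("x", "y"))
  })
}

test_that("identical channels give unit coherency with zero imaginary part", {
  ep <- withr::with_seed(5, {
    base <- matrix(rnorm(3 * coh_fs), 3, coh_fs)
    d <- array(NA_real_, c(3, 2, coh_fs))
    d[, 1, ] <- base
    d[, 2, ] <- base
    epoch_array(d, coh_fs, 1L, c("x", "y"))
  })
  m <- ensemble_wtc(ep, "x", "y", coh_ws)
  inside <- m$coi & m$valid
  expect_true(any(inside))
  expect_equal(max(abs(wtc_map(m)[inside] - 1)), 0, tolerance = 1e-6)
  expect_equal(max(abs(iwtc_map(m)[inside])), 0, tolerance = 1e-6)
  ph <- phase_field(m)
  expect_equal(max(abs(ph$phase[inside])), 0, tolerance = 1e-6)

  # sign flip: anti-phase
  ep$data[, 2, ] <- -ep$data[, 2, ]
  m2 <- ensemble_wtc(ep, "x", "y", coh_ws)
  expect_equal(max(abs(abs(Arg(m2$rhat[m2$coi])) - pi)), 0,
               tolerance = 1e-6)
})

test_that("coherency magnitude is bounded and dominates its imaginary part", {
  ep <- noise_pair_epochs(4, seed = 8)
  m <- ensemble_wtc(ep, "x", "y", coh_ws)
  expect_true(all(Mod(m$rhat) <= 1 + 1e-9))
  expect_true(all(abs(iwtc_map(m)) <= wtc_map(m) + 1e-12))
  expect_equal(iwtc_map(m), Im(m$rhat))
  expect_equal(phase_field(m)$phase, Arg(m$rhat))
})

test_that("quarter-cycle lag makes the coherency purely imaginary", {
  t <- (0:(coh_fs - 1)) / coh_fs
  ep <- withr::with_seed(9, {
    d <- array(NA_real_, c(5, 2, coh_fs))
    for (e in 1:5) {
      d[e, 1, ] <- cos(2 * pi * 10 * t) + rnorm(coh_fs, 0, 0.05)
      d[e, 2, ] <- sin(2 * pi * 10 * t) + rnorm(coh_fs, 0, 0.05)
    }
    epoch_array(d, coh_fs, 1L, c("x", "y"))
  })
  m <- ensemble_wtc(ep, "x", "y", coh_ws)
  ridge <- which.min(abs(m$freqs - 10))
  sel <- m$coi[ridge, ]
  expect_true(any(sel))
  expect_equal(mean(abs(iwtc_map(m)[ridge, sel])),
               mean(wtc_map(m)[ridge, sel]), tolerance = 0.02)
  # cos leads sin by a quarter cycle: phase +pi/2, decoded as "y leads x"
  expect_equal(mean(Arg(m$rhat[ridge, sel])), pi / 2, tolerance = 0.1)
  dd <- dominant_direction(m, f_window = c(9, 11))
  expect_identical(dd$label, "y leads x")
})

test_that("a common source is visible in WTC but suppressed in IWTC", {
  ep <- withr::with_seed(10, {
    d <- array(NA_real_, c(6, 2, coh_fs))
    for (e in 1:6) {
      src <- rnorm(coh_fs)
      d[e, 1, ] <- src + rnorm(coh_fs, 0, 0.1)
      d[e, 2, ] <- src + rnorm(coh_fs, 0, 0.1)
    }
    epoch_array(d, coh_fs, 1L, c("x", "y"))
  })
  m <- ensemble_wtc(ep, "x", "y", coh_ws)
  inside <- m$coi & m$valid
  expect_gt(mean(wtc_map(m)[inside] > 0.9), 0.95)
  expect_lt(max(abs(iwtc_map(m)[inside])), 0.1)
})

test_that("white-noise coherency decreases with the ensemble size", {
  means <- vapply(c(1, 5, 25), function(N) {
    ep <- noise_pair_epochs(N, seed = 11)
    m <- ensemble_wtc(ep, "x", "y", coh_ws)
    mean(wtc_map(m)[m$coi & m$valid])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  expect_lt(means[3], 0.3)
})

test_that("independent white noise yields low mean coherence (N = 50)", {
  ep <- noise_pair_epochs(50, seed = 12)
  m <- ensemble_wtc(ep, "x", "y", coh_ws)
  expect_lt(mean(wtc_map(m)[m$coi & m$valid]), 0.3)
})

test_that("all-pairs maps: combinatorics, reuse and Hermitian symmetry", {
  ep <- withr::with_seed(13, {
    epoch_array(array(rnorm(2 * 4 * coh_fs), c(2, 4, coh_fs)), coh_fs, 1L,
                c("C3", "C4", "F3", "F4"))
  })
  set <- all_pairs_maps(ep, coh_ws)
  expect_length(set$maps, 6)
  expect_identical(names(set$maps)[1], "C3~C4")
  # each pair map equals the standalone computation
  m_alone <- ensemble_wtc(ep, "C4", "F3", coh_ws)
  expect_equal(set$maps[["C4~F3"]]$rhat, m_alone$rhat, tolerance = 1e-12)
  # reversed pair is the conjugate
  rev_m <- conj_map(set$maps[["C3~C4"]])
  expect_identical(rev_m$pair, c("C4", "C3"))
  expect_equal(rev_m$rhat, Conj(set$maps[["C3~C4"]]$rhat))
  # memory guard
  expect_error(all_pairs_maps(ep, coh_ws, memory_cap_bytes = 1000),
               "cap")
  # pre-conditions
  expect_error(ensemble_wtc(ep, "C3", "C3", coh_ws), "different")
  expect_error(ensemble_wtc(ep, "C3", "XX", coh_ws), "unknown channel")
})

test_that("FFT pipeline matches direct per-bin summation on a toy record", {
  fs <- 64
  n <- 64
  # scales large enough that the daughter decays before Nyquist, so the
  # time-sampled oracle kernel is alias-free
  scales <- (2 / fs) * 2^(c(4, 6, 8) / 4)
  spec <- build_scales(fs, 1, n_octaves = 2, voices = 4, smooth_scales = 3)
  spec$scales <- scales
  spec$freqs <- 6 / (2 * pi * scales)
  ep <- withr::with_seed(21, {
    epoch_array(array(rnorm(2 * 2 * n), c(2, 2, n)), fs, 1L, c("x", "y"))
  })
  m <- ensemble_wtc(ep, "x", "y", spec)

  num <- matrix(0 + 0i, 3, n); di <- matrix(0, 3, n); dj <- matrix(0, 3, n)
  for (e in 1:2) {
    wx <- oracle_cwt(ep$data[e, 1, ], fs, scales)
    wy <- oracle_cwt(ep$data[e, 2, ], fs, scales)
    num <- num + oracle_smooth(wx * Conj(wy), scales, fs, 3)
    di <- di + Re(oracle_smooth(Mod(wx)^2 + 0i, scales, fs, 3))
    dj <- dj + Re(oracle_smooth(Mod(wy)^2 + 0i, scales, fs, 3))
  }
  rhat_direct <- num / sqrt(di * dj)
  # compare away from the record edges, where the oracle's truncated kernel
  # and the FFT zero-padding agree
  mid <- 17:48
  expect_equal(m$rhat[, mid], rhat_direct[, mid], tolerance = 1e-6)
})

test_that("a third independent channel shows no sustained ridge", {
  t <- (0:(coh_fs - 1)) / coh_fs
  ep <- withr::with_seed(14, {
    d <- array(NA_real_, c(8, 3, coh_fs))
    for (e in 1:8) {
      d[e, 1, ] <- cos(2 * pi * 12 * t) + rnorm(coh_fs, 0, 0.2)
      d[e, 2, ] <- sin(2 * pi * 12 * t) + rnorm(coh_fs, 0, 0.2)
      d[e, 3, ] <- rnorm(coh_fs)
    }
    epoch_array(d, coh_fs, 1L, c("x", "y", "z"))
  })
  set <- all_pairs_maps(ep, coh_ws)
  ridge <- which.min(abs(coh_ws$freqs - 12))
  m_xy <- set$maps[["x~y"]]
  expect_gt(mean(wtc_map(m_xy)[ridge, m_xy$coi[ridge, ]]), 0.9)
  for (key in c("x~z", "y~z")) {
    m <- set$maps[[key]]
    expect_lt(mean(wtc_map(m)[ridge, m$coi[ridge, ]]), 0.5)
  }
})
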