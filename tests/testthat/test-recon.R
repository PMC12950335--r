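test_that("split_and_merge orders lobes by polarity and merged time", {
  p <- seq_params(N_acq = 2L, N_i = 1L, N_s = 1L, N_k = 16L)
  raw <- simulate_raw(peak_row(1, 1)[0, ], p, jitter = no_jitter(),
                      noise = noise_spec(0), seed = 1)
  # tag each lobe with a recognisable constant
  for (g in 1:4) raw$data[1, 1, g, ] <- g + 0i
  raw <- average_scans(raw)
  S <- split_and_merge(raw)
  expect_equal(unique(Re(S$even[, 1])), 1)  # lobe 0
  expect_equal(unique(Re(S$even[, 2])), 3)  # lobe 2
  expect_equal(unique(Re(S$odd[, 1])), 2)
  expect_equal(as.numeric(S$t2), as.numeric(t2_grid(p)))

  p4 <- tiny_params()
  raw4 <- average_scans(simulate_raw(peak_row(1, 1), p4,
                                     jitter = no_jitter(),
                                     noise = noise_spec(0), seed = 1))
  expect_equal(as.numeric(split_and_merge(raw4)$t2),
               as.numeric(t2_grid(p4)))

  bad <- raw4
  bad$data <- bad$data[1:2, , , , drop = FALSE]
  expect_error(split_and_merge(bad), "interleaves")
})

test_that("odd-lobe reversal aligns echo positions across all columns", {
  p <- tiny_params()
  raw <- average_scans(simulate_raw(peak_row(1.4, 2.0, T2 = 1e6), p,
                                    jitter = no_jitter(),
                                    noise = noise_spec(0), seed = 1))
  S <- split_and_merge(raw)
  pos_even <- apply(Mod(S$even), 2, which.max)
  pos_odd <- apply(Mod(S$odd), 2, which.max)
  expect_equal(length(unique(c(pos_even, pos_odd))), 1L)
})

test_that("default reconstruction emits a 512 x 1024 matrix", {
  sp <- wine_msup_spectrum()
  expect_equal(dim(sp$matrix), c(512L, 1024L))
  expect_true(all(sp$matrix >= 0))
  expect_true(all(diff(sp$f1_axis) < 0))
  expect_true(all(diff(sp$f2_axis) < 0))
})

test_that("zero-fill smaller than the data errors", {
  p <- tiny_params()
  raw <- average_scans(simulate_raw(peak_row(1, 1), p,
                                    jitter = no_jitter(),
                                    noise = noise_spec(0), seed = 1))
  S <- split_and_merge(raw)
  expect_error(process_spectrum(S, proc_config(zerofill = c(16L, 128L))),
               "zero-fill")
  expect_error(process_spectrum(S, proc_config(zerofill = c(128L, 16L))),
               "zero-fill")
})

test_that("round-trip peak positions land within one resolution element", {
  p <- tiny_params()
  dt <- derive_geometry(p)
  zf <- c(256L, 256L)
  res1 <- (dt$f1_span / p$larmor) / zf[1]
  res2 <- (dt$SW2 / p$larmor) / zf[2]
  f2_half <- dt$SW2 / p$larmor / 2
  set.seed(21)
  for (rep in 1:6) {
    f1 <- runif(1, 0.5, 5.5)
    f2 <- runif(1, p$carrier_ppm - 0.9 * f2_half,
                p$carrier_ppm + 0.9 * f2_half)
    sp <- single_peak_spectrum(f1, f2, p, proc_config(zerofill = zf))
    fp <- find_peak(sp)
    expect_lte(abs(fp$f1 - f1), res1)
    expect_lte(abs(fp$f2 - f2), res2)
  }
})

test_that("unitary-transform energy bookkeeping (Parseval)", {
  p <- tiny_params()
  raw <- average_scans(simulate_raw(peak_row(1.7, 2.3), p,
                                    jitter = no_jitter(),
                                    noise = noise_spec(0), seed = 1))
  S <- split_and_merge(raw)
  n_t2 <- ncol(S$even)
  cfg <- proc_config(zerofill = c(p$N_k, n_t2), gauss_sigma = Inf,
                     sine_window = FALSE, polarity = "even")
  sp <- process_spectrum(S, cfg)
  # f1 chain is identity at equal sizes; unnormalised f2 FFT scales the
  # energy by the transform length
  expect_equal(sum(sp$matrix^2), n_t2 * sum(Mod(S$even)^2),
               tolerance = 1e-9)
})

test_that("processing is positively homogeneous in the raw data", {
  p <- tiny_params()
  raw <- average_scans(simulate_raw(peak_row(1.7, 2.3), p,
                                    jitter = no_jitter(),
                                    noise = noise_spec(0), seed = 1))
  S1 <- split_and_merge(raw)
  S2 <- S1
  S2$even <- 2.5 * S2$even; S2$odd <- 2.5 * S2$odd
  sp1 <- process_spectrum(S1); sp2 <- process_spectrum(S2)
  expect_equal(sp2$matrix, 2.5 * sp1$matrix, tolerance = 1e-12)
})

test_that("pipeline adds no spurious ghosts of its own", {
  # on-bin resonance, negligible decay, no window/apodisation, no zero-fill:
  # the conventional-dimension transform of a pure exponential is then an
  # exact delta, so any off-peak intensity would be a bookkeeping artefact
  p <- tiny_params()
  dt <- derive_geometry(p)
  n_t2 <- p$N_acq * p$N_i
  f2 <- p$carrier_ppm + 5 * (dt$SW2 / n_t2) / p$larmor  # exactly on bin 5
  raw <- average_scans(simulate_raw(peak_row(2.0, f2, T2 = 1e9), p,
                                    jitter = no_jitter(),
                                    noise = noise_spec(0), seed = 1))
  sp <- process_spectrum(split_and_merge(raw),
                         proc_config(zerofill = c(p$N_k, n_t2),
                                     gauss_sigma = Inf, sine_window = FALSE,
                                     polarity = "even"))
  pk <- find_peak(sp)
  col <- sp$matrix[pk$i, ]
  expect_lt(max(col[-pk$j]), 1e-8 * pk$value)
})

test_that("two-point calibration recovers affine axis distortions", {
  sp <- list(matrix = matrix(0, 4, 4), f1_axis = seq(6, 0, length.out = 4),
             f2_axis = seq(6, 0, length.out = 4),
             provenance = list())
  class(sp) <- "uf_spectrum"
  anchors <- list(c(0, 0), c(4.47, 4.47))

  # already calibrated: identity map
  cal <- calibrate(sp, anchors, anchors)
  expect_equal(cal$f1_axis, sp$f1_axis, tolerance = 1e-12)
  expect_equal(unname(cal$provenance$calibration$f1), c(1, 0),
               tolerance = 1e-12)

  # pure offset
  off <- sp; off$f1_axis <- off$f1_axis + 0.1; off$f2_axis <- off$f2_axis + 0.1
  cal <- calibrate(off, list(c(0.1, 0.1), c(4.57, 4.57)), anchors)
  expect_equal(unname(cal$provenance$calibration$f1["offset"]), -0.1,
               tolerance = 1e-12)
  expect_equal(cal$f1_axis, sp$f1_axis, tolerance = 1e-12)

  # scale + offset distortion inverts to machine precision
  dis <- sp
  dis$f1_axis <- 1.002 * sp$f1_axis + 0.05
  dis$f2_axis <- 1.002 * sp$f2_axis + 0.05
  meas <- list(c(0.05, 0.05), 1.002 * c(4.47, 4.47) + 0.05)
  cal <- calibrate(dis, meas, anchors)
  expect_equal(cal$f1_axis, sp$f1_axis, tolerance = 1e-12)
  expect_equal(cal$f2_axis, sp$f2_axis, tolerance = 1e-12)

  expect_error(calibrate(sp, list(c(1, 1), c(1, 2)), anchors), "coincident")
})
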