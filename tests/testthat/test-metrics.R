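# Hand-built spectrum: a deterministic "noise" texture plus point peaks.
toy_spectrum <- function(n1 = 64, n2 = 128, seed = 2) {
  set.seed(seed)
  m <- matrix(abs(rnorm(n1 * n2)), n1, n2)
  structure(list(matrix = m,
                 f1_axis = seq(6, 0, length.out = n1),
                 f2_axis = seq(7, -1, length.out = n2),
                 provenance = list()), class = "uf_spectrum")
}

test_that("row-extracted SNR matches its definition and scales out", {
  sp <- toy_spectrum()
  i <- which.min(abs(sp$f1_axis - 3)); j <- which.min(abs(sp$f2_axis - 3))
  sp$matrix[i, j] <- 50
  pd <- peak_def("pk", region(2.8, 3.2, 2.8, 3.2), region(2.8, 3.2, 5, 6.5))
  got <- snr(sp, pd)
  # independent slice/statistics oracle
  rowv <- sp$matrix[i, ]
  jj <- which(sp$f2_axis >= 5 & sp$f2_axis < 6.5)
  expect_equal(got, 50 / sd(rowv[jj]), tolerance = 1e-12)
  sp2 <- sp; sp2$matrix <- sp2$matrix * 17
  expect_equal(snr(sp2, pd), got, tolerance = 1e-12)

  flat <- sp; flat$matrix[] <- 1; flat$matrix[i, j] <- 10
  expect_error(snr(flat, pd), "zero")
})

test_that("snr is exactly max/sd on a constructed row", {
  sp <- toy_spectrum()
  i <- which.min(abs(sp$f1_axis - 2))
  sp$matrix[i, ] <- 1
  jn <- which(sp$f2_axis >= 5 & sp$f2_axis < 6.5)
  sp$matrix[i, jn] <- rep(c(0, 2), length.out = length(jn))  # sd ~ 1
  j <- which.min(abs(sp$f2_axis - 2))
  sp$matrix[i, j] <- 10 * sd(sp$matrix[i, jn])
  pd <- peak_def("pk", region(1.9, 2.1, 1.8, 2.2), region(1.9, 2.1, 5, 6.5))
  expect_equal(snr(sp, pd), 10, tolerance = 1e-12)
})

test_that("peak volumes are additive with half-open membership", {
  sp <- toy_spectrum()
  whole <- region(min(sp$f1_axis), max(sp$f1_axis) + 1,
                  min(sp$f2_axis), max(sp$f2_axis) + 1)
  expect_equal(peak_volume(sp, whole), sum(sp$matrix))
  r <- region(1, 4, 0, 5)
  ra <- region(1, 4, 0, 2.5); rb <- region(1, 4, 2.5, 5)
  expect_equal(peak_volume(sp, ra) + peak_volume(sp, rb),
               peak_volume(sp, r))
  expect_error(peak_volume(sp, region(10, 11, 0, 1)), "no spectrum cells")
})

test_that("volume of a sampled Gaussian line matches its analytic integral", {
  n1 <- 256; n2 <- 256
  f1 <- seq(6, 0, length.out = n1); f2 <- seq(6, 0, length.out = n2)
  s1 <- 0.05; s2 <- 0.08; A <- 3
  m <- A * outer(exp(-(f1 - 3)^2 / (2 * s1^2)),
                 exp(-(f2 - 2)^2 / (2 * s2^2)))
  sp <- structure(list(matrix = m, f1_axis = f1, f2_axis = f2,
                       provenance = list()), class = "uf_spectrum")
  vol <- peak_volume(sp, region(3 - 5 * s1, 3 + 5 * s1,
                                2 - 5 * s2, 2 + 5 * s2))
  d1 <- abs(diff(f1[1:2])); d2 <- abs(diff(f2[1:2]))
  analytic <- A * 2 * pi * s1 * s2 / (d1 * d2)
  expect_equal(vol, analytic, tolerance = 0.02)
})

test_that("relative volumes are referenced to TSP", {
  v <- c(TSP = 4, lactate = 2, tartrate = 8)
  rel <- relative_volumes(v)
  expect_equal(unname(rel), c(1, 0.5, 2))
  expect_error(relative_volumes(c(a = 1)), "reference")
})

test_that("cv matches hand computation and is scale invariant", {
  expect_equal(cv(rep(3.7, 5)), 0)
  expect_equal(cv(c(9, 10, 11)), 10)
  set.seed(9)
  x <- rlnorm(20)
  expect_equal(cv(17 * x), cv(x), tolerance = 1e-12)
  expect_error(cv(5), "replicates")
})

test_that("ghost predictor follows the closed-form DFT", {
  expect_equal(nrow(predict_ghosts(2, 5347.6, 1)), 0L)
  flat <- predict_ghosts(2, 5347.6, 8, 700.28, rep(1.3, 8))
  expect_equal(Mod(flat$amplitude), rep(0, 7), tolerance = 1e-14)

  eps <- 0.01
  g <- predict_ghosts(2, 5347.6, 8, 700.28, c(1 + eps, rep(1, 7)))
  expect_equal(Mod(g$amplitude), rep(eps / (8 + eps), 7), tolerance = 1e-12)
  # positions: parent + m SW2/N_i folded into the window around the carrier
  span <- 5347.6 / 700.28
  raw_pos <- 2 + (1:7) * span / 8
  lo <- 3 - span / 2
  expect_equal(g$f2, ((raw_pos - lo) %% span) + lo, tolerance = 1e-12)
  expect_true(all(g$f2 >= lo & g$f2 < lo + span))
})

test_that("ghost predictor agrees with end-to-end simulation", {
  # idealized, noiseless, systematic per-interleave amplitude factors only;
  # ghost amplitudes measured on the complex difference against a flat
  # reference so parent tails cancel
  p <- tiny_params(N_acq = 32L)
  dt <- derive_geometry(p)
  cfg <- proc_config(zerofill = c(128L, 256L), polarity = "even")
  base <- single_peak_spectrum(2.0, 2.0, p, cfg, complex_out = TRUE)
  set.seed(31)
  for (rep in 1:3) {
    fac <- 1 + runif(p$N_i, -0.02, 0.02)
    jit <- jitter_spec(0, 0, systematic_amp = fac - 1,
                       solvent_multiplier = 1)
    raw <- simulate_raw(peak_row(2.0, 2.0), p, dt, jit, noise_spec(0),
                        seed = 1)
    sp <- process_spectrum(split_and_merge(average_scans(raw)), cfg,
                           complex_out = TRUE)
    pk <- find_peak(sp)
    scale <- sp$matrix[pk$i, pk$j] / base$matrix[pk$i, pk$j]
    diffm <- sp$matrix - scale * base$matrix
    gh <- predict_ghosts(2.0, dt$SW2, p$N_i, p$larmor, fac, p$carrier_ppm)
    for (m in seq_len(nrow(gh))) {
      j2 <- which.min(abs(sp$f2_axis - gh$f2[m]))
      meas <- Mod(diffm[pk$i, j2]) / Mod(pk$value)
      expect_equal(meas, Mod(gh$amplitude[m]), tolerance = 1e-3)
    }
  }
})

test_that("detectable_peaks counts in-window unmasked peaks", {
  sp <- toy_spectrum()
  sp$matrix[] <- 0
  exp_pk <- data.frame(f1 = c(1, 2, 3, 9), f2 = c(1, 2, 3, 1))
  # noiseless + threshold 0: everything inside the window counts
  expect_equal(detectable_peaks(sp, exp_pk, threshold = 0), 3L)
  # ghost exclusion zone
  gh <- data.frame(m = 1, f2 = 2.01, amplitude = 0.5 + 0i)
  expect_equal(detectable_peaks(sp, exp_pk, threshold = 0, ghosts = gh),
               2L)
  # SNR gate: one strong peak over the textured noise floor
  sp2 <- toy_spectrum()
  i <- which.min(abs(sp2$f1_axis - 2)); j <- which.min(abs(sp2$f2_axis - 2))
  sp2$matrix[i, j] <- 1000
  expect_equal(detectable_peaks(sp2, exp_pk, threshold = 20), 1L)
})

test_that("replicate CVs fall as peak amplitude grows", {
  p <- tiny_params(N_acq = 16L)
  vol_cv <- function(amp) {
    vols <- vapply(1:5, function(s) {
      raw <- simulate_raw(peak_row(2, 2, amplitude = amp), p,
                          jitter = no_jitter(), noise = noise_spec(1),
                          seed = 100 + s)
      sp <- process_spectrum(split_and_merge(average_scans(raw)),
                             proc_config(zerofill = c(128L, 128L)))
      peak_volume(sp, region(1.6, 2.4, 1.9, 2.1))
    }, 0)
    cv(vols)
  }
  cvs <- c(vol_cv(3), vol_cv(30), vol_cv(300))
  expect_true(all(diff(cvs) < 0))
})
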