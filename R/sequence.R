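#' Pulse-sequence parameters for interleaved ultrafast COSY
#'
#' Container for every symbol of the acquisition scheme: the two encoding
#' chirp pulses, the EPSI acquisition gradient train, interleaving and
#' averaging counts, and per-transient delays.  Defaults reproduce the
#' published wine-screening protocol on a 700.28 MHz instrument: 15 ms chirps
#' sweeping 28 kHz under +/-3.6 G/cm encoding gradients, +/-50.1 G/cm
#' acquisition gradients applied for 748 us, 64 acquisition loops, 8
#' interleaved scans, 32 averages, 4 dummy transients and a 5 s recovery
#' delay (the minimum rest time recommended for the gradient coil).
#'
#' @param T_chirp Chirp pulse duration in seconds (two chirps per transient).
#' @param sweep Chirp frequency sweep range in Hz.
#' @param G_e Encoding gradient amplitude in G/cm.
#' @param G_a Acquisition (EPSI) gradient amplitude in G/cm.
#' @param T_a Duration of one acquisition gradient lobe in seconds.  The
#'   protocol text gives 748 us; one figure caption prints 784 us -- the body
#'   value is the default and the field stays configurable.
#' @param G_p Post-mixing gradient amplitude in G/cm (provenance only; its
#'   coherence-selection role is not simulated).
#' @param N_acq Number of bipolar gradient pairs in the EPSI train.
#' @param N_i Number of interleaved scans.
#' @param N_s Number of averages per interleave.
#' @param N_dummy Number of dummy transients (counted once in the schedule).
#' @param recovery Recovery delay per transient in seconds.
#' @param t_m NOESY mixing time in seconds.
#' @param larmor Proton Larmor frequency in MHz.
#' @param N_k Complex samples digitised per gradient lobe.  The default 320
#'   keeps the spatial field of view of the EPSI readout
#'   (`2 pi N_k / k_max`, about 2.0 cm) larger than the encoded sample
#'   length (about 1.83 cm); coarser sampling wraps the sample profile in
#'   the spatial domain and biases ultrafast-axis peak positions.
#' @param carrier_ppm Transmitter offset in ppm; reconstruction axes are
#'   referenced to it before calibration, so its exact value is immaterial
#'   after two-point calibration.
#' @param overhead Fixed per-transient overhead in seconds (hard pulses,
#'   purge/coherence gradients).
#' @param aux_gradients Named list of auxiliary gradient metadata (G_1..G_6),
#'   carried as provenance only.
#' @return An object of class `uf_sequence_params`.
#' @seealso [derive_geometry()], [experiment_duration()]
#' @export
#' @examples
#' p <- seq_params()
#' derive_geometry(p)$L * 100 # sample length in cm, about 1.83
seq_params <- function(T_chirp = 15e-3, sweep = 28e3, G_e = 3.6, G_a = 50.1,
                       T_a = 748e-6, G_p = -21.8, N_acq = 64L, N_i = 8L,
                       N_s = 32L, N_dummy = 4L, recovery = 5, t_m = 10e-3,
                       larmor = 700.28, N_k = 320L, carrier_ppm = 3.0,
                       overhead = 6e-3,
                       aux_gradients = list(
                         G_1 = c(amp_G_cm = 31.3, dur_s = 1e-3),
                         G_2 = c(amp_G_cm = 15.6, dur_s = 1e-3),
                         G_3 = c(amp_G_cm = 50.1, dur_s = 800e-6),
                         G_4 = c(amp_G_cm = -50.1, dur_s = 800e-6),
                         G_5 = c(amp_G_cm = 50.1, dur_s = 1e-3),
                         G_6 = c(amp_G_cm = -50.1, dur_s = 1e-3))) {
  for (nm in c("T_chirp", "sweep", "T_a", "recovery", "t_m", "larmor"))
    stopifnot_scalar_num(get(nm), nm, positive = TRUE)
  stopifnot_scalar_num(overhead, "overhead", nonneg = TRUE)
  N_acq <- as.integer(N_acq); N_i <- as.integer(N_i)
  N_s <- as.integer(N_s); N_dummy <- as.integer(N_dummy)
  N_k <- as.integer(N_k)
  if (N_i < 1L) stop("N_i must be >= 1")
  if (N_acq < 1L) stop("N_acq must be >= 1")
  if (N_k < 8L) stop("N_k must be >= 8")
  if (N_s < 0L || N_dummy < 0L) stop("N_s and N_dummy must be >= 0")
  structure(list(
    T_chirp = T_chirp, sweep = sweep, G_e = G_e, G_a = G_a, T_a = T_a,
    G_p = G_p, N_acq = N_acq, N_i = N_i, N_s = N_s, N_dummy = N_dummy,
    recovery = recovery, t_m = t_m, larmor = larmor, N_k = N_k,
    carrier_ppm = carrier_ppm, overhead = overhead,
    aux_gradients = aux_gradients), class = "uf_sequence_params")
}

#' @export
print.uf_sequence_params <- function(x, ...) {
  cat("Interleaved ultrafast COSY sequence parameters\n")
  cat(sprintf("  chirp: %.3g ms sweeping %.3g kHz under G_e = %.3g G/cm\n",
              1e3 * x$T_chirp, 1e-3 * x$sweep, x$G_e))
  cat(sprintf("  EPSI: G_a = %.3g G/cm, T_a = %.0f us, N_acq = %d, N_k = %d\n",
              x$G_a, 1e6 * x$T_a, x$N_acq, x$N_k))
  cat(sprintf("  scans: N_i = %d interleaves x N_s = %d averages (+%d dummies)\n",
              x$N_i, x$N_s, x$N_dummy))
  cat(sprintf("  recovery %.3g s, t_m %.3g ms, %.2f MHz, carrier %.2f ppm\n",
              x$recovery, 1e3 * x$t_m, x$larmor, x$carrier_ppm))
  invisible(x)
}

#' Interleaving delays
#'
#' Pre-acquisition delays for the interleaved scans,
#' `d_i = i * 2 * T_a / N_i` for `i = 0 .. N_i - 1`.  Interleaving slots the
#' echo trains of successive scans between one another, multiplying the
#' conventional-dimension spectral width by `N_i`.
#'
#' @param T_a Acquisition gradient lobe duration in seconds.
#' @param N_i Number of interleaved scans (>= 1).
#' @return Numeric vector of `N_i` delays in seconds, starting at 0.
#' @export
#' @examples
#' interleave_delays(748e-6, 8) # steps of 187 us
interleave_delays <- function(T_a, N_i) {
  stopifnot_scalar_num(T_a, "T_a", positive = TRUE)
  N_i <- as.integer(N_i)
  if (is.na(N_i) || N_i < 1L) stop("N_i must be an integer >= 1")
  (seq_len(N_i) - 1L) * 2 * T_a / N_i
}

#' Derived acquisition geometry
#'
#' Computes the quantities implied by the sequence parameters: the spatially
#' encoded sample length `L = sweep / (gamma_H * G_e)`, the encoding constant
#' `C = 2 * T_chirp / L` mapping position to effective indirect evolution
#' time, the k-space extent of one gradient lobe
#' `k_max = 2 * pi * gamma_H * G_a * T_a`, the ultrafast-dimension span
#' `f1_span = k_max / (2 * pi * C)`, the interleaved conventional-dimension
#' spectral width `SW2 = N_i / (2 * T_a)`, the interleaving delays, and the
#' total experiment duration.
#'
#' `gamma_H = 4257.7` Hz/G is used throughout.
#'
#' @param p A [seq_params()] object.
#' @return An object of class `uf_timing` with fields `L` (m), `C` (s/m),
#'   `k_max` (rad/m), `SW2` (Hz), `f1_span` (Hz), `delays` (s),
#'   `duration` (s).
#' @export
#' @examples
#' dt <- derive_geometry(seq_params())
#' dt$SW2 / seq_params()$larmor # conventional width in ppm, about 7.6
derive_geometry <- function(p) {
  stopifnot(inherits(p, "uf_sequence_params"))
  if (p$G_e == 0 || p$G_a == 0) stop("gradient amplitudes must be non-zero")
  L <- p$sweep / (GAMMA_H * abs(p$G_e) * 100)       # m (gamma*G in Hz/m)
  C <- 2 * p$T_chirp / L                            # s/m
  k_max <- 2 * pi * GAMMA_H * abs(p$G_a) * 100 * p$T_a  # rad/m
  structure(list(
    L = L, C = C, k_max = k_max,
    SW2 = p$N_i / (2 * p$T_a),
    f1_span = k_max / (2 * pi * C),
    delays = interleave_delays(p$T_a, p$N_i),
    duration = experiment_duration(p)), class = "uf_timing")
}

#' @export
print.uf_timing <- function(x, ...) {
  cat(sprintf("Derived geometry: L = %.3f cm, C = %.4g s/m, k_max = %.4g rad/m\n",
              100 * x$L, x$C, x$k_max))
  cat(sprintf("  SW2 = %.1f Hz, f1 span = %.1f Hz, duration = %.1f s\n",
              x$SW2, x$f1_span, x$duration))
  invisible(x)
}

#' Merged conventional-dimension time grid
#'
#' Interleaving merges the same-polarity lobe times `2 m T_a + d_i`
#' (`m = 0 .. N_acq-1`, `i = 0 .. N_i-1`) into a single uniform grid of
#' `N_acq * N_i` points with dwell `2 T_a / N_i`.  The returned attributes
#' record which interleave contributed each grid point; along the grid the
#' interleave index repeats with period `N_i`, which is what makes
#' scan-to-scan differences between interleaves appear as periodic ghost
#' peaks in the conventional dimension.
#'
#' @param p A [seq_params()] object.
#' @return Numeric vector of `N_acq * N_i` times (s), sorted increasing, with
#'   attributes `interleave` (0-based contributing interleave per point),
#'   `loop` (0-based acquisition loop per point) and `dwell` (s).
#' @export
t2_grid <- function(p) {
  stopifnot(inherits(p, "uf_sequence_params"))
  d <- interleave_delays(p$T_a, p$N_i)
  m <- rep(0:(p$N_acq - 1L), each = p$N_i)
  i <- rep(0:(p$N_i - 1L), times = p$N_acq)
  t <- 2 * m * p$T_a + d[i + 1L]
  o <- order(t)
  structure(t[o], interleave = i[o], loop = m[o], dwell = 2 * p$T_a / p$N_i)
}

#' Total experiment duration
#'
#' Wall-clock duration of one acquisition schedule:
#' `(N_i * N_s + N_dummy) * T_transient` with
#' `T_transient = recovery + 2 T_chirp + t_m + 2 N_acq T_a + overhead`.
#' Dummy transients are counted once, not per interleave.  With the default
#' parameters this rounds up to the published 23 minutes per spectrum.
#'
#' @param p A [seq_params()] object.
#' @return Duration in seconds.
#' @export
#' @examples
#' ceiling(experiment_duration(seq_params()) / 60) # 23 minutes
experiment_duration <- function(p) {
  stopifnot(inherits(p, "uf_sequence_params"))
  T_transient <- p$recovery + 2 * p$T_chirp + p$t_m +
    2 * p$N_acq * p$T_a + p$overhead
  (p$N_i * p$N_s + p$N_dummy) * T_transient
}
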