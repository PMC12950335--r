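#' Jitter and noise specifications
#'
#' Scan-to-scan instability is what creates interleaving ghost artefacts:
#' the merged conventional-dimension grid cycles through the interleaves
#' with period `N_i`, so any amplitude or phase difference between
#' interleaves modulates the signal periodically and throws up ghost peaks
#' at multiples of `SW2 / N_i` from each parent peak.  The model separates a
#' random per-transient component (`amp_sigma`, `phase_sigma`), which
#' averages down with the number of scans, from a systematic per-interleave
#' amplitude pattern (`systematic_amp`), which does not.  Solvent peaks --
#' the dominant ghost parents in practice, through partial saturation of the
#' suppression -- have their jitter deviations scaled by
#' `solvent_multiplier`.
#'
#' Defaults (`amp_sigma` 2e-3, `phase_sigma` 2e-3 rad, a sinusoidal
#' per-interleave pattern of amplitude 2e-3, `solvent_multiplier` 5) are
#' model choices tuned to nothing: they make solvent ghosts clearly visible
#' above metabolite peaks while leaving metabolite ghosts negligible.
#'
#' @param amp_sigma Standard deviation of the random per-transient relative
#'   amplitude error.
#' @param phase_sigma Standard deviation of the random per-transient phase
#'   error in radians.
#' @param systematic_amp Per-interleave relative amplitude offsets (length
#'   `N_i`), or `NULL` for the default sinusoidal pattern
#'   `2e-3 * sin(2 pi i / N_i)` built when the simulation runs.
#' @param solvent_multiplier Factor (>= 1) applied to all jitter deviations
#'   of solvent-class peaks.
#' @return An object of class `uf_jitter`.
#' @export
jitter_spec <- function(amp_sigma = 2e-3, phase_sigma = 2e-3,
                        systematic_amp = NULL, solvent_multiplier = 5) {
  stopifnot_scalar_num(amp_sigma, "amp_sigma", nonneg = TRUE)
  stopifnot_scalar_num(phase_sigma, "phase_sigma", nonneg = TRUE)
  stopifnot_scalar_num(solvent_multiplier, "solvent_multiplier")
  if (solvent_multiplier < 1) stop("solvent_multiplier must be >= 1")
  structure(list(amp_sigma = amp_sigma, phase_sigma = phase_sigma,
                 systematic_amp = systematic_amp,
                 solvent_multiplier = solvent_multiplier),
            class = "uf_jitter")
}

#' @rdname jitter_spec
#' @export
no_jitter <- function() jitter_spec(0, 0, numeric(0), 1)

#' @rdname jitter_spec
#' @param sigma_thermal Thermal noise amplitude per real/imaginary component
#'   of each raw sample (>= 0; 0 disables noise).
#' @param seed Integer seed recorded with the data.
#' @export
noise_spec <- function(sigma_thermal = 1.0, seed = 1L) {
  stopifnot_scalar_num(sigma_thermal, "sigma_thermal", nonneg = TRUE)
  structure(list(sigma_thermal = sigma_thermal, seed = as.integer(seed)),
            class = "uf_noise")
}

#' Sample-profile transform
#'
#' Fourier transform of the unit-normalised box profile of a sample of
#' length `L`: `W(q) = sin(qL/2) / (qL/2)`, `W(0) = 1`.  In the
#' spatially encoded experiment each resonance appears in the EPSI readout
#' as this echo shape centred at `k = -C * Omega1`.
#'
#' @param q Spatial frequency in rad/m (vectorised).
#' @param L Sample length in m.
#' @return Numeric vector of the same length as `q`.
#' @export
profile_transform <- function(q, L) {
  stopifnot_scalar_num(L, "L", positive = TRUE)
  x <- q * L / 2
  out <- array(1, dim = dim(x) %||% length(x))
  nz <- x != 0
  out[nz] <- sin(x[nz]) / x[nz]
  if (is.null(dim(q))) out <- as.vector(out)
  out
}

# k positions swept by one gradient lobe; each lobe covers
# [-k_max/2, +k_max/2), positive lobes ascending, negative descending.
lobe_k_grid <- function(p, timing) {
  kappa <- 2 * pi * GAMMA_H * abs(p$G_a) * 100    # rad/(m s)
  tau <- (seq_len(p$N_k) - 0.5) * p$T_a / p$N_k
  k_even <- -kappa * p$T_a / 2 + kappa * tau
  list(even = k_even, odd = rev(k_even), tau = tau)
}

#' Simulate raw interleaved EPSI data
#'
#' Generates the complex readout of every transient under the spatial
#' encoding signal model.  For transient `(i, s)`, gradient lobe `g`
#' (polarity `(-1)^g`) and intra-lobe sample `j`, the noiseless signal is
#' the sum over peaks of
#' `A_p * J_p(i, s) * W(k(g, j) + C * Omega1_p) * exp((1i * Omega2_p - 1/T2_p) * t2)`
#' where `W` is [profile_transform()], `Omega1/Omega2` are the peak's
#' angular offsets from the carrier, `t2 = d_i + g * T_a` in the default
#' idealized mode (chemical-shift evolution frozen within a lobe) or
#' additionally advances by the intra-lobe time in realistic mode, and
#' `J_p(i, s)` is the jitter factor of the peak's class.  Complex Gaussian
#' thermal noise is added per sample.  All randomness comes from one seeded
#' generator: identical inputs and seed give bit-identical output.
#'
#' Realistic mode includes intra-lobe evolution, which shears echo positions
#' slightly; no shear correction is applied downstream, so the idealized
#' mode is the reference surface.
#'
#' @param peaks Peak list (see [peaklist()]), normally after
#'   [apply_suppression()].
#' @param params A [seq_params()] object.
#' @param timing Matching [derive_geometry()] result (recomputed if `NULL`).
#' @param jitter A [jitter_spec()].
#' @param noise A [noise_spec()].
#' @param seed Integer seed; defaults to `noise$seed`.
#' @param mode `"idealized"` (default) or `"realistic"`.
#' @return An object of class `uf_raw`: complex array `data` with
#'   dimensions `(N_i, N_s, 2 * N_acq, N_k)`, plus `params`, `timing`,
#'   `mode` and a `provenance` list.
#' @export
simulate_raw <- function(peaks, params, timing = NULL,
                         jitter = jitter_spec(), noise = noise_spec(),
                         seed = noise$seed,
                         mode = c("idealized", "realistic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "uf_sequence_params"),
            inherits(jitter, "uf_jitter"), inherits(noise, "uf_noise"))
  if (is.null(timing)) timing <- derive_geometry(params)
  p <- params
  G <- 2L * p$N_acq
  kg <- lobe_k_grid(p, timing)
  delays <- timing$delays
  sys_amp <- jitter$systematic_amp
  if (is.null(sys_amp)) sys_amp <- 2e-3 * sin(2 * pi * (0:(p$N_i - 1)) / p$N_i)
  if (length(sys_amp) == 0) sys_amp <- rep(0, p$N_i)
  if (length(sys_amp) != p$N_i)
    stop("systematic_amp must have length N_i")

  base <- list(normal = NULL, solvent = NULL)   # [i, g, j] noiseless signal
  if (nrow(peaks)) {
    nu1 <- (peaks$f1 - p$carrier_ppm) * p$larmor   # Hz
    if (any(abs(nu1) > timing$f1_span / 2))
      warning("some peaks lie outside +/- f1_span/2; their echoes fold")
    om1 <- 2 * pi * nu1
    om2 <- 2 * pi * (peaks$f2 - p$carrier_ppm) * p$larmor
    cc <- 1i * om2 - 1 / peaks$T2
    solv <- peaks$class == "solvent"
    for (cls in c("normal", "solvent")) {
      sel <- if (cls == "solvent") solv else !solv
      if (!any(sel)) next
      A <- peaks$amplitude[sel]
      W_even <- profile_transform(outer(kg$even, timing$C * om1[sel], `+`),
                                  timing$L)          # N_k x P
      W_odd <- profile_transform(outer(kg$odd, timing$C * om1[sel], `+`),
                                 timing$L)
      M_even <- W_even; M_odd <- W_odd
      if (mode == "realistic") {
        V <- exp(outer(kg$tau, cc[sel]))              # N_k x P
        M_even <- M_even * V; M_odd <- M_odd * V
      }
      Eg <- exp(outer(cc[sel], (0:(G - 1)) * p$T_a))  # P x G
      arr <- array(0i, dim = c(p$N_i, G, p$N_k))
      even_g <- seq(1L, G, by = 2L); odd_g <- seq(2L, G, by = 2L)
      for (i in seq_len(p$N_i)) {
        Ei <- Eg * (A * exp(cc[sel] * delays[i]))     # P x G (recycled cols)
        arr[i, even_g, ] <- t(Ei[, even_g, drop = FALSE]) %*% t(M_even)
        arr[i, odd_g, ] <- t(Ei[, odd_g, drop = FALSE]) %*% t(M_odd)
      }
      base[[cls]] <- arr
    }
  }

  data <- array(0i, dim = c(p$N_i, p$N_s, G, p$N_k))
  with_seed(seed, {
    eps <- matrix(stats::rnorm(p$N_i * p$N_s, sd = jitter$amp_sigma),
                  p$N_i, p$N_s)
    phi <- matrix(stats::rnorm(p$N_i * p$N_s, sd = jitter$phase_sigma),
                  p$N_i, p$N_s)
    dev <- sys_amp + eps                               # N_i x N_s
    for (s in seq_len(p$N_s)) {
      J_n <- (1 + dev[, s]) * exp(1i * phi[, s])
      J_s <- (1 + jitter$solvent_multiplier * dev[, s]) *
        exp(1i * jitter$solvent_multiplier * phi[, s])
      for (i in seq_len(p$N_i)) {
        slab <- array(0i, dim = c(G, p$N_k))
        if (!is.null(base$normal)) slab <- slab + J_n[i] * base$normal[i, , ]
        if (!is.null(base$solvent)) slab <- slab + J_s[i] * base$solvent[i, , ]
        data[i, s, , ] <- slab
      }
    }
    if (noise$sigma_thermal > 0)
      data <- data + complex_noise(length(data), noise$sigma_thermal)
  })

  structure(list(
    data = data, params = p, timing = timing, mode = mode, averaged = FALSE,
    provenance = list(seed = as.integer(seed), jitter = unclass(jitter),
                      sigma_thermal = noise$sigma_thermal,
                      systematic_amp = sys_amp,
                      n_peaks = nrow(peaks))), class = "uf_raw")
}

#' @export
print.uf_raw <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Raw interleaved EPSI data: %d interleaves x %d averages x %d lobes x %d samples (%s mode%s)\n",
              d[1], d[2], d[3], d[4], x$mode,
              if (x$averaged) ", averaged" else ""))
  invisible(x)
}

#' Average the scans of a raw data set
#'
#' Takes the mean over the average axis.  Thermal noise shrinks by
#' `sqrt(N_s)`; systematic per-interleave jitter (the same factor in every
#' average) is untouched, which is why its ghosts do not average away.
#'
#' @param raw A `uf_raw` object.
#' @return The same object with the average axis collapsed to length 1 and
#'   `averaged = TRUE`.
#' @export
average_scans <- function(raw) {
  stopifnot(inherits(raw, "uf_raw"))
  d <- dim(raw$data)
  if (d[2] > 1L) {
    m <- aperm(raw$data, c(2, 1, 3, 4))
    dim(m) <- c(d[2], prod(d[-2]))
    avg <- colMeans(m)
    raw$data <- array(avg, dim = c(d[1], 1L, d[3], d[4]))
  }
  raw$averaged <- TRUE
  raw
}

#' Pass raw data through the receiver chain
#'
#' Multiplies every sample by the receiver gain and adds post-gain digitiser
#' noise, the mechanism behind the SNR plateau: once
#' `RG * sigma_thermal >> sigma_adc` further gain buys nothing.  If `RG` is
#' `NULL` it is chosen with [choose_receiver_gain()] from `max_signal` (by
#' default the sum of suppressed peak amplitudes recorded at simulation
#' time is not available here, so `max_signal` must then be given).
#' Clipping is not modelled; the headroom fraction keeps the largest signal
#' below full scale.
#'
#' @param raw A `uf_raw` object.
#' @param g A [gain_model()].
#' @param RG Receiver gain; computed from `max_signal` when `NULL`.
#' @param max_signal Largest residual time-domain amplitude, used when `RG`
#'   is `NULL`.
#' @param seed Seed for the digitiser noise.
#' @return The `uf_raw` object with scaled data and `RG` recorded in its
#'   provenance.
#' @export
apply_receiver <- function(raw, g = gain_model(), RG = NULL,
                           max_signal = NULL, seed = 1L) {
  stopifnot(inherits(raw, "uf_raw"), inherits(g, "uf_gain_model"))
  if (is.null(RG)) {
    if (is.null(max_signal)) stop("give either RG or max_signal")
    RG <- choose_receiver_gain(max_signal, g)
  }
  raw$data <- RG * raw$data
  with_seed(seed, {
    raw$data <- raw$data + complex_noise(length(raw$data), g$sigma_adc)
  })
  raw$provenance$RG <- RG
  raw$provenance$sigma_adc <- g$sigma_adc
  raw
}
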