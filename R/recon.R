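#' Processing configuration
#'
#' @param zerofill Length-2 integer vector: final matrix size, ultrafast
#'   axis first.  The published chain zero-fills to 512 x 1024; here the 512
#'   is assigned to the ultrafast axis (matching its smaller acquired size)
#'   and the 1024 to the conventional axis.
#' @param gauss_sigma Width of the Gaussian apodisation applied in the
#'   spatial domain, as a fraction of the spatial extent.  `Inf` disables
#'   apodisation.
#' @param sine_window Apply the half-sine window along the conventional
#'   dimension before its Fourier transform.
#' @param polarity Which gradient polarity to reconstruct: `"both"`
#'   (magnitude sum, default), `"even"` or `"odd"`.
#' @return An object of class `uf_proc_config`.
#' @export
proc_config <- function(zerofill = c(512L, 1024L), gauss_sigma = 0.25,
                        sine_window = TRUE,
                        polarity = c("both", "even", "odd")) {
  polarity <- match.arg(polarity)
  zerofill <- as.integer(zerofill)
  stopifnot(length(zerofill) == 2L, all(zerofill >= 2L))
  if (!(is.numeric(gauss_sigma) && length(gauss_sigma) == 1L &&
        (is.infinite(gauss_sigma) || gauss_sigma > 0)))
    stop("gauss_sigma must be a positive scalar or Inf")
  structure(list(zerofill = zerofill, gauss_sigma = gauss_sigma,
                 sine_window = isTRUE(sine_window), polarity = polarity),
            class = "uf_proc_config")
}

#' Split lobes by polarity and merge interleaves
#'
#' Partitions the EPSI gradient lobes of an averaged raw data set by
#' polarity, reverses the sample axis of the negative lobes (they sweep
#' k-space backwards), and orders the columns of each polarity by the merged
#' conventional-dimension time grid of [t2_grid()].
#'
#' @param raw An averaged `uf_raw` object (see [average_scans()]).
#' @return List with complex matrices `even` and `odd` of dimension
#'   `N_k x (N_acq * N_i)`, the common time grid `t2`, and the `params` /
#'   `timing` carried over.
#' @export
split_and_merge <- function(raw) {
  stopifnot(inherits(raw, "uf_raw"))
  if (!raw$averaged && dim(raw$data)[2] > 1L)
    stop("average the scans first (average_scans)")
  p <- raw$params
  d <- dim(raw$data)
  if (d[1] != p$N_i)
    stop("raw data is missing interleaves: found ", d[1], ", expected ", p$N_i)
  grid <- t2_grid(p)
  il <- attr(grid, "interleave"); lp <- attr(grid, "loop")
  n <- length(grid)
  even <- matrix(0i, p$N_k, n)
  odd <- matrix(0i, p$N_k, n)
  for (col in seq_len(n)) {
    i <- il[col] + 1L
    even[, col] <- raw$data[i, 1L, 2L * lp[col] + 1L, ]
    odd[, col] <- rev(raw$data[i, 1L, 2L * lp[col] + 2L, ])
  }
  list(even = even, odd = odd, t2 = grid, params = p, timing = raw$timing,
       provenance = raw$provenance)
}

mv_fftshift <- function(m) m[c(seq(floor(nrow(m) / 2) + 1L, nrow(m)),
                               seq_len(floor(nrow(m) / 2))), , drop = FALSE]
mv_ifftshift <- function(m) m[c(seq(ceiling(nrow(m) / 2) + 1L, nrow(m)),
                                seq_len(ceiling(nrow(m) / 2))), , drop = FALSE]

# Ultrafast-axis processing of one polarity matrix (N_k x N_t2):
# inverse transform to the spatial domain, Gaussian apodisation,
# centre-padding to `zf` points, forward transform back to k.
process_f1_axis <- function(m, zf, gauss_sigma) {
  nk <- nrow(m)
  if (zf < nk) stop("ultrafast zero-fill smaller than acquired size")
  z <- mv_fftshift(stats::mvfft(mv_ifftshift(m), inverse = TRUE)) / nk
  if (is.finite(gauss_sigma)) {
    x <- seq_len(nk) - 1 - nk / 2
    z <- z * exp(-x^2 / (2 * (gauss_sigma * nk)^2))
  }
  pad <- matrix(0i, zf, ncol(m))
  pad[(zf - nk) %/% 2 + seq_len(nk), ] <- z
  mv_fftshift(stats::mvfft(mv_ifftshift(pad)))
}

#' Reconstruct a 2D spectrum from merged EPSI data
#'
#' Implements the processing chain: along the ultrafast axis an inverse
#' Fourier transform into the spatial domain, Gaussian apodisation there,
#' zero-filling and a forward transform back; along the conventional axis a
#' half-sine window over the acquired points, zero-filling and a Fourier
#' transform.  Magnitude is taken (the sine window and ultrafast practice
#' imply magnitude-mode display), and with `polarity = "both"` the two
#' gradient-polarity spectra are summed after the odd set's `T_a` time
#' offset is applied as a linear phase.
#'
#' The ultrafast axis is converted to ppm through the encoding constant
#' (`f1 = -k / (2 pi C)` relative to the carrier) and the conventional axis
#' through `SW2` about the carrier; both axes are returned decreasing, the
#' NMR convention.  Axes are nominal until [calibrate()] is applied.
#'
#' @param S Output of [split_and_merge()].
#' @param config A [proc_config()].
#' @param complex_out Return the complex spectrum instead of the magnitude
#'   (with `polarity = "both"` the aligned complex sum).  Used for
#'   phase-sensitive diagnostics such as ghost-amplitude measurement, where
#'   magnitude subtraction cannot cancel interference from neighbouring
#'   peak tails.
#' @return An object of class `uf_spectrum`: non-negative `matrix`
#'   (`zerofill[1] x zerofill[2]`, complex when `complex_out`), `f1_axis`,
#'   `f2_axis` (ppm, decreasing) and `provenance`.
#' @export
process_spectrum <- function(S, config = proc_config(), complex_out = FALSE) {
  stopifnot(inherits(config, "uf_proc_config"))
  p <- S$params; timing <- S$timing
  zf1 <- config$zerofill[1]; zf2 <- config$zerofill[2]
  n_t2 <- ncol(S$even)
  if (zf2 < n_t2) stop("conventional zero-fill smaller than acquired size")
  sw2 <- 1 / attr(S$t2, "dwell")
  f_hz <- (seq_len(zf2) - 1 - zf2 / 2) * sw2 / zf2   # ascending, Hz

  one_pol <- function(m, t_offset) {
    m <- process_f1_axis(m, zf1, config$gauss_sigma)
    if (config$sine_window) {
      w <- sin(pi * (seq_len(n_t2) - 0.5) / n_t2)
      m <- sweep(m, 2, w, `*`)
    }
    mt <- matrix(0i, zf2, zf1)
    mt[seq_len(n_t2), ] <- t(m)
    sp <- mv_fftshift(stats::mvfft(mt))                # zf2 x zf1, f ascending
    if (t_offset != 0) sp <- sp * exp(-2i * pi * f_hz * t_offset)
    t(sp)                                              # zf1 x zf2
  }

  post <- if (complex_out) identity else Mod
  mag <- switch(config$polarity,
    even = post(one_pol(S$even, 0)),
    odd = post(one_pol(S$odd, p$T_a)),
    both = post(one_pol(S$even, 0)) + post(one_pol(S$odd, p$T_a)))

  dk <- timing$k_max / p$N_k
  k_axis <- (seq_len(zf1) - 1 - zf1 / 2) * timing$k_max / zf1 + dk / 2
  f1_ppm <- p$carrier_ppm - k_axis / (2 * pi * timing$C) / p$larmor
  f2_ppm <- p$carrier_ppm + f_hz / p$larmor
  # NMR convention: both axes decreasing
  mag <- mag[, rev(seq_len(zf2)), drop = FALSE]
  f2_ppm <- rev(f2_ppm)
  structure(list(matrix = mag, f1_axis = f1_ppm, f2_axis = f2_ppm,
                 provenance = c(S$provenance,
                                list(processing = unclass(config),
                                     SW2 = sw2, larmor = p$larmor,
                                     N_i = p$N_i))),
            class = "uf_spectrum")
}

#' @export
print.uf_spectrum <- function(x, ...) {
  cat(sprintf("2D spectrum %d x %d, f1 %.2f..%.2f ppm, f2 %.2f..%.2f ppm\n",
              nrow(x$matrix), ncol(x$matrix),
              max(x$f1_axis), min(x$f1_axis),
              max(x$f2_axis), min(x$f2_axis)))
  invisible(x)
}

#' Locate the maximum of a spectral region
#'
#' @param spec A `uf_spectrum`.
#' @param f1_range,f2_range Length-2 ppm windows (any order); `NULL` means
#'   the whole axis.
#' @return List with the peak position `f1`, `f2` (ppm), its `value` and
#'   matrix indices `i`, `j`.
#' @export
find_peak <- function(spec, f1_range = NULL, f2_range = NULL) {
  stopifnot(inherits(spec, "uf_spectrum"))
  ri <- if (is.null(f1_range)) seq_along(spec$f1_axis) else
    which(spec$f1_axis >= min(f1_range) & spec$f1_axis <= max(f1_range))
  rj <- if (is.null(f2_range)) seq_along(spec$f2_axis) else
    which(spec$f2_axis >= min(f2_range) & spec$f2_axis <= max(f2_range))
  if (!length(ri) || !length(rj)) stop("empty search region")
  sub <- spec$matrix[ri, rj, drop = FALSE]
  if (is.complex(sub)) sub <- Mod(sub)
  ij <- arrayInd(which.max(sub), dim(sub))
  i <- ri[ij[1]]; j <- rj[ij[2]]
  list(f1 = spec$f1_axis[i], f2 = spec$f2_axis[j],
       value = spec$matrix[i, j], i = i, j = j)
}

#' Two-point chemical-shift calibration
#'
#' Solves, independently for each axis, the affine map (scale, offset) that
#' sends the two measured peak positions to their reference values, and
#' applies it to the axis.  With the conventional anchors -- the TSP peak at
#' 0.00/0.00 ppm and the tartrate peak at 4.47/4.47 ppm -- the reference
#' peaks land exactly on their reference coordinates.
#'
#' @param spec A `uf_spectrum`.
#' @param measured List of two `c(f1, f2)` measured positions (ppm).
#' @param references List of two `c(f1, f2)` reference positions (ppm).
#' @return The spectrum with calibrated axes; the fitted per-axis maps are
#'   stored in `provenance$calibration`.
#' @export
calibrate <- function(spec, measured, references) {
  stopifnot(inherits(spec, "uf_spectrum"),
            length(measured) == 2L, length(references) == 2L)
  maps <- lapply(1:2, function(ax) {
    m <- c(measured[[1]][ax], measured[[2]][ax])
    r <- c(references[[1]][ax], references[[2]][ax])
    if (m[1] == m[2]) stop("coincident measured reference positions on axis ", ax)
    scale <- (r[1] - r[2]) / (m[1] - m[2])
    c(scale = scale, offset = r[1] - scale * m[1])
  })
  spec$f1_axis <- maps[[1]]["scale"] * spec$f1_axis + maps[[1]]["offset"]
  spec$f2_axis <- maps[[2]]["scale"] * spec$f2_axis + maps[[2]]["offset"]
  spec$provenance$calibration <- list(f1 = maps[[1]], f2 = maps[[2]])
  spec
}
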