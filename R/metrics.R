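#' Rectangular spectral regions and peak definitions
#'
#' Regions use half-open membership on each axis (`min <= x < max`) so that
#' a partition of a region integrates exactly to the whole.
#'
#' @param f1_min,f1_max,f2_min,f2_max Region bounds in ppm (`min < max`).
#' @return An object of class `uf_region`.
#' @export
region <- function(f1_min, f1_max, f2_min, f2_max) {
  if (!(f1_min < f1_max && f2_min < f2_max))
    stop("region bounds must satisfy min < max on both axes")
  structure(list(f1_min = f1_min, f1_max = f1_max,
                 f2_min = f2_min, f2_max = f2_max), class = "uf_region")
}

#' @rdname region
#' @param name Peak name.
#' @param peak_region Region containing the peak.
#' @param noise_region Signal-free region on the same row used for the noise
#'   statistics; its f1 range is ignored (the row is taken through the peak
#'   maximum), its f2 range must not overlap the peak's.
#' @export
peak_def <- function(name, peak_region, noise_region) {
  stopifnot(inherits(peak_region, "uf_region"),
            inherits(noise_region, "uf_region"))
  overlap <- peak_region$f2_min < noise_region$f2_max &&
    noise_region$f2_min < peak_region$f2_max
  if (overlap) stop("peak and noise regions overlap in f2")
  structure(list(name = name, peak_region = peak_region,
                 noise_region = noise_region), class = "uf_peak_def")
}

in_range <- function(x, lo, hi) x >= lo & x < hi

region_indices <- function(spec, r) {
  list(i = which(in_range(spec$f1_axis, r$f1_min, r$f1_max)),
       j = which(in_range(spec$f2_axis, r$f2_min, r$f2_max)))
}

#' Row-extracted signal-to-noise ratio
#'
#' Following the published procedure: the maximum inside the peak region is
#' located (verifying the correct row extraction), the f1 row through it is
#' extracted, and `SNR = max over the peak region / standard deviation over
#' the noise region`, both evaluated on that row.
#'
#' @param spec A `uf_spectrum`.
#' @param pd A [peak_def()].
#' @return SNR (dimensionless).
#' @export
snr <- function(spec, pd) {
  stopifnot(inherits(spec, "uf_spectrum"), inherits(pd, "uf_peak_def"))
  pk <- region_indices(spec, pd$peak_region)
  nz <- region_indices(spec, pd$noise_region)
  if (!length(pk$i) || !length(pk$j)) stop("peak region contains no cells")
  if (length(nz$j) < 2L) stop("noise region needs >= 2 cells in f2")
  sub <- spec$matrix[pk$i, pk$j, drop = FALSE]
  ij <- arrayInd(which.max(sub), dim(sub))
  row <- spec$matrix[pk$i[ij[1]], ]
  s <- stats::sd(row[nz$j])
  if (s == 0) stop("noise standard deviation is zero (noiseless input?)")
  max(row[pk$j]) / s
}

#' 2D peak volumes
#'
#' Volume is the plain sum of matrix cells whose axis coordinates fall in
#' the region (half-open membership).  Relative volumes divide by the volume
#' of a reference peak, by convention the TSP internal standard.
#'
#' @param spec A `uf_spectrum`.
#' @param r A [region()].
#' @return [peak_volume()]: the summed intensity.
#' @export
peak_volume <- function(spec, r) {
  stopifnot(inherits(spec, "uf_spectrum"), inherits(r, "uf_region"))
  idx <- region_indices(spec, r)
  if (!length(idx$i) || !length(idx$j))
    stop("region contains no spectrum cells")
  sum(spec$matrix[idx$i, idx$j])
}

#' @rdname peak_volume
#' @param volumes Named numeric vector of peak volumes.
#' @param reference Name of the reference peak (default `"TSP"`).
#' @return [relative_volumes()]: `volumes / volumes[reference]`.
#' @export
relative_volumes <- function(volumes, reference = "TSP") {
  if (!reference %in% names(volumes))
    stop("reference peak '", reference, "' not among the volumes")
  volumes / volumes[[reference]]
}

#' Coefficient of variation
#'
#' `CV = 100 * sample standard deviation / mean`, in percent, the
#' repeatability statistic computed across replicate peak volumes.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return CV in percent.
#' @export
#' @examples
#' cv(c(9, 10, 11)) # 10
cv <- function(values) {
  if (length(values) < 2L) stop("need at least 2 replicates")
  m <- mean(values)
  if (m == 0) stop("mean of replicate values is zero")
  100 * stats::sd(values) / m
}

#' Predict interleaving ghost peaks
#'
#' Along the merged conventional-dimension grid the interleave index repeats
#' with period `N_i`, so per-interleave amplitude factors multiply the
#' signal by a periodic sequence.  Its DFT decomposes each parent peak into
#' replicas: ghost `m` (`m = 1 .. N_i - 1`) sits at
#' `parent_f2 + m * SW2 / N_i` (folded into the spectral window) with
#' complex amplitude `DFT(factors)[m] / DFT(factors)[0]` relative to the
#' parent.  Equal factors give no ghosts, which is why ghost intensity
#' tracks scan-to-scan instability -- strongest for partially saturated
#' solvent signals.
#'
#' @param parent_f2 Parent peak position in ppm.
#' @param SW2 Conventional-dimension spectral width in Hz.
#' @param N_i Number of interleaves.
#' @param larmor Larmor frequency in MHz.
#' @param interleave_factors Per-interleave complex or real amplitude
#'   factors, length `N_i`.
#' @param carrier_ppm Centre of the spectral window, for folding.
#' @return `data.frame` with columns `m`, `f2` (folded ppm), `amplitude`
#'   (complex, relative to the parent).  Zero rows when `N_i = 1`.
#' @export
predict_ghosts <- function(parent_f2, SW2, N_i, larmor = 700.28,
                           interleave_factors = rep(1, N_i),
                           carrier_ppm = 3.0) {
  N_i <- as.integer(N_i)
  if (N_i < 1L) stop("N_i must be >= 1")
  if (length(interleave_factors) != N_i)
    stop("interleave_factors must have length N_i")
  if (N_i == 1L)
    return(data.frame(m = integer(), f2 = numeric(),
                      amplitude = complex()))
  Fm <- stats::fft(interleave_factors)
  m <- seq_len(N_i - 1L)
  f2 <- parent_f2 + m * (SW2 / N_i) / larmor
  span <- SW2 / larmor
  lo <- carrier_ppm - span / 2
  f2 <- ((f2 - lo) %% span) + lo
  data.frame(m = m, f2 = f2, amplitude = Fm[m + 1L] / Fm[1L])
}

#' Count detectable expected peaks
#'
#' An expected peak counts as detectable when it lies inside the spectral
#' window, its position is not within `linewidth_ppm` (in f2) of a predicted
#' solvent ghost, and its local SNR -- maximum within a small search window
#' over a robust noise estimate -- reaches `threshold`.  A `threshold` of 0
#' skips the SNR test (useful for noiseless spectra).
#'
#' @param spec A `uf_spectrum`.
#' @param expected `data.frame` with columns `f1`, `f2` (ppm).
#' @param threshold Minimum local SNR (default 5; a model choice, the
#'   source protocol states none).
#' @param ghosts Optional ghost table from [predict_ghosts()] (rows with
#'   zero amplitude are ignored).
#' @param linewidth_ppm Exclusion half-width around ghost positions.
#' @param search_f1,search_f2 Half-widths of the per-peak search window.
#' @param noise_sd Noise scale; by default a median-absolute-deviation
#'   estimate over the whole matrix (peaks are sparse, so the MAD tracks the
#'   noise floor).
#' @return Integer count.
#' @export
detectable_peaks <- function(spec, expected, threshold = 5, ghosts = NULL,
                             linewidth_ppm = 0.03, search_f1 = 0.08,
                             search_f2 = 0.03, noise_sd = NULL) {
  stopifnot(inherits(spec, "uf_spectrum"), is.data.frame(expected))
  if (!nrow(expected)) return(0L)
  f1r <- range(spec$f1_axis); f2r <- range(spec$f2_axis)
  if (is.null(noise_sd) && threshold > 0)
    noise_sd <- stats::mad(as.vector(spec$matrix))
  ghost_f2 <- if (!is.null(ghosts) && nrow(ghosts))
    ghosts$f2[Mod(ghosts$amplitude) > 0] else numeric()
  n <- 0L
  for (r in seq_len(nrow(expected))) {
    f1 <- expected$f1[r]; f2 <- expected$f2[r]
    if (f1 < f1r[1] || f1 > f1r[2] || f2 < f2r[1] || f2 > f2r[2]) next
    if (length(ghost_f2) && min(abs(f2 - ghost_f2)) < linewidth_ppm) next
    if (threshold > 0) {
      i1 <- which(abs(spec$f1_axis - f1) <= search_f1)
      if (!length(i1)) i1 <- which.min(abs(spec$f1_axis - f1))
      i2 <- which(abs(spec$f2_axis - f2) <= search_f2)
      if (!length(i2)) i2 <- which.min(abs(spec$f2_axis - f2))
      val <- max(spec$matrix[i1, i2])
      if (noise_sd <= 0 || val / noise_sd < threshold) next
    }
    n <- n + 1L
  }
  n
}

#' Read / write peak-definition tables
#'
#' TSV with columns `name`, `f1_min`, `f1_max`, `f2_min`, `f2_max`,
#' `noise_f1_min`, `noise_f1_max`, `noise_f2_min`, `noise_f2_max`.
#'
#' @param path File path.
#' @return List of [peak_def()] objects.
#' @export
read_peak_defs <- function(path) {
  tb <- utils::read.delim(path, comment.char = "#")
  lapply(seq_len(nrow(tb)), function(r) {
    peak_def(tb$name[r],
             region(tb$f1_min[r], tb$f1_max[r], tb$f2_min[r], tb$f2_max[r]),
             region(tb$noise_f1_min[r], tb$noise_f1_max[r],
                    tb$noise_f2_min[r], tb$noise_f2_max[r]))
  })
}
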