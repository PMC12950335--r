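---
title: "Models and methods behind ufcosy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ufcosy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ufcosy)
```

This vignette documents the models the package implements, the parameters
that matter with their defaults and units, the numerical choices, and what
the synthetic-data generator does and does not emulate. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. Signal model

### Spin systems as peak lists

Mixtures are represented at peak-list level, not as density matrices. A
spin system is a set of proton sites (chemical shift in ppm, number of
equivalent protons, shared T2 in seconds) and scalar couplings (J in Hz).
Each site's resonance is expanded into its first-order multiplet: a
coupling to `n` equivalent partners gives `n + 1` lines with binomial
(Pascal's triangle) weights; multiple couplings convolve. A site's diagonal
COSY block is the outer product of its 1D multiplet with itself, with total
amplitude `concentration * n_protons`. Each coupling contributes a pair of
mirror-symmetric cross blocks.

The cross-block amplitude is `cross_transfer * concentration *
sqrt(n_a * n_b)`. Two choices are bundled here. First, coherence-transfer
amplitudes are not derivable at peak-list level, so `cross_transfer`
(default 0.3, dimensionless in (0, 1]) is purely phenomenological. Second,
"cross amplitude proportional to diagonal amplitude" is ambiguous about
*which* diagonal when the two sites have different proton counts; the
geometric mean `sqrt(n_a * n_b)` is the symmetric resolution and is what
guarantees the mirror-symmetry invariant the tests enforce. Antiphase
cross-peak fine structure is not modelled: at this digital resolution and
in magnitude mode it would be invisible, and modelling it honestly would
require the spin dynamics this package deliberately avoids.

### Encoding geometry

With `gamma_H = 4257.7` Hz/G throughout, the encoded sample length is
`L = sweep / (gamma_H * G_e)` (about 1.83 cm at the default 28 kHz sweep
and 3.6 G/cm), and the constant-time double-chirp convention fixes the
encoding constant `C = 2 * T_chirp / L`, so `C * L = 2 * T_chirp`
identically. One acquisition gradient lobe sweeps
`k in [-k_max/2, +k_max/2)` with `k_max = 2 pi gamma_H G_a T_a`; the
prephasing `-k_max/2` puts the echo of an on-carrier resonance mid-lobe. A
resonance at indirect angular offset `Omega1` appears as the sample-profile
transform `W(k + C * Omega1)`, where `W(q) = sin(qL/2)/(qL/2)` is the
analytic transform of a uniform box of length `L` (a discretised-sample
quadrature oracle backs this in the tests). The ultrafast span is
`f1_span = k_max / (2 pi C)`, about 9.7 kHz (13.9 ppm) at defaults, and the
interleaved conventional width is `SW2 = N_i / (2 T_a)`, about 5.35 kHz
(7.64 ppm), which contains the 0–6 ppm aliphatic window.

### Samples per lobe: why the default is N_k = 320, not 128

The EPSI readout samples k-space with spacing `dk = k_max / N_k`, which
implies a spatial field of view `FOV_z = 2 pi / dk = 2 pi N_k / k_max`.
Physical consistency requires `FOV_z >= L`, i.e.
`N_k >= k_max L / (2 pi) = 2 T_chirp f1_span` (about 292 at defaults).
With `N_k = 128` the box profile wraps in the spatial domain, and the
wrap interacts with the Gaussian apodisation to bias ultrafast peak
positions by several final-grid bins — measurably violating the package's
own round-trip requirement. The default is therefore `N_k = 320`
(`FOV_z` about 2.0 cm, a ~10% margin over `L`, the way a real setup is
configured); it remains configurable, and the scaled-down test geometry
(`T_chirp` 4 ms, `T_a` 200 us, `N_k` 96) satisfies the same inequality.

### Timing and schedule

Interleave delays are `d_i = 2 T_a i / N_i`. Merging the same-polarity
lobe times `2 m T_a + d_i` yields a uniform grid of `N_acq * N_i` points
with dwell `2 T_a / N_i`; the interleave index along the grid repeats with
period `N_i`, which is the root cause of ghost periodicity. The schedule
duration is `(N_i N_s + N_dummy) * T_transient` with
`T_transient = recovery + 2 T_chirp + t_m + 2 N_acq T_a + overhead`;
dummies are counted once (not per interleave) and the fixed per-transient
overhead defaults to 6 ms (hard pulses and purge/coherence gradients).
With the published parameter set this rounds up to 23 minutes. Where the
source protocol prints two values for a symbol (`T_a` 748 vs 784 us, `G_p`
−21.8 vs −28.1 G/cm), the body-text value is the default and the field is
configurable; `G_p` and the auxiliary gradients G_1–G_6 are carried as
metadata only, since their coherence-selection physics is out of scope.

## 2. Solvent suppression model

Suppression is modelled as a *static frequency-domain attenuation* of peak
amplitudes — the level at which suppression quality is actually judged
(residual peak size) — not as time-domain saturation dynamics. Each band
is a Gaussian notch: attenuation
`1 - (1 - floor) * exp(-dnu^2 / (2 sigma^2))` with `sigma = width/2.355`
(printed widths are read as FWHM: 20 Hz for water, 7 Hz for each ethanol
band). Floors are calibration knobs of this model, not published values:
presaturation leaves 1e-3 of water; the multi-band scheme reaches 1e-4 on
water and both ethanol bands; WET gets the ethanol bands at 1e-4 but only
5e-2 on water, encoding its observed failure mode.

Two refinements matter:

* **Site-centre attenuation.** The lines of a multiplet belong to the same
  protons, so saturating the site removes the whole multiplet; attenuation
  is therefore evaluated at the multiplet block centre, not per line.
  Without this, the outer lines of the ethanol triplet (±7 Hz) would slip
  past the 7 Hz band, contradicting the observed complete ethanol
  suppression.
* **Faraway water.** A configurable fraction (default 1e-3) of the water
  amplitude represents nuclei at the coil edge that see an off-nominal RF
  field: these peaks ignore the selective bands entirely and are attenuated
  (by a fixed 1e-2) only when the NOESY block is enabled — which is the
  block's role in the sequence.

Both axes of a 2D peak are attenuated independently, since both derive
from the suppressed longitudinal state.

### Receiver gain and the SNR plateau

The receiver model has pre-gain thermal noise `sigma_thermal` (default 1.0
in raw amplitude units), post-gain digitiser noise `sigma_adc` (default
30), digitiser full scale (default 1e6) and a headroom fraction (0.9). The
gain is chosen as `RG = headroom * full_scale / max_signal`, with
`max_signal` taken as the sum of residual peak amplitudes (a cheap,
deterministic upper bound on the time-domain maximum). Then
`SNR = RG A / sqrt((RG sigma_thermal)^2 + sigma_adc^2)`: monotone in RG,
asymptoting to `A / sigma_thermal`. The defaults put roughly 15 effective
bits between full scale and digitiser noise; they reproduce the observed
*ordering and plateau shape*, not any instrument's absolute RG values
(3.56/128/724 are hardware numbers this model does not target).

## 3. Jitter and ghosts

Per transient `(i, s)` the signal is multiplied by
`(1 + sys[i] + eps) * exp(i phi)` with `eps ~ N(0, amp_sigma)` and
`phi ~ N(0, phase_sigma)` random per transient and `sys` a fixed
per-interleave pattern. Solvent-class peaks have all deviations multiplied
by `solvent_multiplier` — partial saturation makes solvents the dominant
ghost parents in practice. Defaults (`amp_sigma` and `phase_sigma` 2e-3,
`sys[i] = 2e-3 sin(2 pi i / N_i)`, multiplier 5) are stated once and not
tuned: they make solvent ghosts clearly visible while metabolite ghosts
stay negligible. Random jitter averages down as `1/N_s` in ghost energy;
the systematic pattern does not average at all — both behaviours are
property-tested.

Ghost prediction is closed-form: factors `f[0..N_i-1]` modulate the merged
grid periodically, so ghost `m` sits at `parent_f2 + m SW2 / N_i` (folded
into the window) with complex relative amplitude `F_m / F_0`, the DFT of
the factors. Equal factors give exactly no ghosts.

## 4. Processing chain

Per polarity: negative-polarity lobes are reversed along the sample axis
(they sweep k backwards), columns are ordered by the merged time grid, and
then

1. **Ultrafast axis:** inverse FFT into the spatial domain, multiplication
   by a centred Gaussian of relative width `gauss_sigma` (default 0.25 of
   the spatial extent — the protocol names the apodisation but not its
   width), centre-padding to 512 points, forward FFT. Centre-padding in z
   refines the k sampling over an unchanged span, implementing the
   zero-fill-style interpolation.
2. **Conventional axis:** half-sine window `sin(pi (n + 1/2) / N)` over the
   acquired points (the half-sample shift avoids nulling the first point),
   zero-fill to 1024, FFT.
3. Magnitude; with `polarity = "both"` (default) the two polarity spectra
   are summed after the odd set's `T_a` time offset is applied as a linear
   phase. Magnitude-mode display is itself a decision: the protocol never
   states 2D phasing, and the sine window plus ultrafast practice imply
   magnitude.

The printed zero-fill "512 × 1024" does not say which number belongs to
which axis; 512 is assigned to the ultrafast axis (matching its smaller
acquired size) and 1024 to the conventional axis. Both polarities are
co-added because discarding one would only cost SNR; `--polarity` exposes
either alone. Axes are referenced to a configurable carrier (default
3.0 ppm); since two-point calibration (TSP 0.00/0.00, tartrate 4.47/4.47,
exact per-axis affine solve) follows, the carrier choice is immaterial.
The acquired k samples sit half a step off the integer grid the FFT
assumes; the axis construction carries that `dk/2` offset explicitly, and
calibration absorbs any residual.

Idealized mode (default) freezes chemical-shift evolution within a lobe
and is the reference surface for every oracle; realistic mode advances
time within the lobe, shearing echo positions slightly, and ships without
a shear correction — a documented limitation, not a default.

## 5. Metrics

* **SNR** follows the published recipe literally: find the maximum inside
  the peak region (verifying the row), extract that f1 row, and divide the
  in-region row maximum by the standard deviation over a signal-free noise
  region of the same row.
* **Volumes** are plain cell sums with half-open region membership
  `[min, max)`, making partitions exact; relative volumes are referenced
  to TSP (the internal standard; the denominator is configurable since the
  protocol does not name one). CV is `100 * sd / mean` over replicates.
* **Detectability** counts expected peak positions that are in-window, not
  within one linewidth (default 0.03 ppm) of a predicted solvent ghost,
  and whose local maximum exceeds `threshold` (default 5) times a robust
  (MAD) noise estimate. The threshold is a model choice; the source states
  none. In the demo, predicted ghosts only mask positions when their
  absolute amplitude (DFT ratio times residual parent amplitude) exceeds
  5 thermal sigma — a fully suppressed parent cannot mask anything.

### Measuring ghost amplitudes in tests

The ghost oracle is validated end-to-end at 1e-3 relative tolerance. A
naive magnitude-ratio measurement cannot reach that: sine-window sidelobe
tails of the parent (~1e-4 relative) interfere with 1e-3-scale ghosts.
The tests therefore measure on the *complex* spectrum
(`process_spectrum(..., complex_out = TRUE)`, single polarity) and
subtract a flat-factor reference simulation scaled at the parent, which
cancels the parent tail exactly and leaves the ghost amplitude clean.

## 6. The synthetic world, and what green tests establish

The wine fixture (`inst/extdata/wine_mixture.tsv`) states the world once:
water 1e5 relative units, ethanol 1e4 (so solvents exceed metabolites by
more than three orders of magnitude), TSP at exactly 0.00 ppm and tartrate
at exactly 4.47 ppm as calibration anchors, and coupled systems standing
in for lactate, acetate, succinate, glycerol, isopentanol, isobutanol,
acetoin, 1,3-propanediol, myo-inositol and further constituents.
Metabolite shifts other than the anchors are illustrative literature-style
values, flagged non-authoritative in the file header. T2 values (0.35–0.8
s) give ~1 Hz natural lines, narrow against the window-limited resolution.

The generator emulates: spatial-encoding echo formation from a box sample,
interleaved EPSI timing, solvent-dominated receiver-gain limitation,
thermal + digitiser noise, and interleave-periodic ghosting. It does not
emulate: strong coupling, chemical exchange or pH shifts, relaxation
during encoding/mixing, radiation damping, gradient imperfections beyond
the jitter model, coherence-selection artefacts of the auxiliary
gradients, field inhomogeneity, or t1 noise of conventional 2D NMR. A
green suite therefore establishes that the *machinery* — geometry,
bookkeeping, transforms, calibration, metrics, and the stated qualitative
orderings (suppression quality → receiver gain → detectability; ghost
periodicity and DFT amplitudes; SNR plateau; CV falling with amplitude) —
is correct; it does not certify quantitative agreement with any real
spectrometer's SNR or CV values, which depend on hardware the model does
not represent.

## 7. Known limitations

* Realistic-mode intra-lobe evolution has no shear correction.
* The vendor-format reader is best-effort (plain `ser` + `acqus`/`acqu2s`,
  no row padding variants) and exists only to feed external benchmark data
  into the same chain.
* Receiver clipping is not modelled; headroom keeps signals below full
  scale by construction.
* Suppression floors, `cross_transfer`, jitter magnitudes and the
  detectability threshold are stated model knobs; none is fit to data.
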