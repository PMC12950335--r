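# Shared fixtures: tiny acquisition geometries keep simulations fast; the
# full-size wine reconstruction used by several acceptance checks is built
# once and cached.

# Scaled-down but physically consistent geometry: shorter chirps and lobes
# keep the f1 span near the full-size 13.9 ppm while N_k = 96 still
# oversamples the sample profile (spatial FOV 2.2 cm > L 1.83 cm).
tiny_params <- function(...) {
  args <- utils::modifyList(
    list(T_chirp = 4e-3, T_a = 200e-6, N_acq = 8L, N_i = 4L, N_s = 1L,
         N_k = 96L),
    list(...))
  do.call(seq_params, args)
}

# A bare peak-list row, bypassing the mixture machinery.
peak_row <- function(f1, f2, amplitude = 1, T2 = 0.4, kind = "diagonal",
                     system = "x", class = "metabolite", faraway = FALSE) {
  data.frame(f1 = f1, f2 = f2, f1_center = f1, f2_center = f2,
             amplitude = amplitude, T2 = T2, kind = kind, system = system,
             class = class, faraway = faraway)
}

# Minimal mixture with the systems the presets need.
tiny_mix <- function(faraway = 1e-3) {
  mixture_spec(list(
    spin_system("water", data.frame(label = "H2O", shift = 4.8,
                                    n_protons = 2),
                concentration = 1e5, klass = "solvent", T2 = 0.8),
    spin_system("ethanol", data.frame(label = c("CH3", "CH2"),
                                      shift = c(1.18, 3.65),
                                      n_protons = c(3, 2)),
                data.frame(site_a = "CH3", site_b = "CH2", J = 7.1),
                concentration = 1e4, klass = "solvent", T2 = 0.6),
    spin_system("TSP", data.frame(label = "TMS", shift = 0, n_protons = 9),
                concentration = 5, klass = "reference", T2 = 0.5),
    spin_system("tartrate", data.frame(label = "CH", shift = 4.47,
                                       n_protons = 2),
                concentration = 20, klass = "metabolite", T2 = 0.4),
    spin_system("lactate", data.frame(label = c("CH3", "CH"),
                                      shift = c(1.33, 4.11),
                                      n_protons = c(3, 1)),
                data.frame(site_a = "CH3", site_b = "CH", J = 6.9),
                concentration = 10, klass = "metabolite", T2 = 0.4)),
    faraway_water_fraction = faraway)
}

# Simulate + reconstruct one noiseless single-resonance spectrum.
single_peak_spectrum <- function(f1, f2, params = seq_params(N_s = 1L),
                                 proc = proc_config(), amplitude = 1,
                                 T2 = 0.4, complex_out = FALSE) {
  raw <- simulate_raw(peak_row(f1, f2, amplitude, T2), params,
                      jitter = no_jitter(), noise = noise_spec(0), seed = 1)
  process_spectrum(split_and_merge(average_scans(raw)), proc,
                   complex_out = complex_out)
}

# Cached full-size wine reconstruction (noiseless, msup, seed 1) shared by
# the acceptance worked examples.
.fixture_cache <- new.env(parent = emptyenv())

wine_msup_spectrum <- function() {
  if (is.null(.fixture_cache$wine_msup)) {
    mix <- wine_fixture()
    params <- seq_params(N_s = 1L)
    res <- run_pipeline(mix, "msup", params, jitter = no_jitter(),
                        noise = noise_spec(0), gain = NULL, seed = 1L,
                        calibrate = FALSE)
    .fixture_cache$wine_msup <- res$spectrum
  }
  .fixture_cache$wine_msup
}
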