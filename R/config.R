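#' End-to-end run configuration
#'
#' Bundles everything a pipeline run needs -- sequence parameters,
#' suppression scheme, processing configuration, jitter/noise models and the
#' seed -- and round-trips losslessly through JSON, so every output file can
#' embed the exact configuration that produced it.
#'
#' @param sequence A [seq_params()] object.
#' @param suppression Scheme name (`"none"`, `"presat"`, `"msup"`, `"wet"`).
#' @param processing A [proc_config()] object.
#' @param jitter A [jitter_spec()] object.
#' @param noise A [noise_spec()] object.
#' @param seed Integer master seed.
#' @return An object of class `uf_run_config`.
#' @export
run_config <- function(sequence = seq_params(), suppression = "msup",
                       processing = proc_config(), jitter = jitter_spec(),
                       noise = noise_spec(), seed = 1L) {
  stopifnot(inherits(sequence, "uf_sequence_params"),
            inherits(processing, "uf_proc_config"),
            inherits(jitter, "uf_jitter"), inherits(noise, "uf_noise"),
            suppression %in% c("none", "presat", "msup", "wet"))
  structure(list(sequence = sequence, suppression = suppression,
                 processing = processing, jitter = jitter, noise = noise,
                 seed = as.integer(seed)), class = "uf_run_config")
}

#' @rdname run_config
#' @param cfg A `uf_run_config`.
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "uf_run_config"))
  l <- lapply(unclass(cfg), function(x)
    if (is.list(x)) unclass(x) else x)
  l$sequence$aux_gradients <- lapply(l$sequence$aux_gradients, as.list)
  # JSON has no Inf; absence encodes "no apodisation"
  if (is.infinite(l$processing$gauss_sigma)) l$processing$gauss_sigma <- NULL
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  l <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  run_config(
    sequence = params_from_list(l$sequence),
    suppression = l$suppression,
    processing = proc_config(zerofill = unlist(l$processing$zerofill),
                             gauss_sigma = l$processing$gauss_sigma %||% Inf,
                             sine_window = l$processing$sine_window,
                             polarity = l$processing$polarity),
    jitter = jitter_spec(amp_sigma = l$jitter$amp_sigma,
                         phase_sigma = l$jitter$phase_sigma,
                         systematic_amp =
                           if (is.null(l$jitter$systematic_amp)) NULL
                           else unlist(l$jitter$systematic_amp),
                         solvent_multiplier = l$jitter$solvent_multiplier),
    noise = noise_spec(sigma_thermal = l$noise$sigma_thermal,
                       seed = l$noise$seed),
    seed = l$seed)
}
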