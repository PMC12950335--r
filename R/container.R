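# Native single-file container: a 4-byte magic, a JSON metadata block and a
# sequence of named double/complex arrays, all little-endian.  Versioned so
# incompatible layouts are rejected explicitly.

CONTAINER_MAGIC <- "UFC1"
CONTAINER_VERSION <- 1L

#' Save / load the native array container
#'
#' Losslessly stores named numeric or complex arrays together with a JSON
#' metadata block (seeds, configuration echoes, provenance).  The format is
#' versioned; loading a file with a different format version or corrupted
#' magic bytes fails with an explicit error.
#'
#' @param path File path.
#' @param arrays Named list of numeric or complex arrays/vectors/matrices.
#' @param metadata List serialisable to JSON.
#' @return [save_container()] invisibly returns `path`; [load_container()]
#'   returns `list(arrays = ..., metadata = ...)` with bit-identical array
#'   contents.
#' @export
save_container <- function(path, arrays, metadata = list()) {
  stopifnot(is.list(arrays), length(arrays) == 0 ||
              !is.null(names(arrays)) && all(nzchar(names(arrays))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(CONTAINER_MAGIC), con)
  metadata$format_version <- CONTAINER_VERSION
  meta_raw <- charToRaw(jsonlite::toJSON(metadata, auto_unbox = TRUE,
                                         digits = NA, null = "null"))
  writeBin(length(meta_raw), con, size = 4L, endian = "little")
  writeBin(meta_raw, con)
  writeBin(length(arrays), con, size = 4L, endian = "little")
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    if (!(is.numeric(a) || is.complex(a)))
      stop("array '", nm, "' must be numeric or complex")
    nm_raw <- charToRaw(nm)
    writeBin(length(nm_raw), con, size = 4L, endian = "little")
    writeBin(nm_raw, con)
    writeBin(if (is.complex(a)) 2L else 1L, con, size = 4L, endian = "little")
    d <- dim(a) %||% length(a)
    writeBin(length(d), con, size = 4L, endian = "little")
    writeBin(as.integer(d), con, size = 4L, endian = "little")
    if (is.complex(a)) {
      buf <- numeric(2L * length(a))
      buf[c(TRUE, FALSE)] <- Re(a)
      buf[c(FALSE, TRUE)] <- Im(a)
      writeBin(buf, con, size = 8L, endian = "little")
    } else {
      writeBin(as.double(a), con, size = 8L, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname save_container
#' @export
load_container <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, CONTAINER_MAGIC))
    stop("not a ufcosy container (bad magic bytes): ", path)
  nmeta <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  metadata <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", nmeta)),
                                 simplifyDataFrame = FALSE)
  if (!identical(as.integer(metadata$format_version), CONTAINER_VERSION))
    stop("container format version ", metadata$format_version,
         " is not supported (expected ", CONTAINER_VERSION, ")")
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  arrays <- vector("list", n)
  nms <- character(n)
  for (k in seq_len(n)) {
    ln <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    nms[k] <- rawToChar(readBin(con, "raw", ln))
    type <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    nd <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    d <- readBin(con, "integer", nd, size = 4L, endian = "little")
    len <- prod(d)
    if (type == 2L) {
      buf <- readBin(con, "double", 2L * len, size = 8L, endian = "little")
      a <- complex(real = buf[c(TRUE, FALSE)],
                   imaginary = buf[c(FALSE, TRUE)])
    } else {
      a <- readBin(con, "double", len, size = 8L, endian = "little")
    }
    if (nd > 1L) dim(a) <- d
    arrays[[k]] <- a
  }
  names(arrays) <- nms
  list(arrays = arrays, metadata = metadata)
}

# Rebuild seq_params from a JSON-decoded list.
params_from_list <- function(l) {
  aux <- lapply(l$aux_gradients, function(g) unlist(g))
  seq_params(T_chirp = l$T_chirp, sweep = l$sweep, G_e = l$G_e, G_a = l$G_a,
             T_a = l$T_a, G_p = l$G_p, N_acq = l$N_acq, N_i = l$N_i,
             N_s = l$N_s, N_dummy = l$N_dummy, recovery = l$recovery,
             t_m = l$t_m, larmor = l$larmor, N_k = l$N_k,
             carrier_ppm = l$carrier_ppm, overhead = l$overhead,
             aux_gradients = aux)
}

#' Persist raw data and spectra
#'
#' Thin wrappers over the container format.  [save_raw()] stores the complex
#' transient array with the full sequence parameters and provenance;
#' [save_spectrum()] stores the magnitude matrix with its ppm axes.
#'
#' @param raw A `uf_raw` object.
#' @param spec A `uf_spectrum` object.
#' @param path File path.
#' @return The loaders rebuild the corresponding objects.
#' @export
save_raw <- function(raw, path) {
  stopifnot(inherits(raw, "uf_raw"))
  p <- raw$params
  p$aux_gradients <- lapply(p$aux_gradients, as.list)
  save_container(path, list(data = raw$data),
                 metadata = list(kind = "uf_raw", params = unclass(p),
                                 mode = raw$mode, averaged = raw$averaged,
                                 provenance = raw$provenance))
  invisible(path)
}

#' @rdname save_raw
#' @export
load_raw <- function(path) {
  ct <- load_container(path)
  if (!identical(ct$metadata$kind, "uf_raw"))
    stop("container does not hold raw data")
  params <- params_from_list(ct$metadata$params)
  structure(list(data = ct$arrays$data, params = params,
                 timing = derive_geometry(params),
                 mode = ct$metadata$mode,
                 averaged = isTRUE(ct$metadata$averaged),
                 provenance = ct$metadata$provenance), class = "uf_raw")
}

#' @rdname save_raw
#' @export
save_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "uf_spectrum"))
  save_container(path, list(matrix = spec$matrix, f1_axis = spec$f1_axis,
                            f2_axis = spec$f2_axis),
                 metadata = list(kind = "uf_spectrum",
                                 provenance = spec$provenance))
  invisible(path)
}

#' @rdname save_raw
#' @export
load_spectrum <- function(path) {
  ct <- load_container(path)
  if (!identical(ct$metadata$kind, "uf_spectrum"))
    stop("container does not hold a spectrum")
  structure(list(matrix = ct$arrays$matrix, f1_axis = ct$arrays$f1_axis,
                 f2_axis = ct$arrays$f2_axis,
                 provenance = ct$metadata$provenance),
            class = "uf_spectrum")
}

#' Export a spectrum as CSV
#'
#' Plain-text export: first row the f2 axis (ppm), first column the f1 axis,
#' remaining cells the magnitude matrix.
#'
#' @param spec A `uf_spectrum`.
#' @param path Output path.
#' @export
export_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "uf_spectrum"))
  m <- cbind(spec$f1_axis, spec$matrix)
  colnames(m) <- c("f1_ppm", format(spec$f2_axis, digits = 8))
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}
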