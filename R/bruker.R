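# Optional reader for vendor-format 2D raw directories (ser + acqus/acqu2s).
# Needed only to feed externally acquired benchmark data into the same
# processing chain; the core pipeline has no dependency on it.

# Parse a JCAMP-DX style parameter file: "##$KEY= value" lines.
read_acqus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hits <- grep("^##\\$", lines, value = TRUE)
  keys <- sub("^##\\$([^=]+)=.*$", "\\1", hits)
  vals <- trimws(sub("^##\\$[^=]+=", "", hits))
  out <- as.list(vals)
  names(out) <- keys
  num <- suppressWarnings(vapply(vals, as.numeric, 0))
  out[!is.na(num)] <- num[!is.na(num)]
  out
}

#' Read a vendor-layout 2D raw data directory
#'
#' Reads `ser` (32-bit integers, byte order from the `BYTORDA` parameter:
#' 0 little-endian, 1 big-endian) plus the `acqus`/`acqu2s` parameter files.
#' Each row holds `TD` values (interleaved real/imaginary pairs, so `TD/2`
#' complex points); `acqu2s` `TD` gives the row count.  Named parameters are
#' mapped onto sequence fields where they exist (`SFO1` to the Larmor
#' frequency).  The mapping is best effort: deposited-data layouts vary.
#'
#' @param path Directory containing `ser`, `acqus` and `acqu2s`.
#' @return List with the complex `data` matrix (`TD/2 x rows`), the parsed
#'   `acqus`/`acqu2s` lists and `larmor` (MHz) when present.
#' @export
read_bruker2d <- function(path) {
  for (f in c("ser", "acqus", "acqu2s"))
    if (!file.exists(file.path(path, f)))
      stop("missing file '", f, "' in ", path)
  acqus <- read_acqus(file.path(path, "acqus"))
  acqu2s <- read_acqus(file.path(path, "acqu2s"))
  td1 <- acqus$TD
  td2 <- acqu2s$TD
  if (is.null(td1) || is.null(td2) || !is.numeric(td1) || !is.numeric(td2))
    stop("TD missing from parameter files")
  endian <- if (identical(as.numeric(acqus$BYTORDA %||% 1), 0)) "little"
            else "big"
  n <- td1 * td2
  con <- file(file.path(path, "ser"), "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n + 1L, size = 4L, endian = endian)
  if (length(v) != n)
    stop("ser file size does not match TD parameters (",
         length(v), " values, expected ", n, ")")
  cx <- complex(real = v[c(TRUE, FALSE)], imaginary = v[c(FALSE, TRUE)])
  list(data = matrix(cx, nrow = td1 / 2, ncol = td2),
       acqus = acqus, acqu2s = acqu2s,
       larmor = if (is.numeric(acqus$SFO1)) acqus$SFO1 else NA_real_)
}
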