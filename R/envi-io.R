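#' Read an ENVI hyperspectral cube
#'
#' Parses the `key = value` ENVI header dialect and loads the companion
#' binary, returning the cube with in-memory axes (row, col, band) whatever
#' the stored interleave. Required header keys: `samples`, `lines`, `bands`,
#' `data type`, `interleave`, `wavelength`. Supported data types are 4
#' (float32), 5 (float64), 2 (int16) and 12 (uint16); interleaves BSQ
#' (band-sequential), BIL (band-interleaved-by-line) and BIP (by-pixel).
#'
#' @param header_path path to the `.hdr` file; the binary is the same path
#'   without the `.hdr` extension (or with `.raw` appended)
#' @return an [hsi_cube]
#' @export
read_envi_cube <- function(header_path) {
  if (!file.exists(header_path)) stop("read_envi_cube: header not found: ", header_path)
  hdr <- parse_envi_header(header_path)
  for (key in c("samples", "lines", "bands", "data type", "interleave"))
    if (is.null(hdr[[key]])) stop("read_envi_cube: header missing required key '", key, "'")
  if (is.null(hdr[["wavelength"]]))
    stop("read_envi_cube: header has no wavelength list")
  samples <- as.integer(hdr[["samples"]])  # cols
  lines <- as.integer(hdr[["lines"]])      # rows
  bands <- as.integer(hdr[["bands"]])
  wl <- as.numeric(strsplit(gsub("[{}]", "", hdr[["wavelength"]]), ",")[[1]])
  if (length(wl) != bands)
    stop("read_envi_cube: wavelength list length does not match bands")
  dtype <- as.integer(hdr[["data type"]])
  interleave <- tolower(hdr[["interleave"]])
  bin_path <- envi_binary_path(header_path)
  if (is.na(bin_path)) stop("read_envi_cube: binary companion file not found")

  n <- samples * lines * bands
  con <- file(bin_path, "rb")
  on.exit(close(con))
  raw_vals <- switch(as.character(dtype),
    "4" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "5" = readBin(con, "double", n = n, size = 8, endian = "little"),
    "2" = readBin(con, "integer", n = n, size = 2, signed = TRUE, endian = "little"),
    "12" = readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = "little"),
    stop("read_envi_cube: unsupported data type code ", dtype))
  if (length(raw_vals) != n)
    stop("read_envi_cube: binary truncated (expected ", n, " values, got ",
         length(raw_vals), ")")

  # ENVI stores the fastest axis first within each interleave scheme:
  #   BSQ: sample, line, band   BIL: sample, band, line   BIP: band, sample, line
  data <- switch(interleave,
    bsq = aperm(array(raw_vals, c(samples, lines, bands)), c(2, 1, 3)),
    bil = aperm(array(raw_vals, c(samples, bands, lines)), c(3, 1, 2)),
    bip = aperm(array(raw_vals, c(bands, samples, lines)), c(3, 2, 1)),
    stop("read_envi_cube: unsupported interleave '", interleave, "'"))
  calibrated <- identical(hdr[["strawbruise calibrated"]], "1")
  hsi_cube(data, wl, calibrated = calibrated, interleave = interleave)
}

#' Write an ENVI hyperspectral cube
#'
#' Emits a `.hdr` text header (wavelengths listed to two decimals) and a
#' little-endian float32 binary next to it. Round-trips through
#' [read_envi_cube] up to float32 precision.
#'
#' @param cube an [hsi_cube] with finite data
#' @param header_path output `.hdr` path; the binary drops the extension
#' @return `header_path`, invisibly
#' @export
write_envi_cube <- function(cube, header_path) {
  stopifnot(inherits(cube, "hsi_cube"))
  if (!all(is.finite(cube$data)))
    stop("write_envi_cube: cube contains non-finite values")
  d <- dim(cube$data)
  rows <- d[1]; cols <- d[2]; bands <- d[3]
  interleave <- cube$interleave
  hdr_lines <- c(
    "ENVI",
    "description = {strawbruise hyperspectral cube}",
    sprintf("samples = %d", cols),
    sprintf("lines = %d", rows),
    sprintf("bands = %d", bands),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("strawbruise calibrated = %d", as.integer(cube$calibrated)),
    sprintf("wavelength = {%s}",
            paste(sprintf("%.2f", cube$wavelengths), collapse = ", "))
  )
  writeLines(hdr_lines, header_path)
  vals <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),
    bil = as.vector(aperm(cube$data, c(2, 3, 1))),
    bip = as.vector(aperm(cube$data, c(3, 2, 1))))
  con <- file(sub("\\.hdr$", "", header_path), "wb")
  on.exit(close(con))
  writeBin(as.numeric(vals), con, size = 4, endian = "little")
  invisible(header_path)
}

parse_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  # Collapse newlines inside {...} blocks so each key = value is one line.
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "{") depth <- depth + 1L
    else if (chars[i] == "}") depth <- depth - 1L
    else if (chars[i] == "\n" && depth > 0L) chars[i] <- " "
  }
  out <- list()
  for (line in strsplit(paste(chars, collapse = ""), "\n")[[1]]) {
    if (!grepl("=", line, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", line))
    val <- trimws(sub("^[^=]*=", "", line))
    out[[tolower(key)]] <- val
  }
  out
}

envi_binary_path <- function(header_path) {
  cand <- c(sub("\\.hdr$", "", header_path),
            paste0(sub("\\.hdr$", "", header_path), ".raw"),
            paste0(sub("\\.hdr$", "", header_path), ".dat"))
  hit <- cand[file.exists(cand)]
  if (length(hit) == 0L) NA_character_ else hit[1]
}
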