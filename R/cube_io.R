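# ENVI-style cube input/output and white/dark reflectance calibration.
#
# ENVI stores a text header (key = value pairs, lists in {}) next to a raw
# binary file. "samples" are image columns, "lines" are rows. Only the
# fields the pipeline needs are interpreted; unknown keys are ignored.

# ENVI data type codes -> R read/write descriptors
.envi_types <- list(
  `1`  = list(what = "integer", size = 1, signed = FALSE),
  `2`  = list(what = "integer", size = 2, signed = TRUE),
  `4`  = list(what = "numeric", size = 4, signed = TRUE),
  `5`  = list(what = "numeric", size = 8, signed = TRUE),
  `12` = list(what = "integer", size = 2, signed = FALSE)
)

.parse_envi_header <- function(header_path) {
  txt <- paste(readLines(header_path, warn = FALSE), collapse = "\n")
  if (!grepl("ENVI", txt, fixed = TRUE))
    stop("not an ENVI header: ", header_path)
  # fold {...} blocks onto single logical entries
  get_scalar <- function(key) {
    m <- regmatches(txt, regexec(
      paste0("(?mi)^\\s*", key, "\\s*=\\s*([^\\{\\n]+)$"), txt, perl = TRUE))[[1]]
    if (length(m) < 2) return(NA_character_)
    trimws(m[2])
  }
  get_list <- function(key) {
    m <- regmatches(txt, regexec(
      paste0("(?si)", key, "\\s*=\\s*\\{([^\\}]*)\\}"), txt, perl = TRUE))[[1]]
    if (length(m) < 2) return(NULL)
    vals <- strsplit(m[2], "[,\n]")[[1]]
    vals <- trimws(vals)
    as.numeric(vals[nzchar(vals)])
  }
  list(
    samples = as.integer(get_scalar("samples")),
    lines = as.integer(get_scalar("lines")),
    bands = as.integer(get_scalar("bands")),
    data_type = as.integer(get_scalar("data type")),
    interleave = tolower(get_scalar("interleave")),
    byte_order = {
      b <- get_scalar("byte order"); if (is.na(b)) 0L else as.integer(b)
    },
    header_offset = {
      h <- get_scalar("header offset"); if (is.na(h)) 0L else as.integer(h)
    },
    wavelength = get_list("wavelength")
  )
}

#' Read an ENVI cube
#'
#' Reads an ENVI header + raw binary pair into a [Hypercube-class] in
#' canonical rows x cols x bands order, whatever the stored interleave
#' (`bsq`, `bil` or `bip`).
#'
#' @param header_path path to the text header (`.hdr`).
#' @param data_path path to the binary file; by default the header path with
#'   its extension dropped, or with `.dat` appended, whichever exists.
#' @return A [Hypercube-class].
#' @seealso [writeENVI()]
#' @export
readENVI <- function(header_path, data_path = NULL) {
  h <- .parse_envi_header(header_path)
  if (is.na(h$samples) || is.na(h$lines) || is.na(h$bands))
    stop("ENVI header must declare samples, lines and bands")
  if (is.null(h$wavelength))
    stop("ENVI header has no wavelength list")
  if (length(h$wavelength) != h$bands)
    stop(sprintf("header declares %d bands but lists %d wavelengths",
                 h$bands, length(h$wavelength)))
  if (!h$interleave %in% c("bsq", "bil", "bip"))
    stop("unsupported interleave: ", h$interleave)
  tp <- .envi_types[[as.character(h$data_type)]]
  if (is.null(tp))
    stop("unsupported ENVI data type code: ", h$data_type)
  if (is.null(data_path)) {
    base <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
    cand <- c(base, paste0(base, ".dat"), paste0(base, ".raw"),
              paste0(base, ".img"))
    data_path <- cand[file.exists(cand)][1]
    if (is.na(data_path))
      stop("cannot locate the binary data file for ", header_path)
  }
  n <- h$samples * h$lines * h$bands
  endian <- if (h$byte_order == 0L) "little" else "big"
  con <- file(data_path, "rb")
  on.exit(close(con))
  if (h$header_offset > 0) readBin(con, "raw", n = h$header_offset)
  vec <- readBin(con, tp$what, n = n, size = tp$size,
                 signed = tp$signed, endian = endian)
  if (length(vec) != n)
    stop("binary file shorter than declared dimensions")
  vec <- as.numeric(vec)
  rows <- h$lines; cols <- h$samples; bands <- h$bands
  arr <- switch(h$interleave,
    # bsq: sample fastest, then line, then band
    bsq = aperm(array(vec, dim = c(cols, rows, bands)), c(2, 1, 3)),
    # bil: sample fastest, then band, then line
    bil = aperm(array(vec, dim = c(cols, bands, rows)), c(3, 1, 2)),
    # bip: band fastest, then sample, then line
    bip = aperm(array(vec, dim = c(bands, cols, rows)), c(3, 2, 1))
  )
  Hypercube(arr, h$wavelength)
}

#' Write an ENVI cube
#'
#' Writes a [Hypercube-class] as an ENVI header (`<base>.hdr`) plus raw
#' binary (`<base>.dat`), 64-bit little-endian floats.
#'
#' @param cube a [Hypercube-class].
#' @param base_path path without extension; `.hdr` and `.dat` are appended.
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @return invisibly, a character vector `c(header, data)` of the paths
#'   written.
#' @examples
#' cube <- Hypercube(array(runif(24), c(2, 4, 3)), c(500, 600, 700))
#' paths <- writeENVI(cube, file.path(tempdir(), "demo"))
#' cube2 <- readENVI(paths[1])
#' all.equal(cubeData(cube), cubeData(cube2))
#' @export
writeENVI <- function(cube, base_path, interleave = c("bsq", "bil", "bip")) {
  stopifnot(is(cube, "Hypercube"))
  interleave <- match.arg(interleave)
  d <- dim(cube@data)
  rows <- d[1]; cols <- d[2]; bands <- d[3]
  vec <- switch(interleave,
    bsq = as.vector(aperm(cube@data, c(2, 1, 3))),
    bil = as.vector(aperm(cube@data, c(2, 3, 1))),
    bip = as.vector(aperm(cube@data, c(3, 2, 1)))
  )
  hdr_path <- paste0(base_path, ".hdr")
  dat_path <- paste0(base_path, ".dat")
  hdr <- c(
    "ENVI",
    "description = {starchfusion hypercube}",
    sprintf("samples = %d", cols),
    sprintf("lines = %d", rows),
    sprintf("bands = %d", bands),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {",
           paste(sprintf("%.6f", cube@wavelengths), collapse = ", "), "}")
  )
  writeLines(hdr, hdr_path)
  con <- file(dat_path, "wb")
  on.exit(close(con))
  writeBin(vec, con, size = 8, endian = "little")
  invisible(c(hdr_path, dat_path))
}

#' Read or write a single-file cube container
#'
#' RDS-based single-file container (list with elements `data` and
#' `wavelengths`) used for fixture convenience; ENVI remains the
#' interchange format.
#'
#' @param path file path.
#' @return `readCubeRDS` returns a [Hypercube-class]; `writeCubeRDS`
#'   invisibly returns the path.
#' @export
readCubeRDS <- function(path) {
  x <- readRDS(path)
  if (!is.list(x) || is.null(x$data) || is.null(x$wavelengths))
    stop("not a cube container: ", path)
  Hypercube(x$data, x$wavelengths)
}

#' @rdname readCubeRDS
#' @param cube a [Hypercube-class].
#' @export
writeCubeRDS <- function(cube, path) {
  stopifnot(is(cube, "Hypercube"))
  saveRDS(list(data = cube@data, wavelengths = cube@wavelengths), path)
  invisible(path)
}

#' White/dark reflectance calibration
#'
#' Converts raw intensity to relative reflectance with the standard
#' two-point correction R = (I_raw - I_dark) / (I_white - I_dark). Pixels
#' where the white and dark references coincide (dead reference pixels) are
#' set to 0 and counted in the result's `metadata$nInvalid`.
#'
#' @param raw,white,dark [Hypercube-class] objects of identical shape.
#' @return A calibrated [Hypercube-class]; `metadata$nInvalid` holds the
#'   number of zero-denominator entries.
#' @export
calibrateReflectance <- function(raw, white, dark) {
  stopifnot(is(raw, "Hypercube"), is(white, "Hypercube"), is(dark, "Hypercube"))
  if (!identical(dim(raw@data), dim(white@data)) ||
      !identical(dim(raw@data), dim(dark@data)))
    stop("raw, white and dark cubes must have identical dimensions")
  denom <- white@data - dark@data
  bad <- denom == 0
  denom[bad] <- 1
  refl <- (raw@data - dark@data) / denom
  refl[bad] <- 0
  n_bad <- sum(bad)
  if (n_bad > 0)
    message(n_bad, " pixel/band entries had white == dark; set to 0")
  Hypercube(refl, raw@wavelengths, metadata = list(nInvalid = n_bad))
}
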