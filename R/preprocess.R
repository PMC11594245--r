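#' Construct a hyperspectral cube
#'
#' @param values numeric H x W x B array of intensities (a single spectrum
#'   may be passed as a 1 x 1 x B array).
#' @param wavelengths numeric length-B band centres in nanometres, strictly
#'   increasing.
#' @return a [HyperCube-class]
#' @examples
#' cube <- hyperCube(array(runif(4 * 4 * 8), c(4, 4, 8)), seq(900, 1700, length.out = 8))
#' @export
hyperCube <- function(values, wavelengths) {
  new("HyperCube", values = values, wavelengths = as.numeric(wavelengths))
}

#' Dark/white reference calibration of a raw cube
#'
#' Min-max rescales raw sensor counts between a dark-current reference and a
#' white (near-perfect reflector) reference, per pixel and band:
#' reflectance = (raw - dark) / (white - dark). The result is dimensionless
#' reflectance, typically in \[0, ~1.2\]; the effective-pixel mask is left
#' unset.
#'
#' @param raw a [HyperCube-class] of raw counts.
#' @param dark,white [HyperCube-class] reference cubes of identical shape
#'   (dark current and white reference).
#' @return a [CalibratedCube-class] with empty mask
#' @examples
#' wl <- c(1000, 1100)
#' raw <- hyperCube(array(0.6, c(1, 1, 2)), wl)
#' dark <- hyperCube(array(0.1, c(1, 1, 2)), wl)
#' white <- hyperCube(array(1.1, c(1, 1, 2)), wl)
#' cubeValues(calibrateCube(raw, dark, white))  # 0.5 everywhere
#' @export
calibrateCube <- function(raw, dark, white) {
  stopifnot(is(raw, "HyperCube"), is(dark, "HyperCube"), is(white, "HyperCube"))
  if (!identical(dim(raw@values), dim(dark@values)) ||
      !identical(dim(raw@values), dim(white@values)))
    stop("input error: raw, dark and white cubes must have identical shape")
  denom <- white@values - dark@values
  bad <- which(denom <= 0)
  if (length(bad) > 0L) {
    idx <- arrayInd(bad[1L], dim(denom))
    stop(sprintf(paste0("calibration-reference error: white - dark is <= 0 at ",
                        "pixel (%d, %d), band %d (%.1f nm)%s"),
                 idx[1], idx[2], idx[3], raw@wavelengths[idx[3]],
                 if (length(bad) > 1L)
                   sprintf(" and %d further elements", length(bad) - 1L) else ""))
  }
  new("CalibratedCube",
      values = (raw@values - dark@values) / denom,
      wavelengths = raw@wavelengths)
}

#' Select the retained spectral bands
#'
#' Returns the indices of all bands whose centre wavelength lies in the
#' closed interval \[lo, hi\]. NIR cubes carry low signal-to-noise bands at
#' both spectral extremes; the default retains 1000-1600 nm.
#'
#' @param wavelengths numeric band centres (nm), strictly increasing.
#' @param lo,hi interval endpoints in nm (inclusive).
#' @return sorted contiguous integer index vector
#' @examples
#' selectBands(seq(900, 1700, length.out = 256))  # 192 retained bands
#' @export
selectBands <- function(wavelengths, lo = 1000, hi = 1600) {
  stopifnot(lo < hi)
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  idx <- which(wavelengths >= lo & wavelengths <= hi)
  if (length(idx) == 0L)
    stop(sprintf("configuration error: no bands fall inside [%g, %g] nm", lo, hi))
  idx
}

#' Effective-pixel mask
#'
#' A pixel is effective (foreground signal rather than background, shadow,
#' occlusion or a dead sensor element) when its mean calibrated reflectance
#' over the retained bands is strictly greater than `threshold`. The mean is
#' taken over the retained bands so that masking matches the spectra
#' actually used downstream.
#'
#' @param cube a [CalibratedCube-class].
#' @param bandIdx integer indices of the retained bands (see [selectBands()]).
#' @param threshold reflectance cutoff; the default 0.1 separates foreground
#'   from low-reflectance pixels.
#' @return logical H x W matrix (TRUE = effective)
#' @export
effectiveMask <- function(cube, bandIdx, threshold = 0.1) {
  stopifnot(is(cube, "CalibratedCube"), length(bandIdx) >= 1L)
  sub <- cube@values[, , bandIdx, drop = FALSE]
  m <- apply(sub, c(1, 2), mean)
  mask <- m > threshold
  dim(mask) <- dim(cube@values)[1:2]
  mask
}

#' Extract one instance's effective-pixel spectra from a masked cube
#'
#' Collects the spectrum of every effective pixel, restricted to the
#' retained bands, into one N x D matrix; pixel coordinates are kept so
#' per-pixel predictions can be painted back onto the image plane. All
#' effective spectra are used rather than the instance average, which gives
#' the classifier a much larger training pool per physical sample.
#'
#' @param cube a [CalibratedCube-class] with its mask set (see
#'   [effectiveMask()] and [setMask<-]).
#' @param bandIdx integer retained-band indices.
#' @param label integer class index (NA for unlabeled).
#' @param id character instance identifier.
#' @return a [SpectraInstance-class]
#' @export
cubeToInstance <- function(cube, bandIdx, label = NA_integer_, id = "instance") {
  stopifnot(is(cube, "CalibratedCube"))
  if (!hasMask(cube))
    stop("cube has no effective-pixel mask; call effectiveMask() first")
  keep <- which(cube@mask, arr.ind = TRUE)
  if (nrow(keep) == 0L)
    stop(sprintf("degenerate-instance error: instance '%s' has zero effective pixels", id))
  d <- dim(cube@values)
  # flatten to (H*W) x B then index rows by pixel
  flat <- matrix(cube@values, nrow = d[1] * d[2], ncol = d[3])
  rows <- (keep[, 2] - 1L) * d[1] + keep[, 1]
  new("SpectraInstance",
      instanceId = as.character(id),
      label = as.integer(label),
      spectra = flat[rows, bandIdx, drop = FALSE],
      pixelCoords = matrix(as.integer(keep), ncol = 2L,
                           dimnames = list(NULL, c("row", "col"))),
      bandWavelengths = cube@wavelengths[bandIdx])
}

#' Preprocess an instance manifest into spectra instances
#'
#' Runs the full preprocessing chain for every row of a manifest: load cube,
#' calibrate against the shared dark/white references (skipped when cubes
#' are already reflectance), crop bands, mask effective pixels, and extract
#' the instance spectra.
#'
#' @param manifest data.frame with columns `instance_id`, `label`,
#'   `cube_path` (or the result of [utils::read.csv()] on such a file).
#' @param dark,white optional [HyperCube-class] references; when `NULL` the
#'   cubes are treated as already calibrated reflectance.
#' @param lo,hi retained wavelength interval (nm).
#' @param threshold effective-pixel reflectance cutoff.
#' @return list with elements `instances` (list of [SpectraInstance-class])
#'   and `report` (band count, retained interval, per-instance effective
#'   pixel counts)
#' @export
preprocessManifest <- function(manifest, dark = NULL, white = NULL,
                               lo = 1000, hi = 1600, threshold = 0.1) {
  need <- c("instance_id", "label", "cube_path")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns instance_id, label, cube_path")
  instances <- vector("list", nrow(manifest))
  counts <- integer(nrow(manifest))
  bandIdx <- NULL
  for (i in seq_len(nrow(manifest))) {
    cube <- loadCube(manifest$cube_path[i])
    if (!is.null(dark) && !is.null(white)) {
      cube <- calibrateCube(cube, dark, white)
    } else if (!is(cube, "CalibratedCube")) {
      cube <- new("CalibratedCube", values = cube@values,
                  wavelengths = cube@wavelengths)
    }
    if (is.null(bandIdx)) bandIdx <- selectBands(cube@wavelengths, lo, hi)
    setMask(cube) <- effectiveMask(cube, bandIdx, threshold)
    instances[[i]] <- cubeToInstance(cube, bandIdx,
                                     label = manifest$label[i],
                                     id = manifest$instance_id[i])
    counts[i] <- nrow(instances[[i]]@spectra)
  }
  list(instances = instances,
       report = list(bandCount = length(bandIdx),
                     retainedNm = c(lo, hi), threshold = threshold,
                     effectivePixels = stats::setNames(counts,
                                                       manifest$instance_id)))
}

# ---- cube I/O ----------------------------------------------------------

#' Read / write hyperspectral cubes
#'
#' Two on-disk forms are supported. ENVI: a text `.hdr` header (fields
#' `samples`, `lines`, `bands`, `data type`, `interleave`, `byte order`,
#' `wavelength = {...}`) next to a raw binary file; BSQ/BIL/BIP interleaves
#' and IEEE float32/float64 types are handled. Array container: a single
#' `.rds` file serialising the [HyperCube-class] object. `loadCube()`
#' dispatches on the file extension.
#'
#' @param path file path; for ENVI either the `.hdr` or the data file.
#' @param cube a [HyperCube-class] (or [CalibratedCube-class]) to write.
#' @return `readENVI()`/`loadCube()` return a [HyperCube-class];
#'   writers return the data path invisibly.
#' @name cube-io
NULL

#' @rdname cube-io
#' @export
loadCube <- function(path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    if (!file.exists(path)) stop(sprintf("format error: cannot read '%s'", path))
    obj <- readRDS(path)
    if (!is(obj, "HyperCube"))
      stop(sprintf("format error: '%s' does not contain a HyperCube", path))
    return(obj)
  }
  readENVI(path)
}

#' @rdname cube-io
#' @export
writeCube <- function(cube, path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(cube, path)
    return(invisible(path))
  }
  writeENVI(cube, path)
}

enviHeaderPath <- function(path) {
  if (grepl("\\.hdr$", path, ignore.case = TRUE)) path else paste0(path, ".hdr")
}

enviDataPath <- function(path) {
  sub("\\.hdr$", "", path, ignore.case = TRUE)
}

#' @rdname cube-io
#' @export
readENVI <- function(path) {
  hdr <- enviHeaderPath(path)
  dat <- enviDataPath(path)
  if (!file.exists(hdr))
    stop(sprintf("format error: missing ENVI header '%s'", hdr))
  if (!file.exists(dat))
    stop(sprintf("format error: missing ENVI data file '%s'", dat))
  txt <- readLines(hdr, warn = FALSE)
  # join brace-spanning values onto single logical lines
  joined <- paste(txt, collapse = "\n")
  fields <- list()
  pat <- "(?s)([a-zA-Z ]+?)\\s*=\\s*(\\{.*?\\}|[^\n]*)"
  m <- gregexpr(pat, joined, perl = TRUE)[[1]]
  if (m[1] != -1) {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (k in seq_along(starts)) {
      piece <- substr(joined, starts[k], starts[k] + lens[k] - 1L)
      key <- trimws(tolower(sub("=.*", "", piece)))
      val <- trimws(sub("^[^=]*=", "", piece))
      fields[[key]] <- val
    }
  }
  need <- c("samples", "lines", "bands", "data type")
  if (!all(need %in% names(fields)))
    stop(sprintf("format error: ENVI header '%s' lacks %s", hdr,
                 paste(setdiff(need, names(fields)), collapse = ", ")))
  samples <- as.integer(fields[["samples"]])   # W
  lines <- as.integer(fields[["lines"]])       # H
  bands <- as.integer(fields[["bands"]])
  dtype <- as.integer(fields[["data type"]])
  interleave <- tolower(trimws(fields[["interleave"]] %||% "bsq"))
  byteOrder <- as.integer(fields[["byte order"]] %||% "0")
  if (is.null(fields[["wavelength"]]))
    stop(sprintf("format error: ENVI header '%s' has no wavelength block", hdr))
  wlTxt <- gsub("[{}\n]", " ", fields[["wavelength"]])
  wl <- as.numeric(strsplit(trimws(wlTxt), "\\s*,\\s*")[[1]])
  if (length(wl) != bands)
    stop(sprintf("format error: '%s' lists %d wavelengths for %d bands",
                 hdr, length(wl), bands))
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop(sprintf("format error: unsupported ENVI data type %d", dtype)))
  n <- samples * lines * bands
  con <- file(dat, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = size,
               endian = if (byteOrder == 1L) "big" else "little")
  if (length(v) != n)
    stop(sprintf("format error: '%s' holds %d values, expected %d", dat,
                 length(v), n))
  vals <- switch(interleave,
    # file order fastest-to-slowest: bsq = sample,line,band; bil =
    # sample,band,line; bip = band,sample,line
    bsq = aperm(array(v, c(samples, lines, bands)), c(2, 1, 3)),
    bil = aperm(array(v, c(samples, bands, lines)), c(3, 1, 2)),
    bip = aperm(array(v, c(bands, samples, lines)), c(3, 2, 1)),
    stop(sprintf("format error: unsupported interleave '%s'", interleave)))
  hyperCube(vals, wl)
}

#' @rdname cube-io
#' @export
writeENVI <- function(cube, path) {
  stopifnot(is(cube, "HyperCube"))
  dat <- enviDataPath(path)
  hdr <- enviHeaderPath(path)
  d <- dim(cube@values)
  header <- c(
    "ENVI",
    "description = {ProtoDS reflectance cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    sprintf("wavelength = {%s}",
            paste(sprintf("%.17g", cube@wavelengths), collapse = ", ")))
  writeLines(header, hdr)
  con <- file(dat, "wb")
  on.exit(close(con))
  # bsq: sample fastest, then line, then band
  writeBin(as.vector(aperm(cube@values, c(2, 1, 3))), con, size = 8L,
           endian = "little")
  invisible(dat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
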