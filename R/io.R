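#' Read a hyperspectral cube
#'
#' Reads a [spectral_image()] from one of three inspectable on-disk formats:
#'
#' * `"hdf5"` (canonical): datasets `/cube` (H x W x B), `/axis`
#'   (B, cm^-1), optional `/mask` (H x W, 0/1), attributes `pixel_size_um`,
#'   `sample_id`, `group` on `/cube`.
#' * `"envi"`: standard ENVI header/raw pair (`.hdr` plus raw BSQ binary,
#'   8-byte IEEE floats); `wavelength` holds the axis in cm^-1. Masked
#'   pixels are stored as NaN.
#' * `"csv"`: long format with comment-prefixed metadata header and columns
#'   `row`, `col`, `wavenumber`, `absorbance`, `mask` (0-based pixel
#'   coordinates). Intended for tiny fixtures.
#'
#' Files stored with a descending wavenumber axis (the instrument
#' convention) are normalized on read: the axis is reversed together with
#' the cube's band order, so the in-memory axis is always ascending.
#'
#' @param path Path to the file (for ENVI, the `.hdr` or the raw file).
#' @param format One of `"hdf5"`, `"envi"`, `"csv"`. Guessed from the file
#'   extension when missing (`.h5`/`.hdf5`, `.hdr`/`.raw`, `.csv`).
#' @return A [spectral_image()].
#' @seealso [write_cube()]
#' @export
read_cube <- function(path, format = NULL) {
  format <- guess_format(path, format)
  img <- switch(format,
    hdf5 = read_cube_hdf5(path),
    envi = read_cube_envi(path),
    csv  = read_cube_csv(path))
  # normalize: ascending axis
  ax <- img$axis
  if (ax[1] > ax[length(ax)]) {
    img$axis <- rev(ax)
    img$cube <- img$cube[, , rev(seq_along(ax)), drop = FALSE]
  }
  spectral_image(img$cube, img$axis, pixel_size = img$pixel_size,
                 mask = img$mask, sample_id = img$sample_id, group = img$group)
}

#' Write a hyperspectral cube
#'
#' Writes a [spectral_image()] so that `read_cube(write_cube(x, p), p)`
#' reproduces cube, axis, mask and pixel size exactly (values are stored as
#' 8-byte floats in every format). See [read_cube()] for the layouts.
#'
#' @param image A [spectral_image()].
#' @param path Output path.
#' @param format One of `"hdf5"`, `"envi"`, `"csv"`; guessed from the
#'   extension when missing.
#' @return `path`, invisibly.
#' @export
write_cube <- function(image, path, format = NULL) {
  stopifnot(inherits(image, "spectral_image"))
  validate_spectral_image(image)
  format <- guess_format(path, format)
  switch(format,
    hdf5 = write_cube_hdf5(image, path),
    envi = write_cube_envi(image, path),
    csv  = write_cube_csv(image, path))
  invisible(path)
}

guess_format <- function(path, format) {
  if (!is.null(format)) {
    return(match.arg(format, c("hdf5", "envi", "csv")))
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    h5 = , hdf5 = "hdf5",
    hdr = , raw = , img = "envi",
    csv = "csv",
    stop(sprintf("cannot guess cube format from extension '%s'", ext),
         call. = FALSE))
}

# ---- HDF5 ------------------------------------------------------------------

read_cube_hdf5 <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  cnt <- rhdf5::h5ls(path)$name
  if (!("cube" %in% cnt)) stop("HDF5 cube file lacks dataset 'cube'", call. = FALSE)
  if (!("axis" %in% cnt)) stop("HDF5 cube file lacks dataset 'axis'", call. = FALSE)
  cube <- rhdf5::h5read(path, "cube")
  axis <- as.numeric(rhdf5::h5read(path, "axis"))
  if (length(dim(cube)) != 3) stop("dataset 'cube' is not 3-dimensional", call. = FALSE)
  if (dim(cube)[3] != length(axis)) {
    stop(sprintf("axis length (%d) does not match cube band count (%d)",
                 length(axis), dim(cube)[3]), call. = FALSE)
  }
  mask <- if ("mask" %in% cnt) rhdf5::h5read(path, "mask") != 0 else NULL
  at <- rhdf5::h5readAttributes(path, "cube")
  list(cube = cube, axis = axis, mask = mask,
       pixel_size = if (!is.null(at$pixel_size_um)) as.numeric(at$pixel_size_um) else NA_real_,
       sample_id = if (!is.null(at$sample_id)) as.character(at$sample_id) else "sample",
       group = if (!is.null(at$group)) as.character(at$group) else "unknown")
}

write_cube_hdf5 <- function(image, path) {
  if (file.exists(path)) unlink(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(path)
  rhdf5::h5write(image$cube, path, "cube")
  rhdf5::h5write(as.numeric(image$axis), path, "axis")
  rhdf5::h5write(matrix(as.integer(image$mask), nrow(image$mask)), path, "mask")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "cube")
  rhdf5::h5writeAttribute(image$pixel_size, did, "pixel_size_um")
  rhdf5::h5writeAttribute(image$sample_id, did, "sample_id")
  rhdf5::h5writeAttribute(image$group, did, "group")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  path
}

# ---- ENVI ------------------------------------------------------------------

envi_paths <- function(path) {
  if (tolower(tools::file_ext(path)) == "hdr") {
    hdr <- path
    raw <- sub("\\.hdr$", ".raw", path, ignore.case = TRUE)
  } else {
    raw <- path
    hdr <- paste0(tools::file_path_sans_ext(path), ".hdr")
  }
  list(hdr = hdr, raw = raw)
}

read_cube_envi <- function(path) {
  p <- envi_paths(path)
  if (!file.exists(p$hdr)) stop(sprintf("ENVI header not found: %s", p$hdr), call. = FALSE)
  if (!file.exists(p$raw)) stop(sprintf("ENVI raw file not found: %s", p$raw), call. = FALSE)
  hdr <- parse_envi_header(readLines(p$hdr, warn = FALSE))
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) {
    stop(sprintf("ENVI header missing field(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  W <- as.integer(hdr$samples); H <- as.integer(hdr$lines); B <- as.integer(hdr$bands)
  if (tolower(hdr$interleave) != "bsq") {
    stop(sprintf("unsupported ENVI interleave '%s' (only bsq)", hdr$interleave),
         call. = FALSE)
  }
  if (as.integer(hdr$`data type`) != 5) {
    stop(sprintf("unsupported ENVI data type %s (only 5 = float64)", hdr$`data type`),
         call. = FALSE)
  }
  if (is.null(hdr$wavelength)) stop("ENVI header missing 'wavelength'", call. = FALSE)
  axis <- as.numeric(strsplit(gsub("[{}\n]", "", hdr$wavelength), ",")[[1]])
  if (length(axis) != B) {
    stop(sprintf("ENVI wavelength list length (%d) does not match bands (%d)",
                 length(axis), B), call. = FALSE)
  }
  endian <- if (!is.null(hdr$`byte order`) && as.integer(hdr$`byte order`) == 1)
    "big" else "little"
  v <- readBin(p$raw, "double", n = H * W * B, size = 8, endian = endian)
  if (length(v) != H * W * B) stop("ENVI raw file shorter than header implies", call. = FALSE)
  # BSQ order: sample fastest, then line, then band
  cube <- aperm(array(v, c(W, H, B)), c(2, 1, 3))
  mask <- apply(is.finite(cube), c(1, 2), all)
  list(cube = cube, axis = axis, mask = mask,
       pixel_size = if (!is.null(hdr$`pixel size um`)) as.numeric(hdr$`pixel size um`) else NA_real_,
       sample_id = if (!is.null(hdr$`sample id`)) hdr$`sample id` else "sample",
       group = if (!is.null(hdr$group)) hdr$group else "unknown")
}

parse_envi_header <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  if (!grepl("^ENVI", txt)) stop("not an ENVI header (missing ENVI magic)", call. = FALSE)
  # join brace-delimited multi-line values
  txt <- sub("^ENVI\n?", "", txt)
  out <- list()
  pat <- gregexpr("([a-zA-Z ][a-zA-Z0-9 ]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)", txt)[[1]]
  starts <- pat; lens <- attr(pat, "match.length")
  for (i in seq_along(starts)) {
    if (starts[i] < 0) next
    kv <- substr(txt, starts[i], starts[i] + lens[i] - 1)
    eq <- regexpr("=", kv)
    key <- trimws(substr(kv, 1, eq - 1))
    val <- trimws(substr(kv, eq + 1, nchar(kv)))
    out[[tolower(key)]] <- val
  }
  out
}

write_cube_envi <- function(image, path) {
  p <- envi_paths(path)
  d <- dim(image$cube)
  cube <- image$cube
  # persist mask as NaN spectra
  if (!all(image$mask)) {
    nanpix <- which(!image$mask)
    flat <- matrix(cube, d[1] * d[2], d[3])
    flat[nanpix, ] <- NaN
    cube <- array(flat, d)
  }
  hdr <- c(
    "ENVI",
    "description = {spectrofibro hyperspectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Wavenumber",
    sprintf("wavelength = {%s}", paste(format(as.numeric(image$axis), digits = 15),
                                       collapse = ", ")),
    sprintf("pixel size um = %s", format(image$pixel_size, digits = 15)),
    sprintf("sample id = %s", image$sample_id),
    sprintf("group = %s", image$group))
  writeLines(hdr, p$hdr)
  con <- file(p$raw, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(aperm(cube, c(2, 1, 3))), con, size = 8, endian = "little")
  path
}

# ---- CSV -------------------------------------------------------------------

read_cube_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    sep <- regexpr(":", kv)
    if (sep > 0) meta[[trimws(substr(kv, 1, sep - 1))]] <- trimws(substr(kv, sep + 1, nchar(kv)))
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  need <- c("row", "col", "wavenumber", "absorbance")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("CSV cube missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  axis <- sort(unique(df$wavenumber))
  H <- max(df$row) + 1L; W <- max(df$col) + 1L; B <- length(axis)
  if (nrow(df) != H * W * B) {
    stop("CSV cube is not a complete row x col x wavenumber grid", call. = FALSE)
  }
  cube <- array(NA_real_, c(H, W, B))
  bi <- match(df$wavenumber, axis)
  cube[cbind(df$row + 1L, df$col + 1L, bi)] <- df$absorbance
  mask <- matrix(TRUE, H, W)
  if ("mask" %in% names(df)) {
    first <- !duplicated(df[, c("row", "col")])
    mask[cbind(df$row[first] + 1L, df$col[first] + 1L)] <- df$mask[first] != 0
  }
  list(cube = cube, axis = axis, mask = mask,
       pixel_size = if (!is.null(meta$pixel_size_um)) as.numeric(meta$pixel_size_um) else NA_real_,
       sample_id = if (!is.null(meta$sample_id)) meta$sample_id else "sample",
       group = if (!is.null(meta$group)) meta$group else "unknown")
}

write_cube_csv <- function(image, path) {
  d <- dim(image$cube)
  grid <- expand.grid(band = seq_len(d[3]), col = seq_len(d[2]), row = seq_len(d[1]))
  df <- data.frame(
    row = grid$row - 1L,
    col = grid$col - 1L,
    wavenumber = as.numeric(image$axis)[grid$band],
    absorbance = image$cube[cbind(grid$row, grid$col, grid$band)],
    mask = as.integer(image$mask[cbind(grid$row, grid$col)]))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(sprintf("# pixel_size_um: %s", format(image$pixel_size, digits = 15)),
               sprintf("# sample_id: %s", image$sample_id),
               sprintf("# group: %s", image$group)), con)
  utils::write.csv(df, con, row.names = FALSE)
  path
}

# ---- RGB histology ---------------------------------------------------------

#' Read / write an RGB histology image
#'
#' Thin PNG wrappers for Masson's-trichrome section scans. Pixels are 8-bit
#' per channel (H x W x 3 integer array in 0..255); `scale` is the physical
#' size of a pixel in micrometres, carried as an attribute.
#'
#' @param path PNG file path.
#' @param scale Micrometres per pixel (attribute `scale_um`; defaults to
#'   `NA` on read when unknown).
#' @return `read_rgb()`: an `rgb_image` (H x W x 3 integer array, 0..255,
#'   attribute `scale_um`). `write_rgb()`: `path`, invisibly.
#' @export
read_rgb <- function(path, scale = NA_real_) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  a <- a[, , 1:3, drop = FALSE]
  rgb_image(round(a * 255), scale = scale)
}

#' @rdname read_rgb
#' @param image An `rgb_image` (or H x W x 3 array in 0..255).
#' @export
write_rgb <- function(image, path) {
  arr <- unclass(image) / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' @rdname read_rgb
#' @param pixels H x W x 3 numeric array with values in 0..255.
#' @export
rgb_image <- function(pixels, scale = NA_real_) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stop("rgb_image needs an H x W x 3 array", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("rgb_image channel values must lie in [0, 255]", call. = FALSE)
  }
  structure(array(as.integer(round(pixels)), dim(pixels)),
            scale_um = as.numeric(scale), class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d pixels, scale %.3g um/px\n",
              d[1], d[2], attr(x, "scale_um")))
  invisible(x)
}
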