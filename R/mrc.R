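## MRC2014 I/O. Mode 2 (float32) written by default; modes 0/1/2/6 read.
## On disk the column/row/section axes follow the MRC convention (x fastest);
## in memory volumes are (x, y, z) arrays and images (row = y, col = x)
## matrices, mapped explicitly here. 2D vs 3D vs stack is distinguished by
## nz and the ISPG flag (0 = image/stack, 1 = volume).

mrcModeInfo <- list(
  `0` = list(what = "integer", size = 1L, signed = TRUE),
  `1` = list(what = "integer", size = 2L, signed = TRUE),
  `2` = list(what = "numeric", size = 4L, signed = TRUE),
  `6` = list(what = "integer", size = 2L, signed = FALSE))

#' Write an object to an MRC2014 file
#'
#' Writes a [GrayImage-class] (nz = 1), [DensityVolume-class] (ISPG = 1) or
#' [TiltSeries-class] (image stack, ISPG = 0) as little-endian mode-2
#' (float32) MRC2014. For a tilt series the angle list is written to
#' `anglesPath` (one degree value per line; defaults to `<path>.tlt`).
#'
#' @param obj object to write.
#' @param path output file.
#' @param anglesPath sidecar angle file for tilt series.
#' @return `path`, invisibly.
#' @export
writeMRC <- function(obj, path, anglesPath = NULL) {
  if (is(obj, "GrayImage")) {
    nxyz <- c(ncol(obj@pixels), nrow(obj@pixels), 1L)
    dat <- as.vector(t(obj@pixels))
    vs <- if (is.na(obj@pixelSize)) 1 else obj@pixelSize
    ispg <- 0L
  } else if (is(obj, "DensityVolume")) {
    nxyz <- dim(obj@voxels)
    dat <- as.vector(obj@voxels)
    vs <- obj@voxelSize
    ispg <- 1L
  } else if (is(obj, "TiltSeries")) {
    d <- dim(obj@images)
    nxyz <- c(d[2L], d[1L], d[3L])
    dat <- as.vector(aperm(obj@images, c(2L, 1L, 3L)))
    vs <- if (is.na(obj@pixelSize)) 1 else obj@pixelSize
    ispg <- 0L
    if (is.null(anglesPath)) anglesPath <- paste0(path, ".tlt")
    writeAngles(obj@angles, anglesPath)
  } else stop("writeMRC: unsupported object class ", class(obj))

  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4L,
                               endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4L,
                               endian = "little")
  wInt(nxyz)                       # nx ny nz
  wInt(2L)                         # mode 2 = float32
  wInt(c(0L, 0L, 0L))              # nxstart nystart nzstart
  wInt(nxyz)                       # mx my mz
  wFlt(nxyz * vs)                  # cella
  wFlt(c(90, 90, 90))              # cellb
  wInt(c(1L, 2L, 3L))              # mapc mapr maps
  wFlt(c(min(dat), max(dat), mean(dat)))
  wInt(ispg)
  wInt(0L)                         # nsymbt
  wInt(rep(0L, 25L))               # extra (words 26..49)
  wFlt(c(0, 0, 0))                 # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # little-endian stamp
  wFlt(popSd(dat))                 # rms
  wInt(0L)                         # nlabl
  writeBin(raw(800L), con)         # labels
  writeBin(as.numeric(dat), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRC2014 file
#'
#' Reads modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16), either
#' endianness. Returns a [GrayImage-class] when nz = 1, a
#' [DensityVolume-class] when ISPG >= 1 (or `as = "volume"`), and a
#' [TiltSeries-class] for an ISPG = 0 stack, in which case a tilt-angle file
#' (one degree value per line, or JSON) must be supplied or sit next to the
#' file as `<path>.tlt`.
#'
#' @param path MRC file.
#' @param anglesPath tilt-angle sidecar file for stacks.
#' @param as force the interpretation: "auto", "image", "volume" or
#'   "stack".
#' @return A [GrayImage-class], [DensityVolume-class] or
#'   [TiltSeries-class].
#' @export
readMRC <- function(path, anglesPath = NULL,
                    as = c("auto", "image", "volume", "stack")) {
  as <- match.arg(as)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1024L)
  if (length(hdr) < 1024L)
    stop("readMRC: malformed header, file shorter than 1024 bytes (offset ",
         length(hdr), ")")
  machst <- hdr[213:216]
  endian <- if (machst[1L] == as.raw(0x11)) "big" else "little"
  gInt <- function(word, n = 1L)
    readBin(hdr[(4L * (word - 1L) + 1L):(4L * (word - 1L) + 4L * n)],
            "integer", n = n, size = 4L, endian = endian)
  gFlt <- function(word, n = 1L)
    readBin(hdr[(4L * (word - 1L) + 1L):(4L * (word - 1L) + 4L * n)],
            "numeric", n = n, size = 4L, endian = endian)
  nxyz <- gInt(1L, 3L)
  mode <- gInt(4L)
  if (any(nxyz <= 0L) || any(nxyz > 1e5)) {   # wrong endianness fallback
    endian <- if (endian == "little") "big" else "little"
    nxyz <- gInt(1L, 3L); mode <- gInt(4L)
  }
  if (any(nxyz <= 0L))
    stop("readMRC: malformed header, nonpositive dimensions (offset 0)")
  mi <- mrcModeInfo[[as.character(mode)]]
  if (is.null(mi))
    stop("readMRC: unsupported mode ", mode,
         "; supported modes are 0 (int8), 1 (int16), 2 (float32), 6 (uint16)")
  mx <- gInt(8L, 3L)
  cella <- gFlt(11L, 3L)
  ispg <- gInt(23L)
  nsymbt <- gInt(24L)
  vs <- if (mx[1L] > 0 && cella[1L] > 0) cella[1L] / mx[1L] else NA_real_
  if (nsymbt > 0) invisible(readBin(con, "raw", n = nsymbt))
  n <- prod(nxyz)
  dat <- readBin(con, mi$what, n = n, size = mi$size, signed = mi$signed,
                 endian = endian)
  if (length(dat) < n)
    stop("readMRC: truncated data section (got ", length(dat), " of ", n,
         " values)")
  dat <- as.numeric(dat)

  kind <- if (as != "auto") as
    else if (nxyz[3L] == 1L) "image"
    else if (ispg >= 1L) "volume"
    else "stack"
  if (kind == "image") {
    grayImage(t(matrix(dat, nxyz[1L], nxyz[2L])), pixelSize = vs)
  } else if (kind == "volume") {
    densityVolume(array(dat, dim = nxyz), voxelSize = if (is.na(vs)) 1
                  else vs)
  } else {
    if (is.null(anglesPath)) anglesPath <- paste0(path, ".tlt")
    if (!file.exists(anglesPath))
      stop("readMRC: stack needs a tilt-angle file; not found: ", anglesPath)
    angs <- readAngles(anglesPath)
    if (length(angs) != nxyz[3L])
      stop("readMRC: angle file has ", length(angs), " entries for ",
           nxyz[3L], " sections")
    tiltSeries(aperm(array(dat, dim = nxyz), c(2L, 1L, 3L)), angs,
               pixelSize = vs)
  }
}

#' Write a tilt-angle list
#'
#' Plain text, one degree value per line; files ending in `.json` are
#' written as a JSON array.
#'
#' @param angles numeric vector of angles in degrees.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAngles <- function(angles, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(as.numeric(angles), path, digits = NA)
  else
    writeLines(format(as.numeric(angles), trim = TRUE, scientific = FALSE),
               path)
  invisible(path)
}

#' Read a tilt-angle list
#' @param path text file (one angle per line) or JSON array.
#' @return Numeric vector of angles in degrees.
#' @export
readAngles <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.numeric(unlist(jsonlite::read_json(path)))
  } else {
    ln <- trimws(readLines(path, warn = FALSE))
    as.numeric(ln[nzchar(ln)])
  }
}

#' Export a 2D image as PNG or TIFF
#'
#' Min-max scales the image to [0, 1] and writes it with the `png` or
#' `tiff` package (chosen by the file extension).
#'
#' @param img a [GrayImage-class].
#' @param path output file ending in .png or .tif/.tiff.
#' @return `path`, invisibly.
#' @export
writeImage2D <- function(img, path) {
  p <- img@pixels
  rg <- range(p)
  p01 <- if (rg[2L] > rg[1L]) (p - rg[1L]) / (rg[2L] - rg[1L]) else p * 0
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("writeImage2D: package 'png' not available")
    png::writePNG(p01, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("writeImage2D: package 'tiff' not available")
    tiff::writeTIFF(p01, path)
  } else stop("writeImage2D: unsupported extension in ", path)
  invisible(path)
}
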