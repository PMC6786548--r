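#' Write a volume to an MRC2014 file
#'
#' Minimal MRC2014 writer: mode 2 (32-bit float), x fastest axis, voxel size
#' recorded in the cell dimensions (Angstrom, i.e. nm x 10, per the format's
#' convention).
#'
#' @param vol A [volume3d()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  d <- dim(vol$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # nx ny nz
  wi(2)                      # mode 2 = float32
  wi(c(0, 0, 0))             # nxstart
  wi(d)                      # mx my mz
  wf(d * vol$voxel_size * 10) # cella (Angstrom)
  wf(c(90, 90, 90))          # cellb
  wi(c(1, 2, 3))             # mapc mapr maps
  wf(c(min(vol$data), max(vol$data), mean(vol$data))) # dmin dmax dmean
  wi(0)                      # ispg
  wi(0)                      # nsymbt
  wi(rep(0L, 25))            # extra (words 25-49)
  wf(vol$origin * 10)        # origin (Angstrom)
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # machst little-endian
  wf(stats::sd(vol$data))    # rms
  wi(0)                      # nlabl
  writeBin(raw(800), con)    # labels
  wf(as.numeric(vol$data))
  invisible(path)
}

#' Read an MRC volume
#'
#' Reads little-endian MRC2014 files in modes 0 (int8), 1 (int16), 2
#' (float32) and 6 (uint16) with x as the fastest axis.
#'
#' @param path File path.
#' @return A [volume3d()]; voxel size taken from cella/mx (converted to nm).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3)
  m <- ri(3)
  cella <- rf(3)
  rf(3); ri(3); rf(3); ri(2); ri(25)
  orig <- rf(3) / 10
  seek(con, 1024)
  n <- prod(d)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                             endian = "little")),
    stop("unsupported MRC mode: ", mode))
  vs <- if (m[1] > 0 && cella[1] > 0) cella[1] / m[1] / 10 else 1
  volume3d(array(data, d), voxel_size = vs, origin = orig)
}

#' Write a 2D image (or image stack) as TIFF
#'
#' Images are linearly rescaled to [0, 1] before writing; the original range
#' is stored in the TIFF description when `rescale = TRUE`.
#'
#' @param img A matrix, or list of matrices (multi-page TIFF).
#' @param path Output path.
#' @param rescale Rescale intensities to [0, 1] (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path, rescale = TRUE) {
  norm1 <- function(m) {
    if (!rescale) return(m)
    rg <- range(m)
    if (diff(rg) == 0) matrix(0, nrow(m), ncol(m)) else (m - rg[1]) / diff(rg)
  }
  imgs <- if (is.list(img)) lapply(img, norm1) else norm1(img)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a TIFF image (or stack)
#'
#' @param path File path.
#' @return A matrix, or list of matrices for a multi-page file.
#' @export
read_image_tiff <- function(path) {
  x <- tiff::readTIFF(path, all = TRUE)
  if (length(x) == 1) x[[1]] else x
}

#' Write granule centres (and optional labels) to CSV
#'
#' Columns `x_nm, y_nm, z_nm` plus `sector` when labels are given.
#'
#' @param points n x 3 matrix (nm).
#' @param path Output path.
#' @param sector Optional integer label per point.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(points, path, sector = NULL) {
  df <- data.frame(x_nm = points[, 1], y_nm = points[, 2], z_nm = points[, 3])
  if (!is.null(sector)) df$sector <- sector
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read granule centres from CSV
#'
#' @param path File path (columns `x_nm, y_nm, z_nm[, sector]`).
#' @return n x 3 matrix; attribute `"sector"` if present in the file.
#' @export
read_points_csv <- function(path) {
  df <- utils::read.csv(path)
  p <- as.matrix(df[, c("x_nm", "y_nm", "z_nm")])
  colnames(p) <- c("x", "y", "z")
  if ("sector" %in% names(df)) attr(p, "sector") <- df$sector
  p
}
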