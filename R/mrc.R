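#' Volume grid
#'
#' A cubic 3D density grid with voxel size in Angstrom. World coordinates
#' place the origin at the centre of voxel `(n/2, n/2, n/2)` (0-based), so
#' the box is centred on the rotation origin used throughout the package.
#'
#' @param data 3D numeric array with equal extents on all axes.
#' @param voxel_size voxel edge length in Angstrom (> 0).
#' @param origin Angstrom offset of the centre of voxel (0,0,0); recorded in
#'   the MRC header, not used in computations.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, voxel_size, origin = c(0, 0, 0)) {
  d <- dim(data)
  if (length(d) != 3 || length(unique(d)) != 1)
    stop("volume_grid: box must be cubic, got ", paste(d, collapse = "x"))
  if (!is.numeric(voxel_size) || voxel_size <= 0)
    stop("volume_grid: voxel_size must be > 0")
  structure(list(data = data, voxel_size = voxel_size, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d^3 voxels, %.3f A/voxel\n",
              dim(x$data)[1], x$voxel_size))
  invisible(x)
}

mrc_mode_type <- function(mode) {
  switch(as.character(mode),
         "0" = list(what = "integer", size = 1L, signed = TRUE),
         "1" = list(what = "integer", size = 2L, signed = TRUE),
         "2" = list(what = "numeric", size = 4L),
         stop("unsupported MRC mode: ", mode))
}

read_mrc_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4L, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4L, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  if (nx <= 0 || ny <= 0 || nz <= 0 || nx > 1e5 || ny > 1e5 || nz > 1e6)
    stop("malformed MRC header in ", path)
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  cella <- hdr_num[11:13]
  nsymbt <- hdr_int[24]
  origin <- hdr_num[50:52]
  typ <- mrc_mode_type(mode)
  seek(con, 1024 + nsymbt)
  nvals <- as.numeric(nx) * ny * nz
  data <- readBin(con, typ$what, n = nvals, size = typ$size,
                  endian = "little")
  if (length(data) < nvals) stop("truncated MRC data in ", path)
  vx <- if (mx > 0 && cella[1] > 0) cella[1] / mx else 1
  list(data = array(data, dim = c(nx, ny, nz)), voxel_size = vx,
       origin = origin)
}

#' Read an MRC volume
#'
#' Reads a single 3D MRC map (mode 0, 1 or 2). The voxel size is taken from
#' the header cell dimensions. Non-cubic boxes are rejected.
#'
#' @param path path to an MRC file.
#' @return A [volume_grid].
#' @export
read_volume <- function(path) {
  raw <- read_mrc_raw(path)
  d <- dim(raw$data)
  if (length(unique(d)) != 1)
    stop("read_volume: non-cubic box ", paste(d, collapse = "x"),
         " is unsupported")
  volume_grid(raw$data, raw$voxel_size, raw$origin)
}

write_mrc_raw <- function(data, voxel_size, path, origin = c(0, 0, 0)) {
  d <- dim(data)
  if (length(d) == 2) d <- c(d, 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wn <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)                     # nx ny nz
  wi(2L)                    # mode: float32
  wi(c(0L, 0L, 0L))         # nxstart
  wi(d)                     # mx my mz
  wn(d * voxel_size)        # cella
  wn(c(90, 90, 90))         # cellb
  wi(c(1L, 2L, 3L))         # mapc mapr maps
  wn(c(min(data), max(data), mean(data)))
  wi(c(1L, 0L))             # ispg, nsymbt
  wi(rep(0L, 25))           # extra
  wn(origin)                # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wn(stats::sd(data))       # rms
  wi(0L)                    # nlabl
  writeBin(raw(800), con)   # labels
  writeBin(as.numeric(data), con, size = 4L, endian = "little")
  invisible(path)
}

#' Write an MRC volume
#'
#' Writes a [volume_grid] as a mode-2 (float32) MRC file.
#'
#' @param volume a [volume_grid].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  write_mrc_raw(volume$data, volume$voxel_size, path, volume$origin)
}

#' Read an MRCS particle image stack
#'
#' @param path path to an MRCS file (one section per particle).
#' @return list with `images` (n x n x N array) and `pixel_size` (Angstrom).
#' @export
read_image_stack <- function(path) {
  raw <- read_mrc_raw(path)
  d <- dim(raw$data)
  if (d[1] != d[2]) stop("read_image_stack: non-square images")
  list(images = raw$data, pixel_size = raw$voxel_size)
}

#' Write an MRCS particle image stack
#'
#' @param images n x n x N numeric array.
#' @param pixel_size pixel size in Angstrom.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(images, pixel_size, path) {
  write_mrc_raw(images, pixel_size, path)
}
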