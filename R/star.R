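#' Read a STAR file
#'
#' Generic parser for RELION-style STAR files: returns every `data_` block
#' as a data frame (loop blocks) or a named list (key-value blocks). Both
#' the optics-group-aware two-table layout and flat single-table files are
#' handled.
#'
#' @param path path to a STAR file.
#' @return named list of blocks.
#' @export
read_star <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  blocks <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!startsWith(lines[i], "data_")) { i <- i + 1L; next }
    bname <- substring(lines[i], 6L)
    if (bname == "") bname <- "data"
    i <- i + 1L
    while (i <= n && lines[i] == "") i <- i + 1L
    if (i <= n && lines[i] == "loop_") {
      i <- i + 1L
      cols <- character()
      while (i <= n && startsWith(lines[i], "_")) {
        cols <- c(cols, sub("^_", "", strsplit(lines[i], "\\s+")[[1]][1]))
        i <- i + 1L
      }
      rows <- list()
      while (i <= n && lines[i] != "" && !startsWith(lines[i], "data_")) {
        rows[[length(rows) + 1L]] <- strsplit(lines[i], "\\s+")[[1]]
        i <- i + 1L
      }
      m <- do.call(rbind, rows)
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- cols
      for (j in seq_along(df)) {
        v <- suppressWarnings(as.numeric(df[[j]]))
        if (!anyNA(v)) df[[j]] <- v
      }
      blocks[[bname]] <- df
    } else {
      kv <- list()
      while (i <= n && !startsWith(lines[i], "data_")) {
        if (startsWith(lines[i], "_")) {
          parts <- strsplit(lines[i], "\\s+")[[1]]
          key <- sub("^_", "", parts[1])
          val <- paste(parts[-1], collapse = " ")
          vn <- suppressWarnings(as.numeric(val))
          kv[[key]] <- if (!is.na(vn)) vn else val
        }
        i <- i + 1L
      }
      blocks[[bname]] <- kv
    }
  }
  blocks
}

#' Write a STAR file
#'
#' @param blocks named list of data frames (written as `loop_` blocks).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_star <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (bname in names(blocks)) {
    df <- blocks[[bname]]
    writeLines(c(paste0("data_", bname), "", "loop_"), con)
    writeLines(sprintf("_%s #%d", names(df), seq_along(df)), con)
    fmt <- vapply(df, function(col) {
      if (is.numeric(col)) format(col, digits = 12, trim = TRUE,
                                  scientific = FALSE)
      else as.character(col)
    }, FUN.VALUE = character(nrow(df)))
    if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L)
    writeLines(apply(fmt, 1, paste, collapse = "  "), con)
    writeLines("", con)
  }
  invisible(path)
}

star_required <- c("rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi",
                   "rlnDefocusU", "rlnDefocusV", "rlnImageName")

#' Read particle metadata (RELION STAR dialect)
#'
#' Reads a particle STAR file into a `particle_stack`. Pose angles are
#' RELION ZYZ intrinsic Euler angles in degrees; shifts are in Angstrom
#' (`rlnOriginXAngst`/`rlnOriginYAngst`, defaulting to 0 when absent).
#' CTF parameters missing from the particle table are taken from the
#' optics block when present. A missing `rlnRandomSubset` column is filled
#' by row parity (1,2,1,2,...).
#'
#' @param star_path path to the STAR file.
#' @param stack_root directory against which image names are resolved;
#'   `NULL` skips image loading (metadata only).
#' @return A `particle_stack`: list with `meta` (data frame), `images`
#'   (n x n x N array or NULL) and `pixel_size`.
#' @export
read_particles <- function(star_path, stack_root = NULL) {
  blocks <- read_star(star_path)
  tab <- if ("particles" %in% names(blocks)) blocks$particles
         else blocks[[length(blocks)]]
  if (!is.data.frame(tab)) stop("no particle table found in ", star_path)
  optics <- blocks[["optics"]]
  missing_cols <- setdiff(star_required, names(tab))
  # CTF/voltage columns may live in the optics table
  from_optics <- c("rlnVoltage", "rlnSphericalAberration",
                   "rlnAmplitudeContrast", "rlnImagePixelSize")
  for (colname in from_optics) {
    if (!colname %in% names(tab) && is.data.frame(optics) &&
        colname %in% names(optics)) {
      tab[[colname]] <- optics[[colname]][1]
    }
  }
  missing_cols <- setdiff(star_required, names(tab))
  if (length(missing_cols) > 0)
    stop("read_particles: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  nr <- nrow(tab)
  meta <- data.frame(
    image_index = seq_len(nr),
    rot = tab$rlnAngleRot, tilt = tab$rlnAngleTilt, psi = tab$rlnAnglePsi,
    shift_x = if ("rlnOriginXAngst" %in% names(tab)) tab$rlnOriginXAngst else 0,
    shift_y = if ("rlnOriginYAngst" %in% names(tab)) tab$rlnOriginYAngst else 0,
    defocus_u = tab$rlnDefocusU, defocus_v = tab$rlnDefocusV,
    astig_angle = if ("rlnDefocusAngle" %in% names(tab)) tab$rlnDefocusAngle else 0,
    voltage = if ("rlnVoltage" %in% names(tab)) tab$rlnVoltage else 300,
    cs = if ("rlnSphericalAberration" %in% names(tab)) tab$rlnSphericalAberration else 2.7,
    amplitude_contrast = if ("rlnAmplitudeContrast" %in% names(tab)) tab$rlnAmplitudeContrast else 0.1,
    phase_shift = if ("rlnPhaseShift" %in% names(tab)) tab$rlnPhaseShift else 0,
    halfset = if ("rlnRandomSubset" %in% names(tab)) as.integer(tab$rlnRandomSubset)
              else rep_len(c(1L, 2L), nr),
    image_name = as.character(tab$rlnImageName),
    stringsAsFactors = FALSE)
  if (!all(meta$halfset %in% c(1L, 2L)))
    stop("read_particles: halfset labels must be 1 or 2")
  images <- NULL
  pixel_size <- if ("rlnImagePixelSize" %in% names(tab)) tab$rlnImagePixelSize[1] else NA_real_
  if (!is.null(stack_root)) {
    parts <- strsplit(meta$image_name, "@")
    files <- vapply(parts, function(p) p[length(p)], "")
    idx <- vapply(parts, function(p)
      if (length(p) == 2) as.integer(p[1]) else NA_integer_, 1L)
    images <- NULL
    for (f in unique(files)) {
      st <- read_image_stack(file.path(stack_root, f))
      if (is.null(images)) {
        n <- dim(st$images)[1]
        images <- array(0, c(n, n, nr))
        pixel_size <- st$pixel_size
      }
      sel <- which(files == f)
      images[, , sel] <- st$images[, , idx[sel]]
    }
  }
  particle_stack(meta, images, pixel_size)
}

#' Particle stack constructor
#'
#' @param meta data frame of per-particle records (pose, CTF, halfset).
#' @param images n x n x N array of particle images, or NULL.
#' @param pixel_size pixel size in Angstrom.
#' @return object of class `particle_stack`.
#' @export
particle_stack <- function(meta, images = NULL, pixel_size = NA_real_) {
  stopifnot(is.data.frame(meta))
  if (!is.null(images)) {
    stopifnot(dim(images)[3] == nrow(meta))
    box_extent <- dim(images)[1] * pixel_size
    if (any(abs(meta$shift_x) >= box_extent | abs(meta$shift_y) >= box_extent))
      stop("particle_stack: shift magnitudes exceed the box extent")
  }
  structure(list(meta = meta, images = images, pixel_size = pixel_size),
            class = "particle_stack")
}

#' @export
print.particle_stack <- function(x, ...) {
  cat(sprintf("<particle_stack> %d particles (half1: %d, half2: %d)%s\n",
              nrow(x$meta), sum(x$meta$halfset == 1),
              sum(x$meta$halfset == 2),
              if (is.null(x$images)) ", metadata only"
              else sprintf(", %dpx images @ %.2f A", dim(x$images)[1],
                           x$pixel_size)))
  invisible(x)
}

#' Write particle metadata and images
#'
#' Writes an optics-group-aware STAR file and (when images are present) a
#' float32 MRCS stack next to it.
#'
#' @param particles a `particle_stack`.
#' @param star_path output STAR path.
#' @param stack_name MRCS file name recorded in `rlnImageName`.
#' @return `star_path`, invisibly.
#' @export
write_particles <- function(particles, star_path,
                            stack_name = "particles.mrcs") {
  meta <- particles$meta
  optics <- data.frame(
    rlnOpticsGroup = 1, rlnVoltage = meta$voltage[1],
    rlnSphericalAberration = meta$cs[1],
    rlnAmplitudeContrast = meta$amplitude_contrast[1],
    rlnImagePixelSize = particles$pixel_size)
  tab <- data.frame(
    rlnImageName = sprintf("%06d@%s", meta$image_index, stack_name),
    rlnAngleRot = meta$rot, rlnAngleTilt = meta$tilt, rlnAnglePsi = meta$psi,
    rlnOriginXAngst = meta$shift_x, rlnOriginYAngst = meta$shift_y,
    rlnDefocusU = meta$defocus_u, rlnDefocusV = meta$defocus_v,
    rlnDefocusAngle = meta$astig_angle, rlnPhaseShift = meta$phase_shift,
    rlnRandomSubset = meta$halfset, rlnOpticsGroup = 1,
    stringsAsFactors = FALSE)
  write_star(list(optics = optics, particles = tab), star_path)
  if (!is.null(particles$images))
    write_image_stack(particles$images, particles$pixel_size,
                      file.path(dirname(star_path), stack_name))
  invisible(star_path)
}
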