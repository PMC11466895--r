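# Weighted backprojection. The numerator accumulates, per particle, the
# CTF-multiplied image smeared along the viewing direction in real space
# (optionally warped by the particle's deformation); the denominator
# accumulates squared CTFs on central slices of the 3D Fourier grid. The
# final map is numerator / denominator in Fourier space with a Wiener-style
# floor.

recon_accumulate <- function(particles, fields = NULL, box, voxel_size,
                             warp_iters = 10) {
  meta <- particles$meta
  N <- nrow(meta)
  if (N == 0) stop("backprojection: empty particle set")
  n_img <- dim(particles$images)[1]
  stopifnot(n_img == box)
  num <- numeric(box^3)
  den <- numeric(box^3)  # centred 3D Fourier accumulation of CTF^2
  ctf <- ctf_stack(meta, box, particles$pixel_size)
  for (i in seq_len(N)) {
    R <- euler_matrix(meta$rot[i], meta$tilt[i], meta$psi[i])
    ci <- matrix(ctf[, i], box, box)
    yF <- fft2o(particles$images[, , i])
    img <- Re(stats::fft(yF * ci, inverse = TRUE)) / box
    disp <- numeric(0)
    if (!is.null(fields)) {
      f <- if (is.function(fields)) fields(i) else fields[[i]]
      u <- invert_displacement_field(f, iters = warp_iters)
      disp <- as.numeric(u)
    }
    backproject_one_cpp(img, R, c(meta$shift_x[i], meta$shift_y[i]),
                        box, voxel_size, disp, num)
    insert_slice_cpp(as.vector(fftshift2(ci^2)), R, box, den)
  }
  list(num = array(num, rep(box, 3)), den = array(den, rep(box, 3)))
}

recon_divide <- function(acc, voxel_size, wiener = 1e-3) {
  box <- dim(acc$num)[1]
  den <- fftshift3(acc$den)             # back to FFT order
  floor_val <- wiener * max(den)
  den <- pmax(den, floor_val)
  Fnum <- fft3o(acc$num)
  vol <- Re(fft3o(Fnum / den, inverse = TRUE))
  volume_grid(vol, voxel_size)
}

#' Standard weighted backprojection
#'
#' Homogeneous reconstruction: images are CTF-multiplied, backprojected
#' along their poses and normalized by the accumulated squared CTFs in
#' Fourier space with a Wiener-style floor.
#'
#' @param particles a `particle_stack` with images.
#' @param box,voxel_size reconstruction grid (defaults to the image grid).
#' @param wiener relative Wiener floor on the accumulated squared CTFs
#'   (default 1e-3 of the maximum).
#' @return A [volume_grid].
#' @export
backproject_standard <- function(particles, box = dim(particles$images)[1],
                                 voxel_size = particles$pixel_size,
                                 wiener = 1e-3) {
  acc <- recon_accumulate(particles, NULL, box, voxel_size)
  recon_divide(acc, voxel_size, wiener)
}

#' Deformed weighted backprojection
#'
#' As [backproject_standard], but each particle's backprojected volume is
#' warped by its inverse deformation before accumulation (pull-back
#' trilinear sampling). Fields of kind `"inverse"` are converted to
#' pull-back sampling fields by fixed-point inversion; with identity
#' fields the result equals the standard backprojection exactly.
#'
#' @param particles a `particle_stack` with images.
#' @param fields list of `gf_field` objects (one per particle) or a
#'   function `(i) -> gf_field`.
#' @param box,voxel_size reconstruction grid.
#' @param wiener relative Wiener floor.
#' @param warp_iters fixed-point iterations for field inversion.
#' @return A [volume_grid].
#' @export
backproject_deformed <- function(particles, fields,
                                 box = dim(particles$images)[1],
                                 voxel_size = particles$pixel_size,
                                 wiener = 1e-3, warp_iters = 10) {
  acc <- recon_accumulate(particles, fields, box, voxel_size, warp_iters)
  recon_divide(acc, voxel_size, wiener)
}

#' Fourier shell correlation between two maps
#'
#' \deqn{FSC(shell) = \frac{Re \sum A \bar{B}}{\sqrt{\sum |A|^2 \sum |B|^2}}}
#'
#' @param map_a,map_b [volume_grid]s with identical shape and voxel size.
#' @return data frame with columns `shell`, `freq` (1/Angstrom), `fsc`
#'   and `n_voxels`. Shells with zero power in either map are reported as
#'   0 and flagged in the `undefined` column.
#' @export
compute_fsc <- function(map_a, map_b) {
  stopifnot(all(dim(map_a$data) == dim(map_b$data)),
            isTRUE(all.equal(map_a$voxel_size, map_b$voxel_size)))
  n <- dim(map_a$data)[1]
  A <- fft3o(map_a$data)
  B <- fft3o(map_b$data)
  sh <- as.vector(shell_index3(n)) + 1L
  cross <- rowsum(as.vector(Re(A * Conj(B))), sh)[, 1]
  pa <- rowsum(as.vector(Mod(A)^2), sh)[, 1]
  pb <- rowsum(as.vector(Mod(B)^2), sh)[, 1]
  cnt <- rowsum(rep(1, length(sh)), sh)[, 1]
  undef <- pa <= 0 | pb <= 0
  fsc <- ifelse(undef, 0, cross / sqrt(pmax(pa, 1e-300) * pmax(pb, 1e-300)))
  shells <- seq_along(fsc) - 1L
  data.frame(shell = shells,
             freq = shells / (n * map_a$voxel_size),
             fsc = fsc, n_voxels = cnt, undefined = undef)
}

#' Write an FSC curve as two-column text
#'
#' @param fsc data frame from [compute_fsc].
#' @param path output path (spatial frequency in 1/Angstrom, correlation).
#' @return `path`, invisibly.
#' @export
write_fsc <- function(fsc, path) {
  utils::write.table(fsc[, c("freq", "fsc")], path, sep = "\t",
                     row.names = FALSE, col.names = c("freq_invA", "fsc"),
                     quote = FALSE)
  invisible(path)
}
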