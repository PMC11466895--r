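#' CTF parameters
#'
#' @param defocus_u,defocus_v defocus along the major/minor astigmatism axes
#'   (Angstrom; positive = underfocus).
#' @param astig_angle azimuth of the major axis (degrees).
#' @param voltage acceleration voltage (kV).
#' @param cs spherical aberration (mm).
#' @param amplitude_contrast amplitude contrast fraction in `[0, 1]`.
#' @param phase_shift additional phase shift (degrees), e.g. phase plate.
#' @return object of class `ctf_params`.
#' @export
ctf_params <- function(defocus_u, defocus_v = defocus_u, astig_angle = 0,
                       voltage = 300, cs = 2.7, amplitude_contrast = 0.1,
                       phase_shift = 0) {
  if (voltage <= 0) stop("ctf_params: voltage must be > 0")
  if (amplitude_contrast < 0 || amplitude_contrast > 1)
    stop("ctf_params: amplitude_contrast must be in [0, 1]")
  structure(list(defocus_u = defocus_u, defocus_v = defocus_v,
                 astig_angle = astig_angle, voltage = voltage, cs = cs,
                 amplitude_contrast = amplitude_contrast,
                 phase_shift = phase_shift),
            class = "ctf_params")
}

# Relativistic electron wavelength in Angstrom for voltage in kV.
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1e3
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

#' Evaluate the contrast transfer function on a Fourier grid
#'
#' Standard weak-phase-object CTF without an envelope:
#' \deqn{CTF(k) = -(\sqrt{1-A^2}\sin\chi + A\cos\chi)}
#' with aberration phase
#' \deqn{\chi(k) = \pi\lambda z(\alpha) |k|^2 - \frac{\pi}{2} C_s \lambda^3 |k|^4 + \phi_{shift}}
#' where the astigmatic defocus is
#' `z(alpha) = (zu+zv)/2 + (zu-zv)/2 * cos(2(alpha - astig_angle))`.
#' The value at zero frequency is `-A`.
#'
#' @param ctf a [ctf_params].
#' @param box image size in pixels.
#' @param pixel_size pixel size in Angstrom.
#' @return `box` x `box` real matrix in FFT order (DC at `[1, 1]`).
#' @export
ctf_evaluate <- function(ctf, box, pixel_size) {
  fg <- freq_grid2(box, pixel_size)
  k2 <- fg$kx^2 + fg$ky^2
  alpha <- atan2(fg$ky, fg$kx)
  lambda <- electron_wavelength(ctf$voltage)
  zu <- ctf$defocus_u; zv <- ctf$defocus_v
  z <- (zu + zv) / 2 + (zu - zv) / 2 *
    cos(2 * (alpha - ctf$astig_angle * pi / 180))
  chi <- pi * lambda * z * k2 - pi / 2 * (ctf$cs * 1e7) * lambda^3 * k2^2 +
    ctf$phase_shift * pi / 180
  a <- ctf$amplitude_contrast
  -(sqrt(1 - a^2) * sin(chi) + a * cos(chi))
}

# CTF arrays for every row of a particle metadata table (box^2 x N matrix).
ctf_stack <- function(meta, box, pixel_size) {
  out <- matrix(0, box * box, nrow(meta))
  for (i in seq_len(nrow(meta))) {
    ct <- ctf_params(meta$defocus_u[i], meta$defocus_v[i],
                     meta$astig_angle[i], meta$voltage[i], meta$cs[i],
                     meta$amplitude_contrast[i], meta$phase_shift[i])
    out[, i] <- as.vector(ctf_evaluate(ct, box, pixel_size))
  }
  out
}
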