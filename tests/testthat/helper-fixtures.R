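# Shared fixture helpers. Heavy objects are built once per test run and
# cached in this environment.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small random Gaussian model
toy_model <- function(ng = 5, seed = 1, width = 4, amp = 1.5,
                      extent = 15) {
  set.seed(seed)
  gaussian_model(matrix(runif(ng * 3, -extent, extent), ng),
                 widths = width, amplitudes = amp)
}

# Small particle metadata table with varied poses and CTFs
toy_meta <- function(n = 4, seed = 2, box = 24, pixel = 3) {
  set.seed(seed)
  data.frame(
    image_index = seq_len(n),
    rot = runif(n, 0, 360), tilt = acos(runif(n, -1, 1)) * 180 / pi,
    psi = runif(n, 0, 360),
    shift_x = runif(n, -4, 4), shift_y = runif(n, -4, 4),
    defocus_u = runif(n, 8000, 20000), defocus_v = runif(n, 8000, 20000),
    astig_angle = runif(n, 0, 180), voltage = 300, cs = 2.7,
    amplitude_contrast = 0.1, phase_shift = 0,
    halfset = rep_len(c(1L, 2L), n),
    image_name = sprintf("%06d@stack.mrcs", seq_len(n)),
    stringsAsFactors = FALSE)
}

# Tiny noiseless static scene + simulation (fast; shared by several files)
tiny_static_sim <- function() {
  cached("tiny_static_sim", {
    scene <- make_hinge_scene(n_gaussians = 12, n_moving = 3,
                              angle_range = c(0, 0), n_particles = 24,
                              box = 24, pixel_size = 3, snr = 0, seed = 5)
    simulate_particles(scene)
  })
}

# A single-ALA PDB file (heavy atoms only), written to a temp path
write_ala_pdb <- function(path, with_hydrogens = FALSE) {
  lines <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.697   7.143  -4.915  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      13.400   7.620  -5.806  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1      12.217   4.673  -4.899  1.00  0.00           C")
  if (with_hydrogens) {
    lines <- c(lines,
      "ATOM      6  H   ALA A   1      10.500   5.500  -7.000  1.00  0.00           H",
      "ATOM      7  HA  ALA A   1      10.800   6.200  -4.500  1.00  0.00           H")
  }
  writeLines(c(lines, "END"), path)
  path
}

# TRP residue with full side chain
write_trp_pdb <- function(path) {
  atoms <- list(
    c("N",  25.0, 30.0, 10.0, "N"), c("CA", 26.2, 30.5, 10.6, "C"),
    c("C",  27.4, 29.8, 10.0, "C"), c("O",  27.5, 28.6, 10.1, "O"),
    c("CB", 26.3, 32.0, 10.4, "C"), c("CG", 25.2, 32.8, 11.0, "C"),
    c("CD1",24.0, 33.0, 10.4, "C"), c("CD2",25.1, 33.5, 12.2, "C"),
    c("NE1",23.2, 33.8, 11.2, "N"), c("CE2",23.8, 34.1, 12.3, "C"),
    c("CE3",26.0, 33.8, 13.3, "C"), c("CZ2",23.4, 34.9, 13.4, "C"),
    c("CZ3",25.6, 34.6, 14.4, "C"), c("CH2",24.3, 35.1, 14.4, "C"))
  lines <- vapply(seq_along(atoms), function(i) {
    a <- atoms[[i]]
    sprintf("ATOM  %5d %-4s TRP A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, paste0(" ", a[1]), as.numeric(a[2]), as.numeric(a[3]),
            as.numeric(a[4]), a[5])
  }, "")
  writeLines(c(lines, "END"), path)
  path
}

# Single RNA nucleotide (adenosine monophosphate-like)
write_nuc_pdb <- function(path) {
  atoms <- list(
    c("P",   1.0, 1.0, 1.0, "P"), c("OP1", 1.5, 2.2, 1.5, "O"),
    c("OP2", 0.2, 0.3, 2.0, "O"), c("O5'", 2.0, 0.5, 0.0, "O"),
    c("C5'", 3.2, 1.1, -0.4, "C"), c("C4'", 4.1, 0.1, -1.1, "C"),
    c("O4'", 4.5, -0.9, -0.2, "O"), c("C3'", 5.4, 0.7, -1.6, "C"),
    c("O3'", 5.3, 1.0, -3.0, "O"), c("C2'", 6.4, -0.4, -1.3, "C"),
    c("O2'", 7.5, -0.2, -2.1, "O"), c("C1'", 5.7, -1.6, -0.8, "C"),
    c("N9",  6.0, -2.0, 0.6, "N"), c("C8",  5.5, -1.5, 1.8, "C"),
    c("N7",  6.0, -2.1, 2.9, "N"), c("C5",  6.9, -3.0, 2.4, "C"),
    c("C6",  7.8, -4.0, 3.0, "C"), c("N6",  7.9, -4.2, 4.3, "N"),
    c("N1",  8.6, -4.7, 2.2, "N"), c("C2",  8.5, -4.5, 0.9, "C"),
    c("N3",  7.7, -3.6, 0.2, "N"), c("C4",  6.9, -2.9, 1.0, "C"))
  lines <- vapply(seq_along(atoms), function(i) {
    a <- atoms[[i]]
    sprintf("ATOM  %5d %-4s   A B   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, paste0(" ", a[1]), as.numeric(a[2]), as.numeric(a[3]),
            as.numeric(a[4]), a[5])
  }, "")
  writeLines(c(lines, "END"), path)
  path
}
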