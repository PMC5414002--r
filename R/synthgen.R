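#' Specification for synthetic two-domain structures
#'
#' Parameters of the synthetic-structure generator, which emulates the
#' geometry that matters for the structural operations: two compact
#' pseudo-globular Calpha domains (NTD-like and CTD-like) joined by a
#' straight H-7-like helix, with a known interdomain rotation, helix shift
#' and coordinate noise, and crystal-like straight filaments with a fixed
#' axial repeat.
#'
#' @param n_res_ntd,n_res_h7,n_res_ctd residue counts (> 3); defaults match
#'   the FtsZ presets (NTD 12-165, H7 169-195, CTD 196-316).
#' @param applied_angle interdomain rotation to apply, degrees.
#' @param axis rotation axis (unit 3-vector; normalized internally).
#' @param h7_shift helix translation along its own axis, angstrom.
#' @param noise_sigma isotropic Gaussian coordinate noise, angstrom (>= 0).
#' @param repeat_length filament axial repeat, angstrom (default 44).
#' @param seed integer PRNG seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_res_ntd = 154, n_res_h7 = 27, n_res_ctd = 121,
                       applied_angle = 27, axis = c(1, 0, 0), h7_shift = 4,
                       noise_sigma = 0, repeat_length = 44, seed = 1) {
  stopifnot(n_res_ntd > 3, n_res_h7 > 3, n_res_ctd > 3, noise_sigma >= 0,
            repeat_length > 0)
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(n_res_ntd = as.integer(n_res_ntd), n_res_h7 = as.integer(n_res_h7),
                 n_res_ctd = as.integer(n_res_ctd),
                 applied_angle = applied_angle, axis = axis, h7_shift = h7_shift,
                 noise_sigma = noise_sigma, repeat_length = repeat_length,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# deterministic amino-acid sequence for synthetic chains (seeded)
synth_sequence <- function(n, seed) {
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
          "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
  set.seed(seed)
  sample(aa, n, replace = TRUE)
}

#' Generate a synthetic two-domain Calpha structure
#'
#' Deterministic for a given spec/seed: a compact NTD-like blob, a straight
#' H-7-like segment along z, and a compact CTD-like blob, residue-numbered
#' to mimic the FtsZ presets (NTD starting at 12, a 3-residue numbering gap
#' before the helix). Calpha-only — sufficient for superposition, rotation
#' and (with inflated radii) interface tests.
#'
#' @param spec a [synth_spec()].
#' @return List with `structure` ([fts_structure()]) and `domains`
#'   ([domain_definition()] matching the generated numbering).
#' @export
make_two_domain_structure <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  blob <- function(n, center, sd) {
    sweep(matrix(stats::rnorm(3 * n, sd = sd), n, 3), 2, center, "+")
  }
  ntd <- blob(spec$n_res_ntd, c(0, 0, 32), 8)
  h7_z <- seq(18, -18, length.out = spec$n_res_h7)
  h7 <- cbind(stats::rnorm(spec$n_res_h7, sd = 0.3),
              stats::rnorm(spec$n_res_h7, sd = 0.3), h7_z)
  ctd <- blob(spec$n_res_ctd, c(0, 0, -32), 8)
  xyz <- rbind(ntd, h7, ctd)
  ntd_rng <- c(12L, 11L + spec$n_res_ntd)
  h7_rng <- c(ntd_rng[2] + 4L, ntd_rng[2] + 3L + spec$n_res_h7)
  ctd_rng <- c(h7_rng[2] + 1L, h7_rng[2] + spec$n_res_ctd)
  res_seq <- c(seq(ntd_rng[1], ntd_rng[2]), seq(h7_rng[1], h7_rng[2]),
               seq(ctd_rng[1], ctd_rng[2]))
  n <- length(res_seq)
  atoms <- data.frame(chain = "A", res_seq = res_seq, ins = "",
                      res_name = synth_sequence(n, spec$seed + 1L),
                      atom_name = "CA", element = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      occupancy = 1, b = 0, is_hetero = FALSE,
                      stringsAsFactors = FALSE)
  s <- fts_structure(atoms, id = sprintf("synth_seed%d", spec$seed))
  domains <- domain_definition(ntd = ntd_rng, ctd = ctd_rng, h7 = h7_rng)
  list(structure = s, domains = domains)
}

#' Apply a known conformational perturbation
#'
#' Rotates the CTD by `spec$applied_angle` about `spec$axis` through the
#' domain hinge (centroid of the first three CTD residues), translates the
#' H-7 segment by `spec$h7_shift` along its own axis (toward the CTD, i.e.
#' the "downward" helix shift that accompanies domain opening), then adds
#' isotropic Gaussian noise of sd `spec$noise_sigma` to every atom.
#'
#' @param structure an [fts_structure()] (typically from
#'   [make_two_domain_structure()]).
#' @param domains matching [domain_definition()].
#' @param spec a [synth_spec()] carrying angle/axis/shift/noise/seed.
#' @return The perturbed [fts_structure()].
#' @export
perturb_conformation <- function(structure, domains, spec) {
  stopifnot(inherits(structure, "fts_structure"),
            inherits(domains, "domain_definition"), inherits(spec, "synth_spec"))
  a <- structure$atoms
  in_ctd <- a$res_seq >= domains$ctd[1] & a$res_seq <= domains$ctd[2] & !a$is_hetero
  in_h7 <- a$res_seq >= domains$h7[1] & a$res_seq <= domains$h7[2] & !a$is_hetero
  xyz <- as.matrix(a[, c("x", "y", "z")])
  # CTD rotation about the hinge
  hinge_rows <- which(a$res_seq %in% seq(domains$ctd[1], domains$ctd[1] + 2L) & !a$is_hetero)
  hinge <- colMeans(xyz[hinge_rows, , drop = FALSE])
  R <- rotation_about_axis(spec$axis, spec$applied_angle)
  xyz[in_ctd, ] <- sweep(sweep(xyz[in_ctd, , drop = FALSE], 2, hinge) %*% t(R), 2, hinge, "+")
  # H-7 shift along its own axis, pointing from first toward last helix residue
  if (any(in_h7) && spec$h7_shift != 0) {
    h <- xyz[in_h7, , drop = FALSE]
    dir <- h[nrow(h), ] - h[1, ]
    dir <- dir / sqrt(sum(dir^2))
    xyz[in_h7, ] <- sweep(h, 2, spec$h7_shift * dir, "+")
  }
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed + 2L)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = spec$noise_sigma),
                        nrow(xyz), 3)
  }
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  fts_structure(a, cell = structure$cell,
                id = paste0(structure$id, sprintf("_rot%.1f", spec$applied_angle)))
}

#' Generate a synthetic crystal-like filament
#'
#' `n` copies of a subunit related by a fixed axial translation along z
#' (plus an optional twist about z), chain IDs sequential — the geometry of
#' a straight protofilament with a constant repeat extending through a
#' crystal.
#'
#' @param subunit an [fts_structure()].
#' @param repeat_length axial repeat, angstrom.
#' @param n number of chains (>= 2).
#' @param twist per-subunit rotation about z, degrees (default 0).
#' @return A multi-chain [fts_structure()].
#' @export
make_filament_crystal <- function(subunit, repeat_length = 44, n = 3, twist = 0) {
  stopifnot(n >= 2)
  op <- rigid_transform(rotation_about_axis(c(0, 0, 1), twist),
                        c(0, 0, repeat_length))
  fil <- build_filament(subunit, op, n)
  s <- filament_as_structure(fil, id = sprintf("synth_filament_rep%.1f", repeat_length))
  s$cell <- c(80, 80, n * repeat_length, 90, 90, 90)
  s
}
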