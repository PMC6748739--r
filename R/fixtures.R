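#' Analytic buried area of two overlapping expanded spheres
#'
#' Closed-form spherical-cap oracle for the two-body geometry, computed
#' without any point sampling.  With expanded radii `R_A = r_a + probe`
#' and `R_B = r_b + probe` at centre distance `d`, the buried patch on A
#' is the cap cut by B with height
#' `h_A = R_A - (d^2 + R_A^2 - R_B^2) / (2 d)` and area `2 * pi * R_A *
#' h_A`, clamped to `[0, 4 * pi * R_A^2]`: separated spheres give 0,
#' engulfed spheres the full sphere area.
#'
#' @param r_a,r_b vdW radii (Angstrom).
#' @param d Centre distance, `> 0`.
#' @param probe Probe radius, default 1.4.
#' @return Named numeric vector `c(a = , b = )`: buried areas on A and B
#'   in Angstrom^2.
#' @export
analytic_cap_area <- function(r_a, r_b, d, probe = 1.4) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
    stop("`d` must be a single positive distance", call. = FALSE)
  RA <- r_a + probe
  RB <- r_b + probe
  cap <- function(R1, R2) {
    h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
    h <- min(max(h, 0), 2 * R1)
    2 * pi * R1 * h
  }
  c(a = cap(RA, RB), b = cap(RB, RA))
}

# Build a toy-system atom table from coordinates.
.toy_atoms <- function(xyz, radius, object, chain = NULL, resno = NULL,
                       resname = "UNK", element = "C", probe = 1.4) {
  xyz <- matrix(xyz, ncol = 3L)
  n <- nrow(xyz)
  if (is.null(chain)) chain <- c("A", "B", "C", "D")[object]
  if (is.null(resno)) resno <- seq_len(n)
  atoms <- data.frame(
    serial = seq_len(n), name = paste0("C", seq_len(n)),
    element = rep_len(element, n), resname = rep_len(resname, n),
    chain = rep_len(chain, n), resno = rep_len(resno, n), inscode = "",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], occupancy = 1,
    altloc = "", hetero = FALSE, stringsAsFactors = FALSE)
  atoms$radius <- rep_len(radius, n)
  atoms$object <- rep_len(as.integer(object), n)
  attr(atoms, "probe") <- probe
  attr(atoms, "format") <- "synthetic"
  atoms
}

.toy_system <- function(atoms, expected = list()) {
  objects <- data.frame(id = sort(unique(atoms$object)),
                        label = paste0("object", sort(unique(atoms$object))),
                        class = "synthetic", stringsAsFactors = FALSE)
  structure(list(atoms = atoms, format = "synthetic", source = NA_character_,
                 objects = objects, expected = expected),
            class = c("toy_system", "mol_structure"))
}

#' Two-sphere toy system
#'
#' Two atoms on the x axis at distance `d`, one per object; the analytic
#' cap areas are attached under `$expected`.
#'
#' @param r_a,r_b vdW radii (Angstrom).
#' @param d Centre distance.
#' @param probe Probe radius.
#' @return A `toy_system` (subclass of `mol_structure`).
#' @export
make_two_spheres <- function(r_a = 1.6, r_b = 1.6, d = 3.0, probe = 1.4) {
  atoms <- .toy_atoms(rbind(c(0, 0, 0), c(d, 0, 0)),
                      radius = c(r_a, r_b), object = c(1L, 2L),
                      probe = probe)
  cap <- analytic_cap_area(r_a, r_b, d, probe)
  .toy_system(atoms, expected = list(
    cap_on_a = unname(cap["a"]), cap_on_b = unname(cap["b"]),
    sasa_a = 4 * pi * (r_a + probe)^2 - cap[["a"]],
    sasa_b = 4 * pi * (r_b + probe)^2 - cap[["b"]]))
}

#' Three-atom shared-patch toy system
#'
#' Atom A (object 1) is overlapped by atoms B and C (object 2, one shared
#' residue) whose expanded spheres also overlap each other over part of
#' A's surface, so A's buried points form the occluder groups `{B}`,
#' `{C}` and `{B, C}`.  The contact surface of A with B is the area of
#' the `{B}`-only patch plus half of the shared `{B, C}` patch.  B and C
#' are mirror images through the y = 0 plane, so CSA(A,B) and CSA(A,C)
#' agree up to sampling granularity.
#'
#' @param probe Probe radius.
#' @return A `toy_system`; all radii 1.6 Angstrom.
#' @export
make_fig1_triple <- function(probe = 1.4) {
  atoms <- .toy_atoms(rbind(c(0, 0, 0), c(2.5, 1.8, 0), c(2.5, -1.8, 0)),
                      radius = 1.6, object = c(1L, 2L, 2L),
                      resno = c(1L, 1L, 1L), probe = probe)
  .toy_system(atoms)
}

#' Mirror-symmetric pair-of-occluders toy system
#'
#' Atom A at the origin with two occluders B and C placed point-
#' symmetrically about A (`C = -B`) along the z axis.  The lattice's
#' height ladder is mirror-symmetric about the equator, so the two caps
#' are sampled with balanced point counts and CSA(A,B) equals CSA(A,C)
#' to within sampling granularity (one point weight).
#'
#' @param d Centre distance from A to each occluder.
#' @param probe Probe radius.
#' @return A `toy_system`; all radii 1.6 Angstrom.
#' @export
make_mirror_pair <- function(d = 3.0, probe = 1.4) {
  atoms <- .toy_atoms(rbind(c(0, 0, 0), c(0, 0, d), c(0, 0, -d)),
                      radius = 1.6, object = c(1L, 2L, 2L), probe = probe)
  .toy_system(atoms)
}

#' Crowded-interface toy system
#'
#' Object 1 is a single atom A; object 2 is a dimer B--C in which C sits
#' behind B as seen from A (collinear arrangement A .. B .. C).  The part
#' of C's surface facing A is already buried by B in the isolated dimer,
#' so the differential-SASA approximation assigns it no interface area,
#' while the direct contact surface calculation still credits the A--C
#' contact.  On this system the delta-SASA interface area is strictly
#' smaller than the direct CSA total — the deviation direction of
#' SASA-based approximations on crowded interfaces.  Fixed coordinates,
#' no randomness.
#'
#' @param probe Probe radius.
#' @return A `toy_system`; all radii 1.6 Angstrom.
#' @export
make_crowding_pair <- function(probe = 1.4) {
  atoms <- .toy_atoms(rbind(c(-2.5, 0, 0), c(0, 0, 0), c(2, 0, 0)),
                      radius = 1.6, object = c(1L, 2L, 2L), probe = probe)
  .toy_system(atoms)
}

#' Buried-ligand cage toy system
#'
#' A single ligand-like atom (object 2) at the centre of an icosahedral
#' cage of twelve mutually overlapping atoms (object 1).  The ligand is
#' fully buried: its solvent accessible surface is zero.  Cage atoms'
#' patches facing the ligand are typically shared with neighbouring cage
#' atoms, so cross-object-only classification (mode 4) reports larger
#' ligand contact surfaces than all-atom classification (mode 1).
#'
#' @param shell Distance of cage atoms from the centre (Angstrom).
#' @param probe Probe radius.
#' @return A `toy_system`; all radii 1.6 Angstrom.
#' @export
make_buried_cage <- function(shell = 3.5, probe = 1.4) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
             c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
             c(phi, 0, 1), c(phi, 0, -1), c(-phi, 0, 1), c(-phi, 0, -1))
  v <- v / sqrt(1 + phi^2) * shell
  atoms <- .toy_atoms(rbind(c(0, 0, 0), v),
                      radius = 1.6, object = c(2L, rep(1L, 12L)),
                      probe = probe)
  .toy_system(atoms)
}

#' Reproducible random atom cluster
#'
#' `n` atoms uniformly placed in a cubic box, with radii drawn from the
#' values of the shipped united-atom PDB table (1.40--1.90 Angstrom), two
#' objects (first half / second half), and residues of up to three atoms.
#' The generator uses an explicit seed and restores the caller's RNG
#' state.  An optional minimum centre separation is enforced by
#' resampling.
#'
#' @param n Number of atoms, `>= 1`.
#' @param box Cube edge length (Angstrom).
#' @param seed Integer seed; same seed, same cluster.
#' @param min_sep Minimum pairwise centre distance (0 disables).
#' @param probe Probe radius.
#' @return A `toy_system`.
#' @export
make_random_cluster <- function(n, box = 10, seed = 1, min_sep = 0,
                                probe = 1.4) {
  stopifnot(n >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  xyz <- matrix(stats::runif(3L * n, 0, box), n, 3L)
  if (min_sep > 0 && n > 1L) {
    for (tries in seq_len(200L)) {
      d <- as.matrix(stats::dist(xyz))
      diag(d) <- Inf
      bad <- which(apply(d, 1L, min) < min_sep)
      if (!length(bad)) break
      xyz[bad, ] <- matrix(stats::runif(3L * length(bad), 0, box),
                           length(bad), 3L)
    }
  }
  radii <- sample(c(1.40, 1.50, 1.65, 1.76, 1.85, 1.87, 1.90), n,
                  replace = TRUE)
  object <- rep(c(1L, 2L), c(ceiling(n / 2), floor(n / 2)))
  atoms <- .toy_atoms(xyz, radius = radii, object = object,
                      resno = ceiling(seq_len(n) / 3), probe = probe)
  .toy_system(atoms)
}

#' Write a toy system to a PDB file
#'
#' Serialises any `mol_structure` (occupancy in its column, zeros in the
#' B-factor field) so CLI-level tests can run end-to-end on the same
#' fixtures as the library-level tests.
#'
#' @param structure A `mol_structure` or `toy_system`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  atoms <- if (inherits(structure, "mol_structure")) structure$atoms
           else structure
  write_pdb_bfactor(atoms, numeric(nrow(atoms)), path)
}
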