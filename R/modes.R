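#' Run a full surface calculation in one of five modes
#'
#' Modes of operation:
#' \describe{
#'   \item{0}{SASA only (fallback mode).}
#'   \item{1}{Intermolecular contact surfaces: atom- and residue-level CSA
#'     matrices between objects, with occluder scope = all atoms (a point
#'     buried by a same-object neighbour shares its weight with it), plus
#'     per-atom intermolecular BSA column sums.}
#'   \item{2}{Intramolecular residue-level contact map.}
#'   \item{3}{Intramolecular atom-level contact map.}
#'   \item{4}{Intermolecular contact surfaces with occluder scope =
#'     cross-object-only: each object's points are classified against the
#'     other objects' atoms only, so contact surfaces are counted whether
#'     or not they are solvent accessible — useful for deep and internal
#'     binding cavities.}
#' }
#' Modes 1 and 4 require at least two molecular objects (explicit chain
#' `selection` or automatic class detection, see [detect_objects()]).
#'
#' @param structure A [read_structure()] result or toy system; a bare atom
#'   table is also accepted.
#' @param mode Integer 0--4.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Lattice points per atom (default 2000).
#' @param radii A [radii_table()], used when atoms carry no radii yet;
#'   default chosen by input format.
#' @param selection Optional chain selection forwarded to
#'   [detect_objects()].
#' @return Object of class `"surface_result"`: list with `sasa`, `bsa`,
#'   `atom_matrix`, `res_matrix` (entries `NULL` when the mode does not
#'   produce them), `atoms`, `objects`, and `params` (mode, probe,
#'   n_points, radii table name, occluder scope).
#' @export
run_mode <- function(structure, mode, probe = 1.4, n_points = 2000L,
                     radii = NULL, selection = NULL) {
  if (!is.numeric(mode) || length(mode) != 1L || !(mode %in% 0:4))
    stop("`mode` must be one of 0, 1, 2, 3, 4", call. = FALSE)
  mode <- as.integer(mode)
  if (is.data.frame(structure)) {
    structure <- structure(list(atoms = structure,
                                format = attr(structure, "format"),
                                source = NA_character_, objects = NULL),
                           class = "mol_structure")
  }
  stopifnot(inherits(structure, "mol_structure"))
  needs_objects <- mode %in% c(1L, 4L)
  if (!is.null(selection) || (needs_objects && is.null(structure$objects)))
    structure <- detect_objects(structure, selection)
  atoms <- structure$atoms
  radii_name <- "preassigned"
  if (is.null(atoms$radius)) {
    if (is.null(radii))
      radii <- radii_table(if (identical(structure$format, "mol2"))
        "mol2-typed" else "pdb-united")
    atoms <- assign_radii(atoms, radii, probe)
    radii_name <- radii$name
  }
  if (needs_objects &&
      (is.null(atoms$object) || length(unique(atoms$object)) < 2L))
    stop("mode ", mode, " requires at least two molecular objects; ",
         "give a chain selection or use an input with more than one ",
         "molecule class", call. = FALSE)
  lattice <- generate_sphere_points(n_points)
  scope <- if (mode == 4L) "cross" else "all"
  res <- list(sasa = NULL, bsa = NULL, atom_matrix = NULL,
              res_matrix = NULL)
  if (mode == 0L) {
    res$sasa <- compute_sasa(atoms, lattice, probe)
  } else {
    cr <- compute_contacts(atoms, lattice, probe, occluder_scope = scope)
    res$sasa <- cr$sasa
    if (mode %in% c(1L, 4L)) {
      cross <- outer(atoms$object, atoms$object, "!=")
      m <- cr$csa * cross          # intermolecular entries only
      res$atom_matrix <- m
      res$res_matrix <- aggregate_to_residues(m, atoms)
      res$bsa <- derive_bsa(m)
    } else {
      res$atom_matrix <- if (mode == 3L) cr$csa
      res$res_matrix <- aggregate_to_residues(cr$csa, atoms)
      if (mode == 3L) res$res_matrix <- NULL
    }
  }
  structure(list(sasa = res$sasa, bsa = res$bsa,
                 atom_matrix = res$atom_matrix,
                 res_matrix = res$res_matrix,
                 atoms = atoms, objects = structure$objects,
                 params = list(mode = mode, probe = probe,
                               n_points = as.integer(n_points),
                               radii = radii_name, scope = scope)),
            class = "surface_result")
}

#' @export
print.surface_result <- function(x, ...) {
  p <- x$params
  cat(sprintf("Surface calculation, mode %d (probe %.2f A, %d points, %s radii)\n",
              p$mode, p$probe, p$n_points, p$radii))
  cat(sprintf("  %d atoms; total SASA %.2f A^2\n", nrow(x$atoms),
              sum(x$sasa)))
  if (!is.null(x$bsa))
    cat(sprintf("  total BSA %.2f A^2 over %d atoms in contact\n",
                sum(x$bsa), sum(x$bsa > 0)))
  if (!is.null(x$atom_matrix))
    cat(sprintf("  atom contact matrix %d x %d, %d nonzero entries\n",
                nrow(x$atom_matrix), ncol(x$atom_matrix),
                sum(x$atom_matrix > 0)))
  if (!is.null(x$res_matrix))
    cat(sprintf("  residue contact matrix %d x %d\n", nrow(x$res_matrix),
                ncol(x$res_matrix)))
  invisible(x)
}

#' @export
summary.surface_result <- function(object, ...) {
  print(object)
  top <- NULL
  m <- if (!is.null(object$res_matrix)) object$res_matrix
       else object$atom_matrix
  if (!is.null(m) && any(m > 0)) {
    ij <- which(m == max(m), arr.ind = TRUE)[1L, ]
    cat(sprintf("  largest contact: %s -- %s, %.2f A^2\n",
                rownames(m)[ij[1L]], colnames(m)[ij[2L]], max(m)))
    top <- m[ij[1L], ij[2L]]
  }
  invisible(list(total_sasa = sum(object$sasa),
                 total_bsa = if (!is.null(object$bsa)) sum(object$bsa),
                 largest_contact = top))
}

#' Plot a surface result
#'
#' Modes with a contact matrix draw it as a heat map (residue level when
#' available); mode 0 draws a per-atom SASA bar plot.
#'
#' @param x A `surface_result`.
#' @param ... Passed to the internal heat-map renderer.
#' @export
plot.surface_result <- function(x, ...) {
  m <- if (!is.null(x$res_matrix)) x$res_matrix else x$atom_matrix
  if (!is.null(m)) {
    .draw_contact_map(m, ...)
  } else {
    barplot(unname(x$sasa), names.arg = names(x$sasa), las = 2,
            ylab = "SASA (A^2)", cex.names = 0.6)
  }
  invisible(x)
}
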