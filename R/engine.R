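#' Classify the lattice points of one atom by occluding-atom group
#'
#' Places every lattice point at `pos(atom) + (r_atom + probe) * direction`
#' and tests it against the expanded sphere of every neighbour (closed
#' inequality: a point exactly on an occluder's expanded sphere counts as
#' buried).  A buried point may lie inside several neighbours at once; the
#' full set of occluders is the point's group.  The table of distinct
#' groups with their point counts is the unit from which SASA, CSA and BSA
#' are all derived.
#'
#' @param atoms Atom table with radii assigned.
#' @param i Row index of the owner atom.
#' @param neighbors Integer row indices of candidate occluders; `NULL`
#'   computes them from a fresh [build_neighbor_index()].
#' @param lattice A [generate_sphere_points()] lattice.
#' @param probe Probe radius (Angstrom); default from `atoms`, else 1.4.
#' @return Object of class `"occluder_groups"`: list with `owner` (serial),
#'   `members` (list of integer serial vectors, each sorted ascending),
#'   `counts` (points per group), `accessible_points`, `total_points`,
#'   and `point_area` (area of one point on this atom's expanded sphere,
#'   Angstrom^2).
#' @export
classify_points <- function(atoms, i, neighbors = NULL,
                            lattice = generate_sphere_points(2000L),
                            probe = NULL) {
  stopifnot(is.data.frame(atoms), inherits(lattice, "sphere_lattice"))
  if (is.null(probe)) probe <- attr(atoms, "probe")
  if (is.null(probe)) probe <- 1.4
  if (is.null(neighbors))
    neighbors <- build_neighbor_index(atoms, probe)$neighbors[[i]]
  R <- atoms$radius[i] + probe
  np <- lattice$count
  key <- .burial_keys(atoms, i, neighbors, lattice, probe)
  buried <- !is.na(key)
  acc <- sum(!buried)
  if (any(buried)) {
    tab <- table(key[buried])
    members <- lapply(strsplit(names(tab), ",", fixed = TRUE),
                      function(s) sort(atoms$serial[neighbors[as.integer(s)]]))
    counts <- as.integer(tab)
  } else {
    members <- list()
    counts <- integer(0)
  }
  structure(list(owner = atoms$serial[i], members = members,
                 counts = counts, accessible_points = acc,
                 total_points = np,
                 point_area = lattice$point_weight * R^2),
            class = "occluder_groups")
}

# Per-point occluder pattern of atom i: NA for accessible points, else a
# comma-joined string of local neighbour positions (canonical group key).
.burial_keys <- function(atoms, i, neighbors, lattice, probe) {
  R <- atoms$radius[i] + probe
  np <- lattice$count
  k <- length(neighbors)
  if (k == 0L) return(rep(NA_character_, np))
  px <- atoms$x[i] + R * lattice$directions[, 1L]
  py <- atoms$y[i] + R * lattice$directions[, 2L]
  pz <- atoms$z[i] + R * lattice$directions[, 3L]
  M <- matrix(FALSE, np, k)
  for (j in seq_len(k)) {
    nj <- neighbors[j]
    Rj <- atoms$radius[nj] + probe
    M[, j] <- (px - atoms$x[nj])^2 + (py - atoms$y[nj])^2 +
              (pz - atoms$z[nj])^2 <= Rj^2
  }
  buried <- rowSums(M) > 0L
  key <- rep(NA_character_, np)
  if (any(buried)) {
    key[buried] <- apply(M[buried, , drop = FALSE], 1L,
                         function(r) paste(which(r), collapse = ","))
  }
  key
}

#' @export
print.occluder_groups <- function(x, ...) {
  cat(sprintf(
    "Occluder groups of atom %d: %d accessible / %d points, %d group(s)\n",
    x$owner, x$accessible_points, x$total_points, length(x$members)))
  if (length(x$members)) {
    lab <- vapply(x$members, function(m) paste0("{", paste(m, collapse = ","),
                                                "}"), "")
    for (g in order(-x$counts))
      cat(sprintf("  %-18s %6d points\n", lab[g], x$counts[g]))
  }
  invisible(x)
}

#' Solvent accessible surface area per atom
#'
#' Classical Shrake-Rupley estimate: lattice points on each atom's expanded
#' sphere that fall inside no neighbouring expanded sphere are counted and
#' multiplied by the area one point represents,
#' `SASA(A) = accessible_points * (4 * pi / count) * (r_A + probe)^2`.
#'
#' @inheritParams classify_points
#' @return Numeric vector of per-atom SASA in Angstrom^2, named by atom
#'   label; attribute `total` holds the summed SASA.
#' @export
compute_sasa <- function(atoms, lattice = generate_sphere_points(2000L),
                         probe = NULL) {
  res <- compute_contacts(atoms, lattice, probe, matrix = FALSE)
  res$sasa
}

#' Direct contact surface areas with fractional attribution
#'
#' Runs the extended point classification for every atom and assembles the
#' atom-level contact matrix.  A group `G` of occluders of atom `A` owns a
#' patch of area `points(G) * point_weight * (r_A + probe)^2`; the patch is
#' divided evenly among the `|G|` occluders, so
#' `CSA(A, B) = sum over groups G containing B of area(G) / |G|`.
#' The matrix is asymmetric by construction: row `A` lives on `A`'s
#' expanded sphere.  Under `occluder_scope = "all"` every overlapping atom
#' occludes; under `"cross"` only atoms of *other* objects occlude, so
#' contact surfaces need not be solvent accessible (deep cavity mode).
#'
#' @inheritParams classify_points
#' @param occluder_scope `"all"` or `"cross"` (cross-object-only; requires
#'   an `object` column).
#' @param matrix If `FALSE`, skip group bookkeeping and return SASA only.
#' @return List of class `"contact_result"`: `csa` (n x n matrix,
#'   Angstrom^2, zero diagonal), `sasa` (named vector), `groups` (list of
#'   [classify_points()] tables), `probe`, `lattice_count`, `scope`.
#' @export
compute_contacts <- function(atoms, lattice = generate_sphere_points(2000L),
                             probe = NULL,
                             occluder_scope = c("all", "cross"),
                             matrix = TRUE) {
  stopifnot(is.data.frame(atoms), inherits(lattice, "sphere_lattice"))
  occluder_scope <- match.arg(occluder_scope)
  if (is.null(probe)) probe <- attr(atoms, "probe")
  if (is.null(probe)) probe <- 1.4
  n <- nrow(atoms)
  if (occluder_scope == "cross" &&
      (is.null(atoms$object) || anyNA(atoms$object)))
    stop("occluder_scope = \"cross\" requires object ids on every atom ",
         "(run detect_objects() first)", call. = FALSE)
  labs <- atom_label(atoms)
  idx <- build_neighbor_index(atoms, probe)$neighbors
  sasa <- numeric(n)
  csa <- if (matrix) base::matrix(0, n, n, dimnames = list(labs, labs))
  groups <- if (matrix) vector("list", n)
  w <- lattice$point_weight
  pos_of_serial <- setNames(seq_len(n), as.character(atoms$serial))
  for (i in seq_len(n)) {
    nb <- idx[[i]]
    if (occluder_scope == "cross")
      nb <- nb[atoms$object[nb] != atoms$object[i]]
    R <- atoms$radius[i] + probe
    if (!matrix) {
      key <- .burial_keys(atoms, i, nb, lattice, probe)
      sasa[i] <- sum(is.na(key)) * w * R^2
      next
    }
    g <- classify_points(atoms, i, nb, lattice, probe)
    groups[[i]] <- g
    sasa[i] <- g$accessible_points * g$point_area
    if (length(g$members)) {
      for (k in seq_along(g$members)) {
        mem <- pos_of_serial[as.character(g$members[[k]])]
        csa[i, mem] <- csa[i, mem] +
          g$counts[k] * g$point_area / length(mem)
      }
    }
  }
  names(sasa) <- labs
  attr(sasa, "total") <- sum(sasa)
  structure(list(csa = csa, sasa = sasa, groups = groups, probe = probe,
                 lattice_count = lattice$count, scope = occluder_scope),
            class = "contact_result")
}

#' Aggregate an atom-level contact matrix to residue level
#'
#' Entry `(R1, R2)` of the residue matrix is the exact sum of the atom
#' matrix over all atom pairs with those residue keys; totals are preserved
#' exactly.  Residues are ordered by first appearance in the atom table.
#'
#' @param atom_matrix Square atom-level CSA matrix whose rows/columns
#'   follow `atoms` order.
#' @param atoms The atom table the matrix was computed from.
#' @return Residue-level matrix with `"chain/resname resnum[icode]"`
#'   dimnames.
#' @export
aggregate_to_residues <- function(atom_matrix, atoms) {
  stopifnot(is.matrix(atom_matrix), nrow(atom_matrix) == nrow(atoms),
            ncol(atom_matrix) == nrow(atoms))
  rl <- residue_label(atoms)
  f <- factor(rl, levels = unique(rl))
  m <- rowsum(atom_matrix, f)                # sum rows
  m <- t(rowsum(t(m), f))                    # sum columns
  m[, levels(f), drop = FALSE]
}

#' Buried surface area as contact-matrix column sums
#'
#' `BSA(row)` is the sum of the row's entries over a column selection —
#' e.g. the atoms of the other molecular object for intermolecular BSA.
#' An empty selection yields all-zero BSA.
#'
#' @param mat Contact matrix (atom- or residue-level).
#' @param columns Column selection: integer/logical indices or labels;
#'   `NULL` selects all columns.
#' @return Named numeric vector of per-row BSA (Angstrom^2).
#' @export
derive_bsa <- function(mat, columns = NULL) {
  stopifnot(is.matrix(mat))
  if (is.null(columns)) columns <- seq_len(ncol(mat))
  sub <- mat[, columns, drop = FALSE]
  if (ncol(sub) == 0L) return(setNames(numeric(nrow(mat)), rownames(mat)))
  rowSums(sub)
}

#' Differential-SASA approximation of interface area
#'
#' The classical approximation of buried/contact surface: each molecular
#' object's SASA is computed in isolation and in the complex, and the
#' interface area is the per-atom difference summed over both objects.
#' Points of an atom that are already buried by its own object in
#' isolation contribute nothing here even when a partner atom also covers
#' them, which is why this approximation underestimates crowded interfaces
#' relative to the direct contact surface.
#'
#' @inheritParams classify_points
#' @return List: `per_atom` (named vector of `SASA_isolated -
#'   SASA_complex`), `by_object` (sum per object), `total`.
#' @export
delta_sasa_csa <- function(atoms, lattice = generate_sphere_points(2000L),
                           probe = NULL) {
  stopifnot(is.data.frame(atoms))
  if (is.null(atoms$object) || length(unique(atoms$object)) < 2L)
    stop("delta-SASA interface area requires two molecular objects",
         call. = FALSE)
  objs <- sort(unique(atoms$object))
  if (length(objs) != 2L)
    stop("exactly two molecular objects expected, got ", length(objs),
         call. = FALSE)
  if (is.null(probe)) probe <- attr(atoms, "probe")
  if (is.null(probe)) probe <- 1.4
  sasa_cplx <- compute_sasa(atoms, lattice, probe)
  delta <- numeric(nrow(atoms))
  for (o in objs) {
    sel <- which(atoms$object == o)
    iso <- compute_sasa(atoms[sel, , drop = FALSE], lattice, probe)
    delta[sel] <- iso - sasa_cplx[sel]
  }
  names(delta) <- names(sasa_cplx)
  by_obj <- vapply(objs, function(o) sum(delta[atoms$object == o]), 0)
  names(by_obj) <- paste0("object_", objs)
  list(per_atom = delta, by_object = by_obj, total = sum(delta))
}
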