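#' Build a neighbour index over expanded spheres
#'
#' Uniform-grid cell list over atom centres.  Two atoms are neighbours when
#' their solvent-expanded spheres overlap, i.e. when
#' `|pos(A) - pos(B)| < (r_A + probe) + (r_B + probe)`; exactly tangent
#' spheres share only a measure-zero circle and are not neighbours.  The
#' grid cell edge is the largest pair cutoff, so candidate pairs are found
#' in the 27 surrounding cells.  Neighbour lists are returned in ascending
#' atom order, deterministically.
#'
#' @param atoms Atom table with `radius` assigned (see [assign_radii()]).
#' @param probe Probe radius in Angstrom; defaults to the `probe` attribute
#'   stored on `atoms`, else 1.4.
#' @return Object of class `"neighbor_index"`: list with `neighbors` (list
#'   of integer row-index vectors, one per atom) and `probe`.
#' @export
build_neighbor_index <- function(atoms, probe = NULL) {
  stopifnot(is.data.frame(atoms))
  if (is.null(probe)) probe <- attr(atoms, "probe")
  if (is.null(probe)) probe <- 1.4
  n <- nrow(atoms)
  out <- vector("list", max(n, 0L))
  if (n > 0L) {
    if (is.null(atoms$radius) || anyNA(atoms$radius) ||
        any(atoms$radius <= 0))
      stop("atoms must have positive `radius` assigned before neighbour ",
           "indexing", call. = FALSE)
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    if (any(!is.finite(xyz)))
      stop("non-finite atom coordinates", call. = FALSE)
    rexp <- atoms$radius + probe
    edge <- 2 * max(rexp)
    cell <- floor(sweep(xyz, 2L, apply(xyz, 2L, min)) / edge)
    ckey <- paste(cell[, 1L], cell[, 2L], cell[, 3L])
    cells <- split(seq_len(n), ckey)
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    for (i in seq_len(n)) {
      nb_keys <- paste(cell[i, 1L] + offs[, 1L],
                       cell[i, 2L] + offs[, 2L],
                       cell[i, 3L] + offs[, 3L])
      cand <- unlist(cells[nb_keys], use.names = FALSE)
      cand <- cand[cand != i]
      if (length(cand)) {
        d2 <- (xyz[cand, 1L] - xyz[i, 1L])^2 +
              (xyz[cand, 2L] - xyz[i, 2L])^2 +
              (xyz[cand, 3L] - xyz[i, 3L])^2
        hit <- cand[d2 < (rexp[i] + rexp[cand])^2]
        if (any(d2 == 0 & cand > i))
          warning("atoms with exactly coincident centres (rows ", i, ", ",
                  paste(cand[d2 == 0 & cand > i], collapse = ", "),
                  "); both kept", call. = FALSE)
        out[[i]] <- sort(hit)
      } else {
        out[[i]] <- integer(0)
      }
    }
  }
  structure(list(neighbors = out, probe = probe), class = "neighbor_index")
}

#' @export
print.neighbor_index <- function(x, ...) {
  cat(sprintf("Neighbour index: %d atoms, %d overlapping pairs\n",
              length(x$neighbors),
              sum(lengths(x$neighbors)) %/% 2L))
  invisible(x)
}
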