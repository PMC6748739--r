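#' Load a van der Waals radius table
#'
#' Two tables ship with the package as versioned plain-text files under
#' `inst/extdata/radii/`:
#' \describe{
#'   \item{`"pdb-united"`}{United-atom heavy-atom radii for PDB input, keyed
#'     by `"RESNAME ATOMNAME"`, following the Chothia (1976) set used by
#'     NACCESS (trigonal/aromatic C 1.76, tetrahedral C 1.87, N 1.65,
#'     O 1.40, S 1.85 A).  Hydrogens are implicit in the heavy-atom radii.}
#'   \item{`"mol2-typed"`}{Fine-grained radii keyed by SYBYL atom type for
#'     Tripos Mol2 input, following Tsai et al. (1999) as used by UCSF
#'     Chimera.}
#' }
#' Table files are tab-separated `key<TAB>radius` lines; `#` starts a
#' comment, keys of the form `=EL` are element-level fallbacks, and the key
#' `*` sets the global fallback radius.  A custom table in the same format
#' can be supplied via `path` (and, on the command line, `--radii`).
#'
#' @param name `"pdb-united"` or `"mol2-typed"`.
#' @param path Optional path to a custom table file; overrides `name`'s
#'   shipped file but keeps `name` as the lookup dialect.
#' @return An object of class `"radii_table"`: list with `name`, `entries`
#'   (named numeric vector, Angstrom), and `fallback_radius`.
#' @export
radii_table <- function(name = c("pdb-united", "mol2-typed"), path = NULL) {
  name <- match.arg(name)
  if (is.null(path)) {
    file <- c("pdb-united" = "pdb_united.tsv",
              "mol2-typed" = "mol2_typed.tsv")[[name]]
    path <- system.file("extdata", "radii", file, package = "contactarea",
                        mustWork = TRUE)
  }
  if (!file.exists(path))
    stop("radius table file not found: ", path, call. = FALSE)
  ln <- readLines(path, warn = FALSE)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad))
    stop("malformed radius table line: ", ln[which(bad)[1L]], call. = FALSE)
  keys <- vapply(parts, `[[`, "", 1L)
  vals <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(vals) || any(vals <= 0.2) || any(vals >= 3.5))
    stop("radius table values must be numbers in (0.2, 3.5) Angstrom",
         call. = FALSE)
  fb <- if ("*" %in% keys) vals[match("*", keys)] else 1.70
  keep <- keys != "*"
  structure(list(name = name,
                 entries = setNames(vals[keep], keys[keep]),
                 fallback_radius = fb),
            class = "radii_table")
}

#' @export
print.radii_table <- function(x, ...) {
  cat(sprintf("vdW radius table '%s': %d entries, fallback %.2f A\n",
              x$name, length(x$entries), x$fallback_radius))
  invisible(x)
}

#' Assign van der Waals radii to atoms
#'
#' Fills the `radius` column of an atom table.  For the `"pdb-united"`
#' table the lookup key is `"RESNAME ATOMNAME"` with an element-level
#' fallback (`=EL` entries); for the `"mol2-typed"` table the key is the
#' SYBYL atom type (column `sybyl`) with the same element fallback.  Keys
#' absent from the table resolve to the table's global fallback radius and
#' a single warning lists the unknown keys.  The probe radius is validated
#' and stored as the `"probe"` attribute of the returned atom table; it is
#' never added to the stored vdW radii — expansion by the probe happens at
#' sampling time.
#'
#' @param atoms Atom `data.frame` (see [read_structure()]).
#' @param table A [radii_table()]; default chosen from `atoms`' source
#'   format attribute, else `"pdb-united"`.
#' @param probe Probe sphere radius in Angstrom, `>= 0`; default 1.4
#'   (water).
#' @param quiet Suppress the unknown-key warning.
#' @return `atoms` with a populated numeric `radius` column (Angstrom) and
#'   attribute `probe`.
#' @export
assign_radii <- function(atoms, table = NULL, probe = 1.4, quiet = FALSE) {
  stopifnot(is.data.frame(atoms))
  if (!is.numeric(probe) || length(probe) != 1L || !is.finite(probe) ||
      probe < 0)
    stop("`probe` must be a single number >= 0 (Angstrom)", call. = FALSE)
  if (is.null(table)) {
    fmt <- attr(atoms, "format")
    table <- radii_table(if (identical(fmt, "mol2")) "mol2-typed"
                         else "pdb-united")
  }
  stopifnot(inherits(table, "radii_table"))
  n <- nrow(atoms)
  if (n == 0L) {
    atoms$radius <- numeric(0)
    attr(atoms, "probe") <- probe
    return(atoms)
  }
  if (identical(table$name, "mol2-typed") && !is.null(atoms$sybyl)) {
    key1 <- atoms$sybyl
  } else {
    key1 <- paste(atoms$resname, atoms$name)
  }
  r <- unname(table$entries[key1])
  miss1 <- is.na(r)
  if (any(miss1)) {
    ekey <- paste0("=", toupper(atoms$element[miss1]))
    r[miss1] <- unname(table$entries[ekey])
  }
  miss2 <- is.na(r)
  if (any(miss2)) {
    r[miss2] <- table$fallback_radius
    if (!quiet)
      warning("no vdW radius for ", sum(miss2), " atom(s); fallback ",
              sprintf("%.2f", table$fallback_radius), " A used for key(s): ",
              paste(unique(key1[miss2]), collapse = ", "), call. = FALSE)
  }
  atoms$radius <- r
  attr(atoms, "probe") <- probe
  atoms
}
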