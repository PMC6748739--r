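.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")
.NUC <- c("A", "C", "G", "T", "U", "I", "DA", "DC", "DG", "DT", "DU", "DI")
.WATER <- c("HOH", "WAT", "DOD", "H2O", "SOL", "TIP3", "TIP4")

#' Atom and residue labels
#'
#' Canonical labels used for matrix dimnames and TSV files:
#' `"chain/resname resnum[icode]/atomname"` at atom granularity and
#' `"chain/resname resnum[icode]"` at residue granularity.
#'
#' @param atoms Atom table.
#' @return Character vector of labels, one per atom.
#' @export
atom_label <- function(atoms) {
  paste0(residue_label(atoms), "/", atoms$name)
}

#' @rdname atom_label
#' @export
residue_label <- function(atoms) {
  ic <- atoms$inscode
  if (is.null(ic)) ic <- ""
  ic[is.na(ic)] <- ""
  paste0(atoms$chain, "/", atoms$resname, " ", atoms$resno, ic)
}

# Element symbol from a PDB atom name when the element column is absent.
.element_from_name <- function(name, hetero) {
  nm <- toupper(gsub("[^A-Za-z]", "", sub("^[0-9]+", "", name)))
  el <- substr(nm, 1L, 1L)
  two <- substr(nm, 1L, 2L)
  known2 <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE", "CU", "NI",
              "CO", "CD", "HG", "LI", "AL", "SI")
  # HETATM names matching a two-letter element (or CA/K as ions) are taken
  # as that element; in ATOM records CA/CD/... are carbons, HG mercuryless.
  el[hetero & two %in% c(known2, "CA")] <- two[hetero & two %in%
                                                 c(known2, "CA")]
  el[!hetero & two %in% known2 & el %in% c("C", "N", "O", "S", "H")] <-
    el[!hetero & two %in% known2 & el %in% c("C", "N", "O", "S", "H")]
  el
}

#' Read a molecular structure from PDB or Mol2
#'
#' PDB files are parsed with fixed-column semantics (via \pkg{bio3d});
#' Tripos Mol2 files with a section parser for `@<TRIPOS>MOLECULE` /
#' `ATOM`.  For multi-model PDB files only model 1 is used (with a
#' warning).  Alternate locations keep the highest-occupancy record (first
#' record on ties).  Waters are excluded by default; hydrogens are excluded
#' by default for PDB input (united-atom radii make them implicit) and kept
#' by default for Mol2 input.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mol2"`.
#' @param keep_waters Keep water residues (default `FALSE`).
#' @param keep_hydrogens Keep hydrogen/deuterium atoms; default `FALSE`
#'   for PDB, `TRUE` for Mol2.
#' @return Object of class `"mol_structure"`: list with `atoms` (ordered
#'   `data.frame`: `serial`, `name`, `element`, `resname`, `chain`,
#'   `resno`, `inscode`, `x`, `y`, `z`, `occupancy`, `altloc`, `hetero`,
#'   and for Mol2 `sybyl`), `format`, `source`, and `objects` (`NULL`
#'   until [detect_objects()]).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mol2"),
                           keep_waters = FALSE, keep_hydrogens = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "mol2") "mol2" else "pdb"
  }
  if (is.null(keep_hydrogens)) keep_hydrogens <- format == "mol2"
  atoms <- if (format == "pdb") .read_pdb_atoms(path)
           else .read_mol2_atoms(path)
  if (nrow(atoms) == 0L)
    stop("no atoms parsed from ", path, call. = FALSE)
  # altloc resolution: highest occupancy wins, first record on ties
  if (any(atoms$altloc != "")) {
    grp <- paste(atoms$chain, atoms$resno, atoms$inscode, atoms$resname,
                 atoms$name)
    ord <- order(grp, -atoms$occupancy, seq_len(nrow(atoms)))
    keep <- !duplicated(grp[ord])
    atoms <- atoms[sort(ord[keep]), , drop = FALSE]
  }
  if (!keep_waters) atoms <- atoms[!(atoms$resname %in% .WATER), ,
                                   drop = FALSE]
  if (!keep_hydrogens) atoms <- atoms[!(toupper(atoms$element) %in%
                                          c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("structure is empty after filtering: ", path, call. = FALSE)
  rownames(atoms) <- NULL
  attr(atoms, "format") <- format
  structure(list(atoms = atoms, format = format, source = path,
                 objects = NULL),
            class = "mol_structure")
}

.read_pdb_atoms <- function(path) {
  nmodel <- sum(grepl("^MODEL ", readLines(path, warn = FALSE)))
  if (nmodel > 1L)
    warning("multi-model PDB: using model 1 of ", nmodel, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  hetero <- a$type == "HETATM"
  el <- a$elesy
  if (is.null(el)) el <- rep(NA_character_, nrow(a))
  el <- toupper(trimws(el))
  bad <- is.na(el) | el == ""
  if (any(bad))
    el[bad] <- .element_from_name(a$elety[bad], hetero[bad])
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- " "
  ins <- a$insert
  ins[is.na(ins)] <- ""
  alt <- a$alt
  alt[is.na(alt)] <- ""
  occ <- a$o
  occ[is.na(occ)] <- 1
  data.frame(serial = a$eleno, name = trimws(a$elety), element = el,
             resname = trimws(a$resid), chain = chain, resno = a$resno,
             inscode = ins, x = a$x, y = a$y, z = a$z,
             occupancy = occ, altloc = alt, hetero = hetero,
             stringsAsFactors = FALSE)
}

.read_mol2_atoms <- function(path) {
  ln <- readLines(path, warn = FALSE)
  sec <- grep("^@<TRIPOS>", ln)
  if (!length(sec))
    stop("not a Tripos Mol2 file (no @<TRIPOS> sections): ", path,
         call. = FALSE)
  astart <- grep("^@<TRIPOS>ATOM\\s*$", ln)
  if (!length(astart))
    stop("Mol2 file has no @<TRIPOS>ATOM section: ", path, call. = FALSE)
  astart <- astart[1L]
  aend <- sec[sec > astart]
  aend <- if (length(aend)) min(aend) - 1L else length(ln)
  body <- ln[(astart + 1L):aend]
  body_no <- (astart + 1L):aend
  keep <- !grepl("^\\s*(#|$)", body)
  body <- body[keep]; body_no <- body_no[keep]
  rows <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(rows) < 6L)
  if (length(bad))
    stop("malformed Mol2 ATOM record at line ", body_no[bad[1L]], ": ",
         body[bad[1L]], call. = FALSE)
  g <- function(k, default = NA_character_)
    vapply(rows, function(r) if (length(r) >= k) r[[k]] else default, "")
  xyz <- suppressWarnings(cbind(as.numeric(g(3L)), as.numeric(g(4L)),
                                as.numeric(g(5L))))
  if (anyNA(xyz))
    stop("non-numeric coordinates in Mol2 ATOM record at line ",
         body_no[which(is.na(rowSums(xyz)))[1L]], call. = FALSE)
  sybyl <- g(6L)
  subst_id <- suppressWarnings(as.integer(g(7L, "1")))
  subst_id[is.na(subst_id)] <- 1L
  subst_nm <- g(8L, "MOL")
  subst_nm[is.na(subst_nm)] <- "MOL"
  resname <- toupper(sub("[0-9]+$", "", subst_nm))
  resname[resname == ""] <- "MOL"
  data.frame(serial = as.integer(g(1L)), name = g(2L),
             element = toupper(sub("\\..*$", "", sybyl)),
             resname = resname, chain = "A", resno = subst_id,
             inscode = "", x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             occupancy = 1, altloc = "", hetero = !(resname %in% .AA3),
             sybyl = sybyl, stringsAsFactors = FALSE)
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf("Molecular structure (%s): %d atoms", x$format,
              nrow(x$atoms)))
  if (!is.null(x$objects))
    cat(sprintf(", %d object(s): %s", nrow(x$objects),
                paste(x$objects$label, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Partition a structure into molecular objects
#'
#' With an explicit `selection` (a list of chain-id vectors, one element
#' per object) the objects are exactly those chain groups and atoms
#' outside every selection are dropped.  Without a selection, objects are
#' detected automatically by molecule class: residues are classified as
#' protein, nucleic acid (standard residue-name dictionaries) or ligand
#' (anything else, including non-water HETATM), and each class present
#' becomes one object.  The result is a partition: every retained atom
#' belongs to exactly one object.
#'
#' @param structure A [read_structure()] result (or toy system).
#' @param selection Optional list of character vectors of chain ids, e.g.
#'   `list(c("A", "B"), "C")`.
#' @return The structure with `atoms$object` filled and an `objects`
#'   data.frame (`id`, `label`, `class`).
#' @export
detect_objects <- function(structure, selection = NULL) {
  stopifnot(inherits(structure, "mol_structure"))
  atoms <- structure$atoms
  if (!is.null(selection)) {
    if (!is.list(selection)) selection <- list(selection)
    missing <- setdiff(unlist(selection), unique(atoms$chain))
    if (length(missing))
      stop("selection names chain(s) absent from the structure: ",
           paste(missing, collapse = ", "), call. = FALSE)
    dup <- unlist(selection)[duplicated(unlist(selection))]
    if (length(dup))
      stop("chain(s) assigned to more than one object: ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
    obj <- rep(NA_integer_, nrow(atoms))
    for (k in seq_along(selection))
      obj[atoms$chain %in% selection[[k]]] <- k
    keep <- !is.na(obj)
    atoms <- atoms[keep, , drop = FALSE]
    atoms$object <- obj[keep]
    objects <- data.frame(
      id = seq_along(selection),
      label = vapply(selection, paste, "", collapse = ","),
      class = "selection", stringsAsFactors = FALSE)
  } else {
    cls <- ifelse(atoms$resname %in% .AA3, "protein",
           ifelse(atoms$resname %in% .NUC, "nucleic", "ligand"))
    present <- unique(cls)
    atoms$object <- match(cls, present)
    objects <- data.frame(id = seq_along(present), label = present,
                          class = present, stringsAsFactors = FALSE)
  }
  rownames(atoms) <- NULL
  attr(atoms, "format") <- structure$format
  structure$atoms <- atoms
  structure$objects <- objects
  structure
}

#' Write a PDB file with per-atom values in the B-factor column
#'
#' Standard fixed-column ATOM/HETATM records; the value is formatted into
#' the 6-character B-factor field with two decimals.  Values above 999.99
#' are capped at 999.99 with a warning (field width).
#'
#' @param structure A `mol_structure` (or atom table).
#' @param values Numeric vector, one value per atom.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb_bfactor <- function(structure, values, path) {
  atoms <- if (inherits(structure, "mol_structure")) structure$atoms
           else structure
  stopifnot(is.data.frame(atoms))
  if (length(values) != nrow(atoms))
    stop("need exactly one value per atom (", nrow(atoms), " atoms, ",
         length(values), " values)", call. = FALSE)
  if (any(values > 999.99)) {
    warning(sum(values > 999.99),
            " value(s) exceed 999.99 and were capped (B-factor field ",
            "width)", call. = FALSE)
    values <- pmin(values, 999.99)
  }
  nm <- atoms$name
  # standard PDB name alignment: <4-char names start in column 14
  nm <- ifelse(nchar(nm) < 4L, sprintf(" %-3s", nm), sprintf("%-4s", nm))
  rec <- ifelse(atoms$hetero, "HETATM", "ATOM  ")
  el <- substr(toupper(atoms$element), 1L, 2L)
  lines <- sprintf(
    "%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, atoms$serial %% 100000L, nm, substr(atoms$altloc, 1L, 1L),
    atoms$resname, substr(atoms$chain, 1L, 1L), atoms$resno %% 10000L,
    substr(atoms$inscode, 1L, 1L), atoms$x, atoms$y, atoms$z,
    atoms$occupancy, values, el)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write / read a contact matrix as tab-separated values
#'
#' First row: column labels (leading empty cell); first column: row
#' labels; numeric cells with four decimal places (below sampling noise,
#' keeps files diffable).  Row/column order follows the matrix, i.e. file
#' order of the atoms, so identical runs produce byte-identical files.
#'
#' @param mat Matrix with dimnames (atom or residue labels).
#' @param path Output (input) file.
#' @param header Optional character vector written as leading `# ` comment
#'   lines (run-log header); comment lines are skipped on read.
#' @return `path` invisibly; `read_matrix_tsv()` returns the matrix.
#' @export
write_matrix_tsv <- function(mat, path, header = character(0)) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- paste(c("", colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(rownames(mat)[i], sprintf("%.4f", mat[i, ])), collapse = "\t"),
    "")
  if (length(header)) header <- paste0("# ", header)
  writeLines(c(header, hdr, body), con, sep = "\n")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path))
    stop("TSV file not found: ", path, call. = FALSE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 2L)
    stop("malformed matrix TSV (need row labels plus one column): ", path,
         call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("malformed matrix TSV (non-numeric cells): ", path, call. = FALSE)
  rownames(m) <- as.character(df[[1L]])
  m
}
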