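#' Construct a structure from an atom table
#'
#' The package's coordinate model: an ordered atom table plus an optional
#' crystallographic unit cell. Residues are identified by author numbering
#' (`chain`, `res_seq`, insertion code), 1-based, and residue groups are kept
#' contiguous in atom order.
#'
#' @param atoms data.frame with columns `chain`, `res_seq`, `ins`, `res_name`,
#'   `atom_name`, `element`, `x`, `y`, `z`, `occupancy`, `b`, `is_hetero`.
#'   Missing bookkeeping columns are filled with defaults.
#' @param cell optional length-6 unit cell (a, b, c in angstrom; alpha, beta,
#'   gamma in degrees).
#' @param id text label for the structure.
#' @return An object of class `fts_structure`.
#' @export
fts_structure <- function(atoms, cell = NULL, id = "structure") {
  atoms <- as.data.frame(atoms)
  need <- c("chain", "res_seq", "res_name", "atom_name", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"ins" %in% names(atoms)) atoms$ins <- ""
  if (!"element" %in% names(atoms)) atoms$element <- guess_element(atoms$atom_name)
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"b" %in% names(atoms)) atoms$b <- 0
  if (!"is_hetero" %in% names(atoms)) atoms$is_hetero <- FALSE
  atoms$ins[is.na(atoms$ins)] <- ""
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("atom coordinates must be finite")
  if (any(!nzchar(atoms$atom_name))) stop("atom names must be nonempty")
  if (!is.null(cell)) {
    cell <- as.numeric(cell)
    if (length(cell) != 6L) stop("'cell' must have 6 values (lengths + angles)")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, cell = cell, id = id), class = "fts_structure")
}

# crude element guess from the atom name (first alphabetic character run,
# honouring two-letter elements present in protein/nucleotide structures)
guess_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9 ]+", "", atom_name))
  two <- toupper(substr(nm, 1, 2))
  out <- toupper(substr(nm, 1, 1))
  known2 <- c("MG", "MN", "ZN", "FE", "CA", "NA", "CL", "SE")
  # only promote to a 2-letter element for non-standard names like "MG"
  out[two %in% known2 & nchar(nm) == 2] <- two[two %in% known2 & nchar(nm) == 2]
  out
}

#' Read a structure from a PDB or mmCIF file
#'
#' Parsing is delegated to bio3d; the unit cell (CRYST1 / `_cell`) is captured
#' when present. Alternate locations are resolved to the highest-occupancy
#' conformer, ties broken in favour of altloc "A". Atoms are kept in file
#' order; HETATM records are retained (see [select_atoms()]).
#'
#' @param path file path.
#' @param format "auto" (by extension), "pdb" or "cif".
#' @param id label for the structure; defaults to the file base name.
#' @return An [fts_structure()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty model in ", path)
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    res_seq = as.integer(at$resno),
    ins = ifelse(is.na(at$insert), "", at$insert),
    res_name = at$resid,
    atom_name = at$elety,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    element = if ("elesy" %in% names(at)) ifelse(is.na(at$elesy) | at$elesy == "",
                                                 guess_element(at$elety),
                                                 toupper(at$elesy))
              else guess_element(at$elety),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms <- resolve_altloc(atoms)
  atoms$altloc <- NULL
  cell <- read_cell(path, format)
  if (is.null(id)) id <- sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  fts_structure(atoms, cell = cell, id = id)
}

# altloc policy: per (chain, res_seq, ins, atom_name) keep the
# highest-occupancy record; ties go to altloc "A" (then alphabetical).
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$res_seq, atoms$ins, atoms$atom_name, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  alt_rank <- ifelse(atoms$altloc == "", 0L, match(atoms$altloc, c("A", LETTERS[-1]), nomatch = 99L))
  ord <- order(key, -atoms$occupancy, alt_rank)
  keep <- !duplicated(key[ord])
  sel <- sort(ord[keep])  # restore file order
  atoms[sel, , drop = FALSE]
}

read_cell <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") {
    cl <- grep("^CRYST1", lines, value = TRUE)
    if (!length(cl)) return(NULL)
    f <- cl[1]
    vals <- suppressWarnings(as.numeric(c(
      substr(f, 7, 15), substr(f, 16, 24), substr(f, 25, 33),
      substr(f, 34, 40), substr(f, 41, 47), substr(f, 48, 54))))
    if (any(is.na(vals))) return(NULL)
    return(vals)
  }
  tags <- c("_cell.length_a", "_cell.length_b", "_cell.length_c",
            "_cell.angle_alpha", "_cell.angle_beta", "_cell.angle_gamma")
  vals <- vapply(tags, function(tg) {
    ln <- grep(paste0("^", tg, "\\s"), lines, value = TRUE)
    if (!length(ln)) return(NA_real_)
    suppressWarnings(as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]][2]))
  }, numeric(1))
  if (any(is.na(vals))) NULL else unname(vals)
}

#' Write a structure to a PDB file
#'
#' Emits ATOM/HETATM records (and a CRYST1 record when the structure carries
#' a unit cell) via the bio3d writer. Coordinates are written at the PDB
#' format's 3-decimal precision.
#'
#' @param structure an [fts_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "fts_structure"))
  a <- structure$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$is_hetero, "HETATM", "ATOM"),
    resno = a$res_seq, resid = a$res_name,
    eleno = seq_len(nrow(a)), elety = a$atom_name,
    chain = a$chain, insert = ifelse(a$ins == "", NA, a$ins),
    o = a$occupancy, b = a$b, elesy = a$element
  )
  if (!is.null(structure$cell)) {
    cl <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                  structure$cell[1], structure$cell[2], structure$cell[3],
                  structure$cell[4], structure$cell[5], structure$cell[6])
    body <- readLines(path, warn = FALSE)
    writeLines(c(cl, body), path)
  }
  invisible(path)
}

#' Subset a structure
#'
#' Order-preserving selection by chain, author residue interval and atom
#' name. An empty result is valid. HETATM records are kept unless
#' `hetero = FALSE`; pass `hetero = TRUE` to keep only heteroatoms.
#'
#' @param structure an [fts_structure()].
#' @param chain chain identifier(s), or `NULL` for all.
#' @param residues inclusive residue interval `c(lo, hi)` or an explicit
#'   vector of residue numbers, or `NULL` for all.
#' @param atom_names atom name(s) such as `"CA"`, or `NULL` for all.
#' @param hetero `NA` (keep all, default), `FALSE` (drop HETATM) or `TRUE`
#'   (HETATM only).
#' @return An [fts_structure()].
#' @export
select_atoms <- function(structure, chain = NULL, residues = NULL,
                         atom_names = NULL, hetero = NA) {
  stopifnot(inherits(structure, "fts_structure"))
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(residues)) {
    res <- if (length(residues) == 2L) seq(residues[1], residues[2]) else residues
    keep <- keep & a$res_seq %in% res
  }
  if (!is.null(atom_names)) keep <- keep & a$atom_name %in% atom_names
  if (!is.na(hetero)) keep <- keep & (a$is_hetero == hetero)
  fts_structure(a[keep, , drop = FALSE], cell = structure$cell, id = structure$id)
}

#' Apply a rigid transform to all atoms
#'
#' @param structure an [fts_structure()].
#' @param tf a [rigid_transform()].
#' @return The transformed [fts_structure()]; all metadata preserved.
#' @export
apply_transform <- function(structure, tf) {
  stopifnot(inherits(structure, "fts_structure"))
  if (!inherits(tf, "rigid_transform")) stop("'tf' must be a rigid_transform")
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(tf$rotation)
  a$x <- xyz[, 1] + tf$translation[1]
  a$y <- xyz[, 2] + tf$translation[2]
  a$z <- xyz[, 3] + tf$translation[3]
  fts_structure(a, cell = structure$cell, id = structure$id)
}

#' Coordinates as a matrix
#'
#' @param structure an [fts_structure()].
#' @return n x 3 numeric matrix of coordinates.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Calpha records of a structure
#'
#' Non-hetero CA atoms, optionally restricted by chain; one row per residue
#' in atom order. Residues without a CA atom are absent (dropped from all
#' downstream pairing; no interpolation).
#'
#' @param structure an [fts_structure()].
#' @param chain chain id or `NULL`.
#' @return data.frame of CA atom rows.
#' @export
ca_records <- function(structure, chain = NULL) {
  s <- select_atoms(structure, chain = chain, atom_names = "CA", hetero = FALSE)
  s$atoms
}

#' One-letter sequence from Calpha records
#'
#' @param structure an [fts_structure()].
#' @param chain chain id or `NULL`.
#' @return Single string of one-letter codes ("X" for non-standard residues).
#' @export
ca_sequence <- function(structure, chain = NULL) {
  ca <- ca_records(structure, chain)
  if (nrow(ca) == 0L) return("")
  paste(bio3d::aa321(ca$res_name), collapse = "")
}

#' Merge structures into one (for complexes)
#'
#' Concatenates atom tables; chains may be relabelled first via `chains` to
#' avoid collisions.
#'
#' @param ... [fts_structure()] objects.
#' @param chains optional character vector, one chain label per structure.
#' @param id label of the merged structure.
#' @return An [fts_structure()].
#' @export
merge_structures <- function(..., chains = NULL, id = "complex") {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "fts_structure")) xs <- xs[[1]]
  stopifnot(all(vapply(xs, inherits, logical(1), "fts_structure")))
  tabs <- lapply(seq_along(xs), function(i) {
    a <- xs[[i]]$atoms
    if (!is.null(chains)) a$chain <- chains[i]
    a
  })
  fts_structure(do.call(rbind, tabs), cell = xs[[1]]$cell, id = id)
}

#' Number of residues in a structure
#'
#' Distinct (chain, res_seq, ins) groups among non-hetero atoms.
#' @param structure an [fts_structure()].
#' @return Integer count.
#' @export
n_residues <- function(structure) {
  a <- structure$atoms[!structure$atoms$is_hetero, , drop = FALSE]
  length(unique(paste(a$chain, a$res_seq, a$ins, sep = "\r")))
}

#' @export
print.fts_structure <- function(x, ...) {
  cat(sprintf("<fts_structure '%s'> %d atoms, %d residues, chains: %s%s\n",
              x$id, nrow(x$atoms), n_residues(x),
              paste(unique(x$atoms$chain), collapse = ","),
              if (is.null(x$cell)) "" else sprintf(", cell a=%.1f b=%.1f c=%.1f",
                                                   x$cell[1], x$cell[2], x$cell[3])))
  invisible(x)
}
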