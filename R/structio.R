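#' Atomic structure container
#'
#' An ordered set of atom records with named atom-index selections
#' ("labels") and optional free-form metadata (`info`). Coordinates are in
#' Angstrom throughout the package; no other unit appears anywhere.
#'
#' @param atoms data.frame with columns `serial` (integer), `chain`
#'   (character), `resno` (integer), `resid` (character residue name),
#'   `elety` (atom name), `element` (element symbol), `x`, `y`, `z`
#'   (numeric, Angstrom).
#' @param labels named list of integer vectors; each entry is a selection of
#'   atom row indices.
#' @param info named list of metadata (e.g. recorded symmetry axes,
#'   topology); carried along by rigid-body transforms where geometric.
#' @return An object of class `saxs_structure`.
#' @export
saxs_structure <- function(atoms, labels = list(), info = list()) {
  required <- c("serial", "chain", "resno", "resid", "elety", "element",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stopf("atoms is missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[required]
  atoms$serial <- as.integer(atoms$serial)
  atoms$resno <- as.integer(atoms$resno)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stopf("all coordinates must be finite")
  if (anyDuplicated(atoms$serial)) stopf("atom serial numbers must be unique")
  n <- nrow(atoms)
  for (nm in names(labels)) {
    idx <- labels[[nm]]
    if (length(idx) && (min(idx) < 1L || max(idx) > n)) {
      stopf("label '%s' refers to atom indices outside 1..%d", nm, n)
    }
    labels[[nm]] <- as.integer(idx)
  }
  structure(list(atoms = atoms, labels = labels, info = info),
            class = "saxs_structure")
}

#' @export
print.saxs_structure <- function(x, ...) {
  cat(sprintf("<saxs_structure> %d atoms, %d chains, %d labels\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              length(x$labels)))
  if (length(x$labels)) {
    cat("  labels:", paste(names(x$labels), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `saxs_structure`
#' @return integer atom count
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Coordinate matrix of a structure
#'
#' @param s a `saxs_structure`
#' @param idx optional atom indices (or a label name) to subset
#' @return N x 3 numeric matrix in Angstrom
#' @export
coords <- function(s, idx = NULL) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  if (is.null(idx)) return(m)
  if (is.character(idx)) idx <- label_indices(s, idx)
  m[idx, , drop = FALSE]
}

#' Replace the coordinates of a structure
#' @param s a `saxs_structure`
#' @param xyz N x 3 matrix matching `n_atoms(s)`
#' @return the structure with new coordinates
#' @export
set_coords <- function(s, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(s$atoms) || ncol(xyz) != 3) {
    stopf("coordinate matrix must be %d x 3", nrow(s$atoms))
  }
  if (!all(is.finite(xyz))) stopf("all coordinates must be finite")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Resolve a label to atom indices
#' @param s a `saxs_structure`
#' @param name label name
#' @return integer vector of atom indices
#' @export
label_indices <- function(s, name) {
  if (!name %in% names(s$labels)) stopf("no label '%s' in structure", name)
  s$labels[[name]]
}

#' Resolve a (chain, residue-range) rule to atom indices
#'
#' Regions are identified by residue number within a chain, the way antibody
#' domains are specified (e.g. heavy-chain residues 1-211).
#'
#' @param s a `saxs_structure`
#' @param chain chain identifier
#' @param resno_range length-2 integer vector, inclusive
#' @return integer vector of atom indices
#' @export
select_residues <- function(s, chain, resno_range) {
  which(s$atoms$chain == chain &
        s$atoms$resno >= resno_range[1] & s$atoms$resno <= resno_range[2])
}

#' Extract a sub-structure by atom indices
#'
#' Labels are re-indexed; labels that lose all atoms are dropped.
#'
#' @param s a `saxs_structure`
#' @param idx atom indices (or a label name)
#' @return a `saxs_structure` containing only the selected atoms, in order
#' @export
extract_structure <- function(s, idx) {
  if (is.character(idx)) idx <- label_indices(s, idx)
  idx <- sort(unique(as.integer(idx)))
  map <- integer(nrow(s$atoms)); map[idx] <- seq_along(idx)
  labels <- list()
  for (nm in names(s$labels)) {
    kept <- map[intersect(s$labels[[nm]], idx)]
    if (length(kept)) labels[[nm]] <- sort(kept)
  }
  saxs_structure(s$atoms[idx, , drop = FALSE], labels, s$info)
}

#' Concatenate structures into one, with per-unit label prefixes
#'
#' Chains are re-lettered to stay unique, serials renumbered, and every
#' label of unit `u` re-emitted as `<name_u>.<label>`. A plain `<name_u>`
#' label covering each whole unit is added. Geometric metadata (recorded
#' symmetry axes) is namespaced the same way.
#'
#' @param units named list of `saxs_structure` objects
#' @return combined `saxs_structure`
#' @export
combine_structures <- function(units) {
  if (is.null(names(units)) || any(!nzchar(names(units)))) {
    stopf("units must be a fully named list")
  }
  chain_pool <- c(LETTERS, letters, as.character(0:9))
  atoms_list <- list()
  labels <- list()
  info <- list()
  offset <- 0L
  chain_next <- 1L
  for (u in names(units)) {
    s <- units[[u]]
    at <- s$atoms
    old_chains <- unique(at$chain)
    if (chain_next + length(old_chains) - 1L > length(chain_pool)) {
      stopf("too many chains to re-letter")
    }
    new_chains <- chain_pool[chain_next:(chain_next + length(old_chains) - 1L)]
    chain_next <- chain_next + length(old_chains)
    at$chain <- new_chains[match(at$chain, old_chains)]
    atoms_list[[u]] <- at
    labels[[u]] <- offset + seq_len(nrow(at))
    for (nm in names(s$labels)) {
      labels[[paste0(u, ".", nm)]] <- offset + s$labels[[nm]]
    }
    for (nm in names(s$info)) {
      info[[paste0(u, ".", nm)]] <- s$info[[nm]]
    }
    offset <- offset + nrow(at)
  }
  atoms <- do.call(rbind, c(atoms_list, list(make.row.names = FALSE)))
  atoms$serial <- seq_len(nrow(atoms))
  saxs_structure(atoms, labels, info)
}

# ---- PDB I/O (fixed-column v3.3) -------------------------------------------

#' Read a PDB file
#'
#' Parses ATOM/HETATM records from fixed PDB v3.3 columns. The element is
#' taken from columns 77-78 when present, otherwise inferred from the atom
#' name. Only the first alternate location is kept (with a warning). MODEL
#' records beyond the first terminate parsing.
#'
#' @param path file path
#' @return a `saxs_structure`
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  lines <- readLines(path, warn = FALSE)
  first_model_end <- which(startsWith(lines, "ENDMDL"))
  if (length(first_model_end)) lines <- lines[seq_len(first_model_end[1] - 1L)]
  rec <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  if (!length(rec)) stopf("no ATOM/HETATM records in '%s'", path)
  altloc <- substr(rec, 17, 17)
  if (any(!altloc %in% c(" ", "A", ""))) {
    warning("alternate locations present; keeping first altloc only")
  }
  keep <- altloc %in% c(" ", "A", "")
  rec <- rec[keep]
  fldk <- function(a, b) trimws(substr(rec, a, b))
  elety <- fldk(13, 16)
  element <- fldk(77, 78)
  infer <- !nzchar(element)
  if (any(infer)) {
    # first alphabetic character of the atom name, standard PDB heuristic
    element[infer] <- toupper(sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1",
                                  elety[infer]))
  }
  atoms <- data.frame(
    serial = as.integer(fldk(7, 11)),
    chain = substr(rec, 22, 22),
    resno = as.integer(fldk(23, 26)),
    resid = fldk(18, 20),
    elety = elety,
    element = element,
    x = as.numeric(fldk(31, 38)),
    y = as.numeric(fldk(39, 46)),
    z = as.numeric(fldk(47, 54)),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
    stopf("malformed coordinate fields in '%s'", path)
  }
  if (anyDuplicated(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  saxs_structure(atoms)
}

#' Write a PDB file
#'
#' Fixed-column PDB v3.3 ATOM records, TER between chains, END at the end.
#' Serial numbers above 99999 wrap modulo 100000 (toy structures never reach
#' the limit; on re-reading, duplicate serials are renumbered sequentially).
#'
#' @param s a `saxs_structure`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_structure <- function(s, path) {
  at <- s$atoms
  serial <- ((seq_len(nrow(at)) - 1L) %% 99999L) + 1L
  name4 <- ifelse(nchar(at$elety) < 4 & nchar(at$element) == 1,
                  sprintf(" %-3s", at$elety), sprintf("%-4s", at$elety))
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    serial, name4, substr(at$resid, 1, 3), at$chain, at$resno %% 10000L,
    at$x, at$y, at$z, 1, 0, at$element)
  ter_after <- which(at$chain != c(at$chain[-1], NA_character_))
  out <- character(0)
  prev <- 1L
  breaks <- c(ter_after, nrow(at))
  for (b in unique(breaks)) {
    out <- c(out, lines[prev:b], "TER")
    prev <- b + 1L
  }
  out <- c(out, "END")
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot write '%s': %s", path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

# ---- Scattering profile I/O -------------------------------------------------

#' One-dimensional scattering profile
#'
#' @param q momentum transfer grid, strictly increasing, Angstrom^-1
#' @param intensity positive intensities (arbitrary units)
#' @param sigma optional per-point uncertainties, positive, same length
#' @return an object of class `saxs_profile`
#' @export
saxs_profile <- function(q, intensity, sigma = NULL) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity)) stopf("q and intensity lengths differ")
  if (any(!is.finite(q)) || any(!is.finite(intensity))) {
    stopf("q and intensity must be finite")
  }
  if (any(diff(q) <= 0)) stopf("q grid must be strictly increasing")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stopf("sigma length differs from q")
    if (any(!is.finite(sigma)) || any(sigma <= 0)) {
      stopf("sigma must be positive and finite")
    }
  }
  structure(list(q = q, intensity = intensity, sigma = sigma),
            class = "saxs_profile")
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("<saxs_profile> %d points, Q in [%.4g, %.4g] A^-1, sigma %s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "absent" else "present"))
  invisible(x)
}

#' Read a scattering profile from whitespace-delimited text
#'
#' The de-facto SAXS `.dat` dialect: 2 or 3 numeric columns (Q, I, optional
#' sigma), `#` comment lines allowed anywhere. Rows with non-numeric fields
#' are skipped with a warning.
#'
#' @param path file path
#' @return a `saxs_profile`; sigma is `NULL` for 2-column input
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[ \t]+")
  rows <- lapply(toks, function(tk) suppressWarnings(as.numeric(tk)))
  ncols <- vapply(rows, length, 1L)
  ok <- vapply(rows, function(r) length(r) >= 2 && !anyNA(r[1:min(3, length(r))]),
               logical(1))
  if (any(!ok)) {
    warning(sprintf("skipped %d non-numeric row(s) in '%s'", sum(!ok), path))
  }
  rows <- rows[ok]; ncols <- ncols[ok]
  if (length(rows) < 2) stopf("fewer than 2 usable data rows in '%s'", path)
  has_sigma <- all(ncols >= 3)
  q <- vapply(rows, `[`, 0, 1)
  i <- vapply(rows, `[`, 0, 2)
  s <- if (has_sigma) vapply(rows, `[`, 0, 3) else NULL
  if (any(diff(q) <= 0)) stopf("Q column in '%s' is not strictly increasing", path)
  saxs_profile(q, i, s)
}

#' Write a scattering profile as whitespace-delimited text
#'
#' Full precision (>= 9 significant digits); 2 columns without sigma, 3 with.
#'
#' @param p a `saxs_profile`
#' @param path output path
#' @param header optional comment line (written with a leading `#`)
#' @return invisibly, `path`
#' @export
write_profile <- function(p, path, header = NULL) {
  fmt <- function(x) sprintf("%.9e", x)
  if (is.null(p$sigma)) {
    body <- paste(fmt(p$q), fmt(p$intensity))
  } else {
    body <- paste(fmt(p$q), fmt(p$intensity), fmt(p$sigma))
  }
  out <- c(if (!is.null(header)) paste0("# ", header), body)
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot write '%s': %s", path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
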