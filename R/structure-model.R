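# Column layout of the atom table underlying every `lssr_structure`.
ATOM_COLUMNS <- c("chain", "resnum", "icode", "resname", "atom", "altloc",
                  "x", "y", "z", "occ", "b", "element", "het")

#' Construct a structure from an atom table
#'
#' A `lssr_structure` is a light S3 wrapper around a data frame with one row
#' per atom and columns `chain`, `resnum` (author numbering), `icode`,
#' `resname`, `atom` (atom name), `altloc`, `x`, `y`, `z` (Angstrom),
#' `occ`, `b`, `element` and `het` (logical, HETATM origin). Residues are
#' ordered within each chain by `(resnum, icode)`.
#'
#' @param atoms data frame with the columns listed above (missing optional
#'   columns are filled with defaults).
#' @param provenance character scratchpad recording source file and any
#'   selection applied.
#' @return an object of class `lssr_structure`.
#' @export
new_structure <- function(atoms, provenance = character()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  defaults <- list(icode = "", altloc = "", occ = 1, b = 0,
                   element = "", het = FALSE)
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- rep(defaults[[nm]], nrow(atoms))
  }
  missing <- setdiff(ATOM_COLUMNS, names(atoms))
  if (length(missing)) {
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  }
  atoms <- atoms[ATOM_COLUMNS]
  atoms$chain <- as.character(atoms$chain)
  atoms$resnum <- as.integer(atoms$resnum)
  atoms$icode <- as.character(atoms$icode)
  atoms$resname <- as.character(atoms$resname)
  atoms$atom <- as.character(atoms$atom)
  atoms$altloc <- as.character(atoms$altloc)
  for (nm in c("x", "y", "z", "occ", "b")) atoms[[nm]] <- as.numeric(atoms[[nm]])
  atoms$het <- as.logical(atoms$het)
  if (nrow(atoms)) {
    if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
      stop("non-finite atom coordinates")
    }
    key <- atom_key(atoms, with_alt = TRUE)
    if (anyDuplicated(key)) {
      stop("duplicate atom identity: ", key[duplicated(key)][1])
    }
    # order chains as first encountered, residues by (resnum, icode)
    ord <- order(match(atoms$chain, unique(atoms$chain)),
                 atoms$resnum, atoms$icode)
    atoms <- atoms[ord, , drop = FALSE]
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, provenance = as.character(provenance)),
            class = "lssr_structure")
}

# identity key per atom; with_alt distinguishes altloc conformers
atom_key <- function(atoms, with_alt = FALSE) {
  k <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$atom, sep = "|")
  if (with_alt) k <- paste(k, atoms$altloc, sep = "|")
  k
}

residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resnum, atoms$icode, sep = "|")
}

#' @export
print.lssr_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<lssr_structure: %d atoms, %d chains (%s), %d residues>\n",
              nrow(a), length(unique(a$chain)),
              paste(unique(a$chain), collapse = ","),
              length(unique(residue_key(a)))))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `lssr_structure`
#' @return integer atom count
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Chain identifiers of a structure
#' @param s a `lssr_structure`
#' @return character vector of chain ids in file order
#' @export
chain_ids <- function(s) unique(s$atoms$chain)

#' Euclidean distance between two atoms
#'
#' @param a,b single-row atom records (or any list with `x`, `y`, `z`).
#' @return distance in Angstrom.
#' @export
interatomic_distance <- function(a, b) {
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
}

## ---------------------------------------------------------------- PDB input

parse_pdb_lines <- function(lines, path = "<text>") {
  sel <- grepl("^(ATOM  |HETATM)", lines)
  # first model only: truncate at the first ENDMDL
  endmdl <- which(grepl("^ENDMDL", lines))
  if (length(endmdl)) sel[seq_along(sel) > endmdl[1]] <- FALSE
  idx <- which(sel)
  if (!length(idx)) {
    return(new_structure(empty_atom_table(), provenance = path))
  }
  rec <- lines[idx]
  short <- nchar(rec) < 54
  if (any(short)) {
    stop(sprintf("format error in %s: truncated ATOM/HETATM record at line %d",
                 path, idx[which(short)[1]]))
  }
  fx <- function(from, to) substr(rec, from, to)
  num <- function(txt, what) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v) & trimws(txt) != "")
    if (length(bad)) {
      stop(sprintf("format error in %s: bad %s field at line %d",
                   path, what, idx[bad[1]]))
    }
    v
  }
  resnum <- suppressWarnings(as.integer(trimws(fx(23, 26))))
  if (anyNA(resnum)) {
    stop(sprintf("format error in %s: bad residue number at line %d",
                 path, idx[which(is.na(resnum))[1]]))
  }
  occ <- num(fx(55, 60), "occupancy"); occ[is.na(occ)] <- 1
  b <- num(fx(61, 66), "B factor"); b[is.na(b)] <- 0
  element <- trimws(fx(77, 78))
  # fall back to first letter of the atom name when element column is absent
  blank <- element == ""
  element[blank] <- guess_element(trimws(fx(13, 16))[blank])
  atoms <- data.frame(
    chain = fx(22, 22),
    resnum = resnum,
    icode = trimws(fx(27, 27)),
    resname = trimws(fx(18, 20)),
    atom = trimws(fx(13, 16)),
    altloc = trimws(fx(17, 17)),
    x = num(fx(31, 38), "x"), y = num(fx(39, 46), "y"),
    z = num(fx(47, 54), "z"),
    occ = occ, b = b, element = element,
    het = fx(1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
  new_structure(atoms, provenance = path)
}

guess_element <- function(names) {
  el <- sub("^([0-9]*)([A-Za-z]).*$", "\\2", names)
  toupper(el)
}

empty_atom_table <- function() {
  data.frame(chain = character(), resnum = integer(), icode = character(),
             resname = character(), atom = character(), altloc = character(),
             x = numeric(), y = numeric(), z = numeric(), occ = numeric(),
             b = numeric(), element = character(), het = logical(),
             stringsAsFactors = FALSE)
}

## -------------------------------------------------------------- mmCIF input

# Minimal tokenizer for one mmCIF data line (handles '...' and "..." quoting).
cif_tokens <- function(line) {
  out <- character()
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1L
      while (j <= n && !(substr(line, j, j) == ch &&
                         (j == n || substr(line, j + 1, j + 1) %in% c(" ", "\t")))) {
        j <- j + 1L
      }
      out <- c(out, substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !(substr(line, j, j) %in% c(" ", "\t"))) j <- j + 1L
      out <- c(out, substr(line, i, j - 1L))
      i <- j
    }
  }
  out
}

parse_mmcif_lines <- function(lines, path = "<text>") {
  tag_idx <- grep("^_atom_site\\.", lines)
  if (!length(tag_idx)) {
    stop(sprintf("format error in %s: no _atom_site loop found", path))
  }
  tags <- sub("^_atom_site\\.([^ \t]+).*$", "\\1", lines[tag_idx])
  first_row <- max(tag_idx) + 1L
  rows <- list()
  i <- first_row
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*(#|loop_|_[A-Za-z]|data_)", ln) || grepl("^\\s*$", ln)) break
    tok <- cif_tokens(ln)
    if (length(tok) != length(tags)) {
      stop(sprintf("format error in %s: atom_site row %d has %d fields, expected %d",
                   path, i, length(tok), length(tags)))
    }
    rows[[length(rows) + 1L]] <- tok
    i <- i + 1L
  }
  if (!length(rows)) return(new_structure(empty_atom_table(), provenance = path))
  m <- do.call(rbind, rows)
  colnames(m) <- tags
  col <- function(nm, alt = NULL) {
    if (nm %in% tags) return(m[, nm])
    if (!is.null(alt) && alt %in% tags) return(m[, alt])
    rep(NA_character_, nrow(m))
  }
  dot <- function(v) { v[v %in% c(".", "?")] <- ""; v }
  model <- col("pdbx_PDB_model_num")
  keep <- if (all(is.na(model))) rep(TRUE, nrow(m)) else model == model[1]
  numc <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    if (anyNA(out)) stop(sprintf("format error in %s: bad %s value", path, what))
    out
  }
  occ <- suppressWarnings(as.numeric(dot(col("occupancy"))))
  occ[is.na(occ)] <- 1
  bf <- suppressWarnings(as.numeric(dot(col("B_iso_or_equiv"))))
  bf[is.na(bf)] <- 0
  atoms <- data.frame(
    chain = dot(col("auth_asym_id", "label_asym_id"))[keep],
    resnum = as.integer(numc(dot(col("auth_seq_id", "label_seq_id"))[keep],
                             "residue number")),
    icode = dot(col("pdbx_PDB_ins_code"))[keep],
    resname = dot(col("auth_comp_id", "label_comp_id"))[keep],
    atom = dot(col("auth_atom_id", "label_atom_id"))[keep],
    altloc = dot(col("label_alt_id"))[keep],
    x = numc(col("Cartn_x")[keep], "Cartn_x"),
    y = numc(col("Cartn_y")[keep], "Cartn_y"),
    z = numc(col("Cartn_z")[keep], "Cartn_z"),
    occ = occ[keep], b = bf[keep],
    element = dot(col("type_symbol"))[keep],
    het = dot(col("group_PDB"))[keep] == "HETATM",
    stringsAsFactors = FALSE
  )
  new_structure(atoms, provenance = path)
}

## ----------------------------------------------------------------- read/write

#' Read a macromolecular structure from PDB or mmCIF
#'
#' Only the first model of multi-model files is returned; coordinates are
#' taken as deposited with no transformation. All atom records (including
#' HETATM, waters and alternate locations) are kept; apply [select_atoms()]
#' afterwards to filter.
#'
#' @param path path to a PDB or mmCIF file.
#' @param format one of `"auto"` (by extension/content), `"pdb"`, `"mmcif"`.
#' @return a [new_structure()] object.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
      else if (ext %in% c("pdb", "ent")) "pdb"
      else if (any(grepl("^_atom_site\\.", lines))) "mmcif"
      else "pdb"
  }
  switch(format,
         pdb = parse_pdb_lines(lines, path),
         mmcif = parse_mmcif_lines(lines, path))
}

#' Write a structure as PDB
#'
#' Emits ATOM/HETATM records (wwPDB v3.3 columns) with TER after each chain
#' and a final END record.
#'
#' @param s a `lssr_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  lines <- character()
  serial <- 0L
  for (ch in unique(a$chain)) {
    rows <- which(a$chain == ch)
    for (i in rows) {
      serial <- serial + 1L
      nm <- a$atom[i]
      # atom-name column convention: 1-char elements start in column 14
      namefield <- if (nchar(nm) < 4 && nchar(a$element[i]) < 2) {
        formatC(paste0(" ", nm), width = -4)
      } else formatC(nm, width = -4)
      lines <- c(lines, sprintf(
        "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        if (a$het[i]) "HETATM" else "ATOM", serial %% 100000L, namefield,
        a$altloc[i], a$resname[i], a$chain[i], a$resnum[i], a$icode[i],
        a$x[i], a$y[i], a$z[i], a$occ[i], a$b[i],
        formatC(a$element[i], width = 2)))
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      %-3s %1s%4d%1s",
                              serial %% 100000L, a$resname[rows[length(rows)]],
                              ch, a$resnum[rows[length(rows)]],
                              a$icode[rows[length(rows)]]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

## ----------------------------------------------------------------- selection

#' Atom selection policy
#'
#' @param waters keep water molecules (residue names HOH/WAT/DOD)? Default
#'   `FALSE`: waters are excluded from similarity restraints because
#'   equivalent waters would need identical residue numbering.
#' @param hydrogens keep hydrogen/deuterium atoms? Default `FALSE` (heavy
#'   atoms only, the usual X-ray refinement regime).
#' @param hetero keep non-water hetero groups (haems, ligands, ions)?
#'   Default `TRUE`.
#' @param altloc one of `"first"` (keep the first-listed conformer per atom
#'   name, the deterministic default) or `"occupancy"` (keep the
#'   highest-occupancy conformer, first-listed on ties).
#' @return a `selection_policy` list.
#' @export
selection_policy <- function(waters = FALSE, hydrogens = FALSE, hetero = TRUE,
                             altloc = c("first", "occupancy")) {
  altloc <- match.arg(altloc)
  structure(list(waters = waters, hydrogens = hydrogens, hetero = hetero,
                 altloc = altloc), class = "selection_policy")
}

WATER_NAMES <- c("HOH", "WAT", "DOD")

#' Select atoms from a structure
#'
#' Applies a [selection_policy()]: water removal, hydrogen removal, hetero
#' handling and one-conformer-per-atom altloc resolution. The default policy
#' keeps heavy atoms of protein and hetero groups, drops waters and keeps the
#' first-listed alternate location for each atom name.
#'
#' @param s a `lssr_structure`.
#' @param policy a [selection_policy()].
#' @return a new `lssr_structure` (possibly empty).
#' @export
select_atoms <- function(s, policy = selection_policy()) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!policy$waters) keep <- keep & !(a$resname %in% WATER_NAMES)
  if (!policy$hydrogens) keep <- keep & !(toupper(a$element) %in% c("H", "D"))
  if (!policy$hetero) {
    keep <- keep & (!a$het | a$resname %in% WATER_NAMES)
  }
  a <- a[keep, , drop = FALSE]
  if (nrow(a)) {
    key <- atom_key(a)
    if (policy$altloc == "occupancy") {
      ord <- order(match(key, unique(key)), -a$occ)
      a <- a[ord, , drop = FALSE]
    }
    a <- a[!duplicated(atom_key(a)), , drop = FALSE]
    a$altloc <- ""
  }
  new_structure(a, provenance = c(s$provenance,
                                  sprintf("select: waters=%s hydrogens=%s hetero=%s altloc=%s",
                                          policy$waters, policy$hydrogens,
                                          policy$hetero, policy$altloc)))
}
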