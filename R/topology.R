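# Covalent connectivity of the standard amino acids (heavy atoms only).
# Backbone N-CA, CA-C, C-O (+ C-OXT) are implicit for every entry; the table
# lists CA-CB plus side-chain bonds.
SIDECHAIN_BONDS <- list(
  ALA = list(c("CA", "CB")),
  ARG = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "NE"),
             c("NE", "CZ"), c("CZ", "NH1"), c("CZ", "NH2")),
  ASN = list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "ND2")),
  ASP = list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "OD2")),
  CYS = list(c("CA", "CB"), c("CB", "SG")),
  GLN = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
             c("CD", "NE2")),
  GLU = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
             c("CD", "OE2")),
  GLY = list(),
  HIS = list(c("CA", "CB"), c("CB", "CG"), c("CG", "ND1"), c("CG", "CD2"),
             c("ND1", "CE1"), c("CD2", "NE2"), c("CE1", "NE2")),
  ILE = list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2"), c("CG1", "CD1")),
  LEU = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2")),
  LYS = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "CE"),
             c("CE", "NZ")),
  MET = list(c("CA", "CB"), c("CB", "CG"), c("CG", "SD"), c("SD", "CE")),
  PHE = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ")),
  PRO = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "N")),
  SER = list(c("CA", "CB"), c("CB", "OG")),
  THR = list(c("CA", "CB"), c("CB", "OG1"), c("CB", "CG2")),
  TRP = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "NE1"), c("NE1", "CE2"), c("CD2", "CE2"),
             c("CD2", "CE3"), c("CE3", "CZ3"), c("CZ3", "CH2"),
             c("CH2", "CZ2"), c("CZ2", "CE2")),
  TYR = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ"),
             c("CZ", "OH")),
  VAL = list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2"))
)

BACKBONE_BONDS <- list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT"))

PEPTIDE_BOND_MAX <- 2.5    # C(i)-N(i+1) sanity guard, Angstrom
DISULFIDE_MAX <- 2.3       # SG-SG
HETERO_BOND_MAX <- 1.9     # distance-based bonding for non-standard residues

#' Covalent topology of a structure
#'
#' Builds the heavy-atom bond graph from standard residue connectivity plus
#' inter-residue peptide bonds (consecutive residues of a chain with C-N
#' under 2.5 Angstrom) and disulfide bridges (SG-SG under 2.3 Angstrom).
#' Residues absent from the standard table (haems, ligands) fall back to
#' distance-based bonding between heavy atoms at or under 1.9 Angstrom, with
#' a warning naming the residue type.
#'
#' The returned object supports bonded-pair classification: separation 1
#' (1-2) and 2 (1-3) pairs are excluded from restraints, separation exactly
#' 3 is the "1-4" class, anything further (or cross-component) is nonbonded.
#'
#' @param s a `lssr_structure` (post-selection, heavy atoms).
#' @return a `lssr_topology` list with elements `n`, `bonds` (two-column
#'   index matrix), `excl12_13` and `one_four` (sorted numeric pair keys).
#' @export
build_topology <- function(s) {
  a <- s$atoms
  n <- nrow(a)
  bi <- integer(0); bj <- integer(0)
  add_bond <- function(i, j) {
    bi <<- c(bi, i); bj <<- c(bj, j)
  }
  rkey <- residue_key(a)
  res_split <- split(seq_len(n), factor(rkey, levels = unique(rkey)))
  unknown <- character(0)
  for (rows in res_split) {
    rn <- a$resname[rows[1]]
    if (rn %in% WATER_NAMES) next
    if (rn %in% names(SIDECHAIN_BONDS)) {
      tbl <- c(BACKBONE_BONDS, SIDECHAIN_BONDS[[rn]])
      nm <- a$atom[rows]
      for (bp in tbl) {
        i <- rows[match(bp[1], nm)]
        j <- rows[match(bp[2], nm)]
        if (!is.na(i) && !is.na(j)) add_bond(i, j)
      }
    } else {
      unknown <- c(unknown, rn)
      if (length(rows) > 1) {
        d <- as.matrix(stats::dist(a[rows, c("x", "y", "z")]))
        hit <- which(d <= HETERO_BOND_MAX & upper.tri(d), arr.ind = TRUE)
        if (nrow(hit)) {
          bi <- c(bi, rows[hit[, 1]]); bj <- c(bj, rows[hit[, 2]])
        }
      }
    }
  }
  unknown <- unique(unknown)
  if (length(unknown)) {
    warning("no standard topology for residue type(s) ",
            paste(unknown, collapse = ", "),
            "; using distance-based bonding (<= ", HETERO_BOND_MAX, " A)",
            call. = FALSE)
  }
  # peptide links between consecutive residues of the same chain
  for (ch in unique(a$chain)) {
    rlist <- res_split[unique(rkey[a$chain == ch])]
    if (length(rlist) < 2) next
    for (k in seq_len(length(rlist) - 1L)) {
      i <- rlist[[k]][match("C", a$atom[rlist[[k]]])]
      j <- rlist[[k + 1L]][match("N", a$atom[rlist[[k + 1L]]])]
      if (!is.na(i) && !is.na(j) &&
          interatomic_distance(a[i, ], a[j, ]) <= PEPTIDE_BOND_MAX) {
        add_bond(i, j)
      }
    }
  }
  # disulfide bridges, possibly inter-chain
  sg <- which(a$atom == "SG" & a$resname == "CYS")
  if (length(sg) > 1) {
    d <- as.matrix(stats::dist(a[sg, c("x", "y", "z")]))
    hit <- which(d <= DISULFIDE_MAX & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit)) { bi <- c(bi, sg[hit[, 1]]); bj <- c(bj, sg[hit[, 2]]) }
  }
  bonds <- unique(cbind(pmin(bi, bj), pmax(bi, bj)))
  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      adj[[bonds[k, 1]]] <- c(adj[[bonds[k, 1]]], bonds[k, 2])
      adj[[bonds[k, 2]]] <- c(adj[[bonds[k, 2]]], bonds[k, 1])
    }
  }
  # enumerate pairs at bond-path separation 1, 2 and exactly 3
  p12 <- numeric(0); p13 <- numeric(0); p14 <- numeric(0)
  for (i in seq_len(n)) {
    n1 <- adj[[i]]
    if (!length(n1)) next
    n2 <- setdiff(unique(unlist(adj[n1])), c(i, n1))
    n3 <- setdiff(unique(unlist(adj[n2])), c(i, n1, n2))
    p12 <- c(p12, pair_key(i, n1[n1 > i]))
    p13 <- c(p13, pair_key(i, n2[n2 > i]))
    p14 <- c(p14, pair_key(i, n3[n3 > i]))
  }
  structure(list(n = n, bonds = bonds,
                 excl12_13 = sort(unique(c(p12, p13))),
                 one_four = sort(unique(p14))),
            class = "lssr_topology")
}

# unordered pair -> scalar key (i < j assumed by caller)
pair_key <- function(i, j) {
  if (!length(j)) return(numeric(0))
  (i - 1) * 1e7 + j
}

# classify unordered pairs by bond-path separation
pair_class <- function(topo, i, j) {
  key <- pair_key_vec(i, j)
  cls <- rep("nonbonded", length(key))
  cls[key %in% topo$one_four] <- "one_four"
  cls[key %in% topo$excl12_13] <- "excluded"
  cls
}

pair_key_vec <- function(i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (lo - 1) * 1e7 + hi
}
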