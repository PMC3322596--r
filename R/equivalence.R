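#' Detect NCS-related chain groups
#'
#' Two chains are taken as NCS-related when, among residues present in both
#' chains with the same residue number (and insertion code), more than
#' `min_match_fraction` share the residue name. Groups are the connected
#' components of the resulting chain-pair graph.
#'
#' The denominator of the test is the number of residue numbers present in
#' both chains; hetero residues (haems, ligands) participate like any other
#' residue. Chains with no shared residue numbers are never related.
#'
#' @param s a `lssr_structure` (apply [select_atoms()] first).
#' @param min_match_fraction matching fraction that must be exceeded
#'   (strictly) for two chains to be related; default 0.8.
#' @return list of character vectors, each the chain ids of one NCS group
#'   (in file order); empty list when no NCS is present.
#' @export
detect_ncs_groups <- function(s, min_match_fraction = 0.8) {
  a <- s$atoms
  chains <- unique(a$chain)
  if (length(chains) < 2) return(list())
  # residue-number -> residue-name map per chain
  maps <- lapply(chains, function(ch) {
    rows <- a$chain == ch
    rk <- paste(a$resnum[rows], a$icode[rows], sep = "|")
    keep <- !duplicated(rk)
    stats::setNames(a$resname[rows][keep], rk[keep])
  })
  names(maps) <- chains
  nc <- length(chains)
  related <- matrix(FALSE, nc, nc)
  for (i in seq_len(nc - 1)) {
    for (j in seq(i + 1, nc)) {
      shared <- intersect(names(maps[[i]]), names(maps[[j]]))
      if (!length(shared)) next
      frac <- mean(maps[[i]][shared] == maps[[j]][shared])
      if (frac > min_match_fraction) related[i, j] <- related[j, i] <- TRUE
    }
  }
  # connected components by BFS
  seen <- rep(FALSE, nc)
  groups <- list()
  for (i in seq_len(nc)) {
    if (seen[i] || !any(related[i, ])) next
    comp <- i; queue <- i; seen[i] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(related[v, ] & !seen)
      seen[nb] <- TRUE
      comp <- c(comp, nb); queue <- c(queue, nb)
    }
    groups[[length(groups) + 1L]] <- chains[sort(comp)]
  }
  groups
}

new_correspondence <- function(kind, chain_a, chain_b, idx_a, idx_b,
                               unmatched_a = integer(), unmatched_b = integer()) {
  structure(list(kind = kind, chain_a = chain_a, chain_b = chain_b,
                 idx_a = idx_a, idx_b = idx_b,
                 unmatched_a = unmatched_a, unmatched_b = unmatched_b),
            class = "atom_correspondence")
}

#' @export
print.atom_correspondence <- function(x, ...) {
  cat(sprintf("<atom_correspondence (%s): %s <-> %s, %d pairs, %d+%d unmatched>\n",
              x$kind, x$chain_a, x$chain_b, length(x$idx_a),
              length(x$unmatched_a), length(x$unmatched_b)))
  invisible(x)
}

#' Match NCS-equivalent atoms of two chains
#'
#' Pairs every atom of `chain_a` with the `chain_b` atom carrying the same
#' residue number, insertion code and atom name. Unmatched atoms on either
#' side are recorded and excluded from the pairing.
#'
#' @param s a `lssr_structure`.
#' @param chain_a,chain_b chain identifiers present in `s`.
#' @return an `atom_correspondence` with `idx_a`/`idx_b` row indices into
#'   `s$atoms` (ordered by `chain_a` atom order) and `unmatched_a`/`_b`.
#' @export
match_atoms <- function(s, chain_a, chain_b) {
  a <- s$atoms
  for (ch in c(chain_a, chain_b)) {
    if (!ch %in% a$chain) stop("chain not present in structure: ", ch)
  }
  ra <- which(a$chain == chain_a)
  rb <- which(a$chain == chain_b)
  ka <- paste(a$resnum[ra], a$icode[ra], a$atom[ra], sep = "|")
  kb <- paste(a$resnum[rb], a$icode[rb], a$atom[rb], sep = "|")
  hit <- match(ka, kb)
  got <- !is.na(hit)
  if (!any(got)) {
    warning(sprintf("no atoms match between chains %s and %s", chain_a, chain_b),
            call. = FALSE)
  }
  new_correspondence("ncs", chain_a, chain_b,
                     idx_a = ra[got], idx_b = rb[hit[got]],
                     unmatched_a = ra[!got],
                     unmatched_b = setdiff(rb, rb[hit[got]]))
}

#' Match a structure to a fixed target structure
#'
#' As [match_atoms()] but keyed on chain id, residue number, insertion code
#' and atom name across two structures. The target side is fixed: its
#' coordinates never move and receive zero gradient.
#'
#' @param s structure under refinement.
#' @param target fixed target structure (read with the same selection
#'   policy).
#' @return an `atom_correspondence` of kind `"target"`; `idx_a` indexes
#'   `s$atoms`, `idx_b` indexes `target$atoms`.
#' @export
match_target <- function(s, target) {
  a <- s$atoms; b <- target$atoms
  ka <- atom_key(a); kb <- atom_key(b)
  hit <- match(ka, kb)
  got <- !is.na(hit)
  if (!any(got)) {
    stop("no atoms of the structure match the target (wrong target file?)")
  }
  new_correspondence("target", chain_a = "*", chain_b = "*",
                     idx_a = which(got), idx_b = hit[got],
                     unmatched_a = which(!got),
                     unmatched_b = setdiff(seq_len(nrow(b)), hit[got]))
}

# Nomenclature-equivalent side-chain atom pairs. A "swap" exchanges all
# listed pairs of the residue at once (an aromatic ring flip exchanges both
# CD and CE pairs simultaneously).
SWAP_GROUPS_STANDARD <- list(
  ASP = list(c("OD1", "OD2")),
  GLU = list(c("OE1", "OE2")),
  PHE = list(c("CD1", "CD2"), c("CE1", "CE2")),
  TYR = list(c("CD1", "CD2"), c("CE1", "CE2")),
  ARG = list(c("NH1", "NH2"))
)
# "plus" additions exchange physically non-equivalent atoms (imidazole ring
# flip, amide N/O): similarity may improve but chemistry is altered.
SWAP_GROUPS_PLUS <- c(SWAP_GROUPS_STANDARD, list(
  HIS = list(c("ND1", "CD2"), c("CE1", "NE2")),
  ASN = list(c("OD1", "ND2")),
  GLN = list(c("OE1", "NE2"))
))

#' Swap nomenclature-equivalent side-chain atoms to maximise similarity
#'
#' For each candidate residue on the mobile side of each correspondence, the
#' summed LSSR penalty of the restraints touching the residue's swappable
#' atoms is evaluated under the original and the swapped naming (coordinates
#' held fixed, labels exchanged); the lower-penalty labelling is kept. A
#' swap is applied only when it strictly lowers the penalty, which makes the
#' procedure idempotent.
#'
#' Standard mode covers ASP, GLU, PHE, TYR and ARG (label-only exchanges);
#' `mode = "plus"` adds HIS (imidazole ring flip), ASN and GLN, where the
#' exchanged atoms are not chemically equivalent — hydrogen-bond networks
#' can be disrupted, so use with care.
#'
#' @param s structure under refinement (its chains are the mobile side).
#' @param correspondences a single `atom_correspondence` or a list of them.
#'   For NCS the first chain of each correspondence is the fixed reference;
#'   for target correspondences the target structure is the reference and
#'   must be supplied via `target`.
#' @param mode `"standard"` or `"plus"`.
#' @param target fixed target structure for target-kind correspondences.
#' @param params [lssr_params()] used for the penalty evaluations.
#' @return list with `structure` (atom names adjusted) and `report`, a
#'   `swap_report` data frame (chain, resnum, icode, resname, pairs,
#'   penalty_before, penalty_after) plus a `skipped` attribute listing
#'   residues missing one atom of a symmetric pair.
#' @export
swap_equivalent_atoms <- function(s, correspondences, mode = c("standard", "plus"),
                                  target = NULL, params = lssr_params()) {
  mode <- match.arg(mode)
  groups <- if (mode == "plus") SWAP_GROUPS_PLUS else SWAP_GROUPS_STANDARD
  if (inherits(correspondences, "atom_correspondence")) {
    correspondences <- list(correspondences)
  }
  report <- list()
  skipped <- list()
  for (corr in correspondences) {
    is_target <- identical(corr$kind, "target")
    other <- if (is_target) {
      if (is.null(target)) stop("target structure required for target-kind swaps")
      target
    } else s
    # mobile side: chain_b atoms for NCS (chain_a is the reference); for a
    # target correspondence every structure atom is mobile.
    rl <- enumerate_restraints(s, corr, params = params, other = target)
    if (!nrow(rl$restraints)) next
    a <- s$atoms
    mob_idx <- if (is_target) corr$idx_a else corr$idx_b
    rk <- residue_key(a)[mob_idx]
    for (res in unique(rk)) {
      rows <- mob_idx[rk == res]
      rn <- a$resname[rows[1]]
      pairs <- groups[[rn]]
      if (is.null(pairs)) next
      nm <- a$atom[rows]
      p <- lapply(pairs, function(pp) rows[match(pp, nm)])
      if (any(vapply(p, anyNA, logical(1)))) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(chain = a$chain[rows[1]], resnum = a$resnum[rows[1]],
                     icode = a$icode[rows[1]], resname = rn,
                     reason = "incomplete symmetric pair",
                     stringsAsFactors = FALSE)
        next
      }
      swap_rows <- unlist(p)
      cost <- swap_costs(s, other, rl, corr, swap_rows, p, is_target)
      if (cost$after < cost$before - 1e-12) {
        # exchange coordinates (and element/B/occ payload) between labels
        s <- apply_coord_swap(s, p)
        report[[length(report) + 1L]] <- data.frame(
          chain = a$chain[rows[1]], resnum = a$resnum[rows[1]],
          icode = a$icode[rows[1]], resname = rn,
          pairs = paste(vapply(pairs, paste, "", collapse = "<->"),
                        collapse = ";"),
          penalty_before = cost$before, penalty_after = cost$after,
          stringsAsFactors = FALSE)
      }
    }
  }
  rep_df <- if (length(report)) do.call(rbind, report) else
    data.frame(chain = character(), resnum = integer(), icode = character(),
               resname = character(), pairs = character(),
               penalty_before = numeric(), penalty_after = numeric(),
               stringsAsFactors = FALSE)
  attr(rep_df, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  class(rep_df) <- c("swap_report", class(rep_df))
  list(structure = s, report = rep_df)
}

# Penalty over restraints touching `swap_rows` on the mobile side, before and
# after exchanging the coordinates of each pair in `pair_rows`. The restraint
# pair set is held fixed; only distances through the swapped atoms change.
swap_costs <- function(s, other, rl, corr, swap_rows, pair_rows, is_target) {
  r <- rl$restraints
  if (is_target) {
    touch <- r$i1 %in% swap_rows | r$j1 %in% swap_rows
  } else {
    touch <- r$i2 %in% swap_rows | r$j2 %in% swap_rows
  }
  if (!any(touch)) return(list(before = 0, after = 0))
  r <- r[touch, , drop = FALSE]
  co1 <- as.matrix(s$atoms[, c("x", "y", "z")])
  co2 <- as.matrix(other$atoms[, c("x", "y", "z")])
  pen <- function(c1, c2) {
    r1 <- sqrt(rowSums((c1[r$i1, , drop = FALSE] - c1[r$j1, , drop = FALSE])^2))
    r2 <- sqrt(rowSums((c2[r$i2, , drop = FALSE] - c2[r$j2, , drop = FALSE])^2))
    sum(lssr_penalty(abs(r1 - r2), rl$params))
  }
  before <- pen(co1, co2)
  # swapped labelling: exchange coordinates within each pair on the mobile
  # side (the mobile side lives in s)
  co1s <- co1
  for (pp in pair_rows) {
    co1s[pp[1], ] <- co1[pp[2], ]
    co1s[pp[2], ] <- co1[pp[1], ]
  }
  after <- if (is_target) pen(co1s, co2) else {
    # mobile side is copy 2 and also copy 1 coords belong to s; for NCS both
    # copies index s$atoms, so the swapped coordinate set applies to both.
    r1 <- sqrt(rowSums((co1s[r$i1, , drop = FALSE] - co1s[r$j1, , drop = FALSE])^2))
    r2 <- sqrt(rowSums((co1s[r$i2, , drop = FALSE] - co1s[r$j2, , drop = FALSE])^2))
    sum(lssr_penalty(abs(r1 - r2), rl$params))
  }
  list(before = before, after = after)
}

apply_coord_swap <- function(s, pair_rows) {
  cols <- c("x", "y", "z", "occ", "b")
  for (pp in pair_rows) {
    tmp <- s$atoms[pp[1], cols]
    s$atoms[pp[1], cols] <- s$atoms[pp[2], cols]
    s$atoms[pp[2], cols] <- tmp
  }
  s
}
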