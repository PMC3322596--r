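# Shared helpers: hand-written file fixtures and independent oracles.

tiny_pdb_text <- function() {
  c("HEADER    TEST",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  C   ALA A   1       1.980   1.433   0.000  1.00 10.00           C",
    "END")
}

tiny_mmcif_text <- function() {
  c("data_test",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A A 1 ? 0.000 0.000 0.000 1.00 10.00 1",
    "ATOM 2 C CA . ALA A A 1 ? 1.458 0.000 0.000 1.00 10.00 1",
    "ATOM 3 C C . ALA A A 1 ? 1.980 1.433 0.000 1.00 10.00 1",
    "#")
}

write_tmp <- function(lines, ext = ".pdb") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# default mixed sequence exercising backbone + branched side chains
mixed_seq <- c("ALA", "SER", "PHE", "ASP", "GLY", "ARG", "LEU", "GLU")

two_copy_fixture <- function(n_residues = 6, noise_sd = 0.05, seed = 1, ...) {
  generate_ncs_fixture(fixture_spec(
    n_residues = n_residues, n_chains = 2,
    sequence = rep_len(mixed_seq, n_residues),
    noise_sd = noise_sd, seed = seed, ...))
}

# ------------------------------------------------------------------ oracles

# independent bond-path separations by per-atom BFS over the bond list
oracle_separation <- function(bonds, n, max_sep = 3L) {
  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      adj[[bonds[k, 1]]] <- c(adj[[bonds[k, 1]]], bonds[k, 2])
      adj[[bonds[k, 2]]] <- c(adj[[bonds[k, 2]]], bonds[k, 1])
    }
  }
  sep <- matrix(Inf, n, n)
  diag(sep) <- 0
  for (start in seq_len(n)) {
    frontier <- start
    for (d in seq_len(max_sep)) {
      nxt <- setdiff(unique(unlist(adj[frontier])),
                     which(sep[start, ] < Inf))
      if (!length(nxt)) break
      sep[start, nxt] <- d
      frontier <- nxt
    }
  }
  sep
}

# O(n^2) restraint-pair oracle: same three rules, independent code path
oracle_pairs <- function(s, corr, params) {
  topo <- suppressWarnings(build_topology(s))
  sep <- oracle_separation(topo$bonds, nrow(s$atoms))
  co <- as.matrix(s$atoms[, c("x", "y", "z")])
  idx_a <- corr$idx_a; idx_b <- corr$idx_b
  out <- list()
  for (p in seq_along(idx_a)) {
    for (q in seq_along(idx_a)) {
      i <- idx_a[p]; j <- idx_a[q]
      if (i >= j) next
      if (sep[i, j] < 3) next
      r1 <- sqrt(sum((co[i, ] - co[j, ])^2))
      ip <- idx_b[p]; jp <- idx_b[q]
      r2 <- sqrt(sum((co[ip, ] - co[jp, ])^2))
      if (r1 < params$cutoff || r2 < params$cutoff) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(out)) return(matrix(integer(), ncol = 2))
  do.call(rbind, out)
}

pair_ids <- function(m) paste(m[, 1], m[, 2], sep = "-")
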