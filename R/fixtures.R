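# Toy idealised geometry used by the fixture generator. One residue template
# repeated by a rigid translation gives an extended strand with sensible
# bond lengths (N-CA 1.46, CA-C 1.52, C-O 1.23, C-N' 1.33, CA-CB 1.53);
# angles are approximate — these constants define the fixture world, they
# are not refinement-grade stereochemistry.
FIX_T <- c(3.2295, 1.8880, 0)                       # per-residue translation
FIX_BACKBONE <- list(N = c(0, 0, 0), CA = c(1.458, 0, 0),
                     C = c(1.9795, 1.4330, 0), O = c(1.1795, 2.3690, 0))
# orthonormal side-chain frame: u along CA->CB, v and t perpendicular
FIX_U <- c(0.333, -0.577, 0.745)
FIX_V <- c(-0.372, 0.645, 0.667)
FIX_W <- c(-0.866, -0.499, 0)

sidechain_template <- function(resname) {
  u <- FIX_U; v <- FIX_V; tt <- FIX_W
  d1 <- 0.8 * u + 0.6 * v                 # growth direction off CB
  bp <- function(base, len, dir) base + len * dir
  branch <- function(base, len, dir) list(bp(base, len, 0.5 * dir + 0.866 * tt),
                                          bp(base, len, 0.5 * dir - 0.866 * tt))
  CB <- 1.53 * u                          # offset from CA
  out <- list(CB = CB)
  ring6 <- function(cg) {
    ctr <- cg + 1.39 * d1
    vx <- function(th) ctr + 1.39 * (cos(th) * d1 + sin(th) * tt)
    list(CD1 = vx(2 * pi / 3), CE1 = vx(pi / 3), CZ = vx(0),
         CE2 = vx(-pi / 3), CD2 = vx(-2 * pi / 3))
  }
  switch(resname,
    GLY = list(),
    ALA = out,
    SER = c(out, list(OG = bp(CB, 1.42, d1))),
    CYS = c(out, list(SG = bp(CB, 1.81, d1))),
    THR = { b <- branch(CB, 1.48, d1); c(out, list(OG1 = b[[1]], CG2 = b[[2]])) },
    VAL = { b <- branch(CB, 1.52, d1); c(out, list(CG1 = b[[1]], CG2 = b[[2]])) },
    LEU = { CG <- bp(CB, 1.53, d1); b <- branch(CG, 1.52, d1)
            c(out, list(CG = CG, CD1 = b[[1]], CD2 = b[[2]])) },
    ASP = { CG <- bp(CB, 1.52, d1); b <- branch(CG, 1.25, d1)
            c(out, list(CG = CG, OD1 = b[[1]], OD2 = b[[2]])) },
    ASN = { CG <- bp(CB, 1.52, d1); b <- branch(CG, 1.28, d1)
            c(out, list(CG = CG, OD1 = b[[1]], ND2 = b[[2]])) },
    GLU = { CG <- bp(CB, 1.52, d1); CD <- bp(CG, 1.52, d1)
            b <- branch(CD, 1.25, d1)
            c(out, list(CG = CG, CD = CD, OE1 = b[[1]], OE2 = b[[2]])) },
    GLN = { CG <- bp(CB, 1.52, d1); CD <- bp(CG, 1.52, d1)
            b <- branch(CD, 1.28, d1)
            c(out, list(CG = CG, CD = CD, OE1 = b[[1]], NE2 = b[[2]])) },
    LYS = { CG <- bp(CB, 1.52, d1); CD <- bp(CG, 1.52, d1)
            CE <- bp(CD, 1.52, d1)
            c(out, list(CG = CG, CD = CD, CE = CE, NZ = bp(CE, 1.49, d1))) },
    ARG = { CG <- bp(CB, 1.52, d1); CD <- bp(CG, 1.52, d1)
            NE <- bp(CD, 1.46, d1); CZ <- bp(NE, 1.33, d1)
            b <- branch(CZ, 1.33, d1)
            c(out, list(CG = CG, CD = CD, NE = NE, CZ = CZ,
                        NH1 = b[[1]], NH2 = b[[2]])) },
    PHE = { CG <- bp(CB, 1.51, d1); c(out, c(list(CG = CG), ring6(CG))) },
    TYR = { CG <- bp(CB, 1.51, d1); r <- ring6(CG)
            c(out, c(list(CG = CG), r, list(OH = r$CZ + 1.36 * d1))) },
    HIS = { CG <- bp(CB, 1.50, d1); ctr <- CG + 1.19 * d1
            # pentagon: CG at 180 deg, neighbours every 72 deg
            vx <- function(deg) ctr + 1.19 * (cos(deg * pi / 180) * d1 +
                                              sin(deg * pi / 180) * tt)
            c(out, list(CG = CG, ND1 = vx(108), CE1 = vx(36),
                        NE2 = vx(-36), CD2 = vx(-108))) },
    stop("fixture generator has no template for residue type ", resname)
  )
}

#' Specification of a synthetic NCS fixture
#'
#' Describes the stated world of a generated test structure: an idealised
#' extended polypeptide duplicated into NCS copies, with per-atom Gaussian
#' coordinate noise, optional deliberately distinct (displaced) residues and
#' optional side-chain label flips. The same spec and seed always produce a
#' bit-identical fixture.
#'
#' @param n_residues residues per chain.
#' @param n_chains number of NCS copies (chain ids A, B, ...).
#' @param sequence residue names, recycled over `n_residues`; default
#'   poly-alanine with serines, covering the template library as needed.
#' @param noise_sd per-coordinate Gaussian noise, Angstrom (applied to every
#'   copy independently).
#' @param outliers data frame with columns `resnum`, `magnitude`: those
#'   residues are rigidly displaced by `magnitude` Angstrom (seeded random
#'   direction) in every chain except the first, emulating genuinely
#'   distinct conformations.
#' @param flips data frame with columns `chain`, `resnum`: exchange the
#'   nomenclature-equivalent side-chain atom coordinates of that residue
#'   (emulates inconsistent naming between copies).
#' @param seed integer RNG seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_residues = 10, n_chains = 2, sequence = "ALA",
                         noise_sd = 0, outliers = NULL, flips = NULL,
                         seed = 1) {
  structure(list(n_residues = n_residues, n_chains = n_chains,
                 sequence = rep_len(sequence, n_residues),
                 noise_sd = noise_sd, outliers = outliers, flips = flips,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a synthetic NCS fixture structure
#'
#' Builds the idealised chain described by a [fixture_spec()], duplicates it
#' into `n_chains` copies 40 Angstrom apart (identical residue numbering,
#' chain ids A, B, ...), then applies noise, outlier displacements and label
#' flips. Deterministic given the spec seed.
#'
#' @param spec a [fixture_spec()].
#' @return a `lssr_structure`.
#' @export
generate_ncs_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.null(spec$outliers)) {
    bad <- setdiff(spec$outliers$resnum, seq_len(spec$n_residues))
    if (length(bad)) stop("outlier displacement on nonexistent residue ", bad[1])
  }
  # one chain in the template frame
  rows <- list()
  for (i in seq_len(spec$n_residues)) {
    base <- (i - 1) * FIX_T
    rn <- spec$sequence[i]
    atoms <- FIX_BACKBONE
    if (rn == "GLY") atoms <- FIX_BACKBONE
    sc <- sidechain_template(rn)
    ca <- base + FIX_BACKBONE$CA
    for (nm in names(atoms)) {
      rows[[length(rows) + 1L]] <- list(resnum = i, resname = rn, atom = nm,
                                        pos = base + atoms[[nm]])
    }
    for (nm in names(sc)) {
      rows[[length(rows) + 1L]] <- list(resnum = i, resname = rn, atom = nm,
                                        pos = ca + sc[[nm]])
    }
  }
  n_per <- length(rows)
  with_seed(spec$seed, {
    tabs <- lapply(seq_len(spec$n_chains), function(k) {
      ch <- LETTERS[k]
      pos <- t(vapply(rows, `[[`, numeric(3), "pos"))
      pos[, 2] <- pos[, 2] + (k - 1) * 40   # separate the copies in space
      if (spec$noise_sd > 0) {
        pos <- pos + matrix(stats::rnorm(3 * n_per, sd = spec$noise_sd),
                            ncol = 3)
      }
      if (!is.null(spec$outliers) && k > 1) {
        for (q in seq_len(nrow(spec$outliers))) {
          dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
          sel <- vapply(rows, `[[`, 0, "resnum") == spec$outliers$resnum[q]
          pos[sel, ] <- pos[sel, ] +
            rep(spec$outliers$magnitude[q] * dir, each = sum(sel))
        }
      }
      data.frame(chain = ch,
                 resnum = vapply(rows, `[[`, 0, "resnum"),
                 icode = "",
                 resname = vapply(rows, `[[`, "", "resname"),
                 atom = vapply(rows, `[[`, "", "atom"),
                 altloc = "",
                 x = pos[, 1], y = pos[, 2], z = pos[, 3],
                 occ = 1, b = 10,
                 element = substr(vapply(rows, `[[`, "", "atom"), 1, 1),
                 het = FALSE, stringsAsFactors = FALSE)
    })
    s <- new_structure(do.call(rbind, tabs),
                       provenance = sprintf("synthetic fixture (seed %d)",
                                            spec$seed))
    if (!is.null(spec$flips)) {
      for (q in seq_len(nrow(spec$flips))) {
        s <- flip_residue_labels(s, spec$flips$chain[q], spec$flips$resnum[q])
      }
    }
    s
  })
}

# exchange coordinates of the nomenclature-equivalent atom pairs of one
# residue (the 'mislabelled deposit' the swap machinery is meant to repair)
flip_residue_labels <- function(s, chain, resnum) {
  rows <- which(s$atoms$chain == chain & s$atoms$resnum == resnum)
  if (!length(rows)) stop("label flip on nonexistent residue ", chain, resnum)
  rn <- s$atoms$resname[rows[1]]
  pairs <- SWAP_GROUPS_PLUS[[rn]]
  if (is.null(pairs)) stop("residue type ", rn, " has no swappable atoms")
  nm <- s$atoms$atom[rows]
  p <- lapply(pairs, function(pp) rows[match(pp, nm)])
  if (any(vapply(p, anyNA, logical(1)))) stop("incomplete symmetric pair in ",
                                              chain, resnum)
  apply_coord_swap(s, p)
}

#' Toy restrained minimiser
#'
#' Gradient descent with backtracking on the sum of the LSSR energy and an
#' optional harmonic bond term \eqn{k \sum (b - b_0)^2} over the covalent
#' bonds of the structure. Exists to exercise gradients, plateaus and
#' pruning on synthetic fixtures — it is not a refinement engine.
#'
#' @param s starting structure.
#' @param lists restraint list(s) built on `s`.
#' @param target fixed target structure for target-kind lists.
#' @param bonded_k harmonic bond force constant (energy units per
#'   Angstrom^2); 0 disables the bonded term.
#' @param bond_ideal ideal bond lengths: `NULL` takes the lengths in the
#'   starting structure.
#' @param steps maximum accepted steps.
#' @param step_size initial step length multiplier.
#' @return list with `structure`, `trace` (energy after each accepted step,
#'   non-increasing) and `converged`.
#' @export
minimize_lssr <- function(s, lists, target = NULL, bonded_k = 0,
                          bond_ideal = NULL, steps = 200, step_size = 1e-3) {
  stopifnot(steps >= 1)
  topo <- if (bonded_k > 0) build_topology(s) else NULL
  if (bonded_k > 0 && is.null(bond_ideal)) {
    co <- as.matrix(s$atoms[, c("x", "y", "z")])
    bond_ideal <- sqrt(rowSums((co[topo$bonds[, 1], , drop = FALSE] -
                                co[topo$bonds[, 2], , drop = FALSE])^2))
  }
  energy_grad <- function(st) {
    e <- total_lssr(lists, st, target)$total
    g <- lssr_gradient(lists, st, target)
    if (bonded_k > 0) {
      co <- as.matrix(st$atoms[, c("x", "y", "z")])
      dv <- co[topo$bonds[, 1], , drop = FALSE] - co[topo$bonds[, 2], , drop = FALSE]
      bl <- sqrt(rowSums(dv^2))
      e <- e + bonded_k * sum((bl - bond_ideal)^2)
      coef <- 2 * bonded_k * (bl - bond_ideal) / pmax(bl, 1e-12)
      g <- accumulate_rows(g, topo$bonds[, 1], coef * dv)
      g <- accumulate_rows(g, topo$bonds[, 2], -coef * dv)
    }
    list(e = e, g = g)
  }
  cur <- energy_grad(s)
  if (!is.finite(cur$e)) stop("non-finite starting energy")
  trace <- cur$e
  h <- step_size
  for (it in seq_len(steps)) {
    gnorm <- max(abs(cur$g))
    if (gnorm < 1e-10) break
    accepted <- FALSE
    for (try in 1:30) {
      s2 <- s
      s2$atoms[, c("x", "y", "z")] <-
        s$atoms[, c("x", "y", "z")] - h * cur$g
      nxt <- energy_grad(s2)
      if (is.nan(nxt$e)) stop("minimisation diverged (energy NaN)")
      if (nxt$e <= cur$e) { accepted <- TRUE; break }
      h <- h / 2
    }
    if (!accepted) break
    s <- s2; cur <- nxt
    trace <- c(trace, cur$e)
    h <- min(h * 1.5, 1)
  }
  list(structure = s, trace = trace, converged = max(abs(cur$g)) < 1e-10)
}

#' Finite-difference validation of the analytic gradient
#'
#' Central differences of [total_lssr()] with step `h` for every coordinate
#' of every atom that participates in a restraint (target-side atoms are
#' fixed and excluded). The worst relative error is reported, with the
#' analytic gradient's largest magnitude (floored at 1e-6) as the scale.
#'
#' @param lists restraint list(s).
#' @param s structure.
#' @param target fixed target structure for target-kind lists.
#' @param h central-difference step, Angstrom.
#' @return list with `max_rel_error`, `max_abs_error`, `grad_scale`.
#' @export
finite_difference_check <- function(lists, s, target = NULL, h = 1e-5) {
  if (inherits(lists, "restraint_list")) lists <- list(lists)
  ga <- lssr_gradient(lists, s, target)
  mobile <- sort(unique(unlist(lapply(lists, function(rl) {
    r <- rl$restraints
    if (identical(rl$kind, "target")) c(r$i1, r$j1) else c(r$i1, r$j1, r$i2, r$j2)
  }))))
  gn <- matrix(0, nrow(ga), 3)
  cols <- c("x", "y", "z")
  for (i in mobile) {
    for (k in 1:3) {
      sp <- s; sp$atoms[i, cols[k]] <- sp$atoms[i, cols[k]] + h
      sm <- s; sm$atoms[i, cols[k]] <- sm$atoms[i, cols[k]] - h
      gn[i, k] <- (total_lssr(lists, sp, target)$total -
                   total_lssr(lists, sm, target)$total) / (2 * h)
    }
  }
  scale <- max(max(abs(ga)), 1e-6)
  list(max_rel_error = max(abs(gn - ga)) / scale,
       max_abs_error = max(abs(gn - ga)),
       grad_scale = scale)
}
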