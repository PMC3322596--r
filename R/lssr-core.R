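#' LSSR parameter set
#'
#' Parameters of the plateauing penalty
#' \deqn{V(\Delta) = V_{max}\,[1 - \exp(-\alpha \Delta^2 / \sigma^2)]}
#' applied to the absolute difference \eqn{\Delta} between equivalent
#' interatomic distances. The normalisation constant \eqn{\alpha} is fixed
#' by requiring \eqn{V(\sigma) = 1}, giving
#' \eqn{\alpha = \ln(V_{max}/(V_{max}-1))}. With the default
#' \eqn{\sigma = 0.2} Angstrom and \eqn{V_{max} = 3} the penalty is close to
#' harmonic below 0.2 Angstrom and flat above about 0.7 Angstrom, so genuine
#' conformational differences incur a bounded, constant cost.
#'
#' @param sigma similarity scale in Angstrom (default 0.2).
#' @param v_max plateau height, dimensionless (default 3; must exceed 1 for
#'   the normalisation to be possible).
#' @param cutoff distance cutoff in Angstrom: a pair is restrained when it is
#'   closer than this in either copy (default 5.5, small enough to stay
#'   local yet spanning alpha-helix/beta-sheet hydrogen-bond geometry).
#' @param weight per-list weight \eqn{w_{LSSR}} multiplying the summed
#'   penalty (default 1). See [autoncs_weight()] for the multi-copy rule.
#' @return an `lssr_params` list with derived `alpha`.
#' @export
lssr_params <- function(sigma = 0.2, v_max = 3, cutoff = 5.5, weight = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  if (cutoff <= 0) stop("cutoff must be positive")
  if (weight < 0) stop("weight must be nonnegative")
  structure(list(sigma = sigma, v_max = v_max,
                 alpha = lssr_alpha(sigma, v_max),
                 cutoff = cutoff, weight = weight),
            class = "lssr_params")
}

#' Difference between equivalent interatomic distances
#'
#' @param r1 distance between atoms i and j in the first copy (Angstrom).
#' @param r2 distance between the equivalent atoms in the second copy.
#' @return `abs(r1 - r2)`, vectorised.
#' @export
delta <- function(r1, r2) {
  if (any(r1 < 0) || any(r2 < 0)) stop("distances must be nonnegative")
  abs(r1 - r2)
}

#' Penalty normalisation constant
#'
#' Solves \eqn{V(\sigma) = 1} for the saturating form
#' \eqn{V(\Delta) = V_{max}[1 - \exp(-\alpha\Delta^2/\sigma^2)]}, giving the
#' closed form \eqn{\alpha = \ln(V_{max} / (V_{max} - 1))}, independent of
#' \eqn{\sigma}.
#'
#' @param sigma similarity scale (Angstrom); part of the functional form but
#'   not of the closed-form solution.
#' @param v_max plateau height; must exceed 1.
#' @return alpha, dimensionless.
#' @export
lssr_alpha <- function(sigma, v_max) {
  if (v_max <= 1) stop("v_max must exceed 1: normalisation V(sigma)=1 impossible")
  log(v_max / (v_max - 1))
}

#' Plateauing LSSR penalty
#'
#' @param delta_value nonnegative distance difference(s), Angstrom.
#' @param params an [lssr_params()] set.
#' @return penalty value(s) in `[0, v_max)`: zero at zero difference, 1 at
#'   `delta_value = sigma`, saturating at `v_max`.
#' @export
lssr_penalty <- function(delta_value, params = lssr_params()) {
  if (any(delta_value < 0)) stop("delta must be nonnegative")
  params$v_max * (1 - exp(-params$alpha * delta_value^2 / params$sigma^2))
}

# dV/d(delta); smooth through delta = 0 because V depends on delta^2
lssr_penalty_deriv <- function(delta_value, params) {
  2 * params$v_max * params$alpha * delta_value / params$sigma^2 *
    exp(-params$alpha * delta_value^2 / params$sigma^2)
}

#' Multi-copy NCS weight adjustment
#'
#' With `n` NCS-related chains every chain belongs to `n - 1` pairwise
#' restraint lists, so the aggregate pull on an atom grows with the group
#' size. Scaling the user weight by \eqn{1/(N_{chains} - 1)} keeps the
#' aggregate restraint pressure comparable across group sizes; for a single
#' pair the weight is returned unchanged.
#'
#' @param W_LSSR user base weight.
#' @param n_chains number of NCS-related chains (at least 2).
#' @return effective per-list weight.
#' @export
autoncs_weight <- function(W_LSSR, n_chains) {
  if (n_chains < 2) stop("n_chains must be at least 2")
  W_LSSR / (n_chains - 1)
}

## ----------------------------------------------------- restraint enumeration

# all unordered pairs with distance strictly below cutoff; grid cell list
# above `brute_max` atoms, dense otherwise
neighbor_pairs <- function(co, cutoff, brute_max = 700L) {
  n <- nrow(co)
  if (n < 2) return(cbind(i = integer(0), j = integer(0)))
  if (n <= brute_max) {
    d <- as.matrix(stats::dist(co))
    hit <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
    return(cbind(i = as.integer(hit[, 1]), j = as.integer(hit[, 2])))
  }
  cell <- floor(sweep(co, 2, apply(co, 2, min)) / cutoff)
  dim_n <- apply(cell, 2, max) + 2
  cid <- (cell[, 1] * dim_n[2] + cell[, 2]) * dim_n[3] + cell[, 3]
  members <- split(seq_len(n), cid)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  # keep lexicographically positive half plus the zero offset
  offs <- offs[offs$dx > 0 | (offs$dx == 0 & (offs$dy > 0 |
           (offs$dy == 0 & offs$dz >= 0))), ]
  ii <- integer(0); jj <- integer(0)
  keys <- as.numeric(names(members))
  for (k in seq_len(nrow(offs))) {
    dkey <- (offs$dx[k] * dim_n[2] + offs$dy[k]) * dim_n[3] + offs$dz[k]
    if (dkey == 0) {
      for (m in members) {
        if (length(m) < 2) next
        pr <- utils::combn(m, 2)
        ii <- c(ii, pr[1, ]); jj <- c(jj, pr[2, ])
      }
    } else {
      nb <- match(keys + dkey, keys)
      for (c1 in which(!is.na(nb))) {
        m1 <- members[[c1]]; m2 <- members[[nb[c1]]]
        g <- expand.grid(i = m1, j = m2)
        ii <- c(ii, g$i); jj <- c(jj, g$j)
      }
    }
  }
  keep <- sqrt((co[ii, 1] - co[jj, 1])^2 + (co[ii, 2] - co[jj, 2])^2 +
               (co[ii, 3] - co[jj, 3])^2) < cutoff
  cbind(i = pmin(ii, jj)[keep], j = pmax(ii, jj)[keep])
}

#' Build the LSSR restraint list for one correspondence
#'
#' Enumerates every unordered pair (i, j) of matched atoms such that (a)
#' both atoms belong to the correspondence, (b) the bond-path separation of
#' i and j is at least 3 bonds (1-2 and 1-3 pairs are governed by bond and
#' angle terms and excluded; 1-4 pairs and beyond are restrained), and (c)
#' the pair is closer than `params$cutoff` in either copy. Each qualifying
#' pair contributes one four-atom restraint (i, j, i', j').
#'
#' The pair set is decided once, at build time; re-evaluate distances with
#' [total_lssr()] as coordinates move.
#'
#' @param s structure under refinement (copy 1 lives here; for NCS both
#'   copies do).
#' @param corr an `atom_correspondence` from [match_atoms()] or
#'   [match_target()].
#' @param params [lssr_params()].
#' @param other the target structure for target-kind correspondences.
#' @param topology optional precomputed [build_topology()] of `s`.
#' @return a `restraint_list`: list with `restraints` data frame (`i1`,
#'   `j1`, `i2`, `j2` atom row indices, `class`, `r1`, `r2`, `delta`, `v`),
#'   `params`, `kind` and `label`.
#' @export
enumerate_restraints <- function(s, corr, params = lssr_params(), other = NULL,
                                 topology = NULL) {
  if (!inherits(corr, "atom_correspondence")) stop("corr must be an atom_correspondence")
  is_target <- identical(corr$kind, "target")
  if (is_target && is.null(other)) stop("target structure required via `other`")
  s2 <- if (is_target) other else s
  if (is.null(topology)) topology <- build_topology(s)
  co1 <- as.matrix(s$atoms[, c("x", "y", "z")])
  co2 <- as.matrix(s2$atoms[, c("x", "y", "z")])
  idx_a <- corr$idx_a; idx_b <- corr$idx_b
  if (!length(idx_a)) {
    return(new_restraint_list(empty_restraints(), params, corr))
  }
  map_b <- integer(nrow(co1)); map_b[idx_a] <- idx_b
  # candidates: close in copy 1 or close in copy 2 (mapped back to copy 1 ids)
  p1 <- neighbor_pairs(co1[idx_a, , drop = FALSE], params$cutoff)
  p2 <- neighbor_pairs(co2[idx_b, , drop = FALSE], params$cutoff)
  cand <- rbind(cbind(idx_a[p1[, 1]], idx_a[p1[, 2]]),
                cbind(idx_a[p2[, 1]], idx_a[p2[, 2]]))
  if (!nrow(cand)) {
    return(new_restraint_list(empty_restraints(), params, corr))
  }
  lo <- pmin(cand[, 1], cand[, 2]); hi <- pmax(cand[, 1], cand[, 2])
  keep <- !duplicated(pair_key_vec(lo, hi))
  i1 <- lo[keep]; j1 <- hi[keep]
  cls <- pair_class(topology, i1, j1)
  ok <- cls != "excluded"
  i1 <- i1[ok]; j1 <- j1[ok]; cls <- cls[ok]
  i2 <- map_b[i1]; j2 <- map_b[j1]
  r1 <- sqrt(rowSums((co1[i1, , drop = FALSE] - co1[j1, , drop = FALSE])^2))
  r2 <- sqrt(rowSums((co2[i2, , drop = FALSE] - co2[j2, , drop = FALSE])^2))
  ok <- r1 < params$cutoff | r2 < params$cutoff
  rs <- data.frame(i1 = i1[ok], j1 = j1[ok], i2 = i2[ok], j2 = j2[ok],
                   class = cls[ok], r1 = r1[ok], r2 = r2[ok],
                   stringsAsFactors = FALSE)
  ord <- order(rs$i1, rs$j1)
  rs <- rs[ord, , drop = FALSE]
  rs$delta <- abs(rs$r1 - rs$r2)
  rs$v <- lssr_penalty(rs$delta, params)
  rownames(rs) <- NULL
  new_restraint_list(rs, params, corr)
}

empty_restraints <- function() {
  data.frame(i1 = integer(), j1 = integer(), i2 = integer(), j2 = integer(),
             class = character(), r1 = numeric(), r2 = numeric(),
             delta = numeric(), v = numeric(), stringsAsFactors = FALSE)
}

new_restraint_list <- function(rs, params, corr) {
  structure(list(restraints = rs, params = params, kind = corr$kind,
                 label = paste(corr$chain_a, corr$chain_b, sep = ":")),
            class = "restraint_list")
}

#' @export
print.restraint_list <- function(x, ...) {
  cat(sprintf("<restraint_list %s (%s): %d restraints, weight %g>\n",
              x$label, x$kind, nrow(x$restraints), x$params$weight))
  invisible(x)
}

# recompute r1, r2, delta, v of a restraint list at current coordinates
evaluate_restraints <- function(rl, s, target = NULL) {
  r <- rl$restraints
  if (!nrow(r)) return(rl)
  co1 <- as.matrix(s$atoms[, c("x", "y", "z")])
  co2 <- if (identical(rl$kind, "target")) {
    if (is.null(target)) stop("target structure required to evaluate target-kind list")
    as.matrix(target$atoms[, c("x", "y", "z")])
  } else co1
  r$r1 <- sqrt(rowSums((co1[r$i1, , drop = FALSE] - co1[r$j1, , drop = FALSE])^2))
  r$r2 <- sqrt(rowSums((co2[r$i2, , drop = FALSE] - co2[r$j2, , drop = FALSE])^2))
  r$delta <- abs(r$r1 - r$r2)
  r$v <- lssr_penalty(r$delta, rl$params)
  rl$restraints <- r
  rl
}

#' Total LSSR energy
#'
#' Re-evaluates every restraint at the current coordinates and returns the
#' weighted sum \eqn{\sum_{lists} w \sum_k V(\Delta_k)} together with a
#' per-list and per-restraint breakdown.
#'
#' @param lists a `restraint_list` or list of them.
#' @param s structure under refinement (current coordinates).
#' @param target fixed target structure for target-kind lists.
#' @return list with `total`, `by_list` (data frame label/kind/n/weight/
#'   energy) and `lists` (the re-evaluated restraint lists).
#' @export
total_lssr <- function(lists, s, target = NULL) {
  if (inherits(lists, "restraint_list")) lists <- list(lists)
  lists <- lapply(lists, evaluate_restraints, s = s, target = target)
  by_list <- do.call(rbind, lapply(lists, function(rl) {
    data.frame(label = rl$label, kind = rl$kind, n = nrow(rl$restraints),
               weight = rl$params$weight,
               energy = rl$params$weight * sum(rl$restraints$v),
               stringsAsFactors = FALSE)
  }))
  list(total = sum(by_list$energy), by_list = by_list, lists = lists)
}

#' Analytic LSSR gradient
#'
#' Exact gradient of the weighted total penalty with respect to the mobile
#' coordinates. For NCS-kind lists all four atoms of each restraint are
#' mobile and the four gradient vectors of a restraint sum to zero
#' (translation invariance); for target-kind lists only the copy-1 atoms
#' move. A zero-length distance contributes zero gradient for that term.
#'
#' @param lists a `restraint_list` or list of them.
#' @param s structure under refinement.
#' @param target fixed target structure for target-kind lists.
#' @return numeric matrix `n_atoms(s)` x 3 of dE/dx.
#' @export
lssr_gradient <- function(lists, s, target = NULL) {
  if (inherits(lists, "restraint_list")) lists <- list(lists)
  co1 <- as.matrix(s$atoms[, c("x", "y", "z")])
  G <- matrix(0, nrow(co1), 3)
  for (rl in lists) {
    r <- evaluate_restraints(rl, s, target)$restraints
    if (!nrow(r)) next
    is_target <- identical(rl$kind, "target")
    co2 <- if (is_target) as.matrix(target$atoms[, c("x", "y", "z")]) else co1
    d_signed <- r$r1 - r$r2
    w_dv <- rl$params$weight * lssr_penalty_deriv(abs(d_signed), rl$params) *
      sign(d_signed)
    # copy-1 pair: dE/dr1 = +w dV/ddelta * sign(d)
    u1 <- (co1[r$i1, , drop = FALSE] - co1[r$j1, , drop = FALSE]) /
      ifelse(r$r1 > 0, r$r1, Inf)
    G <- accumulate_rows(G, r$i1, w_dv * u1)
    G <- accumulate_rows(G, r$j1, -w_dv * u1)
    if (!is_target) {
      u2 <- (co2[r$i2, , drop = FALSE] - co2[r$j2, , drop = FALSE]) /
        ifelse(r$r2 > 0, r$r2, Inf)
      G <- accumulate_rows(G, r$i2, -w_dv * u2)
      G <- accumulate_rows(G, r$j2, w_dv * u2)
    }
  }
  G
}

accumulate_rows <- function(G, idx, contrib) {
  agg <- rowsum(contrib, group = idx, reorder = FALSE)
  rows <- as.integer(rownames(agg))
  G[rows, ] <- G[rows, , drop = FALSE] + agg
  G
}

## ----------------------------------------------------------- list import/export

restraint_table <- function(rl, s, other = NULL) {
  r <- rl$restraints
  a1 <- s$atoms
  a2 <- if (identical(rl$kind, "target")) other$atoms else a1
  data.frame(
    chain_pair = rl$label,
    i_chain = a1$chain[r$i1], i_resnum = a1$resnum[r$i1],
    i_icode = a1$icode[r$i1], i_atom = a1$atom[r$i1],
    j_chain = a1$chain[r$j1], j_resnum = a1$resnum[r$j1],
    j_icode = a1$icode[r$j1], j_atom = a1$atom[r$j1],
    class = r$class, r1 = r$r1, r2 = r$r2, delta = r$delta, penalty = r$v,
    stringsAsFactors = FALSE
  )
}

#' Export a restraint list as TSV or JSON
#'
#' Numeric fields are written with 17 significant digits so that a
#' write/read cycle reproduces them bit-for-bit.
#'
#' @param rl a `restraint_list`.
#' @param s the structure the list was built on.
#' @param path output path.
#' @param format `"tsv"` or `"json"` (default from extension).
#' @param other target structure for target-kind lists.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(rl, s, path, format = NULL, other = NULL) {
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "tsv"
  }
  tab <- restraint_table(rl, s, other)
  if (format == "json") {
    writeLines(jsonlite::toJSON(tab, digits = I(17), dataframe = "rows"), path)
  } else {
    num <- vapply(tab, is.numeric, logical(1)) &
      !vapply(tab, is.integer, logical(1))
    out <- tab
    out[num] <- lapply(tab[num], function(v) sprintf("%.17g", v))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Import a restraint table written by [write_restraints()]
#'
#' @param path TSV or JSON file.
#' @param format `"tsv"` or `"json"` (default from extension).
#' @return data frame with the exported columns.
#' @export
read_restraints <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "tsv"
  }
  if (format == "json") {
    tab <- jsonlite::fromJSON(path)
    as.data.frame(tab, stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, sep = "\t", header = TRUE,
                      colClasses = c(chain_pair = "character",
                                     i_chain = "character", i_icode = "character",
                                     i_atom = "character", j_chain = "character",
                                     j_icode = "character", j_atom = "character",
                                     class = "character"),
                      stringsAsFactors = FALSE)
  }
}
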