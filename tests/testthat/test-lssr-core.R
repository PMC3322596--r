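# Distance pairs and printed differences from the published per-atom contact
# comparison (horse methaemoglobin, Ser102 OG environment, chains A vs C).
TABLE1 <- data.frame(
  r1 = c(2.912, 3.765, 4.550, 5.102, 2.671, 3.783, 5.056, 4.623, 4.314),
  r2 = c(3.000, 3.724, 4.427, 5.205, 3.051, 4.180, 5.367, 4.273, 3.918),
  printed = c(0.09, 0.04, 0.12, 0.10, 0.38, 0.40, 0.31, 0.35, 0.40))

test_that("delta reproduces the printed contact-difference column", {
  expect_equal(round(delta(TABLE1$r1, TABLE1$r2), 2), TABLE1$printed)
  expect_equal(delta(2.912, 3.000), 0.088)
  expect_equal(delta(2.671, 3.051), 0.380)
  expect_equal(delta(1.234, 1.234), 0)
  expect_equal(delta(3, 2), delta(2, 3))
  expect_error(delta(-1, 2), "nonnegative")
})

test_that("alpha normalises the penalty to 1 at delta = sigma", {
  expect_equal(lssr_alpha(0.2, 3), log(1.5))
  p <- lssr_params(sigma = 0.2, v_max = 3)
  expect_equal(lssr_penalty(0.2, p), 1, tolerance = 1e-12)
  # near-degenerate plateau height still normalises exactly
  p2 <- lssr_params(sigma = 0.2, v_max = 1.0001)
  expect_gt(p2$alpha, 9)
  expect_equal(lssr_penalty(0.2, p2), 1, tolerance = 1e-9)
  expect_error(lssr_alpha(0.2, 1), "v_max")
  expect_error(lssr_alpha(0.2, 0.5), "v_max")
})

test_that("penalty shape: zero at zero, harmonic limit, plateau at v_max", {
  p <- lssr_params()
  expect_equal(lssr_penalty(0, p), 0)
  expect_equal(lssr_penalty(2.0, p), 3, tolerance = 1e-6)
  expect_gte(lssr_penalty(0.7, p), 0.99 * p$v_max)
  expect_error(lssr_penalty(-0.1, p), "nonnegative")
  # strictly increasing until double precision saturates on the plateau
  set.seed(1)
  d <- sort(c(10^runif(40, -3, 0), seq(0.01, 1.2, length.out = 40)))
  v <- lssr_penalty(d, p)
  expect_true(all(diff(v) > 0))
  d2 <- seq(0, 3, by = 0.05)
  expect_true(all(diff(lssr_penalty(d2, p)) >= 0))
  expect_true(all(v >= 0 & v <= p$v_max))
  # V(delta)/delta^2 converges to a positive constant as delta -> 0
  small <- 10^seq(-2, -6, by = -1)
  ratio <- lssr_penalty(small, p) / small^2
  expect_equal(ratio / (p$v_max * p$alpha / p$sigma^2),
               rep(1, length(small)), tolerance = 1e-3)
})

test_that("multi-copy weight rule scales as 1/(n_chains - 1)", {
  expect_equal(autoncs_weight(1, 2), 1)
  expect_equal(autoncs_weight(1, 3), 0.5)
  expect_equal(autoncs_weight(2, 5), 0.5)
  expect_error(autoncs_weight(1, 1), "n_chains")
})

test_that("enumeration applies the either-copy cutoff and bonded exclusions", {
  # two 3-atom chains: pair (1,3) inside one residue has separation 2 (1-3)
  mk <- function(shift_b) {
    new_structure(rbind(
      data.frame(chain = "A", resnum = 1, icode = "", resname = "GLY",
                 atom = c("N", "CA", "C"), altloc = "",
                 x = c(0, 1.458, 1.98), y = c(0, 0, 1.43), z = 0,
                 occ = 1, b = 0, element = c("N", "C", "C"), het = FALSE),
      data.frame(chain = "B", resnum = 1, icode = "", resname = "GLY",
                 atom = c("N", "CA", "C"), altloc = "",
                 x = c(0, 1.458, 1.98) + shift_b[1],
                 y = c(0, 0, 1.43) + 40, z = shift_b[2],
                 occ = 1, b = 0, element = c("N", "C", "C"), het = FALSE)))
  }
  s <- mk(c(0, 0))
  rl <- enumerate_restraints(s, match_atoms(s, "A", "B"))
  expect_equal(nrow(rl$restraints), 0)      # only 1-2/1-3 pairs exist

  # separated atoms: 6.0 A in both copies -> excluded; 5.0/6.0 -> included
  far <- function(xa, xb) new_structure(rbind(
    data.frame(chain = c("A", "A"), resnum = c(1, 9), icode = "",
               resname = "GLY", atom = "CA", altloc = "",
               x = c(0, xa), y = 0, z = 0, occ = 1, b = 0,
               element = "C", het = FALSE),
    data.frame(chain = c("B", "B"), resnum = c(1, 9), icode = "",
               resname = "GLY", atom = "CA", altloc = "",
               x = c(0, xb), y = 40, z = 0, occ = 1, b = 0,
               element = "C", het = FALSE)))
  s66 <- far(6, 6)
  expect_equal(nrow(enumerate_restraints(s66, match_atoms(s66, "A", "B"))$restraints), 0)
  s56 <- far(5, 6)
  rl56 <- enumerate_restraints(s56, match_atoms(s56, "A", "B"))
  expect_equal(nrow(rl56$restraints), 1)
  expect_equal(rl56$restraints$r1, 5)
  expect_equal(rl56$restraints$r2, 6)
  # the cutoff itself is strict
  s55 <- far(5.5, 5.5)
  expect_equal(nrow(enumerate_restraints(s55, match_atoms(s55, "A", "B"))$restraints), 0)
})

test_that("enumeration matches the brute-force oracle on seeded fixtures", {
  for (seed in 1:6) {
    s <- two_copy_fixture(n_residues = 5, noise_sd = 0.3, seed = seed)
    corr <- match_atoms(s, "A", "B")
    rl <- enumerate_restraints(s, corr)
    oracle <- oracle_pairs(s, corr, lssr_params())
    expect_setequal(pair_ids(as.matrix(rl$restraints[c("i1", "j1")])),
                    pair_ids(oracle))
    expect_false(anyDuplicated(pair_ids(as.matrix(rl$restraints[c("i1", "j1")]))) > 0)
  }
})

test_that("1-4 pairs are classified and restrained, 1-2/1-3 never appear", {
  s <- two_copy_fixture(n_residues = 4, noise_sd = 0.05, seed = 20)
  rl <- enumerate_restraints(s, match_atoms(s, "A", "B"))
  topo <- build_topology(s)
  keys <- lssr:::pair_key_vec(rl$restraints$i1, rl$restraints$j1)
  expect_false(any(keys %in% topo$excl12_13))
  expect_true(any(rl$restraints$class == "one_four"))
  expect_true(all(keys[rl$restraints$class == "one_four"] %in% topo$one_four))
})

test_that("chain-order symmetry: (A,B) and (B,A) give the same restraints", {
  s <- two_copy_fixture(n_residues = 5, noise_sd = 0.2, seed = 21)
  ab <- enumerate_restraints(s, match_atoms(s, "A", "B"))
  ba <- enumerate_restraints(s, match_atoms(s, "B", "A"))
  id <- function(rl, i, j) {
    paste(s$atoms$resnum[rl$restraints[[i]]], s$atoms$atom[rl$restraints[[i]]],
          s$atoms$resnum[rl$restraints[[j]]], s$atoms$atom[rl$restraints[[j]]])
  }
  expect_setequal(id(ab, "i1", "j1"), id(ba, "i1", "j1"))
  expect_equal(total_lssr(ab, s)$total, total_lssr(ba, s)$total,
               tolerance = 1e-12)
})

test_that("total energy: zero iff all deltas zero, bounded, sums breakdown", {
  s0 <- two_copy_fixture(n_residues = 4, noise_sd = 0, seed = 1)
  rl0 <- enumerate_restraints(s0, match_atoms(s0, "A", "B"))
  expect_gt(nrow(rl0$restraints), 0)
  expect_equal(total_lssr(rl0, s0)$total, 0)

  s <- two_copy_fixture(n_residues = 4, noise_sd = 0.15, seed = 2)
  params <- lssr_params(weight = 2)
  rl <- enumerate_restraints(s, match_atoms(s, "A", "B"), params = params)
  tot <- total_lssr(rl, s)
  expect_gt(tot$total, 0)
  expect_equal(tot$total, 2 * sum(tot$lists[[1]]$restraints$v),
               tolerance = 1e-12)
  expect_lte(tot$total, 2 * nrow(rl$restraints) * params$v_max)
  expect_equal(tot$total, sum(tot$by_list$energy))
})

test_that("analytic gradient matches central finite differences", {
  s <- two_copy_fixture(n_residues = 4, noise_sd = 0.25, seed = 30)
  rl <- enumerate_restraints(s, match_atoms(s, "A", "B"),
                             params = lssr_params(weight = 1.7))
  chk <- finite_difference_check(rl, s)
  expect_lte(chk$max_rel_error, 1e-5)
  # four gradient vectors of each NCS restraint sum to zero: total gradient
  # over all atoms vanishes (translation invariance)
  G <- lssr_gradient(rl, s)
  expect_equal(colSums(G), c(0, 0, 0), tolerance = 1e-10)
})

test_that("gradient vanishes at delta = 0 and deep in the plateau", {
  s0 <- two_copy_fixture(n_residues = 4, noise_sd = 0, seed = 1)
  rl0 <- enumerate_restraints(s0, match_atoms(s0, "A", "B"))
  expect_equal(max(abs(lssr_gradient(rl0, s0))), 0)
  # plateau: two matched CA pairs, one distance stretched by 2 A
  p <- lssr_params()
  g_sigma <- abs(lssr:::lssr_penalty_deriv(p$sigma, p))
  g_plateau <- abs(lssr:::lssr_penalty_deriv(2.0, p))
  expect_lt(g_plateau / g_sigma, 1e-4)
})

test_that("target-kind lists move only the refined structure", {
  s <- two_copy_fixture(n_residues = 3, noise_sd = 0.1, seed = 31)
  tgt <- two_copy_fixture(n_residues = 3, noise_sd = 0.1, seed = 32)
  corr <- match_target(s, tgt)
  rl <- enumerate_restraints(s, corr, other = tgt)
  expect_gt(nrow(rl$restraints), 0)
  chk <- finite_difference_check(rl, s, target = tgt)
  expect_lte(chk$max_rel_error, 1e-5)
  # an identical target gives zero energy and zero gradient
  corr2 <- match_target(s, s)
  rl2 <- enumerate_restraints(s, corr2, other = s)
  expect_equal(total_lssr(rl2, s, target = s)$total, 0)
  expect_equal(max(abs(lssr_gradient(rl2, s, target = s))), 0)
})

test_that("restraint tables round-trip bit-exactly through TSV and JSON", {
  s <- two_copy_fixture(n_residues = 4, noise_sd = 0.2, seed = 33)
  rl <- enumerate_restraints(s, match_atoms(s, "A", "B"))
  for (ext in c(".tsv", ".json")) {
    f <- tempfile(fileext = ext)
    write_restraints(rl, s, f)
    back <- read_restraints(f)
    ref <- lssr:::restraint_table(rl, s)
    expect_identical(back$r1, ref$r1)
    expect_identical(back$r2, ref$r2)
    expect_identical(back$delta, ref$delta)
    expect_identical(back$penalty, ref$penalty)
    expect_identical(back$i_atom, ref$i_atom)
    expect_identical(back$class, ref$class)
  }
})
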