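test_that("NCS detection follows the 80% residue-name rule", {
  s <- two_copy_fixture(n_residues = 10, noise_sd = 0.02, seed = 2)
  expect_equal(detect_ncs_groups(s), list(c("A", "B")))

  # 7 of 10 shared residue numbers match (70%): below threshold, no group
  a <- s$atoms
  b_rows <- a$chain == "B" & a$resnum %in% 1:3
  a2 <- a[!(b_rows & !a$atom %in% c("N", "CA", "C", "O", "CB")), ]
  a2$resname[a2$chain == "B" & a2$resnum %in% 1:3] <- "XXX"
  expect_equal(detect_ncs_groups(new_structure(a2)), list())
  # and with a permissive threshold the same pair qualifies
  expect_equal(detect_ncs_groups(new_structure(a2), min_match_fraction = 0.5),
               list(c("A", "B")))
})

test_that("tetramer with two distinct sequences groups as {A,C} and {B,D}", {
  alpha <- generate_ncs_fixture(fixture_spec(
    n_residues = 4, n_chains = 2, sequence = c("ALA", "SER", "GLY", "LEU"),
    noise_sd = 0.02, seed = 3))
  beta <- generate_ncs_fixture(fixture_spec(
    n_residues = 4, n_chains = 2, sequence = c("PHE", "ASP", "ARG", "GLU"),
    noise_sd = 0.02, seed = 4))
  ab <- alpha$atoms
  ab$chain <- c(A = "A", B = "C")[ab$chain]
  bb <- beta$atoms
  bb$chain <- c(A = "B", B = "D")[bb$chain]
  bb[c("x", "y", "z")] <- bb[c("x", "y", "z")] + 120
  s <- new_structure(rbind(ab, bb))
  groups <- detect_ncs_groups(s)
  expect_equal(length(groups), 2)
  expect_true(any(vapply(groups, identical, TRUE, c("A", "C"))))
  expect_true(any(vapply(groups, identical, TRUE, c("B", "D"))))
})

test_that("NCS detection is independent of atom record order", {
  s <- two_copy_fixture(n_residues = 8, noise_sd = 0.05, seed = 6)
  set.seed(99)
  shuf <- new_structure(s$atoms[sample(nrow(s$atoms)), ])
  expect_equal(lapply(detect_ncs_groups(shuf), sort),
               lapply(detect_ncs_groups(s), sort))
})

test_that("match_atoms pairs by (resnum, icode, atom name) and reports gaps", {
  s <- two_copy_fixture(n_residues = 5, noise_sd = 0, seed = 1)
  corr <- match_atoms(s, "A", "B")
  n_chain <- sum(s$atoms$chain == "A")
  expect_equal(length(corr$idx_a), n_chain)
  expect_equal(length(corr$unmatched_a), 0)
  expect_identical(s$atoms$atom[corr$idx_a], s$atoms$atom[corr$idx_b])
  expect_identical(s$atoms$resnum[corr$idx_a], s$atoms$resnum[corr$idx_b])

  # remove one side chain from B: those atoms drop out of the pairing
  drop <- s$atoms$chain == "B" & s$atoms$resnum == 3 &
    !s$atoms$atom %in% c("N", "CA", "C", "O")
  s2 <- new_structure(s$atoms[!drop, ])
  corr2 <- match_atoms(s2, "A", "B")
  expect_equal(length(corr2$idx_a), n_chain - sum(drop))
  expect_equal(length(corr2$unmatched_a), sum(drop))
})

test_that("matching is order-independent and composes across chains", {
  s3 <- generate_ncs_fixture(fixture_spec(
    n_residues = 5, n_chains = 3, sequence = rep_len(mixed_seq, 5),
    noise_sd = 0.05, seed = 8))
  set.seed(7)
  shuf <- new_structure(s3$atoms[sample(nrow(s3$atoms)), ])
  key <- function(s, corr) {
    paste(s$atoms$resnum[corr$idx_a], s$atoms$atom[corr$idx_a],
          s$atoms$resnum[corr$idx_b], s$atoms$atom[corr$idx_b])
  }
  expect_setequal(key(shuf, match_atoms(shuf, "A", "B")),
                  key(s3, match_atoms(s3, "A", "B")))
  # composition A->B then B->C equals direct A->C
  ab <- match_atoms(s3, "A", "B")
  bc <- match_atoms(s3, "B", "C")
  ac <- match_atoms(s3, "A", "C")
  composed <- bc$idx_b[match(ab$idx_b, bc$idx_a)]
  expect_identical(composed, ac$idx_b)
})

test_that("match_target keys on chain id too and flags total mismatch", {
  s <- two_copy_fixture(n_residues = 4, noise_sd = 0.05, seed = 9)
  corr <- match_target(s, s)
  expect_equal(length(corr$idx_a), n_atoms(s))
  expect_identical(corr$idx_a, corr$idx_b)
  expect_equal(corr$kind, "target")

  other <- s
  other$atoms$chain <- c(A = "X", B = "Y")[other$atoms$chain]
  expect_error(match_target(s, new_structure(other$atoms)), "target")
})

test_that("residue-type substitution leaves shared atom names matched", {
  s <- generate_ncs_fixture(fixture_spec(
    n_residues = 3, n_chains = 1, sequence = c("ALA", "ARG", "GLY"),
    noise_sd = 0, seed = 1))
  tgt <- generate_ncs_fixture(fixture_spec(
    n_residues = 3, n_chains = 1, sequence = c("ALA", "GLN", "GLY"),
    noise_sd = 0, seed = 1))
  corr <- match_target(s, tgt)
  shared <- intersect(s$atoms$atom[s$atoms$resnum == 2],
                      tgt$atoms$atom[tgt$atoms$resnum == 2])
  matched2 <- s$atoms$atom[corr$idx_a][s$atoms$resnum[corr$idx_a] == 2]
  expect_setequal(matched2, shared)         # backbone + CB/CG/CD for ARG/GLN
  un2 <- s$atoms$atom[corr$unmatched_a]
  expect_setequal(un2, setdiff(s$atoms$atom[s$atoms$resnum == 2], shared))
})

test_that("a label-flipped PHE is found and swapped back, idempotently", {
  s <- generate_ncs_fixture(fixture_spec(
    n_residues = 5, n_chains = 2, sequence = c("ALA", "SER", "PHE", "GLY", "LEU"),
    noise_sd = 0.01, flips = data.frame(chain = "B", resnum = 3), seed = 11))
  corr <- match_atoms(s, "A", "B")
  before <- total_lssr(enumerate_restraints(s, corr), s)$total
  sw <- swap_equivalent_atoms(s, corr)
  expect_equal(nrow(sw$report), 1)
  expect_equal(sw$report$resname, "PHE")
  expect_equal(sw$report$pairs, "CD1<->CD2;CE1<->CE2")
  expect_lt(sw$report$penalty_after, sw$report$penalty_before)
  after <- total_lssr(enumerate_restraints(sw$structure, corr), sw$structure)$total
  expect_lt(after, before)
  # idempotence: nothing further to swap
  sw2 <- swap_equivalent_atoms(sw$structure, corr)
  expect_equal(nrow(sw2$report), 0)
})

test_that("well-matched copies produce zero swaps; plus mode adds HIS/ASN/GLN", {
  s <- generate_ncs_fixture(fixture_spec(
    n_residues = 6, n_chains = 2,
    sequence = c("ASP", "GLU", "TYR", "HIS", "ASN", "GLN"),
    noise_sd = 0.01, seed = 12))
  corr <- match_atoms(s, "A", "B")
  expect_equal(nrow(swap_equivalent_atoms(s, corr, mode = "plus")$report), 0)

  flipped <- generate_ncs_fixture(fixture_spec(
    n_residues = 6, n_chains = 2,
    sequence = c("ASP", "GLU", "TYR", "HIS", "ASN", "GLN"),
    noise_sd = 0.01, flips = data.frame(chain = "B", resnum = 4), seed = 12))
  # HIS flip is invisible to standard mode, repaired by plus mode
  expect_equal(nrow(swap_equivalent_atoms(flipped, corr)$report), 0)
  swp <- swap_equivalent_atoms(flipped, corr, mode = "plus")
  expect_equal(swp$report$resname, "HIS")
})

test_that("swapping never increases any adjusted residue's penalty", {
  for (seed in 1:5) {
    s <- generate_ncs_fixture(fixture_spec(
      n_residues = 6, n_chains = 2,
      sequence = c("ASP", "PHE", "ARG", "TYR", "GLU", "SER"),
      noise_sd = 0.15, seed = seed))
    sw <- swap_equivalent_atoms(s, match_atoms(s, "A", "B"), mode = "standard")
    if (nrow(sw$report)) {
      expect_true(all(sw$report$penalty_after <= sw$report$penalty_before))
    }
  }
  succeed()
})

test_that("residues missing half a symmetric pair are skipped with a log", {
  s <- generate_ncs_fixture(fixture_spec(
    n_residues = 3, n_chains = 2, sequence = c("ALA", "ASP", "GLY"),
    noise_sd = 0.05, seed = 13))
  keep <- !(s$atoms$chain == "B" & s$atoms$resnum == 2 & s$atoms$atom == "OD2")
  s2 <- new_structure(s$atoms[keep, ])
  sw <- swap_equivalent_atoms(s2, match_atoms(s2, "A", "B"))
  skipped <- attr(sw$report, "skipped")
  expect_false(is.null(skipped))
  expect_equal(skipped$resname, "ASP")
})
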