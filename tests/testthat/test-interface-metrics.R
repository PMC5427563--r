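# Single-residue chains whose nearest heavy atoms sit a controlled distance
# apart along x.
gap_dimer <- function(gap) {
  mk <- function(cid, x) {
    chain_structure(cid, data.frame(res_seq = 1L, res_name = "ALA",
                                    atom_name = "CA", element = "C",
                                    x = x, y = 0, z = 0))
  }
  dimer_structure(mk("A", 0), mk("B", gap))
}

test_that("interface_residues honors the 10 A boundary exactly", {
  inside <- interface_residues(gap_dimer(9.9))
  expect_equal(inside$receptor_residues, 1L)
  expect_equal(inside$ligand_residues, 1L)
  outside <- interface_residues(gap_dimer(10.1))
  expect_length(outside$receptor_residues, 0)
  expect_length(outside$ligand_residues, 0)
  expect_error(interface_residues(gap_dimer(5), cutoff = -1), "positive")
})

test_that("interface_residues matches a brute-force all-pair scan on a toy dimer", {
  d <- toy_dimer_fixture()
  got <- interface_residues(d, 10)
  want <- oracle_interface(d, 10)
  expect_identical(as.integer(got$receptor_residues), as.integer(want$receptor))
  expect_identical(as.integer(got$ligand_residues), as.integer(want$ligand))
  expect_gte(length(got$receptor_residues) + length(got$ligand_residues), 20)
})

test_that("contact_map finds exactly the residue pairs within the cutoff", {
  expect_equal(nrow(contact_map(gap_dimer(4.9))$contacts), 1)
  expect_equal(nrow(contact_map(gap_dimer(5.1))$contacts), 0)
  d <- toy_dimer_fixture()
  cm <- contact_map(d, 5)
  # brute-force enumeration over residue pairs
  want <- list()
  for (r in chain_res_seq(d$receptor)) {
    ra <- d$receptor$atoms[d$receptor$atoms$res_seq == r, ]
    for (l in chain_res_seq(d$ligand)) {
      la <- d$ligand$atoms[d$ligand$atoms$res_seq == l, ]
      dmin <- min(sqrt(outer(ra$x, la$x, `-`)^2 + outer(ra$y, la$y, `-`)^2 +
                         outer(ra$z, la$z, `-`)^2))
      if (dmin <= 5) want[[length(want) + 1]] <- c(r, l)
    }
  }
  want <- do.call(rbind, want)
  got <- cm$contacts[order(cm$contacts[, 1], cm$contacts[, 2]), , drop = FALSE]
  want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
  expect_equal(unname(got), unname(want))
})

test_that("irmsd: zero on self, exact under pure ligand translation, rigid-invariant", {
  d <- toy_dimer_fixture()
  expect_equal(irmsd(d, d), 0, tolerance = 1e-9)
  shifted <- perturb_native(d, 0, 3.0, seed = 2)$dimer
  expect_equal(irmsd(shifted, d), 3.0, tolerance = 1e-6)
  tf <- rigid_transform(rotation_about_axis(c(1, 2, 3), 77), c(10, -5, 2))
  moved <- apply_transform(tf, shifted)
  expect_equal(irmsd(moved, d), 3.0, tolerance = 1e-6)
  expect_equal(irmsd(apply_transform(tf, d), d), 0, tolerance = 1e-6)
})

test_that("irmsd errors on empty interfaces and unmatched residues", {
  far <- gap_dimer(50)
  expect_error(irmsd(far, far), "interface")
  d <- toy_dimer_fixture()
  clipped <- d
  clipped$ligand$atoms <- clipped$ligand$atoms[clipped$ligand$atoms$res_seq > 5, ]
  expect_error(irmsd(clipped, d), "missing residues")
})

test_that("pcs: 1 on self, hand-enumerated value, <= 0 on disjoint contacts", {
  d <- toy_dimer_fixture()
  expect_equal(pcs(d, d), 1.0)
  # hand case via the confusion identity: universe 5x5, 5 reference contacts,
  # 4 model contacts of which 3 shared -> TP 3 FP 1 FN 2 TN 19
  expect_equal(classify_metrics(3, 1, 19, 2)$mcc, 55 / sqrt(8400),
               tolerance = 1e-12)
  flipped <- perturb_native(d, 180, 12, seed = 4)$dimer
  if (nrow(contact_map(flipped)$contacts) >= 0) {
    expect_lte(pcs(flipped, d), 0.2)  # far-from-native pose scores near/below 0
  }
  expect_error(pcs(gap_dimer(30), gap_dimer(30)), "no contacts")
})

test_that("classify_metrics matches hand values and handles degenerate counts", {
  m <- classify_metrics(8, 2, 8, 2)
  expect_equal(m$tpr, 0.8)
  expect_equal(m$fpr, 0.2)
  expect_equal(m$acc, 0.8)
  expect_equal(m$mcc, 0.6)
  perfect <- classify_metrics(5, 0, 7, 0)
  expect_equal(c(perfect$tpr, perfect$fpr, perfect$acc, perfect$mcc),
               c(1, 0, 1, 1))
  # always-positive predictor: zero denominator -> MCC 0 by convention
  expect_equal(classify_metrics(10, 10, 0, 0)$mcc, 0)
  expect_error(classify_metrics(0, 0, 0, 0), "zero")
  expect_error(classify_metrics(-1, 0, 1, 0), "non-negative")
})

test_that("interface_overlap_mcc: self-identity, designed overlap, disjoint interfaces", {
  # receptor 80 residues; 20-residue ligand placed near the bottom (A), with a
  # tiny jitter (B), and near the top (C): A~B redundant, A vs C disjoint
  rec <- make_toy_monomer(80, seed = 1, chain_id = "A")
  lig <- make_toy_monomer(20, seed = 2, chain_id = "B")
  shift_ligand <- function(dz) {
    l2 <- lig
    l2$atoms$x <- l2$atoms$x + 10.5
    l2$atoms$z <- l2$atoms$z + dz
    dimer_structure(rec, l2)
  }
  A <- shift_ligand(0)
  B <- perturb_native(A, 2, 0.3, seed = 9)$dimer
  C <- shift_ligand(85)
  expect_equal(interface_overlap_mcc(A, A), 1.0)
  expect_gt(interface_overlap_mcc(A, B), 0.5)
  expect_lt(interface_overlap_mcc(A, C), 0.2)
  expect_error(interface_overlap_mcc(A, toy_dimer_fixture()), "pairable")
})

test_that("success_rate counts targets with a passing model in the top k", {
  native <- toy_dimer_fixture()
  near <- perturb_native(native, 2, 1, seed = 1)$dimer
  far <- perturb_native(native, 90, 25, seed = 2)$dimer
  crit <- acceptance_criteria("model")
  targets <- list(
    list(models = list(native, far), reference = native),       # passes at rank 1
    list(models = list(far, near), reference = native),         # passes at rank 2
    list(models = rep(list(far), 12), reference = native)       # never passes
  )
  expect_equal(success_rate(targets, crit, top_k = 10), 2 / 3)
  expect_equal(success_rate(targets[1:2], crit, top_k = 10), 1.0)
  expect_equal(success_rate(targets[3], crit, top_k = 10), 0.0)
  # rank window matters: the rank-2 hit is invisible at top_k = 1
  expect_equal(success_rate(targets, crit, top_k = 1), 1 / 3)
  expect_error(success_rate(list(), crit), "empty")
})

test_that("failure_spectrum partitions targets and is monotone in threshold", {
  native <- toy_dimer_fixture()
  mk <- function(rot, trans, seed) perturb_native(native, rot, trans, seed)$dimer
  # target 1: native-like at rank 1; target 2: native-like buried at rank 3
  # (scoring failure for top_k = 2); target 3: nothing native-like (sampling)
  targets <- list(
    list(models = list(mk(1, 0.5, 1), mk(60, 15, 2), mk(70, 18, 3)),
         reference = native),
    list(models = list(mk(60, 15, 4), mk(70, 18, 5), mk(1, 0.5, 6)),
         reference = native),
    list(models = list(mk(60, 15, 7), mk(70, 18, 8), mk(80, 20, 9)),
         reference = native)
  )
  qf <- function(m, r) -irmsd(m, r)
  thresholds <- c(-30, -8.5, -2.5, -0.01)
  sp <- failure_spectrum(targets, qf, thresholds, top_k = 2)
  sums <- sp$success_fraction + sp$scoring_failure_fraction +
    sp$sampling_failure_fraction
  expect_equal(sums, rep(1, nrow(sp)), tolerance = 1e-12)
  expect_true(all(diff(sp$success_fraction) <= 1e-12))
  # permissive threshold: everything succeeds
  expect_equal(sp$success_fraction[1], 1)
  # at -2.5 target 2 is a scoring failure, target 3 a sampling failure
  row <- sp[sp$quality_threshold == -2.5, ]
  expect_equal(row$success_fraction, 1 / 3)
  expect_equal(row$scoring_failure_fraction, 1 / 3)
  expect_equal(row$sampling_failure_fraction, 1 / 3)
  expect_error(failure_spectrum(targets, qf, numeric(0)), "empty")
})

test_that("acceptance_criteria presets follow the crystal/model thresholds", {
  crystal <- acceptance_criteria("crystal")
  expect_equal(c(crystal$irmsd_max, crystal$pcs_min), c(2.5, 0.65))
  model <- acceptance_criteria("model")
  expect_equal(c(model$irmsd_max, model$pcs_min), c(8.5, 0.30))
  expect_error(acceptance_criteria(irmsd_max = -1, pcs_min = 0.5), "positive")
  expect_error(acceptance_criteria(irmsd_max = 2, pcs_min = 1.5), "pcs_min")
})
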