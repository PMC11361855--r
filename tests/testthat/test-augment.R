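# SMILES enumeration, cyclic arrangements and replica assembly.

test_that("enumerated SMILES are valid reorderings of the same molecule", {
  base <- parse_peptide("x", "OCC")$canonical
  out <- enumerate_smiles("OCC", 5, 1)
  expect_length(out, 5)
  for (s in out) expect_identical(parse_peptide("x", s)$canonical, base)

  expect_length(enumerate_smiles("OCC", 1, 3), 1)
  # a molecule with distinguishable atoms yields several distinct renderings
  tol <- enumerate_smiles("Cc1ccccc1", 10, 2)
  expect_gte(length(unique(tol)), 2)
  # determinism
  expect_identical(out, enumerate_smiles("OCC", 5, 1))
})

test_that("sequence arrangements enumerate the rotation x translation grid", {
  m <- matrix(1:6, 3, 2)  # rows a, b, c

  # L = max_len: the only arrangements are the 3 cyclic rotations
  arrs <- sequence_arrangements(m, max_len = 3, n = 30, seed = 1)
  keys <- unique(vapply(arrs, function(a) paste(a$matrix, collapse = ","), ""))
  expect_length(keys, 3)
  rots <- lapply(0:2, function(r) m[((0:2 + r) %% 3) + 1, ])
  for (r in rots) {
    expect_true(paste(r, collapse = ",") %in% keys)
  }

  # L = 2, max_len = 4: 2 rotations x 3 offsets = 6 distinct cells
  m2 <- matrix(1:4, 2, 2)
  arrs2 <- sequence_arrangements(m2, max_len = 4, n = 6, seed = 5)
  keys2 <- vapply(arrs2, function(a) paste(a$matrix, collapse = ","), "")
  expect_length(unique(keys2), 6)  # without replacement until exhausted

  # exhausted grid continues with replacement, deterministically
  arrs3 <- sequence_arrangements(m2, max_len = 4, n = 10, seed = 5)
  expect_length(unique(vapply(arrs3[1:6], function(a)
    paste(a$matrix, collapse = ","), "")), 6)
  expect_identical(
    lapply(arrs3, `[[`, "matrix"),
    lapply(sequence_arrangements(m2, max_len = 4, n = 10, seed = 5), `[[`, "matrix"))

  expect_error(sequence_arrangements(m, max_len = 2, n = 1, seed = 1),
               class = "pepperm_size_error")
})

test_that("replica bundles combine the three augmentation schemes coherently", {
  feats <- small_features()
  expect_s3_class(feats, "pepperm_replicas")
  rec <- feats$records[[1]]
  expect_length(rec$replicas, 2)

  # all replicas of a peptide carry the identical label
  labs <- vapply(rec$replicas, `[[`, numeric(1), "label")
  expect_identical(labs, rep(rec$label, 2))

  # same multiset of atoms in every replica
  ord_rows <- function(m) m[do.call(order, as.data.frame(m)), ]
  nf <- lapply(rec$replicas, function(rp)
    node_features(list(atoms = rp$atoms, bonds = rp$bonds)))
  expect_equal(ord_rows(nf[[1]]), ord_rows(nf[[2]]))

  # graph matrices are permutation-related; conf matrices generally differ
  gd <- lapply(rec$replicas, function(rp)
    graph_distance_matrix(list(atoms = rp$atoms, bonds = rp$bonds)))
  expect_equal(sort(c(gd[[1]])), sort(c(gd[[2]])))
  cd <- lapply(rec$replicas, function(rp) conf_distance_matrix(rp$coords))
  expect_gt(max(abs(sort(c(cd[[1]])) - sort(c(cd[[2]])))), 1e-6)

  # monomer row multiset is preserved under arrangement
  expect_identical(nrow(rec$replicas[[1]]$monomer_desc), rec$n_monomers)

  # replica generation is reproducible
  again <- build_replicas(small_synth()$records[1], r = 2, seed = 7)
  expect_identical(again$records[[1]]$replicas[[1]]$coords,
                   rec$replicas[[1]]$coords)
  expect_identical(again$records[[1]]$replicas[[1]]$desc16,
                   rec$replicas[[1]]$desc16)
})

test_that("feature tables export as flat CSV with bitstring fingerprints", {
  feats <- small_features()
  dir <- tempfile(); dir.create(dir)
  write_feature_csv(feats, dir)
  pep <- utils::read.csv(file.path(dir, "peptide_features.csv"),
                         colClasses = c(fingerprint = "character"))
  expect_equal(nrow(pep), length(feats$records) * feats$r)
  expect_true(all(DESCRIPTOR_NAMES %in% names(pep)))
  expect_true(all(nchar(pep$fingerprint) == 2048))
  mono <- utils::read.csv(file.path(dir, "monomer_features.csv"))
  expect_identical(sum(mono$replica == 0),
                   sum(vapply(feats$records, `[[`, 0L, "n_monomers")))
})

test_that("single-replica bundles match the unaugmented featurization", {
  rec <- small_synth()$records[[2]]
  feats <- build_replicas(list(rec), r = 1, seed = 7)
  rep1 <- feats$records[[1]]$replicas[[1]]
  # fingerprint equals the direct computation on the parent SMILES
  expect_identical(feats$records[[1]]$fingerprint, morgan_fingerprint(rec$smiles))
  # descriptors equal the direct computation on the replica conformer
  direct <- compute_descriptors(rep1$smiles, rep1$coords)
  expect_equal(unname(rep1$desc16), unname(direct), tolerance = 1e-9)
})
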