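# Node encodings, pairwise matrices and attenuation.

test_that("node features one-hot encode peptide-relevant chemistry", {
  nf <- node_features("c1ccccc1")
  expect_identical(dim(nf), c(6L, 30L))
  # blocks: type 1-8, degree 9-13, H 14-18, charge 19-22, hyb 23-25,
  # chirality 26-28, ring 29, aromatic 30
  expect_true(all(nf[, 1] == 1))    # carbon slot
  expect_true(all(nf[, 24] == 1))   # sp2
  expect_true(all(nf[, 29] == 1))   # in ring
  expect_true(all(nf[, 30] == 1))   # aromatic

  nm <- node_features("C")          # methane
  expect_equal(nm[1, 18], 1)        # four hydrogens
  expect_equal(nm[1, 13], 1)        # heavy-atom degree 0 -> "other" slot
  expect_equal(nm[1, 29], 0)
})

test_that("every one-hot block contains exactly one 1", {
  blocks <- list(1:8, 9:13, 14:18, 19:22, 23:25, 26:28)
  for (smi in c("CCO", "c1ccccc1", "C[C@H](N)C(=O)O", "FC(Cl)Br", "C[N+](C)(C)C")) {
    nf <- node_features(smi)
    for (b in blocks) {
      expect_true(all(rowSums(nf[, b, drop = FALSE]) == 1),
                  label = sprintf("%s block %s", smi, b[1]))
    }
    expect_true(all(nf[, 29:30] %in% c(0, 1)))
  }
})

test_that("bond matrix uses the fixed weight vocabulary with precedence", {
  bz <- bond_matrix("c1ccccc1")
  expect_equal(bz[1, 2], 1.5)                    # aromatic
  bd <- bond_matrix("C=CC=C")
  expect_equal(bd[2, 3], 1.4)                    # conjugated single
  expect_equal(bd[1, 2], 2.0)                    # double keeps its order
  et <- bond_matrix("CC")
  expect_equal(et[1, 2], 1.0)
  expect_equal(diag(et), c(0, 0))
  yne <- bond_matrix("C#C")
  expect_equal(yne[1, 2], 3.0)

  for (smi in c("c1ccccc1", "C=CC=C", "CC(=O)NC")) {
    b <- bond_matrix(smi)
    expect_identical(b, t(b))
    expect_true(all(b %in% c(0, 1.0, 1.4, 1.5, 2.0, 3.0)))
  }
})

test_that("graph distances equal an independent BFS oracle", {
  pr <- graph_distance_matrix("CCC")
  expect_equal(pr[1, 3], 2)
  bz <- graph_distance_matrix("c1ccccc1")
  expect_equal(bz[1, 4], 3)                      # para pair

  for (smi in c("CCO", "c1ccccc1", "CC(C)CC(=O)NC", "C1CC1CCl")) {
    g <- graph_distance_matrix(smi)
    adj <- (bond_matrix(smi) > 0) * 1
    expect_equal(g, bfs_distances(adj))
    expect_identical(g, t(g))
    expect_true(all(diag(g) == 0))
  }
})

test_that("3D distances follow the Euclidean formula", {
  two <- conf_distance_matrix(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(two[1, 2], 5)
  expect_equal(conf_distance_matrix(rbind(c(1, 1, 1), c(1, 1, 1)))[1, 2], 0)

  set.seed(8)
  pts <- matrix(rnorm(15), 5, 3)
  d <- conf_distance_matrix(pts)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(d[i, j], sqrt(sum((pts[i, ] - pts[j, ])^2)))
  }
  expect_error(conf_distance_matrix(rbind(c(0, 0, 0), c(NA, 1, 1))),
               class = "pepperm_input_error")
})

test_that("attenuation is 1/d, clipped, with unit diagonal and zero padding", {
  d <- matrix(c(0, 2, 4, 2, 0, 0.8, 4, 0.8, 0), 3, 3)
  s <- attenuation(d)
  expect_equal(diag(s), rep(1, 3))
  expect_equal(s[1, 2], 0.5)
  expect_equal(s[1, 3], 0.25)
  expect_equal(s[2, 3], 1)                        # 1/0.8 clipped to 1
  expect_true(all(s >= 0 & s <= 1))

  # degenerate off-diagonal zero distance between real atoms
  dz <- matrix(c(0, 0, 0, 0), 2, 2)
  expect_error(attenuation(dz), class = "pepperm_degeneracy_error")

  # padding is zeroed, diagonal included
  mask <- c(TRUE, TRUE, FALSE)
  sp <- attenuation(d, mask)
  expect_true(all(sp[3, ] == 0) && all(sp[, 3] == 0))

  # monotone non-increasing in distance
  dd <- seq(1, 10, by = 0.5)
  m <- attenuation(as.matrix(stats::dist(cbind(cumsum(dd)))))
  expect_true(all(diff(m[1, -1]) <= 1e-12))
})

test_that("strength of bonded pairs is exactly 1 via graph distance", {
  for (smi in c("CCO", "CC(=O)NC")) {
    g <- graph_distance_matrix(smi)
    s <- attenuation(g)
    b <- bond_matrix(smi) > 0
    expect_true(all(s[b] == 1))
  }
})

test_that("padded atom feature sets are consistent and permutation-covariant", {
  smi <- "CC(=O)NCC(=O)O"
  cs <- generate_conformers(smi, 1, 4)
  afs <- atom_feature_set(smi, cs$coordinates[[1]], n_max = 16)
  n <- afs$n_real
  expect_identical(sum(afs$mask), n)
  expect_true(all(afs$node[(n + 1):16, ] == 0))
  expect_true(all(afs$bond[, (n + 1):16] == 0))
  expect_identical(afs$strength_graph, t(afs$strength_graph))
  expect_equal(diag(afs$strength_conf)[1:n], rep(1, n))

  # an enumerated reordering yields the same multisets of features
  alt <- enumerate_smiles(smi, 1, 31)
  cs2 <- generate_conformers(alt, 1, 4)
  afs2 <- atom_feature_set(alt, cs2$coordinates[[1]], n_max = 16)
  ord_rows <- function(m) m[do.call(order, as.data.frame(m)), ]
  expect_equal(ord_rows(node_features(smi)), ord_rows(node_features(alt)))
  expect_equal(sort(afs$graph[afs$mask, afs$mask]),
               sort(afs2$graph[afs2$mask, afs2$mask]))
  expect_equal(sort(round(c(bond_matrix(smi)), 6)),
               sort(round(c(bond_matrix(alt)), 6)))
})
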