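# Peptide parsing, macrocycle division, capping and conformers.

test_that("parse_peptide validates and counts heavy atoms", {
  rec <- parse_peptide("p1", "C1CC(=O)NC(=O)N1", label = -6.0)
  expect_s3_class(rec, "peptide_record")
  expect_identical(rec$n_heavy, 8L)
  expect_equal(rec$label, -6.0)

  expect_error(parse_peptide("p2", ""), class = "pepperm_input_error")
  expect_error(parse_peptide("p3", "C.C"), class = "pepperm_input_error")
  expect_error(parse_peptide("p4", "not-smiles"), class = "pepperm_input_error")
  expect_error(parse_peptide("p5", "CCCCCCCCCC", max_heavy = 5),
               class = "pepperm_size_error")
})

test_that("divide_monomers cleaves only macrocycle amide bonds", {
  rec <- parse_peptide("g3", "C1NC(=O)CNC(=O)CNC1=O")
  units <- divide_monomers(rec)
  expect_length(units, 3)
  expect_true(all(vapply(units, `[[`, "", "capped_smiles") == "CNCC=O"))
  expect_identical(vapply(units, `[[`, integer(1), "position"), 0:2)

  # atom indices partition the heavy atoms
  idx <- unlist(lapply(units, `[[`, "atom_indices"))
  expect_identical(sort(idx), seq_len(rec$n_heavy))

  # annotation passthrough
  rec2 <- parse_peptide("a6", "C1NC(=O)CNC(=O)CNC1=O",
                        monomer_smiles = rep("CNCC=O", 6))
  expect_length(divide_monomers(rec2), 6)

  # no macrocycle, no annotation
  benz <- parse_peptide("bz", "c1ccccc1")
  expect_error(divide_monomers(benz), class = "pepperm_division_error")
})

test_that("homopolymer macrocycles divide into n identical capped units", {
  for (n in c(3, 5, 7)) {
    smiles <- paste0("N1CC(=O)", strrep("NCC(=O)", n - 2), "NCC1=O")
    rec <- parse_peptide(paste0("g", n), smiles)
    units <- divide_monomers(rec)
    expect_length(units, n)
    expect_length(unique(vapply(units, `[[`, "", "capped_smiles")), 1)
    idx <- unlist(lapply(units, `[[`, "atom_indices"))
    expect_identical(sort(idx), seq_len(rec$n_heavy))  # disjoint cover
  }
})

test_that("capping methylates amine/ester ends and leaves aldehydes", {
  expect_identical(cap_fragment("O=CCN[*]"), "CNCC=O")     # amine N end
  expect_identical(cap_fragment("CCO"), "CCO")             # no markers
  # ester oxygen end gains a methyl
  capped <- cap_fragment("O=CC(C)O[*]")
  expect_identical(capped, "COC(C)C=O")
  # acyl carbon end becomes an aldehyde (H, no methyl)
  expect_identical(cap_fragment("[*]C(=O)CN"), "NCC=O")
})

test_that("conformer generation is seeded, finite and physically sane", {
  cs1 <- generate_conformers("CCO", 3, 42)
  cs2 <- generate_conformers("CCO", 3, 42)
  expect_length(cs1$coordinates, 3)
  expect_true(all(vapply(cs1$coordinates, function(m) all(is.finite(m)), TRUE)))
  expect_identical(cs1$coordinates, cs2$coordinates)  # bitwise reproducible
  expect_identical(cs1$seeds, 42:44)

  # different seeds give different coordinates for a flexible molecule
  cs3 <- generate_conformers("CCCCCC", 1, 1)
  cs4 <- generate_conformers("CCCCCC", 1, 99)
  expect_gt(max(abs(cs3$coordinates[[1]] - cs4$coordinates[[1]])), 1e-4)

  # single atom: one finite point
  c1 <- generate_conformers("C", 1, 0)
  expect_identical(dim(c1$coordinates[[1]]), c(1L, 3L))

  # bonded C-C distances after UFF minimization in the standard range
  hex <- generate_conformers("CCCCCC", 2, 7)
  for (m in hex$coordinates) {
    d <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-6, , drop = FALSE])^2))
    expect_true(all(d > 1.4 & d < 1.7))
  }
})

test_that("conformer sets round-trip through SDF", {
  cs <- generate_conformers("CCO", 2, 5, id = "eth")
  path <- tempfile(fileext = ".sdf")
  write_conformers_sdf(cs, path)
  txt <- readLines(path)
  expect_length(grep("\\$\\$\\$\\$", txt), 2)   # one record per conformer
  expect_true(any(grepl("parent_id", txt)))
  expect_true(any(grepl("^5$", txt)))           # stored seed
})

test_that("peptide CSV and HELM-style sequences load into records", {
  dir <- tempfile(); dir.create(dir)
  write_synth_csv(small_synth(), dir)
  recs <- read_peptides_csv(file.path(dir, "peptides.csv"),
                            monomer_library = file.path(dir, "monomer_library.csv"))
  expect_length(recs, 12)
  expect_true(all(vapply(recs, function(r) !is.null(r$monomers), TRUE)))
  # attached monomer annotation matches the generating one
  orig <- small_synth()$records[[1]]
  got <- recs[vapply(recs, `[[`, "", "id") == orig$id][[1]]
  expect_identical(vapply(got$monomers, `[[`, "", "capped_smiles"),
                   vapply(orig$monomers, `[[`, "", "capped_smiles"))
})
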