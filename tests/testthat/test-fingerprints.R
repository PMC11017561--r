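test_that("SMILES parsing canonicalizes and is idempotent", {
  m1 <- parse_smiles("OCC")
  m2 <- parse_smiles("CCO")
  expect_identical(m1$smiles, m2$smiles)
  expect_identical(parse_smiles(m1$smiles)$smiles, m1$smiles)
  expect_s3_class(parse_smiles("c1ccccc1"), "synfuse_molecule")
  # several equivalent spellings of one molecule
  pairs <- list(c("OCC", "CCO"),
                c("c1ccccc1", "C1=CC=CC=C1"),
                c("CC(=O)O", "OC(C)=O"),
                c("c1ccncc1", "C1=CC=NC=C1"),
                c("CC(C)O", "OC(C)C"),
                c("N#Cc1ccccc1", "c1ccccc1C#N"))
  for (p in pairs) {
    expect_identical(parse_smiles(p[1])$smiles, parse_smiles(p[2])$smiles)
  }
})

test_that("unparsable or empty SMILES raise invalid_smiles_error", {
  expect_error(parse_smiles("C1CC"), class = "invalid_smiles_error")
  expect_error(parse_smiles(""), class = "invalid_smiles_error")
  expect_error(parse_smiles("   "), class = "invalid_smiles_error")
  expect_error(parse_smiles(NA_character_), class = "invalid_smiles_error")
})

test_that("multi-fragment SMILES keep the largest fragment", {
  salt <- parse_smiles("CCN(CC)CCOC(=O)c1ccc(N)cc1.Cl")
  free <- parse_smiles("CCN(CC)CCOC(=O)c1ccc(N)cc1")
  expect_identical(salt$smiles, free$smiles)
})

test_that("MACCS fingerprints are 166-bit binary vectors", {
  for (smi in c("c1ccccc1", "C", "CC(=O)Oc1ccccc1C(=O)O")) {
    fp <- compute_maccs(parse_smiles(smi))
    expect_length(fp, 166L)
    expect_true(all(fp %in% c(0L, 1L)))
  }
  # benzene sets the aromatic/ring keys and nothing hydrogen-ish;
  # positions cross-checked against an independent MACCS implementation
  benz <- compute_maccs(parse_smiles("c1ccccc1"))
  expect_identical(which(benz == 1L), c(162L, 163L, 165L))
  meth <- compute_maccs(parse_smiles("C"))
  expect_identical(which(meth == 1L), 160L)
  expect_false(identical(benz, meth))
})

test_that("hashed torsion fingerprints follow the 4-atom path definition", {
  # propane has no 4-atom path: all-zero with a degenerate-molecule warning
  expect_warning(tt3 <- compute_hashtt(parse_smiles("CCC"), 128L),
                 class = "degenerate_molecule_warning")
  expect_identical(sum(tt3), 0L)
  # n-butane has exactly one torsion fragment: exactly one bit set
  tt4 <- compute_hashtt(parse_smiles("CCCC"), 128L)
  expect_identical(sum(tt4), 1L)
  expect_length(tt4, 128L)
  # determinism and configurable length
  mol <- parse_smiles("CC(=O)Oc1ccccc1C(=O)O")
  expect_identical(compute_hashtt(mol, 256L), compute_hashtt(mol, 256L))
  expect_length(compute_hashtt(mol, 1024L), 1024L)
  expect_error(compute_hashtt(mol, 32L), class = "domain_error")
})

test_that("MAP4 fingerprints are deterministic, binary and length dims", {
  mol <- parse_smiles("CCO")
  for (dims in c(64L, 1024L)) {
    fp <- compute_map4(mol, dims)
    expect_length(fp, dims)
    expect_true(all(fp %in% c(0L, 1L)))
  }
  expect_identical(compute_map4(mol, 128L), compute_map4(mol, 128L))
  expect_false(identical(compute_map4(parse_smiles("CCO"), 128L),
                         compute_map4(parse_smiles("CCN"), 128L)))
  expect_warning(one <- compute_map4(parse_smiles("C"), 64L),
                 class = "degenerate_molecule_warning")
  expect_identical(sum(one), 0L)
})

test_that("equivalent SMILES spellings give identical fingerprints", {
  pairs <- list(c("c1ccccc1", "C1=CC=CC=C1"),
                c("OCCC", "CCCO"),
                c("CC(=O)Oc1ccccc1C(=O)O", "O=C(C)Oc1ccccc1C(O)=O"),
                c("CCN(CC)CC", "C(C)N(CC)CC"),
                c("c1ccc2ccccc2c1", "c1ccc2c(c1)cccc2"))
  for (p in pairs) {
    m1 <- parse_smiles(p[1]); m2 <- parse_smiles(p[2])
    expect_identical(compute_maccs(m1), compute_maccs(m2))
    expect_identical(compute_hashtt(m1, 256L), compute_hashtt(m2, 256L))
    expect_identical(compute_map4(m1, 256L), compute_map4(m2, 256L))
  }
})

test_that("featurize_drug_table caches by structure and aggregates errors", {
  out <- featurize_drug_table(
    data.frame(id = c("d1", "d2", "d3"),
               smiles = c("CCCO", "OCCC", "c1ccccc1")),
    n_bits = 128L, dims = 128L)
  expect_named(out, c("d1", "d2", "d3"))
  expect_identical(out$d1, out$d2) # same structure, identical triple
  expect_named(out$d1, c("hashtt", "map4", "maccs"))
  expect_length(out$d3$maccs, 166L)
  expect_identical(featurize_drug_table(data.frame(id = character(0),
                                                   smiles = character(0))),
                   structure(list(), names = character(0)))
  err <- tryCatch(
    featurize_drug_table(data.frame(id = c("ok", "bad1", "bad2"),
                                    smiles = c("CCCO", "C1CC", "xyz["))),
    invalid_smiles_error = identity)
  expect_s3_class(err, "invalid_smiles_error")
  expect_setequal(err$smiles, c("bad1", "bad2"))
})

test_that("fingerprint matrices carry drug ids and bit columns", {
  out <- featurize_drug_table(data.frame(id = c("a", "b"),
                                         smiles = c("CCCO", "CCCC")),
                              n_bits = 64L, dims = 64L)
  mats <- fingerprint_matrices(out)
  expect_identical(rownames(mats$maccs), c("a", "b"))
  expect_identical(dim(mats$hashtt), c(2L, 64L))
  expect_identical(dim(mats$maccs), c(2L, 166L))
})
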