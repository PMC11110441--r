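test_that("protein vocabulary has exactly 21 residue tokens", {
  vocab <- protein_vocabulary()
  expect_length(vocab, 21L)
  expect_true(all(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                    "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
                  %in% vocab))
})

test_that("protein tokenization is per-residue with X for rare residues", {
  expect_equal(tokenize_protein("MKV"), c("M", "K", "V"))
  expect_equal(tokenize_protein("MBU"), c("M", "X", "X"))
  expect_error(tokenize_protein(""), "empty")
})

test_that("SMILES tokenization follows the greedy bracket/2-char rules", {
  expect_equal(tokenize_smiles("CCl"), c("C", "Cl"))
  expect_equal(tokenize_smiles("c1cc[nH]c1"),
               c("c", "1", "c", "c", "[nH]", "c", "1"))
  expect_equal(tokenize_smiles("C(Br)=O"),
               c("C", "(", "Br", ")", "=", "O"))
  expect_equal(tokenize_smiles("C%12CC%12"),
               c("C", "%12", "C", "C", "%12"))
  expect_error(tokenize_smiles("C[nH"), "unbalanced")
  expect_error(tokenize_smiles("CnH]C"), "position 4")
})

test_that("detokenization inverts tokenization and strips markers", {
  expect_equal(detokenize(c("<start>", "C", "Cl", "<end>")), "CCl")
  expect_equal(detokenize(c("<start>", "<end>")), "")
  smi <- random_toy_smiles(50, seed = 4)
  for (s in smi) expect_identical(detokenize(tokenize_smiles(s)), s)
})

test_that("the potency range yields exactly 852 bins", {
  binner <- potency_binner()
  expect_identical(binner$n_bins, 852L)
  expect_equal(binner$lo, 4.00)
  expect_equal(binner$hi, 12.52)
  expect_equal(binner$width, 0.01)
})

test_that("potency binning matches the interval-enumeration oracle", {
  binner <- potency_binner()
  expect_identical(bin_potency(binner, 4.00), 0L)
  expect_identical(bin_potency(binner, 12.52), 851L)  # closed top bin
  expect_identical(bin_potency(binner, 7.849), 384L)
  # oracle: explicit enumeration of the half-open intervals
  edges <- seq(4.00, 12.52, by = 0.01)
  oracle <- function(p) {
    hits <- which(p >= edges[-length(edges)] - 1e-9 & p < edges[-1] - 1e-9)
    if (!length(hits)) 851L else as.integer(hits[1] - 1L)
  }
  set.seed(11)
  probes <- c(runif(200, 4, 12.52), edges[sample(852, 50)])
  expect_identical(bin_potency(binner, probes),
                   vapply(probes, oracle, integer(1)))
})

test_that("potency binning is monotone and covers all 852 indices", {
  binner <- potency_binner()
  grid <- seq(4.000, 12.52, by = 0.005)
  idx <- bin_potency(binner, grid)
  expect_true(all(diff(idx) >= 0L))
  expect_true(all(diff(idx) <= 1L))
  expect_identical(sort(unique(idx)), 0:851)
})

test_that("out-of-range potency clamps with a warning, NaN errors", {
  binner <- potency_binner()
  expect_warning(lo <- bin_potency(binner, 3.2), "clamped")
  expect_identical(lo, 0L)
  expect_warning(hi <- bin_potency(binner, 13.0), "clamped")
  expect_identical(hi, 851L)
  expect_error(bin_potency(binner, NaN), "non-finite")
})

test_that("SMILES vocabulary encodes/decodes with <unk> for unseen tokens", {
  vocab <- smiles_vocab(c("CCO", "c1ccccc1"))
  ids <- encode_smiles(vocab, "CCO")
  expect_identical(ids[1], unname(vocab["<start>"]))
  expect_identical(ids[length(ids)], unname(vocab["<end>"]))
  expect_identical(decode_smiles(vocab, ids), "CCO")
  # Br never seen in the corpus
  ids2 <- encode_smiles(vocab, "CBr")
  expect_true(unname(vocab["<unk>"]) %in% ids2)
  # JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_vocab(vocab, path)
  expect_identical(read_vocab(path), vocab)
})
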