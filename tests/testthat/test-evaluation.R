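test_that("Tanimoto coefficient follows the bit-set definition", {
  fp <- function(bits, nbits = 4L) {
    structure(as.integer(bits), nbits = as.integer(nbits),
              class = "morgan_fp")
  }
  expect_equal(tanimoto(fp(c(0, 1)), fp(c(0, 1))), 1.0)
  expect_equal(tanimoto(fp(0), fp(2)), 0.0)
  # 4-bit toy: a = 1100, b = 1010 -> intersection 1, union 3
  expect_equal(tanimoto(fp(c(0, 1)), fp(c(0, 2))), 1 / 3)
  expect_equal(tanimoto(fp(integer(0)), fp(integer(0))), 1.0)
  expect_error(tanimoto(fp(0, 4L), fp(0, 8L)), "bit lengths")
})

test_that("fingerprints have the 2048-bit contract and determinism", {
  fps <- morgan_fp(c("CCO", "CCO", "c1ccccc1"))
  expect_identical(attr(fps[[1]], "nbits"), 2048L)
  expect_identical(fps[[1]], fps[[2]])
  expect_true(all(fps[[3]] >= 0 & fps[[3]] < 2048))
})

test_that("1-NN similarity equals the brute-force pairwise oracle", {
  mols <- unique(random_toy_smiles(30, seed = 21))
  query <- mols[1:10]
  ref <- mols[11:min(30, length(mols))]
  got <- nn_similarity(query, ref)
  qf <- morgan_fp(query)
  rf <- morgan_fp(ref)
  oracle <- vapply(seq_along(query), function(i) {
    max(vapply(seq_along(ref), function(j) {
      bitvec_tanimoto(qf[[i]], rf[[j]])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(unname(got), oracle, tolerance = 1e-12)
  # membership gives similarity exactly 1
  expect_equal(unname(nn_similarity(ref[1], ref)), 1.0)
  # single-reference case reduces to pairwise values
  single <- nn_similarity(query, ref[1])
  pairwise <- vapply(qf, function(q) bitvec_tanimoto(q, rf[[1]]),
                     numeric(1))
  expect_equal(unname(single), pairwise, tolerance = 1e-12)
  expect_error(nn_similarity(character(0), ref), "query")
  expect_error(nn_similarity(query, character(0)), "reference")
})

test_that("reproduction counting is canonical-string intersection", {
  a <- c("CCO", "CCN", "CCC")
  expect_identical(count_reproduced(a, a), 3L)
  expect_identical(count_reproduced(a, c("CO", "CN")), 0L)
  expect_identical(count_reproduced(c(a, a), a), 3L)  # duplicates ignored
  expect_lte(count_reproduced(a, c("CCO", "CO")),
             min(length(a), 2L))
})

test_that("potency-distribution comparison applies the star scheme", {
  identical_groups <- list(g1 = c(5, 6, 7), g2 = c(5, 6, 7))
  res <- compare_potency_distributions(identical_groups)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  expect_identical(res$stars, "ns")
  set.seed(4)
  far <- list(lo = rnorm(30, 5, 0.1), hi = rnorm(30, 9, 0.1))
  res2 <- compare_potency_distributions(far)
  expect_lt(res2$p_value, 1e-4)
  expect_identical(res2$stars, "****")
  # borderline pair lands in the single-star band; the oracle p-value is
  # recomputed directly from the same two samples
  set.seed(11)
  x <- rnorm(12); y <- rnorm(12, 0.95)
  p <- stats::t.test(x, y)$p.value
  stopifnot(p > 0.01, p <= 0.05)
  res3 <- compare_potency_distributions(list(a = x, b = y))
  expect_equal(res3$p_value, p)
  expect_identical(res3$stars, "*")
  # undersized groups are annotated, not tested
  res4 <- compare_potency_distributions(list(a = 1, b = c(1, 2, 3)))
  expect_identical(res4$stars, "ns/NA")
})

test_that("SA scores are on the 1-10 scale and deterministic", {
  s <- sa_scores(c("CCO", "CCO"))
  expect_lt(s[1], 3)          # ethanol is trivially accessible
  expect_identical(s[1], s[2])
  expect_true(all(s >= 1 & s <= 10))
  expect_warning(s2 <- sa_scores(c("CCO", "xyz")), "invalid")
  expect_true(is.na(s2[2]))
})

test_that("candidate sampling respects per-instance caps and pools uniquely", {
  ck <- pretrain(list(tiny_triple(smiles = "CCO", pki = 6),
                      tiny_triple(smiles = "CCC", pki = 8)),
                 training_plan(learning_rate = 5e-3,
                               grad_accumulation = 1L, epochs = 30L,
                               seed = 1L),
                 tiny_config(), vocab = tiny_vocab())
  model <- model_from_checkpoint(ck)
  test_records <- data.frame(canonical_smiles = c("CCO", "CCC"),
                             pki = c(6, 8))
  cand <- sample_candidates(model, tiny_protein(), test_records,
                            per_instance = 10L, attempt_cap = 40L,
                            seed = 3L)
  expect_true(all(lengths(cand$per_instance_valid) <= 10L))
  expect_identical(anyDuplicated(cand$pooled), 0L)
  expect_true(all(smiles_valid(cand$pooled)))
  cand2 <- sample_candidates(model, tiny_protein(), test_records,
                             per_instance = 10L, attempt_cap = 40L,
                             seed = 3L)
  expect_identical(cand$pooled, cand2$pooled)
  expect_lte(count_reproduced(cand, test_records$canonical_smiles),
             min(length(cand$pooled), 2L))
})

test_that("class evaluation assembles a coherent report", {
  ft <- data.frame(canonical_smiles = c("CCO", "CCN"), pki = c(6, 7))
  te <- data.frame(canonical_smiles = c("CCC", "CCCC"), pki = c(8, 9))
  fake_cands <- structure(list(
    per_instance_valid = list("CCC", "CCS"),
    pooled = c("CCC", "CCS"), n_draws = 10L, n_valid_draws = 4L,
    flagged = integer(0)), class = "candidate_set")
  rep <- evaluate_class(fake_cands, NULL, ft, te, sa = FALSE)
  expect_identical(rep$conditional$n_reproduced, 1L)
  expect_identical(rep$conditional$n_candidates, 2L)
  expect_true(all(rep$conditional$nn_candidates_vs_test >= 0 &
                    rep$conditional$nn_candidates_vs_test <= 1))
  expect_lte(rep$conditional$n_reproduced, rep$conditional$n_candidates)
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  js <- jsonlite::fromJSON(file.path(dir, "report.json"))
  expect_identical(js$conditional$n_reproduced, 1L)
})
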