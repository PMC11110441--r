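overfit_plan <- function(epochs, seed = 1L) {
  training_plan(learning_rate = 5e-3, grad_accumulation = 1L,
                epochs = epochs, seed = seed)
}

test_that("a single memorized triple is learned and reproduced", {
  triple <- tiny_triple(smiles = "CC(=O)Nc1ccccc1")
  ck <- pretrain(list(triple), overfit_plan(60L), tiny_config(),
                 vocab = tiny_vocab())
  expect_lt(ck$loss, ck$loss_log[1])
  # loss trend decreases monotonically when smoothed over 10 epochs
  smooth <- stats::filter(ck$loss_log, rep(1 / 10, 10), sides = 1)
  smooth <- smooth[!is.na(smooth)]
  expect_true(all(diff(smooth) < 1e-3))
  # sampling reproduces the memorized SMILES almost surely
  model <- model_from_checkpoint(ck)
  out <- sample_compounds(model, encoder_input(triple$protein, triple$pki),
                          n = 10, seed = 2)
  expect_gte(mean(out$canonical == "CC(=O)Nc1ccccc1", na.rm = TRUE), 0.8)
})

test_that("training is deterministic given (data, plan, seed)", {
  triples <- list(tiny_triple(smiles = "CCO", pki = 5.5),
                  tiny_triple(smiles = "c1ccccc1C", pki = 8.2))
  run <- function() pretrain(triples, overfit_plan(5L, seed = 11L),
                             tiny_config(), vocab = tiny_vocab())
  ck1 <- run(); ck2 <- run()
  expect_identical(ck1$loss_log, ck2$loss_log)
  expect_identical(ck1$weights$out_W, ck2$weights$out_W)
})

test_that("checkpoint selection is argmin with earliest-epoch ties", {
  # synthetic selection check through the real log structure
  triples <- list(tiny_triple())
  ck <- pretrain(triples, overfit_plan(8L), tiny_config(),
                 vocab = tiny_vocab())
  expect_identical(ck$epoch, which.min(ck$loss_log))
  expect_equal(ck$loss, min(ck$loss_log))
})

test_that("gradient accumulation equals a single large-batch update", {
  model_a <- tiny_model(seed = 21L)
  model_b <- tiny_model(seed = 21L)
  set.seed(33)
  pool <- c("CCO", "c1ccccc1C", "CC(=O)Nc1ccccc1", "ClCc1cc[nH]c1")
  triples <- lapply(1:8, function(i) {
    tiny_triple(smiles = sample(pool, 1), pki = runif(1, 4.5, 11))
  })
  # accumulated micro-batches of 1
  for (tr in triples) {
    loss <- forward_loss(model_a, tr, dropout = 0)
    ag_backward(loss)
  }
  # one batch-level graph, one backward pass
  loss_b <- forward_loss_batch(model_b, triples, dropout = 0)
  ag_backward(loss_b)
  for (nm in c("tok_emb", "enc1.attn.h1.Wq", "dec2.self.h2.Wk",
               "dec3.ff.W1", "out_W")) {
    ga <- model_a$params[[nm]]$grad / length(triples)
    gb <- model_b$params[[nm]]$grad
    expect_lt(max(abs(ga - gb)) / max(max(abs(gb)), 1e-12), 1e-5)
  }
})

test_that("fine-tuning with zero epochs returns the input weights", {
  ck <- pretrain(list(tiny_triple()), overfit_plan(2L), tiny_config(),
                 vocab = tiny_vocab())
  ck2 <- finetune(ck, list(tiny_triple(smiles = "CCO")),
                  training_plan(epochs = 0L))
  expect_identical(ck2$weights, ck$weights)
})

test_that("fine-tuning maps unseen tokens to <unk> with a warning", {
  ck <- pretrain(list(tiny_triple(smiles = "CCO")), overfit_plan(2L),
                 tiny_config(), vocab = smiles_vocab("CCO"))
  expect_warning(
    finetune(ck, list(tiny_triple(smiles = "CBr")), overfit_plan(1L)),
    "<unk>")
})

test_that("degenerate training inputs error", {
  expect_error(pretrain(list(), overfit_plan(1L), tiny_config()), "empty")
  ck <- pretrain(list(tiny_triple()), overfit_plan(1L), tiny_config(),
                 vocab = tiny_vocab())
  expect_error(finetune(ck, list(), overfit_plan(1L)), "triples")
})

test_that("checkpoints are self-describing and round-trip through disk", {
  ck <- pretrain(list(tiny_triple()), overfit_plan(2L), tiny_config(),
                 vocab = tiny_vocab())
  path <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(ck, path)
  back <- read_checkpoint(path)
  model <- model_from_checkpoint(back)
  expect_identical(model$config, tiny_config())
  expect_identical(as.numeric(forward_loss(model, tiny_triple())$value),
                   as.numeric(forward_loss(model_from_checkpoint(ck),
                                           tiny_triple())$value))
})

test_that("validation-split selection mode runs", {
  triples <- lapply(1:6, function(i) tiny_triple(smiles = "CCO",
                                                 pki = 5 + i * 0.5))
  plan <- training_plan(learning_rate = 5e-3, grad_accumulation = 1L,
                        epochs = 3L, seed = 2L, validation_fraction = 0.34)
  ck <- pretrain(triples, plan, tiny_config(), vocab = tiny_vocab())
  expect_length(ck$loss_log, 3L)
  expect_true(all(is.finite(ck$loss_log)))
})
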