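test_that("the default architecture has 3 encoder and 3 decoder layers", {
  cfg <- model_config()
  expect_identical(cfg$n_encoder_layers, 3L)
  expect_identical(cfg$n_decoder_layers, 3L)
  model <- tiny_model()
  expect_true("enc3.attn.h1.Wq" %in% names(model$params))
  expect_false("enc4.attn.h1.Wq" %in% names(model$params))
  expect_true("dec3.cross.h1.Wq" %in% names(model$params))
  expect_false("dec4.self.h1.Wq" %in% names(model$params))
})

test_that("configuration contracts are enforced", {
  expect_error(model_config(d_model = 16, n_heads = 3), "divide")
  expect_error(build_model(tiny_config(), tiny_vocab(), embedder_dim = 32),
               "embedder dimension")
  uncond <- tiny_model(conditional = FALSE)
  expect_null(uncond$params$pot_emb)
  cond <- tiny_model(conditional = TRUE)
  expect_identical(nrow(cond$params$pot_emb$value), 852L)
})

test_that("untrained loss is close to log vocabulary size", {
  model <- tiny_model()
  loss <- as.numeric(forward_loss(model, tiny_triple())$value)
  expect_equal(loss, log(length(model$vocab)), tolerance = 0.2)
})

test_that("batch loss equals the mean of per-sequence losses", {
  model <- tiny_model()
  triples <- list(tiny_triple(smiles = "CCO"),
                  tiny_triple(smiles = "c1ccccc1C", pki = 9.1),
                  tiny_triple(smiles = "CC(=O)Nc1ccccc1", pki = 5.0))
  singles <- vapply(triples, function(tr) {
    as.numeric(forward_loss(model, tr)$value)
  }, numeric(1))
  batch <- as.numeric(forward_loss_batch(model, triples)$value)
  expect_equal(batch, mean(singles), tolerance = 1e-6)
})

test_that("loss is deterministic with dropout off", {
  model <- tiny_model()
  tr <- tiny_triple()
  expect_identical(as.numeric(forward_loss(model, tr)$value),
                   as.numeric(forward_loss(model, tr)$value))
})

test_that("masked self-attention is causal", {
  # perturbing target token t+1 must never change the logit at position t
  model <- tiny_model()
  ids <- encode_smiles(model$vocab, "CC(=O)Nc1ccccc1")
  dec_in <- ids[-length(ids)]
  pot_bin <- bin_potency(model$binner, 7.3)
  logits_of <- function(input_ids) {
    ag_tape()
    memory <- graph_encode(model, tiny_protein(), pot_bin, 0)
    graph_decode(model, memory, input_ids, 0)$value
  }
  base <- logits_of(dec_in)
  for (t in c(3L, 7L, length(dec_in) - 1L)) {
    perturbed <- dec_in
    perturbed[(t + 1L):length(perturbed)] <-
      sample(5:length(model$vocab), length(perturbed) - t, replace = TRUE)
    after <- logits_of(perturbed)
    expect_equal(after[seq_len(t), ], base[seq_len(t), ], tolerance = 1e-12)
  }
})

test_that("the inference path reproduces the training-graph forward", {
  model <- tiny_model()
  pot_bin <- bin_potency(model$binner, 8.8)
  ids <- encode_smiles(model$vocab, "ClCc1cc[nH]c1")
  ag_tape()
  mem_graph <- graph_encode(model, tiny_protein(), pot_bin, 0)
  logit_graph <- graph_decode(model, mem_graph, ids[-length(ids)], 0)$value
  mem_plain <- plain_encode(model, tiny_protein(), pot_bin)
  expect_equal(mem_plain, mem_graph$value, tolerance = 1e-12)
  logit_plain <- plain_decode_logits(model, mem_plain, ids[-length(ids)])
  expect_equal(logit_plain, logit_graph, tolerance = 1e-10)
})

test_that("multinomial sampling is seed-reproducible", {
  model <- tiny_model()
  input <- encoder_input(tiny_protein(), 7.3)
  s1 <- sample_compounds(model, input, n = 8, seed = 5)
  s2 <- sample_compounds(model, input, n = 8, seed = 5)
  expect_identical(s1$smiles, s2$smiles)
  expect_identical(s1$logp, s2$logp)
  s3 <- sample_compound(model, input, seed = 9)
  expect_true(is.character(s3$smiles))
  expect_true(is.logical(s3$valid))
})

test_that("next-token distributions are normalized", {
  model <- tiny_model()
  mem <- plain_encode(model, tiny_protein(), 100L)
  ids <- encode_smiles(model$vocab, "CCO")
  logits <- plain_decode_logits(model, mem, ids[-length(ids)])
  probs <- exp(logits - apply(logits, 1, max))
  probs <- probs / rowSums(probs)
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
})

test_that("potency conditioning changes the decoder distribution", {
  model <- tiny_model()
  ids <- encode_smiles(model$vocab, "CCO")
  dist_at <- function(m, pki) {
    pot_bin <- if (m$config$conditional) bin_potency(m$binner, pki)
    mem <- plain_encode(m, tiny_protein(), pot_bin)
    logits <- plain_decode_logits(m, mem, ids[-length(ids)])
    p <- exp(logits[1, ] - max(logits[1, ]))
    p / sum(p)
  }
  tv <- 0.5 * sum(abs(dist_at(model, 4.5) - dist_at(model, 12.0)))
  expect_gt(tv, 0)
  uncond <- tiny_model(conditional = FALSE)
  expect_identical(dist_at(uncond, 4.5), dist_at(uncond, 12.0))
})
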