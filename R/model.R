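# The conditional encoder-decoder transformer ("biochemical language
# model"): the encoder reads a length-2 input sequence (protein embedding,
# potency-token embedding) -- length 1 for the unconditional control -- and
# the decoder autoregressively emits SMILES tokens. Post-layer-norm
# residual blocks as in the original transformer; sinusoidal positions on
# the decoder side, learned position vectors for the short encoder input.

#' Model configuration
#'
#' @param d_model hidden size; must equal the protein embedder dimension
#'   (the embedding feeds the encoder unchanged, so the sizes are matched
#'   to avoid information loss through the connection).
#' @param n_encoder_layers,n_decoder_layers encoder/decoder depth
#'   (default 3 + 3).
#' @param n_heads attention heads; must divide `d_model`.
#' @param d_feedforward feed-forward width (default `4 * d_model`).
#' @param dropout dropout rate in `[0, 1)`.
#' @param conditional include the potency conditioning token (FALSE gives
#'   the unconditional control model).
#' @param max_len decoding length cap in tokens.
#' @return object of class `model_config`.
#' @export
model_config <- function(d_model = 1024L, n_encoder_layers = 3L,
                         n_decoder_layers = 3L, n_heads = 8L,
                         d_feedforward = 4L * d_model, dropout = 0.1,
                         conditional = TRUE, max_len = 150L) {
  stopifnot(n_encoder_layers >= 1L, n_decoder_layers >= 1L,
            d_feedforward >= 1L, dropout >= 0, dropout < 1)
  if (d_model %% n_heads != 0L) {
    stop("n_heads (", n_heads, ") must divide d_model (", d_model, ")",
         call. = FALSE)
  }
  structure(list(d_model = as.integer(d_model),
                 n_encoder_layers = as.integer(n_encoder_layers),
                 n_decoder_layers = as.integer(n_decoder_layers),
                 n_heads = as.integer(n_heads),
                 d_feedforward = as.integer(d_feedforward),
                 dropout = dropout, conditional = isTRUE(conditional),
                 max_len = as.integer(max_len)),
            class = "model_config")
}

#' Desk-scale configuration profile
#'
#' Small profile for CPU-scale experiments and tests; the paper-scale
#' profile is `model_config()` with its defaults (1024-dimensional hidden
#' states).
#' @param d_model,n_heads,... passed to [model_config()].
#' @inheritParams model_config
#' @return a `model_config`.
#' @export
desk_config <- function(d_model = 128L, n_heads = 2L, dropout = 0,
                        max_len = 80L, ...) {
  model_config(d_model = d_model, n_heads = n_heads,
               d_feedforward = 4L * d_model, dropout = dropout,
               max_len = max_len, ...)
}

init_mat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
}

new_attn_params <- function(prefix, d, n_heads, params) {
  dk <- d %/% n_heads
  for (h in seq_len(n_heads)) {
    for (w in c("Wq", "Wk", "Wv")) {
      params[[sprintf("%s.h%d.%s", prefix, h, w)]] <-
        ag_new_param(init_mat(d, dk), sprintf("%s.h%d.%s", prefix, h, w))
    }
  }
  params[[paste0(prefix, ".Wo")]] <-
    ag_new_param(init_mat(d, d), paste0(prefix, ".Wo"))
  params
}

new_block_params <- function(prefix, d, dff, params, n_ln) {
  for (i in seq_len(n_ln)) {
    params[[sprintf("%s.ln%d.g", prefix, i)]] <-
      ag_new_param(matrix(1, 1L, d))
    params[[sprintf("%s.ln%d.b", prefix, i)]] <-
      ag_new_param(matrix(0, 1L, d))
  }
  params[[paste0(prefix, ".ff.W1")]] <- ag_new_param(init_mat(d, dff))
  params[[paste0(prefix, ".ff.b1")]] <- ag_new_param(matrix(0, 1L, dff))
  params[[paste0(prefix, ".ff.W2")]] <- ag_new_param(init_mat(dff, d))
  params[[paste0(prefix, ".ff.b2")]] <- ag_new_param(matrix(0, 1L, d))
  params
}

#' Build a biochemical language model
#'
#' Instantiates the encoder stack (self-attention + feed-forward residual
#' blocks), the decoder stack (masked self-attention, cross-attention to the
#' encoder memory, feed-forward), the SMILES token embedding, the potency
#' embedding table (one row per potency bin; absent for the unconditional
#' model), and the output projection. The potency table is separate from the
#' SMILES token table -- they are different vocabularies -- and no weights
#' are tied.
#'
#' @param config a [model_config()].
#' @param vocab a [smiles_vocab()].
#' @param binner a [potency_binner()] (used when `config$conditional`).
#' @param embedder_dim dimension of the protein embedder that will feed this
#'   model; must equal `config$d_model`.
#' @param seed RNG seed for weight initialization.
#' @return object of class `biochem_lm`.
#' @export
build_model <- function(config, vocab, binner = potency_binner(),
                        embedder_dim = config$d_model, seed = 1L) {
  stopifnot(inherits(config, "model_config"), inherits(vocab, "smiles_vocab"))
  if (embedder_dim != config$d_model) {
    stop("configuration error: d_model (", config$d_model,
         ") must equal the protein embedder dimension (", embedder_dim, ")",
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  d <- config$d_model
  dff <- config$d_feedforward
  V <- length(vocab)
  params <- list()
  params$tok_emb <- ag_new_param(init_mat(V, d), "tok_emb")
  if (config$conditional) {
    params$pot_emb <- ag_new_param(init_mat(binner$n_bins, d), "pot_emb")
  }
  params$enc_pos <- ag_new_param(init_mat(2L, d), "enc_pos")
  for (i in seq_len(config$n_encoder_layers)) {
    pre <- sprintf("enc%d", i)
    params <- new_attn_params(paste0(pre, ".attn"), d, config$n_heads, params)
    params <- new_block_params(pre, d, dff, params, n_ln = 2L)
  }
  for (i in seq_len(config$n_decoder_layers)) {
    pre <- sprintf("dec%d", i)
    params <- new_attn_params(paste0(pre, ".self"), d, config$n_heads, params)
    params <- new_attn_params(paste0(pre, ".cross"), d, config$n_heads,
                              params)
    params <- new_block_params(pre, d, dff, params, n_ln = 3L)
  }
  params$out_W <- ag_new_param(init_mat(d, V), "out_W")
  params$out_b <- ag_new_param(matrix(0, 1L, V), "out_b")
  structure(list(config = config, vocab = vocab, binner = binner,
                 params = params),
            class = "biochem_lm")
}

#' @export
print.biochem_lm <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat(sprintf(paste0("biochemical language model (%s): %d+%d layers, ",
                     "d_model %d, %d heads, |SMILES vocab| %d, %s params\n"),
              if (cfg$conditional) "conditional" else "unconditional",
              cfg$n_encoder_layers, cfg$n_decoder_layers, cfg$d_model,
              cfg$n_heads, length(x$vocab), format(n_par, big.mark = ",")))
  invisible(x)
}

# sinusoidal positional encodings, L x d
sinusoidal_pe <- function(L, d) {
  pos <- seq_len(L) - 1L
  i <- seq_len(d) - 1L
  angle <- outer(pos, 10000^(-(i %/% 2L) * 2 / d))
  pe <- matrix(0, L, d)
  even <- seq(1L, d, by = 2L)
  odd <- seq(2L, d, by = 2L)
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, odd] <- cos(angle[, odd, drop = FALSE])
  pe
}

# ---- graph (training) forward ----------------------------------------

graph_attention <- function(params, prefix, xq, xkv, n_heads, mask = NULL) {
  dk <- ncol(xq$value) %/% n_heads
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    q <- ag_matmul(xq, ag_param(params[[sprintf("%s.h%d.Wq", prefix, h)]]))
    k <- ag_matmul(xkv, ag_param(params[[sprintf("%s.h%d.Wk", prefix, h)]]))
    v <- ag_matmul(xkv, ag_param(params[[sprintf("%s.h%d.Wv", prefix, h)]]))
    s <- ag_scale(ag_matmul_nt(q, k), 1 / sqrt(dk))
    a <- ag_softmax_rows(s, mask)
    heads[[h]] <- ag_matmul(a, v)
  }
  ag_matmul(ag_cbind(heads), ag_param(params[[paste0(prefix, ".Wo")]]))
}

graph_sublayer <- function(params, prefix, ln_idx, x, sub, dropout) {
  if (dropout > 0) sub <- ag_dropout(sub, dropout)
  ag_layernorm(ag_add(x, sub),
               ag_param(params[[sprintf("%s.ln%d.g", prefix, ln_idx)]]),
               ag_param(params[[sprintf("%s.ln%d.b", prefix, ln_idx)]]))
}

graph_ff <- function(params, prefix, x, dropout) {
  h <- ag_relu(ag_add_rowvec(
    ag_matmul(x, ag_param(params[[paste0(prefix, ".ff.W1")]])),
    ag_param(params[[paste0(prefix, ".ff.b1")]])))
  if (dropout > 0) h <- ag_dropout(h, dropout)
  ag_add_rowvec(ag_matmul(h, ag_param(params[[paste0(prefix, ".ff.W2")]])),
                ag_param(params[[paste0(prefix, ".ff.b2")]]))
}

# encoder input rows: protein embedding and, when conditional, the
# potency-bin embedding
graph_encode <- function(model, prot_vec, pot_bin, dropout) {
  cfg <- model$config
  params <- model$params
  rows <- list(ag_const(matrix(prot_vec, 1L)))
  if (cfg$conditional) {
    stopifnot(!is.null(pot_bin))
    rows <- c(rows, list(ag_embed(params$pot_emb, pot_bin + 1L)))
  }
  x <- ag_rbind(rows)
  x <- ag_add(x, ag_embed(params$enc_pos, seq_along(rows)))
  for (i in seq_len(cfg$n_encoder_layers)) {
    pre <- sprintf("enc%d", i)
    att <- graph_attention(params, paste0(pre, ".attn"), x, x, cfg$n_heads)
    x <- graph_sublayer(params, pre, 1L, x, att, dropout)
    ff <- graph_ff(params, pre, x, dropout)
    x <- graph_sublayer(params, pre, 2L, x, ff, dropout)
  }
  x
}

graph_decode <- function(model, memory, dec_ids, dropout) {
  cfg <- model$config
  params <- model$params
  L <- length(dec_ids)
  d <- cfg$d_model
  x <- ag_scale(ag_embed(params$tok_emb, dec_ids), sqrt(d))
  x <- ag_add(x, ag_const(sinusoidal_pe(L, d)))
  causal <- matrix(0, L, L)
  causal[upper.tri(causal)] <- -1e9
  for (i in seq_len(cfg$n_decoder_layers)) {
    pre <- sprintf("dec%d", i)
    att <- graph_attention(params, paste0(pre, ".self"), x, x, cfg$n_heads,
                           mask = causal)
    x <- graph_sublayer(params, pre, 1L, x, att, dropout)
    cro <- graph_attention(params, paste0(pre, ".cross"), x, memory,
                           cfg$n_heads)
    x <- graph_sublayer(params, pre, 2L, x, cro, dropout)
    ff <- graph_ff(params, pre, x, dropout)
    x <- graph_sublayer(params, pre, 3L, x, ff, dropout)
  }
  ag_add_rowvec(ag_matmul(x, ag_param(params$out_W)), ag_param(params$out_b))
}

#' Teacher-forced training loss for one triple
#'
#' Mean token-level cross-entropy between the decoder's next-token logits
#' and the ground-truth SMILES token sequence, under teacher forcing.
#' Builds the computation graph on a fresh tape; call [ag_backward()] on the
#' returned node to accumulate parameter gradients.
#'
#' @param model a [build_model()] result.
#' @param triple list with `protein` (numeric embedding of length
#'   `d_model`), `pki` (numeric, ignored by unconditional models), and
#'   `smiles` (target string) or `ids` (precomputed token ids).
#' @param dropout dropout rate; defaults to the model configuration.
#' @return scalar loss node (`$value` is a 1x1 matrix).
#' @export
forward_loss <- function(model, triple, dropout = model$config$dropout) {
  stopifnot(inherits(model, "biochem_lm"))
  ids <- triple$ids %||% encode_smiles(model$vocab, triple$smiles)
  if (length(ids) < 2L) stop("empty target sequence", call. = FALSE)
  ag_tape()
  pot_bin <- if (model$config$conditional) {
    bin_potency(model$binner, triple$pki)
  }
  memory <- graph_encode(model, triple$protein, pot_bin, dropout)
  logits <- graph_decode(model, memory, ids[-length(ids)], dropout)
  ag_cross_entropy(logits, ids[-1L])
}

#' Teacher-forced batch loss (mean of per-sequence losses)
#'
#' Builds one graph covering all triples and returns the mean loss node, so
#' a single backward pass yields the batch gradient.
#' @inheritParams forward_loss
#' @param triples list of triples.
#' @return scalar loss node.
#' @export
forward_loss_batch <- function(model, triples,
                               dropout = model$config$dropout) {
  ag_tape()
  losses <- lapply(triples, function(tr) {
    ids <- tr$ids %||% encode_smiles(model$vocab, tr$smiles)
    if (length(ids) < 2L) stop("empty target sequence", call. = FALSE)
    pot_bin <- if (model$config$conditional) bin_potency(model$binner,
                                                         tr$pki)
    memory <- graph_encode(model, tr$protein, pot_bin, dropout)
    logits <- graph_decode(model, memory, ids[-length(ids)], dropout)
    ag_cross_entropy(logits, ids[-1L])
  })
  ag_mean(losses)
}

# ---- plain (inference) forward with KV caching ------------------------

ln_rows <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  sweep(xc * inv, 2L, as.numeric(g), "*") +
    matrix(as.numeric(b), nrow(x), length(b), byrow = TRUE)
}

relu_mat <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

plain_encode <- function(model, prot_vec, pot_bin) {
  cfg <- model$config
  P <- model$params
  x <- matrix(prot_vec, 1L)
  if (cfg$conditional) {
    x <- rbind(x, P$pot_emb$value[pot_bin + 1L, , drop = FALSE])
  }
  x <- x + P$enc_pos$value[seq_len(nrow(x)), , drop = FALSE]
  nh <- cfg$n_heads
  dk <- cfg$d_model %/% nh
  for (i in seq_len(cfg$n_encoder_layers)) {
    pre <- sprintf("enc%d", i)
    heads <- vector("list", nh)
    for (h in seq_len(nh)) {
      q <- x %*% P[[sprintf("%s.attn.h%d.Wq", pre, h)]]$value
      k <- x %*% P[[sprintf("%s.attn.h%d.Wk", pre, h)]]$value
      v <- x %*% P[[sprintf("%s.attn.h%d.Wv", pre, h)]]$value
      a <- softmax_rows(tcrossprod(q, k) / sqrt(dk))
      heads[[h]] <- a %*% v
    }
    att <- do.call(cbind, heads) %*% P[[paste0(pre, ".attn.Wo")]]$value
    x <- ln_rows(x + att, P[[paste0(pre, ".ln1.g")]]$value,
                 P[[paste0(pre, ".ln1.b")]]$value)
    f <- relu_mat(sweep(x %*% P[[paste0(pre, ".ff.W1")]]$value, 2L,
                        as.numeric(P[[paste0(pre, ".ff.b1")]]$value), "+"))
    f <- sweep(f %*% P[[paste0(pre, ".ff.W2")]]$value, 2L,
               as.numeric(P[[paste0(pre, ".ff.b2")]]$value), "+")
    x <- ln_rows(x + f, P[[paste0(pre, ".ln2.g")]]$value,
                 P[[paste0(pre, ".ln2.b")]]$value)
  }
  x
}

# Teacher-forced plain decoder: next-token logits for every position of the
# decoder input `ids` (which must start with the start token). Inference
# path, no tape; used to cross-check the graph forward and to score given
# sequences.
plain_decode_logits <- function(model, memory, ids) {
  stopifnot(ids[1L] == unname(model$vocab["<start>"]))
  res <- plain_decode_sample(model, memory, n_seq = 1L,
                             max_len = length(ids), forced = ids)
  res$logits
}

# Batched autoregressive decoding with per-layer KV caches. Returns token
# id matrix (B x steps) and per-sequence log-probabilities. When `forced`
# is given (integer vector), its tokens are fed instead of sampled draws
# and the per-step logits are collected.
plain_decode_sample <- function(model, memory, n_seq, max_len,
                                forced = NULL) {
  cfg <- model$config
  P <- model$params
  nh <- cfg$n_heads
  d <- cfg$d_model
  dk <- d %/% nh
  V <- length(model$vocab)
  start_id <- unname(model$vocab["<start>"])
  end_id <- unname(model$vocab["<end>"])
  pe <- sinusoidal_pe(max_len + 1L, d)
  nl <- cfg$n_decoder_layers
  # cross-attention keys/values from the fixed memory, per layer and head
  memK <- vector("list", nl); memV <- vector("list", nl)
  for (i in seq_len(nl)) {
    memK[[i]] <- vector("list", nh); memV[[i]] <- vector("list", nh)
    for (h in seq_len(nh)) {
      memK[[i]][[h]] <- memory %*%
        P[[sprintf("dec%d.cross.h%d.Wk", i, h)]]$value
      memV[[i]][[h]] <- memory %*%
        P[[sprintf("dec%d.cross.h%d.Wv", i, h)]]$value
    }
  }
  cacheK <- lapply(seq_len(nl), function(i)
    lapply(seq_len(nh), function(h) array(0, c(n_seq, max_len, dk))))
  cacheV <- lapply(seq_len(nl), function(i)
    lapply(seq_len(nh), function(h) array(0, c(n_seq, max_len, dk))))
  tokens <- matrix(NA_integer_, n_seq, max_len)
  logp <- numeric(n_seq)
  done <- rep(FALSE, n_seq)
  cur <- rep(start_id, n_seq)
  cum_tri <- upper.tri(diag(V), diag = TRUE)
  logits_out <- if (!is.null(forced)) matrix(NA_real_, max_len, V)
  for (t in seq_len(max_len)) {
    x <- P$tok_emb$value[cur, , drop = FALSE] * sqrt(d) +
      matrix(pe[t, ], n_seq, d, byrow = TRUE)
    for (i in seq_len(nl)) {
      pre <- sprintf("dec%d", i)
      heads <- vector("list", nh)
      for (h in seq_len(nh)) {
        q <- x %*% P[[sprintf("%s.self.h%d.Wq", pre, h)]]$value
        k <- x %*% P[[sprintf("%s.self.h%d.Wk", pre, h)]]$value
        v <- x %*% P[[sprintf("%s.self.h%d.Wv", pre, h)]]$value
        cacheK[[i]][[h]][, t, ] <- k
        cacheV[[i]][[h]][, t, ] <- v
        scores <- matrix(0, n_seq, t)
        for (tt in seq_len(t)) {
          k_tt <- matrix(cacheK[[i]][[h]][, tt, ], n_seq, dk)
          scores[, tt] <- rowSums(q * k_tt)
        }
        a <- softmax_rows(scores / sqrt(dk))
        ctx <- matrix(0, n_seq, dk)
        for (tt in seq_len(t)) {
          v_tt <- matrix(cacheV[[i]][[h]][, tt, ], n_seq, dk)
          ctx <- ctx + a[, tt] * v_tt
        }
        heads[[h]] <- ctx
      }
      att <- do.call(cbind, heads) %*% P[[paste0(pre, ".self.Wo")]]$value
      x <- ln_rows(x + att, P[[paste0(pre, ".ln1.g")]]$value,
                   P[[paste0(pre, ".ln1.b")]]$value)
      heads <- vector("list", nh)
      for (h in seq_len(nh)) {
        q <- x %*% P[[sprintf("%s.cross.h%d.Wq", pre, h)]]$value
        a <- softmax_rows(tcrossprod(q, memK[[i]][[h]]) / sqrt(dk))
        heads[[h]] <- a %*% memV[[i]][[h]]
      }
      att <- do.call(cbind, heads) %*% P[[paste0(pre, ".cross.Wo")]]$value
      x <- ln_rows(x + att, P[[paste0(pre, ".ln2.g")]]$value,
                   P[[paste0(pre, ".ln2.b")]]$value)
      f <- relu_mat(sweep(x %*% P[[paste0(pre, ".ff.W1")]]$value, 2L,
                          as.numeric(P[[paste0(pre, ".ff.b1")]]$value), "+"))
      f <- sweep(f %*% P[[paste0(pre, ".ff.W2")]]$value, 2L,
                 as.numeric(P[[paste0(pre, ".ff.b2")]]$value), "+")
      x <- ln_rows(x + f, P[[paste0(pre, ".ln3.g")]]$value,
                   P[[paste0(pre, ".ln3.b")]]$value)
    }
    logits <- sweep(x %*% P$out_W$value, 2L, as.numeric(P$out_b$value), "+")
    probs <- softmax_rows(logits)
    if (!is.null(forced)) {
      logits_out[t, ] <- logits[1L, ]
      # forced tokens are decoder *inputs*: the input at step t+1
      draw <- rep(if (t < length(forced)) forced[t + 1L] else end_id, n_seq)
    } else {
      u <- stats::runif(n_seq)
      cum <- probs %*% cum_tri
      cum[, V] <- 1
      draw <- max.col(cum >= u, ties.method = "first")
      draw[done] <- end_id
    }
    logp <- logp + ifelse(done, 0, log(probs[cbind(seq_len(n_seq), draw)]))
    tokens[, t] <- ifelse(done, NA_integer_, draw)
    done <- done | draw == end_id
    cur <- draw
    if (is.null(forced) && all(done)) {
      tokens <- tokens[, seq_len(t), drop = FALSE]
      break
    }
  }
  list(tokens = tokens, logp = logp, finished = done, logits = logits_out)
}

#' Encoder input descriptor
#'
#' @param protein numeric protein embedding (length `d_model`).
#' @param pki desired potency (pKi units); required for conditional models,
#'   ignored by unconditional ones.
#' @return list of class `encoder_input`.
#' @export
encoder_input <- function(protein, pki = NULL) {
  structure(list(protein = as.numeric(protein), pki = pki),
            class = "encoder_input")
}

#' Sample one compound from the model
#'
#' Multinomial sampling at temperature 1.0: each step draws from the
#' decoder's softmax distribution until the end token or the length cap.
#' An invalid SMILES is a flagged outcome, not an error.
#'
#' @param model a `biochem_lm` in inference mode (dropout is not applied).
#' @param input an [encoder_input()].
#' @param max_len decoding length cap; defaults to the model configuration.
#' @param seed integer seed making the draw reproducible.
#' @return list with `tokens` (character), `smiles` (raw string),
#'   `canonical` (canonical SMILES or `NA`), `valid` (logical), and `logp`.
#' @export
sample_compound <- function(model, input, max_len = model$config$max_len,
                            seed = 1L) {
  batch <- sample_compounds(model, input, n = 1L, max_len = max_len,
                            seed = seed)
  list(tokens = batch$tokens[[1L]], smiles = batch$smiles[1L],
       canonical = batch$canonical[1L], valid = batch$valid[1L],
       logp = batch$logp[1L])
}

#' Sample a batch of compounds for one encoder input
#'
#' Batched variant of [sample_compound()]: all draws share the encoder
#' memory and are decoded in parallel.
#'
#' @inheritParams sample_compound
#' @param n number of sequences to draw.
#' @return list with `tokens` (list of character vectors), `smiles`,
#'   `canonical`, `valid`, `logp`.
#' @export
sample_compounds <- function(model, input, n, max_len = model$config$max_len,
                             seed = 1L) {
  stopifnot(inherits(model, "biochem_lm"), inherits(input, "encoder_input"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pot_bin <- if (model$config$conditional) {
    if (is.null(input$pki)) {
      stop("conditional model requires a pKi in the encoder input",
           call. = FALSE)
    }
    bin_potency(model$binner, input$pki)
  }
  memory <- plain_encode(model, input$protein, pot_bin)
  dec <- plain_decode_sample(model, memory, n, max_len)
  tok_names <- names(model$vocab)
  tokens <- lapply(seq_len(n), function(b) {
    ids <- dec$tokens[b, ]
    ids <- ids[!is.na(ids)]
    tok_names[ids]
  })
  smiles <- vapply(tokens, detokenize, character(1))
  canonical <- rep(NA_character_, n)
  nonempty <- nzchar(smiles)
  if (any(nonempty)) {
    canonical[nonempty] <- canonicalize_smiles(smiles[nonempty])
  }
  list(tokens = tokens, smiles = smiles, canonical = canonical,
       valid = !is.na(canonical), logp = dec$logp)
}
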