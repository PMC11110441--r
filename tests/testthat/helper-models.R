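# Shared tiny-model helpers: everything is built in code at test time.

# internal APIs exercised by white-box tests
ag_tape <- biochemlm:::ag_tape
ag_node <- biochemlm:::ag_node
ag_new_param <- biochemlm:::ag_new_param
ag_param <- biochemlm:::ag_param
ag_const <- biochemlm:::ag_const
ag_matmul <- biochemlm:::ag_matmul
ag_layernorm <- biochemlm:::ag_layernorm
ag_cross_entropy <- biochemlm:::ag_cross_entropy
ag_backward <- biochemlm:::ag_backward
adam_step <- biochemlm:::adam_step
graph_encode <- biochemlm:::graph_encode
graph_decode <- biochemlm:::graph_decode
plain_encode <- biochemlm:::plain_encode
plain_decode_logits <- biochemlm:::plain_decode_logits
snapshot_weights <- biochemlm:::snapshot_weights

tiny_vocab <- function() {
  smiles_vocab(c("CCO", "c1ccccc1C", "CC(=O)Nc1ccccc1", "ClCc1cc[nH]c1"))
}

tiny_config <- function(d_model = 16L, conditional = TRUE, ...) {
  model_config(d_model = d_model, n_heads = 2L, d_feedforward = 2L * d_model,
               dropout = 0, conditional = conditional, max_len = 40L, ...)
}

tiny_model <- function(conditional = TRUE, seed = 3L, d_model = 16L, ...) {
  build_model(tiny_config(d_model = d_model, conditional = conditional, ...),
              tiny_vocab(), seed = seed)
}

tiny_protein <- function(d = 16L, seq = "MKVLAWGRES") {
  builtin_embedder(seq, d, seed = 1L)
}

tiny_triple <- function(d = 16L, smiles = "CCO", pki = 7.3,
                        seq = "MKVLAWGRES") {
  list(protein = tiny_protein(d, seq), pki = pki, smiles = smiles)
}

# an independently computed logical-vector Tanimoto, used as oracle
bitvec_tanimoto <- function(fp_a, fp_b, nbits = 2048L) {
  a <- rep(FALSE, nbits); a[fp_a + 1L] <- TRUE
  b <- rep(FALSE, nbits); b[fp_b + 1L] <- TRUE
  if (!any(a) && !any(b)) return(1.0)
  sum(a & b) / sum(a | b)
}
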