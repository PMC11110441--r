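# Pre-training on pooled target-compound triples and per-class
# fine-tuning, with per-epoch checkpointing and min-loss selection.

#' Training plan
#'
#' Adam with learning rate 1e-5, micro-batches of one sequence and gradient
#' accumulation to an effective batch of 64, at least 50 epochs, and
#' selection of the checkpoint with minimal cross-entropy loss.
#'
#' @param learning_rate Adam learning rate.
#' @param micro_batch sequences per micro-batch (1: one triple per forward
#'   pass, as when each batch must hold the longest protein sequence).
#' @param grad_accumulation micro-batches accumulated per optimizer update;
#'   effective batch = `micro_batch * grad_accumulation`.
#' @param epochs number of epochs to run (the stopping rule is a fixed
#'   count; selection picks the best epoch).
#' @param seed seed for weight init, shuffling and dropout.
#' @param checkpoint_dir if non-NULL, per-epoch checkpoints are written
#'   there as RDS files.
#' @param validation_fraction optional fraction of triples held out and
#'   used for checkpoint selection instead of the training loss.
#' @return object of class `training_plan`.
#' @export
training_plan <- function(learning_rate = 1e-5, micro_batch = 1L,
                          grad_accumulation = 64L, epochs = 50L, seed = 1L,
                          checkpoint_dir = NULL,
                          validation_fraction = 0) {
  stopifnot(epochs >= 0L, micro_batch >= 1L, grad_accumulation >= 1L,
            learning_rate > 0, validation_fraction >= 0,
            validation_fraction < 1)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 micro_batch = as.integer(micro_batch),
                 grad_accumulation = as.integer(grad_accumulation),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir,
                 validation_fraction = validation_fraction),
            class = "training_plan")
}

snapshot_weights <- function(model) lapply(model$params, function(p) p$value)

restore_weights <- function(model, weights) {
  stopifnot(identical(sort(names(weights)), sort(names(model$params))))
  for (nm in names(weights)) model$params[[nm]]$value <- weights[[nm]]
  invisible(model)
}

new_checkpoint <- function(model, epoch, loss, loss_log) {
  structure(list(epoch = epoch, loss = loss, loss_log = loss_log,
                 weights = snapshot_weights(model), config = model$config,
                 vocab = model$vocab, binner = model$binner),
            class = "bclm_checkpoint")
}

#' @export
print.bclm_checkpoint <- function(x, ...) {
  cat(sprintf("checkpoint: epoch %d, loss %.4f (%d epochs logged)\n",
              x$epoch, x$loss, length(x$loss_log)))
  invisible(x)
}

#' Rebuild a model from a checkpoint
#'
#' Checkpoints are self-describing (config + weights + vocabularies), so no
#' external configuration is needed.
#' @param ckpt a `bclm_checkpoint`.
#' @return a `biochem_lm` with the checkpointed weights.
#' @export
model_from_checkpoint <- function(ckpt) {
  stopifnot(inherits(ckpt, "bclm_checkpoint"))
  model <- build_model(ckpt$config, ckpt$vocab, ckpt$binner, seed = 0L)
  restore_weights(model, ckpt$weights)
  model
}

#' Write / read checkpoints
#' @param ckpt a `bclm_checkpoint`.
#' @param path file path.
#' @export
write_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) readRDS(path)

prepare_triples <- function(triples, vocab, warn_unk = FALSE) {
  unk <- unname(vocab["<unk>"])
  n_unk <- 0L
  out <- lapply(triples, function(tr) {
    tr$ids <- encode_smiles(vocab, tr$smiles)
    n_unk <<- n_unk + sum(tr$ids == unk)
    tr
  })
  if (warn_unk && n_unk > 0L) {
    warning(n_unk, " token(s) absent from the checkpoint vocabulary mapped ",
            "to <unk>", call. = FALSE)
  }
  out
}

# shared training engine: epochs over shuffled micro-batches with gradient
# accumulation; per-epoch mean loss logged; min-loss weights kept (ties
# broken by earliest epoch)
train_epochs <- function(model, triples, plan) {
  if (!length(triples)) stop("no training triples", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(plan$seed)
  n_val <- floor(plan$validation_fraction * length(triples))
  val <- list()
  if (n_val > 0L) {
    vi <- sample(seq_along(triples), n_val)
    val <- triples[vi]
    triples <- triples[-vi]
  }
  best <- list(epoch = 0L, loss = Inf, weights = snapshot_weights(model))
  loss_log <- numeric(0)
  adam_t <- 0L
  for (epoch in seq_len(plan$epochs)) {
    set.seed(plan$seed + epoch)
    order <- sample(seq_along(triples))
    chunks <- split(order, ceiling(seq_along(order) / plan$micro_batch))
    loss_sum <- 0
    pending <- 0L
    for (j in seq_along(chunks)) {
      trs <- triples[chunks[[j]]]
      loss <- if (length(trs) == 1L) forward_loss(model, trs[[1L]]) else
        forward_loss_batch(model, trs)
      lv <- as.numeric(loss$value)
      if (!is.finite(lv)) {
        stop("non-finite loss at epoch ", epoch, ", triple indices ",
             paste(chunks[[j]], collapse = ","), call. = FALSE)
      }
      loss_sum <- loss_sum + lv * length(trs)
      ag_backward(loss)
      pending <- pending + 1L
      if (pending == plan$grad_accumulation || j == length(chunks)) {
        adam_t <- adam_t + 1L
        adam_step(model$params, lr = plan$learning_rate,
                  grad_scale = pending, t = adam_t)
        pending <- 0L
      }
    }
    epoch_loss <- loss_sum / length(order)
    sel_loss <- if (n_val > 0L) {
      mean(vapply(val, function(tr) {
        as.numeric(forward_loss(model, tr, dropout = 0)$value)
      }, numeric(1)))
    } else {
      epoch_loss
    }
    loss_log <- c(loss_log, sel_loss)
    if (!is.null(plan$checkpoint_dir)) {
      dir.create(plan$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      write_checkpoint(new_checkpoint(model, epoch, sel_loss, loss_log),
                       file.path(plan$checkpoint_dir,
                                 sprintf("epoch_%04d.rds", epoch)))
    }
    if (sel_loss < best$loss) {
      best <- list(epoch = epoch, loss = sel_loss,
                   weights = snapshot_weights(model))
    }
  }
  restore_weights(model, best$weights)
  ck <- new_checkpoint(model, best$epoch,
                       if (is.finite(best$loss)) best$loss else NA_real_,
                       loss_log)
  ck
}

#' Pre-train a biochemical language model
#'
#' Trains on pooled target-compound triples; a checkpoint is recorded at
#' the end of every epoch and the one with minimal cross-entropy loss is
#' returned (ties broken by earliest epoch).
#'
#' @param triples list of triples, each `list(protein =, pki =, smiles =)`
#'   with `protein` a numeric embedding of length `config$d_model`.
#' @param plan a [training_plan()].
#' @param config a [model_config()].
#' @param vocab optional [smiles_vocab()]; derived from the triples'
#'   SMILES when NULL.
#' @param binner a [potency_binner()].
#' @return a `bclm_checkpoint`.
#' @export
pretrain <- function(triples, plan = training_plan(),
                     config = model_config(), vocab = NULL,
                     binner = potency_binner()) {
  if (!length(triples)) stop("empty triple list", call. = FALSE)
  if (is.null(vocab)) {
    vocab <- smiles_vocab(vapply(triples, `[[`, character(1), "smiles"))
  }
  model <- build_model(config, vocab, binner, seed = plan$seed)
  triples <- prepare_triples(triples, vocab)
  train_epochs(model, triples, plan)
}

#' Fine-tune from a checkpoint on one activity class
#'
#' Full fine-tuning (all weights updated) with the same checkpointing and
#' min-loss selection rule as pre-training. Class triples must be disjoint
#' from test compounds by canonical SMILES and analogue-series core; that
#' split is enforced upstream by [split_series()]. Tokens absent from the
#' checkpoint vocabulary are mapped to `<unk>` with a warning. With
#' `epochs = 0` the returned checkpoint carries the input weights.
#'
#' @param checkpoint a `bclm_checkpoint` from [pretrain()].
#' @param class_triples fine-tuning triples (see [pretrain()]).
#' @param plan a [training_plan()].
#' @return a `bclm_checkpoint`.
#' @export
finetune <- function(checkpoint, class_triples, plan = training_plan()) {
  model <- model_from_checkpoint(checkpoint)
  if (plan$epochs == 0L) {
    return(new_checkpoint(model, 0L, checkpoint$loss, numeric(0)))
  }
  class_triples <- prepare_triples(class_triples, model$vocab,
                                   warn_unk = TRUE)
  train_epochs(model, class_triples, plan)
}
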