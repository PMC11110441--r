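# Minimal reverse-mode automatic differentiation on matrices.
#
# A tape records nodes in creation order; backward() walks it in reverse.
# Node values are numeric matrices (scalars are 1x1). Trainable parameters
# live in persistent environments (value/grad/Adam state); during a forward
# pass they enter the graph through ag_param() or ag_embed(), and backward()
# accumulates into their $grad field.

.ag <- new.env(parent = emptyenv())

#' Start a fresh autodiff tape
#' @return the tape (an environment); also installed as the current tape.
#' @keywords internal
ag_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 512L)
  tape$n <- 0L
  .ag$tape <- tape
  tape
}

ag_register <- function(node) {
  tape <- .ag$tape
  if (is.null(tape)) stop("no active tape; call ag_tape() first")
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node$id <- n
  node
}

ag_node <- function(value, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$parents <- parents
  node$backward <- backward
  node$grad <- NULL
  ag_register(node)
}

#' Constant (non-differentiable) node
#' @keywords internal
ag_const <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  node <- ag_node(x)
  node$constant <- TRUE
  node
}

#' Create a trainable parameter
#'
#' @param value initial numeric matrix.
#' @param name parameter name (for reporting).
#' @return parameter environment with `$value` and zeroed `$grad`.
#' @keywords internal
ag_new_param <- function(value, name = "") {
  p <- new.env(parent = emptyenv())
  if (!is.matrix(value)) value <- as.matrix(value)
  p$value <- value
  p$grad <- matrix(0, nrow(value), ncol(value))
  p$name <- name
  class(p) <- "ag_param"
  p
}

#' Bring a parameter onto the current tape
#' @keywords internal
ag_param <- function(p) {
  node <- ag_node(p$value)
  node$param <- p
  node
}

#' Embedding lookup: rows `idx` of a parameter table
#' @keywords internal
ag_embed <- function(p, idx) {
  idx <- as.integer(idx)
  node <- ag_node(p$value[idx, , drop = FALSE])
  node$param <- p
  node$embed_idx <- idx
  node
}

# ---- arithmetic ops ---------------------------------------------------

ag_matmul <- function(a, b) {
  ag_node(a$value %*% b$value, list(a, b), function(g, pv) {
    list(tcrossprod(g, pv[[2]]), crossprod(pv[[1]], g))
  })
}

# a %*% t(b)
ag_matmul_nt <- function(a, b) {
  ag_node(tcrossprod(a$value, b$value), list(a, b), function(g, pv) {
    list(g %*% pv[[2]], crossprod(g, pv[[1]]))
  })
}

ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(g, pv) list(g, g))
}

# add a 1 x d row vector to every row of a
ag_add_rowvec <- function(a, v) {
  av <- a$value
  ag_node(sweep(av, 2L, as.numeric(v$value), "+"), list(a, v),
          function(g, pv) list(g, matrix(colSums(g), 1L)))
}

ag_scale <- function(a, k) {
  ag_node(a$value * k, list(a), function(g, pv) list(g * k))
}

ag_relu <- function(a) {
  v <- a$value
  v[v < 0] <- 0
  ag_node(v, list(a), function(g, pv) {
    list(g * (pv[[1]] > 0))
  })
}

ag_dropout <- function(a, p) {
  if (p <= 0) return(a)
  mask <- matrix(stats::rbinom(length(a$value), 1L, 1 - p),
                 nrow(a$value)) / (1 - p)
  ag_node(a$value * mask, list(a), function(g, pv) list(g * mask))
}

# row-wise softmax with an optional additive mask (constant matrix)
ag_softmax_rows <- function(a, mask = NULL) {
  x <- a$value
  if (!is.null(mask)) x <- x + mask
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  s <- e / rowSums(e)
  ag_node(s, list(a), function(g, pv) {
    list((g - rowSums(g * s)) * s)
  })
}

# row-wise layer normalization with gain/bias (1 x d parameters)
ag_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$value
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gm <- as.numeric(gamma$value)
  y <- sweep(xhat, 2L, gm, "*")
  y <- sweep(y, 2L, as.numeric(beta$value), "+")
  ag_node(y, list(a, gamma, beta), function(g, pv) {
    dxhat <- sweep(g, 2L, gm, "*")
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
    list(dx,
         matrix(colSums(g * xhat), 1L),
         matrix(colSums(g), 1L))
  })
}

ag_cbind <- function(nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_node(do.call(cbind, lapply(nodes, function(n) n$value)), nodes,
          function(g, pv) {
            lapply(seq_along(pv), function(i) {
              g[, starts[i]:ends[i], drop = FALSE]
            })
          })
}

ag_rbind <- function(nodes) {
  heights <- vapply(nodes, function(n) nrow(n$value), integer(1))
  ends <- cumsum(heights)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_node(do.call(rbind, lapply(nodes, function(n) n$value)), nodes,
          function(g, pv) {
            lapply(seq_along(pv), function(i) {
              g[starts[i]:ends[i], , drop = FALSE]
            })
          })
}

# mean token-level cross-entropy between logits (L x V) and target ids (L)
ag_cross_entropy <- function(logits, targets) {
  x <- logits$value
  targets <- as.integer(targets)
  stopifnot(length(targets) == nrow(x))
  m <- apply(x, 1L, max)
  lse <- m + log(rowSums(exp(x - m)))
  picked <- x[cbind(seq_len(nrow(x)), targets)]
  loss <- mean(lse - picked)
  probs <- exp(x - lse)
  n <- nrow(x)
  ag_node(matrix(loss, 1L, 1L), list(logits), function(g, pv) {
    d <- probs
    d[cbind(seq_len(n), targets)] <- d[cbind(seq_len(n), targets)] - 1
    list(d * (as.numeric(g) / n))
  })
}

# mean of several scalar nodes (used for batch losses)
ag_mean <- function(nodes) {
  vals <- vapply(nodes, function(n) as.numeric(n$value), numeric(1))
  k <- length(nodes)
  ag_node(matrix(mean(vals), 1L, 1L), nodes, function(g, pv) {
    rep(list(matrix(as.numeric(g) / k, 1L, 1L)), k)
  })
}

# ---- backward pass ----------------------------------------------------

#' Backpropagate from a scalar loss node
#'
#' Walks the current tape in reverse creation order and accumulates
#' gradients into every parameter reached by the graph.
#' @keywords internal
ag_backward <- function(loss) {
  force(loss)  # the loss forward pass must run before the tape is read
  tape <- .ag$tape
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    g <- node$grad
    if (is.null(g)) next
    if (!is.null(node$param)) {
      p <- node$param
      if (is.null(node$embed_idx)) {
        p$grad <- p$grad + g
      } else {
        idx <- node$embed_idx
        for (j in seq_along(idx)) {
          p$grad[idx[j], ] <- p$grad[idx[j], ] + g[j, ]
        }
      }
    }
    if (is.null(node$backward)) next
    pv <- lapply(node$parents, function(pn) pn$value)
    pgrads <- node$backward(g, pv)
    for (j in seq_along(node$parents)) {
      pn <- node$parents[[j]]
      if (isTRUE(pn$constant)) next
      pn$grad <- if (is.null(pn$grad)) pgrads[[j]] else pn$grad + pgrads[[j]]
    }
  }
  invisible(loss)
}

# ---- optimizer --------------------------------------------------------

#' One Adam step over a list of parameters
#'
#' Applies the update using each parameter's accumulated `$grad` divided by
#' `grad_scale` (gradient accumulation), then zeroes the gradients.
#' @keywords internal
adam_step <- function(params, lr = 1e-5, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, grad_scale = 1, t = 1L) {
  for (p in params) {
    g <- p$grad / grad_scale
    if (is.null(p$m)) {
      p$m <- matrix(0, nrow(p$value), ncol(p$value))
      p$v <- matrix(0, nrow(p$value), ncol(p$value))
    }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    p$grad[] <- 0
  }
  invisible(params)
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(params)
}
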