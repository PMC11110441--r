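# Fixed-size protein sequence embeddings through a pluggable backend
# contract. The built-in backend is a deterministic hashed k-mer profile
# embedder so the full pipeline runs without model downloads; an external
# protein language model (e.g. ProtT5) can be plugged in by registering a
# backend that returns per-sequence vectors of the configured dimension.

.embed_cache <- new.env(parent = emptyenv())

#' Create an embedder backend descriptor
#'
#' @param name backend name (`"builtin"` for the hashed k-mer embedder; any
#'   other name must come with a `fun`).
#' @param dim embedding dimension (must equal the transformer `d_model` of
#'   any model the embeddings feed).
#' @param seed integer seed fixing the built-in backend's projection matrix.
#' @param fun for custom backends: `function(seq) numeric(dim)`; must be
#'   deterministic if `deterministic = TRUE`.
#' @param deterministic whether identical sequences always give bitwise
#'   identical vectors.
#' @return object of class `embedder_backend`.
#' @export
embedder_backend <- function(name = "builtin", dim = 1024L, seed = 7L,
                             fun = NULL, deterministic = TRUE) {
  stopifnot(dim >= 8L)
  if (name != "builtin" && is.null(fun)) {
    stop("embedder backend '", name, "' unavailable: no embedding function ",
         "registered for it", call. = FALSE)
  }
  structure(list(name = name, dim = as.integer(dim), seed = as.integer(seed),
                 fun = fun, deterministic = isTRUE(deterministic)),
            class = "embedder_backend")
}

#' @export
print.embedder_backend <- function(x, ...) {
  cat(sprintf("embedder backend '%s': dim %d, %s\n", x$name, x$dim,
              if (x$deterministic) "deterministic" else "stochastic"))
  invisible(x)
}

# seed-determined fixed projection from the 8000-slot k-mer profile space;
# cached because it is the expensive part (8000 x d normals)
builtin_projection <- function(d, seed) {
  key <- sprintf("proj_%d_%d", d, seed)
  if (!is.null(.embed_cache[[key]])) return(.embed_cache[[key]])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  proj <- matrix(stats::rnorm(8000L * d) / sqrt(8000), nrow = 8000L, ncol = d)
  .embed_cache[[key]] <- proj
  proj
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Built-in deterministic k-mer embedder
#'
#' Per-residue representations are one-hot profiles of the circular
#' overlapping 3-mer starting at each position, hashed into a fixed
#' 8000-slot profile; mean pooling along the length axis therefore yields
#' the length-normalized 3-mer count profile, which is projected by a
#' seed-determined fixed random matrix to `d` dimensions and L2-normalized.
#' Circular (wrap-around) 3-mers make mean pooling exactly invariant to
#' sequence repetition. Fully reproducible from `(seq, d, seed)`.
#'
#' @param seq residue string.
#' @param d output dimension (>= 8).
#' @param seed projection seed.
#' @return numeric vector of length `d` with unit L2 norm.
#' @export
builtin_embedder <- function(seq, d = 1024L, seed = 7L) {
  stopifnot(d >= 8L)
  toks <- tokenize_protein(seq)
  code <- match(toks, protein_vocabulary()) - 1L  # 0..20
  n <- length(code)
  k1 <- code
  k2 <- code[(seq_len(n) %% n) + 1L]        # position i+1, wrapping
  k3 <- code[((seq_len(n) + 1L) %% n) + 1L] # position i+2, wrapping
  slot <- ((k1 * 441L + k2 * 21L + k3) %% 8000L) + 1L
  profile <- tabulate(slot, nbins = 8000L) / n
  v <- as.numeric(crossprod(builtin_projection(d, seed), profile))
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("degenerate zero embedding", call. = FALSE)
  v / nrm
}

# deterministic polynomial hash of a residue string (cache file naming)
seq_hash <- function(s) {
  codes <- utf8ToInt(s)
  h1 <- 0; h2 <- 0
  for (c in codes) {
    h1 <- (h1 * 131 + c) %% 1000000007
    h2 <- (h2 * 137 + c) %% 998244353
  }
  sprintf("%09d%09d", h1, h2)
}

#' Embed a protein sequence
#'
#' Produces the fixed-size target embedding used as the first encoder input
#' position. The backend's per-residue representations are mean-pooled along
#' the length dimension, so the output size is independent of sequence
#' length. Results are memoized per (backend, sequence) within the session,
#' and optionally cached on disk keyed by (backend, sequence hash) so one
#' protein is embedded once and reused across all of its triples and runs.
#'
#' @param seq residue string, length 1 to 4000.
#' @param backend an [embedder_backend()].
#' @param cache_dir optional directory for the on-disk embedding cache
#'   (only used for deterministic backends).
#' @return list with `vector` (numeric, length `backend$dim`) and `dim`.
#' @export
embed_sequence <- function(seq, backend = embedder_backend(),
                           cache_dir = NULL) {
  stopifnot(inherits(backend, "embedder_backend"))
  n <- nchar(seq)
  if (n < 1L || n > 4000L) {
    stop("sequence length must be in [1, 4000], got ", n, call. = FALSE)
  }
  key <- sprintf("emb_%s_%d_%d_%s", backend$name, backend$dim, backend$seed,
                 seq)
  if (backend$deterministic && !is.null(.embed_cache[[key]])) {
    return(.embed_cache[[key]])
  }
  cache_file <- NULL
  if (!is.null(cache_dir) && backend$deterministic) {
    cache_file <- file.path(cache_dir, sprintf(
      "%s_%d_%d_%s.rds", backend$name, backend$dim, backend$seed,
      seq_hash(seq)))
    if (file.exists(cache_file)) {
      res <- readRDS(cache_file)
      .embed_cache[[key]] <- res
      return(res)
    }
  }
  v <- if (backend$name == "builtin") {
    builtin_embedder(seq, backend$dim, backend$seed)
  } else {
    out <- backend$fun(seq)
    if (length(out) != backend$dim) {
      stop("backend '", backend$name, "' returned length ", length(out),
           ", expected ", backend$dim, call. = FALSE)
    }
    as.numeric(out)
  }
  if (any(!is.finite(v))) stop("non-finite embedding entries", call. = FALSE)
  res <- list(vector = v, dim = backend$dim)
  if (backend$deterministic) .embed_cache[[key]] <- res
  if (!is.null(cache_file)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(res, cache_file)
  }
  res
}

#' Embed many sequences keyed by target id
#'
#' One protein, one vector: embeddings are computed once per unique sequence
#' and reused across all of that target's triples.
#'
#' @param sequences named character vector (target_id -> residue string).
#' @param backend an [embedder_backend()].
#' @param cache_dir optional on-disk cache directory, see
#'   [embed_sequence()].
#' @return named list of embedding vectors.
#' @export
embed_targets <- function(sequences, backend = embedder_backend(),
                          cache_dir = NULL) {
  stopifnot(!is.null(names(sequences)))
  lapply(sequences, function(s) {
    embed_sequence(s, backend, cache_dir = cache_dir)$vector
  })
}
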