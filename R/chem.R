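# Chemistry layer: canonical SMILES, validity, Morgan fingerprints,
# MMP-style fragmentation and SA scores, provided by RDKit through the
# bundled worker script inst/python/chemtool.py. All calls are batched
# (one interpreter start per request) and memoized per session.

.chem <- new.env(parent = emptyenv())

chem_python <- function() {
  if (!is.null(.chem$python)) return(.chem$python)
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("chemistry backend unavailable: no 'python' interpreter on the PATH",
         call. = FALSE)
  }
  .chem$python <- py
  py
}

chem_script <- function() {
  path <- system.file("python", "chemtool.py", package = "biochemlm")
  if (!nzchar(path)) {
    # during development the package may be loaded from source
    path <- file.path("inst", "python", "chemtool.py")
  }
  if (!file.exists(path)) stop("chemtool.py not found", call. = FALSE)
  path
}

#' Low-level call into the RDKit worker
#'
#' Serializes a request as JSON, runs the bundled `chemtool.py` once, and
#' parses the JSON response. Not memoized; the typed wrappers below are.
#'
#' @param op operation name understood by the worker.
#' @param ... request fields (e.g. `smiles = c(...)`).
#' @return the `result` element of the response.
#' @keywords internal
chem_call <- function(op, ...) {
  req <- c(list(op = op), list(...))
  infile <- tempfile(fileext = ".json")
  on.exit(unlink(infile), add = TRUE)
  writeLines(jsonlite::toJSON(req, auto_unbox = TRUE, null = "null",
                              digits = NA), infile)
  out <- suppressWarnings(
    system2(chem_python(), shQuote(chem_script()), stdin = infile,
            stdout = TRUE, stderr = FALSE)
  )
  status <- attr(out, "status")
  resp <- tryCatch(
    jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE),
    error = function(e) NULL
  )
  if (is.null(resp) || !is.null(resp$error)) {
    msg <- if (!is.null(resp$error)) resp$error else
      paste("worker exited with status", status %||% "unknown")
    stop("chemistry backend error in op '", op, "': ", msg, call. = FALSE)
  }
  resp$result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# memoized vectorized call: one cache entry per (tag, input string)
chem_cached <- function(tag, keys, compute) {
  cache <- .chem$cache
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .chem$cache <- cache
  }
  ids <- paste0(tag, "\r", keys)
  missing_idx <- which(!vapply(ids, exists, logical(1), envir = cache))
  if (length(missing_idx)) {
    vals <- compute(keys[missing_idx])
    for (i in seq_along(missing_idx)) {
      assign(ids[missing_idx[i]], vals[[i]], envir = cache)
    }
  }
  lapply(ids, get, envir = cache)
}

#' Canonicalize SMILES strings
#'
#' Single deterministic canonicalizer used everywhere in the package:
#' compound identity is equality of canonical strings. Invalid SMILES map
#' to `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where unparseable.
#' @export
#' @examples \dontrun{canonicalize_smiles(c("OCC", "c1cc[nH]c1"))}
canonicalize_smiles <- function(smiles) {
  if (!length(smiles)) return(character(0))
  stopifnot(is.character(smiles))
  res <- chem_cached("can", smiles, function(keys) {
    chem_call("canonicalize", smiles = as.list(keys))
  })
  vapply(res, function(x) if (is.null(x)) NA_character_ else x, character(1))
}

#' Test SMILES validity
#' @param smiles character vector.
#' @return logical vector; `TRUE` where RDKit parses the string.
#' @export
smiles_valid <- function(smiles) !is.na(canonicalize_smiles(smiles))

#' Heavy-atom counts
#'
#' Number of non-hydrogen atoms per molecule; attachment-point dummies
#' (`[*:n]`) are excluded from the count.
#'
#' @param smiles character vector (may contain attachment points).
#' @return integer vector, `NA` where unparseable.
#' @export
heavy_atom_count <- function(smiles) {
  if (!length(smiles)) return(integer(0))
  res <- chem_cached("ha", smiles, function(keys) {
    chem_call("heavy_atoms", smiles = as.list(keys))
  })
  vapply(res, function(x) if (is.null(x)) NA_integer_ else as.integer(x),
         integer(1))
}

#' Morgan fingerprints
#'
#' 2048-bit circular substructure (Morgan/ECFP-style) fingerprints with bond
#' radius 3, returned as sorted 0-based on-bit indices.
#'
#' @param smiles character vector of SMILES.
#' @param nbits fingerprint length in bits.
#' @param radius bond radius of the circular environment.
#' @return list of `morgan_fp` objects (integer on-bit indices with an
#'   `nbits` attribute); `NULL` entries for unparseable SMILES.
#' @export
morgan_fp <- function(smiles, nbits = 2048L, radius = 3L) {
  if (!length(smiles)) return(list())
  tag <- sprintf("fp%d_%d", nbits, radius)
  res <- chem_cached(tag, smiles, function(keys) {
    chem_call("morgan_fp", smiles = as.list(keys), nbits = nbits,
              radius = radius)
  })
  lapply(res, function(x) {
    if (is.null(x)) return(NULL)
    structure(as.integer(unlist(x)), nbits = as.integer(nbits),
              class = "morgan_fp")
  })
}

#' Synthetic-accessibility scores
#'
#' Fragment-contribution synthetic-accessibility score (Ertl-Schuffenhauer
#' scheme, RDKit reference implementation) on its 1 (easy) to 10 (hard)
#' scale. Invalid molecules are skipped with a warning and return `NA`.
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector of SA scores.
#' @export
sa_scores <- function(smiles) {
  if (!length(smiles)) return(numeric(0))
  res <- chem_cached("sa", smiles, function(keys) {
    chem_call("sa_score", smiles = as.list(keys))
  })
  out <- vapply(res, function(x) if (is.null(x)) NA_real_ else as.numeric(x),
                numeric(1))
  if (anyNA(out)) {
    warning(sum(is.na(out)), " invalid molecule(s) skipped in SA scoring",
            call. = FALSE)
  }
  out
}

#' Default retrosynthetic cut rules
#'
#' SMARTS patterns for the exocyclic acyclic single bonds eligible for
#' matched-molecular-pair-style cuts: amide C-N, ester C-O, amine C-N,
#' ether C-O, aromatic C to sp3 C, and sulfonamide S-N environments. The
#' rule set is configurable wherever fragmentation is invoked.
#'
#' @return character vector of SMARTS bond patterns.
#' @export
default_cut_rules <- function() {
  c(amide       = "[C;$(C=O)]!@[N;!$(N=*)]",
    ester       = "[C;$(C=O)]!@[O;X2;!$(O=*)]",
    amine       = "[C;X4]!@[N;X3;!$(N=*);!$(N[C]=O)]",
    ether       = "[C;X4]!@[O;X2;!$(O[C]=O)]",
    aryl_alkyl  = "[c]!@[C;X4]",
    sulfonamide = "[S;$(S(=O)(=O))]!@[N]")
}

#' Fragment molecules at retrosynthetic bonds
#'
#' Enumerates all fragmentations obtained by cutting 1..`max_cuts` eligible
#' acyclic single bonds, each yielding one connected core with numbered
#' attachment points (`[*:1]`..`[*:5]`) and one substituent per cut.
#'
#' @param smiles character vector of valid SMILES.
#' @param max_cuts maximum number of simultaneous cuts (1-5).
#' @param rules SMARTS bond patterns; defaults to [default_cut_rules()].
#' @return list (per molecule) of lists of fragmentation records with
#'   elements `core`, `subs`, `core_heavy`, `sub_heavy`, `parent`.
#' @export
fragment_molecules <- function(smiles, max_cuts = 5L,
                               rules = default_cut_rules()) {
  stopifnot(max_cuts >= 1L, max_cuts <= 5L)
  if (!length(smiles)) return(list())
  res <- chem_call("fragment", smiles = as.list(smiles),
                   max_cuts = max_cuts, rules = as.list(unname(rules)))
  bad <- vapply(res, is.null, logical(1))
  if (any(bad)) {
    stop("unparseable SMILES passed to fragment_molecules: ",
         paste(smiles[bad], collapse = ", "), call. = FALSE)
  }
  mapply(function(frags, parent) {
    lapply(frags, function(f) {
      list(core = f$core, subs = as.character(unlist(f$subs)),
           core_heavy = as.integer(f$core_heavy),
           sub_heavy = as.integer(unlist(f$sub_heavy)),
           parent = parent)
    })
  }, res, smiles, SIMPLIFY = FALSE)
}

#' Reattach substituents to a core
#'
#' Joins a core bearing numbered attachment points with substituents carrying
#' matching labels and returns the canonical SMILES of the assembled
#' molecule (`NA` if assembly fails).
#'
#' @param cores character vector of core SMILES with `[*:n]` labels.
#' @param subs list (parallel to `cores`) of character vectors of substituent
#'   SMILES with matching labels.
#' @return character vector of canonical SMILES.
#' @export
reassemble_molecules <- function(cores, subs) {
  stopifnot(length(cores) == length(subs))
  if (!length(cores)) return(character(0))
  pairs <- mapply(function(core, ss) list(core = core, subs = as.list(ss)),
                  cores, subs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  res <- chem_call("reassemble", pairs = pairs)
  vapply(res, function(x) if (is.null(x)) NA_character_ else x, character(1))
}
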