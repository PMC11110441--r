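# Tokenizers for the three input modalities: protein residues, SMILES
# strings and discretized potency values.

NATURAL_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")
RARE_AA <- c("B", "Z", "U", "O", "J")

#' Protein residue vocabulary
#'
#' The 20 natural amino acids plus `"X"` for rare/nonstandard residues:
#' exactly 21 tokens before any special markers.
#'
#' @return character vector of 21 residue tokens.
#' @export
protein_vocabulary <- function() c(NATURAL_AA, "X")

#' Tokenize a protein sequence
#'
#' One token per residue; residues outside the 20 natural amino acids
#' (e.g. B, Z, U, O, J) map to `"X"`.
#'
#' @param seq uppercase residue string.
#' @return character vector of residue tokens.
#' @export
#' @examples tokenize_protein("MKV")
tokenize_protein <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty protein sequence", call. = FALSE)
  tokens <- strsplit(seq, "", fixed = TRUE)[[1]]
  tokens[!(tokens %in% NATURAL_AA)] <- "X"
  tokens
}

# SMILES token pattern, matched greedily left to right: bracket atoms first,
# then %nn ring labels, then the two-character organic-subset atoms, then
# any single character.
.SMILES_TOKEN_RE <- "\\[[^][]*\\]|%[0-9]{2}|Cl|Br|."

#' Tokenize a SMILES string
#'
#' Greedy left-to-right tokenization: bracketed expressions (`[nH]`,
#' `[O-]`, ...) are single tokens, as are two-character organic-subset
#' atoms (`Cl`, `Br`), `%nn` ring labels, and every remaining character.
#'
#' @param s a syntactically valid SMILES string.
#' @return character vector of tokens; concatenating them restores `s`.
#' @export
#' @examples tokenize_smiles("c1cc[nH]c1")
tokenize_smiles <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s))
  if (!nzchar(s)) return(character(0))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "[") - (chars == "]"))
  if (any(depth < 0)) {
    stop("unbalanced ']' at position ", which(depth < 0)[1], " in SMILES: ",
         s, call. = FALSE)
  }
  if (depth[length(depth)] != 0) {
    stop("unbalanced '[' at position ", which(chars == "[")[1],
         " in SMILES: ", s, call. = FALSE)
  }
  m <- gregexpr(.SMILES_TOKEN_RE, s)[[1]]
  regmatches(s, list(m))[[1]]
}

#' Reconstruct a SMILES string from tokens
#'
#' Inverse of [tokenize_smiles()]: concatenates tokens between the optional
#' start marker and the first end marker. Padding must be stripped upstream.
#'
#' @param tokens character vector of tokens, possibly including the special
#'   markers `<start>` and `<end>`.
#' @return SMILES string (empty if no payload tokens; such outputs are
#'   flagged invalid downstream, not an error here).
#' @export
detokenize <- function(tokens) {
  if (!length(tokens)) return("")
  end <- match("<end>", tokens)
  if (!is.na(end)) tokens <- tokens[seq_len(end - 1L)]
  tokens <- tokens[!(tokens %in% c("<start>", "<pad>"))]
  paste(tokens, collapse = "")
}

#' Potency binner
#'
#' Discretizes pKi values over the globally observed potency range
#' [4.00, 12.52] into 852 half-open bins of constant width 0.01 (the top bin
#' is closed at 12.52), one conditioning token per bin.
#'
#' @param lo,hi potency range in pKi units.
#' @param width bin width in pKi units.
#' @return object of class `potency_binner`.
#' @export
potency_binner <- function(lo = 4.00, hi = 12.52, width = 0.01) {
  stopifnot(hi > lo, width > 0)
  n_bins <- as.integer(round((hi - lo) / width))
  structure(list(lo = lo, hi = hi, width = width, n_bins = n_bins),
            class = "potency_binner")
}

#' @export
print.potency_binner <- function(x, ...) {
  cat(sprintf("potency binner: [%.2f, %.2f] pKi, width %.2f, %d bins\n",
              x$lo, x$hi, x$width, x$n_bins))
  invisible(x)
}

#' Map pKi values to potency-bin indices
#'
#' Bin k covers [lo + k*width, lo + (k+1)*width); the last bin is closed at
#' `hi`. Values outside the range are clamped with a warning (the range is
#' the globally observed one, so out-of-range values are new data, not
#' errors). A small floating-point guard avoids representability artifacts
#' at exact bin edges.
#'
#' @param binner a [potency_binner()].
#' @param pki numeric vector of finite pKi values.
#' @return integer vector of 0-based bin indices in `[0, n_bins - 1]`.
#' @export
#' @examples bin_potency(potency_binner(), c(4.0, 7.849, 12.52))
bin_potency <- function(binner, pki) {
  stopifnot(inherits(binner, "potency_binner"), is.numeric(pki))
  if (anyNA(pki) || any(!is.finite(pki))) {
    stop("non-finite pKi passed to bin_potency", call. = FALSE)
  }
  clamped <- pmin(pmax(pki, binner$lo), binner$hi)
  if (any(clamped != pki)) {
    warning(sum(clamped != pki), " pKi value(s) outside [",
            binner$lo, ", ", binner$hi, "] clamped", call. = FALSE)
  }
  idx <- as.integer(floor((clamped - binner$lo) / binner$width + 1e-9))
  pmin(idx, binner$n_bins - 1L)
}

# ---- SMILES vocabulary (corpus-derived) -------------------------------

SPECIAL_TOKENS <- c("<pad>", "<start>", "<end>", "<unk>")

#' Build a SMILES vocabulary from a training corpus
#'
#' Token inventory is derived from the corpus; the four special tokens
#' `<pad>`, `<start>`, `<end>`, `<unk>` occupy the first ids. Unseen tokens
#' at inference map to `<unk>`.
#'
#' @param smiles character vector of (canonical) SMILES strings.
#' @return object of class `smiles_vocab`: named integer vector token -> id
#'   (1-based).
#' @export
smiles_vocab <- function(smiles) {
  stopifnot(length(smiles) > 0)
  toks <- sort(unique(unlist(lapply(smiles, tokenize_smiles))))
  ids <- seq_along(c(SPECIAL_TOKENS, toks))
  structure(stats::setNames(ids, c(SPECIAL_TOKENS, toks)),
            class = "smiles_vocab")
}

#' @export
print.smiles_vocab <- function(x, ...) {
  cat("SMILES vocabulary:", length(x), "tokens (incl. 4 special)\n")
  invisible(x)
}

#' Encode a SMILES string as token ids
#'
#' @param vocab a [smiles_vocab()].
#' @param s SMILES string.
#' @param add_markers wrap the ids in `<start>`/`<end>`.
#' @return integer vector of token ids; unknown tokens map to `<unk>`.
#' @export
encode_smiles <- function(vocab, s, add_markers = TRUE) {
  toks <- tokenize_smiles(s)
  ids <- unname(vocab[toks])
  unk <- unname(vocab["<unk>"])
  ids[is.na(ids)] <- unk
  if (add_markers) ids <- c(unname(vocab["<start>"]), ids,
                            unname(vocab["<end>"]))
  as.integer(ids)
}

#' Decode token ids back to a SMILES string
#' @param vocab a [smiles_vocab()].
#' @param ids integer token ids.
#' @return SMILES string (see [detokenize()]).
#' @export
decode_smiles <- function(vocab, ids) {
  detokenize(names(vocab)[ids])
}

#' Serialize a vocabulary to JSON
#' @param vocab named integer vector (token -> id).
#' @param path output file.
#' @export
write_vocab <- function(vocab, path) {
  jsonlite::write_json(as.list(vocab), path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a vocabulary from JSON
#' @param path JSON file written by [write_vocab()].
#' @return `smiles_vocab` object.
#' @export
read_vocab <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(stats::setNames(as.integer(unlist(x)), names(x)),
            class = "smiles_vocab")
}
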