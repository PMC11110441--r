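# Candidate sampling per test instance and the evaluation statistics:
# exact reproduction counts, 1-NN Tanimoto similarity distributions,
# potency-distribution comparisons and synthetic-accessibility scores.

#' Sample candidate compounds for a class split
#'
#' For each test compound, a (protein embedding, potency embedding) input
#' instance is formed from its experimental potency value, and sequences
#' are drawn by multinomial sampling until `per_instance` valid SMILES are
#' collected or `attempt_cap` draws have been spent. Candidates are
#' canonicalized and pooled per class, keeping unique strings.
#'
#' @param model a fine-tuned `biochem_lm` (or one straight from
#'   pre-training for the no-fine-tuning control).
#' @param protein numeric protein embedding of the class target.
#' @param test_records data.frame with `canonical_smiles` and `pki` of the
#'   test instances.
#' @param per_instance maximum number of valid compounds kept per test
#'   instance (default 100).
#' @param attempt_cap maximum draws per instance.
#' @param seed base seed; instance i uses `seed + i`.
#' @return object of class `candidate_set`: `per_instance_valid` (list of
#'   character vectors of canonical SMILES, one per test instance),
#'   `pooled` (unique canonical SMILES across instances), `n_draws`,
#'   `n_valid_draws`, and `flagged` (instances with zero valid samples).
#' @export
sample_candidates <- function(model, protein, test_records,
                              per_instance = 100L, attempt_cap = 1000L,
                              seed = 1L) {
  stopifnot(inherits(model, "biochem_lm"), per_instance >= 1L,
            attempt_cap >= per_instance)
  n_inst <- nrow(test_records)
  per_valid <- vector("list", n_inst)
  n_draws <- 0L
  n_valid_draws <- 0L
  for (i in seq_len(n_inst)) {
    input <- encoder_input(protein, test_records$pki[i])
    got <- character(0)
    attempts <- 0L
    round <- 0L
    while (length(got) < per_instance && attempts < attempt_cap) {
      # draw in generous batches (validity is rarely above ~50%), so one
      # round usually suffices
      need <- per_instance - length(got)
      batch <- min(max(3L * need, 24L), attempt_cap - attempts)
      round <- round + 1L
      res <- sample_compounds(model, input, n = batch,
                              seed = seed + i * 131L + round)
      attempts <- attempts + batch
      got <- c(got, res$canonical[res$valid])
      n_valid_draws <- n_valid_draws + sum(res$valid)
    }
    n_draws <- n_draws + attempts
    per_valid[[i]] <- utils::head(got, per_instance)
  }
  flagged <- which(!vapply(per_valid, length, integer(1)))
  if (length(flagged)) {
    warning(length(flagged), " test instance(s) yielded no valid sample ",
            "within the attempt cap", call. = FALSE)
  }
  structure(list(per_instance_valid = per_valid,
                 pooled = unique(unlist(per_valid)),
                 n_draws = n_draws, n_valid_draws = n_valid_draws,
                 flagged = flagged),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf(paste0("candidate set: %d instances, %d unique pooled ",
                     "candidates (%d valid / %d draws)\n"),
              length(x$per_instance_valid), length(x$pooled),
              x$n_valid_draws, x$n_draws))
  invisible(x)
}

#' Count exactly reproduced compounds
#'
#' Number of known test compounds exactly reproduced by the candidates,
#' i.e. the size of the intersection by canonical-string equality. Both
#' sides must come from the same canonicalizer.
#'
#' @param candidates character vector of canonical SMILES (or a
#'   `candidate_set`).
#' @param test_set character vector of canonical test SMILES.
#' @return integer count.
#' @export
count_reproduced <- function(candidates, test_set) {
  if (inherits(candidates, "candidate_set")) candidates <- candidates$pooled
  length(intersect(unique(candidates), unique(test_set)))
}

#' Tanimoto coefficient between two fingerprints
#'
#' `|a AND b| / |a OR b|` on bit sets; defined as 1 when both fingerprints
#' are all-zero.
#'
#' @param a,b `morgan_fp` objects of equal bit length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (!identical(attr(a, "nbits"), attr(b, "nbits"))) {
    stop("fingerprint bit lengths differ", call. = FALSE)
  }
  if (!length(a) && !length(b)) return(1.0)
  length(intersect(a, b)) / length(union(a, b))
}

#' 1-nearest-neighbor similarity distribution
#'
#' For each query molecule, the maximum Tanimoto coefficient over the
#' reference set, computed on 2048-bit Morgan fingerprints (radius 3).
#'
#' @param query_set,reference_set character vectors of canonical SMILES
#'   (both non-empty).
#' @return numeric vector of per-query 1-NN similarities, named by query.
#' @export
nn_similarity <- function(query_set, reference_set) {
  if (!length(query_set)) stop("empty query set", call. = FALSE)
  if (!length(reference_set)) stop("empty reference set", call. = FALSE)
  qf <- morgan_fp(query_set)
  rf <- morgan_fp(reference_set)
  ok_q <- !vapply(qf, is.null, logical(1))
  ok_r <- !vapply(rf, is.null, logical(1))
  if (!all(ok_r)) stop("unparseable reference SMILES", call. = FALSE)
  out <- rep(NA_real_, length(query_set))
  for (i in which(ok_q)) {
    out[i] <- max(vapply(rf, tanimoto, numeric(1), a = qf[[i]]))
  }
  stats::setNames(out, query_set)
}

#' Compare potency distributions across compound groups
#'
#' Pairwise independent-samples t-tests (two-sided Welch) between labeled
#' pKi groups, with the star annotation scheme: p <= 1e-4 `****`,
#' <= 1e-3 `***`, <= 0.01 `**`, <= 0.05 `*`, otherwise `ns`. Groups with
#' fewer than 2 values are annotated `ns/NA`.
#'
#' @param groups named list of numeric pKi vectors (typically fine-tuning,
#'   test, reproduced-conditional, reproduced-unconditional).
#' @return data.frame with columns `group1`, `group2`, `p_value`, `stars`.
#' @export
compare_potency_distributions <- function(groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  combs <- utils::combn(names(groups), 2L)
  res <- apply(combs, 2L, function(pair) {
    x <- groups[[pair[1L]]]
    y <- groups[[pair[2L]]]
    if (length(x) < 2L || length(y) < 2L) {
      return(data.frame(group1 = pair[1L], group2 = pair[2L],
                        p_value = NA_real_, stars = "ns/NA"))
    }
    p <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) {
      # degenerate zero-variance groups: identical means are a clear
      # non-difference, different means a clear difference
      if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    })
    data.frame(group1 = pair[1L], group2 = pair[2L], p_value = p,
               stars = potency_stars(p))
  })
  do.call(rbind, res)
}

potency_stars <- function(p) {
  if (is.na(p)) return("ns/NA")
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***" else if (p <= 0.01) "**"
  else if (p <= 0.05) "*" else "ns"
}

#' Evaluate candidates for one activity class
#'
#' Computes the per-class evaluation report: candidate and reproduction
#' counts for the conditional and unconditional candidate sets, 1-NN
#' similarity distributions (candidates vs test compounds; reproduced vs
#' fine-tuning compounds), potency-distribution comparisons with t-test
#' annotations, and synthetic-accessibility score distributions.
#'
#' @param conditional,unconditional `candidate_set`s (unconditional may be
#'   NULL).
#' @param finetune_records,test_records data.frames with
#'   `canonical_smiles`, `pki`.
#' @param sa include SA-score distributions.
#' @return object of class `evaluation_report`.
#' @export
evaluate_class <- function(conditional, unconditional = NULL,
                           finetune_records, test_records, sa = TRUE) {
  test_smiles <- unique(test_records$canonical_smiles)
  ft_smiles <- unique(finetune_records$canonical_smiles)
  pki_of <- function(smiles) {
    test_records$pki[match(smiles, test_records$canonical_smiles)]
  }
  one_side <- function(cands) {
    if (is.null(cands)) return(NULL)
    pooled <- cands$pooled
    reproduced <- intersect(pooled, test_smiles)
    list(n_candidates = length(pooled),
         n_raw_valid = cands$n_valid_draws,
         n_reproduced = length(reproduced),
         reproduced = reproduced,
         nn_candidates_vs_test = if (length(pooled))
           nn_similarity(pooled, test_smiles) else numeric(0),
         nn_reproduced_vs_finetune = if (length(reproduced))
           nn_similarity(reproduced, ft_smiles) else numeric(0),
         sa_scores = if (sa && length(pooled)) sa_scores(pooled)
           else numeric(0))
  }
  cond <- one_side(conditional)
  unc <- one_side(unconditional)
  groups <- list(finetune = finetune_records$pki, test = test_records$pki,
                 reproduced_conditional = pki_of(cond$reproduced),
                 reproduced_unconditional =
                   if (!is.null(unc)) pki_of(unc$reproduced) else numeric(0))
  structure(list(conditional = cond, unconditional = unc,
                 potency_groups = groups,
                 potency_tests = compare_potency_distributions(groups),
                 sa_finetune = if (sa) sa_scores(ft_smiles) else numeric(0)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  fmt <- function(side, label) {
    if (is.null(side)) return(invisible(NULL))
    cat(sprintf("  %s: %d candidates, %d test compounds reproduced\n",
                label, side$n_candidates, side$n_reproduced))
  }
  cat("evaluation report\n")
  fmt(x$conditional, "conditional")
  fmt(x$unconditional, "unconditional")
  invisible(x)
}

#' Write an evaluation report
#'
#' JSON with the counts and per-group statistics plus TSV tables of the
#' similarity and SA distributions.
#'
#' @param report an `evaluation_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  side_summary <- function(side) {
    if (is.null(side)) return(NULL)
    list(n_candidates = side$n_candidates,
         n_raw_valid = side$n_raw_valid,
         n_reproduced = side$n_reproduced)
  }
  jsonlite::write_json(list(
    conditional = side_summary(report$conditional),
    unconditional = side_summary(report$unconditional),
    potency_tests = report$potency_tests),
    file.path(dir, "report.json"), auto_unbox = TRUE, pretty = TRUE,
    dataframe = "rows")
  dump_dist <- function(values, file, label) {
    if (!length(values)) return(invisible(NULL))
    data.table::fwrite(data.table::data.table(smiles = names(values) %||%
                                                seq_along(values),
                                              value = as.numeric(values),
                                              what = label),
                       file.path(dir, file), sep = "\t")
  }
  if (!is.null(report$conditional)) {
    dump_dist(report$conditional$nn_candidates_vs_test,
              "nn_conditional_vs_test.tsv", "1nn_tc")
  }
  if (!is.null(report$unconditional)) {
    dump_dist(report$unconditional$nn_candidates_vs_test,
              "nn_unconditional_vs_test.tsv", "1nn_tc")
  }
  invisible(dir)
}
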