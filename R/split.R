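# Analogue-series (AS) identification via matched-molecular-pair-style
# fragmentation with retrosynthetic cut rules, and structurally disjoint
# fine-tuning/test partitioning of the resulting series.

#' Core-size filter
#'
#' A fragmentation qualifies for analogue-series formation only if the core
#' contains at least twice the number of non-hydrogen atoms of the combined
#' substituents. Attachment-point markers are excluded from the counts.
#'
#' @param core_heavy heavy-atom count of the core.
#' @param sub_heavy integer vector of substituent heavy-atom counts.
#' @return logical.
#' @export
core_size_filter <- function(core_heavy, sub_heavy) {
  core_heavy >= 2L * sum(sub_heavy)
}

#' Group compounds into analogue series
#'
#' Fragments every compound at retrosynthetic bonds (1 to `max_cuts`
#' substitution sites), keeps fragmentations passing the core-size filter,
#' and groups compounds sharing an identical canonical core. Each compound
#' is assigned to at most one series, largest series first (ties broken by
#' lexicographically smallest core). Series of size 1 (singletons) are
#' dropped.
#'
#' @param compounds character vector of canonical SMILES.
#' @param max_cuts maximum substitution sites (up to 5).
#' @param rules retrosynthetic bond SMARTS, see [default_cut_rules()].
#' @return list of `analogue_series`: each
#'   `list(core, members, substituents)` with `members` the canonical
#'   SMILES sharing `core` and `substituents` the per-member substituent
#'   sets.
#' @export
group_series <- function(compounds, max_cuts = 5L,
                         rules = default_cut_rules()) {
  compounds <- unique(compounds)
  frags <- fragment_molecules(compounds, max_cuts = max_cuts, rules = rules)
  # candidate core -> member map (one entry per compound-core pair)
  cand <- list()
  for (i in seq_along(compounds)) {
    for (f in frags[[i]]) {
      if (!core_size_filter(f$core_heavy, f$sub_heavy)) next
      entry <- cand[[f$core]]
      if (is.null(entry)) entry <- list()
      if (is.null(entry[[compounds[i]]])) entry[[compounds[i]]] <- f$subs
      cand[[f$core]] <- entry
    }
  }
  assigned <- character(0)
  series <- list()
  repeat {
    sizes <- vapply(cand, function(m) {
      sum(!(names(m) %in% assigned))
    }, integer(1))
    if (!length(sizes) || max(sizes) < 2L) break
    cores <- names(cand)[sizes == max(sizes)]
    core <- sort(cores)[1L]
    members <- setdiff(names(cand[[core]]), assigned)
    series[[length(series) + 1L]] <- structure(
      list(core = core, members = members,
           substituents = cand[[core]][members]),
      class = "analogue_series")
    assigned <- c(assigned, members)
    cand[[core]] <- NULL
  }
  series
}

#' @export
print.analogue_series <- function(x, ...) {
  cat(sprintf("analogue series: %d members on core %s\n",
              length(x$members), x$core))
  invisible(x)
}

#' Split analogue series into fine-tuning and test sides
#'
#' Series are randomly partitioned 50/50 (an odd series going to the test
#' side); the side with the smaller total number of compounds is labeled
#' fine-tuning and the larger one test. Because whole series move together,
#' no core structure appears on both sides and the compound sets are
#' disjoint.
#'
#' @param series list of `analogue_series` from [group_series()].
#' @param seed integer seed for the random partition.
#' @return object of class `split_result`: lists `finetune_compounds`,
#'   `test_compounds`, `finetune_cores`, `test_cores`, and the `seed`.
#' @export
split_series <- function(series, seed = 1L) {
  if (length(series) < 2L) {
    stop("need at least 2 analogue series to split", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- length(series)
  n_a <- floor(n / 2)               # odd count: extra series to side B (test)
  idx_a <- sample(seq_len(n), n_a)
  side_a <- series[idx_a]
  side_b <- series[-idx_a]
  count <- function(s) sum(vapply(s, function(x) length(x$members),
                                  integer(1)))
  if (count(side_a) <= count(side_b)) {
    ft <- side_a; te <- side_b
  } else {
    ft <- side_b; te <- side_a
  }
  structure(list(
    finetune_compounds = unlist(lapply(ft, `[[`, "members"),
                                use.names = FALSE),
    test_compounds = unlist(lapply(te, `[[`, "members"), use.names = FALSE),
    finetune_cores = vapply(ft, `[[`, character(1), "core"),
    test_cores = vapply(te, `[[`, character(1), "core"),
    finetune_series = ft, test_series = te, seed = as.integer(seed)),
    class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf(paste0("analogue-series split: %d fine-tuning series ",
                     "(%d compounds) / %d test series (%d compounds)\n"),
              length(x$finetune_cores), length(x$finetune_compounds),
              length(x$test_cores), length(x$test_compounds)))
  invisible(x)
}

#' Split one activity class by analogue series
#'
#' Convenience wrapper: groups the class's compounds into analogue series
#' and splits them; per-compound pKi values are carried along.
#'
#' @param records data.frame with `canonical_smiles` and `pki`.
#' @param seed split seed.
#' @param max_cuts,rules passed to [group_series()].
#' @return a `split_result` with additional `finetune_records` /
#'   `test_records` data.tables.
#' @export
split_class <- function(records, seed = 1L, max_cuts = 5L,
                        rules = default_cut_rules()) {
  series <- group_series(records$canonical_smiles, max_cuts = max_cuts,
                         rules = rules)
  sp <- split_series(series, seed = seed)
  dt <- data.table::as.data.table(records)
  sp$finetune_records <- dt[canonical_smiles %in% sp$finetune_compounds]
  sp$test_records <- dt[canonical_smiles %in% sp$test_compounds]
  sp
}

#' Write a split manifest
#'
#' Records the seed, rule set and per-side series/compound membership as
#' JSON, plus per-side TSV files (core, member canonical SMILES).
#'
#' @param split a `split_result`.
#' @param dir output directory.
#' @param rules the rule set used (stored in the manifest).
#' @export
write_split <- function(split, dir, rules = default_cut_rules()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  side_tsv <- function(side, records, file) {
    rows <- data.table::rbindlist(lapply(side, function(s) {
      data.table::data.table(core = s$core, canonical_smiles = s$members)
    }))
    if (!is.null(records)) {
      rows[, pki := records$pki[match(canonical_smiles,
                                      records$canonical_smiles)]]
    }
    data.table::fwrite(rows, file.path(dir, file), sep = "\t")
  }
  side_tsv(split$finetune_series, split$finetune_records,
           "finetune_series.tsv")
  side_tsv(split$test_series, split$test_records, "test_series.tsv")
  jsonlite::write_json(list(
    seed = split$seed, rules = as.list(rules),
    n_finetune_series = length(split$finetune_cores),
    n_test_series = length(split$test_cores),
    n_finetune_compounds = length(split$finetune_compounds),
    n_test_compounds = length(split$test_compounds)),
    file.path(dir, "split_manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
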