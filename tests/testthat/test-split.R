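test_that("molecules without eligible bonds yield no fragmentations", {
  expect_length(fragment_molecules("c1ccccc1")[[1]], 0L)
})

test_that("toluene fragments at the aryl-alkyl bond", {
  frs <- fragment_molecules("Cc1ccccc1")[[1]]
  cores <- vapply(frs, `[[`, character(1), "core")
  expect_true("c1ccc([*:1])cc1" %in% cores)
  ring_core <- frs[[which(cores == "c1ccc([*:1])cc1")]]
  expect_identical(ring_core$subs, "C[*:1]")
  expect_identical(ring_core$core_heavy, 6L)
  expect_identical(ring_core$sub_heavy, 1L)
})

test_that("fragmentation agrees with hand enumeration on 4-ethyltoluene", {
  # eligible bonds: the two aryl-alkyl cuts. By hand: 4 single-cut
  # orientations plus one 2-cut (ring core, both alkyls off), total 5.
  frs <- fragment_molecules("CCc1ccc(C)cc1", max_cuts = 3)[[1]]
  expect_length(frs, 5L)
  n_subs <- vapply(frs, function(f) length(f$subs), integer(1))
  expect_identical(sort(n_subs), c(1L, 1L, 1L, 1L, 2L))
  two_cut <- frs[[which(n_subs == 2L)]]
  expect_identical(two_cut$core_heavy, 6L)
  expect_setequal(two_cut$sub_heavy, c(1L, 2L))
  # reassembly identity for every result
  res <- reassemble_molecules(vapply(frs, `[[`, character(1), "core"),
                              lapply(frs, `[[`, "subs"))
  expect_true(all(res == canonicalize_smiles("CCc1ccc(C)cc1")))
})

test_that("reassembly reproduces the parent across the fixture chemistry", {
  mols <- unique(random_toy_smiles(40, seed = 9))
  frags <- fragment_molecules(mols)
  cores <- unlist(lapply(frags, function(frs)
    vapply(frs, `[[`, character(1), "core")))
  subs <- unlist(lapply(frags, function(frs) lapply(frs, `[[`, "subs")),
                 recursive = FALSE)
  parents <- rep(mols, lengths(frags))
  expect_identical(reassemble_molecules(cores, subs), parents)
})

test_that("attachment markers are excluded from heavy-atom counts", {
  expect_identical(heavy_atom_count("c1ccc([*:1])cc1"),
                   heavy_atom_count("c1ccccc1"))
  expect_identical(heavy_atom_count("C[*:1]"), 1L)
})

test_that("the core-size filter implements the 2x rule", {
  expect_true(core_size_filter(12L, c(3L, 3L)))   # boundary satisfied
  expect_false(core_size_filter(11L, c(3L, 3L)))
  expect_true(core_size_filter(2L, 1L))
})

test_that("analogue-series grouping recovers planted series", {
  scaffold <- "O=C(Nc1ccccc1)c1ccc([*:1])cc1"
  subs <- c("CC[*:1]", "CCC[*:1]", "CC(C)[*:1]", "CCCC[*:1]",
            "CC(C)C[*:1]", "C1CC1[*:1]")
  six <- reassemble_molecules(rep(scaffold, 6), as.list(subs))
  series <- group_series(six)
  expect_length(series, 1L)
  expect_setequal(series[[1]]$members, six)
  # a second scaffold gives a second series; a lone extra compound is a
  # dropped singleton
  other <- reassemble_molecules(rep("O=S(=O)(c1ccccc1)Nc1ccc([*:1])cc1", 2),
                                list("CC[*:1]", "CCC[*:1]"))
  series2 <- group_series(c(six, other, "CCO"))
  expect_length(series2, 2L)
  expect_setequal(unlist(lapply(series2, `[[`, "members")), c(six, other))
})

test_that("grouping recovers the planted world partition exactly", {
  world <- generate_world(toy_world_config(n_targets = 1L))
  triples <- world$triples
  series <- group_series(triples$canonical_smiles)
  expect_length(series, length(unique(triples$series_core)))
  planted <- split(triples$canonical_smiles, triples$series_core)
  recovered <- lapply(series, `[[`, "members")
  # compare as partitions (order-free)
  key <- function(part) sort(vapply(part, function(m)
    paste(sort(m), collapse = "|"), character(1)))
  expect_identical(key(recovered), key(unname(planted)))
})

test_that("series splitting is an even, seed-stable, disjoint partition", {
  world <- generate_world(toy_world_config(n_targets = 1L))
  series <- group_series(world$triples$canonical_smiles)
  sp1 <- split_series(series, seed = 17)
  sp2 <- split_series(series, seed = 17)
  expect_identical(sp1$finetune_cores, sp2$finetune_cores)
  expect_length(sp1$finetune_cores, length(series) %/% 2L)
  expect_length(sp1$test_cores, length(series) - length(series) %/% 2L)
  expect_length(intersect(sp1$finetune_cores, sp1$test_cores), 0L)
  expect_length(intersect(sp1$finetune_compounds, sp1$test_compounds), 0L)
  # union covers every non-singleton compound
  expect_setequal(c(sp1$finetune_compounds, sp1$test_compounds),
                  unlist(lapply(series, `[[`, "members")))
  # the smaller-compound side is fine-tuning
  expect_lte(length(sp1$finetune_compounds), length(sp1$test_compounds))
})

test_that("odd series counts send the extra series to the test side", {
  series <- lapply(1:7, function(i) {
    structure(list(core = paste0("core", i),
                   members = paste0("M", i, "_", seq_len(i + 1)),
                   substituents = NULL), class = "analogue_series")
  })
  sp <- split_series(series, seed = 1)
  expect_length(sp$test_cores, 4L)
  expect_length(sp$finetune_cores, 3L)
  expect_error(split_series(series[1], seed = 1), "at least 2")
})

test_that("split files and manifest are written", {
  world <- generate_world(toy_world_config(n_targets = 1L))
  sp <- split_class(world$triples[, c("canonical_smiles", "pki")], seed = 3)
  dir <- withr::local_tempdir()
  write_split(sp, dir)
  man <- jsonlite::fromJSON(file.path(dir, "split_manifest.json"))
  expect_identical(man$seed, 3L)
  expect_equal(man$n_finetune_compounds, length(sp$finetune_compounds))
  ft <- read_class(file.path(dir, "finetune_series.tsv"))
  expect_setequal(ft$canonical_smiles, sp$finetune_compounds)
})
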