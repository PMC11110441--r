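test_that("potency aggregation takes the geometric mean of consistent Ki", {
  # pKi(10 nM) = -log10(10e-9) = 8
  expect_equal(aggregate_potency(10), 8)
  # frozen oracle: mean of -log10(Ki * 1e-9) computed independently
  expect_equal(aggregate_potency(c(10, 20)), 7.8495, tolerance = 1e-3)
  # log identity: equals the arithmetic mean of element-wise pKi
  set.seed(7)
  for (i in 1:20) {
    ki <- exp(stats::runif(sample(1:5, 1), log(0.5), log(5))) * 10^sample(0:3, 1)
    expect_equal(aggregate_potency(ki), mean(-log10(ki * 1e-9)),
                 tolerance = 1e-9)
  }
})

test_that("inconsistent replicate measurements reject the compound", {
  expect_true(is.na(aggregate_potency(c(10, 200))))   # ratio 20 > 10
  expect_false(is.na(aggregate_potency(c(10, 100))))  # ratio exactly 10
  expect_error(aggregate_potency(c(10, -1)), "positive")
  expect_error(aggregate_potency(c(10, NA)), "positive")
})

make_rows <- function() {
  data.frame(
    smiles = c("CCO", "CCO", "CCN", "CCC", "CCCl", "CCBr"),
    target_id = c("T1", "T1", "T1", "T1", "T2", "T3"),
    relationship = c("D", "D", "D", "N", "D", "D"),
    confidence = c(9L, 9L, 8L, 9L, 9L, 9L),
    ki_nM = c(10, 20, 10, 10, 50, NA),
    stringsAsFactors = FALSE
  )
}

make_seqs <- function() {
  c(T1 = "MKVLAW", T2 = paste(rep("A", 4001), collapse = ""), T3 = "MKW")
}

test_that("row filtering keeps direct high-confidence Ki rows only", {
  filtered <- filter_rows(make_rows(), make_seqs())
  # kept: the two CCO/T1 replicates; dropped: confidence 8, relationship N,
  # missing Ki, sequence > 4000
  expect_equal(nrow(filtered), 2L)
  expect_true(all(filtered$relationship == "D" & filtered$confidence == 9))
  # idempotent
  again <- filter_rows(filtered, make_seqs())
  expect_equal(nrow(again), nrow(filtered))
})

test_that("rows without a sequence are dropped with a warning", {
  rows <- make_rows()[5, ]
  expect_warning(out <- filter_rows(rows, c(T9 = "MKV")), "without a target")
  expect_equal(nrow(out), 0L)
})

test_that("activity classes aggregate per-compound and drop rejects", {
  rows <- data.frame(
    smiles = c("CCO", "OCC", "CCN", "CCOC", "CCOC", "CCC"),
    target_id = c("T1", "T1", "T1", "T2", "T2", "T2"),
    relationship = "D", confidence = 9L,
    ki_nM = c(10, 20, 50, 10, 500, 30),
    stringsAsFactors = FALSE)
  seqs <- c(T1 = "MKVLAW", T2 = "MKW")
  classes <- build_classes(filter_rows(rows, seqs))
  expect_length(classes, 2L)
  t1 <- classes[[1]]$records
  # CCO and OCC are the same canonical compound: replicates collapse
  expect_equal(nrow(t1), 2L)
  expect_equal(t1$pki[t1$canonical_smiles == "CCO"],
               mean(-log10(c(10, 20) * 1e-9)))
  # 10 nM vs 500 nM disagree by > 1 order of magnitude: compound excluded
  t2 <- classes[[2]]$records
  expect_false("CCOC" %in% t2$canonical_smiles)
  expect_equal(t2$canonical_smiles, "CCC")
  # no duplicate (target, compound) pairs anywhere
  for (cl in classes) {
    expect_equal(anyDuplicated(cl$records$canonical_smiles), 0L)
  }
})

test_that("class files round-trip through disk with a manifest", {
  rows <- data.frame(smiles = c("CCO", "CCN"), target_id = "T1",
                     relationship = "D", confidence = 9L, ki_nM = c(10, 40),
                     stringsAsFactors = FALSE)
  classes <- build_classes(filter_rows(rows, c(T1 = "MKVLAW")))
  dir <- withr::local_tempdir()
  write_classes(classes, dir)
  expect_true(file.exists(file.path(dir, "T1.tsv")))
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(manifest$n_compounds, 2L)
  back <- read_class(file.path(dir, "T1.tsv"))
  expect_setequal(back$canonical_smiles, classes[[1]]$records$canonical_smiles)
})
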