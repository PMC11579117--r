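# pipeline stages: load, merge, drop, split, normalize

test_that("a small CSV round-trips with missing cells preserved", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,f00,f01,f02,organism,broad_label,line_tag,subclass_label",
    "a,1.5,2.0,3.0,mouse,0,L1,",
    "b,0.25,,1.0,mouse,1,L2,",
    "c,-1.0,0.5,2.5,human,0,L1,"), csv)
  es <- suppressMessages(loadFeatureTable(csv))
  expect_equal(nSamples(es), 3L)
  expect_equal(ncol(featureMatrix(es)), 3L)
  expect_true(is.na(featureMatrix(es)["b", "f01"]))
  expect_equal(featureMatrix(es)["a", "f00"], 1.5)
  expect_equal(organismLabel(es), c("mouse", "mouse", "human"))
})

test_that("missing required columns and empty files are schema errors", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("f00,f01", "1,2"), csv)
  expect_error(suppressMessages(loadFeatureTable(csv)), "organism")
  empty <- tempfile(fileext = ".csv")
  writeLines("sample_id,f00,organism", empty)
  expect_error(suppressMessages(loadFeatureTable(empty)), "no data rows")
  expect_error(loadFeatureTable(tempfile()), "not found")
})

test_that("line merging relabels, counts exclusions, and rejects unmapped tags", {
  es <- EphysSet(matrix(rnorm(50), 10, 5),
                 organism = rep("mouse", 10), broadLabel = 1L,
                 lineTag = rep(c("A", "B", "C", "A", "C"), 2))
  merged <- suppressMessages(
    mergeLines(es, c(A = "Pvalb", B = "Pvalb", C = "exclude")))
  expect_equal(nSamples(merged), 6L)
  expect_equal(S4Vectors::metadata(merged)$linesExcluded, 4L)
  expect_true(all(subclassLabel(merged) == "Pvalb"))
  expect_error(mergeLines(es, c(A = "Pvalb", B = "Sst")), "C")
})

test_that("an identity-like merge map reproduces the generator's truth", {
  out <- generateCohort(smallSubclassConfig(seed = 3))
  tags <- unique(lineTag(out$table))
  map <- sub("\\.(a|b)$", "", tags)
  names(map) <- tags
  merged <- suppressMessages(mergeLines(out$table, map))
  expect_equal(unname(table(subclassLabel(merged))[names(table(out$truth@classLabel))]),
               unname(table(out$truth@classLabel)))
})

test_that("dropIncomplete removes exactly the rows with missing cells", {
  X <- matrix(rnorm(25), 5, 5)
  X[2, 3] <- NA
  X[4, 1] <- NA
  es <- EphysSet(X, organism = "mouse", broadLabel = 0L)
  out <- suppressMessages(dropIncomplete(es))
  expect_equal(out$nDropped, 2L)
  expect_equal(nSamples(out$table), 3L)
  # identity when nothing is missing
  es2 <- EphysSet(matrix(rnorm(25), 5, 5), organism = "mouse", broadLabel = 0L)
  out2 <- suppressMessages(dropIncomplete(es2))
  expect_equal(out2$nDropped, 0L)
  expect_equal(featureMatrix(out2$table), featureMatrix(es2))
  # all-missing is an error
  X3 <- matrix(NA_real_, 2, 3)
  es3 <- EphysSet(X3, organism = "mouse", broadLabel = 0L)
  expect_error(suppressMessages(dropIncomplete(es3)), "cannot proceed")
})

test_that("generator missing-row bookkeeping matches dropIncomplete", {
  out <- generateCohort(smallBroadConfig(seed = 17, missingRate = 0.1))
  dropped <- suppressMessages(dropIncomplete(out$table))
  expect_equal(dropped$nDropped, sum(out$truth@missingRows))
})

test_that("the study fractions reproduce the 1171/207/345 partition", {
  out <- generateCohort(broadCohortConfig(seed = 1))
  sp <- splitData(out$table, fractions = c(0.6797, 0.1201, 0.2002),
                  stratifyOn = c("organism", "broad_label"), seed = 1)
  expect_equal(nSamples(sp@train), 1171L)
  expect_equal(nSamples(sp@validation), 207L)
  expect_equal(nSamples(sp@test), 345L)
})

test_that("splits are stratified, exhaustive, disjoint and seeded", {
  out <- generateCohort(smallBroadConfig(seed = 2))
  sp1 <- splitData(out$table, fractions = c(0.6, 0.2, 0.2), seed = 5)
  sp2 <- splitData(out$table, fractions = c(0.6, 0.2, 0.2), seed = 5)
  sp3 <- splitData(out$table, fractions = c(0.6, 0.2, 0.2), seed = 6)
  ids <- function(sp) list(colnames(sp@train), colnames(sp@validation),
                           colnames(sp@test))
  expect_identical(ids(sp1), ids(sp2))
  expect_false(identical(ids(sp1), ids(sp3)))
  all1 <- unlist(ids(sp1))
  expect_equal(sort(all1), sort(colnames(out$table)))
  expect_equal(anyDuplicated(all1), 0L)
  # per-stratum proportions within one row
  strat <- paste(organismLabel(out$table), broadLabel(out$table))
  names(strat) <- colnames(out$table)
  for (s in unique(strat)) {
    ns <- sum(strat == s)
    inTrain <- sum(strat[colnames(sp1@train)] == s)
    expect_lte(abs(inTrain - 0.6 * ns), 1)
  }
})

test_that("degenerate fractions put everything in train", {
  out <- generateCohort(smallBroadConfig(seed = 2))
  sp <- splitData(out$table, fractions = c(1, 0, 0), seed = 1)
  expect_equal(nSamples(sp@train), nSamples(out$table))
  expect_equal(nSamples(sp@validation), 0L)
  expect_equal(nSamples(sp@test), 0L)
})

test_that("normalization is fit on train only and applied unchanged elsewhere", {
  sp <- smallBroadSplit(seed = 7)
  Xtr <- featureMatrix(sp@train)
  expect_true(all(abs(colMeans(Xtr)) < 1e-9))
  expect_true(all(abs(apply(Xtr, 2, sd) - 1) < 1e-9))
  # independent one-line oracle on the test partition
  raw <- generateCohort(smallBroadConfig(seed = 7))$table
  sp0 <- splitData(raw, fractions = c(0.6, 0.2, 0.2), seed = 7)
  Xte0 <- featureMatrix(sp0@test)
  oracle <- sweep(sweep(Xte0, 2, colMeans(featureMatrix(sp0@train)), "-"),
                  2, apply(featureMatrix(sp0@train), 2, sd), "/")
  expect_equal(featureMatrix(sp@test), oracle, tolerance = 1e-12)
})

test_that("perturbing test rows leaves normalization statistics unchanged", {
  raw <- generateCohort(smallBroadConfig(seed = 19))$table
  sp <- splitData(raw, fractions = c(0.6, 0.2, 0.2), seed = 19)
  spPerturbed <- sp
  X <- featureMatrix(spPerturbed@test) + 100
  SummarizedExperiment::assay(spPerturbed@test, "features") <- t(X)
  n1 <- normalizeSplit(sp)
  n2 <- normalizeSplit(spPerturbed)
  expect_identical(n1@center, n2@center)
  expect_identical(n1@scale, n2@scale)
})

test_that("zero-variance features pass through unscaled with a warning", {
  X <- matrix(rnorm(60), 20, 3)
  X[, 2] <- 5
  es <- EphysSet(X, organism = "mouse", broadLabel = 0L)
  sp <- splitData(es, fractions = c(0.7, 0.15, 0.15), stratifyOn = character(0),
                  seed = 1)
  expect_warning(nsp <- normalizeSplit(sp), "zero-variance")
  expect_equal(unique(featureMatrix(nsp@train)[, 2]), 5)
})

test_that("empty train partitions cannot be normalized", {
  es <- EphysSet(matrix(rnorm(30), 10, 3), organism = "mouse", broadLabel = 0L)
  sp <- suppressWarnings(
    splitData(es, fractions = c(0, 0.5, 0.5), stratifyOn = character(0),
              seed = 1))
  expect_error(normalizeSplit(sp), "empty train")
})

test_that("row conservation holds across merge and drop", {
  out <- generateCohort(smallBroadConfig(seed = 23, missingRate = 0.05))
  es <- out$table
  tags <- unique(lineTag(es))
  map <- setNames(rep("Pvalb", length(tags)), tags)
  map[[1]] <- "exclude"
  rowsIn <- nSamples(es)
  merged <- suppressMessages(mergeLines(es, map))
  dropped <- suppressMessages(dropIncomplete(merged))
  expect_equal(rowsIn,
               nSamples(dropped$table) + S4Vectors::metadata(merged)$linesExcluded +
                 dropped$nDropped)
})
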