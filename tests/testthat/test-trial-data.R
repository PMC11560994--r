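test_that("long CSV reading preserves records and first-appearance order", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(genotype = "g1", environment = "e1",
                       block = c("b1", "b2", "b3"), yield = c(1, 2, 3)),
            f, row.names = FALSE)
  td <- readTrialLong(f)
  expect_s4_class(td, "TrialData")
  expect_equal(nrow(trialRecords(td)), 3L)
  expect_equal(trialRecords(td)$yield, c(1, 2, 3))

  # column remapping
  write.csv(data.frame(gen = c("b", "a"), loc = "x", rep = "r1",
                       gy = c(2.5, 1.5)), f, row.names = FALSE)
  td2 <- readTrialLong(f, columnMap = c(genotype = "gen", environment = "loc",
                                        block = "rep", yield = "gy"))
  expect_equal(genotypeNames(td2), c("b", "a")) # file order, not sorted
})

test_that("malformed long CSVs fail with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(genotype = "g1", environment = "e1",
                       block = c("b1", "b1"), yield = c(1, 2)),
            f, row.names = FALSE)
  expect_error(readTrialLong(f), "duplicate")

  write.csv(data.frame(genotype = "g1", block = "b1", yield = 1),
            f, row.names = FALSE)
  expect_error(readTrialLong(f), "'environment'")

  write.csv(data.frame(genotype = c("g1", "g2"), environment = "e1",
                       block = "b1", yield = c("1.2", "oops")),
            f, row.names = FALSE)
  expect_error(readTrialLong(f), "row 2")
})

test_that("TrialData validity rejects nonpositive yields", {
  rec <- data.frame(genotype = "g1", environment = "e1", block = "b1",
                    yield = -1)
  expect_error(TrialData(rec), "> 0")
})

test_that("write -> read round-trips a trial exactly", {
  sim <- generateMet(G = 6, E = 3, r = 2, singularValues = c(2, 1), seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  writeTrialLong(sim$trial, f)
  back <- readTrialLong(f)
  expect_equal(genotypeNames(back), genotypeNames(sim$trial))
  expect_equal(environmentNames(back), environmentNames(sim$trial))
  a <- trialRecords(sim$trial); b <- trialRecords(back)
  key <- function(d) d[order(d$genotype, d$environment, d$block), ]
  expect_equal(key(b), key(a), ignore_attr = TRUE)
})

test_that("a full-size generated trial has the written dimensions", {
  sim <- generateMet(G = 69, E = 5, r = 3, seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  writeTrialLong(sim$trial, f)
  td <- readTrialLong(f)
  expect_equal(nrow(trialRecords(td)), 69L * 5L * 3L)
  expect_length(genotypeNames(td), 69L)
  expect_length(environmentNames(td), 5L)
})

test_that("cellMeans averages replicates and records the common count", {
  rec <- data.frame(genotype = "g1", environment = "e1",
                    block = c("b1", "b2", "b3"), yield = c(1, 2, 3))
  cm <- cellMeans(TrialData(rec))
  expect_equal(as.vector(yieldMatrix(cm)), 2.0)
  expect_equal(replicateCount(cm), 3L)
})

test_that("cellMeans agrees with a brute-force per-cell averaging loop", {
  for (seed in 1:5) {
    rec <- random_trial(G = 4, E = 3, r = 2, seed = seed)
    td <- TrialData(rec)
    cm <- cellMeans(td)
    expect_equal(yieldMatrix(cm),
                 oracle_cell_means(rec, genotypeNames(td),
                                   environmentNames(td)),
                 tolerance = 1e-12)
  }
})

test_that("cellMeans rejects incomplete and unbalanced trials", {
  rec <- random_trial(G = 3, E = 3, r = 2, seed = 1)
  miss <- rec[!(rec$genotype == "g02" & rec$environment == "e3"), ]
  expect_error(cellMeans(TrialData(miss)), "g02 x e3")

  unb <- rbind(rec, data.frame(genotype = "g01", environment = "e1",
                               block = "b9", yield = 5))
  expect_error(cellMeans(TrialData(unb)), "unbalanced")
})

test_that("pseudo-replicating a mean table reproduces it through cellMeans", {
  ref <- smoliceMaize()
  td <- pseudoReplicate(ref$means)
  cm <- cellMeans(td)
  expect_equal(yieldMatrix(cm), yieldMatrix(ref$means), tolerance = 1e-12)
  expect_equal(replicateCount(cm), 3L)
})

test_that("wide cell-mean CSVs round-trip and drop a trailing mean column", {
  cm <- planted_means()
  f <- withr::local_tempfile(fileext = ".csv")
  writeCellMeans(cm, f, addMean = TRUE)
  back <- readCellMeans(f, replicateCount = replicateCount(cm))
  expect_equal(yieldMatrix(back), yieldMatrix(cm), tolerance = 1e-12)
  expect_false("mean" %in% environmentNames(back))
})

test_that("the packaged reference dataset is complete and as published", {
  ref <- smoliceMaize()
  Y <- yieldMatrix(ref$means)
  expect_equal(dim(Y), c(69L, 5L))
  expect_false(anyNA(Y))
  expect_equal(replicateCount(ref$means), 3L)
  expect_equal(Y["SMH_16417", "Smolice"], 8.76)
  expect_equal(Y["SMH_16043", "Placzkowo"], 16.89)
  expect_equal(round(unname(colMeans(Y)), 2),
               c(13.66, 12.95, 14.01, 13.49, 11.81))
  # score tables align with the matrix
  expect_equal(ref$genotypeScores$genotype, rownames(Y))
  expect_equal(ref$environmentScores$environment, colnames(Y))
  # published row means are the matrix's own row means (to print precision;
  # a few entries sit exactly at the half-cent rounding boundary)
  expect_lt(max(abs(rowMeans(Y) - ref$genotypeScores$mean)), 0.0065)
})
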