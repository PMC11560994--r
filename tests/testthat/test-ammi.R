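test_that("double-centering removes additive structure", {
  m <- matrix(5, 3, 3, dimnames = list(paste0("g", 1:3), paste0("e", 1:3)))
  dc <- doubleCenter(m)
  expect_equal(dc$mu, 5)
  expect_true(all(dc$alpha == 0) && all(dc$beta == 0))
  expect_true(all(dc$centered == 0))

  a <- c(1, -2, 0.5); b <- c(0.3, -0.1, 0, 2)
  add <- outer(a, b, "+") + 10
  dc2 <- doubleCenter(add)
  expect_lt(max(abs(dc2$centered)), 1e-12)

  dc3 <- doubleCenter(matrix(c(1, 0, 0, 1), 2))
  expect_equal(dc3$mu, 0.5)
  expect_equal(unname(dc3$centered),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2))
})

test_that("rows and columns of a centered matrix sum to zero", {
  dc <- doubleCenter(planted_means(seed = 21))
  expect_lt(max(abs(rowSums(dc$centered))), 1e-10)
  expect_lt(max(abs(colSums(dc$centered))), 1e-10)
})

test_that("the SVD decomposition satisfies its structural identities", {
  for (seed in c(8, 9)) {
    cm <- planted_means(G = 6, E = 4, d = c(2, 1, 0.5), r = 3, seed = seed)
    fit <- fitAmmi(cm, nAxes = "all")
    dc <- doubleCenter(cm)
    d <- fit@singularValues
    gs <- genotypeScores(fit); es <- environmentScores(fit)

    # full reconstruction from sqrt(d)-scaled outer products
    expect_equal(gs %*% t(es), dc$centered, tolerance = 1e-9,
                 ignore_attr = TRUE)
    # score columns sum to zero on both sides
    expect_lt(max(abs(colSums(gs))), 1e-9)
    expect_lt(max(abs(colSums(es))), 1e-9)
    # orthogonality of distinct axes on both sides
    cg <- crossprod(gs); ce <- crossprod(es)
    expect_lt(max(abs(cg[upper.tri(cg)])), 1e-9)
    expect_lt(max(abs(ce[upper.tri(ce)])), 1e-9)
    # symmetric scaling: sum of squared scores equals d on each side
    expect_equal(unname(diag(cg)), d, tolerance = 1e-9)
    expect_equal(unname(diag(ce)), d, tolerance = 1e-9)
    # descending singular values, and plot SS identity with the ANOVA
    expect_true(all(diff(d) <= 1e-12))
    tab <- partitionMeans(cm)
    expect_equal(sum(d^2) * replicateCount(cm),
                 tab$ss[tab$stratum == "GxE"], tolerance = 1e-9)
  }
})

test_that("a planted rank-1 interaction is recovered exactly", {
  cm <- planted_means(G = 7, E = 5, d = 4, r = 2, seed = 10)
  fit <- fitAmmi(cm, nAxes = "all")
  expect_equal(fit@singularValues[1], 4, tolerance = 1e-9)
  expect_lt(max(fit@singularValues[-1]), 1e-9)
  expect_equal(axisSummary(fit)$explainedPct[1], 100, tolerance = 1e-9)
  expect_equal(nAxesAvailable(fit), 1L)
})

test_that("Gollob degrees of freedom follow G + E - 1 - 2n", {
  expect_equal(gollobDf(1, G = 69, E = 5), 71L)
  expect_equal(gollobDf(3, G = 69, E = 5), 67L)
  expect_equal(gollobDf(1, G = 3, E = 3), 3L)
  expect_equal(gollobDf(1:4, G = 69, E = 5), c(71L, 69L, 67L, 65L))
  expect_error(gollobDf(5, G = 69, E = 5), "1..min")
  expect_error(gollobDf(0, G = 10, E = 4), "1..min")
})

test_that("Gollob F tests equal the direct-formula computation", {
  cm <- planted_means(G = 6, E = 4, d = c(2, 1), r = 3, seed = 11)
  fit <- fitAmmi(cm, nAxes = "all")
  gt <- gollobTest(fit, errorMs = 0.4, errorDf = 60)
  d <- fit@singularValues
  r <- replicateCount(cm)
  fExp <- (r * d^2 / gollobDf(seq_along(d), 6, 4)) / 0.4
  expect_equal(gt$table$f, fExp, tolerance = 1e-12)
  expect_equal(gt$table$p,
               pf(fExp, gollobDf(seq_along(d), 6, 4), 60, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(gollobTest(fit, errorMs = 0, errorDf = 60), "positive")
})

test_that("zero-SS axes give F = 0 and are not significant", {
  sim <- generateMet(G = 5, E = 4, r = 2, singularValues = numeric(),
                     blockSd = 0, errorSd = 0, seed = 12)
  fit <- fitAmmi(cellMeans(sim$trial), nAxes = "all")
  gt <- gollobTest(fit, errorMs = 0.5, errorDf = 30)
  expect_true(all(gt$table$f < 1e-12))
  expect_false(any(gt$table$significant))
  expect_equal(gt$recommendedN, 0L)
})

test_that("retention counts leading consecutive significant axes only", {
  expect_equal(metammi:::leading_run(c(TRUE, TRUE, FALSE, TRUE)), 2L)
  expect_equal(metammi:::leading_run(c(FALSE, TRUE)), 0L)
  expect_equal(metammi:::leading_run(logical(0)), 0L)
  # strong first axis, negligible second: recommend exactly 1
  cm <- planted_means(G = 20, E = 6, d = c(6, 0.05), r = 3, seed = 13)
  fit <- fitAmmi(cm, nAxes = "all")
  gt <- gollobTest(fit, errorMs = 0.3, errorDf = 200)
  expect_equal(gt$recommendedN, 1L)
  expect_true(gt$table$significant[1] && !gt$table$significant[2])
})

test_that("axis sign flips leave SS, explained % and ANOVA untouched", {
  cm <- planted_means(G = 8, E = 5, d = c(3, 1.5), r = 2, seed = 14)
  a <- fitAmmi(cm, orient = "env-max")
  b <- fitAmmi(cm, orient = "none")
  expect_equal(a@singularValues, b@singularValues, tolerance = 1e-12)
  expect_equal(axisSummary(a)$ss, axisSummary(b)$ss, tolerance = 1e-12)
  expect_equal(axisSummary(a)$explainedPct, axisSummary(b)$explainedPct,
               tolerance = 1e-12)
  # scores agree up to per-axis sign
  signs <- sign(colSums(genotypeScores(a) * genotypeScores(b)))
  expect_equal(genotypeScores(a),
               sweep(genotypeScores(b), 2, signs, "*"), tolerance = 1e-9)
})

test_that("the env-max orientation makes the top environment positive", {
  fit <- fitAmmi(smoliceMaize()$means)
  es <- environmentScores(fit)
  for (n in seq_len(ncol(es))) {
    expect_gte(es[which.max(abs(es[, n])), n], 0)
  }
})

test_that("nAxes argument is validated and honoured", {
  cm <- planted_means(G = 6, E = 4, d = c(2, 1), r = 2, seed = 15)
  expect_error(fitAmmi(cm, nAxes = 9), "nAxes")
  fit1 <- fitAmmi(cm, nAxes = 1)
  expect_equal(nAxesRetained(fit1), 1L)
  # residual holds exactly the axes beyond the retained one
  dc <- doubleCenter(cm)
  gs <- genotypeScores(fit1); es <- environmentScores(fit1)
  expect_equal(interactionResidual(fit1),
               dc$centered - gs[, 1] %*% t(es[, 1]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("published-scale consistency: env score norms match the axis SS", {
  fit <- fitAmmi(smoliceMaize()$means)
  at <- axisSummary(fit)
  for (n in 1:2) {
    expect_equal(sum(environmentScores(fit)[, n]^2),
                 sqrt(at$ss[n] / replicateCount(fit)),
                 tolerance = 1e-9)
  }
})

test_that("combined AMMI ANOVA table reproduces strata and axis shares", {
  cm <- planted_means(G = 10, E = 5, d = c(3, 2, 1), r = 3, seed = 16)
  fit <- fitAmmi(cm, nAxes = 2)
  tab <- ammiAnovaTable(fit, errorMs = 0.4, errorDf = 100, nAxesShown = 2)
  pm <- partitionMeans(cm)
  expect_equal(tab$ss[tab$stratum == "GxE"],
               pm$ss[pm$stratum == "GxE"], tolerance = 1e-9)
  # axis + residual rows recompose the interaction stratum
  axisRows <- grepl("^IPCA|residual", tab$stratum)
  expect_equal(sum(tab$ss[axisRows]), tab$ss[tab$stratum == "GxE"],
               tolerance = 1e-9)
  expect_equal(sum(tab$df[axisRows]), tab$df[tab$stratum == "GxE"])
  expect_equal(sum(tab$explainedPct[axisRows]), 100, tolerance = 1e-9)
})
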