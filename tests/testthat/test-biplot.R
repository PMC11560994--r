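test_that("AMMI1 coordinates pair means with first-axis scores", {
  fit <- fitAmmi(smoliceMaize()$means)
  co <- ammi1Coords(fit)
  expect_equal(attr(co, "kind"), "AMMI1")
  expect_equal(attr(co, "referenceX"), grandMean(fit))
  gg <- co[co$role == "genotype", ]
  ee <- co[co$role == "environment", ]
  # genotype x coordinates average to the grand mean (conservation)
  expect_equal(mean(gg$x), grandMean(fit), tolerance = 1e-12)
  # environment x coordinates are the environment means
  expect_equal(ee$x, unname(colMeans(yieldMatrix(smoliceMaize()$means))),
               tolerance = 1e-12)
  # Smolice carries the largest absolute environment score on axis 1
  expect_equal(ee$label[which.max(abs(ee$y))], "Smolice")
})

test_that("additive data puts every AMMI1 point on the zero line", {
  sim <- generateMet(G = 6, E = 4, r = 2, singularValues = numeric(),
                     blockSd = 0, errorSd = 0, seed = 31)
  co <- ammi1Coords(fitAmmi(cellMeans(sim$trial)))
  expect_lt(max(abs(co$y)), 1e-6) # scores carry sqrt(d): noise ~ sqrt(eps)
})

test_that("AMMI2 coordinates share one frame and label quadrants", {
  fit <- fitAmmi(smoliceMaize()$means)
  co <- ammi2Coords(fit)
  expect_setequal(unique(co$role), c("genotype", "environment"))
  # all four sectors populated for this dataset
  expect_setequal(unique(co$quadrant[co$role == "genotype"]),
                  c("Q1", "Q2", "Q3", "Q4"))
  # zero coordinates are assigned to the positive side, deterministically
  expect_equal(metammi:::quadrant_of(0, 0), "Q1")
  expect_equal(metammi:::quadrant_of(0, -1), "Q4")
  expect_equal(metammi:::quadrant_of(-1, 0), "Q2")
})

test_that("AMMI2 needs two axes", {
  cm <- planted_means(G = 6, E = 4, d = 2, r = 2, seed = 32)
  fit <- fitAmmi(cm, nAxes = "all")
  expect_no_error(ammi2Coords(fit)) # second column exists, though zero
  m <- CellMeans(yieldMatrix(cm)[, 1:2], replicateCount = 2L)
  expect_error(ammi2Coords(fitAmmi(m)), "two interaction axes")
})

test_that("sign flips reflect AMMI2 points but keep environment angles", {
  fit <- fitAmmi(planted_means(G = 8, E = 5, d = c(3, 1.4), seed = 33))
  co <- ammi2Coords(fit)
  cof <- ammi2Coords(flip_axis(fit, 1))
  ee <- co[co$role == "environment", ]
  eef <- cof[cof$role == "environment", ]
  ang <- function(d) outer(seq_len(nrow(d)), seq_len(nrow(d)),
    Vectorize(function(i, j) {
      u <- c(d$x[i], d$y[i]); v <- c(d$x[j], d$y[j])
      sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    }))
  expect_equal(ang(eef), ang(ee), tolerance = 1e-9)
  expect_equal(eef$x, -ee$x)
})

test_that("fitted values reconstruct, truncate and match the model formula", {
  cm <- planted_means(G = 5, E = 4, d = c(2, 1, 0.4), r = 2, seed = 34)
  fit <- fitAmmi(cm, nAxes = "all")
  Y <- yieldMatrix(cm)
  # all axes: exact reconstruction of the cell means
  expect_equal(fittedMatrix(fit, nAxes = 3), Y, tolerance = 1e-9,
               ignore_attr = TRUE)
  # zero axes: purely additive
  add <- grandMean(fit) + outer(genotypeEffects(fit),
                                environmentEffects(fit), "+")
  expect_equal(fittedMatrix(fit, nAxes = 0), add, tolerance = 1e-12,
               ignore_attr = TRUE)
  # one axis: term-by-term evaluation of the model formula
  gs <- genotypeScores(fit); es <- environmentScores(fit)
  byHand <- matrix(NA_real_, 5, 4)
  for (g in 1:5) {
    for (e in 1:4) {
      byHand[g, e] <- grandMean(fit) + genotypeEffects(fit)[g] +
        environmentEffects(fit)[e] + gs[g, 1] * es[e, 1]
    }
  }
  expect_equal(unname(fittedMatrix(fit, nAxes = 1)), byHand,
               tolerance = 1e-12)
  expect_error(fittedMatrix(fit, nAxes = 9), "nAxes")
})

test_that("residual norm shrinks monotonically as axes are added", {
  cm <- planted_means(G = 9, E = 6, d = c(3, 2, 1, 0.5), r = 2, seed = 35)
  fit <- fitAmmi(cm, nAxes = "all")
  Y <- yieldMatrix(cm)
  norms <- vapply(0:4, function(n) {
    sqrt(sum((Y - fittedMatrix(fit, nAxes = n))^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("per-environment selections obey their invariances", {
  # additive data: same ordering (the genotype main-effect order) everywhere
  sim <- generateMet(G = 7, E = 4, r = 2, singularValues = numeric(),
                     blockSd = 0, errorSd = 0, seed = 36)
  fit <- fitAmmi(cellMeans(sim$trial))
  sel <- perEnvironmentSelections(fit, topK = 7)
  ords <- split(sel$genotype, sel$environment)
  expect_length(unique(vapply(ords, paste, "", collapse = "|")), 1L)
  # top-G is a permutation of all genotypes, per environment
  expect_setequal(ords[[1]], genotypeNames(fit))

  # sign flips do not change selections (score products only)
  fit2 <- fitAmmi(planted_means(G = 8, E = 5, d = c(3, 1.2), seed = 37))
  s1 <- perEnvironmentSelections(fit2, nAxes = 2, topK = 5)
  s2 <- perEnvironmentSelections(flip_axis(flip_axis(fit2, 1), 2),
                                 nAxes = 2, topK = 5)
  expect_equal(s1, s2)
  expect_error(perEnvironmentSelections(fit2, topK = 99), "topK")
})

test_that("biplot drawing runs headless and returns its coordinates", {
  fit <- fitAmmi(planted_means(G = 6, E = 4, d = c(2, 1), seed = 38))
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f)
  co1 <- plotAmmi1(fit, labelGenotypes = TRUE)
  co2 <- plotAmmi2(fit)
  grDevices::dev.off()
  expect_equal(co1, ammi1Coords(fit))
  expect_equal(co2, ammi2Coords(fit))
})
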