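test_that("latent draws reproduce the design covariance", {
  Z <- simulateLatent(1e5, seed = 61)
  expect_equal(ncol(Z), 4)
  expect_equal(var(Z[, 1]), 2.89, tolerance = 0.05)
  expect_equal(cor(Z[, 1], Z[, 2]), 0.5, tolerance = 0.02)
  expect_equal(cor(Z[, 3], Z[, 4]), 0.5, tolerance = 0.02)
  expect_equal(var(Z[, 4]), 2.25, tolerance = 0.05)
  expect_equal(mean(Z), 0, tolerance = 0.02)
  expect_error(simulateLatent(10, matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_identical(simulateLatent(50, seed = 3), simulateLatent(50, seed = 3))
})

test_that("item intercepts fall in their design ranges and are seed-pinned", {
  ip <- simulateItemParams(10, seed = 62)
  expect_equal(dim(ip$delta), c(10L, 5L))
  expect_true(all(ip$delta[, 1] >= -1 & ip$delta[, 1] <= 1))
  expect_true(all(ip$delta[, 2:3] >= -1 & ip$delta[, 2:3] <= 0.5))
  expect_true(all(ip$delta[, 4:5] >= -2.5 & ip$delta[, 4:5] <= -1.5))
  expect_identical(simulateItemParams(10, seed = 62)$delta, ip$delta)
  ## 6 items = 30 pseudo-item intercepts; half the items per trait
  ip6 <- simulateItemParams(6, seed = 62)
  expect_equal(length(ip6$delta), 30L)
  expect_equal(ip6$itemTraitMap, rep(1:2, each = 3))
})

test_that("covariate designs match their distributions and focal masks", {
  cm <- simulateCovariate("metric", 1e5, seed = 63)
  expect_true(all(cm$value > 20 & cm$value < 80))
  expect_equal(mean(cm$focal), 1 / 3, tolerance = 0.01)
  expect_equal(cm$focal, cm$value <= 40)
  cc <- simulateCovariate("categorical", 1e5, seed = 64)
  expect_equal(mean(cc$focal), 0.5, tolerance = 0.01)
  co <- simulateCovariate("ordinal", 1e5, seed = 65)
  expect_equal(as.vector(table(co$value)) / 1e5, rep(0.2, 5),
               tolerance = 0.01)
  expect_equal(co$focal, co$value <= 3)
  cs <- simulateCovariate("ordinal", 1e5, seed = 66,
                          probs = c(.1, .1, .35, .35, .1))
  expect_equal(as.vector(table(cs$value)) / 1e5, c(.1, .1, .35, .35, .1),
               tolerance = 0.01)
})

test_that("response frequencies match quadrature integration of the model", {
  ip <- simulateItemParams(6, 0.8, 0.8, seed = 67)
  n <- 2e4
  latent <- simulateLatent(n, seed = 68)
  resp <- simulateResponses(latent, ip, seed = 69)
  expect_true(all(resp %in% 0:5))
  ## oracle: integrate category probabilities over the latent normal with a
  ## dense Gauss-Hermite grid, for item 1 (trait 1) and item 4 (trait 2)
  quad <- ghGrid(4, 9L)
  L <- t(chol(defaultLatentCovariance()))
  Z <- quad$X %*% t(L)
  for (i in c(1L, 4L)) {
    td <- ip$itemTraitMap[i]
    probs <- vapply(seq_len(nrow(Z)), function(q)
      categoryProbabilities(Z[q, td], Z[q, 3], Z[q, 4], ip$alphaNm,
                            ip$alphaE, ip$delta[i, ]), numeric(6))
    expected <- as.vector(probs %*% quad$w)
    observed <- tabulate(resp[, i] + 1L, 6L) / n
    expect_lt(max(abs(observed - expected)), 0.02)
  }
})

test_that("a zero shift leaves the two groups exchangeable", {
  ip <- simulateItemParams(6, seed = 70)
  latent <- simulateLatent(4000, seed = 71)
  focal <- rep(c(TRUE, FALSE), 2000)
  resp <- simulateResponses(latent, ip, focal = focal, shift = 0, seed = 72)
  tab <- table(resp[focal, 1], dnn = NULL)
  tab2 <- table(resp[!focal, 1], dnn = NULL)
  expect_gt(suppressWarnings(chisq.test(rbind(tab, tab2)))$p.value, 0.01)
})

test_that("a positive extremity shift pushes focal endpoint use", {
  ip <- simulateItemParams(6, 0.8, 0.8, seed = 73)
  latent <- simulateLatent(6000, seed = 74)
  focal <- rep(c(TRUE, FALSE), 3000)
  resp <- simulateResponses(latent, ip, focal = focal, shift = 0.5,
                            shiftWhich = "alpha_e", seed = 75)
  ## the shifted loading amplifies trait-driven extremity: endpoint rates
  ## conditional on the trait sign separate between the groups
  hiTrait <- latent[, 1] > 1
  extreme <- rowMeans(resp[, 1:3] == 5)
  expect_gt(mean(extreme[focal & hiTrait]), mean(extreme[!focal & hiTrait]))
})

test_that("replicates are reproducible from the config seeds", {
  cfg <- simConfig(nPersons = 150, replications = 3, seed = 5)
  d1 <- simulateStudyData(cfg, 2)
  d2 <- simulateStudyData(cfg, 2)
  expect_identical(d1$responses, d2$responses)
  expect_identical(d1$covariate, d2$covariate)
  d3 <- simulateStudyData(cfg, 3)
  expect_false(identical(d1$responses, d3$responses))
  ## item parameters are length-keyed: shared across cells of equal length
  cfgB <- simConfig(nPersons = 150, replications = 3, seed = 999)
  expect_identical(simulateStudyData(cfgB, 1)$itemParams$delta,
                   d1$itemParams$delta)
})

test_that("a small simulation cell returns complete records and summaries", {
  cfg <- simConfig(nPersons = 250, replications = 3, quadPoints = 3,
                   covariate = "categorical", seed = 8)
  res <- runSimulationCell(cfg)
  expect_s3_class(res, "irtreeSimResult")
  expect_equal(nrow(res$records), 3)
  expect_true(all(c("pNm", "pE", "alphaNmHat", "converged") %in%
                  names(res$records)))
  expect_true(res$summary$rejectNm >= 0 && res$summary$rejectNm <= 1)
  expect_equal(res$summary$nReplications, 3)
  f <- tempfile(fileext = ".json"); g <- tempfile(fileext = ".csv")
  writeSimResult(res, f, g)
  expect_true(file.exists(f) && file.exists(g))
  expect_equal(nrow(read.csv(g)), 3)
})
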