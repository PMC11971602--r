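## small fit options shared by the partition tests
popts <- fitOptions(method = "bfgs", quadPoints = 3)

test_that("no admissible split exists when every cut starves a side", {
  dat <- makeOneTraitData(120, seed = 41)
  expect_error(findCutpoint(dat$responses, runif(120), dat$model, popts,
                            minSize = 300),
               "no admissible split")
})

test_that("the cutpoint search finds a gross intercept change", {
  ## two groups whose agreement intercepts differ by 2, change at covariate 40
  set.seed(43)
  ipA <- simulateItemParams(4, 0.6, 0.6, nTraits = 1L, seed = 97)
  ipB <- ipA
  ipB$delta[, 1] <- ipB$delta[, 1] + 2
  n <- 150
  covariate <- rep(c(20, 30, 40, 50, 60, 70), each = n / 2)[sample(3 * n)]
  latent <- simulateLatent(3 * n, defaultLatentCovariance(1L), seed = 44)
  focal <- covariate <= 40
  respA <- simulateResponses(latent[!focal, , drop = FALSE], ipA, seed = 45)
  respB <- simulateResponses(latent[focal, , drop = FALSE], ipB, seed = 46)
  responses <- matrix(NA_integer_, 3 * n, 4)
  responses[!focal, ] <- respA
  responses[focal, ] <- respB
  fc <- findCutpoint(responses, covariate, ipA$model,
                     fitOptions(method = "bfgs", quadPoints = 5),
                     minSize = 100)
  expect_equal(fc$cutpoint, 40)
  expect_equal(nrow(fc$profile), 3)  # cuts at 30|40|50 leave >= 100 a side
  expect_true(all(diff(fc$profile$cut) > 0))
})

test_that("homogeneous data yields a single-node tree", {
  fx <- sharedNullFit()
  tree <- partitionIRTree(fx$dat$responses, fx$dat$covariate, kind = "metric",
                          model = fx$dat$model, level = 0.01, minSize = 200,
                          options = popts, maxCandidates = 4)
  expect_s4_class(tree, "PartitionNode")
  expect_length(tree@children, 0)
  expect_length(tree@tests, 2)
  tab <- partitionTable(tree)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n, 500L)
})

test_that("strong heterogeneity produces a depth-1 tree with a sane cut", {
  cfg <- simConfig(nPersons = 900, replications = 1, quadPoints = 4,
                   covariate = "metric", shift = 0.5, seed = 99)
  dat <- simulateStudyData(cfg, 1)
  tree <- partitionIRTree(dat$responses, dat$covariate, kind = "metric",
                          model = dat$model, minSize = 250, maxDepth = 1,
                          options = fitOptions(method = "bfgs", quadPoints = 4),
                          maxCandidates = 6)
  expect_length(tree@children, 2)
  expect_false(is.na(tree@cutpoint))
  ## both sides >= minSize and they partition the sample
  expect_equal(tree@children[[1]]@n + tree@children[[2]]@n, tree@n)
  expect_gte(min(tree@children[[1]]@n, tree@children[[2]]@n), 250L)
  ## children carry their own subgroup fits
  expect_true(all(vapply(tree@children, function(ch)
    is(ch@fit, "IRTreeFit"), logical(1))))
})

test_that("partitioning is invariant to monotone ordinal relabeling", {
  fx <- sharedNullFit()
  ordCov <- cut(fx$dat$covariate, c(-Inf, 35, 50, 65, Inf), labels = FALSE)
  t1 <- partitionIRTree(fx$dat$responses, ordCov, kind = "ordinal",
                        model = fx$dat$model, minSize = 150,
                        options = popts, maxDepth = 1)
  t2 <- partitionIRTree(fx$dat$responses, ordCov * 10 + 3, kind = "ordinal",
                        model = fx$dat$model, minSize = 150,
                        options = popts, maxDepth = 1)
  p1 <- vapply(t1@tests, function(x) x@pValue, numeric(1))
  p2 <- vapply(t2@tests, function(x) x@pValue, numeric(1))
  expect_equal(p1, p2, tolerance = 1e-10)
  expect_equal(length(t1@children), length(t2@children))
})

test_that("categorical splitting searches binary partitions of the levels", {
  g <- factor(rep(c("a", "b", "c"), each = 60))
  sets <- IRTreeScore:::categoricalCuts(g, minSize = 60)
  expect_equal(length(sets), 3)  # {a}, {b}, {a,b} up to complements
  expect_length(IRTreeScore:::categoricalCuts(g, minSize = 100), 0)
  expect_error(IRTreeScore:::categoricalCuts(factor(rep(1:7, 30)), 10),
               "not supported")
})

test_that("partition JSON export mirrors the tree", {
  fx <- sharedNullFit()
  tree <- partitionIRTree(fx$dat$responses, fx$dat$covariate, kind = "metric",
                          model = fx$dat$model, level = 1e-6, minSize = 200,
                          options = popts)
  f <- tempfile(fileext = ".json")
  writePartitionJSON(tree, f)
  obj <- jsonlite::read_json(f, simplifyVector = FALSE)
  expect_equal(obj$n, 500L)
  expect_equal(length(obj$children), length(tree@children))
})
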