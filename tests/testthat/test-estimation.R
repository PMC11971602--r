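test_that("degenerate and unreached pseudo-items are rejected by name", {
  set.seed(2)
  resp <- matrix(sample(0:5, 60 * 4, TRUE), 60)
  ## category 5 never chosen for item 3: its extremity node i3_n5 is all 0
  resp[resp[, 3] == 5, 3] <- 4
  expect_error(suppressWarnings(fitIRTree(resp, irtreeModel(4))),
               "i3_n5")
  ## item never leaves the moderate categories: its nonmoderate node is
  ## constant (and the extremity nodes behind it are never reached)
  resp2 <- matrix(sample(0:5, 60 * 4, TRUE), 60)
  resp2[, 2] <- sample(2:3, 60, TRUE)
  expect_error(suppressWarnings(fitIRTree(resp2, irtreeModel(4))),
               "degenerate pseudo-item i2_n2")
  ## a pseudo-item that is never reached at all (structural missingness)
  Y <- expandResponses(matrix(sample(0:5, 60 * 2, TRUE), 60))
  Y[, "i1_n5"] <- NA
  expect_error(suppressWarnings(fitIRTree(Y, irtreeModel(2), expanded = TRUE)),
               "i1_n5 is never reached")
})

test_that("quadrature EM increases the marginal log-likelihood monotonically", {
  dat <- makeOneTraitData(250, seed = 7)
  fit <- suppressWarnings(fitIRTree(dat$responses, dat$model,
                  fitOptions(method = "em", quadPoints = 5, maxIter = 40)))
  expect_gt(length(fit@loglikPath), 3)
  expect_true(all(diff(fit@loglikPath) > -1e-6))
})

test_that("EM and direct optimization find the same optimum", {
  dat <- makeOneTraitData(250, seed = 8)
  fem <- suppressWarnings(fitIRTree(dat$responses, dat$model,
                                    fitOptions(method = "em", quadPoints = 5)))
  fbf <- fitIRTree(dat$responses, dat$model,
                   fitOptions(method = "bfgs", quadPoints = 5))
  expect_equal(fem@loglik, fbf@loglik, tolerance = 1e-5)
  expect_equal(coef(fem)[["alpha_nm"]], coef(fbf)[["alpha_nm"]],
               tolerance = 1e-2)
})

test_that("person log-likelihoods integrate the conditional likelihood", {
  fx <- sharedNullFit()
  ll <- personLogLik(fx$fit)
  expect_equal(sum(ll), fx$fit@loglik, tolerance = 1e-8)
  ## all-missing person contributes an empty product: log 1 = 0
  resp <- fx$dat$responses[1:12, ]
  resp[3, ] <- NA
  llm <- personLogLik(fx$fit, responses = resp)
  expect_equal(llm[3], 0)
  ## single person, single observed pseudo-item: closed-form check against
  ## high-resolution 1-d integration of the agreement node
  m1 <- irtreeModel(1, nTraits = 1)
  psi <- defaultPsi(m1)
  psi["d1_i1"] <- 0.4
  psi <- setSigma(m1, psi, diag(c(1.3, 1, 1)))
  Y <- matrix(NA_integer_, 1, 5, dimnames = list(NULL, paste0("i1_n", 1:5)))
  Y[1, 1] <- 1L
  quad <- ghGrid(3, 21L)
  f1 <- new("IRTreeFit", model = m1, psi = psi,
            sigma = paramStructures(m1, psi)$Sigma, loglik = 0,
            nPersons = 1L, converged = TRUE, iterations = 0L,
            method = "bfgs", gradNorm = 0, loglikPath = numeric(0),
            quad = c(quad, list(pointsPerDim = 21L)), pseudoData = Y)
  oracle <- log(integrate(function(z)
    plogis(z + 0.4) * dnorm(z, 0, sqrt(1.3)), -12, 12,
    rel.tol = 1e-12)$value)
  expect_equal(personLogLik(f1)[1], oracle, tolerance = 1e-8)
})

test_that("analytic marginal score matches central finite differences", {
  set.seed(42)
  dat <- makeOneTraitData(20, seed = 12)
  quad <- ghGrid(3, 4L)
  psi <- defaultPsi(dat$model) + rnorm(nParams(dat$model), 0, 0.15)
  fit <- new("IRTreeFit", model = dat$model, psi = psi,
             sigma = paramStructures(dat$model, psi)$Sigma, loglik = 0,
             nPersons = 20L, converged = TRUE, iterations = 0L,
             method = "bfgs", gradNorm = 0, loglikPath = numeric(0),
             quad = c(quad, list(pointsPerDim = 4L)),
             pseudoData = expandResponses(dat$responses))
  S <- scoreContributions(fit, psi = psi)
  h <- 1e-5
  FD <- vapply(seq_along(psi), function(k) {
    pp <- psi; pp[k] <- pp[k] + h
    pm <- psi; pm[k] <- pm[k] - h
    (personLogLik(fit, psi = pp) - personLogLik(fit, psi = pm)) / (2 * h)
  }, numeric(nrow(S)))
  expect_lt(max(abs(S - FD) / (abs(FD) + 1e-4)), 1e-4)
})

test_that("doubling the quadrature resolution barely moves the log-likelihood", {
  ## unit-scale latent variances: the default 11-point rule is converged
  ## there (heavier-tailed latent scales need more points; see the vignette)
  sig <- diag(3); sig[2, 3] <- sig[3, 2] <- 0.3
  ip <- simulateItemParams(6, 0.75, 0.6, nTraits = 1L, seed = 906)
  set.seed(13)
  latent <- matrix(rnorm(150 * 3), 150) %*% chol(sig)
  resp <- simulateResponses(latent, ip, seed = 14)
  fA <- suppressWarnings(fitIRTree(resp, ip$model,
                  fitOptions(method = "bfgs", quadPoints = 11)))
  llA <- personLogLik(fA)
  quadB <- ghGrid(3, 22L)
  fB <- fA; fB@quad <- c(quadB, list(pointsPerDim = 22L))
  llB <- personLogLik(fB)
  expect_lt(mean(abs(llA - llB)), 1e-3)
})

test_that("splitting the sample never lowers the summed log-likelihood", {
  fx <- sharedNullFit()
  opts <- fitOptions(method = "bfgs", quadPoints = 3)
  sl <- splitLogLik(fx$dat$responses, fx$dat$covariate, 50, fx$dat$model,
                    opts, minSize = 150, init = coef(fx$fit))
  expect_gte(sl$loglik, fx$fit@loglik - 1e-4)  # nesting: more free parameters
})

test_that("a split below the minimum subsample size errors", {
  dat <- makeOneTraitData(120, seed = 10)
  expect_error(splitLogLik(dat$responses, seq_len(120), 60, dat$model,
                           minSize = 300),
               "below the minimum size")
})
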