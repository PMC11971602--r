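ordMetric <- function(n) covariateOrdering(seq_len(n), "metric")
ordCat <- function(x) covariateOrdering(factor(x), "categorical")
ordOrd <- function(x) covariateOrdering(x, "ordinal")

test_that("statistics of a zero process are zero and give p = 1", {
  B0 <- matrix(0, 10, 1, dimnames = list(NULL, "p"))
  pm <- manualProcess(B0, ordMetric(10))
  for (w in c("DM", "CvM", "maxLM"))
    expect_equal(fluctuationStatistic(pm, w), 0)
  po <- manualProcess(B0, ordOrd(rep(1:5, each = 2)))
  for (w in c("WDMo", "maxLMo", "LMuo"))
    expect_equal(fluctuationStatistic(po, w), 0)
  expect_equal(scorePValue(0, "DM", 1)$p, 1)
  expect_equal(scorePValue(0, "WDMo", 1, t = c(.25, .5, .75))$p, 1)
  expect_equal(scorePValue(0, "LMuo", 1, m = 3)$p, 1)
})

test_that("DM is the double maximum of the absolute process", {
  B <- matrix(c(0.5, -1.2, 0), 3, 1, dimnames = list(NULL, "p"))
  pr <- manualProcess(B, ordMetric(3))
  expect_equal(fluctuationStatistic(pr, "DM"), 1.2)
})

test_that("ordinal statistics at m = 2 reduce to hand computations", {
  ## boundary at t = .5 with B(v1) = 1: WDMo = (1/4)^(-1/2) = 2, maxLMo = 4
  B <- matrix(c(1, 0), 2, 1, dimnames = list(NULL, "p"))
  pr <- manualProcess(B, ordOrd(c(1, 2)))
  expect_equal(fluctuationStatistic(pr, "WDMo"), 2)
  expect_equal(fluctuationStatistic(pr, "maxLMo"), 4)
  ## LMuo with increments (1, -1) and proportions (.5, .5): 1/.5 + 1/.5
  expect_equal(fluctuationStatistic(pr, "LMuo"), 4)
  expect_equal(fluctuationStatistic(pr, "LMuo", scaleLMuo = FALSE), 2)
})

test_that("two-category LMuo equals the brute-force two-sample LM statistic", {
  set.seed(33)
  n <- 200
  s <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  s <- sweep(s, 2, colMeans(s))      # MLE condition: scores sum to zero
  g <- rep(c("x", "y"), each = n / 2)
  pr <- fluctuationProcess(s, ordCat(g), c("a", "b"))
  lmuo <- fluctuationStatistic(pr, "LMuo")
  ## oracle: quadratic form of the group-1 score sum in its null covariance
  ## n1*(1 - n1/n) * Ihat  (two-sample score test for a mean shift)
  I <- crossprod(s) / n
  g1 <- colSums(s[g == "x", ])
  n1 <- sum(g == "x")
  oracle <- drop(t(g1) %*% solve(I * n1 * (1 - n1 / n)) %*% g1)
  expect_equal(lmuo, oracle, tolerance = 1e-10)
})

test_that("LMuo is invariant to relabeling of unordered categories", {
  set.seed(34)
  s <- matrix(rnorm(300), ncol = 2, dimnames = list(NULL, c("a", "b")))
  s <- sweep(s, 2, colMeans(s))
  g <- sample(c("u", "v", "w"), 150, TRUE)
  relab <- c(u = "v", v = "w", w = "u")[g]
  s1 <- fluctuationStatistic(fluctuationProcess(s, ordCat(g), c("a", "b")), "LMuo")
  s2 <- fluctuationStatistic(fluctuationProcess(s, ordCat(relab), c("a", "b")), "LMuo")
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("trimming bounds for maxLM are validated", {
  B <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "p"))
  pr <- manualProcess(B, ordMetric(20))
  expect_error(fluctuationStatistic(pr, "maxLM", trim = 0.6), "trim")
  expect_error(fluctuationStatistic(pr, "maxLM", trim = 0), "trim")
})

test_that("analytic null quantiles match their closed forms", {
  ## bridge supremum: the .95 point of the Kolmogorov law is ~1.358
  expect_equal(pKolmogorov(1.358), 0.95, tolerance = 1e-3)
  expect_equal(scorePValue(1.358, "DM", 1)$p, 0.05, tolerance = 1e-3)
  ## chi-square(1) survival at 3.841 is .05
  expect_equal(scorePValue(3.841, "LMuo", 1, m = 2)$p, 0.05, tolerance = 1e-3)
  ## WDMo at a single median boundary: p = 1 - (2*Phi(c) - 1)^k
  p <- scorePValue(2, "WDMo", 2, t = 0.5)$p
  expect_equal(p, 1 - (2 * pnorm(2) - 1)^2, tolerance = 1e-4)
})

test_that("analytic p-values agree with Brownian-bridge Monte Carlo", {
  nsim <- 4000L
  ## DM, k = 2: simulate sup|B| over a fine grid
  null <- withr::with_seed(55, {
    g <- 2000
    replicate(nsim, {
      mx <- 0
      for (comp in 1:2) {
        w <- cumsum(rnorm(g)) / sqrt(g)
        mx <- max(mx, max(abs(w - (1:g) / g * w[g])))
      }
      mx
    })
  })
  for (cc in c(1.2, 1.5)) {
    pa <- scorePValue(cc, "DM", 2)$p
    pm <- mean(null >= cc)
    expect_lt(abs(pa - pm), 3 * sqrt(pm * (1 - pm) / nsim) + 0.01)
  }
  ## WDMo, k = 1, skewed boundaries: exact joint-normal law vs MC
  t <- cumsum(c(.1, .1, .35, .35))
  dt <- diff(c(0, t, 1))
  nullW <- withr::with_seed(56, {
    E <- matrix(rnorm(5 * nsim), 5) * sqrt(dt)
    CS <- apply(E, 2, cumsum)
    Bm <- CS[-5, ] - t %o% CS[5, ]
    apply(abs(Bm) / sqrt(t * (1 - t)), 2, max)
  })
  for (cc in c(2, 2.5)) {
    pa <- scorePValue(cc, "WDMo", 1, t = t)$p
    pm <- mean(nullW >= cc)
    expect_lt(abs(pa - pm), 3 * sqrt(pm * (1 - pm) / nsim) + 0.005)
  }
})

test_that("simulated p-values are reproducible and monotone in the statistic", {
  p1 <- scorePValue(0.3, "CvM", 1, nsim = 1000, seed = 9)
  p2 <- scorePValue(0.3, "CvM", 1, nsim = 1000, seed = 9)
  expect_equal(p1$p, p2$p)
  expect_equal(p1$method, "simulated")
  stats <- c(0.05, 0.2, 0.5, 1)
  for (w in c("DM", "CvM", "maxLM")) {
    ps <- vapply(stats, function(s)
      scorePValue(s, w, 1, nsim = 500, seed = 3)$p, numeric(1))
    expect_true(all(diff(ps) <= 1e-12))
  }
  psO <- vapply(c(1, 2, 4, 8), function(s)
    scorePValue(s, "maxLMo", 1, t = c(.4, .7), nsim = 500, seed = 3)$p,
    numeric(1))
  expect_true(all(diff(psO) <= 1e-12))
  psW <- vapply(c(1, 2, 3), function(s)
    scorePValue(s, "WDMo", 2, t = c(.4, .7))$p, numeric(1))
  expect_true(all(diff(psW) < 0))
})
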