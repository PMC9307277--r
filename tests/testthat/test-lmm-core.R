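test_that("no random terms degenerates to ordinary least squares", {
  set.seed(51)
  n <- 40
  X <- cbind(1, rnorm(n))
  y <- X %*% c(2, 0.5) + rnorm(n)
  fit <- remlFit(y, X)
  ols <- lm(y ~ X - 1)
  expect_equal(unname(fixedEffects(fit)), unname(coef(ols)),
               tolerance = 1e-10)
  expect_equal(unname(varianceComponents(fit)["residual"]),
               sum(resid(ols)^2) / (n - 2), tolerance = 1e-10)
  expect_error(remlFit(y, cbind(X, X[, 2])), "rank deficient")
})

test_that("balanced one-way design matches closed-form ANOVA REML", {
  # k groups of size m: sigma2_b = (MSB - MSW) / m, sigma2_e = MSW
  set.seed(52)
  k <- 8; m <- 6
  groups <- rep(letters[1:k], each = m)
  y <- rnorm(k, sd = 1.5)[factor(groups)] + rnorm(k * m)
  fit <- remlFit(y, randomTerms = list(randomTerm("grp", groups = groups)))
  gm <- tapply(y, groups, mean)
  msb <- m * sum((gm - mean(y))^2) / (k - 1)
  msw <- sum((y - gm[groups])^2) / (k * (m - 1))
  expect_equal(unname(varianceComponents(fit)["grp"]),
               max(0, (msb - msw) / m), tolerance = 1e-5)
  expect_equal(unname(varianceComponents(fit)["residual"]), msw,
               tolerance = 1e-4)
})

test_that("restricted likelihood beats a grid and matches dense evaluation", {
  set.seed(53)
  n <- 60
  A <- matrix(rnorm(n * 30), n) / sqrt(30)
  K <- tcrossprod(A)
  X <- cbind(1, rnorm(n))
  L <- chol(K + 1e-8 * diag(n))
  y <- drop(X %*% c(1, 0.3) + sqrt(0.6) * crossprod(L, rnorm(n)) +
              sqrt(0.4) * rnorm(n))
  term <- randomTerm("k", kernel = K)
  fit <- remlFit(y, X, list(term))
  # fitted restricted ll >= every grid point (30 x 30 here; acceptance
  # checks run the full 50 x 50 across 20 replicate problems)
  grid <- expand.grid(g = exp(seq(log(1e-3), log(10), length.out = 30)),
                      e = exp(seq(log(1e-3), log(10), length.out = 30)))
  gridLl <- mapply(function(g, e) denseRemlLogLik(c(g, e), y, X, list(K)),
                   grid$g, grid$e)
  expect_gte(remlLogLik(fit) + 1e-8, max(gridLl))
  # and the reported optimum agrees with the independent dense formula
  expect_equal(remlLogLik(fit),
               denseRemlLogLik(varianceComponents(fit), y, X, list(K)),
               tolerance = 1e-8)
})

test_that("restricted likelihood surface agrees with dense evaluation at
          random points for a multi-term model", {
  set.seed(54)
  n <- 35
  A <- matrix(rnorm(n * 20), n) / sqrt(20)
  Ks <- list(tcrossprod(A))
  groups <- rep(1:7, each = 5)
  terms <- list(randomTerm("k", kernel = Ks[[1]]),
                randomTerm("g", groups = groups))
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  KsAll <- lapply(terms, `[[`, "K")
  for (i in 1:20) {
    s2 <- exp(runif(3, -2, 1))
    ours <- hybridmap:::.llEval(s2, y, X, KsAll)$reml
    expect_equal(ours, denseRemlLogLik(s2, y, X, KsAll), tolerance = 1e-8)
  }
})

test_that("analytic gradient matches numerical differentiation", {
  set.seed(55)
  n <- 30
  A <- matrix(rnorm(n * 15), n) / sqrt(15)
  Ks <- list(tcrossprod(A), tcrossprod(matrix(rnorm(n * 3), n)) / 3)
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  s2 <- c(0.5, 0.3, 0.8)
  ev <- hybridmap:::.llEval(s2, y, X, Ks, gradient = TRUE)
  eps <- 1e-6
  for (k in 1:3) {
    s2p <- s2; s2p[k] <- s2p[k] + eps
    s2m <- s2; s2m[k] <- s2m[k] - eps
    numR <- (hybridmap:::.llEval(s2p, y, X, Ks)$reml -
               hybridmap:::.llEval(s2m, y, X, Ks)$reml) / (2 * eps)
    numM <- (hybridmap:::.llEval(s2p, y, X, Ks)$ml -
               hybridmap:::.llEval(s2m, y, X, Ks)$ml) / (2 * eps)
    expect_equal(ev$gradReml[k], numR, tolerance = 1e-5)
    expect_equal(ev$gradMl[k], numM, tolerance = 1e-5)
  }
})

test_that("REML estimates are invariant to fixed-design reparameterisation", {
  set.seed(56)
  n <- 50
  A <- matrix(rnorm(n * 25), n) / sqrt(25)
  K <- tcrossprod(A)
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- rnorm(n) + X[, 2]
  T <- matrix(c(1, 0.5, -1, 0, 2, 1, 0, 0, 3), 3, 3)   # invertible
  f1 <- remlFit(y, X, list(randomTerm("k", kernel = K)))
  f2 <- remlFit(y, X %*% T, list(randomTerm("k", kernel = K)))
  expect_equal(varianceComponents(f1), varianceComponents(f2),
               tolerance = 1e-6)
})

test_that("fixed-effect LRT: identities and null calibration", {
  expect_equal(pchisq(3.841, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  set.seed(57)
  n <- 60
  groups <- rep(1:10, each = 6)
  term <- randomTerm("g", groups = groups)
  y <- rnorm(10)[groups] * 0.7 + rnorm(n)
  X1 <- matrix(1, n, 1)
  f0 <- remlFit(y, X1, list(term), criterion = "ML")
  expect_equal(lrt(f0, f0, 1)$p, 1)
  expect_equal(lrt(f0, f0, 1)$statistic, 0)
  # under the null, LRT p-values are uniform
  ps <- replicate(400, {
    yy <- rnorm(n)
    x <- rnorm(n)
    f1 <- remlFit(yy, cbind(X1, x), criterion = "ML")
    f0 <- remlFit(yy, X1, criterion = "ML")
    lrt(f1, f0, 1)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("RLRT: boundary gives p ~ 1, signal is detected", {
  set.seed(58)
  n <- 120
  A <- matrix(rnorm(n * 60), n) / sqrt(60)
  K <- tcrossprod(A)
  term <- randomTerm("k", kernel = K)
  expect_error(rlrtTest(rnorm(n), testedTerm = term, nSim = 50), "at least")
  # pure-noise trait: tested component at the boundary most of the time
  y0 <- rnorm(n)
  r0 <- rlrtTest(y0, testedTerm = term, nSim = 200, seed = 1)
  expect_gte(r0$p, 1 / 201)
  # strong genetic signal: small p
  L <- chol(K + 1e-8 * diag(n))
  y1 <- drop(crossprod(L, rnorm(n))) * 2 + rnorm(n) * 0.3
  r1 <- rlrtTest(y1, testedTerm = term, nSim = 200, seed = 2)
  expect_lt(r1$p, 0.02)
  # general (nuisance-term) path agrees in spirit: statistic positive
  nuis <- randomTerm("grp", groups = rep(1:12, each = 10))
  r2 <- rlrtTest(y1, testedTerm = term, nuisanceTerms = list(nuis),
                 nSim = 100, seed = 3)
  expect_lt(r2$p, 0.05)
})

test_that("variance components are never negative; boundary flagged", {
  set.seed(59)
  n <- 45
  groups <- rep(1:9, each = 5)
  # y with zero group variance: component should pin at ~0
  y <- rnorm(n)
  fit <- remlFit(y, randomTerms = list(randomTerm("g", groups = groups),
                                       randomTerm("h", groups = rep(1:5, 9))))
  expect_true(all(varianceComponents(fit) >= 0))
  expect_true(is.logical(fit@boundary))
})
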