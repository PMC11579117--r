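# locally sparse gated classifier: gates, penalties, training, clustering

test_that("the gate threshold function matches direct substitution", {
  expect_equal(stochasticGate(0.2, 0), 0.7)
  expect_equal(stochasticGate(0.6, 0), 1)
  expect_equal(stochasticGate(-0.9, 0.1), 0)
  expect_error(stochasticGate(c(1, 2), 0.5), "shape error")
})

test_that("the gate matches a scalar loop oracle on fuzzed inputs", {
  set.seed(1)
  mu <- runif(1e4, -2, 2)
  eps <- rnorm(1e4, 0, 0.7)
  oracle <- numeric(1e4)
  for (i in seq_len(1e4)) {
    v <- 0.5 + mu[i] + eps[i]
    oracle[i] <- if (v < 0) 0 else if (v > 1) 1 else v
  }
  expect_identical(stochasticGate(mu, eps), oracle)
})

test_that("gate noise is zero at sigma 0, calibrated, and seeded", {
  expect_identical(sampleGateNoise(0, 3, 4), matrix(0, 3, 4))
  set.seed(2)
  eps <- sampleGateNoise(0.5, 1000, 100)
  expect_lt(abs(sd(eps) - 0.5), 0.005)
  set.seed(3)
  a <- sampleGateNoise(0.5, 2, 2)
  set.seed(3)
  b <- sampleGateNoise(0.5, 2, 2)
  expect_identical(a, b)
  expect_error(sampleGateNoise(-0.1, 1, 1), "sigma")
})

forceGateBias <- function(model, value) {
  # drive the gating output bias so tanh saturates at +/- 1
  p <- neurotype:::.netParams(model@gatingNet)
  p[[length(p)]][] <- value
  p[[length(p) - 1L]][] <- 0
  model@gatingNet <- neurotype:::.setNetParams(model@gatingNet, p)
  model
}

test_that("saturated gates reduce to the plain network or a constant", {
  cfg <- lspinConfig(gatingHidden = c(6L, 6L, 6L), predictionHidden = c(8L, 4L),
                     seed = 4)
  set.seed(4)
  model <- neurotype:::.newLSPINModel(cfg, 10L, c("a", "b", "c"))
  set.seed(5)
  x <- matrix(rnorm(60), 6, 10)
  open <- forceGateBias(model, 100)
  fw <- lspinForward(open, x)
  expect_true(all(fw$gates == 1))
  plain <- neurotype:::.mlpForward(model@predictionNet, x)$out
  expect_equal(fw$scores, plain, tolerance = 1e-12)
  closed <- forceGateBias(model, -100)
  fw0 <- lspinForward(closed, x)
  expect_true(all(fw0$gates == 0))
  # with all gates shut the scores ignore the input entirely
  fw0b <- lspinForward(closed, x + 5)
  expect_equal(fw0$scores, fw0b$scores, tolerance = 1e-12)
})

test_that("inference scores equal an independent gated recompute", {
  cfg <- lspinConfig(gatingHidden = c(5L, 5L, 5L), predictionHidden = c(6L, 3L),
                     seed = 6)
  set.seed(6)
  model <- neurotype:::.newLSPINModel(cfg, 7L, c("a", "b"))
  set.seed(7)
  x <- matrix(rnorm(35), 5, 7)
  fw <- lspinForward(model, x, mode = "infer")
  mu <- neurotype:::.mlpForward(model@gatingNet, x)$out
  z <- pmin(pmax(0.5 + mu, 0), 1)
  oracle <- neurotype:::.mlpForward(model@predictionNet, x * z)$out
  expect_equal(fw$scores, oracle, tolerance = 1e-6)
  expect_equal(fw$gates, z)
})

test_that("the sparsity surrogate evaluates the expected open-gate count", {
  expect_equal(sparsityPenalty(matrix(0, 1, 41), 0.5, 0), 0)
  expect_lt(sparsityPenalty(matrix(-100, 1, 41), 0.5, 1), 1e-12)
  # mu = 0, sigma = 0.5, D = 41, lambda1 = 1 -> 41 * Phi(1), with Phi from
  # an independent quadrature of the normal density
  phi1 <- stats::integrate(function(t) exp(-t^2 / 2) / sqrt(2 * pi),
                           -Inf, 1)$value
  expect_equal(sparsityPenalty(matrix(0, 1, 41), 0.5, 1), 41 * phi1,
               tolerance = 1e-8)
})

test_that("the smoothness penalty is zero for equal rows and counts distances", {
  z <- rbind(c(1, 0), c(0, 1))
  K <- matrix(1, 2, 2)
  expect_equal(smoothnessPenalty(rbind(c(0.3, 0.7), c(0.3, 0.7)), K, 1), 0)
  # each sample's term is ||(1,-1)||^2 = 2; batch mean 2
  expect_equal(smoothnessPenalty(z, K, 1), 2)
  expect_equal(smoothnessPenalty(z, K, 0), 0)
  expect_error(smoothnessPenalty(z, -K, 1), "kernel")
})

test_that("the full loss composes from its three terms", {
  cfg <- lspinConfig(gatingHidden = c(5L, 5L, 5L), predictionHidden = c(6L, 4L),
                     lambda1 = 0.3, lambda2 = 0.2, seed = 8)
  set.seed(8)
  model <- neurotype:::.newLSPINModel(cfg, 9L, c("a", "b", "c"))
  for (s in 1:3) {
    set.seed(s)
    x <- matrix(rnorm(54), 6, 9)
    y <- sample(c("a", "b", "c"), 6, replace = TRUE)
    eps <- matrix(rnorm(54, 0, 0.5), 6, 9)
    got <- lspinLoss(model, x, y, eps = eps)
    mu <- neurotype:::.mlpForward(model@gatingNet, x)$out
    z <- stochasticGate(mu, eps)
    P <- neurotype:::.softmax(
      neurotype:::.mlpForward(model@predictionNet, x * z)$out)
    ce <- mean(-log(P[cbind(1:6, match(y, c("a", "b", "c")))]))
    expected <- ce + sparsityPenalty(mu, cfg@sigma, cfg@lambda1) +
      smoothnessPenalty(z, neurotype:::.rbfKernel(x, NA_real_), cfg@lambda2)
    expect_equal(got, expected, tolerance = 1e-9)
  }
  expect_error(lspinLoss(model, matrix(0, 1, 9), "zzz"), "unknown class")
})

test_that("with penalties off and open gates the loss is plain cross-entropy", {
  cfg <- lspinConfig(gatingHidden = c(4L, 4L, 4L), predictionHidden = c(5L, 3L),
                     lambda1 = 0, lambda2 = 0, seed = 9)
  set.seed(9)
  model <- neurotype:::.newLSPINModel(cfg, 6L, c("a", "b"))
  model <- forceGateBias(model, 100)
  set.seed(10)
  x <- matrix(rnorm(30), 5, 6)
  y <- c("a", "b", "a", "b", "a")
  P <- neurotype:::.softmax(neurotype:::.mlpForward(model@predictionNet, x)$out)
  ce <- mean(-log(P[cbind(1:5, match(y, c("a", "b")))]))
  expect_equal(lspinLoss(model, x, y), ce, tolerance = 1e-12)
})

test_that("training is seeded, requires noise, and needs two classes", {
  sp <- smallSubclassSplit(seed = 11)
  cfg <- lspinConfig(gatingHidden = c(8L, 8L, 8L), predictionHidden = c(8L, 4L),
                     epochs = 4L, seed = 11)
  f1 <- trainLSPIN(cfg, sp)
  f2 <- trainLSPIN(cfg, sp)
  expect_identical(f1$history, f2$history)
  cfg0 <- cfg
  cfg0@sigma <- 0
  expect_error(trainLSPIN(cfg0, sp), "sigma")
  one <- sp
  keep <- subclassLabel(one@train) == "Pvalb"
  one@train <- one@train[, keep]
  expect_error(trainLSPIN(cfg, one), "two classes")
})

test_that("extreme sparsity pressure mutes the gates and the classifier", {
  sp <- smallSubclassSplit(seed = 12)
  cfg <- lspinConfig(gatingHidden = c(10L, 10L, 10L),
                     predictionHidden = c(10L, 5L), lambda1 = 10,
                     epochs = 60L, learningRate = 0.0599, seed = 12)
  fit <- trainLSPIN(cfg, sp)
  Z <- gateMatrix(fit$model, sp@test)
  expect_lt(mean(Z), 0.05)
  acc <- mean(as.character(predictSubclass(fit$model, sp@test)) ==
                subclassLabel(sp@test))
  majority <- max(table(subclassLabel(sp@train))) /
    nSamples(sp@train)
  expect_lt(acc, majority + 0.15)
})

test_that("gate matrices are deterministic, bounded, and class-informative", {
  sp <- smallSubclassSplit(seed = 13)
  cfg <- lspinConfig(gatingHidden = c(12L, 12L, 12L),
                     predictionHidden = c(12L, 6L), epochs = 150L, seed = 13)
  fit <- trainLSPIN(cfg, sp)
  Z1 <- gateMatrix(fit$model, sp@test)
  Z2 <- gateMatrix(fit$model, sp@test)
  expect_identical(Z1, Z2)
  expect_true(all(Z1 >= 0 & Z1 <= 1))
  # gates on each class's informative features dominate the others
  truthSets <- smallSubclassConfig(seed = 13)@informativeSets
  lab <- subclassLabel(sp@test)
  margins <- vapply(names(truthSets), function(cl) {
    rows <- lab == cl
    info <- truthSets[[cl]] + 1L
    mean(Z1[rows, info]) - mean(Z1[rows, -info])
  }, 0)
  expect_gt(median(margins), 0.2)
})

test_that("held-out accuracy is high on a separable five-class cohort", {
  sp <- smallSubclassSplit(seed = 14)
  cfg <- lspinConfig(gatingHidden = c(12L, 12L, 12L),
                     predictionHidden = c(12L, 6L), epochs = 150L, seed = 14)
  fit <- trainLSPIN(cfg, sp)
  acc <- mean(as.character(predictSubclass(fit$model, sp@test)) ==
                subclassLabel(sp@test))
  expect_gte(acc, 0.85)
})

test_that("mean gate value decreases as the sparsity weight grows", {
  sp <- smallSubclassSplit(seed = 15)
  means <- vapply(c(0.001, 0.01, 0.1, 1), function(l1) {
    cfg <- lspinConfig(gatingHidden = c(8L, 8L, 8L),
                       predictionHidden = c(8L, 4L), lambda1 = l1,
                       epochs = 60L, seed = 15)
    mean(gateMatrix(trainLSPIN(cfg, sp)$model, sp@test))
  }, 0)
  inversions <- sum(diff(means) > 0)
  expect_lte(inversions, 1L)
})

test_that("gate-matrix clustering orders identical rows together", {
  z <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), c = c(0, 0, 1, 1))
  cl <- clusterGateMatrix(z)
  pos <- match(c(1, 2), cl$rowOrder)
  expect_equal(abs(diff(pos)), 1L)
  one <- clusterGateMatrix(matrix(0.5, 1, 4))
  expect_equal(one$rowOrder, 1L)
  expect_null(one$rowDendrogram)
})

test_that("clustering partitions are equivariant under row permutation", {
  set.seed(16)
  z <- matrix(runif(60), 10, 6)
  perm <- sample(10)
  c1 <- clusterGateMatrix(z)
  c2 <- clusterGateMatrix(z[perm, ])
  for (k in 2:9) {
    p1 <- cutree(c1$rowDendrogram, k)
    p2 <- cutree(c2$rowDendrogram, k)[order(perm)]
    # identical partitions up to label renaming
    expect_equal(length(unique(paste(p1, p2))), k)
  }
})
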