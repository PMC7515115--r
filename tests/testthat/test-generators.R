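test_that("stick-breaking marginals are valid probability vectors", {
  set.seed(89)
  w <- samplePYMarginal(0.55, 50, maxAtoms = 2e4)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(diff(w) <= 0))
  expect_true(all(w > 0))

  # DP degenerate limit: tiny concentration puts almost all mass on one atom
  w0 <- samplePYMarginal(0, 1e-3, seed = 5)
  expect_gt(w0[1], 0.99)

  expect_error(samplePYMarginal(1.2, 10), "discount")
  expect_error(samplePYMarginal(0.5, -1), "alpha")
})

test_that("blocked stick breaking matches a plain-loop implementation", {
  set.seed(97)
  hEnt <- function(w) -sum(w * log(w))
  mref <- replicate(150, hEnt(pyStickLoop(0.3, 10, truncation = 1e-8)))
  mpkg <- replicate(150, hEnt(samplePYMarginal(0.3, 10, truncation = 1e-8)))
  se <- sqrt(var(mref) / 150 + var(mpkg) / 150)
  expect_lt(abs(mean(mref) - mean(mpkg)), 3 * se + 1e-3)
})

test_that("beta conditionals concentrate as the prior dictates", {
  set.seed(101)
  hi <- sampleBetaConditionals(500, 1e5)
  expect_lt(max(abs(hi[, 1] - 0.5)), 0.05)
  lo <- sampleBetaConditionals(500, 1e-3)
  expect_gt(mean(pmin(lo[, 1], lo[, 2]) < 1e-4), 0.95)
  expect_equal(rowSums(sampleBetaConditionals(20, 1.3, c(0.2, 0.3, 0.5))),
               rep(1, 20), tolerance = 1e-12)
})

test_that("information of sampled conditionals averages to the prior mean", {
  set.seed(103)
  beta <- 2.3
  draws <- replicate(200, {
    q <- sampleBetaConditionals(50, beta)[, 1]
    log(2) - mean(h2Oracle(q))
  })
  se <- sd(draws) / sqrt(200)
  expect_lt(abs(mean(draws) - priorMeanInformation(beta)), 3 * se + 1e-3)
})

test_that("sphere model hits its tuning targets", {
  sm <- makeSphereModel()
  qy <- as.vector(sm@qX %*% sm@qCond)[1]
  expect_gt(qy, 0.49); expect_lt(qy, 0.51)
  info <- trueInformation(sm)
  expect_gt(info, 0.49); expect_lt(info, 0.51)
  e <- modelEntropies(sm)
  expect_equal(exp(e[["HXY"]]), 5000, tolerance = 0.1)
  expect_equal(length(sm@qX), 4096L)
})

test_that("sphere conditionals are invariant under a frame rotation", {
  # rotate the icosahedral frame by 72 degrees about a vertex axis: the
  # vertex set maps onto itself, inducing a permutation of the 12 deltas;
  # the spectrum score (hence the conditional) must be permutation-stable.
  v <- sparseMI:::.icosahedronVertices()
  axis <- v[1, ]
  th <- 2 * pi / 5
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  vr <- v %*% t(R)
  perm <- apply(vr, 1, function(p) which.max(v %*% p))
  expect_setequal(perm, 1:12)   # a genuine vertex permutation

  sc <- sparseMI:::.sphereScores()
  set.seed(107)
  for (i in 1:50) {
    bits <- rbinom(12, 1, 0.5)
    id1 <- sum(bits * 2^(0:11)) + 1
    id2 <- sum(bits[perm] * 2^(0:11)) + 1
    expect_equal(sc$score[id1], sc$score[id2], tolerance = 1e-9)
  }
})

test_that("parity model closed forms match enumeration at small D", {
  p <- 0.2; D <- 10
  states <- as.matrix(expand.grid(rep(list(0:1), D)))
  px <- apply(states, 1, function(s) prod(ifelse(s == 1, p, 1 - p)))
  even <- rowSums(states) %% 2 == 0
  expect_equal(parityEvenProbability(p, D), sum(px[even]), tolerance = 1e-12)

  # exact I of the ideal aggregation equals the 3-class joint model's I
  pm <- makeParityModel(p = p, D = D, q0 = 0.1)
  agg <- aggregateParityModel(pm)
  expect_equal(trueInformation(pm), trueInformation(agg), tolerance = 1e-12)
  # q0 = 1/2 wipes out the information
  expect_equal(trueInformation(makeParityModel(q0 = 0.5)), 0,
               tolerance = 1e-12)
  # marginal q_y is exactly 1/2 by the symmetric branch split
  qy <- as.vector(agg@qX %*% agg@qCond)
  expect_equal(qy, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("parity aggregation matches a large plug-in sample of its classes", {
  set.seed(109)
  pm <- makeParityModel()
  agg <- aggregateParityModel(pm)
  n <- 2e5
  cls <- sample.int(3, n, replace = TRUE, prob = agg@qX)
  y <- rbinom(n, 1, agg@qCond[cls, 1])
  ct <- countsFromPairs(as.character(cls), as.character(y))
  se <- 3 / sqrt(n)   # generous binomial-scale slack
  expect_lt(abs(pluginInformation(ct) - trueInformation(pm)), 3 * se)
})

test_that("parity branch hash is balanced and deterministic", {
  set.seed(113)
  bits <- matrix(rbinom(4000 * 40, 1, 0.5), 4000, 40)
  b1 <- sparseMI:::.parityBranch(bits, 0)
  b2 <- sparseMI:::.parityBranch(bits, 0)
  expect_identical(b1, b2)
  expect_lt(abs(mean(b1) - 0.5), 0.05)
  b3 <- sparseMI:::.parityBranch(bits, 12345)
  expect_gt(mean(b1 != b3), 0.3)   # key actually changes assignments
})

test_that("sampling a model conserves totals and is seed-reproducible", {
  set.seed(127)
  model <- makePYBetaModel(maxAtoms = 2e4)
  ct1 <- sampleCounts(model, 400, seed = 8)
  ct2 <- sampleCounts(model, 400, seed = 8)
  expect_identical(countsMatrix(ct1), countsMatrix(ct2))
  expect_equal(sampleTotal(ct1), 400)

  pm <- makeParityModel()
  pt1 <- suppressWarnings(sampleCounts(pm, 300, seed = 9))
  pt2 <- suppressWarnings(sampleCounts(pm, 300, seed = 9))
  expect_identical(countsMatrix(pt1), countsMatrix(pt2))
  expect_equal(sampleTotal(pt1), 300)
})

test_that("sampled y frequencies converge to the model marginal", {
  set.seed(131)
  model <- jointModel(c(0.6, 0.4), rbind(c(0.9, 0.1), c(0.2, 0.8)))
  qy1 <- 0.6 * 0.9 + 0.4 * 0.2
  n <- 1e5
  ct <- sampleCounts(model, n)
  phat <- yFrequencies(ct)[1]
  expect_lt(abs(phat - qy1), 3 * sqrt(qy1 * (1 - qy1) / n))
})

test_that("heavy-tail ensemble effective size is near its nominal value", {
  set.seed(137)
  eh <- replicate(25, {
    m <- makePYBetaModel(beta = 2.3, maxAtoms = 2e5)
    exp(modelEntropies(m)[["HXY"]])
  })
  expect_gt(mean(eh), 800 * 0.7)
  expect_lt(mean(eh), 800 * 1.3)
})
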