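# Synthetic joint distributions mirroring the benchmark families: heavy-tail
# Pitman-Yor marginals with Beta conditionals, a rotation-invariant sphere
# model, and a Bernoulli-parity three-delta mixture.

#' Sample a Pitman-Yor (or Dirichlet-process) marginal by stick breaking
#'
#' Draws stick proportions V_i ~ Beta(1 - d, alpha + i d) and returns the
#' resulting atom weights sorted in decreasing order and renormalized.
#' Breaking stops when the residual stick mass falls below
#' \code{truncation} or when \code{maxAtoms} sticks have been broken,
#' whichever comes first; for heavy tails (large d) the residual decays only
#' polynomially and the atom cap is the binding limit.  d = 0 gives a
#' Dirichlet process.
#'
#' @param d discount (tail) parameter in [0, 1).
#' @param alpha concentration parameter, > -d (positive in practice).
#' @param truncation residual stick mass threshold (default 1e-8).
#' @param maxAtoms hard cap on the number of atoms (default 5e5).
#' @param seed optional integer seed.
#' @return probability vector, decreasing.
#' @export
samplePYMarginal <- function(d, alpha, truncation = 1e-8, maxAtoms = 5e5,
                             seed = NULL) {
  if (d < 0 || d >= 1) stop("discount d must be in [0, 1)")
  if (alpha <= -d) stop("alpha must exceed -d")
  if (truncation <= 0) stop("truncation must be positive")
  .setSeed(seed)
  block <- max(1024L, ceiling(alpha * 4))
  v <- list(); residual <- 1; i0 <- 0L
  while (residual > truncation && i0 < maxAtoms) {
    nb <- as.integer(min(block, maxAtoms - i0))
    idx <- i0 + seq_len(nb)
    vb <- rbeta(nb, 1 - d, alpha + idx * d)
    v[[length(v) + 1L]] <- vb
    residual <- residual * prod(1 - vb)
    i0 <- i0 + nb
  }
  v <- unlist(v)
  w <- v * cumprod(c(1, 1 - v[-length(v)]))
  keep <- cumsum(w) <= 1 - truncation
  if (any(keep)) {
    last <- max(which(keep))
    w <- w[seq_len(min(last + 1L, length(w)))]
  }
  w <- sort(w, decreasing = TRUE)
  w / sum(w)
}

#' Sample conditional rows from the centered Dirichlet prior
#'
#' Rows are i.i.d. Dirichlet(beta * center); for a symmetric binary center
#' each q_{1|x} is Beta(beta/2, beta/2).  Large beta pins all rows at the
#' center (low information); small beta pushes them to the simplex corners
#' (high information).
#'
#' @param kX number of x states (rows).
#' @param beta positive concentration.
#' @param center simplex vector, the prior center.
#' @param seed optional integer seed.
#' @return matrix (kX by length(center)) of conditional rows.
#' @export
sampleBetaConditionals <- function(kX, beta, center = c(0.5, 0.5),
                                   seed = NULL) {
  if (beta <= 0) stop("beta must be positive")
  .checkSimplex(center, "center")
  .setSeed(seed)
  kY <- length(center)
  if (kY == 2L) {
    q <- rbeta(kX, beta * center[1L], beta * center[2L])
    return(cbind(q, 1 - q, deparse.level = 0))
  }
  g <- matrix(rgamma(kX * kY, shape = rep(beta * center, each = kX)), kX, kY)
  s <- rowSums(g)
  bad <- s == 0           # possible underflow at very small beta
  if (any(bad)) {
    corner <- sample.int(kY, sum(bad), replace = TRUE)
    g[bad, ] <- 0
    g[cbind(which(bad), corner)] <- 1
    s <- rowSums(g)
  }
  g / s
}

#' Heavy-tail benchmark model: Pitman-Yor marginal with Beta conditionals
#'
#' The first benchmark family: q_x sampled once from PY(d, alpha) by stick
#' breaking, binary conditionals q_{1|x} ~ Beta(beta/2, beta/2).  With the
#' default parameters (d = 0.55, alpha = 50, beta = 2.3) the effective size
#' exp(H_XY) of the joint system is about 800.
#'
#' @param beta conditional concentration (default 2.3).
#' @param d,alpha Pitman-Yor tail and concentration (defaults 0.55, 50).
#' @param center conditional prior center (default symmetric binary).
#' @param truncation,maxAtoms stick-breaking truncation controls.
#' @param seed optional integer seed.
#' @return a \linkS4class{JointModel}.
#' @export
makePYBetaModel <- function(beta = 2.3, d = 0.55, alpha = 50,
                            center = c(0.5, 0.5), truncation = 1e-8,
                            maxAtoms = 5e5, seed = NULL) {
  .setSeed(seed)
  qx <- samplePYMarginal(d, alpha, truncation, maxAtoms)
  qc <- sampleBetaConditionals(length(qx), beta, center)
  jointModel(qx, qc, meta = list(family = "py_beta", d = d, alpha = alpha,
                                 beta = beta, seed = seed))
}

## ---- sphere model ---------------------------------------------------------

.icosahedronVertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(0,  1,  phi), c(0, -1,  phi), c(0,  1, -phi), c(0, -1, -phi),
             c( 1,  phi, 0), c(-1,  phi, 0), c( 1, -phi, 0), c(-1, -phi, 0),
             c( phi, 0,  1), c( phi, 0, -1), c(-phi, 0,  1), c(-phi, 0, -1))
  v / sqrt(rowSums(v^2))
}

# Real spherical harmonics up to degree 2 at unit vectors (rows of v).
.sphericalHarmonics <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]; z <- v[, 3L]
  cbind(
    l0 = rep(0.5 / sqrt(pi), nrow(v)),
    l1a = sqrt(3 / (4 * pi)) * x,
    l1b = sqrt(3 / (4 * pi)) * y,
    l1c = sqrt(3 / (4 * pi)) * z,
    l2a = 0.5 * sqrt(15 / pi) * x * y,
    l2b = 0.5 * sqrt(15 / pi) * y * z,
    l2c = 0.25 * sqrt(5 / pi) * (3 * z^2 - 1),
    l2d = 0.5 * sqrt(15 / pi) * x * z,
    l2e = 0.25 * sqrt(15 / pi) * (x^2 - y^2))
}

# Rotation-invariant spectrum score pi0 - pi1 - pi2 for every subset of the
# 12 vertex deltas; subsets indexed 0..4095 by their bit pattern.
.sphereScores <- function(vertices = .icosahedronVertices()) {
  Y <- .sphericalHarmonics(vertices)
  bits <- as.matrix(expand.grid(rep(list(0:1), 12L)))  # col j = bit j-1 of row-1
  S <- bits %*% Y
  p0 <- S[, 1L]^2
  p1 <- rowSums(S[, 2:4, drop = FALSE]^2)
  p2 <- rowSums(S[, 5:9, drop = FALSE]^2)
  list(score = p0 - p1 - p2, bits = bits)
}

#' Rotation-invariant sphere benchmark model
#'
#' X is a binary 12-vector marking which of 12 delta functions at the
#' icosahedron vertices are present; all 2^12 states are equiprobable.  The
#' binary conditional is a sigmoid of the rotation-invariant spherical
#' spectrum score pi0 - pi1 - pi2 (power per harmonic degree, l <= 2), so
#' states in the same rotation class share the same conditional.  The
#' sigmoid offset is tuned by root finding so the Y marginal hits
#' \code{targetMarginal} and the gain so the information hits
#' \code{targetInfo}; with the default targets the effective system size
#' exp(H_XY) is about 5000.
#'
#' @param targetInfo target mutual information in nats (default 0.5).
#' @param targetMarginal target q_{y=1} (default 0.5).
#' @param gain,offset explicit sigmoid parameters; when supplied the tuning
#'   step for that parameter is skipped.
#' @return a \linkS4class{JointModel} with tuning metadata in \code{meta}.
#' @export
makeSphereModel <- function(targetInfo = 0.5, targetMarginal = 0.5,
                            gain = NULL, offset = NULL) {
  sc <- .sphereScores()
  s <- sc$score
  offsetFor <- function(g) {
    if (!is.null(offset)) return(offset)
    uniroot(function(s0) mean(stats::plogis(g * (s - s0))) - targetMarginal,
            lower = min(s) - 1, upper = max(s) + 1, tol = 1e-12)$root
  }
  infoAt <- function(g, s0) {
    q <- stats::plogis(g * (s - s0))
    .h2(mean(q)) - mean(.h2(q))
  }
  if (is.null(gain)) {
    f <- function(lg) {
      g <- exp(lg); infoAt(g, offsetFor(g)) - targetInfo
    }
    lo <- log(1e-3); hi <- log(1e3)
    if (f(lo) * f(hi) > 0) stop("target information not attainable")
    gain <- exp(uniroot(f, lower = lo, upper = hi, tol = 1e-10)$root)
  }
  offset <- offsetFor(gain)
  q1 <- stats::plogis(gain * (s - offset))
  labels <- apply(sc$bits, 1L, paste, collapse = "")
  qc <- cbind(`1` = q1, `0` = 1 - q1)
  m <- jointModel(rep(1 / 4096, 4096), qc,
                  meta = list(family = "sphere", gain = gain, offset = offset,
                              score = s))
  rownames(m@qCond) <- labels
  m
}

## ---- parity model ---------------------------------------------------------

# Deterministic keyed branch bit for a set of binary vectors (rows of bits):
# pack the bits into 16-bit words, fold with multiplicative mixing mod 2^31.
# All intermediates stay below 2^53 so double arithmetic is exact.
.parityBranch <- function(bits, key) {
  n <- nrow(bits); D <- ncol(bits)
  h <- rep((key %% 2^31) + 1, n)
  for (k in seq_len(ceiling(D / 16))) {
    cols <- ((k - 1L) * 16L + 1L):min(k * 16L, D)
    w <- as.vector(bits[, cols, drop = FALSE] %*% 2^(seq_along(cols) - 1))
    h <- (h * 69069 + w * 2654435) %% 2^31
    h <- (h * 69069 + 1) %% 2^31
  }
  h <- (h * 69069 + 1) %% 2^31
  floor(h / 1024) %% 2
}

#' Bernoulli-parity benchmark model (three-delta conditionals)
#'
#' X is a D-dimensional Bernoulli(p) binary vector, never enumerated.  The
#' conditional q_{1|x} equals 1/2 when the sum of the components is even;
#' odd-parity states receive q0 or 1 - q0, assigned by a deterministic keyed
#' hash of the bit pattern so both branches occur with equal probability
#' across states.  The resulting conditional law is a three-delta mixture
#' 0.5 d(1/2) + 0.25 d(q0) + 0.25 d(1-q0) that no single Dirichlet
#' concentration can represent.
#'
#' @param p Bernoulli probability (default 0.05).
#' @param D vector dimension (default 40).
#' @param q0 odd-parity conditional level in (0, 1/2] (default 0.1).
#' @param hashKey integer key for the branch hash (default 0).
#' @return a \linkS4class{ParityModel}.
#' @export
makeParityModel <- function(p = 0.05, D = 40, q0 = 0.1, hashKey = 0) {
  new("ParityModel", p = p, D = D, q0 = q0, hashKey = as.numeric(hashKey))
}

#' Probability that a Bernoulli(p)^D vector has even component sum
#'
#' Closed form (1 + (1 - 2p)^D) / 2.
#'
#' @param p Bernoulli probability.
#' @param D vector dimension.
#' @export
parityEvenProbability <- function(p, D) (1 + (1 - 2 * p)^D) / 2

#' Aggregate a parity model into its exact three-class joint model
#'
#' States are grouped by their conditional value: even parity (q = 1/2) and
#' the two odd-parity branches (q0 and 1 - q0), each carrying half of the
#' odd mass in distribution.  Information is invariant under grouping states
#' with identical conditionals, so this small model carries the exact I of
#' the ideal construction.
#'
#' @param model a \linkS4class{ParityModel}.
#' @return a 3-state \linkS4class{JointModel}.
#' @export
aggregateParityModel <- function(model) {
  stopifnot(is(model, "ParityModel"))
  pe <- parityEvenProbability(model@p, model@D)
  po <- 1 - pe
  jointModel(c(even = pe, oddA = po / 2, oddB = po / 2),
             rbind(c(0.5, 0.5),
                   c(model@q0, 1 - model@q0),
                   c(1 - model@q0, model@q0)),
             meta = list(family = "parity_aggregated", p = model@p,
                         D = model@D, q0 = model@q0))
}

#' @describeIn trueInformation Exact I of the ideal three-class aggregation:
#'   P(odd) * (log 2 - H2(q0)).
#' @export
setMethod("trueInformation", "ParityModel", function(model, ...) {
  po <- 1 - parityEvenProbability(model@p, model@D)
  po * (log(2) - .h2(model@q0))
})

#' @describeIn modelEntropies Entropies of the parity construction; H(X) is
#'   the exact Bernoulli product entropy D * H2(p).
#' @export
setMethod("modelEntropies", "ParityModel", function(model, ...) {
  pe <- parityEvenProbability(model@p, model@D)
  hx <- model@D * .h2(model@p)
  hygx <- pe * log(2) + (1 - pe) * .h2(model@q0)
  c(HX = hx, HY = log(2), HYgX = hygx, HXY = hx + hygx,
    I = log(2) - hygx)
})

setMethod("show", "ParityModel", function(object) {
  cat(sprintf("ParityModel: D = %d, p = %.3g, q0 = %.3g, I = %.4f nats\n",
              as.integer(object@D), object@p, object@q0,
              trueInformation(object)))
})

## ---- sampling -------------------------------------------------------------

#' @describeIn sampleCounts Multinomial sampling of an explicit joint model:
#'   state counts n_x ~ Multinomial(n, q_x), then per-state y counts from
#'   the conditional rows.
#' @export
setMethod("sampleCounts", "JointModel", function(model, n, seed = NULL, ...) {
  if (n < 1) stop("n must be >= 1")
  .setSeed(seed)
  kY <- ncol(model@qCond)
  nx <- as.vector(rmultinom(1L, n, model@qX))
  obs <- which(nx > 0)
  labs <- rownames(model@qCond)
  if (is.null(labs)) labs <- paste0("x", seq_along(model@qX))
  if (kY == 2L) {
    n1 <- rbinom(length(obs), nx[obs], model@qCond[obs, 1L])
    m <- cbind(n1, nx[obs] - n1)
  } else {
    m <- t(vapply(seq_along(obs), function(i)
      as.vector(rmultinom(1L, nx[obs[i]], model@qCond[obs[i], ])),
      numeric(kY)))
  }
  cn <- colnames(model@qCond)
  if (is.null(cn)) cn <- paste0("y", seq_len(kY))
  dimnames(m) <- list(labs[obs], cn)
  new("CountsTable", counts = m)
})

#' @describeIn sampleCounts Lazy sampling of the parity model: draws n
#'   Bernoulli vectors, computes parity and the keyed branch, then samples y.
#'   State labels encode the packed bit pattern.
#' @export
setMethod("sampleCounts", "ParityModel", function(model, n, seed = NULL, ...) {
  if (n < 1) stop("n must be >= 1")
  .setSeed(seed)
  D <- as.integer(model@D)
  bits <- matrix(rbinom(n * D, 1L, model@p), n, D)
  parity <- rowSums(bits) %% 2
  branch <- .parityBranch(bits, model@hashKey)
  q1 <- ifelse(parity == 0, 0.5,
               ifelse(branch == 1, model@q0, 1 - model@q0))
  y <- rbinom(n, 1L, q1)
  words <- vapply(seq_len(ceiling(D / 16)), function(k) {
    cols <- ((k - 1L) * 16L + 1L):min(k * 16L, D)
    as.vector(bits[, cols, drop = FALSE] %*% 2^(seq_along(cols) - 1))
  }, numeric(n))
  if (n == 1L) words <- matrix(words, nrow = 1L)
  labels <- apply(words, 1L, paste, collapse = ".")
  countsFromPairs(labels, y, yLevels = c("0", "1"))
})
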