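# Internal entropy helpers. All in nats; 0 log 0 = 0 throughout.

.xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

.entropyVec <- function(p) -sum(.xlogx(p))

# binary entropy, vectorized
.h2 <- function(q) -(.xlogx(q) + .xlogx(1 - q))

# Posterior/prior mean entropy of q ~ Dirichlet(a):
#   <H> = psi0(A + 1) - sum_i (a_i / A) psi0(a_i + 1),  A = sum(a).
.dirEntropyMean <- function(a) {
  A <- sum(a)
  digamma(A + 1) - sum(a / A * digamma(a + 1))
}

# Same, vectorized over binary states: a1, a2 are vectors (one entry per
# x state).  Returns <H(q_{y|x})> per state.
.dirEntropyMean2 <- function(a1, a2) {
  A <- a1 + a2
  digamma(A + 1) - (a1 * digamma(a1 + 1) + a2 * digamma(a2 + 1)) / A
}

# Variance of the entropy of q ~ Dirichlet(a) (Wolpert-Wolf moments).
# E[H^2] combines a same-index and a cross-index term:
#   E[H^2] = sum_i a_i(a_i+1)/(A(A+1)) * [ (psi0(a_i+2) - psi0(A+2))^2
#                                          + psi1(a_i+2) - psi1(A+2) ]
#          + sum_{i != j} a_i a_j /(A(A+1)) * [ (psi0(a_i+1) - psi0(A+2))
#              * (psi0(a_j+1) - psi0(A+2)) - psi1(A+2) ]
.dirEntropyVar <- function(a) {
  A <- sum(a)
  d2 <- digamma(A + 2)
  t2 <- trigamma(A + 2)
  gi <- digamma(a + 1) - d2          # for cross terms
  hi <- digamma(a + 2) - d2          # for same-index terms
  same <- sum(a * (a + 1) * (hi^2 + trigamma(a + 2) - t2))
  crossAll <- sum(a * gi)^2 - sum((a * gi)^2) - t2 * (A^2 - sum(a^2))
  eh2 <- (same + crossAll) / (A * (A + 1))
  v <- eh2 - .dirEntropyMean(a)^2
  max(v, 0)
}

# Vectorized binary version: variance of H(q) for q ~ Beta(a1, a2), per state.
.dirEntropyVar2 <- function(a1, a2) {
  A <- a1 + a2
  d2 <- digamma(A + 2)
  t2 <- trigamma(A + 2)
  g1 <- digamma(a1 + 1) - d2
  g2 <- digamma(a2 + 1) - d2
  h1 <- digamma(a1 + 2) - d2
  h2 <- digamma(a2 + 2) - d2
  same <- a1 * (a1 + 1) * (h1^2 + trigamma(a1 + 2) - t2) +
          a2 * (a2 + 1) * (h2^2 + trigamma(a2 + 2) - t2)
  cross <- 2 * a1 * a2 * (g1 * g2 - t2)
  eh2 <- (same + cross) / (A * (A + 1))
  pmax(eh2 - .dirEntropyMean2(a1, a2)^2, 0)
}

.checkSimplex <- function(p, what = "probability vector", tol = 1e-9) {
  if (any(is.na(p)) || any(p < 0))
    stop(what, " must be non-negative and free of NA")
  if (abs(sum(p) - 1) > tol)
    stop(what, " must sum to 1 (got ", format(sum(p)), ")")
  invisible(p)
}

.setSeed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
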