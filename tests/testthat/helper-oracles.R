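# Independent oracles used across the suite.  These deliberately avoid the
# package's analytic code paths: Monte-Carlo draws from the conjugate
# posterior, direct numeric quadrature of the per-state likelihood
# integrals, and a plain-loop stick-breaking sampler.

# Binary entropy with 0 log 0 = 0 (local copy, not the package helper).
h2Oracle <- function(q) {
  out <- numeric(length(q))
  ok <- q > 0 & q < 1
  out[ok] <- -(q[ok] * log(q[ok]) + (1 - q[ok]) * log(1 - q[ok]))
  out
}

# Conjugate-posterior MC oracle: draws q_{y|x} ~ Dirichlet(beta*center + n_x.)
# independently per state and evaluates I = Hhat(Y) - sum_x qhat_x H(q_{y|x}).
# Returns mean/var of I with their MC standard errors.
mcPosteriorOracle <- function(counts, beta, draws = 2e5) {
  nx <- rowSums(counts); N <- sum(counts)
  ctr <- colSums(counts) / N
  hY <- -sum(ifelse(ctr > 0, ctr * log(ctr), 0))
  stopifnot(ncol(counts) == 2L)
  Hmat <- vapply(seq_len(nrow(counts)), function(i) {
    q <- rbeta(draws, counts[i, 1] + beta * ctr[1], counts[i, 2] + beta * ctr[2])
    h2Oracle(q)
  }, numeric(draws))
  I <- hY - as.vector(Hmat %*% (nx / N))
  m2 <- mean((I - mean(I))^2)
  m4 <- mean((I - mean(I))^4)
  list(mean = mean(I), meanSE = sd(I) / sqrt(draws),
       var = var(I),
       varSE = sqrt(max(m4 - (draws - 3) / (draws - 1) * m2^2, 0) / draws))
}

# Quadrature oracle for the beta marginal likelihood: per x state the
# likelihood factor is the integral of the binomial likelihood against the
# Beta prior, evaluated with adaptive quadrature (no gamma identities).
quadratureLogLik <- function(counts, beta) {
  ctr <- colSums(counts) / sum(counts)
  stopifnot(ncol(counts) == 2L)
  sum(vapply(seq_len(nrow(counts)), function(i) {
    n1 <- counts[i, 1]; n0 <- counts[i, 2]
    # integrate on the logit scale: the endpoint singularities of the Beta
    # density become exponentially decaying tails; assemble the integrand in
    # log space to dodge 0 * Inf at the edges
    a1 <- beta * ctr[1]; a2 <- beta * ctr[2]
    g <- function(x)
      exp((n1 + a1) * stats::plogis(x, log.p = TRUE) +
          (n0 + a2) * stats::plogis(-x, log.p = TRUE) - lbeta(a1, a2))
    # tail decay rates are (n1 + a1) on the left and (n0 + a2) on the right
    lo <- -max(50, 50 / (n1 + a1))
    hi <- max(50, 50 / (n0 + a2))
    log(stats::integrate(g, lo, hi, rel.tol = 1e-11,
                         subdivisions = 1000L)$value)
  }, 0))
}

# Plain-loop stick-breaking sampler for a Pitman-Yor marginal, independent
# of the package's blocked implementation.
pyStickLoop <- function(d, alpha, truncation = 1e-6, maxSticks = 2e5) {
  w <- numeric(0); rem <- 1; i <- 0L
  while (rem > truncation && i < maxSticks) {
    i <- i + 1L
    v <- rbeta(1, 1 - d, alpha + i * d)
    w[i] <- rem * v
    rem <- rem * (1 - v)
  }
  w / sum(w)
}

# Deterministic small binary tables spanning the shapes used by the
# MC-equivalence checks (N <= 12, k_x <= 4).
smallTables <- function() {
  list(
    rbind(c(1, 1)),
    rbind(c(2, 0), c(1, 1)),
    rbind(c(3, 1), c(0, 2)),
    rbind(c(2, 2), c(1, 0), c(0, 1)),
    rbind(c(4, 0), c(0, 4), c(2, 2)),
    rbind(c(1, 0), c(0, 1), c(1, 1), c(2, 1)),
    rbind(c(5, 1), c(1, 2), c(1, 1), c(0, 1)),
    rbind(c(2, 1), c(2, 1), c(2, 1), c(1, 2)))
}

asTable <- function(m) {
  rownames(m) <- paste0("x", seq_len(nrow(m)))
  colnames(m) <- c("y1", "y0")
  countsTable(m)
}

# Random sparse binary table with at least one coincidence.
randomTable <- function(kx = 6L, nmax = 3L) {
  repeat {
    m <- matrix(rpois(kx * 2L, 0.8), kx, 2L)
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (nrow(m) >= 2L && sum(colSums(m) > 0) == 2L &&
        any(rowSums(m) >= 2)) break
  }
  asTable(m)
}
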