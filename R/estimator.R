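# Bayesian estimator of I(X;Y) for undersampled X: a Dirichlet prior on the
# conditionals q_{y|x}, centered at the observed y marginal with
# concentration beta, gives closed-form posterior moments of the information;
# beta is inferred from the multiplicity statistics of coincident x states.

.betaGridDefault <- function(n = 400L, lo = 1e-4, hi = 1e5)
  exp(seq(log(lo), log(hi), length.out = n))

.centerOf <- function(object, center) {
  if (is.null(center)) {
    center <- if (is(object, "Multiplicities")) object@center
              else yFrequencies(object)
  }
  if (any(center <= 0))
    stop("center must be strictly positive; drop y states with zero counts")
  .checkSimplex(center, "center")
  unname(center)
}

#' Log marginal likelihood of the data given beta
#'
#' The beta-dependent part of log p(n | beta) under the Dirichlet prior on
#' the conditionals centered at \code{center}:
#' \deqn{\log p(n|\beta) = \sum_x \left[\log\Gamma(\beta) -
#'   \log\Gamma(n_x+\beta) + \sum_y \log\Gamma(n_{xy}+\beta \hat q_y) -
#'   \log\Gamma(\beta \hat q_y)\right]}
#' (the combinatorial factor independent of beta is dropped).  The sum is
#' grouped over the multiplicity patterns, so a \linkS4class{Multiplicities}
#' object gives an identical result to the full table.  Singleton states
#' contribute a beta-independent constant, so only coincidences shape the
#' curve.
#'
#' @param object a \linkS4class{CountsTable} or \linkS4class{Multiplicities}.
#' @param beta positive concentration (vectorized).
#' @param center y-marginal center of the prior; defaults to the observed
#'   n_y/N.  An order-collapsed Multiplicities requires a symmetric center.
#' @return log-likelihood values, one per beta.
#' @export
logMarginalLikelihoodBeta <- function(object, beta, center = NULL) {
  if (any(beta <= 0)) stop("beta must be positive")
  center <- .centerOf(object, center)
  mm <- if (is(object, "Multiplicities")) object else
    multiplicities(object, collapse = length(unique(center)) == 1L)
  if (!mm@ordered && length(unique(center)) != 1L)
    stop("order-collapsed multiplicities require a symmetric center")
  pat <- mm@patterns
  tot <- rowSums(pat)
  vapply(beta, function(b) {
    a <- sweep(pat, 2L, b * center, "+")
    sum(mm@m * (lgamma(b) - lgamma(tot + b) +
                rowSums(lgamma(a)) - sum(lgamma(b * center))))
  }, 0)
}

#' Maximum of the beta marginal likelihood
#'
#' For a binary symmetric-center table in which no state holds more than two
#' samples, the maximizer has the closed form
#' \deqn{\beta^* = f_{11} / (1/2 - f_{11})}
#' with \eqn{\beta^* = +\infty} when \eqn{f_{11} \ge 1/2} (the y values look
#' independent) — f11 being the fraction of 2-count states split across both
#' y values.  Otherwise the maximum is located numerically on a log-spaced
#' grid refined by \code{optimize}.  With no coincidences the likelihood has
#' no peak and an error is raised; callers should then integrate over the
#' information-uniform prior on log beta.
#'
#' @param object a \linkS4class{CountsTable} or \linkS4class{Multiplicities}.
#' @param center prior center (defaults to the observed y marginal).
#' @param grid beta grid for the numeric search.
#' @return list with elements \code{beta} (positive value or Inf),
#'   \code{closedForm} (logical) and \code{flags} (character).
#' @export
betaMAP <- function(object, center = NULL, grid = .betaGridDefault()) {
  center <- .centerOf(object, center)
  mm <- if (is(object, "Multiplicities")) object else
    multiplicities(object, collapse = length(unique(center)) == 1L)
  if (coincidenceCount(mm) == 0L)
    stop("no coincidences: the beta likelihood has no peak ",
         "(integrate over the prior instead)")
  tot <- rowSums(mm@patterns)
  symc <- length(unique(center)) == 1L && mm@kY == 2L
  if (symc && max(tot) <= 2) {
    fr <- f11(mm)
    if (fr >= 0.5)
      return(list(beta = Inf, closedForm = TRUE, flags = "f11_ge_half"))
    if (fr == 0)
      return(list(beta = min(grid), closedForm = TRUE, flags = "boundary_low"))
    return(list(beta = fr / (0.5 - fr), closedForm = TRUE,
                flags = character()))
  }
  ll <- logMarginalLikelihoodBeta(mm, grid, center)
  i <- which.max(ll)
  # exact beta -> Inf limit of the log likelihood: every conditional is
  # pinned at the center, so each pattern contributes sum_y n_y log(c_y);
  # if no finite grid value beats it, the likelihood has no interior peak
  llInf <- sum(mm@m * (mm@patterns %*% log(center)))
  if (llInf >= ll[i] - 1e-9 * max(1, abs(ll[i])))
    return(list(beta = Inf, closedForm = FALSE, flags = "no_interior_max"))
  if (i == 1L)
    return(list(beta = grid[1L], closedForm = FALSE, flags = "boundary_low"))
  lo <- grid[max(i - 1L, 1L)]
  hi <- if (i == length(grid)) grid[i] * 100 else grid[i + 1L]
  opt <- optimize(function(lb) logMarginalLikelihoodBeta(mm, exp(lb), center),
                  lower = log(lo), upper = log(hi), maximum = TRUE,
                  tol = 1e-10)
  list(beta = exp(opt$maximum), closedForm = FALSE, flags = character())
}

#' Prior mean information
#'
#' Expected mutual information under the prior alone (no data):
#' \deqn{\langle I|\beta\rangle = H(\hat q_y) - \psi_0(\beta+1) +
#'       \sum_y \hat q_y\, \psi_0(\beta \hat q_y + 1)}
#' Strictly decreasing in beta, from H(center) as beta -> 0 to 0 as
#' beta -> Inf.
#'
#' @param beta non-negative concentration (vectorized; Inf allowed).
#' @param center simplex vector, the prior center (default symmetric binary).
#' @return prior mean information in nats.
#' @examples
#' priorMeanInformation(2)    # log(2) - 1/2
#' @export
priorMeanInformation <- function(beta, center = c(0.5, 0.5)) {
  .checkSimplex(center, "center")
  if (any(beta < 0)) stop("beta must be non-negative")
  h <- .entropyVec(center)
  out <- vapply(beta, function(b) {
    if (!is.finite(b)) return(0)
    h - digamma(b + 1) + sum(center * digamma(b * center + 1))
  }, 0)
  out
}

#' Posterior mean information
#'
#' The analytic posterior expectation of I given the counts and beta:
#' \deqn{\langle I|n,\beta\rangle = \hat H(Y) - \sum_x \frac{n_x}{N}\Big[
#'   \psi_0(\beta+n_x+1) - \sum_y \frac{\beta \hat q_y + n_{xy}}{\beta+n_x}
#'   \psi_0(\beta \hat q_y + n_{xy} + 1)\Big]}
#' where \eqn{\hat H(Y)} is the plug-in marginal entropy of Y.  For
#' well-sampled tables this converges to the plug-in information; with only
#' singleton states it reduces to the prior mean information.
#'
#' @param object a \linkS4class{CountsTable}.
#' @param beta positive concentration (vectorized; Inf gives the limit 0).
#' @param center prior center; defaults to the observed y marginal (in which
#'   case \eqn{\hat H(Y)} is the plug-in entropy; with an explicit center,
#'   H(center) is used).
#' @return posterior mean information in nats.
#' @export
posteriorMeanInformation <- function(object, beta, center = NULL) {
  stopifnot(is(object, "CountsTable"))
  if (any(beta < 0)) stop("beta must be positive")
  hY <- if (is.null(center)) .entropyVec(yFrequencies(object))
        else .entropyVec(center)
  center <- .centerOf(object, center)
  cts <- object@counts
  nx <- rowSums(cts); N <- sum(cts)
  vapply(beta, function(b) {
    if (!is.finite(b)) return(0)
    a <- sweep(cts, 2L, b * center, "+")
    A <- b + nx
    cond <- digamma(A + 1) - rowSums(a * digamma(a + 1)) / A
    hY - sum(nx / N * cond)
  }, 0)
}

#' Posterior variance of the information
#'
#' Under the fixed-beta posterior the conditionals of distinct x states are
#' independent Dirichlet(beta center + n_x.) vectors, q_x is held at n_x/N
#' and H(Y) at its plug-in value, so the variance of I is the weighted sum
#' of per-state entropy variances:
#' \deqn{\sigma^2(I|n,\beta) = \sum_x (n_x/N)^2\,
#'       \mathrm{Var}[H(q_{y|x})]}
#' with the Dirichlet entropy variance in closed form.  Replicating the same
#' multiplicity pattern over more states halves the weights quadratically,
#' so the variance scales as 1/k_x: the method gains confidence from many
#' available x states even when each is undersampled.
#'
#' @inheritParams posteriorMeanInformation
#' @return posterior variance in nats^2 (>= 0).
#' @export
posteriorVarInformation <- function(object, beta, center = NULL) {
  stopifnot(is(object, "CountsTable"))
  if (any(beta < 0)) stop("beta must be positive")
  center <- .centerOf(object, center)
  cts <- object@counts
  nx <- rowSums(cts); N <- sum(cts)
  vapply(beta, function(b) {
    if (!is.finite(b)) return(0)
    if (ncol(cts) == 2L) {
      v <- .dirEntropyVar2(cts[, 1L] + b * center[1L],
                           cts[, 2L] + b * center[2L])
    } else {
      a <- sweep(cts, 2L, b * center, "+")
      v <- apply(a, 1L, .dirEntropyVar)
    }
    sum((nx / N)^2 * v)
  }, 0)
}

# Grouped (multiplicity) evaluation of the posterior mean/variance; exact
# regrouping of the per-state sums, used on hot paths.
.postMeanMult <- function(mm, beta, center, hY) {
  pat <- mm@patterns
  tot <- rowSums(pat)
  w <- mm@m * tot / mm@N
  vapply(beta, function(b) {
    if (!is.finite(b)) return(0)
    a <- sweep(pat, 2L, b * center, "+")
    A <- b + tot
    cond <- digamma(A + 1) - rowSums(a * digamma(a + 1)) / A
    hY - sum(w * cond)
  }, 0)
}

.postVarMult <- function(mm, beta, center) {
  pat <- mm@patterns
  tot <- rowSums(pat)
  w <- mm@m * (tot / mm@N)^2
  vapply(beta, function(b) {
    if (!is.finite(b)) return(0)
    a <- sweep(pat, 2L, b * center, "+")
    A <- b + tot
    v <- if (ncol(pat) == 2L)
      .dirEntropyVar2(a[, 1L], a[, 2L])
    else apply(a, 1L, .dirEntropyVar)
    sum(w * v)
  }, 0)
}

#' Information-uniform prior on log beta
#'
#' Log density (in log beta) of the prior that makes the prior mean
#' information uniform over its range [0, H(center)]:
#' \deqn{p(\log\beta) = \frac{\beta\,|\psi_1(\beta+1) - \sum_y \hat q_y^2
#'   \psi_1(\beta \hat q_y + 1)|}{H(\hat q_y)}}
#' For the symmetric binary center this reduces to
#' \eqn{(\beta/2\log 2)\,|2\psi_1(\beta+1)-\psi_1(\beta/2+1)|}.  The density
#' integrates to 1 over beta in (0, Inf) because the prior information is a
#' strictly monotone map onto its range.
#'
#' @param beta positive concentration (vectorized).
#' @param center prior center.
#' @return log density values.
#' @export
logBetaPrior <- function(beta, center = c(0.5, 0.5)) {
  if (any(beta <= 0)) stop("beta must be positive")
  .checkSimplex(center, "center")
  h <- .entropyVec(center)
  vapply(beta, function(b) {
    d <- trigamma(b + 1) - sum(center^2 * trigamma(b * center + 1))
    log(b) + log(abs(d)) - log(h)
  }, 0)
}

#' Sample from the information-uniform prior on log beta
#'
#' Exact inverse-CDF sampling: the cumulative distribution of log beta is
#' 1 - priorMeanInformation(beta)/H(center), a strictly monotone map, so a
#' uniform draw is inverted with \code{uniroot}.
#'
#' @param n number of draws.
#' @param center prior center.
#' @param seed optional integer seed.
#' @return numeric vector of log-beta draws.
#' @export
sampleLogBetaPrior <- function(n, center = c(0.5, 0.5), seed = NULL) {
  .setSeed(seed)
  h <- .entropyVec(center)
  u <- pmin(pmax(runif(n), 1e-12), 1 - 1e-12)
  vapply(u, function(ui) {
    uniroot(function(lb) priorMeanInformation(exp(lb), center) - (1 - ui) * h,
            lower = -34, upper = 34, tol = 1e-10)$root
  }, 0)
}

#' Log marginal likelihood of the X margin given the DP concentration
#'
#' Under a Dirichlet-process prior on q_x with concentration alpha, the
#' marginal likelihood of observing k1 distinct states in N samples is
#' \deqn{p(n_x|\alpha) \propto \frac{\Gamma(1+\alpha)}{\Gamma(N+\alpha)}
#'       \alpha^{k_1 - 1}}
#' (the tail-free special case d = 0 of a Pitman-Yor prior).
#'
#' @param object a \linkS4class{CountsTable}.
#' @param alpha positive concentration (vectorized).
#' @return log-likelihood values (up to an additive constant).
#' @export
logMarginalLikelihoodAlpha <- function(object, alpha) {
  stopifnot(is(object, "CountsTable"))
  if (any(alpha <= 0)) stop("alpha must be positive")
  N <- sampleTotal(object); k1 <- nrow(object@counts)
  # log Gamma(1+a) - log Gamma(N+a) = -sum_{j=1}^{N-1} log(a+j); the exact
  # sum avoids the cancellation that swamps the lgamma difference at a >> N
  if (N <= 5000) {
    j <- seq_len(N - 1)
    vapply(alpha, function(a) -sum(log(a + j)) + (k1 - 1) * log(a), 0)
  } else {
    lgamma(1 + alpha) - lgamma(N + alpha) + (k1 - 1) * log(alpha)
  }
}

#' MAP of the DP concentration on a log grid
#'
#' @param object a \linkS4class{CountsTable}.
#' @param grid alpha grid (default 300 log-spaced points in [1e-2, 1e8]).
#' @return list with \code{alpha} and \code{flags}; a likelihood increasing
#'   up to the top of the grid (no coincidences in X) is flagged
#'   "divergent".
#' @export
alphaMAP <- function(object, grid = exp(seq(log(1e-2), log(1e8),
                                            length.out = 300L))) {
  ll <- logMarginalLikelihoodAlpha(object, grid)
  i <- which.max(ll)
  if (i == length(grid))
    return(list(alpha = grid[i], flags = "divergent"))
  if (i == 1L)
    return(list(alpha = grid[1L], flags = "boundary_low"))
  opt <- optimize(function(la) logMarginalLikelihoodAlpha(object, exp(la)),
                  lower = log(grid[i - 1L]), upper = log(grid[i + 1L]),
                  maximum = TRUE, tol = 1e-10)
  list(alpha = exp(opt$maximum), flags = character())
}

#' Posterior mean information with the DP correction for unobserved states
#'
#' Mixing the observed-state posterior with the prior according to the
#' pseudo-count weight of the Dirichlet-process prior on q_x:
#' \deqn{\langle I|n,\alpha,\beta\rangle = \frac{N}{N+\alpha}
#'   \langle I|n,\beta\rangle_{obs} + \frac{\alpha}{N+\alpha}
#'   \langle I|\beta\rangle_{prior}}
#' Reduces to the observed-state posterior as alpha -> 0 and to the prior
#' mean as alpha -> Inf.
#'
#' @inheritParams posteriorMeanInformation
#' @param alpha positive DP concentration.
#' @return posterior mean information in nats.
#' @export
posteriorMeanInformationDP <- function(object, beta, alpha, center = NULL) {
  if (alpha <= 0) stop("alpha must be positive")
  ctr <- .centerOf(object, center)
  N <- sampleTotal(object)
  obs <- posteriorMeanInformation(object, beta, center)
  pri <- priorMeanInformation(beta, ctr)
  N / (N + alpha) * obs + alpha / (N + alpha) * pri
}

#' Estimate the mutual information of a contingency table
#'
#' The full pipeline: builds the multiplicity statistics, locates the
#' maximum of the beta marginal likelihood (closed form where available) and
#' evaluates the posterior mean and variance of I there.  When the table
#' holds at most two coincident states the likelihood peak is weak and the
#' posterior is instead integrated over the information-uniform prior on
#' log beta (trapezoid rule on the grid); with no coincidences at all the
#' integration is the only option and is flagged.  An optional
#' Dirichlet-process correction accounts for never-observed x states via the
#' MAP concentration alpha.
#'
#' @param object a \linkS4class{CountsTable}.
#' @param method "auto" (default), "map" or "integrate".  "auto" uses the
#'   MAP unless there are two or fewer coincidences.
#' @param dp logical; apply the DP correction for unobserved x states.
#' @param units "nats" (default) or "bits".
#' @param center optional prior center overriding the observed y marginal.
#' @param betaGrid beta grid for likelihood evaluation and integration.
#' @return a \linkS4class{PosteriorSummary}.
#' @examples
#' ct <- countsFromPairs(rep(letters[1:6], each = 2),
#'                       c(0,0, 1,1, 0,0, 1,1, 0,1, 0,1))
#' estimateMI(ct)
#' @export
estimateMI <- function(object, method = c("auto", "map", "integrate"),
                       dp = FALSE, units = c("nats", "bits"),
                       center = NULL, betaGrid = .betaGridDefault()) {
  stopifnot(is(object, "CountsTable"))
  method <- match.arg(method)
  units <- match.arg(units)
  flags <- character()

  cts <- object@counts
  ny <- colSums(cts)
  if (any(ny == 0)) {
    warning("dropping y state(s) with zero counts: ",
            paste(colnames(cts)[ny == 0], collapse = ", "))
    flags <- c(flags, "zero_count_y_dropped")
    object <- countsTable(cts[, ny > 0, drop = FALSE])
    cts <- object@counts
    ny <- colSums(cts)
  }
  N <- sum(cts)
  if (ncol(cts) < 2L) {
    warning("Y has a single state: information is identically zero")
    return(new("PosteriorSummary", iMean = 0, iSd = 0, betaMap = NA_real_,
               alphaMap = NA_real_, betaGrid = data.frame(),
               method = method, hYHat = 0, units = units, nObs = N,
               k1 = nrow(cts), coincidences = 0L, f11 = NA_real_,
               warnings = c(flags, "k_y_1_zero_information")))
  }
  if (min(ny) < 10) {
    warning("smallest y margin is ", min(ny),
            ": the method assumes Y well sampled")
    flags <- c(flags, "y_undersampled")
  }

  ctr <- .centerOf(object, center)
  hY <- if (is.null(center)) .entropyVec(ny / N) else .entropyVec(ctr)
  symc <- length(unique(ctr)) == 1L
  mm <- multiplicities(object, collapse = symc)
  coinc <- coincidenceCount(mm)
  fr <- f11(mm)

  if (coinc == 0L) {
    flags <- c(flags, "no_coincidences_prior_integration")
    method <- "integrate"
  } else if (method == "auto") {
    if (coinc <= 2L) {
      flags <- c(flags, "few_coincidences_integrated")
      method <- "integrate"
    } else method <- "map"
  }

  ll <- logMarginalLikelihoodBeta(mm, betaGrid, ctr)
  bmap <- if (coinc > 0L) betaMAP(mm, ctr, betaGrid) else
    list(beta = NA_real_, flags = character())
  flags <- c(flags, bmap$flags)

  amap <- NA_real_
  alphaW <- 0
  if (dp) {
    am <- alphaMAP(object)
    if ("divergent" %in% am$flags) {
      warning("alpha likelihood has no peak (no coincidences in X): ",
              "DP correction disabled")
      flags <- c(flags, "alpha_divergent_dp_disabled")
    } else {
      amap <- am$alpha
      alphaW <- amap / (N + amap)
    }
  }
  mixDP <- function(mu, b)   # DP mixing of observed posterior with prior
    (1 - alphaW) * mu + alphaW * priorMeanInformation(b, ctr)

  if (method == "map") {
    b <- bmap$beta
    if (!is.finite(b)) {
      flags <- c(flags, "beta_infinite")
      iMean <- mixDP(0, 1e12)
      iVar <- 0
    } else {
      iMean <- mixDP(.postMeanMult(mm, b, ctr, hY), b)
      iVar <- .postVarMult(mm, b, ctr)
    }
    betaRep <- b
  } else {
    lw <- ll + logBetaPrior(betaGrid, ctr)
    tw <- rep(1, length(betaGrid)); tw[c(1L, length(tw))] <- 0.5
    w <- exp(lw - max(lw)) * tw
    w <- w / sum(w)
    mu <- mixDP(.postMeanMult(mm, betaGrid, ctr, hY), betaGrid)
    v <- .postVarMult(mm, betaGrid, ctr)
    iMean <- sum(w * mu)
    iVar <- max(sum(w * (v + mu^2)) - iMean^2, 0)
    betaRep <- if (coinc > 0L) bmap$beta else NA_real_
  }

  iMean <- max(iMean, 0)
  scale <- if (units == "bits") 1 / log(2) else 1
  new("PosteriorSummary",
      iMean = iMean * scale, iSd = sqrt(iVar) * scale,
      betaMap = betaRep, alphaMap = amap,
      betaGrid = data.frame(logBeta = log(betaGrid), logLik = ll),
      method = method, hYHat = hY * scale, units = units, nObs = N,
      k1 = nrow(cts), coincidences = as.integer(coinc), f11 = fr,
      warnings = unique(flags))
}

setMethod("show", "PosteriorSummary", function(object) {
  cat(sprintf("PosteriorSummary: I = %.4f +/- %.4f %s (method: %s)\n",
              object@iMean, object@iSd, object@units, object@method))
  cat(sprintf("  beta* = %s, N = %d, k1 = %d, coincidences = %d, f11 = %s\n",
              format(object@betaMap), as.integer(object@nObs), object@k1,
              object@coincidences, format(object@f11)))
  if (!is.na(object@alphaMap))
    cat(sprintf("  alpha* = %.3g (DP correction applied)\n", object@alphaMap))
  if (length(object@warnings))
    cat("  flags:", paste(object@warnings, collapse = ", "), "\n")
})

#' Serialize a PosteriorSummary to JSON
#'
#' @param object a \linkS4class{PosteriorSummary}.
#' @param path optional file path; if NULL the JSON string is returned.
#' @export
summaryJSON <- function(object, path = NULL) {
  stopifnot(is(object, "PosteriorSummary"))
  out <- list(I_mean = object@iMean, I_sd = object@iSd,
              units = object@units, beta_map = object@betaMap,
              alpha_map = object@alphaMap, method = object@method,
              N = object@nObs, k1 = object@k1,
              coincidences = object@coincidences, f11 = object@f11,
              warnings = as.list(object@warnings))
  if (is.null(path))
    return(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, na = "null"))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
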