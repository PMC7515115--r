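# Simulation experiments: bias of the estimator versus sample size and
# versus the underlying information, and the Bayesian calibration study
# that groups simulated cases by multiplicity class.

.estimatorFuns <- function(names) {
  all <- list(
    posterior = function(ct) estimateMI(ct)@iMean,
    plugin = function(ct) pluginInformation(ct))
  if (!all(names %in% names(all)))
    stop("unknown estimator(s): ", paste(setdiff(names, names(all)),
                                         collapse = ", "))
  all[names]
}

#' Estimator bias as a function of the number of samples
#'
#' For each sample size in \code{nGrid}, draws \code{replicates} independent
#' contingency tables from the model and records the mean and standard
#' deviation of each estimator, alongside the exact information of the
#' model.  A per-replicate estimator failure is recorded as NA, not fatal.
#'
#' @param model a \linkS4class{JointModel} or \linkS4class{ParityModel}.
#' @param nGrid sample sizes (default c(120, 250, 500, 1000)).
#' @param replicates replicate tables per grid point (default 50).
#' @param estimators character subset of c("posterior", "plugin").
#' @param seed optional integer seed; results are reproducible given
#'   (model, seed).
#' @return data.frame with columns n, estimator, mean, sd, trueI,
#'   replicates.
#' @export
biasVsSamples <- function(model, nGrid = c(120, 250, 500, 1000),
                          replicates = 50L,
                          estimators = c("posterior", "plugin"),
                          seed = NULL) {
  if (replicates < 2L) stop("need at least 2 replicates")
  .setSeed(seed)
  funs <- .estimatorFuns(estimators)
  truth <- trueInformation(model)
  rows <- list()
  for (n in nGrid) {
    est <- matrix(NA_real_, replicates, length(funs),
                  dimnames = list(NULL, names(funs)))
    for (r in seq_len(replicates)) {
      ct <- suppressWarnings(sampleCounts(model, n))
      for (e in names(funs))
        est[r, e] <- tryCatch(suppressWarnings(funs[[e]](ct)),
                              error = function(err) NA_real_)
    }
    for (e in names(funs))
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, estimator = e, mean = mean(est[, e], na.rm = TRUE),
        sd = sd(est[, e], na.rm = TRUE), trueI = truth,
        replicates = replicates)
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  out
}

#' Estimator bias as a function of the underlying information
#'
#' Sweeps the parameter controlling the information of a benchmark family —
#' the conditional concentration beta for "py_beta" (the x marginal is
#' sampled once and reused across the sweep), the sigmoid gain for "sphere",
#' or the odd-parity level q0 for "parity" — drawing fresh conditionals and
#' \code{replicates} tables of \code{nSamples} at each point.
#'
#' @param family one of "py_beta", "sphere", "parity".
#' @param sweep parameter values; defaults per family: 5 log-spaced betas in
#'   [0.04, 14]; gains in [0.05, 5]; q0 in [0.01, 0.4].
#' @param nSamples samples per table (default 500 for py_beta, 2000
#'   otherwise).
#' @param replicates replicate tables per sweep point (default 50).
#' @param estimators character subset of c("posterior", "plugin").
#' @param seed optional integer seed.
#' @param ... family parameters passed to the model constructor.
#' @return data.frame with columns sweep, trueI, estimator, mean, sd.
#' @export
biasVsInformation <- function(family = c("py_beta", "sphere", "parity"),
                              sweep = NULL, nSamples = NULL,
                              replicates = 50L,
                              estimators = c("posterior", "plugin"),
                              seed = NULL, ...) {
  family <- match.arg(family)
  .setSeed(seed)
  funs <- .estimatorFuns(estimators)
  dots <- list(...)
  if (is.null(sweep))
    sweep <- switch(family,
      py_beta = exp(seq(log(0.04), log(14), length.out = 5)),
      sphere = exp(seq(log(0.05), log(5), length.out = 5)),
      parity = seq(0.01, 0.4, length.out = 5))
  if (is.null(nSamples)) nSamples <- if (family == "py_beta") 500L else 2000L
  qx <- NULL
  if (family == "py_beta") {
    d <- if (is.null(dots$d)) 0.55 else dots$d
    alpha <- if (is.null(dots$alpha)) 50 else dots$alpha
    maxAtoms <- if (is.null(dots$maxAtoms)) 2e5 else dots$maxAtoms
    qx <- samplePYMarginal(d, alpha, maxAtoms = maxAtoms)
  }
  rows <- list()
  for (sv in sweep) {
    model <- switch(family,
      py_beta = jointModel(qx, sampleBetaConditionals(length(qx), sv),
                           meta = list(family = "py_beta", beta = sv)),
      sphere = do.call(makeSphereModel,
                       c(list(gain = sv),
                         dots[intersect(names(dots), "offset")])),
      parity = do.call(makeParityModel, c(list(q0 = sv), dots[
        intersect(names(dots), c("p", "D", "hashKey"))])))
    truth <- trueInformation(model)
    est <- matrix(NA_real_, replicates, length(funs),
                  dimnames = list(NULL, names(funs)))
    for (r in seq_len(replicates)) {
      ct <- suppressWarnings(sampleCounts(model, nSamples))
      for (e in names(funs))
        est[r, e] <- tryCatch(suppressWarnings(funs[[e]](ct)),
                              error = function(err) NA_real_)
    }
    for (e in names(funs))
      rows[[length(rows) + 1L]] <- data.frame(
        sweep = sv, trueI = truth, estimator = e,
        mean = mean(est[, e], na.rm = TRUE), sd = sd(est[, e], na.rm = TRUE))
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  out
}

## ---- calibration study ----------------------------------------------------

# Canonical class key from per-state binary counts (unordered patterns).
.multKeyBinary <- function(n1, n0) {
  hi <- pmax(n1, n0); lo <- pmin(n1, n0)
  lab <- paste0(hi, ":", lo)
  tab <- table(lab)
  pats <- strsplit(names(tab), ":", fixed = TRUE)
  tot <- vapply(pats, function(v) as.numeric(v[1L]) + as.numeric(v[2L]), 0)
  hi1 <- vapply(pats, function(v) as.numeric(v[1L]), 0)
  ord <- order(tot, hi1, decreasing = TRUE)
  paste(paste0(names(tab)[ord], "x", as.integer(tab)[ord]), collapse = "|")
}

# Parse a class key back into (hi, lo, m) pattern rows.
.parseMultKey <- function(key) {
  parts <- strsplit(strsplit(key, "|", fixed = TRUE)[[1L]], "[:x]")
  do.call(rbind, lapply(parts, function(v)
    c(hi = as.numeric(v[1L]), lo = as.numeric(v[2L]), m = as.numeric(v[3L]))))
}

# Integrated posterior mean and sd of I for a multiplicity class under the
# symmetric binary center, weighting the beta grid by the marginal
# likelihood and the information-uniform prior on log beta.
.classPrediction <- function(pat, N, betaGrid = .betaGridDefault()) {
  hi <- pat[, "hi"]; lo <- pat[, "lo"]; m <- pat[, "m"]
  tot <- hi + lo
  ll <- vapply(betaGrid, function(b)
    sum(m * (lgamma(b) - lgamma(tot + b) + lgamma(hi + b / 2) +
             lgamma(lo + b / 2) - 2 * lgamma(b / 2))), 0)
  lw <- ll + logBetaPrior(betaGrid)
  tw <- rep(1, length(betaGrid)); tw[c(1L, length(tw))] <- 0.5
  w <- exp(lw - max(lw)) * tw
  w <- w / sum(w)
  wState <- m * tot / N
  wVar <- m * (tot / N)^2
  mu <- vapply(betaGrid, function(b)
    log(2) - sum(wState * .dirEntropyMean2(hi + b / 2, lo + b / 2)), 0)
  v <- vapply(betaGrid, function(b)
    sum(wVar * .dirEntropyVar2(hi + b / 2, lo + b / 2)), 0)
  iMean <- sum(w * mu)
  iVar <- max(sum(w * (v + mu^2)) - iMean^2, 0)
  c(predMean = max(iMean, 0), predSd = sqrt(iVar))
}

#' Bayesian calibration of the posterior mean and spread
#'
#' Generates an ensemble of joint distributions — q_x from a Dirichlet
#' process with concentration drawn equiprobably from \code{alphas}, binary
#' conditionals Beta(beta/2, beta/2) with log beta drawn from the
#' information-uniform prior — and, from each, \code{setsPerModel}
#' independent sets of \code{nSamples} samples.  Every sampled case is
#' reduced to its multiplicity class; within each of the \code{topK} most
#' frequent classes the empirical mean and SD of the true information are
#' compared with the analytic posterior mean and SD given the class
#' (integrated over the log-beta prior).  Also reports the fraction of all
#' cases covered by the topK classes.
#'
#' @param nModels number of joint distributions (default 13500).
#' @param setsPerModel sample sets per distribution (default 5).
#' @param nSamples samples per set (default 40).
#' @param alphas candidate DP concentrations (default exp(4:6)).
#' @param topK number of leading classes to analyze (default 100).
#' @param truncation,maxAtoms stick-breaking controls for the DP draws.
#' @param predict logical; compute the analytic per-class predictions.
#' @param seed optional integer seed.
#' @return list with elements \code{classes} (data.frame: key, count,
#'   empMean, empSd, predMean, predSd), \code{coverage} (fraction of cases
#'   in the topK classes), \code{nCases}, and the generation parameters.
#' @export
calibrationStudy <- function(nModels = 13500L, setsPerModel = 5L,
                             nSamples = 40L, alphas = exp(4:6),
                             topK = 100L, truncation = 1e-8,
                             maxAtoms = 2e5, predict = TRUE, seed = NULL) {
  .setSeed(seed)
  nCases <- nModels * setsPerModel
  keys <- character(nCases)
  trueI <- numeric(nCases)
  case <- 0L
  for (mdl in seq_len(nModels)) {
    alpha <- alphas[sample.int(length(alphas), 1L)]
    beta <- exp(sampleLogBetaPrior(1L))
    qx <- samplePYMarginal(0, alpha, truncation, maxAtoms)
    K <- length(qx)
    q1 <- rbeta(K, beta / 2, beta / 2)
    qy <- sum(qx * q1)
    iModel <- .h2(qy) - sum(qx * .h2(q1))
    idx <- sample.int(K, setsPerModel * nSamples, replace = TRUE, prob = qx)
    for (s in seq_len(setsPerModel)) {
      si <- idx[((s - 1L) * nSamples + 1L):(s * nSamples)]
      nx <- tabulate(si, nbins = K)
      obs <- which(nx > 0)
      n1 <- rbinom(length(obs), nx[obs], q1[obs])
      case <- case + 1L
      keys[case] <- .multKeyBinary(n1, nx[obs] - n1)
      trueI[case] <- iModel
    }
  }
  tab <- sort(table(keys), decreasing = TRUE)
  topK <- min(topK, length(tab))
  top <- names(tab)[seq_len(topK)]
  coverage <- sum(tab[seq_len(topK)]) / nCases
  cls <- data.frame(key = top, count = as.integer(tab[seq_len(topK)]),
                    empMean = NA_real_, empSd = NA_real_,
                    predMean = NA_real_, predSd = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(topK)) {
    vals <- trueI[keys == top[i]]
    cls$empMean[i] <- mean(vals)
    if (length(vals) >= 2L) cls$empSd[i] <- sd(vals)
    if (predict) {
      pr <- .classPrediction(.parseMultKey(top[i]), nSamples)
      cls$predMean[i] <- pr["predMean"]
      cls$predSd[i] <- pr["predSd"]
    }
  }
  list(classes = cls, coverage = as.numeric(coverage), nCases = nCases,
       nModels = nModels, setsPerModel = setsPerModel, nSamples = nSamples,
       alphas = alphas, seed = seed)
}
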