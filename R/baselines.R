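#' Plug-in Shannon entropy
#'
#' Entropy of a probability vector in nats, with the convention
#' 0 log 0 = 0.  Frequencies may contain zeros; negative entries are an
#' error.
#'
#' @param freqs probability vector (must sum to 1 within 1e-9).
#' @return entropy in nats.
#' @examples
#' pluginEntropy(c(0.5, 0.5))   # log(2)
#' @export
pluginEntropy <- function(freqs) {
  .checkSimplex(freqs, "freqs")
  .entropyVec(freqs)
}

#' Plug-in mutual information of a contingency table
#'
#' Computes H(X) + H(Y) - H(X,Y) from the observed frequencies.  This naive
#' estimator is consistent but, in the undersampled regime, typically
#' over-estimates the information.  An optional first-order Miller-Madow
#' bias correction (subtracting (cells - rows - cols + 1)/(2N)) is offered
#' for context only; it is not part of the Bayesian estimator.
#'
#' @param object a \linkS4class{CountsTable}.
#' @param correction "none" (default) or "millermadow".
#' @return information in nats (>= 0 for "none").
#' @export
pluginInformation <- function(object, correction = c("none", "millermadow")) {
  stopifnot(is(object, "CountsTable"))
  correction <- match.arg(correction)
  cts <- object@counts
  N <- sum(cts)
  if (N < 1) stop("empty table")
  hx <- .entropyVec(rowSums(cts) / N)
  hy <- .entropyVec(colSums(cts) / N)
  hxy <- .entropyVec(as.vector(cts) / N)
  info <- hx + hy - hxy
  if (correction == "millermadow") {
    kxy <- sum(cts > 0); kx <- nrow(cts); ky <- sum(colSums(cts) > 0)
    info <- info - (kxy - kx - ky + 1) / (2 * N)
  }
  info
}

#' Construct an explicit ground-truth joint model
#'
#' @param qX probability vector over x states.
#' @param qCond matrix of conditional rows q_{y|x} (k_x by k_y).
#' @param meta optional metadata list.
#' @return a \linkS4class{JointModel}.
#' @examples
#' m <- jointModel(c(0.5, 0.5), rbind(c(1, 0), c(0, 1)))
#' trueInformation(m)   # log(2)
#' @export
jointModel <- function(qX, qCond, meta = list()) {
  new("JointModel", qX = as.numeric(qX), qCond = as.matrix(qCond), meta = meta)
}

#' @describeIn trueInformation Exact I from the explicit probabilities,
#'   computed as the q_x-weighted Kullback-Leibler divergence of each
#'   conditional from the y marginal.
#' @export
setMethod("trueInformation", "JointModel", function(model, ...) {
  qy <- as.vector(model@qX %*% model@qCond)
  lqy <- ifelse(qy > 0, log(qy), 0)
  kl <- rowSums(.xlogx(model@qCond)) - as.vector(model@qCond %*% lqy)
  sum(model@qX * kl)
})

#' @describeIn modelEntropies Exact entropies from the explicit probabilities.
#' @export
setMethod("modelEntropies", "JointModel", function(model, ...) {
  hx <- .entropyVec(model@qX)
  qy <- as.vector(model@qX %*% model@qCond)
  hy <- .entropyVec(qy)
  hygx <- -sum(model@qX * rowSums(.xlogx(model@qCond)))
  c(HX = hx, HY = hy, HYgX = hygx, HXY = hx + hygx,
    I = hy - hygx)
})

setMethod("show", "JointModel", function(object) {
  e <- modelEntropies(object)
  cat("JointModel:", length(object@qX), "x states,", ncol(object@qCond),
      "y states\n")
  cat(sprintf("  HX = %.4f, HY = %.4f, HXY = %.4f, I = %.4f nats\n",
              e["HX"], e["HY"], e["HXY"], e["I"]))
  if (length(object@meta))
    cat("  family:", if (!is.null(object@meta$family)) object@meta$family
        else "custom", "\n")
})
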