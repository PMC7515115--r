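#' @import methods
#' @importFrom stats rbeta rbinom rgamma rmultinom runif optimize uniroot integrate setNames sd var
#' @importFrom utils read.delim read.csv write.table head
NULL

#' CountsTable: observed contingency data for an (X, Y) pair
#'
#' Stores the observed joint counts n_xy for a discrete pair (X, Y), where X
#' is the (possibly severely undersampled) large-alphabet variable and Y the
#' small, well-sampled one.  Rows are observed x states (every stored row has
#' at least one count; unobserved x states are never stored, their posterior
#' weight enters only through the Dirichlet-process correction), columns are
#' the declared y states.  A declared y state that was never observed is kept
#' with a zero column so that readers can flag it.
#'
#' @slot counts numeric matrix of non-negative integers, x states in rows,
#'   y states in columns, with dimnames giving the opaque state labels.
#' @export
setClass("CountsTable", representation(counts = "matrix"))

setValidity("CountsTable", function(object) {
  cts <- object@counts
  if (!is.numeric(cts)) return("counts must be a numeric matrix")
  if (any(is.na(cts))) return("counts must not contain NA")
  if (any(cts < 0)) return("counts must be non-negative")
  if (any(abs(cts - round(cts)) > 1e-8)) return("counts must be integer-valued")
  if (is.null(rownames(cts)) || is.null(colnames(cts)))
    return("counts must carry x labels (rownames) and y labels (colnames)")
  if (anyDuplicated(rownames(cts))) return("duplicated x labels")
  if (anyDuplicated(colnames(cts))) return("duplicated y labels")
  if (nrow(cts) < 1L) return("need at least one observed x state")
  if (any(rowSums(cts) < 1)) return("every stored x state must have n_x >= 1")
  if (sum(cts) < 1) return("need at least one sample")
  TRUE
})

#' Multiplicities: sufficient statistics for the concentration hyper-parameter
#'
#' The multiplicity table counts how many x states share the same per-y count
#' pattern.  Patterns are the sufficient statistics for the concentration
#' beta: states sampled once (singletons) contribute a constant likelihood
#' factor, so only coincident states (n_x >= 2) shape the beta posterior.
#'
#' When \code{ordered} is TRUE the pattern columns are aligned with the y
#' states of the originating table (required for an asymmetric center); when
#' FALSE each pattern is sorted in decreasing order, the unordered convention
#' appropriate for a symmetric center.
#'
#' @slot patterns numeric matrix, one row per distinct count pattern.
#' @slot m integer vector of multiplicities (states per pattern).
#' @slot N total number of samples of the originating table.
#' @slot k1 number of observed x states.
#' @slot kY number of y states.
#' @slot ordered logical; FALSE when patterns are order-collapsed.
#' @slot center numeric; the y-marginal the patterns refer to.
#' @export
setClass("Multiplicities", representation(
  patterns = "matrix", m = "integer", N = "numeric", k1 = "integer",
  kY = "integer", ordered = "logical", center = "numeric"))

setValidity("Multiplicities", function(object) {
  if (nrow(object@patterns) != length(object@m))
    return("one multiplicity per pattern required")
  if (any(object@m < 1L)) return("multiplicities must be >= 1")
  if (sum(object@m) != object@k1) return("multiplicities must partition the k1 states")
  if (abs(sum(rowSums(object@patterns) * object@m) - object@N) > 1e-8)
    return("pattern totals times multiplicities must sum to N")
  if (ncol(object@patterns) != object@kY) return("pattern width must equal kY")
  if (length(object@center) != object@kY) return("center length must equal kY")
  TRUE
})

#' Virtual parent for ground-truth joint models
#' @export
setClass("MIModel", representation("VIRTUAL"))

#' JointModel: an explicit ground-truth joint distribution
#'
#' Holds the marginal q_x and the conditional rows q_{y|x} of a known joint
#' distribution, used to validate generators and to score estimators against
#' the exact mutual information.
#'
#' @slot qX numeric probability vector over x states.
#' @slot qCond numeric matrix (k_x by k_y); each row a conditional q_{y|x}.
#' @slot meta list of generator metadata (family, parameters, seed).
#' @export
setClass("JointModel", contains = "MIModel",
         representation(qX = "numeric", qCond = "matrix", meta = "list"))

setValidity("JointModel", function(object) {
  if (length(object@qX) != nrow(object@qCond))
    return("qX length must match the rows of qCond")
  if (any(object@qX < 0) || abs(sum(object@qX) - 1) > 1e-9)
    return("qX must be a probability vector")
  if (any(object@qCond < 0) || any(abs(rowSums(object@qCond) - 1) > 1e-9))
    return("rows of qCond must lie on the simplex")
  TRUE
})

#' ParityModel: lazy Bernoulli-parity mixture model
#'
#' X is a D-dimensional Bernoulli(p) binary vector (never enumerated); the
#' binary conditional q_{1|x} equals 1/2 for even-parity states and q0 or
#' 1 - q0 for odd-parity states, the branch assigned by a deterministic keyed
#' hash of the bit pattern so that both options occur with equal probability
#' across states while staying consistent within a run.
#'
#' @slot p Bernoulli success probability per component.
#' @slot D vector dimension.
#' @slot q0 odd-parity conditional level, in (0, 1/2].
#' @slot hashKey integer key mixed into the branch hash.
#' @export
setClass("ParityModel", contains = "MIModel",
         representation(p = "numeric", D = "numeric", q0 = "numeric",
                        hashKey = "numeric"))

setValidity("ParityModel", function(object) {
  if (object@p <= 0 || object@p >= 1) return("p must be in (0, 1)")
  if (object@D < 1) return("D must be >= 1")
  if (object@q0 <= 0 || object@q0 > 0.5) return("q0 must be in (0, 1/2]")
  TRUE
})

#' PosteriorSummary: result of a mutual-information estimate
#'
#' @slot iMean posterior mean information (nats or bits, see units).
#' @slot iSd posterior standard deviation of the information.
#' @slot betaMap maximum of the beta marginal likelihood (may be Inf).
#' @slot alphaMap MAP of the Dirichlet-process concentration, or NA.
#' @slot betaGrid data.frame with columns logBeta and logLik.
#' @slot method "map" or "integrate".
#' @slot hYHat plug-in marginal entropy of Y (same units as iMean).
#' @slot units "nats" or "bits".
#' @slot nObs total number of samples.
#' @slot k1 number of observed x states.
#' @slot coincidences number of x states with two or more samples.
#' @slot f11 fraction of 2-count states split across both y values (binary),
#'   NA when undefined.
#' @slot warnings character vector of diagnostic flags.
#' @export
setClass("PosteriorSummary", representation(
  iMean = "numeric", iSd = "numeric", betaMap = "numeric",
  alphaMap = "numeric", betaGrid = "data.frame", method = "character",
  hYHat = "numeric", units = "character", nObs = "numeric", k1 = "integer",
  coincidences = "integer", f11 = "numeric", warnings = "character"))

setValidity("PosteriorSummary", function(object) {
  if (object@iMean < -1e-9) return("posterior mean information must be non-negative")
  if (object@iSd < 0) return("posterior sd must be non-negative")
  if (!object@units %in% c("nats", "bits")) return("units must be nats or bits")
  TRUE
})
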