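#' Build a CountsTable from a count matrix
#'
#' @param counts non-negative integer matrix, x states in rows and y states
#'   in columns.  Rows with a zero total (never-observed x states) are
#'   dropped with a warning; all-zero columns (declared but unobserved y
#'   states) are kept and flagged downstream.
#' @param xIds,yIds optional state labels; default to the dimnames or to
#'   "x1..", "y1..".
#' @return a \linkS4class{CountsTable}.
#' @examples
#' ct <- countsTable(rbind(a = c(1, 1), b = c(2, 0)), yIds = c("0", "1"))
#' sampleTotal(ct)
#' @export
countsTable <- function(counts, xIds = NULL, yIds = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(xIds)) xIds <- rownames(counts)
  if (is.null(yIds)) yIds <- colnames(counts)
  if (is.null(xIds)) xIds <- paste0("x", seq_len(nrow(counts)))
  if (is.null(yIds)) yIds <- paste0("y", seq_len(ncol(counts)))
  dimnames(counts) <- list(as.character(xIds), as.character(yIds))
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warning(sum(empty), " x state(s) with zero counts dropped")
    counts <- counts[!empty, , drop = FALSE]
  }
  new("CountsTable", counts = counts)
}

#' Tally paired samples into a CountsTable
#'
#' @param x,y vectors of equal length with the sampled labels; coerced to
#'   character.  Rows and columns are ordered lexicographically.
#' @param yLevels optional declared y labels; levels never observed are kept
#'   as zero columns.
#' @return a \linkS4class{CountsTable}.
#' @examples
#' countsFromPairs(c("a", "a", "b", "b"), c(0, 1, 0, 0))
#' @export
countsFromPairs <- function(x, y, yLevels = NULL) {
  if (length(x) == 0L) stop("empty input: no sample pairs")
  if (length(x) != length(y)) stop("x and y must have equal length")
  x <- as.character(x); y <- as.character(y)
  ylv <- sort(unique(c(y, as.character(yLevels))))
  tab <- table(factor(x, levels = sort(unique(x))), factor(y, levels = ylv))
  m <- matrix(as.numeric(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  if (any(colSums(m) == 0))
    warning("declared y label(s) never observed: ",
            paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  new("CountsTable", counts = m)
}

## ---- accessors ------------------------------------------------------------

#' Accessors for CountsTable
#'
#' \code{countsMatrix} returns the raw count matrix; \code{xCounts} and
#' \code{yCounts} the margins n_x and n_y; \code{xFrequencies} and
#' \code{yFrequencies} the maximum-likelihood frequencies n_x/N and n_y/N.
#'
#' @param object a \linkS4class{CountsTable}.
#' @name countsAccessors
#' @aliases countsMatrix xIds yIds sampleTotal xCounts yCounts xFrequencies yFrequencies
NULL

#' @rdname countsAccessors
#' @export
setMethod("countsMatrix", "CountsTable", function(object) object@counts)
#' @rdname countsAccessors
#' @export
setMethod("xIds", "CountsTable", function(object) rownames(object@counts))
#' @rdname countsAccessors
#' @export
setMethod("yIds", "CountsTable", function(object) colnames(object@counts))
#' @rdname countsAccessors
#' @export
setMethod("sampleTotal", "CountsTable", function(object) sum(object@counts))
#' @rdname countsAccessors
#' @export
setMethod("xCounts", "CountsTable", function(object) rowSums(object@counts))
#' @rdname countsAccessors
#' @export
setMethod("yCounts", "CountsTable", function(object) colSums(object@counts))
#' @rdname countsAccessors
#' @export
setMethod("xFrequencies", "CountsTable",
          function(object) rowSums(object@counts) / sum(object@counts))
#' @rdname countsAccessors
#' @export
setMethod("yFrequencies", "CountsTable",
          function(object) colSums(object@counts) / sum(object@counts))

setMethod("show", "CountsTable", function(object) {
  cat("CountsTable:", nrow(object@counts), "observed x states,",
      ncol(object@counts), "y states, N =", sum(object@counts), "\n")
  ny <- colSums(object@counts)
  cat("  y margin:", paste(colnames(object@counts), ny, sep = "=",
                           collapse = ", "), "\n")
  nx <- rowSums(object@counts)
  cat("  coincidences (n_x >= 2):", sum(nx >= 2), "of", nrow(object@counts),
      "states\n")
})

## ---- multiplicities -------------------------------------------------------

#' @describeIn multiplicities Reduce a CountsTable to its multiplicity table.
#'
#' @param collapse if TRUE (the default when the y margin is balanced),
#'   patterns are order-collapsed (sorted decreasing), the unordered
#'   convention valid for a symmetric center; if FALSE patterns stay aligned
#'   with the y states, required when the center is asymmetric.
#' @export
setMethod("multiplicities", "CountsTable", function(object, collapse = NULL) {
  cts <- object@counts
  ny <- colSums(cts)
  if (is.null(collapse)) collapse <- length(unique(ny)) == 1L
  pat <- cts
  if (collapse)
    pat <- t(apply(pat, 1L, sort, decreasing = TRUE))
  if (ncol(cts) == 1L) pat <- matrix(pat, ncol = 1L)
  key <- apply(pat, 1L, paste, collapse = ",")
  tab <- table(key)
  first <- pat[match(names(tab), key), , drop = FALSE]
  ord <- do.call(order, c(split(first, col(first)),
                          list(decreasing = TRUE)))
  new("Multiplicities",
      patterns = unname(first[ord, , drop = FALSE]),
      m = as.integer(tab)[ord],
      N = sum(cts), k1 = nrow(cts), kY = ncol(cts),
      ordered = !collapse, center = unname(ny / sum(cts)))
})

#' Accessors for Multiplicities
#'
#' \code{coincidenceCount} is the number of x states with at least two
#' samples; \code{f11} the fraction of 2-count states with one count of each
#' y value (binary case; NA when there are no 2-count states);
#' \code{classKey} a canonical string naming the multiplicity class,
#' e.g. "2:0x3|1:0x30".
#'
#' @param object a \linkS4class{Multiplicities}.
#' @name multAccessors
#' @aliases coincidenceCount f11 classKey
NULL

#' @rdname multAccessors
#' @export
setMethod("coincidenceCount", "Multiplicities", function(object) {
  sum(object@m[rowSums(object@patterns) >= 2])
})

#' @rdname multAccessors
#' @export
setMethod("f11", "Multiplicities", function(object) {
  tot <- rowSums(object@patterns)
  two <- tot == 2
  if (!any(two)) return(NA_real_)
  m2 <- sum(object@m[two])
  m11 <- sum(object@m[two & apply(object@patterns, 1L, max) == 1])
  m11 / m2
})

#' @rdname multAccessors
#' @export
setMethod("classKey", "Multiplicities", function(object) {
  pat <- t(apply(object@patterns, 1L, sort, decreasing = TRUE))
  if (object@kY == 1L) pat <- matrix(pat, ncol = 1L)
  lab <- apply(pat, 1L, paste, collapse = ":")
  agg <- tapply(object@m, lab, sum)
  tot <- vapply(strsplit(names(agg), ":"), function(v) sum(as.numeric(v)), 0)
  ord <- order(tot, names(agg), decreasing = TRUE)
  paste(paste0(names(agg)[ord], "x", agg[ord]), collapse = "|")
})

#' Fraction of samples falling in r-count states
#'
#' Returns the named vector f_r: for each observed state total r, the
#' fraction of the N samples that fall in x states with exactly r counts.
#'
#' @param object a \linkS4class{Multiplicities}.
#' @return named numeric vector indexed by r.
#' @export
sampleFractions <- function(object) {
  stopifnot(is(object, "Multiplicities"))
  tot <- rowSums(object@patterns)
  fr <- tapply(tot * object@m, tot, sum) / object@N
  fr[order(as.numeric(names(fr)))]
}

setMethod("show", "Multiplicities", function(object) {
  cat("Multiplicities: N =", object@N, ", k1 =", object@k1,
      ", coincidences =", coincidenceCount(object), "\n")
  lab <- apply(object@patterns, 1L, paste, collapse = ",")
  cat("  ", paste0("m(", lab, ")=", object@m, collapse = "  "), "\n")
  if (object@kY == 2L) cat("  f11 =", format(f11(object)), "\n")
})

## ---- conditional entropy from multiplicities ------------------------------

#' Posterior mean conditional entropy from multiplicities (binary Y)
#'
#' Evaluates the multiplicity decomposition of the posterior mean conditional
#' entropy for a symmetric binary Y:
#' \deqn{\langle H_{Y|X}\rangle(\beta) = \sum_r f_r \sum_{n+n'=r} f_{nn'}
#'       H_{nn'}(\beta)}
#' where f_r is the fraction of samples in r-count states, f_{nn'} the
#' fraction of r-count states with split (n, n'), and H_{nn'} the posterior
#' mean entropy of a binary conditional after (n, n') counts under a
#' Beta(beta/2, beta/2) prior.  Identical (to float precision) to the
#' per-state conditional part of the posterior mean information.
#'
#' @param object a \linkS4class{Multiplicities} with kY = 2.
#' @param beta positive concentration (vectorized).
#' @return conditional entropy in nats, one value per beta.
#' @export
conditionalEntropyMultiplicities <- function(object, beta) {
  stopifnot(is(object, "Multiplicities"))
  if (object@kY != 2L)
    stop("the multiplicity decomposition is implemented for binary Y only")
  if (any(beta <= 0)) stop("beta must be positive")
  n1 <- object@patterns[, 1L]
  n2 <- object@patterns[, 2L]
  w <- object@m * (n1 + n2) / object@N   # = f_r * f_{nn'} aggregated
  vapply(beta, function(b) {
    sum(w * .dirEntropyMean2(n1 + b / 2, n2 + b / 2))
  }, 0)
}

#' Pattern entropy H_nn'(beta)
#'
#' Posterior mean entropy of a binary conditional observed with counts
#' (n, n') under a symmetric Beta(beta/2, beta/2) prior.  Satisfies
#' H_00 = H_10 (a lone count carries no evidence of imbalance).
#'
#' @param n,n1 the two counts.
#' @param beta positive concentration.
#' @return entropy in nats.
#' @export
patternEntropy <- function(n, n1, beta) {
  if (any(beta <= 0)) stop("beta must be positive")
  .dirEntropyMean2(n + beta / 2, n1 + beta / 2)
}

## ---- file formats ---------------------------------------------------------

#' Read and write contingency data
#'
#' \code{readCountsLong} reads a long TSV with header columns \code{x_id},
#' \code{y_id}, \code{count}; \code{readCountsDense} a dense CSV (first
#' column x labels, remaining columns y states); \code{readCountsPairs} a
#' two-column whitespace-separated sample-pair file.  \code{writeCountsLong}
#' writes the long format back; the round trip is exact.
#'
#' @param path file path.
#' @return a \linkS4class{CountsTable} (readers), invisibly \code{path}
#'   (writer).
#' @name countsIO
NULL

#' @rdname countsIO
#' @export
readCountsLong <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "numeric"))
  if (!all(c("x_id", "y_id", "count") %in% names(df)))
    stop("long format requires header columns x_id, y_id, count")
  df <- stats::aggregate(count ~ x_id + y_id, df, sum)
  xlv <- sort(unique(df$x_id)); ylv <- sort(unique(df$y_id))
  m <- matrix(0, length(xlv), length(ylv), dimnames = list(xlv, ylv))
  m[cbind(match(df$x_id, xlv), match(df$y_id, ylv))] <- df$count
  countsTable(m)
}

#' @rdname countsIO
#' @export
readCountsDense <- function(path) {
  df <- read.csv(path, header = TRUE, row.names = 1, check.names = FALSE)
  countsTable(as.matrix(df))
}

#' @rdname countsIO
#' @export
readCountsPairs <- function(path) {
  df <- read.table(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("pair format requires two whitespace-separated columns")
  countsFromPairs(df[[1L]], df[[2L]])
}

#' @rdname countsIO
#' @param object a \linkS4class{CountsTable}.
#' @export
writeCountsLong <- function(object, path) {
  stopifnot(is(object, "CountsTable"))
  cts <- object@counts
  idx <- which(cts > 0, arr.ind = TRUE)
  df <- data.frame(x_id = rownames(cts)[idx[, 1L]],
                   y_id = colnames(cts)[idx[, 2L]],
                   count = cts[idx])
  df <- df[order(df$x_id, df$y_id), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dump a multiplicity table as JSON for diagnostics
#'
#' @param object a \linkS4class{Multiplicities}.
#' @param path file path.
#' @export
writeMultiplicitiesJSON <- function(object, path) {
  stopifnot(is(object, "Multiplicities"))
  out <- list(
    N = object@N, k1 = object@k1, kY = object@kY,
    ordered = object@ordered, center = object@center,
    coincidences = coincidenceCount(object), f11 = f11(object),
    classKey = classKey(object),
    patterns = apply(object@patterns, 1L, paste, collapse = ","),
    m = object@m)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
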