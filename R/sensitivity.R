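#' @include scoring.R
NULL

#' Latin hypercube sample of parameter multipliers
#'
#' Stratified uniform sampling on [low, high] per parameter: each column
#' holds exactly one sample in each of n equiprobable strata, with the
#' within-stratum positions and the stratum permutations drawn
#' reproducibly from the seed.
#'
#' @param parameterIds parameters to vary.
#' @param nSamples number of samples (>= 2).
#' @param low,high multiplier range (default 0.5 to 2).
#' @param seed integer seed.
#' @return an \code{LHSDesign}.
#' @export
lhsSample <- function(parameterIds, nSamples, low = 0.5, high = 2,
                      seed = 1L) {
  if (low >= high) stop("low must be < high")
  if (nSamples < 2) stop("need at least 2 samples")
  u <- withr::with_seed(as.integer(seed),
                        lhs::randomLHS(nSamples, length(parameterIds)))
  m <- low + u * (high - low)
  colnames(m) <- parameterIds
  new("LHSDesign", parameterIds = parameterIds, multipliers = m,
      range = c(low, high), seed = as.integer(seed))
}

#' Evaluate model outputs over an LHS design
#'
#' For each sample, scales the base parameters by the row's multipliers,
#' runs the stimulus protocol (default OGD 6 h / reoxygenation 24 h), and
#' computes the module outputs and the cell-function score, summarized at
#' the protocol endpoint or as area under the curve. Failed simulations
#' are recorded as missing and reported; more than \code{maxFailFraction}
#' failures aborts the analysis.
#'
#' @param network a ReactionNetwork.
#' @param baseParams ParameterSet.
#' @param design an LHSDesign.
#' @param protocol a StimulusProtocol (default OGD 6 h / R 24 h).
#' @param outputs output ids among inflammation, growth, tight_junction,
#'   cell_function.
#' @param horizonStat "endpoint" or "auc".
#' @param state quiescent starting state.
#' @param settings integration settings.
#' @param maxFailFraction failure tolerance.
#' @return matrix samples x outputs with NA rows for failures; the failure
#'   count is attached as attribute "failures".
#' @export
evaluateDesign <- function(network, baseParams, design,
                           protocol = makeOGDRProtocol(6, 24),
                           outputs = c("inflammation", "growth",
                                       "tight_junction", "cell_function"),
                           horizonStat = c("endpoint", "auc"),
                           state = initialState(network),
                           settings = simSettings(),
                           maxFailFraction = 0.05) {
  horizonStat <- match.arg(horizonStat)
  m <- design@multipliers
  out <- matrix(NA_real_, nrow(m), length(outputs),
                dimnames = list(NULL, outputs))
  fails <- 0L
  for (i in seq_len(nrow(m))) {
    p <- scaleParameters(baseParams, m[i, ])
    res <- tryCatch({
      traj <- runProtocol(network, p, state, protocol, settings)
      base <- stimulusBaseline(traj)
      series <- lapply(outputs, function(o) {
        if (o == "cell_function")
          cellFunctionScore(traj, base)@cellFunction
        else moduleOutput(traj, o, base)
      })
      sel <- traj@times >= 0
      vapply(series, function(y) {
        if (horizonStat == "endpoint") y[length(y)]
        else { tt <- traj@times[sel]; yy <- y[sel]
               sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2) }
      }, numeric(1))
    }, error = function(e) NULL)
    if (is.null(res)) fails <- fails + 1L else out[i, ] <- res
  }
  if (fails / nrow(m) > maxFailFraction)
    stop("analysis error: ", fails, "/", nrow(m), " samples failed")
  if (fails) message(fails, " sample(s) failed and were excluded")
  attr(out, "failures") <- fails
  out
}

# rank-based partial correlation of each column of X against y, via the
# inverse correlation matrix of [rank(X), rank(y)]; falls back to explicit
# rank regressions when the correlation matrix is singular (e.g. an output
# identical to one parameter)
.prccVector <- function(X, y) {
  R <- cbind(apply(X, 2, rank), rank(y))
  C <- stats::cor(R)
  k <- ncol(X)
  P <- tryCatch(solve(C), error = function(e) NULL)
  if (!is.null(P)) {
    out <- numeric(k)
    for (j in seq_len(k))
      out[j] <- -P[j, k + 1] / sqrt(P[j, j] * P[k + 1, k + 1])
    return(out)
  }
  out <- vapply(seq_len(k), function(j) {
    others <- R[, setdiff(seq_len(k), j), drop = FALSE]
    e1 <- if (ncol(others)) stats::resid(stats::lm(R[, j] ~ others))
          else R[, j] - mean(R[, j])
    e2 <- if (ncol(others)) stats::resid(stats::lm(R[, k + 1] ~ others))
          else R[, k + 1] - mean(R[, k + 1])
    if (stats::sd(e1) == 0 || stats::sd(e2) == 0) return(NA_real_)
    stats::cor(e1, e2)
  }, numeric(1))
  if (anyNA(out)) stop("numerical error: collinear design columns")
  out
}

#' Partial rank correlation coefficients of a design
#'
#' Rank-transforms inputs and outputs; each parameter's PRCC is the
#' Pearson correlation between the residuals of its ranks and of the
#' output ranks after regressing both on all other parameters' ranks.
#' P-values use the t approximation with df = n - 2 - (k - 1). Constant
#' outputs yield PRCC 0 with p = 1. Incomplete samples (failed
#' simulations) are excluded listwise.
#'
#' @param design an LHSDesign.
#' @param outputs matrix samples x outputs from
#'   \code{\link{evaluateDesign}}.
#' @return a \code{SensitivityResult} with raw and Benjamini-Hochberg
#'   adjusted p-values.
#' @export
prcc <- function(design, outputs) {
  X <- design@multipliers
  keep <- stats::complete.cases(outputs)
  X <- X[keep, , drop = FALSE]
  Y <- outputs[keep, , drop = FALSE]
  n <- nrow(X)
  if (n < 10) stop("need at least 10 complete samples")
  k <- ncol(X)
  prccM <- matrix(0, k, ncol(Y),
                  dimnames = list(design@parameterIds, colnames(Y)))
  pM <- matrix(1, k, ncol(Y), dimnames = dimnames(prccM))
  df <- n - 2 - (k - 1)
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    if (stats::sd(y) == 0) {
      message("output ", colnames(Y)[j], " is constant; PRCC set to 0")
      next
    }
    r <- .prccVector(X, y)
    r <- pmin(pmax(r, -1), 1)
    prccM[, j] <- r
    tstat <- r * sqrt(pmax(df, 1) / pmax(1 - r^2, 1e-300))
    pM[, j] <- 2 * stats::pt(-abs(tstat), df = pmax(df, 1))
  }
  pAdj <- apply(pM, 2, stats::p.adjust, method = "BH")
  dimnames(pAdj) <- dimnames(pM)
  new("SensitivityResult", parameterIds = design@parameterIds,
      outputIds = colnames(Y), prcc = prccM, pValues = pM,
      pAdjusted = pAdj, nSamples = as.integer(n))
}

#' Rank intervention targets by PRCC magnitude
#'
#' Parameters with p below \code{alpha} are sorted by |PRCC| descending
#' (ties broken lexicographically by parameter id).
#'
#' @param result a SensitivityResult.
#' @param outputId one of the result's output ids.
#' @param topK maximum entries returned.
#' @param alpha significance cutoff on the raw p-value.
#' @return data.frame(parameter, prcc, p) ordered by |PRCC|.
#' @export
rankTargets <- function(result, outputId, topK = 10, alpha = 0.05) {
  j <- match(outputId, result@outputIds)
  if (is.na(j)) stop("unknown output id: ", outputId)
  df <- data.frame(parameter = result@parameterIds,
                   prcc = result@prcc[, j], p = result@pValues[, j],
                   stringsAsFactors = FALSE, row.names = NULL)
  df <- df[df$p < alpha, , drop = FALSE]
  df <- df[order(-abs(df$prcc), df$parameter), , drop = FALSE]
  utils::head(df, topK)
}

#' Export sensitivity results as tidy CSV
#' @param result a SensitivityResult.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeSensitivityCSV <- function(result, file) {
  rows <- do.call(rbind, lapply(seq_along(result@outputIds), function(j)
    data.frame(parameter = result@parameterIds,
               output = result@outputIds[j], prcc = result@prcc[, j],
               p = result@pValues[, j], p_adj = result@pAdjusted[, j],
               n = result@nSamples, stringsAsFactors = FALSE)))
  rownames(rows) <- NULL
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}
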