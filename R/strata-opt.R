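#' Combined FDR across strata at given thresholds
#'
#' The combined FDR is the sum of expected false positives across strata
#' divided by the total expected number of predictions:
#' sum(t_i pi0_i N_i) / sum(F_i(t_i) N_i).
#'
#' @param strata a \linkS4class{StratumCollection}.
#' @param thresholds numeric vector, one p-value threshold per stratum.
#' @return the combined FDR (a probability).
#' @export
combinedFdr <- function(strata, thresholds) {
  stopifnot(is(strata, "StratumCollection"),
            length(thresholds) == length(strata@specs))
  num <- 0; den <- 0
  for (i in seq_along(strata@specs)) {
    sp <- strata@specs[[i]]; t <- thresholds[i]
    num <- num + t * sp@pi0 * sp@nTotal
    den <- den + mixtureCdf(sp, t) * sp@nTotal
  }
  if (den <= 0)
    stop("no predictions: all thresholds zero (combined FDR undefined)")
  num / den
}

# F_i(t) N-free closed form; F(0) = 0 handled without 0^a warnings.
mixtureCdf <- function(spec, t) {
  ifelse(t <= 0, 0, spec@pi0 * t + (1 - spec@pi0) * t^spec@altShape)
}

#' Expected number of predictions across strata
#'
#' @inheritParams combinedFdr
#' @return sum of F_i(t_i) * N_i.
#' @export
expectedPredictions <- function(strata, thresholds) {
  stopifnot(is(strata, "StratumCollection"),
            length(thresholds) == length(strata@specs))
  sum(vapply(seq_along(strata@specs), function(i) {
    sp <- strata@specs[[i]]
    mixtureCdf(sp, thresholds[i]) * sp@nTotal
  }, numeric(1)))
}

# Invert lFDR_i(t) = lambda for one stratum.  For pi0 < 1 and a < 1 the
# lFDR is strictly increasing in t with infimum 0, and the inverse has the
# closed form t = [pi0 (1 - lambda) / (lambda (1 - pi0) a)]^(1/(a-1)).
# Degenerate strata (constant lFDR): threshold is all-or-nothing.
invertLfdr <- function(spec, lambda) {
  pi0 <- spec@pi0; a <- spec@altShape
  if (lambda <= 0) return(0)
  if (pi0 == 0) return(1)                  # lFDR identically 0
  if (pi0 == 1) return(if (lambda >= 1) 1 else 0)  # lFDR identically 1
  if (a == 1) return(if (lambda >= pi0) 1 else 0)  # lFDR identically pi0
  lfdrAt1 <- pi0 / (pi0 + (1 - pi0) * a)
  if (lambda >= lfdrAt1) return(1)
  t <- (pi0 * (1 - lambda) / (lambda * (1 - pi0) * a))^(1 / (a - 1))
  min(max(t, 0), 1)
}

equalLfdrSolution <- function(strata, lambda) {
  vapply(strata@specs, invertLfdr, numeric(1), lambda = lambda)
}

makeSolution <- function(strata, thresholds, lambda = NA_real_) {
  lf <- vapply(seq_along(strata@specs), function(i) {
    if (thresholds[i] <= 0) return(NA_real_)
    mixtureLfdr(strata@specs[[i]], thresholds[i])
  }, numeric(1))
  ev <- sum(vapply(seq_along(strata@specs), function(i) {
    sp <- strata@specs[[i]]
    thresholds[i] * sp@pi0 * sp@nTotal
  }, numeric(1)))
  ep <- expectedPredictions(strata, thresholds)
  cf <- if (ep > 0) ev / ep else NA_real_
  new("ThresholdSolution", thresholds = thresholds, lfdrLevel = lambda,
      lfdrValues = lf, combinedFdr = cf, combinedEvalue = ev,
      expectedPredictions = ep)
}

#' Equal-lFDR thresholds under a combined FDR budget
#'
#' Finds per-stratum p-value thresholds maximizing the expected number of
#' predictions subject to combined FDR <= budgetQ.  At the optimum the
#' local FDR of every participating stratum is equal to a common level
#' lambda'; the solver finds lambda' by monotone bisection on the combined
#' FDR (the combined FDR at the equal-lFDR thresholds is non-decreasing in
#' lambda').  Strata whose minimum attainable lFDR exceeds lambda' (e.g.
#' pure-null strata) receive threshold 0.
#'
#' @param strata a \linkS4class{StratumCollection}.
#' @param budgetQ combined FDR budget in (0, 1).
#' @param tol bisection tolerance on the combined FDR (default 1e-10).
#' @return a \linkS4class{ThresholdSolution}.
#' @examples
#' sc <- StratumCollection(list(MixtureSpec(0.9, 0.3, 1000),
#'                              MixtureSpec(0.5, 0.5, 500)))
#' equalLfdrThresholds(sc, 0.05)
#' @export
equalLfdrThresholds <- function(strata, budgetQ, tol = 1e-10) {
  stopifnot(is(strata, "StratumCollection"), budgetQ > 0, budgetQ < 1)
  if (all(vapply(strata@specs, function(s) s@pi0 >= 1, logical(1))))
    stop("infeasible budget: all strata are pure null, combined FDR is 1 ",
         "for any non-empty prediction set")
  g <- function(lambda) {
    th <- equalLfdrSolution(strata, lambda)
    if (all(th <= 0)) return(0)
    combinedFdr(strata, th)
  }
  hi <- 1
  if (g(hi) <= budgetQ)           # budget not binding: accept everything
    return(makeSolution(strata, equalLfdrSolution(strata, hi), lambda = hi))
  lo <- 0
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    val <- g(mid)
    if (abs(val - budgetQ) <= tol) { lo <- hi <- mid; break }
    if (val > budgetQ) hi <- mid else lo <- mid
    if (hi - lo < .Machine$double.eps * max(1, hi)) break
  }
  lambda <- (lo + hi) / 2
  makeSolution(strata, equalLfdrSolution(strata, lambda), lambda = lambda)
}

#' Equal-lFDR thresholds under a combined E-value budget
#'
#' Same optimization with the constraint sum(t_i pi0_i N_i) = budgetE
#' (expected false positives across strata); the optimum again equalizes
#' the per-stratum lFDRs.
#'
#' @param strata a \linkS4class{StratumCollection}.
#' @param budgetE combined E-value budget (> 0).
#' @param tol bisection tolerance on the combined E-value.
#' @return a \linkS4class{ThresholdSolution}.
#' @export
equalLfdrThresholdsEvalue <- function(strata, budgetE, tol = 1e-10) {
  stopifnot(is(strata, "StratumCollection"), budgetE > 0)
  h <- function(lambda) {
    th <- equalLfdrSolution(strata, lambda)
    sum(vapply(seq_along(strata@specs), function(i) {
      sp <- strata@specs[[i]]
      th[i] * sp@pi0 * sp@nTotal
    }, numeric(1)))
  }
  hi <- 1
  if (h(hi) <= budgetE)
    return(makeSolution(strata, equalLfdrSolution(strata, hi), lambda = hi))
  lo <- 0
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    val <- h(mid)
    if (abs(val - budgetE) <= tol) { lo <- hi <- mid; break }
    if (val > budgetE) hi <- mid else lo <- mid
    if (hi - lo < .Machine$double.eps * max(1, hi)) break
  }
  lambda <- (lo + hi) / 2
  makeSolution(strata, equalLfdrSolution(strata, lambda), lambda = lambda)
}

#' Brute-force threshold search (oracle)
#'
#' Exhaustively searches a per-stratum threshold grid (log-spaced between
#' 1e-8 and 1, plus the exact point t = 0) for the feasible threshold
#' vector maximizing the expected number of predictions.  Intended as an
#' independent oracle for \code{\link{equalLfdrThresholds}} on small
#' problems; the returned solution reports the achieved per-stratum lFDRs,
#' whose near-equality at the optimum is the testable content of the
#' equal-lFDR optimality result.
#'
#' @param strata a \linkS4class{StratumCollection} with at most 4 strata.
#' @param budget the combined FDR budget (type "fdr") or combined E-value
#'   budget (type "evalue").
#' @param gridSize number of non-zero grid points per stratum (<= 200).
#' @param type constraint type, "fdr" or "evalue".
#' @return a \linkS4class{ThresholdSolution} (slot \code{lfdrLevel} is NA;
#'   inspect \code{lfdrValues}).
#' @export
bruteForceThresholds <- function(strata, budget, gridSize = 100,
                                 type = c("fdr", "evalue")) {
  type <- match.arg(type)
  stopifnot(is(strata, "StratumCollection"), budget > 0, gridSize >= 2)
  k <- length(strata@specs)
  if (k > 4) stop("brute-force search supports at most 4 strata")
  if (gridSize > 200) stop("gridSize must be <= 200")
  grid <- c(0, 10^seq(-8, 0, length.out = gridSize))
  # per-stratum contributions at each grid point
  vmat <- lapply(strata@specs, function(sp) grid * sp@pi0 * sp@nTotal)
  rmat <- lapply(strata@specs, function(sp) mixtureCdf(sp, grid) * sp@nTotal)
  idx <- do.call(expand.grid, rep(list(seq_along(grid)), k))
  num <- 0; den <- 0
  for (i in seq_len(k)) {
    num <- num + vmat[[i]][idx[[i]]]
    den <- den + rmat[[i]][idx[[i]]]
  }
  feas <- if (type == "fdr") den > 0 & num <= budget * den else num <= budget
  if (!any(feas)) stop("no feasible grid point under the given budget")
  best <- which(feas)[which.max(den[feas])]
  th <- vapply(seq_len(k), function(i) grid[idx[[i]][best]], numeric(1))
  makeSolution(strata, th, lambda = NA_real_)
}
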