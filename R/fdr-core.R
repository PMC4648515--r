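#' E-values from censored stratum p-values
#'
#' The E-value at threshold t is the expected number of false positives,
#' t * pi0 * N, with N the number of tests in the stratum.  Evaluated at
#' each reported p-value.
#'
#' @param pset a \linkS4class{PValueSet}.
#' @param pi0 null proportion; the conservative default is 1.
#' @return numeric vector of expected false-positive counts, one per
#'   reported p-value, in the same (ascending) order.
#' @examples
#' evalues(PValueSet(1e-8, nTotal = 3.8e6))  # 0.038
#' @export
evalues <- function(pset, pi0 = 1) {
  stopifnot(is(pset, "PValueSet"), pi0 >= 0, pi0 <= 1)
  pset@pvalues * pi0 * pset@nTotal
}

#' q-values from censored stratum p-values
#'
#' Step-up q-value estimation adapted for censored tests.  At rank k
#' (ascending p) the raw pFDR estimate is p_(k) * pi0 * N / k; the q-value
#' is the minimum raw estimate over ranks >= k, capped at 1.  Because the
#' numerator scales by the total test count N -- not by the number of
#' reported p-values -- censoring (only p <= c reported) requires no further
#' correction: every unreported test has p > c and can only appear at larger
#' ranks.
#'
#' @param pset a \linkS4class{PValueSet}.
#' @param pi0 null proportion, default 1 (slightly conservative).
#' @return numeric vector of q-values, non-decreasing in p, in [0, 1].
#' @examples
#' qvaluesCensored(PValueSet(c(0.001, 0.002, 0.01), nTotal = 100))
#' @export
qvaluesCensored <- function(pset, pi0 = 1) {
  stopifnot(is(pset, "PValueSet"), pi0 >= 0, pi0 <= 1)
  p <- pset@pvalues
  m <- length(p)
  if (!m) return(numeric(0))
  if (pset@nTotal < m)
    stop("invalid input: nTotal smaller than the number of reported p-values")
  raw <- p * pi0 * pset@nTotal / seq_len(m)
  q <- rev(cummin(rev(raw)))       # step-up: min over ranks >= k
  pmin(q, 1)
}

#' Local FDR from censored stratum p-values
#'
#' Estimates lFDR(p) = pi0 / f(p), the posterior probability that a test
#' with p-value exactly p is null, from the censored sample.  The density f
#' of the full p-value distribution is estimated on the score scale
#' s = -log10(p): a Gaussian kernel density of the reported s values is
#' scaled by m/N (the estimated probability mass below the censoring point)
#' and converted back by the change of variables f(p) = g(s) / (p * ln 10).
#' The alternative mass concentrates near p = 0 and is close to log-uniform
#' in s, which keeps the kernel estimate stable in the significant tail.
#' Estimated values are clamped to [0, 1] and regularized by a running
#' maximum in ascending p, since the true lFDR is non-decreasing in p for
#' monotone likelihood-ratio mixtures.
#'
#' @param pset a \linkS4class{PValueSet} with at least 2 distinct p-values.
#' @param pi0 null proportion, default 1.
#' @param bandwidth kernel bandwidth on the -log10(p) scale, or "auto"
#'   (Silverman's rule, \code{bw.nrd0}).
#' @return numeric vector of lFDR values, one per reported p-value
#'   (ascending), non-decreasing and in [0, 1].
#' @seealso \code{\link{mixtureEval}} for the closed-form oracle.
#' @export
lfdrCensored <- function(pset, pi0 = 1, bandwidth = "auto") {
  stopifnot(is(pset, "PValueSet"), pi0 >= 0, pi0 <= 1)
  p <- pset@pvalues
  if (length(unique(p)) < 2L)
    stop("insufficient data: need at least 2 distinct p-values for density estimation")
  if (any(p <= 0))
    stop("p-values must be strictly positive for the log transform")
  if (pi0 == 0) return(rep(0, length(p)))
  s <- -log10(p)
  bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(s) else
    as.numeric(bandwidth)
  # reflect about the censoring boundary s0 = -log10(c): scores live on
  # [s0, Inf) and an unreflected kernel halves the density at the edge
  s0 <- -log10(pset@censorC)
  aug <- c(s, 2 * s0 - s)
  dens <- stats::density(aug, bw = bw, n = 2048,
                         from = s0, to = max(s) + 4 * bw)
  gs <- 2 * stats::approx(dens$x, dens$y, xout = s, rule = 2)$y
  mass <- length(p) / pset@nTotal       # estimated Pr(p <= censorC)
  fhat <- mass * gs / (p * log(10))     # back to the p scale
  lf <- pmin(1, pmax(0, pi0 / fhat))
  cummax(lf)                            # monotone regularization in p
}

#' Evaluate the two-component mixture at a threshold
#'
#' Closed forms for the mixture F(t) = pi0 t + (1 - pi0) t^a,
#' f(t) = pi0 + (1 - pi0) a t^(a-1), the positive FDR
#' pFDR(t) = t pi0 / F(t), and the local FDR lFDR(t) = pi0 / f(t).
#'
#' @param spec a \linkS4class{MixtureSpec}.
#' @param t p-value threshold(s) in (0, 1]; vectorized.
#' @return a list with numeric components \code{F}, \code{f}, \code{pfdr},
#'   \code{lfdr}.
#' @examples
#' mixtureEval(MixtureSpec(0.5, 0.5), 0.25)$pfdr  # 1/3
#' @export
mixtureEval <- function(spec, t) {
  stopifnot(is(spec, "MixtureSpec"))
  if (any(t <= 0))
    stop("undefined ratio at t = 0 (0/0); t must be in (0, 1]")
  if (any(t > 1)) stop("t must be in (0, 1]")
  pi0 <- spec@pi0; a <- spec@altShape
  Fv <- pi0 * t + (1 - pi0) * t^a
  fv <- pi0 + (1 - pi0) * a * t^(a - 1)
  list(F = Fv, f = fv, pfdr = t * pi0 / Fv, lfdr = pi0 / fv)
}

# lFDR of the mixture as a plain function of t (vectorized), used by the
# threshold solver.  For a < 1 this is continuous and strictly increasing
# in t when pi0 < 1; constant (= pi0) when a = 1; constant 1 when pi0 = 1.
mixtureLfdr <- function(spec, t) {
  pi0 <- spec@pi0; a <- spec@altShape
  pi0 / (pi0 + (1 - pi0) * a * t^(a - 1))
}

#' Draw a censored p-value sample from a mixture
#'
#' Samples N p-values from the two-component mixture (null uniform with
#' probability pi0, else Beta(a, 1)), keeps those at or below the censoring
#' threshold, and returns the \linkS4class{PValueSet} together with the
#' ground-truth null indicator of each retained p-value.
#'
#' @param spec a \linkS4class{MixtureSpec} with \code{nTotal} > 0.
#' @param censorC censoring threshold (default 0.01); use 1 for no censoring.
#' @param stratumId optional identifier.
#' @return list with \code{pset} (a PValueSet) and \code{isNull} (logical,
#'   aligned with \code{pvalues(pset)}).
#' @export
rmixture <- function(spec, censorC = 0.01, stratumId = NA_character_) {
  stopifnot(is(spec, "MixtureSpec"), spec@nTotal >= 1)
  n <- spec@nTotal
  isNull <- runif(n) < spec@pi0
  p <- numeric(n)
  p[isNull] <- runif(sum(isNull))
  # Beta(a, 1) via inverse CDF: t = u^(1/a)
  p[!isNull] <- runif(sum(!isNull))^(1 / spec@altShape)
  keep <- p <= censorC
  o <- order(p[keep])
  list(
    pset = PValueSet(p[keep][o], nTotal = n, censorC = censorC,
                     stratumId = stratumId),
    isNull = isNull[keep][o]
  )
}
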