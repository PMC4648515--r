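#' Per-family empirical FDR with pseudocounts
#'
#' efFDR = (1 + FP) / (1 + TP + FP); the +1 pseudocount keeps the
#' log-deviation finite when no FPs are observed.
#'
#' @param tp,fp non-negative TP and FP counts (vectorized).
#' @return empirical family-level FDR in (0, 1].
#' @examples
#' effdr(99, 0)   # 0.01
#' @export
effdr <- function(tp, fp) {
  stopifnot(all(tp >= 0), all(fp >= 0))
  (1 + fp) / (1 + tp + fp)
}

#' Log-deviation of a family's empirical FDR from the nominal threshold
#'
#' LD = log2(efFDR / q); zero means perfect agreement, positive values an
#' underestimated FDR (noisier family than the q-value claims).
#'
#' @param effdrValue empirical family FDR in (0, 1].
#' @param qThreshold nominal q-value threshold in (0, 1].
#' @return LD on the log2 scale.
#' @export
logDeviation <- function(effdrValue, qThreshold) {
  if (any(effdrValue <= 0) || any(effdrValue > 1) ||
      any(qThreshold <= 0) || any(qThreshold > 1))
    stop("effdrValue and qThreshold must lie in (0, 1]")
  log2(effdrValue / qThreshold)
}

#' Two-tailed Poisson test for an observed FP count
#'
#' p = min(1, 2 * min(P(X <= k), P(X >= k))) for X ~ Poisson(expected) --
#' the doubled one-sided minimum, a simple conservative two-tailed test.
#' Boundary cases: expected = 0 gives p = 1 when k = 0 and p = 0 when
#' k > 0.
#'
#' @param fpObserved observed FP count k.
#' @param expected Poisson mean (the expected FP count).
#' @return two-tailed p-value.
#' @examples
#' poissonTwoTailed(0, 1)   # 2 * exp(-1)
#' @export
poissonTwoTailed <- function(fpObserved, expected) {
  stopifnot(all(expected >= 0), all(fpObserved >= 0))
  k <- fpObserved
  mapply(function(k, lam) {
    if (lam == 0) return(if (k == 0) 1 else 0)
    lower <- stats::ppois(k, lam)                 # P(X <= k)
    upper <- stats::ppois(k - 1, lam, lower.tail = FALSE)  # P(X >= k)
    min(1, 2 * min(lower, upper))
  }, k, expected)
}

#' Per-family noise scan at a q-value threshold
#'
#' For each family, sums TP/FP counts over proteins among hits passing the
#' q-value threshold, computes the pseudocounted efFDR, its log-deviation
#' LD from the threshold, and a two-tailed Poisson p-value of the observed
#' FP count against the expectation q * (TP + FP) (pseudocount excluded).
#' q-values across families (q_Poisson) come from the Benjamini-Hochberg
#' step-up (pi0 = 1).  Effect classes: "insignificant" if
#' q_Poisson > 1e-3, else "positive" (LD > 2), "negative" (LD < -2) or
#' "small" (|LD| <= 2).
#'
#' @param labeledHits hit table with \code{family_id}, \code{label} and
#'   \code{qvalue} columns; REMOVED hits are ignored.
#' @param qThreshold the q-value threshold defining the scanned hit set
#'   (default 1e-2); rows with \code{qvalue} > threshold are dropped.
#'   Set to NULL if the table is already filtered.
#' @param significanceQ q_Poisson significance cutoff (default 1e-3).
#' @return data.frame with one row per family: \code{family_id},
#'   \code{tp}, \code{fp}, \code{effdr}, \code{ld}, \code{p_poisson},
#'   \code{q_poisson}, \code{effect}.
#' @export
familyNoiseScan <- function(labeledHits, qThreshold = 1e-2,
                            significanceQ = 1e-3) {
  h <- labeledHits[labeledHits$label %in% c("TP", "FP"), , drop = FALSE]
  qt <- if (is.null(qThreshold)) 1e-2 else qThreshold
  if (!is.null(qThreshold))
    h <- h[h$qvalue <= qThreshold, , drop = FALSE]
  if (!nrow(h))
    return(data.frame(family_id = character(0), tp = integer(0),
                      fp = integer(0), effdr = numeric(0), ld = numeric(0),
                      p_poisson = numeric(0), q_poisson = numeric(0),
                      effect = character(0)))
  tp <- tapply(h$label == "TP", h$family_id, sum)
  fp <- tapply(h$label == "FP", h$family_id, sum)
  fam <- names(tp)
  tp <- as.integer(tp); fp <- as.integer(fp)
  ef <- effdr(tp, fp)
  ld <- logDeviation(ef, qt)
  pp <- poissonTwoTailed(fp, qt * (tp + fp))
  qp <- stats::p.adjust(pp, method = "BH")
  effect <- ifelse(qp > significanceQ, "insignificant",
            ifelse(ld > 2, "positive",
            ifelse(ld < -2, "negative", "small")))
  data.frame(family_id = fam, tp = tp, fp = fp, effdr = ef, ld = ld,
             p_poisson = pp, q_poisson = qp, effect = effect,
             row.names = NULL)
}

#' Majority-vote noise classes across empirical tests
#'
#' Combines per-family noise scans from several empirical tests (the
#' convention is four: ClanOv, ContextC, OrthoC, RevSeq) into mutually
#' exclusive classes: "increased" if at least \code{minVotes} tests give a
#' significant positive effect, "decreased" for significant negative
#' effects, "as_expected" if at least \code{minVotes} tests give a small
#' deviation (effect "small", or "insignificant" with |LD| <= 2), and
#' otherwise "unclassified".  Precedence: increased > decreased >
#' as_expected.
#'
#' @param scans list of data.frames from \code{\link{familyNoiseScan}},
#'   one per test (>= \code{minVotes} entries advisable).
#' @param minVotes votes needed to assign a class (default 3).
#' @return data.frame with \code{family_id}, vote counts and
#'   \code{noise_class}.
#' @export
classifyFamilies <- function(scans, minVotes = 3) {
  stopifnot(is.list(scans), length(scans) >= 1)
  fams <- sort(unique(unlist(lapply(scans, `[[`, "family_id"))))
  votes <- matrix(0L, nrow = length(fams), ncol = 3,
                  dimnames = list(fams, c("positive", "negative", "small")))
  for (sc in scans) {
    i <- match(sc$family_id, fams)
    votes[i, "positive"] <- votes[i, "positive"] + (sc$effect == "positive")
    votes[i, "negative"] <- votes[i, "negative"] + (sc$effect == "negative")
    asExp <- sc$effect == "small" |
      (sc$effect == "insignificant" & abs(sc$ld) <= 2)
    votes[i, "small"] <- votes[i, "small"] + asExp
  }
  cls <- ifelse(votes[, "positive"] >= minVotes, "increased",
         ifelse(votes[, "negative"] >= minVotes, "decreased",
         ifelse(votes[, "small"] >= minVotes, "as_expected",
                "unclassified")))
  data.frame(family_id = fams,
             votes_positive = votes[, "positive"],
             votes_negative = votes[, "negative"],
             votes_small = votes[, "small"],
             noise_class = unname(cls), row.names = NULL)
}
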