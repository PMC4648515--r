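#' @import methods
#' @importFrom stats density approx ppois p.adjust runif rgamma pchisq
#'   setNames sd bw.nrd0
NULL

#' PValueSet: censored p-values for one stratum
#'
#' Holds the reported (censored) p-values of one stratum -- here, all tests
#' of one domain family's profile HMM against a protein database -- together
#' with the total number of tests performed \code{nTotal} and the reporting
#' (censoring) cutoff \code{censorC}.  Search software only reports hits with
#' p <= censorC, so the reported list is a censored sample; all estimators in
#' this package scale by \code{nTotal}, never by the reported count.
#'
#' @slot stratumId single character identifier (e.g. a family accession).
#' @slot pvalues numeric, ascending, all in [0, censorC].
#' @slot nTotal number of tests performed in the stratum (proteins scanned).
#' @slot censorC reporting cutoff c in (0, 1].
#'
#' @aliases PValueSet-class
#' @exportClass PValueSet
setClass("PValueSet",
  representation(
    stratumId = "character",
    pvalues   = "numeric",
    nTotal    = "numeric",
    censorC   = "numeric"
  ),
  prototype(stratumId = NA_character_, pvalues = numeric(0),
            nTotal = 0, censorC = 0.01)
)

setValidity("PValueSet", function(object) {
  msg <- character(0)
  p <- object@pvalues
  if (length(object@censorC) != 1L || is.na(object@censorC) ||
      object@censorC <= 0 || object@censorC > 1)
    msg <- c(msg, "censorC must be a single value in (0, 1]")
  if (length(object@nTotal) != 1L || is.na(object@nTotal) ||
      object@nTotal < 0)
    msg <- c(msg, "nTotal must be a single non-negative count")
  if (length(p) > object@nTotal)
    msg <- c(msg, "more reported p-values than tests (length(pvalues) > nTotal)")
  if (length(p)) {
    if (anyNA(p) || any(p < 0) || any(p > object@censorC))
      msg <- c(msg, "pvalues must lie in [0, censorC]")
    if (is.unsorted(p))
      msg <- c(msg, "pvalues must be sorted ascending")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PValueSet
#'
#' @param pvalues numeric vector of reported p-values (sorted internally).
#' @param nTotal total number of tests performed in the stratum.
#' @param censorC censoring threshold; only p <= censorC are reported
#'   (default 0.01, the conventional reporting cutoff).
#' @param stratumId optional identifier.
#' @return a \linkS4class{PValueSet}.
#' @examples
#' ps <- PValueSet(c(1e-4, 1e-3, 5e-3), nTotal = 1000)
#' qvaluesCensored(ps)
#' @export
PValueSet <- function(pvalues, nTotal, censorC = 0.01,
                      stratumId = NA_character_) {
  new("PValueSet", stratumId = as.character(stratumId)[1L],
      pvalues = sort(as.numeric(pvalues)), nTotal = as.numeric(nTotal)[1L],
      censorC = as.numeric(censorC)[1L])
}

#' @describeIn PValueSet number of reported p-values
#' @param x,object a PValueSet
#' @export
setMethod("length", "PValueSet", function(x) length(x@pvalues))

#' Accessors for PValueSet
#' @param x a \linkS4class{PValueSet}
#' @return \code{pvalues} returns the reported p-values; \code{nTotal} the
#'   total test count; \code{censorC} the censoring threshold.
#' @export
pvalues <- function(x) x@pvalues
#' @rdname pvalues
#' @export
nTotal <- function(x) x@nTotal
#' @rdname pvalues
#' @export
censorC <- function(x) x@censorC

setMethod("show", "PValueSet", function(object) {
  cat("PValueSet", if (!is.na(object@stratumId)) object@stratumId else "",
      "\n  ", length(object@pvalues), " reported p-values of ",
      format(object@nTotal), " tests (censored at p <= ",
      format(object@censorC), ")\n", sep = "")
})

#' MixtureSpec: analytic two-component p-value mixture
#'
#' The canonical two-component model for a stratum's p-values: a uniform
#' null of mass pi0 and a Beta(a, 1) alternative (density a * t^(a-1),
#' peaked at 0 for a < 1).  Closed forms:
#' F(t) = pi0 * t + (1 - pi0) * t^a and f(t) = pi0 + (1 - pi0) * a * t^(a-1).
#' Serves as the exact oracle for pFDR, lFDR and the threshold optimizer.
#'
#' @slot pi0 null-component mass in [0, 1].
#' @slot altShape Beta shape a in (0, 1].
#' @slot nTotal number of tests in the stratum.
#' @aliases MixtureSpec-class
#' @exportClass MixtureSpec
setClass("MixtureSpec",
  representation(pi0 = "numeric", altShape = "numeric", nTotal = "numeric"),
  prototype(pi0 = 1, altShape = 1, nTotal = 0)
)

setValidity("MixtureSpec", function(object) {
  msg <- character(0)
  if (length(object@pi0) != 1L || is.na(object@pi0) ||
      object@pi0 < 0 || object@pi0 > 1)
    msg <- c(msg, "pi0 must be a single probability in [0, 1]")
  if (length(object@altShape) != 1L || is.na(object@altShape) ||
      object@altShape <= 0 || object@altShape > 1)
    msg <- c(msg, "altShape must be a single value in (0, 1]")
  if (length(object@nTotal) != 1L || is.na(object@nTotal) || object@nTotal < 0)
    msg <- c(msg, "nTotal must be a single non-negative count")
  if (length(msg)) msg else TRUE
})

#' Construct a MixtureSpec
#' @param pi0 null mass in [0, 1].
#' @param altShape Beta(a, 1) alternative shape, a in (0, 1].
#' @param nTotal test count (needed for E-values and optimization).
#' @return a \linkS4class{MixtureSpec}.
#' @examples
#' mixtureEval(MixtureSpec(0.5, 0.5), 0.25)
#' @export
MixtureSpec <- function(pi0, altShape, nTotal = 0) {
  new("MixtureSpec", pi0 = as.numeric(pi0)[1L],
      altShape = as.numeric(altShape)[1L], nTotal = as.numeric(nTotal)[1L])
}

setMethod("show", "MixtureSpec", function(object) {
  cat(sprintf("MixtureSpec: pi0 = %g, Beta(%g, 1) alternative, N = %g\n",
              object@pi0, object@altShape, object@nTotal))
})

#' StratumCollection: one MixtureSpec per stratum
#'
#' @slot specs list of \linkS4class{MixtureSpec}, one per stratum.
#' @aliases StratumCollection-class
#' @exportClass StratumCollection
setClass("StratumCollection", representation(specs = "list"))

setValidity("StratumCollection", function(object) {
  if (!length(object@specs))
    return("at least one stratum is required")
  ok <- vapply(object@specs, is, logical(1), class2 = "MixtureSpec")
  if (!all(ok)) return("all specs must be MixtureSpec objects")
  TRUE
})

#' Construct a StratumCollection
#' @param specs a list of \linkS4class{MixtureSpec} (or several specs given
#'   as separate arguments).
#' @param ... further MixtureSpec objects.
#' @return a \linkS4class{StratumCollection}.
#' @export
StratumCollection <- function(specs, ...) {
  if (is(specs, "MixtureSpec")) specs <- c(list(specs), list(...))
  new("StratumCollection", specs = specs)
}

#' @describeIn StratumCollection number of strata
#' @param x,object a StratumCollection
#' @export
setMethod("length", "StratumCollection", function(x) length(x@specs))

setMethod("show", "StratumCollection", function(object) {
  cat("StratumCollection with", length(object@specs), "strata\n")
})

#' ThresholdSolution: per-stratum thresholds meeting a combined budget
#'
#' Result of the equal-lFDR optimization or of the brute-force grid search:
#' per-stratum p-value thresholds, the common lFDR level attained at those
#' thresholds, the achieved combined FDR, and the expected number of
#' predictions.
#'
#' @slot thresholds numeric, one p-value threshold per stratum.
#' @slot lfdrLevel the common lFDR value at the thresholds (NA for
#'   brute-force solutions where the per-stratum lFDRs need not be equal).
#' @slot lfdrValues per-stratum lFDR at the chosen thresholds.
#' @slot combinedFdr achieved combined FDR.
#' @slot combinedEvalue achieved combined E-value (expected false positives).
#' @slot expectedPredictions sum of F_i(t_i) * N_i.
#' @aliases ThresholdSolution-class
#' @exportClass ThresholdSolution
setClass("ThresholdSolution",
  representation(
    thresholds = "numeric",
    lfdrLevel = "numeric",
    lfdrValues = "numeric",
    combinedFdr = "numeric",
    combinedEvalue = "numeric",
    expectedPredictions = "numeric"
  )
)

#' Accessors for ThresholdSolution
#' @param x a \linkS4class{ThresholdSolution}
#' @export
thresholds <- function(x) x@thresholds
#' @rdname thresholds
#' @export
lfdrLevel <- function(x) x@lfdrLevel
#' @rdname thresholds
#' @export
lfdrValues <- function(x) x@lfdrValues
#' @rdname thresholds
#' @export
achievedFdr <- function(x) x@combinedFdr
#' @rdname thresholds
#' @export
achievedEvalue <- function(x) x@combinedEvalue
#' @rdname thresholds
#' @export
expectedPredictionCount <- function(x) x@expectedPredictions

setMethod("show", "ThresholdSolution", function(object) {
  cat("ThresholdSolution\n")
  cat("  thresholds:", paste(format(object@thresholds, digits = 4),
                             collapse = ", "), "\n")
  if (!is.na(object@lfdrLevel))
    cat("  common lFDR level:", format(object@lfdrLevel, digits = 6), "\n")
  cat("  combined FDR:", format(object@combinedFdr, digits = 6),
      "  combined E-value:", format(object@combinedEvalue, digits = 6), "\n")
  cat("  expected predictions:",
      format(object@expectedPredictions, digits = 8), "\n")
})
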