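#' Stratified statistics for a domain hit table
#'
#' The core annotation pipeline: hits are ranked by p-value, overlapping
#' predictions are resolved (keeping the most significant, honouring the
#' nesting whitelist), and E-values, q-values and local FDRs are then
#' estimated per family stratum from the censored domain p-values of the
#' kept hits.  Removed hits are not deleted: they keep their exact
#' E-values and receive q-values and lFDRs by per-family interpolation
#' (the empirical FDR tests need overlapping hits with statistics).
#'
#' @param hits a hit table (see \code{\link{validateHits}}).
#' @param nTotal number of tests per stratum, i.e. proteins scanned
#'   (a single number, or a named vector by family_id).
#' @param pi0 null proportion, default 1 (conservative).
#' @param censorC censoring threshold of the reported p-values.
#' @param nesting a \code{\link{familyPairs}} whitelist or NULL.
#' @param mode,frac overlap definition, see \code{\link{regionsOverlap}}.
#' @param withLfdr estimate lFDRs as well (needs >= 2 distinct p-values
#'   per family; families below that get NA).
#' @return the ranked hit table with columns \code{evalue}, \code{qvalue},
#'   \code{lfdr} and \code{removed_overlap}.
#' @examples
#' sim <- generateDataset(simConfig(nFamilies = 3, nProteins = 200,
#'                                  seed = 1))
#' ann <- stratifiedStats(sim$hits, nTotal = 200)
#' head(ann)
#' @export
stratifiedStats <- function(hits, nTotal, pi0 = 1, censorC = 0.01,
                            nesting = NULL, mode = c("permissive", "any"),
                            frac = 0.4, withLfdr = TRUE) {
  mode <- match.arg(mode)
  hits <- removeOverlaps(hits, nesting = nesting, mode = mode, frac = frac)
  hits$evalue <- NA_real_
  hits$qvalue <- NA_real_
  hits$lfdr <- NA_real_
  famN <- function(f) {
    if (length(nTotal) == 1L && is.null(names(nTotal))) return(nTotal)
    n <- nTotal[[f]]
    if (is.null(n)) stop("no nTotal entry for family ", f)
    n
  }
  for (fam in unique(hits$family_id)) {
    rows <- which(hits$family_id == fam)
    N <- famN(fam)
    hits$evalue[rows] <- hits$p_domain[rows] * pi0 * N
    kept <- rows[!hits$removed_overlap[rows]]
    if (!length(kept)) next
    o <- kept[order(hits$p_domain[kept])]
    cc <- max(censorC, max(hits$p_domain[o]))
    pset <- PValueSet(hits$p_domain[o], nTotal = N, censorC = cc,
                      stratumId = fam)
    hits$qvalue[o] <- qvaluesCensored(pset, pi0 = pi0)
    if (withLfdr && length(unique(hits$p_domain[o])) >= 2L)
      hits$lfdr[o] <- lfdrCensored(pset, pi0 = pi0)
    rem <- rows[hits$removed_overlap[rows]]
    if (length(rem)) {
      interp <- interpolateStats(hits[rem, , drop = FALSE],
                                 hits[o, , drop = FALSE])
      hits$qvalue[rem] <- interp$qvalue
      hits$lfdr[rem] <- interp$lfdr
    }
  }
  hits
}
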