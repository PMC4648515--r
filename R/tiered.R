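#' Per-(protein, family) sequence-score table
#'
#' Collapses a domain hit table to one row per (protein, family) pair
#' carrying the sequence p-value (which combines the evidence of every
#' domain of that family on the protein).  Errors if a pair carries
#' inconsistent sequence p-values.
#'
#' @param hits a hit table.
#' @return data.frame with \code{protein_id}, \code{family_id},
#'   \code{p_sequence}, one row per pair.
#' @export
sequenceTable <- function(hits) {
  validateHits(hits)
  tab <- unique(hits[, c("protein_id", "family_id", "p_sequence")])
  key <- paste(tab$protein_id, tab$family_id, sep = "\r")
  if (anyDuplicated(key))
    stop("inconsistent p_sequence values within a (protein, family) pair")
  rownames(tab) <- NULL
  tab
}

#' Tier-1: sequence-level q-values per family stratum
#'
#' Applies the censored step-up to the sequence p-values, one test per
#' (protein, family) pair, stratified by family; nTotal is the number of
#' proteins scanned.
#'
#' @param seqTab output of \code{\link{sequenceTable}} (one row per pair;
#'   duplicated pairs are an error).
#' @param nTotal proteins scanned per stratum (single number or named by
#'   family).
#' @param pi0 null proportion, default 1.
#' @param censorC censoring threshold of the reported sequence p-values.
#' @return \code{seqTab} with a \code{q_sequence} column.
#' @export
sequenceQvalues <- function(seqTab, nTotal, pi0 = 1, censorC = 0.01) {
  key <- paste(seqTab$protein_id, seqTab$family_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (protein, family) rows violate the one-per-pair contract")
  seqTab$q_sequence <- NA_real_
  for (fam in unique(seqTab$family_id)) {
    rows <- which(seqTab$family_id == fam)
    N <- if (length(nTotal) == 1L && is.null(names(nTotal))) nTotal
         else nTotal[[fam]]
    o <- rows[order(seqTab$p_sequence[rows])]
    cc <- max(censorC, max(seqTab$p_sequence[o]))
    pset <- PValueSet(seqTab$p_sequence[o], nTotal = N, censorC = cc,
                      stratumId = fam)
    seqTab$q_sequence[o] <- qvaluesCensored(pset, pi0 = pi0)
  }
  seqTab
}

#' Tier-2: conditional domain q-values after the sequence gate
#'
#' Recomputes per-family censored q-values on the domain p-values of hits
#' whose (protein, family) pair passed the sequence-level threshold.  The
#' stratum size nTotal stays at the original protein count: the domain
#' p-values remain marginal, only the candidate set shrinks, and the
#' resulting threshold is interpreted conditionally on tier 1.
#'
#' @param hits a hit table restricted to tier-1 survivors.
#' @param nTotal test count per stratum for tier 2.  The default (NULL)
#'   uses the number of surviving domain p-values in the stratum, i.e. the
#'   classical step-up on the conditional candidate set -- the source of
#'   the tier's extra power, since the multiple-testing burden after the
#'   sequence gate is the surviving set, not the full database.  Supply a
#'   number (or named vector) to override.
#' @param pi0 null proportion.
#' @param censorC censoring threshold.
#' @return \code{hits} with a \code{q_dom_cond} column.
#' @export
conditionalDomainQvalues <- function(hits, nTotal = NULL, pi0 = 1,
                                     censorC = 0.01) {
  hits$q_dom_cond <- NA_real_
  if (!nrow(hits)) return(hits)
  for (fam in unique(hits$family_id)) {
    rows <- which(hits$family_id == fam)
    N <- if (is.null(nTotal)) length(rows)
         else if (length(nTotal) == 1L && is.null(names(nTotal))) nTotal
         else nTotal[[fam]]
    o <- rows[order(hits$p_domain[rows])]
    cc <- max(censorC, max(hits$p_domain[o]))
    pset <- PValueSet(hits$p_domain[o], nTotal = N, censorC = cc,
                      stratumId = fam)
    hits$q_dom_cond[o] <- qvaluesCensored(pset, pi0 = pi0)
  }
  hits
}

#' Two-tier (sequence then domain) stratified q-value selection
#'
#' Tier 1 thresholds the per-(protein, family) sequence q-values at
#' \code{qSeq}; tier 2 recomputes domain q-values on the surviving hits
#' only and thresholds them at \code{qDomGivenSeq}.  The combined FDR of
#' the final set is approximately \code{qSeq + qDomGivenSeq} when both are
#' small and tiers are independent; a warning is issued if either
#' threshold is >= 0.1, where the additive approximation degrades.  The
#' sequence statistic pools repeating domains, so families whose entire
#' signal comes from combining individually-weak repeat units can pass
#' tier 1 and survive a permissive tier 2.  Tiered selection is
#' experimental: it is more powerful than domain-only q-values but its FDR
#' estimates are less accurate.
#'
#' @param hits a hit table (overlaps are resolved after selection by the
#'   caller if needed).
#' @param nTotal proteins scanned per stratum (used by tier 1; tier 2
#'   uses the surviving domain count as its conditional test count).
#' @param qSeq tier-1 sequence q-value threshold.
#' @param qDomGivenSeq tier-2 conditional domain q-value threshold
#'   (default: equal to \code{qSeq}).
#' @param pi0 null proportion.
#' @param censorC censoring threshold.
#' @return list with \code{hits} (tier-2 survivors, carrying
#'   \code{q_sequence} and \code{q_dom_cond}), \code{approxCombinedFdr}
#'   (= qSeq + qDomGivenSeq) and the thresholds used.
#' @export
tieredSelect <- function(hits, nTotal, qSeq, qDomGivenSeq = qSeq,
                         pi0 = 1, censorC = 0.01) {
  stopifnot(qSeq > 0, qSeq <= 1, qDomGivenSeq > 0, qDomGivenSeq <= 1)
  if (qSeq >= 0.1 || qDomGivenSeq >= 0.1)
    warning("additive combined-FDR approximation is unreliable: ",
            "both tier thresholds should be < 0.1")
  seqTab <- sequenceTable(hits)
  seqTab <- sequenceQvalues(seqTab, nTotal, pi0 = pi0, censorC = censorC)
  pass <- seqTab[seqTab$q_sequence <= qSeq, , drop = FALSE]
  key <- paste(hits$protein_id, hits$family_id, sep = "\r")
  surv <- hits[key %in% paste(pass$protein_id, pass$family_id,
                              sep = "\r"), , drop = FALSE]
  # a vacuous sequence gate (qSeq = 1) means no conditioning at all:
  # tier 2 is then plain censored domain q-values over the full database
  n2 <- if (qSeq >= 1) nTotal else NULL
  surv <- conditionalDomainQvalues(surv, nTotal = n2, pi0 = pi0,
                                   censorC = censorC)
  i <- match(paste(surv$protein_id, surv$family_id, sep = "\r"),
             paste(pass$protein_id, pass$family_id, sep = "\r"))
  surv$q_sequence <- pass$q_sequence[i]
  out <- surv[surv$q_dom_cond <= qDomGivenSeq, , drop = FALSE]
  rownames(out) <- NULL
  list(hits = out, approxCombinedFdr = qSeq + qDomGivenSeq,
       qSeq = qSeq, qDomGivenSeq = qDomGivenSeq)
}
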