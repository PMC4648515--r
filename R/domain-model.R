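#' Domain hit tables
#'
#' Scored domain predictions are kept as plain data.frames with the columns
#' \code{protein_id}, \code{family_id}, \code{clan_id} (NA when the family
#' belongs to no clan), \code{env_start}, \code{env_end} (envelope
#' coordinates, 1-based inclusive), \code{bitscore}, \code{p_domain} and
#' \code{p_sequence}.  Annotated tables add \code{evalue}, \code{qvalue},
#' \code{lfdr} and \code{removed_overlap}.
#'
#' @param hits a candidate hit table.
#' @param annotated require the statistic columns as well.
#' @return invisibly TRUE; stops with an informative error otherwise.
#' @export
validateHits <- function(hits, annotated = FALSE) {
  need <- c("protein_id", "family_id", "clan_id", "env_start", "env_end",
            "bitscore", "p_domain", "p_sequence")
  if (annotated) need <- c(need, "evalue", "qvalue", "lfdr")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hit table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(hits)) {
    if (any(hits$env_start < 1 | hits$env_end < hits$env_start))
      stop("envelope coordinates must satisfy 1 <= env_start <= env_end")
    if (any(hits$p_domain <= 0 | hits$p_domain > 1))
      stop("p_domain must lie in (0, 1]")
    if (any(hits$p_sequence <= 0 | hits$p_sequence > 1))
      stop("p_sequence must lie in (0, 1]")
  }
  invisible(TRUE)
}

#' Rank domain hits by significance
#'
#' Orders hits by ascending domain p-value with a deterministic tie-break:
#' higher bitscore first, then longer envelope, then lexicographic
#' (protein_id, family_id, env_start).
#'
#' @param hits a hit table (see \code{\link{validateHits}}).
#' @return the table reordered, with row names dropped.
#' @export
rankHits <- function(hits) {
  validateHits(hits)
  if (!nrow(hits)) return(hits)
  len <- hits$env_end - hits$env_start + 1
  o <- order(hits$p_domain, -hits$bitscore, -len,
             hits$protein_id, hits$family_id, hits$env_start)
  out <- hits[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test whether two envelopes on the same protein overlap
#'
#' Mode "any" flags a single shared amino acid; mode "permissive" requires
#' the shared length to exceed \code{frac} times the shorter envelope
#' (default 0.4).
#'
#' @param a,b single-row hit tables (or lists) with \code{protein_id},
#'   \code{env_start}, \code{env_end}.
#' @param mode "permissive" or "any".
#' @param frac permissive-overlap fraction of the shorter region.
#' @return logical flag.
#' @export
regionsOverlap <- function(a, b, mode = c("permissive", "any"), frac = 0.4) {
  mode <- match.arg(mode)
  if (!identical(as.character(a$protein_id), as.character(b$protein_id)))
    stop("invalid comparison: hits are on different proteins")
  overlapFlag(a$env_start, a$env_end, b$env_start, b$env_end, mode, frac)
}

# vectorized overlap predicate on coordinates
overlapFlag <- function(s1, e1, s2, e2, mode, frac) {
  shared <- pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
  if (mode == "any") return(shared >= 1)
  shared > frac * pmin(e1 - s1 + 1, e2 - s2 + 1)
}

# canonical unordered-pair keys for nesting / context-pair lookups
pairKeys <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Family-pair lists (nesting whitelist, context pairs)
#'
#' Both the nesting whitelist (family pairs whose overlapping predictions
#' are permitted) and the context-pair list L (family pairs observed
#' together in the same sequence; self-pairs mark repeating families) are
#' symmetric sets of unordered family-id pairs, stored as two-column
#' data.frames.
#'
#' @param familyA,familyB character vectors of family ids (recycled).
#' @return a data.frame with columns \code{family_a}, \code{family_b}.
#' @export
familyPairs <- function(familyA = character(0), familyB = character(0)) {
  data.frame(family_a = as.character(familyA),
             family_b = as.character(familyB))
}

#' @rdname familyPairs
#' @param pairs a familyPairs data.frame (or NULL for the empty set).
#' @param a,b family ids to test (vectorized).
#' @return \code{pairContains}: logical, whether each unordered pair (a, b)
#'   is in the set.
#' @export
pairContains <- function(pairs, a, b) {
  if (is.null(pairs) || !nrow(pairs)) return(rep(FALSE, length(a)))
  pairKeys(a, b) %in% pairKeys(pairs$family_a, pairs$family_b)
}

#' Resolve overlapping domain predictions
#'
#' Greedy scan in rank order (ranking is recomputed internally, so the
#' result does not depend on the input row order): a hit is kept iff it
#' overlaps no already-kept hit on the same protein, or every kept hit it
#' overlaps forms a nesting-list pair with it.  Hits removed by a better
#' hit do not block later hits.  Proteins are processed independently.
#'
#' @param hits a hit table (any number of proteins).
#' @param nesting a \code{\link{familyPairs}} whitelist or NULL.
#' @param mode,frac overlap definition, see \code{\link{regionsOverlap}}.
#' @return the ranked table with a logical column \code{removed_overlap};
#'   removed hits are flagged, not deleted.
#' @export
removeOverlaps <- function(hits, nesting = NULL,
                           mode = c("permissive", "any"), frac = 0.4) {
  mode <- match.arg(mode)
  hits <- rankHits(hits)
  hits$removed_overlap <- logical(nrow(hits))
  if (!nrow(hits)) return(hits)
  for (idx in split(seq_len(nrow(hits)), hits$protein_id)) {
    keptIdx <- integer(0)
    for (i in idx) {           # idx is in rank order within the protein
      if (length(keptIdx)) {
        ov <- overlapFlag(hits$env_start[i], hits$env_end[i],
                          hits$env_start[keptIdx], hits$env_end[keptIdx],
                          mode, frac)
        if (any(ov)) {
          nested <- pairContains(nesting, hits$family_id[i],
                                 hits$family_id[keptIdx][ov])
          if (!all(nested)) { hits$removed_overlap[i] <- TRUE; next }
        }
      }
      keptIdx <- c(keptIdx, i)
    }
  }
  hits
}

#' Interpolate statistics for overlap-removed hits
#'
#' q-values and lFDRs are estimated on overlap-free hits only; removed
#' hits that the empirical tests still need are assigned statistics by
#' piecewise-linear interpolation, per family, of the kept hits'
#' (log10 p -> statistic) curves.  A removed p below (above) the kept
#' range takes the smallest (largest) kept statistic; results are clamped
#' to [0, 1].
#'
#' @param removed hit table of removed hits (with \code{p_domain}).
#' @param keptAnnotated annotated kept hits of the same families, with
#'   columns \code{qvalue} and \code{lfdr} monotone in p within family.
#' @return \code{removed} with interpolated \code{evalue} (NA; E-values
#'   are exact, p * pi0 * N, and should be computed directly), \code{qvalue}
#'   and \code{lfdr} columns.
#' @export
interpolateStats <- function(removed, keptAnnotated) {
  if (!nrow(keptAnnotated)) stop("cannot interpolate: empty kept set")
  removed$qvalue <- NA_real_
  removed$lfdr <- NA_real_
  for (fam in unique(removed$family_id)) {
    k <- keptAnnotated[keptAnnotated$family_id == fam, , drop = FALSE]
    r <- which(removed$family_id == fam)
    if (!nrow(k))
      stop("cannot interpolate: no kept hits for family ", fam)
    xr <- log10(removed$p_domain[r])
    o <- order(k$p_domain)
    oneNode <- length(unique(k$p_domain)) < 2L
    for (col in c("qvalue", "lfdr")) {
      if (all(is.na(k[[col]]))) {
        removed[[col]][r] <- NA_real_
        next
      }
      if (oneNode) {
        # tied kept p-values carry identical statistics
        removed[[col]][r] <- k[[col]][o][1L]
      } else {
        removed[[col]][r] <- stats::approx(
          log10(k$p_domain[o]), k[[col]][o], xout = xr, rule = 2,
          ties = mean)$y
      }
      removed[[col]][r] <- pmin(1, pmax(0, removed[[col]][r]))
    }
  }
  removed
}

#' Prediction-count metrics for a thresholded hit set
#'
#' Counts kept domains, unique (family, protein) pairs, amino acids
#' covered (the size of the union of envelope intervals per protein, so
#' residues under several domains are not double-counted), and proteins
#' with at least one prediction.
#'
#' @param hits hit table of predictions passing the chosen threshold, with
#'   overlaps already resolved (rows flagged \code{removed_overlap} are
#'   excluded if the column is present).
#' @return list with \code{domains}, \code{uniqueFamilyProteinPairs},
#'   \code{aminoAcidsCovered}, \code{proteinsWithPredictions}.
#' @export
coverageMetrics <- function(hits) {
  if (!is.null(hits$removed_overlap))
    hits <- hits[!hits$removed_overlap, , drop = FALSE]
  if (!nrow(hits))
    return(list(domains = 0L, uniqueFamilyProteinPairs = 0L,
                aminoAcidsCovered = 0L, proteinsWithPredictions = 0L))
  aa <- sum(vapply(split(hits, hits$protein_id), function(h) {
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = h$env_start, end = h$env_end))))
  }, numeric(1)))
  list(
    domains = nrow(hits),
    uniqueFamilyProteinPairs =
      nrow(unique(hits[, c("protein_id", "family_id")])),
    aminoAcidsCovered = as.integer(aa),
    proteinsWithPredictions = length(unique(hits$protein_id))
  )
}
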