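#' Clan-overlap (ClanOv) TP/FP labeling
#'
#' Empirical-FDR test built on the expectation that overlapping domain
#' predictions should be evolutionarily related (same clan).  Hits are
#' ranked by p-value and scanned: a hit overlapping a higher-ranking
#' retained hit of the same clan is REMOVED (it would not be counted as a
#' separate prediction and does not block later hits); a hit overlapping a
#' higher-ranking retained hit of a different clan is an FP (FP hits stay
#' in the retained set and block later hits); otherwise the hit is a TP.
#' Nesting-whitelist pairs never trigger removal or FP.  Families without
#' a clan are treated as singleton clans.
#'
#' @param hits hit table (any number of proteins; ranking is recomputed).
#' @param clanMap named character vector, family_id -> clan_id; families
#'   absent from the map (or mapped to NA) are clanless.
#' @param nesting a \code{\link{familyPairs}} whitelist or NULL.
#' @param mode,frac overlap definition, see \code{\link{regionsOverlap}}.
#' @return the ranked table with a character column \code{label} in
#'   {"TP", "FP", "REMOVED"}.
#' @export
labelClanov <- function(hits, clanMap, nesting = NULL,
                        mode = c("permissive", "any"), frac = 0.4) {
  mode <- match.arg(mode)
  hits <- rankHits(hits)
  hits$label <- character(nrow(hits))
  if (!nrow(hits)) return(hits)
  clan <- unname(clanMap[hits$family_id])
  solo <- is.na(clan)
  clan[solo] <- paste0("\r.solo.", hits$family_id[solo])
  for (idx in split(seq_len(nrow(hits)), hits$protein_id)) {
    keptIdx <- integer(0)
    for (i in idx) {
      lab <- "TP"
      if (length(keptIdx)) {
        ov <- overlapFlag(hits$env_start[i], hits$env_end[i],
                          hits$env_start[keptIdx], hits$env_end[keptIdx],
                          mode, frac)
        ov[ov] <- !pairContains(nesting, hits$family_id[i],
                                hits$family_id[keptIdx][ov])
        if (any(ov)) {
          same <- clan[keptIdx][ov] == clan[i]
          lab <- if (any(same)) "REMOVED" else "FP"
        }
      }
      hits$label[i] <- lab
      if (lab != "REMOVED") keptIdx <- c(keptIdx, i)
    }
  }
  hits
}

#' Context-coherence (ContextC) TP/FP labeling
#'
#' Empirical-FDR test based on whether co-predicted family pairs have been
#' observed together before.  Within each protein the highest-ranking hit
#' is always a TP; every later hit is a TP iff some higher-ranking hit's
#' family forms a pair with its family in the context list L (self-pairs
#' cover repeating families), regardless of that higher-ranking hit's own
#' label; otherwise it is an FP.
#'
#' @param hits hit table (ranking recomputed internally).
#' @param pairs the context-pair list L as \code{\link{familyPairs}}.
#' @return the ranked table with a character column \code{label}.
#' @export
labelContextc <- function(hits, pairs) {
  hits <- rankHits(hits)
  hits$label <- character(nrow(hits))
  if (!nrow(hits)) return(hits)
  for (idx in split(seq_len(nrow(hits)), hits$protein_id)) {
    for (j in seq_along(idx)) {
      i <- idx[j]
      hits$label[i] <- if (j == 1L) "TP" else {
        prior <- hits$family_id[idx[seq_len(j - 1L)]]
        if (any(pairContains(pairs, hits$family_id[i], prior))) "TP" else "FP"
      }
    }
  }
  hits
}

#' Per-protein empirical FDR
#'
#' epFDR of one protein: FP / (TP + FP) over its labeled hits; REMOVED
#' hits are excluded from both counts.
#'
#' @param labels character vector of labels for one protein's hits.
#' @return the protein's empirical FDR.
#' @export
proteinEpfdr <- function(labels) {
  tp <- sum(labels == "TP"); fp <- sum(labels == "FP")
  if (tp + fp == 0)
    stop("undefined epFDR: protein has no countable (TP/FP) hits")
  fp / (tp + fp)
}

#' Method-level empirical FDR
#'
#' Averages the per-protein empirical FDRs over all proteins with at least
#' one countable hit (so proteins with hundreds of domains weigh the same
#' as proteins with one), and totals FPs across all proteins and families
#' as the empirical E-value.
#'
#' @param labeledHits hit table with \code{protein_id} and \code{label}
#'   columns (output of \code{\link{labelClanov}} or
#'   \code{\link{labelContextc}}).
#' @return list with \code{meanEpfdr}, \code{seEpfdr} (standard error over
#'   proteins), \code{empiricalEvalue} (total FP count) and
#'   \code{nProteins}; all-NA with \code{nProteins = 0} when no protein
#'   has countable hits.
#' @export
methodLevelFdr <- function(labeledHits) {
  keep <- labeledHits$label %in% c("TP", "FP")
  h <- labeledHits[keep, , drop = FALSE]
  if (!nrow(h))
    return(list(meanEpfdr = NA_real_, seEpfdr = NA_real_,
                empiricalEvalue = 0, nProteins = 0L))
  per <- vapply(split(h$label, h$protein_id), proteinEpfdr, numeric(1))
  list(
    meanEpfdr = mean(per),
    seEpfdr = if (length(per) > 1L) stats::sd(per) / sqrt(length(per))
              else NA_real_,
    empiricalEvalue = sum(h$label == "FP"),
    nProteins = length(per)
  )
}

#' Reversed-sequence decoys
#'
#' Character-reverses every protein sequence (the classical decoy set for
#' target-decoy FDR estimation); identifiers get a "_rev" suffix.  Empty
#' sequences are skipped with a warning.
#'
#' @param records an \code{AAStringSet} (or named character vector).
#' @return an \code{AAStringSet} of reversed sequences, lengths preserved.
#' @export
reverseSequences <- function(records) {
  x <- Biostrings::AAStringSet(records)
  empty <- Biostrings::width(x) == 0L
  if (any(empty)) {
    warning(sum(empty), " empty sequence(s) skipped")
    x <- x[!empty]
  }
  out <- Biostrings::reverse(x)
  names(out) <- paste0(names(x), "_rev")
  out
}

#' MarkovModel: second-order residue model of a protein corpus
#'
#' @slot alphabet residue characters observed in the corpus.
#' @slot initPair distribution over ordered residue pairs at sequence
#'   starts (length K^2, row-major in the first residue).
#' @slot trans K^2 x K matrix: P(next | previous two); unseen contexts are
#'   filled in from the lower-order fallbacks, so every row sums to 1.
#' @slot order1 K x K fallback P(next | previous).
#' @slot order0 length-K marginal residue distribution.
#' @slot lengths training sequence lengths (the default length source for
#'   generation).
#' @aliases MarkovModel-class
#' @exportClass MarkovModel
setClass("MarkovModel",
  representation(alphabet = "character", initPair = "numeric",
                 trans = "matrix", order1 = "matrix", order0 = "numeric",
                 lengths = "numeric"))

setValidity("MarkovModel", function(object) {
  K <- length(object@alphabet)
  msg <- character(0)
  if (!K) msg <- c(msg, "alphabet with zero symbols")
  if (length(object@initPair) != K * K ||
      abs(sum(object@initPair) - 1) > 1e-9)
    msg <- c(msg, "initPair must be a distribution over K^2 ordered pairs")
  if (!all(dim(object@trans) == c(K * K, K)) ||
      any(abs(rowSums(object@trans) - 1) > 1e-9))
    msg <- c(msg, "trans rows must be K^2 distributions over K symbols")
  if (any(object@trans < 0) || any(object@initPair < 0))
    msg <- c(msg, "probabilities must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MarkovModel", function(object) {
  cat("Second-order MarkovModel over alphabet {",
      paste(object@alphabet, collapse = ""), "}, trained on ",
      length(object@lengths), " sequences\n", sep = "")
})

#' Train a second-order Markov model on protein sequences
#'
#' Counts residue trigrams over the corpus and converts them into
#' transition probabilities P(next | previous two); the initial-pair
#' distribution comes from sequence starts, and order-1 / order-0
#' fallbacks (used to fill contexts never seen in training) from the same
#' corpus.
#'
#' @param records an \code{AAStringSet} or named character vector; total
#'   residues >= 1000 recommended.
#' @param order model order; only 2 is supported.
#' @return a \linkS4class{MarkovModel}.
#' @export
trainMarkov <- function(records, order = 2) {
  if (order != 2) stop("only order = 2 is implemented")
  seqs <- as.character(Biostrings::AAStringSet(records))
  seqs <- seqs[nchar(seqs) > 0]
  if (!length(seqs)) stop("alphabet with zero counts: empty corpus")
  chars <- strsplit(seqs, "", fixed = TRUE)
  alphabet <- sort(unique(unlist(chars, use.names = FALSE)))
  K <- length(alphabet)
  codes <- lapply(chars, match, table = alphabet)
  order0 <- tabulate(unlist(codes, use.names = FALSE), nbins = K)
  initPair <- numeric(K * K)
  trig <- numeric(K * K * K)
  big <- numeric(K * K)
  for (v in codes) {
    n <- length(v)
    if (n >= 2) {
      ip <- (v[1] - 1) * K + v[2]
      initPair[ip] <- initPair[ip] + 1
      bi <- (v[-n] - 1) * K + v[-1]
      big <- big + tabulate(bi, nbins = K * K)
    }
    if (n >= 3) {
      ctx <- (v[1:(n - 2)] - 1) * K + v[2:(n - 1)]
      tri <- (ctx - 1) * K + v[3:n]
      trig <- trig + tabulate(tri, nbins = K * K * K)
    }
  }
  order0 <- order0 / sum(order0)
  if (sum(initPair) == 0) stop("no sequence of length >= 2 in corpus")
  initPair <- initPair / sum(initPair)
  o1 <- matrix(big, nrow = K, ncol = K, byrow = TRUE)
  o1rs <- rowSums(o1)
  o1 <- o1 / ifelse(o1rs > 0, o1rs, 1)
  o1[o1rs == 0, ] <- rep(order0, each = sum(o1rs == 0))
  trans <- matrix(trig, nrow = K * K, ncol = K, byrow = TRUE)
  rs <- rowSums(trans)
  trans <- trans / ifelse(rs > 0, rs, 1)
  # unseen contexts fall back to P(next | previous), i.e. the second
  # residue of the context, then to the marginal
  if (any(rs == 0)) {
    prev2 <- rep(seq_len(K), times = K)  # second residue of each context
    trans[rs == 0, ] <- o1[prev2[rs == 0], , drop = FALSE]
  }
  new("MarkovModel", alphabet = alphabet, initPair = initPair,
      trans = trans, order1 = o1, order0 = order0,
      lengths = as.numeric(nchar(seqs)))
}

#' Generate random protein sequences from a Markov model
#'
#' Draws each sequence length with replacement from the training length
#' distribution (or a supplied list), the first two residues from the
#' initial-pair distribution, and subsequent residues from the
#' second-order transitions.  Identical seeds give identical output.
#'
#' @param model a \linkS4class{MarkovModel}.
#' @param n number of sequences.
#' @param lengths optional numeric vector to sample lengths from
#'   (defaults to the training lengths).
#' @param seed integer seed (required for reproducibility).
#' @param prefix identifier prefix for the generated records.
#' @return an \code{AAStringSet} of n sequences.
#' @export
generateMarkovSequences <- function(model, n, lengths = NULL, seed,
                                    prefix = "markov") {
  stopifnot(is(model, "MarkovModel"))
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (n == 0) return(Biostrings::AAStringSet())
  set.seed(as.integer(seed))
  if (is.null(lengths)) lengths <- model@lengths
  K <- length(model@alphabet)
  len <- pmax(2L, as.integer(sample(lengths, n, replace = TRUE)))
  maxlen <- max(len)
  mat <- matrix(NA_integer_, nrow = n, ncol = maxlen)
  ip <- sample.int(K * K, n, replace = TRUE, prob = model@initPair)
  mat[, 1] <- (ip - 1L) %/% K + 1L
  mat[, 2] <- (ip - 1L) %% K + 1L
  cumTrans <- t(apply(model@trans, 1L, cumsum))
  if (maxlen >= 3) for (p in 3:maxlen) {
    act <- which(len >= p)
    if (!length(act)) next
    ctx <- (mat[act, p - 2] - 1L) * K + mat[act, p - 1]
    u <- runif(length(act))
    mat[act, p] <- rowSums(cumTrans[ctx, , drop = FALSE] < u) + 1L
  }
  out <- vapply(seq_len(n), function(i)
    paste(model@alphabet[mat[i, seq_len(len[i])]], collapse = ""),
    character(1))
  res <- Biostrings::AAStringSet(out)
  names(res) <- sprintf("%s_%0*d", prefix, nchar(as.character(n)),
                        seq_len(n))
  res
}

#' Decoy-based FDR estimate per threshold
#'
#' Target-decoy FDR: the number of decoy hits passing each threshold,
#' scaled by the real-to-decoy sequence-count ratio, divided by the number
#' of real hits passing, capped at 1.
#'
#' @param realPassing,decoyPassing non-negative counts per threshold
#'   (vectors of equal length).
#' @param nRealSeqs,nDecoySeqs sizes of the real and decoy sequence sets.
#' @return numeric FDR per threshold; NA where no real hit passes.
#' @export
decoyFdr <- function(realPassing, decoyPassing, nRealSeqs, nDecoySeqs) {
  stopifnot(length(realPassing) == length(decoyPassing),
            all(realPassing >= 0), all(decoyPassing >= 0), nDecoySeqs > 0)
  est <- decoyPassing * (nRealSeqs / nDecoySeqs) / realPassing
  est[realPassing == 0] <- NA_real_
  pmin(1, est)
}
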