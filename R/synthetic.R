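#' SimConfig: synthetic domain-prediction study configuration
#'
#' Parameters of the synthetic data generator.  Each family j is a stratum
#' with its own two-component p-value mixture (null mass pi0_j, Beta(a_j, 1)
#' alternative); a configurable fraction of families are repeat-domain
#' families whose truly-present proteins carry several individually-weak
#' domain units, the scenario where sequence-level (tiered) statistics pay
#' off.  The seed is mandatory: identical configurations give identical
#' datasets.
#'
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nFamilies = "integer", pi0 = "numeric", altShape = "numeric",
    nProteins = "integer", censorC = "numeric",
    familiesPerClan = "integer", contextDensity = "numeric",
    lengthMean = "numeric", repeatFraction = "numeric",
    repeatUnits = "integer", repeatUnitShape = "numeric",
    withSequences = "logical", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nFamilies < 1) msg <- c(msg, "nFamilies must be >= 1")
  if (object@nProteins < 1)
    msg <- c(msg, "infeasible config: zero proteins")
  if (any(object@pi0 < 0 | object@pi0 > 1, na.rm = TRUE))
    msg <- c(msg, "pi0 must lie in [0, 1]")
  if (any(object@altShape <= 0 | object@altShape > 1, na.rm = TRUE))
    msg <- c(msg, "altShape must lie in (0, 1]")
  if (object@censorC <= 0 || object@censorC > 1)
    msg <- c(msg, "censorC must lie in (0, 1]")
  if (object@repeatFraction < 0 || object@repeatFraction > 1)
    msg <- c(msg, "repeatFraction must lie in [0, 1]")
  if (object@contextDensity < 0 || object@contextDensity > 1)
    msg <- c(msg, "contextDensity must lie in [0, 1]")
  if (is.na(object@seed)) msg <- c(msg, "a seed is mandatory")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' @param nFamilies number of domain families (strata).
#' @param pi0 per-family null mass; scalar recycled, or NA to draw each
#'   family's value uniformly in [0.8, 0.95] (families differ in how many
#'   proteins truly carry them).
#' @param altShape per-family Beta(a, 1) alternative shape; scalar
#'   recycled, or NA to draw uniformly in [0.15, 0.35].
#' @param nProteins proteins scanned (tests per stratum).
#' @param censorC reporting cutoff for domain p-values (default 0.01).
#' @param familiesPerClan consecutive families grouped per clan (default
#'   2; a trailing remainder stays clanless).
#' @param contextDensity probability that a truly co-occurring family pair
#'   is recorded in the context list L (default 1).
#' @param lengthMean mean protein length (gamma-distributed, shape 4).
#' @param repeatFraction fraction of families that are repeat-domain
#'   families (default 0.25).
#' @param repeatUnits domain units per truly-present protein in repeat
#'   families (default 4).
#' @param repeatUnitShape shape of the truncated unit-level alternative in
#'   repeat families: unit p-values are censorC * U^(1/shape), i.e. the
#'   Beta(shape, 1) alternative conditioned on being reported.  The
#'   default 0.6 makes single units individually weak (median p about
#'   3e-3) while their combination is strongly significant -- the scenario
#'   where sequence-level evidence outperforms domain-level evidence.
#' @param withSequences also generate protein FASTA records (default TRUE).
#' @param seed integer seed (mandatory).
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(nFamilies = 12, pi0 = NA_real_,
                      altShape = NA_real_, nProteins = 1000,
                      censorC = 0.01, familiesPerClan = 2L,
                      contextDensity = 1, lengthMean = 400,
                      repeatFraction = 0.25, repeatUnits = 4L,
                      repeatUnitShape = 0.6, withSequences = TRUE, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  new("SimConfig", nFamilies = as.integer(nFamilies),
      pi0 = rep_len(as.numeric(pi0), nFamilies),
      altShape = rep_len(as.numeric(altShape), nFamilies),
      nProteins = as.integer(nProteins), censorC = censorC,
      familiesPerClan = as.integer(familiesPerClan),
      contextDensity = contextDensity, lengthMean = lengthMean,
      repeatFraction = repeatFraction,
      repeatUnits = as.integer(repeatUnits),
      repeatUnitShape = repeatUnitShape,
      withSequences = withSequences, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nFamilies, "families x", object@nProteins,
      "proteins, censored at p <=", object@censorC, "; seed",
      object@seed, "\n")
})

# background residue frequencies (rough natural amino acid composition)
aaBackground <- function() {
  f <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9, E = 6.7,
         G = 7.1, H = 2.3, I = 5.9, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
         P = 4.7, S = 6.6, T = 5.4, W = 1.1, Y = 2.9, V = 6.9)
  f / sum(f)
}

#' Generate a complete ground-truthed synthetic dataset
#'
#' Draws, for every (protein, family) pair, a null/alternative state with
#' probability pi0_j; null domain p-values are Uniform(0, 1) and
#' alternative ones Beta(a_j, 1) (repeat families draw
#' \code{repeatUnits} alternative units per present protein).  Only hits
#' with p <= censorC are reported.  Sequence p-values combine each pair's
#' domain p-values (reported or not) by Fisher's method.  Alternative hits
#' get non-overlapping envelope coordinates laid out along the protein;
#' null hits land at random positions.  Families are interleaved into
#' co-occurrence modules (about four families each) and, where the
#' marginal presence probability permits, occur only on their module's
#' proteins -- this keeps truly co-occurring family pairs sparse, so
#' context-coherence labeling has cross-module noise to detect.  Clans
#' group consecutive families; the context list L records truly
#' co-occurring family pairs (including self-pairs of repeat families);
#' the nesting whitelist holds the clan partners of repeat families
#' (overlap-tolerant pairs).
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with \code{hits} (reported hit table), \code{truth}
#'   (list: \code{isNull} per reported hit, \code{presence} data.frame of
#'   truly-present pairs, \code{repeatFamilies}, \code{pi0},
#'   \code{altShape}), \code{clanMap} (named vector), \code{nesting},
#'   \code{contextPairs} (\code{\link{familyPairs}} tables), and
#'   \code{proteins} (AAStringSet, or NULL).
#' @examples
#' sim <- generateDataset(simConfig(nFamilies = 4, nProteins = 300,
#'                                  seed = 7))
#' table(sim$truth$isNull)
#' @export
generateDataset <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  J <- config@nFamilies; N <- config@nProteins; cc <- config@censorC
  famIds <- sprintf("fam_%02d", seq_len(J))
  protIds <- sprintf("prot_%04d", seq_len(N))
  nRepeat <- floor(config@repeatFraction * J)
  isRepeat <- seq_len(J) <= nRepeat
  pi0 <- config@pi0
  # defaults: ordinary families are moderately common; repeat families
  # are rare (their whole signal sits in combining weak units, the case
  # where a protein family sparsely populates the database)
  nap <- is.na(pi0)
  pi0[nap & isRepeat] <- runif(sum(nap & isRepeat), 0.95, 0.99)
  pi0[nap & !isRepeat] <- runif(sum(nap & !isRepeat), 0.8, 0.95)
  a <- config@altShape
  a[is.na(a)] <- runif(sum(is.na(a)), 0.15, 0.35)
  domLen <- sample(30:120, J, replace = TRUE)

  # clans over consecutive families; remainder left clanless
  fpc <- max(1L, config@familiesPerClan)
  nClans <- J %/% fpc
  clanMap <- setNames(rep(NA_character_, J), famIds)
  if (nClans >= 1) {
    grp <- rep(seq_len(nClans), each = fpc)
    clanMap[seq_along(grp)] <- sprintf("clan_%02d", grp)
  }

  lengths <- pmax(80L, as.integer(round(
    rgamma(N, shape = 4, scale = config@lengthMean / 4))))

  # co-occurrence modules: families only occur on proteins of their
  # module (marginal presence probability preserved), so the context
  # list stays sparse across modules the way real domain co-occurrence
  # is; families too common to fit their module occur globally
  nModules <- max(1L, J %/% 4L)
  famModule <- ((seq_len(J) - 1L) %% nModules) + 1L
  protModule <- sample.int(nModules, N, replace = TRUE)

  rows <- vector("list", J)
  presence <- vector("list", J)
  usedEnd <- integer(N)   # residues consumed by true domains per protein
  for (j in seq_len(J)) {
    pAlt <- 1 - pi0[j]
    present <- if (nModules > 1L && nModules * pAlt <= 1)
      protModule == famModule[j] & runif(N) < nModules * pAlt
    else runif(N) < pAlt
    nUnits <- ifelse(present, if (isRepeat[j]) config@repeatUnits else 1L,
                     1L)
    protein <- rep(seq_len(N), times = nUnits)
    alt <- rep(present, times = nUnits)
    nDraw <- length(protein)
    p <- numeric(nDraw)
    p[!alt] <- runif(sum(!alt))
    p[alt] <- if (isRepeat[j])
      cc * runif(sum(alt))^(1 / config@repeatUnitShape)
    else runif(sum(alt))^(1 / a[j])
    # sequence p-value per (protein, family): Fisher over the pair's units
    stat <- tapply(-2 * log(p), protein, sum)
    nUnitsOf <- tapply(p, protein, length)
    pseq <- setNames(pchisq(as.numeric(stat), df = 2 * as.numeric(nUnitsOf),
                            lower.tail = FALSE), names(stat))
    keep <- p <= cc
    if (any(keep)) {
      kp <- protein[keep]
      start <- integer(sum(keep)); endv <- integer(sum(keep))
      kalt <- alt[keep]
      # true domains: consecutive non-overlapping blocks along the protein
      for (i in which(kalt)) {
        pr <- kp[i]
        s <- usedEnd[pr] + 1L
        e <- s + domLen[j] - 1L
        if (e > lengths[pr]) lengths[pr] <- e + 10L  # grow to fit truth
        usedEnd[pr] <- e + 2L
        start[i] <- s; endv[i] <- e
      }
      for (i in which(!kalt)) {     # spurious matches: random placement
        pr <- kp[i]
        s <- sample.int(max(1L, lengths[pr] - domLen[j] + 1L), 1L)
        start[i] <- s; endv[i] <- min(lengths[pr], s + domLen[j] - 1L)
      }
      rows[[j]] <- data.frame(
        protein_id = protIds[kp],
        family_id = famIds[j],
        clan_id = unname(clanMap[j]),
        env_start = start, env_end = endv,
        bitscore = round(-log2(p[keep]) + stats::rnorm(sum(keep)), 1),
        p_domain = p[keep],
        p_sequence = pmin(1, pmax(pseq[as.character(kp)],
                                  .Machine$double.xmin)),
        is_null = !kalt,
        row.names = NULL)
    }
    presence[[j]] <- data.frame(protein_id = protIds[present],
                                family_id = rep(famIds[j], sum(present)))
  }
  hits <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(hits))
    hits <- data.frame(protein_id = character(0), family_id = character(0),
                       clan_id = character(0), env_start = integer(0),
                       env_end = integer(0), bitscore = numeric(0),
                       p_domain = numeric(0), p_sequence = numeric(0),
                       is_null = logical(0))
  isNull <- hits$is_null
  hits$is_null <- NULL
  presence <- do.call(rbind, presence)

  # context pairs: family pairs truly co-occurring in >= 1 protein,
  # sampled at contextDensity; repeat families pair with themselves
  byProt <- split(presence$family_id, presence$protein_id)
  co <- unique(do.call(rbind, lapply(byProt, function(f) {
    f <- unique(f)
    if (length(f) < 2) return(NULL)
    t(utils::combn(sort(f), 2))
  })))
  ctx <- familyPairs()
  if (!is.null(co) && nrow(co)) {
    pick <- runif(nrow(co)) <= config@contextDensity
    ctx <- familyPairs(co[pick, 1], co[pick, 2])
  }
  ctx <- rbind(ctx, familyPairs(famIds[isRepeat], famIds[isRepeat]))

  # nesting whitelist: same-clan partners of repeat families (their
  # overlaps are tolerated)
  nest <- familyPairs()
  for (j in which(isRepeat)) {
    mates <- famIds[which(clanMap == clanMap[j] & famIds != famIds[j])]
    if (!is.na(clanMap[j]) && length(mates))
      nest <- rbind(nest, familyPairs(famIds[j], mates))
  }

  proteins <- NULL
  if (config@withSequences) {
    bg <- aaBackground()
    proteins <- Biostrings::AAStringSet(vapply(seq_len(N), function(i)
      paste(sample(names(bg), lengths[i], replace = TRUE, prob = bg),
            collapse = ""), character(1)))
    names(proteins) <- protIds
  }

  list(hits = hits,
       truth = list(isNull = isNull, presence = presence,
                    repeatFamilies = famIds[isRepeat],
                    pi0 = setNames(pi0, famIds),
                    altShape = setNames(a, famIds)),
       clanMap = clanMap, nesting = nest, contextPairs = ctx,
       proteins = proteins)
}
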