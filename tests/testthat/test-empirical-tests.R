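clanMapToy <- c(famA = "clanX", famB = "clanX", famC = "clanY")

test_that("ClanOv labels follow the same-clan/different-clan rules", {
  single <- hit("p", "famA", 1, 100, 1e-9, clan = "clanX")
  expect_equal(labelClanov(single, clanMapToy)$label, "TP")
  sameClan <- hitTable(hit("p", "famA", 1, 100, 1e-9),
                       hit("p", "famB", 50, 150, 1e-5))
  expect_equal(labelClanov(sameClan, clanMapToy)$label,
               c("TP", "REMOVED"))
  crossClan <- hitTable(hit("p", "famA", 1, 100, 1e-9),
                        hit("p", "famC", 50, 150, 1e-5))
  expect_equal(labelClanov(crossClan, clanMapToy)$label, c("TP", "FP"))
})

test_that("ClanOv honours nesting pairs and blocking by FP hits", {
  crossClan <- hitTable(hit("p", "famA", 1, 100, 1e-9),
                        hit("p", "famC", 50, 150, 1e-5))
  nested <- labelClanov(crossClan, clanMapToy,
                        nesting = familyPairs("famA", "famC"))
  expect_equal(nested$label, c("TP", "TP"))
  # famC is an FP vs famA but still blocks the same-clan famC2 later
  clanMap2 <- c(clanMapToy, famC2 = "clanY")
  three <- hitTable(hit("p", "famA", 1, 100, 1e-9),
                    hit("p", "famC", 50, 150, 1e-5),
                    hit("p", "famC2", 80, 180, 1e-4))
  expect_equal(labelClanov(three, clanMap2)$label,
               c("TP", "FP", "REMOVED"))
  # a REMOVED hit does not block later hits
  clanMap3 <- c(famA = "clanX", famB = "clanX", famD = "clanZ")
  four <- hitTable(hit("p", "famA", 1, 100, 1e-9),
                   hit("p", "famB", 60, 200, 1e-6),
                   hit("p", "famD", 150, 260, 1e-4))
  expect_equal(labelClanov(four, clanMap3)$label,
               c("TP", "REMOVED", "TP"))
})

test_that("clanless families behave as singleton clans", {
  # two clanless families overlapping: different singleton clans -> FP
  h <- hitTable(hit("p", "noclan1", 1, 100, 1e-9),
                hit("p", "noclan2", 50, 150, 1e-5))
  expect_equal(labelClanov(h, clanMapToy)$label, c("TP", "FP"))
  # the same clanless family twice: same singleton clan -> REMOVED
  h2 <- hitTable(hit("p", "noclan1", 1, 100, 1e-9),
                 hit("p", "noclan1", 50, 150, 1e-5))
  expect_equal(labelClanov(h2, clanMapToy)$label, c("TP", "REMOVED"))
})

test_that("ContextC labels by pair membership with rank-1 always TP", {
  single <- hit("p", "famA", 1, 100, 1e-9)
  expect_equal(labelContextc(single, familyPairs())$label, "TP")
  two <- hitTable(hit("p", "famA", 1, 100, 1e-9),
                  hit("p", "famB", 150, 250, 1e-5))
  expect_equal(labelContextc(two, familyPairs("famA", "famB"))$label,
               c("TP", "TP"))
  # only (B, C) in L: B has no pair with A -> FP; C pairs with B -> TP,
  # regardless of B's own label
  three <- hitTable(hit("p", "famA", 1, 100, 1e-9),
                    hit("p", "famB", 150, 250, 1e-6),
                    hit("p", "famC", 300, 400, 1e-4))
  expect_equal(labelContextc(three, familyPairs("famB", "famC"))$label,
               c("TP", "FP", "TP"))
  # self-pairs cover repeating families
  rep2 <- hitTable(hit("p", "famR", 1, 100, 1e-8),
                   hit("p", "famR", 150, 250, 1e-5))
  expect_equal(labelContextc(rep2, familyPairs("famR", "famR"))$label,
               c("TP", "TP"))
  expect_equal(labelContextc(rep2, familyPairs())$label, c("TP", "FP"))
})

test_that("ContextC limit cases: complete and empty pair lists", {
  set.seed(22)
  fams <- sprintf("f%02d", 1:6)
  h <- do.call(rbind, lapply(1:30, function(i)
    hit(sprintf("p%02d", sample(1:8, 1)), sample(fams, 1),
        s <- sample(1:500, 1), s + 40, 10^runif(1, -9, -2))))
  allPairs <- do.call(rbind, c(
    lapply(seq_along(fams), function(i)
      familyPairs(fams[i], fams[i:length(fams)]))))
  labAll <- labelContextc(h, allPairs)
  expect_true(all(labAll$label == "TP"))
  labNone <- labelContextc(h, familyPairs())
  tpPerProt <- tapply(labNone$label == "TP", labNone$protein_id, sum)
  expect_true(all(tpPerProt == 1))
})

test_that("per-protein and method-level empirical FDRs aggregate correctly", {
  expect_equal(proteinEpfdr(c("TP")), 0)
  expect_equal(proteinEpfdr(c("FP")), 1)
  expect_equal(proteinEpfdr(c("TP", "TP", "TP", "FP")), 0.25)
  expect_equal(proteinEpfdr(c("TP", "REMOVED", "FP")), 0.5)
  expect_error(proteinEpfdr(c("REMOVED")), "no countable")

  lab <- data.frame(
    protein_id = c("a", "a", "b", "b", "b", "b"),
    label = c("TP", "FP", "TP", "TP", "TP", "FP"))
  r <- methodLevelFdr(lab)
  expect_equal(r$meanEpfdr, mean(c(0.5, 0.25)))
  expect_equal(r$empiricalEvalue, 2)
  expect_equal(r$nProteins, 2)
  # invariant to protein ordering
  r2 <- methodLevelFdr(lab[sample(nrow(lab)), ])
  expect_equal(r2$meanEpfdr, r$meanEpfdr)
  # all-TP and all-FP limits
  expect_equal(methodLevelFdr(data.frame(protein_id = "a",
                                         label = "TP"))$meanEpfdr, 0)
  oneFp <- methodLevelFdr(data.frame(protein_id = c("a", "a"),
                                     label = c("FP", "FP")))
  expect_equal(oneFp$meanEpfdr, 1)
  expect_equal(oneFp$empiricalEvalue, 2)
  empty <- methodLevelFdr(data.frame(protein_id = character(0),
                                     label = character(0)))
  expect_equal(empty$nProteins, 0)
})

test_that("non-overlapping ClanOv hit sets have zero empirical FDR", {
  h <- hitTable(hit("p1", "famA", 1, 100, 1e-9),
                hit("p1", "famC", 200, 300, 1e-5),
                hit("p2", "famB", 1, 80, 1e-4))
  lab <- labelClanov(h, clanMapToy)
  expect_true(all(lab$label == "TP"))
  expect_equal(methodLevelFdr(lab)$meanEpfdr, 0)
})

test_that("sequence reversal preserves lengths and marks decoys", {
  x <- Biostrings::AAStringSet(c(s1 = "ACD", s2 = "ACA", s3 = "MKLV"))
  r <- reverseSequences(x)
  expect_equal(as.character(r),
               c(s1_rev = "DCA", s2_rev = "ACA", s3_rev = "VLKM"))
  expect_equal(Biostrings::width(r), Biostrings::width(x))
  expect_warning(reverseSequences(c(a = "MK", b = "")), "empty")
})

test_that("a single-letter corpus trains a deterministic model", {
  m <- trainMarkov(c(a = "AAAAAAAA", b = "AAAA"))
  expect_equal(m@alphabet, "A")
  expect_equal(as.numeric(m@trans), 1)
  g <- generateMarkovSequences(m, 3, seed = 1)
  expect_true(all(grepl("^A+$", as.character(g))))
})

test_that("Markov model distributions are proper and generation is seed-deterministic", {
  set.seed(23)
  corpus <- Biostrings::AAStringSet(vapply(1:40, function(i)
    paste(sample(c("A", "C", "D", "E", "G"), sample(50:150, 1),
                 replace = TRUE, prob = c(0.3, 0.1, 0.2, 0.25, 0.15)),
          collapse = ""), character(1)))
  names(corpus) <- paste0("s", 1:40)
  m <- trainMarkov(corpus)
  expect_equal(sum(m@initPair), 1)
  expect_true(all(abs(rowSums(m@trans) - 1) < 1e-9))
  expect_true(all(m@trans >= 0))
  g1 <- generateMarkovSequences(m, 20, seed = 99)
  g2 <- generateMarkovSequences(m, 20, seed = 99)
  expect_identical(as.character(g1), as.character(g2))
  g3 <- generateMarkovSequences(m, 20, seed = 100)
  expect_false(identical(as.character(g1), as.character(g3)))
})

test_that("generated trigram frequencies match training within 3 SE", {
  set.seed(24)
  alpha <- c("A", "C", "D", "E")
  corpus <- vapply(1:30, function(i)
    paste(sample(alpha, 400, replace = TRUE,
                 prob = c(0.4, 0.1, 0.3, 0.2)), collapse = ""),
    character(1))
  names(corpus) <- paste0("s", 1:30)
  m <- trainMarkov(corpus)
  g <- generateMarkovSequences(m, 300, lengths = 400, seed = 7)
  countTri <- function(seqs) {
    v <- unlist(lapply(strsplit(as.character(seqs), ""), match,
                       table = alpha))
    tab <- numeric(64)
    for (s in strsplit(as.character(seqs), "")) {
      vv <- match(s, alpha); n <- length(vv)
      idx <- (vv[1:(n - 2)] - 1) * 16 + (vv[2:(n - 1)] - 1) * 4 + vv[3:n]
      tab <- tab + tabulate(idx, nbins = 64)
    }
    tab
  }
  trTrain <- countTri(corpus); trGen <- countTri(g)
  pTrain <- trTrain / sum(trTrain)
  pGen <- trGen / sum(trGen)
  # both sides are sampled, so the SE of the difference pools them
  se <- sqrt(pTrain * (1 - pTrain) * (1 / sum(trGen) + 1 / sum(trTrain)))
  expect_true(all(abs(pGen - pTrain) <= 3 * se + 1e-12))
})

test_that("generated sequence lengths follow the source distribution", {
  set.seed(25)
  lens <- sample(60:400, 2000, replace = TRUE)
  m <- trainMarkov(c(a = paste(rep("AC", 600), collapse = ""),
                     b = paste(rep("CA", 600), collapse = "")))
  g <- generateMarkovSequences(m, 2000, lengths = lens, seed = 3)
  ks <- suppressWarnings(ks.test(Biostrings::width(g), lens))
  expect_gt(ks$p.value, 0.01)
})

test_that("decoy FDR scales by set size and is capped", {
  expect_equal(decoyFdr(100, 0, 1000, 1000), 0)
  expect_equal(decoyFdr(100, 5, 1000, 1000), 0.05)
  expect_equal(decoyFdr(100, 10, 1000, 500), 0.2)   # decoy set half size
  expect_equal(decoyFdr(10, 50, 1000, 1000), 1)     # capped
  expect_true(is.na(decoyFdr(0, 5, 1000, 1000)))
  expect_equal(decoyFdr(c(100, 50), c(5, 5), 100, 100), c(0.05, 0.1))
})

test_that("ContextC epFDR tracks the true per-protein FDP on ground-truthed data", {
  cfg <- simConfig(nFamilies = 16, nProteins = 1500, pi0 = 0.75,
                   altShape = 0.15, repeatFraction = 0, seed = 91,
                   withSequences = FALSE)
  sim <- generateDataset(cfg)
  ann <- stratifiedStats(sim$hits, nTotal = 1500, withLfdr = FALSE)
  key <- function(d) paste(d$protein_id, d$family_id, d$env_start)
  isNull <- sim$truth$isNull[match(key(ann), key(sim$hits))]
  for (qt in c(1e-3, 1e-2, 1e-1)) {
    s <- !is.na(ann$qvalue) & ann$qvalue <= qt
    lab <- labelContextc(ann[s, ], sim$contextPairs)
    ctx <- methodLevelFdr(lab)
    nl <- isNull[s][match(key(lab), key(ann[s, ]))]
    cnt <- lab$label != "REMOVED"
    perProt <- tapply(nl[cnt], lab$protein_id[cnt], mean)
    expect_lt(abs(ctx$meanEpfdr - mean(perProt)), 0.05)
  }
})
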