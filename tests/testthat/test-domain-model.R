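test_that("ranking is by p-value with the stated deterministic tie-breaks", {
  empty <- hit("p", "f", 1, 10, 0.5)[0, ]
  expect_equal(nrow(rankHits(empty)), 0)
  h <- hitTable(hit("p1", "A", 1, 50, 1e-5),
                hit("p1", "B", 60, 120, 1e-9))
  expect_equal(rankHits(h)$family_id, c("B", "A"))
  tied <- hitTable(hit("p1", "A", 1, 50, 1e-5, bitscore = 40),
                   hit("p1", "B", 60, 120, 1e-5, bitscore = 50))
  expect_equal(rankHits(tied)$family_id, c("B", "A"))
  tied2 <- hitTable(hit("p1", "A", 1, 40, 1e-5, bitscore = 40),
                    hit("p1", "B", 1, 80, 1e-5, bitscore = 40))
  expect_equal(rankHits(tied2)$family_id, c("B", "A"))  # longer envelope
})

test_that("overlap predicate honours both modes and the fraction boundary", {
  a <- hit("p", "A", 1, 100, 1e-5)
  expect_false(regionsOverlap(a, hit("p", "B", 101, 200, 1e-4), "any"))
  expect_false(regionsOverlap(a, hit("p", "B", 101, 200, 1e-4),
                              "permissive"))
  expect_true(regionsOverlap(a, hit("p", "B", 100, 200, 1e-4), "any"))
  # shared = 40 is not > 0.4 * 100; shared = 41 is
  expect_false(regionsOverlap(a, hit("p", "B", 61, 160, 1e-4),
                              "permissive", frac = 0.4))
  expect_true(regionsOverlap(a, hit("p", "B", 60, 159, 1e-4),
                             "permissive", frac = 0.4))
  expect_error(regionsOverlap(a, hit("q", "B", 1, 100, 1e-4)),
               "different proteins")
})

test_that("overlap removal keeps the most significant hit and honours nesting", {
  disjoint <- hitTable(hit("p", "A", 1, 100, 1e-9),
                       hit("p", "B", 150, 250, 1e-5))
  expect_false(any(removeOverlaps(disjoint)$removed_overlap))
  over <- hitTable(hit("p", "A", 1, 100, 1e-9),
                   hit("p", "B", 50, 150, 1e-5))
  res <- removeOverlaps(over)
  expect_equal(res$removed_overlap, c(FALSE, TRUE))
  nest <- familyPairs("A", "B")
  resNest <- removeOverlaps(over, nesting = nest)
  expect_false(any(resNest$removed_overlap))
})

test_that("a removed hit does not block later hits (greedy against kept only)", {
  # B removed by A; C overlaps only B, so C stays
  h <- hitTable(hit("p", "A", 1, 100, 1e-9),
                hit("p", "B", 60, 200, 1e-6),
                hit("p", "C", 140, 240, 1e-4))
  res <- removeOverlaps(h)
  expect_equal(res$removed_overlap[match(c("A", "B", "C"), res$family_id)],
               c(FALSE, TRUE, FALSE))
})

test_that("overlap removal is invariant to input row order and keeps a maximal set", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 15
    h <- do.call(rbind, lapply(seq_len(n), function(i) {
      s <- sample(1:300, 1)
      hit("p1", sprintf("F%02d", i), s, s + sample(20:80, 1),
          10^runif(1, -9, -2))
    }))
    a <- removeOverlaps(h)
    b <- removeOverlaps(h[sample(n), ])
    keyA <- with(a[!a$removed_overlap, ], paste(family_id, env_start))
    keyB <- with(b[!b$removed_overlap, ], paste(family_id, env_start))
    expect_setequal(keyA, keyB)
    # maximality: every removed hit overlaps some kept hit
    kept <- a[!a$removed_overlap, ]
    for (i in which(a$removed_overlap)) {
      ov <- overlapFlag <- mapply(function(s, e)
        regionsOverlap(a[i, ], data.frame(protein_id = "p1",
                                          env_start = s, env_end = e)),
        kept$env_start, kept$env_end)
      expect_true(any(ov))
    }
  }
})

test_that("interpolation in log10 p reproduces exact nodes, midpoints and boundary rules", {
  kept <- hitTable(hit("p", "F", 1, 50, 1e-6),
                   hit("p", "F", 60, 110, 1e-4))
  kept$qvalue <- c(0.001, 0.01)
  kept$lfdr <- c(0.002, 0.02)
  rem <- hitTable(hit("p", "F", 10, 55, 1e-6),   # exact node
                  hit("p", "F", 20, 70, 1e-5),   # log-midpoint
                  hit("p", "F", 30, 80, 1e-8))   # below all kept
  out <- interpolateStats(rem, kept)
  expect_equal(out$qvalue, c(0.001, 0.0055, 0.001))
  expect_equal(out$lfdr, c(0.002, 0.011, 0.002))
  expect_error(interpolateStats(rem, kept[0, ]), "empty kept")
})

test_that("coverage metrics count domains, families, residues and proteins", {
  z <- coverageMetrics(hit("p", "F", 1, 10, 0.001)[0, ])
  expect_equal(unlist(z), c(domains = 0, uniqueFamilyProteinPairs = 0,
                            aminoAcidsCovered = 0,
                            proteinsWithPredictions = 0))
  h <- hitTable(hit("p1", "F", 1, 10, 1e-5),
                hit("p1", "F", 5, 20, 1e-4))
  m <- coverageMetrics(h)
  expect_equal(m$domains, 2)
  expect_equal(m$uniqueFamilyProteinPairs, 1)
  expect_equal(m$aminoAcidsCovered, 20)      # union of [1,10] and [5,20]
  expect_equal(m$proteinsWithPredictions, 1)
  h2 <- hitTable(hit("p1", "F", 1, 10, 1e-5),
                 hit("p2", "F", 1, 10, 1e-5))
  expect_equal(coverageMetrics(h2)$uniqueFamilyProteinPairs, 2)
  # removed hits are excluded when the flag is present
  h$removed_overlap <- c(FALSE, TRUE)
  expect_equal(coverageMetrics(h)$domains, 1)
})

test_that("annotation pipeline attaches monotone per-family statistics", {
  sim <- generateDataset(simConfig(nFamilies = 4, nProteins = 500,
                                   repeatFraction = 0, seed = 31,
                                   withSequences = FALSE))
  ann <- stratifiedStats(sim$hits, nTotal = 500)
  expect_true(all(c("evalue", "qvalue", "lfdr", "removed_overlap")
                  %in% names(ann)))
  expect_equal(ann$evalue, ann$p_domain * 500)
  for (f in unique(ann$family_id)) {
    k <- ann[ann$family_id == f & !ann$removed_overlap, ]
    k <- k[order(k$p_domain), ]
    expect_true(all(diff(k$qvalue) >= -1e-12))
    lf <- k$lfdr[!is.na(k$lfdr)]
    expect_true(all(diff(lf) >= -1e-12))
  }
  expect_true(all(!is.na(ann$qvalue)))
})
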