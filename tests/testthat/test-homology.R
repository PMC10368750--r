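profiles <- thresholdProfiles()

test_that("the shipped profile configuration reproduces the five cutoff
           sets exactly", {
  expect_equal(profiles$rbh@minPident, 70)
  expect_equal(profiles$rbh@minQcov, 70)
  expect_true(is.na(profiles$rbh@maxEvalue))
  expect_equal(profiles$est@minPident, 95)
  expect_equal(profiles$est@minQcov, 95)
  expect_equal(profiles$est@maxEvalue, 1e-5)
  expect_equal(profiles$own_lnc@topN, 3)
  expect_equal(profiles$zebrafish_lnc@minPident, 50)
  expect_equal(profiles$zebrafish_lnc@minQcov, 50)
  expect_equal(profiles$human_lnc@minQcov, 25)
  expect_equal(profiles$fish_screen@maxEvalue, 1e-3)
  expect_equal(profiles$fish_screen@minQcov, 60)
})

test_that("local alignment of identical and contained sequences gives
           full identity and coverage", {
  withr::with_seed(7, {
    s <- randomDnaOracle(300)
    h <- localAlign(s, s)
    expect_equal(h$pident, 100)
    expect_equal(h$qcovs, 100)
    long <- randomDnaOracle(500)
    frag <- substr(long, 101, 250)
    h2 <- localAlign(frag, long)
    expect_equal(h2$qcovs, 100)
    expect_equal(h2$pident, 100)
    # minus-strand hits are found and flagged by sstart > send
    h3 <- localAlign(revcompOracle(frag), long)
    expect_equal(h3$qcovs, 100)
    expect_gt(h3$sstart, h3$send)
  })
  expect_error(localAlign("", "ACGT"), "empty")
})

test_that("aligner score matches the quadratic-space DP oracle on random
           pairs", {
  withr::with_seed(31, {
    for (k in 1:60) {
      a <- randomDnaOracle(sample(20:80, 1))
      b <- randomDnaOracle(sample(20:80, 1))
      h <- localAlign(a, b)
      raw <- swOracle(a, b)
      if (raw <= 0) {
        expect_equal(nrow(h), 0)
      } else {
        expect_equal(h$bitscore, bitFromRaw(raw), tolerance = 1e-9)
      }
    }
  })
})

test_that("hit filtering is inclusive at every documented boundary and
           monotone in the thresholds", {
  mkHit <- function(pident, qcovs, evalue = 1e-10) {
    data.frame(qseqid = "q", sseqid = "s", pident = pident, length = 100,
               mismatch = 0, gapopen = 0, qstart = 1, qend = 100,
               sstart = 1, send = 100, evalue = evalue, bitscore = 180,
               qcovs = qcovs, stringsAsFactors = FALSE)
  }
  # boundary kept / one unit below rejected, for each profile
  cases <- list(
    list(profiles$est, 95, 95), list(profiles$rbh, 70, 70),
    list(profiles$zebrafish_lnc, 50, 50),
    list(profiles$human_lnc, 50, 25),
    list(profiles$fish_screen, 0, 60)
  )
  for (cs in cases) {
    p <- cs[[1]]
    expect_equal(nrow(filterHits(mkHit(cs[[2]], cs[[3]]), p)), 1,
                 info = p@name)
    expect_equal(nrow(filterHits(mkHit(cs[[2]], cs[[3]] - 1), p)), 0,
                 info = p@name)
    if (cs[[2]] > 0) {
      expect_equal(nrow(filterHits(mkHit(cs[[2]] - 1, cs[[3]]), p)), 0,
                   info = p@name)
    }
  }
  # e-value boundary inclusive
  expect_equal(nrow(filterHits(mkHit(99, 99, 1e-5), profiles$est)), 1)
  expect_equal(nrow(filterHits(mkHit(99, 99, 1.1e-5), profiles$est)), 0)

  # monotonicity: raising any threshold never grows the retained set
  hits <- randomHitTable(20, 20, seed = 5)
  base <- ThresholdProfile("b", minPident = 50, minQcov = 40,
                           maxEvalue = 1e-3)
  n0 <- nrow(filterHits(hits, base))
  for (p in list(ThresholdProfile("p", 1e-3, 60, 40),
                 ThresholdProfile("q", 1e-3, 50, 50),
                 ThresholdProfile("e", 1e-4, 50, 40))) {
    expect_lte(nrow(filterHits(hits, p)), n0)
  }
})

test_that("top-hit selection uses the total sort key", {
  h <- data.frame(
    qseqid = "q", sseqid = c("s1", "s2", "s3", "s4", "s5"),
    pident = c(90, 95, 95, 80, 85), length = 100, mismatch = 0,
    gapopen = 0, qstart = 1, qend = 100, sstart = 1, send = 100,
    evalue = c(1e-10, 1e-12, 1e-12, 1e-3, 1e-5),
    bitscore = c(200, 200, 200, 90, 120),
    qcovs = 100, stringsAsFactors = FALSE)
  top3 <- topHits(h, 3)
  # bitscore ties resolved by evalue, then pident, then subject id
  expect_setequal(top3$sseqid, c("s2", "s3", "s1"))
  expect_equal(topHits(h, 1)$sseqid, "s2")
  expect_equal(nrow(topHits(h[1:2, ], 3)), 2)
})

test_that("reciprocal best hits agree with the brute-force oracle on
           random tables and form a partial matching", {
  for (seed in c(11, 23, 37)) {
    hAB <- randomHitTable(15, 15, seed = seed)
    hBA <- randomHitTable(15, 15, seed = seed + 100)
    # reverse direction: set-B ids (s..) query against set-A ids (q..)
    tmp <- hBA$qseqid
    hBA$qseqid <- hBA$sseqid
    hBA$sseqid <- tmp
    got <- reciprocalBestHits(hAB, hBA, profiles$rbh)
    want <- rbhOracle(hAB, hBA)
    expect_equal(got[c("id_A", "id_B")], want,
                 ignore_attr = TRUE)
    expect_false(anyDuplicated(got$id_A) > 0)
    expect_false(anyDuplicated(got$id_B) > 0)
  }
})

test_that("one-sided best hits do not produce pairs", {
  mk <- function(q, s, bit) {
    data.frame(qseqid = q, sseqid = s, pident = 99, length = 100,
               mismatch = 0, gapopen = 0, qstart = 1, qend = 100,
               sstart = 1, send = 100, evalue = 1e-20, bitscore = bit,
               qcovs = 100, stringsAsFactors = FALSE)
  }
  hAB <- rbind(mk("a1", "b1", 300))
  hBA <- rbind(mk("b1", "a2", 300), mk("b1", "a1", 200))
  expect_equal(nrow(reciprocalBestHits(hAB, hBA, profiles$rbh)), 0)
  hBA2 <- rbind(mk("b1", "a1", 300))
  pair <- reciprocalBestHits(hAB, hBA2, profiles$rbh)
  expect_equal(pair$id_A, "a1")
  expect_equal(pair$id_B, "b1")
})

test_that("EST validation follows the 95/95 profile on planted ESTs", {
  tx <- data.frame(transcript_id = sprintf("c%02d", 1:8),
                   length = rep(700, 8), stringsAsFactors = FALSE)
  sq <- makeSequencesAndEsts(tx, estFraction = 0.5, estMutationRate = 0,
                             nDecoys = 0, seed = 3)
  hits <- alignSets(sq$ests, sq$seqsA)
  v <- validateEsts(hits, profiles$est)
  parents <- unique(sq$truth$est_parent[sq$truth$role == "est"])
  expect_setequal(v, parents)

  # heavily mutated ESTs fall below the identity floor; long ESTs keep
  # the binomial spread of the observed identity tight around 90
  sqBad <- makeSequencesAndEsts(tx, estFraction = 0.5,
                                estMutationRate = 0.10, nDecoys = 0,
                                minEstLength = 400, seed = 3)
  hitsBad <- alignSets(sqBad$ests, sqBad$seqsA, wordSize = 8)
  expect_length(validateEsts(hitsBad, profiles$est), 0)
})

test_that("tiered annotation partitions candidates into known and novel
           with closed overlap counts", {
  ids <- sprintf("x%02d", 1:10)
  mkT <- function(q) {
    data.frame(qseqid = q, sseqid = paste0("db_", q), pident = 90,
               length = 100, mismatch = 0, gapopen = 0, qstart = 1,
               qend = 100, sstart = 1, send = 100, evalue = 1e-20,
               bitscore = 180, qcovs = 90, stringsAsFactors = FALSE)
  }
  tables <- list(
    own_lnc = mkT(c("x01", "x02", "x03")),
    zebrafish_lnc = mkT(c("x02", "x04")),
    human_lnc = mkT(c("x02", "x03", "x05"))
  )
  res <- tieredAnnotation(tables, profiles, ids)
  rec <- res$records
  expect_equal(sum(rec$status == "known"), 5)
  expect_equal(sum(rec$status == "novel"), 5)
  expect_equal(sum(rec$status == "known") + sum(rec$status == "novel"),
               length(ids))
  # inclusion-exclusion closure: region counts partition the known set
  expect_equal(sum(res$overlap$n), sum(rec$status == "known"))
  expect_equal(res$overlap$n[res$overlap$region ==
                               "own_lnc&zebrafish_lnc&human_lnc"], 1)
  expect_error(tieredAnnotation(list(mystery = mkT("x01")), profiles,
                                ids),
               "mystery")
})

test_that("the fish screen drops hitless species in round one and counts
           conserved lncRNAs per surviving species", {
  mkT <- function(q, qcovs, evalue = 1e-10) {
    if (!length(q)) return(emptyFish())
    data.frame(qseqid = q, sseqid = paste0("s_", q), pident = 80,
               length = 100, mismatch = 0, gapopen = 0, qstart = 1,
               qend = 100, sstart = 1, send = 100, evalue = evalue,
               bitscore = 150, qcovs = qcovs, stringsAsFactors = FALSE)
  }
  emptyFish <- function() mkT("z", 10)[0, ]
  tables <- list(
    speciesA = mkT(c("l1", "l2"), c(75, 60)),    # both pass; 60 inclusive
    speciesB = mkT("l1", 59.9),                  # below floor -> dropped
    speciesC = mkT("l3", 80, evalue = 1e-2),     # e-value fails -> dropped
    speciesD = mkT(c("l2", "l2"), c(90, 95))     # one lncRNA, two hits
  )
  res <- fishConservation(tables)
  expect_setequal(res$droppedSpecies, c("speciesB", "speciesC"))
  counts <- setNames(res$speciesCounts$n, res$speciesCounts$species)
  expect_equal(counts[["speciesA"]], 2)
  expect_equal(counts[["speciesD"]], 1)
  expect_setequal(
    res$perLncRNA$species[res$perLncRNA$lncRNA_id == "l2"],
    c("speciesA", "speciesD"))
})
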