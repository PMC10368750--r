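#' Simulate five coding-potential tool verdicts
#'
#' Each of the five tools reports the true coding status independently
#' with probability \code{1 - errorRate} and the flipped verdict
#' otherwise, mimicking per-tool misclassification.
#'
#' @param truth data.frame with columns \code{transcript_id} and
#'   \code{true_coding} (\code{"coding"} / \code{"noncoding"}).
#' @param errorRate per-tool flip probability in \[0, 1\].
#' @param seed integer seed.
#' @return data.frame \code{transcript_id}, \code{tool1} .. \code{tool5}
#'   with verdicts \code{"C"} / \code{"NC"}.
#' @export
simulateVotes <- function(truth, errorRate = 0.1, seed = 1L) {
  stopifnot(errorRate >= 0, errorRate <= 1,
            all(truth$true_coding %in% c("coding", "noncoding")))
  n <- nrow(truth)
  with_seed(as.integer(seed), {
    trueV <- ifelse(truth$true_coding == "coding", "C", "NC")
    out <- data.frame(transcript_id = truth$transcript_id,
                      stringsAsFactors = FALSE)
    for (t in 1:5) {
      flip <- runif(n) < errorRate
      out[[paste0("tool", t)]] <- ifelse(
        flip, ifelse(trueV == "C", "NC", "C"), trueV)
    }
    out
  })
}

#' Simulate a per-transcript FPKM table
#'
#' Exactly \code{round(n * belowFloorFraction)} transcripts (chosen at
#' random) receive an FPKM drawn uniformly in \[0, 1) and so fall below
#' the expression floor; the remainder are shifted log-normal
#' (\code{1 + rlnorm(mu, sigma)}), hence always >= 1.
#'
#' @param ids transcript ids.
#' @param mu,sigma log-normal parameters on the log scale.
#' @param belowFloorFraction fraction planted below FPKM 1, in \[0, 1).
#' @param seed integer seed.
#' @return data.frame \code{transcript_id}, \code{fpkm}.
#' @export
makeExpression <- function(ids, mu = 1, sigma = 1,
                           belowFloorFraction = 0.25, seed = 1L) {
  stopifnot(belowFloorFraction >= 0, belowFloorFraction < 1)
  n <- length(ids)
  nLow <- round(n * belowFloorFraction)
  with_seed(as.integer(seed), {
    low <- sample(n, nLow)
    fpkm <- 1 + rlnorm(n, mu, sigma)
    fpkm[low] <- runif(nLow, 0, 1)
    data.frame(transcript_id = ids, fpkm = fpkm, stringsAsFactors = FALSE)
  })
}

#' Generate morphotype sequence sets, orthologs, ESTs and decoys
#'
#' Builds random nucleotide sequences for set A transcripts, a
#' counterpart set B in which each selected transcript's ortholog
#' differs by point substitutions at \code{orthologSubstitutionRate},
#' an EST library of mutated contiguous subsequences of set-A parents,
#' and unrelated uniform-composition decoys appended to both sets.
#'
#' @param transcripts data.frame with \code{transcript_id} and
#'   \code{length} (nt).
#' @param estFraction fraction of set-A transcripts that spawn one EST.
#' @param estMutationRate per-base substitution rate of ESTs.
#' @param orthologSubstitutionRate per-base substitution rate between
#'   ortholog pairs.
#' @param orthologFraction fraction of set-A transcripts given a set-B
#'   ortholog.
#' @param nDecoys number of decoys added to each set.
#' @param decoyLength decoy length (nt).
#' @param minEstLength parents shorter than this are skipped with a
#'   warning; EST lengths are drawn uniformly in
#'   \code{[minEstLength, min(parent, 800)]}.
#' @param seed integer seed.
#' @return list: \code{seqsA}, \code{seqsB}, \code{ests}
#'   (\code{DNAStringSet}s), \code{truth} (data.frame
#'   \code{id}, \code{set}, \code{role}, \code{ortholog_of},
#'   \code{est_parent}).
#' @export
makeSequencesAndEsts <- function(transcripts, estFraction = 0.3,
                                 estMutationRate = 0.02,
                                 orthologSubstitutionRate = 0.05,
                                 orthologFraction = 1,
                                 nDecoys = 25L, decoyLength = 300L,
                                 minEstLength = 100L, seed = 1L) {
  stopifnot(all(c(estFraction, estMutationRate,
                  orthologSubstitutionRate, orthologFraction) >= 0),
            all(c(estFraction, estMutationRate,
                  orthologSubstitutionRate, orthologFraction) <= 1))
  with_seed(as.integer(seed), makeSeqsImpl(
    transcripts, estFraction, estMutationRate, orthologSubstitutionRate,
    orthologFraction, as.integer(nDecoys), as.integer(decoyLength),
    as.integer(minEstLength)
  ))
}

makeSeqsImpl <- function(tx, estFrac, estMut, orthSub, orthFrac,
                         nDecoys, decoyLen, minEst) {
  n <- nrow(tx)
  seqA <- vapply(tx$length, randomSeq, character(1L))
  names(seqA) <- tx$transcript_id

  nOrth <- round(n * orthFrac)
  orthIdx <- sort(sample(n, nOrth))
  seqB <- vapply(seqA[orthIdx], mutateSeq, character(1L), rate = orthSub)
  idsB <- paste0("B_", tx$transcript_id[orthIdx])
  names(seqB) <- idsB

  decoyA <- setNames(vapply(rep(decoyLen, nDecoys), randomSeq,
                            character(1L)),
                     sprintf("decoyA%03d", seq_len(nDecoys)))
  decoyB <- setNames(vapply(rep(decoyLen, nDecoys), randomSeq,
                            character(1L)),
                     sprintf("decoyB%03d", seq_len(nDecoys)))

  nEst <- round(n * estFrac)
  estParents <- sort(sample(n, nEst))
  ests <- character(); estParentIds <- character()
  for (i in estParents) {
    L <- tx$length[i]
    if (L < minEst) {
      warning(sprintf("EST parent %s shorter than %d nt; skipped",
                      tx$transcript_id[i], minEst))
      next
    }
    w <- sampleRange(c(minEst, min(L, 800L)))
    s <- sampleRange(c(1L, L - w + 1L))
    ests <- c(ests, mutateSeq(substr(seqA[i], s, s + w - 1L), estMut))
    estParentIds <- c(estParentIds, tx$transcript_id[i])
  }
  if (length(ests)) names(ests) <- sprintf("est%04d", seq_along(ests))

  truth <- rbind(
    data.frame(id = names(seqA), set = "A", role = "transcript",
               ortholog_of = ifelse(
                 tx$transcript_id %in% tx$transcript_id[orthIdx],
                 paste0("B_", tx$transcript_id), NA_character_),
               est_parent = NA_character_, stringsAsFactors = FALSE),
    data.frame(id = idsB, set = "B", role = "transcript",
               ortholog_of = tx$transcript_id[orthIdx],
               est_parent = NA_character_, stringsAsFactors = FALSE),
    if (nDecoys > 0L) {
      data.frame(id = c(names(decoyA), names(decoyB)),
                 set = rep(c("A", "B"), each = nDecoys), role = "decoy",
                 ortholog_of = NA_character_,
                 est_parent = NA_character_, stringsAsFactors = FALSE)
    },
    if (length(ests)) {
      data.frame(id = names(ests), set = "A", role = "est",
                 ortholog_of = NA_character_, est_parent = estParentIds,
                 stringsAsFactors = FALSE)
    }
  )

  list(
    seqsA = DNAStringSet(c(seqA, decoyA)),
    seqsB = DNAStringSet(c(seqB, decoyB)),
    ests = DNAStringSet(ests),
    truth = truth
  )
}

randomSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Point-mutate a nucleotide sequence
#'
#' Substitutes each position independently with probability \code{rate}
#' (always to a different base), the divergence model used for planted
#' orthologs, ESTs and synthetic database relatives. Uses the current
#' RNG state; wrap in [withr::with_seed()] for reproducibility.
#'
#' @param seq a nucleotide string.
#' @param rate per-base substitution probability in \[0, 1\].
#' @return The mutated sequence (character).
#' @export
mutateSequence <- function(seq, rate) {
  stopifnot(rate >= 0, rate <= 1)
  mutateSeq(as.character(seq), rate)
}

mutateSeq <- function(seq, rate) {
  if (rate <= 0) return(unname(seq))
  ch <- strsplit(unname(seq), "")[[1L]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Build a complete cascade input set with planted defect groups
#'
#' Generates transcripts, votes, annotation flags and FPKM values in
#' which disjoint groups are planted to fail exactly one cascade stage:
#' too short (< 200 nt), coding consensus, EnTAP/Infernal-style
#' annotation, redundant (exact substring of a clean transcript), or
#' FPKM below 1. Because the groups are disjoint, each stage of
#' [runCascade()] removes exactly the planted count.
#'
#' @param n total number of transcripts.
#' @param fracShort,fracCoding,fracAnnotated,fracLowExpression,fracDuplicate
#'   planted fractions; their sum must be < 1.
#' @param seed integer seed.
#' @return list: \code{transcripts} (data.frame \code{transcript_id},
#'   \code{sequence}, \code{length}), \code{votes}, \code{flags},
#'   \code{fpkm}, \code{truth} (data.frame \code{transcript_id},
#'   \code{defect}).
#' @export
makeCascadeInputs <- function(n = 400L, fracShort = 0.25,
                              fracCoding = 0.10, fracAnnotated = 0.10,
                              fracLowExpression = 0.25,
                              fracDuplicate = 0.05, seed = 1L) {
  fr <- c(fracShort, fracCoding, fracAnnotated, fracLowExpression,
          fracDuplicate)
  stopifnot(all(fr >= 0), sum(fr) < 1)
  with_seed(as.integer(seed), makeCascadeImpl(as.integer(n), fr))
}

makeCascadeImpl <- function(n, fr) {
  counts <- round(n * fr)
  defect <- rep("none", n)
  pos <- 0L
  for (k in seq_along(counts)) {
    lab <- c("short", "coding", "annotated", "low_expression",
             "duplicate")[k]
    if (counts[k] > 0L) defect[pos + seq_len(counts[k])] <- lab
    pos <- pos + counts[k]
  }
  defect <- sample(defect)  # shuffle positions
  ids <- sprintf("tx%05d", seq_len(n))

  len <- ifelse(defect == "short",
                sampleRangeN(c(100L, 199L), n),
                sampleRangeN(c(250L, 1500L), n))
  seqs <- vapply(len, randomSeq, character(1L))

  # duplicates: exact strict substrings of clean transcripts, so the
  # clean original (longer) stays as representative
  clean <- which(defect == "none")
  dup <- which(defect == "duplicate")
  if (length(dup) && !length(clean)) stop("no clean transcripts to copy")
  for (d in dup) {
    p <- if (length(clean) > 1L) sample(clean, 1L) else clean
    w <- max(200L, nchar(seqs[p]) - 50L)
    seqs[d] <- substr(seqs[p], 1L, w)
    len[d] <- w
  }

  truthCoding <- data.frame(
    transcript_id = ids,
    true_coding = ifelse(defect == "coding", "coding", "noncoding"),
    stringsAsFactors = FALSE
  )
  votes <- simulateVotes(truthCoding, errorRate = 0,
                         seed = sample.int(2^31 - 1L, 1L))

  isAnn <- defect == "annotated"
  half <- isAnn & (seq_len(n) %% 2L == 0L)
  flags <- data.frame(
    transcript_id = ids,
    protein_annotated = isAnn & !half,
    ncrna_family = ifelse(half, "snoRNA", NA_character_),
    stringsAsFactors = FALSE
  )

  fpkm <- data.frame(
    transcript_id = ids,
    fpkm = ifelse(defect == "low_expression", runif(n, 0, 1),
                  1 + rlnorm(n, 1, 1)),
    stringsAsFactors = FALSE
  )

  list(
    transcripts = data.frame(transcript_id = ids, sequence = unname(seqs),
                             length = len, stringsAsFactors = FALSE),
    votes = votes, flags = flags, fpkm = fpkm,
    truth = data.frame(transcript_id = ids, defect = defect,
                       stringsAsFactors = FALSE)
  )
}
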