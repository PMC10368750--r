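# Karlin-Altschul defaults for the megablast-like scoring scheme
# (match +2, mismatch -3, gap open 5, gap extend 2). E-values from the
# internal aligner are approximate; threshold logic on synthetic data
# rests on pident/qcov.
KA_LAMBDA <- 0.625
KA_K <- 0.41

hitColumns <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                "gapopen", "qstart", "qend", "sstart", "send",
                "evalue", "bitscore", "qcovs")

emptyHits <- function() {
  out <- data.frame(qseqid = character(), sseqid = character(),
                    pident = numeric(), length = integer(),
                    mismatch = integer(), gapopen = integer(),
                    qstart = integer(), qend = integer(),
                    sstart = integer(), send = integer(),
                    evalue = numeric(), bitscore = numeric(),
                    qcovs = numeric(), stringsAsFactors = FALSE)
  out
}

dnaScoreMatrix <- function() {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-3, 5, 5, dimnames = list(letters, letters))
  diag(m) <- 2
  m["N", "N"] <- -3  # N never matches, itself included
  m
}

#' Smith-Waterman local alignment of two nucleotide sequences
#'
#' Optimal local alignment under megablast-like scoring (match +2,
#' mismatch -3, gap open -5, gap extend -2 per position), computed with
#' \pkg{Biostrings}. Both strands of the query are tried and the better
#' scoring one kept. Percent identity is identities over alignment
#' columns; query coverage is the aligned query span over the query
#' length. Bit scores use Karlin-Altschul defaults and e-values are
#' approximate (search space = query length x subject length unless
#' \code{dbLength} is given).
#'
#' @param query,subject nucleotide sequences (character or
#'   \code{DNAString}).
#' @param queryId,subjectId ids written into the hit row.
#' @param dbLength effective database length for the e-value; defaults
#'   to the subject length.
#' @return One-row BLAST-outfmt6-style hit data.frame (columns
#'   \code{qseqid sseqid pident length mismatch gapopen qstart qend
#'   sstart send evalue bitscore qcovs}), or a zero-row frame when no
#'   positive-scoring alignment exists. Minus-strand hits have
#'   \code{sstart > send}.
#' @examples
#' localAlign("ACGTACGTAC", "ACGTACGTAC")$pident  # 100
#' @export
localAlign <- function(query, subject, queryId = "query",
                       subjectId = "subject", dbLength = NULL) {
  q <- as.character(query)
  s <- as.character(subject)
  if (!nchar(q) || !nchar(s)) stop("empty sequence")
  qlen <- nchar(q)
  slen <- nchar(s)
  if (is.null(dbLength)) dbLength <- slen

  mat <- dnaScoreMatrix()
  alnF <- pairwiseAlignment(DNAString(q), DNAString(s), type = "local",
                            substitutionMatrix = mat,
                            gapOpening = 5, gapExtension = 2)
  qrc <- as.character(reverseComplement(DNAString(q)))
  alnR <- pairwiseAlignment(DNAString(qrc), DNAString(s), type = "local",
                            substitutionMatrix = mat,
                            gapOpening = 5, gapExtension = 2)
  minus <- score(alnR) > score(alnF)
  aln <- if (minus) alnR else alnF
  sc <- score(aln)
  if (sc <= 0) return(emptyHits())

  alnCols <- nchar(as.character(aligned(pattern(aln))))
  nid <- nmatch(aln)
  nmm <- nmismatch(aln)
  pstr <- as.character(aligned(pattern(aln)))
  sstr <- as.character(aligned(subject(aln)))
  gapopen <- countGapOpens(pstr) + countGapOpens(sstr)

  pr <- pattern(aln)
  sr <- subject(aln)
  qs <- start(pr); qe <- end(pr)
  if (minus) {
    # report on the original (plus) query coordinates
    tmp <- qlen - qe + 1L
    qe <- qlen - qs + 1L
    qs <- tmp
    ss <- end(sr); se <- start(sr)  # sstart > send flags minus strand
  } else {
    ss <- start(sr); se <- end(sr)
  }

  bit <- (KA_LAMBDA * sc - log(KA_K)) / log(2)
  evalue <- qlen * dbLength * 2^(-bit)
  data.frame(
    qseqid = queryId, sseqid = subjectId,
    pident = 100 * nid / alnCols, length = alnCols,
    mismatch = nmm, gapopen = gapopen,
    qstart = qs, qend = qe, sstart = ss, send = se,
    evalue = evalue, bitscore = bit,
    qcovs = 100 * (qe - qs + 1L) / qlen,
    stringsAsFactors = FALSE
  )
}

countGapOpens <- function(alignedStr) {
  length(gregexpr("-+", alignedStr)[[1L]][
    gregexpr("-+", alignedStr)[[1L]] > 0])
}

#' All-vs-all local alignment of two sequence sets
#'
#' Word-seeded wrapper around [localAlign()]: only query/subject pairs
#' sharing at least one exact word of \code{wordSize} nt (on either
#' strand) are aligned, mirroring how seeded aligners restrict the
#' search space. Returns one best hit row per aligned pair.
#'
#' @param query,subject named \code{DNAStringSet}s (or named character
#'   vectors).
#' @param wordSize seed word length; default 14 (long enough that
#'   unrelated random sequences rarely share a seed, short enough that
#'   homologs at 10 percent divergence always do).
#' @return BLAST-outfmt6-style hit data.frame (possibly zero rows).
#' @export
alignSets <- function(query, subject, wordSize = 14L) {
  qs <- asCharSet(query)
  ss <- asCharSet(subject)
  index <- wordIndex(ss, wordSize)
  dbLen <- sum(nchar(ss))
  rows <- vector("list", length(qs))
  for (i in seq_along(qs)) {
    w <- unique(c(seqWords(qs[[i]], wordSize),
                  seqWords(revcompChar(qs[[i]]), wordSize)))
    cand <- unique(unlist(index[w], use.names = FALSE))
    if (!length(cand)) next
    sub <- lapply(sort(cand), function(j) {
      localAlign(qs[[i]], ss[[j]], queryId = names(qs)[i],
                 subjectId = names(ss)[j], dbLength = dbLen)
    })
    rows[[i]] <- do.call(rbind, sub)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) emptyHits() else out
}

asCharSet <- function(x) {
  out <- if (is(x, "DNAStringSet")) setNames(as.character(x), names(x))
    else x
  stopifnot(!is.null(names(out)), !anyDuplicated(names(out)))
  out
}

seqWords <- function(s, w) {
  L <- nchar(s)
  if (L < w) return(character())
  unique(substring(s, 1:(L - w + 1L), w:L))
}

wordIndex <- function(seqs, w) {
  words <- lapply(seqs, seqWords, w = w)
  split(rep(seq_along(seqs), lengths(words)),
        unlist(words, use.names = FALSE))
}

#' Filter a hit table by a threshold profile
#'
#' Retains a hit iff its e-value is at most \code{maxEvalue} (when the
#' profile sets one), its percent identity is at least
#' \code{minPident} and its query coverage at least \code{minQcov} —
#' all comparisons inclusive, so a hit exactly at a floor is kept.
#' The profile's \code{topN} restriction, when set, is applied after
#' thresholding via [topHits()].
#'
#' @param hits BLAST-outfmt6-style data.frame (needs \code{pident},
#'   \code{qcovs}; \code{evalue} when the profile bounds it).
#' @param profile a \linkS4class{ThresholdProfile}.
#' @return The retained subset, same columns.
#' @export
filterHits <- function(hits, profile) {
  stopifnot(is(profile, "ThresholdProfile"))
  validObject(profile)
  if (!nrow(hits)) return(hits)
  keep <- hits$pident >= profile@minPident &
    hits$qcovs >= profile@minQcov
  if (!is.na(profile@maxEvalue)) {
    keep <- keep & hits$evalue <= profile@maxEvalue
  }
  out <- hits[keep, , drop = FALSE]
  if (!is.na(profile@topN)) out <- topHits(out, profile@topN)
  rownames(out) <- NULL
  out
}

#' Per-query top-n hits
#'
#' Sorts each query's hits by (bit score descending, e-value ascending,
#' percent identity descending, subject id ascending) and keeps the
#' first \code{n}. The sort key is total, so ties cannot change the
#' selection.
#'
#' @param hits hit data.frame.
#' @param n hits kept per query; default 3.
#' @return The restricted hit table.
#' @export
topHits <- function(hits, n = 3L) {
  stopifnot(n >= 1)
  if (!nrow(hits)) return(hits)
  ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, -hits$pident,
               hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$qseqid),
                        head, n = n), use.names = FALSE)
  out <- hits[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

bestHitPerQuery <- function(hits) topHits(hits, 1L)

#' Reciprocal best hits between two candidate sets
#'
#' Both hit tables are filtered by \code{profile}; a pair (a, b) is
#' emitted iff b is a's unique best hit in the A-to-B table and a is b's
#' unique best in the B-to-A table, under the [topHits()] sort key. The
#' result is a partial matching: no id appears in more than one pair.
#'
#' @param hitsAB hits of set-A queries against set B.
#' @param hitsBA hits of set-B queries against set A.
#' @param profile a \linkS4class{ThresholdProfile} (the 70/70 profile in
#'   the shipped configuration).
#' @return data.frame \code{id_A}, \code{id_B}, \code{bitscore_AB},
#'   \code{bitscore_BA}, \code{pident_AB}.
#' @export
reciprocalBestHits <- function(hitsAB, hitsBA, profile) {
  fAB <- filterHits(hitsAB, profile)
  fBA <- filterHits(hitsBA, profile)
  empty <- data.frame(id_A = character(), id_B = character(),
                      bitscore_AB = numeric(), bitscore_BA = numeric(),
                      pident_AB = numeric(), stringsAsFactors = FALSE)
  if (!nrow(fAB) || !nrow(fBA)) return(empty)
  bAB <- bestHitPerQuery(fAB)
  bBA <- bestHitPerQuery(fBA)
  backOf <- setNames(bBA$sseqid, bBA$qseqid)
  mutual <- !is.na(backOf[bAB$sseqid]) &
    backOf[bAB$sseqid] == bAB$qseqid
  pairs <- bAB[mutual, , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  back <- bBA[match(pairs$sseqid, bBA$qseqid), , drop = FALSE]
  out <- data.frame(id_A = pairs$qseqid, id_B = pairs$sseqid,
                    bitscore_AB = pairs$bitscore,
                    bitscore_BA = back$bitscore,
                    pident_AB = pairs$pident, stringsAsFactors = FALSE)
  out[order(out$id_A), , drop = FALSE]
}

#' EST in-silico validation
#'
#' A candidate lncRNA is validated iff at least one hit linking it to an
#' EST passes the EST threshold profile (identity and coverage >= 95,
#' e-value <= 1e-5 in the shipped configuration). The EST library is
#' expected to be deduplicated with [dedupIdentity()] first.
#' \code{candidateSide} names the hit-table column holding the
#' candidates: with synthetic mutated-subsequence ESTs the EST is the
#' natural query (its coverage of the parent is complete), so
#' \code{"subject"} is the default; hit tables produced by querying
#' candidates against an EST database use \code{"query"}.
#'
#' @param hits hit data.frame between candidates and ESTs.
#' @param profile a \linkS4class{ThresholdProfile}.
#' @param candidateSide \code{"subject"} or \code{"query"}.
#' @return Character vector of validated candidate ids (sorted).
#' @export
validateEsts <- function(hits, profile,
                         candidateSide = c("subject", "query")) {
  candidateSide <- match.arg(candidateSide)
  passed <- filterHits(hits, profile)
  col <- if (candidateSide == "subject") "sseqid" else "qseqid"
  sort(unique(passed[[col]]))
}

#' Tiered conservation annotation and known/novel partition
#'
#' Applies one threshold profile per database tier (own-species,
#' zebrafish, human in the shipped configuration), marks a candidate
#' known iff any tier retains at least one hit for it, and tallies the
#' Venn-style tier-overlap regions, which partition the known set.
#'
#' @param hitTables named list of hit data.frames, one per tier
#'   (candidates as queries).
#' @param profiles named list of \linkS4class{ThresholdProfile}s; names
#'   must cover \code{names(hitTables)}.
#' @param candidateIds character vector of all candidate ids.
#' @return list: \code{records} (data.frame with \code{lncRNA_id}, one
#'   logical column per tier, \code{status}), \code{overlap} (data.frame
#'   \code{region}, \code{n}; regions are exclusive combinations).
#' @export
tieredAnnotation <- function(hitTables, profiles, candidateIds) {
  tiers <- names(hitTables)
  missing <- setdiff(tiers, names(profiles))
  if (length(missing)) {
    stop("no profile for tier(s): ", paste(missing, collapse = ", "))
  }
  rec <- data.frame(lncRNA_id = candidateIds, stringsAsFactors = FALSE)
  for (t in tiers) {
    passed <- filterHits(hitTables[[t]], profiles[[t]])
    rec[[t]] <- candidateIds %in% passed$qseqid
  }
  flagMat <- as.matrix(rec[tiers])
  rec$status <- ifelse(rowSums(flagMat) > 0, "known", "novel")

  region <- apply(flagMat, 1L, function(r) {
    paste(tiers[r], collapse = "&")
  })
  region <- region[rec$status == "known"]
  tab <- table(region)
  overlap <- data.frame(region = names(tab), n = as.integer(tab),
                        stringsAsFactors = FALSE)
  list(records = rec, overlap = overlap)
}

#' Two-round fish-panel conservation screen
#'
#' Round one discards every species database in which the query set has
#' no hit passing the screen thresholds (e-value <= 1e-3, query
#' coverage >= 60 in the shipped configuration). Round two filters the
#' merged hits of the surviving species with the same floors and
#' reports, per species, the number of distinct conserved lncRNAs, and
#' per lncRNA the species it matches.
#'
#' @param hitTables named list of hit data.frames, one per species
#'   (lncRNAs as queries).
#' @param profile a \linkS4class{ThresholdProfile}; default e-value
#'   <= 1e-3, qcov >= 60.
#' @return list: \code{speciesCounts} (data.frame \code{species},
#'   \code{n}), \code{perLncRNA} (data.frame \code{lncRNA_id},
#'   \code{species}), \code{droppedSpecies} (character).
#' @export
fishConservation <- function(hitTables,
                             profile = ThresholdProfile(
                               "fish", maxEvalue = 1e-3, minQcov = 60)) {
  species <- names(hitTables)
  pass1 <- lapply(hitTables, filterHits, profile = profile)
  survived <- species[vapply(pass1, nrow, integer(1L)) > 0L]
  dropped <- setdiff(species, survived)

  if (!length(survived)) {
    return(list(
      speciesCounts = data.frame(species = character(), n = integer(),
                                 stringsAsFactors = FALSE),
      perLncRNA = data.frame(lncRNA_id = character(),
                             species = character(),
                             stringsAsFactors = FALSE),
      droppedSpecies = dropped))
  }
  merged <- do.call(rbind, lapply(survived, function(sp) {
    h <- hitTables[[sp]]
    if (nrow(h)) h$species <- sp else h$species <- character()
    h
  }))
  pass2 <- filterHits(merged, profile)
  perLnc <- unique(pass2[, c("qseqid", "species")])
  names(perLnc) <- c("lncRNA_id", "species")
  perLnc <- perLnc[order(perLnc$lncRNA_id, perLnc$species), , drop = FALSE]
  rownames(perLnc) <- NULL
  tab <- table(factor(perLnc$species, levels = survived))
  list(
    speciesCounts = data.frame(species = survived, n = as.integer(tab),
                               stringsAsFactors = FALSE),
    perLncRNA = perLnc,
    droppedSpecies = dropped
  )
}

#' Load the shipped threshold profiles
#'
#' Reads the versioned profile configuration installed with the package
#' and returns the named cutoff sets used across the pipeline:
#' \code{rbh} (70/70), \code{est} (95/95, e <= 1e-5), \code{own_lnc}
#' (70/70, e <= 1e-5, top 3), \code{zebrafish_lnc} (50/50, e <= 1e-5),
#' \code{human_lnc} (50/25, e <= 1e-5) and \code{fish_screen}
#' (qcov >= 60, e <= 1e-3).
#'
#' @param path optional alternative YAML file.
#' @return Named list of \linkS4class{ThresholdProfile}s.
#' @examples
#' thresholdProfiles()$rbh
#' @export
thresholdProfiles <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "threshold_profiles.yaml",
                        package = "lncSieve", mustWork = TRUE)
  }
  cfg <- read_yaml(path)
  out <- lapply(names(cfg$profiles), function(nm) {
    p <- cfg$profiles[[nm]]
    ThresholdProfile(
      name = nm,
      maxEvalue = if (is.null(p$max_evalue)) NA_real_ else p$max_evalue,
      minPident = if (is.null(p$min_pident)) 0 else p$min_pident,
      minQcov = if (is.null(p$min_qcov)) 0 else p$min_qcov,
      topN = if (is.null(p$top_n)) NA_real_ else p$top_n
    )
  })
  setNames(out, names(cfg$profiles))
}
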