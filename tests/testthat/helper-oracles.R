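# Independent oracles used to cross-check the package implementations.
# These are deliberately written from first principles (plain loops,
# position-set enumeration) and share no code with the package.

# --- Smith-Waterman affine-gap DP, quadratic space, one strand -------------
swOracleOneStrand <- function(a, b, match = 2, mismatch = -3,
                              gapOpen = 5, gapExt = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      M[i, j] <- max(0, M[i - 1, j - 1] + s, Ix[i - 1, j - 1] + s,
                     Iy[i - 1, j - 1] + s)
      Ix[i, j] <- max(M[i - 1, j] - gapOpen - gapExt, Ix[i - 1, j] - gapExt)
      Iy[i, j] <- max(M[i, j - 1] - gapOpen - gapExt, Iy[i, j - 1] - gapExt)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

revcompOracle <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# best local score over both query strands, as the aligner reports
swOracle <- function(query, subject, ...) {
  max(swOracleOneStrand(query, subject, ...),
      swOracleOneStrand(revcompOracle(query), subject, ...))
}

bitFromRaw <- function(raw) (0.625 * raw - log(0.41)) / log(2)

# --- positional-classification oracle by position-set enumeration ---------
# exons given as data.frames with start/end (1-based closed)
classifyOracle <- function(lncChrom, lncStrand, lncExons,
                           geneChrom, geneStrand, geneExons,
                           window = Inf) {
  if (lncChrom != geneChrom) return(NULL)
  lncSpan <- seq(min(lncExons$start), max(lncExons$end))
  geneSpan <- seq(min(geneExons$start), max(geneExons$end))
  ov <- length(intersect(lncSpan, geneSpan))
  direction <- if (lncStrand == geneStrand) "sense" else "antisense"
  if (ov >= 1) {
    lncBases <- unlist(mapply(seq, lncExons$start, lncExons$end,
                              SIMPLIFY = FALSE))
    geneBases <- unlist(mapply(seq, geneExons$start, geneExons$end,
                               SIMPLIFY = FALSE))
    location <- if (length(intersect(lncBases, geneBases)) > 0)
      "exonic" else "intronic"
    subtype <- if (all(geneSpan %in% lncSpan)) "containing"
      else if (all(lncSpan %in% geneSpan)) "nested"
      else "overlapping"
    list(type = "genic", direction = direction, location = location,
         subtype = subtype, distance = 0, overlap_bp = ov)
  } else {
    lncIsLeft <- max(lncExons$end) < min(geneExons$start)
    distance <- if (lncIsLeft) min(geneSpan) - max(lncSpan)
      else min(lncSpan) - max(geneSpan)
    if (distance > window) return(NULL)
    location <- if (geneStrand == "+") {
      if (lncIsLeft) "upstream" else "downstream"
    } else {
      if (lncIsLeft) "downstream" else "upstream"
    }
    subtype <- if (direction == "sense") "same_strand"
      else if (location == "upstream") "divergent" else "convergent"
    list(type = "intergenic", direction = direction, location = location,
         subtype = subtype, distance = distance, overlap_bp = 0)
  }
}

# --- naive all-pairs dedup oracle ------------------------------------------
isSubstringOracle <- function(s, t) {
  ls <- nchar(s); lt <- nchar(t)
  if (ls > lt) return(FALSE)
  for (k in 1:(lt - ls + 1)) {
    if (substr(t, k, k + ls - 1) == s) return(TRUE)
  }
  FALSE
}

dedupOracle <- function(seqs, strandBoth = TRUE) {
  ids <- names(seqs)
  ord <- ids[order(-nchar(seqs), ids)]
  reps <- character()
  assign <- setNames(character(length(ids)), ids)
  for (id in ord) {
    s <- seqs[[id]]
    owner <- NA_character_
    for (r in reps) {
      if (isSubstringOracle(s, seqs[[r]]) ||
          (strandBoth && isSubstringOracle(s, revcompOracle(seqs[[r]])))) {
        owner <- r
        break
      }
    }
    if (is.na(owner)) {
      reps <- c(reps, id)
      assign[id] <- id
    } else {
      assign[id] <- owner
    }
  }
  data.frame(transcript_id = ids, representative = unname(assign[ids]),
             stringsAsFactors = FALSE)
}

# --- brute-force RBH oracle over hit tables --------------------------------
rbhOracle <- function(hitsAB, hitsBA, minPident = 70, minQcov = 70) {
  keepF <- function(h) h[h$pident >= minPident & h$qcovs >= minQcov, ,
                         drop = FALSE]
  bestOf <- function(h, q) {
    rows <- h[h$qseqid == q, , drop = FALSE]
    if (!nrow(rows)) return(NA_character_)
    best <- rows[1, ]
    if (nrow(rows) > 1) for (k in 2:nrow(rows)) {
      r <- rows[k, ]
      better <- r$bitscore > best$bitscore ||
        (r$bitscore == best$bitscore && r$evalue < best$evalue) ||
        (r$bitscore == best$bitscore && r$evalue == best$evalue &&
           r$pident > best$pident) ||
        (r$bitscore == best$bitscore && r$evalue == best$evalue &&
           r$pident == best$pident && r$sseqid < best$sseqid)
      if (better) best <- r
    }
    best$sseqid
  }
  fAB <- keepF(hitsAB); fBA <- keepF(hitsBA)
  pairs <- list()
  for (a in unique(fAB$qseqid)) {
    b <- bestOf(fAB, a)
    if (!is.na(b) && identical(bestOf(fBA, b), a)) {
      pairs[[length(pairs) + 1]] <- data.frame(
        id_A = a, id_B = b, stringsAsFactors = FALSE)
    }
  }
  if (!length(pairs)) {
    return(data.frame(id_A = character(), id_B = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, pairs)
  out[order(out$id_A), , drop = FALSE]
}

# --- random fixtures --------------------------------------------------------
randomHitTable <- function(nQuery, nSubject, seed) {
  withr::with_seed(seed, {
    n <- nQuery * 3L
    data.frame(
      qseqid = sample(sprintf("q%02d", seq_len(nQuery)), n, replace = TRUE),
      sseqid = sample(sprintf("s%02d", seq_len(nSubject)), n,
                      replace = TRUE),
      pident = round(runif(n, 40, 100), 2),
      length = sample(100:900, n, replace = TRUE),
      mismatch = 0L, gapopen = 0L,
      qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
      evalue = 10^runif(n, -30, -1),
      bitscore = round(runif(n, 30, 600), 1),
      qcovs = round(runif(n, 30, 100), 2),
      stringsAsFactors = FALSE
    )
  })
}

randomDnaOracle <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
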