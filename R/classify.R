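#' The 16-class positional taxonomy
#'
#' Enumerates the valid lncRNA-gene positional classes: 12 genic
#' (direction sense/antisense x location exonic/intronic x subtype
#' containing/nested/overlapping) and 4 intergenic (sense upstream/
#' downstream = same_strand; antisense upstream = divergent, antisense
#' downstream = convergent). Full labels are
#' \code{type/direction/location/subtype}.
#'
#' @return data.frame with columns \code{type}, \code{direction},
#'   \code{location}, \code{subtype}, \code{label}.
#' @examples
#' nrow(positionalClasses())  # 16
#' @export
positionalClasses <- function() {
  genic <- expand.grid(
    type = "genic",
    direction = c("sense", "antisense"),
    location = c("exonic", "intronic"),
    subtype = c("containing", "nested", "overlapping"),
    stringsAsFactors = FALSE
  )
  inter <- data.frame(
    type = "intergenic",
    direction = c("sense", "sense", "antisense", "antisense"),
    location = c("upstream", "downstream", "upstream", "downstream"),
    subtype = c("same_strand", "same_strand", "divergent", "convergent"),
    stringsAsFactors = FALSE
  )
  out <- rbind(genic, inter)
  out$label <- with(out, paste(type, direction, location, subtype,
                               sep = "/"))
  out
}

#' Classify one lncRNA against one gene
#'
#' Positional classification of a mapped lncRNA relative to one
#' protein-coding gene. Genic (spans overlap by >= 1 bp): direction is
#' sense iff the strands agree; location is exonic iff any lncRNA exon
#' overlaps any gene exon, otherwise intronic; subtype is containing iff
#' the lncRNA span contains the gene span (equal spans included), nested
#' iff the gene span strictly contains the lncRNA, otherwise
#' overlapping. Intergenic (disjoint spans within \code{window}):
#' location is upstream iff the lncRNA lies on the reference feature's
#' 5' side (the partner gene by default, see \code{frame}); antisense
#' pairs are divergent when upstream and convergent when downstream.
#' Distance is counted between nearest span ends so that adjacent
#' features have distance 1.
#'
#' @param lncExons \code{GRanges} of the lncRNA's exon blocks (one
#'   chromosome, one strand).
#' @param gene single-row \code{GRanges} gene span carrying
#'   \code{gene_id}.
#' @param geneExons \code{GRanges} of that gene's exons.
#' @param window maximum intergenic distance considered (bp).
#' @param frame reference for upstream/downstream: \code{"gene"} (the
#'   partner's 5' side, default) or \code{"lncrna"}.
#' @return One-row data.frame (\code{lncRNA_id}, \code{partner_gene_id},
#'   \code{type}, \code{direction}, \code{location}, \code{subtype},
#'   \code{label}, \code{distance}, \code{overlap_bp}) or \code{NULL}
#'   when the pair is out of range or on different chromosomes.
#' @examples
#' lnc <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1000, 3000), c(1499, 3499)), strand = "+")
#' names(lnc) <- c("lncA", "lncA")
#' gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2000, 2499),
#'   strand = "+", gene_id = "g1")
#' classifyPair(lnc, gene, gene)  # genic/sense/intronic/containing
#' @export
classifyPair <- function(lncExons, gene, geneExons, window = Inf,
                         frame = c("gene", "lncrna")) {
  frame <- match.arg(frame)
  lncId <- if (!is.null(names(lncExons))) names(lncExons)[1L] else "lnc"
  chromL <- unique(as.character(seqnames(lncExons)))
  strandL <- unique(as.character(strand(lncExons)))
  stopifnot(length(chromL) == 1L, length(strandL) == 1L)
  chromG <- as.character(seqnames(gene))[1L]
  strandG <- as.character(strand(gene))[1L]
  if (strandL == "*" || strandG == "*") {
    warning(sprintf("undefined strand for pair (%s, %s); skipped",
                    lncId, gene$gene_id[1L]))
    return(NULL)
  }
  if (chromL != chromG) return(NULL)

  sL <- min(start(lncExons)); eL <- max(end(lncExons))
  sG <- start(gene)[1L]; eG <- end(gene)[1L]
  overlap <- min(eL, eG) - max(sL, sG) + 1

  sense <- strandL == strandG
  direction <- if (sense) "sense" else "antisense"

  if (overlap >= 1) {
    exonHit <- any(overlapsAny(ranges(lncExons), ranges(geneExons)))
    location <- if (exonHit) "exonic" else "intronic"
    subtype <- if (sL <= sG && eL >= eG) "containing"
      else if (sG <= sL && eG >= eL) "nested"
      else "overlapping"
    res <- data.frame(
      lncRNA_id = lncId, partner_gene_id = gene$gene_id[1L],
      type = "genic", direction = direction, location = location,
      subtype = subtype, distance = 0, overlap_bp = overlap,
      stringsAsFactors = FALSE
    )
  } else {
    lncLeft <- eL < sG
    distance <- if (lncLeft) sG - eL else sL - eG
    if (distance > window) return(NULL)
    refStrand <- if (frame == "gene") strandG else strandL
    refIsPlus <- refStrand == "+"
    # frame = "gene": lnc on gene's 5' side; frame = "lncrna": gene on
    # lnc's 5' side. Both reduce to comparing the left/right side with
    # the reference strand (the two features swap sides symmetrically).
    onFivePrime <- if (frame == "gene") (lncLeft == refIsPlus)
      else (!lncLeft == refIsPlus)
    location <- if (onFivePrime) "upstream" else "downstream"
    subtype <- if (sense) "same_strand"
      else if (location == "upstream") "divergent" else "convergent"
    res <- data.frame(
      lncRNA_id = lncId, partner_gene_id = gene$gene_id[1L],
      type = "intergenic", direction = direction, location = location,
      subtype = subtype, distance = distance, overlap_bp = 0,
      stringsAsFactors = FALSE
    )
  }
  res$label <- paste(res$type, res$direction, res$location, res$subtype,
                     sep = "/")
  res
}

#' Classify all mapped lncRNAs against an annotation
#'
#' Runs [classifyPair()] for every lncRNA against every gene within
#' \code{window} on its chromosome and flags the single best partner per
#' lncRNA (\code{isBest}). Ranking: any genic partner beats any
#' intergenic one; among genic, larger span overlap wins; among
#' intergenic, smaller distance wins; remaining ties go to the
#' lexicographically smallest \code{gene_id}.
#'
#' @param maps a \linkS4class{TranscriptMaps}.
#' @param annotation a \linkS4class{GeneAnnotation}.
#' @param window maximum intergenic distance (bp); default 100000.
#' @param frame see [classifyPair()].
#' @param bestOnly if \code{TRUE} return only the \code{isBest} rows.
#' @return data.frame of classification records with an \code{isBest}
#'   column (integer 0/1); partnerless lncRNA ids are attached as
#'   attribute \code{"partnerless"}.
#' @export
classifyTranscripts <- function(maps, annotation, window = 1e5,
                                frame = c("gene", "lncrna"),
                                bestOnly = FALSE) {
  frame <- match.arg(frame)
  stopifnot(is(maps, "TranscriptMaps"), is(annotation, "GeneAnnotation"))
  g <- genes(annotation)
  ex <- geneExons(annotation)
  exByGene <- split(ex, ex$gene_id)
  exl <- txExons(maps)

  spans <- unlist(range(exl))
  hits <- findOverlaps(spans, g, maxgap = ceiling(window),
                       ignore.strand = TRUE)
  rows <- vector("list", length(hits))
  for (k in seq_along(hits)) {
    i <- queryHits(hits)[k]
    j <- subjectHits(hits)[k]
    lnc <- exl[[i]]
    names(lnc) <- rep(names(exl)[i], length(lnc))
    rows[[k]] <- classifyPair(lnc, g[j], exByGene[[g$gene_id[j]]],
                              window = window, frame = frame)
  }
  out <- do.call(rbind, rows)
  allIds <- names(exl)
  if (is.null(out) || !nrow(out)) {
    out <- emptyClassification()
    attr(out, "partnerless") <- allIds
    return(out)
  }
  # best-partner ranking within each lncRNA
  keyGroup <- ifelse(out$type == "genic", 0, 1)
  keyWithin <- ifelse(out$type == "genic", -out$overlap_bp, out$distance)
  ord <- order(out$lncRNA_id, keyGroup, keyWithin, out$partner_gene_id)
  out <- out[ord, , drop = FALSE]
  out$isBest <- as.integer(!duplicated(out$lncRNA_id))
  rownames(out) <- NULL
  attr(out, "partnerless") <- setdiff(allIds, out$lncRNA_id)
  if (bestOnly) {
    keep <- out[out$isBest == 1L, , drop = FALSE]
    attr(keep, "partnerless") <- attr(out, "partnerless")
    rownames(keep) <- NULL
    keep
  } else {
    out
  }
}

emptyClassification <- function() {
  data.frame(lncRNA_id = character(), partner_gene_id = character(),
             type = character(), direction = character(),
             location = character(), subtype = character(),
             distance = numeric(), overlap_bp = numeric(),
             label = character(), isBest = integer(),
             stringsAsFactors = FALSE)
}

#' Collapse full positional classes to the six GENCODE-style categories
#'
#' Genic classes map to exonic / intronic / overlapping (the subtype
#' wins when it is \code{overlapping}, else the location); intergenic
#' classes keep their subtype (same_strand / convergent / divergent).
#'
#' @param classification data.frame from [classifyTranscripts()] (or any
#'   frame with \code{type}, \code{location}, \code{subtype}).
#' @return The input with an added \code{category} column.
#' @export
summarizeGencode <- function(classification) {
  valid <- positionalClasses()
  lbl <- paste(classification$type, classification$direction,
               classification$location, classification$subtype, sep = "/")
  bad <- setdiff(lbl, valid$label)
  if (length(bad)) {
    stop("invalid positional class: ", paste(unique(bad), collapse = ", "))
  }
  classification$category <- ifelse(
    classification$type == "genic",
    ifelse(classification$subtype == "overlapping", "overlapping",
           classification$location),
    classification$subtype
  )
  classification
}

#' Per-chromosome distribution of mapped lncRNAs
#'
#' @param maps a \linkS4class{TranscriptMaps}.
#' @return data.frame (\code{chrom}, \code{n}, \code{pct}) sorted by
#'   chromosome; counts sum to the number of mapped transcripts and
#'   percentages to 100 up to rounding.
#' @export
chromosomeDistribution <- function(maps) {
  stopifnot(is(maps, "TranscriptMaps"))
  exl <- txExons(maps)
  if (!length(exl)) {
    return(data.frame(chrom = character(), n = integer(), pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  chrom <- vapply(exl, function(gr) as.character(seqnames(gr))[1L],
                  character(1L))
  tab <- table(chrom)
  data.frame(chrom = names(tab), n = as.integer(tab),
             pct = round(100 * as.integer(tab) / length(exl), 2),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ingest transcript-to-genome alignments
#'
#' Builds a \linkS4class{TranscriptMaps} from an exon-block table
#' (columns \code{transcript_id}, \code{chrom}, \code{strand},
#' \code{start}, \code{end}, optional \code{part_index} and
#' \code{alignment_id}). Alignments on chromosomes outside
#' \code{chromWhitelist} are dropped (unplaced-scaffold exclusion).
#' Transcripts whose blocks within one alignment mix chromosomes or
#' strands are chimeric and excluded. When one transcript has several
#' alignments, the one covering the largest fraction of the transcript
#' is kept and the record is flagged \code{multiply_aligned}.
#'
#' @param blocks exon-block data.frame, 1-based closed coordinates.
#' @param chromWhitelist chromosomes to keep, or \code{NULL} for all.
#' @param transcriptLengths optional named vector of transcript lengths
#'   used for coverage fractions; without it, aligned bases are compared
#'   directly.
#' @return list with elements \code{maps} (a
#'   \linkS4class{TranscriptMaps}) and \code{excluded} (data.frame
#'   \code{transcript_id}, \code{reason}).
#' @export
intakeAlignments <- function(blocks, chromWhitelist = NULL,
                             transcriptLengths = NULL) {
  need <- c("transcript_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(blocks))) {
    stop("blocks must have columns: ", paste(need, collapse = ", "))
  }
  if (any(blocks$end < blocks$start)) {
    bad <- blocks$transcript_id[blocks$end < blocks$start]
    stop("malformed block (end < start) for: ",
         paste(unique(bad), collapse = ", "))
  }
  if (is.null(blocks$alignment_id)) {
    blocks$alignment_id <- rep(1L, nrow(blocks))
  }

  excluded <- data.frame(transcript_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  if (!is.null(chromWhitelist)) {
    off <- !(blocks$chrom %in% chromWhitelist)
    if (any(off)) {
      gone <- setdiff(unique(blocks$transcript_id[off]),
                      unique(blocks$transcript_id[!off]))
      if (length(gone)) {
        excluded <- rbind(excluded, data.frame(
          transcript_id = gone, reason = "off_whitelist",
          stringsAsFactors = FALSE))
      }
      blocks <- blocks[!off, , drop = FALSE]
    }
  }

  keyAln <- paste(blocks$transcript_id, blocks$alignment_id, sep = "\r")
  chimTx <- character()
  if (nrow(blocks)) {
    chimericAln <- tapply(seq_len(nrow(blocks)), keyAln, function(i) {
      length(unique(blocks$chrom[i])) > 1L ||
        length(unique(blocks$strand[i])) > 1L
    })
    chimTx <- unique(blocks$transcript_id[
      keyAln %in% names(chimericAln)[chimericAln]])
  }
  if (length(chimTx)) {
    excluded <- rbind(excluded, data.frame(
      transcript_id = chimTx, reason = "chimeric", stringsAsFactors = FALSE))
    blocks <- blocks[!(blocks$transcript_id %in% chimTx), , drop = FALSE]
  }

  ids <- unique(blocks$transcript_id)
  grl <- vector("list", length(ids))
  multi <- logical(length(ids))
  cov <- numeric(length(ids))
  for (i in seq_along(ids)) {
    b <- blocks[blocks$transcript_id == ids[i], , drop = FALSE]
    alns <- unique(b$alignment_id)
    covered <- vapply(alns, function(a) {
      bi <- b[b$alignment_id == a, , drop = FALSE]
      sum(bi$end - bi$start + 1)
    }, numeric(1L))
    best <- alns[order(-covered, alns)][1L]
    bb <- b[b$alignment_id == best, , drop = FALSE]
    bb <- bb[order(bb$start), , drop = FALSE]
    grl[[i]] <- GRanges(bb$chrom, IRanges(bb$start, bb$end),
                        strand = bb$strand)
    multi[i] <- length(alns) > 1L
    denom <- if (!is.null(transcriptLengths) &&
                 ids[i] %in% names(transcriptLengths)) {
      as.numeric(transcriptLengths[[ids[i]]])
    } else {
      NA_real_
    }
    cov[i] <- if (is.na(denom)) NA_real_ else max(covered) / denom
  }
  names(grl) <- ids
  maps <- new("TranscriptMaps",
              exons = GRangesList(grl),
              flags = DataFrame(transcript_id = ids,
                                multiply_aligned = multi,
                                coverage = cov))
  list(maps = maps, excluded = excluded)
}
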