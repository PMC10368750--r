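#' Specification of a synthetic genome
#'
#' Parameter bundle consumed by [makeGenome()]. Lengths are in base pairs;
#' ranges are two-element integer vectors \code{c(min, max)} sampled
#' uniformly. Defaults are sized so that every positional geometry the
#' classifier distinguishes (including intronic placements, which need
#' introns of several hundred bp) can be planted on any gene.
#'
#' @slot nChromosomes number of chromosomes.
#' @slot chromosomeLengths chromosome lengths in bp, recycled to
#'   \code{nChromosomes}.
#' @slot nGenes total number of genes, distributed round-robin over
#'   chromosomes.
#' @slot exonsPerGene range of exon counts per gene.
#' @slot exonLength range of exon lengths (bp).
#' @slot intronLength range of intron lengths (bp).
#' @slot intergenicGap range of gaps between consecutive genes (bp).
#'
#' @exportClass GenomeSpec
setClass("GenomeSpec",
  representation(
    nChromosomes = "integer",
    chromosomeLengths = "numeric",
    nGenes = "integer",
    exonsPerGene = "integer",
    exonLength = "integer",
    intronLength = "integer",
    intergenicGap = "integer"
  )
)

setValidity("GenomeSpec", function(object) {
  msg <- character()
  if (object@nChromosomes < 1L) msg <- c(msg, "nChromosomes must be >= 1")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (any(object@chromosomeLengths < 1)) {
    msg <- c(msg, "chromosome lengths must be positive")
  }
  for (nm in c("exonsPerGene", "exonLength", "intronLength",
               "intergenicGap")) {
    r <- slot(object, nm)
    if (length(r) != 2L || any(r < 1L) || r[2L] < r[1L]) {
      msg <- c(msg, sprintf("%s must be an increasing positive pair", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeSpec
#'
#' @param nChromosomes,chromosomeLengths,nGenes,exonsPerGene,exonLength,intronLength,intergenicGap
#'   see the class documentation \linkS4class{GenomeSpec}.
#' @return A \linkS4class{GenomeSpec}.
#' @examples
#' GenomeSpec(nChromosomes = 2, nGenes = 8)
#' @export
GenomeSpec <- function(nChromosomes = 4L,
                       chromosomeLengths = 2e6,
                       nGenes = 40L,
                       exonsPerGene = c(3L, 5L),
                       exonLength = c(400L, 600L),
                       intronLength = c(800L, 2000L),
                       intergenicGap = c(15000L, 30000L)) {
  new("GenomeSpec",
    nChromosomes = as.integer(nChromosomes),
    chromosomeLengths = rep_len(as.numeric(chromosomeLengths),
                                as.integer(nChromosomes)),
    nGenes = as.integer(nGenes),
    exonsPerGene = as.integer(exonsPerGene),
    exonLength = as.integer(exonLength),
    intronLength = as.integer(intronLength),
    intergenicGap = as.integer(intergenicGap)
  )
}

#' Protein-coding gene models on a set of chromosomes
#'
#' Container for the annotation side of the positional classifier: one
#' \code{GRanges} of gene spans (metadata column \code{gene_id}) and one
#' of exons (\code{gene_id}, \code{exon_number}), sharing a
#' \code{Seqinfo} with chromosome lengths. Coordinates are 1-based
#' closed, the native GRanges convention.
#'
#' @slot genes \code{GRanges} of gene spans.
#' @slot exons \code{GRanges} of exons.
#'
#' @exportClass GeneAnnotation
setClass("GeneAnnotation",
  representation(genes = "GRanges", exons = "GRanges")
)

setValidity("GeneAnnotation", function(object) {
  msg <- character()
  g <- object@genes
  e <- object@exons
  if (is.null(g$gene_id) || anyDuplicated(g$gene_id)) {
    msg <- c(msg, "genes must carry unique gene_id")
  }
  if (is.null(e$gene_id) || !all(e$gene_id %in% g$gene_id)) {
    msg <- c(msg, "every exon must belong to a known gene")
  }
  if (any(strand(g) == "*")) msg <- c(msg, "gene strand must be + or -")
  # exons contained in their gene span, ordered and disjoint within a gene
  if (length(e) && length(g)) {
    sp <- g[match(e$gene_id, g$gene_id)]
    if (!all(start(e) >= start(sp) & end(e) <= end(sp) &
             as.character(seqnames(e)) == as.character(seqnames(sp)))) {
      msg <- c(msg, "exons must lie within their gene span")
    }
    byGene <- split(seq_along(e), e$gene_id)
    ok <- vapply(byGene, function(i) {
      s <- start(e)[i][order(start(e)[i])]
      en <- end(e)[i][order(start(e)[i])]
      length(i) == 1L || all(s[-1L] > en[-length(en)])
    }, logical(1L))
    if (!all(ok)) msg <- c(msg, "exons of a gene must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' Genome-mapped transcripts (post chimera exclusion)
#'
#' Exon-block alignments of transcripts to a genome, one \code{GRanges}
#' per transcript (single chromosome, single strand, sorted blocks), as
#' produced by [intakeAlignments()]. \code{flags} records per-transcript
#' bookkeeping: whether the transcript had multiple colinear alignments
#' (best coverage kept) and the fraction of the transcript covered.
#'
#' @slot exons named \code{GRangesList}, one element per transcript.
#' @slot flags \code{DataFrame} with columns \code{transcript_id},
#'   \code{multiply_aligned}, \code{coverage}.
#'
#' @exportClass TranscriptMaps
setClass("TranscriptMaps",
  representation(exons = "GRangesList", flags = "DataFrame")
)

setValidity("TranscriptMaps", function(object) {
  msg <- character()
  if (is.null(names(object@exons)) || anyDuplicated(names(object@exons))) {
    msg <- c(msg, "exons must be uniquely named by transcript id")
  }
  if (!identical(nrow(object@flags), length(object@exons))) {
    msg <- c(msg, "flags must have one row per transcript")
  }
  onePlace <- vapply(object@exons, function(gr) {
    length(unique(as.character(seqnames(gr)))) == 1L &&
      length(unique(as.character(strand(gr)))) == 1L
  }, logical(1L))
  if (!all(onePlace)) {
    msg <- c(msg, "each transcript must map to one chromosome and strand")
  }
  if (length(msg)) msg else TRUE
})

#' An immutable alignment-hit threshold profile
#'
#' Named cutoff set applied to BLAST-style hit tables by
#' [filterHits()]. All comparisons are inclusive: a hit at exactly the
#' floor is retained. \code{maxEvalue} and \code{topN} may be \code{NA}
#' (not applied).
#'
#' @slot name profile name.
#' @slot maxEvalue maximum e-value retained, or \code{NA}.
#' @slot minPident minimum percent identity (0-100).
#' @slot minQcov minimum query coverage (0-100).
#' @slot topN per-query top-n restriction by bit score, or \code{NA}.
#'
#' @exportClass ThresholdProfile
setClass("ThresholdProfile",
  representation(name = "character", maxEvalue = "numeric",
                 minPident = "numeric", minQcov = "numeric",
                 topN = "numeric")
)

setValidity("ThresholdProfile", function(object) {
  msg <- character()
  if (object@minPident < 0 || object@minPident > 100) {
    msg <- c(msg, "minPident must be in [0, 100]")
  }
  if (object@minQcov < 0 || object@minQcov > 100) {
    msg <- c(msg, "minQcov must be in [0, 100]")
  }
  if (!is.na(object@maxEvalue) && object@maxEvalue < 0) {
    msg <- c(msg, "maxEvalue must be non-negative")
  }
  if (!is.na(object@topN) && object@topN < 1) {
    msg <- c(msg, "topN must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ThresholdProfile
#'
#' @param name profile name.
#' @param maxEvalue,minPident,minQcov,topN see
#'   \linkS4class{ThresholdProfile}.
#' @return A \linkS4class{ThresholdProfile}.
#' @examples
#' ThresholdProfile("rbh", minPident = 70, minQcov = 70)
#' @export
ThresholdProfile <- function(name, maxEvalue = NA_real_, minPident = 0,
                             minQcov = 0, topN = NA_real_) {
  new("ThresholdProfile", name = as.character(name),
      maxEvalue = as.numeric(maxEvalue), minPident = as.numeric(minPident),
      minQcov = as.numeric(minQcov), topN = as.numeric(topN))
}

#' Result of the candidate filter cascade
#'
#' @slot candidates data.frame of retained putative lncRNAs
#'   (\code{transcript_id}, \code{length}, \code{fpkm}, \code{label}).
#' @slot stageCounts ordered data.frame of per-stage bookkeeping
#'   (\code{stage}, \code{n_in}, \code{n_removed}, \code{n_out}).
#' @slot clusterMap data.frame mapping every dedup input id to its
#'   representative.
#' @slot sideChannel list with the coding and undetermined id sets, kept
#'   for downstream inspection (potential bi-functional transcripts)
#'   rather than silently dropped.
#'
#' @exportClass CascadeResult
setClass("CascadeResult",
  representation(candidates = "data.frame", stageCounts = "data.frame",
                 clusterMap = "data.frame", sideChannel = "list")
)

setValidity("CascadeResult", function(object) {
  sc <- object@stageCounts
  msg <- character()
  if (nrow(sc)) {
    if (!all(sc$n_in == sc$n_removed + sc$n_out)) {
      msg <- c(msg, "stage counts must satisfy n_in = n_removed + n_out")
    }
    if (nrow(sc) > 1L && !all(sc$n_out[-nrow(sc)] == sc$n_in[-1L])) {
      msg <- c(msg, "stage counts must telescope")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenomeSpec", function(object) {
  cat("GenomeSpec:", object@nGenes, "genes on", object@nChromosomes,
      "chromosome(s)\n")
  cat("  exons/gene:", paste(object@exonsPerGene, collapse = "-"),
      " exon bp:", paste(object@exonLength, collapse = "-"),
      " intron bp:", paste(object@intronLength, collapse = "-"), "\n")
})

setMethod("show", "GeneAnnotation", function(object) {
  cat("GeneAnnotation:", length(object@genes), "genes,",
      length(object@exons), "exons on",
      length(seqlevels(object@genes)), "chromosome(s)\n")
})

setMethod("show", "TranscriptMaps", function(object) {
  cat("TranscriptMaps:", length(object@exons), "mapped transcripts (",
      sum(object@flags$multiply_aligned), "multiply aligned )\n")
})

setMethod("show", "ThresholdProfile", function(object) {
  cat(sprintf(
    "ThresholdProfile '%s': pident >= %g, qcov >= %g%s%s\n",
    object@name, object@minPident, object@minQcov,
    if (is.na(object@maxEvalue)) "" else
      sprintf(", evalue <= %g", object@maxEvalue),
    if (is.na(object@topN)) "" else sprintf(", top %d hits", object@topN)
  ))
})

setMethod("show", "CascadeResult", function(object) {
  cat("CascadeResult:", nrow(object@candidates), "candidate lncRNAs\n")
  print(object@stageCounts, row.names = FALSE)
})
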