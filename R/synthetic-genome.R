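#' Generate a synthetic annotated genome
#'
#' Lays out non-overlapping multi-exon protein-coding gene models on a
#' set of chromosomes, drawing exon counts, exon/intron lengths, strand
#' and intergenic gaps from the ranges in \code{spec}. Genes are placed
#' sequentially per chromosome (round-robin across chromosomes), so the
#' layout is deterministic under a fixed seed.
#'
#' @param spec a \linkS4class{GenomeSpec}.
#' @param seed integer seed; the generator is byte-deterministic given
#'   the same spec and seed.
#' @return A \linkS4class{GeneAnnotation}.
#' @examples
#' ann <- makeGenome(GenomeSpec(nChromosomes = 1, nGenes = 3), seed = 7)
#' genes(ann)
#' @export
makeGenome <- function(spec, seed = 1L) {
  stopifnot(is(spec, "GenomeSpec"))
  validObject(spec)
  with_seed(as.integer(seed), makeGenomeImpl(spec))
}

makeGenomeImpl <- function(spec) {
  nChrom <- spec@nChromosomes
  chromNames <- sprintf("chr%d", seq_len(nChrom))
  chromLen <- setNames(spec@chromosomeLengths, chromNames)
  chromOfGene <- rep(seq_len(nChrom), length.out = spec@nGenes)

  cursor <- setNames(rep(1, nChrom), chromNames)
  exonRows <- vector("list", spec@nGenes)
  geneRows <- vector("list", spec@nGenes)

  for (i in seq_len(spec@nGenes)) {
    chrom <- chromNames[chromOfGene[i]]
    gap <- sampleRange(spec@intergenicGap)
    nEx <- sampleRange(spec@exonsPerGene)
    exW <- sampleRangeN(spec@exonLength, nEx)
    inW <- if (nEx > 1L) sampleRangeN(spec@intronLength, nEx - 1L) else integer()
    strand <- sample(c("+", "-"), 1L)

    gStart <- cursor[chrom] + gap
    width <- sum(exW) + sum(inW)
    gEnd <- gStart + width - 1
    if (gEnd > chromLen[chrom]) {
      stop(sprintf(
        "chromosome %s too short (%d bp) to host gene %d of %d",
        chrom, as.integer(chromLen[chrom]), i, spec@nGenes
      ))
    }
    exStart <- gStart + cumsum(c(0, head(exW, -1L) + inW))
    exEnd <- exStart + exW - 1
    gid <- sprintf("gene%04d", i)
    exonRows[[i]] <- data.frame(
      chrom = chrom, start = exStart, end = exEnd, strand = strand,
      gene_id = gid, exon_number = seq_len(nEx),
      stringsAsFactors = FALSE
    )
    geneRows[[i]] <- data.frame(
      chrom = chrom, start = gStart, end = gEnd, strand = strand,
      gene_id = gid, stringsAsFactors = FALSE
    )
    cursor[chrom] <- gEnd + 1
  }

  exdf <- do.call(rbind, exonRows)
  gdf <- do.call(rbind, geneRows)
  si <- Seqinfo(seqnames = chromNames, seqlengths = as.integer(chromLen))
  genes <- GRanges(gdf$chrom, IRanges(gdf$start, gdf$end),
                   strand = gdf$strand, gene_id = gdf$gene_id,
                   seqinfo = si)
  exons <- GRanges(exdf$chrom, IRanges(exdf$start, exdf$end),
                   strand = exdf$strand, gene_id = exdf$gene_id,
                   exon_number = exdf$exon_number, seqinfo = si)
  new("GeneAnnotation", genes = genes, exons = exons)
}

sampleRange <- function(r) {
  if (r[1L] == r[2L]) r[1L] else sample(seq(r[1L], r[2L]), 1L)
}

sampleRangeN <- function(r, n) {
  if (r[1L] == r[2L]) rep(r[1L], n)
  else sample(seq(r[1L], r[2L]), n, replace = TRUE)
}

#' Write gene models as GTF
#'
#' Emits one \code{gene}, one \code{transcript} and per-exon \code{exon}
#' rows per gene in a fixed, fully deterministic text layout (1-based
#' closed coordinates, tab-separated, \code{gene_id}/\code{transcript_id}
#' attributes), so identical annotations produce byte-identical files.
#'
#' @param annotation a \linkS4class{GeneAnnotation}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGtf <- function(annotation, path) {
  stopifnot(is(annotation, "GeneAnnotation"))
  g <- genes(annotation)
  e <- geneExons(annotation)
  lines <- character()
  for (i in seq_along(g)) {
    gid <- g$gene_id[i]
    tid <- paste0(gid, ".t1")
    attrsG <- sprintf('gene_id "%s";', gid)
    attrsT <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
    base <- sprintf("%s\tlncSieve\t%%s\t%%d\t%%d\t.\t%s\t.\t%%s",
                    as.character(seqnames(g))[i],
                    as.character(strand(g))[i])
    lines <- c(lines,
      sprintf(base, "gene", start(g)[i], end(g)[i], attrsG),
      sprintf(base, "transcript", start(g)[i], end(g)[i], attrsT))
    ei <- e[e$gene_id == gid]
    ei <- ei[order(start(ei))]
    lines <- c(lines, sprintf(base, "exon", start(ei), end(ei), attrsT))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Parses a GTF (via \pkg{rtracklayer}) and reconstructs a
#' \linkS4class{GeneAnnotation} from its exon rows; gene spans are the
#' range of each gene's exons. Rows without a \code{gene_id} are
#' rejected.
#'
#' @param path GTF file.
#' @param chromSizes optional named vector of chromosome lengths for the
#'   resulting \code{Seqinfo}.
#' @return A \linkS4class{GeneAnnotation}.
#' @export
readGtfAnnotation <- function(path, chromSizes = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop("GTF contains no exon rows")
  if (is.null(ex$gene_id) || anyNA(ex$gene_id)) {
    stop("GTF exon rows must carry gene_id")
  }
  ord <- order(ex$gene_id, start(ex))
  ex <- ex[ord]
  byGene <- split(ex, ex$gene_id)
  gdf <- data.frame(
    gene_id = names(byGene),
    chrom = vapply(byGene, function(x) as.character(seqnames(x))[1L],
                   character(1L)),
    start = vapply(byGene, function(x) min(start(x)), numeric(1L)),
    end = vapply(byGene, function(x) max(end(x)), numeric(1L)),
    strand = vapply(byGene, function(x) as.character(strand(x))[1L],
                    character(1L)),
    stringsAsFactors = FALSE
  )
  si <- if (!is.null(chromSizes)) {
    Seqinfo(seqnames = names(chromSizes),
            seqlengths = as.integer(chromSizes))
  } else {
    Seqinfo(seqnames = sort(unique(gdf$chrom)))
  }
  genes <- GRanges(gdf$chrom, IRanges(gdf$start, gdf$end),
                   strand = gdf$strand, gene_id = gdf$gene_id, seqinfo = si)
  exonNum <- unlist(lapply(byGene, function(x) {
    if (as.character(strand(x))[1L] == "-") rev(seq_along(x))
    else seq_along(x)
  }), use.names = FALSE)
  exons <- GRanges(as.character(seqnames(ex)),
                   IRanges(start(ex), end(ex)),
                   strand = as.character(strand(ex)),
                   gene_id = ex$gene_id, exon_number = exonNum,
                   seqinfo = si)
  new("GeneAnnotation", genes = genes, exons = exons)
}
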