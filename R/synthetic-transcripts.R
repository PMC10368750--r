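#' Plant mapped transcripts with known positional classes
#'
#' Places synthetic lncRNA alignments around the genes of a synthetic
#' annotation so that classifying each transcript with
#' [classifyTranscripts()] recovers exactly the requested label, host
#' gene included (the geometry keeps every planted transcript closer to
#' its host than to any neighbouring gene, so the host is also the best
#' partner). Host genes are cycled round-robin; intronic placements
#' require a host with an intron of at least 300 bp and raise an error
#' naming the label when none exists.
#'
#' @param annotation a \linkS4class{GeneAnnotation}, typically from
#'   [makeGenome()] with default spacing.
#' @param plan data.frame with columns \code{count} and \code{label}
#'   (full labels as in [positionalClasses()]), or a named integer
#'   vector \code{label = count}.
#' @param seed integer seed.
#' @param window maximum intergenic distance the downstream classifier
#'   will use; intergenic placements stay within it.
#' @param intergenicDistance range the planted intergenic gap is drawn
#'   from; capped at \code{min(window, 5000)} so planted transcripts
#'   stay nearest to their host.
#' @return list: \code{maps} (a \linkS4class{TranscriptMaps}),
#'   \code{truth} (data.frame \code{transcript_id}, \code{true_class},
#'   \code{host_gene}, \code{length}).
#' @examples
#' ann <- makeGenome(GenomeSpec(nChromosomes = 1, nGenes = 4), seed = 2)
#' p <- plantTranscripts(ann, c("genic/sense/intronic/containing" = 2),
#'                       seed = 3)
#' p$truth
#' @export
plantTranscripts <- function(annotation, plan, seed = 1L, window = 1e5,
                             intergenicDistance = c(100L, 5000L)) {
  stopifnot(is(annotation, "GeneAnnotation"))
  if (!is.data.frame(plan)) {
    plan <- data.frame(count = as.integer(plan), label = names(plan),
                       stringsAsFactors = FALSE)
  }
  valid <- positionalClasses()$label
  bad <- setdiff(plan$label, valid)
  if (length(bad)) {
    stop("invalid positional class label(s): ", paste(bad, collapse = ", "))
  }
  with_seed(as.integer(seed), plantTranscriptsImpl(
    annotation, plan, window,
    c(intergenicDistance[1L], min(intergenicDistance[2L], window, 5000))
  ))
}

plantTranscriptsImpl <- function(annotation, plan, window, interDist) {
  g <- genes(annotation)
  ex <- geneExons(annotation)
  chromLen <- chromSizes(annotation)
  exByGene <- split(ex, ex$gene_id)

  labels <- rep(plan$label, plan$count)
  n <- length(labels)
  ids <- sprintf("lnc%04d", seq_len(n))
  rows <- vector("list", n)
  truth <- vector("list", n)
  nG <- length(g)
  hostIdx <- 0L

  for (i in seq_len(n)) {
    parts <- strsplit(labels[i], "/", fixed = TRUE)[[1L]]
    placed <- FALSE
    for (try in seq_len(nG)) {
      hostIdx <- hostIdx %% nG + 1L
      gi <- g[hostIdx]
      geom <- placeOne(parts, gi, exByGene[[gi$gene_id]],
                       chromLen[[as.character(seqnames(gi))]], interDist)
      if (is.null(geom)) next
      rows[[i]] <- data.frame(
        transcript_id = ids[i], chrom = as.character(seqnames(gi)),
        strand = geom$strand, start = geom$starts, end = geom$ends,
        part_index = seq_along(geom$starts), stringsAsFactors = FALSE
      )
      truth[[i]] <- data.frame(
        transcript_id = ids[i], true_class = labels[i],
        host_gene = gi$gene_id, length = sum(geom$ends - geom$starts + 1),
        stringsAsFactors = FALSE
      )
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(sprintf("unachievable placement for label '%s'", labels[i]))
    }
  }

  blocks <- do.call(rbind, rows)
  maps <- intakeAlignments(blocks)$maps
  list(maps = maps, truth = do.call(rbind, truth))
}

# geometry recipes; coordinates 1-based closed. Returns NULL when the
# host gene cannot realise the requested geometry.
placeOne <- function(parts, gene, geneEx, chromLen, interDist) {
  gs <- start(gene); ge <- end(gene)
  gStrand <- as.character(strand(gene))
  type <- parts[1L]; direction <- parts[2L]
  location <- parts[3L]; subtype <- parts[4L]

  if (type == "genic") {
    lncStrand <- if (direction == "sense") gStrand else flipStrand(gStrand)
    geneEx <- geneEx[order(start(geneEx))]
    introns <- geneIntrons(geneEx)
    if (location == "exonic") {
      if (subtype == "containing") {
        s <- c(gs - 300); e <- c(ge + 300)
      } else if (subtype == "nested") {
        e1 <- geneEx[1L]
        if (width(e1) < 300) return(NULL)
        s <- start(e1) + 50; e <- s + 249
      } else { # overlapping
        s <- gs - 300; e <- gs + 99
        if (e >= ge) return(NULL)
      }
    } else { # intronic
      if (subtype == "containing") {
        s <- c(gs - 400, ge + 101); e <- c(gs - 101, ge + 400)
      } else if (subtype == "nested") {
        ok <- which(width(introns) >= 300)
        if (!length(ok)) return(NULL)
        it <- introns[ok[1L]]
        s <- start(it) + 25; e <- s + 249
      } else { # overlapping
        if (!length(introns) || width(introns)[1L] < 300) return(NULL)
        i1 <- introns[1L]
        s <- c(gs - 400, start(i1) + 25)
        e <- c(gs - 151, start(i1) + 274)
        if (max(e) >= ge) return(NULL)
      }
    }
  } else { # intergenic
    lncStrand <- if (direction == "sense") gStrand else flipStrand(gStrand)
    d <- sampleRange(interDist)
    # upstream = the gene's 5' side (gene reference frame)
    leftSide <- if (location == "upstream") gStrand == "+" else gStrand == "-"
    if (leftSide) {
      e <- gs - d; s <- e - 399
    } else {
      s <- ge + d; e <- s + 399
    }
  }
  if (any(s < 1) || any(e > chromLen)) return(NULL)
  list(strand = lncStrand, starts = s, ends = e)
}

flipStrand <- function(s) if (s == "+") "-" else "+"

geneIntrons <- function(geneEx) {
  if (length(geneEx) < 2L) return(IRanges())
  IRanges(end(geneEx)[-length(geneEx)] + 1, start(geneEx)[-1L] - 1)
}

#' Serialize a TranscriptMaps to an exon-block table
#'
#' Inverse of the block-table input accepted by [intakeAlignments()]:
#' columns \code{transcript_id}, \code{chrom}, \code{strand},
#' \code{start}, \code{end}, \code{part_index}.
#'
#' @param maps a \linkS4class{TranscriptMaps}.
#' @return data.frame of exon blocks in fixed column order.
#' @export
mapsToBlocks <- function(maps) {
  stopifnot(is(maps, "TranscriptMaps"))
  exl <- txExons(maps)
  do.call(rbind, lapply(names(exl), function(id) {
    gr <- exl[[id]]
    data.frame(transcript_id = id,
               chrom = as.character(seqnames(gr)),
               strand = as.character(strand(gr)),
               start = start(gr), end = end(gr),
               part_index = seq_along(gr), stringsAsFactors = FALSE)
  }))
}
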