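mkLnc <- function(chrom, strand, starts, ends, id = "lnc") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                               strand = strand)
  names(gr) <- rep(id, length(gr))
  gr
}
mkGene <- function(chrom, strand, start, end, id = "g1",
                   exStarts = start, exEnds = end) {
  list(
    span = GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                  strand = strand, gene_id = id),
    exons = GenomicRanges::GRanges(chrom,
                                   IRanges::IRanges(exStarts, exEnds),
                                   strand = strand, gene_id = id)
  )
}

test_that("reference geometries classify to their expected labels", {
  # gene inside the lncRNA intron, same strand -> intronic containing
  g <- mkGene("chr1", "+", 2000, 2499)
  lnc <- mkLnc("chr1", "+", c(1000, 3000), c(1499, 3499))
  r <- classifyPair(lnc, g$span, g$exons)
  expect_equal(r$label, "genic/sense/intronic/containing")
  expect_equal(r$overlap_bp, 500)

  # downstream antisense, transcribing toward each other -> convergent
  g2 <- mkGene("chr1", "+", 5000, 5999)
  r2 <- classifyPair(mkLnc("chr1", "-", 8000, 8999), g2$span, g2$exons)
  expect_equal(r2$label, "intergenic/antisense/downstream/convergent")
  expect_equal(r2$distance, 2001)

  # upstream antisense, transcribing away from each other -> divergent
  r3 <- classifyPair(mkLnc("chr1", "-", 1000, 1999), g2$span, g2$exons)
  expect_equal(r3$label, "intergenic/antisense/upstream/divergent")

  # lncRNA exon inside a gene intron, gene span contains it -> nested
  g3 <- mkGene("chr1", "+", 4000, 8000,
               exStarts = c(4000, 7900), exEnds = c(4050, 8000))
  r4 <- classifyPair(mkLnc("chr1", "+", 4100, 4400), g3$span, g3$exons)
  expect_equal(r4$label, "genic/sense/intronic/nested")

  # equal spans count as containing
  g4 <- mkGene("chr1", "+", 100, 400)
  r5 <- classifyPair(mkLnc("chr1", "+", 100, 400), g4$span, g4$exons)
  expect_equal(r5$subtype, "containing")

  # different chromosome or out-of-window -> no record
  expect_null(classifyPair(mkLnc("chr2", "+", 100, 200), g4$span,
                           g4$exons))
  expect_null(classifyPair(mkLnc("chr1", "+", 5000, 5100), g4$span,
                           g4$exons, window = 1000))
  expect_warning(
    expect_null(classifyPair(mkLnc("chr1", "*", 500, 600), g4$span,
                             g4$exons)),
    "undefined strand")
})

test_that("upstream/downstream can be framed by the lncRNA instead of
           the gene", {
  g <- mkGene("chr1", "+", 5000, 5999)
  lnc <- mkLnc("chr1", "-", 8000, 8999)
  rGene <- classifyPair(lnc, g$span, g$exons, frame = "gene")
  rLnc <- classifyPair(lnc, g$span, g$exons, frame = "lncrna")
  # gene frame: lnc right of a + gene = downstream of the gene;
  # lncRNA frame: the gene sits left of the minus-strand lnc, i.e. on
  # the lnc's 3' side, so it is also downstream
  expect_equal(rGene$location, "downstream")
  expect_equal(rLnc$location, "downstream")
  # antisense geometry is frame-independent; same-strand pairs disagree:
  # a + lnc upstream of a + gene has that gene downstream of itself
  lnc2 <- mkLnc("chr1", "+", 1000, 1999)
  g2 <- mkGene("chr1", "+", 5000, 5999)
  expect_equal(classifyPair(lnc2, g2$span, g2$exons,
                            frame = "gene")$location, "upstream")
  expect_equal(classifyPair(lnc2, g2$span, g2$exons,
                            frame = "lncrna")$location, "downstream")
})

test_that("classifyPair agrees with the enumeration oracle on random
           geometries", {
  withr::with_seed(123, {
    for (rep in 1:300) {
      chromL <- sample(c("c1", "c2"), 1)
      strandL <- sample(c("+", "-"), 1)
      strandG <- sample(c("+", "-"), 1)
      # random exon chains in a small coordinate space
      mk <- function() {
        nEx <- sample(1:3, 1)
        s <- sort(sample(1:3000, nEx))
        w <- sample(20:400, nEx, replace = TRUE)
        e <- s + w
        if (nEx > 1) for (k in 2:nEx) {
          if (s[k] <= e[k - 1]) s[k] <- e[k - 1] + sample(5:50, 1)
          e[k] <- s[k] + w[k]
        }
        data.frame(start = s, end = e)
      }
      lncEx <- mk(); geneEx <- mk()
      got <- classifyPair(
        mkLnc(chromL, strandL, lncEx$start, lncEx$end),
        GenomicRanges::GRanges("c1",
          IRanges::IRanges(min(geneEx$start), max(geneEx$end)),
          strand = strandG, gene_id = "g"),
        GenomicRanges::GRanges("c1",
          IRanges::IRanges(geneEx$start, geneEx$end), strand = strandG),
        window = 1500)
      want <- classifyOracle(chromL, strandL, lncEx, "c1", strandG,
                             geneEx, window = 1500)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got$type, want$type)
        expect_equal(got$direction, want$direction)
        expect_equal(got$location, want$location)
        expect_equal(got$subtype, want$subtype)
        expect_equal(got$distance, want$distance)
        expect_equal(got$overlap_bp, want$overlap_bp)
      }
    }
  })
})

test_that("classification is invariant under coordinate reflection plus
           strand flip", {
  g <- mkGene("chr1", "+", 2000, 2499)
  lnc <- mkLnc("chr1", "+", c(1000, 3000), c(1499, 3499))
  r <- classifyPair(lnc, g$span, g$exons)
  M <- 10000
  refl <- function(s, e) c(start = M - e, end = M - s)
  gR <- mkGene("chr1", "-", M - 2499, M - 2000)
  lncR <- mkLnc("chr1", "-", c(M - 1499, M - 3499), c(M - 1000, M - 3000))
  rR <- classifyPair(sort(lncR), gR$span, gR$exons)
  for (f in c("type", "direction", "location", "subtype")) {
    expect_equal(rR[[f]], r[[f]])
  }
})

test_that("best-partner ranking prefers genic, then overlap, then
           distance, then gene id", {
  genesGr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1000, 2100, 2500), c(1900, 2300, 3200)),
    strand = "+", gene_id = c("gC", "gA", "gB"))
  exons <- genesGr
  ann <- new("GeneAnnotation", genes = genesGr, exons = exons)
  blocks <- data.frame(
    transcript_id = "lncX", chrom = "chr1", strand = "+",
    start = 1800, end = 2050, part_index = 1, stringsAsFactors = FALSE)
  maps <- intakeAlignments(blocks)$maps
  cl <- classifyTranscripts(maps, ann, window = 1e5)
  # genic overlap with gC (101 bp) beats the 50 bp-away intergenic gA
  expect_equal(cl$partner_gene_id[cl$isBest == 1], "gC")
  expect_equal(sum(cl$isBest), 1)
  # among intergenic partners, smaller distance ranks earlier
  inter <- cl[cl$type == "intergenic", ]
  expect_equal(inter$partner_gene_id[order(inter$distance)][1], "gA")
})

test_that("partnerless lncRNAs are reported and get no isBest record", {
  genesGr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 2000),
                                    strand = "+", gene_id = "g1")
  ann <- new("GeneAnnotation", genes = genesGr, exons = genesGr)
  blocks <- data.frame(
    transcript_id = "far", chrom = "chr1", strand = "+",
    start = 900000, end = 900500, part_index = 1,
    stringsAsFactors = FALSE)
  cl <- classifyTranscripts(intakeAlignments(blocks)$maps, ann,
                            window = 1000)
  expect_equal(nrow(cl), 0)
  expect_equal(attr(cl, "partnerless"), "far")
})

test_that("gencode summary maps genic to exonic/intronic/overlapping and
           intergenic to its subtype", {
  df <- data.frame(
    type = c("genic", "genic", "genic", "intergenic"),
    direction = c("sense", "antisense", "antisense", "antisense"),
    location = c("intronic", "exonic", "exonic", "downstream"),
    subtype = c("containing", "overlapping", "nested", "convergent"),
    stringsAsFactors = FALSE)
  out <- summarizeGencode(df)
  expect_equal(out$category,
               c("intronic", "overlapping", "exonic", "convergent"))
  bad <- data.frame(type = "genic", direction = "sense",
                    location = "upstream", subtype = "containing",
                    stringsAsFactors = FALSE)
  expect_error(summarizeGencode(bad), "invalid")
})

test_that("alignment intake excludes chimeras, keeps best coverage of
           multiple alignments and applies the whitelist", {
  blocks <- rbind(
    data.frame(transcript_id = "chim", chrom = c("chr1", "chr2"),
               strand = "+", start = c(100, 100), end = c(200, 200),
               part_index = 1:2, alignment_id = 1,
               stringsAsFactors = FALSE),
    data.frame(transcript_id = "multi", chrom = "chr1", strand = "+",
               start = c(100, 1000), end = c(190, 1500),
               part_index = c(1, 1), alignment_id = c(1, 2),
               stringsAsFactors = FALSE),
    data.frame(transcript_id = "clean", chrom = "chr3", strand = "-",
               start = c(10, 300, 600, 900), end = c(100, 400, 700, 980),
               part_index = 1:4, alignment_id = 1,
               stringsAsFactors = FALSE),
    data.frame(transcript_id = "scaffolded", chrom = "scaffold_12",
               strand = "+", start = 5, end = 400, part_index = 1,
               alignment_id = 1, stringsAsFactors = FALSE))
  res <- intakeAlignments(blocks,
                          chromWhitelist = c("chr1", "chr2", "chr3"),
                          transcriptLengths = c(multi = 600))
  expect_setequal(names(txExons(res$maps)), c("multi", "clean"))
  expect_setequal(res$excluded$transcript_id, c("chim", "scaffolded"))
  fl <- txFlags(res$maps)
  expect_true(fl$multiply_aligned[fl$transcript_id == "multi"])
  # the 501-bp alignment wins over the 91-bp one
  expect_equal(GenomicRanges::start(txExons(res$maps)[["multi"]]), 1000)
  expect_equal(fl$coverage[fl$transcript_id == "multi"], 501 / 600)
  expect_length(txExons(res$maps)[["clean"]], 4)
  expect_error(intakeAlignments(
    data.frame(transcript_id = "x", chrom = "chr1", strand = "+",
               start = 100, end = 50, stringsAsFactors = FALSE)),
    "malformed")
})

test_that("per-chromosome counts conserve totals", {
  blocks <- data.frame(
    transcript_id = c("a", "b", "c", "d"),
    chrom = c("chr1", "chr1", "chr1", "chr2"), strand = "+",
    start = c(1, 100, 200, 1), end = c(50, 150, 250, 60),
    part_index = 1, stringsAsFactors = FALSE)
  maps <- intakeAlignments(blocks)$maps
  cd <- chromosomeDistribution(maps)
  expect_equal(cd$n, c(3, 1))
  expect_equal(cd$pct, c(75, 25))
  expect_equal(sum(cd$n), 4)
  empty <- intakeAlignments(blocks[0, ])$maps
  expect_equal(nrow(chromosomeDistribution(empty)), 0)
})
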