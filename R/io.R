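# Plain-text table and FASTA I/O for the pipeline's external formats.
# All tables are tab-separated with a header row and fixed column order.

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read/write pipeline tables
#'
#' Thin TSV readers/writers with the pipeline's fixed column orders:
#' votes (\code{transcript_id}, \code{tool1..tool5}), annotation flags
#' (\code{transcript_id}, \code{protein_annotated},
#' \code{ncrna_family}), expression (\code{transcript_id},
#' \code{fpkm}), exon blocks (\code{transcript_id}, \code{chrom},
#' \code{strand}, \code{start}, \code{end}, \code{part_index}, optional
#' \code{alignment_id}) and BLAST-outfmt6 hit tables with a
#' \code{qcovs} column (headerless files get the standard column
#' names).
#'
#' @param path file path.
#' @param df,hits,blocks the table to write.
#' @return The parsed data.frame, or (for writers) \code{path}
#'   invisibly.
#' @name table-io
NULL

#' @rdname table-io
#' @export
readVotes <- function(path) {
  df <- readTsv(path)
  need <- c("transcript_id", paste0("tool", 1:5))
  if (!all(need %in% names(df))) {
    stop("votes table must have columns: ", paste(need, collapse = ", "))
  }
  df[need]
}

#' @rdname table-io
#' @export
writeVotes <- function(df, path) {
  writeTsv(df[c("transcript_id", paste0("tool", 1:5))], path)
}

#' @rdname table-io
#' @export
readFlags <- function(path) {
  df <- readTsv(path)
  df$protein_annotated <- as.logical(df$protein_annotated)
  df$ncrna_family[df$ncrna_family %in% c("", "NA", "none")] <-
    NA_character_
  df
}

#' @rdname table-io
#' @export
readExpression <- function(path) {
  readTsv(path)[c("transcript_id", "fpkm")]
}

#' @rdname table-io
#' @export
readExonBlocks <- function(path) {
  readTsv(path)
}

#' @rdname table-io
#' @export
writeExonBlocks <- function(blocks, path) {
  writeTsv(blocks, path)
}

#' @rdname table-io
#' @export
readHitTable <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, "qseqid")) {
    readTsv(path)
  } else {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df) <- hitColumns[seq_len(ncol(df))]
    df
  }
}

#' @rdname table-io
#' @export
writeHitTable <- function(hits, path) {
  writeTsv(hits[intersect(hitColumns, names(hits))], path)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector or \code{DNAStringSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file as a DNAStringSet
#'
#' @param path FASTA path.
#' @return \code{DNAStringSet}.
#' @export
readFasta <- function(path) {
  readDNAStringSet(path)
}
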