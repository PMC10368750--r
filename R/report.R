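#' Interaction network between lncRNAs and candidate genes
#'
#' Restricts best-partner classifications to a candidate-gene list
#' (eye-loss genes in the motivating study) and builds an edge list,
#' marking lncRNAs that are shared between the two morphotypes (i.e.
#' participate in a reciprocal-best-hit pair). A per-gene degree table
#' captures the "many lncRNAs on one partner" view.
#'
#' @param best classification data.frame restricted to \code{isBest == 1}
#'   rows (see [classifyTranscripts()]); a \code{category} column is
#'   added via [summarizeGencode()] if absent.
#' @param geneList character vector of candidate gene ids (non-empty).
#' @param rbhPairs data.frame from [reciprocalBestHits()], or
#'   \code{NULL}.
#' @return list: \code{edges} (data.frame \code{lncRNA_id},
#'   \code{gene_id}, \code{gencode_category}, \code{is_shared}),
#'   \code{degree} (data.frame \code{gene_id}, \code{degree}).
#' @export
partnerNetwork <- function(best, geneList, rbhPairs = NULL) {
  if (!length(geneList)) stop("candidate gene list is empty")
  stopifnot(all(best$isBest == 1L))
  if (is.null(best$category)) best <- summarizeGencode(best)
  sel <- best[best$partner_gene_id %in% geneList, , drop = FALSE]
  sharedIds <- if (is.null(rbhPairs)) character()
    else c(rbhPairs$id_A, rbhPairs$id_B)
  edges <- data.frame(
    lncRNA_id = sel$lncRNA_id, gene_id = sel$partner_gene_id,
    gencode_category = sel$category,
    is_shared = sel$lncRNA_id %in% sharedIds,
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$gene_id, edges$lncRNA_id), , drop = FALSE]
  rownames(edges) <- NULL
  deg <- table(factor(edges$gene_id, levels = sort(unique(edges$gene_id))))
  list(edges = edges,
       degree = data.frame(gene_id = names(deg), degree = as.integer(deg),
                           stringsAsFactors = FALSE))
}

#' Single-gene interaction report
#'
#' All lncRNAs whose best partner is \code{geneId}, with a display
#' classification ("Intronic containing", "Intergenic convergent", ...),
#' the morphotype label, transcript length and a shared flag for
#' reciprocal-best-hit members — the shape of a per-gene results table
#' such as the sox2 one in the motivating study.
#'
#' @param best best-partner classification rows (\code{isBest == 1}).
#' @param geneId the gene of interest.
#' @param rbhPairs data.frame from [reciprocalBestHits()], or
#'   \code{NULL}.
#' @param lengths named vector of transcript lengths (nt), optional.
#' @param morphotype label written into every row (default "A").
#' @param knownGenes optional universe of annotated gene ids; when
#'   given, an unknown \code{geneId} is an error rather than an empty
#'   report.
#' @return data.frame \code{gene}, \code{lncRNA_id},
#'   \code{classification}, \code{morphotype}, \code{length},
#'   \code{shared}.
#' @export
geneFocus <- function(best, geneId, rbhPairs = NULL, lengths = NULL,
                      morphotype = "A", knownGenes = NULL) {
  if (!is.null(knownGenes) && !(geneId %in% knownGenes)) {
    stop("unknown gene id: ", geneId)
  }
  stopifnot(all(best$isBest == 1L))
  sel <- best[best$partner_gene_id == geneId, , drop = FALSE]
  sharedIds <- if (is.null(rbhPairs)) character()
    else c(rbhPairs$id_A, rbhPairs$id_B)
  classDisp <- ifelse(
    sel$type == "genic",
    paste(capitalize(sel$location), sel$subtype),
    paste("Intergenic", sel$subtype)
  )
  out <- data.frame(
    gene = rep(geneId, nrow(sel)), lncRNA_id = sel$lncRNA_id,
    classification = classDisp, morphotype = rep(morphotype, nrow(sel)),
    length = if (is.null(lengths)) rep(NA_real_, nrow(sel))
      else as.numeric(lengths[sel$lncRNA_id]),
    shared = sel$lncRNA_id %in% sharedIds,
    stringsAsFactors = FALSE
  )
  out[order(out$lncRNA_id), , drop = FALSE]
}

capitalize <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), substr(x, 2L, nchar(x)))
}

#' Shared/exclusive arithmetic between two candidate sets
#'
#' Counts reciprocal-best-hit pairs as shared lncRNAs and derives the
#' per-morphotype exclusives, enforcing the identities
#' \code{n_exclusive + n_shared = n_total} on each side.
#'
#' @param candidatesA,candidatesB character vectors of candidate ids.
#' @param rbhPairs data.frame from [reciprocalBestHits()].
#' @return data.frame with one row: \code{n_total_A}, \code{n_total_B},
#'   \code{n_shared}, \code{n_exclusive_A}, \code{n_exclusive_B}.
#' @export
setSummary <- function(candidatesA, candidatesB, rbhPairs) {
  out <- setdiff(rbhPairs$id_A, candidatesA)
  out2 <- setdiff(rbhPairs$id_B, candidatesB)
  if (length(out) || length(out2)) {
    stop("RBH ids outside the candidate sets: ",
         paste(c(out, out2), collapse = ", "))
  }
  nShared <- nrow(rbhPairs)
  data.frame(
    n_total_A = length(candidatesA), n_total_B = length(candidatesB),
    n_shared = nShared,
    n_exclusive_A = length(candidatesA) - nShared,
    n_exclusive_B = length(candidatesB) - nShared
  )
}

#' Tally ncRNA family annotations
#'
#' Counts transcripts per ncRNA family label and aggregates the small
#' non-coding supergroups (miRNA, snoRNA, other).
#'
#' @param flags data.frame with \code{transcript_id} and
#'   \code{ncrna_family} (\code{NA} = unannotated).
#' @return list: \code{families} (data.frame \code{family}, \code{n}),
#'   \code{groups} (data.frame \code{group}, \code{n}).
#' @export
familyTally <- function(flags) {
  fam <- flags$ncrna_family[!is.na(flags$ncrna_family)]
  if (!length(fam)) {
    return(list(
      families = data.frame(family = character(), n = integer(),
                            stringsAsFactors = FALSE),
      groups = data.frame(group = character(), n = integer(),
                          stringsAsFactors = FALSE)))
  }
  tab <- table(fam)
  grp <- ifelse(grepl("mir|miRNA", fam, ignore.case = TRUE), "miRNA",
         ifelse(grepl("sno", fam, ignore.case = TRUE), "snoRNA", "other"))
  gtab <- table(grp)
  list(
    families = data.frame(family = names(tab), n = as.integer(tab),
                          stringsAsFactors = FALSE),
    groups = data.frame(group = names(gtab), n = as.integer(gtab),
                        stringsAsFactors = FALSE)
  )
}

#' Assemble the machine-readable run report
#'
#' Collects the cascade stage counts, per-chromosome distribution,
#' classification proportions (genic/intergenic and the six-way
#' summary), known/novel partition, validation count, the full
#' threshold configuration and the seed into one list, serialisable
#' with [writeStageReport()] and checkable with [validateReport()].
#'
#' @param cascade a \linkS4class{CascadeResult}.
#' @param maps a \linkS4class{TranscriptMaps} of the mapped candidates.
#' @param classification full classification data.frame (with
#'   \code{isBest}).
#' @param summary optional [setSummary()] row.
#' @param conservation optional [tieredAnnotation()] result.
#' @param validated optional character vector of EST-validated ids.
#' @param config named list of thresholds echoed verbatim.
#' @param seed the run seed.
#' @return A nested list (the report).
#' @export
stageReport <- function(cascade, maps, classification, summary = NULL,
                        conservation = NULL, validated = NULL,
                        config = list(), seed = NA_integer_) {
  best <- classification[classification$isBest == 1L, , drop = FALSE]
  best <- summarizeGencode(best)
  nBest <- nrow(best)
  sixWay <- if (nBest) {
    tab <- table(best$category)
    data.frame(category = names(tab), n = as.integer(tab),
               pct = round(100 * as.integer(tab) / nBest, 2),
               stringsAsFactors = FALSE)
  } else {
    data.frame(category = character(), n = integer(), pct = numeric())
  }
  knownNovel <- if (!is.null(conservation)) {
    as.list(table(conservation$records$status))
  } else {
    NULL
  }
  list(
    tool = "lncSieve",
    tool_version = as.character(packageVersion("lncSieve")),
    seed = seed,
    config = config,
    stage_counts = stageCounts(cascade),
    per_chromosome = chromosomeDistribution(maps),
    class_proportions = list(
      n_classified = nBest,
      genic_pct = if (nBest) round(100 * mean(best$type == "genic"), 2)
        else NA_real_,
      intergenic_pct = if (nBest)
        round(100 * mean(best$type == "intergenic"), 2) else NA_real_,
      six_way = sixWay
    ),
    known_novel = knownNovel,
    n_validated = if (is.null(validated)) NULL else length(validated),
    set_summary = summary
  )
}

#' Write a run report as JSON (plus per-table TSVs)
#'
#' @param report list from [stageReport()].
#' @param dir output directory (created if needed).
#' @return The JSON path, invisibly.
#' @export
writeStageReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonPath <- file.path(dir, "run_report.json")
  write_json(report, jsonPath, auto_unbox = TRUE, digits = NA,
             dataframe = "rows", null = "null")
  writeTsv(report$stage_counts, file.path(dir, "stage_counts.tsv"))
  writeTsv(report$per_chromosome, file.path(dir, "per_chromosome.tsv"))
  writeTsv(report$class_proportions$six_way,
           file.path(dir, "class_proportions.tsv"))
  invisible(jsonPath)
}

#' Structural validation of a run report
#'
#' Checks the report against the shape [stageReport()] promises:
#' required top-level fields, telescoping stage counts, six-way
#' proportions summing to 100 (up to rounding) and percentage bounds.
#'
#' @param report list from [stageReport()].
#' @return \code{TRUE} (invisibly) or an error describing the defect.
#' @export
validateReport <- function(report) {
  need <- c("tool", "tool_version", "seed", "config", "stage_counts",
            "per_chromosome", "class_proportions")
  miss <- setdiff(need, names(report))
  if (length(miss)) {
    stop("report missing field(s): ", paste(miss, collapse = ", "))
  }
  sc <- report$stage_counts
  if (!all(sc$n_in == sc$n_removed + sc$n_out)) {
    stop("stage counts do not conserve")
  }
  if (nrow(sc) > 1L && !all(sc$n_out[-nrow(sc)] == sc$n_in[-1L])) {
    stop("stage counts do not telescope")
  }
  sw <- report$class_proportions$six_way
  if (nrow(sw) && abs(sum(sw$pct) - 100) > 0.5) {
    stop("six-way proportions do not sum to 100")
  }
  invisible(TRUE)
}
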