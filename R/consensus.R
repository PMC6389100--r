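#' Merge per-stage tag clusters into consensus promoter regions
#'
#' Tag clusters with total tpm above \code{minTpm}, represented by their
#' interquantile intervals \code{[q_low, q_up]}, are merged across stages
#' when they lie on the same chromosome and strand with a gap of at most
#' \code{mergeDist} bp between intervals. The consensus span is the union of
#' the merged intervals; per-stage expression is the sum of member-cluster
#' tpm.
#'
#' @param clusters named list of per-stage tag cluster \code{GRanges} (as
#'   from \code{\link{clusterCTSS}}); names are the stage labels.
#' @param minTpm clusters with \code{total_tpm} at or below this are excluded
#'   (default 5; the rule is strict: tpm must exceed the threshold).
#' @param mergeDist maximum gap (bp) between interquantile intervals merged
#'   into one region (default 100).
#' @return A \code{RangedSummarizedExperiment}: rows are consensus promoter
#'   regions (strand-aware \code{rowRanges}, with \code{consensus_id}),
#'   columns are stages; assays \code{tpm} (summed member tpm),
#'   \code{dominant_pos} and \code{iq_width} (of each stage's strongest
#'   member cluster; \code{NA} where a stage has no member).
#' @examples
#' cs <- normalizeTPM(CTSSSet("chr1", c(100L, 205L), c("+", "+"),
#'                            c(60L, 40L), "s1"))
#' tc <- clusterCTSS(cs)
#' se <- buildConsensus(list(s1 = tc))
#' SummarizedExperiment::rowRanges(se)
#' @export
buildConsensus <- function(clusters, minTpm = 5, mergeDist = 100L) {
  stopifnot(is.list(clusters), !is.null(names(clusters)))
  stages <- names(clusters)
  pooled <- do.call(c, lapply(stages, function(s) {
    g <- clusters[[s]]
    g <- g[g$total_tpm > minTpm]
    if (length(g)) {
      iq <- GRanges(seqnames(g), IRanges(g$q_low, g$q_up),
                    strand = strand(g))
      mcols(iq) <- mcols(g)
      iq
    } else GRanges()
  }))
  if (length(pooled) == 0L)
    stop("no tag clusters exceed the tpm threshold")
  red <- GenomicRanges::reduce(pooled, min.gapwidth = mergeDist + 1L,
                               with.revmap = TRUE)
  n <- length(red)
  tpm <- matrix(0, n, length(stages), dimnames = list(NULL, stages))
  dom <- matrix(NA_integer_, n, length(stages),
                dimnames = list(NULL, stages))
  iqw <- matrix(NA_integer_, n, length(stages),
                dimnames = list(NULL, stages))
  revmap <- red$revmap
  for (i in seq_len(n)) {
    mem <- pooled[revmap[[i]]]
    for (s in stages) {
      ms <- mem[mem$stage == s]
      if (length(ms)) {
        tpm[i, s] <- sum(ms$total_tpm)
        top <- which.max(ms$total_tpm)
        dom[i, s] <- ms$dominant_pos[top]
        iqw[i, s] <- ms$iq_width[top]
      }
    }
  }
  rr <- granges(red)
  rr$consensus_id <- sprintf("cons%05d", seq_len(n))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = tpm, dominant_pos = dom, iq_width = iqw),
    rowRanges = rr,
    colData = DataFrame(stage = stages, row.names = stages))
}

#' Per-position expression matrix across stages
#'
#' Builds a CTSS-level expression matrix (positions x stages, tpm) from a
#' list of normalized per-stage \code{\linkS4class{CTSSSet}} objects, for
#' CTSS-level SOM clustering.
#'
#' @param ctss named list of normalized \code{CTSSSet} objects.
#' @param minTpm keep positions whose maximal tpm across stages is at least
#'   this (default 1).
#' @return numeric matrix with rownames \code{"chrom:pos:strand"}.
#' @export
ctssExpressionMatrix <- function(ctss, minTpm = 1) {
  stopifnot(is.list(ctss), !is.null(names(ctss)))
  keys <- lapply(ctss, function(x) {
    df <- as.data.frame(x)
    stats::setNames(df$tpm, paste(df$chrom, df$pos, df$strand, sep = ":"))
  })
  allk <- sort(unique(unlist(lapply(keys, names))))
  m <- vapply(keys, function(v) {
    out <- numeric(length(allk))
    out[match(names(v), allk)] <- v
    out
  }, numeric(length(allk)))
  rownames(m) <- allk
  m[apply(m, 1L, max) >= minTpm, , drop = FALSE]
}
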