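#' Promoter shifting score between two samples
#'
#' Quantifies how much of the lower-expressed sample's transcription
#' initiation occurs up- or downstream of the compared sample's initiation
#' within one consensus promoter region. Both signals are reduced to
#' cumulative fractions along the region (5' to 3' on the region's strand,
#' each normalized to 1); the score is the maximal absolute difference of
#' the two cumulative curves, i.e. the fraction of the lower sample's
#' initiation lying beyond the other sample's initiation at the point of
#' largest divergence. A score of 0 means identical positional usage, 1.0
#' completely disjoint usage. The direction reports whether the lower
#' sample's excess mass lies upstream or downstream.
#'
#' @param posA,sigA positions and per-position signal (tpm) of sample A
#'   within the region.
#' @param posB,sigB same for sample B.
#' @param strand region strand (\code{"+"} or \code{"-"}).
#' @param rawA,rawB total raw tag counts of each sample in the region, used
#'   only to decide which sample is the lower-expressed one (defaults: the
#'   signal sums).
#' @return list with \code{score} in [0, 1], \code{direction}
#'   (\code{"upstream"}/\code{"downstream"}: location of the lower sample's
#'   excess initiation relative to the other sample's), and \code{at} (the
#'   position of maximal divergence).
#' @examples
#' # 60% of the lower sample initiates upstream of everything in B
#' shiftingScore(c(10, 100), c(60, 40), 100, 100)$score  # 0.6
#' @export
shiftingScore <- function(posA, sigA, posB, sigB, strand = "+",
                          rawA = sum(sigA), rawB = sum(sigB)) {
  if (sum(sigA) <= 0 || sum(sigB) <= 0)
    stop("shifting score undefined: zero signal in one sample")
  sigB <- rep_len(sigB, length(posB))
  grid <- sort(unique(c(posA, posB)), decreasing = (strand == "-"))
  fa <- cumsum(vapply(grid, function(p) sum(sigA[posA == p]),
                      numeric(1))) / sum(sigA)
  fb <- cumsum(vapply(grid, function(p) sum(sigB[posB == p]),
                      numeric(1))) / sum(sigB)
  d <- fa - fb
  k <- which.max(abs(d))
  lowerIsA <- rawA <= rawB
  lowerLeads <- if (lowerIsA) d[k] > 0 else d[k] < 0
  # the leading (5') cumulative excess of the lower sample means its
  # initiation lies upstream of the compared sample's
  list(score = abs(d[k]),
       direction = if (lowerLeads) "upstream" else "downstream",
       at = grid[k])
}

kolmogorovPValue <- function(lambda) {
  if (is.na(lambda)) return(NA_real_)
  if (lambda < 1e-3) return(1)
  k <- 1:101
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov test for a promoter shift
#'
#' Computes the two-sample KS statistic on the per-position cumulative
#' signal distributions of the two samples within a region, with the
#' asymptotic p-value evaluated at the effective sample size
#' \code{nEffA * nEffB / (nEffA + nEffB)} (raw tag counts).
#'
#' @param posA,sigA,posB,sigB per-position signal as in
#'   \code{\link{shiftingScore}}.
#' @param nEffA,nEffB raw (un-normalized) tag counts of each sample within
#'   the region.
#' @return list with \code{statistic}, \code{p_value}, \code{n_eff}, and
#'   \code{small_n} (TRUE when either count is below 10, where the
#'   asymptotic p-value is unreliable).
#' @export
ksShiftTest <- function(posA, sigA, posB, sigB, nEffA, nEffB) {
  if (sum(sigA) <= 0 || sum(sigB) <= 0)
    stop("KS test undefined: zero signal in one sample")
  grid <- sort(unique(c(posA, posB)))
  fa <- cumsum(vapply(grid, function(p) sum(sigA[posA == p]),
                      numeric(1))) / sum(sigA)
  fb <- cumsum(vapply(grid, function(p) sum(sigB[posB == p]),
                      numeric(1))) / sum(sigB)
  d <- max(abs(fa - fb))
  neff <- nEffA * nEffB / (nEffA + nEffB)
  list(statistic = d, p_value = kolmogorovPValue(sqrt(neff) * d),
       n_eff = neff, small_n = min(nEffA, nEffB) < 10)
}

#' Detect shifting promoters between two stages
#'
#' For every consensus promoter region, gathers the per-position tpm signal
#' of both stages, computes the shifting score and the KS test, and applies
#' Benjamini-Hochberg FDR control across all tested regions. A promoter is
#' called shifting when \code{score > scoreMin} and \code{fdr < fdrMax}.
#' Regions with zero signal in either stage are skipped (reported with
#' \code{NA} statistics).
#'
#' @param consensus consensus regions: a \code{RangedSummarizedExperiment}
#'   from \code{\link{buildConsensus}} or a \code{GRanges} with a
#'   \code{consensus_id} column.
#' @param ctss named list of normalized \code{\linkS4class{CTSSSet}} objects
#'   containing at least the two stages.
#' @param stageA,stageB the two stage labels to compare.
#' @param scoreMin shifting-score threshold (default 0.6, strict).
#' @param fdrMax FDR threshold (default 0.01, strict).
#' @return \code{data.frame} with one row per region: \code{consensus_id},
#'   \code{stage_a}, \code{stage_b}, \code{shifting_score},
#'   \code{direction}, \code{ks_statistic}, \code{n_eff}, \code{p_value},
#'   \code{fdr}, \code{is_shift}, \code{tc_overlap} (fractional overlap of
#'   the two stages' interquantile intervals within the region, computed as
#'   intersection over the shorter interval) and \code{tested}.
#' @export
detectShifts <- function(consensus, ctss, stageA, stageB, scoreMin = 0.6,
                         fdrMax = 0.01) {
  gr <- if (is(consensus, "SummarizedExperiment"))
    SummarizedExperiment::rowRanges(consensus) else consensus
  stopifnot(all(c(stageA, stageB) %in% names(ctss)))
  sa <- ctssRanges(ctss[[stageA]])
  sb <- ctssRanges(ctss[[stageB]])
  n <- length(gr)
  res <- data.frame(
    consensus_id = gr$consensus_id, stage_a = stageA, stage_b = stageB,
    shifting_score = NA_real_, direction = NA_character_,
    ks_statistic = NA_real_, n_eff = NA_real_, p_value = NA_real_,
    fdr = NA_real_, is_shift = FALSE, tc_overlap = NA_real_,
    tested = FALSE, stringsAsFactors = FALSE)
  ha <- GenomicRanges::findOverlaps(gr, sa)
  hb <- GenomicRanges::findOverlaps(gr, sb)
  la <- split(S4Vectors::subjectHits(ha), factor(S4Vectors::queryHits(ha),
                                                 levels = seq_len(n)))
  lb <- split(S4Vectors::subjectHits(hb), factor(S4Vectors::queryHits(hb),
                                                 levels = seq_len(n)))
  nskip <- 0L
  for (i in seq_len(n)) {
    ia <- la[[i]]; ib <- lb[[i]]
    if (!length(ia) || !length(ib)) { nskip <- nskip + 1L; next }
    pa <- start(sa)[ia]; ta <- mcols(sa)$tpm[ia]; ca <- mcols(sa)$count[ia]
    pb <- start(sb)[ib]; tb <- mcols(sb)$tpm[ib]; cb <- mcols(sb)$count[ib]
    str <- as.character(strand(gr))[i]
    sc <- shiftingScore(pa, ta, pb, tb, strand = str,
                        rawA = sum(ca), rawB = sum(cb))
    ks <- ksShiftTest(pa, ta, pb, tb, sum(ca), sum(cb))
    qa <- interquantileWidth(pa, ta, str)
    qb <- interquantileWidth(pb, tb, str)
    inter <- max(0L, min(qa$q_up, qb$q_up) - max(qa$q_low, qb$q_low) + 1L)
    res$shifting_score[i] <- sc$score
    res$direction[i] <- sc$direction
    res$ks_statistic[i] <- ks$statistic
    res$n_eff[i] <- ks$n_eff
    res$p_value[i] <- ks$p_value
    res$tc_overlap[i] <- inter / min(qa$iq_width, qb$iq_width)
    res$tested[i] <- TRUE
  }
  if (nskip) message(nskip, " region(s) skipped (zero signal in a stage)")
  tested <- res$tested
  res$fdr[tested] <- stats::p.adjust(res$p_value[tested], method = "BH")
  res$is_shift <- tested & res$shifting_score > scoreMin & res$fdr < fdrMax
  res
}

#' Pairwise shifting-promoter count matrix
#'
#' Runs \code{\link{detectShifts}} for every pair of stages and counts the
#' promoters called shifting in each comparison.
#'
#' @param consensus,ctss,scoreMin,fdrMax as in \code{\link{detectShifts}}.
#' @param stages stage labels to compare (default: all names of
#'   \code{ctss}).
#' @return symmetric integer matrix of shifting-promoter counts.
#' @export
shiftCountMatrix <- function(consensus, ctss, stages = names(ctss),
                             scoreMin = 0.6, fdrMax = 0.01) {
  m <- matrix(0L, length(stages), length(stages),
              dimnames = list(stages, stages))
  for (i in seq_along(stages)) for (j in seq_along(stages)) {
    if (j <= i) next
    if (length(ctss[[stages[i]]]) == 0L ||
        length(ctss[[stages[j]]]) == 0L) next
    sh <- detectShifts(consensus, ctss, stages[i], stages[j],
                       scoreMin, fdrMax)
    m[i, j] <- m[j, i] <- sum(sh$is_shift)
  }
  m
}
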