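#' Cluster CTSSes into tag clusters
#'
#' Groups neighbouring CTSSes of one sample into tag clusters: CTSSes below
#' \code{minCtssTpm} are discarded first; retained CTSSes on the same
#' chromosome and strand are merged into one cluster when consecutive
#' positions are at most \code{maxGap} bp apart; resulting single-CTSS
#' clusters below \code{minSingletonTpm} are then discarded. For each cluster
#' the dominant CTSS (maximal tpm; ties broken 5'-most on the cluster's
#' strand) and the interquantile boundaries/width (see
#' \code{\link{interquantileWidth}}) are computed.
#'
#' @param x a normalized \code{\linkS4class{CTSSSet}}.
#' @param maxGap maximum distance (bp) between CTSSes within a cluster;
#'   default 20 (inclusive: positions 20 bp apart merge).
#' @param minCtssTpm CTSSes with tpm below this are discarded before
#'   clustering (default 1).
#' @param minSingletonTpm single-CTSS clusters with tpm below this are
#'   discarded (default 5).
#' @param qLow,qUp quantiles bounding the interquantile width (defaults 0.1
#'   and 0.9).
#' @return A \code{GRanges} of clusters (closed 1-based spans) with columns
#'   \code{cluster_id}, \code{stage}, \code{n_ctss}, \code{dominant_pos},
#'   \code{dominant_tpm}, \code{total_tpm}, \code{q_low}, \code{q_up},
#'   \code{iq_width}.
#' @examples
#' cs <- CTSSSet("chr1", c(100L, 120L, 141L), rep("+", 3), c(10L, 5L, 8L), "s1")
#' cs <- normalizeTPM(cs)
#' clusterCTSS(cs, minSingletonTpm = 0)
#' @export
clusterCTSS <- function(x, maxGap = 20L, minCtssTpm = 1, minSingletonTpm = 5,
                        qLow = 0.1, qUp = 0.9) {
  stopifnot(is(x, "CTSSSet"))
  gr <- x@ranges
  if (anyNA(mcols(gr)$tpm))
    stop("CTSSSet must be normalized first (see normalizeTPM)")
  keep <- mcols(gr)$tpm >= minCtssTpm
  gr <- gr[keep]
  empty <- GRanges()
  if (length(gr) == 0L) return(empty)
  chrom <- as.character(seqnames(gr))
  str <- as.character(strand(gr))
  pos <- start(gr)
  o <- order(chrom, str, pos)
  chrom <- chrom[o]; str <- str[o]; pos <- pos[o]
  tpm <- mcols(gr)$tpm[o]
  n <- length(pos)
  newclust <- c(TRUE, chrom[-1L] != chrom[-n] | str[-1L] != str[-n] |
                  (pos[-1L] - pos[-n]) > maxGap)
  cid <- cumsum(newclust)
  idx <- split(seq_len(n), cid)
  stats <- lapply(idx, function(i) {
    d <- dominantCTSS(pos[i], tpm[i], str[i][1L])
    q <- interquantileWidth(pos[i], tpm[i], str[i][1L], qLow, qUp)
    c(start = min(pos[i]), end = max(pos[i]), n_ctss = length(i),
      dominant_pos = d$pos, dominant_tpm = d$tpm, total_tpm = sum(tpm[i]),
      q_low = q$q_low, q_up = q$q_up, iq_width = q$iq_width)
  })
  m <- do.call(rbind, stats)
  firsts <- vapply(idx, `[`, integer(1), 1L)
  out <- GRanges(chrom[firsts], IRanges(m[, "start"], m[, "end"]),
                 strand = str[firsts])
  singleton <- m[, "n_ctss"] == 1 & m[, "total_tpm"] < minSingletonTpm
  out <- out[!singleton]
  m <- m[!singleton, , drop = FALSE]
  if (length(out) == 0L) return(empty)
  mcols(out) <- DataFrame(
    cluster_id = paste0(x@stage, "_TC", seq_along(out)),
    stage = x@stage, n_ctss = as.integer(m[, "n_ctss"]),
    dominant_pos = as.integer(m[, "dominant_pos"]),
    dominant_tpm = m[, "dominant_tpm"], total_tpm = m[, "total_tpm"],
    q_low = as.integer(m[, "q_low"]), q_up = as.integer(m[, "q_up"]),
    iq_width = as.integer(m[, "iq_width"]))
  out
}

#' Dominant CTSS of a cluster
#'
#' Position of maximal tpm within one cluster; ties are broken by the 5'-most
#' position on the cluster's strand (smallest position on \code{+}, largest
#' on \code{-}).
#'
#' @param pos integer positions of the cluster's CTSSes.
#' @param tpm their tpm values.
#' @param strand cluster strand, \code{"+"} or \code{"-"}.
#' @return list with \code{pos}, \code{tpm} and \code{tie} (logical: was the
#'   maximum tied?).
#' @export
dominantCTSS <- function(pos, tpm, strand) {
  stopifnot(length(pos) == length(tpm), length(pos) >= 1L)
  mx <- max(tpm)
  cand <- pos[tpm == mx]
  tie <- length(cand) > 1L
  p <- if (strand == "-") max(cand) else min(cand)
  list(pos = p, tpm = mx, tie = tie)
}

#' Interquantile boundaries and width of a tag cluster
#'
#' Walking 5' to 3' along the cluster's strand, \code{q_low} is the first
#' position at which the cumulative tpm reaches \code{qLow} of the cluster
#' total, and \code{q_up} the first position at which it reaches \code{qUp}.
#' The width is the genomic distance \code{|q_up - q_low| + 1} in bp. The
#' returned \code{q_low}/\code{q_up} are in genomic order (\code{q_low <=
#' q_up}) regardless of strand; the convention is strand-mirror symmetric.
#'
#' @param pos,tpm,strand cluster signal as in \code{\link{dominantCTSS}}.
#' @param qLow,qUp cumulative-fraction bounds (defaults 0.1, 0.9).
#' @return list with \code{q_low}, \code{q_up}, \code{iq_width}.
#' @examples
#' interquantileWidth(101:110, rep(1, 10), "+")  # width 9
#' @export
interquantileWidth <- function(pos, tpm, strand, qLow = 0.1, qUp = 0.9) {
  stopifnot(length(pos) == length(tpm), length(pos) >= 1L)
  o <- if (strand == "-") order(pos, decreasing = TRUE) else order(pos)
  p <- pos[o]
  cum <- cumsum(tpm[o])
  total <- cum[length(cum)]
  a <- p[match(TRUE, cum >= qLow * total)]
  b <- p[match(TRUE, cum >= qUp * total)]
  list(q_low = min(a, b), q_up = max(a, b),
       iq_width = abs(b - a) + 1L)
}

#' Classify tag clusters into sharp/broad shape classes
#'
#' Computes quartiles of interquantile width over the supplied (typically
#' all-stage pooled) cluster set: width at or below the lower quartile is
#' \code{sharp}, at or above the upper quartile \code{broad}, otherwise
#' \code{intermediate}. The pooled mean is used to divide the intermediate
#' range into a sharp side and a broad side (four width strata in total,
#' reported via \code{shape_side}). If the quartiles coincide (degenerate
#' width distribution) every cluster is \code{intermediate} and a message is
#' emitted.
#'
#' @param clusters a \code{GRanges} of tag clusters with an \code{iq_width}
#'   column (pool stages with \code{c()} before calling), or a list of such
#'   \code{GRanges} which is pooled internally and returned as a list.
#' @return The input with added columns \code{shape_class} (sharp /
#'   intermediate / broad) and \code{shape_side} (sharp / broad by the pooled
#'   mean threshold); the thresholds are stored in
#'   \code{metadata()$shape_thresholds}.
#' @export
classifyShape <- function(clusters) {
  islist <- !is(clusters, "GRanges")
  lst <- if (islist) clusters else list(clusters)
  w <- unlist(lapply(lst, function(g) g$iq_width))
  qs <- stats::quantile(w, c(0.25, 0.75), names = FALSE)
  mw <- mean(w)
  degenerate <- qs[1] == qs[2]
  if (degenerate)
    message("degenerate width distribution (Q1 == Q3): ",
            "all clusters classed intermediate")
  lst <- lapply(lst, function(g) {
    cls <- rep("intermediate", length(g))
    if (!degenerate) {
      cls[g$iq_width <= qs[1]] <- "sharp"
      cls[g$iq_width >= qs[2]] <- "broad"
    }
    g$shape_class <- cls
    g$shape_side <- ifelse(g$iq_width <= mw, "sharp", "broad")
    metadata(g)$shape_thresholds <- c(q1 = qs[1], mean = mw, q3 = qs[2])
    g
  })
  if (islist) lst else lst[[1L]]
}

#' Classify tag clusters by CpG content
#'
#' Counts CG dinucleotides in a window centred on each cluster's dominant
#' CTSS; the CpG frequency is that count divided by \code{window - 1}
#' (the number of dinucleotide positions in the window). Clusters in the
#' upper quartile of pooled frequencies are \code{HCG} (high CpG), in the
#' lower quartile \code{LCG}, otherwise \code{mid}.
#'
#' @param clusters \code{GRanges} of tag clusters with \code{dominant_pos}.
#' @param genome a \code{DNAStringSet} keyed by chromosome.
#' @param window window size in bp centred on the dominant CTSS (default 200).
#' @return \code{clusters} with added \code{cpg_freq} and \code{cpg_class}
#'   columns.
#' @export
classifyCpG <- function(clusters, genome, window = 200L) {
  stopifnot(is(clusters, "GRanges"))
  half <- window %/% 2L
  chrom <- as.character(seqnames(clusters))
  dom <- clusters$dominant_pos
  from <- pmax(1L, dom - half)
  to <- pmin(Biostrings::width(genome)[match(chrom, names(genome))],
             dom + half - 1L)
  win <- GRanges(chrom, IRanges(from, to), strand = "+")
  seqs <- extractRegions(genome, win)
  ncg <- Biostrings::vcountPattern("CG", seqs)
  freq <- ncg / (window - 1L)
  qs <- stats::quantile(freq, c(0.25, 0.75), names = FALSE)
  cls <- rep("mid", length(freq))
  if (qs[1] < qs[2]) {
    cls[freq <= qs[1]] <- "LCG"
    cls[freq >= qs[2]] <- "HCG"
  }
  clusters$cpg_freq <- freq
  clusters$cpg_class <- cls
  clusters
}

#' Extract strand-oriented sequences for regions
#'
#' @param genome \code{DNAStringSet} keyed by chromosome.
#' @param gr \code{GRanges}; minus-strand regions are reverse-complemented.
#' @return \code{DNAStringSet}, one sequence per range.
#' @export
extractRegions <- function(genome, gr) {
  chrom <- as.character(seqnames(gr))
  miss <- setdiff(unique(chrom), names(genome))
  if (length(miss)) stop("chromosome(s) absent from genome: ",
                         paste(miss, collapse = ", "))
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
    as.character(Biostrings::subseq(genome[[chrom[i]]],
                                    start(gr)[i], end(gr)[i]))
  }, character(1)))
  neg <- as.character(strand(gr)) == "-"
  if (any(neg))
    seqs[neg] <- Biostrings::reverseComplement(seqs[neg])
  names(seqs) <- if (!is.null(names(gr))) names(gr) else
    paste0(chrom, ":", start(gr), "-", end(gr))
  seqs
}
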