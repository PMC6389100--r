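#' Tukey's biweight mean
#'
#' Iteratively reweighted robust location estimate: weights
#' \code{(1 - u^2)^2} for \code{|u| < 1} with \code{u = (x - t) / (c * S)},
#' \code{S} the median absolute deviation from the current estimate;
#' iterated from the median until the estimate moves less than \code{tol}.
#'
#' @param x numeric vector (NAs removed).
#' @param c tuning constant (default 4.685, the standard 95-percent
#'   efficiency value).
#' @param tol convergence tolerance on the location estimate (default 1e-6).
#' @param maxIter iteration cap (default 100).
#' @return the biweight mean (scalar).
#' @examples
#' tukeyBiweightMean(c(rnorm(100), 50))  # outlier down-weighted
#' @export
tukeyBiweightMean <- function(x, c = 4.685, tol = 1e-6, maxIter = 100L) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  t0 <- stats::median(x)
  for (it in seq_len(maxIter)) {
    S <- stats::median(abs(x - t0))
    if (S == 0) return(t0)
    u <- (x - t0) / (c * S)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    t1 <- sum(w * x) / sum(w)
    if (abs(t1 - t0) < tol) return(t1)
    t0 <- t1
  }
  t0
}

#' Normalize tiling-array probe intensities
#'
#' Computes \code{raw_log2 = log2(cy5/cy3)} per probe and removes the
#' sample-wide systematic dye/labelling bias by subtracting the Tukey
#' biweight mean of all raw log-ratios. Probes with non-positive intensity
#' in either channel are dropped with a message.
#'
#' @param probes \code{data.frame} with \code{chrom}, \code{pos},
#'   \code{cy5}, \code{cy3} (as from \code{\link{readProbes}} or
#'   \code{\link{simulateArray}}).
#' @param c,tol passed to \code{\link{tukeyBiweightMean}}.
#' @return the probe track: input rows (valid probes only, sorted by
#'   chromosome and position) with added \code{raw_log2} and
#'   \code{norm_log2} columns.
#' @export
normalizeProbes <- function(probes, c = 4.685, tol = 1e-6) {
  bad <- !(probes$cy5 > 0 & probes$cy3 > 0)
  if (any(bad)) {
    message(sum(bad), " probe(s) with non-positive intensity dropped")
    probes <- probes[!bad, , drop = FALSE]
  }
  probes$raw_log2 <- log2(probes$cy5 / probes$cy3)
  probes$norm_log2 <- probes$raw_log2 -
    tukeyBiweightMean(probes$raw_log2, c = c, tol = tol)
  probes <- probes[order(probes$chrom, probes$pos), , drop = FALSE]
  rownames(probes) <- NULL
  probes
}

#' Running-median smoothing of a probe track
#'
#' Replaces each probe's normalized log-ratio by the median over all probes
#' within \code{window/2} bp on the same chromosome; the smoothed value is
#' missing (NA) wherever fewer than \code{minSupport} probes with non-zero
#' value fall in the window.
#'
#' @param track normalized probe track from \code{\link{normalizeProbes}}.
#' @param window window size in bp (default 150, about one nucleosome).
#' @param minSupport minimum number of non-zero probes in the window
#'   (default 3).
#' @return \code{track} with an added \code{smooth_log2} column.
#' @export
smoothTrack <- function(track, window = 150L, minSupport = 3L) {
  half <- window / 2
  track$smooth_log2 <- NA_real_
  for (chrom in unique(track$chrom)) {
    sel <- which(track$chrom == chrom)
    pos <- track$pos[sel]
    o <- order(pos)
    pos <- pos[o]
    val <- track$norm_log2[sel][o]
    lo <- findInterval(pos - half - 0.5, pos) + 1L
    hi <- findInterval(pos + half + 0.5 - 1e-9, pos)
    sm <- vapply(seq_along(pos), function(i) {
      v <- val[lo[i]:hi[i]]
      if (sum(v != 0, na.rm = TRUE) < minSupport) NA_real_
      else stats::median(v, na.rm = TRUE)
    }, numeric(1))
    track$smooth_log2[sel[o]] <- sm
  }
  track
}

#' Metagene profile around dominant TSSs with bootstrap CIs
#'
#' Maps probes to strand-aware offsets relative to each promoter's dominant
#' TSS within a window of \code{2 * halfWindow} bp, bins offsets at probe
#' resolution (\code{binWidth}), and reports the mean signal per offset
#' with a percentile bootstrap confidence interval for the mean obtained by
#' resampling promoters with replacement. Promoters whose windows overlap
#' another promoter's window are excluded first (their probes would be
#' counted twice).
#'
#' @param track probe track with the signal column.
#' @param promoters \code{GRanges} of dominant TSSs (width 1, stranded).
#' @param halfWindow half-window in bp (default 500).
#' @param boot bootstrap replicates (default 1000).
#' @param seed integer RNG seed for the bootstrap.
#' @param value signal column name (default \code{"norm_log2"}; use
#'   \code{"smooth_log2"} for the smoothed track).
#' @param binWidth offset bin width in bp; default: the median probe
#'   spacing of the track.
#' @param level confidence level (default 0.95).
#' @return \code{data.frame} with \code{offset}, \code{mean},
#'   \code{ci_low}, \code{ci_high}, \code{n} (promoters contributing at
#'   that offset); the number of promoters used is in
#'   \code{attr(, "n_promoters")}.
#' @export
metagene <- function(track, promoters, halfWindow = 500L, boot = 1000L,
                     seed = 1L, value = "norm_log2", binWidth = NULL,
                     level = 0.95) {
  if (length(promoters) == 0L) stop("empty promoter group")
  if (!value %in% names(track)) stop("no '", value, "' column in track")
  win <- GRanges(seqnames(promoters),
                 IRanges(start(promoters) - halfWindow,
                         start(promoters) + halfWindow))
  novl <- IRanges::countOverlaps(win, win, ignore.strand = TRUE)
  if (any(novl > 1L)) {
    message(sum(novl > 1L), " promoter(s) with overlapping windows excluded")
    promoters <- promoters[novl == 1L]
    if (length(promoters) == 0L)
      stop("no promoters left after overlap exclusion")
  }
  if (is.null(binWidth)) {
    sp <- unlist(lapply(split(track$pos, track$chrom),
                        function(p) diff(sort(unique(p)))))
    binWidth <- if (length(sp)) stats::median(sp) else 1
  }
  np <- length(promoters)
  pgr <- GRanges(track$chrom, IRanges(track$pos, width = 1L))
  hit <- GenomicRanges::findOverlaps(pgr,
                                     GRanges(seqnames(promoters),
                                             IRanges(start(promoters) -
                                                       halfWindow,
                                                     start(promoters) +
                                                       halfWindow)),
                                     ignore.strand = TRUE)
  pi <- S4Vectors::queryHits(hit)
  qi <- S4Vectors::subjectHits(hit)
  str <- as.character(strand(promoters))[qi]
  off <- ifelse(str == "-", start(promoters)[qi] - track$pos[pi],
                track$pos[pi] - start(promoters)[qi])
  bin <- round(off / binWidth) * binWidth
  sig <- track[[value]][pi]
  keep <- !is.na(sig)
  bin <- bin[keep]; sig <- sig[keep]; qi <- qi[keep]
  if (!length(sig)) stop("no probe signal within the promoter windows")
  bins <- sort(unique(bin))
  M <- matrix(NA_real_, np, length(bins))
  M[cbind(qi, match(bin, bins))] <- sig
  npb <- colSums(!is.na(M))
  mu <- colMeans(M, na.rm = TRUE)
  set.seed(seed)
  alpha <- (1 - level) / 2
  if (anyNA(M)) {
    bm <- matrix(NA_real_, boot, length(bins))
    for (b in seq_len(boot)) {
      idx <- sample.int(np, np, replace = TRUE)
      bm[b, ] <- colMeans(M[idx, , drop = FALSE], na.rm = TRUE)
    }
  } else {
    W <- stats::rmultinom(boot, np, rep(1, np)) / np
    bm <- t(W) %*% M
  }
  ci <- apply(bm, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  out <- data.frame(offset = bins, mean = mu, ci_low = pmin(ci[1L, ], mu),
                    ci_high = pmax(ci[2L, ], mu), n = npb)
  attr(out, "n_promoters") <- np
  out
}
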