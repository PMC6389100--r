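#' Strand-oriented promoter windows around dominant CTSSes
#'
#' Extracts sequences covering \code{up} bp upstream through \code{down} bp
#' downstream of each dominant CTSS, reverse-complemented for minus-strand
#' promoters so that all sequences read 5' to 3'. With the defaults the
#' window is 200 bp with the TSS at oriented index \code{up + 1} = 101.
#' Offsets throughout the motif functions follow the convention: distance
#' from a motif's 5'-most base to the dominant TSS, positive = upstream
#' (oriented index \code{j} corresponds to offset \code{up + 1 - j}).
#'
#' @param genome \code{DNAStringSet}.
#' @param tss \code{GRanges} of dominant CTSS positions (width 1, stranded),
#'   or a tag cluster \code{GRanges} with \code{dominant_pos} (used if
#'   present). Windows truncated by a chromosome edge are dropped with a
#'   message.
#' @param up,down bp upstream/downstream of the TSS (defaults 100 and 99).
#' @return \code{DNAStringSet} of equal-length oriented sequences; the TSS
#'   index is carried in the \code{"tssIndex"} attribute.
#' @export
promoterWindows <- function(genome, tss, up = 100L, down = 99L) {
  if (!is.null(mcols(tss)$dominant_pos)) {
    tss <- GRanges(seqnames(tss),
                   IRanges(mcols(tss)$dominant_pos, width = 1L),
                   strand = strand(tss),
                   promoter_id = if (!is.null(mcols(tss)$cluster_id))
                     mcols(tss)$cluster_id else as.character(seq_along(tss)))
  }
  str <- as.character(strand(tss))
  from <- ifelse(str == "+", start(tss) - up, start(tss) - down)
  to <- ifelse(str == "+", start(tss) + down, start(tss) + up)
  lens <- Biostrings::width(genome)[match(as.character(seqnames(tss)),
                                          names(genome))]
  ok <- from >= 1L & to <= lens
  if (any(!ok)) message(sum(!ok), " window(s) at chromosome edges dropped")
  win <- GRanges(seqnames(tss)[ok], IRanges(from[ok], to[ok]),
                 strand = str[ok])
  seqs <- extractRegions(genome, win)
  names(seqs) <- if (!is.null(mcols(tss)$promoter_id))
    mcols(tss)$promoter_id[ok] else names(seqs)
  attr(seqs, "tssIndex") <- up + 1L
  seqs
}

allKmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE)[, k:1, drop = FALSE])
}

#' Exhaustive k-mer positional occurrence and enrichment
#'
#' Counts every k-mer (k in \code{kRange}) at every offset across a set of
#' equal-length, strand-oriented promoter sequences, and ranks k-mers by
#' peak positional enrichment: the maximum over offsets of observed count
#' over the count expected from each sequence's own mononucleotide
#' composition (which controls GC skew). Windows containing N are skipped
#' (logged).
#'
#' @param seqs \code{DNAStringSet} of equal-length oriented sequences, as
#'   from \code{\link{promoterWindows}}.
#' @param kRange k values to scan (default 1:6).
#' @param tssIndex oriented index of the TSS base (default from the
#'   \code{"tssIndex"} attribute, else 101).
#' @return named list (one element per k) of lists with \code{counts}
#'   (k-mers x offsets occurrence matrix, columns named by offset),
#'   \code{expected} (per-k-mer expected count at any one offset) and
#'   \code{ranking} (data.frame \code{kmer}, \code{peak_enrichment},
#'   \code{peak_offset}, sorted by decreasing peak enrichment).
#' @export
scanKmers <- function(seqs, kRange = 1:6, tssIndex = NULL) {
  if (is.null(tssIndex))
    tssIndex <- if (!is.null(attr(seqs, "tssIndex")))
      attr(seqs, "tssIndex") else 101L
  chars <- as.character(seqs)
  L <- unique(nchar(chars))
  if (length(L) != 1L) stop("sequences must be of equal length")
  nN <- sum(grepl("N", chars, fixed = TRUE))
  if (nN) message(nN, " sequence(s) contain N; affected windows skipped")
  # per-sequence mononucleotide composition for the positional null
  basefreq <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  basefreq <- basefreq / rowSums(basefreq)
  logp <- log(pmax(basefreq, 1e-12))
  out <- list()
  for (k in kRange) {
    kmers <- allKmers(k)
    noff <- L - k + 1L
    counts <- matrix(0L, length(kmers), noff,
                     dimnames = list(kmers, tssIndex - seq_len(noff)))
    for (j in seq_len(noff)) {
      sub <- substr(chars, j, j + k - 1L)
      counts[, j] <- tabulate(factor(sub, levels = kmers),
                              nbins = length(kmers))
    }
    nb <- t(vapply(strsplit(kmers, ""), function(b)
      c(sum(b == "A"), sum(b == "C"), sum(b == "G"), sum(b == "T")),
      numeric(4)))
    expected <- rowSums(exp(nb %*% t(logp)))
    enr <- counts / pmax(expected, .Machine$double.eps)
    peak <- apply(enr, 1L, max)
    peakat <- as.integer(colnames(counts))[apply(enr, 1L, which.max)]
    rk <- data.frame(kmer = kmers, peak_enrichment = peak,
                     peak_offset = peakat, stringsAsFactors = FALSE)
    rk <- rk[order(-rk$peak_enrichment), ]
    rownames(rk) <- NULL
    out[[paste0("k", k)]] <- list(counts = counts, expected = expected,
                                  ranking = rk)
  }
  out
}

#' Search an IUPAC motif in a fixed upstream window
#'
#' Matches an IUPAC consensus (W = A/T, R = A/G, etc.) anywhere within a
#' strand-aware upstream window of each promoter, recording every hit's
#' offset (motif 5' base to dominant TSS). Window bounds are closed offsets:
#' e.g. the 37-22 bp upstream TATA window means offsets 22 through 37
#' inclusive.
#'
#' @param seqs oriented \code{DNAStringSet} from
#'   \code{\link{promoterWindows}}.
#' @param motif IUPAC motif string.
#' @param winFrom,winTo closed offset bounds of the search window (order
#'   free; e.g. 37 and 22).
#' @param tssIndex oriented TSS index (default: attribute, else 101).
#' @return list with \code{hits} (data.frame \code{promoter_id},
#'   \code{motif}, \code{offset}, \code{score}) and \code{present} (named
#'   logical, one per promoter).
#' @examples
#' s <- Biostrings::DNAStringSet(c(p1 = paste0(strrep("A", 70), "TATAAAG",
#'                                             strrep("A", 123))))
#' searchFixedWindow(s, "TATAW", 37, 22, tssIndex = 101)$hits
#' @export
searchFixedWindow <- function(seqs, motif, winFrom, winTo, tssIndex = NULL) {
  if (is.null(tssIndex))
    tssIndex <- if (!is.null(attr(seqs, "tssIndex")))
      attr(seqs, "tssIndex") else 101L
  lo <- min(winFrom, winTo)
  hi <- max(winFrom, winTo)
  m <- Biostrings::vmatchPattern(motif, seqs, fixed = FALSE)
  ids <- if (!is.null(names(seqs))) names(seqs) else
    as.character(seq_along(seqs))
  rows <- list()
  for (i in seq_along(seqs)) {
    st <- BiocGenerics::start(m[[i]])
    off <- tssIndex - st
    off <- off[off >= lo & off <= hi]
    if (length(off))
      rows[[length(rows) + 1L]] <- data.frame(
        promoter_id = ids[i], motif = motif, offset = off, score = 1,
        stringsAsFactors = FALSE)
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(promoter_id = character(0), motif = character(0),
               offset = integer(0), score = numeric(0))
  present <- stats::setNames(ids %in% hits$promoter_id, ids)
  list(hits = hits, present = present)
}

#' Positional dinucleotide frequency profile
#'
#' Frequency of each of the 16 dinucleotides at each oriented offset across
#' a promoter set; at every position the 16 frequencies sum to 1 (sequences
#' with N at a position are excluded from that position's denominator).
#'
#' @param seqs oriented equal-length \code{DNAStringSet}.
#' @param tssIndex oriented TSS index (default: attribute, else 101).
#' @return 16 x (L-1) matrix; rows are dinucleotides, columns named by the
#'   offset of the dinucleotide's first base.
#' @export
dinucleotideProfile <- function(seqs, tssIndex = NULL) {
  if (is.null(tssIndex))
    tssIndex <- if (!is.null(attr(seqs, "tssIndex")))
      attr(seqs, "tssIndex") else 101L
  chars <- as.character(seqs)
  L <- unique(nchar(chars))
  if (length(L) != 1L) stop("sequences must be of equal length")
  dn <- allKmers(2L)
  out <- matrix(0, 16L, L - 1L,
                dimnames = list(dn, tssIndex - seq_len(L - 1L)))
  for (j in seq_len(L - 1L)) {
    sub <- substr(chars, j, j + 1L)
    tab <- tabulate(factor(sub, levels = dn), nbins = 16L)
    tot <- sum(tab)
    out[, j] <- if (tot > 0) tab / tot else 0
  }
  out
}

#' Position weight matrix from base probabilities
#'
#' Converts a probability matrix (rows A, C, G, T; columns = motif
#' positions) into a log2-odds scoring matrix against a background. Zero
#' probabilities (pseudocount 0) are floored at a machine-small value so
#' scores remain finite; an exact consensus still attains relative score 1.
#'
#' @param prob 4 x w probability matrix, rownames A/C/G/T.
#' @param background background base probabilities (default uniform).
#' @param pseudocount added to every probability before renormalizing
#'   (default 0).
#' @return 4 x w numeric log2-odds matrix.
#' @export
pwmFromProbabilities <- function(prob, background = rep(0.25, 4),
                                 pseudocount = 0) {
  prob <- as.matrix(prob)[c("A", "C", "G", "T"), , drop = FALSE]
  if (pseudocount > 0) {
    prob <- prob + pseudocount * background
    prob <- sweep(prob, 2L, colSums(prob), "/")
  }
  log2(pmax(prob, 1e-12) / background)
}

#' Scan promoter upstream regions with a position weight matrix
#'
#' Slides a log-odds PWM over each oriented sequence restricted to the
#' upstream region of length \code{upstreamLen}, scoring each window as the
#' sum of column scores and reporting hits whose relative score
#' \code{(S - Smin) / (Smax - Smin)} reaches \code{minRelScore}
#' (\code{Smin}/\code{Smax} = minimal/maximal attainable PWM score).
#'
#' @param seqs oriented \code{DNAStringSet} (windows containing N are
#'   skipped).
#' @param pwm 4 x w log-odds matrix (see
#'   \code{\link{pwmFromProbabilities}}).
#' @param upstreamLen length of the upstream region scanned (default 101
#'   bp, i.e. offsets \code{upstreamLen} down to motif-width constraints).
#' @param minRelScore relative score threshold (default 0.85).
#' @param tssIndex oriented TSS index (default: attribute, else 101).
#' @return data.frame \code{promoter_id}, \code{offset} (motif 5' base to
#'   TSS), \code{score} (relative score).
#' @export
pwmScan <- function(seqs, pwm, upstreamLen = 101L, minRelScore = 0.85,
                    tssIndex = NULL) {
  if (is.null(tssIndex))
    tssIndex <- if (!is.null(attr(seqs, "tssIndex")))
      attr(seqs, "tssIndex") else 101L
  w <- ncol(pwm)
  smin <- sum(apply(pwm, 2L, min))
  smax <- sum(apply(pwm, 2L, max))
  chars <- as.character(seqs)
  ids <- if (!is.null(names(seqs))) names(seqs) else
    as.character(seq_along(seqs))
  # scanned oriented indices: motif 5' base offsets upstreamLen .. 1
  jmin <- max(1L, tssIndex - upstreamLen)
  jmax <- tssIndex - 1L
  rows <- list()
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (i in seq_along(chars)) {
    b <- code[strsplit(chars[i], "")[[1]]]
    for (j in jmin:min(jmax, length(b) - w + 1L)) {
      idx <- b[j:(j + w - 1L)]
      if (anyNA(idx)) next
      s <- sum(pwm[cbind(idx, seq_len(w))])
      rel <- (s - smin) / (smax - smin)
      if (rel >= minRelScore)
        rows[[length(rows) + 1L]] <- data.frame(
          promoter_id = ids[i], offset = tssIndex - j, score = rel,
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(promoter_id = character(0), offset = integer(0),
               score = numeric(0))
}

#' Read motifs in MEME minimal format
#'
#' Parses a MEME minimal motif file and returns the letter-probability
#' matrices.
#'
#' @param path MEME minimal format file.
#' @return named list of 4 x w probability matrices (rownames A/C/G/T).
#' @export
readMemeMotif <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  curname <- NULL
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^MOTIF\\b", ln)) {
      curname <- strsplit(ln, "\\s+")[[1]][2]
    } else if (grepl("^letter-probability matrix", ln)) {
      wm <- regmatches(ln, regexec("w=\\s*(\\d+)", ln))[[1]][2]
      w <- as.integer(wm)
      block <- lines[(i + 1L):(i + w)]
      m <- t(vapply(block, function(x)
        as.numeric(strsplit(trimws(x), "\\s+")[[1]][1:4]), numeric(4)))
      mat <- t(m)
      rownames(mat) <- c("A", "C", "G", "T")
      out[[if (is.null(curname)) paste0("motif", length(out) + 1L)
           else curname]] <- mat
      i <- i + w
    }
    i <- i + 1L
  }
  if (!length(out)) stop("no motifs found in ", path)
  out
}

#' Association between motif presence and SOM expression classes
#'
#' For one motif: (i) the percentage of promoters within each SOM class that
#' contain the motif, (ii) the percentage of motif-containing promoters
#' falling in each class, and a chi-square test of the motif-by-class
#' association (without Yates continuity correction by default, matching
#' the conventional reporting style; enable with \code{correct = TRUE}).
#'
#' @param present named logical: motif presence per promoter.
#' @param units named character: SOM unit per promoter (names matched to
#'   \code{present}).
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with \code{pct_of_class_with_motif},
#'   \code{pct_of_motif_by_class} (named numeric, percent), and
#'   \code{chisq} (the \code{htest}, or NULL when degenerate).
#' @export
motifExpressionAssociation <- function(present, units, correct = FALSE) {
  common <- intersect(names(present), names(units))
  p <- present[common]
  u <- units[common]
  keep <- !is.na(u)
  p <- p[keep]; u <- u[keep]
  byclass <- tapply(p, u, function(z) 100 * mean(z))
  ofmotif <- if (any(p)) 100 * table(u[p]) / sum(p) else
    stats::setNames(rep(0, length(unique(u))), sort(unique(u)))
  chs <- NULL
  if (any(p) && !all(p) && length(unique(u)) > 1L)
    chs <- suppressWarnings(stats::chisq.test(table(p, u),
                                              correct = correct))
  list(pct_of_class_with_motif = byclass,
       pct_of_motif_by_class = c(ofmotif), chisq = chs)
}

#' Positional density matrix of a motif across promoters
#'
#' Indicator matrix of motif 5'-base occurrences at every offset for every
#' promoter, with rows ordered from broad to sharp (decreasing interquantile
#' width) when widths are supplied — the plot-ready form of a positional
#' motif heatmap.
#'
#' @param seqs oriented equal-length \code{DNAStringSet} (e.g.
#'   \code{\link{promoterWindows}} with \code{up = 500, down = 500}).
#' @param motif IUPAC motif.
#' @param iqWidths optional numeric vector (named by promoter or in
#'   \code{seqs} order) used to order rows broad to sharp.
#' @param tssIndex oriented TSS index (default: attribute, else 101).
#' @return integer matrix, promoters x offsets; \code{1} marks a motif
#'   start, column names are offsets (positive = upstream).
#' @export
positionalDensity <- function(seqs, motif, iqWidths = NULL,
                              tssIndex = NULL) {
  if (is.null(tssIndex))
    tssIndex <- if (!is.null(attr(seqs, "tssIndex")))
      attr(seqs, "tssIndex") else 101L
  L <- unique(Biostrings::width(seqs))
  if (length(L) != 1L) stop("sequences must be of equal length")
  noff <- L - nchar(motif) + 1L
  ids <- if (!is.null(names(seqs))) names(seqs) else
    as.character(seq_along(seqs))
  m <- matrix(0L, length(seqs), noff,
              dimnames = list(ids, tssIndex - seq_len(noff)))
  hits <- Biostrings::vmatchPattern(motif, seqs, fixed = FALSE)
  for (i in seq_along(seqs)) {
    st <- BiocGenerics::start(hits[[i]])
    m[i, st[st <= noff]] <- 1L
  }
  if (!is.null(iqWidths)) {
    w <- if (!is.null(names(iqWidths))) iqWidths[ids] else iqWidths
    m <- m[order(-w), , drop = FALSE]
  }
  m
}
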