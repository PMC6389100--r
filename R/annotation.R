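#' Assign tag clusters to gene models
#'
#' A cluster is associated with a gene when its dominant CTSS lies within
#' the gene body or the 500 bp (strand-oriented) upstream region. When the
#' dominant CTSS falls in several genes' windows the gene whose annotated
#' start is nearest wins; remaining ties go to the 5'-most gene on the
#' strand. The frequency of ambiguous assignments is reported with a
#' message.
#'
#' @param clusters tag cluster \code{GRanges} with \code{cluster_id} and
#'   \code{dominant_pos}.
#' @param genes gene \code{GRanges} with \code{gene_id}, \code{operon_id},
#'   \code{operon_pos}.
#' @param upstream upstream window in bp (default 500).
#' @return \code{data.frame}: \code{cluster_id}, \code{gene_id} (NA when
#'   unassigned), \code{relation} (\code{in_gene_body} /
#'   \code{in_upstream_500}), \code{operon_id}, \code{operon_pos}.
#' @export
assignToGenes <- function(clusters, genes, upstream = 500L) {
  str <- as.character(strand(genes))
  win <- GRanges(seqnames(genes),
                 IRanges(ifelse(str == "+", start(genes) - upstream,
                                start(genes)),
                         ifelse(str == "+", end(genes),
                                end(genes) + upstream)),
                 strand = str)
  pts <- GRanges(seqnames(clusters),
                 IRanges(clusters$dominant_pos, width = 1L),
                 strand = strand(clusters))
  hit <- GenomicRanges::findOverlaps(pts, win)
  qh <- S4Vectors::queryHits(hit)
  sh <- S4Vectors::subjectHits(hit)
  n <- length(clusters)
  out <- data.frame(cluster_id = clusters$cluster_id,
                    gene_id = NA_character_, relation = NA_character_,
                    operon_id = NA_character_, operon_pos = NA_integer_,
                    stringsAsFactors = FALSE)
  nambig <- 0L
  for (i in unique(qh)) {
    cand <- sh[qh == i]
    if (length(cand) > 1L) {
      nambig <- nambig + 1L
      gstart <- ifelse(str[cand] == "+", start(genes)[cand],
                       end(genes)[cand])
      d <- abs(gstart - clusters$dominant_pos[i])
      cand <- cand[d == min(d)]
      if (length(cand) > 1L) {
        gs <- ifelse(str[cand] == "+", start(genes)[cand],
                     -end(genes)[cand])
        cand <- cand[which.min(gs)]
      } else cand <- cand[1L]
    }
    g <- cand[1L]
    inbody <- clusters$dominant_pos[i] >= start(genes)[g] &
      clusters$dominant_pos[i] <= end(genes)[g]
    out$gene_id[i] <- genes$gene_id[g]
    out$relation[i] <- if (inbody) "in_gene_body" else "in_upstream_500"
    out$operon_id[i] <- genes$operon_id[g]
    out$operon_pos[i] <- genes$operon_pos[g]
  }
  if (nambig) message(nambig, " cluster(s) overlapped several gene windows;",
                      " resolved to the nearest annotated start")
  out
}

#' Classify genes as spliced-leader trans-spliced
#'
#' A gene is SL trans-spliced when an SL site lies within its body or
#' 500 bp (strand-oriented) upstream region, is supported by more than one
#' tag, and has the AG acceptor dinucleotide immediately upstream on its
#' strand in the reference sequence. Classification depends only on the SL
#' table, the gene models and the genome.
#'
#' @param genes gene \code{GRanges} with \code{gene_id}.
#' @param slSites SL site \code{GRanges} (width 1, stranded, \code{count}).
#' @param genome \code{DNAStringSet}.
#' @param upstream upstream window in bp (default 500).
#' @return \code{data.frame}: \code{gene_id}, \code{is_trans_spliced},
#'   supporting site \code{sl_chrom}, \code{sl_pos}, \code{sl_strand},
#'   \code{sl_count} (the strongest qualifying, else strongest overlapping,
#'   site) and \code{acceptor_ok}.
#' @export
classifySL <- function(genes, slSites, genome, upstream = 500L) {
  str <- as.character(strand(genes))
  win <- GRanges(seqnames(genes),
                 IRanges(ifelse(str == "+", start(genes) - upstream,
                                start(genes)),
                         ifelse(str == "+", end(genes),
                                end(genes) + upstream)),
                 strand = str)
  accOK <- if (length(slSites)) slAcceptorOK(slSites, genome) else logical(0)
  hit <- GenomicRanges::findOverlaps(slSites, win)
  out <- data.frame(gene_id = genes$gene_id, is_trans_spliced = FALSE,
                    sl_chrom = NA_character_, sl_pos = NA_integer_,
                    sl_strand = NA_character_, sl_count = NA_integer_,
                    acceptor_ok = NA, stringsAsFactors = FALSE)
  for (g in unique(S4Vectors::subjectHits(hit))) {
    si <- S4Vectors::queryHits(hit)[S4Vectors::subjectHits(hit) == g]
    pass <- si[slSites$count[si] > 1L & accOK[si]]
    best <- if (length(pass)) pass[which.max(slSites$count[pass])] else
      si[which.max(slSites$count[si])]
    out$is_trans_spliced[g] <- length(pass) > 0L
    out$sl_chrom[g] <- as.character(seqnames(slSites))[best]
    out$sl_pos[g] <- start(slSites)[best]
    out$sl_strand[g] <- as.character(strand(slSites))[best]
    out$sl_count[g] <- slSites$count[best]
    out$acceptor_ok[g] <- accOK[best]
  }
  out
}

#' Check the AG acceptor dinucleotide of SL sites
#'
#' Verifies, against the reference, that the two bases immediately upstream
#' (strand-oriented) of each site are AG.
#'
#' @param slSites SL site \code{GRanges}.
#' @param genome \code{DNAStringSet}.
#' @return logical vector.
#' @export
slAcceptorOK <- function(slSites, genome) {
  str <- as.character(strand(slSites))
  pos <- start(slSites)
  from <- ifelse(str == "+", pos - 2L, pos + 1L)
  to <- ifelse(str == "+", pos - 1L, pos + 2L)
  lens <- Biostrings::width(genome)[match(as.character(seqnames(slSites)),
                                          names(genome))]
  ok <- from >= 1L & to <= lens
  res <- rep(FALSE, length(slSites))
  if (any(ok)) {
    din <- extractRegions(genome,
                          GRanges(seqnames(slSites)[ok],
                                  IRanges(from[ok], to[ok]),
                                  strand = str[ok]))
    res[ok] <- as.character(din) == "AG"
  }
  res
}

#' Find operon-internal promoters
#'
#' A tag cluster is operon-internal when its dominant CTSS is assigned to a
#' gene inside an operon at position 2 or later (i.e. a gene normally
#' transcribed from the operon's single upstream promoter).
#'
#' @param clusters tag cluster \code{GRanges}.
#' @param genes gene \code{GRanges}.
#' @param assignments optional precomputed \code{\link{assignToGenes}}
#'   output.
#' @return \code{data.frame} of internal promoters: \code{cluster_id},
#'   \code{operon_id}, \code{gene_id}, \code{operon_pos}, plus the
#'   cluster's \code{stage}, \code{shape_class} and \code{som_unit} columns
#'   when present on \code{clusters}.
#' @export
findInternalPromoters <- function(clusters, genes, assignments = NULL) {
  if (is.null(assignments)) assignments <- assignToGenes(clusters, genes)
  sel <- !is.na(assignments$operon_pos) & assignments$operon_pos >= 2L
  out <- assignments[sel, c("cluster_id", "operon_id", "gene_id",
                            "operon_pos")]
  for (col in c("stage", "shape_class", "som_unit"))
    if (!is.null(mcols(clusters)[[col]]))
      out[[col]] <- mcols(clusters)[[col]][sel]
  rownames(out) <- NULL
  out
}

#' Detect motif-driven exclusion of trans-splice acceptor sites
#'
#' Emits an event when a promoter's TCTAGA-type motif hit has its internal
#' AG (motif positions 4-5) coinciding genomically with an SL acceptor's AG
#' and the promoter's dominant TSS lies 3' of the acceptor position —
#' transcripts initiated at this TSS cannot contain the acceptor and thus
#' escape trans-splicing.
#'
#' @param hits motif hit \code{data.frame} (\code{promoter_id},
#'   \code{offset}) as from \code{\link{searchFixedWindow}}.
#' @param tss \code{GRanges} of dominant TSSs, width 1, stranded, with a
#'   \code{promoter_id} column matching \code{hits}.
#' @param slSites SL site \code{GRanges} (width 1, stranded, \code{count}).
#' @param agPos position of the A of the acceptor AG within the motif
#'   (default 4, i.e. TCT-AG-A).
#' @param motifLen motif length (default 6).
#' @return \code{data.frame} of events: \code{promoter_id}, \code{chrom},
#'   \code{strand}, \code{motif_start} (genomic 5' base), \code{acceptor_pos},
#'   \code{tss}, \code{sl_count}.
#' @export
detectSLExclusion <- function(hits, tss, slSites, agPos = 4L,
                              motifLen = 6L) {
  empty <- data.frame(promoter_id = character(0), chrom = character(0),
                      strand = character(0), motif_start = integer(0),
                      acceptor_pos = integer(0), tss = integer(0),
                      sl_count = integer(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L || length(slSites) == 0L) return(empty)
  idx <- match(hits$promoter_id, tss$promoter_id)
  str <- as.character(strand(tss))[idx]
  chrom <- as.character(seqnames(tss))[idx]
  tp <- start(tss)[idx]
  g5 <- ifelse(str == "+", tp - hits$offset, tp + hits$offset)
  # acceptor position implied by the motif: its AG is at motif positions
  # agPos..agPos+1, so the first transcribed base is motif position agPos+2
  acc <- ifelse(str == "+", g5 + (agPos + 1L), g5 - (agPos + 1L))
  downstream <- ifelse(str == "+", tp > acc, tp < acc)
  slkey <- paste(as.character(seqnames(slSites)), start(slSites),
                 as.character(strand(slSites)))
  m <- match(paste(chrom, acc, str), slkey)
  sel <- which(!is.na(m) & downstream)
  if (!length(sel)) return(empty)
  data.frame(promoter_id = hits$promoter_id[sel], chrom = chrom[sel],
             strand = str[sel], motif_start = g5[sel],
             acceptor_pos = acc[sel], tss = tp[sel],
             sl_count = slSites$count[m[sel]], stringsAsFactors = FALSE)
}

#' Intersect enrichment regions with promoter windows of start sites
#'
#' Tests, for each annotated start site, whether any enriched region
#' overlaps the window from \code{up} bp upstream to \code{down} bp
#' downstream of the site (strand-oriented, closed intervals; any >= 1 bp
#' overlap counts).
#'
#' @param regions enriched-region \code{GRanges} (strand ignored).
#' @param starts \code{GRanges} of annotated start sites (width 1,
#'   stranded).
#' @param up,down window extent in bp (defaults 500 and 100).
#' @return logical vector, one per start site.
#' @export
intersectPromoterMarks <- function(regions, starts, up = 500L,
                                   down = 100L) {
  str <- as.character(strand(starts))
  pos <- start(starts)
  win <- GRanges(seqnames(starts),
                 IRanges(ifelse(str == "+", pos - up, pos - down),
                         ifelse(str == "+", pos + down, pos + up)))
  IRanges::overlapsAny(win, regions, ignore.strand = TRUE)
}
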