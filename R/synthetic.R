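#' Default developmental stage labels
#'
#' Six stages spanning a 6-day life cycle: oocyte, tailbud, tadpole, day-2
#' juvenile, day-6 female and day-6 male.
#' @return character vector of length 6.
#' @export
defaultStages <- function() {
  c("oocyte", "tailbud", "tadpole", "day2", "female_d6", "male_d6")
}

#' Default promoter archetypes
#'
#' A study-condition set of six archetypes emulating the major promoter
#' classes: broad maternal, zygotic and ubiquitous promoters (dispersed
#' initiation, no core motif) and sharp ubiquitous (ACCATAA at 56 bp),
#' adult tissue-specific TATA (TATAA at 30 bp) and male/spermatogenic
#' (TCTAGA at 44 bp) promoters.
#'
#' @return list of \code{\linkS4class{PromoterArchetype}} objects.
#' @export
defaultArchetypes <- function() {
  list(
    promoterArchetype("maternal_broad", "broad",
                      stageProfile = c(1, 0.7, 0.4, 0.15, 0.1, 0.05),
                      spreadSd = 10),
    promoterArchetype("zygotic_broad", "broad",
                      stageProfile = c(0.05, 1, 0.8, 0.4, 0.2, 0.1),
                      spreadSd = 8),
    promoterArchetype("ubiquitous_broad", "broad",
                      stageProfile = c(1, 1, 1, 1, 1, 1), spreadSd = 8),
    promoterArchetype("ubiquitous_sharp", "sharp", motif = "ACCATAA",
                      motifOffset = 56L,
                      stageProfile = c(0.8, 1, 1, 1, 0.9, 0.8),
                      spreadSd = 0.5),
    promoterArchetype("adult_tata_sharp", "sharp", motif = "TATAA",
                      motifOffset = 30L,
                      stageProfile = c(0, 0, 0, 0.3, 1, 0.4),
                      spreadSd = 0.5),
    promoterArchetype("male_sharp", "sharp", motif = "TCTAGA",
                      motifOffset = 44L,
                      stageProfile = c(0, 0, 0, 0, 0.05, 1),
                      spreadSd = 0.5))
}

#' Generate a small synthetic genome with gene and operon annotation
#'
#' Produces random chromosome sequences of a given GC content and a set of
#' non-overlapping gene models on both strands; a stated fraction of genes is
#' grouped into operons of 2-4 consecutive same-strand genes carrying
#' \code{operon_id} and \code{operon_pos} (1-based order) attributes.
#' Deterministic for a fixed seed.
#'
#' @param nChrom number of chromosomes (>= 1).
#' @param chromLen chromosome length in bp (>= 10000).
#' @param gc GC content in [0, 1].
#' @param nGenes total number of genes to place (split across chromosomes).
#' @param operonFraction target fraction of genes inside operons (default
#'   0.278).
#' @param seed integer RNG seed.
#' @return list with \code{genome} (\code{DNAStringSet}) and \code{genes}
#'   (\code{GRanges} with \code{gene_id}, \code{operon_id}, \code{operon_pos}).
#' @examples
#' gen <- generateGenome(1, 50000, gc = 0.4, nGenes = 20, seed = 1)
#' gen$genes
#' @export
generateGenome <- function(nChrom = 2L, chromLen = 100000L, gc = 0.4,
                           nGenes = 100L, operonFraction = 0.278,
                           seed = 1L) {
  if (nChrom < 1L) stop("nChrom must be >= 1")
  if (chromLen < 10000L) stop("chromLen must be >= 10000")
  if (is.na(gc) || gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  if (operonFraction < 0 || operonFraction >= 1)
    stop("operonFraction must be in [0, 1)")
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  genome <- Biostrings::DNAStringSet(vapply(seq_len(nChrom), function(i) {
    paste(sample(names(probs), chromLen, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1)))
  names(genome) <- paste0("chr", seq_len(nChrom))

  # probability that a transcription unit is an operon, chosen so the
  # expected fraction of genes inside operons matches operonFraction
  msize <- 3
  qop <- operonFraction / (msize - operonFraction * (msize - 1))
  perChrom <- diff(round(seq(0, nGenes, length.out = nChrom + 1L)))
  rows <- list()
  gidx <- 0L
  opidx <- 0L
  for (ci in seq_len(nChrom)) {
    chrom <- names(genome)[ci]
    cursor <- 1500L
    placed <- 0L
    while (placed < perChrom[ci]) {
      isop <- stats::runif(1) < qop
      ngu <- if (isop) sample(2:4, 1L) else 1L
      ngu <- min(ngu, perChrom[ci] - placed)
      if (ngu < 2L) isop <- FALSE
      str <- sample(c("+", "-"), 1L)
      lens <- sample(600:1200, ngu, replace = TRUE)
      gaps <- if (ngu > 1L) sample(80:200, ngu - 1L, replace = TRUE)
        else integer(0)
      span <- sum(lens) + sum(gaps)
      if (cursor + span > chromLen - 1500L) break
      if (isop) opidx <- opidx + 1L
      starts <- cursor + cumsum(c(0L, lens[-ngu] + gaps))
      # operon_pos is transcriptional order: first gene is 5'-most on strand
      ord <- if (str == "-") rev(seq_len(ngu)) else seq_len(ngu)
      for (k in seq_len(ngu)) {
        gidx <- gidx + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = starts[k], end = starts[k] + lens[k] - 1L,
          strand = str, gene_id = sprintf("g%04d", gidx),
          operon_id = if (isop) sprintf("op%03d", opidx) else NA_character_,
          operon_pos = if (isop) ord[k] else NA_integer_,
          stringsAsFactors = FALSE)
      }
      placed <- placed + ngu
      # intergenic spacing wide enough that neighbouring genes' planted
      # promoter territories cannot collide
      cursor <- cursor + span + sample(800:2000, 1L)
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0L)
    stop("no genes could be placed; increase chromLen or reduce nGenes")
  genes <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  genes$gene_id <- df$gene_id
  genes$operon_id <- df$operon_id
  genes$operon_pos <- df$operon_pos
  list(genome = genome, genes = genes)
}

#' Plant promoters (and their core motifs) into a synthetic genome
#'
#' Anchors promoters of each archetype at gene starts (or, for a configurable
#' fraction, at internal operon genes with \code{operon_pos >= 2}) and edits
#' the reference so that each archetype's motif appears with its 5'-most base
#' exactly \code{motifOffset} bp upstream of the true dominant TSS,
#' strand-aware. Placements are spaced so that every emitted CAGE tag is
#' attributable to exactly one promoter; colliding placements are retried up
#' to a budget.
#'
#' @param gen output of \code{\link{generateGenome}}.
#' @param archetypes list of \code{\linkS4class{PromoterArchetype}}.
#' @param nPerArchetype promoters planted per archetype (recycled).
#' @param internalFraction fraction of each archetype's promoters anchored at
#'   operon-internal genes (default 0).
#' @param seed integer RNG seed.
#' @param guard half-width (bp) of the exclusive territory reserved around
#'   each TSS (default 300).
#' @return list with the edited \code{genome}, the \code{genes} annotation and
#'   \code{truth}: a list holding \code{promoters} (data.frame with
#'   promoter_id, archetype, shape, chrom, strand, tss, motif, motif_offset,
#'   spread_sd, gene_id, operon_id, operon_pos, operon_internal),
#'   \code{profiles} (promoter x stage weight matrix) and \code{stages}.
#' @export
plantPromoters <- function(gen, archetypes = defaultArchetypes(),
                           nPerArchetype = 20L, internalFraction = 0,
                           seed = 1L, guard = 300L) {
  set.seed(seed)
  genome <- gen$genome
  genes <- gen$genes
  nPerArchetype <- rep_len(nPerArchetype, length(archetypes))
  internal_ok <- !is.na(genes$operon_pos) & genes$operon_pos >= 2L
  first_ok <- !internal_ok
  used <- rep(FALSE, length(genes))
  reserved <- GRanges()
  rows <- list()
  profiles <- list()
  pid <- 0L
  chromlen <- stats::setNames(Biostrings::width(genome), names(genome))

  pick_gene <- function(wantInternal) {
    pool <- which(!used & if (wantInternal) internal_ok else first_ok)
    if (!length(pool)) return(NA_integer_)
    if (length(pool) == 1L) pool else sample(pool, 1L)
  }

  for (ai in seq_along(archetypes)) {
    arch <- archetypes[[ai]]
    nint <- round(internalFraction * nPerArchetype[ai])
    for (j in seq_len(nPerArchetype[ai])) {
      placedOK <- FALSE
      for (try in 1:50) {
        gi <- pick_gene(j <= nint)
        if (is.na(gi)) break
        g <- genes[gi]
        str <- as.character(strand(g))
        u <- sample(20:80, 1L)
        tss <- if (str == "+") start(g) - u else end(g) + u
        lo <- tss - guard
        hi <- tss + guard
        if (lo < 1L || hi > chromlen[as.character(seqnames(g))]) {
          used[gi] <- TRUE
          next
        }
        terr <- GRanges(seqnames(g), IRanges(lo, hi))
        if (length(reserved) &&
            any(IRanges::overlapsAny(terr, reserved, ignore.strand = TRUE))) {
          used[gi] <- TRUE
          next
        }
        used[gi] <- TRUE
        reserved <- c(reserved, terr)
        pid <- pid + 1L
        chrom <- as.character(seqnames(g))
        if (!is.na(arch@motif)) {
          mlen <- nchar(arch@motif)
          if (str == "+") {
            ms <- tss - arch@motifOffset
            genome[[chrom]] <- replaceMotif(genome[[chrom]], ms, arch@motif)
          } else {
            ms <- tss + arch@motifOffset - mlen + 1L
            genome[[chrom]] <- replaceMotif(
              genome[[chrom]], ms,
              as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(arch@motif))))
          }
        }
        rows[[pid]] <- data.frame(
          promoter_id = sprintf("p%04d", pid), archetype = arch@id,
          shape = arch@shape, chrom = chrom, strand = str, tss = tss,
          motif = arch@motif, motif_offset = arch@motifOffset,
          spread_sd = arch@spreadSd, gene_id = g$gene_id,
          operon_id = g$operon_id, operon_pos = g$operon_pos,
          operon_internal = !is.na(g$operon_pos) && g$operon_pos >= 2L,
          stringsAsFactors = FALSE)
        profiles[[pid]] <- arch@stageProfile
        placedOK <- TRUE
        break
      }
      if (!placedOK)
        stop("could not place promoter for archetype '", arch@id,
             "' within the retry budget (genome too small or too few genes)")
    }
  }
  prom <- do.call(rbind, rows)
  prof <- do.call(rbind, profiles)
  rownames(prof) <- prom$promoter_id
  colnames(prof) <- defaultStages()[seq_len(ncol(prof))]
  list(genome = genome, genes = genes,
       truth = list(promoters = prom, profiles = prof,
                    stages = colnames(prof)))
}

replaceMotif <- function(seq, at, motif) {
  Biostrings::replaceLetterAt(
    seq, at + seq_len(nchar(motif)) - 1L,
    Biostrings::DNAString(motif))
}

#' Simulate per-stage CTSS tables from planted ground truth
#'
#' For each stage, \code{depth} tags are allocated among promoters with
#' gamma-perturbed weights proportional to each promoter's stage profile
#' (a Dirichlet-multinomial, i.e. negative-binomial-like overdispersion of
#' per-promoter counts while conserving the per-stage total exactly). Tag
#' positions scatter around the true dominant TSS as a discretized normal
#' with the archetype's \code{spreadSd} (strand-aware); sharp promoters
#' (sd <= 1) therefore emit >= 90 percent of tags within 2 bp of the TSS.
#'
#' @param truth ground truth from \code{\link{plantPromoters}}.
#' @param depth tags per stage (>= 1000).
#' @param dispersion overdispersion of per-promoter tag counts (default 0.2).
#' @param seed integer RNG seed.
#' @return named list of \code{\linkS4class{CTSSSet}} (one per stage, raw
#'   counts; normalize with \code{\link{normalizeTPM}}).
#' @export
simulateCAGE <- function(truth, depth = 10000L, dispersion = 0.2, seed = 1L) {
  if (depth < 1000L) stop("depth must be >= 1000")
  set.seed(seed)
  prom <- truth$promoters
  prof <- truth$profiles
  out <- list()
  for (s in seq_along(truth$stages)) {
    w <- prof[, s]
    if (all(w == 0)) {
      out[[truth$stages[s]]] <- CTSSSet(character(0), integer(0),
                                        character(0), integer(0),
                                        stage = truth$stages[s])
      next
    }
    gsh <- 1 / dispersion
    gw <- ifelse(w > 0, stats::rgamma(length(w), shape = gsh,
                                      scale = w * dispersion), 0)
    if (all(gw == 0)) gw <- w
    counts <- as.integer(stats::rmultinom(1L, depth, gw))
    recs <- lapply(which(counts > 0L), function(i) {
      off <- if (prom$spread_sd[i] > 0)
        as.integer(round(stats::rnorm(counts[i], 0, prom$spread_sd[i])))
      else integer(counts[i])
      pos <- if (prom$strand[i] == "+") prom$tss[i] + off
        else prom$tss[i] - off
      data.frame(chrom = prom$chrom[i], pos = pos, strand = prom$strand[i])
    })
    df <- do.call(rbind, recs)
    agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                            df[c("chrom", "pos", "strand")], sum)
    out[[truth$stages[s]]] <- CTSSSet(agg$chrom, agg$pos, agg$strand,
                                      agg$count, stage = truth$stages[s])
  }
  out
}

#' Simulate spliced-leader trans-splice acceptor sites
#'
#' Emits SL acceptor sites inside gene bodies of a fraction of planted
#' promoters' genes, editing the reference so that each site has the AG
#' acceptor dinucleotide immediately upstream on its strand. Optionally, a
#' subset of sites is placed so that the AG of a planted TCTAGA motif (motif
#' positions 4-5) is itself the acceptor, with the acceptor position at motif
#' position 6 — the configuration in which male promoters exclude the
#' trans-splice site from their transcripts.
#'
#' @param genome \code{DNAStringSet} (possibly motif-edited).
#' @param truth ground truth from \code{\link{plantPromoters}}.
#' @param genes gene \code{GRanges}.
#' @param fractionSl fraction of promoters' genes given an ordinary SL site
#'   (default 0.39).
#' @param nExclusion number of TCTAGA-bearing promoters whose motif AG is
#'   made an acceptor site (default 0).
#' @param seed integer RNG seed.
#' @return list with the (possibly edited) \code{genome}, \code{sites}
#'   (\code{GRanges}, width 1, columns \code{count}, \code{exclusion},
#'   \code{gene_id}) — empty when \code{fractionSl = 0} and
#'   \code{nExclusion = 0}.
#' @export
simulateSLSites <- function(genome, truth, genes, fractionSl = 0.39,
                            nExclusion = 0L, seed = 1L) {
  set.seed(seed)
  prom <- truth$promoters
  excl_pool <- which(!is.na(prom$motif) & prom$motif == "TCTAGA")
  if (nExclusion > length(excl_pool))
    stop("fewer TCTAGA promoters than requested exclusion sites")
  excl <- if (nExclusion > 0L) sample(excl_pool, nExclusion) else integer(0)
  rest <- setdiff(seq_len(nrow(prom)), excl)
  nsl <- round(fractionSl * nrow(prom))
  ordinary <- if (nsl > 0L && length(rest))
    sample(rest, min(nsl, length(rest))) else integer(0)

  rows <- list()
  for (i in ordinary) {
    g <- genes[match(prom$gene_id[i], genes$gene_id)]
    d <- sample(50:200, 1L)
    if (prom$strand[i] == "+") {
      pos <- start(g) + d
      genome[[prom$chrom[i]]] <- replaceMotif(genome[[prom$chrom[i]]],
                                              pos - 2L, "AG")
    } else {
      pos <- end(g) - d
      genome[[prom$chrom[i]]] <- replaceMotif(genome[[prom$chrom[i]]],
                                              pos + 1L, "CT")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = prom$chrom[i], pos = pos, strand = prom$strand[i],
      count = 2L + stats::rpois(1L, 3), exclusion = FALSE,
      gene_id = prom$gene_id[i], stringsAsFactors = FALSE)
  }
  for (i in excl) {
    # acceptor = motif AG (positions 4-5); site pos = motif position 6
    pos <- if (prom$strand[i] == "+")
      prom$tss[i] - prom$motif_offset[i] + 5L
    else prom$tss[i] + prom$motif_offset[i] - 5L
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = prom$chrom[i], pos = pos, strand = prom$strand[i],
      count = 2L + stats::rpois(1L, 3), exclusion = TRUE,
      gene_id = prom$gene_id[i], stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    sites <- GRanges()
    sites$count <- integer(0)
    sites$exclusion <- logical(0)
    sites$gene_id <- character(0)
    return(list(genome = genome, sites = sites))
  }
  df <- do.call(rbind, rows)
  sites <- GRanges(df$chrom, IRanges(df$pos, width = 1L), strand = df$strand)
  sites$count <- df$count
  sites$exclusion <- df$exclusion
  sites$gene_id <- df$gene_id
  list(genome = genome, sites = sites)
}

#' Simulate a tiling-array probe table
#'
#' Places probes at fixed spacing along every chromosome. Around each broad
#' promoter the log2(Cy5/Cy3) signal follows a phased cosine (nucleosome
#' ordering: period ~175 bp, trough at the TSS) within \code{halfWindow} bp;
#' around sharp promoters the signal is flat. Gaussian probe noise and a
#' global multiplicative dye bias are added so that normalization is
#' exercised.
#'
#' @param genome \code{DNAStringSet} (only chromosome lengths are used).
#' @param truth ground truth from \code{\link{plantPromoters}}.
#' @param probeSpacing probe spacing in bp (default 50).
#' @param amplitude cosine amplitude in log2 units (default 0.4).
#' @param period nucleosome phasing period in bp (default 175).
#' @param noiseSd probe noise s.d. in log2 units (default 0.25).
#' @param dyeBias multiplicative Cy5/Cy3 dye bias (default 1.3).
#' @param halfWindow phased-signal half-width around each TSS (default 500).
#' @param seed integer RNG seed.
#' @return \code{data.frame} with \code{chrom, pos, cy5, cy3} plus the
#'   noise-free planted log-ratio in \code{true_log2}.
#' @export
simulateArray <- function(genome, truth, probeSpacing = 50L, amplitude = 0.4,
                          period = 175, noiseSd = 0.25, dyeBias = 1.3,
                          halfWindow = 500L, seed = 1L) {
  set.seed(seed)
  prom <- truth$promoters
  broad <- prom[prom$shape == "broad", , drop = FALSE]
  out <- lapply(names(genome), function(chrom) {
    pos <- seq(1L, Biostrings::width(genome)[match(chrom, names(genome))],
               by = probeSpacing)
    s <- numeric(length(pos))
    bp <- broad[broad$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(bp))) {
      d <- pos - bp$tss[i]
      in_win <- abs(d) <= halfWindow
      s[in_win] <- s[in_win] - amplitude * cos(2 * pi * d[in_win] / period)
    }
    data.frame(chrom = chrom, pos = pos, true_log2 = s)
  })
  df <- do.call(rbind, out)
  base <- stats::rnorm(nrow(df), 10, 0.5)
  ratio <- df$true_log2 + stats::rnorm(nrow(df), 0, noiseSd) + log2(dyeBias)
  df$cy3 <- 2^base
  df$cy5 <- df$cy3 * 2^ratio
  df[, c("chrom", "pos", "cy5", "cy3", "true_log2")]
}

#' Simulate a two-stage dataset with planted promoter shifts
#'
#' Builds consensus-promoter-like regions on one chromosome and per-stage
#' CTSS signal within each: non-shifting promoters draw both stages' tags
#' from the same discretized normal around the region centre; shifting
#' promoters draw the second stage from a block displaced by
#' \code{shiftOffset} bp (disjoint TSS usage). Half of the regions are on the
#' minus strand.
#'
#' @param nPromoters total regions (default 500).
#' @param nShifts planted shifting promoters among them (default 50).
#' @param tagsPerPromoter tags per stage per promoter (default 200).
#' @param spreadSd within-stage initiation s.d. in bp (default 5).
#' @param shiftOffset displacement of the shifted stage's initiation (bp,
#'   default 60).
#' @param stages labels of the two stages (default \code{c("tailbud",
#'   "male_d6")}).
#' @param seed integer RNG seed.
#' @return list with \code{ctss} (list of two \code{\linkS4class{CTSSSet}}),
#'   \code{consensus} (\code{GRanges} regions) and \code{truth} (logical:
#'   planted shift per region).
#' @export
simulateShiftData <- function(nPromoters = 500L, nShifts = 50L,
                              tagsPerPromoter = 200L, spreadSd = 5,
                              shiftOffset = 60L,
                              stages = c("tailbud", "male_d6"), seed = 1L) {
  stopifnot(nShifts <= nPromoters)
  set.seed(seed)
  centre <- 500L + seq_len(nPromoters) * 1000L
  str <- rep(c("+", "-"), length.out = nPromoters)
  is_shift <- seq_len(nPromoters) %in% sample(nPromoters, nShifts)
  draw <- function(mu, n) as.integer(round(stats::rnorm(n, mu, spreadSd)))
  mk <- list(a = list(), b = list())
  for (i in seq_len(nPromoters)) {
    pa <- draw(centre[i], tagsPerPromoter)
    muB <- if (is_shift[i]) centre[i] +
      (if (str[i] == "+") shiftOffset else -shiftOffset) else centre[i]
    pb <- draw(muB, tagsPerPromoter)
    mk$a[[i]] <- data.frame(pos = pa, strand = str[i])
    mk$b[[i]] <- data.frame(pos = pb, strand = str[i])
  }
  tab <- function(lst, stage) {
    df <- do.call(rbind, lst)
    agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                            df[c("pos", "strand")], sum)
    normalizeTPM(CTSSSet(rep("chrS", nrow(agg)), agg$pos, agg$strand,
                         agg$count, stage = stage))
  }
  cons <- GRanges("chrS", IRanges(centre - 200L, centre + 200L +
                                    shiftOffset), strand = str)
  cons$consensus_id <- sprintf("cons%04d", seq_len(nPromoters))
  list(ctss = stats::setNames(list(tab(mk$a, stages[1]), tab(mk$b, stages[2])),
                              stages),
       consensus = cons, truth = is_shift)
}

#' Write a synthetic dataset to disk
#'
#' Writes the genome FASTA, gene models GFF3 (with \code{operon_id} and
#' \code{operon_pos} attributes), per-stage CTSS TSV tables, the SL site TSV,
#' the probe TSV and the ground truth as JSON.
#'
#' @param dir output directory (created if absent).
#' @param genome \code{DNAStringSet}.
#' @param genes gene \code{GRanges}.
#' @param ctss named list of \code{\linkS4class{CTSSSet}}.
#' @param slSites SL site \code{GRanges} (optional).
#' @param probes probe \code{data.frame} (optional).
#' @param truth ground truth list (optional).
#' @return \code{dir}, invisibly.
#' @export
writeSyntheticDataset <- function(dir, genome, genes, ctss, slSites = NULL,
                                  probes = NULL, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
  writeGeneModels(genes, file.path(dir, "genes.gff3"))
  for (s in names(ctss))
    writeCTSS(ctss[[s]], file.path(dir, paste0("ctss_", s, ".tsv")))
  if (!is.null(slSites) && length(slSites))
    writeSLSites(slSites, file.path(dir, "sl_sites.tsv"))
  if (!is.null(probes))
    writeProbes(probes, file.path(dir, "probes.tsv"))
  if (!is.null(truth)) {
    truth$profiles <- as.data.frame(truth$profiles)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(dir)
}

#' Simulate a complete study
#'
#' Convenience wrapper chaining \code{\link{generateGenome}},
#' \code{\link{plantPromoters}}, \code{\link{simulateCAGE}},
#' \code{\link{simulateSLSites}} and \code{\link{simulateArray}} under one
#' master seed.
#'
#' @param seed master integer seed (sub-generators use small fixed offsets).
#' @param nChrom,chromLen,gc,nGenes,operonFraction see
#'   \code{\link{generateGenome}}.
#' @param archetypes,nPerArchetype,internalFraction see
#'   \code{\link{plantPromoters}}.
#' @param depth tags per stage for \code{\link{simulateCAGE}}.
#' @param fractionSl,nExclusion see \code{\link{simulateSLSites}}.
#' @param dyeBias,noiseSd see \code{\link{simulateArray}}.
#' @return list with \code{genome}, \code{genes}, \code{truth}, \code{ctss}
#'   (per-stage \code{\linkS4class{CTSSSet}}, raw counts), \code{slSites},
#'   \code{probes}.
#' @export
simulateStudy <- function(seed = 1L, nChrom = 2L, chromLen = 150000L,
                          gc = 0.4, nGenes = 200L, operonFraction = 0.278,
                          archetypes = defaultArchetypes(),
                          nPerArchetype = 15L, internalFraction = 0,
                          depth = 20000L, fractionSl = 0.39,
                          nExclusion = 5L, dyeBias = 1.3, noiseSd = 0.25) {
  seed <- as.integer(seed) %% 2000000000L
  gen <- generateGenome(nChrom, chromLen, gc, nGenes, operonFraction,
                        seed = seed)
  pl <- plantPromoters(gen, archetypes, nPerArchetype, internalFraction,
                       seed = seed + 1L)
  ctss <- simulateCAGE(pl$truth, depth = depth, seed = seed + 2L)
  sl <- simulateSLSites(pl$genome, pl$truth, pl$genes,
                        fractionSl = fractionSl, nExclusion = nExclusion,
                        seed = seed + 3L)
  probes <- simulateArray(sl$genome, pl$truth, dyeBias = dyeBias,
                          noiseSd = noiseSd, seed = seed + 4L)
  list(genome = sl$genome, genes = pl$genes, truth = pl$truth,
       ctss = ctss, slSites = sl$sites, probes = probes)
}
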