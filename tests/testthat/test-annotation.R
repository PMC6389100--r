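mk_gene <- function(chrom, lo, hi, strand, id, op = NA_character_,
                    oppos = NA_integer_) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(lo, hi),
                              strand = strand)
  g$gene_id <- id
  g$operon_id <- op
  g$operon_pos <- oppos
  g
}

mk_tc <- function(chrom, dom, strand, id = paste0("tc", seq_along(dom))) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(dom, width = 1),
                              strand = strand)
  g$cluster_id <- id
  g$dominant_pos <- as.integer(dom)
  g
}

test_that("gene assignment window is gene body plus 500 bp upstream", {
  genes <- mk_gene("chr1", 2000, 3000, "+", "gA")
  near <- assignToGenes(mk_tc("chr1", 1600, "+"), genes)  # 400 bp upstream
  expect_equal(near$gene_id, "gA")
  expect_equal(near$relation, "in_upstream_500")
  inb <- assignToGenes(mk_tc("chr1", 2500, "+"), genes)
  expect_equal(inb$relation, "in_gene_body")
  far <- assignToGenes(mk_tc("chr1", 1499, "+"), genes)  # 501 bp upstream
  expect_true(is.na(far$gene_id))
  wrongstr <- assignToGenes(mk_tc("chr1", 1600, "-"), genes)
  expect_true(is.na(wrongstr$gene_id))
  # minus-strand gene: upstream extends beyond the end coordinate
  genes2 <- mk_gene("chr1", 2000, 3000, "-", "gB")
  up2 <- assignToGenes(mk_tc("chr1", 3400, "-"), genes2)
  expect_equal(up2$relation, "in_upstream_500")
})

test_that("ambiguous overlaps resolve to the nearest annotated start", {
  genes <- c(mk_gene("chr1", 1000, 2000, "+", "g1"),
             mk_gene("chr1", 2100, 3000, "+", "g2"))
  expect_message(a <- assignToGenes(mk_tc("chr1", 1950, "+"), genes),
                 "nearest")
  expect_equal(a$gene_id, "g2")  # 150 bp from g2's start, 950 from g1's
})

test_that("assignment equals an exhaustive interval-check oracle", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 12
    lo <- sort(sample.int(50000, n))
    genes <- do.call(c, lapply(seq_len(n), function(i)
      mk_gene("chr1", lo[i], lo[i] + sample(300:900, 1),
              sample(c("+", "-"), 1), paste0("g", i))))
    doms <- sample.int(52000, 40)
    strs <- sample(c("+", "-"), 40, replace = TRUE)
    got <- suppressMessages(assignToGenes(mk_tc("chr1", doms, strs), genes))
    for (k in 1:40) {
      ok <- which(vapply(seq_len(n), function(i) {
        st <- as.character(GenomicRanges::strand(genes))[i]
        a <- GenomicRanges::start(genes)[i]
        b <- GenomicRanges::end(genes)[i]
        if (st != strs[k]) return(FALSE)
        if (st == "+") doms[k] >= a - 500 && doms[k] <= b
        else doms[k] >= a && doms[k] <= b + 500
      }, logical(1)))
      if (!length(ok)) {
        expect_true(is.na(got$gene_id[k]))
      } else {
        starts <- ifelse(as.character(
          GenomicRanges::strand(genes))[ok] == "+",
          GenomicRanges::start(genes)[ok], GenomicRanges::end(genes)[ok])
        best <- ok[which.min(abs(starts - doms[k]))]
        expect_equal(got$gene_id[k], genes$gene_id[best])
      }
    }
  }
})

test_that("SL classification truth table over its three conditions", {
  # reference: AG upstream of position 103 (+); TG upstream of 203
  seq <- strrep("T", 300)
  substr(seq, 101, 102) <- "AG"
  substr(seq, 201, 202) <- "TG"
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  gene <- mk_gene("chr1", 50, 250, "+", "g1")
  mkSL <- function(pos, count) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1),
                                 strand = "+")
    gr$count <- as.integer(count)
    gr
  }
  # AG + count > 1 + in window: trans-spliced
  expect_true(classifySL(gene, mkSL(103, 3), genome)$is_trans_spliced)
  # count == 1 fails the "> 1 tag" rule
  expect_false(classifySL(gene, mkSL(103, 1), genome)$is_trans_spliced)
  # upstream TG fails the acceptor rule
  expect_false(classifySL(gene, mkSL(203, 3), genome)$is_trans_spliced)
  # outside the gene window: not trans-spliced even with AG and count
  gene2 <- mk_gene("chr1", 150, 250, "-", "g2")
  expect_false(classifySL(gene2, mkSL(103, 3), genome)$is_trans_spliced)
  # idempotent and CTSS-independent: same output on repeated calls
  r1 <- classifySL(gene, mkSL(103, 3), genome)
  r2 <- classifySL(gene, mkSL(103, 3), genome)
  expect_identical(r1, r2)
})

test_that("minus-strand SL acceptor check reads the reverse complement", {
  seq <- strrep("T", 100)
  substr(seq, 51, 52) <- "CT"   # minus-strand AG upstream of pos 50
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, width = 1),
                               strand = "-")
  gr$count <- 3L
  expect_true(slAcceptorOK(gr, genome))
  gr2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(60, width = 1),
                                strand = "-")
  gr2$count <- 3L
  expect_false(slAcceptorOK(gr2, genome))
})

test_that("operon-internal promoters exclude first genes", {
  genes <- c(mk_gene("chr1", 1000, 1800, "+", "g1", "op1", 1L),
             mk_gene("chr1", 1900, 2700, "+", "g2", "op1", 2L),
             mk_gene("chr1", 5000, 5800, "+", "g3"))
  tcs <- mk_tc("chr1", c(900, 1850, 4900), "+",
               c("tc_first", "tc_internal", "tc_mono"))
  internal <- findInternalPromoters(tcs, genes)
  expect_equal(internal$cluster_id, "tc_internal")
  expect_equal(internal$operon_pos, 2L)
  expect_equal(internal$operon_id, "op1")
})

test_that("planted operon-internal promoters are recovered from the
           generator", {
  gen <- generateGenome(2, 200000, gc = 0.4, nGenes = 160,
                        operonFraction = 0.35, seed = 51)
  arch <- list(promoterArchetype("m", "sharp", motif = "TCTAGA",
                                 motifOffset = 44L,
                                 stageProfile = c(0, 0, 0, 0, 0, 1),
                                 spreadSd = 0.5))
  pl <- plantPromoters(gen, arch, nPerArchetype = 10,
                       internalFraction = 0.5, seed = 52)
  pr <- pl$truth$promoters
  tcs <- mk_tc(pr$chrom, pr$tss, pr$strand, pr$promoter_id)
  asg <- suppressMessages(assignToGenes(tcs, pl$genes))
  internal <- findInternalPromoters(tcs, pl$genes, asg)
  expect_setequal(internal$cluster_id,
                  pr$promoter_id[pr$operon_internal])
  expect_true(all(internal$operon_pos >= 2L))
})

test_that("SL-exclusion events: planted sites detected, no false events", {
  gen <- generateGenome(2, 200000, gc = 0.4, nGenes = 160, seed = 61)
  pl <- plantPromoters(gen, nPerArchetype = 10, seed = 62)
  sl <- simulateSLSites(pl$genome, pl$truth, pl$genes, fractionSl = 0.4,
                        nExclusion = 4, seed = 63)
  pr <- pl$truth$promoters
  tss <- GenomicRanges::GRanges(pr$chrom, IRanges::IRanges(pr$tss, width = 1),
                                strand = pr$strand,
                                promoter_id = pr$promoter_id)
  win <- promoterWindows(sl$genome, tss)
  hits <- searchFixedWindow(win, "TCTAGA", 52, 22)$hits
  ev <- detectSLExclusion(hits, tss, sl$sites)
  planted <- sl$sites[sl$sites$exclusion]
  expect_equal(sort(ev$acceptor_pos), sort(GenomicRanges::start(planted)))
  expect_equal(nrow(ev), 4L)
  # TCTAGA hits without an SL site at their AGA produce no event
  nosl <- detectSLExclusion(hits, tss, sl$sites[sl$sites$exclusion][0])
  expect_equal(nrow(nosl), 0L)
})

test_that("an acceptor upstream of the motif is not an exclusion event", {
  hits <- data.frame(promoter_id = "p1", motif = "TCTAGA", offset = 44L,
                     score = 1)
  tss <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, width = 1),
                                strand = "+", promoter_id = "p1")
  # correct acceptor position would be 1000 - 44 + 5 = 961
  at961 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(961, width = 1),
                                  strand = "+")
  at961$count <- 5L
  expect_equal(nrow(detectSLExclusion(hits, tss, at961)), 1L)
  upstream <- GenomicRanges::GRanges("chr1", IRanges::IRanges(900, width = 1),
                                     strand = "+")
  upstream$count <- 5L
  expect_equal(nrow(detectSLExclusion(hits, tss, upstream)), 0L)
})

test_that("promoter-mark intersection window is closed at both ends", {
  starts <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, width = 1),
                                   strand = "+")
  touching <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4000, 4500))
  expect_true(intersectPromoterMarks(touching, starts))  # ends at start-500
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4000, 4399))
  expect_false(intersectPromoterMarks(far, starts))
  down <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5100, 5600))
  expect_true(intersectPromoterMarks(down, starts))     # +100 downstream
  beyond <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5101, 5600))
  expect_false(intersectPromoterMarks(beyond, starts))
  # random-instance oracle
  set.seed(71)
  regions <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample.int(20000, 30), width = sample(50:400, 30,
                                                           replace = TRUE)))
  ss <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample.int(20000, 25), width = 1),
    strand = sample(c("+", "-"), 25, replace = TRUE))
  got <- intersectPromoterMarks(regions, ss)
  for (k in 1:25) {
    st <- as.character(GenomicRanges::strand(ss))[k]
    p <- GenomicRanges::start(ss)[k]
    a <- if (st == "+") p - 500 else p - 100
    b <- if (st == "+") p + 100 else p + 500
    want <- any(GenomicRanges::start(regions) <= b &
                  GenomicRanges::end(regions) >= a)
    expect_equal(got[k], want)
  }
})
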