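test_that("genome generation is deterministic and honours composition", {
  g1 <- generateGenome(1, 100000, gc = 0.4, nGenes = 30, seed = 7)
  g2 <- generateGenome(1, 100000, gc = 0.4, nGenes = 30, seed = 7)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(as.data.frame(g1$genes), as.data.frame(g2$genes))

  at <- generateGenome(1, 20000, gc = 0, nGenes = 5, seed = 1)
  freq <- Biostrings::letterFrequency(at$genome, c("A", "C", "G", "T"))
  expect_true(all(freq[, c("C", "G")] == 0))
  expect_error(generateGenome(1, 20000, gc = 1.5, nGenes = 5, seed = 1),
               "gc")
  expect_error(generateGenome(1, 5000, gc = 0.4, nGenes = 5, seed = 1),
               "chromLen")
})

test_that("a stated fraction of genes is grouped into operons of >= 2 genes", {
  gen <- generateGenome(2, 200000, gc = 0.4, nGenes = 120,
                        operonFraction = 0.3, seed = 11)
  genes <- gen$genes
  frac <- mean(!is.na(genes$operon_id))
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.45)
  sizes <- table(genes$operon_id[!is.na(genes$operon_id)])
  expect_true(all(sizes >= 2 & sizes <= 4))
  # first operon gene is 5'-most on its strand
  for (op in names(sizes)) {
    sel <- genes[!is.na(genes$operon_id) & genes$operon_id == op]
    first <- sel[sel$operon_pos == 1L]
    expect_equal(length(first), 1L)
    if (as.character(GenomicRanges::strand(first)) == "+")
      expect_equal(GenomicRanges::start(first),
                   min(GenomicRanges::start(sel)))
    else
      expect_equal(GenomicRanges::end(first), max(GenomicRanges::end(sel)))
  }
})

test_that("planted motifs are re-findable at their recorded coordinates", {
  gen <- generateGenome(2, 120000, gc = 0.4, nGenes = 120, seed = 5)
  pl <- plantPromoters(gen, nPerArchetype = 8, seed = 9)
  pr <- pl$truth$promoters
  withmotif <- pr[!is.na(pr$motif), ]
  expect_gt(nrow(withmotif), 0)
  for (i in seq_len(nrow(withmotif))) {
    m <- withmotif[i, ]
    len <- nchar(m$motif)
    if (m$strand == "+") {
      s <- Biostrings::subseq(pl$genome[[m$chrom]],
                              m$tss - m$motif_offset,
                              m$tss - m$motif_offset + len - 1L)
      expect_identical(as.character(s), m$motif)
    } else {
      s <- Biostrings::subseq(pl$genome[[m$chrom]],
                              m$tss + m$motif_offset - len + 1L,
                              m$tss + m$motif_offset)
      expect_identical(as.character(
        Biostrings::reverseComplement(s)), m$motif)
    }
  }
  # broad archetypes record no motif
  expect_true(all(is.na(pr$motif[pr$shape == "broad"])))
  # both strands exercised
  expect_true(all(c("+", "-") %in% pr$strand))
})

test_that("CAGE simulation conserves depth, follows stage profiles and is
           deterministic", {
  gen <- generateGenome(1, 100000, gc = 0.4, nGenes = 60, seed = 2)
  arch <- c(defaultArchetypes()[1:3],
            list(promoterArchetype("male_sharp", "sharp", motif = "TCTAGA",
                                   motifOffset = 44L,
                                   stageProfile = c(0, 0, 0, 0, 0, 1),
                                   spreadSd = 0.5)))
  pl <- plantPromoters(gen, arch, nPerArchetype = 6, seed = 4)
  ct1 <- simulateCAGE(pl$truth, depth = 3000, seed = 8)
  ct2 <- simulateCAGE(pl$truth, depth = 3000, seed = 8)
  for (s in names(ct1)) {
    expect_identical(as.data.frame(ct1[[s]]), as.data.frame(ct2[[s]]))
    expect_equal(sum(as.data.frame(ct1[[s]])$count), 3000)
  }
  # male-only promoters emit no tags outside the male stage
  pr <- pl$truth$promoters
  male <- pr[pr$archetype == "male_sharp", ]
  for (s in setdiff(names(ct1), "male_d6")) {
    df <- as.data.frame(ct1[[s]])
    near <- vapply(seq_len(nrow(male)), function(i)
      sum(df$count[df$chrom == male$chrom[i] &
                     abs(df$pos - male$tss[i]) <= 5 &
                     df$strand == male$strand[i]]), numeric(1))
    expect_true(all(near == 0))
  }
  expect_error(simulateCAGE(pl$truth, depth = 10), "depth")
})

test_that("sharp promoters are tight and broad spread matches spreadSd", {
  arch <- list(
    promoterArchetype("s", "sharp", stageProfile = rep(1, 6), spreadSd = 1),
    promoterArchetype("b", "broad", stageProfile = rep(1, 6), spreadSd = 10))
  gen <- generateGenome(1, 100000, gc = 0.4, nGenes = 60, seed = 3)
  pl <- plantPromoters(gen, arch, nPerArchetype = c(5, 5), seed = 6)
  ct <- simulateCAGE(pl$truth, depth = 20000, seed = 12)
  df <- as.data.frame(ct[[1]])
  pr <- pl$truth$promoters
  for (i in seq_len(nrow(pr))) {
    sel <- df$chrom == pr$chrom[i] & df$strand == pr$strand[i] &
      abs(df$pos - pr$tss[i]) <= 60
    d <- df$pos[sel] - pr$tss[i]
    w <- df$count[sel]
    if (pr$shape[i] == "sharp") {
      expect_gte(sum(w[abs(d) <= 2]) / sum(w), 0.9)
    } else {
      sdhat <- sqrt(sum(w * d^2) / sum(w) - (sum(w * d) / sum(w))^2)
      expect_lt(abs(sdhat - 10), 1.2)
    }
  }
})

test_that("SL sites carry AG acceptors; the exclusion subset reuses the
           motif's AG", {
  gen <- generateGenome(2, 120000, gc = 0.4, nGenes = 120, seed = 21)
  pl <- plantPromoters(gen, nPerArchetype = 8, seed = 22)
  sl0 <- simulateSLSites(pl$genome, pl$truth, pl$genes, fractionSl = 0,
                         nExclusion = 0, seed = 1)
  expect_equal(length(sl0$sites), 0L)

  sl <- simulateSLSites(pl$genome, pl$truth, pl$genes, fractionSl = 0.4,
                        nExclusion = 3, seed = 23)
  expect_true(all(slAcceptorOK(sl$sites, sl$genome)))
  exc <- sl$sites[sl$sites$exclusion]
  expect_equal(length(exc), 3L)
  pr <- pl$truth$promoters
  for (i in seq_along(exc)) {
    p <- pr[pr$gene_id == exc$gene_id[i], ]
    # acceptor AG = motif positions 4-5: site position is motif base 6
    expected <- if (p$strand == "+") p$tss - p$motif_offset + 5L
      else p$tss + p$motif_offset - 5L
    expect_equal(GenomicRanges::start(exc)[i], expected)
  }
  expect_true(all(sl$sites$count > 1))
})

test_that("array simulation injects the dye bias and the planted cosine", {
  gen <- generateGenome(1, 150000, gc = 0.4, nGenes = 60, seed = 31)
  pl <- plantPromoters(gen, nPerArchetype = 6, seed = 32)
  pb <- simulateArray(pl$genome, pl$truth, probeSpacing = 50,
                      noiseSd = 0, dyeBias = 2, seed = 33)
  expect_equal(nrow(pb), 3000L)  # 150 kb at 50 bp spacing
  raw <- log2(pb$cy5 / pb$cy3)
  expect_equal(mean(raw - pb$true_log2), 1, tolerance = 1e-9)
  # noise-free: normalized ratios equal the planted curve up to the
  # residual (biweight-estimated) bias constant
  tr <- normalizeProbes(pb)
  expect_lt(max(abs((tr$norm_log2 - tr$true_log2) -
                      mean(tr$norm_log2 - tr$true_log2))), 1e-9)
})
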