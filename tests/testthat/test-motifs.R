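test_that("k-mer scan recovers a planted hexamer at its exact offset", {
  set.seed(17)
  seqs <- plant_in_seqs(rand_dna(120, 200), "TCTAGA", 44)
  ss <- Biostrings::DNAStringSet(seqs)
  res <- scanKmers(ss, kRange = 6, tssIndex = 101)
  rk <- res$k6$ranking
  expect_equal(rk$kmer[1], "TCTAGA")
  expect_equal(rk$peak_offset[1], 44L)
  # occurrence matrix: all sequences carry the motif at offset 44
  expect_equal(unname(res$k6$counts["TCTAGA", "44"]), 120L)
})

test_that("k-mer positional enrichment stays at null levels on random
           sequences", {
  set.seed(18)
  obs <- scanKmers(Biostrings::DNAStringSet(rand_dna(80, 200)),
                   kRange = 6)$k6$ranking
  nulls <- replicate(8, {
    max(scanKmers(Biostrings::DNAStringSet(rand_dna(80, 200)),
                  kRange = 6)$k6$ranking$peak_enrichment)
  })
  # the top observed enrichment is of the same order as the null maxima;
  # a planted motif by contrast towers over the null by orders of magnitude
  expect_lt(obs$peak_enrichment[1], 3 * max(nulls))
  planted <- scanKmers(Biostrings::DNAStringSet(
    plant_in_seqs(rand_dna(80, 200), "TCTAGA", 44)), kRange = 6)$k6$ranking
  expect_gt(planted$peak_enrichment[1], 10 * max(nulls))
})

test_that("k = 1 on homopolymers gives full occupancy and N is skipped", {
  ss <- Biostrings::DNAStringSet(rep(strrep("A", 50), 10))
  res <- scanKmers(ss, kRange = 1, tssIndex = 26)
  expect_true(all(res$k1$counts["A", ] == 10))
  expect_true(all(res$k1$counts[c("C", "G", "T"), ] == 0))

  withN <- Biostrings::DNAStringSet(c(strrep("A", 50),
                                      paste0(strrep("A", 25), "N",
                                             strrep("A", 24))))
  expect_message(resN <- scanKmers(withN, kRange = 1, tssIndex = 26), "N")
  expect_equal(unname(resN$k1$counts["A", "0"]), 1L)  # N window skipped
})

test_that("fixed-window IUPAC search honours window bounds and degeneracy", {
  s <- paste0(strrep("C", 63), "TATAAAG", strrep("C", 130))  # 5' base j=64
  ss <- Biostrings::DNAStringSet(c(p1 = s))
  r <- searchFixedWindow(ss, "TATAW", 37, 22, tssIndex = 101)
  expect_true(r$present[["p1"]])
  expect_equal(r$hits$offset, 37L)

  # shift the motif outside the window: no hit
  s2 <- paste0(strrep("C", 40), "TATAAAG", strrep("C", 153))
  r2 <- searchFixedWindow(Biostrings::DNAStringSet(c(p1 = s2)),
                          "TATAW", 37, 22, tssIndex = 101)
  expect_false(r2$present[["p1"]])

  # degenerate letters: W = A/T, R = A/G
  s3 <- paste0(strrep("C", 70), "TATATAAG", strrep("C", 122))
  r3 <- searchFixedWindow(Biostrings::DNAStringSet(c(p1 = s3)),
                          "TATAWAWR", 40, 20, tssIndex = 101)
  expect_true(r3$present[["p1"]])
  r3b <- searchFixedWindow(Biostrings::DNAStringSet(c(p1 = s3)),
                           "TATAWAR", 40, 20, tssIndex = 101)
  expect_true(r3b$present[["p1"]])
  s4 <- paste0(strrep("C", 70), "TGTAA", strrep("C", 125))
  r4 <- searchFixedWindow(Biostrings::DNAStringSet(c(p1 = s4)),
                          "TATAW", 37, 22, tssIndex = 101)
  expect_false(r4$present[["p1"]])
})

test_that("offset convention audit: planting at offset d recovers median d", {
  set.seed(19)
  for (d in c(10L, 30L, 44L, 56L, 80L)) {
    seqs <- plant_in_seqs(rand_dna(40, 200), "ACCATAA", d)
    r <- searchFixedWindow(Biostrings::DNAStringSet(seqs), "ACCATAA",
                           d + 5, d - 5, tssIndex = 101)
    expect_equal(stats::median(r$hits$offset), d)
  }
})

test_that("strand handling: genome mirror leaves offsets unchanged", {
  gen <- generateGenome(1, 60000, gc = 0.4, nGenes = 40, seed = 41)
  arch <- list(promoterArchetype("m", "sharp", motif = "TCTAGA",
                                 motifOffset = 44L,
                                 stageProfile = rep(1, 6), spreadSd = 0.5))
  pl <- plantPromoters(gen, arch, nPerArchetype = 12, seed = 42)
  pr <- pl$truth$promoters
  tss <- GenomicRanges::GRanges(pr$chrom, IRanges::IRanges(pr$tss, width = 1),
                                strand = pr$strand,
                                promoter_id = pr$promoter_id)
  win <- promoterWindows(pl$genome, tss)
  hits <- searchFixedWindow(win, "TCTAGA", 52, 22)$hits
  expect_equal(nrow(hits), 12L)
  expect_true(all(hits$offset == 44L))
  # plus- and minus-strand promoters both recovered
  expect_true(all(c("+", "-") %in%
                    pr$strand[pr$promoter_id %in% hits$promoter_id]))
})

test_that("dinucleotide profile is normalized and sees planted Inr", {
  ss <- Biostrings::DNAStringSet(rep(strrep("A", 60), 5))
  pf <- dinucleotideProfile(ss, tssIndex = 31)
  expect_true(all(pf["AA", ] == 1))
  expect_equal(unname(colSums(pf)), rep(1, ncol(pf)))

  set.seed(23)
  seqs <- rand_dna(100, 200)
  plant <- sample(100, 90)
  substr(seqs[plant], 100, 101) <- "CA"  # CA initiator at (-1, +1)
  pf2 <- dinucleotideProfile(Biostrings::DNAStringSet(seqs))
  expect_gte(pf2["CA", "1"], 0.9)
  expect_equal(unname(colSums(pf2)), rep(1, ncol(pf2)), tolerance = 1e-12)
})

test_that("PWM scan: relative-score convention and brute-force equality", {
  cons <- "TATAAA"
  prob <- matrix(0, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in 1:6) prob[substr(cons, j, j), j] <- 1
  pwm <- pwmFromProbabilities(prob)

  s <- paste0(strrep("C", 63), cons, strrep("C", 131))
  ss <- Biostrings::DNAStringSet(c(p = s))
  hits <- pwmScan(ss, pwm, minRelScore = 1.0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$score, 1.0)
  expect_equal(hits$offset, 37L)

  # brute-force oracle on random sequences at the default threshold
  set.seed(29)
  prob2 <- prop.table(matrix(stats::runif(4 * 5, 0.05, 1), 4, 5,
                             dimnames = list(c("A", "C", "G", "T"), NULL)),
                      2)
  pwm2 <- pwmFromProbabilities(prob2)
  seqs <- rand_dna(30, 200)
  got <- pwmScan(Biostrings::DNAStringSet(seqs), pwm2, minRelScore = 0.85)
  smin <- sum(apply(pwm2, 2, min)); smax <- sum(apply(pwm2, 2, max))
  want <- list()
  for (i in seq_along(seqs)) for (j in 1:100) {
    sc <- sum(vapply(1:5, function(l)
      pwm2[substr(seqs[i], j + l - 1, j + l - 1), l], numeric(1)))
    rel <- (sc - smin) / (smax - smin)
    if (rel >= 0.85)
      want[[length(want) + 1]] <- data.frame(promoter_id = as.character(i),
                                             offset = 101L - j, score = rel)
  }
  want <- if (length(want)) do.call(rbind, want) else
    data.frame(promoter_id = character(0), offset = integer(0),
               score = numeric(0))
  expect_equal(got$offset, want$offset)
  expect_equal(got$score, want$score, tolerance = 1e-12)
})

test_that("MEME minimal motifs parse into probability matrices", {
  f <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF TATA1", "letter-probability matrix: alength= 4 w= 3 nsites= 20 E= 1e-5",
               " 0.1 0.2 0.3 0.4", " 1.0 0.0 0.0 0.0", " 0.0 0.0 0.0 1.0"),
             f)
  m <- readMemeMotif(f)
  expect_named(m, "TATA1")
  expect_equal(dim(m$TATA1), c(4L, 3L))
  expect_equal(m$TATA1["A", 2], 1.0)
  expect_equal(unname(colSums(m$TATA1)), rep(1, 3))
})

test_that("motif/SOM association percentages and chi-square", {
  present <- stats::setNames(rep(c(TRUE, FALSE), each = 10), paste0("p", 1:20))
  units <- stats::setNames(rep(c("4_4", "0_0"), each = 10), paste0("p", 1:20))
  r <- motifExpressionAssociation(present, units)
  expect_equal(unname(r$pct_of_class_with_motif["4_4"]), 100)
  expect_equal(unname(r$pct_of_class_with_motif["0_0"]), 0)
  expect_equal(unname(r$pct_of_motif_by_class["4_4"]), 100)
  # 2x2 table (10,0 / 0,10): chi-square 20 without continuity correction
  expect_equal(unname(r$chisq$statistic), 20)
  expect_equal(unname(r$chisq$parameter), 1)

  none <- stats::setNames(rep(FALSE, 20), paste0("p", 1:20))
  r0 <- motifExpressionAssociation(none, units)
  expect_true(all(r0$pct_of_class_with_motif == 0))
  expect_true(all(r0$pct_of_motif_by_class == 0))
  expect_null(r0$chisq)
})

test_that("positional density matrix marks motif starts, broad-to-sharp", {
  set.seed(53)
  seqs <- plant_in_seqs(rand_dna(6, 200), "TCTAGA", 44)
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- paste0("p", 1:6)
  w <- c(p1 = 2, p2 = 30, p3 = 10, p4 = 25, p5 = 1, p6 = 12)
  m <- positionalDensity(ss, "TCTAGA", iqWidths = w, tssIndex = 101)
  expect_true(all(m[, "44"] == 1L))
  expect_equal(rownames(m)[1], "p2")          # broadest first
  expect_equal(rownames(m)[nrow(m)], "p5")    # sharpest last
  expect_equal(dim(m), c(6L, 195L))
})
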