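# Independent oracles and small fixture builders used across test files.

# O(n^2) single-linkage clustering oracle: connect CTSSes on the same
# chrom+strand whose positions are at most `gap` apart, then take graph
# components (igraph). Returns a partition label per row.
oracle_partition <- function(df, gap = 20L) {
  n <- nrow(df)
  if (n == 0L) return(integer(0))
  key <- paste(df$chrom, df$strand)
  adj <- outer(key, key, "==") &
    abs(outer(df$pos, df$pos, "-")) <= gap
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# Cumulative-sum oracle for interquantile boundaries, written as a naive
# walk along the strand.
oracle_iqwidth <- function(pos, tpm, strand, qlo = 0.1, qhi = 0.9) {
  o <- if (strand == "-") order(-pos) else order(pos)
  p <- pos[o]; v <- tpm[o]
  total <- sum(v)
  cum <- 0
  a <- b <- NA_integer_
  for (k in seq_along(p)) {
    cum <- cum + v[k]
    if (is.na(a) && cum >= qlo * total) a <- p[k]
    if (is.na(b) && cum >= qhi * total) b <- p[k]
  }
  list(q_low = min(a, b), q_up = max(a, b), iq_width = abs(b - a) + 1L)
}

# Canonical partition signature (sets of positions) for comparing two
# partitions irrespective of label numbering.
partition_signature <- function(pos, labels) {
  unname(sort(vapply(split(pos, labels),
                     function(p) paste(sort(p), collapse = ","),
                     character(1))))
}

rand_ctss_instance <- function(n, nchrom = 2L, span = 500L) {
  data.frame(
    chrom = sample(paste0("chr", seq_len(nchrom)), n, replace = TRUE),
    pos = sample.int(span, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    count = sample.int(50L, n, replace = TRUE))
}

# Build a normalized CTSSSet from a bare data.frame, summing duplicates.
as_ctss <- function(df, stage = "s1") {
  agg <- stats::aggregate(list(count = df$count),
                          df[c("chrom", "pos", "strand")], sum)
  normalizeTPM(CTSSSet(agg$chrom, agg$pos, agg$strand, agg$count, stage))
}

# Random DNA of given length(s)
rand_dna <- function(n, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(names(p), len, TRUE, p), collapse = ""), character(1))
}

# Write a motif into a set of sequences so that its 5' base sits at a given
# upstream offset from a TSS at oriented index tss_index.
plant_in_seqs <- function(seqs, motif, offset, tss_index = 101L) {
  j <- tss_index - offset
  substr(seqs, j, j + nchar(motif) - 1L) <- motif
  seqs
}

# Majority-vote mapping of SOM units to truth labels, for recovery scoring.
map_units_to_truth <- function(units, truth) {
  tab <- table(units, truth)
  best <- colnames(tab)[apply(tab, 1L, which.max)]
  stats::setNames(best, rownames(tab))[units]
}
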