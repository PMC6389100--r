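#' Read a CTSS table
#'
#' Reads a 4-column tab-separated CTSS table (\code{chrom pos strand count},
#' no header by default) into a \code{\linkS4class{CTSSSet}}. Malformed rows
#' (non-positive or non-integer position, strand outside +/-, negative or
#' non-integer count) are rejected with an error naming the offending line.
#' Rows duplicating a (chrom, pos, strand) key are summed with a warning.
#'
#' @param path path to the TSV file.
#' @param stage stage label to attach to the table.
#' @param header logical; does the file carry a header row?
#' @return A \code{\linkS4class{CTSSSet}} (tpm not yet computed).
#' @seealso \code{\link{normalizeTPM}}, \code{\link{writeCTSS}}
#' @export
readCTSS <- function(path, stage, header = FALSE) {
  if (!file.exists(path)) stop("CTSS file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = header,
                          colClasses = "character", quote = "",
                          comment.char = "#")
  if (ncol(df) < 4L) stop("CTSS table must have 4 columns (chrom pos strand count)")
  df <- df[, 1:4]
  names(df) <- c("chrom", "pos", "strand", "count")
  lineno <- seq_len(nrow(df)) + as.integer(header)
  pos <- suppressWarnings(as.numeric(df$pos))
  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- is.na(pos) | pos < 1 | pos != round(pos) |
    is.na(cnt) | cnt < 0 | cnt != round(cnt) |
    !df$strand %in% c("+", "-")
  if (any(bad))
    stop("malformed CTSS rows at line(s): ",
         paste(lineno[bad], collapse = ", "))
  key <- paste(df$chrom, pos, df$strand)
  if (anyDuplicated(key)) {
    warning("duplicate (chrom, pos, strand) keys summed: ",
            sum(duplicated(key)), " row(s)")
    agg <- rowsum(cnt, key)
    first <- !duplicated(key)
    df <- df[first, ]
    pos <- pos[first]
    cnt <- agg[match(key[first], rownames(agg)), 1L]
  }
  CTSSSet(df$chrom, as.integer(pos), df$strand, as.integer(cnt), stage = stage)
}

#' Write a CTSS table
#'
#' Writes the 4-column TSV dialect read by \code{\link{readCTSS}} (counts
#' only; tpm is recomputed on read via \code{\link{normalizeTPM}}).
#'
#' @param x a \code{\linkS4class{CTSSSet}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCTSS <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.table(df[, c("chrom", "pos", "strand", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Normalize CTSS counts to tags per million
#'
#' Computes \code{tpm = count * 1e6 / librarySize}. The library size defaults
#' to the table's total tag count (so that tpm sums to 1e6); supply the total
#' mapped-read count of the library when it is known externally.
#'
#' @param x a \code{\linkS4class{CTSSSet}}.
#' @param librarySize optional library size; defaults to \code{sum(count)}.
#' @return The \code{CTSSSet} with \code{tpm} filled in and the library size
#'   recorded; raw counts are unchanged.
#' @examples
#' cs <- CTSSSet("chr1", 100L, "+", 4L, stage = "s1")
#' as.data.frame(normalizeTPM(cs, librarySize = 2e6))$tpm  # 2.0
#' @export
normalizeTPM <- function(x, librarySize = NULL) {
  stopifnot(is(x, "CTSSSet"))
  total <- sum(mcols(x@ranges)$count)
  if (is.null(librarySize)) librarySize <- total
  if (length(x) == 0L || librarySize <= 0)
    stop("cannot normalize: empty table or non-positive library size")
  mcols(x@ranges)$tpm <- mcols(x@ranges)$count * 1e6 / librarySize
  x@librarySize <- as.numeric(librarySize)
  validObject(x)
  x
}

#' Read a genome FASTA
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet} that trims FASTA
#' descriptions to the first word so sequence names match annotation
#' seqnames.
#'
#' @param path FASTA file.
#' @return A \code{DNAStringSet}.
#' @export
readGenome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 annotation and returns gene features as a \code{GRanges}
#' with columns \code{gene_id}, \code{operon_id} (\code{NA} for
#' non-operon genes) and \code{operon_pos} (1-based order within the operon).
#'
#' @param path GFF3 file.
#' @return \code{GRanges} of gene models.
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  out <- granges(gr)
  out$gene_id <- if (!is.null(gr$ID)) as.character(gr$ID) else
    as.character(gr$gene_id)
  out$operon_id <- if ("operon_id" %in% colnames(mcols(gr)))
    as.character(gr$operon_id) else NA_character_
  out$operon_pos <- if ("operon_pos" %in% colnames(mcols(gr)))
    as.integer(gr$operon_pos) else NA_integer_
  out
}

#' Write gene models to GFF3
#'
#' @param genes \code{GRanges} with \code{gene_id}, \code{operon_id},
#'   \code{operon_pos} columns (as from \code{\link{generateGenome}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModels <- function(genes, path) {
  gr <- granges(genes)
  gr$source <- "promarch"
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$operon_id <- genes$operon_id
  gr$operon_pos <- genes$operon_pos
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a spliced-leader trans-splice site table
#'
#' 4-column TSV: \code{chrom pos strand count}, where \code{pos} is the first
#' transcribed base 3' of the AG acceptor dinucleotide.
#'
#' @param path TSV file.
#' @return \code{GRanges} of width 1 with a \code{count} column.
#' @export
readSLSites <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "pos", "strand", "count"))
  gr <- GRanges(df$chrom, IRanges(df$pos, width = 1L), strand = df$strand)
  gr$count <- as.integer(df$count)
  gr
}

#' @rdname readSLSites
#' @param x \code{GRanges} of SL sites with a \code{count} column.
#' @export
writeSLSites <- function(x, path) {
  df <- data.frame(chrom = as.character(seqnames(x)), pos = start(x),
                   strand = as.character(strand(x)), count = x$count)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a tiling-array probe table
#'
#' 4-column TSV: \code{chrom pos cy5 cy3} with probe centre positions and the
#' two channel intensities (Cy5 = IP, Cy3 = input).
#'
#' @param path TSV file.
#' @return \code{data.frame} with columns \code{chrom, pos, cy5, cy3}.
#' @export
readProbes <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "pos", "cy5", "cy3"))
}

#' @rdname readProbes
#' @param x probe \code{data.frame}.
#' @export
writeProbes <- function(x, path) {
  utils::write.table(x[, c("chrom", "pos", "cy5", "cy3")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
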