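#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end strand granges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
NULL

#' CTSSSet: per-stage CAGE transcription start site signal
#'
#' A \code{CTSSSet} holds the single-nucleotide CAGE signal of one sample
#' (developmental stage): one record per (chromosome, position, strand) with a
#' raw tag count and, after \code{\link{normalizeTPM}}, a tags-per-million
#' value. Internally the records are a width-1 \code{GRanges} with metadata
#' columns \code{count} and \code{tpm}.
#'
#' @slot ranges \code{GRanges} of width 1 with mcols \code{count} (non-negative
#'   integer) and \code{tpm} (non-negative numeric, \code{NA} before
#'   normalization).
#' @slot stage single character label of the sample/stage.
#' @slot librarySize numeric; total mapped-tag count used for tpm
#'   normalization (\code{NA} before normalization).
#'
#' @seealso \code{\link{CTSSSet}}, \code{\link{readCTSS}},
#'   \code{\link{normalizeTPM}}, \code{\link{clusterCTSS}}
#' @export
setClass("CTSSSet",
  representation(ranges = "GRanges", stage = "character",
                 librarySize = "numeric"),
  prototype(stage = NA_character_, librarySize = NA_real_))

setValidity("CTSSSet", function(object) {
  gr <- object@ranges
  msg <- character()
  if (length(gr)) {
    if (!all(BiocGenerics::width(gr) == 1L))
      msg <- c(msg, "all CTSS ranges must have width 1")
    if (!all(as.character(strand(gr)) %in% c("+", "-")))
      msg <- c(msg, "CTSS strand must be '+' or '-'")
    if (!all(c("count", "tpm") %in% colnames(mcols(gr))))
      msg <- c(msg, "mcols must contain 'count' and 'tpm'")
    else {
      if (any(mcols(gr)$count < 0)) msg <- c(msg, "counts must be >= 0")
      if (any(!is.na(mcols(gr)$tpm) & mcols(gr)$tpm < 0))
        msg <- c(msg, "tpm must be >= 0")
      key <- paste(seqnames(gr), start(gr), strand(gr))
      if (anyDuplicated(key))
        msg <- c(msg, "(chrom, pos, strand) must be unique")
    }
  }
  if (length(object@stage) != 1L)
    msg <- c(msg, "stage must be a single label")
  if (length(msg)) msg else TRUE
})

#' Construct a CTSSSet
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param strand character vector, \code{"+"} or \code{"-"}.
#' @param count non-negative integer tag counts.
#' @param stage single character stage label.
#' @param tpm optional numeric tags-per-million; \code{NA} until
#'   \code{\link{normalizeTPM}} is run.
#' @param librarySize optional library size already used to compute \code{tpm}.
#'
#' @return A \code{\linkS4class{CTSSSet}}.
#' @examples
#' cs <- CTSSSet("chr1", c(100L, 105L), c("+", "+"), c(4L, 1L), stage = "oocyte")
#' cs
#' @export
CTSSSet <- function(chrom, pos, strand, count, stage,
                    tpm = rep(NA_real_, length(pos)),
                    librarySize = NA_real_) {
  if (any(pos < 1)) stop("positions must be positive 1-based integers")
  gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L), strand = strand)
  mcols(gr)$count <- as.integer(count)
  mcols(gr)$tpm <- as.numeric(tpm)
  gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
  new("CTSSSet", ranges = gr, stage = as.character(stage)[1L],
      librarySize = as.numeric(librarySize)[1L])
}

#' PromoterArchetype: a planted promoter class for the synthetic generator
#'
#' Describes one class of synthetic promoter: its initiation shape (sharp or
#' broad), an optional core promoter motif planted at a fixed strand-aware
#' offset upstream of the dominant TSS, a relative expression weight per
#' developmental stage, and the dispersion (s.d. in bp) of initiation around
#' the dominant TSS.
#'
#' @slot id character identifier.
#' @slot shape \code{"sharp"} or \code{"broad"}.
#' @slot motif optional DNA string over A/C/G/T (\code{NA} for none).
#' @slot motifOffset integer; distance in bp from the motif 5'-most base to the
#'   dominant TSS, strand-aware, positive = upstream.
#' @slot stageProfile non-negative numeric vector of relative expression
#'   weights, one per stage.
#' @slot spreadSd non-negative numeric; s.d. (bp) of initiation dispersion.
#' @export
setClass("PromoterArchetype",
  representation(id = "character", shape = "character", motif = "character",
                 motifOffset = "integer", stageProfile = "numeric",
                 spreadSd = "numeric"))

setValidity("PromoterArchetype", function(object) {
  msg <- character()
  if (!object@shape %in% c("sharp", "broad"))
    msg <- c(msg, "shape must be 'sharp' or 'broad'")
  if (!is.na(object@motif)) {
    if (!grepl("^[ACGT]+$", object@motif))
      msg <- c(msg, "motif must be over {A,C,G,T}")
    if (is.na(object@motifOffset) || object@motifOffset <= 0L)
      msg <- c(msg, "motifOffset must be > 0 when a motif is set")
  }
  if (!any(object@stageProfile > 0))
    msg <- c(msg, "stageProfile needs at least one positive entry")
  if (any(object@stageProfile < 0))
    msg <- c(msg, "stageProfile must be non-negative")
  if (object@spreadSd < 0) msg <- c(msg, "spreadSd must be >= 0")
  if (object@shape == "sharp" && object@spreadSd > 1)
    msg <- c(msg, "sharp archetypes must have spreadSd <= 1")
  if (object@shape == "broad" && object@spreadSd < 5)
    msg <- c(msg, "broad archetypes must have spreadSd >= 5")
  if (length(msg)) msg else TRUE
})

#' Construct a PromoterArchetype
#'
#' @param id identifier.
#' @param shape \code{"sharp"} or \code{"broad"}.
#' @param motif optional DNA motif (default none).
#' @param motifOffset offset in bp from motif 5' base to dominant TSS
#'   (positive = upstream); required when \code{motif} is given.
#' @param stageProfile non-negative relative expression weights per stage.
#' @param spreadSd s.d. (bp) of initiation dispersion; sharp requires
#'   \code{<= 1}, broad \code{>= 5}.
#' @return A \code{\linkS4class{PromoterArchetype}}.
#' @examples
#' promoterArchetype("male_sharp", "sharp", motif = "TCTAGA", motifOffset = 44,
#'                   stageProfile = c(0, 0, 0, 0, 0, 1), spreadSd = 0.5)
#' @export
promoterArchetype <- function(id, shape, motif = NA_character_,
                              motifOffset = NA_integer_,
                              stageProfile, spreadSd) {
  new("PromoterArchetype", id = as.character(id), shape = shape,
      motif = toupper(as.character(motif)),
      motifOffset = as.integer(motifOffset),
      stageProfile = as.numeric(stageProfile),
      spreadSd = as.numeric(spreadSd))
}

#' @describeIn CTSSSet-class number of CTSS records
#' @param x a \code{CTSSSet}
#' @export
setMethod("length", "CTSSSet", function(x) length(x@ranges))

#' Accessors for CTSSSet
#'
#' \code{ctssRanges} returns the underlying width-1 \code{GRanges} (mcols
#' \code{count}, \code{tpm}); \code{stageLabel} the stage label;
#' \code{librarySize} the library size used for tpm normalization.
#'
#' @param x a \code{\linkS4class{CTSSSet}}.
#' @return See individual descriptions.
#' @export
ctssRanges <- function(x) {
  stopifnot(is(x, "CTSSSet"))
  x@ranges
}

#' @rdname ctssRanges
#' @export
stageLabel <- function(x) {
  stopifnot(is(x, "CTSSSet"))
  x@stage
}

#' @rdname ctssRanges
#' @export
librarySize <- function(x) {
  stopifnot(is(x, "CTSSSet"))
  x@librarySize
}

#' @rdname ctssRanges
#' @param row.names,optional,... passed through (as.data.frame interface).
#' @export
setMethod("as.data.frame", "CTSSSet",
  function(x, row.names = NULL, optional = FALSE, ...) {
    gr <- x@ranges
    data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
               strand = as.character(strand(gr)),
               count = mcols(gr)$count, tpm = mcols(gr)$tpm,
               stringsAsFactors = FALSE)
  })

setMethod("show", "CTSSSet", function(object) {
  cat("CTSSSet of", length(object), "CTSS positions")
  if (!is.na(object@stage)) cat(" [stage:", object@stage, "]")
  cat("\n  total count:", sum(mcols(object@ranges)$count))
  if (!is.na(object@librarySize))
    cat("  library size:", object@librarySize)
  cat("\n  normalized:", !anyNA(mcols(object@ranges)$tpm), "\n")
})

setMethod("show", "PromoterArchetype", function(object) {
  cat("PromoterArchetype", object@id, sprintf("(%s)", object@shape), "\n")
  if (!is.na(object@motif))
    cat("  motif", object@motif, "at", object@motifOffset, "bp upstream\n")
  cat("  stage profile:", paste(signif(object@stageProfile, 3),
                                collapse = " "), "\n")
  cat("  spread sd:", object@spreadSd, "bp\n")
})
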