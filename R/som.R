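#' Self-organizing map clustering of expression profiles
#'
#' Clusters rows of an expression matrix (promoters or CTSSes by stages) on a
#' rectangular self-organizing map, yielding one expression class per row
#' labelled \code{"row_col"} (0-based grid coordinates, e.g. \code{"4_4"}).
#' Rows are first scaled to relative expression by dividing by their maximum
#' (all-zero rows are excluded). Training is the classic online algorithm:
#' Gaussian neighbourhood, with the neighbourhood radius and the learning
#' rate decaying linearly over epochs; it is deterministic for a fixed seed.
#'
#' @param x numeric matrix, rows = profiles, columns = stages/conditions.
#' @param gridRows,gridCols SOM grid dimensions (default 5 x 5 = 25 units).
#' @param epochs training epochs (default 100).
#' @param alpha learning rate, decayed linearly from \code{alpha[1]} to
#'   \code{alpha[2]} (default 0.05 to 0.01).
#' @param seed integer RNG seed.
#' @param scale row scaling: \code{"max"} (relative expression, default),
#'   \code{"zscore"}, or \code{"none"}.
#' @return list with \code{units} (character vector \code{"r_c"} named by
#'   rownames of \code{x}, \code{NA} for excluded all-zero rows),
#'   \code{codebook} (units x columns matrix), \code{grid}, and
#'   \code{scaled} (the scaled training matrix).
#' @examples
#' m <- rbind(matrix(rep(c(1, 0), each = 3), 20, 6, byrow = TRUE),
#'            matrix(rep(c(0, 1), each = 3), 20, 6, byrow = TRUE))
#' som <- somCluster(m, gridRows = 2, gridCols = 2, seed = 1)
#' table(som$units)
#' @export
somCluster <- function(x, gridRows = 5L, gridCols = 5L, epochs = 100L,
                       alpha = c(0.05, 0.01), seed = 1L,
                       scale = c("max", "zscore", "none")) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  nunits <- gridRows * gridCols
  rowmax <- apply(abs(x), 1L, max)
  keep <- rowmax > 0
  if (sum(keep) < nunits)
    stop("fewer non-zero rows (", sum(keep), ") than SOM units (", nunits,
         "); use a smaller grid")
  xs <- x[keep, , drop = FALSE]
  xs <- switch(scale,
    max = xs / apply(xs, 1L, max),
    zscore = t(scale(t(xs))),
    none = xs)
  xs[!is.finite(xs)] <- 0
  n <- nrow(xs)

  set.seed(seed)
  grid <- cbind(row = rep(seq_len(gridRows) - 1L, each = gridCols),
                col = rep(seq_len(gridCols) - 1L, times = gridRows))
  gd2 <- as.matrix(stats::dist(grid))^2
  codebook <- xs[sample(n, nunits, replace = n < nunits), , drop = FALSE]
  codebook <- codebook + matrix(stats::rnorm(length(codebook), 0, 1e-4),
                                nunits)
  r0 <- max(gridRows, gridCols) / 2
  tmax <- epochs
  for (e in seq_len(epochs)) {
    frac <- (e - 1) / max(1, tmax - 1)
    a <- alpha[1] + (alpha[2] - alpha[1]) * frac
    sigma <- r0 + (0.5 - r0) * frac
    ord <- sample.int(n)
    for (i in ord) {
      v <- xs[i, ]
      d2 <- rowSums((codebook - rep(v, each = nunits))^2)
      bmu <- which.min(d2)
      h <- a * exp(-gd2[bmu, ] / (2 * sigma^2))
      codebook <- codebook + h * (rep(v, each = nunits) - codebook)
    }
  }
  d2all <- outer(rowSums(xs^2), rowSums(codebook^2), "+") -
    2 * xs %*% t(codebook)
  bmu <- max.col(-d2all, ties.method = "first")
  lab <- paste0(grid[, "row"], "_", grid[, "col"])
  units <- rep(NA_character_, nrow(x))
  units[keep] <- lab[bmu]
  names(units) <- rownames(x)
  list(units = units, codebook = codebook, grid = c(gridRows, gridCols),
       scaled = xs)
}

#' Attach SOM expression classes to a consensus promoter experiment
#'
#' Runs \code{\link{somCluster}} on the consensus tpm assay and stores the
#' unit labels in \code{rowData(se)$som_unit}.
#'
#' @param se a \code{RangedSummarizedExperiment} from
#'   \code{\link{buildConsensus}}.
#' @param ... passed to \code{\link{somCluster}}.
#' @return \code{se} with \code{som_unit} in its rowData.
#' @export
assignSOM <- function(se, ...) {
  m <- SummarizedExperiment::assay(se, "tpm")
  rownames(m) <- SummarizedExperiment::rowData(se)$consensus_id
  som <- somCluster(m, ...)
  SummarizedExperiment::rowData(se)$som_unit <- som$units
  S4Vectors::metadata(se)$som <- som[c("codebook", "grid")]
  se
}
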