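#' Normalize raw pseudotime to the unit interval
#'
#' Affine min-max rescaling so the earliest cell gets 0 and the latest 1;
#' the ordering is preserved. A constant vector signals that pseudotime
#' inference failed and raises a degenerate-pseudotime error.
#'
#' @param raw numeric vector of raw pseudotime values (length >= 2, no
#'   missing values).
#' @return numeric vector in [0, 1], names preserved.
#' @examples
#' normalizePseudotime(c(2, 4, 6))  # 0, 0.5, 1
#' @export
normalizePseudotime <- function(raw) {
  if (length(raw) < 2) stop("need at least 2 pseudotime values")
  if (anyNA(raw)) stop("pseudotime contains missing values")
  rng <- range(raw)
  if (rng[1] == rng[2])
    stop(structure(class = c("ptDE_degenerate_pseudotime", "error",
                             "condition"),
                   list(message = "degenerate pseudotime: all values equal",
                        call = sys.call(-1))))
  out <- (raw - rng[1]) / (rng[2] - rng[1])
  names(out) <- names(raw)
  out
}

#' Draw cell subsamples for uncertainty estimation
#'
#' Draws B index sets of size floor(fraction * n) without replacement
#' (sampling with replacement would duplicate cells, which breaks many
#' pseudotime methods). With `groups`, stratified sampling first takes
#' floor(fraction * group size) cells within each group; any shortfall
#' relative to floor(fraction * n) is filled by sampling uniformly from the
#' remaining cells. Each subsample uses its own counter-derived seed, so
#' the sets are independent of execution order.
#'
#' @param n number of cells.
#' @param fraction subsampling fraction in (0, 1); default 0.8.
#' @param B number of subsamples; default 1000.
#' @param groups optional length-n vector of cell groups for stratified
#'   sampling.
#' @param seed master seed.
#' @return list of B integer index vectors.
#' @export
drawSubsamples <- function(n, fraction = 0.8, B = 1000, groups = NULL,
                           seed = 1) {
  n <- .assertCount(n, "n", min = 2L)
  fraction <- .assertFraction(fraction, "fraction")
  B <- .assertCount(B, "B")
  size <- floor(fraction * n)
  if (size < 2) stop("fraction * n must be at least 2")
  if (!is.null(groups) && length(groups) != n)
    stop("groups must have length n")
  lapply(seq_len(B), function(b) {
    set.seed(.deriveSeed(seed, .purpose["subsample"], b))
    if (is.null(groups)) {
      sort(sample.int(n, size))
    } else {
      idx <- unlist(lapply(split(seq_len(n), groups), function(g) {
        k <- floor(fraction * length(g))
        if (k > 0) sample(g, k) else integer(0)
      }), use.names = FALSE)
      short <- size - length(idx)
      if (short > 0) {
        pool <- setdiff(seq_len(n), idx)
        idx <- c(idx, sample(pool, short))
      } else if (short < 0) {
        idx <- sample(idx, size)
      }
      sort(idx)
    }
  })
}

#' Principal-component pseudotime (built-in reference method)
#'
#' A minimal, deterministic pseudotime: library-size normalization, log1p,
#' restriction to the most variable genes (the standard feature-selection
#' step, which also keeps most tested genes out of the ordering), column
#' centering, then each cell's projection onto the first principal axis,
#' min-max rescaled to [0, 1]. The sign of the axis is fixed by positive
#' correlation with library size (ties resolved toward the first cell),
#' making the output invariant to SVD sign ambiguity and equivariant under
#' cell permutations. Intended as a light-weight single-lineage ordering
#' for testing and as a default when no external method is supplied; it is
#' a surrogate for a principal curve, not a replacement for full
#' trajectory-inference tools.
#'
#' @param counts cells x genes count matrix (or SingleCellExperiment).
#' @param nComponents number of principal components computed (ordering
#'   uses the first axis).
#' @param nHVG number of highly variable genes used for the projection;
#'   the default keeps the top 20\% (at least 50, at most all).
#' @return named numeric pseudotime vector in [0, 1].
#' @export
builtinPseudotime <- function(counts, nComponents = 2, nHVG = NULL) {
  m <- .coerceCounts(counts)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least 2 cells and 2 genes")
  lib <- rowSums(m)
  if (any(lib == 0)) stop("cells with zero total counts; remove them first")
  x <- log1p(m / lib * stats::median(lib))
  if (is.null(nHVG)) nHVG <- max(50, round(ncol(x) / 5))
  if (nHVG < ncol(x)) {
    v <- colMeans(x^2) - colMeans(x)^2
    keep <- order(v, decreasing = TRUE)[seq_len(nHVG)]
    x <- x[, sort(keep), drop = FALSE]
  }
  x <- sweep(x, 2, colMeans(x))
  if (max(abs(x)) == 0)
    stop(structure(class = c("ptDE_degenerate_pseudotime", "error",
                             "condition"),
                   list(message = "degenerate matrix: zero variance",
                        call = sys.call(-1))))
  sv <- svd(x, nu = min(nComponents, dim(x)), nv = 0)
  score <- sv$u[, 1] * sv$d[1]
  sgn <- sign(cor(score, lib))
  if (is.na(sgn) || sgn == 0) sgn <- if (score[1] >= 0) 1 else -1
  score <- sgn * score
  out <- normalizePseudotime(score)
  names(out) <- rownames(m)
  out
}

#' Re-infer pseudotime on each cell subsample
#'
#' Applies the user's pseudotime method to every subsample's count
#' submatrix and records the normalized result. Failures (method error,
#' constant output, missing values) are recorded with status "failed" and
#' excluded downstream; if fewer than `minSubsamples` succeed, the
#' uncertainty estimate is considered unusable and an error is raised.
#'
#' @param counts cells x genes count matrix (or SingleCellExperiment).
#' @param indexSets list of cell index vectors from [drawSubsamples()].
#' @param method a function mapping a cells x genes count submatrix to one
#'   raw pseudotime value per row; it must be the same method, with the
#'   same settings, used on the full data.
#' @param original optional full-data pseudotime (normalized); computed by
#'   `method` on the full matrix when missing.
#' @param fraction the subsampling fraction used (stored for bookkeeping).
#' @param minSubsamples minimum number of usable subsamples (default 50).
#' @param seed master seed recorded in the object.
#' @return a [PseudotimeDraws-class] (permuted slots unset; see
#'   [permutePseudotime()]).
#' @export
inferSubsamplePseudotime <- function(counts, indexSets, method,
                                     original = NULL, fraction = 0.8,
                                     minSubsamples = 50, seed = 1L) {
  m <- .coerceCounts(counts)
  if (is.null(original)) original <- normalizePseudotime(method(m))
  if (length(original) != nrow(m))
    stop("original pseudotime length does not match cell count")
  if (is.null(names(original))) names(original) <- rownames(m)
  subs <- lapply(indexSets, function(idx) {
    rec <- list(indices = as.integer(idx), inferred = NULL, permuted = NULL,
                status = "failed")
    raw <- tryCatch(method(m[idx, , drop = FALSE]), error = function(e) NULL)
    if (is.null(raw) || length(raw) != length(idx) || anyNA(raw) ||
        diff(range(raw)) == 0)
      return(rec)
    pt <- normalizePseudotime(raw)
    names(pt) <- rownames(m)[idx]
    rec$inferred <- pt
    rec$status <- "ok"
    rec
  })
  draws <- new("PseudotimeDraws", original = original, subsamples = subs,
               fraction = fraction, n = nrow(m), seed = as.integer(seed))
  nOk <- length(usableSubsamples(draws))
  if (nOk < min(minSubsamples, length(indexSets)))
    stop(sprintf(paste0("uncertainty estimation failed: only %d of %d ",
                        "subsamples usable (minimum %d)"),
                 nOk, length(indexSets), minSubsamples))
  draws
}

#' Permute each subsample's pseudotime
#'
#' Fills the `permuted` slot of every usable subsample with an independent
#' uniform random permutation of its inferred pseudotime (independent
#' across subsamples, each from a counter-derived seed). Permutation severs
#' any expression--pseudotime association while preserving both marginals,
#' which is what makes the downstream null statistics valid.
#'
#' @param draws a [PseudotimeDraws-class] object.
#' @param seed master seed.
#' @return the updated [PseudotimeDraws-class].
#' @export
permutePseudotime <- function(draws, seed = 1) {
  if (length(usableSubsamples(draws)) < 1)
    stop("no usable subsamples to permute")
  draws@subsamples <- lapply(seq_along(draws@subsamples), function(b) {
    rec <- draws@subsamples[[b]]
    if (rec$status != "ok") return(rec)
    set.seed(.deriveSeed(seed, .purpose["permutation"], b))
    perm <- if (length(rec$inferred) == 1) rec$inferred else
      sample(rec$inferred)
    names(perm) <- names(rec$inferred)
    rec$permuted <- perm
    rec
  })
  validObject(draws)
  draws
}

#' Per-cell summary of pseudotime uncertainty
#'
#' For each cell: how many usable subsamples contain it and the mean, sd
#' and 5\%/95\% quantiles of its inferred pseudotime across them. Because
#' pseudotime direction is unidentifiable, each subsample is first oriented
#' against the original pseudotime (flipped to 1 - T when its Spearman
#' correlation over shared cells is negative); orientation matters only for
#' reporting, not for testing, where permutation makes direction
#' irrelevant. The long-format table behind the summary is attached as
#' attribute "long".
#'
#' @param draws a [PseudotimeDraws-class] with at least 2 usable subsamples.
#' @return data.frame with columns cell_id, n_subsamples, mean, sd, q05,
#'   q95.
#' @export
uncertaintySummary <- function(draws) {
  ok <- usableSubsamples(draws)
  if (length(ok) < 2) stop("need at least 2 usable subsamples")
  long <- do.call(rbind, lapply(ok, function(b) {
    rec <- draws@subsamples[[b]]
    pt <- rec$inferred
    shared <- draws@original[names(pt)]
    rho <- suppressWarnings(cor(pt, shared, method = "spearman"))
    if (!is.na(rho) && rho < 0) pt <- 1 - pt
    data.frame(subsample = b, cell_id = names(pt), pseudotime = unname(pt),
               stringsAsFactors = FALSE)
  }))
  cells <- names(draws@original)
  byCell <- split(long$pseudotime, factor(long$cell_id, levels = cells))
  out <- data.frame(
    cell_id = cells,
    n_subsamples = vapply(byCell, length, 0L),
    mean = vapply(byCell, function(v) if (length(v)) mean(v) else NA_real_, 0),
    sd = vapply(byCell, function(v)
      if (length(v) > 1) sd(v) else if (length(v) == 1) 0 else NA_real_, 0),
    q05 = vapply(byCell, function(v)
      if (length(v)) unname(quantile(v, 0.05)) else NA_real_, 0),
    q95 = vapply(byCell, function(v)
      if (length(v)) unname(quantile(v, 0.95)) else NA_real_, 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "long") <- long
  out
}
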