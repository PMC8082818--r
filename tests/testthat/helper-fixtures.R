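# Shared fixtures: built in code at test time, cached per session.

# small single-lineage dataset as a cells x genes matrix plus truth
tinyLineage <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sce <- simulateLineage(120, 80, propDE = 0.3, dispersion = "medium",
                             seed = 7)
      cache <<- list(
        sce = sce,
        counts = t(as.matrix(SummarizedExperiment::assay(sce, "counts"))),
        tt = SummarizedExperiment::colData(sce)$true_time,
        isDE = SummarizedExperiment::rowData(sce)$is_de)
    }
    cache
  }
})

# a PseudotimeDraws object built by hand (no inference), for permutation
# and null-statistic tests
handDraws <- function(n, B, fraction = 0.8, original = NULL, seed = 5) {
  if (is.null(original))
    original <- setNames(normalizePseudotime(seq_len(n)),
                         paste0("cell", seq_len(n)))
  size <- floor(fraction * n)
  idx <- drawSubsamples(n, fraction = fraction, B = B, seed = seed)
  subs <- lapply(idx, function(ix) {
    # oracle inference: the subsample sees exactly the original pseudotime
    list(indices = as.integer(ix),
         inferred = original[ix],
         permuted = NULL, status = "ok")
  })
  new("PseudotimeDraws", original = original, subsamples = subs,
      fraction = fraction, n = as.integer(n), seed = as.integer(seed))
}

# random symmetric PSD matrix of given dimension and rank
randomPSD <- function(dim, rank) {
  A <- matrix(rnorm(dim * rank), dim, rank)
  V <- A %*% t(A)
  (V + t(V)) / 2
}

# brute-force rank-truncated pseudoinverse quadratic form (independent
# oracle for the test statistic)
bruteStat <- function(fhat, Vf, cap = NULL) {
  ed <- eigen((Vf + t(Vf)) / 2, symmetric = TRUE)
  keep <- which(ed$values > sqrt(.Machine$double.eps) * max(ed$values))
  if (!is.null(cap)) keep <- keep[seq_len(min(length(keep), cap))]
  Vinv <- ed$vectors[, keep, drop = FALSE] %*%
    diag(1 / ed$values[keep], length(keep)) %*%
    t(ed$vectors[, keep, drop = FALSE])
  drop(t(fhat) %*% Vinv %*% fhat)
}
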