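#' Read a count matrix from disk
#'
#' Accepts a directory (or .mtx file) holding MatrixMarket `matrix.mtx` +
#' `genes.tsv` + `cells.tsv` (also `barcodes.tsv`), or a dense delimited
#' table (.csv/.tsv/.txt with row and column names). The result is
#' normalized to the cells x genes orientation: MatrixMarket input is
#' assumed genes x cells (the single-cell convention) and dense tables are
#' auto-detected by assuming genes outnumber cells; use `orientation` to
#' override.
#'
#' @param path directory, .mtx file, or delimited text file.
#' @param orientation "auto", or "cells" / "genes" stating what the rows of
#'   the stored matrix are.
#' @return an integer cells x genes matrix with unique identifiers.
#' @export
readCounts <- function(path, orientation = c("auto", "cells", "genes")) {
  orientation <- match.arg(orientation)
  if (dir.exists(path) || grepl("\\.mtx$", path)) {
    dir <- if (dir.exists(path)) path else dirname(path)
    mtx <- if (dir.exists(path)) file.path(path, "matrix.mtx") else path
    m <- as.matrix(Matrix::readMM(mtx))
    gf <- file.path(dir, "genes.tsv")
    cf <- file.path(dir, "cells.tsv")
    if (!file.exists(cf)) cf <- file.path(dir, "barcodes.tsv")
    rownames(m) <- readLines(gf)
    colnames(m) <- readLines(cf)
    if (orientation != "cells") m <- t(m)  # stored genes x cells
  } else {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    m <- as.matrix(read.table(path, header = TRUE, sep = sep,
                              row.names = 1, check.names = FALSE))
    flip <- switch(orientation,
                   auto = nrow(m) > ncol(m),  # more rows than cols: genes
                   cells = FALSE, genes = TRUE)
    if (flip) m <- t(m)
  }
  if (any(m < 0)) stop("format error: negative entries")
  if (any(abs(m - round(m)) > 1e-8)) stop("format error: non-integer entries")
  storage.mode(m) <- "integer"
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("format error: duplicate identifiers")
  m
}

#' Filter genes by zero proportion
#'
#' Removes genes whose fraction of zero counts exceeds `maxZeroProp`
#' (strictly greater; a gene at exactly the threshold is kept). Genes that
#' are almost all zeros carry little information for a smooth fit and slow
#' the permutation stage down.
#'
#' @param counts cells x genes matrix or SingleCellExperiment.
#' @param maxZeroProp maximum tolerated zero fraction, in (0, 1]
#'   (default 0.9).
#' @param verbose print how many genes were kept.
#' @return the filtered object, same class as the input.
#' @export
filterGenes <- function(counts, maxZeroProp = 0.9, verbose = TRUE) {
  if (length(maxZeroProp) != 1 || maxZeroProp <= 0 || maxZeroProp > 1)
    stop("maxZeroProp must be in (0, 1]")
  isSE <- is(counts, "SummarizedExperiment")
  m <- .coerceCounts(counts)
  zfrac <- colMeans(m == 0)
  keep <- zfrac <= maxZeroProp
  if (!any(keep)) stop("all genes removed by the zero filter")
  .msg(verbose, sprintf("filterGenes: kept %d / %d genes (zero fraction <= %g)",
                        sum(keep), length(keep), maxZeroProp))
  if (isSE) counts[keep, ]
  else if (is.matrix(counts)) counts[, keep, drop = FALSE]
  else m[, keep, drop = FALSE]
}

#' Run the pseudotime differential-expression workflow
#'
#' The four-step workflow: (1) subsample cells, (2) re-run pseudotime
#' inference on every subsample and permute each subsample's pseudotime,
#' (3) fit the per-gene NB-GAM / ZINB-GAM on the original data, (4) refit
#' on the permuted subsamples to build each gene's null distribution and
#' compute empirical and parametric p-values. In `fixed = TRUE` mode the
#' subsampling steps are skipped and p-values come from the asymptotic
#' approximation that treats pseudotime as fixed (faster, but ignores
#' pseudotime uncertainty).
#'
#' @param counts cells x genes count matrix, or a SingleCellExperiment /
#'   SummarizedExperiment with a `counts` assay (genes x cells).
#' @param pseudotime `"builtin"` (principal-component ordering), a function
#'   mapping a cells x genes submatrix to one raw pseudotime per row, or a
#'   numeric vector of precomputed pseudotime (one per cell; requires
#'   `subsamplePseudotime` or `fixed = TRUE`, since a fixed vector cannot
#'   be re-inferred on subsamples).
#' @param B number of subsamples (default 1000).
#' @param fraction subsampling fraction (default 0.8).
#' @param knots spline basis dimension K (default 6).
#' @param model "auto" (AIC selection), "nb" or "zinb".
#' @param aicDelta AIC improvement required to prefer ZINB (default 10).
#' @param lrtAlpha level of the gamma-vs-mixture LRT (default 0.01).
#' @param zeroFilter remove genes with zero fraction above this (default
#'   0.9); NULL skips filtering.
#' @param fixed treat pseudotime as fixed (no subsampling; asymptotic
#'   p-values).
#' @param groups optional cell groups for stratified subsampling.
#' @param subsamplePseudotime optional precomputed per-subsample pseudotime
#'   from an external tool: a data.frame (subsample_id, cell_id,
#'   pseudotime) or a TSV path with those columns. Subsample ids must be in
#'   1..B and cover each subsample's cells.
#' @param seed master seed; all randomness (subsampling, permutation)
#'   derives from it.
#' @param workers parallel workers for the permutation stage (results are
#'   independent of the worker count).
#' @param minSubsamples minimum usable subsamples / null values per gene.
#' @param criterion smoothing criterion ("REML" or "GCV").
#' @param outputDir if non-NULL, write `results.tsv`, `uncertainty.tsv` and
#'   `manifest.json` there.
#' @param verbose stage-level progress messages.
#' @return a [PseudotimeDEResults-class]; see [resultsTable()].
#' @examples
#' sce <- simulateLineage(60, 40, propDE = 0.3, seed = 1)
#' res <- runPseudotimeDE(sce, B = 60, minSubsamples = 30, seed = 1,
#'                        verbose = FALSE)
#' head(resultsTable(res))
#' @export
runPseudotimeDE <- function(counts, pseudotime = "builtin", B = 1000,
                            fraction = 0.8, knots = 6,
                            model = c("auto", "nb", "zinb"), aicDelta = 10,
                            lrtAlpha = 0.01, zeroFilter = 0.9,
                            fixed = FALSE, groups = NULL,
                            subsamplePseudotime = NULL, seed = 1,
                            workers = 1, minSubsamples = 50,
                            criterion = c("REML", "GCV"), outputDir = NULL,
                            verbose = TRUE) {
  model <- match.arg(model)
  criterion <- match.arg(criterion)
  m <- .coerceCounts(counts)

  # drop cells without any counts: they carry no ordering information
  libs <- rowSums(m)
  if (any(libs == 0)) {
    warning(sprintf("dropping %d cells with zero total counts",
                    sum(libs == 0)))
    keep <- libs > 0
    m <- m[keep, , drop = FALSE]
    if (!is.null(groups)) groups <- groups[keep]
  }
  if (!is.null(zeroFilter)) m <- filterGenes(m, zeroFilter, verbose = verbose)
  n <- nrow(m); nGenes <- ncol(m)

  # resolve the pseudotime source
  ptFun <- NULL
  if (is.function(pseudotime)) {
    ptFun <- pseudotime
  } else if (identical(pseudotime, "builtin")) {
    ptFun <- builtinPseudotime
  } else if (is.numeric(pseudotime)) {
    if (length(pseudotime) != n)
      stop("precomputed pseudotime length does not match cell count")
    if (!fixed && is.null(subsamplePseudotime))
      stop(paste("a fixed pseudotime vector cannot be re-inferred on",
                 "subsamples; supply a callable, subsamplePseudotime,",
                 "or set fixed = TRUE"))
  } else stop("unsupported 'pseudotime' argument")

  .msg(verbose, "inferring pseudotime on the full data")
  ptOrig <- if (is.numeric(pseudotime)) normalizePseudotime(pseudotime)
            else normalizePseudotime(ptFun(m))
  names(ptOrig) <- rownames(m)

  basis <- buildSplineBasis(unname(ptOrig), K = knots)
  fitCfg <- list(K = knots, criterion = criterion, maxit = 50, tol = 1e-8)

  .msg(verbose, sprintf("fitting observed models (%d genes, mode %s)",
                        nGenes, model))
  obs <- .observedFits(m, ptOrig, basis, model, aicDelta, fitCfg, workers)

  if (fixed) {
    pAsym <- vapply(obs, function(o)
      if (is.null(o$fit)) NA_real_ else asymptoticPvalue(o$fit), 0)
    tab <- .assembleTable(m, obs, pEmp = rep(NA_real_, nGenes),
                          pParam = rep(NA_real_, nGenes), pAsym = pAsym,
                          bUsed = rep(NA_integer_, nGenes),
                          nullModel = rep(NA_character_, nGenes),
                          gofP = rep(NA_real_, nGenes),
                          padj = bhAdjust(pAsym))
    draws <- new("PseudotimeDraws", original = ptOrig, subsamples = list(),
                 fraction = fraction, n = n, seed = as.integer(seed))
    unc <- data.frame()
  } else {
    .msg(verbose, sprintf("drawing %d subsamples (fraction %g)", B, fraction))
    idx <- drawSubsamples(n, fraction = fraction, B = B, groups = groups,
                          seed = seed)
    .msg(verbose, "re-inferring pseudotime on subsamples")
    draws <- if (!is.null(subsamplePseudotime))
      .attachPrecomputed(m, idx, subsamplePseudotime, ptOrig, fraction,
                         minSubsamples, seed)
    else
      inferSubsamplePseudotime(m, idx, ptFun, original = ptOrig,
                               fraction = fraction,
                               minSubsamples = minSubsamples, seed = seed)
    draws <- permutePseudotime(draws, seed = seed)
    .msg(verbose, sprintf("computing null statistics on %d subsamples",
                          length(usableSubsamples(draws))))
    flavors <- vapply(obs, function(o)
      if (is.null(o$fit)) "NB" else o$fit@flavor, "")
    nullMat <- .nullStatsMatrix(m, draws, flavors, knots, criterion,
                                fitCfg$maxit, fitCfg$tol, workers)
    .msg(verbose, "fitting parametric nulls and computing p-values")
    pEmp <- pParam <- gofP <- rep(NA_real_, nGenes)
    bUsed <- rep(NA_integer_, nGenes)
    nullModel <- rep(NA_character_, nGenes)
    for (j in seq_len(nGenes)) {
      o <- obs[[j]]
      nulls <- nullMat[, j]
      nulls <- nulls[!is.na(nulls)]
      bUsed[j] <- length(nulls)
      if (is.null(o$fit) || length(nulls) <
          min(minSubsamples, length(usableSubsamples(draws)))) next
      s <- o$fit@statistic
      pEmp[j] <- empiricalPvalue(s, nulls)
      nf <- fitParametricNull(nulls, lrtAlpha = lrtAlpha,
                              minNull = minSubsamples)
      nullModel[j] <- nf@chosen
      gofP[j] <- nf@gofP
      if (nf@chosen != "empirical_only") pParam[j] <- parametricPvalue(s, nf)
    }
    tab <- .assembleTable(m, obs, pEmp = pEmp, pParam = pParam,
                          pAsym = rep(NA_real_, nGenes), bUsed = bUsed,
                          nullModel = nullModel, gofP = gofP,
                          padj = bhAdjust(pParam))
    unc <- uncertaintySummary(draws)
  }

  manifest <- list(
    n_cells = n, n_genes = nGenes, B = if (fixed) 0L else B,
    fraction = fraction, knots = knots, model = model, aic_delta = aicDelta,
    lrt_alpha = lrtAlpha, zero_filter = zeroFilter, fixed = fixed,
    seed = seed, workers = workers, min_subsamples = minSubsamples,
    criterion = criterion,
    pseudotime_source = if (is.numeric(pseudotime)) "precomputed"
      else if (identical(pseudotime, "builtin")) "builtin" else "callable",
    B_used = if (fixed) 0L else length(usableSubsamples(draws)),
    package_version = as.character(packageVersion("ptDE")),
    warnings = character(0))

  res <- new("PseudotimeDEResults", table = tab, draws = draws,
             uncertainty = unc, manifest = manifest)
  if (!is.null(outputDir)) {
    if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
    writeResults(res, file.path(outputDir, "results.tsv"))
    if (nrow(unc))
      write.table(unc, file.path(outputDir, "uncertainty.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

# observed per-gene fits with model selection; NULL fit marks a failure
.observedFits <- function(m, ptime, basis, model, aicDelta, cfg, workers) {
  pt <- unname(ptime)
  oneGene <- function(j) {
    y <- m[, j]
    if (all(y == 0)) return(list(fit = NULL))
    fit <- tryCatch({
      nb <- fitNBGAM(y, pt, basis = basis, criterion = cfg$criterion,
                     maxit = cfg$maxit, tol = cfg$tol)
      if (model == "nb" || !any(y == 0)) nb
      else {
        zinb <- tryCatch(
          fitZINBGAM(y, pt, basis = basis, criterion = cfg$criterion,
                     maxit = cfg$maxit, tol = cfg$tol),
          error = function(e) NULL)
        if (model == "zinb") (if (is.null(zinb)) nb else zinb)
        else selectModel(nb, zinb, mode = "auto", delta = aicDelta)
      }
    }, error = function(e) NULL)
    list(fit = fit)
  }
  if (workers > 1L)
    parallel::mclapply(seq_len(ncol(m)), oneGene, mc.cores = workers)
  else lapply(seq_len(ncol(m)), oneGene)
}

.assembleTable <- function(m, obs, pEmp, pParam, pAsym, bUsed, nullModel,
                           gofP, padj) {
  S4Vectors::DataFrame(
    gene = colnames(m),
    statistic = vapply(obs, function(o)
      if (is.null(o$fit)) NA_real_ else o$fit@statistic, 0),
    rank = vapply(obs, function(o)
      if (is.null(o$fit)) NA_integer_ else o$fit@rank, 0L),
    model = vapply(obs, function(o)
      if (is.null(o$fit)) NA_character_ else o$fit@flavor, ""),
    B_used = bUsed,
    p_emp = pEmp,
    p_param = pParam,
    p_asymptotic = pAsym,
    padj_param = padj,
    null_model = nullModel,
    gof_p = gofP,
    converged = vapply(obs, function(o)
      if (is.null(o$fit)) NA else o$fit@converged, TRUE))
}

# attach per-subsample pseudotime computed out-of-band by an external tool
.attachPrecomputed <- function(m, idx, src, ptOrig, fraction,
                               minSubsamples, seed) {
  df <- if (is.character(src))
    read.table(src, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  else as.data.frame(src)
  need <- c("subsample_id", "cell_id", "pseudotime")
  if (!all(need %in% names(df)))
    stop("subsamplePseudotime needs columns: ", paste(need, collapse = ", "))
  subs <- lapply(seq_along(idx), function(b) {
    rec <- list(indices = as.integer(idx[[b]]), inferred = NULL,
                permuted = NULL, status = "failed")
    dfb <- df[df$subsample_id == b, ]
    cells <- rownames(m)[idx[[b]]]
    if (!all(cells %in% dfb$cell_id)) return(rec)
    v <- setNames(dfb$pseudotime, dfb$cell_id)[cells]
    if (anyNA(v) || diff(range(v)) == 0) return(rec)
    rec$inferred <- normalizePseudotime(v)
    rec$status <- "ok"
    rec
  })
  draws <- new("PseudotimeDraws", original = ptOrig, subsamples = subs,
               fraction = fraction, n = nrow(m), seed = as.integer(seed))
  if (length(usableSubsamples(draws)) < min(minSubsamples, length(idx)))
    stop("too few usable precomputed subsamples")
  draws
}

#' Write a result table to TSV
#'
#' Deterministic row order (input gene order); missing values written as
#' "NA".
#'
#' @param results a [PseudotimeDEResults-class] or its table.
#' @param path output file path.
#' @export
writeResults <- function(results, path) {
  tab <- if (is(results, "PseudotimeDEResults")) results@table else results
  if (!nrow(tab)) stop("empty result table")
  write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a result table written by [writeResults()]
#'
#' @param path TSV path.
#' @return data.frame with the result-table columns.
#' @export
readResults <- function(path)
  read.table(path, header = TRUE, sep = "\t", na.strings = "NA",
             stringsAsFactors = FALSE)
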