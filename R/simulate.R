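#' Simulate lineage-structured single-cell count data
#'
#' Generates negative-binomial counts along a latent time for validating
#' the pseudotime DE workflow. Each cell gets a latent time uniform on
#' [0, 1] (rescaled to span it exactly). Differentially expressed genes get
#' a random smooth log-mean trend in latent time, drawn from one of three
#' shape families -- monotone, sigmoidal or transient (single bump) -- with
#' amplitude drawn so the max/min mean ratio is at least 2-fold (up to
#' ~6-fold); non-DE genes have constant mean. Per-gene NB size parameters are drawn
#' log-uniformly within a dispersion tier: low (20, 200), medium (5, 50),
#' high (1, 10) -- smaller size means noisier counts. In the bifurcation
#' topology, cells are assigned to one of two branches that share the trend
#' on a common root segment (latent time up to 0.4) and diverge smoothly
#' afterwards.
#'
#' @param nCells number of cells (>= 10).
#' @param nGenes number of genes (>= 2).
#' @param propDE fraction of genes that are DE, in [0, 1].
#' @param dispersion dispersion tier: "low", "medium" or "high".
#' @param topology "single" (one lineage) or "bifurcation" (two branches).
#' @param seed integer seed; output is fully deterministic given it.
#' @return a [SingleCellExperiment::SingleCellExperiment] with assays
#'   `counts` (genes x cells, integer) and `mu` (the generator means);
#'   colData `true_time` and `lineage_id` (0 for single lineage, 1/2 for
#'   the two branches); rowData `is_de`; generation parameters in
#'   `metadata(x)$params`.
#' @examples
#' sce <- simulateLineage(100, 50, propDE = 0.2, seed = 1)
#' table(SummarizedExperiment::rowData(sce)$is_de)
#' @export
simulateLineage <- function(nCells, nGenes, propDE = 0.2,
                            dispersion = c("high", "medium", "low"),
                            topology = c("single", "bifurcation"),
                            seed = 1) {
  nCells <- .assertCount(nCells, "nCells", min = 10L)
  nGenes <- .assertCount(nGenes, "nGenes", min = 2L)
  propDE <- .assertFraction(propDE, "propDE", open = FALSE)
  dispersion <- match.arg(dispersion)
  topology <- match.arg(topology)
  seed <- .assertCount(seed, "seed", min = 0L)
  set.seed(.deriveSeed(seed, .purpose["simulation"]))

  tt <- normalizePseudotime(runif(nCells))
  branch <- if (topology == "bifurcation")
    sample(c(1L, 2L), nCells, replace = TRUE) else rep(0L, nCells)

  nDE <- round(propDE * nGenes)
  isDE <- rep(FALSE, nGenes)
  if (nDE > 0) isDE[sample.int(nGenes, nDE)] <- TRUE

  tierRange <- switch(dispersion, low = c(20, 200), medium = c(5, 50),
                      high = c(1, 10))
  size <- 10^runif(nGenes, log10(tierRange[1]), log10(tierRange[2]))
  beta0 <- stats::rnorm(nGenes, mean = log(3), sd = 1)

  # random smooth trend from one of three shape families (monotone,
  # sigmoidal, transient), centered and scaled so the log-mean spans a
  # target >= 2-fold (up to ~6-fold) amplitude
  shapes <- rep("none", nGenes)
  shapes[isDE] <- sample(c("monotone", "sigmoid", "transient"), sum(isDE),
                         replace = TRUE)
  trend <- function(x, shape) {
    f <- switch(shape,
      monotone = {
        pw <- runif(1, 0.5, 2)
        sign(runif(1, -1, 1)) * x^pw
      },
      sigmoid = {
        k <- runif(1, 5, 15)
        t0 <- runif(1, 0.25, 0.75)
        sign(runif(1, -1, 1)) * plogis(k * (x - t0))
      },
      transient = {
        t0 <- runif(1, 0.2, 0.8)
        w <- runif(1, 0.1, 0.25)
        sign(runif(1, -1, 1)) * exp(-(x - t0)^2 / (2 * w^2))
      })
    f <- f - mean(f)
    amp <- runif(1, log(2), log(6))
    span <- max(f) - min(f)
    if (span < 1e-8) return(rep(0, length(x)))
    f * amp / span
  }

  logmu <- matrix(rep(beta0, each = nCells), nCells, nGenes)
  rootT <- 0.4
  for (j in which(isDE)) {
    if (topology == "single") {
      logmu[, j] <- logmu[, j] + trend(tt, shapes[j])
    } else {
      shared <- trend(pmin(tt, rootT), shapes[j])
      # smooth branch divergence after the root segment (C1 at the split)
      u <- pmax(tt - rootT, 0) / (1 - rootT)
      cdev <- runif(1, log(2), log(4)) * sample(c(-1, 1), 1)
      dev <- cdev * u^2
      f <- shared + ifelse(branch == 2L, dev, 0)
      logmu[, j] <- logmu[, j] + f - mean(f)
    }
  }
  mu <- exp(pmin(logmu, 15))
  counts <- matrix(rnbinom(nCells * nGenes, mu = mu,
                           size = rep(size, each = nCells)),
                   nCells, nGenes)

  geneIds <- sprintf("g%04d", seq_len(nGenes))
  cellIds <- sprintf("c%04d", seq_len(nCells))
  dimnames(counts) <- dimnames(mu) <- list(cellIds, geneIds)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = t(counts), mu = t(mu)),
    colData = S4Vectors::DataFrame(true_time = tt, lineage_id = branch,
                                   row.names = cellIds),
    rowData = S4Vectors::DataFrame(is_de = isDE, size = size,
                                   trend_shape = shapes,
                                   row.names = geneIds))
  S4Vectors::metadata(sce)$params <- list(
    n_cells = nCells, n_genes = nGenes, prop_de = propDE,
    dispersion_level = dispersion, topology = topology, seed = seed)
  sce
}

#' Impose zero inflation on a simulated dataset
#'
#' Each count is kept with probability \eqn{p_{ij}},
#' \eqn{\mathrm{logit}(p_{ij}) = \alpha_0 + \alpha_1 \log\mu_{ij}} with
#' \eqn{\mu} the generator mean, and set to zero otherwise -- the same
#' dropout mechanism the zero-inflated NB-GAM assumes, so EM parameter
#' recovery can be tested against the truth. The realized keep indicators
#' are stored in assay `kept`.
#'
#' @param sce a dataset from [simulateLineage()] (must carry assay `mu`).
#' @param alpha0,alpha1 dropout-model coefficients.
#' @param seed integer seed.
#' @return the modified SingleCellExperiment (counts zeroed where dropped;
#'   assay `kept`; `metadata(x)$zero_inflation` records the parameters).
#' @export
simulateZeroInflation <- function(sce, alpha0, alpha1, seed = 1) {
  if (!is(sce, "SingleCellExperiment") ||
      !"mu" %in% SummarizedExperiment::assayNames(sce))
    stop("sce must come from simulateLineage() (assay 'mu' required)")
  if (!is.finite(alpha0) || !is.finite(alpha1))
    stop("alpha0 and alpha1 must be finite")
  set.seed(.deriveSeed(seed, .purpose["zeroinfl"]))
  mu <- SummarizedExperiment::assay(sce, "mu")
  p <- plogis(alpha0 + alpha1 * log(mu))
  kept <- matrix(rbinom(length(p), 1L, p), nrow(p), ncol(p),
                 dimnames = dimnames(p))
  counts <- SummarizedExperiment::assay(sce, "counts") * kept
  SummarizedExperiment::assay(sce, "counts") <- counts
  SummarizedExperiment::assay(sce, "kept") <- kept
  S4Vectors::metadata(sce)$zero_inflation <-
    list(alpha0 = alpha0, alpha1 = alpha1, seed = seed)
  sce
}

#' Shuffle selected genes' expression across cells
#'
#' Independently permutes each named gene's values across cells, leaving
#' other genes untouched. The per-gene multiset of counts is preserved
#' exactly, so shuffled genes are true non-DE genes with realistic
#' marginals -- the standard construction of a negative control set.
#'
#' @param x a SingleCellExperiment (genes in rows) or a cells x genes
#'   count matrix.
#' @param geneIds character vector of gene identifiers to shuffle.
#' @param seed integer seed.
#' @return object of the same class with the named genes shuffled.
#' @export
shuffleNullGenes <- function(x, geneIds, seed = 1) {
  if (is(x, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(x, "counts")
    bad <- setdiff(geneIds, rownames(m))
    if (length(bad)) stop("unknown gene id(s): ", paste(bad, collapse = ", "))
    for (k in seq_along(geneIds)) {
      set.seed(.deriveSeed(seed, .purpose["shuffle"], k))
      g <- geneIds[k]
      m[g, ] <- m[g, sample.int(ncol(m))]
    }
    SummarizedExperiment::assay(x, "counts") <- m
    x
  } else {
    m <- x
    bad <- setdiff(geneIds, colnames(m))
    if (length(bad)) stop("unknown gene id(s): ", paste(bad, collapse = ", "))
    for (k in seq_along(geneIds)) {
      set.seed(.deriveSeed(seed, .purpose["shuffle"], k))
      g <- geneIds[k]
      m[, g] <- m[sample.int(nrow(m)), g]
    }
    m
  }
}

#' Write / read a simulated dataset as plain-text files
#'
#' `writeSimulatedDataset` stores counts as MatrixMarket `matrix.mtx` with
#' `genes.tsv` / `cells.tsv` name files, cell truth (`truth.tsv`: cell,
#' true_time, lineage_id) and gene truth (`gene_truth.tsv`: gene, is_de).
#' `readSimulatedDataset` reconstructs the SingleCellExperiment (without
#' the generator means).
#'
#' @param sce dataset from [simulateLineage()].
#' @param dir directory to write to / read from (created if needed).
#' @return `writeSimulatedDataset`: the directory, invisibly;
#'   `readSimulatedDataset`: a SingleCellExperiment.
#' @export
writeSimulatedDataset <- function(sce, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(methods::as(methods::as(counts, "CsparseMatrix"),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "cells.tsv"))
  cd <- SummarizedExperiment::colData(sce)
  write.table(data.frame(cell = rownames(cd), true_time = cd$true_time,
                         lineage_id = cd$lineage_id),
              file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  rd <- SummarizedExperiment::rowData(sce)
  write.table(data.frame(gene = rownames(rd), is_de = rd$is_de),
              file.path(dir, "gene_truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @rdname writeSimulatedDataset
#' @export
readSimulatedDataset <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "cells.tsv"))
  truth <- read.table(file.path(dir, "truth.tsv"), header = TRUE, sep = "\t")
  gtruth <- read.table(file.path(dir, "gene_truth.tsv"), header = TRUE,
                       sep = "\t")
  stopifnot(identical(truth$cell, colnames(m)),
            identical(gtruth$gene, rownames(m)))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(true_time = truth$true_time,
                                   lineage_id = truth$lineage_id,
                                   row.names = truth$cell),
    rowData = S4Vectors::DataFrame(is_de = gtruth$is_de,
                                   row.names = gtruth$gene))
}
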