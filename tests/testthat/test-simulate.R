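test_that("simulated lineage datasets satisfy their structural invariants", {
  sce <- simulateLineage(100, 50, propDE = 0.2, dispersion = "low", seed = 3)
  cm <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
  expect_equal(dim(cm), c(50, 100))
  expect_true(all(cm >= 0) && all(cm == round(cm)))
  rd <- SummarizedExperiment::rowData(sce)
  expect_equal(sum(rd$is_de), round(0.2 * 50))
  tt <- SummarizedExperiment::colData(sce)$true_time
  expect_equal(range(tt), c(0, 1))
  expect_true(all(SummarizedExperiment::colData(sce)$lineage_id == 0L))

  # bifurcation: both branch labels present, same gene/cell counts
  scb <- simulateLineage(100, 20, propDE = 0.2, topology = "bifurcation",
                         seed = 3)
  expect_setequal(unique(SummarizedExperiment::colData(scb)$lineage_id),
                  c(1L, 2L))

  # byte-identical reproducibility for identical seeds
  sce2 <- simulateLineage(100, 50, propDE = 0.2, dispersion = "low", seed = 3)
  expect_identical(as.matrix(SummarizedExperiment::assay(sce2, "counts")), cm)
  sce3 <- simulateLineage(100, 50, propDE = 0.2, dispersion = "low", seed = 4)
  expect_false(identical(as.matrix(SummarizedExperiment::assay(sce3, "counts")),
                         cm))

  expect_error(simulateLineage(5, 50), "nCells")
  expect_error(simulateLineage(100, 50, propDE = 1.5), "propDE")
  expect_error(simulateLineage(100, 50, dispersion = "extreme"))
})

test_that("with no DE genes, expression is uncorrelated with latent time", {
  sce <- simulateLineage(100, 50, propDE = 0, dispersion = "low", seed = 9)
  expect_false(any(SummarizedExperiment::rowData(sce)$is_de))
  cm <- t(as.matrix(SummarizedExperiment::assay(sce, "counts")))
  tt <- SummarizedExperiment::colData(sce)$true_time
  rho <- apply(cm, 2, function(y)
    suppressWarnings(cor(y, tt, method = "spearman")))
  # null |rho| for n = 100: E|rho| ~ 0.080, sd|rho| ~ 0.061; the mean over
  # 50 independent genes stays below E + 3 * sd / sqrt(50)
  n <- length(tt)
  sdRho <- 1 / sqrt(n - 1)
  bound <- sdRho * sqrt(2 / pi) + 3 * sdRho * sqrt(1 - 2 / pi) / sqrt(50)
  expect_lt(mean(abs(rho), na.rm = TRUE), bound)
  # per-gene sample means are flat across time bins (zero-DE case)
  bins <- cut(tt, breaks = quantile(tt, 0:4 / 4), include.lowest = TRUE)
  mu <- SummarizedExperiment::assay(sce, "mu")
  binRange <- apply(mu, 1, function(m) diff(range(tapply(m, bins, mean))))
  expect_true(all(binRange < 1e-10))
})

test_that("zero inflation thins counts at the modeled logistic rate", {
  sce <- simulateLineage(200, 100, propDE = 0.3, dispersion = "medium",
                         seed = 5)
  base <- SummarizedExperiment::assay(sce, "counts")

  # no-dropout and all-dropout limits
  z1 <- simulateZeroInflation(sce, alpha0 = 20, alpha1 = 0, seed = 1)
  expect_identical(SummarizedExperiment::assay(z1, "counts"), base)
  z0 <- simulateZeroInflation(sce, alpha0 = -20, alpha1 = 0, seed = 1)
  expect_true(all(SummarizedExperiment::assay(z0, "counts") == 0))

  # alpha0 = 0, alpha1 = 0: keep rate 1/2 within 3 binomial s.e.
  zh <- simulateZeroInflation(sce, alpha0 = 0, alpha1 = 0, seed = 1)
  kept <- SummarizedExperiment::assay(zh, "kept")
  se <- sqrt(0.25 / length(kept))
  expect_lt(abs(mean(kept) - 0.5), 3 * se)

  # mu-dependent dropout: empirical keep rate tracks logistic(a0+a1 log mu)
  # within 4 binomial s.e. in every mu decile
  zz <- simulateZeroInflation(sce, alpha0 = 0.5, alpha1 = 0.3, seed = 2)
  kept <- SummarizedExperiment::assay(zz, "kept")
  mu <- SummarizedExperiment::assay(zz, "mu")
  dec <- cut(log(mu), quantile(log(mu), 0:10 / 10), include.lowest = TRUE)
  for (d in levels(dec)) {
    sel <- dec == d
    pbar <- mean(plogis(0.5 + 0.3 * log(mu[sel])))
    se <- sqrt(pbar * (1 - pbar) / sum(sel))
    expect_lt(abs(mean(kept[sel]) - pbar), 4 * se)
  }
})

test_that("shuffling null genes preserves each gene's count multiset", {
  x <- tinyLineage()
  m <- x$counts
  m[, "g0001"] <- 5L  # constant column: shuffling is a no-op
  sh <- shuffleNullGenes(m, c("g0001", "g0002", "g0003"), seed = 2)
  expect_identical(unname(sh[, "g0001"]), unname(m[, "g0001"]))
  expect_identical(sort(unname(sh[, "g0002"])), sort(unname(m[, "g0002"])))
  expect_false(identical(unname(sh[, "g0002"]), unname(m[, "g0002"])))
  expect_identical(sh[, "g0004"], m[, "g0004"])
  expect_error(shuffleNullGenes(m, "nope", seed = 1), "unknown gene")

  # the SingleCellExperiment method agrees with the matrix method
  shSce <- shuffleNullGenes(x$sce, c("g0002"), seed = 2)
  expect_identical(
    sort(unname(SummarizedExperiment::assay(shSce, "counts")["g0002", ])),
    sort(unname(m[, "g0002"])))
})

test_that("shuffling a strong DE gene destroys its pseudotime signal", {
  x <- tinyLineage()
  basis <- buildSplineBasis(x$tt)
  # pick the strongest DE gene by observed statistic
  deIdx <- which(x$isDE)
  stats <- vapply(deIdx[1:10], function(j)
    fitNBGAM(x$counts[, j], x$tt, basis = basis)@statistic, 0)
  g <- deIdx[which.max(stats)]
  ps <- vapply(1:100, function(r) {
    ysh <- shuffleNullGenes(x$counts[, g, drop = FALSE], colnames(x$counts)[g],
                            seed = r)[, 1]
    asymptoticPvalue(fitNBGAM(ysh, x$tt, basis = basis))
  }, 0)
  expect_gte(mean(ps > 0.01), 0.95)
})

test_that("simulated datasets round-trip through plain-text files", {
  sce <- simulateLineage(30, 15, propDE = 0.2, seed = 2)
  dir <- tempfile("simio")
  writeSimulatedDataset(sce, dir)
  back <- readSimulatedDataset(dir)
  expect_identical(as.matrix(SummarizedExperiment::assay(back, "counts")),
                   as.matrix(SummarizedExperiment::assay(sce, "counts")))
  expect_equal(SummarizedExperiment::colData(back)$true_time,
               SummarizedExperiment::colData(sce)$true_time)
  expect_identical(SummarizedExperiment::rowData(back)$is_de,
                   SummarizedExperiment::rowData(sce)$is_de)
  unlink(dir, recursive = TRUE)
})
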