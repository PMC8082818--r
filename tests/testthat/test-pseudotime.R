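test_that("pseudotime normalization is an order-preserving affine map", {
  expect_equal(normalizePseudotime(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalizePseudotime(c(5, 1, 3)), c(1, 0, 0.5))
  x <- c(0, 0.25, 0.8, 1)
  expect_equal(normalizePseudotime(x), x)  # idempotent on [0,1] input
  expect_error(normalizePseudotime(rep(2, 5)), "degenerate")
  expect_error(normalizePseudotime(1), "at least 2")
  expect_error(normalizePseudotime(c(1, NA, 3)), "missing")
})

test_that("subsamples have exact floor sizes with distinct indices", {
  idx <- drawSubsamples(500, fraction = 0.8, B = 20, seed = 1)
  expect_length(idx, 20)
  expect_true(all(vapply(idx, length, 0L) == 400))
  idx2 <- drawSubsamples(10, fraction = 0.8, B = 3, seed = 1)
  expect_true(all(vapply(idx2, function(i) length(unique(i)), 0L) == 8))
  expect_equal(length(drawSubsamples(390, 0.8, B = 1, seed = 1)[[1]]),
               312)  # floor(0.8 * 390)
  expect_error(drawSubsamples(100, fraction = 1.2, B = 2), "fraction")
  # reproducible from the seed, different across seeds
  expect_identical(drawSubsamples(50, B = 5, seed = 9),
                   drawSubsamples(50, B = 5, seed = 9))
  expect_false(identical(drawSubsamples(50, B = 5, seed = 9),
                         drawSubsamples(50, B = 5, seed = 10)))
})

test_that("stratified subsampling takes floor(fraction * size) per group", {
  groups <- rep(c("a", "b", "c"), c(50, 30, 20))
  idx <- drawSubsamples(100, fraction = 0.8, B = 10, groups = groups,
                        seed = 4)
  for (i in idx) {
    expect_length(i, 80)
    tabs <- table(groups[i])
    # per-group floor(0.8 * g), with the single-cell shortfall filled from
    # the remaining pool (so counts may exceed the floor by the fill)
    expect_gte(tabs[["a"]], 40); expect_gte(tabs[["b"]], 24)
    expect_gte(tabs[["c"]], 16)
  }
})

test_that("principal-component pseudotime recovers monotone structure", {
  # half the genes rise strictly along true time, half stay flat, so the
  # compositional profile changes monotonically cell by cell
  n <- 50
  tt <- seq(0, 1, length.out = n)
  up <- outer(exp(3 * tt), 10 * (1:10))
  flat <- matrix(50, n, 10)
  m <- round(cbind(up, flat))
  pt <- builtinPseudotime(m)
  expect_equal(abs(cor(pt, tt, method = "spearman")), 1)

  # equivariance: permuting cells permutes the output identically
  perm <- sample(n)
  m2 <- m; rownames(m2) <- paste0("cell", seq_len(n))
  expect_equal(unname(builtinPseudotime(m2[perm, ])),
               unname(builtinPseudotime(m2)[perm]))

  expect_error(builtinPseudotime(matrix(0L, 5, 5)), "zero total")
})

test_that("principal-component pseudotime tracks simulated latent time", {
  sce <- simulateLineage(200, 200, propDE = 0.5, dispersion = "medium",
                         seed = 21)
  m <- t(as.matrix(SummarizedExperiment::assay(sce, "counts")))
  tt <- SummarizedExperiment::colData(sce)$true_time
  expect_gte(abs(cor(builtinPseudotime(m), tt, method = "spearman")), 0.8)
})

test_that("subsample re-inference records failures and keeps the rest", {
  x <- tinyLineage()
  idx <- drawSubsamples(nrow(x$counts), B = 5, seed = 2)

  # oracle method returning the latent time: perfect per-subsample ordering
  tt <- setNames(x$tt, rownames(x$counts))
  oracle <- function(sub) tt[rownames(sub)]
  draws <- inferSubsamplePseudotime(x$counts, idx, oracle, original = tt,
                                    minSubsamples = 3, seed = 2)
  expect_length(usableSubsamples(draws), 5)
  for (b in 1:5) {
    rec <- draws@subsamples[[b]]
    expect_equal(abs(cor(rec$inferred, tt[names(rec$inferred)],
                         method = "spearman")), 1)
  }

  # a method that raises on the third subsample: B' = 4, one failed record
  counter <- 0
  flaky <- function(sub) {
    counter <<- counter + 1
    if (counter == 3) stop("boom")
    tt[rownames(sub)]
  }
  draws2 <- inferSubsamplePseudotime(x$counts, idx, flaky, original = tt,
                                     minSubsamples = 3, seed = 2)
  expect_length(usableSubsamples(draws2), 4)
  expect_equal(draws2@subsamples[[3]]$status, "failed")

  # too many failures aborts
  expect_error(
    inferSubsamplePseudotime(x$counts, idx, function(sub) stop("no"),
                             original = tt, minSubsamples = 3, seed = 2),
    "uncertainty estimation failed")

  # built-in method on a strong simulation: median subsample accuracy high
  sce <- simulateLineage(200, 200, propDE = 0.5, dispersion = "medium",
                         seed = 13)
  m <- t(as.matrix(SummarizedExperiment::assay(sce, "counts")))
  tts <- SummarizedExperiment::colData(sce)$true_time
  names(tts) <- rownames(m)
  idx3 <- drawSubsamples(200, B = 20, seed = 13)
  dr3 <- inferSubsamplePseudotime(m, idx3, builtinPseudotime,
                                  minSubsamples = 10, seed = 13)
  rho <- vapply(usableSubsamples(dr3), function(b) {
    rec <- dr3@subsamples[[b]]
    abs(cor(rec$inferred, tts[names(rec$inferred)], method = "spearman"))
  }, 0)
  expect_gte(median(rho), 0.8)
})

test_that("permutation preserves multisets and is uniform over orderings", {
  draws <- handDraws(n = 10, B = 3)
  pd <- permutePseudotime(draws, seed = 8)
  for (b in 1:3) {
    rec <- pd@subsamples[[b]]
    expect_equal(sort(unname(rec$permuted)), sort(unname(rec$inferred)))
  }
  # length-1 vector is unchanged
  one <- new("PseudotimeDraws", original = c(a = 0, b = 1),
             subsamples = list(list(indices = 1L, inferred = c(a = 0.3),
                                    permuted = NULL, status = "ok")),
             fraction = 0.6, n = 2L, seed = 1L)
  p1 <- permutePseudotime(one, seed = 1)
  expect_equal(p1@subsamples[[1]]$permuted, p1@subsamples[[1]]$inferred)

  # over 1000 independent permutations of 4 values, all 24 orderings occur
  # at frequency 1/24 (chi-square GOF at alpha = 0.001, plus a max-deviation
  # guard at 4 s.e.)
  d4 <- handDraws(n = 5, B = 1000, fraction = 0.8)
  p4 <- permutePseudotime(d4, seed = 3)
  codes <- vapply(p4@subsamples, function(r)
    paste(rank(unname(r$permuted)), collapse = ""), "")
  tab <- table(codes)
  expect_length(tab, 24)
  expect_gt(chisq.test(as.numeric(tab), p = rep(1 / 24, 24))$p.value, 0.001)
  se <- sqrt((1 / 24) * (23 / 24) / 1000)
  expect_lt(max(abs(as.numeric(tab) / 1000 - 1 / 24)), 4 * se)

  # permutations differ across subsamples (independence smoke check)
  expect_gt(length(unique(codes[1:50])), 10)
})

test_that("uncertainty summaries orient subsamples and count coverage", {
  # oracle inference: per-cell sd is exactly zero
  n <- 40
  orig <- setNames(normalizePseudotime(seq_len(n)), paste0("cell", seq_len(n)))
  draws <- handDraws(n = n, B = 30, original = orig)
  draws <- permutePseudotime(draws, seed = 2)
  us <- uncertaintySummary(draws)
  expect_true(all(us$sd[us$n_subsamples > 1] < 1e-12))

  # each cell appears in about fraction * B subsamples
  B <- 30
  se <- sqrt(B * 0.8 * 0.2)
  expect_true(all(abs(us$n_subsamples - 0.8 * B) <= 5 * se))

  # a direction-reversed subsample is flipped before aggregation
  rev1 <- draws
  rec <- rev1@subsamples[[1]]
  rec$inferred <- 1 - rec$inferred
  rev1@subsamples[[1]] <- rec
  us2 <- uncertaintySummary(rev1)
  expect_true(all(us2$sd[us2$n_subsamples > 1] < 1e-8))
})
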