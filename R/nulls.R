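#' Null statistics for one gene from permuted subsamples
#'
#' For every usable subsample, restricts the gene's counts to the
#' subsample's cells, rebuilds the spline basis on the permuted pseudotime,
#' fits the same model configuration used for the observed statistic, and
#' records the test statistic. Subsamples where the gene is all-zero or the
#' fit fails are dropped (decrementing the usable count B').
#'
#' @param y the gene's counts over all cells (named or aligned with the
#'   draws' cells).
#' @param draws a permuted [PseudotimeDraws-class].
#' @param flavor model flavor used for the observed statistic ("NB" or
#'   "ZINB").
#' @param K,criterion,maxit,tol fitting configuration; must equal the
#'   observed fit's configuration (the exchangeability contract).
#' @param minNull minimum number of usable null values; fewer raises an
#'   error and the gene should be reported with missing p-values.
#' @return numeric vector of null statistics with attribute "nDropped".
#' @export
nullStatistics <- function(y, draws, flavor = c("NB", "ZINB"), K = 6,
                           criterion = c("REML", "GCV"), maxit = 50,
                           tol = 1e-8, minNull = 50) {
  flavor <- match.arg(flavor)
  criterion <- match.arg(criterion)
  if (length(y) != draws@n) stop("y length does not match draws")
  ok <- usableSubsamples(draws)
  if (!length(ok)) stop("draws contain no usable subsamples")
  if (is.null(draws@subsamples[[ok[1]]]$permuted))
    stop("draws are not permuted; call permutePseudotime() first")
  out <- vapply(ok, function(b) {
    rec <- draws@subsamples[[b]]
    yb <- y[rec$indices]
    if (all(yb == 0)) return(NA_real_)
    tryCatch({
      basis <- buildSplineBasis(unname(rec$permuted), K = K)
      fit <- if (flavor == "ZINB")
        fitZINBGAM(yb, unname(rec$permuted), basis = basis,
                   criterion = criterion, maxit = maxit, tol = tol)
      else
        fitNBGAM(yb, unname(rec$permuted), basis = basis,
                 criterion = criterion, maxit = maxit, tol = tol)
      fit@statistic
    }, error = function(e) NA_real_)
  }, 0)
  vals <- out[!is.na(out)]
  if (length(vals) < min(minNull, length(ok)))
    stop(sprintf("only %d usable null statistics (minimum %d)",
                 length(vals), minNull))
  attr(vals, "nDropped") <- sum(is.na(out))
  vals
}

# Batched null statistics for the pipeline: one basis per subsample reused
# across all NB-flavored genes (C++ loop); ZINB genes fitted one at a time.
# Returns a B_ok x m matrix (NA where a fit was dropped). Identical code
# path per fit to nullStatistics(), so results match exactly.
.nullStatsMatrix <- function(counts, draws, flavors, K, criterion, maxit,
                             tol, workers = 1L) {
  ok <- usableSubsamples(draws)
  m <- ncol(counts)
  isNB <- flavors == "NB"
  oneSub <- function(b) {
    rec <- draws@subsamples[[b]]
    pt <- unname(rec$permuted)
    row <- rep(NA_real_, m)
    basis <- tryCatch(buildSplineBasis(pt, K = K), error = function(e) NULL)
    if (is.null(basis)) return(row)
    Y <- counts[rec$indices, , drop = FALSE]
    Z <- cbind(1, basis@design)
    q <- ncol(Z)
    Sfull <- matrix(0, q, q)
    Sfull[-1, -1] <- basis@penalty
    if (any(isNB)) {
      st <- .nbgam_stats_cpp(Y[, isNB, drop = FALSE], Z, Sfull,
                             as.integer(maxit), tol,
                             if (criterion == "GCV") 1L else 0L)
      row[isNB] <- st$statistic
    }
    for (j in which(!isNB)) {
      yb <- Y[, j]
      if (all(yb == 0)) next
      row[j] <- tryCatch(
        fitZINBGAM(yb, pt, basis = basis, criterion = criterion,
                   maxit = maxit, tol = tol)@statistic,
        error = function(e) NA_real_)
    }
    row
  }
  rows <- if (workers > 1L)
    parallel::mclapply(ok, oneSub, mc.cores = workers)
  else lapply(ok, oneSub)
  mat <- do.call(rbind, rows)
  colnames(mat) <- colnames(counts)
  mat
}

#' Permutation (empirical) p-value
#'
#' \eqn{p = (\#\{b: s^b \ge s\} + 1) / (B' + 1)}; ties count as exceeding,
#' and the add-one correction makes the smallest attainable value
#' \eqn{1/(B'+1)}, the resolution floor of the permutation test.
#'
#' @param s observed statistic.
#' @param nulls vector of null statistics.
#' @return p-value in (0, 1].
#' @examples
#' empiricalPvalue(5, c(1, 2, 3, 4))  # 0.2
#' @export
empiricalPvalue <- function(s, nulls) {
  if (!length(nulls)) stop("empty null sample")
  if (is.na(s)) return(NA_real_)
  (sum(nulls >= s) + 1) / (length(nulls) + 1)
}

#' Fit a parametric null distribution to permutation statistics
#'
#' Fits (1) a gamma distribution by maximum likelihood (via
#' \pkg{fitdistrplus}) and (2) a two-component gamma mixture by EM with
#' five restarts, then chooses between them with a likelihood ratio test on
#' 3 degrees of freedom: the mixture is used when the LRT p-value is at or
#' below `lrtAlpha` (default 0.01). An Anderson-Darling goodness-of-fit
#' p-value of the chosen distribution is recorded as a diagnostic (never
#' used to reject a gene). Exact zeros (degenerate fits) are excluded from
#' the parametric fit but belong in the empirical p-value; if more than 10
#' percent of the null values are zero, or fewer than `minNull` positive
#' values remain, the gene falls back to `empirical_only`.
#'
#' @param nulls null statistic values.
#' @param lrtAlpha LRT level for choosing the mixture.
#' @param minNull minimum positive null values for a parametric fit.
#' @return a [NullFit-class] object.
#' @export
fitParametricNull <- function(nulls, lrtAlpha = 0.01, minNull = 50) {
  nulls <- nulls[!is.na(nulls)]
  if (any(nulls < 0)) stop("null statistics must be non-negative")
  nz <- sum(nulls == 0)
  x <- nulls[nulls > 0]
  emptyFit <- function() new("NullFit", nullValues = nulls,
    gammaPars = c(shape = NA_real_, rate = NA_real_),
    mixturePars = c(gamma = NA_real_, shape1 = NA_real_, rate1 = NA_real_,
                    shape2 = NA_real_, rate2 = NA_real_),
    loglikGamma = NA_real_, loglikMixture = NA_real_, lrtStat = NA_real_,
    lrtP = NA_real_, chosen = "empirical_only", gofP = NA_real_,
    nZeroDropped = nz)
  if (length(x) < minNull || nz > 0.1 * length(nulls)) return(emptyFit())
  gfit <- tryCatch(
    fitdistrplus::fitdist(x, "gamma", method = "mle", keepdata = FALSE),
    error = function(e) NULL)
  if (is.null(gfit) || anyNA(gfit$estimate)) return(emptyFit())
  gpars <- c(shape = unname(gfit$estimate["shape"]),
             rate = unname(gfit$estimate["rate"]))
  llg <- sum(dgamma(x, gpars[1], gpars[2], log = TRUE))
  mix <- .gammaMixEM(x, gpars)
  if (is.null(mix)) {
    warning("gamma mixture EM failed; falling back to single gamma")
    return(new("NullFit", nullValues = nulls, gammaPars = gpars,
               mixturePars = c(gamma = NA_real_, shape1 = NA_real_,
                               rate1 = NA_real_, shape2 = NA_real_,
                               rate2 = NA_real_),
               loglikGamma = llg, loglikMixture = llg, lrtStat = 0,
               lrtP = 1, chosen = "gamma",
               gofP = .adTestP(x, function(q) pgamma(q, gpars[1], gpars[2])),
               nZeroDropped = nz))
  }
  lrt <- max(0, 2 * (mix$loglik - llg))
  lrtP <- pchisq(lrt, df = 3, lower.tail = FALSE)
  chosen <- if (lrtP <= lrtAlpha) "mixture" else "gamma"
  cdf <- if (chosen == "mixture")
    function(q) mix$pars["gamma"] * pgamma(q, mix$pars["shape1"],
                                           mix$pars["rate1"]) +
      (1 - mix$pars["gamma"]) * pgamma(q, mix$pars["shape2"],
                                       mix$pars["rate2"])
  else function(q) pgamma(q, gpars[1], gpars[2])
  new("NullFit", nullValues = nulls, gammaPars = gpars,
      mixturePars = mix$pars, loglikGamma = llg,
      loglikMixture = max(mix$loglik, llg), lrtStat = lrt, lrtP = lrtP,
      chosen = chosen, gofP = .adTestP(x, cdf), nZeroDropped = nz)
}

# Two-component gamma mixture MLE by EM with restarts. Initializations:
# a median split, an upper-quantile split, a split of the single-gamma fit
# (which starts the EM exactly at the nested model, guaranteeing the
# mixture log-likelihood is never below the gamma one), and two random
# responsibility draws. gamma (the mixing weight) is clipped to
# [0.01, 0.99] to guard against component collapse.
.gammaMixEM <- function(x, gpars, tol = 1e-8, maxit = 150, restarts = 5) {
  n <- length(x)
  logx <- log(x)
  # the random restarts use a private, fixed RNG stream
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  }
  momFit <- function(xx) {
    m <- mean(xx); v <- var(xx)
    if (!is.finite(v) || v <= 0) v <- m^2
    c(shape = m^2 / v, rate = m / v)
  }
  inits <- list()
  med <- stats::median(x)
  inits[[1]] <- list(g = 0.5, p1 = momFit(x[x <= med]),
                     p2 = momFit(x[x > med]))
  q8 <- quantile(x, 0.8, names = FALSE)
  inits[[2]] <- list(g = 0.8, p1 = momFit(x[x <= q8]),
                     p2 = momFit(x[x > q8]))
  inits[[3]] <- list(g = 0.5,
                     p1 = c(shape = gpars[[1]], rate = gpars[[2]]),
                     p2 = c(shape = gpars[[1]], rate = gpars[[2]]))
  for (r in 4:restarts) {
    set.seed(1000 + r)
    w0 <- runif(n)
    inits[[r]] <- list(g = mean(w0),
                       p1 = momFit(sample(x, max(10, n %/% 2))),
                       p2 = momFit(sample(x, max(10, n %/% 2))))
  }
  wmle <- function(xx, w) {
    sw <- sum(w)
    m <- sum(w * xx) / sw
    lbar <- sum(w * logx) / sw
    d <- log(m) - lbar
    if (d <= 0) return(c(shape = 500, rate = 500 / m))
    a <- (3 - d + sqrt((d - 3)^2 + 24 * d)) / (12 * d) # moment start
    for (i in 1:15) {
      g <- log(a) - digamma(a) - d
      h <- 1 / a - trigamma(a)
      step <- g / h
      aNew <- a - step
      if (!is.finite(aNew) || aNew <= 0) aNew <- a / 2
      if (abs(aNew - a) < 1e-10 * a) { a <- aNew; break }
      a <- aNew
    }
    a <- min(max(a, 1e-3), 1e5)
    c(shape = a, rate = a / m)
  }
  best <- NULL
  for (ini in inits) {
    g <- min(max(ini$g, 0.01), 0.99)
    p1 <- ini$p1; p2 <- ini$p2
    if (anyNA(c(p1, p2)) || any(c(p1, p2) <= 0)) next
    ll <- -Inf
    ok <- TRUE
    for (it in seq_len(maxit)) {
      # gamma densities with the log(x) term cached (hot loop)
      d1 <- exp(p1[1] * log(p1[2]) - lgamma(p1[1]) + (p1[1] - 1) * logx -
                p1[2] * x)
      d2 <- exp(p2[1] * log(p2[2]) - lgamma(p2[1]) + (p2[1] - 1) * logx -
                p2[2] * x)
      den <- g * d1 + (1 - g) * d2
      if (any(!is.finite(den)) || any(den <= 0)) { ok <- FALSE; break }
      llNew <- sum(log(den))
      if (abs(llNew - ll) < tol * (abs(llNew) + 0.1)) { ll <- llNew; break }
      ll <- llNew
      w <- g * d1 / den
      g <- min(max(mean(w), 0.01), 0.99)
      p1 <- wmle(x, w)
      p2 <- wmle(x, 1 - w)
    }
    if (ok)  # evaluate at the final parameters (M-steps only increase ll)
      ll <- sum(log(g * dgamma(x, p1[1], p1[2]) +
                    (1 - g) * dgamma(x, p2[1], p2[2])))
    if (ok && is.finite(ll) && (is.null(best) || ll > best$loglik))
      best <- list(loglik = ll,
                   pars = c(gamma = unname(g), shape1 = unname(p1[1]),
                            rate1 = unname(p1[2]), shape2 = unname(p2[1]),
                            rate2 = unname(p2[2])))
  }
  best
}

# Anderson-Darling goodness-of-fit p-value against a fitted CDF (classical
# asymptotic approximation; logged diagnostic only, parameters are treated
# as known).
.adTestP <- function(x, cdf) {
  n <- length(x)
  u <- sort(pmin(pmax(cdf(sort(x)), 1e-12), 1 - 1e-12))
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
  if (!is.finite(A2)) return(NA_real_)
  z <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  if (z < 0.2) 1 - exp(-13.436 + 101.14 * z - 223.73 * z^2)
  else if (z < 0.34) 1 - exp(-8.318 + 42.796 * z - 59.938 * z^2)
  else if (z < 0.6) exp(0.9177 - 4.279 * z - 1.38 * z^2)
  else min(1, exp(1.2937 - 5.709 * z + 0.0186 * z^2))
}

#' Parametric p-value from a fitted null distribution
#'
#' \eqn{p = 1 - \hat F(s)} with \eqn{\hat F} the chosen null CDF (gamma or
#' gamma mixture), floored at 1e-300 to avoid exact zeros. Parametric
#' p-values refine the empirical resolution floor of 1/(B'+1).
#'
#' @param s observed statistic.
#' @param nf a [NullFit-class] with `chosen` "gamma" or "mixture".
#' @return p-value in (0, 1].
#' @export
parametricPvalue <- function(s, nf) {
  if (nf@chosen == "empirical_only")
    stop(structure(class = c("ptDE_empirical_only", "error", "condition"),
                   list(message = "no parametric null; report p_emp only",
                        call = sys.call(-1))))
  if (is.na(s)) return(NA_real_)
  p <- if (nf@chosen == "gamma") {
    pgamma(s, nf@gammaPars["shape"], nf@gammaPars["rate"],
           lower.tail = FALSE)
  } else {
    mp <- nf@mixturePars
    mp[["gamma"]] * pgamma(s, mp[["shape1"]], mp[["rate1"]],
                           lower.tail = FALSE) +
      (1 - mp[["gamma"]]) * pgamma(s, mp[["shape2"]], mp[["rate2"]],
                                   lower.tail = FALSE)
  }
  unname(min(max(p, 1e-300), 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values capped at 1; missing p-values are excluded
#' from the multiplicity count and propagated as missing.
#'
#' @param pvals raw p-values in (0, 1] (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(pvals) p.adjust(pvals, method = "BH")
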