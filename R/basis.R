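#' Build the spline basis for a smooth of pseudotime
#'
#' Constructs a cubic B-spline basis with a second-derivative roughness
#' penalty, interior knots at quantiles of the observed pseudotime, and the
#' sum-to-zero (centering) constraint over the observed cells absorbed into
#' the basis, making the smooth identifiable next to an intercept. The
#' default basis dimension is K = 6 spline coefficients; within the knot
#' range the basis reproduces any cubic polynomial exactly.
#'
#' If the pseudotime has fewer than K distinct values, K is reduced with a
#' warning (minimum 3); fewer than 3 distinct values is an error.
#'
#' @param ptime numeric vector of pseudotime values in [0, 1].
#' @param K basis dimension (number of spline coefficients before the
#'   constraint is absorbed); default 6.
#' @return a [SplineBasis-class] object.
#' @examples
#' b <- buildSplineBasis(seq(0, 1, length.out = 50))
#' colMeans(b@design)  # ~ 0: constraint absorbed
#' @export
buildSplineBasis <- function(ptime, K = 6) {
  K <- .assertCount(K, "K", min = 3L)
  if (anyNA(ptime)) stop("pseudotime contains missing values")
  ux <- sort(unique(ptime))
  if (length(ux) < 3)
    stop("degenerate basis: fewer than 3 distinct pseudotime values")
  if (length(ux) < K) {
    warning(sprintf("only %d distinct pseudotime values; reducing K from %d",
                    length(ux), K))
    K <- max(3L, length(ux))
  }
  # interior knots at quantiles; a cubic B-spline with K coefficients needs
  # K - 2 within-range knots plus 3 exterior knots on each side
  repeat {
    inner <- as.numeric(quantile(ux, seq(0, 1, length.out = K - 2),
                                 names = FALSE, type = 7))
    if (!anyDuplicated(inner)) break
    K <- K - 1L
    if (K < 3L) stop("degenerate basis: duplicated quantile knots")
    warning("duplicated quantile knots; reducing K to ", K)
  }
  dlo <- inner[2] - inner[1]
  dhi <- inner[length(inner)] - inner[length(inner) - 1]
  knots <- c(inner[1] - (3:1) * dlo, inner,
             inner[length(inner)] + (1:3) * dhi)
  dat <- data.frame(t = as.numeric(ptime))
  sm <- mgcv::smoothCon(mgcv::s(t, k = K, bs = "bs", m = c(3, 2)),
                        data = dat, knots = list(t = knots),
                        absorb.cons = TRUE)[[1]]
  new("SplineBasis", design = sm$X, penalty = sm$S[[1]], knots = knots,
      K = K, ptime = as.numeric(ptime), smooth = sm)
}

# Evaluate an existing basis at new pseudotime values (same constraint).
.evalBasis <- function(basis, ptime) {
  mgcv::PredictMat(basis@smooth, data = data.frame(t = as.numeric(ptime)))
}
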