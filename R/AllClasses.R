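#' Spline basis for a smooth of pseudotime
#'
#' Cubic B-spline basis (second-derivative roughness penalty) with interior
#' knots at pseudotime quantiles and the sum-to-zero constraint over the
#' observed cells absorbed, so the smooth is identifiable next to an
#' intercept. Built by [buildSplineBasis()].
#'
#' @slot design centered n x p basis evaluation matrix (column sums zero).
#' @slot penalty p x p positive semidefinite roughness penalty.
#' @slot knots full knot sequence on the pseudotime axis.
#' @slot K requested basis dimension (number of spline coefficients before
#'   the centering constraint is absorbed).
#' @slot ptime the pseudotime values the basis was evaluated at.
#' @slot smooth the underlying \pkg{mgcv} smooth object, kept so the basis
#'   can be re-evaluated at new pseudotime values.
#' @export
setClass("SplineBasis",
  representation(design = "matrix", penalty = "matrix", knots = "numeric",
                 K = "integer", ptime = "numeric", smooth = "ANY"))

setValidity("SplineBasis", function(object) {
  msg <- NULL
  if (ncol(object@design) != nrow(object@penalty))
    msg <- c(msg, "design and penalty dimensions disagree")
  if (ncol(object@design) < 2)
    msg <- c(msg, "basis must have at least 2 columns")
  if (max(abs(colMeans(object@design))) > 1e-8)
    msg <- c(msg, "design is not centered")
  if (max(abs(object@penalty - t(object@penalty))) > 1e-8)
    msg <- c(msg, "penalty is not symmetric")
  if (is.null(msg)) TRUE else msg
})

#' One gene's fitted pseudotime GAM
#'
#' A negative-binomial (or zero-inflated negative-binomial) generalized
#' additive model of one gene's counts on pseudotime, as returned by
#' [fitNBGAM()] / [fitZINBGAM()]. The smooth is
#' \eqn{f(T_i) = \sum_k b_k(T_i)\beta_k} with a cubic spline basis; the NB
#' mean is \eqn{\log\mu_i = \beta_0 + f(T_i)} and, for the zero-inflated
#' flavor, counts are observed with probability \eqn{p_i} where
#' \eqn{\mathrm{logit}(p_i) = \alpha_0 + \alpha_1\log\mu_i} (otherwise zero).
#'
#' @slot flavor "NB" or "ZINB".
#' @slot beta0 intercept.
#' @slot beta spline coefficients.
#' @slot phi NB size (dispersion) parameter; variance is
#'   \eqn{\mu + \mu^2/\phi}.
#' @slot alpha0,alpha1 zero-inflation coefficients (NA for plain NB).
#' @slot fhat fitted centered smooth at the observed pseudotime.
#' @slot Vbs Bayesian covariance of the spline coefficients (the full
#'   covariance of \code{fhat} is \code{design \%*\% Vbs \%*\% t(design)}).
#' @slot basis the [SplineBasis-class] used.
#' @slot rank rank used in the test-statistic pseudoinverse.
#' @slot statistic observed quadratic-form test statistic.
#' @slot edf,edf1 effective degrees of freedom of the smooth (and the
#'   upper-bound variant used as reference df for the asymptotic test).
#' @slot loglik,aic maximized log-likelihood and AIC (parameter count is
#'   total edf + 1 for the dispersion, + 2 more for the ZINB alphas).
#' @slot lambda smoothing parameter.
#' @slot converged convergence flag.
#' @slot n number of cells fitted.
#' @slot pzero fitted observation probabilities (ZINB only).
#' @slot emTrace penalized observed-data log-likelihood per EM iteration
#'   (ZINB only).
#' @slot notes character vector of fitting notes/warnings.
#' @export
setClass("GAMFit",
  representation(flavor = "character", beta0 = "numeric", beta = "numeric",
                 phi = "numeric", alpha0 = "numeric", alpha1 = "numeric",
                 fhat = "numeric", Vbs = "matrix", basis = "SplineBasis",
                 rank = "integer", statistic = "numeric", edf = "numeric",
                 edf1 = "numeric", loglik = "numeric", aic = "numeric",
                 lambda = "numeric", converged = "logical", n = "integer",
                 pzero = "numeric", emTrace = "numeric", notes = "character"))

setValidity("GAMFit", function(object) {
  msg <- NULL
  if (!object@flavor %in% c("NB", "ZINB"))
    msg <- c(msg, "flavor must be 'NB' or 'ZINB'")
  if (!is.na(object@phi) && object@phi <= 0)
    msg <- c(msg, "phi must be positive")
  if (length(object@fhat) &&
      abs(mean(object@fhat)) > 1e-6 * (max(abs(object@fhat)) + 1e-8))
    msg <- c(msg, "fhat is not centered")
  if (is.null(msg)) TRUE else msg
})

#' Pseudotime draws across cell subsamples
#'
#' The original normalized pseudotime plus, for each of B subsamples of
#' \eqn{\lfloor fraction \cdot n \rfloor} cells, the pseudotime re-inferred
#' on that subsample and a permuted copy of it. Produced by
#' [inferSubsamplePseudotime()] and [permutePseudotime()].
#'
#' @slot original named numeric, the full-data pseudotime in [0, 1].
#' @slot subsamples list of records with elements \code{indices} (cell
#'   indices), \code{inferred} (normalized pseudotime over those cells),
#'   \code{permuted} (a permutation of \code{inferred}) and \code{status}
#'   ("ok" or "failed").
#' @slot fraction subsampling fraction.
#' @slot n number of cells in the full data.
#' @slot seed master seed the index sets were drawn from.
#' @export
setClass("PseudotimeDraws",
  representation(original = "numeric", subsamples = "list",
                 fraction = "numeric", n = "integer", seed = "integer"))

setValidity("PseudotimeDraws", function(object) {
  msg <- NULL
  size <- floor(object@fraction * object@n)
  for (rec in object@subsamples) {
    if (!is.list(rec) || is.null(rec$indices) || is.null(rec$status)) {
      msg <- c(msg, "malformed subsample record"); break
    }
    if (anyDuplicated(rec$indices)) {
      msg <- c(msg, "duplicated indices within a subsample"); break
    }
    if (length(rec$indices) != size) {
      msg <- c(msg, "subsample size != floor(fraction * n)"); break
    }
    if (rec$status == "ok" && !is.null(rec$permuted) &&
        !isTRUE(all.equal(sort(unname(rec$permuted)),
                          sort(unname(rec$inferred))))) {
      msg <- c(msg, "permuted pseudotime is not a rearrangement"); break
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Null-distribution fit for one gene's test statistic
#'
#' The permutation null sample of the test statistic together with its
#' parametric summaries: a gamma MLE, a two-component gamma mixture MLE,
#' the 3-df likelihood ratio test between them, the selected null CDF and
#' an Anderson-Darling goodness-of-fit diagnostic. See
#' [fitParametricNull()].
#'
#' @slot nullValues null statistic values (one per usable subsample).
#' @slot gammaPars named (shape, rate).
#' @slot mixturePars named (gamma, shape1, rate1, shape2, rate2).
#' @slot loglikGamma,loglikMixture maximized log-likelihoods.
#' @slot lrtStat,lrtP likelihood ratio statistic and its chi-square(3) p.
#' @slot chosen "gamma", "mixture" or "empirical_only".
#' @slot gofP Anderson-Darling goodness-of-fit p-value of the chosen CDF.
#' @slot nZeroDropped exact zeros excluded from the parametric fit.
#' @export
setClass("NullFit",
  representation(nullValues = "numeric", gammaPars = "numeric",
                 mixturePars = "numeric", loglikGamma = "numeric",
                 loglikMixture = "numeric", lrtStat = "numeric",
                 lrtP = "numeric", chosen = "character", gofP = "numeric",
                 nZeroDropped = "integer"))

setValidity("NullFit", function(object) {
  msg <- NULL
  if (any(object@nullValues < 0)) msg <- c(msg, "null values must be >= 0")
  if (!object@chosen %in% c("gamma", "mixture", "empirical_only"))
    msg <- c(msg, "invalid 'chosen'")
  if (object@chosen != "empirical_only" &&
      object@loglikMixture < object@loglikGamma - 1e-6)
    msg <- c(msg, "mixture log-likelihood below nested gamma log-likelihood")
  if (is.null(msg)) TRUE else msg
})

#' Results of a pseudotime differential-expression run
#'
#' @slot table per-gene result [S4Vectors::DataFrame] with columns gene,
#'   statistic, rank, model, B_used, p_emp, p_param, p_asymptotic,
#'   padj_param, null_model, gof_p, converged.
#' @slot draws the [PseudotimeDraws-class] used (empty in fixed mode).
#' @slot uncertainty per-cell pseudotime uncertainty summary (data.frame).
#' @slot manifest list of all run parameters and seeds; re-running
#'   [runPseudotimeDE()] with these reproduces the table exactly.
#' @export
setClass("PseudotimeDEResults",
  representation(table = "DataFrame", draws = "PseudotimeDraws",
                 uncertainty = "data.frame", manifest = "list"))

## ---- show methods ----

setMethod("show", "SplineBasis", function(object) {
  cat("SplineBasis: cubic B-spline, K =", object@K,
      "(", ncol(object@design), "centered columns ),",
      length(object@ptime), "evaluation points\n")
})

setMethod("show", "GAMFit", function(object) {
  cat(sprintf("%s-GAM fit on %d cells\n", object@flavor, object@n))
  cat(sprintf("  edf %.2f, phi %.3g, loglik %.2f, AIC %.2f\n",
              object@edf, object@phi, object@loglik, object@aic))
  cat(sprintf("  statistic %.4g (rank %d), converged: %s\n",
              object@statistic, object@rank, object@converged))
  if (object@flavor == "ZINB")
    cat(sprintf("  zero-inflation: alpha0 %.3f, alpha1 %.3f\n",
                object@alpha0, object@alpha1))
  if (length(object@notes)) cat("  notes:", object@notes, "\n")
})

setMethod("show", "PseudotimeDraws", function(object) {
  ok <- sum(vapply(object@subsamples, function(r) r$status == "ok", TRUE))
  cat(sprintf(paste0("PseudotimeDraws: %d cells, %d subsamples of size %d ",
                     "(fraction %.2f), %d usable\n"),
              object@n, length(object@subsamples),
              floor(object@fraction * object@n), object@fraction, ok))
})

setMethod("show", "NullFit", function(object) {
  cat(sprintf("NullFit: %d null values, chosen = %s (LRT p = %.3g)\n",
              length(object@nullValues), object@chosen, object@lrtP))
})

setMethod("show", "PseudotimeDEResults", function(object) {
  cat(sprintf("PseudotimeDEResults: %d genes\n", nrow(object@table)))
  pa <- object@table$padj_param
  if (!all(is.na(pa)))
    cat(sprintf("  %d genes at BH-adjusted parametric p <= 0.05\n",
                sum(pa <= 0.05, na.rm = TRUE)))
  show(head(object@table, 5))
})

## ---- accessors ----

#' Number of subsamples (total and usable)
#'
#' @param draws a [PseudotimeDraws-class] object.
#' @return `nSubsamples`: total number of subsamples drawn;
#'   `usableSubsamples`: integer indices of subsamples whose pseudotime
#'   inference succeeded.
#' @export
nSubsamples <- function(draws) length(draws@subsamples)

#' @rdname nSubsamples
#' @export
usableSubsamples <- function(draws)
  which(vapply(draws@subsamples, function(r) r$status == "ok", TRUE))

#' Access the per-gene result table
#'
#' @param x a [PseudotimeDEResults-class] object.
#' @return a [S4Vectors::DataFrame] with one row per gene.
#' @export
resultsTable <- function(x) x@table

#' Access the run manifest
#'
#' @param x a [PseudotimeDEResults-class] object.
#' @return named list of all parameters and seeds of the run.
#' @export
runManifest <- function(x) x@manifest

#' Dense covariance of the fitted smooth
#'
#' Reconstructs \eqn{\hat V_f}, the n x n Bayesian covariance of the fitted
#' smooth values, from its low-rank factors.
#'
#' @param fit a [GAMFit-class] object.
#' @return an n x n symmetric positive semidefinite matrix.
#' @export
smoothCovariance <- function(fit) {
  X <- fit@basis@design
  V <- X %*% fit@Vbs %*% t(X)
  (V + t(V)) / 2
}
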