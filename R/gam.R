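#' Fit a negative-binomial GAM of counts on pseudotime
#'
#' Fits \eqn{y_i \sim NB(\mu_i, \phi)}, \eqn{\log\mu_i = \beta_0 + f(T_i)}
#' with \eqn{f} a penalized cubic spline, by penalized IRLS. The smoothing
#' parameter is chosen by a Laplace-approximate REML criterion (or GCV) and
#' the dispersion \eqn{\phi} by alternating profile maximum likelihood. The
#' identical fitting configuration is used for observed data and for every
#' permuted subsample, which is what makes the permutation null exchangeable.
#'
#' @param y non-negative integer counts, one per cell.
#' @param ptime pseudotime values aligned with `y` (typically in [0, 1]).
#' @param basis optional precomputed [SplineBasis-class] for `ptime`;
#'   built with `K` knots if missing.
#' @param K basis dimension when `basis` is missing.
#' @param weights optional prior observation weights (used by the ZINB EM).
#' @param criterion smoothing-parameter criterion, "REML" (default) or "GCV".
#' @param maxit,tol IRLS iteration cap and relative penalized-deviance
#'   tolerance.
#' @return a [GAMFit-class] with flavor "NB".
#' @examples
#' t <- seq(0, 1, length.out = 100)
#' y <- rnbinom(100, mu = exp(1 + sin(2 * pi * t)), size = 2)
#' fitNBGAM(y, t)
#' @export
fitNBGAM <- function(y, ptime, basis = NULL, K = 6, weights = NULL,
                     criterion = c("REML", "GCV"), maxit = 50, tol = 1e-8) {
  criterion <- match.arg(criterion)
  y <- as.numeric(y)
  if (length(y) != length(ptime)) stop("y and ptime lengths differ")
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("y must be non-negative integer counts")
  if (all(y == 0)) stop("all-zero gene: nothing to fit")
  if (is.null(basis)) basis <- buildSplineBasis(ptime, K = K)
  if (is.null(weights)) weights <- rep(1, length(y))
  .gamFitFromEngine(y, basis, weights, fixedLambda = -1, fixedTheta = -1,
                    maxit = maxit, tol = tol, criterion = criterion)
}

# shared constructor around the C++ engine
.gamFitFromEngine <- function(y, basis, weights, fixedLambda, fixedTheta,
                              maxit, tol, criterion) {
  X <- basis@design
  Z <- cbind(1, X)
  q <- ncol(Z)
  Sfull <- matrix(0, q, q)
  Sfull[-1, -1] <- basis@penalty
  f <- .nbgam_fit_cpp(y, Z, Sfull, weights, fixedLambda, fixedTheta,
                      as.integer(maxit), tol,
                      if (criterion == "GCV") 1L else 0L)
  fhat <- as.numeric(X %*% f$beta[-1])
  new("GAMFit", flavor = "NB", beta0 = f$beta[1], beta = as.numeric(f$beta[-1]),
      phi = f$theta, alpha0 = NA_real_, alpha1 = NA_real_, fhat = fhat,
      Vbs = f$Vb[-1, -1, drop = FALSE], basis = basis,
      rank = as.integer(f$rank), statistic = f$statistic,
      edf = f$edf_smooth, edf1 = f$edf1_smooth, loglik = f$loglik,
      aic = -2 * f$loglik + 2 * (f$edf + 1),
      lambda = f$lambda, converged = as.logical(f$converged),
      n = length(y), pzero = numeric(0), emTrace = numeric(0),
      notes = character(0))
}

#' Fit a zero-inflated negative-binomial GAM by EM
#'
#' Model: a count is observed from the NB-GAM with probability
#' \eqn{p_i}, \eqn{\mathrm{logit}(p_i) = \alpha_0 + \alpha_1 \log\mu_i},
#' and is a structural zero otherwise. The E-step computes the posterior
#' probability that each zero came from the NB component; the M-step fits a
#' prior-weighted NB-GAM and a logistic regression of the posterior
#' indicator on \eqn{\log\hat\mu}. The smoothing parameter is selected in
#' the first M-step and then held fixed, so each subsequent iteration
#' ascends a fixed penalized observed-data likelihood (recorded in
#' `emTrace`).
#'
#' If `y` has no zeros the model reduces to plain NB and the NB fit is
#' returned with a note.
#'
#' @inheritParams fitNBGAM
#' @param emMaxit,emTol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return a [GAMFit-class] with flavor "ZINB" (AIC counts two extra
#'   parameters for the alphas).
#' @export
fitZINBGAM <- function(y, ptime, basis = NULL, K = 6,
                       criterion = c("REML", "GCV"), maxit = 50, tol = 1e-8,
                       emMaxit = 100, emTol = 1e-6) {
  criterion <- match.arg(criterion)
  y <- as.numeric(y)
  if (length(y) != length(ptime)) stop("y and ptime lengths differ")
  if (all(y == 0)) stop("all-zero gene: nothing to fit")
  if (is.null(basis)) basis <- buildSplineBasis(ptime, K = K)
  n <- length(y)
  if (!any(y == 0)) {
    fit <- fitNBGAM(y, ptime, basis = basis, criterion = criterion,
                    maxit = maxit, tol = tol)
    fit@notes <- "no zeros: ZINB reduces to NB"
    return(fit)
  }
  ispos <- y > 0
  # initial NB fit and logistic initialization of the alphas
  nb <- .gamFitFromEngine(y, basis, rep(1, n), -1, -1, maxit, tol, criterion)
  mu <- exp(pmin(nb@beta0 + nb@fhat, 30))
  alpha <- .logisticFit(as.numeric(ispos), log(mu))
  w <- rep(1, n)
  lambdaFix <- -1
  trace <- numeric(0)
  fit <- nb
  clipped <- FALSE
  for (it in seq_len(emMaxit)) {
    # E-step
    p <- plogis(alpha[1] + alpha[2] * log(mu))
    f0 <- (fit@phi / (fit@phi + mu))^fit@phi
    w <- ifelse(ispos, 1, p * f0 / (p * f0 + (1 - p)))
    w <- pmin(pmax(w, 1e-10), 1)
    # M-step: weighted NB-GAM (lambda fixed after the first iteration)
    fit <- .gamFitFromEngine(y, basis, w, lambdaFix, -1, maxit, tol,
                             criterion)
    if (it == 1) lambdaFix <- fit@lambda
    mu <- exp(pmin(fit@beta0 + fit@fhat, 30))
    alpha <- .logisticFit(w, log(mu))
    if (any(abs(alpha) >= 30)) clipped <- TRUE
    # penalized observed-data log-likelihood
    p <- plogis(alpha[1] + alpha[2] * log(mu))
    llobs <- .zinbLoglik(y, mu, fit@phi, p)
    pen <- 0.5 * lambdaFix *
      as.numeric(t(fit@beta) %*% basis@penalty %*% fit@beta)
    trace <- c(trace, llobs - pen)
    if (it > 1 && abs(trace[it] - trace[it - 1]) <
        emTol * (abs(trace[it]) + 0.1)) break
  }
  converged <- it < emMaxit
  p <- plogis(alpha[1] + alpha[2] * log(mu))
  llobs <- .zinbLoglik(y, mu, fit@phi, p)
  notes <- character(0)
  # boundary case: if the plain NB solution beats the EM's interior
  # solution, the MLE sits at the no-dropout boundary (p -> 1); return the
  # NB fit re-expressed as a degenerate ZINB (alpha0 at its clip bound)
  muNB <- exp(pmin(nb@beta0 + nb@fhat, 30))
  pOne <- rep(plogis(30), n)
  llBoundary <- .zinbLoglik(y, muNB, nb@phi, pOne)
  if (llBoundary > llobs) {
    fit <- nb
    mu <- muNB
    alpha <- c(30, 0)
    p <- pOne
    llobs <- llBoundary
    converged <- nb@converged
    notes <- "no evidence of zero inflation: ZINB at the no-dropout boundary"
  }
  if (clipped) {
    notes <- c(notes,
               "separation in the zero-inflation logistic step; alphas clipped")
    warning(notes[length(notes)])
  }
  edfTotal <- fit@edf + 1 # smooth + intercept
  new("GAMFit", flavor = "ZINB", beta0 = fit@beta0, beta = fit@beta,
      phi = fit@phi, alpha0 = alpha[1], alpha1 = alpha[2], fhat = fit@fhat,
      Vbs = fit@Vbs, basis = basis, rank = fit@rank,
      statistic = fit@statistic, edf = fit@edf, edf1 = fit@edf1,
      loglik = llobs, aic = -2 * llobs + 2 * (edfTotal + 1 + 2),
      lambda = fit@lambda, converged = converged && fit@converged,
      n = n, pzero = p, emTrace = trace, notes = notes)
}

# observed-data ZINB log-likelihood
.zinbLoglik <- function(y, mu, theta, p) {
  ll <- numeric(length(y))
  pos <- y > 0
  ll[pos] <- log(p[pos]) + dnbinom(y[pos], size = theta, mu = mu[pos],
                                   log = TRUE)
  f0 <- (theta / (theta + mu[!pos]))^theta
  ll[!pos] <- log(p[!pos] * f0 + (1 - p[!pos]))
  sum(ll)
}

# weighted logistic regression of a fractional response on log-mean,
# with coefficients clipped to +-30 to guard against separation
.logisticFit <- function(w, logmu) {
  co <- tryCatch(
    suppressWarnings(glm.fit(cbind(1, logmu), w,
                             family = quasibinomial())$coefficients),
    error = function(e) c(qlogis(mean(pmin(pmax(w, 1e-6), 1 - 1e-6))), 0))
  co[!is.finite(co)] <- 0
  pmin(pmax(co, -30), 30)
}

#' Choose between the NB and ZINB fits of one gene
#'
#' In "auto" mode the zero-inflated model is returned only when its AIC
#' improves on the NB AIC by at least `delta` (default 10); a smaller
#' improvement, or an unconverged ZINB fit, falls back to NB. Forced modes
#' bypass the comparison.
#'
#' @param nb,zinb the two [GAMFit-class] fits of the same gene.
#' @param mode "auto", "nb" or "zinb".
#' @param delta AIC improvement required to prefer ZINB.
#' @return the selected [GAMFit-class].
#' @export
selectModel <- function(nb, zinb, mode = c("auto", "nb", "zinb"),
                        delta = 10) {
  mode <- match.arg(mode)
  if (mode == "nb") return(nb)
  if (mode == "zinb") return(zinb)
  if (is.null(zinb)) return(nb)
  if (!zinb@converged) {
    warning("unconverged ZINB fit; falling back to NB")
    return(nb)
  }
  if (nb@aic - zinb@aic >= delta) zinb else nb
}

#' Quadratic-form test statistic of a fitted smooth
#'
#' Computes \eqn{s = \hat f^\top \hat V_f^{r-} \hat f}, where
#' \eqn{\hat V_f^{r-}} is the rank-r pseudoinverse of the smooth's
#' covariance. The rank is the number of eigenvalues exceeding
#' \eqn{\sqrt{\epsilon}\,\lambda_{max}}, capped at round(edf) + 1 when an
#' effective degrees of freedom is available. Under the null hypothesis
#' that the smooth is identically zero, large values are evidence of
#' differential expression along pseudotime.
#'
#' @param object a [GAMFit-class], or a numeric vector \eqn{\hat f}.
#' @param Vf covariance matrix of \eqn{\hat f} (numeric-vector method only).
#' @param edf optional effective degrees of freedom used to cap the rank.
#' @param ... unused.
#' @return the statistic, with the rank used in attribute "rank".
#' @export
setGeneric("computeStatistic",
           function(object, ...) standardGeneric("computeStatistic"))

#' @rdname computeStatistic
#' @export
setMethod("computeStatistic", "GAMFit", function(object, ...) {
  X <- object@basis@design
  R <- chol(crossprod(X))
  M <- R %*% object@Vbs %*% t(R)
  .statFromSpectrum(eigen((M + t(M)) / 2, symmetric = TRUE),
                    as.numeric(R %*% object@beta), object@edf)
})

#' @rdname computeStatistic
#' @export
setMethod("computeStatistic", "numeric", function(object, Vf, edf = NULL,
                                                  ...) {
  if (!isTRUE(all.equal(dim(Vf), rep(length(object), 2L))))
    stop("Vf dimensions do not match fhat")
  V <- (Vf + t(Vf)) / 2
  ed <- eigen(V, symmetric = TRUE)
  .statFromSpectrum(ed, drop(crossprod(ed$vectors, object)), edf,
                    projected = TRUE)
})

# s = sum over retained eigendirections of (projection)^2 / eigenvalue.
# 'proj' is R %*% beta in the low-rank route (to be rotated by the
# eigenvectors), or the already-rotated projections when projected = TRUE.
.statFromSpectrum <- function(ed, proj, edf, projected = FALSE) {
  lam <- ed$values
  lmax <- max(lam)
  if (!(lmax > 0)) stop("statistic undefined: covariance numerically zero")
  keep <- which(lam > sqrt(.Machine$double.eps) * lmax)
  cap <- if (is.null(edf)) length(keep) else max(1L, as.integer(round(edf)) + 1L)
  keep <- keep[seq_len(min(length(keep), cap))]
  co <- if (projected) proj[keep] else
    drop(crossprod(ed$vectors[, keep, drop = FALSE], proj))
  s <- sum(co^2 / lam[keep])
  attr(s, "rank") <- length(keep)
  s
}

#' Asymptotic p-value for a fixed-pseudotime fit
#'
#' Right-tail p-value of the smooth-term test treating pseudotime as fixed,
#' using the fractional-rank pseudoinverse construction for penalized
#' smooths (reference df = the upper-bound edf), with the tail probability
#' of the resulting weighted chi-square sum from [mgcv::psum.chisq]. Used
#' in fixed mode, where no subsampling/permutation null is available; when
#' pseudotime is itself inferred (random), prefer the permutation-based
#' p-values, which remain calibrated.
#'
#' @param fit a [GAMFit-class] object.
#' @return p-value in (0, 1].
#' @export
asymptoticPvalue <- function(fit) {
  X <- fit@basis@design
  R <- chol(crossprod(X))
  V <- R %*% fit@Vbs %*% t(R)
  V <- (V + t(V)) / 2
  ed <- eigen(V, symmetric = TRUE)
  rank <- min(max(fit@edf1, 1), ncol(X))
  k <- max(0L, floor(rank))
  nu <- rank - k
  k1 <- if (nu > 0) k + 1L else k
  rEst <- sum(ed$values > max(ed$values) * .Machine$double.eps^0.9)
  if (rEst < k1) { k1 <- k <- rEst; nu <- 0; rank <- rEst }
  if (k1 == 0L) return(1)
  vec <- ed$vectors[, seq_len(k1), drop = FALSE]
  if (nu > 0 && k > 0) {
    if (k > 1)
      vec[, seq_len(k - 1)] <-
        sweep(vec[, seq_len(k - 1), drop = FALSE], 2,
              sqrt(ed$values[seq_len(k - 1)]), "/")
    b12 <- sqrt(max(0.5 * nu * (1 - nu), 0))
    B <- matrix(c(1, b12, b12, nu), 2, 2)
    ev <- diag(ed$values[k:k1]^-0.5, nrow = 2)
    B <- ev %*% B %*% ev
    eb <- eigen(B, symmetric = TRUE)
    rB <- eb$vectors %*% diag(sqrt(pmax(eb$values, 0)), 2) %*% t(eb$vectors)
    vec[, k:k1] <- t(rB %*% t(vec[, k:k1, drop = FALSE]))
  } else {
    vec <- sweep(vec, 2, sqrt(ed$values[seq_len(k1)]), "/")
    if (k == 1) rank <- 1
  }
  d <- sum((crossprod(vec, R %*% fit@beta))^2)
  if (!is.finite(d)) return(NA_real_)
  if (nu > 0 && k1 > 1) {
    val <- rep(1, k1)
    rp <- nu + 1
    val[k] <- (rp + sqrt(rp * (2 - rp))) / 2
    val[k1] <- rp - val[k]
    p <- mgcv::psum.chisq(d, val)
  } else {
    p <- pchisq(d, df = max(rank, 1), lower.tail = FALSE)
  }
  min(max(p, 1e-300), 1)
}
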