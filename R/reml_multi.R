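# Average-information REML for y = X b + sum_c u_c + e with
# u_c ~ N(0, s_c K_c) and e ~ N(0, s_e I). Used for the local-heritability
# variance partitioning; the single-K GWAS null model has its own faster
# spectral route in reml_null().

#' Multi-kinship variance-component REML
#'
#' Average-information iterations with expectation-maximization fallback
#' steps; components constrained non-negative (a component that hits the
#' lower bound is reported as 0 and flagged). Starting values are equal
#' shares of the phenotypic variance, so the fit is deterministic.
#'
#' @param y trait vector (complete cases only).
#' @param X fixed-effect design matrix (default intercept).
#' @param Klist list of n x n kinship matrices; the residual identity
#'   component is added automatically.
#' @param maxit,tol iteration cap and convergence tolerance on the
#'   restricted log-likelihood.
#' @param init optional starting variance components (length C+1, last
#'   element residual); used for warm restarts.
#' @return list with `varcomp` (length C+1; last element residual),
#'   `loglik`, `converged`, `iterations`, `boundary` (logical per
#'   component), `beta`.
#' @export
reml_multi <- function(y, X = NULL, Klist, maxit = 200, tol = 1e-6,
                       init = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  C <- length(Klist)
  Ks <- c(lapply(Klist, function(K) (K + t(K)) / 2), list(diag(n)))
  vp <- stats::var(y)
  lb <- 1e-8 * vp
  theta <- if (is.null(init)) rep(vp / (C + 1), C + 1) else pmax(init, lb)
  stopifnot(length(theta) == C + 1)

  loglik_parts <- function(theta) {
    V <- matrix(0, n, n)
    for (c in seq_len(C + 1)) V <- V + theta[c] * Ks[[c]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    XtVinv <- crossprod(X, Vinv)
    XtVinvX <- XtVinv %*% X
    chX <- tryCatch(chol(XtVinvX), error = function(e) NULL)
    if (is.null(chX)) return(NULL)
    beta <- backsolve(chX, forwardsolve(t(chX), XtVinv %*% y))
    P <- Vinv - t(XtVinv) %*% chol2inv(chX) %*% XtVinv
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) +
                    sum(y * Py))
    list(P = P, Py = Py, ll = ll, beta = drop(beta))
  }

  st <- loglik_parts(theta)
  if (is.null(st)) stop("initial variance matrix not positive definite")
  ll_old <- st$ll
  converged <- FALSE
  it <- 0
  for (it in seq_len(maxit)) {
    P <- st$P; Py <- st$Py
    KPy <- lapply(Ks, function(K) K %*% Py)
    trPK <- vapply(Ks, function(K) sum(P * K), numeric(1))
    grad <- vapply(seq_len(C + 1), function(c) {
      -0.5 * (trPK[c] - sum(Py * KPy[[c]]))
    }, numeric(1))
    AI <- matrix(0, C + 1, C + 1)
    PT <- lapply(KPy, function(t) P %*% t)
    for (a in seq_len(C + 1)) for (b in a:(C + 1)) {
      AI[a, b] <- AI[b, a] <- 0.5 * sum(KPy[[a]] * PT[[b]])
    }
    step <- tryCatch(solve(AI + diag(1e-10, C + 1), grad),
                     error = function(e) NULL)
    improved <- FALSE
    if (!is.null(step)) {
      fac <- 1
      for (h in 1:10) {
        cand <- pmax(theta + fac * step, lb)
        stc <- loglik_parts(cand)
        if (!is.null(stc) && stc$ll >= ll_old - 1e-10) {
          theta <- cand; st <- stc; improved <- TRUE
          break
        }
        fac <- fac / 2
      }
    }
    if (!improved) { # EM fallback step (guaranteed uphill direction)
      cand <- pmax(theta + theta^2 * (vapply(seq_len(C + 1), function(c)
        sum(Py * KPy[[c]]), numeric(1)) - trPK) / n, lb)
      stc <- loglik_parts(cand)
      if (is.null(stc))
        stop("non-convergence: variance matrix became singular; theta = ",
             paste(signif(theta, 4), collapse = ", "))
      theta <- cand; st <- stc
    }
    if (abs(st$ll - ll_old) < tol) { converged <- TRUE; ll_old <- st$ll; break }
    ll_old <- st$ll
  }
  if (!converged && it >= maxit)
    warning("AI-REML reached the iteration cap without meeting the tolerance")
  vc <- theta
  vc[vc <= lb * 1.01] <- 0
  list(varcomp = vc, loglik = ll_old, converged = converged,
       iterations = it, boundary = theta <= lb * 1.01, beta = st$beta)
}
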