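#' Genomic relationship matrix
#'
#' K_jk = sum_i (x_ij - c_i)(x_ik - c_i) / sum_i 2 p_i (1 - p_i), with
#' allele counts x in \{0,1,2\} and p_i the allele frequency. The default
#' centering constant is VanRaden's c_i = 2 p_i; `centering = "p"`
#' reproduces the single-p variant. Monomorphic markers are dropped.
#'
#' @param genotypes allele-count matrix (varieties x markers) or a
#'   [genotype_panel()].
#' @param centering "2p" (default) or "p".
#' @return symmetric n x n kinship matrix.
#' @export
compute_grm <- function(genotypes, centering = c("2p", "p")) {
  centering <- match.arg(centering)
  if (inherits(genotypes, "genotype_panel")) genotypes <- genotypes$genotypes
  G <- as.matrix(genotypes)
  if (anyNA(G)) {
    # mean-impute per marker: standard practice for GRM construction
    mj <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mj[idx[, 2]]
  }
  p <- colMeans(G) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers monomorphic")
  G <- G[, poly, drop = FALSE]; p <- p[poly]
  ctr <- if (centering == "2p") 2 * p else p
  Z <- sweep(G, 2, ctr)
  K <- tcrossprod(Z) / sum(2 * p * (1 - p))
  (K + t(K)) / 2
}

# REML profile log-likelihood machinery for a single-kinship mixed model,
# via the spectral decomposition of K (EMMA-style 1-D optimization).
.reml_profile <- function(loglam, d, Xs, ys) {
  lam <- exp(loglam)
  n <- length(ys); q <- ncol(Xs)
  w <- 1 / (lam * d + 1)
  XtWX <- crossprod(Xs * w, Xs)
  XtWy <- crossprod(Xs * w, ys)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  b <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- ys - Xs %*% b
  rss <- sum(w * r^2)
  nq <- n - q
  -0.5 * (nq * log(rss / nq) + sum(log(lam * d + 1)) +
            2 * sum(log(diag(ch))) + nq)
}

#' REML fit of the null mixed model
#'
#' y = X beta + g + e with g ~ N(0, sigma_g^2 K), e ~ N(0, sigma_e^2 I).
#' The kinship is eigen-decomposed once and the REML criterion is
#' maximized in one dimension over the variance ratio.
#'
#' @param y trait vector (no missing values).
#' @param X fixed-effect design (default intercept only); typically
#'   intercept + year.
#' @param K kinship matrix from [compute_grm()].
#' @return list with `sigma_g2`, `sigma_e2`, `loglik` (restricted),
#'   `beta`, and the reusable spectral parts `eigen_U`, `eigen_d`.
#' @export
reml_null <- function(y, X = NULL, K) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 10) stop("need n >= 10")
  if (any(!is.finite(y))) stop("non-finite trait values")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 1e-9)
  Us <- eig$vectors
  ys <- drop(crossprod(Us, y))
  Xs <- crossprod(Us, X)
  opt <- stats::optimize(function(l) .reml_profile(l, d, Xs, ys),
                         interval = c(-12, 12), maximum = TRUE, tol = 1e-9)
  lam <- exp(opt$maximum)
  w <- 1 / (lam * d + 1)
  XtWX <- crossprod(Xs * w, Xs)
  b <- solve(XtWX, crossprod(Xs * w, ys))
  rss <- sum(w * (ys - Xs %*% b)^2)
  sigma_e2 <- rss / (n - ncol(X))
  list(sigma_g2 = lam * sigma_e2, sigma_e2 = sigma_e2,
       loglik = opt$objective, beta = drop(b),
       eigen_U = Us, eigen_d = d)
}

#' Mixed-model GWAS scan with fixed variance components
#'
#' Per-marker generalized least squares with V = sigma_g^2 K + sigma_e^2 I
#' held at the null-model REML estimates (P3D-style): fixed effects are
#' the mean, year and the marker's allele count; Wald Z and two-sided p
#' per marker, with a Bonferroni threshold attached. Monomorphic markers
#' and markers collinear with the fixed effects are flagged.
#'
#' @param panel a [genotype_panel()].
#' @param y trait vector aligned to panel rows.
#' @param varcomp output of [reml_null()] (fitted with the same fixed
#'   design minus the marker column).
#' @param X fixed-effect design without the marker (default mean + year).
#' @param alpha family-wise level.
#' @return data.frame of class `gwas_scan` with `beta_hat`, `se`, `z`,
#'   `p`, `significant` per map marker; attributes `bonferroni`,
#'   `m_fitted`, `varcomp`.
#' @export
scan_gls <- function(panel, y, varcomp, X = NULL, alpha = 0.05) {
  G <- panel$genotypes
  n <- nrow(G)
  if (is.null(X)) X <- cbind(1, panel$varieties$year)
  X <- as.matrix(X)
  U <- varcomp$eigen_U
  w <- 1 / (varcomp$sigma_g2 * varcomp$eigen_d + varcomp$sigma_e2)
  sw <- sqrt(w)
  Xt <- sw * crossprod(U, X)
  yt <- sw * drop(crossprod(U, y))
  Gi <- G
  if (anyNA(Gi)) {
    mj <- colMeans(Gi, na.rm = TRUE)
    idx <- which(is.na(Gi), arr.ind = TRUE)
    Gi[idx] <- mj[idx[, 2]]
  }
  p <- colMeans(Gi) / 2
  poly <- p > 0 & p < 1
  Mt <- sw * crossprod(U, Gi)
  # residualize marker columns and the trait on the shared fixed effects
  rM <- Mt - Xt %*% solve(crossprod(Xt), crossprod(Xt, Mt))
  ry <- drop(yt - Xt %*% solve(crossprod(Xt), crossprod(Xt, yt)))
  denom <- colSums(rM^2)
  ok <- poly & denom > 1e-8 * n
  beta <- ifelse(ok, colSums(rM * ry) / denom, NA_real_)
  se <- ifelse(ok, sqrt(1 / denom), NA_real_)
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  thr <- alpha / sum(ok)
  out <- data.frame(marker_id = panel$map$marker_id,
                    chrom = panel$map$chrom, cm = panel$map$cm,
                    beta_hat = beta, se = se, z = z, p = pval,
                    significant = !is.na(pval) & pval < thr,
                    stringsAsFactors = FALSE)
  attr(out, "bonferroni") <- thr
  attr(out, "m_fitted") <- sum(ok)
  attr(out, "varcomp") <- varcomp[c("sigma_g2", "sigma_e2")]
  class(out) <- c("gwas_scan", "data.frame")
  out
}

#' Genomic BLUP of genetic values
#'
#' Best linear unbiased prediction of the random genetic effect from a
#' fitted null mixed model: g_hat = sigma_g^2 K V^-1 (y - X beta_hat).
#'
#' @param y trait vector.
#' @param X fixed design used in [reml_null()].
#' @param K kinship matrix.
#' @param varcomp output of [reml_null()].
#' @return vector of predicted genetic values.
#' @export
gblup <- function(y, X = NULL, K, varcomp) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  U <- varcomp$eigen_U
  w <- 1 / (varcomp$sigma_g2 * varcomp$eigen_d + varcomp$sigma_e2)
  Xt <- sqrt(w) * crossprod(U, X)
  yt <- sqrt(w) * drop(crossprod(U, y))
  b <- solve(crossprod(Xt), crossprod(Xt, yt))
  r <- drop(y - X %*% b)
  Vinv_r <- U %*% (w * drop(crossprod(U, r)))
  drop(varcomp$sigma_g2 * K %*% Vinv_r)
}
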