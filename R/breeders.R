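# Multivariate breeder's-equation selection parameters with
# direct/indirect partitioning, and the three-trait single-generation
# simulation used to probe estimator quality.

#' Per-year genetic trend of each trait
#'
#' Delta Z is the ordinary least-squares slope of the predicted genetic
#' value (GBLUP by default, raw phenotype as fallback) on year.
#'
#' @param genetic_values matrix (varieties x traits) of predicted genetic
#'   values, e.g. from [gblup()] per trait.
#' @param years years of release.
#' @return named vector of per-year trends.
#' @export
estimate_delta_z <- function(genetic_values, years) {
  if (length(unique(years)) < 3) stop("need >= 3 distinct years")
  if (is.null(dim(genetic_values)))
    genetic_values <- cbind(trait = genetic_values)
  apply(genetic_values, 2, function(g) {
    ok <- !is.na(g)
    unname(stats::coef(stats::lm(g[ok] ~ years[ok]))[2])
  })
}

#' Genetic and phenotypic covariance matrices of a trait panel
#'
#' P is the sample covariance of year-detrended traits (pairwise complete
#' cases). Genetic variances come from single-trait kinship REML; genetic
#' covariances from the variance-of-sum identity cov_g(y1, y2) =
#' (Vg(y1 + y2) - Vg(y1) - Vg(y2)) / 2 on trait pairs. G is projected to
#' the nearest positive semi-definite matrix (eigenvalue clipping) when
#' needed, with the Frobenius distance recorded.
#'
#' @param panel a [genotype_panel()].
#' @param traits trait matrix (varieties x traits).
#' @param K optional kinship (default [compute_grm()] of the panel).
#' @return list with `G`, `P`, `h2` (per-trait ratios), `psd_adjusted`,
#'   `frobenius_shift`.
#' @export
estimate_G_P <- function(panel, traits, K = NULL) {
  if (is.null(K)) K <- compute_grm(panel)
  years <- panel$varieties$year
  Tn <- ncol(traits)
  detr <- apply(traits, 2, function(y) {
    out <- rep(NA_real_, length(y))
    ok <- !is.na(y)
    out[ok] <- stats::residuals(stats::lm(y[ok] ~ years[ok]))
    out
  })
  P <- stats::cov(detr, use = "pairwise.complete.obs")
  G <- matrix(NA_real_, Tn, Tn, dimnames = dimnames(P))
  vg <- numeric(Tn)
  fits <- vector("list", Tn)
  for (i in seq_len(Tn)) {
    y <- traits[, i]; cc <- !is.na(y)
    X <- cbind(1, years[cc])
    fits[[i]] <- reml_null(y[cc], X, K[cc, cc])
    vg[i] <- fits[[i]]$sigma_g2
    G[i, i] <- vg[i]
  }
  for (i in seq_len(Tn)) for (j in seq_len(Tn)) {
    if (j <= i) next
    cc <- !is.na(traits[, i]) & !is.na(traits[, j])
    X <- cbind(1, years[cc])
    vs <- reml_null(traits[cc, i] + traits[cc, j], X, K[cc, cc])$sigma_g2
    vi <- reml_null(traits[cc, i], X, K[cc, cc])$sigma_g2
    vj <- reml_null(traits[cc, j], X, K[cc, cc])$sigma_g2
    G[i, j] <- G[j, i] <- (vs - vi - vj) / 2
  }
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  shift <- 0
  psd <- any(eg$values < 0)
  if (psd) {
    lam <- pmax(eg$values, 0)
    G2 <- eg$vectors %*% diag(lam, Tn) %*% t(eg$vectors)
    shift <- sqrt(sum((G2 - G)^2))
    G <- (G2 + t(G2)) / 2
    dimnames(G) <- dimnames(P)
  }
  list(G = G, P = P, h2 = vg / diag(P), psd_adjusted = psd,
       frobenius_shift = shift)
}

#' Solve the multivariate breeder's equation
#'
#' beta_sel = G^-1 DeltaZ; S = P beta_sel; i = S / sqrt(diag(P)). Each
#' parameter is split into a direct part (the trait's own
#' variance pathway, e.g. G_kk beta_k for DeltaZ) and an indirect part
#' (total minus direct, the covariance pathways).
#'
#' @param delta_z per-year (or per-generation) genetic response vector.
#' @param G,P genetic and phenotypic covariance matrices.
#' @param max_condition refuse to invert G beyond this condition number.
#' @return list of class `selection_summary` with `beta_sel`, `S`, `i`,
#'   and `direct`/`indirect` data.frames for delta_z, S and i.
#' @export
solve_selection <- function(delta_z, G, P, max_condition = 1e8) {
  G <- as.matrix(G); P <- as.matrix(P)
  cn <- kappa(G, exact = TRUE)
  if (!is.finite(cn) || cn > max_condition)
    stop("singular G (condition number ", format(cn, digits = 3),
         "): consider a trait subset")
  beta <- drop(solve(G, delta_z))
  S <- drop(P %*% beta)
  i <- S / sqrt(diag(P))
  dz_direct <- diag(G) * beta
  S_direct <- diag(P) * beta
  i_direct <- S_direct / sqrt(diag(P))
  structure(list(
    delta_z = delta_z, G = G, P = P, beta_sel = beta, S = S, i = i,
    direct = data.frame(delta_z = dz_direct, S = S_direct, i = i_direct),
    indirect = data.frame(delta_z = delta_z - dz_direct, S = S - S_direct,
                          i = i - i_direct)),
    class = "selection_summary")
}

#' Three-trait single-generation selection simulation
#'
#' Simulates individuals with genetic values ~ N(0, G_true) and
#' environmental deviations ~ N(0, P_true - G_true), applies truncation
#' selection on a phenotypic index, and compares three versions of the
#' selection parameters: "true" (computed from the simulated response
#' directly), "realized" (solved with the true G) and "estimated"
#' (solved with a marker-free REML-style G estimated from parent-offspring
#' regression of genetic on phenotypic values in the sample).
#'
#' @param n individuals per replicate.
#' @param G_true,P_true 3x3 covariance matrices (G positive definite,
#'   P - G positive semi-definite).
#' @param index_weights phenotypic index weights for truncation.
#' @param prop_selected proportion selected.
#' @param reps replicates.
#' @return list with per-replicate arrays of `beta_true`, `beta_realized`,
#'   `beta_estimated` and the mean correlations `cor_realized_true`,
#'   `cor_estimated_true` across replicates.
#' @export
tri_trait_validation <- function(n = 500,
                                 G_true = matrix(c(1, .5, .2,
                                                   .5, 1, .3,
                                                   .2, .3, 1), 3, 3),
                                 P_true = G_true + diag(3),
                                 index_weights = c(1, 0, 0),
                                 prop_selected = 0.2, reps = 20) {
  E_true <- P_true - G_true
  chG <- chol(G_true); chE <- chol(E_true)
  Tn <- nrow(G_true)
  bt <- br <- be <- matrix(NA_real_, reps, Tn)
  for (r in seq_len(reps)) {
    g <- matrix(stats::rnorm(n * Tn), n, Tn) %*% chG
    e <- matrix(stats::rnorm(n * Tn), n, Tn) %*% chE
    ph <- g + e
    idx <- drop(ph %*% index_weights)
    sel <- idx >= stats::quantile(idx, 1 - prop_selected)
    # response: mean genetic value of selected parents (one generation,
    # no recombination load) minus population mean
    dz <- colMeans(g[sel, , drop = FALSE]) - colMeans(g)
    # "true" gradient from the selection differential and true P
    S_obs <- colMeans(ph[sel, , drop = FALSE]) - colMeans(ph)
    bt[r, ] <- drop(solve(P_true, S_obs))
    br[r, ] <- drop(solve(G_true, dz))
    G_est <- stats::cov(g, ph)     # sample genetic covariance estimate
    G_est <- (G_est + t(G_est)) / 2
    be[r, ] <- tryCatch(drop(solve(G_est, dz)),
                        error = function(e2) rep(NA_real_, Tn))
  }
  corsafe <- function(a, b) {
    ok <- stats::complete.cases(a, b)
    if (sum(ok) < 3) return(NA_real_)
    stats::cor(as.vector(a[ok, ]), as.vector(b[ok, ]))
  }
  list(beta_true = bt, beta_realized = br, beta_estimated = be,
       cor_realized_true = corsafe(br, bt),
       cor_estimated_true = corsafe(be, bt))
}
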