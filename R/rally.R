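#' Per-marker logistic regression of allele counts on year (RALLY)
#'
#' Every marker is fitted with a two-trial binomial logistic model: the
#' allele count of a variety (0/1/2, out of 2) regressed on year of
#' release via the logit link, logit(p) = mu_R + beta_R * year (+ optional
#' covariates). A positive beta_R means the coded allele rose in frequency
#' over the panel's years. Fitting is iteratively reweighted least squares
#' shared across all markers; years are centered internally and the
#' intercept is back-transformed to the year-0 origin for reporting.
#'
#' @param panel a [genotype_panel()].
#' @param covariates optional numeric design columns (n x q, e.g. country
#'   dummies from [country_dummies()]).
#' @param maf_min minor-allele-frequency filter (markers below are not
#'   fitted).
#' @param alpha family-wise level for the attached Bonferroni threshold.
#' @param exclude optional marker column indices dropped before fitting.
#' @param beta_guard separation guard: |beta_hat| above this (centered
#'   scale) flags the fit as non-converged.
#' @return data.frame of class `rally_scan`, one row per map marker:
#'   `mu_hat` (year-0 log-odds), `mu_hat_centered`, `beta_hat`, `se`, `z`,
#'   `p`, `delta_p_hat` (predicted |frequency change| over the observed
#'   year span), `converged`, `fitted`, `n_used`, `maf`. Attributes:
#'   `bonferroni` (per-test threshold alpha/m over fitted markers),
#'   `year_range`, `m_fitted`.
#' @export
rally_scan <- function(panel, covariates = NULL, maf_min = 0.01,
                       alpha = 0.05, exclude = NULL, beta_guard = 15) {
  G <- panel$genotypes
  years <- panel$varieties$year
  n <- nrow(G); m <- ncol(G)
  obs <- !is.na(G)
  n_used <- colSums(obs)
  freq <- colSums(G, na.rm = TRUE) / (2 * n_used)
  maf <- pmin(freq, 1 - freq)
  fit_ok <- maf >= maf_min & n_used >= 2
  # need >= 2 distinct years among non-missing entries
  if (anyNA(G)) {
    multi_year <- vapply(seq_len(m), function(j) {
      yr <- years[obs[, j]]
      length(unique(yr)) >= 2
    }, logical(1))
  } else multi_year <- rep(length(unique(years)) >= 2, m)
  fit_ok <- fit_ok & multi_year & maf > 0
  if (!is.null(exclude)) fit_ok[exclude] <- FALSE
  if (!any(fit_ok)) stop("scan error: no markers left to fit")

  ybar <- mean(years)
  X <- cbind(intercept = 1, year = years - ybar)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    X <- cbind(X, covariates)
  }
  fit <- .irls_binom2(G[, fit_ok, drop = FALSE], X, beta_guard = beta_guard)

  out <- data.frame(marker_id = panel$map$marker_id,
                    chrom = panel$map$chrom, cm = panel$map$cm,
                    bp = panel$map$bp, maf = maf, n_used = n_used,
                    fitted = fit_ok,
                    mu_hat = NA_real_, mu_hat_centered = NA_real_,
                    beta_hat = NA_real_, se = NA_real_, z = NA_real_,
                    p = NA_real_, delta_p_hat = NA_real_,
                    converged = FALSE, stringsAsFactors = FALSE)
  out$mu_hat_centered[fit_ok] <- fit$b0
  out$beta_hat[fit_ok] <- fit$b1
  out$mu_hat[fit_ok] <- fit$b0 - fit$b1 * ybar   # back to calendar origin
  out$se[fit_ok] <- fit$se
  out$converged[fit_ok] <- fit$converged
  z <- fit$b1 / fit$se
  z[!fit$converged] <- NA_real_
  out$z[fit_ok] <- z
  out$p[fit_ok] <- 2 * stats::pnorm(-abs(z))
  ymin <- min(years); ymax <- max(years)
  dp <- abs(stats::plogis(fit$b0 + fit$b1 * (ymax - ybar)) -
            stats::plogis(fit$b0 + fit$b1 * (ymin - ybar)))
  dp[!fit$converged] <- NA_real_
  out$delta_p_hat[fit_ok] <- dp

  attr(out, "bonferroni") <- alpha / sum(fit_ok)
  attr(out, "m_fitted") <- sum(fit_ok)
  attr(out, "year_range") <- c(ymin, ymax)
  attr(out, "year_mean") <- ybar
  class(out) <- c("rally_scan", "data.frame")
  out
}

# batch IRLS for the 2-trial binomial GLM with shared design X.
# G: n x m allele counts (0/1/2, NA = missing), X: n x p design.
# Returns per-marker intercept (b0), year slope (b1), Wald SE of b1,
# convergence flag. Missing entries get zero prior weight.
.irls_binom2 <- function(G, X, beta_guard = 15, maxit = 50, tol = 1e-10) {
  n <- nrow(G); m <- ncol(G); p <- ncol(X)
  w0 <- 2 * (!is.na(G))            # binomial trials per observation
  Y <- G / 2                       # observed allele proportion
  Y[is.na(Y)] <- 0.5               # irrelevant under zero weight
  B <- matrix(0, p, m)
  # moment start for the intercept
  B[1, ] <- stats::qlogis(pmin(pmax(colSums(w0 * Y) / colSums(w0), 1e-3), 1 - 1e-3))
  active <- rep(TRUE, m)
  if (p == 2L) {
    x2 <- X[, 2]
    for (it in seq_len(maxit)) {
      if (!any(active)) break
      eta <- X %*% B
      mu <- stats::plogis(eta)
      mw <- pmin(pmax(mu * (1 - mu), 1e-10), 0.25)
      W <- w0 * mw
      Zw <- eta + (Y - mu) / mw    # working response
      s11 <- colSums(W); s12 <- colSums(W * x2); s22 <- colSums(W * x2 * x2)
      r1 <- colSums(W * Zw); r2 <- colSums(W * x2 * Zw)
      det <- s11 * s22 - s12 * s12
      det[det < 1e-300] <- NA
      b0 <- (s22 * r1 - s12 * r2) / det
      b1 <- (s11 * r2 - s12 * r1) / det
      step <- pmax(abs(b0 - B[1, ]), abs(b1 - B[2, ]))
      upd <- active & !is.na(step)
      B[1, upd] <- b0[upd]; B[2, upd] <- b1[upd]
      active[is.na(step)] <- FALSE # singular information: give up
      diverged <- abs(B[2, ]) > beta_guard | abs(B[1, ]) > 5 * beta_guard
      active <- active & !diverged & step > tol
    }
    eta <- X %*% B
    mu <- stats::plogis(eta)
    W <- w0 * pmin(pmax(mu * (1 - mu), 1e-10), 0.25)
    s11 <- colSums(W); s12 <- colSums(W * x2); s22 <- colSums(W * x2 * x2)
    det <- s11 * s22 - s12 * s12
    se <- sqrt(ifelse(det > 0, s11 / det, NA))
    conv <- abs(B[2, ]) <= beta_guard & abs(B[1, ]) <= 5 * beta_guard &
      is.finite(se)
    return(list(b0 = B[1, ], b1 = B[2, ], se = se, converged = conv))
  }
  # general design: per-marker solves on vectorized cross-products
  pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  XP <- X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]
  conv_step <- rep(Inf, m)
  for (it in seq_len(maxit)) {
    if (!any(active)) break
    eta <- X %*% B
    mu <- stats::plogis(eta)
    mw <- pmin(pmax(mu * (1 - mu), 1e-10), 0.25)
    W <- w0 * mw
    Zw <- eta + (Y - mu) / mw
    S <- crossprod(XP, W)          # npair x m
    R <- crossprod(X, W * Zw)      # p x m
    for (j in which(active)) {
      A <- matrix(0, p, p)
      A[cbind(pairs[, 1], pairs[, 2])] <- S[, j]
      A[cbind(pairs[, 2], pairs[, 1])] <- S[, j]
      bnew <- tryCatch(solve(A, R[, j]), error = function(e) NULL)
      if (is.null(bnew)) { active[j] <- FALSE; conv_step[j] <- NA; next }
      conv_step[j] <- max(abs(bnew - B[, j]))
      B[, j] <- bnew
      if (abs(B[2, j]) > beta_guard || conv_step[j] <= tol) active[j] <- FALSE
    }
  }
  eta <- X %*% B
  mu <- stats::plogis(eta)
  W <- w0 * pmin(pmax(mu * (1 - mu), 1e-10), 0.25)
  S <- crossprod(XP, W)
  se <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    A <- matrix(0, p, p)
    A[cbind(pairs[, 1], pairs[, 2])] <- S[, j]
    A[cbind(pairs[, 2], pairs[, 1])] <- S[, j]
    v <- tryCatch(solve(A)[2, 2], error = function(e) NA_real_)
    se[j] <- sqrt(v)
  }
  conv <- abs(B[2, ]) <= beta_guard & is.finite(se) & !is.na(conv_step)
  list(b0 = B[1, ], b1 = B[2, ], se = se, converged = conv)
}

#' Fit the RALLY model at a single marker
#'
#' @param allele_counts vector of allele counts (0/1/2, NA allowed).
#' @param years integer years of release.
#' @param covariates optional design columns.
#' @param beta_guard separation guard on the centered-year slope.
#' @return one-row data.frame with `mu_hat`, `mu_hat_centered`,
#'   `beta_hat`, `se`, `z`, `p`, `delta_p_hat`, `converged`, `n_used`.
#' @export
fit_marker_logistic <- function(allele_counts, years, covariates = NULL,
                                beta_guard = 15) {
  obs <- !is.na(allele_counts)
  if (length(unique(years[obs])) < 2)
    stop("need >= 2 distinct years among non-missing entries")
  g <- allele_counts[obs]
  if (stats::var(g) == 0) {
    return(data.frame(mu_hat = NA_real_, mu_hat_centered = NA_real_,
                      beta_hat = NA_real_, se = NA_real_, z = NA_real_,
                      p = NA_real_, delta_p_hat = NA_real_,
                      converged = FALSE, monomorphic = TRUE,
                      n_used = sum(obs)))
  }
  ybar <- mean(years)
  X <- cbind(1, years - ybar)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  fit <- .irls_binom2(matrix(allele_counts, ncol = 1), X,
                      beta_guard = beta_guard)
  z <- if (fit$converged) fit$b1 / fit$se else NA_real_
  ymin <- min(years); ymax <- max(years)
  dp <- if (fit$converged)
    abs(stats::plogis(fit$b0 + fit$b1 * (ymax - ybar)) -
        stats::plogis(fit$b0 + fit$b1 * (ymin - ybar))) else NA_real_
  data.frame(mu_hat = fit$b0 - fit$b1 * ybar, mu_hat_centered = fit$b0,
             beta_hat = ifelse(fit$converged, fit$b1, NA_real_),
             se = ifelse(fit$converged, fit$se, NA_real_),
             z = z, p = 2 * stats::pnorm(-abs(z)), delta_p_hat = dp,
             converged = fit$converged, monomorphic = FALSE,
             n_used = sum(obs))
}

#' Predicted allele-frequency change of a fitted marker
#'
#' Evaluates |logistic(mu + beta * year_max) - logistic(mu + beta *
#' year_min)| on the reported (calendar-origin) scale.
#'
#' @param mu_hat,beta_hat RALLY coefficients (calendar-year origin).
#' @param year_min,year_max span over which to predict.
#' @return absolute predicted frequency change.
#' @export
predicted_delta_p <- function(mu_hat, beta_hat, year_min, year_max) {
  abs(stats::plogis(mu_hat + beta_hat * year_max) -
      stats::plogis(mu_hat + beta_hat * year_min))
}

#' Prune markers in cross-chromosome LD
#'
#' Walks markers in map order; a marker is removed when its squared
#' correlation with any still-retained marker on a different chromosome
#' exceeds the threshold (so of a duplicated cross-chromosome pair,
#' exactly the earlier-visited member is removed).
#'
#' @param panel a [genotype_panel()].
#' @param r2_threshold squared-correlation threshold.
#' @return pruned [genotype_panel()] with attribute `n_pruned`.
#' @export
prune_cross_chromosome_ld <- function(panel, r2_threshold = 0.2) {
  G <- panel$genotypes
  chrom <- panel$map$chrom
  if (length(unique(chrom)) < 2) stop("need >= 2 chromosomes")
  m <- ncol(G)
  # adjacency of offending cross-chromosome pairs, blockwise by chromosome
  adj <- vector("list", m)
  chroms <- unique(chrom)
  idx_by <- split(seq_len(m), chrom)[chroms]
  for (a in seq_along(chroms)) for (b in seq_along(chroms)) {
    if (b <= a) next
    ia <- idx_by[[a]]; ib <- idx_by[[b]]
    cc <- suppressWarnings(stats::cor(G[, ia, drop = FALSE],
                                      G[, ib, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    cc[is.na(cc)] <- 0
    hits <- which(cc^2 > r2_threshold, arr.ind = TRUE)
    if (nrow(hits)) {
      for (h in seq_len(nrow(hits))) {
        i <- ia[hits[h, 1]]; j <- ib[hits[h, 2]]
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  dropped <- logical(m)
  for (i in seq_len(m)) {
    nb <- adj[[i]]
    if (length(nb) && any(!dropped[nb])) dropped[i] <- TRUE
  }
  keep <- which(!dropped)
  out <- genotype_panel(G[, keep, drop = FALSE],
                        panel$map[keep, , drop = FALSE], panel$varieties)
  for (extra in setdiff(names(panel), names(out))) out[[extra]] <- panel[[extra]]
  attr(out, "n_pruned") <- sum(dropped)
  out
}

#' Country dummy columns for use as scan covariates
#'
#' Countries with fewer than `min_n` varieties are merged into "other"
#' before dummy coding (first level is the reference and gets no column).
#'
#' @param varieties variety table with a `country` column.
#' @param min_n minimum varieties per retained country level.
#' @return numeric matrix of 0/1 dummies (possibly zero columns).
#' @export
country_dummies <- function(varieties, min_n = 5) {
  ctry <- as.character(varieties$country)
  ctry[is.na(ctry)] <- "other"
  tab <- table(ctry)
  ctry[ctry %in% names(tab)[tab < min_n]] <- "other"
  f <- factor(ctry)
  if (nlevels(f) < 2) return(matrix(0, length(ctry), 0))
  stats::model.matrix(~f)[, -1, drop = FALSE]
}
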