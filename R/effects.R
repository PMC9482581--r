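# Marker-effect estimation (ridge / LASSO), direction concordance with
# the RALLY year coefficient, and pairwise trait contingency tests.

# -1/0/1 coding of a 0/1/2 allele-count matrix (mean-imputed for fitting)
.code_pm1 <- function(G) {
  M <- as.matrix(G) - 1
  if (anyNA(M)) {
    mj <- colMeans(M, na.rm = TRUE)
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- mj[idx[, 2]]
  }
  M
}

#' Ridge (RR-BLUP) marker effects
#'
#' Fits y = mu + M u + e with u ~ N(0, sigma_u^2 I) and markers coded
#' -1/0/1. The penalty lambda = sigma_e^2 / sigma_u^2 is set by REML of
#' the equivalent random-effect model (kinship M M'), and the effects are
#' recovered through the n x n dual: u = M' (M M' + lambda I)^-1 (y - mu).
#'
#' @param panel a [genotype_panel()].
#' @param traits trait matrix (varieties x traits); constant traits are
#'   skipped.
#' @return list of class `marker_effects`: `u` (m x T effect matrix),
#'   `lambda` (per trait), `method = "ridge"`.
#' @export
fit_ridge <- function(panel, traits) {
  if (is.null(dim(traits))) traits <- cbind(trait = traits)
  M <- .code_pm1(panel$genotypes)
  m <- ncol(M)
  U <- matrix(NA_real_, m, ncol(traits),
              dimnames = list(colnames(M), colnames(traits)))
  lambda <- stats::setNames(rep(NA_real_, ncol(traits)), colnames(traits))
  for (tr in colnames(traits)) {
    y_all <- traits[, tr]
    cc <- which(!is.na(y_all))
    if (length(cc) < 2 || stats::var(y_all[cc]) == 0) next
    y <- y_all[cc]
    Mc <- M[cc, , drop = FALSE]
    K <- tcrossprod(Mc)
    vc <- reml_null(y, X = matrix(1, length(y), 1), K = K)
    lam <- vc$sigma_e2 / vc$sigma_g2
    n <- length(y)
    # dual solve with the fixed mean profiled out by GLS
    H <- K + diag(lam, n)
    Hinv1 <- solve(H, rep(1, n))
    mu <- sum(Hinv1 * y) / sum(Hinv1)
    U[, tr] <- drop(crossprod(Mc, solve(H, y - mu)))
    lambda[tr] <- lam
  }
  structure(list(u = U, lambda = lambda, method = "ridge"),
            class = "marker_effects")
}

#' Multi-task LASSO marker effects
#'
#' Fits the multivariate (grouped) LASSO so that a marker is selected for
#' all traits or none, with the penalty chosen by seeded 10-fold
#' cross-validation at the minimum mean CV error.
#'
#' @param panel a [genotype_panel()].
#' @param traits trait matrix; rows with any missing trait are dropped
#'   (the grouped fit needs complete responses).
#' @param nfolds CV folds.
#' @param seed fold-assignment seed.
#' @return list of class `marker_effects`: `u` (m x T), `lambda` (shared
#'   CV choice), `method = "lasso"`.
#' @export
fit_lasso <- function(panel, traits, nfolds = 10, seed = 1) {
  if (is.null(dim(traits))) traits <- cbind(trait = traits)
  M <- .code_pm1(panel$genotypes)
  cc <- which(stats::complete.cases(traits))
  if (length(cc) < nfolds) stop("CV undefined: fewer complete cases than folds")
  Y <- as.matrix(traits[cc, , drop = FALSE])
  Mc <- M[cc, , drop = FALSE]
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(nfolds), length(cc)))
  single <- ncol(Y) == 1
  fam <- if (single) "gaussian" else "mgaussian"
  yy <- if (single) drop(Y) else Y
  cv <- glmnet::cv.glmnet(Mc, yy, family = fam, foldid = foldid,
                          standardize = FALSE)
  cf <- glmnet::coef.glmnet(cv$glmnet.fit, s = cv$lambda.min)
  if (single) cf <- list(cf)
  U <- do.call(cbind, lapply(cf, function(x) as.numeric(x)[-1]))
  dimnames(U) <- list(colnames(M), colnames(Y))
  structure(list(u = U, lambda = cv$lambda.min, method = "lasso",
                 foldid = foldid), class = "marker_effects")
}

#' Direction concordance of marker effects with allele-frequency trends
#'
#' For every (marker, trait): u_sign is the sign of the estimated marker
#' effect, rally_sign the sign of the RALLY year coefficient (both refer
#' to the same coded allele), and d = u_sign * rally_sign; d = +1 means
#' the allele rising in frequency raises the trait. Markers are also
#' classed by PC-adjusted significance: 1 below the Bonferroni threshold,
#' 2 between Bonferroni and `alpha`, 3 above `alpha`.
#'
#' @param effects a `marker_effects` object.
#' @param scan an adjusted scan from [pc_adjust()].
#' @param alpha nominal level separating classes 2 and 3.
#' @return data.frame with `marker_id`, `trait`, `u_sign`, `rally_sign`,
#'   `d`, `class` (markers without a converged RALLY fit are dropped).
#' @export
direction_table <- function(effects, scan, alpha = 0.05) {
  mk <- rownames(effects$u)
  row <- match(mk, scan$marker_id)
  if (anyNA(row))
    stop("alignment error: effect markers missing from the scan")
  ok <- scan$converged[row] & !is.na(scan$p_adj[row])
  thr <- attr(scan, "bonferroni_adj")
  cls <- ifelse(scan$p_adj[row] < thr, 1L,
                ifelse(scan$p_adj[row] < alpha, 2L, 3L))
  bsign <- sign(scan$beta_hat[row])
  out <- do.call(rbind, lapply(colnames(effects$u), function(tr) {
    data.frame(marker_id = mk, trait = tr,
               u_sign = sign(effects$u[, tr]),
               rally_sign = bsign, d = sign(effects$u[, tr]) * bsign,
               class = cls, stringsAsFactors = FALSE)[ok, ]
  }))
  rownames(out) <- NULL
  attr(out, "method") <- effects$method
  out
}

# Yates-corrected chi-square (df = 1) on a 2x2 count table
.yates_chisq <- function(tab) {
  stats::chisq.test(tab, correct = TRUE)
}

#' Pairwise trait contingency tests of effect directions
#'
#' For each trait pair, markers whose coded allele is increasing
#' (rally_sign = +1) and has a nonzero effect direction on both traits
#' are cross-classified into (+/+, +/-, -/+, -/-) and tested with a
#' Yates-corrected 1-df chi-square. Only meaningful for LASSO effects
#' (ridge effects are not independent). Significance is Bonferroni over
#' the C(T,2) pairs.
#'
#' @param dtab a [direction_table()] result (method "lasso").
#' @param alpha family-wise level.
#' @return data.frame per pair: counts `pp`, `pm`, `mp`, `mm`,
#'   `neglog10p`, `significant`, `skipped` (expected cell < 1).
#' @export
pairwise_tests <- function(dtab, alpha = 0.05) {
  if (!identical(attr(dtab, "method"), "lasso"))
    stop("pairwise tests are defined for LASSO effects only")
  traits <- unique(dtab$trait)
  pairs <- utils::combn(traits, 2)
  n_pairs <- ncol(pairs)
  thr <- -log10(alpha / n_pairs)
  inc <- dtab[dtab$rally_sign == 1 & dtab$d != 0, ]
  res <- lapply(seq_len(n_pairs), function(k) {
    t1 <- pairs[1, k]; t2 <- pairs[2, k]
    d1 <- inc[inc$trait == t1, c("marker_id", "d")]
    d2 <- inc[inc$trait == t2, c("marker_id", "d")]
    mg <- merge(d1, d2, by = "marker_id")
    tab <- matrix(c(sum(mg$d.x == 1 & mg$d.y == 1),
                    sum(mg$d.x == 1 & mg$d.y == -1),
                    sum(mg$d.x == -1 & mg$d.y == 1),
                    sum(mg$d.x == -1 & mg$d.y == -1)),
                  2, 2, byrow = TRUE)
    exp_ok <- all(outer(rowSums(tab), colSums(tab)) / max(1, sum(tab)) >= 1)
    nl <- if (exp_ok)
      -log10(suppressWarnings(.yates_chisq(tab)$p.value)) else NA_real_
    data.frame(trait1 = t1, trait2 = t2,
               pp = tab[1, 1], pm = tab[1, 2], mp = tab[2, 1], mm = tab[2, 2],
               neglog10p = nl,
               significant = !is.na(nl) && nl >= thr,
               skipped = !exp_ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "bonferroni_neglog10") <- thr
  out
}

#' Yates chi-square from the four direction counts
#'
#' Convenience wrapper used for worked examples: counts are (+/+, +/-,
#' -/+, -/-).
#'
#' @param pp,pm,mp,mm cell counts.
#' @return -log10 p of the Yates-corrected 1-df chi-square.
#' @export
pairwise_chisq <- function(pp, pm, mp, mm) {
  tab <- matrix(c(pp, pm, mp, mm), 2, 2, byrow = TRUE)
  -log10(.yates_chisq(tab)$p.value)
}
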