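#' Two-kinship local-heritability fit
#'
#' Fits y = X beta + g_a + g_b + e with g_a ~ N(0, s_ga K_a) built from
#' the markers of one QSL group and g_b ~ N(0, s_gb K_b) from all other
#' markers; the local heritability is s_ga / (s_ga + s_gb + s_e).
#'
#' @param y trait vector.
#' @param X fixed-effect design (mean, year, country dummies).
#' @param K_a,K_b group and background kinship matrices.
#' @return list with `sigma_ga2`, `sigma_gb2`, `sigma_e2`, `h2_l`,
#'   `loglik`, `converged`.
#' @export
fit_two_grm <- function(y, X = NULL, K_a, K_b) {
  if (length(y) < 30)
    warning("fewer than 30 observations: variance components will be imprecise")
  fit <- reml_multi(y, X, list(K_a, K_b))
  vc <- fit$varcomp
  list(sigma_ga2 = vc[1], sigma_gb2 = vc[2], sigma_e2 = vc[3],
       h2_l = vc[1] / sum(vc), loglik = fit$loglik,
       converged = fit$converged)
}

#' Likelihood-ratio test for a nonzero local heritability
#'
#' Compares the two-kinship model against the background-only model.
#' Because the group variance is tested on the boundary of its parameter
#' space, the null is the half-half mixture of a point mass at zero and a
#' 1-df chi-square.
#'
#' @param y,X,K_a,K_b as in [fit_two_grm()].
#' @return list with `lr`, `p`, `full`, `reduced`.
#' @export
lrt_nonzero <- function(y, X = NULL, K_a, K_b) {
  full <- reml_multi(y, X, list(K_a, K_b))
  reduced <- reml_multi(y, X, list(K_b))
  if (full$loglik < reduced$loglik - 1e-8) {
    # warm restart from the reduced optimum (group variance on the
    # boundary); the full model nests the reduced so this cannot be worse
    warm <- reml_multi(y, X, list(K_a, K_b),
                       init = c(1e-6 * stats::var(y), reduced$varcomp))
    if (warm$loglik > full$loglik) full <- warm
  }
  lr <- 2 * (full$loglik - reduced$loglik)
  if (lr < -1e-3)
    stop("optimization error: full model log-likelihood below reduced; refit")
  lr <- max(lr, 0)
  p <- if (lr <= 0) 1 else 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  list(lr = lr, p = p, full = full, reduced = reduced)
}

#' Local heritabilities of QSL groups across traits
#'
#' For each (trait, group) pair fits the two-kinship model; groups with
#' pairwise h2_l > 0.001 are then refitted jointly (one random term per
#' retained group plus the background) and the joint shares
#' s_ga / (sum_a s_ga + s_gb + s_e) are reported as the final local
#' heritabilities, together with the background ("others") share.
#'
#' @param panel a [genotype_panel()].
#' @param traits trait matrix (varieties x traits) as from
#'   [align_traits()], or a single named vector.
#' @param groups list of QSL groups from [group_significant()].
#' @param X optional fixed design (default mean + year).
#' @param min_cases traits with fewer complete cases are skipped.
#' @param h2_min threshold for retaining a group in the joint refit.
#' @return data.frame with one row per (trait, group) plus per-trait
#'   `Total` and `Others` rows; columns `trait`, `group`, `h2_pairwise`,
#'   `h2_joint`, `lrt_p`.
#' @export
local_h2_all <- function(panel, traits, groups, X = NULL, min_cases = 30,
                         h2_min = 0.001) {
  if (is.null(dim(traits))) traits <- cbind(trait = traits)
  G <- panel$genotypes
  m <- ncol(G)
  member_idx <- lapply(groups, function(g) match(g$members, colnames(G)))
  rows <- list()
  for (tr in colnames(traits)) {
    y_all <- traits[, tr]
    cc <- which(!is.na(y_all))
    if (length(cc) < min_cases) {
      message("skipping trait ", tr, ": only ", length(cc), " complete cases")
      next
    }
    y <- y_all[cc]
    Xt <- if (is.null(X)) cbind(1, panel$varieties$year[cc]) else
      as.matrix(X)[cc, , drop = FALSE]
    Gc <- G[cc, , drop = FALSE]
    pair_fits <- vector("list", length(groups))
    for (a in seq_along(groups)) {
      ma <- member_idx[[a]]
      K_a <- compute_grm(Gc[, ma, drop = FALSE])
      K_b <- compute_grm(Gc[, -ma, drop = FALSE])
      ft <- fit_two_grm(y, Xt, K_a, K_b)
      lp <- tryCatch(lrt_nonzero(y, Xt, K_a, K_b)$p, error = function(e) NA_real_)
      pair_fits[[a]] <- list(h2 = ft$h2_l, p = lp)
    }
    keep <- which(vapply(pair_fits, function(f) f$h2 > h2_min, logical(1)))
    h2_joint <- rep(0, length(groups))
    if (length(keep)) {
      Klist <- lapply(keep, function(a)
        compute_grm(Gc[, member_idx[[a]], drop = FALSE]))
      bg <- setdiff(seq_len(m), unlist(member_idx[keep]))
      Klist <- c(Klist, list(compute_grm(Gc[, bg, drop = FALSE])))
      jf <- reml_multi(y, Xt, Klist)
      tot <- sum(jf$varcomp)
      h2_joint[keep] <- jf$varcomp[seq_along(keep)] / tot
      others <- jf$varcomp[length(keep) + 1] / tot
    } else {
      bg_fit <- reml_multi(y, Xt, list(compute_grm(Gc)))
      others <- bg_fit$varcomp[1] / sum(bg_fit$varcomp)
    }
    gnames <- if (is.null(names(groups))) paste0("QSL", seq_along(groups))
              else names(groups)
    for (a in seq_along(groups)) {
      rows[[length(rows) + 1]] <- data.frame(
        trait = tr, group = gnames[a],
        h2_pairwise = pair_fits[[a]]$h2, h2_joint = h2_joint[a],
        lrt_p = pair_fits[[a]]$p, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- data.frame(
      trait = tr, group = "Total", h2_pairwise = NA_real_,
      h2_joint = sum(h2_joint), lrt_p = NA_real_, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      trait = tr, group = "Others", h2_pairwise = NA_real_,
      h2_joint = others, lrt_p = NA_real_, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
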