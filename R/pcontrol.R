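#' Genomic-control inflation factor
#'
#' lambda = median(Z^2) / qchisq(0.5, 1); the reference constant is the
#' exact chi-square(1 df) median 0.4549364.
#'
#' @param z vector of Z statistics (length >= 10).
#' @return inflation factor lambda.
#' @export
gc_lambda <- function(z) {
  z <- z[is.finite(z)]
  if (length(z) < 10) stop("estimation error: need >= 10 Z statistics")
  stats::median(z^2) / stats::qchisq(0.5, df = 1)
}

#' Select the null marker set from a RALLY scan
#'
#' Null markers are converged markers whose predicted absolute allele
#' frequency change over the panel's year span is below `t`; they are
#' assumed to reflect drift only.
#'
#' @param scan a [rally_scan()] result.
#' @param t threshold on |predicted delta p| (default 0.20).
#' @return integer vector of scan row indices.
#' @export
select_null <- function(scan, t = 0.20) {
  idx <- which(scan$converged & !is.na(scan$delta_p_hat) &
                 abs(scan$delta_p_hat) < t)
  if (!length(idx))
    stop("estimation error: empty null set; increase t")
  idx
}

# negative composite log-likelihood of the two-component reflection
# mixture: Z ~ 0.5 N(delta, sigma^2) + 0.5 N(-delta, sigma^2)
.nll_folded <- function(par, z) {
  delta <- par[1]; sigma <- par[2]
  if (sigma <= 0) return(Inf)
  a <- stats::dnorm(z, mean = delta, sd = sigma, log = TRUE)
  b <- stats::dnorm(z, mean = -delta, sd = sigma, log = TRUE)
  mx <- pmax(a, b)
  -sum(mx + log(0.5 * (exp(a - mx) + exp(b - mx))))
}

#' Folded-normal composite-likelihood fit of null Z statistics
#'
#' Under drift plus structure the null Z statistics behave as an
#' equal-weight mixture of N(delta, sigma^2) and N(-delta, sigma^2);
#' maximizing the composite likelihood over delta >= 0, sigma > 0 gives
#' the structure-induced mean shift and scale inflation. Multi-start
#' box-constrained quasi-Newton (L-BFGS-B).
#'
#' @param z_null vector of null-marker Z statistics (length >= 30).
#' @return list with `delta_hat`, `sigma_hat`, `loglik`, `degenerate`
#'   (TRUE when sigma hit its lower bound).
#' @export
fit_folded_normal <- function(z_null) {
  z <- z_null[is.finite(z_null)]
  if (length(z) < 30) stop("estimation error: need >= 30 null statistics")
  sig_lo <- 1e-4
  starts <- expand.grid(delta = c(0, mean(abs(z))),
                        sigma = unique(c(1, max(stats::sd(z), sig_lo))))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(c(starts$delta[s], starts$sigma[s]), .nll_folded, z = z,
                   method = "L-BFGS-B", lower = c(0, sig_lo),
                   upper = c(Inf, Inf),
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("estimation error: folded-normal optimizer failed from all starts")
  list(delta_hat = best$par[1], sigma_hat = best$par[2],
       loglik = -best$value, degenerate = best$par[2] <= sig_lo * 1.01)
}

#' Parametric control of a RALLY scan
#'
#' Estimates (delta, sigma) from the null marker set by folded-normal
#' composite likelihood, then standardizes every converged marker's
#' statistic as Z_adj = (|Z| - |delta|) / sigma. Because the folded null
#' makes only large |Z| evidence of selection, the adjusted p value is
#' upper-tail one-sided by default (`tail = "two"` doubles it).
#'
#' @param scan a [rally_scan()] result.
#' @param t null-set threshold on |predicted delta p|.
#' @param alpha family-wise level for the Bonferroni threshold on
#'   adjusted p values.
#' @param tail "one" (default) or "two".
#' @return the scan with added columns `z_adj`, `p_adj`, `significant`,
#'   plus attribute `pc_fit` (list: `t`, `null_index`, `delta_hat`,
#'   `sigma_hat`, `lambda_gc`, `loglik`).
#' @export
pc_adjust <- function(scan, t = 0.20, alpha = 0.05, tail = c("one", "two")) {
  tail <- match.arg(tail)
  null_idx <- select_null(scan, t)
  fit <- fit_folded_normal(scan$z[null_idx])
  lam <- gc_lambda(scan$z[null_idx])
  out <- scan
  out$z_adj <- (abs(out$z) - abs(fit$delta_hat)) / fit$sigma_hat
  out$p_adj <- stats::pnorm(out$z_adj, lower.tail = FALSE)
  if (tail == "two") out$p_adj <- pmin(1, 2 * out$p_adj)
  thr <- alpha / attr(scan, "m_fitted")
  out$significant <- !is.na(out$p_adj) & out$p_adj < thr
  attr(out, "pc_fit") <- list(t = t, null_index = null_idx,
                              delta_hat = fit$delta_hat,
                              sigma_hat = fit$sigma_hat,
                              lambda_gc = lam, loglik = fit$loglik,
                              degenerate = fit$degenerate)
  attr(out, "bonferroni_adj") <- thr
  out
}

#' Significance of the uncorrected scan
#'
#' @param scan a [rally_scan()] result.
#' @param alpha family-wise level.
#' @return logical vector over scan rows (Bonferroni on the unadjusted
#'   two-sided p).
#' @export
naive_significant <- function(scan, alpha = 0.05) {
  thr <- alpha / attr(scan, "m_fitted")
  !is.na(scan$p) & scan$p < thr
}

#' Null-set threshold calibration on a selected/unselected panel pair
#'
#' Runs the full PC pipeline on both panels of a pair over a grid of
#' null-set thresholds and reports the percentage of markers significant
#' in each, plus the uncorrected row (t = NA).
#'
#' @param scan_s,scan_u [rally_scan()] results for the selected and
#'   unselected panel.
#' @param t_grid thresholds (default 0.05..0.50 step 0.01).
#' @param alpha family-wise level.
#' @return data.frame with columns `t`, `pct_sig_s`, `pct_sig_u`.
#' @export
calibrate_threshold <- function(scan_s, scan_u,
                                t_grid = seq(0.05, 0.50, by = 0.01),
                                alpha = 0.05) {
  pct <- function(sig, scan) 100 * sum(sig) / nrow(scan)
  rows <- data.frame(t = NA_real_,
                     pct_sig_s = pct(naive_significant(scan_s, alpha), scan_s),
                     pct_sig_u = pct(naive_significant(scan_u, alpha), scan_u))
  for (t in t_grid) {
    ps <- tryCatch(pct(pc_adjust(scan_s, t, alpha)$significant, scan_s),
                   error = function(e) NA_real_)
    pu <- tryCatch(pct(pc_adjust(scan_u, t, alpha)$significant, scan_u),
                   error = function(e) NA_real_)
    rows <- rbind(rows, data.frame(t = t, pct_sig_s = ps, pct_sig_u = pu))
  }
  rows
}

#' Drift variance of an allele-frequency change
#'
#' @param p allele frequency in \[0, 1\].
#' @param N population size (> 0).
#' @return p(1-p) / (2N).
#' @export
drift_variance <- function(p, N) {
  if (any(N <= 0)) stop("domain error: N must be positive")
  if (any(p < 0 | p > 1)) stop("domain error: p must lie in [0, 1]")
  p * (1 - p) / (2 * N)
}
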