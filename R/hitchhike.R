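# Deterministic marker-QTL hitch-hiking under a forced sweep, and
# finite-sample power of the RALLY scan at increasing marker distances.

#' Forced QTL frequency trajectory
#'
#' Linear: p(t) = p0 + t (p_final - p0) / T. Logistic: the logit of p is
#' linear in t between logit(p0) and logit(p_final). Endpoints are exact.
#'
#' @param p0 initial frequency (0 < p0 < p_final).
#' @param p_final final frequency (< 1).
#' @param T number of generations.
#' @param shape "logistic" or "linear".
#' @return frequency path of length T + 1.
#' @export
qtl_trajectory <- function(p0, p_final = 31 / 32, T = 50,
                           shape = c("logistic", "linear")) {
  shape <- match.arg(shape)
  if (!(p0 > 0 && p0 < p_final && p_final < 1))
    stop("domain error: need 0 < p0 < p_final < 1")
  t <- 0:T
  if (shape == "linear") p0 + t * (p_final - p0) / T
  else stats::plogis(stats::qlogis(p0) +
                       t * (stats::qlogis(p_final) - stats::qlogis(p0)) / T)
}

#' Map distance to recombination fraction
#'
#' Haldane: theta = 0.5 (1 - exp(-2d)) with d in Morgans (input in cM);
#' Kosambi: theta = 0.5 tanh(2d).
#'
#' @param d_cm genetic distance in cM (>= 0).
#' @param map_function "haldane" (default) or "kosambi".
#' @return recombination fraction in \[0, 0.5).
#' @export
cm_to_theta <- function(d_cm, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(d_cm < 0)) stop("domain error: negative distance")
  d <- d_cm / 100
  if (map_function == "haldane") 0.5 * (1 - exp(-2 * d))
  else 0.5 * tanh(2 * d)
}

#' Expected marker frequency path under hitch-hiking
#'
#' Infinite-population recursion: per generation the conditional
#' marker-given-QTL frequencies relax toward the marginal as
#' f'(M|Q) = (1 - theta) f(M|Q) + theta f(M) (likewise given q), while
#' the QTL frequency follows the forced trajectory. The marker frequency
#' is the mixture p_q(t) f(M|Q) + (1 - p_q(t)) f(M|q).
#'
#' @param traj QTL frequency path from [qtl_trajectory()].
#' @param theta recombination fraction in \[0, 0.5\].
#' @param f_MQ,f_Mq initial conditional marker frequencies given the
#'   sweeping (Q) and alternative (q) allele.
#' @return numeric vector: expected marker frequency per generation
#'   (length of `traj`).
#' @export
marker_recursion <- function(traj, theta, f_MQ, f_Mq) {
  if (theta < 0 || theta > 0.5) stop("domain error: theta outside [0, 0.5]")
  stopifnot(f_MQ >= 0, f_MQ <= 1, f_Mq >= 0, f_Mq <= 1)
  Tn <- length(traj)
  fM <- numeric(Tn)
  a <- f_MQ; b <- f_Mq
  fM[1] <- traj[1] * a + (1 - traj[1]) * b
  for (t in 2:Tn) {
    m <- traj[t - 1] * a + (1 - traj[t - 1]) * b
    a <- (1 - theta) * a + theta * m
    b <- (1 - theta) * b + theta * m
    fM[t] <- traj[t] * a + (1 - traj[t]) * b
  }
  fM
}

#' Marker-QTL haplotype-frequency grid
#'
#' Enumerates initial conditional frequencies f(M|Q) and f(M|q) on a
#' 0..1 grid with the 32-founder granularity (step 1/8 by default),
#' keeping combinations whose implied marker frequency is polymorphic.
#'
#' @param p0 initial QTL frequency.
#' @param step grid step.
#' @return data.frame with `f_MQ`, `f_Mq`, `f_M`.
#' @export
haplotype_grid <- function(p0, step = 1 / 8) {
  g <- expand.grid(f_MQ = seq(0, 1, by = step), f_Mq = seq(0, 1, by = step))
  g$f_M <- p0 * g$f_MQ + (1 - p0) * g$f_Mq
  g[g$f_M > 0 & g$f_M < 1, , drop = FALSE]
}

#' Finite-sample power of RALLY on hitch-hiking markers
#'
#' For each marker distance and initial haplotype configuration, the
#' deterministic expected marker-frequency path is sampled (binomial, 2
#' trials per individual, `n_per_gen` individuals per generation) and
#' scanned with the single-marker RALLY fit; power is the fraction of
#' replicates significant at the Bonferroni level over the tested
#' markers.
#'
#' @param p0 initial QTL frequency.
#' @param distances_cm marker distances from the QTL in cM.
#' @param configs data.frame with columns `f_MQ`, `f_Mq` (defaults to
#'   the fully associated configuration f(M|Q)=1, f(M|q)=0).
#' @param shape trajectory shape.
#' @param T generations; `n_per_gen` individuals sampled per generation.
#' @param reps replicates per (distance, configuration).
#' @param alpha family-wise level (Bonferroni over the distances).
#' @param map_function passed to [cm_to_theta()].
#' @return data.frame per (distance, configuration): `power` and the
#'   expected final marker frequency.
#' @export
power_study <- function(p0 = 1 / 32, distances_cm = 1:10,
                        configs = data.frame(f_MQ = 1, f_Mq = 0),
                        shape = "logistic", T = 50, n_per_gen = 8,
                        reps = 100, alpha = 0.05,
                        map_function = "haldane") {
  traj <- qtl_trajectory(p0, shape = shape, T = T)
  years <- rep(1:T, each = n_per_gen)
  thr <- alpha / length(distances_cm)
  out <- list()
  for (ci in seq_len(nrow(configs))) {
    for (d in distances_cm) {
      th <- cm_to_theta(d, map_function)
      fM <- marker_recursion(traj, th, configs$f_MQ[ci], configs$f_Mq[ci])
      probs <- rep(fM[-1], each = n_per_gen) # generations 1..T
      hits <- 0L
      for (r in seq_len(reps)) {
        counts <- stats::rbinom(length(probs), 2, probs)
        fit <- tryCatch(fit_marker_logistic(counts, years),
                        error = function(e) NULL)
        if (!is.null(fit) && isTRUE(fit$converged) &&
            !is.na(fit$p) && fit$p < thr)
          hits <- hits + 1L
      }
      out[[length(out) + 1]] <- data.frame(
        distance_cm = d, f_MQ = configs$f_MQ[ci], f_Mq = configs$f_Mq[ci],
        power = hits / reps, final_freq = fM[length(fM)])
    }
  }
  do.call(rbind, out)
}
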