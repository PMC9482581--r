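#' Default simulated genome
#'
#' Ten chromosomes of 100, 120, ..., 280 cM with one marker every 0.1 cM
#' (19,000 markers in total).
#'
#' @param chrom_lengths_cm positive chromosome lengths in cM.
#' @param marker_spacing_cm marker spacing in cM; every length must be an
#'   exact multiple of the spacing.
#' @return A list with `chrom_lengths_cm` and `marker_spacing_cm`.
#' @export
genome_spec <- function(chrom_lengths_cm = seq(100, 280, by = 20),
                        marker_spacing_cm = 0.1) {
  stopifnot(all(chrom_lengths_cm > 0), marker_spacing_cm > 0)
  ratio <- chrom_lengths_cm / marker_spacing_cm
  if (any(abs(ratio - round(ratio)) > 1e-9))
    stop("spec error: each chromosome length must be divisible by the marker spacing")
  list(chrom_lengths_cm = chrom_lengths_cm,
       marker_spacing_cm = marker_spacing_cm)
}

#' Build the marker map of a simulated genome
#'
#' Markers sit at spacing, 2*spacing, ..., length on each chromosome, with
#' ids `c{chrom}m{idx}`.
#'
#' @param spec a [genome_spec()].
#' @return A marker map data.frame (`marker_id`, `chrom`, `cm`, `bp`).
#' @export
build_genome <- function(spec = genome_spec()) {
  n_per <- as.integer(round(spec$chrom_lengths_cm / spec$marker_spacing_cm))
  maps <- lapply(seq_along(n_per), function(c) {
    idx <- seq_len(n_per[c])
    data.frame(marker_id = sprintf("c%dm%d", c, idx),
               chrom = sprintf("%02d", c),
               cm = idx * spec$marker_spacing_cm,
               bp = NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, maps)
}

#' Simulate inbred founder haplotypes
#'
#' Per-marker derived-allele founder counts are drawn from the neutral site
#' frequency spectrum, P(k) proportional to 1/k for k = 1..(n-1). Carrier
#' sets persist along a chromosome (probability `persistence` per 0.1 cM
#' step of keeping the previous carrier set) so neighbouring markers are in
#' LD; at persistence 0 adjacent carrier sets are independent. Marker
#' columns are resampled until every founder count class 1..16 is realized
#' at two or more markers (needed for QTL assignment).
#'
#' @param map marker map from [build_genome()].
#' @param n_founders number of inbred founders (one haplotype each).
#' @param persistence probability per 0.1 cM step of carrying the previous
#'   carrier set forward; rescaled for other spacings.
#' @param max_tries resampling attempts before giving up.
#' @return A list with `haplotypes` (n_founders x m binary matrix) and
#'   `founder_count` (derived-allele count per marker).
#' @export
simulate_founders <- function(map, n_founders = 32L, persistence = 0.98,
                              max_tries = 20L) {
  m <- nrow(map)
  if (m == 0L) stop("empty marker map")
  kmax <- n_founders - 1L
  pk <- (1 / seq_len(kmax)) / sum(1 / seq_len(kmax))
  for (try in seq_len(max_tries)) {
    H <- matrix(0L, n_founders, m)
    counts <- integer(m)
    for (chr in unique(map$chrom)) {
      j_idx <- which(map$chrom == chr)
      cm <- map$cm[j_idx]
      prev <- NULL
      for (jj in seq_along(j_idx)) {
        step <- if (jj == 1L) Inf else (cm[jj] - cm[jj - 1L]) / 0.1
        keep <- !is.null(prev) && stats::runif(1) < persistence^step
        if (!keep) {
          k <- sample.int(kmax, 1L, prob = pk)
          prev <- sample.int(n_founders, k)
        }
        H[prev, j_idx[jj]] <- 1L
        counts[j_idx[jj]] <- length(prev)
      }
    }
    cls <- tabulate(counts, nbins = n_founders)
    if (all(cls[1:16] >= 2L))
      return(list(haplotypes = H, founder_count = counts))
  }
  stop("simulation error: could not realize >=2 markers in every founder count class 1..16")
}

# effect tier by founder-count class: 1 -> 4, 2-3 -> 3, 4-7 -> 2, 8-16 -> 1
qtl_tier_effect <- function(k) {
  ifelse(k == 1, 4, ifelse(k <= 3, 3, ifelse(k <= 7, 2, 1)))
}

#' Assign causal QTLs to founder markers
#'
#' Chooses two QTL markers at every founder frequency k/32 for k = 1..16
#' (32 QTLs), assigns tier effects (4, 3, 2, 1 for the rarest to the most
#' common classes) and rescales them so the total additive variance at the
#' founder frequencies, sum of 2 p(1-p) beta^2 over QTLs, equals 1. With a
#' residual variance of 1 this yields a broad-sense heritability of 0.5.
#'
#' @param founders output of [simulate_founders()].
#' @return A list with `qtl_index`, `founder_freq`, `raw_effect`,
#'   `scaled_effect` and `residual_var` (fixed at 1).
#' @export
assign_qtls <- function(founders) {
  counts <- founders$founder_count
  n_f <- nrow(founders$haplotypes)
  idx <- unlist(lapply(1:16, function(k) {
    pool <- which(counts == k)
    if (length(pool) < 2L)
      stop("simulation error: fewer than 2 markers at founder count ", k)
    sample(pool, 2L)
  }))
  p <- counts[idx] / n_f
  raw <- qtl_tier_effect(counts[idx])
  # for fully inbred lines count/2 is Bernoulli(p), so with genetic value
  # sum((count/2) * beta) the additive variance is sum p(1-p) beta^2;
  # rescale the tier effects so that sum equals 1 exactly
  v_raw <- sum(p * (1 - p) * raw^2)
  b <- raw / sqrt(v_raw)
  list(qtl_index = idx, founder_freq = p, raw_effect = raw,
       scaled_effect = b, residual_var = 1)
}

#' Additive genetic values and phenotypes
#'
#' Genetic value is sum((allele count / 2) * scaled effect) over the QTLs,
#' so residual heterozygotes contribute half an allele effect; the
#' phenotype adds N(0, residual_var) noise.
#'
#' @param genotypes allele-count matrix (varieties x markers, 0/1/2).
#' @param qtl QTL model from [assign_qtls()].
#' @param noise add residual noise (set `FALSE` for pure genetic values).
#' @return numeric vector of phenotypic (or genetic) values.
#' @export
phenotype <- function(genotypes, qtl, noise = TRUE) {
  g <- as.matrix(genotypes[, qtl$qtl_index, drop = FALSE]) %*% (qtl$scaled_effect / 2)
  g <- drop(g)
  if (noise) g <- g + stats::rnorm(length(g), 0, sqrt(qtl$residual_var))
  g
}

#' Classify significant markers by proximity to QTLs
#'
#' @param significant logical vector over the map's markers.
#' @param qtl QTL model ([assign_qtls()]), indices into `map` rows.
#' @param map marker map.
#' @param near_cm distance threshold in cM (same chromosome).
#' @return list with `near`, `far` and `pct_sig` (percent of all markers
#'   significant).
#' @export
evaluate_scan <- function(significant, qtl, map, near_cm = 5) {
  stopifnot(length(significant) == nrow(map))
  sig <- which(significant)
  if (!length(sig))
    return(list(near = 0L, far = 0L, pct_sig = 0))
  qchrom <- map$chrom[qtl$qtl_index]
  qcm <- map$cm[qtl$qtl_index]
  near <- vapply(sig, function(j) {
    same <- qchrom == map$chrom[j]
    any(same) && min(abs(qcm[same] - map$cm[j])) <= near_cm
  }, logical(1))
  list(near = sum(near), far = sum(!near),
       pct_sig = 100 * length(sig) / nrow(map))
}
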