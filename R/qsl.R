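#' Squared-correlation LD between two markers
#'
#' Squared Pearson correlation of allele counts across varieties,
#' pairwise-complete. `NA` when either marker is monomorphic among the
#' complete cases.
#'
#' @param panel a [genotype_panel()].
#' @param i,j marker indices or ids.
#' @return r-squared in \[0, 1\] or `NA`.
#' @export
ld_r2 <- function(panel, i, j) {
  G <- panel$genotypes
  if (is.character(i)) i <- match(i, colnames(G))
  if (is.character(j)) j <- match(j, colnames(G))
  cc <- stats::complete.cases(G[, i], G[, j])
  x <- G[cc, i]; y <- G[cc, j]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Group significant markers into quantitative selection loci
#'
#' Iterates significant markers by decreasing significance within each
#' chromosome: the current focal marker collects every still-unassigned
#' significant marker on its chromosome with r-squared above `r2_min`.
#' Groups smaller than `min_size` are discarded; groups sharing a member
#' are merged (transitive closure). Equally significant focal candidates
#' are broken by chromosome then position.
#'
#' @param scan an adjusted scan from [pc_adjust()] (needs `significant`
#'   and `p_adj` columns) or any data.frame with those columns aligned to
#'   the panel map.
#' @param panel the [genotype_panel()] the scan came from.
#' @param r2_min LD threshold for joining a focal marker's group.
#' @param min_size minimum members per retained group.
#' @return list of groups, each a list with `focal`, `members`, `chrom`,
#'   `peak_neglog10p`; empty list when nothing is significant.
#' @export
group_significant <- function(scan, panel, r2_min = 0.2, min_size = 10) {
  sig <- which(scan$significant)
  if (!length(sig)) return(list())
  G <- panel$genotypes
  p <- scan$p_adj[sig]
  ord <- sig[order(p, scan$chrom[sig], scan$cm[sig], method = "radix")]
  assigned <- integer(0)
  raw_groups <- list()
  for (focal in ord) {
    if (focal %in% assigned) next
    same_chr <- sig[scan$chrom[sig] == scan$chrom[focal]]
    cand <- setdiff(same_chr, assigned)
    r2 <- vapply(cand, function(j) {
      if (j == focal) return(1)
      v <- ld_r2(panel, focal, j)
      if (is.na(v)) 0 else v
    }, numeric(1))
    members <- cand[r2 > r2_min | cand == focal]
    assigned <- c(assigned, members)
    raw_groups[[length(raw_groups) + 1]] <-
      list(focal = focal, members = members)
  }
  # transitive-closure merge of groups sharing any member
  merged <- list()
  taken <- logical(length(raw_groups))
  for (i in seq_along(raw_groups)) {
    if (taken[i]) next
    mem <- raw_groups[[i]]$members
    repeat {
      grew <- FALSE
      for (j in seq_along(raw_groups)) {
        if (taken[j] || j == i) next
        if (length(intersect(mem, raw_groups[[j]]$members))) {
          mem <- union(mem, raw_groups[[j]]$members)
          taken[j] <- TRUE
          grew <- TRUE
        }
      }
      if (!grew) break
    }
    taken[i] <- TRUE
    merged[[length(merged) + 1]] <- list(focal = raw_groups[[i]]$focal,
                                         members = mem)
  }
  keep <- Filter(function(g) length(g$members) >= min_size, merged)
  lapply(keep, function(g) {
    list(focal = scan$marker_id[g$focal],
         members = scan$marker_id[g$members],
         chrom = scan$chrom[g$focal],
         peak_neglog10p = -log10(scan$p_adj[g$focal]))
  })
}

#' Physical interval of a QSL group
#'
#' Start/end are the min/max physical positions of the members mapped on
#' the focal marker's chromosome; members without a position (or on
#' another chromosome) stay in the membership but are excluded from the
#' interval.
#'
#' @param group one element of [group_significant()]'s result.
#' @param map marker map with `bp` positions.
#' @return list with `chrom`, `start_bp`, `end_bp`, `peak_bp`,
#'   `peak_neglog10p`, `n_members`.
#' @export
qsl_interval <- function(group, map) {
  rows <- map[match(group$members, map$marker_id), , drop = FALSE]
  on_chr <- rows[!is.na(rows$bp) & rows$chrom == group$chrom, , drop = FALSE]
  if (!nrow(on_chr))
    stop("no mapped members on the focal chromosome")
  focal_bp <- map$bp[match(group$focal, map$marker_id)]
  list(chrom = group$chrom, start_bp = min(on_chr$bp),
       end_bp = max(on_chr$bp), peak_bp = focal_bp,
       peak_neglog10p = group$peak_neglog10p,
       n_members = length(group$members))
}

#' Randomization test of interval overlap between two QSL/QTL sets
#'
#' The statistic is the number of intervals in set A overlapping any
#' interval in set B (same chromosome, positions intersecting). The null
#' re-places each A interval uniformly within its chromosome, preserving
#' its length; the two-tailed p is 2 * min(P(>= obs), P(<= obs)), capped
#' at 1.
#'
#' @param intervals_a,intervals_b data.frames with columns `chrom`,
#'   `start`, `end`.
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param n_perm permutation count.
#' @return list with `observed`, `p`, `null_mean`.
#' @export
overlap_randomization_test <- function(intervals_a, intervals_b,
                                       chrom_sizes, n_perm = 1e4) {
  a <- as.data.frame(intervals_a); b <- as.data.frame(intervals_b)
  if (!nrow(a) || !nrow(b)) stop("both interval sets must be nonempty")
  len <- a$end - a$start
  if (any(chrom_sizes[a$chrom] < len))
    stop("placement error: interval longer than its chromosome")
  count_overlap <- function(starts) {
    ends <- starts + len
    sum(vapply(seq_len(nrow(a)), function(i) {
      same <- b$chrom == a$chrom[i]
      any(same & b$start <= ends[i] & b$end >= starts[i])
    }, logical(1)))
  }
  obs <- count_overlap(a$start)
  null_stats <- vapply(seq_len(n_perm), function(k) {
    s <- stats::runif(nrow(a)) * (chrom_sizes[a$chrom] - len)
    count_overlap(s)
  }, numeric(1))
  p_hi <- mean(null_stats >= obs)
  p_lo <- mean(null_stats <= obs)
  list(observed = obs, p = min(1, 2 * min(p_hi, p_lo)),
       null_mean = mean(null_stats))
}
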