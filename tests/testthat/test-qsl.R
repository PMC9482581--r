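# build a panel with prescribed LD blocks plus a fake adjusted scan
.block_panel <- function(blocks, n = 80, seed = 1, chrom = NULL) {
  set.seed(seed)
  cols <- list(); labels <- character(0)
  for (b in seq_along(blocks)) {
    base <- rbinom(n, 2, 0.5)
    for (k in seq_len(blocks[b])) {
      noise <- rbinom(n, 1, 0.02)
      cols[[length(cols) + 1]] <- pmin(2, pmax(0, base + noise))
      labels <- c(labels, sprintf("b%dm%d", b, k))
    }
  }
  G <- do.call(cbind, cols)
  dimnames(G) <- list(paste0("v", 1:n), labels)
  if (is.null(chrom)) chrom <- rep("01", ncol(G))
  map <- data.frame(marker_id = labels, chrom = chrom,
                    cm = ave(seq_len(ncol(G)), chrom, FUN = seq_along),
                    bp = seq_len(ncol(G)) * 1000L)
  genotype_panel(G, map, data.frame(variety_id = paste0("v", 1:n),
                                    year = rep(1:8, length.out = n)))
}

.fake_scan <- function(panel, sig, p_adj = NULL) {
  m <- ncol(panel$genotypes)
  if (is.null(p_adj)) p_adj <- seq(1e-10, 1e-8, length.out = m)
  data.frame(marker_id = panel$map$marker_id, chrom = panel$map$chrom,
             cm = panel$map$cm, significant = sig, p_adj = p_adj,
             stringsAsFactors = FALSE)
}

test_that("LD r2 matches correlation identities", {
  pan <- .block_panel(c(3), n = 200, seed = 5)
  expect_gt(ld_r2(pan, 1, 2), 0.8)
  G <- pan$genotypes
  G2 <- cbind(G, comp = 2 - G[, 1])
  pan2 <- genotype_panel(G2, rbind(pan$map,
                                   data.frame(marker_id = "comp", chrom = "01",
                                              cm = 99, bp = 99000L)),
                         pan$varieties)
  expect_equal(ld_r2(pan2, "b1m1", "comp"), 1, tolerance = 1e-12)
  set.seed(6)
  big <- matrix(rbinom(1e4 * 2, 2, 0.5), 1e4, 2,
                dimnames = list(paste0("v", 1:1e4), c("a", "b")))
  pan3 <- genotype_panel(big, data.frame(marker_id = c("a", "b"),
                                         chrom = "01", cm = 1:2),
                         data.frame(variety_id = rownames(big),
                                    year = rep(1:10, 1000)))
  expect_lt(ld_r2(pan3, "a", "b"), 0.01)
})

test_that("grouping collects LD mates, filters size, merges overlaps", {
  pan <- .block_panel(c(12), n = 120, seed = 7)
  sc <- .fake_scan(pan, sig = rep(TRUE, 12))
  gr <- group_significant(sc, pan, min_size = 10)
  expect_length(gr, 1L)
  expect_length(gr[[1]]$members, 12L)

  # two independent blocks of 6: both below min_size
  pan2 <- .block_panel(c(6, 6), n = 120, seed = 8)
  sc2 <- .fake_scan(pan2, sig = rep(TRUE, 12))
  gr2 <- group_significant(sc2, pan2, min_size = 10)
  expect_length(gr2, 0L)
  # with min_size 5 they form two distinct groups
  gr2b <- group_significant(sc2, pan2, min_size = 5)
  expect_length(gr2b, 2L)
  expect_length(intersect(gr2b[[1]]$members, gr2b[[2]]$members), 0L)
})

test_that("group membership is invariant to allele recoding", {
  pan <- .block_panel(c(8, 5), n = 150, seed = 9)
  sc <- .fake_scan(pan, sig = rep(TRUE, 13))
  gr <- group_significant(sc, pan, min_size = 4)
  G2 <- pan$genotypes
  G2[, 3] <- 2 - G2[, 3]
  pan2 <- genotype_panel(G2, pan$map, pan$varieties)
  gr2 <- group_significant(sc, pan2, min_size = 4)
  expect_equal(lapply(gr, `[[`, "members"), lapply(gr2, `[[`, "members"))
})

test_that("intervals span member positions on the focal chromosome", {
  g <- list(focal = "m2", members = c("m1", "m2", "m3"), chrom = "01",
            peak_neglog10p = 8)
  map <- data.frame(marker_id = c("m1", "m2", "m3"),
                    chrom = c("01", "01", "01"),
                    cm = 1:3, bp = c(10L, 50L, 30L))
  iv <- qsl_interval(g, map)
  expect_equal(c(iv$start_bp, iv$end_bp), c(10L, 50L))
  expect_equal(iv$peak_bp, 50L)
  # single-member group degenerates to a point
  g1 <- list(focal = "m1", members = "m1", chrom = "01", peak_neglog10p = 5)
  iv1 <- qsl_interval(g1, map)
  expect_equal(iv1$start_bp, iv1$end_bp)
  # cross-chromosome member stays in the membership, out of the interval
  map2 <- map; map2$chrom[3] <- "02"
  iv2 <- qsl_interval(g, map2)
  expect_equal(c(iv2$start_bp, iv2$end_bp), c(10L, 50L))
  expect_equal(iv2$n_members, 3L)
})

test_that("overlap randomization test behaves at the extremes", {
  sizes <- c("01" = 1e6, "02" = 1e6)
  a <- data.frame(chrom = c("01", "02"), start = c(100, 200),
                  end = c(1100, 1200))
  set.seed(10)
  self <- overlap_randomization_test(a, a, sizes, n_perm = 2000)
  expect_lt(self$p, 0.05)
  whole <- data.frame(chrom = c("01", "02"), start = c(0, 0),
                      end = c(1e6, 1e6))
  set.seed(11)
  degen <- overlap_randomization_test(whole, a, sizes, n_perm = 200)
  expect_equal(degen$p, 1)
  expect_error(overlap_randomization_test(
    data.frame(chrom = "01", start = 0, end = 2e6), a, sizes, 10),
    "placement error")
})
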