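test_that("genome construction matches the marker-count bookkeeping", {
  map <- build_genome(genome_spec())
  expect_equal(nrow(map), 19000L)
  expect_equal(length(unique(map$chrom)), 10L)
  one <- build_genome(genome_spec(chrom_lengths_cm = 100,
                                  marker_spacing_cm = 1))
  expect_equal(nrow(one), 100L)
  expect_error(genome_spec(chrom_lengths_cm = 100, marker_spacing_cm = 0.3),
               "spec error")
})

test_that("founder generator realizes the 1/k spectrum with LD blocks", {
  map <- build_genome(genome_spec(chrom_lengths_cm = c(100, 100),
                                  marker_spacing_cm = 0.1))
  set.seed(11)
  f <- simulate_founders(map, persistence = 0.9)
  expect_equal(dim(f$haplotypes), c(32L, 2000L))
  expect_true(all(tabulate(f$founder_count, 32)[1:16] >= 2))
  expect_true(all(colSums(f$haplotypes) == f$founder_count))

  # persistence 0: adjacent carrier sets independent; counts follow 1/k
  set.seed(12)
  f0 <- simulate_founders(map, persistence = 0)
  r <- sapply(seq_len(500), function(j) {
    suppressWarnings(cor(f0$haplotypes[, j], f0$haplotypes[, j + 1]))
  })
  expect_lt(mean(r^2, na.rm = TRUE), 0.12) # near the 1/(n-1) null level
  pk <- (1 / (1:31)) / sum(1 / (1:31))
  gof <- suppressWarnings(
    chisq.test(tabulate(f0$founder_count, 31), p = pk))
  expect_gt(gof$p.value, 0.001)

  # two seeds differ but share the marginal law
  set.seed(13); fa <- simulate_founders(map, persistence = 0)
  expect_false(identical(fa$haplotypes, f0$haplotypes))
  gof2 <- suppressWarnings(
    chisq.test(tabulate(fa$founder_count, 31), p = pk))
  expect_gt(gof2$p.value, 0.001)
})

test_that("QTL assignment standardizes total additive variance to 1", {
  map <- build_genome(genome_spec(chrom_lengths_cm = c(100, 100),
                                  marker_spacing_cm = 0.1))
  set.seed(21)
  f <- simulate_founders(map, persistence = 0)
  q <- assign_qtls(f)
  expect_length(q$qtl_index, 32L)
  expect_equal(sort(table(q$founder_freq * 32)), sort(rep(2L, 16)),
               ignore_attr = TRUE)
  expect_equal(sum(q$founder_freq * (1 - q$founder_freq) * q$scaled_effect^2),
               1, tolerance = 1e-12)
  # tier map
  expect_equal(unique(q$raw_effect[q$founder_freq == 1 / 32]), 4)
  expect_equal(unique(q$raw_effect[q$founder_freq == 8 / 32]), 1)
  # single QTL at p = 0.5 with raw effect 1 scales to 2
  shares <- q$founder_freq * (1 - q$founder_freq) * q$scaled_effect^2
  expect_equal(max(shares) / 2, 0.0314155, tolerance = 1e-4)
})

test_that("meiosis recombinant fraction follows the Haldane closed form", {
  map <- data.frame(marker_id = c("a", "b"), chrom = "01", cm = c(0.01, 10.01))
  hapA <- c(0L, 0L); hapB <- c(1L, 1L)
  set.seed(31)
  rec <- mean(replicate(2e4, {
    g <- meiosis(hapA, hapB, map, chrom_lengths = 20)
    g[1] != g[2]
  }))
  expect_lt(abs(rec - 0.5 * (1 - exp(-0.2))), 0.008)
  # identical parents reproduce themselves
  expect_equal(meiosis(hapA, hapA, map, chrom_lengths = 20), hapA)
})

test_that("F6 RILs keep the Mendelian residual heterozygosity", {
  map <- data.frame(marker_id = c("a", "b"), chrom = c("01", "02"),
                    cm = c(50, 50))
  set.seed(41)
  rils <- derive_rils(rep(0L, 2), rep(2L, 2), 5000, map,
                      chrom_lengths = c(100, 100))
  # F2 is half heterozygous after selfing the F1; four more selfings
  # halve that each time: (1/2)^5 at F6
  het <- mean(rils == 1)
  expect_lt(abs(het - (1 / 2)^5), 0.01)
  # allele frequency stays at 1/2 per parent for unlinked markers
  expect_equal(mean(rils) / 2, 0.5, tolerance = 0.02)
  expect_error(derive_rils(c(0L, 1L), rep(2L, 2), 5, map), "inbred")
  same <- derive_rils(rep(2L, 2), rep(2L, 2), 10, map,
                      chrom_lengths = c(100, 100))
  expect_true(all(same == 2))
})

test_that("dense RIL derivation and program panel agree on marginals", {
  pp <- small_sim()
  sel <- pp$selected; uns <- pp$unselected
  expect_equal(nrow(sel$genotypes), 400L)
  expect_equal(unname(table(sel$varieties$year)), rep(8L, 50),
               ignore_attr = TRUE)
  # selection raises the phenotype over years; no trend without selection
  b_sel <- coef(lm(sel$phenotype ~ sel$varieties$year))[2]
  fit_u <- summary(lm(uns$phenotype ~ uns$varieties$year))
  expect_gt(b_sel, 0)
  expect_lt(abs(fit_u$coefficients[2, 1]),
            4 * fit_u$coefficients[2, 2] + 0.05)
  # phenotype = genetic value + unit noise; use the unselected panel since
  # truncation selection shrinks the retained lines' residuals
  resid <- uns$phenotype - uns$genetic_value
  expect_lt(abs(var(resid) - 1), 0.25)
})

test_that("selected QTL alleles rise in frequency; unselected drift is symmetric", {
  pp <- small_sim()
  qidx <- pp$qtl$qtl_index
  first <- pp$selected$varieties$year <= 10
  last <- pp$selected$varieties$year > 40
  f0 <- colMeans(pp$selected$genotypes[first, qidx, drop = FALSE]) / 2
  f1 <- colMeans(pp$selected$genotypes[last, qidx, drop = FALSE]) / 2
  expect_gt(mean(f1 - f0), 0)
  # unselected panel: frequency changes are sign-symmetric
  u0 <- colMeans(pp$unselected$genotypes[first, , drop = FALSE]) / 2
  u1 <- colMeans(pp$unselected$genotypes[last, , drop = FALSE]) / 2
  dch <- (u1 - u0)[abs(u1 - u0) > 1e-9]
  bt <- binom.test(sum(dch > 0), length(dch))
  expect_gt(bt$p.value, 1e-6)
})

test_that("scan evaluation classifies near/far markers and percentages", {
  map <- build_genome(genome_spec(chrom_lengths_cm = c(100, 100),
                                  marker_spacing_cm = 0.1))
  qtl <- list(qtl_index = c(500L, 1500L)) # 50 cM on each chromosome
  sig <- rep(FALSE, nrow(map))
  sig[c(500, 520, 1500, 1900)] <- TRUE # 520 is 2 cM away; 1900 is 40 cM
  ev <- evaluate_scan(sig, qtl, map, near_cm = 5)
  expect_equal(ev$near, 3L)
  expect_equal(ev$far, 1L)
  expect_equal(ev$pct_sig, 100 * 4 / 2000)
  none <- evaluate_scan(rep(FALSE, nrow(map)), qtl, map)
  expect_equal(unlist(none), c(near = 0, far = 0, pct_sig = 0))
})

test_that("markers within 5 cM of 32 spaced QTLs total 3200 at 0.1 cM", {
  map <- build_genome(genome_spec())
  # place QTLs far apart: 32 positions, one per 50 cM alternating chromosomes
  qidx <- integer(32)
  per_chr <- split(seq_len(nrow(map)), map$chrom)
  k <- 1L
  for (chr in names(per_chr)) {
    idx <- per_chr[[chr]]
    want <- seq(20, max(map$cm[idx]) - 20, by = 40)
    centers <- idx[vapply(map$cm[idx],
                          function(x) any(abs(x - want) < 1e-9), logical(1))]
    take <- utils::head(centers, 4)
    for (q in take) { if (k <= 32) { qidx[k] <- q; k <- k + 1L } }
  }
  qidx <- qidx[qidx > 0][1:32]
  near <- sum(vapply(seq_len(nrow(map)), function(j) {
    same <- map$chrom[qidx] == map$chrom[j]
    any(same) && min(abs(map$cm[qidx[same]] - map$cm[j])) <= 5
  }, logical(1)))
  expect_equal(near, 32 * 100 + 32) # 100 neighbours within +/-5 cM plus the QTL
})
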