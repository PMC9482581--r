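test_that("single-marker fit matches the general-purpose GLM oracle", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 80
    yr <- sample(1:25, n, replace = TRUE)
    cov1 <- rnorm(n)
    cnt <- rbinom(n, 2, plogis(-0.5 + 0.07 * (yr - mean(yr)) + 0.4 * cov1))
    if (var(cnt) == 0) next
    f <- fit_marker_logistic(cnt, yr, covariates = cbind(cov1))
    g <- glm(cbind(cnt, 2 - cnt) ~ I(yr - mean(yr)) + cov1,
             family = binomial())
    expect_equal(f$beta_hat, unname(coef(g)[2]), tolerance = 1e-6)
    expect_equal(f$se, unname(sqrt(vcov(g)[2, 2])), tolerance = 1e-5)
  }
})

test_that("monomorphic and separated markers are flagged, not fitted", {
  yr <- 1:5
  mono <- fit_marker_logistic(c(2, 2, 2, 2, 2), yr)
  expect_true(mono$monomorphic)
  expect_false(mono$converged)
  sep <- fit_marker_logistic(c(0, 0, 2, 2, 2), yr)
  expect_false(sep$converged)
  expect_true(is.na(sep$p))
  ok <- fit_marker_logistic(c(0, 2, 0, 2, 2), yr)
  expect_true(ok$converged)
  g <- glm(cbind(k, 2 - k) ~ I(yr - 3), data = list(k = c(0, 2, 0, 2, 2)),
           family = binomial())
  expect_equal(ok$beta_hat, unname(coef(g)[2]), tolerance = 1e-6)
})

test_that("two-year design recovers the log odds-ratio in closed form", {
  yr <- rep(c(0L, 1L), each = 20)
  set.seed(7)
  cnt <- c(rbinom(20, 2, 0.3), rbinom(20, 2, 0.6))
  f <- fit_marker_logistic(cnt, yr)
  p0 <- sum(cnt[yr == 0]) / 40; p1 <- sum(cnt[yr == 1]) / 40
  expect_equal(f$beta_hat, qlogis(p1) - qlogis(p0), tolerance = 1e-8)
})

test_that("allele recoding flips coefficients and preserves |Z| and p", {
  pan <- toy_panel(n = 60, m = 8, seed = 5)
  sc <- rally_scan(pan, maf_min = 0)
  G2 <- 2 - pan$genotypes
  pan2 <- genotype_panel(G2, pan$map, pan$varieties)
  sc2 <- rally_scan(pan2, maf_min = 0)
  ok <- sc$converged & sc2$converged
  expect_equal(sc2$beta_hat[ok], -sc$beta_hat[ok], tolerance = 1e-8)
  expect_equal(sc2$mu_hat_centered[ok], -sc$mu_hat_centered[ok],
               tolerance = 1e-8)
  expect_equal(abs(sc2$z[ok]), abs(sc$z[ok]), tolerance = 1e-8)
  expect_equal(sc2$p[ok], sc$p[ok], tolerance = 1e-8)
  expect_equal(sc2$delta_p_hat[ok], sc$delta_p_hat[ok], tolerance = 1e-8)
})

test_that("|Z| on a deterministic sweep grows with varieties per year", {
  path <- plogis(seq(qlogis(0.1), qlogis(0.9), length.out = 25))
  zs <- sapply(c(8, 16, 32), function(nper) {
    mean(sapply(1:5, function(s) {
      set.seed(1000 + s)
      yr <- rep(1:25, each = nper)
      cnt <- rbinom(length(yr), 2, rep(path, each = nper))
      abs(fit_marker_logistic(cnt, yr)$z)
    }))
  })
  expect_true(all(diff(zs) > 0))
})

test_that("scan applies maf filter and Bonferroni over fitted markers", {
  set.seed(9)
  n <- 100
  G <- cbind(m1 = rbinom(n, 2, 0.5),
             m2 = c(1, rep(0, n - 1)),        # maf 0.005 -> filtered
             m3 = rbinom(n, 2, 0.4))
  rownames(G) <- paste0("v", 1:n)
  pan <- genotype_panel(G, toy_map(3),
                        data.frame(variety_id = paste0("v", 1:n),
                                   year = rep(1:20, each = 5)))
  sc <- rally_scan(pan, maf_min = 0.01)
  expect_false(sc$fitted[sc$marker_id == "m2"])
  expect_equal(attr(sc, "m_fitted"), 2L)
  expect_equal(attr(sc, "bonferroni"), 0.05 / 2)
})

test_that("predicted frequency change evaluates the logistic difference", {
  expect_equal(predicted_delta_p(0, 0, 0, 50), 0)
  expect_equal(predicted_delta_p(0, 0.1, 0, 50), plogis(5) - 0.5,
               tolerance = 1e-12)
  expect_equal(predicted_delta_p(0, -0.1, 0, 50),
               predicted_delta_p(0, 0.1, 0, 50))
})

test_that("cross-chromosome LD pruning follows the sequential-drop rule", {
  set.seed(31)
  n <- 50
  a <- rbinom(n, 2, 0.5)
  ind <- replicate(3, rbinom(n, 2, 0.5))
  # A (chr1) duplicated as B and C (chr2): A is visited first and dropped,
  # then B and C survive (their mutual LD is within-chromosome)
  G <- cbind(A = a, x1 = ind[, 1], B = a, C = a, x2 = ind[, 2])
  rownames(G) <- paste0("v", 1:n)
  map <- data.frame(marker_id = c("A", "x1", "B", "C", "x2"),
                    chrom = c("01", "01", "02", "02", "02"),
                    cm = c(1, 2, 1, 2, 3))
  pan <- genotype_panel(G, map,
                        data.frame(variety_id = paste0("v", 1:n),
                                   year = rep(1:10, 5)))
  pr <- prune_cross_chromosome_ld(pan, 0.2)
  expect_setequal(pr$map$marker_id, c("x1", "B", "C", "x2"))
  expect_equal(attr(pr, "n_pruned"), 1L)
  # independent markers are untouched
  G2 <- ind; colnames(G2) <- paste0("m", 1:3); rownames(G2) <- paste0("v", 1:n)
  pan2 <- genotype_panel(G2, toy_map(3),
                         data.frame(variety_id = paste0("v", 1:n),
                                    year = rep(1:10, 5)))
  pr2 <- prune_cross_chromosome_ld(pan2, 0.2)
  expect_equal(ncol(pr2$genotypes), 3L)
})

test_that("rare countries are merged before dummy coding", {
  v <- data.frame(variety_id = paste0("v", 1:12),
                  year = 1:12,
                  country = c(rep("UK", 6), rep("FR", 5), "DE"))
  d <- country_dummies(v, min_n = 5)
  expect_equal(ncol(d), 2L) # UK/FR/other -> 2 dummies
})
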