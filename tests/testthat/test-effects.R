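.effects_panel <- function(n = 120, m = 200, seed = 1, h2 = 0.5, nqtl = 8) {
  set.seed(seed)
  G <- sapply(runif(m, 0.15, 0.85), function(p) rbinom(n, 2, p))
  dimnames(G) <- list(paste0("v", 1:n), paste0("g", 1:m))
  b <- numeric(m); qt <- sample(m, nqtl); b[qt] <- rnorm(nqtl, 0, 1)
  gv <- drop(scale((G - 1) %*% b))
  y <- sqrt(h2) * gv + rnorm(n, 0, sqrt(1 - h2))
  pan <- genotype_panel(G, data.frame(marker_id = colnames(G), chrom = "01",
                                      cm = seq_len(m)),
                        data.frame(variety_id = rownames(G),
                                   year = rep(1:20, length.out = n)))
  list(panel = pan, y = y, qtl = qt, b = b)
}

test_that("ridge dual solution equals the primal closed form", {
  sim <- .effects_panel(n = 60, m = 150, seed = 2)
  fit <- fit_ridge(sim$panel, cbind(y = sim$y))
  lam <- fit$lambda["y"]
  M <- sim$panel$genotypes - 1
  n <- nrow(M)
  # primal oracle at the same lambda and GLS mean
  H <- tcrossprod(M) + diag(lam, n)
  mu <- sum(solve(H, rep(1, n)) * sim$y) / sum(solve(H, rep(1, n)))
  u_primal <- solve(crossprod(M) + diag(lam, ncol(M)),
                    crossprod(M, sim$y - mu))
  expect_equal(unname(fit$u[, "y"]), unname(drop(u_primal)),
               tolerance = 1e-6)
})

test_that("ridge limits: infinite shrinkage kills effects, none gives OLS", {
  set.seed(3)
  n <- 50
  x <- rbinom(n, 2, 0.5)
  y <- 0.4 * (x - 1) + rnorm(n, 0, 0.3)
  M <- cbind(x - 1)
  # lambda -> large: effects -> 0
  u_big <- drop(crossprod(M, solve(tcrossprod(M) + diag(1e8, n), y - mean(y))))
  expect_lt(abs(u_big), 1e-4)
  # lambda -> 0 on a single marker with an unpenalized intercept: OLS
  A <- cbind(1, M)
  sol <- solve(crossprod(A) + diag(c(0, 1e-10)), crossprod(A, y))
  ols <- coef(lm(y ~ M))
  expect_equal(drop(sol), unname(ols), tolerance = 1e-6)
})

test_that("single-trait LASSO reproduces soft thresholding when orthonormal", {
  set.seed(4)
  n <- 64
  Q <- qr.Q(qr(matrix(rnorm(n * n), n)))[, 1:8] * sqrt(n)
  bt <- c(2, -1.5, 0.8, 0.3, 0, 0, 0, 0)
  y <- drop(Q %*% bt)
  lam <- 0.4
  g <- glmnet::glmnet(Q, y, lambda = lam, standardize = FALSE,
                      intercept = FALSE, thresh = 1e-12)
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  oracle <- soft(drop(crossprod(Q, y)) / n, lam)
  expect_equal(as.numeric(g$beta), oracle, tolerance = 1e-6)
})

test_that("multi-task LASSO enforces shared support across traits", {
  sim <- .effects_panel(n = 100, m = 80, seed = 5)
  y2 <- rnorm(100) # second trait: pure noise
  fit <- fit_lasso(sim$panel, cbind(t1 = sim$y, t2 = y2), seed = 9)
  nz1 <- fit$u[, "t1"] != 0
  nz2 <- fit$u[, "t2"] != 0
  expect_equal(nz1, nz2)
  expect_gt(sum(nz1), 0)
  # the noise trait gets smaller coefficients on the shared support
  expect_lt(mean(abs(fit$u[nz2, "t2"])), mean(abs(fit$u[nz1, "t1"])) + 1e-9)
})

test_that("direction concordance is the sign product and recoding-invariant", {
  sim <- .effects_panel(n = 120, m = 60, seed = 6)
  sc <- rally_scan(sim$panel, maf_min = 0)
  adj <- pc_adjust(sc, t = 0.99)
  eff <- fit_ridge(sim$panel, cbind(y = sim$y))
  dt <- direction_table(eff, adj)
  expect_true(all(dt$d == dt$u_sign * dt$rally_sign))
  expect_true(all(dt$class %in% 1:3))
  # recode one marker: both signs flip, product invariant
  G2 <- sim$panel$genotypes; G2[, 5] <- 2 - G2[, 5]
  pan2 <- genotype_panel(G2, sim$panel$map, sim$panel$varieties)
  adj2 <- pc_adjust(rally_scan(pan2, maf_min = 0), t = 0.99)
  eff2 <- fit_ridge(pan2, cbind(y = sim$y))
  dt2 <- direction_table(eff2, adj2)
  j <- dt$marker_id == "g5"
  expect_equal(dt2$d[j], dt$d[j])
  expect_equal(dt2$u_sign[j], -dt$u_sign[j])
})

test_that("pairwise Yates chi-square matches printed worked examples", {
  expect_equal(pairwise_chisq(270, 43, 145, 59), 4.435, tolerance = 0.01)
  expect_equal(pairwise_chisq(75, 56, 59, 327), 20.083, tolerance = 0.01)
  # brute-force oracle for the Yates statistic
  yates_oracle <- function(o) {
    o <- matrix(o, 2, 2, byrow = TRUE)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    x2 <- sum((abs(o - e) - 0.5)^2 / e)
    -log10(pchisq(x2, 1, lower.tail = FALSE))
  }
  for (cnt in list(c(270, 43, 145, 59), c(75, 56, 59, 327),
                   c(40, 10, 12, 44))) {
    expect_equal(pairwise_chisq(cnt[1], cnt[2], cnt[3], cnt[4]),
                 yates_oracle(cnt), tolerance = 1e-6)
  }
  # independence-exact counts give a tiny statistic
  expect_lt(pairwise_chisq(50, 50, 50, 50), 0.05)
})

test_that("pairwise tests count increasing alleles with nonzero directions", {
  sim <- .effects_panel(n = 120, m = 60, seed = 8)
  y2 <- sim$y * -0.8 + rnorm(120, 0, 0.5)
  adj <- pc_adjust(rally_scan(sim$panel, maf_min = 0), t = 0.99)
  eff <- fit_lasso(sim$panel, cbind(t1 = sim$y, t2 = y2), seed = 3)
  dt <- direction_table(eff, adj)
  pw <- pairwise_tests(dt)
  expect_equal(nrow(pw), 1L)
  expect_equal(attr(pw, "bonferroni_neglog10"), -log10(0.05 / 1))
  expect_equal(pw$pp + pw$pm + pw$mp + pw$mm,
               length(intersect(
                 dt$marker_id[dt$trait == "t1" & dt$rally_sign == 1 & dt$d != 0],
                 dt$marker_id[dt$trait == "t2" & dt$rally_sign == 1 & dt$d != 0])))
  # ridge effects are refused
  effr <- fit_ridge(sim$panel, cbind(t1 = sim$y, t2 = y2))
  dtr <- direction_table(effr, adj)
  expect_error(pairwise_tests(dtr), "LASSO")
})

test_that("Bonferroni threshold for 12 traits matches the printed constant", {
  expect_equal(-log10(0.05 / choose(12, 2)), 3.121, tolerance = 0.001)
})
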