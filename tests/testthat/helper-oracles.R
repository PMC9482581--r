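# Independent oracle for the hitch-hiking recursion: full 4-haplotype
# dynamics (MQ, Mq, mQ, mq) — recombination toward linkage equilibrium,
# then the forced QTL-frequency rescale within Q and q classes.
.haplo_oracle <- function(traj, theta, f_MQ, f_Mq) {
  p0 <- traj[1]
  h <- c(MQ = p0 * f_MQ, Mq = (1 - p0) * f_Mq,
         mQ = p0 * (1 - f_MQ), mq = (1 - p0) * (1 - f_Mq))
  fM <- numeric(length(traj))
  fM[1] <- h[["MQ"]] + h[["Mq"]]
  for (t in 2:length(traj)) {
    pM <- h[["MQ"]] + h[["Mq"]]; pQ <- h[["MQ"]] + h[["mQ"]]
    D <- h[["MQ"]] - pM * pQ
    h <- c(MQ = h[["MQ"]] - theta * D, Mq = h[["Mq"]] + theta * D,
           mQ = h[["mQ"]] + theta * D, mq = h[["mq"]] - theta * D)
    pQ <- h[["MQ"]] + h[["mQ"]]
    scaleQ <- traj[t] / pQ; scaleq <- (1 - traj[t]) / (1 - pQ)
    h <- c(MQ = h[["MQ"]] * scaleQ, Mq = h[["Mq"]] * scaleq,
           mQ = h[["mQ"]] * scaleQ, mq = h[["mq"]] * scaleq)
    fM[t] <- h[["MQ"]] + h[["Mq"]]
  }
  fM
}

# simulate a trait with prescribed variance shares on two marker sets
.sim_two_set <- function(n = 200, ma = 60, mb = 240, s_a = 0.3, s_b = 0.3,
                         s_e = 0.4, seed = 1) {
  set.seed(seed)
  Ga <- sapply(runif(ma, 0.2, 0.8), function(p) rbinom(n, 2, p))
  Gb <- sapply(runif(mb, 0.2, 0.8), function(p) rbinom(n, 2, p))
  K_a <- compute_grm(Ga); K_b <- compute_grm(Gb)
  ga <- drop(crossprod(chol(K_a + diag(1e-6, n)), rnorm(n)))
  gb <- drop(crossprod(chol(K_b + diag(1e-6, n)), rnorm(n)))
  y <- sqrt(s_a) * scale(ga) + sqrt(s_b) * scale(gb) +
    rnorm(n, 0, sqrt(s_e))
  list(y = drop(y), K_a = K_a, K_b = K_b, Ga = Ga, Gb = Gb)
}

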