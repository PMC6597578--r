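# Independent oracles, kept deliberately naive and separate from the
# package implementation.

# Brute-force gene-level CN assignment: for every gene x sample,
# enumerate overlapping segments and apply argmax |severity| directly
# (ties: larger overlap, then the positive state).
oracle_gene_cn <- function(segments, genes) {
  sev_map <- c(NEUT = 0, HOMD = -2, AMP = 2, HETD = -1, GAIN = 1)
  samples <- unique(segments$sample)
  states <- matrix(NA_character_, nrow(genes), length(samples),
                   dimnames = list(genes$gene, samples))
  lr <- matrix(NA_real_, nrow(genes), length(samples),
               dimnames = list(genes$gene, samples))
  for (gi in seq_len(nrow(genes))) {
    for (s in samples) {
      seg <- segments[segments$sample == s &
                        segments$chrom == genes$chrom[gi] &
                        segments$start < genes$end[gi] &
                        segments$end > genes$start[gi], ]
      if (nrow(seg) == 0) next
      sev <- sev_map[seg$state]
      ovl <- pmin(seg$end, genes$end[gi]) - pmax(seg$start, genes$start[gi])
      best <- which(abs(sev) == max(abs(sev)))
      if (length(best) > 1) best <- best[ovl[best] == max(ovl[best])]
      if (length(best) > 1) best <- best[which.max(sev[best])]
      states[gi, s] <- seg$state[best]
      lr[gi, s] <- seg$logratio[best]
    }
  }
  list(states = states, logratio = lr)
}

# Textbook Newton-Raphson fit of the Cox partial likelihood with the
# Efron tie correction, written directly from the estimating equations.
oracle_coxph <- function(time, event, X, tol = 1e-10, maxit = 50) {
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    w <- exp(eta)
    U <- rep(0, p)
    I <- matrix(0, p, p)
    ll <- 0
    for (t0 in sort(unique(time[event == 1]))) {
      D <- which(time == t0 & event == 1)
      R <- which(time >= t0)
      d <- length(D)
      s0r <- sum(w[R]); s1r <- colSums(w[R] * X[R, , drop = FALSE])
      s2r <- crossprod(sqrt(w[R]) * X[R, , drop = FALSE])
      s0d <- sum(w[D]); s1d <- colSums(w[D] * X[D, , drop = FALSE])
      s2d <- crossprod(sqrt(w[D]) * X[D, , drop = FALSE])
      for (l in seq_len(d) - 1) {
        s0 <- s0r - (l / d) * s0d
        s1 <- s1r - (l / d) * s1d
        s2 <- s2r - (l / d) * s2d
        ll <- ll - log(s0)
        U <- U - s1 / s0
        I <- I + s2 / s0 - tcrossprod(s1 / s0)
      }
      ll <- ll + sum(eta[D])
      U <- U + colSums(X[D, , drop = FALSE])
    }
    step <- solve(I, U)
    beta <- beta + step
    if (sqrt(sum(U^2)) < tol) break
  }
  list(coef = beta, loglik = ll)
}

# Exhaustive-scan ROC cutoff: try all midpoints of sorted unique
# scores plus sentinels; maximize sensitivity + specificity,
# tie-break to the smallest candidate.
oracle_best_cutoff <- function(score, label) {
  u <- sort(unique(score))
  cands <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  best <- -Inf; best_c <- NA_real_
  for (cc in cands) {
    sens <- mean(score[label == 1] > cc)
    spec <- mean(score[label == 0] <= cc)
    if (sens + spec > best + 1e-12) {
      best <- sens + spec; best_c <- cc
    }
  }
  best_c
}

# Plain DerSimonian-Laird pooling of Fisher-z correlations written
# straight from the moment-estimator formulas.
oracle_dl <- function(rho, n) {
  z <- atanh(rho)
  v <- 1 / (n - 3)
  w <- 1 / v
  zf <- sum(w * z) / sum(w)
  Q <- sum(w * (z - zf)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (length(z) - 1)) / C)
  ws <- 1 / (v + tau2)
  list(effect = tanh(sum(ws * z) / sum(ws)), tau2 = tau2)
}
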