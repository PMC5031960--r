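# Amino-acid substitution machinery: reversible rate matrix from an
# empirical exchangeability set, transition probabilities via spectral
# decomposition, and discrete-Gamma rate heterogeneity.

aa_models <- function() c("LG", "Poisson")

# Build the normalized (1 expected substitution/site) rate matrix Q and
# its spectral decomposition for fast expm(Q t).
aa_model <- function(model = "LG") {
  model <- match.arg(model, aa_models())
  k <- 20L
  if (model == "LG") {
    ex <- .lg_exch
    pi <- .lg_freq
  } else {
    ex <- rep(1, 190)
    pi <- rep(1 / 20, 20)
  }
  S <- matrix(0, k, k, dimnames = list(.aa_alphabet, .aa_alphabet))
  S[upper.tri(S)] <- 0
  idx <- 1L
  for (j in 1:(k - 1)) for (i in (j + 1):k) {
    S[i, j] <- S[j, i] <- ex[idx]
    idx <- idx + 1L
  }
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  # symmetrize: B = diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(
    name = model, pi = pi, Q = Q,
    values = e$values,
    U = diag(1 / sp) %*% e$vectors,      # right eigenvectors of Q
    Uinv = t(e$vectors) %*% diag(sp)
  )
}

# P(t) = U exp(diag(values t)) U^{-1}, rows sum to 1.
aa_pmatrix <- function(mod, t) {
  P <- mod$U %*% (exp(mod$values * t) * mod$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

# Mean rates of k equal-probability discrete-Gamma categories with shape
# `alpha` (mean 1): r_i proportional to incomplete-gamma differences.
discrete_gamma_rates <- function(alpha, k = 4L) {
  if (k == 1L) return(1)
  q <- stats::qgamma(seq_len(k - 1) / k, shape = alpha, rate = alpha)
  # mean within each equal-probability bin via the incomplete gamma of
  # shape alpha+1 (mean-one parameterization)
  upper <- c(stats::pgamma(q, shape = alpha + 1, rate = alpha), 1)
  lower <- c(0, stats::pgamma(q, shape = alpha + 1, rate = alpha))
  r <- (upper - lower) * k
  r / mean(r)
}

# Expected proportion of differing sites between the ends of a branch of
# length t (used by the simulator's calibration checks).
expected_pdist <- function(mod, t) {
  P <- aa_pmatrix(mod, t)
  1 - sum(mod$pi * diag(P))
}
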