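# Brute-force likelihood oracle: enumerates every hidden state path
# (strata 1..S plus the absorbing dead state 0) consistent with a history
# and sums the path probabilities. Independent of the package's forward
# algorithm; usable for short histories only.
#
# phi, p: [S, T-1] matrices (p column t = detection at occasion t+1);
# psi: [S, S, T-1] with the stay probability on the diagonal.
oracle_history_prob <- function(codes, phi, p, psi) {
  S <- nrow(phi)
  T <- length(codes)
  f <- which(codes > 0)[1]
  recurse <- function(t, state) {
    if (t == T) return(1)
    obs <- codes[t + 1]
    if (state == 0)  # dead stays dead and unseen
      return(if (obs == 0) recurse(t + 1, 0) else 0)
    tot <- (1 - phi[state, t]) * (if (obs == 0) recurse(t + 1, 0) else 0)
    for (s2 in seq_len(S)) {
      move <- phi[state, t] * psi[state, s2, t]
      det <- if (obs == s2) p[s2, t] * recurse(t + 1, s2)
             else if (obs == 0) (1 - p[s2, t]) * recurse(t + 1, s2)
             else 0
      tot <- tot + move * det
    }
    tot
  }
  recurse(f, codes[f])
}

# All encounter histories of T occasions over S strata (at least one
# detection), as an integer matrix
all_histories <- function(S, T) {
  g <- as.matrix(expand.grid(rep(list(0:S), T)))
  colnames(g) <- NULL
  g[rowSums(g > 0) > 0, , drop = FALSE]
}

# A saturated (stratum x interval) design over adult-only histories whose
# coefficients can be solved to reproduce arbitrary phi/p/psi arrays
saturated_design <- function(histories) {
  spec <- ms_spec(phi = "sub:year", p = "sub:year", psi = "sub:year")
  compile_design(spec, histories)
}

# Solve the design's beta so the real-parameter arrays equal the targets
beta_for_arrays <- function(design, phi, p, psi) {
  solve_block <- function(part, eta_target) {
    X <- part$X[, part$keep, drop = FALSE]
    qr.solve(crossprod(X), crossprod(X, eta_target))
  }
  eta_phi <- rep(qlogis(as.vector(phi)), 2)  # both age slices identical
  eta_p <- rep(qlogis(as.vector(p)), 2)
  cells <- design$psi$cells
  o <- match(as.character(cells$origin), design$strata)
  d <- match(as.character(cells$dest), design$strata)
  t <- match(as.character(cells$year), as.character(design$intervals))
  eta_psi <- log(psi[cbind(o, d, t)] / psi[cbind(o, o, t)])
  c(solve_block(design$phi, eta_phi),
    solve_block(design$p, eta_p),
    solve_block(design$psi, eta_psi))
}

# Random smooth parameter arrays (detection and survival away from the
# boundaries; transition rows from a multinomial logit draw)
random_arrays <- function(S, T) {
  NI <- T - 1L
  phi <- matrix(runif(S * NI, 0.2, 0.95), S, NI)
  p <- matrix(runif(S * NI, 0.2, 0.95), S, NI)
  psi <- array(0, c(S, S, NI))
  for (t in seq_len(NI)) for (r in seq_len(S)) {
    eta <- rnorm(S - 1, -1, 0.7)
    e <- exp(eta)
    psi[r, setdiff(seq_len(S), r), t] <- e / (1 + sum(e))
    psi[r, r, t] <- 1 / (1 + sum(e))
  }
  list(phi = phi, p = p, psi = psi)
}
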