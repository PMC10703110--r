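# Independent oracle: the exact per-server hypercube (2^n states, loss
# operation). Each server is an individual binary coordinate; within a
# group the lowest-index free server is dispatched (group-level measures
# are invariant to that choice because co-located same-type servers are
# exchangeable). Written directly from first principles, sharing no code
# with the aggregated model.
exact_hypercube <- function(sys, dp, mu_inv) {
  gr <- dp$groups
  sub <- dp$subatoms
  servers <- rep(seq_len(nrow(gr)), gr$n)      # group of each server
  n <- length(servers)
  S <- 2^n
  busy <- matrix(0L, S, n)
  for (s in seq_len(S)) busy[s, ] <- as.integer(intToBits(s - 1)[1:n])

  disp <- matrix(0L, S, nrow(sub))             # serving server or 0 = lost
  for (j in seq_len(nrow(sub))) {
    for (s in seq_len(S)) {
      for (g in dp$pref[[j]]) {
        free <- which(servers == g & busy[s, ] == 0L)
        if (length(free)) { disp[s, j] <- free[1]; break }
      }
    }
  }

  Q <- matrix(0, S, S)
  for (s in seq_len(S)) {
    for (j in seq_len(nrow(sub))) {
      i <- disp[s, j]
      if (i > 0L) {
        d <- sum(busy[s, ] * 2^(seq_len(n) - 1)) + 2^(i - 1) + 1
        Q[s, d] <- Q[s, d] + sub$lambda[j]
      }
    }
    for (i in which(busy[s, ] == 1L)) {
      d <- sum(busy[s, ] * 2^(seq_len(n) - 1)) - 2^(i - 1) + 1
      Q[s, d] <- Q[s, d] + 1 / mu_inv[servers[i]]
    }
  }
  diag(Q) <- -rowSums(Q)
  M <- t(Q); M[1, ] <- 1
  P <- solve(M, c(1, numeric(S - 1)))

  rho_server <- as.vector(crossprod(busy, P))
  rho_group <- as.vector(tapply(rho_server, servers, mean))

  f <- matrix(0, nrow(gr), nrow(sub))          # dispatch prob by group
  loss <- numeric(nrow(sub))
  for (j in seq_len(nrow(sub))) {
    for (s in seq_len(S)) {
      i <- disp[s, j]
      if (i > 0L) f[servers[i], j] <- f[servers[i], j] + P[s]
      else loss[j] <- loss[j] + P[s]
    }
  }
  resp <- sys$travel[gr$atom, sub$atom, drop = FALSE] +
    sys$on_scene[gr$type]
  sub_time <- colSums(f * resp) / colSums(f)
  list(rho = rho_group, sub_time = sub_time, loss = loss,
       empty = P[1], f = f)
}
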