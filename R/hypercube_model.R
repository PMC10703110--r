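# Transition structure, steady-state solution and performance measures of
# the aggregated hypercube model.

# Per-state dispatch decision for every sub atom:
#   value > 0  : index of the serving group (first free group in preference)
#   value == 0 : call joins the queue
#   value == -1: call is lost
dispatch_table <- function(space, policy) {
  S <- space$S
  nsub <- nrow(policy$subatoms)
  free <- space$busy < matrix(space$n, S, space$Tn, byrow = TRUE)
  can_queue <- space$Q_l > 0L & (space$qs + space$qu) < space$Q_l
  D <- matrix(-1L, S, nsub)
  for (j in seq_len(nsub)) {
    p <- policy$pref[[j]]
    Fp <- free[, p, drop = FALSE]
    any_free <- rowSums(Fp) > 0
    first <- max.col(Fp %*% diag(rev(seq_along(p)), length(p)),
                     ties.method = "first")
    D[, j] <- ifelse(any_free, p[first], ifelse(can_queue, 0L, -1L))
  }
  D
}

#' Build the transition-rate structure of the aggregated hypercube
#'
#' Arrivals move the preferred free group's busy count up, join the queue
#' when no eligible group is free and capacity remains, or are lost.
#' Completions move a busy count down; when calls are waiting, the freed
#' server immediately takes the head of the queue non-preemptively
#' (serious before regular; dedicated servers only take serious calls, and
#' a freed dedicated server with only regular calls waiting goes idle).
#' Every row of the resulting generator sums to zero.
#'
#' @param space state space from [build_state_space()].
#' @param policy dispatch policy from [make_dispatch_policy()].
#' @param sys an [ems_system()].
#' @param mu_inv named-by-group numeric vector of mean service times
#'   (minutes) per group, e.g. calibrated values; defaults to the
#'   type-level system values.
#' @return A list with the sparse generator `G` (class `dgCMatrix`), the
#'   dispatch table, and the static transition triplets reused during
#'   calibration.
#' @export
build_generator <- function(space, policy, sys, mu_inv = NULL) {
  if (is.null(mu_inv)) mu_inv <- sys$service_time[space$groups$type]
  if (any(mu_inv <= 0)) stop2("service times must be > 0")
  D <- dispatch_table(space, policy)
  sub <- policy$subatoms
  code <- space$code
  idxof <- function(dest_code) space$index[dest_code + 1L]

  arr_i <- arr_j <- integer(0); arr_x <- numeric(0)
  for (j in seq_len(nrow(sub))) {
    if (sub$lambda[j] <= 0) next
    srv <- which(D[, j] > 0L)
    if (length(srv)) {
      dest <- idxof(code[srv] + space$rad[D[srv, j]])
      arr_i <- c(arr_i, srv); arr_j <- c(arr_j, dest)
      arr_x <- c(arr_x, rep.int(sub$lambda[j], length(srv)))
    }
    enq <- which(D[, j] == 0L)
    if (length(enq)) {
      step <- if (sub$priority[j] == "serious") space$rad_qs else space$rad_qu
      dest <- idxof(code[enq] + step)
      arr_i <- c(arr_i, enq); arr_j <- c(arr_j, dest)
      arr_x <- c(arr_x, rep.int(sub$lambda[j], length(enq)))
    }
  }

  comp_i <- comp_j <- comp_t <- comp_b <- integer(0)
  for (t in seq_len(space$Tn)) {
    busy_t <- which(space$busy[, t] > 0L)
    if (!length(busy_t)) next
    dest_code <- code[busy_t] - space$rad[t]
    take_s <- space$qs[busy_t] > 0L
    dest_code[take_s] <- code[busy_t][take_s] - space$rad_qs
    if (!space$ded[t]) {
      take_u <- !take_s & space$qu[busy_t] > 0L
      dest_code[take_u] <- code[busy_t][take_u] - space$rad_qu
    }
    comp_i <- c(comp_i, busy_t)
    comp_j <- c(comp_j, idxof(dest_code))
    comp_t <- c(comp_t, rep.int(t, length(busy_t)))
    comp_b <- c(comp_b, space$busy[busy_t, t])
  }
  if (any(c(arr_j, comp_j) == 0L))
    stop2("internal error: transition to a state outside the space")

  gen <- list(arr_i = arr_i, arr_j = arr_j, arr_x = arr_x,
              comp_i = comp_i, comp_j = comp_j, comp_t = comp_t,
              comp_b = comp_b, S = space$S, dispatch = D)
  # aggregation map for duplicate (from, to) pairs, reused every time the
  # generator is reassembled with new service times during calibration
  all_i <- c(arr_i, comp_i)
  all_j <- c(arr_j, comp_j)
  key <- (as.double(all_j) - 1) * space$S + all_i
  gen$ukey <- sort(unique(key))
  gen$grp <- match(key, gen$ukey)
  gen$reach <- reachable_states(all_i, all_j, space$index[1L], space$S)
  gen$G <- assemble_generator(gen, mu_inv)
  gen$mu_inv <- mu_inv
  gen
}

# Assemble the generator for given per-group mean service times: a dense
# base matrix when small (sparse-class dispatch overhead dominates at these
# sizes), a sparse Matrix beyond `dense_limit` states.
assemble_generator <- function(gen, mu_inv, dense_limit = 1000L) {
  x <- c(gen$arr_x, gen$comp_b / mu_inv[gen$comp_t])
  if (any(x < 0)) stop2("internal error: negative transition rate")
  if (gen$S <= dense_limit) {
    xagg <- as.vector(rowsum(x, gen$grp))
    G <- matrix(0, gen$S, gen$S)
    G[gen$ukey] <- xagg
    diag(G) <- diag(G) - rowSums(G)
    G
  } else {
    G <- Matrix::sparseMatrix(i = c(gen$arr_i, gen$comp_i),
                              j = c(gen$arr_j, gen$comp_j),
                              x = x, dims = c(gen$S, gen$S))
    G - Matrix::Diagonal(gen$S, Matrix::rowSums(G))
  }
}

# States reachable from the empty system (breadth-first over transitions).
reachable_states <- function(from, to, start, S) {
  adj <- split(to, from)
  reached <- logical(S)
  reached[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    frontier <- nxt[!reached[nxt]]
    reached[frontier] <- TRUE
  }
  reached
}

#' Solve the steady state of the hypercube generator
#'
#' Solves the global balance equations restricted to the states reachable
#' from the empty system: a direct sparse LU solve by default, with a
#' Gauss--Seidel sweep fallback above a size threshold. Unreachable states
#' receive probability zero.
#'
#' @param gen transition structure from [build_generator()].
#' @param space the matching state space.
#' @param direct_limit largest state count solved directly (default 20000).
#' @param tol convergence tolerance for the iterative fallback.
#' @param max_sweeps maximum Gauss--Seidel sweeps.
#' @return A list with the probability vector `P`, the balance residual,
#'   the method used and iteration count.
#' @export
solve_steady_state <- function(gen, space, direct_limit = 20000L,
                               tol = 1e-10, max_sweeps = 10000L) {
  reach <- gen$reach
  dense <- is.matrix(gen$G)
  Gr <- gen$G[reach, reach, drop = FALSE]
  m <- nrow(Gr)
  if (dense) {
    M <- t(Gr)
    M[1L, ] <- 1  # replace one balance equation by normalization
    p <- solve(M, c(1, numeric(m - 1L)))
    iters <- 1L
    method <- "direct"
  } else if (m <= direct_limit) {
    M <- Matrix::t(Gr)
    M[1L, ] <- 1
    p <- as.vector(Matrix::solve(M, c(1, numeric(m - 1L))))
    iters <- 1L
    method <- "direct"
  } else {
    M <- Matrix::t(Gr)
    p <- gauss_seidel_pi(M, tol, max_sweeps)
    iters <- attr(p, "iterations")
    method <- "gauss-seidel"
    if (!attr(p, "converged"))
      stop2("Gauss-Seidel did not converge after ", iters,
            " sweeps; residual ", format(attr(p, "residual")))
  }
  p[p < 0 & p > -1e-12] <- 0
  if (any(p < 0)) stop2("negative steady-state probability: solver failure")
  p <- p / sum(p)
  P <- numeric(gen$S)
  P[reach] <- p
  residual <- if (dense) max(abs(as.vector(P %*% gen$G)))
              else max(abs(as.vector(Matrix::t(gen$G) %*% P)))
  if (residual > 1e-8)
    warning("steady-state residual ", format(residual), " above 1e-8")
  list(P = P, residual = residual, method = method, iterations = iters,
       reachable = reach)
}

# Gauss-Seidel on the balance equations M p = 0 (M = t(Q)), normalized.
gauss_seidel_pi <- function(M, tol, max_sweeps) {
  m <- nrow(M)
  p <- rep.int(1 / m, m)
  Mc <- as(M, "CsparseMatrix")
  dp <- Matrix::diag(M)
  converged <- FALSE
  it <- 0L
  for (sweep in seq_len(max_sweeps)) {
    it <- sweep
    old <- p
    for (jj in seq_len(m)) {
      rng <- (Mc@p[jj] + 1L):Mc@p[jj + 1L]
      rows <- Mc@i[rng] + 1L
      vals <- Mc@x[rng]
      keep <- rows != jj
      p[jj] <- sum(vals[keep] * p[rows[keep]]) / (-dp[jj])
    }
    p <- p / sum(p)
    if (max(abs(p - old)) < tol) { converged <- TRUE; break }
  }
  structure(p, iterations = it, converged = converged,
            residual = max(abs(as.vector(M %*% p))))
}

#' Per-server workloads
#'
#' The workload of each server in group `t` is
#' `sum_r n_tr P_r / n_t`: the expected busy fraction, equal for all
#' servers of a group.
#'
#' @param solution result of [solve_steady_state()].
#' @param space the matching state space.
#' @return A data frame with one row per group (`type`, `atom`, `n`,
#'   `rho`).
#' @export
compute_workloads <- function(solution, space) {
  rho <- as.vector(crossprod(space$busy, solution$P)) / space$n
  cbind(space$groups, rho = rho)
}

#' Response times, dispatch frequencies and system probabilities
#'
#' The mean response time of a sub atom is the dispatch-probability
#' weighted mean over serving groups of (journey time from the group's
#' atom + the type's on-scene component). Calls served from the queue
#' cannot retain their origin in the aggregate state, so their serving
#' group is attributed pro rata to the eligible groups' aggregate service
#' rates. Lost calls are excluded from the means and reported as loss
#' probabilities.
#'
#' @param solution result of [solve_steady_state()].
#' @param space the matching state space.
#' @param policy the dispatch policy used to build the generator.
#' @param sys an [ems_system()].
#' @param mu_inv per-group mean service times used in the generator.
#' @param dispatch optional precomputed dispatch table.
#' @param response `"total"` (journey + on-scene, the default) or
#'   `"travel"` (journey only) for the reported response times.
#' @return An object of class `ems_measures`: per-group workloads and mean
#'   response times, per-sub-atom mean response times and loss shares, the
#'   group-by-sub-atom dispatch rate matrix, and loss / empty-system
#'   probabilities.
#' @export
compute_response_times <- function(solution, space, policy, sys,
                                   mu_inv = NULL, dispatch = NULL,
                                   response = c("total", "travel")) {
  response <- match.arg(response)
  if (is.null(dispatch)) dispatch <- dispatch_table(space, policy)
  if (is.null(mu_inv)) mu_inv <- sys$service_time[space$groups$type]
  sub <- policy$subatoms
  gr <- space$groups
  P <- solution$P
  Tn <- space$Tn
  nsub <- nrow(sub)

  # immediate dispatch probability per (group, sub atom), queue and loss shares
  f <- matrix(0, Tn, nsub)
  q_share <- loss_share <- numeric(nsub)
  for (j in seq_len(nsub)) {
    dj <- dispatch[, j]
    f[, j] <- vapply(seq_len(Tn), function(t) sum(P[dj == t]), 0)
    q_share[j] <- sum(P[dj == 0L])
    loss_share[j] <- sum(P[dj == -1L])
  }
  # queued calls: serving group attributed pro rata to eligible capacity
  fq <- f
  mu_rate <- gr$n / mu_inv
  for (j in seq_len(nsub)) {
    if (q_share[j] <= 0) next
    elig <- policy$pref[[j]]
    w <- mu_rate[elig] / sum(mu_rate[elig])
    fq[elig, j] <- fq[elig, j] + q_share[j] * w
  }
  served <- colSums(fq)
  if (any(served <= 0))
    stop2("sub atom ", which(served <= 0)[1], " has zero dispatch probability")

  tt <- sys$travel[gr$atom, sub$atom, drop = FALSE]   # Tn x nsub journey times
  resp <- tt + if (response == "total") sys$on_scene[gr$type] else 0

  sub_time <- colSums(fq * resp) / served
  Frate <- fq * matrix(sub$lambda, Tn, nsub, byrow = TRUE)  # dispatch rates
  g_tot <- rowSums(Frate)
  grp_time <- ifelse(g_tot > 0, rowSums(Frate * resp) / g_tot, NA_real_)
  grp_travel <- ifelse(g_tot > 0, rowSums(Frate * tt) / g_tot, NA_real_)

  lam <- sub$lambda
  structure(list(
    groups = cbind(gr, rho = compute_workloads(solution, space)$rho,
                   mean_time = grp_time, mean_travel = grp_travel,
                   dispatch_rate = g_tot),
    subatoms = cbind(sub, mean_time = sub_time, queue_prob = q_share,
                     loss_prob = loss_share),
    dispatch_rate = Frate,
    loss_prob = if (sum(lam) > 0) sum(lam * loss_share) / sum(lam) else 0,
    empty_prob = P[space$index[1L]],
    response = response
  ), class = "ems_measures")
}

#' @export
print.ems_measures <- function(x, ...) {
  cat("Hypercube performance measures\n")
  cat(sprintf("  loss probability %.4g, empty-system probability %.4g\n",
              x$loss_prob, x$empty_prob))
  print(x$groups, digits = 4)
  invisible(x)
}

#' Calibrate service times and evaluate one configuration
#'
#' The mean service time of a group is its on-scene component plus the
#' mean journey time of the calls it actually serves, which in turn
#' depends on the steady-state dispatch frequencies. `calibrate` runs the
#' fixed-point iteration: solve the model, recompute each group's mean
#' journey component from its dispatch frequencies, update the service
#' times, and repeat until the largest change falls below `tol`.
#'
#' @param config a configuration.
#' @param sys an [ems_system()].
#' @param Q_l queue capacity for the `"queue"` policy (default 5).
#' @param policy `"queue"` or `"no_queue"`.
#' @param seed seed for the randomized dispatch backup ordering.
#' @param tol convergence tolerance on service times, minutes.
#' @param max_iter maximum fixed-point iterations.
#' @param response response-time definition passed to
#'   [compute_response_times()].
#' @param dispatch_policy optional prebuilt [make_dispatch_policy()] object.
#' @return A list: `measures` (an `ems_measures`), calibrated `mu_inv`,
#'   `iterations`, `converged`, plus the `space`, `policy` and final
#'   `solution`. Non-convergence yields a warning, not an error.
#' @export
calibrate <- function(config, sys, Q_l = 5L, policy = c("queue", "no_queue"),
                      seed = 1L, tol = 1e-6, max_iter = 50L,
                      response = c("total", "travel"),
                      dispatch_policy = NULL) {
  policy <- match.arg(policy)
  response <- match.arg(response)
  if (tol <= 0) stop2("tol must be > 0")
  dp <- dispatch_policy %||% make_dispatch_policy(config, sys, seed)
  space <- build_state_space(dp$groups, Q_l = Q_l, policy = policy)
  mu_inv <- unname(sys$service_time[space$groups$type])
  gen <- build_generator(space, dp, sys, mu_inv)
  on_scene <- unname(sys$on_scene[space$groups$type])

  converged <- FALSE
  sol <- NULL
  it <- 0L
  for (iter in seq_len(max_iter)) {
    it <- iter
    sol <- solve_steady_state(gen, space)
    meas <- compute_response_times(sol, space, dp, sys, mu_inv,
                                   dispatch = gen$dispatch, response = response)
    new_mu <- on_scene + ifelse(is.na(meas$groups$mean_travel),
                                mu_inv - on_scene, meas$groups$mean_travel)
    delta <- max(abs(new_mu - mu_inv))
    mu_inv <- new_mu
    if (delta < tol) { converged <- TRUE; break }
    gen$G <- assemble_generator(gen, mu_inv)
  }
  if (!converged)
    warning("calibration did not converge after ", max_iter,
            " iterations (last change ", format(delta), " min)")
  meas <- compute_response_times(sol, space, dp, sys, mu_inv,
                                 dispatch = gen$dispatch, response = response)
  list(measures = meas, mu_inv = mu_inv, iterations = it,
       converged = converged, space = space, policy = dp, solution = sol)
}
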