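# Small systems used across tests, built in code.

# A-atom system with a single movable fleet and demand concentrated as
# given; constant travel time makes calibration converge immediately and
# keeps closed forms exact.
toy_system <- function(A = 2, n_bsu = 1, lambda_reg = NULL, lambda_ser = NULL,
                       travel = NULL, service = 10, n_asu = 0,
                       asu_atoms = NULL, service_asu = service) {
  lambda_reg <- lambda_reg %||% c(0.05, rep(0, A - 1))
  lambda_ser <- lambda_ser %||% rep(0, A)
  travel <- travel %||% matrix(4, A, A)
  fleets <- list(fleet("BSU", n_bsu))
  st <- c(BSU = service)
  if (n_asu > 0) {
    fixed <- integer(A)
    for (a in asu_atoms %||% rep(1, n_asu)) fixed[a] <- fixed[a] + 1L
    fleets <- c(fleets, list(fleet("ASU", n_asu, TRUE, fixed)))
    st["ASU"] <- service_asu
  }
  ems_system(paste0("z", seq_len(A)), cbind(lambda_ser, lambda_reg),
             travel, fleets, st)
}

# configuration placing all BSUs in atom 1 (plus pinned ASUs)
toy_config <- function(sys, bsu_alloc) {
  alloc <- list(BSU = as.integer(bsu_alloc))
  for (fl in sys$fleets) if (fl$dedicated) alloc[[fl$type]] <- fl$fixed_atoms
  list(id = 1L, alloc = alloc)
}

# solve a toy at fixed service times (no calibration), returning measures
solve_toy <- function(sys, bsu_alloc, Q_l = 0, policy = "no_queue",
                      seed = 1, mu_inv = NULL) {
  cfg <- toy_config(sys, bsu_alloc)
  dp <- make_dispatch_policy(cfg, sys, seed)
  space <- build_state_space(dp$groups, Q_l = Q_l, policy = policy)
  if (is.null(mu_inv)) mu_inv <- unname(sys$service_time[space$groups$type])
  gen <- build_generator(space, dp, sys, mu_inv)
  sol <- solve_steady_state(gen, space)
  list(space = space, policy = dp, gen = gen, sol = sol,
       meas = compute_response_times(sol, space, dp, sys, mu_inv,
                                     dispatch = gen$dispatch))
}

erlang_b <- function(n, a) {
  inv <- sum(a^(0:n) / factorial(0:n))
  (a^n / factorial(n)) / inv
}

# realistic correlated DEA test data: serious reciprocal times close to
# regular ones, as response-time data are
random_dea_problem <- function(N, A, I) {
  y <- matrix(runif(N * A, 1 / 60, 1 / 20), N)
  dea_problem(
    inputs = matrix(runif(N * I, 0.2, 0.9), N),
    out_y = y,
    out_ys = y * matrix(runif(N * A, 0.85, 1.2), N),
    out_z = matrix(runif(N * I, 1 / 60, 1 / 20), N)
  )
}
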