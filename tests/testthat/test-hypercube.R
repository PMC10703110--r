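test_that("co-located same-type servers aggregate into single groups", {
  sys <- toy_system(A = 3, n_bsu = 4, lambda_reg = c(.01, .01, .01),
                    lambda_ser = c(.002, 0, 0), n_asu = 2, asu_atoms = c(1, 1))
  g <- build_server_groups(toy_config(sys, c(2, 1, 1)), sys)
  expect_equal(nrow(g), 4)  # three BSU groups + one ASU group of 2
  expect_equal(g$n[g$type == "BSU"], c(2L, 1L, 1L))
  expect_equal(g$n[g$type == "ASU"], 2L)
  g1 <- build_server_groups(toy_config(sys, c(4, 0, 0)), sys)
  expect_equal(nrow(g1), 2)
  expect_equal(g1$n, c(4L, 2L))
  expect_error(
    build_server_groups(list(id = 1, alloc = list(BSU = c(1, 1, 1))), sys),
    "does not sum")
})

test_that("state counts follow the product and queue-state formulas", {
  g1 <- data.frame(type = "BSU", atom = 1, n = 3L, dedicated = FALSE)
  expect_equal(build_state_space(g1, policy = "no_queue")$S, 4)
  g2 <- data.frame(type = "BSU", atom = 1:2, n = c(2L, 1L), dedicated = FALSE)
  expect_equal(build_state_space(g2, policy = "no_queue")$S, 6)
  # n_ds = 1, Q_l = 2: |Q| = 1*2 + choose(4, 2) - 1 = 7
  g3 <- rbind(g2, data.frame(type = "ASU", atom = 1, n = 1L, dedicated = TRUE))
  sp <- build_state_space(g3, Q_l = 2, policy = "queue")
  expect_equal(sp$n_qds + sp$n_qpr, 7)
  expect_equal(sp$S, prod(c(2, 1, 1) + 1) + 7)

  # property: random group shapes, single dedicated group
  set.seed(11)
  for (rep in 1:15) {
    Tn <- sample(1:3, 1)
    n <- sample(1:3, Tn, replace = TRUE)
    n_ds <- sample(0:2, 1)
    Q_l <- sample(0:4, 1)
    g <- data.frame(type = "BSU", atom = seq_len(Tn), n = n, dedicated = FALSE)
    if (n_ds > 0)
      g <- rbind(g, data.frame(type = "ASU", atom = 1, n = n_ds,
                               dedicated = TRUE))
    sp <- build_state_space(g, Q_l = Q_l,
                            policy = if (Q_l > 0) "queue" else "no_queue")
    expect_equal(sp$S, prod(g$n + 1) + n_ds * Q_l + choose(2 + Q_l, Q_l) - 1)
  }
  # two separate dedicated groups generalize the dedicated-queue count
  g4 <- rbind(g2, data.frame(type = "ASU", atom = 1:2, n = c(1L, 1L),
                             dedicated = TRUE))
  sp4 <- build_state_space(g4, Q_l = 3, policy = "queue")
  expect_equal(sp4$n_qds, (2 * 2 - 1) * 3)
  expect_error(build_state_space(g2, max_states = 4), "too large")
})

test_that("dispatch preferences honor locality, dedication and the seed", {
  sys <- toy_system(A = 3, n_bsu = 3, lambda_reg = c(.01, .01, .01),
                    lambda_ser = c(.002, .002, .002), n_asu = 1,
                    asu_atoms = 2,
                    travel = matrix(c(5, 9, 7, 9, 5, 8, 7, 8, 5), 3))
  cfg <- toy_config(sys, c(1, 1, 1))
  dp <- make_dispatch_policy(cfg, sys, seed = 4)
  sub <- dp$subatoms
  for (j in seq_len(nrow(sub))) {
    p <- dp$pref[[j]]
    gsel <- dp$groups[p, ]
    if (sub$priority[j] == "regular") {
      expect_false(any(gsel$dedicated))          # ASUs never on regular lists
      expect_equal(gsel$atom[1], sub$atom[j])    # same-atom group first
      # remaining groups ordered by journey time to the call
      tt <- sys$travel[gsel$atom[-1], sub$atom[j]]
      expect_equal(tt, sort(tt))
    } else {
      expect_true(gsel$dedicated[1])             # dedicated unit first
      expect_equal(gsel$atom[2], sub$atom[j])    # then local basic unit
    }
    expect_true(length(p) >= 1)
  }
  expect_equal(make_dispatch_policy(cfg, sys, seed = 4)$pref, dp$pref)
  # seeded backup randomization: some seed pair must reorder the tail
  tails <- vapply(1:6, function(s) {
    paste(unlist(make_dispatch_policy(cfg, sys, seed = s)$pref), collapse = ",")
  }, "")
  expect_gt(length(unique(tails)), 1)
})

test_that("generator rows conserve rate and arrivals never preempt", {
  sys <- toy_system(A = 2, n_bsu = 2, lambda_reg = c(.02, .01),
                    lambda_ser = c(.004, .002), n_asu = 1, asu_atoms = 1)
  r <- solve_toy(sys, c(1, 1), Q_l = 3, policy = "queue")
  G <- r$gen$G
  expect_true(all(abs(rowSums(G)) < 1e-12))
  expect_true(all(G[row(G) != col(G)] >= 0))
  # arrival transitions only ever increase busy counts or the queue
  for (k in seq_along(r$gen$arr_i)) {
    from <- r$gen$arr_i[k]; to <- r$gen$arr_j[k]
    d_busy <- r$space$busy[to, ] - r$space$busy[from, ]
    d_q <- (r$space$qs[to] + r$space$qu[to]) -
      (r$space$qs[from] + r$space$qu[from])
    expect_true(all(d_busy >= 0))
    expect_equal(sum(d_busy) + d_q, 1)
  }
})

test_that("single-group loss systems reproduce Erlang-B exactly", {
  for (n in 1:5) for (a in c(0.5, 1, 2)) {
    mu_inv <- 10
    sys <- toy_system(A = 2, n_bsu = n, lambda_reg = c(a / mu_inv, 0),
                      service = mu_inv)
    r <- solve_toy(sys, c(n, 0), Q_l = 0, policy = "no_queue")
    expect_equal(r$meas$loss_prob, erlang_b(n, a), tolerance = 1e-12)
  }
  # the M/M/2 loss case with offered load 1 blocks 20% of calls
  sys <- toy_system(A = 2, n_bsu = 2, lambda_reg = c(.1, 0), service = 10)
  expect_equal(solve_toy(sys, c(2, 0))$meas$loss_prob, 0.2, tolerance = 1e-12)
})

test_that("single-server queue matches the M/M/1/K closed form", {
  rho <- 0.5
  sys <- toy_system(A = 2, n_bsu = 1, lambda_reg = c(rho / 10, 0),
                    service = 10)
  for (Q_l in c(2, 10, 40)) {
    r <- solve_toy(sys, c(1, 0), Q_l = Q_l, policy = "queue")
    K <- Q_l + 1  # system capacity
    pk <- rho^(0:K) * (1 - rho) / (1 - rho^(K + 1))
    expect_equal(r$meas$empty_prob, pk[1], tolerance = 1e-12)
    expect_equal(r$meas$loss_prob, pk[K + 1], tolerance = 1e-12)
  }
  # large queue: empty-system probability approaches 1 - rho
  r <- solve_toy(sys, c(1, 0), Q_l = 40, policy = "queue")
  expect_equal(r$meas$empty_prob, 0.5, tolerance = 1e-10)
})

test_that("steady-state probabilities are a distribution with small residual", {
  set.seed(5)
  for (rep in 1:8) {
    sys <- generate_synthetic_system(sample(2:4, 1), sample(2:4, 1),
                                     sample(0:1, 1), seed = rep)
    cfg <- enumerate_configurations(sys)[[1]]
    cal <- calibrate(cfg, sys, Q_l = sample(0:4, 1), seed = rep)
    P <- cal$solution$P
    expect_true(all(P >= 0))
    expect_equal(sum(P), 1, tolerance = 1e-10)
    expect_lt(cal$solution$residual, 1e-8)
  }
})

test_that("workloads implement the busy-count expectation per group", {
  g <- data.frame(type = "BSU", atom = 1, n = 2L, dedicated = FALSE)
  sp <- build_state_space(g, policy = "no_queue")
  # states are busy counts 0,1,2 in order
  expect_equal(sp$busy[, 1], 0:2)
  sol <- list(P = c(0.4, 0.4, 0.2))
  expect_equal(compute_workloads(sol, sp)$rho, 0.4)

  # M/M/1: workload equals lambda/mu
  sys <- toy_system(A = 2, n_bsu = 1, lambda_reg = c(.05, 0), service = 10)
  r <- solve_toy(sys, c(1, 0), Q_l = 40, policy = "queue")
  expect_equal(r$meas$groups$rho[1], 0.5, tolerance = 1e-10)

  # symmetric two-atom system: equal workloads by symmetry
  sys2 <- toy_system(A = 2, n_bsu = 2, lambda_reg = c(.02, .02),
                     travel = matrix(c(5, 8, 8, 5), 2), service = 10)
  r2 <- solve_toy(sys2, c(1, 1))
  expect_equal(r2$meas$groups$rho[1], r2$meas$groups$rho[2], tolerance = 1e-12)
})

test_that("response times weight journeys by dispatch and conserve mass", {
  b <- load_system(ems_fixture("bauru"))
  # single basic unit in atom 1 serving only atom-1 regular calls:
  # the journey component is the intra-atom time 8.2
  sys <- ems_system(b$atoms, cbind(rep(0, 6), c(.01, 0, 0, 0, 0, 0)),
                    b$travel, list(fleet("BSU", 1)), c(BSU = 40))
  r <- solve_toy(sys, c(1, 0, 0, 0, 0, 0))
  sa <- r$meas$subatoms
  expect_equal(sa$mean_time[sa$atom == 1 & sa$priority == "regular"],
               8.2 + sys$on_scene[["BSU"]])
  expect_equal(r$meas$groups$mean_travel[1], 8.2)

  # dispatch shares per sub atom sum to 1 - loss share
  sys3 <- toy_system(A = 3, n_bsu = 3, lambda_reg = c(.03, .02, .01),
                     lambda_ser = c(.005, .004, .003), n_asu = 1,
                     asu_atoms = 2)
  r3 <- solve_toy(sys3, c(2, 1, 0), Q_l = 2, policy = "queue", seed = 9)
  fq <- r3$meas$dispatch_rate / matrix(r3$meas$subatoms$lambda,
                                       nrow(r3$meas$groups), 6, byrow = TRUE)
  expect_equal(colSums(fq), 1 - r3$meas$subatoms$loss_prob,
               tolerance = 1e-12, ignore_attr = TRUE)
  # travel-only response option drops the on-scene component
  m_tr <- compute_response_times(r3$sol, r3$space, r3$policy, sys3,
                                 r3$gen$mu_inv, response = "travel")
  gap <- r3$meas$subatoms$mean_time - m_tr$subatoms$mean_time
  expect_true(all(gap > 0))
})

test_that("aggregated model equals the exact per-server hypercube", {
  set.seed(21)
  for (rep in 1:10) {
    A <- sample(2:3, 1)
    n_bsu <- sample(2:3, 1)
    n_asu <- sample(0:1, 1)
    sys <- toy_system(
      A = A, n_bsu = n_bsu,
      lambda_reg = runif(A, .01, .04), lambda_ser = runif(A, .002, .01),
      travel = matrix(runif(A * A, 5, 15), A),
      service = 12, n_asu = n_asu,
      asu_atoms = if (n_asu) sample(A, n_asu, replace = TRUE),
      service_asu = 15)
    alloc <- tabulate(sample(A, n_bsu, replace = TRUE), nbins = A)
    r <- solve_toy(sys, alloc, Q_l = 0, policy = "no_queue", seed = rep)
    ex <- exact_hypercube(sys, r$policy, r$gen$mu_inv)
    expect_equal(r$meas$groups$rho, ex$rho, tolerance = 1e-8)
    expect_equal(r$meas$subatoms$mean_time, ex$sub_time, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(r$meas$subatoms$loss_prob, ex$loss, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(r$meas$empty_prob, ex$empty, tolerance = 1e-8)
  }
})

test_that("calibration is an immediate fixed point under constant travel", {
  sys <- toy_system(A = 3, n_bsu = 2, lambda_reg = c(.02, .01, .01),
                    travel = matrix(7, 3, 3), service = 30)
  cal <- calibrate(toy_config(sys, c(1, 1, 0)), sys, Q_l = 2)
  expect_true(cal$converged)
  expect_equal(cal$iterations, 1L)
  expect_equal(cal$mu_inv, rep(30, 2), tolerance = 1e-12)
})

test_that("calibration converges and the stopping rule holds", {
  sys <- load_system(ems_fixture("ribeirao_preto"))
  cfgs <- enumerate_configurations(sys)
  cal <- calibrate(cfgs[[100]], sys, Q_l = 5, seed = 2, tol = 1e-6)
  expect_true(cal$converged)
  expect_true(all(cal$mu_inv > 0))
  # the converged service times reproduce themselves under one more update
  meas <- cal$measures
  on_scene <- unname(sys$on_scene[cal$space$groups$type])
  expect_equal(cal$mu_inv, on_scene + meas$groups$mean_travel,
               tolerance = 1e-5)
})
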