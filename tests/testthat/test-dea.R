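# Two-point VRS oracle for the toy case: with units A(x=1, y=2) and
# B(x=1, y=1), the output-oriented VRS expansion of B onto the frontier
# {A, B} is phi = 2 (B's output doubles to reach A), while A is efficient.

test_that("the two-unit VRS toy reproduces the enveloped expansion factor", {
  y <- c(2, 1)
  pr <- dea_problem(inputs = cbind(c(1, 1)), out_y = cbind(y),
                    out_ys = cbind(y), out_z = cbind(y))
  for (method in c("dual", "multiplier")) {
    rA <- solve_bcc_output(1, pr, P = 0, eps = 1e-9, method = method)
    rB <- solve_bcc_output(2, pr, P = 0, eps = 1e-9, method = method)
    expect_equal(rA$phi, 1, tolerance = 1e-7)
    expect_equal(rB$phi, 2, tolerance = 1e-7)
    expect_equal(rB$efficiency, 0.5, tolerance = 1e-7)
  }
  # the dominated unit lies on the inverted (worst-practice) frontier
  iB <- solve_bcc_output(2, pr, P = 0, eps = 1e-9, inverted = TRUE)
  expect_equal(iB$efficiency, 1, tolerance = 1e-7)
  iA <- solve_bcc_output(1, pr, P = 0, eps = 1e-9, inverted = TRUE)
  expect_lte(iB$phi, iA$phi + 1e-7)
  # composite still separates them, dominant unit first
  ci <- composite_index(c(rA <- 1, 0.5), c(iA$efficiency, iB$efficiency))
  expect_equal(ci$rank, c(1L, 2L))
})

test_that("self-dominant units score 1 and duplicates tie exactly", {
  set.seed(31)
  pr <- random_dea_problem(8, 2, 2)
  # make DMU 3 dominate everywhere: minimal inputs, maximal outputs
  pr$inputs[3, ] <- apply(pr$inputs, 2, min) * 0.9
  pr$out_y[3, ] <- apply(pr$out_y, 2, max) * 1.1
  pr$out_ys[3, ] <- apply(pr$out_ys, 2, max) * 1.1
  pr$out_z[3, ] <- apply(pr$out_z, 2, max) * 1.1
  r <- solve_bcc_output(3, pr, P = 0, eps = 1e-9)
  expect_equal(r$phi, 1, tolerance = 1e-7)

  pr$inputs[5, ] <- pr$inputs[4, ]; pr$out_y[5, ] <- pr$out_y[4, ]
  pr$out_ys[5, ] <- pr$out_ys[4, ]; pr$out_z[5, ] <- pr$out_z[4, ]
  r4 <- solve_bcc_output(4, pr, P = 20, eps = 1e-6)
  r5 <- solve_bcc_output(5, pr, P = 20, eps = 1e-6)
  expect_equal(r4$phi, r5$phi, tolerance = 1e-7)
})

test_that("weakly dominated units score below 1 across the batch", {
  set.seed(32)
  pr <- random_dea_problem(7, 2, 2)
  # DMU 7: strictly worse than DMU 1 on every column
  pr$inputs[7, ] <- pr$inputs[1, ] * 1.3
  pr$out_y[7, ] <- pr$out_y[1, ] * 0.8
  pr$out_ys[7, ] <- pr$out_ys[1, ] * 0.8
  pr$out_z[7, ] <- pr$out_z[1, ] * 0.8
  eff <- efficiency_all(pr, P = 0, eps = 1e-9)
  expect_true(all(eff$status == "optimal"))
  expect_equal(max(eff$efficiency), 1, tolerance = 1e-7)  # frontier non-empty
  expect_lt(eff$efficiency[7], 1 - 1e-6)
})

test_that("multiplier and envelopment routes agree and optima satisfy all
           printed constraints", {
  set.seed(33)
  for (rep in 1:12) {
    pr <- random_dea_problem(sample(5:9, 1), sample(1:2, 1), sample(1:2, 1))
    o <- sample(pr$N, 1)
    for (inverted in c(FALSE, TRUE)) {
      r1 <- solve_bcc_output(o, pr, P = 20, eps = 1e-6, inverted = inverted,
                             method = "dual")
      r2 <- solve_bcc_output(o, pr, P = 20, eps = 1e-6, inverted = inverted,
                             method = "multiplier")
      expect_equal(r1$status, "optimal")
      expect_equal(r1$phi, r2$phi, tolerance = 1e-6)
      expect_gte(r1$phi, 1 - 1e-7)

      # audit on the normalized scale used by the solver
      prn <- emsrank:::normalize_problem(pr)
      Y <- cbind(prn$out_y, prn$out_ys, prn$out_z)
      R <- prn$inputs
      u <- c(r1$alpha, r1$alpha_s, r1$beta)
      expect_true(all(c(u, r1$gamma) >= 1e-6 - 1e-9))           # weight bounds
      expect_true(all(r1$alpha_s - r1$alpha >= 1e-6 - 1e-8))    # assurance
      if (!inverted) {
        expect_equal(sum(u * Y[o, ]), 1, tolerance = 1e-7)      # normalization
        slack <- as.vector(Y %*% u - R %*% r1$gamma) + r1$w
        expect_true(all(slack <= 1e-6))                         # frontier rows
        expect_gte(sum(r1$alpha * prn$out_y[o, ]), 0.2 - 1e-7)  # group floors
        expect_gte(sum(r1$alpha_s * prn$out_ys[o, ]), 0.2 - 1e-7)
        expect_gte(sum(r1$beta * prn$out_z[o, ]), 0.2 - 1e-7)
        expect_equal(sum(r1$gamma * R[o, ]) - r1$w, r1$phi, tolerance = 1e-7)
      } else {
        expect_equal(sum(r1$gamma * R[o, ]), 1, tolerance = 1e-7)
        slack <- as.vector(R %*% r1$gamma - Y %*% u) + r1$w
        expect_true(all(slack <= 1e-6))
        virt <- sum(u * Y[o, ])
        expect_gte(sum(r1$alpha * prn$out_y[o, ]), 0.2 * virt - 1e-7)
        expect_gte(sum(r1$alpha_s * prn$out_ys[o, ]), 0.2 * virt - 1e-7)
        expect_gte(sum(r1$beta * prn$out_z[o, ]), 0.2 * virt - 1e-7)
      }
    }
  }
})

test_that("efficiencies are invariant to positive column rescaling", {
  set.seed(34)
  pr <- random_dea_problem(8, 2, 2)
  base <- efficiency_all(pr, P = 20, eps = 1e-6)
  prs <- pr
  prs$inputs[, 1] <- prs$inputs[, 1] * 37
  prs$out_ys[, 2] <- prs$out_ys[, 2] / 19
  prs$out_z[, 1] <- prs$out_z[, 1] * 0.013
  resc <- efficiency_all(prs, P = 20, eps = 1e-6)
  expect_equal(resc$efficiency, base$efficiency, tolerance = 1e-6)
})

test_that("enlarging the comparison set never lowers any expansion factor", {
  set.seed(35)
  pr <- random_dea_problem(6, 1, 2)
  base <- efficiency_all(pr, P = 0, eps = 1e-9)
  # append a dominated copy of DMU 2: nothing changes for the others
  grow <- dea_problem(rbind(pr$inputs, pr$inputs[2, ] * 1.2),
                      rbind(pr$out_y, pr$out_y[2, ] * 0.9),
                      rbind(pr$out_ys, pr$out_ys[2, ] * 0.9),
                      rbind(pr$out_z, pr$out_z[2, ] * 0.9))
  g1 <- efficiency_all(grow, P = 0, eps = 1e-9)
  expect_equal(g1$phi[1:6], base$phi, tolerance = 1e-7)
  # append a strong unit: factors can only grow (efficiency can only drop)
  grow2 <- dea_problem(rbind(pr$inputs, apply(pr$inputs, 2, min)),
                       rbind(pr$out_y, apply(pr$out_y, 2, max) * 1.5),
                       rbind(pr$out_ys, apply(pr$out_ys, 2, max) * 1.5),
                       rbind(pr$out_z, apply(pr$out_z, 2, max) * 1.5))
  g2 <- efficiency_all(grow2, P = 0, eps = 1e-9)
  expect_true(all(g2$phi[1:6] >= base$phi - 1e-8))
})

test_that("inverted frontier edge cases: single unit and order invariance", {
  set.seed(36)
  pr1 <- random_dea_problem(1, 1, 1)
  expect_equal(solve_bcc_output(1, pr1, P = 0, eps = 1e-9)$efficiency, 1,
               tolerance = 1e-7)
  expect_equal(solve_bcc_output(1, pr1, P = 0, eps = 1e-9,
                                inverted = TRUE)$efficiency, 1,
               tolerance = 1e-7)

  pr <- random_dea_problem(6, 2, 1)
  inv <- inverted_efficiency_all(pr, P = 0, eps = 1e-8)
  perm <- c(4, 2, 6, 1, 3, 5)
  prp <- dea_problem(pr$inputs[perm, ], pr$out_y[perm, ],
                     pr$out_ys[perm, ], pr$out_z[perm, ])
  invp <- inverted_efficiency_all(prp, P = 0, eps = 1e-8)
  expect_equal(invp$efficiency, inv$efficiency[perm], tolerance = 1e-6)
})

test_that("composite index follows the normalized-mean formula", {
  expect_equal(composite_index(1, 0)$composite, 1)
  ci <- composite_index(c(1, 0.8), c(0.6, 1))
  expect_equal((c(1, 0.8) + 1 - c(0.6, 1)) / 2, c(0.7, 0.4))
  expect_equal(ci$composite, c(1, 0.4 / 0.7))
  expect_equal(ci$composite[2], 0.5714, tolerance = 1e-4)
  expect_equal(ci$rank, c(1L, 2L))
  # identical rows tie on the composite with stable id-order ranks
  expect_message(tie <- composite_index(c(.7, .7), c(.4, .4)), "tie")
  expect_equal(tie$composite, c(1, 1))
  expect_equal(tie$rank, c(1L, 2L))
  expect_error(composite_index(c(1, 1), 1), "length")
})

test_that("hypercube measures assemble into the documented DEA dataset", {
  b <- load_system(ems_fixture("bauru"))
  cfgs <- enumerate_configurations(b)[c(1, 50, 400)]
  meas <- lapply(cfgs, function(cfg)
    calibrate(cfg, b, Q_l = 5, seed = 1)$measures)
  pr <- build_dea_dataset(meas, ids = c(1, 50, 400))
  expect_equal(pr$N, 3)
  expect_equal(pr$I, 7)                  # one input per basic unit
  expect_equal(2 * pr$A + pr$I, 19)      # twelve sub atoms + seven servers
  expect_true(all(pr$inputs > 0 & pr$inputs < 1))
  expect_true(all(cbind(pr$out_y, pr$out_ys, pr$out_z) > 0))
  # outputs are reciprocals: a 50-minute time would map to 0.02 per minute
  expect_equal(pr$out_y[2, 3], 1 / meas[[2]]$subatoms$mean_time[6])
  expect_equal(pr$out_ys[3, 1], 1 / meas[[3]]$subatoms$mean_time[1])
  expect_error(build_dea_dataset(list()), "length")
})
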