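# Output-oriented BCC (variable returns) multiplier model with
# non-Archimedean weight bounds, per-atom assurance regions
# (serious-call weight >= regular-call weight), minimum group-contribution
# constraints, the inverted frontier, and the composite index.

#' Assemble a DEA problem from hypercube performance measures
#'
#' Inputs are the per-server workloads of the movable basic units (servers
#' expanded from their groups, ordered by atom). Outputs are the
#' reciprocals of the per-sub-atom mean response times (regular and
#' serious, per atom) and of the per-basic-server mean response times;
#' dedicated advanced units are excluded from both sides. All entries must
#' be strictly positive.
#'
#' @param measures list of `ems_measures`, one per configuration.
#' @param ids configuration ids (defaults to list position).
#' @return An `ems_dea_problem`: matrices `inputs` (workloads, N x I),
#'   `out_y` / `out_ys` (reciprocal regular / serious response times,
#'   N x A) and `out_z` (reciprocal per-server response times, N x I).
#' @export
build_dea_dataset <- function(measures, ids = NULL) {
  stopifnot(length(measures) >= 1L)
  ids <- ids %||% seq_along(measures)
  one <- function(m) {
    g <- m$groups[!m$groups$dedicated, , drop = FALSE]
    g <- g[order(g$atom), , drop = FALSE]
    idx <- rep(seq_len(nrow(g)), g$n)
    sa <- m$subatoms
    list(rho = g$rho[idx],
         y = 1 / sa$mean_time[sa$priority == "regular"],
         ys = 1 / sa$mean_time[sa$priority == "serious"],
         z = 1 / g$mean_time[idx])
  }
  rows <- lapply(measures, one)
  dims <- vapply(rows, function(r) c(length(r$rho), length(r$y)), c(0, 0))
  if (length(unique(dims[1, ])) > 1L || length(unique(dims[2, ])) > 1L)
    stop2("configurations do not share input/output dimensions")
  inputs <- do.call(rbind, lapply(rows, `[[`, "rho"))
  out_y <- do.call(rbind, lapply(rows, `[[`, "y"))
  out_ys <- do.call(rbind, lapply(rows, `[[`, "ys"))
  out_z <- do.call(rbind, lapply(rows, `[[`, "z"))
  dea_problem(inputs, out_y, out_ys, out_z, ids)
}

#' Construct a DEA problem from raw matrices
#'
#' @param inputs N x I matrix of undesirable measures (workloads).
#' @param out_y,out_ys N x A matrices of desirable measures for regular
#'   and serious calls per atom (reciprocal response times).
#' @param out_z N x I desirable per-server measures.
#' @param ids DMU identifiers.
#' @return An `ems_dea_problem`.
#' @export
dea_problem <- function(inputs, out_y, out_ys, out_z, ids = NULL) {
  inputs <- as.matrix(inputs); out_y <- as.matrix(out_y)
  out_ys <- as.matrix(out_ys); out_z <- as.matrix(out_z)
  N <- nrow(inputs)
  if (!all(nrow(out_y) == N, nrow(out_ys) == N, nrow(out_z) == N))
    stop2("all matrices must have one row per DMU")
  if (ncol(out_y) != ncol(out_ys))
    stop2("regular and serious output blocks must pair per atom")
  bad <- which(apply(cbind(inputs, out_y, out_ys, out_z), 1,
                     function(r) any(!is.finite(r) | r <= 0)))
  if (length(bad))
    stop2("non-positive or non-finite DEA entries for DMU(s) ",
          paste(utils::head(bad, 5), collapse = ", "))
  structure(list(inputs = inputs, out_y = out_y, out_ys = out_ys,
                 out_z = out_z, ids = ids %||% seq_len(N),
                 N = N, I = ncol(inputs), A = ncol(out_y)),
            class = "ems_dea_problem")
}

#' @export
print.ems_dea_problem <- function(x, ...) {
  cat("DEA/BoD problem:", x$N, "DMUs,", x$I, "inputs,",
      2 * x$A + x$I, "outputs (2 x", x$A, "atoms +", x$I, "servers)\n")
  invisible(x)
}

# Mean-normalize columns for numerical conditioning (efficiencies are
# invariant to positive column scalings; the weight bound applies on the
# normalized scale).
normalize_problem <- function(pr) {
  nm <- function(M) sweep(M, 2, colMeans(M), "/")
  pr$inputs <- nm(pr$inputs); pr$out_y <- nm(pr$out_y)
  pr$out_ys <- nm(pr$out_ys); pr$out_z <- nm(pr$out_z)
  pr
}

# Build the multiplier-form LP for DMU `o` in standard form
# (min c'x, rows <=/==/>=, x >= 0). Variables, after shifting every
# weight by its lower bound eps and splitting the free scale factor w:
#   [a (A), aS (A), bta (I), g (I), wp, wm]
# `inverted = TRUE` swaps the roles of inputs and outputs; the assurance
# region follows the serious/regular columns to the input side and the
# group contributions are taken relative to that side's virtual value.
build_bcc_lp <- function(pr, o, P = 20, eps = 1e-6, inverted = FALSE) {
  A <- pr$A; I <- pr$I; N <- pr$N
  Y <- cbind(pr$out_y, pr$out_ys, pr$out_z)   # response-time block
  R <- pr$inputs                               # workload block
  nY <- 2 * A + I
  iA <- seq_len(A); iAS <- A + iA; iZ <- 2 * A + seq_len(I)
  nv <- nY + I + 2L
  wp <- nY + I + 1L; wm <- nY + I + 2L

  row <- function(yc = numeric(nY), rc = numeric(I), w = 0) c(yc, rc, w, -w)

  if (!inverted) {
    # normalization on outputs, objective on inputs
    obj <- row(rc = R[o, ], w = -1)
    obj_const <- eps * sum(R[o, ])
    mat <- rbind(
      row(yc = Y[o, ]),                                         # == 1 - eps*sum
      t(vapply(seq_len(N), function(k) row(Y[k, ], -R[k, ], 1), numeric(nv))),
      if (P > 0) rbind(
        row(yc = c(Y[o, iA], numeric(A + I))),
        row(yc = c(numeric(A), Y[o, iAS], numeric(I))),
        row(yc = c(numeric(2 * A), Y[o, iZ]))),
      t(vapply(iA, function(h) {
        v <- numeric(nv); v[A + h] <- 1; v[h] <- -1; v
      }, numeric(nv))))
    dir <- c("==", rep("<=", N),
             if (P > 0) rep(">=", 3), rep(">=", A))
    rhs <- c(1 - eps * sum(Y[o, ]),
             eps * (rowSums(R) - rowSums(Y)),
             if (P > 0) 0.01 * P - eps * c(sum(Y[o, iA]), sum(Y[o, iAS]),
                                           sum(Y[o, iZ])),
             rep(eps, A))
  } else {
    # roles swapped: normalization on the workload block, objective and
    # group shares on the response-time block
    obj <- row(yc = Y[o, ], w = -1)
    obj_const <- eps * sum(Y[o, ])
    grp <- function(sel) {
      # group share >= 0.01P of the input-side virtual at DMU o:
      # (1 - 0.01P) * sel - 0.01P * rest >= shift
      v <- numeric(nY)
      v[sel] <- (1 - 0.01 * P) * Y[o, sel]
      v[-sel] <- -0.01 * P * Y[o, -sel]
      row(yc = v)
    }
    mat <- rbind(
      row(rc = R[o, ]),                                         # == 1 - eps*sum
      t(vapply(seq_len(N), function(k) row(-Y[k, ], R[k, ], 1), numeric(nv))),
      if (P > 0) rbind(grp(iA), grp(iAS), grp(iZ)),
      t(vapply(iA, function(h) {
        v <- numeric(nv); v[A + h] <- 1; v[h] <- -1; v
      }, numeric(nv))))
    shift <- function(sel) {
      eps * ((1 - 0.01 * P) * sum(Y[o, sel]) - 0.01 * P * sum(Y[o, -sel]))
    }
    dir <- c("==", rep("<=", N),
             if (P > 0) rep(">=", 3), rep(">=", A))
    rhs <- c(1 - eps * sum(R[o, ]),
             eps * (rowSums(Y) - rowSums(R)),
             if (P > 0) -c(shift(iA), shift(iAS), shift(iZ)),
             rep(eps, A))
  }
  list(obj = obj, mat = mat, dir = dir, rhs = rhs,
       obj_const = obj_const, nv = nv, eps = eps, nY = nY, I = I,
       wp = wp, wm = wm)
}

# Solve a standard-form LP via its dual (few rows when the primal has few
# variables); returns the primal solution recovered from the dual values.
lp_solve_via_dual <- function(obj, mat, dir, rhs, ...) {
  m <- nrow(mat)
  sgn <- ifelse(dir == "<=", -1, 1)          # y <= 0 becomes -v, v >= 0
  eq <- dir == "=="
  Dm <- t(mat) * rep(sgn, each = ncol(mat))
  Dobj <- rhs * sgn
  if (any(eq)) {                             # free duals: add mirrored cols
    Dm <- cbind(Dm, -Dm[, eq, drop = FALSE])
    Dobj <- c(Dobj, -Dobj[eq])
  }
  res <- lp_solve(Dobj, Dm, rep("<=", ncol(mat)), obj, maximize = TRUE, ...)
  if (res$status != "optimal") {
    st <- if (res$status == "unbounded") "infeasible" else
          if (res$status == "infeasible") "unbounded" else res$status
    return(list(status = st))
  }
  yd <- res$solution[seq_len(m)]
  if (any(eq)) yd[eq] <- yd[eq] - res$solution[m + seq_len(sum(eq))]
  list(status = "optimal", solution = res$duals, objval = res$objval,
       duals = yd * sgn)
}

#' Solve the constrained output-oriented BCC model for one DMU
#'
#' Minimizes the virtual input of the unit under evaluation minus the free
#' scale factor, subject to: unit virtual output (normalization); the
#' frontier inequalities of every DMU; minimum group contributions of P%
#' for the regular-atom, serious-atom and per-server output groups (when
#' `P > 0`); the per-atom assurance region (serious weight at least the
#' regular weight plus `eps`); and the non-Archimedean bound `eps` on all
#' weights. The efficiency is `1 / phi` where `phi` is the optimum.
#'
#' @param o index of the DMU under evaluation.
#' @param pr an `ems_dea_problem`.
#' @param P minimum group contribution, percent (0 disables the group
#'   constraints).
#' @param eps non-Archimedean lower bound on weights (on the
#'   mean-normalized data scale).
#' @param inverted evaluate against the inverted frontier (roles of
#'   inputs and outputs swapped, constraints mirrored).
#' @param normalize mean-normalize columns first (recommended).
#' @param method `"dual"` (envelopment side; fast for many DMUs) or
#'   `"multiplier"` (direct; useful for audits).
#' @return A list: `status`, `phi`, `efficiency`, and weight vectors
#'   `alpha`, `alpha_s`, `beta`, `gamma`, `w` on the (normalized) data
#'   scale. On infeasibility the bound is relaxed once to `eps / 10`
#'   with a warning before giving up.
#' @export
solve_bcc_output <- function(o, pr, P = 20, eps = 1e-6, inverted = FALSE,
                             normalize = TRUE,
                             method = c("dual", "multiplier")) {
  method <- match.arg(method)
  if (P < 0 || 3 * 0.01 * P > 1)
    stop2("P must satisfy 0 <= P and 3 * 0.01 * P <= 1")
  if (normalize) pr <- normalize_problem(pr)
  solve_once <- function(eps_use) {
    lp <- build_bcc_lp(pr, o, P = P, eps = eps_use, inverted = inverted)
    res <- if (method == "dual")
      lp_solve_via_dual(lp$obj, lp$mat, lp$dir, lp$rhs)
    else lp_solve(lp$obj, lp$mat, lp$dir, lp$rhs)
    if (method == "dual" && res$status == "iteration_limit")
      res <- lp_solve(lp$obj, lp$mat, lp$dir, lp$rhs)  # degenerate: direct
    list(res = res, lp = lp)
  }
  out <- solve_once(eps)
  if (out$res$status == "infeasible") {
    warning("BCC model infeasible for DMU ", pr$ids[o],
            "; relaxing weight bound to eps/10")
    out <- solve_once(eps / 10)
  }
  res <- out$res; lp <- out$lp
  if (res$status != "optimal")
    return(list(status = res$status, phi = NA_real_, efficiency = NA_real_))
  phi <- res$objval + lp$obj_const
  x <- res$solution
  A <- pr$A; I <- pr$I
  list(status = "optimal", phi = phi, efficiency = 1 / phi,
       alpha = x[seq_len(A)] + lp$eps,
       alpha_s = x[A + seq_len(A)] + lp$eps,
       beta = x[2 * A + seq_len(I)] + lp$eps,
       gamma = x[2 * A + I + seq_len(I)] + lp$eps,
       w = x[lp$wp] - x[lp$wm],
       eps_used = lp$eps)
}

#' Efficiencies of every DMU against the standard frontier
#'
#' @param pr an `ems_dea_problem`.
#' @param ... passed to [solve_bcc_output()].
#' @return A data frame (`id`, `phi`, `efficiency`, `status`) with the
#'   weight matrix in attribute `"weights"`.
#' @export
efficiency_all <- function(pr, ...) {
  res <- lapply(seq_len(pr$N), function(o) solve_bcc_output(o, pr, ...))
  wts <- t(vapply(res, function(r) {
    if (r$status == "optimal") c(r$alpha, r$alpha_s, r$beta, r$gamma, r$w)
    else rep(NA_real_, 2 * pr$A + 2 * pr$I + 1)
  }, numeric(2 * pr$A + 2 * pr$I + 1)))
  out <- data.frame(id = pr$ids,
                    phi = vapply(res, `[[`, 0, "phi"),
                    efficiency = vapply(res, `[[`, 0, "efficiency"),
                    status = vapply(res, `[[`, "", "status"))
  attr(out, "weights") <- wts
  out
}

#' Efficiencies against the inverted frontier
#'
#' Runs the same machinery with inputs and outputs swapped; a score of 1
#' marks a unit on the frontier of worst practice.
#'
#' @inheritParams efficiency_all
#' @return As [efficiency_all()].
#' @export
inverted_efficiency_all <- function(pr, ...) {
  efficiency_all(pr, inverted = TRUE, ...)
}

#' Composite index and ranking
#'
#' The composite index is the normalized mean of the standard-frontier
#' efficiency and one minus the inverted-frontier efficiency:
#' `raw = (standard + 1 - inverted) / 2`, scaled so the best unit scores
#' 1. Ranks are by descending index, ties broken by id order (stable).
#'
#' @param standard,inverted efficiency vectors in (0, 1].
#' @param ids DMU identifiers.
#' @return A data frame: `id`, `standard_eff`, `inverted_eff`,
#'   `composite`, `rank`.
#' @export
composite_index <- function(standard, inverted, ids = seq_along(standard)) {
  stopifnot(length(standard) == length(inverted))
  raw <- (standard + (1 - inverted)) / 2
  if (max(raw) <= 0) stop2("degenerate composite: all raw scores <= 0")
  composite <- raw / max(raw)
  ord <- order(-composite, seq_along(composite))
  rank <- integer(length(composite))
  rank[ord] <- seq_along(composite)
  if (length(unique(round(raw, 12))) == 1L)
    message("all composite scores tie; ranks follow id order")
  data.frame(id = ids, standard_eff = standard, inverted_eff = inverted,
             composite = composite, rank = rank)
}

#' Rank configurations by the DEA/BoD composite index
#'
#' Convenience wrapper: both frontiers plus [composite_index()].
#'
#' @param pr an `ems_dea_problem`.
#' @param P,eps,... passed to [solve_bcc_output()].
#' @return The [composite_index()] data frame.
#' @export
dea_rank <- function(pr, P = 20, eps = 1e-6, ...) {
  std <- efficiency_all(pr, P = P, eps = eps, ...)
  inv <- inverted_efficiency_all(pr, P = P, eps = eps, ...)
  composite_index(std$efficiency, inv$efficiency, ids = pr$ids)
}
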