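# Dense two-phase primal simplex with dual values.
#
# Solves   min c'x  s.t.  A x (<=, >=, ==) b,  x >= 0.
# Small/medium problems only; the DEA layer keeps the row count low by
# solving the envelopment (dual) form of the multiplier model and reading
# the multiplier weights off the dual values returned here.

#' Solve a linear program
#'
#' @param obj objective coefficient vector (minimized unless `maximize`).
#' @param mat constraint matrix.
#' @param dir character vector of `"<="`, `">="`, `"=="` per row.
#' @param rhs right-hand sides.
#' @param maximize maximize instead of minimize.
#' @param tol pivot/feasibility tolerance.
#' @param max_iter iteration cap.
#' @return A list: `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), `solution`, `objval`, and `duals` (one value
#'   per constraint row, signed for the minimization problem so that
#'   `objval == sum(duals * rhs)` at an optimum).
#' @keywords internal
#' @export
lp_solve <- function(obj, mat, dir, rhs, maximize = FALSE,
                     tol = 1e-9, max_iter = 20000L) {
  mat <- as.matrix(mat)
  m <- nrow(mat); n <- ncol(mat)
  stopifnot(length(obj) == n, length(dir) == m, length(rhs) == m)
  obj <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # standardize: flip rows to make b >= 0, add slack/artificial columns
  flip <- rhs < 0
  A <- mat; b <- as.numeric(rhs); d <- dir
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  d[flip] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[d[flip]]

  n_slack <- sum(d != "==")
  slack_col <- integer(m); art_col <- integer(m)
  Asl <- matrix(0, m, n_slack)
  k <- 0L
  for (i in seq_len(m)) {
    if (d[i] != "==") {
      k <- k + 1L
      Asl[i, k] <- if (d[i] == "<=") 1 else -1
      slack_col[i] <- n + k
    }
  }
  need_art <- d != "<="
  n_art <- sum(need_art)
  Aart <- matrix(0, m, n_art)
  k <- 0L
  for (i in seq_len(m)) {
    if (need_art[i]) {
      k <- k + 1L
      Aart[i, k] <- 1
      art_col[i] <- n + n_slack + k
    }
  }
  Tm <- cbind(A, Asl, Aart, b, deparse.level = 0)
  dimnames(Tm) <- NULL
  ntot <- n + n_slack + n_art
  rhs_col <- ntot + 1L

  basis <- ifelse(need_art, art_col, slack_col)
  # identity column associated with each row, for reading B^{-1} later
  id_col <- ifelse(need_art, art_col, slack_col)

  pivot <- function(Tm, zrow, pr, pc) {
    piv <- Tm[pr, pc]
    Tm[pr, ] <- Tm[pr, ] / piv
    fac <- Tm[, pc]; fac[pr] <- 0
    Tm <- Tm - outer(fac, Tm[pr, ])
    zf <- zrow[pc]
    zrow <- zrow - zf * Tm[pr, ]
    list(Tm = Tm, zrow = zrow)
  }

  run_phase <- function(Tm, basis, cost, allowed) {
    # zrow = reduced costs (c_j - z_j) with RHS cell = -objective value
    cb <- cost[basis]
    zrow <- c(cost, 0) - as.vector(cb %*% Tm)
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(status = "iteration_limit"))
      cand <- which(allowed & zrow[seq_len(ntot)] < -tol)
      if (!length(cand)) break
      pc <- if (it > 5L * (m + ntot)) min(cand)          # Bland fallback
            else cand[which.min(zrow[cand])]
      col <- Tm[, pc]
      pos <- which(col > tol)
      if (!length(pos)) return(list(status = "unbounded"))
      ratio <- Tm[pos, rhs_col] / col[pos]
      pr <- pos[which.min(ratio + 1e-12 * basis[pos])]   # deterministic ties
      st <- pivot(Tm, zrow, pr, pc)
      Tm <- st$Tm; zrow <- st$zrow
      basis[pr] <- pc
    }
    list(status = "optimal", Tm = Tm, basis = basis, zrow = zrow)
  }

  allowed <- rep(TRUE, ntot)
  if (n_art > 0) {
    cost1 <- c(numeric(n + n_slack), rep(1, n_art))
    ph1 <- run_phase(Tm, basis, cost1, allowed)
    if (ph1$status != "optimal") return(list(status = ph1$status))
    obj1 <- -ph1$zrow[rhs_col]
    if (obj1 > 1e-7) return(list(status = "infeasible"))
    Tm <- ph1$Tm; basis <- ph1$basis
    # drive leftover basic artificials out where possible
    for (i in which(basis > n + n_slack)) {
      row_nz <- which(abs(Tm[i, seq_len(n + n_slack)]) > tol)
      if (length(row_nz)) {
        st <- pivot(Tm, numeric(rhs_col), i, row_nz[1])
        Tm <- st$Tm
        basis[i] <- row_nz[1]
      }
    }
    allowed[(n + n_slack + 1L):ntot] <- FALSE
  }
  cost2 <- c(obj, numeric(n_slack + n_art))
  ph2 <- run_phase(Tm, basis, cost2, allowed)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  Tm <- ph2$Tm; basis <- ph2$basis; zrow <- ph2$zrow

  x <- numeric(ntot)
  x[basis] <- Tm[, rhs_col]
  sol <- x[seq_len(n)]
  val <- -zrow[rhs_col]
  # duals: y_i = z-value of row i's initial identity column = -reduced cost
  y <- -zrow[id_col] + cost2[id_col]
  y[flip] <- -y[flip]
  if (maximize) { val <- -val; y <- -y }
  list(status = "optimal", solution = sol, objval = val, duals = y)
}
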