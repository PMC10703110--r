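#' Discrete-event simulation of the emergency system
#'
#' Independent validation oracle for the analytic hypercube results:
#' Poisson arrivals per sub atom, exponential service per group, the same
#' dispatch preference policy, non-preemptive priority queueing (or loss
#' when `Q_l = 0`). Serious queued calls are taken first; dedicated units
#' take only serious calls and go idle otherwise. Statistics are collected
#' after `warmup` and summarized with batch-means confidence intervals.
#'
#' @param config a configuration.
#' @param sys an [ems_system()].
#' @param horizon simulated minutes (`> warmup`).
#' @param warmup warm-up period, minutes (default 10% of horizon).
#' @param seed integer seed; results are reproducible per seed.
#' @param Q_l queue capacity (0 = pure loss system).
#' @param mu_inv optional per-group mean service times (minutes);
#'   defaults to the type-level system values.
#' @param dispatch_policy optional prebuilt [make_dispatch_policy()]
#'   object (its seed governs backup ordering, `seed` the event stream).
#' @param n_batches number of batches for the confidence intervals.
#' @param conf confidence level for the half-widths (default 0.99).
#' @return An object of class `ems_simulation`: per-group busy fractions
#'   and mean response times with half-widths, per-sub-atom mean response
#'   times, loss fraction, event counts.
#' @export
simulate_system <- function(config, sys, horizon, warmup = 0.1 * horizon,
                            seed = 1L, Q_l = 5L, mu_inv = NULL,
                            dispatch_policy = NULL, n_batches = 20L,
                            conf = 0.99) {
  if (horizon <= warmup || warmup < 0) stop2("need horizon > warmup >= 0")
  dp <- dispatch_policy %||% make_dispatch_policy(config, sys, seed)
  gr <- dp$groups
  sub <- dp$subatoms
  Tn <- nrow(gr)
  if (is.null(mu_inv)) mu_inv <- unname(sys$service_time[gr$type])
  on_scene <- unname(sys$on_scene[gr$type])
  lam <- sub$lambda
  Lam <- sum(lam)
  if (Lam <= 0) stop2("system has no demand")
  resp_tj <- sys$travel[gr$atom, sub$atom, drop = FALSE] +
    matrix(on_scene, Tn, nrow(sub))

  batch_len <- (horizon - warmup) / n_batches
  busy_int <- matrix(0, n_batches, Tn)      # busy-server time integrals
  rt_sum <- matrix(0, n_batches, Tn)        # response-time sums per group
  rt_n <- matrix(0L, n_batches, Tn)
  sub_sum <- numeric(nrow(sub))
  sub_n <- integer(nrow(sub))
  arrivals <- losses <- 0L

  with_seed(seed, {
    busy <- integer(Tn)
    ct <- numeric(0); cg <- integer(0)      # pending completions
    qs_list <- integer(0); qu_list <- integer(0)  # queued sub atoms (FIFO)
    now <- 0
    next_arr <- stats::rexp(1, Lam)
    last <- 0

    accrue <- function(upto) {
      # spread busy-time integral over the batch grid
      if (upto <= warmup || last >= horizon) return(invisible())
      a <- max(last, warmup); b <- min(upto, horizon)
      while (a < b) {
        k <- min(n_batches, floor((a - warmup) / batch_len) + 1)
        edge <- min(b, warmup + k * batch_len)
        busy_int[k, ] <<- busy_int[k, ] + busy * (edge - a)
        a <- edge
      }
      invisible()
    }
    batch_of <- function(tm) max(1L, min(n_batches,
                                         floor((tm - warmup) / batch_len) + 1L))
    record <- function(t_grp, j, tm) {
      if (tm <= warmup) return(invisible())
      k <- batch_of(tm)
      rt_sum[k, t_grp] <<- rt_sum[k, t_grp] + resp_tj[t_grp, j]
      rt_n[k, t_grp] <<- rt_n[k, t_grp] + 1L
      sub_sum[j] <<- sub_sum[j] + resp_tj[t_grp, j]
      sub_n[j] <<- sub_n[j] + 1L
      invisible()
    }
    start_service <- function(t_grp, j, tm) {
      record(t_grp, j, tm)
      ct <<- c(ct, tm + stats::rexp(1, 1 / mu_inv[t_grp]))
      cg <<- c(cg, t_grp)
      invisible()
    }

    while (TRUE) {
      nc <- if (length(ct)) which.min(ct) else 0L
      t_next <- if (nc) min(next_arr, ct[nc]) else next_arr
      if (t_next >= horizon) { accrue(horizon); break }
      accrue(t_next)
      last <- t_next
      now <- t_next
      if (nc && ct[nc] <= next_arr) {         # completion event
        t_grp <- cg[nc]
        ct <- ct[-nc]; cg <- cg[-nc]
        if (length(qs_list)) {                # serious head first
          j <- qs_list[1L]; qs_list <- qs_list[-1L]
          start_service(t_grp, j, now)
        } else if (!gr$dedicated[t_grp] && length(qu_list)) {
          j <- qu_list[1L]; qu_list <- qu_list[-1L]
          start_service(t_grp, j, now)
        } else busy[t_grp] <- busy[t_grp] - 1L
      } else {                                # arrival event
        next_arr <- now + stats::rexp(1, Lam)
        j <- sample.int(nrow(sub), 1L, prob = lam)
        if (now > warmup) arrivals <- arrivals + 1L
        p <- dp$pref[[j]]
        free <- p[busy[p] < gr$n[p]]
        if (length(free)) {
          t_grp <- free[1L]
          busy[t_grp] <- busy[t_grp] + 1L
          start_service(t_grp, j, now)
        } else if (length(qs_list) + length(qu_list) < Q_l) {
          if (sub$priority[j] == "serious") qs_list <- c(qs_list, j)
          else qu_list <- c(qu_list, j)
        } else if (now > warmup) losses <- losses + 1L
      }
    }
  })

  half <- function(m) {  # batch-means half-width
    s <- apply(m, 2, stats::sd)
    s * stats::qt(1 - (1 - conf) / 2, n_batches - 1L) / sqrt(n_batches)
  }
  busy_frac <- busy_int / batch_len
  rho <- colMeans(busy_frac) / gr$n
  rho_half <- half(sweep(busy_frac, 2, gr$n, "/"))
  grp_time <- ifelse(colSums(rt_n) > 0, colSums(rt_sum) / colSums(rt_n), NA)

  structure(list(
    groups = cbind(gr, rho = rho, rho_half = rho_half, mean_time = grp_time),
    subatoms = cbind(sub, mean_time = ifelse(sub_n > 0, sub_sum / sub_n, NA),
                     served = sub_n),
    loss_frac = if (arrivals > 0) losses / arrivals else 0,
    arrivals = arrivals, losses = losses,
    horizon = horizon, warmup = warmup, seed = seed, conf = conf
  ), class = "ems_simulation")
}

#' @export
print.ems_simulation <- function(x, ...) {
  cat("Discrete-event simulation:", x$arrivals, "arrivals after warmup,",
      sprintf("loss fraction %.4f (seed %d)\n", x$loss_frac, x$seed))
  print(x$groups, digits = 4)
  invisible(x)
}
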