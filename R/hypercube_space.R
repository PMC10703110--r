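#' Aggregate a configuration into server groups
#'
#' Co-located servers of the same type are homogeneous and
#' indistinguishable, so the state space tracks only the busy count of each
#' (type, atom) group rather than each individual server. Groups are
#' ordered deterministically by (fleet order, atom index).
#'
#' @param config a configuration (list with `id` and `alloc`, as produced
#'   by [enumerate_configurations()]).
#' @param sys an [ems_system()].
#' @return A data frame with one row per group: `type`, `atom`, `n`,
#'   `dedicated`.
#' @export
build_server_groups <- function(config, sys) {
  rows <- list()
  for (fl in sys$fleets) {
    v <- config$alloc[[fl$type]]
    if (is.null(v)) next
    if (sum(v) != fl$count)
      stop2("allocation for type '", fl$type, "' does not sum to its count")
    at <- which(v > 0)
    if (length(at))
      rows[[length(rows) + 1L]] <- data.frame(
        type = fl$type, atom = at, n = as.integer(v[at]),
        dedicated = fl$dedicated)
  }
  if (!length(rows)) stop2("empty configuration: no servers allocated")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the aggregated state space
#'
#' States record the busy count of every server group plus a queue
#' descriptor `(qs, qu)`: the numbers of serious and regular calls waiting.
#' Three state classes exist:
#' \itemize{
#'   \item core states: any busy-count combination, empty queue —
#'     `prod(n_t + 1)` states;
#'   \item dedicated-induced queue states: all non-dedicated groups busy,
#'     dedicated groups not all busy, a queue of regular calls only
#'     (regular calls cannot use the free dedicated units) —
#'     `(prod over dedicated groups (n_g + 1) - 1) * Q_l` states, which is
#'     `n_ds * Q_l` when the dedicated servers form a single group;
#'   \item saturated queue states: every server busy and a two-priority
#'     queue multiset — `choose(Q_l + 2, 2) - 1` states.
#' }
#'
#' @param groups group table from [build_server_groups()].
#' @param Q_l queue capacity (`>= 0`); forced to 0 when
#'   `policy = "no_queue"`.
#' @param policy `"queue"` or `"no_queue"`.
#' @param max_states guard on the state count (default `2e5`).
#' @return An object of class `ems_state_space` with the state table,
#'   index radices and counts.
#' @export
build_state_space <- function(groups, Q_l = 5L, policy = c("queue", "no_queue"),
                              max_states = 2e5) {
  policy <- match.arg(policy)
  if (policy == "no_queue") Q_l <- 0L
  Q_l <- as.integer(Q_l)
  if (Q_l < 0L) stop2("Q_l must be >= 0")
  Tn <- nrow(groups)
  n <- groups$n
  ded <- groups$dedicated

  n_core <- prod(n + 1)
  ded_patterns <- if (any(ded)) prod(n[ded] + 1) - 1 else 0
  n_qds <- ded_patterns * Q_l
  n_qpr <- choose(Q_l + 2, 2) - 1
  S <- n_core + n_qds + n_qpr
  if (S > max_states)
    stop2("state space too large: ", S, " states exceeds cap ", max_states)

  # core states: mixed-radix enumeration of busy counts
  core <- as.matrix(expand.grid(lapply(n, function(k) 0:k),
                                KEEP.OUT.ATTRS = FALSE))
  dimnames(core) <- NULL
  qs <- integer(nrow(core))
  qu <- integer(nrow(core))

  if (Q_l > 0L) {
    # dedicated-induced: non-dedicated groups full, dedicated not all full
    if (ded_patterns > 0) {
      dp <- as.matrix(expand.grid(lapply(n[ded], function(k) 0:k),
                                  KEEP.OUT.ATTRS = FALSE))
      dp <- dp[rowSums(dp) < sum(n[ded]), , drop = FALSE]
      for (q in seq_len(Q_l)) {
        b <- matrix(rep(n, each = nrow(dp)), nrow(dp), Tn)
        b[, ded] <- dp
        core <- rbind(core, b)
        qs <- c(qs, integer(nrow(dp)))
        qu <- c(qu, rep.int(q, nrow(dp)))
      }
    }
    # saturated: everything busy, queue multiset (qs, qu), 1 <= qs+qu <= Q_l
    sat <- expand.grid(qs = 0:Q_l, qu = 0:Q_l)
    sat <- sat[sat$qs + sat$qu >= 1 & sat$qs + sat$qu <= Q_l, ]
    core <- rbind(core, matrix(rep(n, each = nrow(sat)), nrow(sat), Tn))
    qs <- c(qs, sat$qs)
    qu <- c(qu, sat$qu)
  }
  storage.mode(core) <- "integer"

  # mixed-radix code for O(1) state lookup
  rad <- cumprod(c(1, n + 1))
  rad_qs <- rad[Tn + 1]
  rad_qu <- rad_qs * (Q_l + 1)
  code <- as.vector(core %*% rad[seq_len(Tn)]) + qs * rad_qs + qu * rad_qu
  index <- integer(rad_qu * (Q_l + 1))
  index[code + 1L] <- seq_along(code)

  structure(list(
    groups = groups, n = n, ded = ded, Tn = Tn,
    Q_l = Q_l, policy = policy,
    busy = core, qs = as.integer(qs), qu = as.integer(qu),
    S = nrow(core), n_core = n_core, n_qds = n_qds, n_qpr = n_qpr,
    rad = rad[seq_len(Tn)], rad_qs = rad_qs, rad_qu = rad_qu,
    code = code, index = index
  ), class = "ems_state_space")
}

#' @export
print.ems_state_space <- function(x, ...) {
  cat("Aggregated hypercube state space:", x$S, "states\n")
  cat("  ", x$Tn, "server group(s); core", x$n_core,
      "+ dedicated-queue", x$n_qds, "+ saturated-queue", x$n_qpr, "\n")
  invisible(x)
}

subatom_table <- function(sys) {
  A <- sys$A
  data.frame(
    subatom = seq_len(2L * A),
    atom = rep(seq_len(A), each = 2L),
    priority = rep(c("serious", "regular"), A),
    lambda = as.vector(t(sys$arrival[, c("serious", "regular"), drop = FALSE]))
  )
}

#' Build a dispatch preference policy
#'
#' For every sub atom an ordered preference list over server groups.
#' Serious calls: dedicated (ASU) groups first, nearest first with seeded
#' random tie-breaks; then the basic-unit group in the call's atom; then
#' the remaining basic groups in seeded random order (they act as backups
#' chosen at random). Regular calls: the basic group in the call's atom
#' first, then the remaining basic groups ordered by mean journey time to
#' the call with seeded random tie-breaks. Dedicated units never serve
#' regular calls. Reproducible for a fixed seed.
#'
#' @param config a configuration.
#' @param sys an [ems_system()].
#' @param seed integer seed for the randomized backup ordering.
#' @return An object of class `ems_dispatch_policy` carrying the group
#'   table and per-sub-atom preference lists.
#' @export
make_dispatch_policy <- function(config, sys, seed = 1L) {
  groups <- build_server_groups(config, sys)
  sub <- subatom_table(sys)
  bsu_idx <- which(!groups$dedicated)
  ded_idx <- which(groups$dedicated)
  if (!length(bsu_idx)) stop2("no non-dedicated groups: regular calls unservable")

  pref <- with_seed(seed, lapply(seq_len(nrow(sub)), function(j) {
    a <- sub$atom[j]
    tt_bsu <- sys$travel[groups$atom[bsu_idx], a]
    local_b <- bsu_idx[groups$atom[bsu_idx] == a]
    rest_b <- setdiff(bsu_idx, local_b)
    if (sub$priority[j] == "serious") {
      tt_ded <- sys$travel[groups$atom[ded_idx], a]
      ded_ord <- ded_idx[order(tt_ded, stats::runif(length(ded_idx)))]
      rest_ord <- rest_b[sample.int(length(rest_b))]
      c(ded_ord, local_b, rest_ord)
    } else {
      tt_rest <- sys$travel[groups$atom[rest_b], a]
      rest_ord <- rest_b[order(tt_rest, stats::runif(length(rest_b)))]
      c(local_b, rest_ord)
    }
  }))
  structure(list(groups = groups, subatoms = sub, pref = pref, seed = seed),
            class = "ems_dispatch_policy")
}

#' @export
print.ems_dispatch_policy <- function(x, ...) {
  cat("Dispatch policy over", nrow(x$groups), "group(s),",
      nrow(x$subatoms), "sub atoms (seed", x$seed, ")\n")
  invisible(x)
}
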