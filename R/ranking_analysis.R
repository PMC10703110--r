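# Post-ranking pattern analysis: Spearman correlations between per-atom
# ambulance counts (and allocation dispersion) and ranks, concentration
# grouping, and cross-scenario rank agreement.

#' Spearman rank correlation with a t-approximation p-value
#'
#' Average ranks for ties; two-sided p-value from the large-sample
#' t approximation `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return A list with `rho` and `p_value`; a constant vector yields
#'   `NA` for both (undefined coefficient).
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop2("need at least 3 observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p_value = NA_real_))
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), n - 2)
  }
  list(rho = rho, p_value = p)
}

sig_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Correlations between per-atom server counts and ranking
#'
#' For each atom, the Spearman correlation between the number of movable
#' servers placed in it and the configuration rank, per scenario; plus a
#' dispersion row correlating the standard deviation of each allocation
#' vector with the rank. Significance stars: * 0.05, ** 0.01, *** 0.001.
#'
#' @param alloc N x A matrix of per-atom server counts, one row per
#'   configuration.
#' @param ranks named list (or data frame) of rank vectors, one per
#'   scenario, aligned with the rows of `alloc`.
#' @param atom_names optional atom labels.
#' @return A data frame with `A + 1` rows (atoms then `sd`) and, per
#'   scenario, `<label>_rho` and `<label>_sig` columns.
#' @export
atom_correlations <- function(alloc, ranks, atom_names = NULL) {
  alloc <- as.matrix(alloc)
  if (is.data.frame(ranks)) ranks <- as.list(ranks)
  for (lab in names(ranks))
    if (length(ranks[[lab]]) != nrow(alloc))
      stop2("rank vector '", lab, "' is not aligned with the configurations")
  A <- ncol(alloc)
  vars <- cbind(alloc, sd = apply(alloc, 1, stats::sd))
  labels <- c(atom_names %||% paste0("A", seq_len(A)), "sd")
  out <- data.frame(variable = labels)
  for (lab in names(ranks)) {
    res <- apply(vars, 2, function(v) spearman(v, ranks[[lab]]))
    out[[paste0(lab, "_rho")]] <- vapply(res, `[[`, 0, "rho")
    out[[paste0(lab, "_sig")]] <-
      sig_stars(vapply(res, `[[`, 0, "p_value"))
  }
  out
}

#' Concentration groups and their rank profiles
#'
#' Partitions configurations by allocation shape (the sorted multiset of
#' per-atom counts), ordered from fully spread (group `A`) to fully
#' concentrated in one atom, and summarizes the ranks within each group.
#'
#' @param alloc N x A allocation matrix.
#' @param ranks rank vector aligned with `alloc` rows.
#' @return A data frame per group: label, shape, number of occupied
#'   atoms, allocation standard deviation, configuration count, and mean,
#'   standard deviation, min and max of the ranks.
#' @export
concentration_groups <- function(alloc, ranks) {
  alloc <- as.matrix(alloc)
  if (length(ranks) != nrow(alloc)) stop2("ranks not aligned with alloc")
  shape <- apply(alloc, 1, function(v) paste(sort(v, decreasing = TRUE),
                                             collapse = "+"))
  sdv <- apply(alloc, 1, stats::sd)
  occ <- rowSums(alloc > 0)
  shapes <- unique(shape[order(sdv, -occ)])
  lab <- make.unique(LETTERS[pmin(seq_along(shapes), 26L)], sep = "")
  idx <- match(shape, shapes)
  out <- do.call(rbind, lapply(seq_along(shapes), function(g) {
    r <- ranks[idx == g]
    data.frame(group = lab[g], shape = shapes[g],
               occupied_atoms = occ[match(shapes[g], shape)],
               alloc_sd = sdv[match(shapes[g], shape)],
               n_configs = length(r), mean_rank = mean(r),
               sd_rank = stats::sd(r), min_rank = min(r), max_rank = max(r))
  }))
  rownames(out) <- NULL
  out
}

#' Cross-scenario rank agreement matrix
#'
#' Spearman correlations between the rank vectors of every scenario pair;
#' symmetric with unit diagonal.
#'
#' @param ranks named list (or data frame) of aligned rank vectors.
#' @return A square correlation matrix.
#' @export
rank_agreement <- function(ranks) {
  if (is.data.frame(ranks)) ranks <- as.list(ranks)
  labs <- names(ranks)
  M <- diag(1, length(ranks))
  dimnames(M) <- list(labs, labs)
  if (length(ranks) > 1L)
    for (i in seq_along(ranks)) for (j in seq_along(ranks))
      if (i != j) M[i, j] <- spearman(ranks[[i]], ranks[[j]])$rho
  M
}
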