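#' Integer partitions with a bounded number of parts
#'
#' All partitions of `n` into at most `max_parts` positive parts, each
#' exactly once, in reverse-lexicographic order (largest first part first).
#' Zero-filled to `max_parts` terms, a partition is the multiset of group
#' sizes a configuration can take over the atoms.
#'
#' @param n positive integer to partition.
#' @param max_parts maximum number of positive parts (`>= 1`).
#' @return A list of integer vectors (non-increasing positive terms).
#' @examples
#' integer_partitions(4, 4)  # 4; 3+1; 2+2; 2+1+1; 1+1+1+1
#' @export
integer_partitions <- function(n, max_parts = n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop2("n must be a positive integer")
  max_parts <- as.integer(max_parts)
  if (max_parts < 1L) stop2("max_parts must be >= 1")
  out <- list()
  rec <- function(remaining, max_term, parts) {
    if (remaining == 0L) {
      out[[length(out) + 1L]] <<- parts
      return(invisible())
    }
    if (length(parts) == max_parts) return(invisible())
    for (term in seq.int(min(max_term, remaining), 1L)) {
      rec(remaining - term, term, c(parts, term))
    }
  }
  rec(n, n, integer(0))
  out
}

#' Number of distinct permutations of a zero-filled partition
#'
#' A partition of `n` zero-filled to `A` terms yields `A! / prod(R_j!)`
#' distinct atom assignments, where `R_j` counts how often the value `j`
#' (including 0) repeats among the terms. Computed exactly in integer
#' arithmetic.
#'
#' @param partition integer vector of positive partition terms (zeros are
#'   added automatically up to length `A`).
#' @param A number of atoms; must be `>= length(partition)`.
#' @return Integer count of distinct permutations.
#' @examples
#' count_permutations(c(2, 1, 1), 3)  # 3!/2! = 3
#' count_permutations(c(3, 1), 3)     # 3! = 6
#' @export
count_permutations <- function(partition, A) {
  partition <- as.integer(partition[partition != 0L])
  if (length(partition) > A)
    stop2("partition has more positive terms than atoms")
  filled <- c(partition, integer(A - length(partition)))
  reps <- table(filled)
  # exact integer A! / prod(R_j!): cancel the largest factorial first
  r <- sort(as.integer(reps), decreasing = TRUE)
  num <- seq_len(A)
  num <- num[num > r[1]]
  val <- 1
  for (x in num) val <- val * x
  for (rr in r[-1]) val <- val / factorial(rr)
  as.integer(round(val))
}

#' Enumerate all allocations of n indistinguishable servers to A atoms
#'
#' Every distinct length-`A` vector of non-negative integers summing to
#' `n`, generated partition-by-partition (each partition contributing its
#' distinct permutations), in reverse-lexicographic order. The count equals
#' the weak-composition number `choose(n + A - 1, A - 1)`.
#'
#' @param n number of servers (`>= 0`).
#' @param A number of atoms (`>= 1`).
#' @return An integer matrix with `A` columns, one row per allocation.
#' @examples
#' nrow(enumerate_allocations(4, 3))  # 15
#' nrow(enumerate_allocations(7, 6))  # 792
#' @export
enumerate_allocations <- function(n, A) {
  n <- as.integer(n)
  A <- as.integer(A)
  if (n < 0L) stop2("n must be >= 0")
  if (A < 1L) stop2("A must be >= 1")
  if (n == 0L) return(matrix(0L, 1L, A))
  # recursive weak compositions in reverse-lexicographic order
  rec <- function(remaining, slots) {
    if (slots == 1L) return(matrix(remaining, 1L, 1L))
    blocks <- lapply(seq.int(remaining, 0L), function(first) {
      rest <- rec(remaining - first, slots - 1L)
      cbind(first, rest, deparse.level = 0)
    })
    do.call(rbind, blocks)
  }
  out <- rec(n, A)
  dimnames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

#' Combine per-type allocation lists into configurations
#'
#' The enumeration is run separately per server type; the full configuration
#' set is the Cartesian product of the per-type lists, with sequential ids.
#'
#' @param per_type_lists named list mapping server type to an allocation
#'   matrix (as from [enumerate_allocations()]).
#' @return A list of configurations; each has `id` and `alloc` (a named
#'   list of per-type allocation vectors).
#' @examples
#' bsu <- enumerate_allocations(4, 3)
#' asu <- enumerate_allocations(1, 3)
#' length(combine_server_types(list(BSU = bsu, ASU = asu)))  # 45
#' @export
combine_server_types <- function(per_type_lists) {
  if (length(per_type_lists) == 0L) stop2("no server types given")
  for (ty in names(per_type_lists)) {
    if (is.null(per_type_lists[[ty]]) || nrow(per_type_lists[[ty]]) == 0L)
      stop2("empty allocation list for type '", ty, "'")
  }
  sizes <- vapply(per_type_lists, nrow, 0L)
  idx <- expand.grid(lapply(rev(sizes), seq_len), KEEP.OUT.ATTRS = FALSE)
  idx <- idx[, rev(seq_along(sizes)), drop = FALSE]  # first type varies slowest
  names(idx) <- names(sizes)
  lapply(seq_len(nrow(idx)), function(i) {
    alloc <- lapply(names(per_type_lists), function(ty) {
      per_type_lists[[ty]][idx[i, ty], ]
    })
    names(alloc) <- names(per_type_lists)
    list(id = i, alloc = alloc)
  })
}

#' Enumerate the configurations of a system
#'
#' Convenience wrapper: enumerates allocations for every movable fleet of
#' `sys` and pins dedicated fleets to their base atoms (`fixed_atoms`).
#' With `enumerate_dedicated = TRUE` dedicated fleets are enumerated too.
#'
#' @param sys an [ems_system()].
#' @param enumerate_dedicated also enumerate dedicated fleets over atoms.
#' @return A list of configurations as in [combine_server_types()].
#' @export
enumerate_configurations <- function(sys, enumerate_dedicated = FALSE) {
  lists <- list()
  for (fl in sys$fleets) {
    lists[[fl$type]] <-
      if (fl$dedicated && !enumerate_dedicated)
        matrix(fl$fixed_atoms, 1L, sys$A)
      else enumerate_allocations(fl$count, sys$A)
  }
  combine_server_types(lists)
}
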