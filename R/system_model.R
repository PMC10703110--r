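#' Emergency-system description
#'
#' An `ems_system` object is the canonical description of a spatially
#' distributed emergency care system: geographic zones ("atoms"), Poisson
#' call arrival rates per sub atom (atom crossed with call priority:
#' `serious` calls are life-threatening and handled preferentially by
#' dedicated advanced units, `regular` calls by basic units), a mean
#' inter-atom journey-time matrix, and one or more server fleets.
#'
#' Rates are stored per minute internally; loaders convert from the
#' per-hour rates used in data files. Times are minutes throughout.
#'
#' @param atoms character vector of atom names (length `A >= 2`).
#' @param arrival numeric `A x 2` matrix of arrival rates per minute with
#'   columns `serious` and `regular`.
#' @param travel numeric `A x A` matrix of mean journey times in minutes
#'   (rows: server base atom; columns: call atom). Strictly positive, not
#'   required to be symmetric; intra-atom entries may exceed inter-atom ones.
#' @param fleets list of fleet records as built by [fleet()].
#' @param service_time named numeric vector, mean total response time
#'   (travel plus on-scene component) in minutes per server type.
#'
#' @return An object of class `ems_system`.
#' @seealso [load_system()], [generate_synthetic_system()], [scale_demand()]
#' @export
ems_system <- function(atoms, arrival, travel, fleets, service_time) {
  arrival <- as.matrix(arrival)
  colnames(arrival) <- c("serious", "regular")
  travel <- as.matrix(travel)
  on_scene <- service_time - mean(diag(travel))
  sys <- structure(
    list(
      atoms = as.character(atoms),
      A = length(atoms),
      arrival = arrival,
      travel = travel,
      fleets = fleets,
      service_time = service_time,
      on_scene = on_scene,
      time_unit = "minutes"
    ),
    class = "ems_system"
  )
  validate_system(sys)
  sys
}

#' Fleet record
#'
#' A fleet is a set of indistinguishable servers of one type. Dedicated
#' fleets (advanced units, ASU) answer only serious calls and are pinned to
#' base atoms via `fixed_atoms`; movable fleets (basic units, BSU) are the
#' ones enumerated over atoms.
#'
#' @param type server-type tag, e.g. `"BSU"` or `"ASU"`.
#' @param count number of servers (`>= 1`).
#' @param dedicated logical; `TRUE` for fleets reserved for serious calls.
#' @param fixed_atoms integer allocation vector (length `A`) summing to
#'   `count`, required when `dedicated` is `TRUE`.
#' @return A list of class `ems_fleet`.
#' @export
fleet <- function(type, count, dedicated = FALSE, fixed_atoms = NULL) {
  count <- as.integer(count)
  if (count < 1L) stop2("fleet '", type, "': count must be >= 1")
  if (dedicated) {
    if (is.null(fixed_atoms) || sum(fixed_atoms) != count)
      stop2("dedicated fleet '", type, "': fixed_atoms must sum to count")
  }
  structure(list(type = type, count = count, dedicated = isTRUE(dedicated),
                 fixed_atoms = if (!is.null(fixed_atoms)) as.integer(fixed_atoms)),
            class = "ems_fleet")
}

validate_system <- function(sys) {
  A <- sys$A
  if (A < 2L) stop2("system must have at least 2 atoms")
  if (any(sys$arrival < 0)) stop2("arrival rates must be >= 0")
  if (all(sys$arrival == 0)) stop2("at least one arrival rate must be > 0")
  if (!is.matrix(sys$travel) || nrow(sys$travel) != A || ncol(sys$travel) != A)
    stop2("travel-time matrix must be square ", A, "x", A)
  if (any(sys$travel <= 0)) stop2("travel times must be strictly positive")
  if (any(sys$service_time <= 0)) stop2("service times must be > 0")
  for (fl in sys$fleets) {
    if (!fl$type %in% names(sys$service_time))
      stop2("no service time for fleet type '", fl$type, "'")
    if (fl$dedicated && length(fl$fixed_atoms) != A)
      stop2("dedicated fleet '", fl$type, "': fixed_atoms must have length A")
  }
  invisible(sys)
}

#' @export
print.ems_system <- function(x, ...) {
  cat("Emergency system:", x$A, "atoms,", 2L * x$A, "sub atoms\n")
  for (fl in x$fleets)
    cat(sprintf("  %s: %d server(s)%s, mean service time %.1f min\n", fl$type,
                fl$count, if (fl$dedicated) " [dedicated]" else "",
                x$service_time[[fl$type]]))
  cat(sprintf("  total demand %.4f calls/h, offered load %.2f erlangs\n",
              sum(x$arrival) * 60, sum(x$arrival) * mean(x$service_time)))
  invisible(x)
}

#' Load a system description from a directory of CSV files
#'
#' Reads `atoms.csv`, `arrival_rates.csv`, `travel_times.csv` and
#' `servers.csv` (schemas documented in the packaged `extdata/README.md`)
#' and returns a validated [ems_system()]. File rates are per hour; the
#' returned object stores rates per minute. Atom ordering is the order of
#' `atoms.csv`.
#'
#' @param path directory containing the four CSV files.
#' @return An `ems_system`.
#' @examples
#' sys <- load_system(system.file("extdata", "bauru", package = "emsrank"))
#' sys
#' @export
load_system <- function(path) {
  need <- c("atoms.csv", "arrival_rates.csv", "travel_times.csv", "servers.csv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop2("missing system file(s) in '", path, "': ", paste(missing, collapse = ", "))
  atoms <- utils::read.csv(file.path(path, "atoms.csv"))
  rates <- utils::read.csv(file.path(path, "arrival_rates.csv"))
  tt <- utils::read.csv(file.path(path, "travel_times.csv"))
  srv <- utils::read.csv(file.path(path, "servers.csv"))

  A <- nrow(atoms)
  aid <- atoms$atom_id
  if (!identical(sort(unique(c(tt$from_atom, tt$to_atom))), sort(aid)) ||
      nrow(tt) != A * A)
    stop2("travel_times.csv does not define a square matrix over the ",
          A, " atoms of atoms.csv")
  bad <- setdiff(unique(rates$priority), c("serious", "regular"))
  if (length(bad))
    stop2("unknown priority tag(s) in arrival_rates.csv: ",
          paste(bad, collapse = ", "))
  if (any(rates$rate_per_hour < 0)) {
    off <- rates[rates$rate_per_hour < 0, ][1, ]
    stop2("negative arrival rate for atom ", off$atom_id, " (", off$priority, ")")
  }

  arrival <- matrix(0, A, 2, dimnames = list(atoms$name, c("serious", "regular")))
  for (i in seq_len(nrow(rates))) {
    a <- match(rates$atom_id[i], aid)
    arrival[a, rates$priority[i]] <- rates$rate_per_hour[i] / 60
  }
  travel <- matrix(NA_real_, A, A)
  travel[cbind(match(tt$from_atom, aid), match(tt$to_atom, aid))] <- tt$minutes

  service_time <- c()
  fleets <- list()
  for (type in unique(srv$server_type)) {
    rows <- srv[srv$server_type == type, ]
    service_time[type] <- rows$mean_service_time_min[1]
    dedicated <- any(rows$dedicated == 1)
    if (dedicated) {
      fixed <- integer(A)
      for (i in seq_len(nrow(rows))) {
        a <- match(rows$base_atom[i], aid)
        if (is.na(a)) stop2("dedicated fleet '", type, "' has no valid base_atom")
        fixed[a] <- fixed[a] + rows$count[i]
      }
      fleets[[length(fleets) + 1L]] <- fleet(type, sum(rows$count), TRUE, fixed)
    } else {
      fleets[[length(fleets) + 1L]] <- fleet(type, sum(rows$count))
    }
  }
  ems_system(atoms$name, arrival, travel, fleets, service_time)
}

#' Write a system description to a directory of CSV files
#'
#' Inverse of [load_system()]: rates are written per hour. A subsequent
#' [load_system()] round-trips to an identical system.
#'
#' @param sys an `ems_system`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_system <- function(sys, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  A <- sys$A
  utils::write.csv(data.frame(atom_id = seq_len(A), name = sys$atoms),
                   file.path(path, "atoms.csv"), row.names = FALSE, quote = FALSE)
  rates <- data.frame(
    atom_id = rep(seq_len(A), each = 2),
    priority = rep(c("serious", "regular"), A),
    rate_per_hour = as.vector(t(sys$arrival)) * 60
  )
  utils::write.csv(rates, file.path(path, "arrival_rates.csv"),
                   row.names = FALSE, quote = FALSE)
  tt <- data.frame(
    from_atom = rep(seq_len(A), each = A),
    to_atom = rep(seq_len(A), A),
    minutes = as.vector(t(sys$travel))
  )
  utils::write.csv(tt, file.path(path, "travel_times.csv"),
                   row.names = FALSE, quote = FALSE)
  srv <- do.call(rbind, lapply(sys$fleets, function(fl) {
    if (fl$dedicated) {
      at <- which(fl$fixed_atoms > 0)
      data.frame(server_type = fl$type, count = fl$fixed_atoms[at],
                 dedicated = 1L, base_atom = at,
                 mean_service_time_min = sys$service_time[[fl$type]])
    } else {
      data.frame(server_type = fl$type, count = fl$count, dedicated = 0L,
                 base_atom = NA_integer_,
                 mean_service_time_min = sys$service_time[[fl$type]])
    }
  }))
  utils::write.csv(srv, file.path(path, "servers.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Scale the demand of a system
#'
#' Multiplies every sub-atom arrival rate by `factor`, leaving everything
#' else unchanged. Used to build the increased-demand scenarios (e.g.
#' +25%, +50% over the observed rates).
#'
#' @param sys an `ems_system`.
#' @param factor positive demand multiplier.
#' @return A new `ems_system`; the input is not modified.
#' @export
scale_demand <- function(sys, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop2("demand factor must be a positive number")
  sys$arrival <- sys$arrival * factor
  validate_system(sys)
  sys
}

#' Path to a packaged case system
#'
#' @param name `"bauru"` or `"ribeirao_preto"`.
#' @return Directory path suitable for [load_system()].
#' @export
ems_fixture <- function(name = c("bauru", "ribeirao_preto")) {
  name <- match.arg(name)
  system.file("extdata", name, package = "emsrank", mustWork = TRUE)
}

#' Generate a random synthetic emergency system
#'
#' Draws a system with the same structure as the packaged cases: a strictly
#' positive journey-time matrix whose intra-atom entries are on the same
#' scale as inter-atom entries, two priority layers per atom (serious calls
#' are roughly a tenth of demand), exponential service with type-specific
#' mean times, `n_bsu` movable basic units and `n_asu` dedicated advanced
#' units pinned to random base atoms. Total offered load is kept below fleet
#' capacity (system utilization about 0.5, always < 0.9).
#'
#' @param A number of atoms (`>= 2`).
#' @param n_bsu number of basic units (`>= 1`).
#' @param n_asu number of dedicated advanced units (`>= 0`).
#' @param seed integer seed; the result is reproducible per seed.
#' @return An `ems_system`.
#' @export
generate_synthetic_system <- function(A, n_bsu, n_asu = 0L, seed = 1L) {
  if (A < 2L) stop2("A must be >= 2")
  if (n_bsu < 1L) stop2("n_bsu must be >= 1")
  if (n_asu < 0L) stop2("n_asu must be >= 0")
  with_seed(seed, {
    travel <- matrix(stats::runif(A * A, 6, 18), A, A)
    diag(travel) <- stats::runif(A, 6, 14)
    service_time <- c(BSU = stats::runif(1, 30, 48))
    if (n_asu > 0)
      service_time["ASU"] <- service_time[["BSU"]] * stats::runif(1, 1.1, 1.4)
    # target ~50% utilization of the whole fleet
    lambda_tot <- 0.5 * (n_bsu + n_asu) / mean(service_time)
    wt <- stats::runif(A, 0.2, 1)
    serious_share <- stats::runif(A, 0.05, 0.15)
    per_atom <- lambda_tot * wt / sum(wt)
    arrival <- cbind(serious = per_atom * serious_share,
                     regular = per_atom * (1 - serious_share))
    fleets <- list(fleet("BSU", n_bsu))
    if (n_asu > 0) {
      fixed <- tabulate(sample.int(A, n_asu, replace = TRUE), nbins = A)
      fleets <- c(fleets, list(fleet("ASU", n_asu, TRUE, fixed)))
    }
    ems_system(paste0("atom", seq_len(A)), arrival, travel, fleets, service_time)
  })
}
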