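# Permeation event counting, conductance / I-V estimation, state
# populations with bootstrap confidence intervals, and composition
# sanity checks.

#' Detect complete permeation events from per-ion site series
#'
#' Uses a two-gate state machine: an outward (+z) event is recorded when
#' an ion that last touched the bath below the cavity reaches the bath
#' above S0 without returning below in between; inward events are the
#' mirror image. The two gates (SCav lower bound and S0 upper bound) give
#' hysteresis, so boundary flicker at a single plane can never double
#' count. Each full traversal yields exactly one event, stamped with the
#' time of first arrival in the destination bath.
#'
#' @param st A `state_trajectory` whose `ion_sites` matrix tracks ion site
#'   indices (1-6 = S0-SCav, 0 = bath above, 7 = bath below).
#' @return Data frame of class `perm_events` with columns `ion_id`,
#'   `time_ns` and `direction` (+1 outward, -1 inward); zero rows if
#'   nothing permeates.
#' @export
detect_permeation_events <- function(st) {
  stopifnot(inherits(st, "state_trajectory"))
  out <- list()
  if (!is.null(st$ion_sites) && ncol(st$ion_sites) > 0) {
    for (ion in colnames(st$ion_sites)) {
      s <- st$ion_sites[, ion]
      keep <- !is.na(s) & (s == BATH_ABOVE | s == BATH_BELOW)
      if (!any(keep)) next
      bath <- s[keep]
      t_bath <- st$times[keep]
      chg <- c(TRUE, diff(bath) != 0)
      bath <- bath[chg]
      t_bath <- t_bath[chg]
      if (length(bath) < 2) next
      dir <- ifelse(bath[-1] == BATH_ABOVE, +1L, -1L)
      out[[ion]] <- data.frame(ion_id = ion, time_ns = t_bath[-1],
                               direction = dir, stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(ion_id = character(), time_ns = numeric(), direction = integer(),
               stringsAsFactors = FALSE)
  ev <- ev[order(ev$time_ns), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("perm_events", "data.frame")
  ev
}

#' Net signed permeation event count
#'
#' @param events A `perm_events` data frame.
#' @return Outward minus inward event count (integer).
#' @export
net_event_count <- function(events) {
  if (nrow(events) == 0) return(0L)
  as.integer(sum(events$direction))
}

#' Convert a permeation event count to current and conductance
#'
#' Each permeating ion carries one full elementary charge regardless of
#' any scaled partial charge (charge scaling is a mean-field treatment of
#' electronic polarization; the transported physical charge is still e).
#' Current is `n_events * e / duration`; conductance is current divided by
#' voltage, so net outward events at positive voltage give positive
#' conductance.
#'
#' @param n_events Net signed event count (outward minus inward).
#' @param duration_ns Total sampled time in ns (sum over replicas).
#' @param voltage_mV Applied voltage in mV; may be 0 only if conductance
#'   is not requested.
#' @return List with `current_pA` and (if `voltage_mV != 0`)
#'   `conductance_pS`.
#' @export
#' @examples
#' conductance_from_events(515, 10 * 500, 150)  # 16.50 pA, 110.0 pS
conductance_from_events <- function(n_events, duration_ns, voltage_mV) {
  stopifnot(is.numeric(n_events), is.numeric(duration_ns), is.numeric(voltage_mV))
  if (duration_ns <= 0) stop("duration must be positive")
  current_pA <- n_events * .ecc_const$e_C / (duration_ns * 1e-9) * 1e12
  if (voltage_mV == 0) {
    return(list(current_pA = current_pA, conductance_pS = NULL))
  }
  # pS = pA / V; voltage given in mV
  list(current_pA = current_pA,
       conductance_pS = current_pA / (voltage_mV / 1000))
}

#' Aggregate per-replica conductances into a mean with SEM
#'
#' @param per_replica_pS Numeric vector of per-replica conductances (pS).
#' @param voltage_mV Voltage the replicas were run at.
#' @return Object of class `conductance_estimate`: list with `mean`,
#'   `sem` (sd/sqrt(N); 0 for a single replica), `n_replicas`, `voltage`.
#' @export
aggregate_replicas <- function(per_replica_pS, voltage_mV) {
  stopifnot(is.numeric(per_replica_pS), length(per_replica_pS) >= 1)
  n <- length(per_replica_pS)
  sem <- if (n > 1) stats::sd(per_replica_pS) / sqrt(n) else 0
  structure(
    list(mean = mean(per_replica_pS), sem = sem, n_replicas = n,
         voltage = voltage_mV),
    class = "conductance_estimate"
  )
}

#' @export
print.conductance_estimate <- function(x, ...) {
  cat(sprintf("Conductance: %.1f +- %.1f pS (SEM, N = %d) at %+g mV\n",
              x$mean, x$sem, x$n_replicas, x$voltage))
  invisible(x)
}

#' Current-voltage curve from per-voltage replica event counts
#'
#' @param events_by_voltage Named list: voltage (mV, as name or via
#'   `voltages`) -> integer vector of net event counts per replica.
#' @param replica_duration_ns Duration of each replica in ns.
#' @param voltages Optional numeric voltages overriding the list names.
#' @return Data frame with `voltage_mV`, `current_pA`, `current_sem_pA`,
#'   `conductance_pS` (NA at 0 mV).
#' @export
iv_curve <- function(events_by_voltage, replica_duration_ns, voltages = NULL) {
  if (is.null(voltages)) voltages <- as.numeric(names(events_by_voltage))
  stopifnot(length(voltages) == length(events_by_voltage))
  rows <- lapply(seq_along(voltages), function(i) {
    ev <- events_by_voltage[[i]]
    cur <- vapply(ev, function(n)
      conductance_from_events(n, replica_duration_ns, 0)$current_pA, 0)
    data.frame(
      voltage_mV = voltages[i], current_pA = mean(cur),
      current_sem_pA = if (length(cur) > 1) stats::sd(cur) / sqrt(length(cur)) else 0,
      conductance_pS = if (voltages[i] != 0) mean(cur) / (voltages[i] / 1000) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$voltage_mV), ]
}

#' Occupancy-state populations with bootstrap confidence intervals
#'
#' Population fractions of each occupancy code, with 95% percentile
#' bootstrap confidence intervals from resampling frames. A block length
#' > 1 resamples contiguous frame blocks (moving-block bootstrap) to
#' respect autocorrelation.
#'
#' @param st A `state_trajectory` (or anything with a `codes` element).
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed RNG seed for the bootstrap.
#' @param block_length Frames per bootstrap block (default 1 =
#'   frame-level resampling).
#' @param conf Confidence level (default 0.95).
#' @return Data frame with `code`, `fraction`, `ci_lo`, `ci_hi`, sorted by
#'   decreasing fraction; fractions sum to 1.
#' @export
state_populations <- function(st, n_boot = 1000, seed = NULL,
                              block_length = 1, conf = 0.95) {
  codes <- if (inherits(st, "state_trajectory")) st$codes else as.character(st)
  n <- length(codes)
  stopifnot(n >= 1, n_boot >= 100, block_length >= 1)
  if (!is.null(seed)) set.seed(seed)
  lev <- sort(unique(codes))
  frac <- as.numeric(table(factor(codes, levels = lev))) / n
  idx_codes <- match(codes, lev)

  n_blocks <- ceiling(n / block_length)
  boot <- matrix(0, nrow = n_boot, ncol = length(lev))
  starts_pool <- seq_len(max(n - block_length + 1, 1))
  for (b in seq_len(n_boot)) {
    starts <- sample(starts_pool, n_blocks, replace = TRUE)
    take <- as.vector(outer(0:(block_length - 1), starts, "+"))
    take <- take[take <= n][seq_len(n)]
    boot[b, ] <- tabulate(idx_codes[take], nbins = length(lev)) / n
  }
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  out <- data.frame(code = lev, fraction = frac,
                    ci_lo = ci[1, ], ci_hi = ci[2, ],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fraction), ]
  rownames(out) <- NULL
  out
}

#' Salt concentration implied by ion and water counts
#'
#' A simulation box with `n_cations` cations per `n_waters` waters has a
#' salt concentration of `(n_cations / n_waters) * 55.5` mol/L (55.5
#' mol/L being the molarity of pure water).
#'
#' @param n_cations Number of cations.
#' @param n_waters Number of water molecules (> 0).
#' @return Concentration in mol/L.
#' @export
#' @examples
#' salt_concentration(160, 11134)  # ~0.8
salt_concentration <- function(n_cations, n_waters) {
  stopifnot(is.numeric(n_cations), is.numeric(n_waters))
  if (any(n_waters <= 0)) stop("water count must be positive")
  (n_cations / n_waters) * .ecc_const$water_molarity
}

#' Write a permeation-events CSV
#'
#' @param events A `perm_events` data frame.
#' @param path Output path.
#' @param header Optional header comment lines.
#' @return Invisibly, the path.
#' @export
write_events_csv <- function(events, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# eccperm permeation events v1", paste0("# ", header)), con)
  utils::write.csv(as.data.frame(events), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
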