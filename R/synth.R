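# Synthetic trajectory generators with known ground truth: a state-level
# continuous-time Markov chain over occupancy codes, and a coordinate-
# level single-file ion-hopping channel emulating direct knock-on
# permeation. Every analysis stage of the package can be validated
# against these generators without any MD output.

#' Specify a continuous-time Markov chain over occupancy states
#'
#' @param states Character state labels (typically 6-letter occupancy
#'   codes, but any labels work for state-level analyses).
#' @param rate_matrix Square generator matrix in 1/ns: off-diagonal
#'   entries are jump rates, rows must sum to zero (the diagonal is
#'   overwritten with minus the off-diagonal row sums).
#' @param stride Observation stride in ns.
#' @param duration Total simulated time in ns (> stride).
#' @param seed RNG seed.
#' @return Object of class `ctmc_spec`.
#' @export
ctmc_spec <- function(states, rate_matrix, stride, duration, seed = 1L) {
  rate_matrix <- as.matrix(rate_matrix)
  stopifnot(length(states) == nrow(rate_matrix),
            nrow(rate_matrix) == ncol(rate_matrix),
            stride > 0, duration > stride)
  off <- rate_matrix
  diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be non-negative")
  diag(rate_matrix) <- -rowSums(off)
  dimnames(rate_matrix) <- list(states, states)
  structure(list(states = states, rate_matrix = rate_matrix, stride = stride,
                 duration = duration, seed = as.integer(seed)),
            class = "ctmc_spec")
}

#' Stationary distribution of a CTMC generator matrix
#'
#' Solves pi Q = 0 with sum(pi) = 1; the analytic ground truth for
#' population-recovery tests.
#'
#' @param rate_matrix Generator matrix (diagonal = minus row sums).
#' @return Named stationary probability vector.
#' @export
ctmc_stationary <- function(rate_matrix) {
  Q <- as.matrix(rate_matrix)
  off <- Q
  diag(off) <- 0
  diag(Q) <- -rowSums(off)
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  pi_hat <- stats::setNames(as.numeric(qr.solve(A, c(rep(0, n), 1))),
                            rownames(Q))
  pi_hat / sum(pi_hat)
}

#' Simulate a CTMC and observe it at a uniform stride
#'
#' Exact stochastic simulation: exponential waiting times with the
#' state's total exit rate, categorical jump choice proportional to the
#' off-diagonal rates. The continuous-time jump log is retained as ground
#' truth alongside the stride-sampled `state_trajectory`. An absorbing
#' state simply holds for the rest of the run.
#'
#' @param spec A `ctmc_spec`.
#' @return List with `trajectory` (a `state_trajectory`) and `jumps`
#'   (data frame `time_ns`, `from`, `to`).
#' @export
simulate_ctmc <- function(spec) {
  stopifnot(inherits(spec, "ctmc_spec"))
  set.seed(spec$seed)
  Q <- spec$rate_matrix
  S <- length(spec$states)
  state <- 1L
  t_now <- 0
  jump_t <- numeric(0); jump_from <- integer(0); jump_to <- integer(0)
  obs_times <- seq(0, spec$duration, by = spec$stride)
  obs_state <- integer(length(obs_times))
  obs_i <- 1L
  while (t_now <= spec$duration) {
    k_out <- -Q[state, state]
    t_next <- if (k_out > 0) t_now + stats::rexp(1, k_out) else Inf
    while (obs_i <= length(obs_times) && obs_times[obs_i] < t_next) {
      obs_state[obs_i] <- state
      obs_i <- obs_i + 1L
    }
    if (obs_i > length(obs_times) || !is.finite(t_next)) break
    rates <- Q[state, ]
    rates[state] <- 0
    nxt <- sample.int(S, 1, prob = rates)
    jump_t <- c(jump_t, t_next); jump_from <- c(jump_from, state)
    jump_to <- c(jump_to, nxt)
    state <- nxt
    t_now <- t_next
  }
  if (obs_i <= length(obs_times)) obs_state[obs_i:length(obs_times)] <- state
  list(
    trajectory = state_trajectory(obs_times, spec$states[obs_state]),
    jumps = data.frame(time_ns = jump_t, from = spec$states[jump_from],
                       to = spec$states[jump_to], stringsAsFactors = FALSE)
  )
}

#' Specify a coordinate-level synthetic channel simulation
#'
#' Ions perform single-file, voltage-biased hops between the six
#' binding-site centers of a [build_site_geometry()] geometry and the two
#' baths, under the exclusion rule of at most one ion per site (direct
#' knock-on: no co-permeating water between ions). `hop_rate_fwd` /
#' `hop_rate_rev` is the outward/inward hop-rate ratio that emulates the
#' applied voltage. Ion-free sites are filled with a water oxygen with
#' probability `p_water` per frame. Emitted coordinates place each
#' particle at its site center plus sub-boundary jitter (a fixed fraction
#' of the smallest site half-width), so site assignment is always
#' unambiguous and discretization reproduces the generator's state
#' sequence exactly.
#'
#' @param geometry A `site_geometry`.
#' @param n_ions Total ion roster (circulating plus staged in the lower
#'   bath); at least 1.
#' @param hop_rate_fwd,hop_rate_rev Outward (+z) and inward hop rates in
#'   1/ns.
#' @param entry_rate_below,entry_rate_above Entry rates (1/ns) from the
#'   lower bath into SCav and the upper bath into S0.
#' @param p_water Probability an ion-free site shows a water oxygen in a
#'   frame.
#' @param duration,stride Simulated time and observation stride in ns.
#' @param jitter_frac Jitter amplitude as a fraction of the smallest site
#'   half-width (kept < 0.5 so assignment is unambiguous).
#' @param seed RNG seed.
#' @param init_sites Site indices (1-6) initially holding an ion.
#' @param init_bath Bath ("below" or "above") where the remaining roster
#'   ions are staged; stage them above to drive inward permeation.
#' @return Object of class `channel_sim_spec`.
#' @export
channel_sim_spec <- function(geometry, n_ions = 16,
                             hop_rate_fwd = 2, hop_rate_rev = 0.2,
                             entry_rate_below = 2, entry_rate_above = 0.2,
                             p_water = 0.9, duration = 100, stride = 0.1,
                             jitter_frac = 0.25, seed = 1L,
                             init_sites = c(2L, 3L, 4L, 6L),
                             init_bath = c("below", "above")) {
  init_bath <- match.arg(init_bath)
  stopifnot(inherits(geometry, "site_geometry"), n_ions >= 1,
            hop_rate_fwd >= 0, hop_rate_rev >= 0,
            entry_rate_below >= 0, entry_rate_above >= 0,
            p_water >= 0, p_water <= 1, duration > stride, stride > 0,
            jitter_frac >= 0, jitter_frac < 0.5,
            all(init_sites %in% 1:6), !anyDuplicated(init_sites),
            length(init_sites) <= n_ions)
  structure(list(geometry = geometry, n_ions = as.integer(n_ions),
                 hop_rate_fwd = hop_rate_fwd, hop_rate_rev = hop_rate_rev,
                 entry_rate_below = entry_rate_below,
                 entry_rate_above = entry_rate_above, p_water = p_water,
                 duration = duration, stride = stride,
                 jitter_frac = jitter_frac, seed = as.integer(seed),
                 init_sites = as.integer(init_sites), init_bath = init_bath),
            class = "channel_sim_spec")
}

# site centers in z, indexed 1..6 (S0..SCav); bath rest positions sit
# outside the stacked sites
.site_centers_z <- function(geometry) {
  rowMeans(geometry$bounds)
}

#' Simulate the coordinate-level synthetic channel
#'
#' Event-driven (exponential waiting time) simulation of the hop dynamics
#' in [channel_sim_spec()], observed at a uniform stride. Ions that exit
#' to a bath rest there (and may re-enter at the bath's entry rate);
#' permeation ground truth is recorded whenever an ion reaches the bath
#' opposite to the last bath it touched, i.e. with exactly the two-gate
#' convention used by [detect_permeation_events()].
#'
#' @param spec A `channel_sim_spec`.
#' @return List with `frames` (coordinate frames consumable by
#'   [discretize_trajectory()]), `truth_codes` (character, per frame),
#'   `truth_events` (events at observation resolution: `ion_id`,
#'   `time_ns`, `direction`), `event_log` (every bath-to-bath crossing at
#'   continuous jump resolution), `truth_sites` (frames x ions site-index
#'   matrix) and `geometry`.
#' @export
simulate_channel <- function(spec) {
  stopifnot(inherits(spec, "channel_sim_spec"))
  set.seed(spec$seed)
  geom <- spec$geometry
  centers <- .site_centers_z(geom)
  half_w <- min(geom$bounds[, 2] - geom$bounds[, 1]) / 2
  jit <- spec$jitter_frac * half_w
  z_above <- geom$bounds["S0", "upper"] + 3 * half_w
  z_below <- geom$bounds["SCav", "lower"] - 3 * half_w
  lat_jit <- min(jit, geom$axis_radius * 0.5)

  n_ions <- spec$n_ions
  ion_ids <- sprintf("ion%02d", seq_len(n_ions))
  # site occupant (0 = empty) and per-ion location (1..6 site, 0 above, 7 below)
  site_occ <- integer(6)
  rest_bath <- if (identical(spec$init_bath, "above")) BATH_ABOVE else BATH_BELOW
  loc <- rep(rest_bath, n_ions)
  loc[seq_along(spec$init_sites)] <- spec$init_sites
  site_occ[spec$init_sites] <- seq_along(spec$init_sites)
  last_bath <- rep(rest_bath, n_ions)

  obs_times <- seq(0, spec$duration, by = spec$stride)
  n_frames <- length(obs_times)
  truth_sites <- matrix(NA_integer_, n_frames, n_ions,
                        dimnames = list(NULL, ion_ids))
  ev_ion <- character(0); ev_t <- numeric(0); ev_dir <- integer(0)

  # enabled moves: (kind, ion, from, to, rate); recomputed after each event
  moves <- function() {
    m <- list()
    for (i in seq_len(n_ions)) {
      l <- loc[i]
      if (l >= 1 && l <= 6) {
        # outward = toward S0 = decreasing site index; site 1 exits above
        dest_out <- l - 1L
        if (spec$hop_rate_fwd > 0 &&
            (dest_out == 0L || site_occ[dest_out] == 0L)) {
          m[[length(m) + 1L]] <- c(i, l, if (dest_out == 0L) BATH_ABOVE else dest_out,
                                   spec$hop_rate_fwd)
        }
        dest_in <- l + 1L
        if (spec$hop_rate_rev > 0 &&
            (dest_in == 7L || site_occ[dest_in] == 0L)) {
          m[[length(m) + 1L]] <- c(i, l, if (dest_in == 7L) BATH_BELOW else dest_in,
                                   spec$hop_rate_rev)
        }
      }
    }
    # entry is a property of the bath (one candidate ion per bath), so the
    # total entry rate does not grow with the number of staged ions
    below_ions <- which(loc == BATH_BELOW)
    if (length(below_ions) > 0 && spec$entry_rate_below > 0 && site_occ[6] == 0L) {
      m[[length(m) + 1L]] <- c(below_ions[1], BATH_BELOW, 6L, spec$entry_rate_below)
    }
    above_ions <- which(loc == BATH_ABOVE)
    if (length(above_ions) > 0 && spec$entry_rate_above > 0 && site_occ[1] == 0L) {
      m[[length(m) + 1L]] <- c(above_ions[1], BATH_ABOVE, 1L, spec$entry_rate_above)
    }
    if (length(m) == 0) NULL else do.call(rbind, m)
  }

  t_now <- 0
  obs_i <- 1L
  snapshot <- function() loc
  repeat {
    mv <- moves()
    total <- if (is.null(mv)) 0 else sum(mv[, 4])
    t_next <- if (total > 0) t_now + stats::rexp(1, total) else Inf
    while (obs_i <= n_frames && obs_times[obs_i] < t_next) {
      truth_sites[obs_i, ] <- snapshot()
      obs_i <- obs_i + 1L
    }
    if (obs_i > n_frames || !is.finite(t_next)) break
    k <- if (nrow(mv) == 1) 1L else sample.int(nrow(mv), 1, prob = mv[, 4])
    i <- mv[k, 1]; from <- mv[k, 2]; to <- mv[k, 3]
    if (from >= 1 && from <= 6) site_occ[from] <- 0L
    if (to >= 1 && to <= 6) site_occ[to] <- i
    loc[i] <- as.integer(to)
    if (to == BATH_ABOVE || to == BATH_BELOW) {
      if (to != last_bath[i]) {
        ev_ion <- c(ev_ion, ion_ids[i]); ev_t <- c(ev_t, t_next)
        ev_dir <- c(ev_dir, if (to == BATH_ABOVE) +1L else -1L)
      }
      last_bath[i] <- as.integer(to)
    }
    t_now <- t_next
  }
  if (obs_i <= n_frames) {
    for (j in obs_i:n_frames) truth_sites[j, ] <- snapshot()
  }

  # water fill decisions per frame, frozen into both coordinates and codes
  codes <- character(n_frames)
  frames <- vector("list", n_frames)
  box <- c(4, 4, (z_above - z_below) + 6 * half_w)
  axis <- geom$axis_xy
  z_of_loc <- c(z_above, centers, z_below)  # index by loc + 1
  for (f in seq_len(n_frames)) {
    locs <- truth_sites[f, ]
    ion_xyz <- cbind(
      axis[1] + stats::runif(n_ions, -lat_jit, lat_jit),
      axis[2] + stats::runif(n_ions, -lat_jit, lat_jit),
      z_of_loc[locs + 1L] + stats::runif(n_ions, -jit, jit))
    rownames(ion_xyz) <- ion_ids
    occupied <- locs[locs >= 1 & locs <= 6]
    free_sites <- setdiff(1:6, occupied)
    wet <- free_sites[stats::runif(length(free_sites)) < spec$p_water]
    water_xyz <- NULL
    if (length(wet) > 0) {
      water_xyz <- cbind(
        axis[1] + stats::runif(length(wet), -lat_jit, lat_jit),
        axis[2] + stats::runif(length(wet), -lat_jit, lat_jit),
        centers[wet] + stats::runif(length(wet), -jit, jit))
    }
    lets <- rep("0", 6)
    lets[occupied] <- "K"
    lets[wet] <- "W"
    codes[f] <- paste(lets, collapse = "")
    frames[[f]] <- list(
      time = obs_times[f], ion_positions = ion_xyz,
      water_o_positions = water_xyz, sf_oxygen_z = geom$plane_z, box = box)
  }
  # event log at jump resolution (continuous time) ...
  event_log <- data.frame(ion_id = ev_ion, time_ns = ev_t,
                          direction = ev_dir, stringsAsFactors = FALSE)
  # ... and ground-truth events at observation resolution: same two-gate
  # convention applied to the sampled site series, so a bath excursion
  # too brief to be observed at this stride is (consistently) absent
  # from both the truth and anything recoverable from the frames.
  tev <- list()
  for (i in seq_len(n_ions)) {
    s <- truth_sites[, i]
    keep <- s == BATH_ABOVE | s == BATH_BELOW
    bath <- s[keep]; tb <- obs_times[keep]
    chg <- c(TRUE, diff(bath) != 0)
    bath <- bath[chg]; tb <- tb[chg]
    if (length(bath) >= 2) {
      tev[[length(tev) + 1L]] <- data.frame(
        ion_id = ion_ids[i], time_ns = tb[-1],
        direction = ifelse(bath[-1] == BATH_ABOVE, +1L, -1L),
        stringsAsFactors = FALSE)
    }
  }
  truth_events <- if (length(tev) > 0) do.call(rbind, tev) else
    data.frame(ion_id = character(), time_ns = numeric(),
               direction = integer(), stringsAsFactors = FALSE)
  truth_events <- truth_events[order(truth_events$time_ns), , drop = FALSE]
  rownames(truth_events) <- NULL
  list(frames = frames, truth_codes = codes, truth_events = truth_events,
       event_log = event_log, truth_sites = truth_sites, geometry = geom)
}
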