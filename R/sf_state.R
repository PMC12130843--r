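# Selectivity-filter binding-site geometry and discretization of
# trajectories into 6-letter occupancy codes over sites S0-SCav.

SITE_NAMES <- c("S0", "S1", "S2", "S3", "S4", "SCav")
BATH_ABOVE <- 0L   # extracellular side, +z
BATH_BELOW <- 7L   # cavity/intracellular side, -z

#' Build the selectivity-filter binding-site geometry
#'
#' The filter is modeled as a cylinder around the pore axis sliced into
#' six stacked sites: the five oxygen-layer planes (top carbonyl plane
#' down to the threonine hydroxyl plane) bound sites S1-S4 between
#' successive planes, S0 extends `s0_cap` above the top plane and SCav
#' `scav_depth` below the bottom plane. z increases toward the
#' extracellular side, so "outward" permeation is +z.
#'
#' @param sf_oxygen_z_layers Five oxygen-layer mean z values (nm); any
#'   order, but must be strictly distinct.
#' @param s0_cap Height of S0 above the top plane (nm).
#' @param scav_depth Depth of SCav below the bottom plane (nm).
#' @param axis_radius Lateral cutoff from the pore axis (nm).
#' @param axis_xy Pore-axis (x, y) position (nm).
#' @return An object of class `site_geometry` with a 6 x 2 matrix
#'   `bounds` (rows S0..SCav, columns `lower`/`upper` z, intervals
#'   half-open: lower-inclusive, upper-exclusive).
#' @export
#' @examples
#' geom <- build_site_geometry(c(1.0, 1.3, 1.6, 1.9, 2.2))
#' geom$bounds["S2", ]  # [1.6, 1.9]
build_site_geometry <- function(sf_oxygen_z_layers, s0_cap = 0.4,
                                scav_depth = 0.4, axis_radius = 0.25,
                                axis_xy = c(0, 0)) {
  z <- sort(as.numeric(sf_oxygen_z_layers))
  if (length(z) != 5 || any(!is.finite(z))) {
    stop("need 5 finite oxygen-layer z values")
  }
  if (any(diff(z) <= 0)) {
    stop("oxygen-layer planes must be strictly ordered after sorting; ",
         "got z = ", paste(signif(z, 6), collapse = ", "),
         " (degenerate layers suggest a broken filter or misselection)")
  }
  stopifnot(s0_cap > 0, scav_depth > 0, axis_radius > 0, length(axis_xy) == 2)
  bounds <- rbind(
    S0 = c(z[5], z[5] + s0_cap),
    S1 = c(z[4], z[5]),
    S2 = c(z[3], z[4]),
    S3 = c(z[2], z[3]),
    S4 = c(z[1], z[2]),
    SCav = c(z[1] - scav_depth, z[1])
  )
  colnames(bounds) <- c("lower", "upper")
  structure(
    list(plane_z = z, bounds = bounds, s0_cap = s0_cap,
         scav_depth = scav_depth, axis_radius = axis_radius,
         axis_xy = as.numeric(axis_xy)),
    class = "site_geometry"
  )
}

#' @export
print.site_geometry <- function(x, ...) {
  cat("Selectivity-filter site geometry (z in nm, half-open [lower, upper)):\n")
  for (s in SITE_NAMES) {
    cat(sprintf("  %-4s [%7.3f, %7.3f)\n", s, x$bounds[s, 1], x$bounds[s, 2]))
  }
  cat(sprintf("  axis (%.3f, %.3f), radius %.3f nm\n",
              x$axis_xy[1], x$axis_xy[2], x$axis_radius))
  invisible(x)
}

# Site index for each row of an n x 3 coordinate matrix:
# 1..6 = S0..SCav, 0 = bath above, 7 = bath below. A particle belongs to
# a site iff its z is in the half-open interval and it lies within
# axis_radius of the pore axis; everything else is bath, split by z
# relative to the geometry midpoint.
.site_index <- function(xyz, geometry) {
  if (length(xyz) == 0 || nrow(xyz) == 0) return(integer(0))
  b <- geometry$bounds
  z <- xyz[, 3]
  lat2 <- (xyz[, 1] - geometry$axis_xy[1])^2 + (xyz[, 2] - geometry$axis_xy[2])^2
  inside_r <- lat2 <= geometry$axis_radius^2
  idx <- ifelse(z >= (b["S0", "upper"] + b["SCav", "lower"]) / 2,
                BATH_ABOVE, BATH_BELOW)
  for (s in seq_len(6)) {
    hit <- inside_r & z >= b[s, 1] & z < b[s, 2]
    idx[hit] <- s
  }
  # bath side overrides for in-radius particles beyond the stack
  idx[z >= b["S0", "upper"]] <- BATH_ABOVE
  idx[z < b["SCav", "lower"]] <- BATH_BELOW
  as.integer(idx)
}

#' Assign the 6-letter occupancy code of one frame
#'
#' Each site S0-SCav receives the letter `K` if at least one ion lies in
#' it, else `W` if at least one water oxygen does, else `0`. A particle
#' is in a site iff its z falls in the site's half-open interval and its
#' lateral distance to the pore axis is at most `axis_radius`; everything
#' else is bath. When a site holds both an ion and a water the ion wins
#' (occupancy codes never show joint occupancy); multiple ions in a site
#' still yield a single `K` with a warning.
#'
#' @param frame A list with `ion_positions` (named n x 3 matrix or NULL)
#'   and `water_o_positions` (m x 3 matrix or NULL), coordinates in nm.
#' @param geometry A `site_geometry`.
#' @return List with `code` (6-character string over K/W/0, positions
#'   S0..SCav) and `ion_sites` (named integer vector: 1-6 for S0-SCav, 0
#'   bath above, 7 bath below).
#' @export
assign_frame_occupancy <- function(frame, geometry) {
  stopifnot(inherits(geometry, "site_geometry"))
  ions <- frame$ion_positions
  waters <- frame$water_o_positions
  ion_sites <- if (is.null(ions)) integer(0) else .site_index(ions, geometry)
  if (!is.null(ions) && !is.null(rownames(ions))) names(ion_sites) <- rownames(ions)
  water_sites <- if (is.null(waters)) integer(0) else .site_index(waters, geometry)

  letters_out <- rep("0", 6)
  in_site <- ion_sites[ion_sites >= 1 & ion_sites <= 6]
  if (anyDuplicated(in_site)) {
    warning("multiple ions share a site; code shows a single K (counts kept in ion_sites)")
  }
  letters_out[unique(in_site)] <- "K"
  w_in <- unique(water_sites[water_sites >= 1 & water_sites <= 6])
  letters_out[setdiff(w_in, in_site)] <- "W"
  list(code = paste(letters_out, collapse = ""), ion_sites = ion_sites)
}

#' Discretize a trajectory into an occupancy-code time series
#'
#' Applies [assign_frame_occupancy()] to every frame. With
#' `geometry_mode = "per-frame"` the site geometry is rebuilt each frame
#' from that frame's filter-oxygen layer means (`sf_oxygen_z` element), so
#' the sites track filter breathing; with `"static"` the supplied
#' geometry is used throughout.
#'
#' @param frames List of frames; each frame is a list with `time` (ns),
#'   `ion_positions`, `water_o_positions` and (for per-frame mode)
#'   `sf_oxygen_z` (5 layer means). Times must be strictly increasing with
#'   uniform stride.
#' @param geometry A `site_geometry` (required for `"static"` mode; used
#'   for cap/radius settings in `"per-frame"` mode).
#' @param geometry_mode `"static"` or `"per-frame"`.
#' @return An object of class `state_trajectory`: list with `times` (ns),
#'   `codes` (character), `ion_sites` (frames x ions integer matrix,
#'   columns named by ion id) and `stride` (ns).
#' @export
discretize_trajectory <- function(frames, geometry,
                                  geometry_mode = c("static", "per-frame")) {
  geometry_mode <- match.arg(geometry_mode)
  if (length(frames) < 2) stop("need at least 2 frames")
  times <- vapply(frames, function(f) as.numeric(f$time), 0)
  strides <- diff(times)
  if (any(strides <= 0) ||
      any(abs(strides - strides[1]) > 1e-6 * max(strides[1], 1e-12))) {
    stop("non-uniform frame stride; measured strides (ns): ",
         paste(signif(unique(round(strides, 9)), 6), collapse = ", "))
  }
  ion_ids <- unique(unlist(lapply(frames, function(f) rownames(f$ion_positions))))
  if (is.null(ion_ids)) ion_ids <- character(0)
  codes <- character(length(frames))
  ion_sites <- matrix(NA_integer_, nrow = length(frames), ncol = length(ion_ids),
                      dimnames = list(NULL, ion_ids))
  for (i in seq_along(frames)) {
    g <- if (geometry_mode == "per-frame") {
      build_site_geometry(frames[[i]]$sf_oxygen_z, s0_cap = geometry$s0_cap,
                          scav_depth = geometry$scav_depth,
                          axis_radius = geometry$axis_radius,
                          axis_xy = geometry$axis_xy)
    } else {
      geometry
    }
    occ <- assign_frame_occupancy(frames[[i]], g)
    codes[i] <- occ$code
    if (length(occ$ion_sites) > 0) {
      ion_sites[i, names(occ$ion_sites)] <- occ$ion_sites
    }
  }
  state_trajectory(times, codes, ion_sites)
}

#' Construct a state trajectory
#'
#' Low-level constructor for the occupancy-code time series consumed by
#' the permeation and mechanism-graph analyses.
#'
#' @param times Strictly increasing, uniformly strided times in ns.
#' @param codes Character vector of 6-letter occupancy codes (or arbitrary
#'   state labels for state-level analyses).
#' @param ion_sites Optional frames x ions integer matrix of site indices
#'   (1-6 = S0-SCav, 0 = bath above, 7 = bath below).
#' @return An object of class `state_trajectory`.
#' @export
state_trajectory <- function(times, codes, ion_sites = NULL) {
  times <- as.numeric(times)
  stopifnot(length(times) == length(codes))
  if (length(times) >= 2) {
    strides <- diff(times)
    if (any(strides <= 0) ||
        any(abs(strides - strides[1]) > 1e-6 * max(strides[1], 1e-12))) {
      stop("times must be strictly increasing with uniform stride")
    }
  }
  if (!is.null(ion_sites)) {
    ion_sites <- as.matrix(ion_sites)
    stopifnot(nrow(ion_sites) == length(times))
  }
  structure(
    list(times = times, codes = as.character(codes), ion_sites = ion_sites,
         stride = if (length(times) >= 2) times[2] - times[1] else NA_real_),
    class = "state_trajectory"
  )
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("State trajectory: %d frames, stride %.6g ns, %d distinct states",
              length(x$times), x$stride, length(unique(x$codes))))
  if (!is.null(x$ion_sites)) cat(sprintf(", %d tracked ions", ncol(x$ion_sites)))
  cat("\n")
  tab <- sort(table(x$codes), decreasing = TRUE)
  top <- utils::head(tab, 5)
  cat("  top states:",
      paste(sprintf("%s (%.1f%%)", names(top), 100 * top / length(x$codes)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write / read the per-frame occupancy-code table
#'
#' The CSV interchange format (`time_ns`, `code`, plus one `ion_<id>`
#' column per tracked ion) consumed by the permeation and mechanism-graph
#' analyses. A `#`-prefixed header line records provenance.
#'
#' @param st A `state_trajectory`.
#' @param path Output CSV path.
#' @param header Optional extra header comment lines.
#' @return `write_code_table`: invisibly, the path. `read_code_table`: a
#'   `state_trajectory`.
#' @export
write_code_table <- function(st, path, header = character()) {
  stopifnot(inherits(st, "state_trajectory"))
  df <- data.frame(time_ns = st$times, code = st$codes,
                   stringsAsFactors = FALSE)
  if (!is.null(st$ion_sites)) {
    extra <- as.data.frame(st$ion_sites)
    names(extra) <- paste0("ion_", colnames(st$ion_sites))
    df <- cbind(df, extra)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# eccperm code table v1"), paste0("# ", header)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_code_table
#' @param path Path of a code-table CSV.
#' @export
read_code_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = c(code = "character"))
  ion_cols <- grep("^ion_", names(df), value = TRUE)
  ion_sites <- NULL
  if (length(ion_cols) > 0) {
    ion_sites <- as.matrix(df[ion_cols])
    colnames(ion_sites) <- sub("^ion_", "", ion_cols)
  }
  state_trajectory(df$time_ns, df$code, ion_sites)
}
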