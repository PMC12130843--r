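# Permeation mechanism graphs: MFPT-derived rates between occupancy
# states, net fluxes, progressive lumping above a rate cutoff, and
# rate-limiting-step identification.

.as_traj_list <- function(trajs) {
  if (inherits(trajs, "state_trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1,
            all(vapply(trajs, inherits, TRUE, "state_trajectory")))
  trajs
}

#' Pairwise transition counts, MFPTs and net fluxes
#'
#' For every ordered state pair (A, B) over one or more discretized
#' trajectories: the number of direct A -> B transitions, the mean first
#' passage time (mean, over entries into A, of the time until the first
#' subsequent visit to B), the rate 1/MFPT, and the net flux
#' count(A->B) - count(B->A). Passages not completed before the end of a
#' trajectory are censored (excluded). Replicas are pooled by averaging
#' passage times over all entries across replicas, never by averaging
#' per-replica rates, and trajectories are never spliced.
#'
#' @param trajs A `state_trajectory` or a list of them (replicas).
#' @return Object of class `transition_stats`: list with `states`,
#'   matrices `counts`, `mfpt` (ns; NA where no passage completed),
#'   `rate` (1/ns), `net_flux`, and `n_frames`.
#' @export
pairwise_transition_stats <- function(trajs) {
  trajs <- .as_traj_list(trajs)
  states <- sort(unique(unlist(lapply(trajs, function(x) x$codes))))
  S <- length(states)
  counts <- matrix(0, S, S, dimnames = list(states, states))
  psum <- matrix(0, S, S, dimnames = list(states, states))
  pn <- matrix(0, S, S, dimnames = list(states, states))

  for (tr in trajs) {
    s <- match(tr$codes, states)
    tt <- tr$times
    n <- length(s)
    if (n >= 2) {
      from <- s[-n]; to <- s[-1]
      keep <- from != to
      if (any(keep)) {
        tab <- table(factor(from[keep], levels = seq_len(S)),
                     factor(to[keep], levels = seq_len(S)))
        counts <- counts + as.matrix(tab)
      }
    }
    # nxt[b, i]: smallest frame j >= i with s[j] == b (Inf if none);
    # one reverse cumulative pass per state
    nxt <- matrix(Inf, S, n)
    for (b in seq_len(S)) {
      v <- ifelse(s == b, seq_len(n), Inf)
      nxt[b, ] <- rev(cummin(rev(v)))
    }
    entries_by_state <- lapply(seq_len(S), function(a)
      which(s == a & c(TRUE, s[-n] != a)))
    for (a in seq_len(S)) {
      entries <- entries_by_state[[a]]
      entries <- entries[entries < n]  # an entry at the last frame is censored
      if (length(entries) == 0) next
      J <- nxt[, entries + 1L, drop = FALSE]        # S x m first-visit frames
      fin <- is.finite(J)
      Tj <- array(NA_real_, dim(J))
      Tj[fin] <- tt[J[fin]]
      D <- sweep(Tj, 2, tt[entries], "-")
      add_p <- rowSums(D, na.rm = TRUE)
      add_n <- rowSums(fin)
      add_p[a] <- 0; add_n[a] <- 0
      psum[a, ] <- psum[a, ] + add_p
      pn[a, ] <- pn[a, ] + add_n
    }
  }
  mfpt <- ifelse(pn > 0, psum / pn, NA_real_)
  dimnames(mfpt) <- list(states, states)
  structure(
    list(states = states, counts = counts, mfpt = mfpt, rate = 1 / mfpt,
         net_flux = counts - t(counts),
         n_frames = sum(vapply(trajs, function(x) length(x$codes), 0L))),
    class = "transition_stats"
  )
}

#' @export
print.transition_stats <- function(x, ...) {
  cat(sprintf("Transition stats over %d states, %d frames\n",
              length(x$states), x$n_frames))
  finite <- is.finite(x$rate)
  if (any(finite)) {
    i <- which(x$rate == max(x$rate[finite]), arr.ind = TRUE)[1, ]
    cat(sprintf("  fastest rate: %s -> %s at %.4g 1/ns\n",
                x$states[i[1]], x$states[i[2]], max(x$rate[finite])))
  }
  invisible(x)
}

# K-ion count of an occupancy code over the given letter positions
# (default all six, S0..SCav).
.ion_class <- function(code, positions = 1:6) {
  if (nchar(code) < max(positions)) return(NA_integer_)
  sum(strsplit(code, "")[[1]][positions] == "K")
}

#' Build a mechanism graph from transition statistics
#'
#' One node per (possibly lumped) state, annotated with its population
#' fraction and ion-count class (number of K letters over S0-SCav, window
#' configurable); one edge per unordered state pair with the forward and
#' backward MFPT-inverse rates and the net flux.
#'
#' @param stats A `transition_stats`.
#' @param populations Named numeric vector (or data frame with `code`,
#'   `fraction` columns as from [state_populations()]) giving each state's
#'   population; propagated to nodes unchanged.
#' @param members Optional named list mapping node label to its original
#'   member codes (used after lumping); defaults to each state being its
#'   own member.
#' @param ion_positions Letter positions counted for the ion class
#'   (default `1:6` = S0..SCav; use `2:5` for the S1-S4 window).
#' @return Object of class `mech_graph`: list with data frames `nodes`
#'   (`state`, `population`, `n_ions`, `members` list-column) and `edges`
#'   (`state_a`, `state_b`, `rate_ab`, `rate_ba`, `count_ab`, `count_ba`,
#'   `net_flux` where positive flux flows a -> b).
#' @export
build_mechanism_graph <- function(stats, populations, members = NULL,
                                  ion_positions = 1:6) {
  stopifnot(inherits(stats, "transition_stats"))
  if (is.data.frame(populations)) {
    populations <- stats::setNames(populations$fraction, populations$code)
  }
  states <- stats$states
  pop <- populations[states]
  pop[is.na(pop)] <- 0
  if (is.null(members)) members <- stats::setNames(as.list(states), states)
  member_codes <- lapply(states, function(s) members[[s]])
  n_ions <- vapply(states, function(s) {
    cls <- unique(vapply(members[[s]], .ion_class, 0L, positions = ion_positions))
    if (length(cls) == 1) cls else NA_integer_
  }, 0L)
  nodes <- data.frame(state = states, population = as.numeric(pop),
                      n_ions = n_ions, stringsAsFactors = FALSE)
  nodes$members <- member_codes

  pairs <- which(upper.tri(stats$counts), arr.ind = TRUE)
  a <- pairs[, 1]; b <- pairs[, 2]
  ab <- cbind(a, b); ba <- cbind(b, a)
  keep <- stats$counts[ab] + stats$counts[ba] > 0 |
    is.finite(stats$rate[ab]) | is.finite(stats$rate[ba])
  ab <- ab[keep, , drop = FALSE]; ba <- ba[keep, , drop = FALSE]
  edges <- data.frame(
    state_a = states[ab[, 1]], state_b = states[ab[, 2]],
    rate_ab = stats$rate[ab], rate_ba = stats$rate[ba],
    count_ab = stats$counts[ab], count_ba = stats$counts[ba],
    net_flux = stats$counts[ab] - stats$counts[ba],
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(
    list(nodes = nodes, edges = edges, lump_cutoff = NA_real_,
         total_flux = NA_real_),
    class = "mech_graph"
  )
}

#' Progressively lump a mechanism graph above a rate cutoff
#'
#' Starting from the raw occupancy codes, the state pair with the fastest
#' MFPT-inverse rate is merged whenever at least one of its forward or
#' backward rates exceeds the cutoff; the trajectory is relabeled and all
#' rates recomputed on the lumped labels, and the procedure repeats until
#' the fastest remaining inter-pair rate is at or below the cutoff.
#' Re-estimation is done on the relabeled discrete trajectory, not by
#' algebraic contraction of the graph. Lumped states are named by joining
#' their member codes with `+` in lexicographic order.
#'
#' @param trajs A `state_trajectory` or list of replicas.
#' @param cutoff Lumping rate cutoff in 1/ns (> 0).
#' @param ion_positions Passed to [build_mechanism_graph()].
#' @return A `mech_graph` on the lumped labels, with `lump_cutoff` set,
#'   node populations equal to lumped frame fractions, and `total_flux`
#'   set to the net permeation event count when ion tracks are available.
#' @export
lump_graph <- function(trajs, cutoff, ion_positions = 1:6) {
  stopifnot(is.numeric(cutoff), cutoff > 0)
  trajs <- .as_traj_list(trajs)
  orig_codes <- sort(unique(unlist(lapply(trajs, function(x) x$codes))))
  label_of <- stats::setNames(orig_codes, orig_codes)

  relabel <- function() {
    lapply(trajs, function(tr) {
      state_trajectory(tr$times, unname(label_of[tr$codes]), tr$ion_sites)
    })
  }
  repeat {
    cur <- relabel()
    stats_now <- pairwise_transition_stats(cur)
    r <- stats_now$rate
    diag(r) <- NA
    if (!any(is.finite(r))) break
    mx <- max(r, na.rm = TRUE)
    if (mx <= cutoff || length(stats_now$states) <= 1) break
    ij <- which(r == mx, arr.ind = TRUE)[1, ]
    a <- stats_now$states[ij[1]]; b <- stats_now$states[ij[2]]
    merged_members <- sort(names(label_of)[label_of %in% c(a, b)])
    new_label <- paste(merged_members, collapse = "+")
    label_of[label_of %in% c(a, b)] <- new_label
  }
  cur <- relabel()
  stats_final <- pairwise_transition_stats(cur)
  all_codes <- unlist(lapply(cur, function(x) x$codes))
  pops <- table(all_codes) / length(all_codes)
  members <- split(names(label_of), unname(label_of))
  g <- build_mechanism_graph(stats_final, stats::setNames(as.numeric(pops), names(pops)),
                             members = members, ion_positions = ion_positions)
  g$lump_cutoff <- cutoff
  if (all(vapply(trajs, function(x) !is.null(x$ion_sites), TRUE))) {
    g$total_flux <- sum(vapply(trajs, function(x)
      net_event_count(detect_permeation_events(x)), 0L))
  }
  g
}

#' Identify the rate-limiting step of a mechanism graph
#'
#' Among unordered node pairs whose absolute net flux is at least
#' `flux_fraction_threshold` times the total permeation flux, returns the
#' one with the smallest forward rate (forward = the direction of the
#' pair's positive net flux). If no pair meets the threshold, the
#' maximal-flux pair is returned with `below_threshold = TRUE` and a
#' warning.
#'
#' @param graph A `mech_graph`.
#' @param total_flux Total net permeation event count over the same
#'   trajectories; defaults to the value stored on the graph by
#'   [lump_graph()].
#' @param flux_fraction_threshold Fraction of the total flux an edge must
#'   carry to qualify (default 0.5).
#' @return List with `from`, `to` (oriented along the net flux),
#'   `rate_fwd` (1/ns), `net_flux`, `flux_fraction` and `below_threshold`.
#' @export
rate_limiting_step <- function(graph, total_flux = NULL,
                               flux_fraction_threshold = 0.5) {
  stopifnot(inherits(graph, "mech_graph"))
  if (is.null(total_flux)) total_flux <- graph$total_flux
  e <- graph$edges
  if (nrow(e) == 0) stop("graph has no edges")
  if (is.na(total_flux) || total_flux <= 0) {
    warning("total permeation flux is zero or unknown; ",
            "returning the maximal-flux edge")
    total_flux <- NA_real_
  }
  aflux <- abs(e$net_flux)
  eligible <- if (is.na(total_flux)) rep(FALSE, nrow(e)) else
    aflux >= flux_fraction_threshold * total_flux
  below <- FALSE
  if (!any(eligible)) {
    if (!is.na(total_flux)) {
      warning("no edge carries >= ", flux_fraction_threshold,
              " of the total flux; returning the maximal-flux edge")
    }
    below <- TRUE
    eligible <- aflux == max(aflux)
  }
  cand <- e[eligible, , drop = FALSE]
  fwd_rate <- ifelse(cand$net_flux >= 0, cand$rate_ab, cand$rate_ba)
  k <- which.min(fwd_rate)
  sel <- cand[k, ]
  fwd <- sel$net_flux >= 0
  list(
    from = if (fwd) sel$state_a else sel$state_b,
    to = if (fwd) sel$state_b else sel$state_a,
    rate_fwd = unname(fwd_rate[k]),
    net_flux = abs(sel$net_flux),
    flux_fraction = if (is.na(total_flux)) NA_real_ else abs(sel$net_flux) / total_flux,
    below_threshold = below
  )
}

#' @export
print.mech_graph <- function(x, ...) {
  cat(sprintf("Mechanism graph: %d nodes, %d edges", nrow(x$nodes), nrow(x$edges)))
  if (!is.na(x$lump_cutoff)) cat(sprintf(" (lumped at %.4g 1/ns)", x$lump_cutoff))
  cat("\n")
  top <- utils::head(x$nodes[order(-x$nodes$population), ], 5)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-20s pop %.3f  %s-ion\n", top$state[i], top$population[i],
                ifelse(is.na(top$n_ions[i]), "?", top$n_ions[i])))
  }
  invisible(x)
}

#' @export
plot.mech_graph <- function(x, ...) {
  n <- nrow(x$nodes)
  theta <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  px <- cos(theta); py <- sin(theta)
  plot(px, py, type = "n", axes = FALSE, xlab = "", ylab = "",
       xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4), asp = 1, ...)
  pos <- stats::setNames(seq_len(n), x$nodes$state)
  for (i in seq_len(nrow(x$edges))) {
    a <- pos[[x$edges$state_a[i]]]; b <- pos[[x$edges$state_b[i]]]
    r <- max(x$edges$rate_ab[i], x$edges$rate_ba[i], na.rm = TRUE)
    lw <- if (is.finite(r)) 0.5 + 2 * log1p(r) else 0.5
    graphics::segments(px[a], py[a], px[b], py[b], lwd = lw, col = "grey50")
    graphics::text((px[a] + px[b]) / 2, (py[a] + py[b]) / 2,
                   labels = x$edges$net_flux[i], cex = 0.7, col = "grey30")
  }
  cls <- x$nodes$n_ions
  cols <- ifelse(!is.na(cls) & cls >= 4, "orange",
                 ifelse(!is.na(cls) & cls == 3, "steelblue", "grey80"))
  graphics::points(px, py, pch = 21, bg = cols,
                   cex = 2 + 8 * x$nodes$population)
  graphics::text(px, py * 1.15 + 0.12 * sign(py + 1e-9), x$nodes$state, cex = 0.7)
  invisible(x)
}

#' Export a mechanism graph as JSON or DOT
#'
#' JSON carries nodes (label, members, population, ion class) and edges
#' (forward/backward rates, counts, net flux); DOT renders node size by
#' population and edge width by rate for Graphviz.
#'
#' @param graph A `mech_graph`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_graph_json <- function(graph, path) {
  stopifnot(inherits(graph, "mech_graph"))
  nodes <- lapply(seq_len(nrow(graph$nodes)), function(i) {
    list(state = graph$nodes$state[i],
         members = graph$nodes$members[[i]],
         population = graph$nodes$population[i],
         n_ions = graph$nodes$n_ions[i])
  })
  payload <- list(
    lump_cutoff = graph$lump_cutoff, total_flux = graph$total_flux,
    nodes = nodes,
    edges = graph$edges
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}

#' @rdname write_graph_json
#' @export
write_graph_dot <- function(graph, path) {
  stopifnot(inherits(graph, "mech_graph"))
  q <- function(s) paste0('"', s, '"')
  lines <- c("digraph mechanism {", "  node [shape=circle];")
  for (i in seq_len(nrow(graph$nodes))) {
    nd <- graph$nodes[i, ]
    col <- if (!is.na(nd$n_ions) && nd$n_ions >= 4) "orange" else "steelblue"
    lines <- c(lines, sprintf(
      "  %s [width=%.2f, style=filled, fillcolor=%s, label=%s];",
      q(nd$state), 0.5 + 2 * nd$population, col,
      q(sprintf("%s\\n%.1f%%", nd$state, 100 * nd$population))))
  }
  for (i in seq_len(nrow(graph$edges))) {
    ed <- graph$edges[i, ]
    add <- function(a, b, rate, flux) {
      if (!is.finite(rate)) return(character(0))
      sprintf("  %s -> %s [penwidth=%.2f, label=\"%g\"];",
              q(a), q(b), 0.3 + log1p(rate), flux)
    }
    lines <- c(lines,
               add(ed$state_a, ed$state_b, ed$rate_ab, ed$net_flux),
               add(ed$state_b, ed$state_a, ed$rate_ba, -ed$net_flux))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
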