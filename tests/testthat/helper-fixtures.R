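# Shared fixtures and independent oracles used across the suite.
# All fixtures are generated in code; nothing is read from disk except
# files the helpers themselves write to tempdir().

# ---- topology fixtures ------------------------------------------------

# Write a synthetic [atoms]-block topology. `residues` is a data frame
# with columns residue, formal (integer charge); each residue gets two
# "backbone" atoms summing to 0 and a charged group of `group_n` atoms
# whose charges sum exactly to `formal` (a deterministic split).
write_test_topology <- function(path, residues, group_n = 3) {
  lines <- c("; synthetic test topology", "[ moleculetype ]", "TST 3", "",
             "[ atoms ]")
  nr <- 0; cg <- 0
  group_atoms <- list()
  for (r in seq_len(nrow(residues))) {
    res <- residues$residue[r]
    formal <- residues$formal[r]
    cg <- cg + 1
    for (bb in c("BB1", "BB2")) {
      nr <- nr + 1
      q <- if (bb == "BB1") 0.37 else -0.37
      lines <- c(lines, sprintf("%5d %6s %5d %6s %6s %5d %10.6f %10.4f",
                                nr, "X", r, res, bb, cg, q, 12.0))
    }
    cg <- cg + 1
    # deterministic uneven split of the formal charge over the group
    w <- seq_len(group_n)
    qg <- formal * w / sum(w)
    atoms <- sprintf("G%d", seq_len(group_n))
    for (k in seq_len(group_n)) {
      nr <- nr + 1
      lines <- c(lines, sprintf("%5d %6s %5d %6s %6s %5d %10.6f %10.4f",
                                nr, "X", r, res, atoms[k], cg, qg[k], 12.0))
    }
    group_atoms[[res]] <- atoms
  }
  writeLines(lines, path)
  group_atoms
}

# ---- MFPT brute-force scan oracle ------------------------------------

# O(n^2) literal implementation of the MFPT definition: for every entry
# into A, scan forward to the first visit of B; censored if none.
mfpt_oracle <- function(codes, times) {
  states <- sort(unique(codes))
  out <- matrix(NA_real_, length(states), length(states),
                dimnames = list(states, states))
  n <- length(codes)
  for (a in states) {
    for (b in states) {
      if (a == b) next
      passages <- numeric(0)
      for (i in seq_len(n)) {
        if (codes[i] == a && (i == 1 || codes[i - 1] != a)) {
          j <- i + 1
          while (j <= n && codes[j] != b) j <- j + 1
          if (j <= n) passages <- c(passages, times[j] - times[i])
        }
      }
      if (length(passages) > 0) out[a, b] <- mean(passages)
    }
  }
  out
}

# ---- RDF brute-force oracle ------------------------------------------

# Literal double loop over minimum-image pair distances in an
# orthorhombic box, with its own normalization arithmetic.
rdf_oracle <- function(ref_frames, tgt_frames, box, bin_width, r_max) {
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  counts <- numeric(length(breaks) - 1)
  n_ref <- 0
  for (f in seq_along(ref_frames)) {
    ref <- ref_frames[[f]]; tgt <- tgt_frames[[f]]
    for (i in seq_len(nrow(ref))) {
      for (j in seq_len(nrow(tgt))) {
        d <- tgt[j, ] - ref[i, ]
        d <- d - box * round(d / box)
        r <- sqrt(sum(d^2))
        if (r > 1e-12 && r < breaks[length(breaks)]) {
          k <- findInterval(r, breaks, left.open = TRUE)
          counts[k] <- counts[k] + 1
        }
      }
    }
    n_ref <- n_ref + nrow(ref)
  }
  rho <- nrow(tgt_frames[[1]]) / prod(box)
  shell_vol <- 4 / 3 * pi * diff(breaks^3)
  counts / (n_ref * rho * shell_vol)
}

# ---- common geometry / synthetic runs --------------------------------

test_geometry <- function() build_site_geometry(seq(1.0, 2.2, by = 0.3))

# A short knock-on-regime channel run used by several files.
test_channel_run <- function(seed = 42, duration = 60, n_ions = 80) {
  simulate_channel(channel_sim_spec(test_geometry(), n_ions = n_ions,
                                    duration = duration, stride = 0.1,
                                    seed = seed))
}

# Sampled exact Gaussian RDF profile on the 0.002 nm grid.
gaussian_rdf <- function(center = 0.280, sigma = 0.012, amplitude = 8,
                         bin_width = 0.002, noise = 0) {
  r <- seq(0.2, 0.4, by = bin_width)
  g <- amplitude * exp(-(r - center)^2 / (2 * sigma^2))
  if (noise > 0) g <- pmax(g + stats::runif(length(g), -noise, noise), 0)
  structure(list(bin_centers = r, g = g, bin_width = bin_width,
                 n_frames = 1L, mean_targets = NA_real_, density = NA_real_),
            class = "rdf_profile")
}
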