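# Shared file I/O: the columnar fixture trajectory format and the
# trajectory reader front end.

#' Write / read the columnar fixture trajectory format
#'
#' A plain-text CSV with columns `frame`, `time_ns`, `particle_id`,
#' `kind` (`ion`, `water`, `sf_oxygen`), `x`, `y`, `z` (nm). The format
#' is the interchange representation emitted by [simulate_channel()] and
#' accepted wherever a trajectory is needed, so every analysis stage runs
#' without binary MD files.
#'
#' @param frames List of coordinate frames (as produced by
#'   [simulate_channel()]).
#' @param path Output CSV path.
#' @param header Optional header comment lines.
#' @return `write_fixture_trajectory`: invisibly, the path;
#'   `read_fixture_trajectory`: a list of coordinate frames.
#' @export
write_fixture_trajectory <- function(frames, path, header = character()) {
  rows <- lapply(seq_along(frames), function(f) {
    fr <- frames[[f]]
    out <- list()
    if (!is.null(fr$ion_positions) && nrow(fr$ion_positions) > 0) {
      ids <- rownames(fr$ion_positions)
      if (is.null(ids)) ids <- sprintf("ion%02d", seq_len(nrow(fr$ion_positions)))
      out$ions <- data.frame(frame = f, time_ns = fr$time, particle_id = ids,
                             kind = "ion", x = fr$ion_positions[, 1],
                             y = fr$ion_positions[, 2], z = fr$ion_positions[, 3])
    }
    if (!is.null(fr$water_o_positions) && nrow(fr$water_o_positions) > 0) {
      out$waters <- data.frame(frame = f, time_ns = fr$time,
                               particle_id = sprintf("w%03d", seq_len(nrow(fr$water_o_positions))),
                               kind = "water", x = fr$water_o_positions[, 1],
                               y = fr$water_o_positions[, 2],
                               z = fr$water_o_positions[, 3])
    }
    if (!is.null(fr$sf_oxygen_z)) {
      out$sf <- data.frame(frame = f, time_ns = fr$time,
                           particle_id = sprintf("layer%d", seq_along(fr$sf_oxygen_z)),
                           kind = "sf_oxygen", x = 0, y = 0, z = fr$sf_oxygen_z)
    }
    do.call(rbind, out)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# eccperm fixture trajectory v1", paste0("# ", header)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fixture_trajectory
#' @param box Box dimensions (nm) attached to every frame on reading.
#' @export
read_fixture_trajectory <- function(path, box = NULL) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("frame", "time_ns", "particle_id", "kind", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("fixture trajectory must have columns: ", paste(need, collapse = ", "))
  }
  lapply(split(df, df$frame), function(fr) {
    ions <- fr[fr$kind == "ion", , drop = FALSE]
    waters <- fr[fr$kind == "water", , drop = FALSE]
    sf <- fr[fr$kind == "sf_oxygen", , drop = FALSE]
    ion_positions <- NULL
    if (nrow(ions) > 0) {
      ion_positions <- as.matrix(ions[, c("x", "y", "z")])
      rownames(ion_positions) <- ions$particle_id
    }
    list(
      time = fr$time_ns[1],
      ion_positions = ion_positions,
      water_o_positions = if (nrow(waters) > 0)
        as.matrix(waters[, c("x", "y", "z")]) else NULL,
      sf_oxygen_z = if (nrow(sf) > 0) sf$z else NULL,
      box = box
    )
  })
}

#' Read a trajectory into coordinate frames
#'
#' Front end over the supported trajectory sources. The columnar fixture
#' CSV (see [read_fixture_trajectory()]) is the native format; multi-model
#' PDB files are read via the bio3d package when installed, with
#' selections given as name prefixes and coordinates converted from
#' Angstrom to nm. Binary MD formats (XTC/TRR/DCD) are not read directly;
#' convert to multi-model PDB or the fixture CSV first.
#'
#' @param path Trajectory path (`.csv` fixture or multi-model `.pdb`).
#' @param ion_select,water_select,sf_select For PDB input: atom-name
#'   selections (exact names) for ions, water oxygens and filter oxygens.
#' @param dt_ns For PDB input: frame stride in ns.
#' @param angstrom For PDB input: if TRUE (default) divide coordinates by
#'   10 to convert to nm.
#' @param box Optional box attached to frames.
#' @return List of coordinate frames for [discretize_trajectory()].
#' @export
read_trajectory <- function(path, ion_select = c("K", "POT"),
                            water_select = c("OW", "OH2"),
                            sf_select = NULL, dt_ns = NULL,
                            angstrom = TRUE, box = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "txt", "dat")) {
    return(read_fixture_trajectory(path, box = box))
  }
  if (ext == "pdb") {
    if (!requireNamespace("bio3d", quietly = TRUE)) {
      stop("reading PDB trajectories requires the bio3d package")
    }
    if (is.null(dt_ns)) stop("dt_ns (frame stride in ns) is required for PDB input")
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    xyz <- pdb$xyz
    scale <- if (angstrom) 0.1 else 1
    nm <- pdb$atom$elety
    ion_rows <- which(nm %in% ion_select)
    wat_rows <- which(nm %in% water_select)
    if (length(ion_rows) == 0) stop("ion selection matched nothing: ",
                                    paste(ion_select, collapse = ","))
    n_models <- nrow(xyz)
    lapply(seq_len(n_models), function(m) {
      co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE) * scale
      ion_positions <- co[ion_rows, , drop = FALSE]
      rownames(ion_positions) <- paste0("ion", ion_rows)
      sf_z <- NULL
      if (!is.null(sf_select)) {
        sf_rows <- which(nm %in% sf_select)
        if (length(sf_rows) == 0) stop("sf selection matched nothing")
        sf_z <- sort(co[sf_rows, 3])
      }
      list(time = (m - 1) * dt_ns, ion_positions = ion_positions,
           water_o_positions = if (length(wat_rows) > 0)
             co[wat_rows, , drop = FALSE] else NULL,
           sf_oxygen_z = sf_z, box = box)
    })
  } else {
    stop("unsupported trajectory format '.", ext,
         "'; use the columnar fixture CSV or multi-model PDB")
  }
}
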