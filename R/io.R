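#' Build a trajectory frame from a state
#'
#' Expands the rigid bodies into the 10N world-frame beads with their type
#' labels, molecule ids and per-star image flags.
#'
#' @param state an `ns_state`.
#' @return a `frame` list: `positions`, `type`, `mol`, `image`, `box_L`,
#'   `time`, `step`.
#' @export
frame_from_state <- function(state, step = 0L) {
  stopifnot(inherits(state, "ns_state"))
  tpl <- state$template
  n <- nrow(state$centers)
  pos <- cpp_world_beads(state$centers, state$quats, tpl$bead_positions)
  list(positions = pos,
       type = rep(tpl$types, n),
       mol = rep(seq_len(n), each = 10L),
       image = state$images[rep(seq_len(n), each = 10L), , drop = FALSE],
       box_L = state$box_L, time = state$time, step = as.integer(step))
}

#' Write frames as extended XYZ
#'
#' One block per frame: atom count, a comment line carrying
#' `Lattice`, `Properties=species:S:1:pos:R:3:mol:I:1:image:I:3`, `Time`
#' and `Step`, then one row per bead.
#'
#' @param frame a frame (see [frame_from_state()]) or list of frames.
#' @param file output path.
#' @param append append instead of overwrite.
#' @export
write_xyz <- function(frame, file, append = FALSE) {
  frames <- if (!is.null(frame$positions)) list(frame) else frame
  con <- base::file(file, if (append) "a" else "w")
  on.exit(close(con))
  for (f in frames) {
    n <- nrow(f$positions)
    writeLines(as.character(n), con)
    writeLines(sprintf(
      paste0('Lattice="%g 0 0 0 %g 0 0 0 %g" ',
             'Properties=species:S:1:pos:R:3:mol:I:1:image:I:3 ',
             "Time=%.10g Step=%d"),
      f$box_L, f$box_L, f$box_L, f$time, f$step), con)
    writeLines(sprintf("%s %.9g %.9g %.9g %d %d %d %d",
                       f$type, f$positions[, 1], f$positions[, 2],
                       f$positions[, 3], f$mol,
                       f$image[, 1], f$image[, 2], f$image[, 3]), con)
  }
  invisible(file)
}

#' Read an extended-XYZ trajectory
#'
#' @param file path written by [write_xyz()] (or compatible).
#' @return list of frames.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ header at line ", i, call. = FALSE)
    if (i + 1L + n > length(lines)) {
      stop("bead-count mismatch: frame at line ", i, " promises ", n,
           " beads", call. = FALSE)
    }
    hdr <- lines[i + 1L]
    lat <- regmatches(hdr, regexpr('Lattice="[^"]*"', hdr))
    box_L <- if (length(lat)) {
      as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", lat), " +")[[1]])[1]
    } else NA_real_
    tm <- regmatches(hdr, regexpr("Time=[-0-9.eE+]+", hdr))
    st <- regmatches(hdr, regexpr("Step=[0-9]+", hdr))
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "[ \t]+")
    bad <- which(vapply(rows, length, 1L) != 8L)
    if (length(bad)) {
      stop("malformed bead row at line ", i + 1L + bad[1], call. = FALSE)
    }
    m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[2:8])))
    frames[[length(frames) + 1L]] <- list(
      positions = m[, 1:3, drop = FALSE],
      type = vapply(rows, `[[`, "", 1L),
      mol = as.integer(m[, 4]),
      image = matrix(as.integer(m[, 5:7]), n, 3),
      box_L = box_L,
      time = if (length(tm)) as.numeric(sub("Time=", "", tm)) else NA_real_,
      step = if (length(st)) as.integer(sub("Step=", "", st)) else NA_integer_)
    i <- i + 2L + n
  }
  frames
}

#' Write frames in the LAMMPS dump dialect
#'
#' `ITEM: ATOMS id mol type x y z ix iy iz` with numeric types
#' 1 = CORE, 2 = ARM, 3 = PATCH.
#'
#' @inheritParams write_xyz
#' @export
write_lammps_dump <- function(frame, file, append = FALSE) {
  frames <- if (!is.null(frame$positions)) list(frame) else frame
  con <- base::file(file, if (append) "a" else "w")
  on.exit(close(con))
  for (f in frames) {
    n <- nrow(f$positions)
    tcode <- match(f$type, c("CORE", "ARM", "PATCH"))
    writeLines(c("ITEM: TIMESTEP", as.character(f$step),
                 "ITEM: NUMBER OF ATOMS", as.character(n),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("0 %.10g", rep(f$box_L, 3)),
                 "ITEM: ATOMS id mol type x y z ix iy iz"), con)
    writeLines(sprintf("%d %d %d %.9g %.9g %.9g %d %d %d",
                       seq_len(n), f$mol, tcode,
                       f$positions[, 1], f$positions[, 2], f$positions[, 3],
                       f$image[, 1], f$image[, 2], f$image[, 3]), con)
  }
  invisible(file)
}

#' Read a LAMMPS dump trajectory
#'
#' @param file path to a dump with `id mol type x y z ix iy iz` columns.
#' @return list of frames (types mapped back to CORE/ARM/PATCH).
#' @export
read_lammps_dump <- function(file) {
  lines <- readLines(file)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "ITEM: TIMESTEP")) {
      stop("malformed dump at line ", i, ": expected ITEM: TIMESTEP",
           call. = FALSE)
    }
    step <- as.integer(lines[i + 1L])
    n <- as.integer(lines[i + 3L])
    box_hi <- as.numeric(strsplit(trimws(lines[i + 5L]), "[ \t]+")[[1]])
    box_L <- box_hi[2] - box_hi[1]
    rows <- strsplit(trimws(lines[(i + 9L):(i + 8L + n)]), "[ \t]+")
    m <- do.call(rbind, lapply(rows, as.numeric))
    if (ncol(m) != 9) stop("expected 9 dump columns at line ", i + 9L,
                           call. = FALSE)
    ord <- order(m[, 1])
    m <- m[ord, , drop = FALSE]
    frames[[length(frames) + 1L]] <- list(
      positions = m[, 4:6, drop = FALSE],
      type = c("CORE", "ARM", "PATCH")[m[, 3]],
      mol = as.integer(m[, 2]),
      image = matrix(as.integer(m[, 7:9]), n, 3),
      box_L = box_L, time = NA_real_, step = step)
    i <- i + 9L + n
  }
  frames
}

#' Unwrap a frame's coordinates using its image flags
#'
#' @param frame a frame.
#' @return the frame with continuous (unwrapped) positions.
#' @export
unwrap_frame <- function(frame) {
  frame$positions <- frame$positions + frame$image * frame$box_L
  frame
}

#' Write an observable table with a units header
#'
#' CSV preceded by `#` comment lines recording the reduced units and the
#' seed, so every table is self-describing.
#'
#' @param df data frame.
#' @param file output path.
#' @param seed the seed that produced the data.
#' @param extra optional named character vector of extra header fields.
#' @export
write_observables <- function(df, file, seed = NA, extra = NULL) {
  hdr <- c("# units: length sigma, energy eps, time tau_Br (k_B = 1)",
           sprintf("# seed: %s", format(seed)))
  if (!is.null(extra)) {
    hdr <- c(hdr, sprintf("# %s: %s", names(extra), unname(extra)))
  }
  con <- base::file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}

#' Read a table written by [write_observables()]
#' @param file path.
#' @export
read_observables <- function(file) {
  utils::read.csv(file, comment.char = "#")
}

#' Run configuration
#'
#' Bundles everything a simulation run needs: the system (N, d_p, box, T),
#' the interaction depth, run length and cadence, the mode, and the seed.
#'
#' @param N number of nanostars.
#' @param d_p planarity.
#' @param box_L box edge (sigma).
#' @param temperature temperature (eps / k_B).
#' @param eps_m Morse depth (epsilon).
#' @param dt time step (tau_Br).
#' @param n_steps run length.
#' @param record_every observable cadence (steps).
#' @param seed integer seed.
#' @param mode one of quench, melt_sweep, viscosity, metadyn_demo.
#' @return validated `run_config` list.
#' @export
run_config <- function(N = 175L, d_p = 0, box_L = 40, temperature = 1,
                       eps_m = ff_params()$eps_m, dt = 1e-4,
                       n_steps = 100000L,
                       record_every = 1000L, seed = 1L,
                       mode = c("quench", "melt_sweep", "viscosity",
                                "metadyn_demo")) {
  mode <- match.arg(mode)
  cfg <- list(N = as.integer(N), d_p = d_p, box_L = box_L,
              temperature = temperature, eps_m = eps_m, dt = dt,
              n_steps = as.integer(n_steps),
              record_every = as.integer(record_every),
              seed = as.integer(seed), mode = mode)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  need <- c("N", "d_p", "box_L", "temperature", "eps_m", "dt", "n_steps",
            "record_every", "seed", "mode")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config missing field(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  with(cfg, {
    stopifnot(N >= 1, d_p >= 0, d_p < 1, box_L > 0, temperature > 0,
              eps_m >= 0, dt > 0, n_steps >= 0, record_every >= 0)
  })
  cfg[need]
}

#' Read / write a run configuration as YAML
#' @param file path.
#' @export
read_config <- function(file) validate_config(yaml::read_yaml(file))

#' @param cfg a [run_config()].
#' @rdname read_config
#' @export
write_config <- function(cfg, file) {
  yaml::write_yaml(validate_config(cfg), file)
  invisible(file)
}
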