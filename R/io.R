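# Plain-text interchange: extended XYZ snapshots/trajectories and TSV tables.

#' Write and read extended-XYZ snapshots
#'
#' `write_xyz()` writes one or more frames of a system in extended XYZ:
#' an atom count, a comment line carrying the periodic box
#' (`Lattice="Lx 0 0 0 Ly 0 0 0 Lz"`), a `Properties=species:S:1:pos:R:3`
#' declaration and the time, then one `species x y z` row per bead.
#' `read_xyz()` reads such a file back into a list of frames.
#'
#' @param state A `brush_system`, or a list of N x 3 coordinate matrices
#'   (frames) together with `species`.
#' @param file Path to write to / read from.
#' @param species Per-bead species labels (taken from the system if given).
#' @param box Periodic box `c(Lx, Ly)`; the z extent written is the frame's
#'   maximum coordinate (the box is open above).
#' @param times Per-frame times for multi-frame output.
#' @return `write_xyz()` returns `file` invisibly; `read_xyz()` returns a
#'   list with `frames` (list of coordinate matrices), `species`, `box`
#'   and `times`.
#' @export
write_xyz <- function(state, file, species = NULL, box = NULL, times = NULL) {
  if (inherits(state, "brush_system")) {
    frames <- list(state$positions)
    species <- state$species
    box <- state$box
  } else {
    frames <- if (is.matrix(state)) list(state) else state
    stopifnot(!is.null(species), !is.null(box))
  }
  if (is.null(times)) times <- seq_along(frames) - 1
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    m <- frames[[f]]
    zmax <- max(m[, 3]) + 1
    writeLines(as.character(nrow(m)), con)
    writeLines(sprintf(
      'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3 Time=%g',
      box[1], box[2], zmax, times[f]), con)
    writeLines(sprintf("%s %.10g %.10g %.10g", species, m[, 1], m[, 2], m[, 3]),
               con)
  }
  invisible(file)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list()
  times <- numeric(0)
  species <- NULL
  box <- NULL
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    comment <- lines[i + 1]
    lat <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]][2]
    lv <- as.numeric(strsplit(lat, " +")[[1]])
    box <- c(lv[1], lv[5])
    tm <- regmatches(comment, regexec("Time=([-0-9.eE+]+)", comment))[[1]][2]
    times <- c(times, as.numeric(tm))
    rows <- strsplit(lines[(i + 2):(i + 1 + n)], " +")
    species <- vapply(rows, `[[`, character(1), 1)
    m <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- m
    i <- i + 2 + n
  }
  list(frames = frames, species = species, box = box, times = times)
}

#' Write an MSD table as TSV
#'
#' Columns: t, msd_xy_all, msd_z_all, msd_xy_in, msd_z_in, n_in, with a
#' commented header line.
#'
#' @param msd An `msd_result`.
#' @param file Output path.
#' @export
write_msd_tsv <- function(msd, file) {
  df <- data.frame(t = msd$times, msd_xy_all = msd$msd_xy_all,
                   msd_z_all = msd$msd_z_all, msd_xy_in = msd$msd_xy_inbrush,
                   msd_z_in = msd$msd_z_inbrush, n_in = msd$n_inbrush)
  .write_tsv(df, file, comment = sprintf("dual MSD over %d realizations", msd$n))
  invisible(file)
}

.write_tsv <- function(df, file, comment = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
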