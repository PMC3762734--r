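#' Snapshot archive
#'
#' An ordered set of field frames from a tissue run: times, per-frame named
#' field matrices (`V_m`, optionally `V_f` and `I_Na`), grid geometry, and
#' optional metadata.
#'
#' @param t frame times (ms), strictly increasing.
#' @param frames list of named lists of `nx` x `ny` matrices.
#' @param nx,ny,dx grid geometry.
#' @param meta optional metadata list (stored, round-tripped as YAML text).
#' @return an `mf_archive`.
#' @export
snapshot_archive <- function(t, frames, nx, ny, dx, meta = list()) {
  stopifnot(length(t) == length(frames))
  if (length(t) > 1 && any(diff(t) <= 0)) stop("frame times must increase")
  structure(list(t = as.numeric(t), frames = frames, nx = as.integer(nx),
                 ny = as.integer(ny), dx = dx, meta = meta),
            class = "mf_archive")
}

#' @export
print.mf_archive <- function(x, ...) {
  cat(sprintf("snapshot archive: %d frames, %d x %d grid, dx = %g mm\n",
              length(x$t), x$nx, x$ny, x$dx))
  if (length(x$t))
    cat(sprintf("  t in [%g, %g] ms; fields: %s\n", min(x$t), max(x$t),
                paste(names(x$frames[[1]]), collapse = ", ")))
  invisible(x)
}

# Binary layout (little-endian, all doubles unless noted):
#   char[4] "MFWV", int32 version = 1, int32 nx, int32 ny, double dx,
#   int32 nframes, int32 nfields, nfields x (int32 namelen, chars),
#   int32 metalen, chars (YAML),
#   then per frame: double t, nfields x (nx*ny doubles, column-major).

#' Write a snapshot archive to a flat binary file
#'
#' @param archive an `mf_archive`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snapshots <- function(archive, path) {
  stopifnot(inherits(archive, "mf_archive"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("MFWV", con, 4, eos = NULL)
  writeBin(c(1L, archive$nx, archive$ny), con, size = 4, endian = "little")
  writeBin(archive$dx, con, size = 8, endian = "little")
  fields <- if (length(archive$frames)) names(archive$frames[[1]]) else character(0)
  writeBin(c(length(archive$t), length(fields)), con, size = 4,
           endian = "little")
  for (f in fields) {
    writeBin(nchar(f), con, size = 4, endian = "little")
    writeChar(f, con, nchar(f), eos = NULL)
  }
  meta <- yaml::as.yaml(archive$meta)
  writeBin(nchar(meta, type = "bytes"), con, size = 4, endian = "little")
  writeChar(meta, con, nchar(meta, type = "bytes"), eos = NULL)
  for (k in seq_along(archive$t)) {
    writeBin(archive$t[k], con, size = 8, endian = "little")
    for (f in fields)
      writeBin(as.vector(archive$frames[[k]][[f]]), con, size = 8,
               endian = "little")
  }
  invisible(path)
}

#' Read a snapshot archive written by [write_snapshots()]
#'
#' @param path file path.
#' @return an `mf_archive`; the round trip is bitwise exact.
#' @export
read_snapshots <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "MFWV")) stop("not an mfwave snapshot file: ", path)
  hdr <- readBin(con, "integer", 3, size = 4, endian = "little")
  if (hdr[1] != 1L) stop("unsupported snapshot version: ", hdr[1])
  nx <- hdr[2]; ny <- hdr[3]
  dx <- readBin(con, "double", 1, size = 8, endian = "little")
  cnt <- readBin(con, "integer", 2, size = 4, endian = "little")
  nframes <- cnt[1]; nfields <- cnt[2]
  fields <- character(nfields)
  for (k in seq_len(nfields)) {
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    fields[k] <- readChar(con, len, useBytes = TRUE)
  }
  mlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  meta <- yaml::yaml.load(readChar(con, mlen, useBytes = TRUE))
  if (is.null(meta)) meta <- list()
  t <- numeric(nframes)
  frames <- vector("list", nframes)
  for (k in seq_len(nframes)) {
    t[k] <- readBin(con, "double", 1, size = 8, endian = "little")
    fr <- list()
    for (f in fields)
      fr[[f]] <- matrix(readBin(con, "double", nx * ny, size = 8,
                                endian = "little"), nx, ny)
    frames[[k]] <- fr
  }
  snapshot_archive(t, frames, nx, ny, dx, meta)
}

#' Write / read a run configuration as YAML
#'
#' A run is reproducible from its configuration alone; these helpers
#' serialize the plain-list content of the package's config objects.
#'
#' @param config a named list (possibly nested) of scalars/vectors.
#' @param path file path.
#' @return `read_run_config` returns the list; the writer returns `path`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(.strip_classes(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file does not contain a mapping: ", path)
  cfg
}

.strip_classes <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), .strip_classes))
  unclass(x)
}

#' Generate deterministic test fixtures
#'
#' \describe{
#'   \item{resting-strip}{frames of a quiescent strip at the resting
#'     potential;}
#'   \item{plane-wave-strip}{a constructed (not simulated) front moving one
#'     node per frame, for which the conduction velocity is exactly
#'     `dx / frame_dt`;}
#'   \item{synthetic-rotor-field}{an analytic Archimedean-spiral activation
#'     field rotating about a known core (stored in the metadata), used to
#'     validate the tip tracker without any ODE integration;}
#'   \item{small-spiral}{a simulated spiral on a reduced domain via
#'     [initiate_spiral()] (expensive; sizes above 300 x 300 are refused).}
#' }
#'
#' @param kind fixture type, see above.
#' @param nx,ny grid size (refused above 300 x 300).
#' @param n_frames number of frames.
#' @param frame_dt frame spacing (ms).
#' @param dx lattice spacing (mm).
#' @return an `mf_archive`.
#' @export
generate_fixture <- function(kind = c("resting-strip", "plane-wave-strip",
                                      "synthetic-rotor-field", "small-spiral"),
                             nx = 60, ny = 7, n_frames = 10, frame_dt = 1,
                             dx = 0.225) {
  kind <- match.arg(kind)
  if (nx * ny > 300 * 300) stop("fixture size refused: ", nx, " x ", ny)
  if (kind == "resting-strip") {
    v <- matrix(-86.2, nx, ny)
    return(snapshot_archive((seq_len(n_frames) - 1) * frame_dt,
                            replicate(n_frames, list(V_m = v),
                                      simplify = FALSE),
                            nx, ny, dx, meta = list(kind = kind)))
  }
  if (kind == "plane-wave-strip") {
    frames <- lapply(seq_len(n_frames), function(k) {
      v <- matrix(-86.2, nx, ny)
      if (k > 1) v[seq_len(min(k - 1, nx)), ] <- 20
      list(V_m = v)
    })
    return(snapshot_archive((seq_len(n_frames) - 1) * frame_dt, frames,
                            nx, ny, dx,
                            meta = list(kind = kind, cv_mm_ms = dx / frame_dt)))
  }
  if (kind == "synthetic-rotor-field") {
    core <- c(x = (nx - 1) / 2 * dx, y = (ny - 1) / 2 * dx)
    xs <- (seq_len(nx) - 1) * dx
    ys <- (seq_len(ny) - 1) * dx
    pitch <- nx * dx / 6        # radial spacing of the spiral arm (mm)
    omega <- 2 * pi / (n_frames * frame_dt)
    frames <- lapply(seq_len(n_frames), function(k) {
      t <- (k - 1) * frame_dt
      f <- outer(xs - core[1], ys - core[2], function(px, py) {
        r <- sqrt(px^2 + py^2)
        th <- (atan2(py, px) + omega * t) %% (2 * pi)
        # distance to the two-turn Archimedean curve r = pitch*(th/2pi + k);
        # the curve starts exactly at the core, so the arm terminus marks it
        d <- pmin(abs(r - pitch * th / (2 * pi)),
                  abs(r - pitch * (th / (2 * pi) + 1)))
        ifelse(r < 0.45 * nx * dx & d < 0.75 * dx, -400, 0)
      })
      list(I_Na = f)
    })
    return(snapshot_archive((seq_len(n_frames) - 1) * frame_dt, frames,
                            nx, ny, dx,
                            meta = list(kind = kind, core = as.list(core))))
  }
  # small-spiral: simulate on a reduced (rescaled-D) domain, store I_Na frames
  grid <- scaled_spiral_grid(nx, coupling_config("zero_sided", G_gap = 0),
                             dx = dx)
  init <- initiate_spiral(grid, spiral_protocol_scaled())
  run <- run_tissue(init$grid, init$grid$t + n_frames * frame_dt,
                    snapshot_times = init$grid$t +
                      (seq_len(n_frames) - 1) * frame_dt,
                    snapshot_fields = c("V_m", "I_Na"), sample_every = 50L)
  a <- run$snapshots
  a$meta <- list(kind = kind, t_init = init$grid$t)
  a
}
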