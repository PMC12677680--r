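#' Build a 5-D movie container
#'
#' The universal pipeline input: an intensity array ordered
#' time x channel x z x y x x, together with the physical voxel sizes and
#' the frame interval. All downstream operations take positions in
#' micrometres with (z, y, x) axis order.
#'
#' @param data numeric array with `dim = c(t, c, nz, ny, nx)`.
#' @param voxel_size numeric length-3, (z, y, x) voxel edge in um.
#' @param dt frame interval in seconds.
#' @param channel_names character vector, one per channel.
#' @return An object of class `movie5d`.
#' @export
movie5d <- function(data, voxel_size, dt,
                    channel_names = paste0("ch", seq_len(dim(data)[2L]) - 1L)) {
  if (length(dim(data)) != 5L) abort("`data` must be a 5-D t,c,z,y,x array")
  if (dim(data)[1L] < 1L || dim(data)[2L] < 1L) abort("need >= 1 frame and >= 1 channel")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) abort("`voxel_size` must be 3 positive values (z, y, x)")
  if (!is.numeric(dt) || dt <= 0) abort("`dt` must be a positive frame interval in seconds")
  if (length(channel_names) != dim(data)[2L]) abort("one channel name per channel required")
  structure(
    list(data = data, voxel_size = voxel_size, dt = dt,
         channel_names = as.character(channel_names)),
    class = "movie5d")
}

#' @export
print.movie5d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie5d> %d frames x %d channels x %d z x %d y x %d x\n",
              d[1L], d[2L], d[3L], d[4L], d[5L]))
  cat(sprintf("  voxel (z,y,x): %s um; dt = %g s; channels: %s\n",
              paste(signif(x$voxel_size, 4), collapse = " x "),
              x$dt, paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' @export
dim.movie5d <- function(x) dim(x$data)

# Extract one frame/channel as a (z, y, x) volume.
#' Extract a single 3-D volume from a movie
#' @param movie a [movie5d()].
#' @param frame 1-based frame index.
#' @param channel 1-based channel index.
#' @return 3-D numeric array (z, y, x).
#' @export
movie_volume <- function(movie, frame, channel = 1L) {
  v <- movie$data[frame, channel, , , , drop = TRUE]
  dim(v) <- dim(movie$data)[3:5]
  v
}

#' Write a movie to multi-page TIFF with a JSON metadata sidecar
#'
#' Pages are written in TCZYX order (z fastest) as 32-bit floats after
#' scaling into `[0, 1]`; the sidecar (`<path>.json`) records the axes,
#' intensity scale, voxel sizes, frame interval and channel names so that
#' [read_movie()] restores the array bit-for-bit within float precision.
#'
#' @param movie a [movie5d()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  d <- dim(movie$data)
  lo <- min(movie$data)
  hi <- max(movie$data)
  scale <- max(hi - lo, 1e-12)   # writeTIFF needs samples in [0, 1]
  pages <- vector("list", d[1L] * d[2L] * d[3L])
  p <- 0L
  for (t in seq_len(d[1L])) for (ch in seq_len(d[2L])) for (z in seq_len(d[3L])) {
    p <- p + 1L
    pages[[p]] <- matrix((movie$data[t, ch, z, , ] - lo) / scale, d[4L], d[5L])
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(axes = "TCZYX",
               shape = as.integer(d),
               intensity_scale = scale,
               intensity_offset = lo,
               voxel_size_um = movie$voxel_size,
               dt_s = movie$dt,
               channel_names = movie$channel_names)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie from TIFF
#'
#' Reads the JSON sidecar written by [write_movie()] when present; else
#' parses OME-XML from the first page's ImageDescription; else requires
#' explicit `shape`, `voxel_size` and `dt` overrides. Axis order of the
#' restored array is always TCZYX.
#'
#' @param path `.tif` path.
#' @param shape optional integer length-5 (t, c, z, y, x) page layout when
#'   no metadata is available.
#' @param voxel_size,dt,channel_names overrides when no metadata is present.
#' @return A [movie5d()].
#' @export
read_movie <- function(path, shape = NULL, voxel_size = NULL, dt = NULL,
                       channel_names = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- 1
  offset <- 0
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    shape <- as.integer(meta$shape)
    voxel_size <- voxel_size %||% as.numeric(meta$voxel_size_um)
    dt <- dt %||% meta$dt_s
    channel_names <- channel_names %||% meta$channel_names
    scale <- meta$intensity_scale %||% 1
    offset <- meta$intensity_offset %||% 0
  } else {
    desc <- attr(pages[[1L]], "description")
    ome <- if (!is.null(desc)) parse_ome_meta(desc) else NULL
    if (!is.null(ome)) {
      shape <- shape %||% ome$shape
      voxel_size <- voxel_size %||% ome$voxel_size
      dt <- dt %||% ome$dt
    }
  }
  if (is.null(shape) || is.null(voxel_size) || is.null(dt)) {
    abort(paste0("no usable metadata in ", path,
                 ": pass `shape` (t,c,z,y,x), `voxel_size` and `dt` explicitly"))
  }
  shape <- as.integer(shape)
  if (length(pages) != prod(shape[1:3])) {
    abort(sprintf("page count %d does not match t*c*z = %d",
                  length(pages), prod(shape[1:3])))
  }
  data <- array(0, dim = shape)
  p <- 0L
  for (t in seq_len(shape[1L])) for (ch in seq_len(shape[2L])) for (z in seq_len(shape[3L])) {
    p <- p + 1L
    data[t, ch, z, , ] <- pages[[p]] * scale + offset
  }
  movie5d(data, voxel_size, dt,
          channel_names %||% paste0("ch", seq_len(shape[2L]) - 1L))
}

# Minimal OME-XML reader: SizeT/C/Z/Y/X + PhysicalSize attributes.
parse_ome_meta <- function(desc) {
  g <- function(attr) {
    m <- regmatches(desc, regexpr(paste0(attr, '="[^"]*"'), desc))
    if (!length(m)) return(NA_real_)
    as.numeric(sub('"$', "", sub(paste0(attr, '="'), "", m)))
  }
  st <- g("SizeT"); sc <- g("SizeC"); sz <- g("SizeZ"); sy <- g("SizeY"); sx <- g("SizeX")
  if (anyNA(c(st, sc, sz, sy, sx))) return(NULL)
  vz <- g("PhysicalSizeZ"); vy <- g("PhysicalSizeY"); vx <- g("PhysicalSizeX")
  ti <- g("TimeIncrement")
  list(shape = as.integer(c(st, sc, sz, sy, sx)),
       voxel_size = if (anyNA(c(vz, vy, vx))) NULL else c(vz, vy, vx),
       dt = if (is.na(ti)) NULL else ti)
}
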