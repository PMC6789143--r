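#' Frame sequence
#'
#' An ordered set of equally sized grayscale frames with acquisition
#' metadata, the input of [compute_motion_fields()].
#'
#' @param frames list of numeric matrices, all of identical dimension.
#' @param fps frame rate (frames/second, > 0).
#' @param um_per_px pixel size (micrometres per pixel, > 0).
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps, um_per_px) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("a frame sequence needs at least 2 frames")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have the same dimensions")
  for (p in c(fps = fps, um_per_px = um_per_px))
    if (!is.finite(p) || p <= 0)
      stop("'fps' and 'um_per_px' must be finite and positive")
  structure(list(frames = frames, fps = fps, um_per_px = um_per_px,
                 dim = dims[, 1]),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames of %dx%d px @ %g fps, %g um/px\n",
              length(x$frames), x$dim[1], x$dim[2], x$fps, x$um_per_px))
  invisible(x)
}

#' Read a frame sequence from plain-text image files
#'
#' Accepts a directory, a glob pattern or an explicit vector of files;
#' lexicographic file order is time order. Supported per-frame formats are
#' PGM (ASCII `P2` or binary `P5`) and delimited numeric matrices
#' (`.csv`/`.tsv`/`.txt`). TIFF/PNG stacks are not supported in this build;
#' convert externally (e.g. one PGM per frame).
#'
#' @param path directory, glob, or character vector of frame files.
#' @inheritParams frame_sequence
#' @return A [frame_sequence()].
#' @export
read_frames <- function(path, fps, um_per_px) {
  files <- path
  if (length(path) == 1L) {
    if (dir.exists(path)) {
      files <- list.files(path, full.names = TRUE,
                          pattern = "\\.(pgm|csv|tsv|txt)$", ignore.case = TRUE)
    } else if (grepl("[*?]", path)) {
      files <- Sys.glob(path)
    }
  }
  files <- sort(files)
  if (length(files) < 2L) stop("need at least 2 frame files, got ",
                               length(files))
  frames <- lapply(files, read_frame_file)
  frame_sequence(frames, fps = fps, um_per_px = um_per_px)
}

read_frame_file <- function(f) {
  if (grepl("\\.pgm$", f, ignore.case = TRUE)) return(read_pgm(f))
  as.matrix(data.table::fread(f, header = FALSE))
}

# Minimal PGM reader (P2 ASCII / P5 binary, maxval <= 65535). No pre-installed
# R package reads PGM; the format is trivial and text-friendly for fixtures.
read_pgm <- function(f) {
  con <- file(f, "rb")
  on.exit(close(con))
  tok <- character(0)
  while (length(tok) < 4L) {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated PGM header in ", f)
    line <- sub("#.*$", "", line)
    tok <- c(tok, strsplit(trimws(line), "\\s+")[[1]])
    tok <- tok[nzchar(tok)]
  }
  magic <- tok[1]
  nc <- as.integer(tok[2]); nr <- as.integer(tok[3])
  maxval <- as.integer(tok[4])
  n <- nr * nc
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (magic == "P5") {
    size <- if (maxval > 255L) 2L else 1L
    vals <- readBin(con, "integer", n = n, size = size, signed = FALSE,
                    endian = "big")
  } else stop("unsupported PGM magic '", magic, "' in ", f)
  if (length(vals) != n) stop("truncated PGM data in ", f)
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}

#' Write a frame sequence as ASCII PGM files
#'
#' Frames are linearly rescaled to 0..65535 (16-bit) over the global intensity
#' range of the sequence and written as `P2` files `prefix_0001.pgm`, ...
#'
#' @param seq a [frame_sequence()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Invisibly, the vector of file paths.
#' @export
write_frames_pgm <- function(seq, dir, prefix = "frame") {
  stopifnot(inherits(seq, "frame_sequence"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rng <- range(unlist(lapply(seq$frames, range)))
  span <- if (diff(rng) > 0) diff(rng) else 1
  paths <- character(length(seq$frames))
  for (k in seq_along(seq$frames)) {
    m <- round((seq$frames[[k]] - rng[1]) / span * 65535)
    paths[k] <- file.path(dir, sprintf("%s_%04d.pgm", prefix, k))
    con <- file(paths[k], "wt")
    writeLines(c("P2", paste(ncol(m), nrow(m)), "65535"), con)
    write(t(m), file = con, ncolumns = ncol(m))
    close(con)
  }
  invisible(paths)
}
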