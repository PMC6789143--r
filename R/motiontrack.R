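#' Block-matching motion fields
#'
#' Exhaustive block matching between consecutive frames: each macroblock of
#' frame k (non-overlapping `block_size` x `block_size` tiles) is matched to
#' the position in frame k+1 within `+/- search_radius` pixels that minimizes
#' the sum of absolute intensity differences (SAD). Ties are broken toward
#' the smaller displacement magnitude, then scan order. Search windows are
#' clipped at the frame border. Coordinates are (row, col) = (y, x), origin
#' top-left; a displacement is the matched position in frame k+1 minus the
#' block position in frame k.
#'
#' @param seq a [frame_sequence()] (>= 2 frames).
#' @param block_size macroblock side in pixels (>= 4).
#' @param search_radius search range in pixels (>= 1).
#' @param subpixel logical; refine each displacement component by parabolic
#'   interpolation of the SAD around the integer optimum (off by default:
#'   integer matching is exact for rigid integer shifts).
#' @return List of `motion_field` objects, one per consecutive frame pair,
#'   each with matrices `dy`, `dx` (grid `floor(dims / block_size)`),
#'   `block_size`, `search_radius`.
#' @export
compute_motion_fields <- function(seq, block_size = 16L, search_radius = 7L,
                                  subpixel = FALSE) {
  if (!inherits(seq, "frame_sequence")) stop("'seq' must be a frame_sequence")
  block_size <- as.integer(block_size)
  search_radius <- as.integer(search_radius)
  if (block_size < 4) stop("'block_size' must be >= 4")
  if (search_radius < 1) stop("'search_radius' must be >= 1")
  if (any(seq$dim < block_size))
    stop("frames must be at least one block in size")
  n <- length(seq$frames)
  fields <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    a <- seq$frames[[k]]; b <- seq$frames[[k + 1L]]
    storage.mode(a) <- "double"; storage.mode(b) <- "double"
    bm <- cpp_block_match(a, b, block_size, search_radius)
    dy <- bm$dy; dx <- bm$dx
    if (subpixel) {
      ref <- refine_subpixel(a, b, dy, dx, block_size)
      dy <- ref$dy; dx <- ref$dx
    }
    fields[[k]] <- structure(list(dy = dy, dx = dx, block_size = block_size,
                                  search_radius = search_radius),
                             class = "motion_field")
  }
  fields
}

# Parabolic refinement of SAD around the integer optimum, per component.
refine_subpixel <- function(a, b, dy, dx, block) {
  nr <- nrow(a); nc <- ncol(a)
  sad_at <- function(r0, c0, sy, sx) {
    if (r0 + sy < 1 || r0 + sy + block - 1 > nr ||
        c0 + sx < 1 || c0 + sx + block - 1 > nc) return(NA_real_)
    sum(abs(a[r0:(r0 + block - 1), c0:(c0 + block - 1)] -
              b[(r0 + sy):(r0 + sy + block - 1),
                (c0 + sx):(c0 + sx + block - 1)]))
  }
  out_dy <- matrix(as.numeric(dy), nrow(dy))
  out_dx <- matrix(as.numeric(dx), nrow(dx))
  for (bi in seq_len(nrow(dy))) {
    for (bj in seq_len(ncol(dy))) {
      r0 <- (bi - 1) * block + 1; c0 <- (bj - 1) * block + 1
      sy <- dy[bi, bj]; sx <- dx[bi, bj]
      for (axis in 1:2) {
        o <- if (axis == 1) c(-1, 0, 1) else c(0, 0, 0)
        p <- if (axis == 1) c(0, 0, 0) else c(-1, 0, 1)
        s <- vapply(1:3, function(i) sad_at(r0, c0, sy + o[i], sx + p[i]),
                    numeric(1))
        if (any(is.na(s))) next
        den <- s[1] - 2 * s[2] + s[3]
        if (den <= 0) next
        delta <- 0.5 * (s[1] - s[3]) / den
        if (axis == 1) out_dy[bi, bj] <- sy + delta
        else out_dx[bi, bj] <- sx + delta
      }
    }
  }
  list(dy = out_dy, dx = out_dx)
}

#' Collapse motion fields into a contraction-motion waveform
#'
#' The waveform sample for each frame pair is the mean block displacement
#' magnitude converted to a speed:
#' `S = mean(sqrt(dx^2 + dy^2)) * um_per_px * fps` (um/s). The first
#' inter-frame speed is duplicated so the waveform has one sample per video
#' frame.
#'
#' @param fields non-empty list of `motion_field` (from
#'   [compute_motion_fields()]).
#' @param fps frame rate (frames/s).
#' @param um_per_px pixel size (um/px).
#' @param meta provenance list stored on the waveform.
#' @return A [motion_waveform()] of length `length(fields) + 1`.
#' @export
fields_to_waveform <- function(fields, fps, um_per_px, meta = list()) {
  if (!length(fields)) stop("'fields' must be a non-empty list")
  speeds <- vapply(fields, function(f)
    mean(sqrt(f$dx^2 + f$dy^2)) * um_per_px * fps, numeric(1))
  motion_waveform(c(speeds[1], speeds), fps = fps,
                  meta = c(meta, list(reduction = "mean block |d| * um/px * fps",
                                      um_per_px = um_per_px)))
}

#' Track a video end to end
#'
#' Convenience wrapper: [compute_motion_fields()] then
#' [fields_to_waveform()].
#'
#' @inheritParams compute_motion_fields
#' @param ... passed to [compute_motion_fields()].
#' @return A [motion_waveform()].
#' @export
track_video <- function(seq, block_size = 16L, search_radius = 7L, ...) {
  fields <- compute_motion_fields(seq, block_size = block_size,
                                  search_radius = search_radius, ...)
  fields_to_waveform(fields, fps = seq$fps, um_per_px = seq$um_per_px,
                     meta = list(source = "block-matching tracker",
                                 block_size = block_size,
                                 search_radius = search_radius))
}
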