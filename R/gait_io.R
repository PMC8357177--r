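#' Construct a gait silhouette sequence
#'
#' A gait sequence is an ordered stack of equally sized binary silhouette
#' frames (foreground = 1) for one walking sequence, optionally labelled with
#' the subject/class identity and the number of frames per gait cycle.
#'
#' @param frames list of numeric matrices with values in \{0, 1\}; all frames
#'   must share dimensions.
#' @param class_label optional identifier of the subject/class.
#' @param cycle_length optional frames-per-gait-cycle (positive integer, at
#'   most the number of frames).
#' @param speed optional walking-speed annotation (dimensionless).
#' @return an object of class `"gait_sequence"`.
#' @export
gait_sequence <- function(frames, class_label = NULL, cycle_length = NULL,
                          speed = NULL) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("no frames", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("mixed sizes: all frames of a sequence must share dimensions",
         call. = FALSE)
  for (f in frames) {
    if (!is.numeric(f) || !all(f %in% c(0, 1)))
      stop("frames must be binary (values exactly 0 or 1)", call. = FALSE)
  }
  if (!is.null(cycle_length)) {
    cycle_length <- as.integer(cycle_length)
    if (cycle_length < 1L || cycle_length > length(frames))
      stop("cycle_length must be in [1, number of frames]", call. = FALSE)
  }
  structure(list(frames = frames, class_label = class_label,
                 cycle_length = cycle_length, speed = speed),
            class = "gait_sequence")
}

#' @export
print.gait_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Gait sequence: %d frames of %dx%d", length(x$frames), d[1], d[2]))
  if (!is.null(x$class_label)) cat(sprintf(", class '%s'", x$class_label))
  if (!is.null(x$cycle_length)) cat(sprintf(", cycle %d frames", x$cycle_length))
  cat("\n")
  invisible(x)
}

#' @export
length.gait_sequence <- function(x) length(x$frames)

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    # skip whitespace and '#' comment lines in the PGM header
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PGM header: ", path, call. = FALSE)
      if (ch == "#") { repeat { c2 <- readChar(con, 1L, useBytes = TRUE)
        if (length(c2) == 0L || c2 == "\n") break } }
      else if (!grepl("^[[:space:]]$", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || grepl("^[[:space:]]$", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (magic != "P5") stop("not a binary (P5) PGM file: ", path, call. = FALSE)
  w <- as.integer(tok()); h <- as.integer(tok()); maxv <- as.integer(tok())
  n <- w * h
  raw <- if (maxv < 256L) as.integer(readBin(con, "raw", n)) else
    readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
  if (length(raw) < n) stop("truncated PGM data: ", path, call. = FALSE)
  matrix(raw / maxv, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(mat, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(mat), nrow(mat)), con,
            eos = NULL, useBytes = TRUE)
  vals <- as.integer(round(t(mat) * 255))
  writeBin(as.raw(pmin(pmax(vals, 0L), 255L)), con)
  invisible(path)
}

read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           pgm = read_pgm(path),
           stop("unsupported frame format '", ext, "'", call. = FALSE)),
    error = function(e) stop("cannot read frame file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # collapse RGB(A) to one channel
  (img != 0) * 1
}

#' Load a silhouette sequence from a directory of image frames
#'
#' Frames are ordered by lexicographic filename sort (matching `frame_0001.png`
#' style numbering) and binarized: any nonzero intensity becomes foreground 1.
#'
#' @param directory_path directory containing the frame images.
#' @param pattern filename glob, default `"*.png"` (also supports `*.pgm`).
#' @param class_label,cycle_length,speed passed to [gait_sequence()].
#' @return a [gait_sequence()].
#' @export
load_sequence <- function(directory_path, pattern = "*.png",
                          class_label = NULL, cycle_length = NULL,
                          speed = NULL) {
  files <- sort(list.files(directory_path, pattern = utils::glob2rx(pattern),
                           full.names = TRUE))
  if (length(files) == 0L)
    stop("no frames in '", directory_path, "' matching '", pattern, "'",
         call. = FALSE)
  frames <- lapply(files, read_frame_file)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("mixed sizes in '", directory_path, "'", call. = FALSE)
  gait_sequence(frames, class_label = class_label,
                cycle_length = cycle_length, speed = speed)
}

#' Save a silhouette sequence as numbered image frames
#'
#' @param seq a [gait_sequence()].
#' @param directory_path output directory (created if missing).
#' @param format `"png"` or `"pgm"` (binary P5).
#' @param prefix filename prefix; frames are written as `<prefix>0001.<ext>`.
#' @return the directory path, invisibly.
#' @export
save_sequence <- function(seq, directory_path, format = c("png", "pgm"),
                          prefix = "frame_") {
  format <- match.arg(format)
  dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(seq$frames)) {
    path <- file.path(directory_path,
                      sprintf("%s%04d.%s", prefix, i, format))
    if (format == "png") png::writePNG(seq$frames[[i]], path)
    else write_pgm(seq$frames[[i]], path)
  }
  invisible(directory_path)
}

resize_bilinear <- function(mat, nr, nc) {
  out <- EBImage::resize(mat, w = nr, h = nc, filter = "bilinear")
  matrix(as.numeric(out), nr, nc)
}

#' Normalize a silhouette frame to a fixed canvas
#'
#' The foreground bounding box is extracted, rescaled (bilinear) so its height
#' equals `target_height` while preserving the aspect ratio, re-binarized at
#' threshold 0.5, and centred horizontally on a zero canvas of
#' `target_height x target_width`. This is the standard height normalization
#' applied to gait silhouettes before any subspace modelling.
#'
#' @param frame binary silhouette matrix with at least one foreground pixel.
#' @param target_height,target_width canvas size in pixels.
#' @return a binary `target_height x target_width` matrix.
#' @export
normalize_silhouette <- function(frame, target_height = 64L,
                                 target_width = 44L) {
  fg <- which(frame == 1, arr.ind = TRUE)
  if (nrow(fg) == 0L) stop("empty frame", call. = FALSE)
  r1 <- min(fg[, 1]); r2 <- max(fg[, 1])
  c1 <- min(fg[, 2]); c2 <- max(fg[, 2])
  box <- frame[r1:r2, c1:c2, drop = FALSE]
  new_w <- max(1L, as.integer(round(ncol(box) * target_height / nrow(box))))
  scaled <- (resize_bilinear(box, target_height, new_w) >= 0.5) * 1
  if (new_w > target_width) {
    off <- (new_w - target_width) %/% 2L
    scaled <- scaled[, (off + 1L):(off + target_width), drop = FALSE]
    warning("silhouette wider than target canvas; clipped", call. = FALSE)
    new_w <- target_width
  }
  canvas <- matrix(0, target_height, target_width)
  left <- (target_width - new_w) %/% 2L
  canvas[, (left + 1L):(left + new_w)] <- scaled
  canvas
}

lower_half_width <- function(frame) {
  # count columns with >= 2 foreground pixels: isolated flipped pixels must
  # not stretch the measured leg spread
  a <- nrow(frame)
  lower <- frame[(a %/% 2L + 1L):a, , drop = FALSE]
  sum(colSums(lower) >= 2)
}

#' Estimate the gait cycle length of a sequence
#'
#' The per-frame horizontal extent of the foreground in the lower half of each
#' frame (the leg region) is the strongest periodic signal in side-view gait.
#' The period is taken as the lag of the dominant peak of its autocorrelation.
#' If the sequence already carries a `cycle_length` it is returned unchanged.
#'
#' @param seq a [gait_sequence()].
#' @return frames per gait cycle (positive integer).
#' @export
estimate_gait_cycle <- function(seq) {
  stopifnot(inherits(seq, "gait_sequence"))
  if (!is.null(seq$cycle_length)) return(seq$cycle_length)
  sig <- vapply(seq$frames, lower_half_width, numeric(1))
  n <- length(sig)
  if (n < 4L || stats::var(sig) == 0)
    stop("aperiodic sequence", call. = FALSE)
  # unbiased-normalized autocorrelation: the biased (1/n) estimator damps
  # large lags, which would favour the half-cycle lag over the full cycle
  x <- sig - mean(sig)
  c0 <- mean(x^2)
  lags <- seq_len(n %/% 2L)
  vals <- vapply(lags, function(k)
    mean(x[seq_len(n - k)] * x[(k + 1L):n]) / c0, numeric(1))
  a <- c(1, vals)
  left <- c(a[1], vals[-length(vals)])
  right <- c(vals[-1], -Inf)
  peak <- vals >= left & vals >= right & vals > 0
  if (!any(peak)) stop("aperiodic sequence", call. = FALSE)
  best <- max(vals[peak])
  lags[peak][which(vals[peak] >= best - 1e-12)[1]]
}

#' Truncate a sequence to one gait cycle
#'
#' @param seq a [gait_sequence()].
#' @param cycle optional cycle length; estimated with [estimate_gait_cycle()]
#'   when missing.
#' @return a [gait_sequence()] containing the first cycle.
#' @export
truncate_to_cycle <- function(seq, cycle = NULL) {
  if (is.null(cycle)) cycle <- estimate_gait_cycle(seq)
  gait_sequence(seq$frames[seq_len(min(cycle, length(seq$frames)))],
                class_label = seq$class_label, cycle_length = cycle,
                speed = seq$speed)
}

#' Gait energy image (GEI)
#'
#' Pixelwise mean of the silhouette frames: the classical speed-variant gait
#' feature, equivalent to modelling the sequence as a 0-dimensional affine
#' subspace (a single point) of image space.
#'
#' @param seq a [gait_sequence()].
#' @return a real-valued matrix with values in \[0, 1\].
#' @export
compute_gei <- function(seq) {
  stopifnot(inherits(seq, "gait_sequence"))
  Reduce(`+`, seq$frames) / length(seq$frames)
}
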