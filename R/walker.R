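# Parametric 2D side-view articulated walker: identity lives in the body
# proportions (WalkerParams), walking speed modulates stride, cadence and arm
# swing (GaitStyle). Far-side limbs are drawn slightly shorter and thinner
# (self-occlusion / perspective in a side view) and the far-side step is a
# little shallower than the near-side one; both asymmetries make the full gait
# cycle -- two slightly unequal steps -- observable in the silhouette, as it
# is in real gait, instead of collapsing to a half-cycle period.

.walker_ranges <- list(
  leg_length     = c(24, 30),
  torso_height   = c(15, 21),
  torso_halfwidth = c(3, 6),
  head_radius    = c(3.5, 5.5),
  arm_length     = c(15, 20),
  limb_thickness = c(1.5, 3)
)

# appearance/kinematic asymmetry constants (fixed, not subject identity)
.far_length_scale <- 0.9
.far_thick_scale  <- 0.7
.far_stride_scale <- 0.85
.step_asymmetry   <- 0.15  # one step slightly longer than the other

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw a synthetic walker identity
#'
#' Body proportions (leg length, torso height and half-width, head radius, arm
#' length, limb thickness, in pixels) are drawn uniformly from fixed per-field
#' ranges; the parameter tuple IS the subject identity. Deterministic in the
#' seed.
#'
#' @param seed integer seed.
#' @return an object of class `"walker_params"`.
#' @export
walker_subject <- function(seed) {
  vals <- with_seed(as.integer(seed), {
    vapply(.walker_ranges, function(rg) stats::runif(1, rg[1], rg[2]),
           numeric(1))
  })
  structure(c(as.list(vals), list(seed = as.integer(seed))),
            class = "walker_params")
}

#' @export
print.walker_params <- function(x, ...) {
  cat("Walker identity (seed", x$seed, "):\n")
  for (f in names(.walker_ranges))
    cat(sprintf("  %-15s %.2f px\n", f, x[[f]]))
  invisible(x)
}

#' Walking style induced by a speed parameter
#'
#' Stride amplitude (radians of hip swing), cadence (gait cycles per frame)
#' and arm swing grow affinely with the dimensionless speed:
#' `stride = a0 + a1*speed`, `cadence = f0 + f1*speed`,
#' `arm_swing = b0 + b1*speed`. Defaults keep limbs on a 64x44 canvas over
#' speeds in roughly \[0.5, 2\].
#'
#' @param speed dimensionless walking speed (>= 0).
#' @param a0,a1 stride-amplitude intercept/slope (radians).
#' @param f0,f1 cadence intercept/slope (cycles/frame).
#' @param b0,b1 arm-swing intercept/slope (radians).
#' @param phase0 initial phase (radians).
#' @param cadence,stride_amplitude,arm_swing optional direct overrides.
#' @return an object of class `"gait_style"`.
#' @export
gait_style <- function(speed, a0 = 0.25, a1 = 0.20, f0 = 0.03, f1 = 0.02,
                       b0 = 0.15, b1 = 0.10, phase0 = 0,
                       cadence = NULL, stride_amplitude = NULL,
                       arm_swing = NULL) {
  stopifnot(speed >= 0)
  st <- list(
    speed = speed,
    stride_amplitude = if (is.null(stride_amplitude)) a0 + a1 * speed
                       else stride_amplitude,
    cadence = if (is.null(cadence)) f0 + f1 * speed else cadence,
    arm_swing = if (is.null(arm_swing)) b0 + b1 * speed else arm_swing,
    phase0 = phase0
  )
  if (st$stride_amplitude <= 0 || st$stride_amplitude >= pi / 2)
    stop("stride_amplitude must lie in (0, pi/2)", call. = FALSE)
  if (st$cadence <= 0 || st$cadence >= 0.5)
    stop("cadence must lie in (0, 0.5)", call. = FALSE)
  structure(st, class = "gait_style")
}

draw_segment <- function(canvas, x0, y0, x1, y1, halfwidth) {
  # rasterize a thick segment (rounded caps) by distance to the segment;
  # x = column, y = row, origin top-left
  nr <- nrow(canvas); nc <- ncol(canvas)
  rmin <- max(1L, floor(min(y0, y1) - halfwidth)); rmax <- min(nr, ceiling(max(y0, y1) + halfwidth))
  cmin <- max(1L, floor(min(x0, x1) - halfwidth)); cmax <- min(nc, ceiling(max(x0, x1) + halfwidth))
  if (rmin > rmax || cmin > cmax) return(canvas)
  ys <- rmin:rmax; xs <- cmin:cmax
  gy <- matrix(ys, length(ys), length(xs))
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) 0 else pmin(pmax(((gx - x0) * dx + (gy - y0) * dy) / len2, 0), 1)
  d2 <- (gx - (x0 + t * dx))^2 + (gy - (y0 + t * dy))^2
  patch <- canvas[ys, xs, drop = FALSE]
  patch[d2 <= halfwidth^2] <- 1
  canvas[ys, xs] <- patch
  canvas
}

draw_disc <- function(canvas, x0, y0, radius) {
  draw_segment(canvas, x0, y0, x0, y0, radius)
}

render_walker_frame <- function(params, style, phase, canvas_dim) {
  A <- canvas_dim[1]; B <- canvas_dim[2]
  p <- params
  hw <- p$limb_thickness / 2
  hip_x <- (B + 1) / 2
  hip_y <- A - p$leg_length - 1
  if (hip_y - p$torso_height - 2 * p$head_radius < 1)
    stop("canvas too small", call. = FALSE)
  amp_max <- style$stride_amplitude * (1 + .step_asymmetry)
  reach <- max(p$leg_length * sin(min(amp_max, pi / 2)),
               p$arm_length * sin(style$arm_swing)) + p$limb_thickness
  if (hip_x - reach < 1 || hip_x + reach > B ||
      hip_x - p$torso_halfwidth < 1 || hip_x + p$torso_halfwidth > B)
    stop("canvas too small", call. = FALSE)

  cv <- matrix(0, A, B)
  sh_y <- hip_y - p$torso_height
  # torso + head
  cv <- draw_segment(cv, hip_x, hip_y, hip_x, sh_y, p$torso_halfwidth)
  cv <- draw_disc(cv, hip_x, sh_y - p$head_radius, p$head_radius)
  # legs: near leg at full stride, far leg in antiphase at reduced stride.
  # g(phase) adds a step-length asymmetry (the forward step is deeper than
  # the backward one) so the two steps of a cycle are distinguishable, as in
  # real gait; g has the full gait-cycle period.
  g <- sin(phase) + .step_asymmetry * sin(phase)^2
  a_near <- style$stride_amplitude * g
  a_far <- -style$stride_amplitude * .far_stride_scale * g
  cv <- draw_segment(cv, hip_x, hip_y,
                     hip_x + p$leg_length * sin(a_near),
                     hip_y + p$leg_length * cos(a_near), hw)
  lf <- p$leg_length * .far_length_scale
  cv <- draw_segment(cv, hip_x, hip_y,
                     hip_x + lf * sin(a_far),
                     hip_y + lf * cos(a_far), hw * .far_thick_scale)
  # arms swing in antiphase to their ipsilateral legs
  b_near <- -style$arm_swing * sin(phase)
  b_far <- style$arm_swing * .far_stride_scale * sin(phase)
  cv <- draw_segment(cv, hip_x, sh_y,
                     hip_x + p$arm_length * sin(b_near),
                     sh_y + p$arm_length * cos(b_near), hw)
  af <- p$arm_length * .far_length_scale
  cv <- draw_segment(cv, hip_x, sh_y,
                     hip_x + af * sin(b_far),
                     sh_y + af * cos(b_far), hw * .far_thick_scale)
  cv
}

#' Render a synthetic silhouette sequence
#'
#' Per frame t (0-based) the hip angle is
#' `stride_amplitude * sin(2*pi*cadence*t + phase0)`; the two legs move in
#' antiphase and each arm in antiphase to its ipsilateral leg. Limbs are
#' rasterized as thick segments and the head as a disc. Each frame is height
#' normalized onto the target canvas with [normalize_silhouette()]; finally
#' each pixel is flipped independently with probability `flip_noise_p`.
#'
#' @param params a [walker_subject()] identity.
#' @param style a [gait_style()].
#' @param n_frames number of frames (>= 1).
#' @param canvas output frame size `c(height, width)` in pixels.
#' @param flip_noise_p per-pixel flip probability.
#' @param seed integer seed for the pixel noise.
#' @return a [gait_sequence()] annotated with the style's speed.
#' @export
render_sequence <- function(params, style, n_frames, canvas = c(64L, 44L),
                            flip_noise_p = 0, seed = 1L) {
  stopifnot(inherits(params, "walker_params"), inherits(style, "gait_style"),
            n_frames >= 1)
  frames <- lapply(seq_len(n_frames) - 1L, function(t) {
    phase <- 2 * pi * style$cadence * t + style$phase0
    raw <- render_walker_frame(params, style, phase, canvas)
    normalize_silhouette(raw, canvas[1], canvas[2])
  })
  if (flip_noise_p > 0) {
    frames <- with_seed(as.integer(seed), lapply(frames, function(f) {
      flip <- matrix(stats::runif(length(f)) < flip_noise_p, nrow(f), ncol(f))
      out <- f
      out[flip] <- 1 - out[flip]
      out
    }))
  }
  gait_sequence(frames, class_label = params$seed, speed = style$speed)
}

#' Generate a labelled cross-speed gait benchmark
#'
#' One gallery sequence per subject at `gallery_speed` and one probe sequence
#' per subject per probe speed, fully deterministic in the seed. This emulates
#' the cross-speed identification protocol: enrol everyone at one walking
#' speed, query at others.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param gallery_speed speed of the enrolled sequences.
#' @param probe_speeds vector of probe speeds.
#' @param frames_per_seq frames per sequence.
#' @param seed master integer seed; all subject identities, phases and noise
#'   derive from it.
#' @param flip_noise_p per-pixel flip probability applied to every sequence.
#' @param canvas frame size `c(height, width)`.
#' @return a list with `gallery` (named list of [gait_sequence()], one per
#'   subject) and `probes` (list of sequences, each annotated with
#'   `class_label` and `speed`), plus a `labels` data frame.
#' @export
make_benchmark <- function(n_subjects, gallery_speed = 1.0,
                           probe_speeds = 1.0, frames_per_seq = 60L,
                           seed = 1L, flip_noise_p = 0,
                           canvas = c(64L, 44L)) {
  stopifnot(n_subjects >= 2)
  seed <- as.integer(seed) %% 100000L
  ids <- sprintf("S%02d", seq_len(n_subjects))
  subjects <- lapply(seq_len(n_subjects),
                     function(i) walker_subject(seed * 131L + i))
  names(subjects) <- ids
  gallery <- list()
  for (i in seq_len(n_subjects)) {
    s <- render_sequence(subjects[[i]], gait_style(gallery_speed),
                         frames_per_seq, canvas, flip_noise_p,
                         seed = seed * 131L + 50000L + i)
    s$class_label <- ids[i]
    gallery[[ids[i]]] <- s
  }
  probes <- list()
  labels <- NULL
  k <- 0L
  for (j in seq_along(probe_speeds)) {
    for (i in seq_len(n_subjects)) {
      k <- k + 1L
      st <- gait_style(probe_speeds[j],
                       phase0 = 2 * pi * ((i * 7L + j * 3L) %% 12L) / 12L)
      s <- render_sequence(subjects[[i]], st, frames_per_seq, canvas,
                           flip_noise_p,
                           seed = seed * 131L + 100000L + 97L * j + i)
      s$class_label <- ids[i]
      probes[[k]] <- s
      labels <- rbind(labels, data.frame(
        probe_id = sprintf("P%03d", k), class_id = ids[i],
        speed = probe_speeds[j], stringsAsFactors = FALSE))
    }
  }
  names(probes) <- labels$probe_id
  list(gallery = gallery, probes = probes, labels = labels,
       subjects = subjects)
}
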