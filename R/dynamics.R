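#' @title Orientation-channel boundary dynamics
#' @name dynamics
#' @description
#' Converts a luminance image into orientation-channel boundary activity via
#' quadrature (odd/even) oriented edge-energy filters, then evolves a
#' deterministic rate dynamic: a first-order rise toward the static drive
#' after stimulus onset and an exponential decay after offset, so that
#' responses are strong by ~100 ms and persist beyond offset. Activity is
#' reported as accumulated maps over trailing 20-ms windows, mirroring
#' accumulated spike counts of an integrate-and-fire circuit without its
#' stochasticity.
NULL

#' Simulation clock
#'
#' Stimulus onset at 20 ms, offset at 140 ms (120 ms presentation),
#' simulation end at 300 ms, activity accumulated over trailing 20-ms
#' windows at 1-ms resolution.
#'
#' @param dt_ms Integration step (ms).
#' @param onset_ms,offset_ms Stimulus onset/offset (ms).
#' @param end_ms Simulation end (ms).
#' @param window_ms Accumulation window (ms); must tile `end - offset`.
#' @return An object of class `simulation_clock`.
#' @export
simulation_clock <- function(dt_ms = 1, onset_ms = 20, offset_ms = 140,
                             end_ms = 300, window_ms = 20) {
  if (end_ms < offset_ms) stop("clock error: end_ms < offset_ms")
  stopifnot(dt_ms > 0, onset_ms < offset_ms, window_ms >= dt_ms,
            (end_ms - offset_ms) %% window_ms == 0)
  structure(list(dt_ms = dt_ms, onset_ms = onset_ms, offset_ms = offset_ms,
                 end_ms = end_ms, window_ms = window_ms),
            class = "simulation_clock")
}

#' Channel names of the orientation bank
#' @return `c("vertical", "horizontal", "diag45", "diag135")`.
#' @export
channel_names <- function() c("vertical", "horizontal", "diag45", "diag135")

# Quadrature kernel pair for one channel. `theta` is the contour axis angle
# (deg, 0 = horizontal axis); filtering happens across the axis (direction
# theta + 90). Odd = first cross-derivative of a Gaussian (edge detector),
# even = second cross-derivative (bar detector). Both are exactly zero-sum,
# and for the axis-aligned channels the even part is additionally zero-sum
# along the cross direction, so a long uniform bar drives only its own
# channel away from the terminators.
make_kernel_pair <- function(theta_deg, ppd, sigma_deg = 0.06,
                             support_deg = 0.3) {
  k <- max(2L, as.integer(ceiling(support_deg / 2 * ppd)))
  sigma <- max(0.6, sigma_deg * ppd)
  xs <- -k:k
  x <- matrix(xs, 2 * k + 1, 2 * k + 1, byrow = TRUE)   # column offset
  y <- matrix(xs, 2 * k + 1, 2 * k + 1)                 # row offset (down)
  a <- (theta_deg + 90) * pi / 180
  u <- x * cos(a) + y * sin(a)
  g <- exp(-(x^2 + y^2) / (2 * sigma^2))
  odd <- u * g
  even <- (u^2 / sigma^2 - 1) * g
  if (theta_deg %% 90 == 0) {
    # enforce zero cross-sums exactly (separable case)
    f <- (xs^2 / sigma^2 - 1) * exp(-xs^2 / (2 * sigma^2))
    f <- f - mean(f)
    gax <- exp(-xs^2 / (2 * sigma^2))
    # horizontal axis (theta 0): cross direction is y, f varies along rows;
    # vertical axis (theta 90): cross direction is x, f varies along columns
    even <- if (theta_deg %% 180 == 0) outer(f, gax) else outer(gax, f)
  }
  even <- even - mean(even)
  list(odd = odd / sqrt(sum(odd^2)), even = even / sqrt(sum(even^2)))
}

# 2-D correlation with edge replication (no spurious border responses)
conv2_same <- function(m, kern) {
  k <- (nrow(kern) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, k), seq_len(nr), rep(nr, k))
  ci <- c(rep(1L, k), seq_len(nc), rep(nc, k))
  pm <- m[ri, ci]
  out <- matrix(0, nr, nc)
  for (dr in -k:k) {
    for (dc in -k:k) {
      w <- kern[dr + k + 1L, dc + k + 1L]
      if (w == 0) next
      out <- out + w * pm[(1L + k + dr):(nr + k + dr),
                          (1L + k + dc):(nc + k + dc)]
    }
  }
  out
}

#' Static oriented-energy response of an image
#'
#' Quadrature energy (sqrt of odd^2 + even^2) at four orientations. The
#' response is contrast-polarity invariant and exactly zero on any uniform
#' image. Along the body of a vertical bar only the vertical channel
#' responds; horizontal responses appear only near the bar's terminators.
#'
#' @param img A `luminance_image`.
#' @param sigma_deg Gaussian envelope width of the kernels (deg).
#' @param support_deg Kernel support (deg); half-support is rounded up to
#'   pixels with a floor of 2 px.
#' @return A `channel_map`: list with `energy` (rows x cols x 4 array,
#'   channels per [channel_names()]), and the image geometry (`ppd`, `row0`,
#'   `col0`).
#' @export
oriented_response <- function(img, sigma_deg = 0.06, support_deg = 0.3) {
  axes <- c(vertical = 90, horizontal = 0, diag45 = 45, diag135 = 135)
  nr <- nrow(img$grid); nc <- ncol(img$grid)
  energy <- array(0, dim = c(nr, nc, 4L),
                  dimnames = list(NULL, NULL, channel_names()))
  for (i in seq_along(axes)) {
    kp <- make_kernel_pair(axes[[i]], img$ppd, sigma_deg, support_deg)
    o <- conv2_same(img$grid, kp$odd)
    e <- conv2_same(img$grid, kp$even)
    energy[, , i] <- sqrt(o^2 + e^2)
  }
  structure(list(energy = energy, ppd = img$ppd,
                 row0 = img$row0, col0 = img$col0),
            class = "channel_map")
}

#' @export
print.channel_map <- function(x, ...) {
  cat("<channel_map>", paste(dim(x$energy)[1:2], collapse = " x "),
      "px, peak energy", signif(max(x$energy), 3), "\n")
  invisible(x)
}

# shared temporal gain profile g(t), t = 1..end_ms (all units have the same
# time constants, so activity(p, c, t) = static(p, c) * g(t))
temporal_profile <- function(clock, tau_rise = 20, tau_decay = 60) {
  tt <- seq_len(clock$end_ms)
  g <- numeric(clock$end_ms)
  a <- 0
  for (t in tt) {
    drive <- if (t > clock$onset_ms && t <= clock$offset_ms) 1 else 0
    tau <- if (drive > 0) tau_rise else tau_decay
    a <- a + clock$dt_ms / tau * (drive - a)
    g[t] <- a
  }
  g
}

#' Evolve a static channel map through the rate dynamic
#'
#' Each unit follows `da/dt = (drive - a)/tau_r` while the stimulus is on
#' (drive = static response) and decays with time constant `tau_d` after
#' offset. With the defaults the response reaches >= 90% of its asymptote by
#' 100 ms and is still positive 60 ms after offset.
#'
#' @param static A `channel_map` from [oriented_response()].
#' @param clock A [simulation_clock()].
#' @param tau_rise,tau_decay Rise/decay time constants (ms).
#' @return An `orientation_field`: the static map, the scalar temporal gain
#'   profile, and the clock.
#' @export
evolve <- function(static, clock = simulation_clock(),
                   tau_rise = 20, tau_decay = 60) {
  stopifnot(inherits(static, "channel_map"), inherits(clock, "simulation_clock"))
  structure(list(static = static,
                 profile = temporal_profile(clock, tau_rise, tau_decay),
                 clock = clock),
            class = "orientation_field")
}

#' Instantaneous activity of an orientation field
#' @param field An `orientation_field`.
#' @param t Time in ms (`1 <= t <= end_ms`).
#' @return Rows x cols x 4 activity array.
#' @export
field_activity <- function(field, t) {
  stopifnot(t >= 1, t <= field$clock$end_ms)
  field$static$energy * field$profile[[t]]
}

#' Accumulated activity over the trailing window
#'
#' Discrete sum of activity over `(t - window, t]`, the model analogue of
#' accumulated spike counts over the preceding 20 ms.
#'
#' @param field An `orientation_field`.
#' @param t Window end time in ms.
#' @param window_ms Window length; defaults to the clock's.
#' @return A `channel_map` whose `energy` holds the per-channel window sums.
#' @export
accumulate <- function(field, t, window_ms = field$clock$window_ms) {
  if (t < window_ms || t > field$clock$end_ms) {
    stop("accumulation time ", t, " outside [window, end_ms]")
  }
  scale <- sum(field$profile[seq.int(t - window_ms + 1L, t)])
  out <- field$static
  out$energy <- out$energy * scale
  out
}
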