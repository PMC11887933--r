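#' @title Vernier-offset template decoding
#' @name decision
#' @description
#' The decision variable is the difference between the normalized match of
#' the default-layer (Layer 0) vertical-channel activity to a right-offset
#' vernier template and to a left-offset template, averaged over the
#' post-offset readout windows. Because the templates pool everything inside
#' their support, ungrouped flanker activity left in Layer 0 dilutes the
#' match (crowding); segmentation that removes the flankers restores it
#' (uncrowding).
NULL

#' Decision / template parameters
#'
#' @param support_factor The template support is a square window of
#'   `support_factor` times the vernier length, centred on the vernier; 1.5
#'   admits the flanker columns at 0.4-1.2 deg but excludes the Pacmans.
#' @param blur_deg Gaussian tolerance blur applied to the templates (deg).
#' @return An object of class `decision_params`.
#' @export
decision_params <- function(support_factor = 1.5, blur_deg = 0.1) {
  stopifnot(support_factor > 0, blur_deg >= 0)
  structure(list(support_factor = support_factor, blur_deg = blur_deg),
            class = "decision_params")
}

gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  k <- max(1L, as.integer(ceiling(3 * sigma_px)))
  g <- exp(-(-k:k)^2 / (2 * sigma_px^2))
  g <- g / sum(g)
  kern <- outer(g, g)
  conv2_same(m, kern)
}

# matrix indices of the square template support window, symmetric about the
# centre column so that mirroring maps the support onto itself
support_window <- function(map, vspec, params) {
  half_px <- as.integer(floor(params$support_factor * vspec$length_deg / 2 *
                                map$ppd + 1e-9))
  rows <- (map$row0 - half_px):(map$row0 + half_px)
  cols <- (map$col0 - half_px):(map$col0 + half_px)
  rows <- rows[rows >= 1 & rows <= dim(map$energy)[1]]
  cols <- cols[cols >= 1 & cols <= dim(map$energy)[2]]
  list(rows = rows, cols = cols)
}

#' Build the left/right vernier templates
#'
#' The right template is the vertical-channel oriented energy of an isolated
#' right-offset vernier, blurred by the tolerance kernel, cropped to the
#' support window and normalized to unit energy. The left template is its
#' exact horizontal mirror about the upper-segment column.
#'
#' @param vspec A [vernier_spec()] (offset direction is ignored; the right
#'   template is always built from a right offset).
#' @param config A [display_config()].
#' @param params A [decision_params()].
#' @return A `vernier_template`: list with `right`, `left` (matrices),
#'   `rows`, `cols` (matrix indices of the support in full-field maps).
#' @export
build_templates <- function(vspec, config = display_config(),
                            params = decision_params()) {
  vr <- vernier_spec(eccentricity_deg = vspec$eccentricity_deg,
                     length_deg = vspec$length_deg,
                     width_arcsec = vspec$width_arcsec,
                     offset_deg = vspec$offset_deg,
                     offset_direction = "right")
  spec <- structure(list(condition = "VERNIER_ONLY", vernier = vr,
                         flankers = NULL, pacmen = NULL),
                    class = "stimulus_spec")
  resp <- oriented_response(render(spec, config))
  win <- support_window(resp, vr, params)
  tmpl <- gaussian_blur(resp$energy[, , "vertical"],
                        params$blur_deg * config$pixels_per_degree)
  right <- tmpl[win$rows, win$cols, drop = FALSE]
  right <- right / sqrt(sum(right^2))
  left <- right[, rev(seq_len(ncol(right))), drop = FALSE]
  structure(list(right = right, left = left,
                 rows = win$rows, cols = win$cols),
            class = "vernier_template")
}

#' Evidence for a right vernier from Layer-0 activity
#'
#' For each readout window (trailing windows from stimulus offset to the end
#' of the simulation) the accumulated vertical-channel activity at Layer-0
#' boundary nodes inside the template support is matched against the right
#' and left templates; the per-window evidence is the difference of the two
#' matches normalized by the activity norm, and the score is the mean over
#' windows. A window with no active Layer-0 node in the support contributes
#' 0 (with a warning).
#'
#' @param field An `orientation_field` from [evolve()].
#' @param bg The `boundary_graph` built from the field's accumulated map.
#' @param state The `segmentation_state` from [spread()].
#' @param tmpl A `vernier_template` from [build_templates()].
#' @return An `evidence_score`: list with `value` (mean over windows) and
#'   `per_window` (data frame: t_ms, evidence).
#' @export
evidence <- function(field, bg, state, tmpl) {
  clock <- field$clock
  times <- seq(clock$offset_ms + clock$window_ms, clock$end_ms,
               by = clock$window_ms)
  nr <- dim(field$static$energy)[1]
  nc <- dim(field$static$energy)[2]
  # node mask per layer-0: matrix TRUE where a layer-0 node sits
  node_lin <- (bg$nodes$col + field$static$col0 - 1L) * nr +
    (bg$nodes$row + field$static$row0)
  vals <- numeric(length(times))
  empty <- FALSE
  for (i in seq_along(times)) {
    t <- times[i]
    acc <- accumulate(field, t)$energy[, , "vertical"]
    mask <- matrix(FALSE, nr, nc)
    mask[node_lin[layer_at(state, t) == 0L]] <- TRUE
    a <- acc * mask
    a <- a[tmpl$rows, tmpl$cols, drop = FALSE]
    nrm <- sqrt(sum(a^2))
    if (nrm == 0) {
      empty <- TRUE
      vals[i] <- 0
    } else {
      vals[i] <- (sum(a * tmpl$right) - sum(a * tmpl$left)) / nrm
    }
  }
  if (empty) warning("no active Layer-0 nodes in the template support for ",
                     "at least one readout window; evidence 0 there")
  structure(list(value = mean(vals),
                 per_window = data.frame(t_ms = times, evidence = vals)),
            class = "evidence_score")
}

#' @export
print.evidence_score <- function(x, ...) {
  cat("<evidence_score>", signif(x$value, 4), "over",
      nrow(x$per_window), "windows\n")
  invisible(x)
}

#' Run the full model pipeline for one condition
#'
#' Render, filter, evolve, group, select, spread, decode.
#'
#' @param condition One of [condition_names()].
#' @param offset_direction Vernier offset direction.
#' @param config A [display_config()].
#' @param clock A [simulation_clock()].
#' @param bipole A [bipole_params()].
#' @param dparams A [decision_params()].
#' @param selection_radius_deg Selection disk radius (deg).
#' @param speed_deg_per_ms Selection spreading speed.
#' @param enable_spread If `FALSE`, segmentation is ablated (all nodes stay
#'   in Layer 0).
#' @return List with `condition`, `evidence` (scalar), `score`
#'   (`evidence_score`), `graph`, `state`, `spec`, `field`.
#' @export
model_condition <- function(condition, offset_direction = "right",
                            config = display_config(),
                            clock = simulation_clock(),
                            bipole = bipole_params(),
                            dparams = decision_params(),
                            selection_radius_deg = 1.5,
                            speed_deg_per_ms = 0.1,
                            enable_spread = TRUE) {
  spec <- make_condition_spec(condition, offset_direction)
  img <- render(spec, config)
  field <- evolve(oriented_response(img), clock)
  bg <- build_graph(accumulate(field, clock$offset_ms), bipole)
  signal <- place_selection(spec, selection_radius_deg)
  state <- spread(bg, signal, clock, speed_deg_per_ms, enabled = enable_spread)
  tmpl <- build_templates(spec$vernier, config, dparams)
  sc <- evidence(field, bg, state, tmpl)
  list(condition = condition, evidence = sc$value, score = sc,
       graph = bg, state = state, spec = spec, field = field)
}

#' Run the condition battery
#'
#' @param conditions Conditions to run (default: all eight).
#' @param offset_direction Vernier offset direction.
#' @param ... Passed to [model_condition()].
#' @return Data frame with columns `condition` and `evidence`, one row per
#'   condition, plus attribute `details` (the per-condition model outputs).
#'   A condition whose pipeline fails is reported with `NA` evidence and the
#'   error message; the others still run.
#' @export
run_battery <- function(conditions = condition_names(),
                        offset_direction = "right", ...) {
  details <- vector("list", length(conditions))
  names(details) <- conditions
  ev <- rep(NA_real_, length(conditions))
  err <- rep(NA_character_, length(conditions))
  for (i in seq_along(conditions)) {
    res <- tryCatch(
      suppressWarnings(model_condition(conditions[i], offset_direction, ...)),
      error = function(e) e)
    if (inherits(res, "error")) {
      err[i] <- conditionMessage(res)
      message("condition ", conditions[i], " failed: ", err[i])
    } else {
      details[[i]] <- res
      ev[i] <- res$evidence
    }
  }
  out <- data.frame(condition = conditions, evidence = ev, error = err)
  attr(out, "details") <- details
  out
}

#' Correlate model evidence with empirical accuracies
#'
#' @param evidence_table Data frame with `condition` and `evidence` (as from
#'   [run_battery()]).
#' @param accuracy_table Data frame with `condition` and `accuracy`
#'   (proportion correct per condition, e.g. read from a user CSV).
#' @return List with `r` (Pearson correlation), `n` (shared conditions) and
#'   the merged table.
#' @export
correlate_with_empirical <- function(evidence_table, accuracy_table) {
  stopifnot(all(c("condition", "evidence") %in% names(evidence_table)),
            all(c("condition", "accuracy") %in% names(accuracy_table)))
  m <- merge(evidence_table[c("condition", "evidence")],
             accuracy_table[c("condition", "accuracy")], by = "condition")
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 3) {
    stop("insufficient data: need >= 3 shared conditions, got ", nrow(m))
  }
  list(r = stats::cor(m$evidence, m$accuracy), n = nrow(m), table = m)
}
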