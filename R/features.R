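#' Geometric features of a swim trajectory
#'
#' Computes the scale-free summaries used by the rule-based classifier:
#' occupancy of the outer 10% wall annulus, number of distinct pool
#' quadrants visited, path efficiency (straight start-to-end distance over
#' path length), turning-direction consistency, mean absolute turning angle
#' per step, the radius of the path's minimal enclosing circle relative to
#' the pool, mean radial position, escape latency and mean swim speed.
#' Turning angles come from consecutive displacement vectors; samples moving
#' less than 1e-6 m are skipped because their heading is undefined.
#'
#' @param traj a `swim_trajectory` (see [simulate_trajectory()]), or any
#'   tibble with `time_s`, `x_m`, `y_m` plus a `geometry` attribute.
#' @return a one-row tibble of features together with the trial metadata
#'   (`mouse_id`, `group`, `day`, `trial`, `label`, `escaped`).
#' @examples
#' compute_features(simulate_trajectory("Thigmotaxis", seed = 2))
#' @export
compute_features <- function(traj) {
  if (nrow(traj) < 3) abort("a trajectory needs at least 3 points")
  geometry <- attr(traj, "geometry")
  .check_geometry(geometry)
  R <- geometry$pool_radius
  x <- traj$x_m
  y <- traj$y_m
  t <- traj$time_s
  r <- sqrt(x^2 + y^2)

  dx <- diff(x)
  dy <- diff(y)
  seg <- sqrt(dx^2 + dy^2)
  path_len <- sum(seg)
  chord <- sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
  efficiency <- if (path_len < 1e-12) 0 else min(chord / path_len, 1)

  keep <- seg >= 1e-6
  headings <- atan2(dy[keep], dx[keep])
  turns <- diff(headings)
  turns <- atan2(sin(turns), cos(turns))  # wrap to (-pi, pi]
  signed <- turns[abs(turns) > 1e-9]
  consistency <- if (length(signed) == 0) {
    1
  } else {
    max(mean(signed > 0), mean(signed < 0))
  }
  mean_abs_turn <- if (length(turns) == 0) 0 else mean(abs(turns))

  duration <- t[length(t)] - t[1]
  tibble(
    wall_zone_fraction = mean(r > 0.9 * R),
    quadrant_count = dplyr::n_distinct(.quadrant(x, y)),
    path_efficiency = efficiency,
    turn_sign_consistency = consistency,
    mean_abs_turn = mean_abs_turn,
    spatial_extent_ratio = min(.min_enclosing_radius(cbind(x, y)) / R, 1),
    mean_radial_position = min(mean(r) / R, 1),
    latency_s = attr(traj, "latency_s") %||% t[length(t)],
    mean_speed = if (duration > 0) path_len / duration else 0,
    escaped = isTRUE(attr(traj, "escaped")),
    mouse_id = attr(traj, "mouse_id") %||% NA_character_,
    group = attr(traj, "group") %||% NA_character_,
    day = attr(traj, "day") %||% NA_integer_,
    trial = attr(traj, "trial") %||% NA_integer_,
    label = attr(traj, "label") %||% NA_character_
  )
}

#' Feature table for a whole cohort
#'
#' Applies [compute_features()] to every trial of a simulated cohort.
#'
#' @param cohort a `swim_cohort` (see [simulate_cohort()]).
#' @return a tibble with one feature row per trial.
#' @export
cohort_features <- function(cohort) {
  geometry <- attr(cohort, "geometry")
  .check_geometry(geometry)
  rows <- purrr::pmap(
    list(cohort$path, cohort$mouse_id, cohort$group, cohort$day,
         cohort$trial, cohort$label, cohort$escaped, cohort$latency_s),
    function(path, mouse_id, group, day, trial, label, escaped, latency_s) {
      tr <- structure(path, geometry = geometry, label = label,
                      escaped = escaped, latency_s = latency_s,
                      mouse_id = mouse_id, group = group, day = day,
                      trial = trial)
      compute_features(tr)
    })
  dplyr::bind_rows(rows)
}

#' Classification thresholds for the rule-based labeller
#'
#' Numeric operationalization of the verbal class definitions: the wall
#' annulus occupancy that counts as wall hugging, the path efficiency of a
#' straight escape, the turning-sign consistency of sustained circling, the
#' enclosing-circle ratio of a confined twisting path, and its minimum
#' turning rate.
#'
#' @param wall_zone minimum wall-annulus occupancy for thigmotaxis.
#' @param efficiency minimum path efficiency for direct swim.
#' @param extent maximum enclosing-circle ratio for rotating.
#' @param turn minimum mean absolute turning angle (rad/step) for rotating.
#' @param sign_consistency minimum turning-sign consistency for circling.
#' @param radial maximum mean radial position for circling.
#' @return a named list of thresholds.
#' @export
rule_thresholds <- function(wall_zone = 0.8, efficiency = 0.8, extent = 0.5,
                            turn = 0.4, sign_consistency = 0.75,
                            radial = 0.9) {
  list(wall_zone = wall_zone, efficiency = efficiency, extent = extent,
       turn = turn, sign_consistency = sign_consistency, radial = radial)
}

#' Rule-based strategy classification
#'
#' Assigns exactly one strategy class per trial by a fixed-priority decision
#' list: (1) thigmotaxis if the path stays in the outer wall annulus at
#' least `wall_zone` of the time; (2) direct swim if the path is efficient
#' and ends on the platform; (3) rotating if the path is confined
#' (`spatial_extent_ratio <= extent`) with a high turning rate; (4) circling
#' if turning direction is consistent away from the wall; (5) focal search
#' if at most two quadrants were visited; (6) scanning otherwise.
#'
#' @param features a feature tibble from [compute_features()] or
#'   [cohort_features()] (any number of rows).
#' @param thresholds a [rule_thresholds()] list.
#' @return character vector of predicted strategy labels, one per row.
#' @examples
#' fv <- compute_features(simulate_trajectory("Circling", seed = 3))
#' classify_by_rules(fv)
#' @export
classify_by_rules <- function(features, thresholds = rule_thresholds()) {
  th <- thresholds
  dplyr::case_when(
    features$wall_zone_fraction >= th$wall_zone ~ "Thigmotaxis",
    features$path_efficiency >= th$efficiency & features$escaped ~ "Direct swim",
    features$spatial_extent_ratio <= th$extent &
      features$mean_abs_turn > th$turn ~ "Rotating",
    features$turn_sign_consistency >= th$sign_consistency &
      features$mean_radial_position <= th$radial ~ "Circling",
    features$quadrant_count <= 2 ~ "Focal search",
    TRUE ~ "Scanning"
  )
}
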