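#' Simulation parameters
#'
#' Kinematic settings for the trajectory simulator. The time step gives
#' roughly 1200 samples over a full 120 s trial; swim speed defaults to the
#' typical mouse value of 0.117 m/s. Per-class kinematics control how each
#' strategy class is generated (drift strengths, turning-angle spread, zone
#' constraints, speed multipliers) and are exposed so that degenerate
#' variants (for example a pure tangential wall-following path) can be
#' constructed in tests.
#'
#' @param dt time step in seconds.
#' @param max_duration trial cap in seconds (trials end at platform contact
#'   or at this cap).
#' @param speed_mean,speed_sd per-step swim speed distribution (m/s).
#' @param per_class named list of per-class kinematic parameters; entries
#'   are merged over the defaults.
#' @return an object of class `sim_params`.
#' @examples
#' sim_params(dt = 0.05)
#' @export
sim_params <- function(dt = 0.1, max_duration = 120,
                       speed_mean = 0.117, speed_sd = 0.015,
                       per_class = list()) {
  if (dt <= 0) abort("dt must be positive")
  if (max_duration <= 0) abort("max_duration must be positive")
  if (dt >= max_duration) abort("dt must be smaller than max_duration")
  if (speed_mean <= 0) abort("speed_mean must be positive")
  if (speed_sd < 0) abort("speed_sd must be non-negative")
  defaults <- list(
    "Thigmotaxis" = list(radius_frac = 0.95, radial_sd = 0.015,
                         reverse_prob = 0.004, speed_mult = 0.9),
    "Scanning" = list(wp_rmin = 0.3, wp_rmax = 0.8, heading_sd = 0.1,
                      speed_mult = 1.05, quadrant_quota = 3),
    "Circling" = list(radius_min = 0.62, radius_max = 0.8, heading_sd = 0.02,
                      speed_mult = 1.0),
    "Focal search" = list(region_rmax = 0.85, heading_sd = 0.06,
                          speed_mult = 0.95, avoid_time = 15),
    "Rotating" = list(center_frac = 0.6, confine_frac = 0.18, turn_sd = 1.1,
                      speed_mult = 0.85),
    "Direct swim" = list(heading_sd = 0.12, speed_mult = 1.3)
  )
  .check_labels(names(per_class))
  for (nm in names(per_class)) {
    defaults[[nm]][names(per_class[[nm]])] <- per_class[[nm]]
  }
  structure(
    list(dt = dt, max_duration = max_duration, speed_mean = speed_mean,
         speed_sd = speed_sd, per_class = defaults),
    class = "sim_params"
  )
}

.check_params <- function(params) {
  if (!inherits(params, "sim_params")) abort("params must be a sim_params object")
  invisible(params)
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(1, 0) else v / n
}

.on_platform <- function(p, geometry) {
  sum((p - geometry$platform_center)^2) <= geometry$platform_radius^2
}

.step_len <- function(params, mult) {
  sp <- stats::rnorm(1, params$speed_mean * mult, params$speed_sd)
  max(sp, 0.25 * params$speed_mean * mult) * params$dt
}

# squared distance from point cc to segment a-b
.seg_dist2 <- function(a, b, cc) {
  ab <- b - a
  denom <- sum(ab^2)
  t <- if (denom < 1e-18) 0 else max(0, min(1, sum((cc - a) * ab) / denom))
  sum((a + t * ab - cc)^2)
}

.quadrant <- function(x, y) {
  ifelse(x >= 0 & y >= 0, 1L,
         ifelse(x < 0 & y >= 0, 2L,
                ifelse(x < 0 & y < 0, 3L, 4L)))
}

# ---- per-class path generators ------------------------------------------
# Each returns the points matrix (first row = start), stopping at platform
# contact or after n_max steps. All draw from the current RNG stream.

.gen_direct <- function(start, geometry, params, par, n_max) {
  pts <- matrix(NA_real_, n_max + 1, 2)
  pts[1, ] <- p <- start
  cc <- geometry$platform_center
  for (k in seq_len(n_max)) {
    h <- atan2(cc[2] - p[2], cc[1] - p[1]) + stats::rnorm(1, 0, par$heading_sd)
    ds <- .step_len(params, par$speed_mult)
    p <- reflect_at_wall(p, ds * c(cos(h), sin(h)), geometry)
    pts[k + 1, ] <- p
    if (.on_platform(p, geometry)) return(pts[seq_len(k + 1), , drop = FALSE])
  }
  pts
}

.gen_thigmotaxis <- function(start, geometry, params, par, n_max) {
  R <- geometry$pool_radius
  pts <- matrix(NA_real_, n_max + 1, 2)
  pts[1, ] <- start
  phi <- atan2(start[2], start[1])
  dirn <- sample(c(-1, 1), 1)
  for (k in seq_len(n_max)) {
    if (par$reverse_prob > 0 && stats::runif(1) < par$reverse_prob) {
      dirn <- -dirn
    }
    r <- par$radius_frac * R + stats::rnorm(1, 0, par$radial_sd * R)
    r <- min(max(r, 0.905 * R), 0.995 * R)
    ds <- .step_len(params, par$speed_mult)
    phi <- phi + dirn * ds / r
    p <- r * c(cos(phi), sin(phi))
    pts[k + 1, ] <- p
    if (.on_platform(p, geometry)) return(pts[seq_len(k + 1), , drop = FALSE])
  }
  pts
}

.gen_circling <- function(start, geometry, params, par, n_max) {
  R <- geometry$pool_radius
  pts <- matrix(NA_real_, n_max + 1, 2)
  pts[1, ] <- start
  phi <- atan2(start[2], start[1])
  r_t <- sqrt(sum(start^2))
  r0 <- stats::runif(1, par$radius_min, par$radius_max) * R
  dirn <- sample(c(-1, 1), 1)
  p <- start
  h <- NA_real_
  for (k in seq_len(n_max)) {
    ds <- .step_len(params, par$speed_mult)
    if (is.na(h) && r_t > r0 + 1e-9) {
      # inward spiral from the release point down to the circling radius
      dr <- min(0.5 * ds, r_t - r0)
      r_t <- r_t - dr
      phi <- phi + dirn * sqrt(max(ds^2 - dr^2, 0)) / r_t
      p <- r_t * c(cos(phi), sin(phi))
    } else {
      # heading integration with steering bounded to half the nominal
      # curvature: the turning direction can never flip, while the radius
      # is pulled back toward the target circle
      if (is.na(h)) h <- phi + dirn * pi / 2
      curv <- ds / r0
      steer <- min(max(5 * (sqrt(sum(p^2)) - r0), -0.5 * curv), 0.5 * curv)
      h <- h + dirn * (curv + steer) + stats::rnorm(1, 0, par$heading_sd)
      p <- reflect_at_wall(p, ds * c(cos(h), sin(h)), geometry)
    }
    pts[k + 1, ] <- p
    if (.on_platform(p, geometry)) return(pts[seq_len(k + 1), , drop = FALSE])
  }
  pts
}

.gen_rotating <- function(start, geometry, params, par, n_max) {
  R <- geometry$pool_radius
  pts <- matrix(NA_real_, n_max + 1, 2)
  pts[1, ] <- p <- start
  c0 <- par$center_frac * R * .unit(start)
  confine <- par$confine_frac * R
  h <- atan2(c0[2] - p[2], c0[1] - p[1])
  for (k in seq_len(n_max)) {
    ds <- .step_len(params, par$speed_mult)
    if (sqrt(sum((p - c0)^2)) > confine) {
      h <- atan2(c0[2] - p[2], c0[1] - p[1]) + stats::rnorm(1, 0, 0.3)
    } else {
      h <- h + stats::rnorm(1, 0, par$turn_sd)
    }
    p <- reflect_at_wall(p, ds * c(cos(h), sin(h)), geometry)
    pts[k + 1, ] <- p
    if (.on_platform(p, geometry)) return(pts[seq_len(k + 1), , drop = FALSE])
  }
  pts
}

# the four closed half-discs (pairs of adjacent quadrants), keyed by the
# inward normal of the bounding diameter
.halves <- list(
  list(a = c(0, 1), quads = c(1L, 2L)),
  list(a = c(0, -1), quads = c(3L, 4L)),
  list(a = c(1, 0), quads = c(1L, 4L)),
  list(a = c(-1, 0), quads = c(2L, 3L))
)

.gen_focal <- function(start, geometry, params, par, n_max) {
  R <- geometry$pool_radius
  cc <- geometry$platform_center
  q0 <- .quadrant(start[1], start[2])
  cand <- Filter(function(h) q0 %in% h$quads, .halves)
  half <- cand[[sample.int(length(cand), 1)]]
  a <- half$a
  margin <- geometry$platform_radius + 0.07 * R
  new_wp <- function(from, avoid) {
    for (i in 1:30) {
      r <- par$region_rmax * R * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      w <- r * c(cos(th), sin(th))
      if (sum(w * a) < 0.05 * R) next
      if (sqrt(sum((w - cc)^2)) < margin) next
      if (avoid && .seg_dist2(from, w, cc) < margin^2) next
      return(w)
    }
    # fall back to a point deep inside the half, away from the platform
    0.4 * R * a
  }
  pts <- matrix(NA_real_, n_max + 1, 2)
  pts[1, ] <- p <- start
  w <- new_wp(p, TRUE)
  for (k in seq_len(n_max)) {
    ds <- .step_len(params, par$speed_mult)
    if (sqrt(sum((w - p)^2)) < 1.5 * ds) {
      w <- new_wp(p, (k * params$dt) < par$avoid_time)
    }
    h <- atan2(w[2] - p[2], w[1] - p[1]) + stats::rnorm(1, 0, par$heading_sd)
    p <- reflect_at_wall(p, ds * c(cos(h), sin(h)), geometry)
    # mirror across the bounding diameter so the path stays in two quadrants
    s <- sum(p * a)
    if (s < 1e-12) p <- p - 2 * min(s, 0) * a + 1e-9 * a
    pts[k + 1, ] <- p
    if (.on_platform(p, geometry)) return(pts[seq_len(k + 1), , drop = FALSE])
  }
  pts
}

.gen_scanning <- function(start, geometry, params, par, n_max) {
  R <- geometry$pool_radius
  cc <- geometry$platform_center
  margin <- geometry$platform_radius + 0.05 * R
  quad_wp <- function(q) {
    # a point well inside quadrant q (angular margin keeps the arrival
    # tolerance from crossing a quadrant boundary)
    th0 <- (q - 1) * pi / 2
    th <- stats::runif(1, th0 + 0.25, th0 + pi / 2 - 0.25)
    r <- R * sqrt(stats::runif(1, par$wp_rmin^2, par$wp_rmax^2))
    r * c(cos(th), sin(th))
  }
  free_wp <- function() {
    r <- par$wp_rmax * R * sqrt(stats::runif(1))
    th <- stats::runif(1, 0, 2 * pi)
    r * c(cos(th), sin(th))
  }
  quota <- sample.int(4)[seq_len(par$quadrant_quota)]
  pending <- quota
  pts <- matrix(NA_real_, n_max + 1, 2)
  pts[1, ] <- p <- start
  next_wp <- function(from) {
    if (length(pending) > 0) {
      q <- pending[1]
      for (i in 1:30) {
        w <- quad_wp(q)
        if (.seg_dist2(from, w, cc) >= margin^2) return(w)
      }
      return(quad_wp(q))
    }
    free_wp()
  }
  w <- next_wp(p)
  for (k in seq_len(n_max)) {
    ds <- .step_len(params, par$speed_mult)
    if (sqrt(sum((w - p)^2)) < 1.5 * ds) {
      if (length(pending) > 0) pending <- pending[-1]
      w <- next_wp(p)
    }
    h <- atan2(w[2] - p[2], w[1] - p[1]) + stats::rnorm(1, 0, par$heading_sd)
    p <- reflect_at_wall(p, ds * c(cos(h), sin(h)), geometry)
    pts[k + 1, ] <- p
    # while quadrant waypoints are pending the platform is routed around,
    # so incidental contact before three quadrants are visited is avoided
    if (length(pending) == 0 && .on_platform(p, geometry)) {
      return(pts[seq_len(k + 1), , drop = FALSE])
    }
  }
  pts
}

# ---- public simulation API ----------------------------------------------

#' Simulate one labelled swim trajectory
#'
#' Generates a time-stamped swim path of the requested strategy class inside
#' the pool. Each class has a dedicated generative rule built from its
#' defining geometric property: wall hugging in the outer annulus
#' (thigmotaxis), small twisting loops in a confined patch (rotating),
#' linear search restricted to two adjacent quadrants (focal search), wide
#' jagged foraging across at least three quadrants (scanning), sustained
#' one-directional circling at intermediate radius (circling), and a fast
#' straight run to the platform (direct swim). The trial ends at platform
#' contact or at the 120 s cap. Fully reproducible from `seed`.
#'
#' @param label strategy class name (see [strategy_levels()]).
#' @param geometry a [pool_geometry()].
#' @param params a [sim_params()].
#' @param seed integer seed for this trajectory.
#' @param start_point release point; defaults to the first of
#'   `geometry$start_points`.
#' @param mouse_id,group,day,trial optional trial metadata carried on the
#'   result.
#' @return a `swim_trajectory`: a tibble with columns `time_s`, `x_m`,
#'   `y_m` and attributes `geometry`, `label`, `escaped`, `latency_s` and
#'   the metadata fields.
#' @examples
#' traj <- simulate_trajectory("Direct swim", seed = 1)
#' attr(traj, "escaped")
#' @export
simulate_trajectory <- function(label, geometry = pool_geometry(),
                                params = sim_params(), seed = 1,
                                start_point = NULL,
                                mouse_id = NA_character_,
                                group = NA_character_,
                                day = NA_integer_, trial = NA_integer_) {
  .check_labels(label)
  .check_geometry(geometry)
  .check_params(params)
  start <- start_point %||% geometry$start_points[[1]]
  par <- params$per_class[[label]]
  n_max <- floor(params$max_duration / params$dt)
  gen <- switch(label,
    "Thigmotaxis" = .gen_thigmotaxis,
    "Scanning" = .gen_scanning,
    "Circling" = .gen_circling,
    "Focal search" = .gen_focal,
    "Rotating" = .gen_rotating,
    "Direct swim" = .gen_direct
  )
  pts <- .with_seed(seed, gen(start, geometry, params, par, n_max))
  n <- nrow(pts)
  escaped <- .on_platform(pts[n, ], geometry)
  latency <- if (escaped) (n - 1) * params$dt else params$max_duration
  out <- tibble(time_s = (seq_len(n) - 1) * params$dt,
                x_m = pts[, 1], y_m = pts[, 2])
  structure(out,
            class = c("swim_trajectory", class(out)),
            geometry = geometry, label = label, escaped = escaped,
            latency_s = latency, mouse_id = mouse_id, group = group,
            day = day, trial = trial, seed = seed)
}

#' Cohort specification
#'
#' Describes a simulated study cohort: group sizes, the per-(group, stage)
#' strategy-class mixtures, and the strength of per-mouse correlation. Class
#' mixtures default to the early/late frequency tables of a 22 control + 28
#' lesion cohort. Each mouse receives its own mixture drawn from a
#' Dirichlet distribution centred on the group mixture
#' (`p_mouse ~ Dirichlet(concentration * p_group)`), which preserves the
#' group mixture in expectation while making strategy use a stable
#' per-animal trait; stage-specific draws share the same underlying uniforms
#' so a wall-hugging mouse stays wall-hugging across stages. On top of the
#' Dirichlet tilt, each mouse carries an anxious/bold phenotype that
#' transfers probability mass between thigmotaxis and direct swim (capped
#' by the smaller component and symmetric across mice, so group mixtures
#' are preserved exactly in expectation); its amplitude is
#' `trait_strength`.
#'
#' @param n_control,n_lesion number of mice per group.
#' @param class_mixture a tibble as returned by [default_class_mixtures()]
#'   with columns `group`, `stage`, `label`, `prob`.
#' @param concentration Dirichlet concentration for the per-mouse tilt;
#'   larger values give more homogeneous mice.
#' @param trait_strength amplitude in [0, 1] of the anxious/bold
#'   thigmotaxis-vs-direct-swim transfer; 0 disables the phenotype.
#' @param seed integer master seed; all labels and paths derive from it.
#' @return an object of class `cohort_spec`.
#' @examples
#' cohort_spec(n_control = 4, n_lesion = 4)
#' @export
cohort_spec <- function(n_control = 22, n_lesion = 28,
                        class_mixture = default_class_mixtures(),
                        concentration = 15, trait_strength = 0.9,
                        seed = 1) {
  if (trait_strength < 0 || trait_strength > 1) {
    abort("trait_strength must lie in [0, 1]")
  }
  if (n_control < 1 || n_lesion < 1) {
    abort("both groups must contain at least one mouse")
  }
  mix <- as_tibble(class_mixture)
  for (g in c("control", "lesion")) {
    for (s in c("early", "late")) {
      p <- mix$prob[mix$group == g & mix$stage == s]
      if (length(p) != 6 || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
        abort("each (group, stage) mixture must be 6 non-negative probabilities summing to 1")
      }
    }
  }
  structure(
    list(n_control = n_control, n_lesion = n_lesion, class_mixture = mix,
         concentration = concentration, trait_strength = trait_strength,
         seed = seed),
    class = "cohort_spec"
  )
}

#' Default strategy-class mixtures
#'
#' Early-stage (days 1-2) and late-stage (days 4-5) class frequencies for
#' control and lesion groups, expressed as probabilities. These are the
#' per-group class proportions of a 50-mouse training study (220 control and
#' 280 lesion trials per stage).
#'
#' @return a tibble with columns `group`, `stage`, `label`, `prob`.
#' @export
default_class_mixtures <- function() {
  lv <- strategy_levels()
  # counts per class in score order (T, S, C, F, R, D)
  counts <- list(
    control_early = c(15, 68, 31, 41, 41, 24),
    lesion_early = c(30, 73, 54, 49, 44, 30),
    control_late = c(10, 18, 14, 49, 51, 78),
    lesion_late = c(16, 40, 37, 53, 57, 77)
  )
  out <- lapply(names(counts), function(nm) {
    parts <- strsplit(nm, "_")[[1]]
    tibble(group = parts[1], stage = parts[2], label = lv,
           prob = counts[[nm]] / sum(counts[[nm]]))
  })
  dplyr::bind_rows(out)
}

.mixture_vector <- function(mix, g, s) {
  m <- mix[mix$group == g & mix$stage == s, ]
  stats::setNames(m$prob[match(strategy_levels(), m$label)], strategy_levels())
}

#' Draw per-trial strategy labels for a cohort
#'
#' Samples the 5 days x 5 trials label schedule for every mouse. Days 1-2
#' use the early mixture, days 4-5 the late mixture, and day 3 the
#' arithmetic mean of the two. Per-mouse mixtures are Dirichlet tilts of the
#' group mixture (see [cohort_spec()]).
#'
#' @param spec a [cohort_spec()].
#' @return a tibble with columns `mouse_id`, `group`, `day`, `trial`,
#'   `label`.
#' @examples
#' draw_cohort_labels(cohort_spec(n_control = 2, n_lesion = 2))
#' @export
draw_cohort_labels <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("spec must be a cohort_spec")
  lv <- strategy_levels()
  conc <- spec$concentration
  mice <- dplyr::bind_rows(
    tibble(group = "control", idx = seq_len(spec$n_control)),
    tibble(group = "lesion", idx = seq_len(spec$n_lesion))
  )
  mice$mouse_id <- sprintf("%s_%03d", mice$group, mice$idx)
  rows <- vector("list", nrow(mice))
  for (i in seq_len(nrow(mice))) {
    g <- mice$group[i]
    p0e <- .mixture_vector(spec$class_mixture, g, "early")
    p0l <- .mixture_vector(spec$class_mixture, g, "late")
    rows[[i]] <- .with_seed(.derive_seed(spec$seed, i), {
      # shared uniforms -> comonotonic Gamma draws: each stage mixture is
      # exactly Dirichlet(conc * p0) yet tilts are correlated across stages
      u <- stats::runif(6)
      # anxious/bold phenotype: a symmetric transfer between the
      # thigmotaxis and direct-swim components (anxious mice hug walls
      # more and escape directly less, in both stages). The transfer has
      # zero mean and is capped by the smaller component, so every group
      # mixture is preserved exactly in expectation.
      w <- spec$trait_strength * (if (stats::runif(1) < 0.5) -1 else 1)
      ge <- stats::qgamma(u, shape = conc * p0e)
      gl <- stats::qgamma(u, shape = conc * p0l)
      pe <- if (sum(ge) > 0) ge / sum(ge) else p0e
      pl <- if (sum(gl) > 0) gl / sum(gl) else p0l
      te <- w * min(pe[1], pe[6])
      pe[1] <- pe[1] + te
      pe[6] <- pe[6] - te
      tl <- w * min(pl[1], pl[6])
      pl[1] <- pl[1] + tl
      pl[6] <- pl[6] - tl
      pm <- (pe + pl) / 2
      lab <- character(25)
      for (d in 1:5) {
        p <- if (d <= 2) pe else if (d >= 4) pl else pm
        lab[(d - 1) * 5 + 1:5] <- sample(lv, 5, replace = TRUE, prob = p)
      }
      tibble(mouse_id = mice$mouse_id[i], group = g,
             day = rep(1:5, each = 5), trial = rep(1:5, times = 5),
             label = lab)
    })
  }
  dplyr::bind_rows(rows)
}

#' Simulate a full training cohort
#'
#' Generates `n_mice x 5 days x 5 trials` labelled trajectories. Labels are
#' drawn by [draw_cohort_labels()]; each trial's path is then simulated with
#' its own derived seed, with the release point cycling through the four
#' perimeter start points across trials. The result is reproducible
#' trial-by-trial from the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @param geometry a [pool_geometry()].
#' @param params a [sim_params()].
#' @return a `swim_cohort` tibble with one row per trial: `mouse_id`,
#'   `group`, `day`, `trial`, `label`, `escaped`, `latency_s` and a `path`
#'   list-column of `time_s`/`x_m`/`y_m` tibbles. The pool geometry and
#'   simulation parameters are carried as attributes.
#' @examples
#' co <- simulate_cohort(cohort_spec(n_control = 1, n_lesion = 1, seed = 7))
#' nrow(co)  # 2 mice x 5 days x 5 trials
#' @export
simulate_cohort <- function(spec, geometry = pool_geometry(),
                            params = sim_params()) {
  if (!inherits(spec, "cohort_spec")) abort("spec must be a cohort_spec")
  .check_geometry(geometry)
  .check_params(params)
  labels <- draw_cohort_labels(spec)
  n <- nrow(labels)
  path <- vector("list", n)
  escaped <- logical(n)
  latency <- numeric(n)
  starts <- geometry$start_points
  for (i in seq_len(n)) {
    sp <- starts[[(labels$trial[i] - 1) %% length(starts) + 1]]
    tr <- simulate_trajectory(
      labels$label[i], geometry, params,
      seed = .derive_seed(spec$seed + 1000003, i),
      start_point = sp, mouse_id = labels$mouse_id[i],
      group = labels$group[i], day = labels$day[i], trial = labels$trial[i])
    path[[i]] <- tibble(time_s = tr$time_s, x_m = tr$x_m, y_m = tr$y_m)
    escaped[i] <- attr(tr, "escaped")
    latency[i] <- attr(tr, "latency_s")
  }
  out <- labels
  out$escaped <- escaped
  out$latency_s <- latency
  out$path <- path
  structure(out, class = c("swim_cohort", class(out)),
            geometry = geometry, params = params, spec = spec)
}

#' Trial metadata of a cohort without the paths
#'
#' @param cohort a `swim_cohort`.
#' @return the manifest tibble (one row per trial, no `path` column).
#' @export
cohort_manifest <- function(cohort) {
  out <- as_tibble(cohort)
  out$path <- NULL
  out
}

# stage -> day window used throughout the analyses
.stage_days <- function(stage) {
  switch(stage,
    early = c(1L, 2L),
    late = c(4L, 5L),
    abort("stage must be 'early' or 'late'")
  )
}
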