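# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities by the most literal method available so they share no
# code with the implementation under test.

# per-point quadrant membership scan over a polyline
oracle_quadrant_count <- function(x, y) {
  q <- integer(length(x))
  for (i in seq_along(x)) {
    if (x[i] >= 0 && y[i] >= 0) q[i] <- 1
    else if (x[i] < 0 && y[i] >= 0) q[i] <- 2
    else if (x[i] < 0 && y[i] < 0) q[i] <- 3
    else q[i] <- 4
  }
  length(unique(q))
}

# exact cell coverage: a segment marks a cell iff it intersects the closed
# unit square of that cell (Liang-Barsky clipping), so this enumerates the
# cells a continuous polyline passes through without any sampling
oracle_cell_count <- function(u, v) {
  hits_cell <- function(x0, y0, x1, y1, cx, cy) {
    dx <- x1 - x0
    dy <- y1 - y0
    t0 <- 0
    t1 <- 1
    for (pq in list(c(-dx, x0 - cx), c(dx, cx + 1 - x0),
                    c(-dy, y0 - cy), c(dy, cy + 1 - y0))) {
      p <- pq[1]
      q <- pq[2]
      if (p == 0) {
        if (q < 0) return(FALSE)
      } else {
        r <- q / p
        if (p < 0) t0 <- max(t0, r) else t1 <- min(t1, r)
      }
    }
    t0 <= t1
  }
  cells <- character(0)
  for (s in seq_len(length(u) - 1)) {
    for (cx in floor(min(u[s], u[s + 1])):floor(max(u[s], u[s + 1]))) {
      for (cy in floor(min(v[s], v[s + 1])):floor(max(v[s], v[s + 1]))) {
        if (hits_cell(u[s], v[s], u[s + 1], v[s + 1], cx, cy)) {
          cells <- c(cells, paste(cx, cy))
        }
      }
    }
  }
  length(unique(cells))
}

# O(n^3) minimal enclosing circle: try all 2- and 3-point support circles
oracle_mec_radius <- function(pts) {
  n <- nrow(pts)
  best <- Inf
  covers <- function(cx, cy, r2) {
    all((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2 <= r2 * (1 + 1e-9) + 1e-12)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cx <- (pts[i, 1] + pts[j, 1]) / 2
    cy <- (pts[i, 2] + pts[j, 2]) / 2
    r2 <- (pts[i, 1] - cx)^2 + (pts[i, 2] - cy)^2
    if (r2 < best && covers(cx, cy, r2)) best <- r2
  }
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ax <- pts[i, 1]; ay <- pts[i, 2]
    bx <- pts[j, 1]; by <- pts[j, 2]
    cx <- pts[k, 1]; cy <- pts[k, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-14) next
    a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
    ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
    uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    if (r2 < best && covers(ux, uy, r2)) best <- r2
  }
  sqrt(best)
}

# a hand-rolled trajectory object from raw coordinates
make_traj <- function(x, y, geometry = pool_geometry(), dt = 0.1,
                      escaped = FALSE, label = NA_character_) {
  structure(tibble::tibble(time_s = (seq_along(x) - 1) * dt, x_m = x, y_m = y),
            geometry = geometry, escaped = escaped, label = label,
            latency_s = (length(x) - 1) * dt)
}

# run code under a temporary RNG state without disturbing the session's
.with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

.dataset_head <- function(ds, n) {
  swimmaze:::.dataset_subset(ds, seq_len(n))
}

# small labelled cohort reused by dataset/evaluation tests
small_cohort <- function(n_control = 2, n_lesion = 2, seed = 5) {
  simulate_cohort(cohort_spec(n_control = n_control, n_lesion = n_lesion,
                              seed = seed))
}
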