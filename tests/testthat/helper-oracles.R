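# Brute-force oracles written independently of the package internals:
# plain loops and direct arithmetic only.

# Morphological gradient (3x3 dilation minus 3x3 erosion) by exhaustive
# neighbourhood scan.
oracle_contour <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- max(1, i - 1):min(nr, i + 1)
    jj <- max(1, j - 1):min(nc, j + 1)
    nb <- mask[ii, jj]
    dil <- as.numeric(any(nb > 0))
    ero <- as.numeric(all(nb > 0))
    out[i, j] <- as.numeric(dil - ero > 0)
  }
  out
}

# Gaussian blur by direct spatial convolution with replicated boundary,
# kernel truncated at ceiling(3*sigma) (minimum half-width 1).
oracle_blur <- function(m, sigma) {
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-half):half
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- outer(g, g)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (di in -half:half) for (dj in -half:half) {
      ii <- min(max(i + di, 1), nr)
      jj <- min(max(j + dj, 1), nc)
      s <- s + m[ii, jj] * k[di + half + 1, dj + half + 1]
    }
    out[i, j] <- s
  }
  out
}

# Negative squared gradient magnitude of the blurred image, central
# differences, zero at the borders.
oracle_field <- function(m, sigma) {
  s <- oracle_blur(m, sigma)
  nr <- nrow(s); nc <- ncol(s)
  out <- matrix(0, nr, nc)
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    gy <- (s[i + 1, j] - s[i - 1, j]) / 2
    gx <- (s[i, j + 1] - s[i, j - 1]) / 2
    out[i, j] <- -(gx^2 + gy^2)
  }
  out
}

# One serial greedy sweep, replayed with scalar loops: each movable point,
# in contour order, moves to the strictly lowest-energy candidate of its 3x3
# neighbourhood (current position scanned first, then row-major order).
oracle_sweep <- function(pts, movable, field, alpha, beta, gamma) {
  n <- nrow(pts)
  dists <- numeric(n - 1)
  for (i in seq_len(n - 1))
    dists[i] <- sqrt((pts[i + 1, 1] - pts[i, 1])^2 +
                     (pts[i + 1, 2] - pts[i, 2])^2)
  d_bar <- mean(dists)
  nr <- nrow(field); nc <- ncol(field)
  for (i in seq_len(n)) {
    if (!movable[i]) next
    prev <- if (i == 1) pts[2, ] else pts[i - 1, ]
    nxt <- if (i == n) pts[n - 1, ] else pts[i + 1, ]
    cands <- rbind(c(0, 0))
    for (dy in -1:1) for (dx in -1:1)
      if (!(dy == 0 && dx == 0)) cands <- rbind(cands, c(dx, dy))
    best_e <- Inf
    best <- pts[i, ]
    for (k in seq_len(nrow(cands))) {
      cx <- pts[i, 1] + cands[k, 1]
      cy <- pts[i, 2] + cands[k, 2]
      if (cx < 1 || cx > nc || cy < 1 || cy > nr) next
      e_ela <- d_bar - sqrt((cx - prev[1])^2 + (cy - prev[2])^2)
      e_curv <- (nxt[1] - 2 * cx + prev[1])^2 + (nxt[2] - 2 * cy + prev[2])^2
      e <- alpha * e_ela + beta * e_curv + gamma * field[cy, cx]
      if (e < best_e) { best_e <- e; best <- c(cx, cy) }
    }
    pts[i, ] <- best
  }
  pts
}

# Replay every recorded sweep of a tracked contour against oracle_sweep;
# returns the number of point-position mismatches across the whole run.
replay_mismatches <- function(state, field, cfg) {
  stopifnot(!is.null(state$history))
  w <- cfg$weights
  bad <- 0L
  for (k in seq_len(length(state$history) - 1)) {
    got <- state$history[[k + 1]]$points
    want <- oracle_sweep(state$history[[k]]$points, state$movable, field,
                         w$alpha, w$beta, w$gamma)
    bad <- bad + sum(got != want)
    # fixed points must be bitwise unchanged from the initial state
    fixed <- !state$movable
    bad <- bad + sum(got[fixed, ] != state$history[[1]]$points[fixed, ])
  }
  bad
}

# Mean distance from each point of `pts` to the nearest point of the dense
# polyline `truth` (both two-column (x, y) matrices).
mean_dist_to_curve <- function(pts, truth) {
  mean(apply(pts, 1, function(p)
    min(sqrt((truth[, 1] - p[1])^2 + (truth[, 2] - p[2])^2))))
}

# Track one phantom frame against its own truth landmarks and return the
# mean tracked-contour-to-truth distance plus the replay mismatch count.
track_and_score <- function(fr, pre = preprocess_config(),
                            cfg = snake_config()) {
  plane <- palatal_plane(fr$truth$ans, fr$truth$pns)
  mask <- extract_cavity_mask(fr$frame, pre)
  segs <- filter_segments(label_segments(mask), fr$truth$jaw_mask, pre)
  cavity <- select_cavity_component(segs, plane)
  init <- select_initial_points(cavity, pre$n_upper, pre$n_lower,
                                pre$close_radius)
  field <- image_energy_field(fr$frame, cfg$weights$sigma)
  state <- run_snake(fr$frame, init, cfg, field = field, keep_history = TRUE)
  list(dist = mean_dist_to_curve(snake_contour(state),
                                 fr$truth$tongue_contour),
       mismatches = replay_mismatches(state, field, cfg),
       converged = state$converged)
}
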