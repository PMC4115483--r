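#' Energy weights of the greedy active contour
#'
#' The contour minimizes, per candidate pixel, the weighted sum
#' `alpha * E_ela + beta * E_curv + gamma * E_img`. The defaults are the
#' values tuned for midsagittal tongue tracking at 1.057 px/mm:
#' `alpha = 1.2`, `beta = 1`, `gamma = 5.2`, with the image energy computed
#' on a `sigma = 5` px Gaussian-blurred gradient.
#'
#' @param alpha Elasticity weight (> 0).
#' @param beta Curvature weight (> 0).
#' @param gamma Image-energy weight (> 0).
#' @param sigma Gaussian standard deviation (px) of the image-energy blur.
#' @return A list of class `energy_weights`.
#' @export
energy_weights <- function(alpha = 1.2, beta = 1, gamma = 5.2, sigma = 5) {
  stopifnot(alpha > 0, beta > 0, gamma > 0, sigma > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, sigma = sigma),
            class = "energy_weights")
}

#' Snake configuration
#'
#' @param weights An [energy_weights()].
#' @param max_iter Maximum number of greedy sweeps (default 200).
#' @param stop_fraction The contour stops when fewer than
#'   `stop_fraction * n` points move in a sweep (default 1/10 of the points).
#' @param neighborhood_radius Candidate search radius in pixels (1 = the 3x3
#'   neighbourhood of the classic greedy snake).
#' @param normalize_neighborhood If `TRUE`, each energy term is min-max
#'   normalized over the candidate neighbourhood before weighting (the
#'   classic greedy-snake variant). Off by default: the tuned weights match
#'   the unnormalized formulation.
#' @param stop_rule `"count"` (default) stops on the number of moved points;
#'   `"displacement"` stops when the mean per-point displacement of a sweep
#'   falls below `stop_fraction`.
#' @return A list of class `snake_config`.
#' @export
snake_config <- function(weights = energy_weights(), max_iter = 200,
                         stop_fraction = 0.1, neighborhood_radius = 1,
                         normalize_neighborhood = FALSE,
                         stop_rule = c("count", "displacement")) {
  stopifnot(inherits(weights, "energy_weights"), max_iter >= 1,
            stop_fraction > 0, stop_fraction <= 1, neighborhood_radius >= 1)
  structure(list(weights = weights, max_iter = as.integer(max_iter),
                 stop_fraction = stop_fraction,
                 neighborhood_radius = as.integer(neighborhood_radius),
                 normalize_neighborhood = isTRUE(normalize_neighborhood),
                 stop_rule = match.arg(stop_rule)),
            class = "snake_config")
}

#' Elasticity energy of a candidate point
#'
#' `d_bar - |cand - prev|`: the signed difference between the contour's mean
#' inter-point distance and the candidate's distance to its predecessor.
#' Used exactly as written (it may be negative).
#'
#' @param prev,cand Length-2 `(x, y)` vectors.
#' @param d_bar Mean consecutive-point distance of the current contour (>= 0).
#' @return Scalar energy.
#' @export
elasticity_energy <- function(prev, cand, d_bar) {
  stopifnot(d_bar >= 0)
  d_bar - sqrt(sum((cand - prev)^2))
}

#' Curvature energy of a candidate point
#'
#' Squared norm of the discrete second difference `next - 2*cur + prev`.
#'
#' @param prev,cur,nxt Length-2 `(x, y)` vectors.
#' @return Scalar energy (>= 0).
#' @export
curvature_energy <- function(prev, cur, nxt) {
  sum((nxt - 2 * cur + prev)^2)
}

#' Image energy field
#'
#' Negative squared gradient magnitude of the Gaussian-blurred frame:
#' `-(|grad(G_sigma * I)|^2)`, evaluated with central differences (one-sided
#' at the borders gives zero there). Minima lie on intensity edges; blurring
#' lets edges attract the contour from a distance of roughly `2*sigma` px.
#'
#' @param frame A [vt_frame()] or a numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return Numeric matrix of non-positive energies, same shape as the frame.
#' @export
image_energy_field <- function(frame, sigma = 5) {
  stopifnot(sigma > 0)
  px <- if (inherits(frame, "vt_frame")) frame$pixels else frame
  s <- gaussian_blur(px, sigma)
  nr <- nrow(s); nc <- ncol(s)
  gy <- matrix(0, nr, nc); gx <- matrix(0, nr, nc)
  if (nr > 2) gy[2:(nr - 1), ] <- (s[3:nr, ] - s[1:(nr - 2), ]) / 2
  if (nc > 2) gx[, 2:(nc - 1)] <- (s[, 3:nc] - s[, 1:(nc - 2)]) / 2
  e <- -(gx^2 + gy^2)
  # the gradient is undefined on the one-pixel border; leave it neutral
  e[c(1, nr), ] <- 0
  e[, c(1, nc)] <- 0
  e
}

#' Combined snake energy
#'
#' @param e_ela,e_curv,e_img Energy terms.
#' @param w An [energy_weights()].
#' @return `alpha*e_ela + beta*e_curv + gamma*e_img`.
#' @export
combined_energy <- function(e_ela, e_curv, e_img, w = energy_weights()) {
  w$alpha * e_ela + w$beta * e_curv + w$gamma * e_img
}

#' Build a snake state from initial points
#'
#' The contour is the open polyline formed by the movable upper points
#' (anterior to posterior) followed by the fixed lower points (posterior to
#' anterior), so consecutive points are spatial neighbours and the open gap
#' sits at the anterior end.
#'
#' @param init An `initial_points` object from [select_initial_points()].
#' @return A list of class `snake_state` with `points` (two-column `(x, y)`
#'   matrix), `movable` (logical), `iteration`, `moved_last`.
#' @export
snake_state <- function(init) {
  stopifnot(inherits(init, "initial_points"))
  pts <- rbind(init$upper, init$lower[rev(seq_len(nrow(init$lower))), , drop = FALSE])
  structure(list(points = pts,
                 movable = c(rep(TRUE, nrow(init$upper)),
                             rep(FALSE, nrow(init$lower))),
                 iteration = 0L, moved_last = NA_integer_),
            class = "snake_state")
}

#' @export
print.snake_state <- function(x, ...) {
  cat(sprintf("<snake_state> %d points (%d movable), iteration %d, moved_last %s\n",
              nrow(x$points), sum(x$movable), x$iteration,
              ifelse(is.na(x$moved_last), "-", x$moved_last)))
  invisible(x)
}

neighbour_offsets <- function(r) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[order(g$dy, g$dx), ]
  # current position first, remaining candidates in row-major order
  cur <- g$dy == 0 & g$dx == 0
  rbind(c(0, 0), as.matrix(g[!cur, c("dx", "dy")]))
}

#' One greedy sweep of the snake
#'
#' Each movable point, visited in contour order (anterior to posterior and
#' seeing earlier moves within the sweep), is moved to the candidate pixel of
#' its `(2r+1)^2` neighbourhood with the lowest combined energy. The mean
#' inter-point distance `d_bar` is recomputed once at the start of the sweep.
#' Candidates outside the image are excluded; ties keep the earliest
#' candidate (current position first, then row-major order), so a point only
#' moves on a strict improvement. Endpoints of the open polyline use their
#' single interior neighbour in place of the missing one.
#'
#' @param state A `snake_state`.
#' @param field Image-energy matrix from [image_energy_field()].
#' @param cfg A [snake_config()].
#' @return The updated `snake_state` (`iteration` incremented, `moved_last`
#'   set to the number of points that changed position, and
#'   `displacement_last` to their mean displacement).
#' @export
snake_step <- function(state, field, cfg = snake_config()) {
  stopifnot(inherits(state, "snake_state"), is.matrix(field))
  pts <- state$points
  n <- nrow(pts)
  w <- cfg$weights
  offs <- neighbour_offsets(cfg$neighborhood_radius)
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  d_bar <- mean(d)
  nr <- nrow(field); nc <- ncol(field)
  moved <- 0L
  disp <- 0
  for (i in seq_len(n)) {
    if (!state$movable[i]) next
    prev <- if (i == 1) pts[2, ] else pts[i - 1, ]
    nxt <- if (i == n) pts[n - 1, ] else pts[i + 1, ]
    cx <- pts[i, 1] + offs[, 1]
    cy <- pts[i, 2] + offs[, 2]
    ok <- cx >= 1 & cx <= nc & cy >= 1 & cy <= nr
    cx <- cx[ok]; cy <- cy[ok]
    e_ela <- d_bar - sqrt((cx - prev[1])^2 + (cy - prev[2])^2)
    e_curv <- (nxt[1] - 2 * cx + prev[1])^2 + (nxt[2] - 2 * cy + prev[2])^2
    e_img <- field[cbind(cy, cx)]
    if (cfg$normalize_neighborhood) {
      norm01 <- function(v) {
        rng <- max(v) - min(v)
        if (rng < .Machine$double.eps) rep(0, length(v)) else (v - min(v)) / rng
      }
      e_ela <- norm01(e_ela); e_curv <- norm01(e_curv); e_img <- norm01(e_img)
    }
    e <- w$alpha * e_ela + w$beta * e_curv + w$gamma * e_img
    best <- which.min(e)  # earliest index wins ties; index 1 is the current pixel
    if (best != 1L) {
      disp <- disp + sqrt((cx[best] - pts[i, 1])^2 + (cy[best] - pts[i, 2])^2)
      pts[i, ] <- c(cx[best], cy[best])
      moved <- moved + 1L
    }
  }
  state$points <- pts
  state$iteration <- state$iteration + 1L
  state$moved_last <- moved
  state$displacement_last <- disp / n
  state
}

#' Run the greedy snake to convergence
#'
#' Repeats [snake_step()] until fewer than `stop_fraction * n` points move in
#' a sweep (or, with `stop_rule = "displacement"`, until the mean per-point
#' displacement drops below `stop_fraction`), or `max_iter` sweeps have run.
#' Deterministic for identical inputs.
#'
#' @param frame A [vt_frame()] (or a matrix) from which the image energy is
#'   computed, or a precomputed energy matrix via `field`.
#' @param init An `initial_points` object.
#' @param cfg A [snake_config()].
#' @param field Optional precomputed [image_energy_field()]; computed from
#'   `frame` with `cfg$weights$sigma` when missing.
#' @param keep_history If `TRUE`, all intermediate states are returned in
#'   `$history` (the initial state first).
#' @return The final `snake_state`, with `$iterations` (sweeps run),
#'   `$moved_history` (moved-point count per sweep) and `$converged`
#'   (`TRUE` when the stopping rule fired before `max_iter`).
#' @export
run_snake <- function(frame, init, cfg = snake_config(), field = NULL,
                      keep_history = FALSE) {
  if (is.null(field)) field <- image_energy_field(frame, cfg$weights$sigma)
  state <- snake_state(init)
  pts <- state$points
  if (any(pts[, 1] < 1 | pts[, 1] > ncol(field) |
          pts[, 2] < 1 | pts[, 2] > nrow(field)))
    stop("initial points fall outside the frame", call. = FALSE)
  n <- nrow(pts)
  history <- if (keep_history) list(state) else NULL
  moved_history <- integer(0)
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    state <- snake_step(state, field, cfg)
    moved_history <- c(moved_history, state$moved_last)
    if (keep_history) history[[length(history) + 1L]] <- state
    stopval <- if (cfg$stop_rule == "count") state$moved_last
               else state$displacement_last
    limit <- if (cfg$stop_rule == "count") cfg$stop_fraction * n
             else cfg$stop_fraction
    if (stopval < limit) { converged <- TRUE; break }
  }
  state$iterations <- length(moved_history)
  state$moved_history <- moved_history
  state$converged <- converged
  state$history <- history
  state
}

#' Tracked tongue contour of a snake state
#'
#' @param state A `snake_state`.
#' @return Two-column `(x, y)` matrix of the movable points, anterior to
#'   posterior.
#' @export
snake_contour <- function(state) {
  stopifnot(inherits(state, "snake_state"))
  state$points[state$movable, , drop = FALSE]
}
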