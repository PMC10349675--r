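# Global-best particle swarm optimisation with inertia weight, minimisation
# convention.  Velocity: v' = w v + R1 c1 (pbest - x) + R2 c2 (gbest - x),
# with per-dimension uniform draws R1, R2; position: x' = x + v', clipped to
# the box with velocity zeroed on clipped dimensions.

#' PSO parameters
#'
#' @param c1,c2 acceleration constants toward the personal and global best
#'   (defaults 2, 2 -- the classic setting; never fixed by the method's
#'   description).
#' @param w inertia weight: a single value for constant inertia, or the
#'   default `NULL` for a linear 0.9 -> 0.4 schedule over `max_iter`
#'   (the standard dynamic adjustment).
#' @param bounds 2 x D matrix (rows: lower, upper) or length-2 vector
#'   recycled over dimensions.
#' @param dim problem dimension D.
#' @param swarm_size,max_iter counts.
#' @param v_max per-dimension velocity clamp; `NULL` (default) uses
#'   0.2 * (upper - lower), `Inf` disables clamping.
#' @return An object of class `pso_params`.
#' @export
pso_params <- function(dim, bounds = c(-5, 5), c1 = 2, c2 = 2, w = NULL,
                       swarm_size = 30L, max_iter = 200L, v_max = NULL) {
  dim <- check_count(dim, "dim")
  if (is.matrix(bounds)) {
    stopifnot(nrow(bounds) == 2L, ncol(bounds) == dim)
  } else {
    stopifnot(length(bounds) == 2L)
    bounds <- matrix(rep(as.numeric(bounds), dim), nrow = 2L)
  }
  if (any(bounds[1, ] >= bounds[2, ])) {
    stop_field("bounds", "lower bound must be below upper bound")
  }
  if (!is.null(w)) w <- check_number(w, "w", lower = 0, upper = 1,
                                     open_lower = TRUE)
  if (is.null(v_max)) v_max <- 0.2 * (bounds[2, ] - bounds[1, ])
  v_max <- rep_len(as.numeric(v_max), dim)
  structure(list(dim = dim, bounds = bounds,
                 c1 = check_number(c1, "c1", lower = 0),
                 c2 = check_number(c2, "c2", lower = 0),
                 w = w,
                 swarm_size = check_count(swarm_size, "swarm_size"),
                 max_iter = check_count(max_iter, "max_iter"),
                 v_max = v_max),
            class = "pso_params")
}

.pso_w_at <- function(params, iter) {
  if (!is.null(params$w)) return(params$w)
  if (params$max_iter <= 1L) return(0.9)
  0.9 - (0.9 - 0.4) * (iter - 1) / (params$max_iter - 1)
}

#' Inertia-weight velocity update
#'
#' `v' = w * v + R1 * c1 * (pbest - x) + R2 * c2 * (gbest - x)` elementwise,
#' then clamped to `[-v_max, v_max]`.  At `w = 1` this is exactly the
#' original (inertia-free) update rule.
#'
#' @param x,v,pbest,gbest numeric vectors of equal length.
#' @param params a [pso_params()].
#' @param w inertia weight for this step (default: constant `params$w` or
#'   0.9 if scheduled).
#' @param R1,R2 per-dimension uniform draws in \[0, 1\]; supplied explicitly
#'   in tests, drawn from the session RNG otherwise.
#' @return The new velocity vector.
#' @export
update_velocity <- function(x, v, pbest, gbest, params,
                            w = .pso_w_at(params, 1L),
                            R1 = stats::runif(length(x)),
                            R2 = stats::runif(length(x))) {
  d <- length(x)
  if (length(v) != d || length(pbest) != d || length(gbest) != d) {
    stop("dimension mismatch between position, velocity and bests",
         call. = FALSE)
  }
  R1 <- rep_len(R1, d); R2 <- rep_len(R2, d)
  vn <- w * v + R1 * params$c1 * (pbest - x) + R2 * params$c2 * (gbest - x)
  pmin(pmax(vn, -params$v_max), params$v_max)
}

#' Position update with box clipping
#'
#' `x' = x + v'`, clipped to the bounds; the velocity component of any
#' clipped dimension is zeroed (returned in the `velocity` attribute).
#'
#' @param x position, `v` updated velocity.
#' @param params a [pso_params()].
#' @return New position with attribute `velocity` (possibly zeroed where
#'   clipping occurred).
#' @export
update_position <- function(x, v, params) {
  xn <- x + v
  lo <- params$bounds[1, ]; hi <- params$bounds[2, ]
  clipped <- xn < lo | xn > hi
  xn <- pmin(pmax(xn, lo), hi)
  v[clipped] <- 0
  attr(xn, "velocity") <- v
  xn
}

#' Run global-best PSO
#'
#' Uniform random initialisation in the box; per-iteration velocity,
#' position, personal-best and global-best updates.  Minimisation.
#'
#' @param objective function of a numeric vector returning a finite scalar.
#' @param params a [pso_params()].
#' @param seed integer seed (NULL uses the current RNG state).
#' @return List of class `pso_result`: `gbest` (position), `gbest_fitness`,
#'   `history` (gbest fitness after each iteration, non-increasing),
#'   `swarm` (final positions matrix).
#' @export
run_pso <- function(objective, params, seed = NULL) {
  stopifnot(inherits(params, "pso_params"))
  with_seed(seed, {
    d <- params$dim; n <- params$swarm_size
    lo <- params$bounds[1, ]; hi <- params$bounds[2, ]
    x <- matrix(stats::runif(n * d, rep(lo, each = n), rep(hi, each = n)),
                n, d)
    v <- matrix(0, n, d)
    eval1 <- function(xi) {
      f <- objective(xi)
      if (!is.finite(f)) {
        stop(sprintf("non-finite objective at (%s)",
                     paste(signif(xi, 4), collapse = ", ")), call. = FALSE)
      }
      f
    }
    pfit <- apply(x, 1, eval1)
    pbest <- x
    gi <- which.min(pfit)
    gbest <- pbest[gi, ]; gfit <- pfit[gi]
    history <- numeric(params$max_iter)
    for (it in seq_len(params$max_iter)) {
      w <- .pso_w_at(params, it)
      for (p in seq_len(n)) {
        vn <- update_velocity(x[p, ], v[p, ], pbest[p, ], gbest, params,
                              w = w)
        xn <- update_position(x[p, ], vn, params)
        v[p, ] <- attr(xn, "velocity")
        x[p, ] <- as.numeric(xn)
        f <- eval1(x[p, ])
        if (f < pfit[p]) {
          pfit[p] <- f
          pbest[p, ] <- x[p, ]
          if (f < gfit) {
            gfit <- f
            gbest <- x[p, ]
          }
        }
      }
      history[it] <- gfit
    }
    structure(list(gbest = gbest, gbest_fitness = gfit, history = history,
                   swarm = x),
              class = "pso_result")
  })
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf("pso_result: gbest fitness %.6g after %d iterations\n",
              x$gbest_fitness, length(x$history)))
  invisible(x)
}
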