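#' Seeded particle-swarm minimization with local polish
#'
#' A compact inertia-weight particle swarm over a box, followed by an
#' L-BFGS-B polish from the best particle. Used as the global stage of
#' model calibration; any evaluation that errors or returns a non-finite
#' value is assigned a large finite penalty so the swarm can continue.
#' Fully reproducible under `seed`.
#'
#' @param fn Objective function of a numeric vector.
#' @param lower,upper Numeric bounds (finite, `lower < upper`).
#' @param n_particles Swarm size (default `10 + 2 * d`).
#' @param max_iter Iterations (default 40).
#' @param seed Integer seed.
#' @param inertia,c_cog,c_soc Standard PSO coefficients (0.7298, 1.49618,
#'   1.49618).
#' @param polish Run the local polish (default TRUE).
#' @param penalty Value assigned to failed evaluations (default 1e12).
#' @return List with `par`, `value`, `evals`, and the swarm `trace`
#'   (best value per iteration).
#' @export
pso_optimize <- function(fn, lower, upper,
                         n_particles = NULL, max_iter = 40, seed = 1,
                         inertia = 0.7298, c_cog = 1.49618,
                         c_soc = 1.49618, polish = TRUE, penalty = 1e12) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(lower)), all(is.finite(upper)),
            all(lower < upper))
  if (is.null(n_particles)) n_particles <- 10L + 2L * d
  evals <- 0L
  safe_fn <- function(x) {
    evals <<- evals + 1L
    v <- tryCatch(fn(x), error = function(e) penalty)
    if (!is.finite(v)) penalty else v
  }
  span <- upper - lower
  with_seed(seed, {
    X <- matrix(stats::runif(n_particles * d), n_particles, d)
    X <- sweep(sweep(X, 2L, span, "*"), 2L, lower, "+")
    V <- matrix(stats::runif(n_particles * d, -1, 1), n_particles, d)
    V <- sweep(V, 2L, span / 5, "*")
    f <- apply(X, 1L, safe_fn)
    Pbest <- X; fP <- f
    g <- which.min(f)
    trace <- numeric(max_iter)
    for (it in seq_len(max_iter)) {
      r1 <- matrix(stats::runif(n_particles * d), n_particles, d)
      r2 <- matrix(stats::runif(n_particles * d), n_particles, d)
      V <- inertia * V + c_cog * r1 * (Pbest - X) +
        c_soc * r2 * sweep(-X, 2L, Pbest[g, ], "+")
      X <- X + V
      # reflect at the box, damp the velocity
      for (j in seq_len(d)) {
        lo <- X[, j] < lower[j]; hi <- X[, j] > upper[j]
        X[lo, j] <- pmin(2 * lower[j] - X[lo, j], upper[j])
        X[hi, j] <- pmax(2 * upper[j] - X[hi, j], lower[j])
        V[lo | hi, j] <- -0.5 * V[lo | hi, j]
      }
      f <- apply(X, 1L, safe_fn)
      imp <- f < fP
      Pbest[imp, ] <- X[imp, , drop = FALSE]
      fP[imp] <- f[imp]
      g <- which.min(fP)
      trace[it] <- fP[g]
    }
    par <- Pbest[g, ]
    val <- fP[g]
    if (polish) {
      pol <- tryCatch(
        stats::optim(par, safe_fn, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 200)),
        error = function(e) NULL)
      if (!is.null(pol) && pol$value <= val) {
        par <- pmin(pmax(pol$par, lower), upper)
        val <- pol$value
      }
    }
    list(par = par, value = val, evals = evals, trace = trace)
  })
}
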