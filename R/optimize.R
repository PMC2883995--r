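#' Optimizer settings
#'
#' Controls for [minimize_energy]. `annealed` is gradient descent with
#' additive Gaussian noise whose scale decays geometrically
#' (`noise_scale0 * noise_decay^step`); once the scale drops below
#' `noise_floor` the descent is purely deterministic, with a backtracking
#' line search guaranteeing a non-increasing energy. `newton` is a damped
#' (Levenberg-style) Newton method using the analytic Hessian, intended
#' for small problems. Iteration stops when the gradient infinity-norm,
#' the relative energy change `|dH|/(|H|+1e-12)`, or the maximum relative
#' coordinate displacement falls below `tolerance`.
#'
#' @param method `"annealed"` or `"newton"`.
#' @param tolerance convergence threshold on all three monitors.
#' @param max_steps iteration cap.
#' @param seed optional integer seed for the thermal noise.
#' @param noise_scale0 initial thermal-noise standard deviation.
#' @param noise_decay per-step geometric decay factor, in (0, 1).
#' @param noise_floor scale below which noise is switched off.
#' @return A list of class `optimizer_control`.
#' @export
optimizer_control <- function(method = c("annealed", "newton"),
                              tolerance = 2e-6, max_steps = 1e6,
                              seed = NULL, noise_scale0 = 0.1,
                              noise_decay = 0.99, noise_floor = 1e-8) {
  method <- match.arg(method)
  stopifnot(tolerance > 0, max_steps >= 1,
            noise_scale0 >= 0, noise_decay > 0, noise_decay < 1)
  structure(list(method = method, tolerance = tolerance,
                 max_steps = as.integer(max_steps), seed = seed,
                 noise_scale0 = noise_scale0, noise_decay = noise_decay,
                 noise_floor = noise_floor),
            class = "optimizer_control")
}

#' Minimize the configuration energy
#'
#' Drives a configuration to a (local, in practice global) minimum of the
#' signed-graph energy. With the annealed method the early noisy phase
#' lets the configuration escape shallow minima; the final deterministic
#' phase is monotone in energy.
#'
#' @param x0 initial `N x d` configuration (rows index `g`'s words).
#' @param g a [signed_graph].
#' @param params an [energy_params] object.
#' @param control an [optimizer_control] object.
#' @return List with `config` (the minimizing matrix), `converged`,
#'   `steps`, `final_energy` and `monitor` (which criterion fired).
#' @export
minimize_energy <- function(x0, g, params = energy_params(),
                            control = optimizer_control()) {
  check_config(x0, g)
  if (!is.null(control$seed)) set.seed(control$seed)
  if (control$method == "annealed") {
    res <- .descend_cpp(x0, g$W, params$pair_coeff, params$quartic_coeff,
                        control$tolerance, control$max_steps,
                        control$noise_scale0, control$noise_decay,
                        control$noise_floor)
    res$config <- unname(res$config)
    res
  } else {
    newton_minimize(x0, g, params, control)
  }
}

# Damped Newton on the flattened coordinates; Hessian blocks are
# d x d per word plus -pair * W_ij * I couplings. Dense, so only for
# small problems.
newton_minimize <- function(x0, g, params, control) {
  n <- nrow(x0); d <- ncol(x0)
  if (n * d > 4000)
    stop("newton method is limited to small problems (N*d <= 4000)")
  W <- as.matrix(g$W)
  pc <- params$pair_coeff; qc <- params$quartic_coeff
  x <- x0
  E <- map_energy(x, g, params)
  eps <- 1e-12
  converged <- FALSE; monitor <- "max_steps"; it <- 0L
  for (it in seq_len(control$max_steps)) {
    G <- map_energy_gradient(x, g, params)
    # Hessian over vec(t(x)): word-major blocks
    H <- kronecker(-pc * W, diag(d))
    rs <- rowSums(x^2)
    for (i in seq_len(n)) {
      blk <- 4 * qc * (rs[i] * diag(d) + 2 * tcrossprod(x[i, ]))
      ii <- ((i - 1) * d + 1):(i * d)
      H[ii, ii] <- H[ii, ii] + blk
    }
    gvec <- as.vector(t(G))
    mu <- 0
    repeat {
      ok <- tryCatch({
        R <- chol(H + mu * diag(n * d)); TRUE
      }, error = function(e) FALSE)
      if (ok) break
      mu <- if (mu == 0) 1e-4 * max(abs(diag(H))) else mu * 10
      if (!is.finite(mu) || mu > 1e12) stop("Hessian damping failed")
    }
    dir <- backsolve(R, forwardsolve(t(R), gvec))
    step <- 1
    repeat {
      xn <- x - step * matrix(dir, n, d, byrow = TRUE)
      En <- map_energy(xn, g, params)
      if (is.finite(En) && En <= E - 1e-14) break
      step <- step / 2
      if (step < 1e-14) { xn <- x; En <- E; break }
    }
    ginf <- max(abs(G))
    rel_e <- abs(En - E) / (abs(E) + eps)
    rel_x <- max(abs(xn - x)) / (max(sqrt(rowSums(xn^2))) + eps)
    x <- xn; E <- En
    if (!is.finite(E)) stop("optimization diverged at step ", it)
    if (ginf < control$tolerance) { converged <- TRUE; monitor <- "gradient"; break }
    if (rel_e < control$tolerance) { converged <- TRUE; monitor <- "energy"; break }
    if (rel_x < control$tolerance) { converged <- TRUE; monitor <- "coordinates"; break }
  }
  list(config = x, converged = converged, steps = it,
       final_energy = E, monitor = monitor)
}
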