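# Time integration, Newton steady states, stimuli, and pattern stability.
#
# The coupling makes the system stiff (bi-Laplacian eigenvalues grow like
# Lam^2), so the integrator treats the linear coupling implicitly and the
# local force explicitly:
#   (Id + dt C) u_{n+1} = u_n + dt f(u_n),   C = 2 L2 + L4.
# The matrix Id + dt C is symmetric positive definite for dt < 1 (the
# spectrum of C is 2 Lam + Lam^2 >= -1), and its Cholesky factor is computed
# once per (network, dt) and cached.

#' Activation energy of a state
#'
#' The squared Euclidean norm `sum(u^2)`, the measure used on the vertical
#' axis of snaking diagrams.  Functions that report energies accept an
#' `energy_fn` argument to swap in another functional.
#'
#' @param u nodal state vector.
#' @return non-negative scalar, zero iff `u` is identically zero.
#' @export
activation_energy <- function(u) sum(u^2)

new_pattern <- function(u, params, residual_norm, energy = activation_energy(u),
                        converged = TRUE) {
  structure(list(u = as.vector(u), mu = params$mu, b = params$b,
                 residual_norm = residual_norm, energy = energy,
                 converged = converged),
            class = "shnet_pattern")
}

#' @export
print.shnet_pattern <- function(x, ...) {
  cat(sprintf("<shnet_pattern> %d nodes, mu = %g, energy = %.6g, residual = %.2e%s\n",
              length(x$u), x$mu, x$energy, x$residual_norm,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Right-hand side of the network model
#'
#' `F(u) = f(u_i, mu) + I_i` with the interaction current
#' `I = -(2 L2 + L4) u`: the per-node rate of change.
#'
#' @param net an `shnet` network.
#' @param u state vector.
#' @param params an [sh_params()] object.
#' @return numeric vector `du/dt`.
#' @export
sh_rhs <- function(net, u, params) {
  local_force(u, params) + interaction_current(net, u)
}

#' Jacobian of the right-hand side
#'
#' `J = diag(f'(u_i)) - (2 L2 + L4)`, symmetric.
#'
#' @param net an `shnet` network.
#' @param u state vector.
#' @param params an [sh_params()] object.
#' @return sparse symmetric matrix.
#' @export
sh_jacobian <- function(net, u, params) {
  Matrix::Diagonal(net$n, local_force_prime(u, params)) - coupling_matrix(net)
}

step_factor <- function(net, dt) {
  key <- sprintf("chol_dt_%.17g", dt)
  cache_get(net, key, function() {
    M <- Matrix::Diagonal(net$n) + dt * coupling_matrix(net)
    Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE)
  })
}

#' Integrate the dynamics to equilibrium
#'
#' Semi-implicit first-order stepping (implicit coupling, explicit local
#' force) from `u0` until the residual `max |F(u)|` drops below
#' `settle_tol` or `t_max` is reached.  The endpoint is then polished with
#' [newton_steady()] so the returned pattern is stationary to Newton
#' tolerance.
#'
#' @param net an `shnet` network.
#' @param u0 initial state vector.
#' @param params an [sh_params()] object.
#' @param dt time step (default 0.05; must satisfy `dt < 1` for the implicit
#'   solve to stay positive definite).
#' @param t_max maximum integration time.
#' @param settle_tol residual threshold for declaring equilibrium.
#' @param polish polish the endpoint with Newton (default `TRUE`).
#' @param energy_fn energy functional (default [activation_energy()]).
#' @return an `shnet_pattern` with attribute `trajectory`: data.frame of
#'   sampled `time`, `energy`, `residual`.
#' @export
evolve <- function(net, u0, params, dt = 0.05, t_max = 5000,
                   settle_tol = 1e-8, polish = TRUE,
                   energy_fn = activation_energy) {
  if (dt <= 0 || dt >= 1) stop("dt must lie in (0, 1)", call. = FALSE)
  if (length(u0) != net$n) stop("dimension-error: u0 length", call. = FALSE)
  fac <- step_factor(net, dt)
  u <- as.numeric(u0)
  t <- 0
  n_steps <- ceiling(t_max / dt)
  sample_every <- max(1L, floor(n_steps / 200))
  traj_t <- traj_e <- traj_r <- numeric(0)
  res <- max(abs(sh_rhs(net, u, params)))
  settled <- res < settle_tol
  step <- 0L
  while (!settled && step < n_steps) {
    # reaction substep: explicit Euler, sub-cycled so h * |f'| <= 1/2 —
    # the local cubic is confining, but a single explicit step of size dt
    # overshoots for |u| >> 1 (strong stimuli, large noise)
    v <- u
    tau <- 0
    repeat {
      h <- min(dt - tau, 0.5 / max(1, max(abs(local_force_prime(v, params)))))
      v <- v + h * local_force(v, params)
      tau <- tau + h
      if (tau >= dt - 1e-15) break
    }
    u_new <- as.numeric(Matrix::solve(fac, v))
    step <- step + 1L
    t <- step * dt
    if (max(abs(u_new)) > 1e6) {
      cond <- structure(class = c("shnet_blowup", "error", "condition"),
                        list(message = sprintf("blow-up at t = %g", t),
                             call = sys.call(-1), last_state = u))
      stop(cond)
    }
    # cheap settle proxy: implicit-step displacement rate
    moved <- max(abs(u_new - u)) / dt
    u <- u_new
    if (moved < settle_tol) {
      res <- max(abs(sh_rhs(net, u, params)))
      settled <- res < settle_tol * 10  # true residual, modest slack pre-polish
    }
    if (step %% sample_every == 0L || settled) {
      traj_t <- c(traj_t, t); traj_e <- c(traj_e, energy_fn(u))
      traj_r <- c(traj_r, max(abs(sh_rhs(net, u, params))))
    }
  }
  pat <- if (polish) {
    newton_steady(net, u, params, energy_fn = energy_fn)
  } else {
    new_pattern(u, params, max(abs(sh_rhs(net, u, params))),
                energy = energy_fn(u))
  }
  attr(pat, "trajectory") <- data.frame(time = traj_t, energy = traj_e,
                                        residual = traj_r)
  attr(pat, "settled") <- settled
  pat
}

#' Newton solve for a stationary pattern
#'
#' Damped Newton iteration on `F(u) = 0` with the exact sparse Jacobian.
#' Non-convergence is reported in the returned pattern (`converged = FALSE`,
#' with a warning), never silently accepted.
#'
#' @param net an `shnet` network.
#' @param u0 starting state.
#' @param params an [sh_params()] object.
#' @param tol residual max-norm tolerance.
#' @param max_iter iteration cap.
#' @param energy_fn energy functional.
#' @return an `shnet_pattern`.
#' @export
newton_steady <- function(net, u0, params, tol = 1e-10, max_iter = 50,
                          energy_fn = activation_energy) {
  if (any(!is.finite(u0))) stop("u0 must be finite", call. = FALSE)
  u <- as.numeric(u0)
  F <- sh_rhs(net, u, params)
  res <- max(abs(F))
  iter <- 0L
  while (res > tol && iter < max_iter) {
    J <- sh_jacobian(net, u, params)
    du <- tryCatch(as.numeric(Matrix::solve(J, -F)),
                   error = function(e)
                     stop("fold-proximity: singular Jacobian in newton_steady (",
                          conditionMessage(e), ")", call. = FALSE))
    # backtracking line search on the residual norm
    alpha <- 1
    repeat {
      u_try <- u + alpha * du
      F_try <- sh_rhs(net, u_try, params)
      if (max(abs(F_try)) < res || alpha < 1 / 64) break
      alpha <- alpha / 2
    }
    u <- u_try; F <- F_try; res <- max(abs(F))
    iter <- iter + 1L
  }
  conv <- res <= tol
  if (!conv)
    warning(sprintf("newton_steady: no convergence in %d iterations (residual %.2e)",
                    max_iter, res), call. = FALSE)
  new_pattern(u, params, res, energy = energy_fn(u), converged = conv)
}

#' Build a step-like stimulus vector
#'
#' The stimulus support is a node's closed two-jump neighbourhood: the
#' centre (optional, included by default), its neighbours, and its two-jump
#' neighbours.  The vector is `amplitude` on the support plus, when
#' `noise_amplitude > 0`, per-node uniform noise on `[-a, +a]` restricted to
#' the support, drawn with the given seed.
#'
#' @param net an `shnet` network.
#' @param center node id (0-based) or `"best-connected"` (maximum degree,
#'   ties broken by lowest id).
#' @param amplitude step height.
#' @param noise_amplitude uniform noise half-width (`>= 0`).
#' @param seed RNG seed for the noise.
#' @param include_center whether the centre node is part of the support.
#' @return numeric stimulus vector with attribute `support` (0-based ids).
#' @export
make_stimulus <- function(net, center = "best-connected", amplitude,
                          noise_amplitude = 0, seed = 1,
                          include_center = TRUE) {
  A <- net$adjacency
  if (identical(center, "best-connected")) {
    center <- which.max(Matrix::rowSums(A)) - 1L
  }
  c1 <- as.integer(center) + 1L
  if (c1 < 1 || c1 > net$n) stop("center out of range", call. = FALSE)
  nb1 <- which(A[c1, ] > 0)
  B_row <- as.vector(A[c1, , drop = FALSE] %*% A)
  nb2 <- which(B_row > 0 & A[c1, ] == 0)
  nb2 <- setdiff(nb2, c1)
  support <- sort(unique(c(if (include_center) c1, nb1, nb2)))
  u <- numeric(net$n)
  u[support] <- amplitude
  if (noise_amplitude > 0) {
    noise <- with_seed(seed, stats::runif(length(support), -noise_amplitude,
                                          noise_amplitude))
    u[support] <- u[support] + noise
  }
  attr(u, "support") <- support - 1L
  u
}

#' Leading stability eigenvalue of a stationary pattern
#'
#' Most-positive eigenvalue of the (symmetric) Jacobian at the pattern;
#' the pattern is linearly stable iff it is negative (tolerance 1e-8).
#'
#' @param net an `shnet` network.
#' @param pattern an `shnet_pattern` (or plain state vector).
#' @param params an [sh_params()] object; defaults to the pattern's own
#'   parameters.
#' @return the leading eigenvalue (scalar).
#' @export
pattern_stability <- function(net, pattern, params = NULL) {
  u <- if (inherits(pattern, "shnet_pattern")) pattern$u else as.numeric(pattern)
  if (is.null(params)) {
    stopifnot(inherits(pattern, "shnet_pattern"))
    params <- sh_params(pattern$mu, pattern$b)
  }
  J <- sh_jacobian(net, u, params)
  max(eigen(as.matrix(J), symmetric = TRUE, only.values = TRUE)$values)
}

#' Write / read a pattern file
#'
#' Delimited `node,u` table preceded by a `#`-prefixed JSON header carrying
#' `mu`, `b`, `energy`, `residual`, `converged` and free-form provenance.
#'
#' @param pattern an `shnet_pattern`.
#' @param path file path.
#' @param provenance optional named list merged into the header.
#' @return `path` (write) or an `shnet_pattern` (read).
#' @export
write_pattern <- function(pattern, path, provenance = list()) {
  hdr <- c(list(mu = pattern$mu, b = pattern$b, energy = pattern$energy,
                residual = pattern$residual_norm,
                converged = pattern$converged), provenance)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA)), con)
  writeLines("node,u", con)
  writeLines(sprintf("%d,%.17g", seq_along(pattern$u) - 1L, pattern$u), con)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(sub("^#\\s*", "", lines[1]))
  tab <- utils::read.csv(text = lines[-1])
  p <- sh_params(hdr$mu, hdr$b)
  new_pattern(tab$u, p, hdr$residual, converged = isTRUE(hdr$converged))
}
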