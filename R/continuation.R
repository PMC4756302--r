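# Pseudo-arclength continuation of stationary states in mu.
#
# Unknown x = (u, mu).  Each step solves the bordered system
#   F(u, mu) = 0
#   t_u . (u - u_pred0) + t_mu (mu - mu_pred0) - ds = 0
# by Newton, using block elimination on the sparse Jacobian:
#   J a = -F,  J b = -F_mu  (F_mu = -u),
#   d_mu = -(N + t_u.a) / (t_mu + t_u.b),  d_u = a + d_mu b.
# The predictor is a secant tangent (first step: from the Jacobian null-space
# direction).  ds is halved on corrector failure, doubled after fast
# convergence, clamped to [ds0/16, 4 ds0].  Folds are sign changes of
# consecutive d_mu; stability is tagged at every accepted point.

#' Continue a branch of stationary patterns
#'
#' @param net an `shnet` network.
#' @param start a stationary `shnet_pattern` (residual below `tol`); its `mu`
#'   and `b` seed the branch.
#' @param ds arclength step (the (u, mu) metric weights both equally).
#'   Default `0.5 / sqrt(n)` (0.05 on a single-node network).
#' @param n_steps number of continuation steps to attempt.
#' @param direction initial sign of d_mu (+1 or -1); ignored when
#'   `tangent0` is given.
#' @param adapt adaptive step policy (halve on failure, double on fast
#'   convergence, clamp to `[ds/16, 4 ds]`); `FALSE` keeps `ds` fixed.
#' @param tangent0 optional explicit initial tangent of length `n + 1`
#'   (components `(du, dmu)`), e.g. a secant from a previous branch.
#' @param tol corrector residual tolerance for the bordered system.
#' @param max_corrector Newton iterations per step.
#' @param tag_stability compute the leading Jacobian eigenvalue at every
#'   accepted point (set `FALSE` or an integer stride to thin for speed).
#' @param energy_fn energy functional.
#' @return object of class `shnet_branch`: list with `points` (data.frame
#'   `mu`, `energy`, `stable`, `n_unstable` — the Morse index, i.e. the
#'   count of unstable directions — and `residual`), `states` (list of u
#'   vectors),
#'   `folds` (indices), `truncated` flag and the step-control `provenance`.
#' @export
continue_branch <- function(net, start, ds = NULL, n_steps = 100,
                            direction = -1, tol = 1e-8, max_corrector = 12,
                            tag_stability = TRUE, adapt = TRUE,
                            tangent0 = NULL,
                            energy_fn = activation_energy) {
  stopifnot(inherits(start, "shnet_pattern"))
  if (start$residual_norm > 1e-8)
    stop("start pattern is not stationary (residual ",
         format(start$residual_norm), ")", call. = FALSE)
  n <- net$n
  if (is.null(ds)) ds <- if (n == 1) 0.05 else 0.5 / sqrt(n)
  ds0 <- ds
  ds_min <- if (adapt) ds0 / 16 else ds0
  ds_max <- if (adapt) 4 * ds0 else ds0
  stride <- if (isTRUE(tag_stability)) 1L else if (is.numeric(tag_stability))
    as.integer(tag_stability) else 0L

  params_at <- function(mu) sh_params(mu, start$b)
  Ffun <- function(u, mu) sh_rhs(net, u, params_at(mu))
  Jfun <- function(u, mu) sh_jacobian(net, u, params_at(mu))

  u <- start$u; mu <- start$mu
  if (is.null(tangent0)) {
    # initial tangent from J v = -F_mu = u, t = (v, 1)/|.|, oriented by direction
    J <- Jfun(u, mu)
    v <- tryCatch(as.numeric(Matrix::solve(J, u)),
                  error = function(e) rep(0, n))
    t_vec <- c(v, 1) / sqrt(sum(v^2) + 1)
    if (sign(t_vec[n + 1]) != sign(direction)) t_vec <- -t_vec
  } else {
    stopifnot(length(tangent0) == n + 1)
    t_vec <- tangent0 / sqrt(sum(tangent0^2))
  }

  # leading Jacobian eigenvalue and Morse index (count of unstable directions)
  stab_info <- function(u, mu) {
    ev <- eigen(as.matrix(Jfun(u, mu)), symmetric = TRUE,
                only.values = TRUE)$values
    list(stable = ev[1] < 1e-8, n_unstable = sum(ev > 1e-8))
  }
  mus <- mu; energies <- energy_fn(u); residuals <- max(abs(Ffun(u, mu)))
  s0 <- if (stride > 0) stab_info(u, mu) else list(stable = NA, n_unstable = NA_integer_)
  stables <- s0$stable; n_unst <- s0$n_unstable
  states <- list(u)
  truncated <- FALSE

  k <- 1L
  while (k <= n_steps) {
    accepted <- FALSE
    while (!accepted) {
      x_pred <- c(u, mu) + ds * t_vec
      u_c <- x_pred[1:n]; mu_c <- x_pred[n + 1]
      ok <- TRUE
      for (it in seq_len(max_corrector)) {
        F <- Ffun(u_c, mu_c)
        Nres <- sum(t_vec[1:n] * (u_c - u)) + t_vec[n + 1] * (mu_c - mu) - ds
        if (max(abs(F)) < tol && abs(Nres) < tol) break
        J <- Jfun(u_c, mu_c)
        sol <- tryCatch({
          a <- as.numeric(Matrix::solve(J, -F))
          b <- as.numeric(Matrix::solve(J, u_c))   # -F_mu = u
          denom <- t_vec[n + 1] + sum(t_vec[1:n] * b)
          if (abs(denom) < 1e-14) stop("singular bordered system")
          d_mu <- -(Nres + sum(t_vec[1:n] * a)) / denom
          list(du = a + d_mu * b, dmu = d_mu)
        }, error = function(e) NULL)
        if (is.null(sol)) { ok <- FALSE; break }
        u_c <- u_c + sol$du; mu_c <- mu_c + sol$dmu
        if (!all(is.finite(u_c)) || max(abs(u_c)) > 1e6) { ok <- FALSE; break }
      }
      if (ok) {
        F <- Ffun(u_c, mu_c)
        Nres <- sum(t_vec[1:n] * (u_c - u)) + t_vec[n + 1] * (mu_c - mu) - ds
        ok <- max(abs(F)) < tol && abs(Nres) < tol
      }
      if (ok) {
        # branch invariant: no jumping — consecutive points at most 2 ds
        # apart, and the secant may not reverse against the tangent
        step_len <- sqrt(sum((u_c - u)^2) + (mu_c - mu)^2)
        sec_dot <- sum(c(u_c - u, mu_c - mu) * t_vec)
        ok <- step_len <= 2 * ds && sec_dot > 0
      }
      if (ok) {
        accepted <- TRUE
        new_t <- c(u_c - u, mu_c - mu)
        new_t <- new_t / sqrt(sum(new_t^2))
        u <- u_c; mu <- mu_c; t_vec <- new_t
        mus <- c(mus, mu); energies <- c(energies, energy_fn(u))
        residuals <- c(residuals, max(abs(F)))
        si <- if (stride > 0 && (k %% stride == 0L)) stab_info(u, mu)
              else list(stable = NA, n_unstable = NA_integer_)
        stables <- c(stables, si$stable)
        n_unst <- c(n_unst, si$n_unstable)
        states[[length(states) + 1L]] <- u
        if (it <= 3 && ds < ds_max) ds <- min(2 * ds, ds_max)
      } else {
        if (ds <= ds_min) { truncated <- TRUE; break }
        ds <- max(ds / 2, ds_min)
      }
    }
    if (truncated) break
    k <- k + 1L
  }

  pts <- data.frame(mu = mus, energy = energies, stable = stables,
                    n_unstable = n_unst, residual = residuals)
  br <- structure(list(points = pts, states = states,
                       folds = detect_folds(mus),
                       truncated = truncated,
                       provenance = list(ds0 = ds0, ds_min = ds_min,
                                         ds_max = ds_max, n_steps = n_steps,
                                         direction = direction, tol = tol,
                                         b = start$b, start_mu = start$mu)),
                  class = "shnet_branch")
  br
}

#' Detect folds (saddle-node turns) along a branch
#'
#' A fold is an index where the sign of consecutive `d mu` flips (zero steps
#' inherit the previous sign).
#'
#' @param branch an `shnet_branch`, or a numeric mu sequence.
#' @return integer vector of 1-based point indices at the turns.
#' @export
detect_folds <- function(branch) {
  mus <- if (inherits(branch, "shnet_branch")) branch$points$mu else as.numeric(branch)
  if (length(mus) < 3) return(integer(0))
  d <- diff(mus)
  s <- sign(d)
  # carry the last nonzero sign through exact-zero steps
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  which(diff(s) != 0 & s[-length(s)] != 0) + 1L
}

#' Snaking diagram table
#'
#' @param branch an `shnet_branch`.
#' @param warn warn if stability does not alternate across folds (the
#'   standard saddle-node exchange).
#' @return data.frame `mu`, `energy`, `stable`, `fold_flag`.
#' @export
snaking_diagram <- function(branch, warn = TRUE) {
  stopifnot(inherits(branch, "shnet_branch"))
  pts <- branch$points
  if (!nrow(pts)) stop("empty branch", call. = FALSE)
  fold_flag <- logical(nrow(pts))
  fold_flag[branch$folds] <- TRUE
  out <- data.frame(mu = pts$mu, energy = pts$energy, stable = pts$stable,
                    fold_flag = fold_flag)
  if (warn && length(branch$folds) && !any(is.na(pts$stable))) {
    seg <- segment_stability(pts$stable, branch$folds)
    if (any(diff(seg) == 0))
      warning("stability does not alternate across every fold", call. = FALSE)
  }
  out
}

# majority stability per inter-fold segment (excluding the fold points
# themselves, where the leading eigenvalue crosses zero)
segment_stability <- function(stable, folds) {
  bounds <- c(1L, folds, length(stable))
  vapply(seq_len(length(bounds) - 1L), function(i) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    idx <- setdiff(lo:hi, folds)
    mean(stable[idx]) >= 0.5
  }, logical(1))
}

#' @export
print.shnet_branch <- function(x, ...) {
  cat(sprintf("<shnet_branch> %d points, mu in [%.4g, %.4g], %d folds%s\n",
              nrow(x$points), min(x$points$mu), max(x$points$mu),
              length(x$folds), if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' @export
plot.shnet_branch <- function(x, ...) {
  pts <- x$points
  col <- ifelse(is.na(pts$stable), "grey50",
                ifelse(pts$stable, "black", "grey70"))
  graphics::plot(pts$mu, pts$energy, type = "l", col = "grey85",
                 xlab = expression(mu), ylab = "activation energy E", ...)
  graphics::points(pts$mu, pts$energy, pch = 16, cex = 0.5, col = col)
  graphics::points(pts$mu[x$folds], pts$energy[x$folds], pch = 1, col = "red")
  invisible(x)
}

#' Write a branch diagram (and optional per-point patterns)
#'
#' @param branch an `shnet_branch`.
#' @param path CSV output for the diagram table.
#' @param meta_path optional JSON path for the step-control provenance.
#' @return `path`, invisibly.
#' @export
write_branch <- function(branch, path, meta_path = NULL) {
  utils::write.csv(snaking_diagram(branch, warn = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path))
    jsonlite::write_json(branch$provenance, meta_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  invisible(path)
}
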