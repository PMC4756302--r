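# Robustness protocols: stimulus-amplitude sweep with threshold / plateau
# detection, and Monte Carlo over noisy stimuli.

# deterministic per-realization seed derived from a master seed; stays
# inside 32-bit integer range
spawn_seed <- function(master, i, r = 0L) {
  as.integer((as.numeric(master) * 48271 + 92821 * as.numeric(i) +
                7919 * as.numeric(r)) %% 2147483629)
}

run_stimulus <- function(net, params, amplitude, center, noise_amplitude,
                         seed, include_center, dt, t_max, settle_tol) {
  u0 <- make_stimulus(net, center = center, amplitude = amplitude,
                      noise_amplitude = noise_amplitude, seed = seed,
                      include_center = include_center)
  tryCatch(evolve(net, u0, params, dt = dt, t_max = t_max,
                  settle_tol = settle_tol),
           shnet_blowup = function(e) {
             p <- new_pattern(e$last_state, params, Inf, converged = FALSE)
             attr(p, "blowup") <- TRUE
             p
           })
}

#' Stimulus-amplitude sweep
#'
#' For each amplitude in an increasing grid: build the step stimulus on the
#' two-jump neighbourhood of `center`, integrate to equilibrium, polish, and
#' record the final activation energy.  Rows are classified `relaxed`
#' (energy below `eps_zero`: the stimulus decayed back to rest), `robust`
#' (member of the terminal energy plateau, which further amplitude
#' increases do not leave) or `fragile` (a quantized state below the robust
#' plateau).  Plateaus are 1-D segments of consecutive non-relaxed energies
#' within `plateau_tol` relative spread.
#'
#' @param net an `shnet` network.
#' @param params an [sh_params()] object with `mu > 0` (localized regime).
#' @param amplitudes increasing amplitude grid.
#' @param center stimulus centre (see [make_stimulus()]).
#' @param include_center include the centre node in the support.
#' @param eps_zero energy below which a run counts as relaxed.
#' @param plateau_tol relative energy spread within one plateau.
#' @param dt,t_max,settle_tol integrator settings.
#' @return object of class `shnet_sweep`: `table` (amplitude, energy,
#'   outcome, plateau id), `patterns` (final states), and the run
#'   configuration in `config`.
#' @export
amplitude_sweep <- function(net, params, amplitudes,
                            center = "best-connected", include_center = TRUE,
                            eps_zero = 1e-6, plateau_tol = 1e-3,
                            dt = 0.05, t_max = 2000, settle_tol = 1e-8) {
  stopifnot(all(diff(amplitudes) > 0) || length(amplitudes) == 1)
  pats <- vector("list", length(amplitudes))
  energy <- numeric(length(amplitudes))
  blow <- logical(length(amplitudes))
  for (i in seq_along(amplitudes)) {
    p <- run_stimulus(net, params, amplitudes[i], center, 0, 0L,
                      include_center, dt, t_max, settle_tol)
    pats[[i]] <- p
    energy[i] <- p$energy
    blow[i] <- isTRUE(attr(p, "blowup"))
  }
  relaxed <- energy < eps_zero & !blow
  plateau <- assign_plateaus(energy, relaxed | blow, plateau_tol)
  outcome <- rep("fragile", length(amplitudes))
  outcome[relaxed] <- "relaxed"
  outcome[blow] <- "blow-up"
  # robust = the terminal plateau (contains the largest amplitude)
  last_p <- plateau[length(plateau)]
  if (!is.na(last_p)) outcome[!is.na(plateau) & plateau == last_p] <- "robust"
  tab <- data.frame(amplitude = amplitudes, energy = energy,
                    outcome = outcome, plateau = plateau)
  structure(list(table = tab, patterns = pats,
                 config = list(params = params, center = center,
                               include_center = include_center,
                               eps_zero = eps_zero, plateau_tol = plateau_tol,
                               dt = dt, t_max = t_max,
                               settle_tol = settle_tol),
                 net = net),
            class = "shnet_sweep")
}

# segment consecutive non-excluded energies into plateaus by relative spread
assign_plateaus <- function(energy, exclude, plateau_tol) {
  plateau <- rep(NA_integer_, length(energy))
  cur <- 0L; ref <- NA_real_
  for (i in seq_along(energy)) {
    if (exclude[i]) { ref <- NA_real_; next }
    if (is.na(ref) || abs(energy[i] - ref) > plateau_tol * max(abs(ref), 1)) {
      cur <- cur + 1L
      ref <- energy[i]
    }
    plateau[i] <- cur
  }
  plateau
}

#' @export
print.shnet_sweep <- function(x, ...) {
  tb <- table(x$table$outcome)
  cat(sprintf("<shnet_sweep> %d rows (%s); %d plateaus\n", nrow(x$table),
              paste(names(tb), tb, sep = ":", collapse = ", "),
              length(unique(stats::na.omit(x$table$plateau)))))
  invisible(x)
}

#' @export
plot.shnet_sweep <- function(x, ...) {
  tab <- x$table
  xcol <- if ("noise_ratio" %in% names(tab)) tab$noise_ratio else tab$amplitude
  ycol <- if ("mean_energy" %in% names(tab)) tab$mean_energy else tab$energy
  graphics::plot(xcol, ycol, type = "b", pch = 16,
                 xlab = if ("noise_ratio" %in% names(tab)) "noise ratio"
                        else "stimulus amplitude",
                 ylab = "final activation energy", ...)
  invisible(x)
}

#' Estimate the activation threshold amplitude
#'
#' Brackets the threshold between the last relaxed and the first
#' quantized-state amplitude of a sweep, then refines it by bisection
#' (re-running the stimulate-integrate pipeline at each midpoint) until the
#' bracket width is at most `grid_step / 8`.
#'
#' @param sweep an `shnet_sweep` from [amplitude_sweep()].
#' @return list with `lower`, `upper` (final bracket) and `n_bisections`.
#' @export
threshold_estimate <- function(sweep) {
  tab <- sweep$table
  relaxed <- tab$outcome == "relaxed"
  formed <- tab$outcome %in% c("fragile", "robust")
  if (!any(relaxed) || !any(formed))
    stop("no-threshold: sweep must contain both relaxed and quantized rows",
         call. = FALSE)
  first_formed <- min(which(formed))
  below <- which(relaxed & seq_along(relaxed) < first_formed)
  if (!length(below))
    stop("no-threshold: no relaxed row below the first quantized row",
         call. = FALSE)
  lo <- tab$amplitude[max(below)]
  hi <- tab$amplitude[first_formed]
  cfg <- sweep$config
  target <- (hi - lo) / 8
  nb <- 0L
  while (hi - lo > target) {
    mid <- (lo + hi) / 2
    p <- run_stimulus(sweep$net, cfg$params, mid, cfg$center, 0, 0L,
                      cfg$include_center, cfg$dt, cfg$t_max, cfg$settle_tol)
    if (p$energy < cfg$eps_zero) lo <- mid else hi <- mid
    nb <- nb + 1L
  }
  list(lower = lo, upper = hi, n_bisections = nb)
}

#' Monte Carlo robustness to stimulus noise
#'
#' Starting from the step stimulus that yields the robust quantized state,
#' adds support-restricted uniform noise of half-width
#' `ratio * base_amplitude` and records the equilibrium energy over `n_real`
#' seeded realizations per noise ratio.  A realization "matches" the base
#' state when its energy agrees to 1e-3 relative.
#'
#' The table carries both `noise_ratio` (noise/signal) and
#' `signal_to_noise` (its reciprocal).
#'
#' @param net an `shnet` network.
#' @param params an [sh_params()] object.
#' @param base_amplitude amplitude of the noise-free stimulus (should be in
#'   the robust regime).
#' @param noise_ratios grid of noise/signal ratios (>= 0).
#' @param n_real realizations per ratio (default 100).
#' @param seed master seed; realization `r` at ratio index `i` uses the
#'   derived seed `spawn(seed, i, r)`, recorded in `realizations`.
#' @param center,include_center,dt,t_max,settle_tol as in [amplitude_sweep()].
#' @return object of class `shnet_sweep` whose `table` has one row per
#'   ratio: `noise_ratio`, `signal_to_noise`, `mean_energy`, `sd_energy`,
#'   `match_fraction`; per-realization energies in `realizations`.
#' @export
noise_monte_carlo <- function(net, params, base_amplitude, noise_ratios,
                              n_real = 100, seed = 1,
                              center = "best-connected", include_center = TRUE,
                              dt = 0.05, t_max = 2000, settle_tol = 1e-8) {
  stopifnot(n_real >= 1, all(noise_ratios >= 0))
  base <- run_stimulus(net, params, base_amplitude, center, 0, 0L,
                       include_center, dt, t_max, settle_tol)
  E0 <- base$energy
  rows <- vector("list", length(noise_ratios))
  reals <- vector("list", length(noise_ratios))
  for (i in seq_along(noise_ratios)) {
    rho <- noise_ratios[i]
    E <- numeric(n_real); seeds <- integer(n_real)
    for (r in seq_len(n_real)) {
      seeds[r] <- spawn_seed(seed, i, r)
      p <- run_stimulus(net, params, base_amplitude, center,
                        rho * base_amplitude, seeds[r], include_center,
                        dt, t_max, settle_tol)
      E[r] <- p$energy
    }
    match <- abs(E - E0) <= 1e-3 * max(abs(E0), .Machine$double.eps)
    rows[[i]] <- data.frame(noise_ratio = rho,
                            signal_to_noise = ifelse(rho > 0, 1 / rho, Inf),
                            mean_energy = mean(E),
                            sd_energy = stats::sd(E),
                            match_fraction = mean(match))
    reals[[i]] <- data.frame(noise_ratio = rho, realization = seq_len(n_real),
                             seed = seeds, energy = E, match = match)
  }
  structure(list(table = do.call(rbind, rows),
                 realizations = do.call(rbind, reals),
                 base_energy = E0, base_pattern = base,
                 config = list(params = params, base_amplitude = base_amplitude,
                               n_real = n_real, seed = seed, center = center,
                               include_center = include_center, dt = dt,
                               t_max = t_max, settle_tol = settle_tol),
                 net = net),
            class = "shnet_sweep")
}
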