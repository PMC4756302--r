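# On-node nonlinearity and linear theory of the flat states.
#
# The local force is f(u, mu) = -(1 + mu) u + b u^2 - u^3 (default b = 3/2),
# so the full model du/dt = f(u) - (2 L2 + L4) u is the network analogue of
# the quadratic-cubic Swift-Hohenberg equation
#   du/dt = -mu u - (Id + L2)^2 u + b u^2 - u^3.
# mu is the bifurcation parameter: the trivial state u = 0 is linearly
# stable for mu > 0 (where stimuli can pin localized states) and gives way
# to global Turing patterns for mu < 0.

#' Model parameters
#'
#' @param mu bifurcation parameter.
#' @param b quadratic coefficient of the local force (`b > 0`); the default
#'   `3/2` places the flat saddle-node at `mu = -0.4375`.
#' @return list of class `sh_params`.
#' @export
sh_params <- function(mu, b = 1.5) {
  if (!is.numeric(mu) || length(mu) != 1 || !is.finite(mu))
    stop("mu must be a finite number", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1 || b <= 0)
    stop("b must be a positive number", call. = FALSE)
  structure(list(mu = mu, b = b), class = "sh_params")
}

#' @export
print.sh_params <- function(x, ...) {
  cat(sprintf("<sh_params> mu = %g, b = %g\n", x$mu, x$b))
  invisible(x)
}

#' Local force and its derivative
#'
#' `f(u, mu) = -(1 + mu) u + b u^2 - u^3`, the gradient of a single-well
#' potential with an inflection point; `local_force_prime` is df/du.
#'
#' @param u nodal state (vectorized).
#' @param params an [sh_params()] object.
#' @return numeric vector the shape of `u`.
#' @export
local_force <- function(u, params) {
  -(1 + params$mu) * u + params$b * u^2 - u^3
}

#' @rdname local_force
#' @export
local_force_prime <- function(u, params) {
  -(1 + params$mu) + 2 * params$b * u - 3 * u^2
}

#' Flat (uniform) stationary states
#'
#' Roots of `f(u, mu) = 0`: always `u0 = 0`, plus
#' `u_pm = (b +/- sqrt(b^2 - 4(1+mu))) / 2` when the discriminant is
#' non-negative (i.e. `mu <= b^2/4 - 1`).
#'
#' @param params an [sh_params()] object.
#' @return list with `u0`, `u_plus`, `u_minus` (the latter two `NA` when
#'   absent) and logical `nonzero_exist`.
#' @export
flat_states <- function(params) {
  disc <- params$b^2 - 4 * (1 + params$mu)
  if (disc >= 0) {
    up <- (params$b + sqrt(disc)) / 2
    um <- (params$b - sqrt(disc)) / 2
    list(u0 = 0, u_plus = up, u_minus = um, nonzero_exist = TRUE)
  } else {
    list(u0 = 0, u_plus = NA_real_, u_minus = NA_real_, nonzero_exist = FALSE)
  }
}

#' Normal-mode growth rate
#'
#' Linearizing about a flat state `u_bar` and expanding over the Laplacian
#' eigenbasis decouples the system into N scalar modes with growth rate
#' `lambda(Lam) = f'(u_bar, mu) - 2 Lam - Lam^2` for Laplacian eigenvalue
#' `Lam <= 0`.  A mode is unstable when its rate is positive.
#'
#' @param u_bar flat state value.
#' @param params an [sh_params()] object.
#' @param lam Laplacian eigenvalue(s), non-positive (vectorized).
#' @return growth rate(s).
#' @export
dispersion <- function(u_bar, params, lam) {
  local_force_prime(u_bar, params) - 2 * lam - lam^2
}

#' Maximum growth rate over a network's spectrum
#'
#' Maximizes [dispersion()] over the actual Laplacian eigenvalues of `net`.
#' On sparse spectra this can miss the continuum optimum at `Lam = -1`;
#' the dense-spectrum idealization is available through
#' [flat_bifurcation_points()].
#'
#' @param net an `shnet` network.
#' @param u_bar flat state value.
#' @param params an [sh_params()] object.
#' @return list with `lambda_max` (the rate) and `lam_critical` (the
#'   Laplacian eigenvalue attaining it).
#' @export
max_growth_rate <- function(net, u_bar, params) {
  lam <- network_spectrum(net, values_only = TRUE)$values
  rates <- dispersion(u_bar, params, lam)
  i <- which.max(rates)
  list(lambda_max = rates[i], lam_critical = lam[i])
}

#' Bifurcation points of the flat states (dense-spectrum idealization)
#'
#' Treating the Laplacian eigenvalue as a continuous variable `Lam <= 0`
#' (a large network whose spectrum is dense near `Lam = -1`):
#' * `mu0 = 0`: the trivial state's maximal rate `-mu - (1 + Lam)^2` crosses
#'   zero (critical mode `Lam = -1`).
#' * `mu1 = b^2/4 - 1`: saddle-node where `u_plus` and `u_minus` coalesce.
#' * `mu_plus`, `mu_minus`: the nonzero branches change stability to
#'   non-uniform perturbations where `f(u) = 0` and `f'(u) = -1`
#'   simultaneously (rate maximum `f' + 1 = 0`); closed form via
#'   `2 u^2 - b u - 1 = 0`.
#'
#' For the default `b = 3/2` these are `0`, `-0.4375`, `-0.6185`, `-1.8190`.
#'
#' @param b quadratic coefficient (`b > 0`).
#' @return list with `mu0`, `mu1`, `mu_plus`, `mu_minus`.
#' @export
flat_bifurcation_points <- function(b = 1.5) {
  if (!is.numeric(b) || b <= 0) stop("b must be positive", call. = FALSE)
  # roots of 2u^2 - b u - 1 = 0: the states where f' = -1 on a flat branch
  r <- sqrt(b^2 + 8)
  u_hi <- (b + r) / 4           # on the upper (u_plus) branch
  u_lo <- (b - r) / 4           # negative: lower (u_minus) branch
  mu_of <- function(u) b * u - u^2 - 1   # from f(u)=0, u != 0
  list(mu0 = 0,
       mu1 = b^2 / 4 - 1,
       mu_plus = mu_of(u_hi),
       mu_minus = mu_of(u_lo))
}

#' Topological eigenvalues of the trivial state
#'
#' The network analogue of the spatial eigenvalues of the homoclinic
#' linearization about `u = 0`: the four roots `s` of `(1 + s^2)^2 = -mu`.
#' Their collision structure signals where localized states can exist:
#' a complex quartet for `mu > 0` (reversible 1:1 resonance), pairwise
#' collision on the imaginary axis at `mu = 0`, four distinct imaginary
#' roots for `-1 < mu < 0`, a double root at the origin at `mu = -1`, and
#' two real roots for `mu < -1`.
#'
#' @param mu bifurcation parameter.
#' @return list with `quartet` (complex, sorted by imaginary then real part)
#'   and `regime` (character).
#' @export
topological_eigenvalues <- function(mu) {
  # (1 + s^2)^2 + mu = s^4 + 2 s^2 + (1 + mu)
  s <- polyroot(c(1 + mu, 0, 2, 0, 1))
  tol <- 1e-9
  s <- complex(real = ifelse(abs(Re(s)) < tol, 0, Re(s)),
               imaginary = ifelse(abs(Im(s)) < tol, 0, Im(s)))
  s <- s[order(Im(s), Re(s))]
  regime <-
    if (mu > 0) "complex-quartet"
    else if (mu == 0) "imaginary-pairwise-collision"
    else if (mu > -1) "imaginary-split"
    else if (mu == -1) "origin-collision"
    else "real-pair"
  list(quartet = s, regime = regime)
}

#' Stability regime report
#'
#' Classifies parameter values by the linear theory of the trivial state:
#' `mu > 0` trivial state stable, localized (quantized) states possible;
#' `mu = 0` threshold; `mu < 0` global Turing patterns.  The upper boundary
#' `mu*` of the localized window is an empirical output of continuation and
#' is not part of this classification.
#'
#' @param mu numeric vector of parameter values.
#' @param path optional path; when given, the report is written there as JSON
#'   keyed by `mu`.
#' @return data.frame with `mu`, `regime`, `quartet_regime`.
#' @export
regime_report <- function(mu, path = NULL) {
  regime <- ifelse(mu > 0, "stable-localized-capable",
                   ifelse(mu == 0, "threshold", "global-pattern"))
  qr <- vapply(mu, function(m) topological_eigenvalues(m)$regime, "")
  out <- data.frame(mu = mu, regime = regime, quartet_regime = qr)
  if (!is.null(path)) {
    obj <- stats::setNames(
      lapply(seq_along(mu), function(i)
        list(regime = regime[i], topological = qr[i])),
      vapply(mu, function(m) format(m, trim = TRUE), ""))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
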