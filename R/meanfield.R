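# Degree / two-jump-degree mean-field approximation (MFA) of the global
# Turing patterns.
#
# Closure: the local neighbour field sum_j A_ij u_j is replaced by k_i H_u,
# the degree-weighted global mean; the two-jump field by k_i u_i + k2_i H_uu;
# and the degree-weighted neighbour field sum_j A_ij k_j u_j by s_i H_uu.
# Propagating this closure through L4 = (L2)^2 reduces the steady model on
# each node class (alpha = k, beta = k2, s = two-walk count) to the cubic
#   g(u) = f(u, mu) + (alpha - alpha^2) u + (alpha^2 - 2 alpha) H_u
#        + (s - beta) H_uu = 0.
# With the tree-consistent substitution s = alpha + beta, every flat state
# of the full model is an exact fixed point of the reduction.

#' Global mean fields of a state
#'
#' `H_u = sum_i k_i u_i / sum_i k_i` (degree-weighted mean) and
#' `H_uu = sum_i k2_i u_i / sum_i k2_i` (two-jump-degree-weighted mean).
#' For a constant state both fields equal the constant.  A `k^2`-weighted
#' variant of `H_uu` is available for sensitivity checks.
#'
#' @param net an `shnet` network.
#' @param u state vector.
#' @param weighting `"k2"` (two-jump degree, default) or `"ksq"`
#'   (degree squared) for the second field.
#' @return list with `H_u` and `H_uu`.
#' @export
global_fields <- function(net, u, weighting = c("k2", "ksq")) {
  weighting <- match.arg(weighting)
  if (length(u) != net$n) stop("dimension-error", call. = FALSE)
  prof <- connectivity_profile(net)
  w2 <- if (weighting == "k2") prof$k2 else prof$k^2
  list(H_u = sum(prof$k * u) / sum(prof$k),
       H_uu = if (sum(w2) > 0) sum(w2 * u) / sum(w2) else 0)
}

#' Node class for the mean-field reduction
#'
#' @param alpha degree `k`.
#' @param beta two-jump degree `k2`.
#' @param s two-walk count; defaults to the tree-consistent `alpha + beta`.
#' @return list of class `shnet_nodeclass`.
#' @export
node_class <- function(alpha, beta, s = alpha + beta) {
  structure(list(alpha = alpha, beta = beta, s = s), class = "shnet_nodeclass")
}

#' Reduced per-node right-hand side
#'
#' `g(u) = f(u, mu) + (alpha - alpha^2) u + (alpha^2 - 2 alpha) H_u +
#' (s - beta) H_uu`.  When `u = H_u = H_uu = c` and `s = alpha + beta` the
#' coupling terms cancel and `g = f(c, mu)`: flat states are preserved.
#'
#' @param u scalar (or vector) node state.
#' @param cls a [node_class()].
#' @param fields list with `H_u`, `H_uu` (see [global_fields()]).
#' @param params an [sh_params()] object.
#' @return `g(u)`.
#' @export
reduced_rhs <- function(u, cls, fields, params) {
  local_force(u, params) + (cls$alpha - cls$alpha^2) * u +
    (cls$alpha^2 - 2 * cls$alpha) * fields$H_u +
    (cls$s - cls$beta) * fields$H_uu
}

# derivative of the reduced rhs in u (fields held fixed)
reduced_rhs_prime <- function(u, cls, params) {
  local_force_prime(u, params) + cls$alpha - cls$alpha^2
}

#' Equilibria of the reduced cubic for one node class
#'
#' Real roots of `g(u) = 0` (ascending), each polished by Newton and flagged
#' stable when `g'(u) = f'(u) + alpha - alpha^2 < 0`.
#'
#' @param cls a [node_class()].
#' @param fields global mean fields.
#' @param params an [sh_params()] object.
#' @return data.frame with `root` and `stable`; 1 or 3 rows (2 at exact
#'   tangencies).
#' @export
node_branches <- function(cls, fields, params) {
  cst <- (cls$alpha^2 - 2 * cls$alpha) * fields$H_u +
    (cls$s - cls$beta) * fields$H_uu
  lin <- -(1 + params$mu) + cls$alpha - cls$alpha^2
  roots <- polyroot(c(cst, lin, params$b, -1))
  scale <- max(Mod(roots), 1)
  re <- Re(roots[abs(Im(roots)) < 1e-8 * scale])
  # polish each real root on the real cubic
  g <- function(u) reduced_rhs(u, cls, fields, params)
  gp <- function(u) reduced_rhs_prime(u, cls, params)
  re <- vapply(re, function(u) {
    for (it in 1:5) {
      d <- gp(u)
      if (abs(d) < 1e-14) break
      step <- g(u) / d
      u <- u - step
      if (abs(step) < 1e-15 * max(abs(u), 1)) break
    }
    u
  }, numeric(1))
  re <- sort(re)
  data.frame(root = re, stable = gp(re) < 0)
}

#' Mean-field overlay of a global Turing pattern
#'
#' Computes the global fields from a converged pattern, solves the reduced
#' cubic for every node's `(alpha, beta, s)` class, and reports the distance
#' from each simulated `u_i` to the nearest stable reduced root.  Nodes are
#' ordered by increasing degree `k`, then two-jump degree `k2` (the Fig-4
#' style profile ordering).
#'
#' @param net an `shnet` network.
#' @param pattern a stationary `shnet_pattern` (residual below 1e-6) at
#'   `mu < 0`.
#' @param params optional [sh_params()]; defaults to the pattern's own.
#' @param tol_fraction deviation tolerance as a fraction of the pattern
#'   range `max(u) - min(u)`.
#' @param weighting field weighting, see [global_fields()].
#' @param tree_consistent replace the measured two-walk count by the
#'   tree-consistent `s = alpha + beta` in every node class; under that
#'   substitution flat states are exact fixed points of the reduction, but
#'   the per-node cubic loses its `k2` dependence (`s - beta` collapses to
#'   `alpha`).  Default `FALSE`: use the measured `s`.
#' @return object of class `shnet_mfa`: `table` (node, k, k2, s, u_sim,
#'   u_mfa, deviation, within_tol, sorted), `fields`, `fraction_within`,
#'   `smoothness` (total variation of the stable-root curve over the sorted
#'   index, normalized by the pattern range) and the settings used.
#' @export
mfa_overlay <- function(net, pattern, params = NULL, tol_fraction = 0.15,
                        weighting = "k2", tree_consistent = FALSE) {
  stopifnot(inherits(pattern, "shnet_pattern"))
  if (!is.finite(pattern$residual_norm) || pattern$residual_norm > 1e-6)
    stop("invalid-input: pattern is not stationary", call. = FALSE)
  if (is.null(params)) params <- sh_params(pattern$mu, pattern$b)
  u <- pattern$u
  fields <- global_fields(net, u, weighting = weighting)
  prof <- connectivity_profile(net)
  cls_s <- if (tree_consistent) prof$k + prof$k2 else prof$s
  classes <- unique(data.frame(k = prof$k, k2 = prof$k2, s = cls_s))
  key <- paste(prof$k, prof$k2, cls_s)
  ckey <- paste(classes$k, classes$k2, classes$s)
  roots_by_class <- lapply(seq_len(nrow(classes)), function(i)
    node_branches(node_class(classes$k[i], classes$k2[i], classes$s[i]),
                  fields, params))
  idx <- match(key, ckey)
  u_mfa <- dev <- numeric(net$n)
  for (i in seq_len(net$n)) {
    rb <- roots_by_class[[idx[i]]]
    stable_roots <- rb$root[rb$stable]
    if (!length(stable_roots)) stable_roots <- rb$root  # all-unstable class
    j <- which.min(abs(stable_roots - u[i]))
    u_mfa[i] <- stable_roots[j]
    dev[i] <- abs(stable_roots[j] - u[i])
  }
  rng <- diff(range(u))
  # absolute floor keeps degenerate (flat) patterns from a zero tolerance
  within <- dev <= tol_fraction * rng + 1e-10
  ord <- order(prof$k, prof$k2)
  tab <- data.frame(node = prof$node, k = prof$k, k2 = prof$k2, s = prof$s,
                    u_sim = u, u_mfa = u_mfa, deviation = dev,
                    within_tol = within)[ord, ]
  tab$sorted_index <- seq_len(nrow(tab))
  smooth <- sum(abs(diff(tab$u_mfa))) / max(rng, .Machine$double.eps)
  structure(list(table = tab, fields = fields,
                 fraction_within = mean(within),
                 smoothness = smooth,
                 tol_fraction = tol_fraction, weighting = weighting,
                 mu = params$mu, b = params$b),
            class = "shnet_mfa")
}

#' @export
print.shnet_mfa <- function(x, ...) {
  cat(sprintf("<shnet_mfa> mu = %g: %.1f%% of nodes within %.0f%% of range; H_u = %.4g, H_uu = %.4g\n",
              x$mu, 100 * x$fraction_within, 100 * x$tol_fraction,
              x$fields$H_u, x$fields$H_uu))
  invisible(x)
}

#' @export
plot.shnet_mfa <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab$sorted_index, tab$u_sim, pch = 4, cex = 0.4,
                 col = "steelblue", xlab = "node index (sorted by k, k2)",
                 ylab = "activation u", ...)
  graphics::lines(tab$sorted_index, tab$u_mfa, col = "black", lwd = 1.5)
  invisible(x)
}

#' Write an overlay report
#'
#' @param mfa an `shnet_mfa`.
#' @param path CSV path for the per-node table.
#' @param summary_path optional JSON path for fields / fractions / settings.
#' @return `path`, invisibly.
#' @export
write_mfa_report <- function(mfa, path, summary_path = NULL) {
  utils::write.csv(mfa$table, path, row.names = FALSE, quote = FALSE)
  if (!is.null(summary_path))
    jsonlite::write_json(list(mu = mfa$mu, b = mfa$b, fields = mfa$fields,
                              fraction_within = mfa$fraction_within,
                              smoothness = mfa$smoothness,
                              tol_fraction = mfa$tol_fraction,
                              weighting = mfa$weighting),
                         summary_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  invisible(path)
}
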