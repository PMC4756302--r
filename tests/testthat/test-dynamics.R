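# Time integration, Newton solving, stimuli and pattern stability.

test_that("rhs composes force and current; flat states are fixed points", {
  net <- generate_ba(60, 2, seed = 2)
  p <- sh_params(-1)
  expect_equal(sh_rhs(net, rep(0, net$n), p), rep(0, net$n))
  fs <- flat_states(p)
  expect_equal(max(abs(sh_rhs(net, rep(fs$u_plus, net$n), p))), 0,
               tolerance = 1e-12)
  # explicit per-node loop as an independent composition path
  set.seed(3)
  u <- runif(net$n, -1, 1)
  C <- as.matrix(coupling_matrix(net))
  manual <- vapply(seq_len(net$n), function(i)
    local_force(u[i], p) - sum(C[i, ] * u), numeric(1))
  expect_equal(sh_rhs(net, u, p), manual, tolerance = 1e-12)
})

test_that("integration relaxes, stays on fixed points, is dt-robust", {
  net <- generate_ba(200, 1, seed = 7)
  # zero stays exactly zero
  pat <- evolve(net, rep(0, net$n), sh_params(0.2))
  expect_identical(max(abs(pat$u)), 0)
  # small random perturbation relaxes for mu > 0
  set.seed(1)
  pat <- evolve(net, runif(net$n, -0.01, 0.01), sh_params(0.1))
  expect_lt(pat$energy, 1e-12)
  # mu < 0: global Turing pattern with positive energy
  set.seed(1)
  pat <- evolve(net, runif(net$n, -0.01, 0.01), sh_params(-0.25))
  expect_gt(pat$energy, 1)
  expect_lt(pat$residual_norm, 1e-10)
  # endpoint energy reproducible across dt
  u0 <- make_stimulus(net, "best-connected", 1.5)
  e1 <- evolve(net, u0, sh_params(0.2), dt = 0.01)$energy
  e2 <- evolve(net, u0, sh_params(0.2), dt = 0.005)$energy
  expect_lt(abs(e1 - e2) / e1, 1e-4)
})

test_that("newton_steady converges, polishes without drift, flags failure", {
  net <- generate_ba(100, 2, seed = 5)
  p <- sh_params(-1)
  # flat state recovered from a noisy start
  set.seed(2)
  pat <- newton_steady(net, 1.5 + rnorm(net$n, sd = 1e-3), p)
  expect_lt(max(abs(pat$u - 1.5)), 1e-10)
  expect_lt(pat$residual_norm, 1e-10)
  # zero returns zero
  pat <- newton_steady(net, rep(0, net$n), p)
  expect_identical(pat$u, rep(0, net$n))
  # single-node degenerate network: scalar root finding
  # (mu = -0.5: simple roots at 0, 0.5, 1)
  n1 <- single_node()
  p2 <- sh_params(-0.5)
  expect_equal(newton_steady(n1, 1.4, p)$u, 1.5, tolerance = 1e-9)
  expect_equal(newton_steady(n1, 0.05, p2)$u, 0, tolerance = 1e-9)
  expect_equal(newton_steady(n1, 1.1, p2)$u, 1, tolerance = 1e-9)
  # polishing an integrated state must not move it appreciably
  u0 <- make_stimulus(net, "best-connected", 1.5)
  rough <- evolve(net, u0, sh_params(0.2), settle_tol = 1e-6, polish = FALSE)
  polished <- newton_steady(net, rough$u, sh_params(0.2))
  expect_lt(polished$residual_norm, 1e-10)
  expect_lt(max(abs(polished$u - rough$u)), 1e-4)
})

test_that("stimulus support: best-connected centre, two-jump closure, noise", {
  # star: the hub is the best-connected node
  u <- make_stimulus(star4(), "best-connected", 1)
  expect_equal(attr(u, "support"), 0:3)
  # path 0-1-2 from an end covers all three nodes
  u <- make_stimulus(path3(), 0, 2)
  expect_equal(as.vector(u), c(2, 2, 2))
  # determinism and support-restricted noise
  net <- generate_ba(150, 1, seed = 3)
  a <- make_stimulus(net, "best-connected", 1.5, noise_amplitude = 0.2, seed = 9)
  b <- make_stimulus(net, "best-connected", 1.5, noise_amplitude = 0.2, seed = 9)
  expect_identical(as.vector(a), as.vector(b))
  d <- make_stimulus(net, "best-connected", 1.5, noise_amplitude = 0.2, seed = 10)
  expect_false(identical(as.vector(a), as.vector(d)))
  off <- setdiff(seq_len(net$n), attr(a, "support") + 1)
  expect_true(all(a[off] == 0))
  # centre exclusion drops exactly the centre
  inc <- make_stimulus(net, "best-connected", 1, include_center = TRUE)
  exc <- make_stimulus(net, "best-connected", 1, include_center = FALSE)
  expect_equal(setdiff(attr(inc, "support"), attr(exc, "support")),
               which.max(degrees(net)) - 1L)
})

test_that("pattern stability matches the dispersion relation on flat states", {
  net <- generate_ba(400, 2, seed = 6)
  # trivial state: stable for mu > 0, unstable for mu < 0 (dense spectrum)
  expect_lt(pattern_stability(net, rep(0, net$n), sh_params(0.1)), 0)
  expect_gt(pattern_stability(net, rep(0, net$n), sh_params(-0.25)), 0)
  # leading eigenvalue equals max dispersion over the spectrum
  lead <- pattern_stability(net, rep(0, net$n), sh_params(-0.25))
  expect_equal(lead, max_growth_rate(net, 0, sh_params(-0.25))$lambda_max,
               tolerance = 1e-8)
  # J phi = dispersion(Lam) phi on an eigenvector, flat state
  sp <- network_spectrum(net)
  a <- 5
  p <- sh_params(-0.6)
  fs <- flat_states(p)
  J <- sh_jacobian(net, rep(fs$u_plus, net$n), p)
  lhs <- as.vector(J %*% sp$vectors[, a])
  expect_equal(lhs, dispersion(fs$u_plus, p, sp$values[a]) * sp$vectors[, a],
               tolerance = 1e-10)
})

test_that("upper flat branch exchanges stability at mu_plus", {
  # the threshold mu_plus is where f'(u_plus) = -1: above it (toward mu1)
  # the maximal rate f'(u_plus) + 1 is positive, below it negative
  net <- generate_ba(2000, 2, seed = 1)
  p_in <- sh_params(-0.5)    # mu_plus < -0.5 < mu1: unstable
  g <- max_growth_rate(net, flat_states(p_in)$u_plus, p_in)
  expect_gt(g$lambda_max, 0)
  p_out <- sh_params(-0.8)   # below mu_plus = -0.6185: stable
  g <- max_growth_rate(net, flat_states(p_out)$u_plus, p_out)
  expect_lt(g$lambda_max, 0)
})

test_that("pattern files round-trip with JSON header", {
  net <- generate_ba(40, 1, seed = 2)
  set.seed(4)
  pat <- evolve(net, runif(net$n, -0.01, 0.01), sh_params(-0.3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_pattern(pat, f, provenance = list(note = "fixture"))
  back <- read_pattern(f)
  expect_equal(back$u, pat$u, tolerance = 1e-15)
  expect_equal(back$mu, pat$mu)
  expect_equal(back$energy, pat$energy, tolerance = 1e-12)
})
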