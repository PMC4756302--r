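# Local force, flat states, dispersion relation and topological eigenvalues.

test_that("local force: roots, derivative consistency", {
  p <- sh_params(-1, b = 1.5)
  expect_equal(local_force(0, sh_params(0.3)), 0)
  expect_equal(local_force(1.5, p), 0, tolerance = 1e-14)
  expect_equal(local_force_prime(0, sh_params(0.7)), -(1 + 0.7))
  # finite-difference check of f'
  for (u in c(-1.2, 0.3, 2)) {
    h <- 1e-6
    fd <- (local_force(u + h, p) - local_force(u - h, p)) / (2 * h)
    expect_equal(local_force_prime(u, p), fd, tolerance = 1e-6)
  }
  expect_error(sh_params(0, b = -1), "positive")
})

test_that("flat states: existence and quadratic roots", {
  fs <- flat_states(sh_params(0))
  expect_false(fs$nonzero_exist)        # discriminant 2.25 - 4 < 0
  fs <- flat_states(sh_params(-1))
  expect_equal(fs$u_plus, 1.5)
  expect_equal(fs$u_minus, 0)
  fs <- flat_states(sh_params(-0.4375)) # discriminant zero: double root
  expect_equal(fs$u_plus, 0.75)
  expect_equal(fs$u_minus, 0.75)
  # every returned root is a root
  for (mu in c(-2, -1.3, -0.6)) {
    p <- sh_params(mu)
    fs <- flat_states(p)
    expect_lt(abs(local_force(fs$u_plus, p)), 1e-12)
    expect_lt(abs(local_force(fs$u_minus, p)), 1e-12)
  }
})

test_that("dispersion relation values and network maximum", {
  expect_equal(dispersion(0, sh_params(0.5), -1), -0.5)
  expect_equal(dispersion(0, sh_params(-0.25), -1), 0.25)
  expect_equal(dispersion(0, sh_params(0.3), 0), -(1 + 0.3))
  # C4 spectrum {0,-2,-2,-4} misses the continuum optimum at -1; the
  # maximal rate -0.75 is tied between Lam = 0 and Lam = -2
  g <- max_growth_rate(cycle_n(4), 0, sh_params(-0.25))
  expect_equal(g$lambda_max, -0.75, tolerance = 1e-10)
  expect_true(min(abs(g$lam_critical - c(0, -2))) < 1e-10)
  # trivial state stable for mu > 0 on any connected graph
  g <- max_growth_rate(generate_ba(100, 2, seed = 4), 0, sh_params(0.1))
  expect_lt(g$lambda_max, 0)
})

test_that("dense BA spectrum approaches the continuum growth maximum", {
  net <- generate_ba(2000, 2, seed = 1)
  g <- max_growth_rate(net, 0, sh_params(-0.25))
  # continuum idealization: max over Lam <= 0 of -mu - (1+Lam)^2 = 0.25
  expect_lt(abs(g$lambda_max - 0.25), 0.05)
  expect_lt(abs(g$lam_critical - (-1)), 0.5)
})

test_that("flat bifurcation points reproduce the printed values at b = 3/2", {
  bp <- flat_bifurcation_points(1.5)
  expect_equal(bp$mu0, 0)
  expect_equal(bp$mu1, -0.4375)
  expect_equal(round(bp$mu1, 2), -0.44)
  expect_equal(round(bp$mu_plus, 2), -0.62)
  expect_equal(round(bp$mu_minus, 2), -1.82)
  expect_true(bp$mu_minus < bp$mu_plus &&
              bp$mu_plus < bp$mu1 && bp$mu1 < bp$mu0)
  # defining conditions hold exactly: f = 0 and f' = -1 at the tangency
  for (mu in c(bp$mu_plus, bp$mu_minus)) {
    p <- sh_params(mu)
    fs <- flat_states(p)
    u <- if (mu == bp$mu_plus) fs$u_plus else fs$u_minus
    expect_lt(abs(local_force_prime(u, p) + 1), 1e-10)
  }
})

test_that("topological eigenvalue quartet: regimes and symmetry", {
  # mu = -1: pairwise collision at the origin
  q <- topological_eigenvalues(-1)$quartet
  expect_equal(sort(Mod(q)), c(0, 0, sqrt(2), sqrt(2)), tolerance = 1e-7)
  # mu = 0: pairwise collision at +-i
  q <- topological_eigenvalues(0)$quartet
  expect_equal(sort(Re(q)), rep(0, 4), tolerance = 1e-7)
  expect_equal(sort(Im(q)), c(-1, -1, 1, 1), tolerance = 1e-7)
  # -1 < mu < 0: four distinct imaginary roots
  q <- topological_eigenvalues(-0.25)$quartet
  expect_equal(sort(Re(q)), rep(0, 4), tolerance = 1e-9)
  expect_equal(sort(Im(q)),
               c(-sqrt(1.5), -sqrt(0.5), sqrt(0.5), sqrt(1.5)),
               tolerance = 1e-9)
  # quartet closed under negation and conjugation; defining quartic satisfied
  for (mu in c(0.5, 0.05, -0.5, -1, -1.7)) {
    q <- topological_eigenvalues(mu)$quartet
    expect_lt(max(abs((1 + q^2)^2 + mu)), 1e-10)
    for (s in q) {
      expect_lt(min(Mod(q - (-s))), 1e-7)
      expect_lt(min(Mod(q - Conj(s))), 1e-7)
    }
  }
})

test_that("regime report classifies and serializes", {
  rep <- regime_report(c(-0.5, 0, 0.3))
  expect_equal(rep$regime,
               c("global-pattern", "threshold", "stable-localized-capable"))
  f <- withr::local_tempfile(fileext = ".json")
  regime_report(c(-1, 0.2), f)
  js <- jsonlite::fromJSON(f)
  expect_equal(js[["0.2"]]$regime, "stable-localized-capable")
  expect_equal(js[["-1"]]$topological, "origin-collision")
})
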