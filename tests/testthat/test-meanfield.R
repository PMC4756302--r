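# Degree / two-jump-degree mean-field reduction and the pattern overlay.

test_that("global mean fields: constants, star example, linearity", {
  net <- star4()
  expect_equal(global_fields(net, rep(3.3, 4)), list(H_u = 3.3, H_uu = 3.3))
  # centre active: H_u = 3/6, H_uu = 0 (centre has k2 = 0)
  f <- global_fields(net, c(1, 0, 0, 0))
  expect_equal(f$H_u, 0.5)
  expect_equal(f$H_uu, 0)
  # linearity
  g <- generate_ba(50, 2, seed = 1)
  set.seed(5)
  u <- runif(g$n); v <- runif(g$n)
  fu <- global_fields(g, u); fv <- global_fields(g, v)
  fw <- global_fields(g, 2 * u - 3 * v)
  expect_equal(fw$H_u, 2 * fu$H_u - 3 * fv$H_u, tolerance = 1e-12)
  expect_equal(fw$H_uu, 2 * fu$H_uu - 3 * fv$H_uu, tolerance = 1e-12)
})

test_that("reduced rhs: uniform consistency and degenerate classes", {
  p <- sh_params(-0.7)
  # u = H_u = H_uu = c with s = alpha + beta collapses to the local force
  for (c0 in c(-0.4, 0.3, 1.2)) {
    g <- reduced_rhs(c0, node_class(4, 9), list(H_u = c0, H_uu = c0), p)
    expect_equal(g, local_force(c0, p), tolerance = 1e-12)
  }
  # alpha = 0 formal limit: bare local force
  expect_equal(reduced_rhs(0.8, node_class(0, 0, 0),
                           list(H_u = 5, H_uu = -2), sh_params(0.1)),
               local_force(0.8, sh_params(0.1)))
  # alpha = 1, beta = 1, zero fields at mu = -1: roots of f
  # (0 is a double root of f(u, -1) = u^2 (1.5 - u), kept with multiplicity)
  cls <- node_class(1, 1)
  nb <- node_branches(cls, list(H_u = 0, H_uu = 0), sh_params(-1))
  expect_equal(unique(round(nb$root, 8)), c(0, 1.5), tolerance = 1e-7)
  # stability from f' alone (alpha - alpha^2 = 0): f'(0) = 0 marginal,
  # f'(1.5) = -2.25 stable
  expect_true(nb$stable[nb$root > 1])
})

test_that("node branches: root count, residuals, ordering", {
  p <- sh_params(-0.25)
  fields <- list(H_u = 0.09, H_uu = 0.08)
  for (k in c(1, 2, 5, 12)) {
    nb <- node_branches(node_class(k, 3 * k), fields, p)
    expect_true(nrow(nb) %in% c(1, 2, 3))
    expect_equal(nb$root, sort(nb$root))
    g <- reduced_rhs(nb$root, node_class(k, 3 * k), fields, p)
    expect_lt(max(abs(g)), 1e-12)
  }
  # strongly negative discriminant: single real root
  nb <- node_branches(node_class(10, 30), fields, p)
  expect_equal(nrow(nb), 1)
})

test_that("overlay of a flat pattern has zero deviation everywhere", {
  net <- generate_ba(80, 2, seed = 4)
  p <- sh_params(-1)
  pat <- newton_steady(net, rep(1.5, net$n), p)
  # under the tree-consistent substitution the coupling terms cancel on
  # uniform states, so the flat state is an exact reduced fixed point
  ov <- mfa_overlay(net, pat, p, tree_consistent = TRUE)
  expect_lt(max(ov$table$deviation), 1e-8)
  expect_equal(ov$fraction_within, 1)
  # on this non-tree graph the measured-walk-count classes do not cancel
  ov2 <- mfa_overlay(net, pat, p)
  expect_gt(max(ov2$table$deviation), 1e-8)
  # on a tree the two class conventions coincide
  tr <- generate_ba(60, 1, seed = 3)
  pt <- newton_steady(tr, rep(1.5, tr$n), p)
  ovt <- mfa_overlay(tr, pt, p)
  expect_lt(max(ovt$table$deviation), 1e-8)
})

test_that("overlay report: ordering contract and serialization", {
  net <- suppressMessages(generate_er(300, 6, seed = 2))
  set.seed(9)
  pat <- evolve(net, runif(net$n, -0.01, 0.01), sh_params(-0.25))
  ov <- mfa_overlay(net, pat)
  tab <- ov$table
  # emitted order: non-decreasing k; within equal k, non-decreasing k2
  expect_true(all(diff(tab$k) >= 0))
  expect_true(all(tapply(tab$k2, tab$k, function(x) all(diff(x) >= 0))))
  expect_true(all(tab$deviation >= 0))
  expect_equal(mean(tab$within_tol), ov$fraction_within)
  f <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_mfa_report(ov, f, js)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), net$n)
  meta <- jsonlite::fromJSON(js)
  expect_equal(meta$fraction_within, ov$fraction_within, tolerance = 1e-12)
  # non-stationary input is rejected
  bad <- pat; bad$residual_norm <- 1
  expect_error(mfa_overlay(net, bad), "invalid-input")
})
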