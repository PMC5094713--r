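test_that("the solver matches a brute-force grid search on the toy pathway", {
  m <- toy_pathway()
  sol <- ecm_solve(m, "EMC3SP")

  # independent oracle: direct demand formulas with all constants 1
  # (E = (1 + s + p)/(s - p) per reaction), minimized on a grid
  X <- 1; Y <- 0.01
  g <- seq(log(1e-3), log(10), length.out = 120)
  best <- Inf
  for (a in exp(g)) {
    for (b in exp(g)) {
      if (a < X && b < a && b > Y) {
        q <- (1 + X + a) / (X - a) + (1 + a + b) / (a - b) +
          (1 + b + Y) / (b - Y)
        best <- min(best, q)
      }
    }
  }
  expect_lte(sol$q_opt, best + 1e-9)          # grid value is an upper bound
  # and a tight one, up to the resolution of the 120-point grid
  expect_lt((best - sol$q_opt) / best, 5e-3)
  expect_true(sol$diagnostics$converged)
  expect_equal(enzyme_cost(sol$x_opt, orient_reactions(m),
                           cost_function_spec("EMC3SP"))$q,
               sol$q_opt, tolerance = 1e-9)
})

test_that("EMC2S on a symmetric chain optimizes to equal forces at the MDF point", {
  m <- toy_pathway()
  sol <- ecm_solve(m, "EMC2S")
  mo <- orient_reactions(m)
  th <- driving_forces(sol$x_opt, mo)
  expect_equal(unname(th), rep(log(100) / 3, 3), tolerance = 1e-5)
  mdf <- max_min_driving_force(build_polytope(mo))
  expect_equal(sol$x_opt[c("A", "B")], mdf$x[c("A", "B")], tolerance = 1e-5)
})

test_that("thermodynamically infeasible fluxes raise an infeasibility error", {
  expect_error(ecm_solve(toy_pathway(X = 1, Y = 1), "EMC3SP"),
               class = "ecm_infeasible_error")
})

test_that("the regularizer breaks ties deterministically for flat tiers", {
  m <- toy_pathway()
  # EMC1 cost is constant; the quadratic term pins the solution to x_hat
  s1 <- ecm_solve(m, "EMC1", x_hat = c(A = -1, B = -2))
  s2 <- ecm_solve(m, "EMC1", x_hat = c(A = -0.5, B = -3))
  expect_equal(s1$q_opt, s2$q_opt, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(s1$x_opt, s2$x_opt, tolerance = 1e-4)))
  expect_equal(s1$x_opt[c("A", "B")], c(A = -1, B = -2), tolerance = 1e-2)

  # identical inputs give identical output
  s3 <- ecm_solve(m, "EMC1", x_hat = c(A = -1, B = -2))
  expect_identical(s1$x_opt, s3$x_opt)
})

test_that("strictly convex tiers are insensitive to the regularizer anchor", {
  m <- toy_pathway()
  s_mid <- ecm_solve(m, "EMC3SP")                       # midpoint anchor
  s_one <- ecm_solve(m, "EMC3SP", x_hat = c(A = 0, B = 0))
  expect_equal(s_mid$x_opt, s_one$x_opt, tolerance = 1e-4)
  expect_equal(s_mid$q_opt, s_one$q_opt, tolerance = 1e-9)
})

test_that("solutions are invariant to the reaction writing convention", {
  m <- toy_pathway()
  # rewrite R2 in the reversed convention with negated flux
  m_rev <- m
  m_rev$network$stoichiometry[, "R2"] <- -m$network$stoichiometry[, "R2"]
  kf <- m$params$kcat_fwd["R2"]
  m_rev$params$kcat_fwd["R2"] <- m$params$kcat_rev["R2"]
  m_rev$params$kcat_rev["R2"] <- kf
  m_rev$params$K_eq["R2"] <- 1 / m$params$K_eq["R2"]
  m_rev$params$dG0_over_RT["R2"] <- -m$params$dG0_over_RT["R2"]
  m_rev$flux <- flux_profile(c(R1 = 1, R2 = -1, R3 = 1))

  s1 <- ecm_solve(m, "EMC3SP")
  s2 <- ecm_solve(m_rev, "EMC3SP")
  expect_equal(s1$x_opt, s2$x_opt, tolerance = 1e-9)
  expect_equal(s1$E_opt, s2$E_opt, tolerance = 1e-9)
})

test_that("no sampled feasible point beats the reported optimum", {
  for (build in list(function() toy_pathway(),
                     function() random_model(5, "chain", seed = 13))) {
    m <- build()
    mo <- orient_reactions(m)
    poly <- build_polytope(mo)
    for (vv in c("EMC2SP", "EMC3SP", "EMC4CM")) {
      sol <- ecm_solve(m, vv)
      pts <- sample_metabolite_profiles(
        poly, mode = "broad",
        config = sampling_config(n_samples = 2000, seed = 17)
      )
      spec <- cost_function_spec(vv)
      qs <- apply(pts, 1L, function(x) enzyme_cost(x, mo, spec)$q)
      expect_true(all(sol$q_opt <= qs + 1e-6 * abs(qs)))
    }
  }
})

test_that("tolerance ranges collapse at alpha 0 and nest with alpha", {
  m <- toy_pathway()
  sol <- ecm_solve(m, "EMC3SP")

  tr0 <- tolerance_ranges(sol, m, "EMC3SP", alpha = 0)
  expect_equal(tr0$metabolites$x_lo, tr0$metabolites$x_hi)
  expect_equal(tr0$enzymes$E_lo, tr0$enzymes$E_hi)

  tr1 <- tolerance_ranges(sol, m, "EMC3SP", alpha = 0.01)
  tr2 <- tolerance_ranges(sol, m, "EMC3SP", alpha = 0.02)

  # every range contains the optimum
  expect_true(all(tr1$metabolites$x_lo <= sol$x_opt[c("A", "B")] + 1e-9))
  expect_true(all(tr1$metabolites$x_hi >= sol$x_opt[c("A", "B")] - 1e-9))
  expect_true(all(tr1$enzymes$E_lo <= sol$E_opt + 1e-9))
  expect_true(all(tr1$enzymes$E_hi >= sol$E_opt - 1e-9))

  # nested level sets: wider alpha gives wider ranges
  expect_true(all(tr2$metabolites$x_lo <= tr1$metabolites$x_lo + 1e-9))
  expect_true(all(tr2$metabolites$x_hi >= tr1$metabolites$x_hi - 1e-9))

  expect_error(tolerance_ranges(sol, m, "EMC3SP", alpha = -0.1),
               class = "ecm_domain_error")
})

test_that("metabolite tolerance endpoints sit exactly on the cost budget", {
  m <- toy_pathway()
  sol <- ecm_solve(m, "EMC3SP")
  tr <- tolerance_ranges(sol, m, "EMC3SP", alpha = 0.01)
  mo <- orient_reactions(m)
  spec <- cost_function_spec("EMC3SP")
  ids <- tr$metabolites$metabolite
  for (j in seq_along(ids)) {
    for (side in c("x_lo", "x_hi")) {
      a <- tr$metabolites[j, side]
      other <- setdiff(seq_along(ids), j)
      # inner 1-d minimization oracle over the remaining coordinate
      f <- function(t) {
        x <- stats::setNames(numeric(2), ids)
        x[j] <- a; x[other] <- t
        tryCatch(enzyme_cost(x, mo, spec)$q, error = function(e) 1e9)
      }
      mval <- suppressWarnings(
        stats::optimize(f, c(log(1e-3), log(10)), tol = 1e-10)$objective
      )
      expect_equal(mval, tr$q_tol, tolerance = 1e-6)
    }
  }
  # enzyme upper bounds are flagged as the heuristic they are
  expect_true(all(tr$enzymes$method == "heuristic"))
})
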