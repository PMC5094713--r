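test_that("the reversibility factor follows 1 - exp(-Theta)", {
  expect_equal(eta_rev(0), 0)
  expect_equal(eta_rev(log(2)), 0.5, tolerance = 1e-12)
  expect_equal(signif(eta_rev(0.1), 1), 0.1)       # ~0.095
  expect_equal(eta_rev(-3), 0)                      # clamped, no error
  th <- seq(0.01, 10, length.out = 200)
  expect_true(all(diff(eta_rev(th)) > 0))           # strictly increasing
  expect_true(all(eta_rev(th) < 1))
  expect_true(all(eta_rev(th) <= th))               # 1 - e^-x <= x
})

test_that("saturation factors match the tier denominators", {
  # 1S tier saturates to 1 as s/K_M grows
  sr_sat <- single_reaction_model(s = 1e6, p = 1e-6)
  expect_equal(unname(eta_kin(numeric(), sr_sat, "EMC3S")), 1,
               tolerance = 1e-5)

  # 1SP tier at s/K_S = p/K_P = 1: S/(1+S+P) = 1/3
  sr <- single_reaction_model(s = 1, p = 1)
  expect_equal(unname(eta_kin(numeric(), sr, "EMC3SP")), 1 / 3,
               tolerance = 1e-12)

  # common modular denominator for one substrate/one product collapses to
  # the 1SP form: (1+1) + (1+1) - 1 = 3
  expect_equal(unname(eta_kin(numeric(), sr, "EMC4CM")), 1 / 3,
               tolerance = 1e-12)
  set.seed(31)
  for (k in 1:20) {
    srk <- single_reaction_model(s = 10^stats::runif(1, -2, 2),
                                 p = 10^stats::runif(1, -2, 2),
                                 K_S = 10^stats::runif(1, -1, 1),
                                 K_P = 10^stats::runif(1, -1, 1))
    expect_equal(eta_kin(numeric(), srk, "EMC4CM"),
                 eta_kin(numeric(), srk, "EMC3SP"), tolerance = 1e-12)
  }

  # reversibility-only tiers have eta_kin exactly 1
  expect_equal(unname(eta_kin(numeric(), sr, "EMC2S")), 1)

  # EMC2SP depends on the profile only through the driving force
  m <- orient_reactions(toy_pathway())
  set.seed(32)
  for (k in 1:20) {
    x <- c(A = stats::runif(1, -3, 0), B = stats::runif(1, -4, -1))
    th <- driving_forces(x, m)
    kappa <- m$params$kcat_fwd / m$params$kcat_rev
    expect_equal(eta_kin(x, m, "EMC2SP"),
                 1 / (1 + exp(-th) * kappa), tolerance = 1e-12)
  }
})

test_that("a noncompetitive inhibitor at its K_I halves the efficiency", {
  m <- toy_pathway()
  m$params$modifiers <- data.frame(reaction = "R2", compound = "B",
                                   K_I = 0.5, mechanism = "noncompetitive")
  x <- c(A = log(0.5), B = log(0.5))   # [B] = K_I
  er <- eta_reg(x, orient_reactions(m))
  expect_equal(unname(er["R2"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(er["R1"]), 1)
})

test_that("enzyme demand inverts the reversible rate law", {
  # all constants 1, v = 1, s = 2, p = 1: E = (1+s+p)/(s-p) = 4
  sr <- single_reaction_model(s = 2, p = 1)
  E <- enzyme_demand(numeric(), sr, "EMC3SP")
  expect_equal(unname(E["R1"]), 4, tolerance = 1e-12)

  # capacity limit: saturated substrate, negligible product
  sr_cap <- single_reaction_model(s = 1e8, p = 1e-8)
  expect_equal(unname(enzyme_demand(numeric(), sr_cap, "EMC3SP")["R1"]),
               1, tolerance = 1e-4)

  # zero driving force is an infeasible point, named in the error
  sr_eq <- single_reaction_model(s = 1, p = 1, K_eq = 1)
  expect_error(enzyme_demand(numeric(), sr_eq, "EMC3SP"),
               class = "ecm_infeasible_error", regexp = "R1")
})

test_that("demand plugged back into the rate law reproduces the flux", {
  set.seed(41)
  m <- orient_reactions(toy_pathway())
  poly <- build_polytope(m)
  pts <- feasible_points(poly, 30, seed = 41)
  for (i in seq_len(nrow(pts))) {
    x <- pts[i, ]
    for (vv in c("EMC3SP", "EMC4CM")) {
      E <- enzyme_demand(x, m, vv)
      conc <- exp(full_log_conc_for_test(x, m))
      denom <- if (vv == "EMC4CM") "CM" else "1SP"
      v_back <- reaction_rate(conc, E, m, denominator = denom)
      expect_equal(unname(v_back), unname(m$flux$v), tolerance = 1e-9)
    }
  }
})

test_that("total cost matches hand-evaluated tier formulas on the toy", {
  m <- orient_reactions(toy_pathway())
  x_any <- c(A = -1, B = -2)

  # EMC0 with unit weights: sum of fluxes
  expect_equal(enzyme_cost(x_any, m, cost_function_spec("EMC0"))$q, 3)

  # EMC1 with h = kcat = 1, v = 1: q = 3, constant in x
  q1a <- enzyme_cost(x_any, m, cost_function_spec("EMC1"))$q
  q1b <- enzyme_cost(c(A = -0.2, B = -3), m, cost_function_spec("EMC1"))$q
  expect_equal(q1a, 3)
  expect_equal(q1a, q1b)

  # EMC2S at the equal-force point: 3/(1 - exp(-ln(100)/3))
  x_eq <- c(A = -log(100) / 3, B = -2 * log(100) / 3)
  q2 <- enzyme_cost(x_eq, m, cost_function_spec("EMC2S"))$q
  expect_equal(q2, 3 / (1 - exp(-log(100) / 3)), tolerance = 1e-9)
})

test_that("analytic gradients match central finite differences", {
  m <- orient_reactions(toy_pathway())
  m$params$modifiers <- data.frame(reaction = "R1", compound = "B",
                                   K_I = 0.4, mechanism = "noncompetitive")
  h <- 1e-6
  pts <- list(c(A = -0.5, B = -2), c(A = -1.2, B = -2.8),
              c(A = -0.1, B = -0.9))
  for (vv in c("EMC2S", "EMC2SP", "EMC3S", "EMC3SP", "EMC4CM")) {
    spec <- cost_function_spec(vv)
    for (x in pts) {
      g <- enzyme_cost(x, m, spec)$gradient[c("A", "B")]
      num <- vapply(c("A", "B"), function(i) {
        xp <- x; xp[i] <- xp[i] + h
        xm <- x; xm[i] <- xm[i] - h
        (enzyme_cost(xp, m, spec)$q - enzyme_cost(xm, m, spec)$q) / (2 * h)
      }, numeric(1))
      expect_lt(max(abs(g - num) / pmax(abs(num), 1e-8)), 1e-6)
    }
  }
  # constant tiers have zero gradient
  expect_equal(unname(enzyme_cost(pts[[1]], m,
                                  cost_function_spec("EMC1"))$gradient),
               rep(0, 4))
})

test_that("each cost tier lower-bounds the next at feasible points", {
  m <- orient_reactions(toy_pathway())
  poly <- build_polytope(m)
  pts <- feasible_points(poly, 100, seed = 51)
  chains <- list(c("EMC1", "EMC2S", "EMC3S"),
                 c("EMC1", "EMC2SP", "EMC3SP", "EMC4CM"))
  for (i in seq_len(nrow(pts))) {
    for (chain in chains) {
      qs <- vapply(chain, function(vv) {
        enzyme_cost(pts[i, ], m, cost_function_spec(vv))$q
      }, numeric(1))
      expect_true(all(diff(qs) >= -1e-9))
    }
  }
})

test_that("enzyme cost is convex along random feasible segments", {
  models <- list(orient_reactions(toy_pathway()),
                 orient_reactions(random_model(5, "chain", seed = 7)))
  for (m in models) {
    poly <- build_polytope(m)
    a <- feasible_points(poly, 150, seed = 61)
    b <- feasible_points(poly, 150, seed = 62)
    for (vv in c("EMC1", "EMC2S", "EMC2SP", "EMC3S", "EMC3SP", "EMC4CM")) {
      spec <- cost_function_spec(vv)
      for (i in seq_len(nrow(a))) {
        qa <- enzyme_cost(a[i, ], m, spec)$q
        qb <- enzyme_cost(b[i, ], m, spec)$q
        qm <- enzyme_cost((a[i, ] + b[i, ]) / 2, m, spec)$q
        expect_lte(qm, (qa + qb) / 2 + 1e-9)
      }
    }
  }
})

test_that("reversibility-based cost dominates the 1/Theta lower estimate", {
  m <- orient_reactions(toy_pathway())
  poly <- build_polytope(m)
  pts <- feasible_points(poly, 50, seed = 71)
  for (i in seq_len(nrow(pts))) {
    th <- driving_forces(pts[i, ], m)
    q2 <- enzyme_cost(pts[i, ], m, cost_function_spec("EMC2S"))$q
    expect_gte(q2, sum(1 / th) - 1e-9)    # since 1 - e^-x <= x
  }
})

test_that("flux burdens decompose the cost and respect the capacity bound", {
  m <- orient_reactions(toy_pathway())

  # ideal enzyme: all efficiency factors 1 under EMC1
  fb1 <- flux_burden(c(A = -1, B = -2), m, "EMC1")
  expect_equal(fb1$a_v, fb1$a_cat, tolerance = 1e-12)
  expect_equal(fb1$a_cat,
               unname(m$params$h_E / m$params$kcat_fwd), tolerance = 1e-12)

  # Theta = 0.1 with full saturation: a_v = 1/(1 - e^-0.1) ~ 10.5
  sr <- single_reaction_model(s = 1, p = 1, K_eq = exp(0.1))
  fb2 <- flux_burden(numeric(), sr, "EMC2S")
  expect_equal(fb2$a_v, 1 / (1 - exp(-0.1)), tolerance = 1e-9)

  # q = sum(a_v * v) and a_v >= a_cat everywhere feasible
  poly <- build_polytope(m)
  pts <- feasible_points(poly, 20, seed = 81)
  for (i in seq_len(nrow(pts))) {
    fb <- flux_burden(pts[i, ], m, "EMC4CM")
    q <- enzyme_cost(pts[i, ], m, cost_function_spec("EMC4CM"))$q
    expect_equal(sum(fb$a_v * m$flux$v), q, tolerance = 1e-12)
    expect_true(all(fb$a_v >= fb$a_cat - 1e-12))
  }
})

test_that("pathway specific activity follows from mass bookkeeping", {
  # dimensional oracle: E in mM, m_l in Da (g/mol) => q in mg/l;
  # A_pw = v/q in mmol/s per mg enzyme
  m_l <- c(R1 = 40000, R2 = 40000, R3 = 40000)
  E <- c(R1 = 1, R2 = 1, R3 = 1)
  q_mass <- sum(m_l * E)                 # 120000 mg/l
  expect_equal(pathway_specific_activity(1, q_mass), 1 / 120000)

  # doubling enzyme at fixed flux halves the specific activity
  expect_equal(pathway_specific_activity(1, sum(m_l * 2 * E)),
               pathway_specific_activity(1, q_mass) / 2)

  expect_equal(pathway_specific_activity(0, q_mass), 0)
  expect_error(pathway_specific_activity(1, 0), class = "ecm_domain_error")
})

test_that("mass-based burdens wire protein masses into the cost", {
  m <- orient_reactions(toy_pathway())
  x <- c(A = -1, B = -2)
  spec_u <- cost_function_spec("EMC3SP", burden_mode = "uniform")
  spec_m <- cost_function_spec("EMC3SP", burden_mode = "protein_mass")
  qu <- enzyme_cost(x, m, spec_u)
  qm <- enzyme_cost(x, m, spec_m)
  expect_equal(qm$q, 40000 * qu$q, tolerance = 1e-12)
  a <- pathway_specific_activity(1, qm$q)
  expect_equal(a, 1 / sum(40000 * qu$breakdown$E_l), tolerance = 1e-12)
})

test_that("tier validation fails fast when required constants are absent", {
  m <- orient_reactions(toy_pathway())
  m$params$K_eq[] <- NA_real_
  m$params$dG0_over_RT[] <- NA_real_
  expect_error(enzyme_cost(c(A = -1, B = -2), m,
                           cost_function_spec("EMC2S")),
               class = "ecm_parameter_error")
  m2 <- orient_reactions(toy_pathway())
  m2$params$K_M["A", "R2"] <- NA_real_
  expect_error(enzyme_cost(c(A = -1, B = -2), m2,
                           cost_function_spec("EMC3SP")),
               class = "ecm_parameter_error")
  # EMC2S does not need K_M: same model must evaluate fine
  expect_silent(enzyme_cost(c(A = -1, B = -2), m2,
                            cost_function_spec("EMC2S")))
})
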