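test_that("reaction formula grammar parses coefficients and rejects malformed input", {
  f <- parse_reaction_formula("2 A + B <=> C")
  expect_equal(f$substrates$id, c("A", "B"))
  expect_equal(f$substrates$coef, c(2, 1))
  expect_equal(f$products$id, "C")
  expect_error(parse_reaction_formula("A -> B"), "<=>")
  expect_error(parse_reaction_formula("A <=> B <=> C"), "<=>")
  expect_error(parse_reaction_formula("2 A A + B <=> C"), "cannot parse")
})

test_that("the toy pathway writes and reloads with chain structure intact", {
  m <- toy_pathway()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model(m, path)
  m2 <- load_model(path)

  S <- m2$network$stoichiometry
  expect_equal(dim(S), c(4L, 3L))
  expect_equal(unname(S[, "R1"]), c(-1, 1, 0, 0))
  expect_equal(unname(S[, "R2"]), c(0, -1, 1, 0))
  expect_equal(unname(S[, "R3"]), c(0, 0, -1, 1))

  # full numeric round trip
  expect_equal(m2$network$stoichiometry, m$network$stoichiometry)
  expect_equal(m2$network$fixed_values, m$network$fixed_values,
               tolerance = 1e-12)
  for (fld in c("kcat_fwd", "kcat_rev", "K_eq", "h_E", "m_l")) {
    expect_equal(m2$params[[fld]], m$params[[fld]], tolerance = 1e-12)
  }
  expect_equal(m2$params$K_M, m$params$K_M, tolerance = 1e-12)
  expect_equal(m2$flux$v, m$flux$v, tolerance = 1e-12)
  expect_equal(m2$bounds$lower, m$bounds$lower, tolerance = 1e-12)
  expect_equal(m2$bounds$upper, m$bounds$upper, tolerance = 1e-12)
})

test_that("measurement tables round-trip through the SBtab writer", {
  m <- toy_pathway()
  m$measurements <- measurement_set(
    metabolite_conc = c(A = 0.5, B = 0.2),
    enzyme_conc = c(R1 = 4, R2 = 5, R3 = 6)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$measurements$metabolite_conc,
               m$measurements$metabolite_conc, tolerance = 1e-12)
  expect_equal(m2$measurements$enzyme_conc,
               m$measurements$enzyme_conc, tolerance = 1e-12)
})

test_that("loading rejects degenerate and inconsistent table sets", {
  write_tables <- function(..., drop_reactions = FALSE, extra_param = NULL,
                           dup_param = FALSE, drop_kcat = FALSE) {
    m <- toy_pathway()
    path <- tempfile(fileext = ".tsv")
    write_model(m, path)
    tabs <- read_sbtab(path)
    if (drop_reactions) tabs$Reaction <- tabs$Reaction[0, , drop = FALSE]
    if (!is.null(extra_param)) {
      row <- tabs$Parameter[1, , drop = FALSE]
      row$`Reaction:SBML:reaction:id` <- extra_param
      tabs$Parameter <- rbind(tabs$Parameter, row)
    }
    if (dup_param) tabs$Parameter <- rbind(tabs$Parameter, tabs$Parameter[1, ])
    if (drop_kcat) {
      qt <- tabs$Parameter$QuantityType
      tabs$Parameter <-
        tabs$Parameter[qt != "substrate catalytic rate constant", ]
    }
    out <- tempfile(fileext = ".tsv")
    write_sbtab(tabs, out)
    out
  }
  expect_error(load_model(write_tables(drop_reactions = TRUE)),
               class = "ecm_reference_error")
  expect_error(load_model(write_tables(extra_param = "R99")),
               class = "ecm_reference_error")
  expect_error(load_model(write_tables(dup_param = TRUE)),
               class = "ecm_conflict_error")
  expect_error(load_model(write_tables(drop_kcat = TRUE)),
               class = "ecm_parameter_error")
})

test_that("missing Michaelis constants are filled with the flagged default prior", {
  m <- toy_pathway()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model(m, path)
  tabs <- read_sbtab(path)
  qt <- tabs$Parameter$QuantityType
  cpd <- tabs$Parameter$`Compound:SBML:species:id`
  tabs$Parameter <- tabs$Parameter[!(qt == "michaelis constant" & cpd == "A"), ]
  out <- withr::local_tempfile(fileext = ".tsv")
  write_sbtab(tabs, out)
  m2 <- load_model(out)
  expect_equal(unname(m2$params$K_M["A", c("R1", "R2")]), c(0.1, 0.1))
  expect_true(all(m2$params$km_filled["A", c("R1", "R2")]))
  expect_false(any(m2$params$km_filled["B", c("R2", "R3")]))
})

test_that("orientation flips stoichiometry, kinetics and thermodynamics together", {
  m <- two_step_chain(K_eq = c(R1 = 10, R2 = 1),
                      kcat_fwd = c(R1 = 2, R2 = 1))
  # write reaction 1 against its flux
  m_rev <- m
  m_rev$network$stoichiometry[, "R1"] <- -m$network$stoichiometry[, "R1"]
  m_rev$params$kcat_fwd["R1"] <- m$params$kcat_rev["R1"]
  m_rev$params$kcat_rev["R1"] <- m$params$kcat_fwd["R1"]
  m_rev$params$K_eq["R1"] <- 1 / m$params$K_eq["R1"]
  m_rev$params$dG0_over_RT["R1"] <- -m$params$dG0_over_RT["R1"]
  m_rev$flux <- flux_profile(c(R1 = -1, R2 = 1))

  back <- orient_reactions(m_rev)
  expect_equal(back$network$stoichiometry, m$network$stoichiometry)
  expect_equal(back$params$kcat_fwd, m$params$kcat_fwd)
  expect_equal(back$params$kcat_rev, m$params$kcat_rev)
  expect_equal(back$params$K_eq, m$params$K_eq)
  expect_equal(back$flux$v, m$flux$v)

  # an already-oriented model passes through unchanged (involution fixpoint)
  expect_equal(orient_reactions(back), back)

  # the physical rate is convention-independent: the reversed reaction run
  # on the same concentrations carries the negated rate
  conc <- c(X = 1, A = 0.3, Y = 0.05)
  E <- c(R1 = 1, R2 = 1)
  v_fwd <- reaction_rate(conc, E, m)
  v_rev <- reaction_rate(conc, E, m_rev)
  expect_equal(unname(v_rev["R1"]), -unname(v_fwd["R1"]), tolerance = 1e-12)
})

test_that("zero-flux reactions drop out of cost terms and polytope constraints", {
  m <- toy_pathway()
  m$flux <- flux_profile(c(R1 = 1, R2 = 1, R3 = 0))
  mo <- orient_reactions(m)
  poly <- build_polytope(mo)
  expect_equal(poly$active_ids, c("R1", "R2"))
  ec <- enzyme_cost(max_min_driving_force(poly)$x, mo,
                    cost_function_spec("EMC3SP"))
  expect_setequal(ec$breakdown$reaction, c("R1", "R2"))
})

test_that("Haldane balancing reproduces closed forms and the least-squares projection", {
  S <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "R1"))
  net <- network_model(S)
  KM <- S; KM[] <- 1

  # closed form: kcat_rev = kcat_fwd * K_P / (K_S * K_eq)
  par <- kinetic_parameters(net, kcat_fwd = c(R1 = 1), K_M = KM,
                            K_eq = c(R1 = 10))
  bal <- balance_haldane(par, net)
  expect_equal(unname(bal$kcat_rev["R1"]), 0.1, tolerance = 1e-12)
  expect_lt(abs(haldane_residuals(bal, net)["R1"]), 1e-9)

  # already-consistent sets are fixed points of the projection
  bal2 <- balance_haldane(bal, net)
  expect_equal(log(bal2$kcat_fwd), log(bal$kcat_fwd), tolerance = 1e-12)
  expect_equal(log(bal2$kcat_rev), log(bal$kcat_rev), tolerance = 1e-12)
  expect_equal(log(bal2$K_eq), log(bal$K_eq), tolerance = 1e-12)
  expect_equal(log(bal2$K_M["A", 1]), log(bal$K_M["A", 1]),
               tolerance = 1e-12)

  # conflicting observations: compare against an lm() fit of the same
  # weighted least-squares problem in the free coordinates
  # (d = ln K_eq, kf = ln kcat_fwd, kS, kP = ln K_M)
  par3 <- kinetic_parameters(net, kcat_fwd = c(R1 = 2), kcat_rev = c(R1 = 1),
                             K_M = KM, K_eq = c(R1 = 8))
  bal3 <- balance_haldane(par3, net)
  X <- rbind(
    c(1, 0, 0, 0),   # kf observation
    c(1, -1, -1, 1), # ln kcat_rev = kf - d - kS + kP... sign check below
    c(0, 1, 0, 0),   # d observation
    c(0, 0, 1, 0),   # kS
    c(0, 0, 0, 1)    # kP
  )
  # Haldane: ln kcat_rev = kf - d + kP - kS
  X[2, ] <- c(1, -1, -1, 1)
  y <- c(log(2), log(1), log(8), 0, 0)
  fit <- stats::lm.fit(X, y)
  co <- fit$coefficients
  expect_equal(unname(log(bal3$kcat_fwd["R1"])), unname(co[1]),
               tolerance = 1e-9)
  expect_equal(unname(log(bal3$K_eq["R1"])), unname(co[2]),
               tolerance = 1e-9)
  expect_equal(unname(log(bal3$K_M["A", 1])), unname(co[3]),
               tolerance = 1e-9)
  expect_equal(unname(log(bal3$K_M["B", 1])), unname(co[4]),
               tolerance = 1e-9)
  expect_lt(abs(haldane_residuals(bal3, net)["R1"]), 1e-9)

  # idempotence on the balanced output
  bal4 <- balance_haldane(bal3, net)
  expect_equal(log(bal4$K_eq), log(bal3$K_eq), tolerance = 1e-10)
})

test_that("under-determined balancing without thermodynamic data errors", {
  # two-reaction chain with no K_eq, dG0 or kcat_rev anywhere: the
  # equilibrium constants are not pinned down
  S <- matrix(0, 3, 2, dimnames = list(c("A", "B", "C"), c("R1", "R2")))
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  S["B", "R2"] <- -1; S["C", "R2"] <- 1
  net <- network_model(S)
  KM <- S; KM[] <- ifelse(S != 0, 1, NA_real_)
  par <- kinetic_parameters(net, kcat_fwd = c(R1 = 1, R2 = 2), K_M = KM)
  expect_error(balance_haldane(par, net), class = "ecm_parameter_error",
               regexp = "priors")
})
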