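# Shared fixture builders for the test suite.

# Two-reaction chain X <=> A <=> Y with configurable constants; A free.
two_step_chain <- function(K_eq = c(R1 = 10, R2 = 1),
                           kcat_fwd = c(R1 = 1, R2 = 1),
                           X = 1, Y = 1, v = 1,
                           conc_min = 1e-4, conc_max = 1e4) {
  S <- matrix(0, 3, 2, dimnames = list(c("X", "A", "Y"), c("R1", "R2")))
  S["X", "R1"] <- -1; S["A", "R1"] <- 1
  S["A", "R2"] <- -1; S["Y", "R2"] <- 1
  net <- network_model(S, fixed_values = c(X = X, Y = Y))
  KM <- S
  KM[] <- ifelse(S != 0, 1, NA_real_)
  par <- kinetic_parameters(
    net, kcat_fwd = kcat_fwd, kcat_rev = kcat_fwd / K_eq,
    K_M = KM, K_eq = K_eq
  )
  ecm_model(net, par, flux_profile(c(R1 = v, R2 = v)),
            bounds = list(lower = c(A = conc_min), upper = c(A = conc_max)))
}

# Single reaction A <=> B with both reactants clamped, used to probe the
# rate law at chosen substrate/product levels.
single_reaction_model <- function(s, p, K_eq = 1, kcat_fwd = 1,
                                  kcat_rev = kcat_fwd / K_eq,
                                  K_S = 1, K_P = 1, v = 1) {
  S <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "R1"))
  net <- network_model(S, fixed_values = c(A = s, B = p))
  KM <- matrix(c(K_S, K_P), 2, 1, dimnames = dimnames(S))
  par <- kinetic_parameters(net, kcat_fwd = c(R1 = kcat_fwd),
                            kcat_rev = c(R1 = kcat_rev),
                            K_M = KM, K_eq = c(R1 = K_eq))
  ecm_model(net, par, flux_profile(c(R1 = v)),
            bounds = list(lower = NULL, upper = NULL))
}

# Random feasible interior points of a polytope: convex mixtures of the
# extreme points and the witness, pulled toward the witness to stay off
# the boundary.
feasible_points <- function(poly, n, seed = 1, pull = 0.2) {
  set.seed(seed)
  ep <- rbind(extreme_points(poly), poly$witness[poly$free_ids])
  k <- nrow(ep)
  w <- matrix(stats::rgamma(n * k, 1), n, k)
  w <- w / rowSums(w)
  pts <- w %*% ep
  pts <- (1 - pull) * pts +
    pull * matrix(poly$witness[poly$free_ids], n, ncol(pts), byrow = TRUE)
  colnames(pts) <- poly$free_ids
  pts
}

full_log_conc_for_test <- function(x, model) {
  enzcost:::full_log_concentrations(x, model)
}

expect_rel_equal <- function(actual, expected, tol = 1e-6) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
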