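# Built-in test models: the three-reaction toy pathway, random
# thermodynamically consistent models, and synthetic measurements.

#' The three-reaction toy pathway
#'
#' The linear pathway `X <=> A <=> B <=> Y` with reversible
#' Michaelis-Menten kinetics and all equilibrium constants, turnover
#' numbers, Michaelis constants and burdens equal to 1. The boundary
#' metabolites X and Y are clamped; the intermediates A and B are free
#' within physiological bounds. With the default boundary levels the total
#' driving force along the chain is `ln(X/Y) = ln 100`, so the max-min
#' driving force solution splits it evenly: `MDF = ln(100)/3`.
#'
#' @param X,Y Boundary concentrations in mM (defaults 1 and 0.01).
#' @param v Pathway flux in mM/s through all three reactions (default 1).
#' @param conc_min,conc_max Concentration bounds for the free intermediates
#'   in mM (defaults 1e-3 and 10).
#' @param m_l Protein masses in Da assigned to the three enzymes (default
#'   40000, a typical enzyme mass; only used by mass-based burden modes).
#' @return An [ecm_model()].
#' @export
toy_pathway <- function(X = 1, Y = 0.01, v = 1,
                        conc_min = 1e-3, conc_max = 10, m_l = 40000) {
  assert_positive(c(X, Y), "boundary concentrations")
  mets <- c("X", "A", "B", "Y")
  rxns <- c("R1", "R2", "R3")
  S <- matrix(0, 4, 3, dimnames = list(mets, rxns))
  S["X", "R1"] <- -1; S["A", "R1"] <- 1
  S["A", "R2"] <- -1; S["B", "R2"] <- 1
  S["B", "R3"] <- -1; S["Y", "R3"] <- 1
  net <- network_model(S, fixed_values = c(X = X, Y = Y))
  ones <- stats::setNames(rep(1, 3), rxns)
  KM <- S
  KM[] <- ifelse(S != 0, 1, NA_real_)
  par <- kinetic_parameters(
    net, kcat_fwd = ones, kcat_rev = ones, K_M = KM, K_eq = ones,
    h_E = ones, m_l = stats::setNames(rep(m_l, 3), rxns)
  )
  ecm_model(
    net, par, flux_profile(stats::setNames(rep(v, 3), rxns)),
    bounds = list(
      lower = c(A = conc_min, B = conc_min),
      upper = c(A = conc_max, B = conc_max)
    )
  )
}

#' Generate a random thermodynamically consistent model
#'
#' Draws metabolite formation energies first and derives equilibrium
#' constants from them, so Wegscheider cycle conditions hold by
#' construction; Michaelis constants and forward turnover numbers are drawn
#' log-normally around typical values (0.1 mM and 10/s) and backward
#' turnover numbers follow from the Haldane relationship. Boundary
#' concentrations are then placed so that the unit flux along the pathway
#' is thermodynamically feasible, which is verified by building the
#' polytope before returning.
#'
#' @param n_metabolites Number of metabolites (>= 3).
#' @param topology `"chain"` (linear pathway) or `"branched"` (a linear
#'   backbone with one branch leaving from its midpoint to an extra
#'   boundary metabolite).
#' @param seed RNG seed; the returned bundle is a deterministic function of
#'   it.
#' @return An [ecm_model()].
#' @export
random_model <- function(n_metabolites, topology = c("chain", "branched"),
                         seed = 1L) {
  topology <- match.arg(topology)
  if (n_metabolites < 3L) {
    stopf("n_metabolites must be at least 3", class = "ecm_domain_error")
  }
  set.seed(seed)
  n <- n_metabolites
  mets <- paste0("M", seq_len(n))

  if (topology == "chain") {
    edges <- cbind(seq_len(n - 1L), seq(2L, n))
    boundary <- c(1L, n)
    v <- rep(1, n - 1L)
  } else {
    mets <- c(mets, "Mb")
    mid <- max(2L, ceiling(n / 2))
    edges <- rbind(cbind(seq_len(n - 1L), seq(2L, n)),
                   c(mid, n + 1L))
    boundary <- c(1L, n, n + 1L)
    # backbone carries the full unit flux up to the branch point, after
    # which it splits evenly between the two sinks
    v <- c(rep(1, mid - 1L), rep(0.5, n - mid), 0.5)
  }
  rxns <- paste0("R", seq_len(nrow(edges)))
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, rxns))
  for (k in seq_len(nrow(edges))) {
    S[edges[k, 1L], k] <- -1
    S[edges[k, 2L], k] <- 1
  }

  for (attempt in seq_len(100L)) {
    g <- stats::rnorm(length(mets), 0, 2)     # formation energies, RT units
    ln_keq <- -drop(crossprod(S, g))
    KM <- S
    KM[] <- NA_real_
    idx <- which(S != 0)
    KM[idx] <- 10^stats::rnorm(length(idx), -1, 0.5)   # ~0.1 mM typical
    kf <- 10^stats::rnorm(length(rxns), 1, 0.5)        # ~10/s typical
    ln_krev <- log(kf) - ln_keq
    pairs <- which(S != 0, arr.ind = TRUE)
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1L]; l <- pairs[p, 2L]
      ln_krev[l] <- ln_krev[l] + sign(S[i, l]) * abs(S[i, l]) * log(KM[i, l])
    }

    # place boundary levels so each source-to-sink route has a comfortable
    # positive total driving force (one RT per reaction step); the source
    # sits at the standard concentration
    x_fix <- stats::setNames(rep(0, length(boundary)), mets[boundary])
    if (topology == "chain") {
      route <- seq_len(n - 1L)
      x_fix[mets[n]] <- sum(ln_keq[route]) - length(route)
    } else {
      mid <- edges[nrow(edges), 1L]
      route_main <- seq_len(n - 1L)
      route_branch <- c(seq_len(mid - 1L), nrow(edges))
      x_fix[mets[n]] <- sum(ln_keq[route_main]) - length(route_main)
      x_fix[mets[n + 1L]] <- sum(ln_keq[route_branch]) - length(route_branch)
    }
    fixed_values <- exp(x_fix)

    net <- network_model(S, fixed_values = fixed_values)
    par <- kinetic_parameters(
      net,
      kcat_fwd = stats::setNames(kf, rxns),
      kcat_rev = stats::setNames(exp(ln_krev), rxns),
      K_M = KM, K_eq = stats::setNames(exp(ln_keq), rxns)
    )
    free <- mets[-boundary]
    span <- exp(range(c(0, x_fix)))
    model <- ecm_model(
      net, par, flux_profile(stats::setNames(v, rxns)),
      bounds = list(
        lower = stats::setNames(rep(min(span[1L], 1) * 1e-4, length(free)),
                                free),
        upper = stats::setNames(rep(max(span[2L], 1) * 1e4, length(free)),
                                free)
      )
    )
    ok <- tryCatch({
      build_polytope(orient_reactions(model))
      TRUE
    }, ecm_infeasible_error = function(e) FALSE)
    if (ok) return(model)
  }
  stopf("could not generate a feasible random model in 100 draws")
}

#' Generate synthetic noisy measurements from a solved state
#'
#' Multiplies each predicted level by `10^epsilon` with
#' `epsilon ~ N(0, noise_log10_sd)`, mimicking log-normally distributed
#' measurement error.
#'
#' @param sol An [ecm_solve()] result.
#' @param noise_log10_sd Log10-scale noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return A [measurement_set()] with enzyme and metabolite levels.
#' @export
synthetic_measurements <- function(sol, noise_log10_sd = 0.3, seed = 1L) {
  if (noise_log10_sd < 0) {
    stopf("noise_log10_sd must be nonnegative", class = "ecm_domain_error")
  }
  set.seed(seed)
  E <- sol$E_opt * 10^stats::rnorm(length(sol$E_opt), 0, noise_log10_sd)
  conc <- sol$c_opt * 10^stats::rnorm(length(sol$c_opt), 0, noise_log10_sd)
  measurement_set(metabolite_conc = conc, enzyme_conc = E)
}
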