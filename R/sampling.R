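# Monte-Carlo sensitivity to parameter/flux uncertainty, and the
# cost-optimality test against measured enzyme levels.

#' Configuration for stochastic sampling
#'
#' @param n_samples Number of Monte-Carlo draws.
#' @param seed RNG seed; recorded in every output.
#' @param kcat_log10_sd Log10-scale standard deviation for forward turnover
#'   numbers (default 0.2).
#' @param km_log10_sd Log10-scale standard deviation for Michaelis constants
#'   (default 0.2).
#' @param formation_sd_RT Standard deviation of metabolite formation
#'   energies in RT units (default 0.05); equilibrium constants are derived
#'   from the perturbed formation energies, so every sampled set satisfies
#'   the Haldane relationships and Wegscheider conditions exactly.
#' @param flux_rel_sd Relative standard deviation of fluxes (default 0.15,
#'   a typical experimental error bar). Draws that would flip a flux sign
#'   are rejected and redrawn.
#' @param fixed_met_rel_range Fixed metabolite concentrations are varied
#'   uniformly within +/- this fraction (default 0.05).
#' @param metabolite_ln_sd Natural-log-scale standard deviation for local
#'   metabolite-profile sampling around the optimum (default 0.05).
#' @return An object of class `sampling_config`.
#' @export
sampling_config <- function(n_samples = 100L, seed = 1L,
                            kcat_log10_sd = 0.2, km_log10_sd = 0.2,
                            formation_sd_RT = 0.05, flux_rel_sd = 0.15,
                            fixed_met_rel_range = 0.05,
                            metabolite_ln_sd = 0.05) {
  sds <- c(kcat_log10_sd, km_log10_sd, formation_sd_RT, flux_rel_sd,
           fixed_met_rel_range, metabolite_ln_sd)
  if (any(sds < 0)) {
    stopf("all sampling standard deviations must be nonnegative",
          class = "ecm_domain_error")
  }
  structure(
    list(n_samples = as.integer(n_samples), seed = as.integer(seed),
         kcat_log10_sd = kcat_log10_sd, km_log10_sd = km_log10_sd,
         formation_sd_RT = formation_sd_RT, flux_rel_sd = flux_rel_sd,
         fixed_met_rel_range = fixed_met_rel_range,
         metabolite_ln_sd = metabolite_ln_sd),
    class = "sampling_config"
  )
}

# Minimum-norm formation energies (RT units) reproducing the equilibrium
# constants: ln K_eq = -S' g.
formation_energies <- function(par, net) {
  bal <- attr(par, "balance")
  if (!is.null(bal$formation_energy_RT)) {
    return(bal$formation_energy_RT)
  }
  S <- net$stoichiometry
  ok <- !is.na(par$K_eq)
  A <- -t(S[, ok, drop = FALSE])
  y <- log(par$K_eq[ok])
  sv <- svd(A)
  pos <- sv$d > max(dim(A)) * max(sv$d, 0) * .Machine$double.eps
  g <- drop(sv$v[, pos, drop = FALSE] %*%
              ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos]))
  resid <- max(abs(A %*% g - y), 0)
  if (resid > 1e-6) {
    stopf("equilibrium constants violate the Wegscheider cycle conditions (residual %.3g); balance the parameters first",
          resid, class = "ecm_parameter_error")
  }
  stats::setNames(g, net$metabolite_ids)
}

#' Sample thermodynamically consistent kinetic parameter sets
#'
#' Draws parameter sets around a balanced base set by perturbing the free
#' coordinates only - metabolite formation energies, log forward turnover
#' numbers, and log Michaelis constants - and deriving equilibrium
#' constants and backward turnover numbers from them. Every sample
#' therefore satisfies the Haldane relationships exactly.
#'
#' @param par A balanced [kinetic_parameters()] (see [balance_haldane()]).
#' @param net The corresponding [network_model()].
#' @param config A [sampling_config()].
#' @return List of `config$n_samples` [kinetic_parameters()] objects.
#' @export
sample_parameters <- function(par, net, config = sampling_config()) {
  res <- haldane_residuals(par, net)
  if (any(abs(res) > 1e-6, na.rm = TRUE)) {
    stopf("base parameters are not Haldane-consistent; run balance_haldane first",
          class = "ecm_parameter_error")
  }
  g0 <- formation_energies(par, net)
  S <- net$stoichiometry
  pairs <- which(S != 0, arr.ind = TRUE)
  ln10 <- log(10)
  set.seed(config$seed)
  lapply(seq_len(config$n_samples), function(i) {
    g <- g0 + stats::rnorm(length(g0), 0, config$formation_sd_RT)
    lkf <- log(par$kcat_fwd) +
      stats::rnorm(length(par$kcat_fwd), 0, config$kcat_log10_sd * ln10)
    KM <- par$K_M
    KM[pairs] <- exp(log(par$K_M[pairs]) +
                       stats::rnorm(nrow(pairs), 0,
                                    config$km_log10_sd * ln10))
    ln_keq <- -drop(crossprod(S, g))
    ln_krev <- lkf - ln_keq
    for (p in seq_len(nrow(pairs))) {
      ii <- pairs[p, 1L]; ll <- pairs[p, 2L]
      ln_krev[ll] <- ln_krev[ll] +
        sign(S[ii, ll]) * abs(S[ii, ll]) * log(KM[ii, ll])
    }
    kinetic_parameters(
      net,
      kcat_fwd = stats::setNames(exp(lkf), net$reaction_ids),
      kcat_rev = stats::setNames(exp(ln_krev), net$reaction_ids),
      K_M = KM,
      K_eq = stats::setNames(exp(ln_keq), net$reaction_ids),
      h_E = par$h_E, m_l = par$m_l, modifiers = par$modifiers,
      kcat_inf = par$kcat_inf, km_filled = par$km_filled
    )
  })
}

#' Monte-Carlo sensitivity of the cost-optimal state
#'
#' Repeatedly perturbs kinetic parameters (Haldane-consistently), fluxes
#' (relative Gaussian noise, sign-preserving) and fixed metabolite levels
#' (uniform within a relative range), re-solves the cost minimization for
#' each draw, and summarizes the resulting enzyme level distributions.
#'
#' @param model An [ecm_model()] with balanced parameters.
#' @param spec A [cost_function_spec()] or tier name.
#' @param config A [sampling_config()].
#' @return List with `summary` (per-enzyme median and 25%/75% quantiles
#'   over the feasible draws), `samples` (matrix of enzyme levels, one row
#'   per feasible draw), `n_infeasible`, `warn_majority_infeasible`, and
#'   the seed used.
#' @export
monte_carlo_ecm <- function(model, spec = "EMC4CM",
                            config = sampling_config()) {
  if (!inherits(spec, "cost_function_spec")) spec <- cost_function_spec(spec)
  model <- orient_reactions(model)
  pars <- sample_parameters(model$params, model$network, config)
  net <- model$network
  v0 <- model$flux$v
  active <- net$reaction_ids[model$flux$active_mask]
  set.seed(config$seed + 1L)
  draws <- list()
  n_inf <- 0L
  for (i in seq_len(config$n_samples)) {
    v <- v0
    for (l in names(v0)[v0 != 0]) {
      repeat {
        cand <- v0[l] * (1 + stats::rnorm(1L, 0, config$flux_rel_sd))
        if (sign(cand) == sign(v0[l])) {
          v[l] <- cand
          break
        }
      }
    }
    net_i <- net
    if (any(net$fixed_mask)) {
      r <- config$fixed_met_rel_range
      fac <- stats::runif(length(net$fixed_values), 1 - r, 1 + r)
      net_i$fixed_values <- net$fixed_values * fac
    }
    model_i <- ecm_model(net_i, pars[[i]], flux_profile(v, sd = model$flux$sd),
                         bounds = model$bounds,
                         measurements = model$measurements)
    sol <- tryCatch(
      ecm_solve(model_i, spec, seed = config$seed + i),
      ecm_infeasible_error = function(e) NULL
    )
    if (is.null(sol)) {
      n_inf <- n_inf + 1L
    } else {
      draws[[length(draws) + 1L]] <- sol$E_opt[active]
    }
  }
  samples <- if (length(draws)) do.call(rbind, draws) else
    matrix(numeric(), 0L, length(active), dimnames = list(NULL, active))
  summary <- data.frame(
    reaction = active,
    median = apply(samples, 2L, stats::median),
    q25 = apply(samples, 2L, stats::quantile, probs = 0.25, names = FALSE),
    q75 = apply(samples, 2L, stats::quantile, probs = 0.75, names = FALSE),
    stringsAsFactors = FALSE
  )
  list(
    summary = summary, samples = samples,
    n_infeasible = n_inf,
    warn_majority_infeasible = n_inf > config$n_samples / 2,
    seed = config$seed
  )
}

#' Sample metabolite profiles in the polytope
#'
#' Two sampling regimes used by the cost-optimality test: `"local"` draws
#' Gaussian perturbations (sd `config$metabolite_ln_sd`, natural-log scale)
#' around the optimal profile, rejecting infeasible draws; `"broad"` draws
#' convex combinations of the polytope's extreme points with flat
#' (symmetric Dirichlet, concentration 1) weights.
#'
#' @param poly A [build_polytope()] result.
#' @param x_opt Optimal log-concentration vector (needed for local mode).
#' @param mode `"local"` or `"broad"`.
#' @param config A [sampling_config()]; `n_samples` profiles are returned.
#' @return Matrix with one row per profile, columns the free metabolites.
#' @export
sample_metabolite_profiles <- function(poly, x_opt = NULL,
                                       mode = c("local", "broad"),
                                       config = sampling_config()) {
  mode <- match.arg(mode)
  free <- poly$free_ids
  m <- length(free)
  n <- config$n_samples
  set.seed(config$seed)
  if (mode == "local") {
    if (is.null(x_opt)) {
      stopf("local mode requires the optimal profile x_opt")
    }
    x0 <- x_opt[free]
    out <- matrix(NA_real_, n, m, dimnames = list(NULL, free))
    got <- 0L
    tried <- 0L
    while (got < n) {
      x <- x0 + stats::rnorm(m, 0, config$metabolite_ln_sd)
      tried <- tried + 1L
      if (polytope_contains(poly, stats::setNames(x, free))) {
        got <- got + 1L
        out[got, ] <- x
      }
      if (tried >= 100L * n && got < tried / 100L) {
        stopf("local-mode rejection rate above 99%%; use a smaller metabolite_ln_sd",
              class = "ecm_domain_error")
      }
    }
    return(out)
  }
  ep <- extreme_points(poly)
  k <- nrow(ep)
  w <- matrix(stats::rgamma(n * k, shape = 1), n, k)
  w <- w / rowSums(w)
  out <- w %*% ep
  colnames(out) <- free
  out
}

#' Test the cost-optimality hypothesis against measured enzyme levels
#'
#' Compares enzyme-level predictions from (i) the cost-optimal metabolite
#' profile, (ii) profiles sampled locally around it, and (iii) profiles
#' sampled broadly over the whole polytope. If measured enzyme levels are
#' predicted clearly better by the optimum and its neighborhood than by
#' broad profiles, the data support cost-optimality of the metabolic
#' state.
#'
#' @param model An [ecm_model()].
#' @param spec A [cost_function_spec()] or tier name.
#' @param measured A [measurement_set()] with enzyme levels for at least
#'   two active reactions.
#' @param config A [sampling_config()]; `n_samples` profiles are drawn per
#'   sampling class.
#' @return Data frame with one row per profile: `class` (optimum | local |
#'   broad), `cost` (total enzyme cost at that profile) and `rmse`
#'   (log10-scale enzyme prediction error).
#' @export
cost_optimality_test <- function(model, spec = "EMC4CM",
                                 measured = model$measurements,
                                 config = sampling_config()) {
  if (!inherits(spec, "cost_function_spec")) spec <- cost_function_spec(spec)
  model <- orient_reactions(model)
  active <- model$network$reaction_ids[model$flux$active_mask]
  have <- intersect(names(measured$enzyme_conc), active)
  if (length(have) < 2L) {
    stopf("measured enzyme levels needed for at least two active reactions; missing: %s",
          paste(setdiff(active, have), collapse = ", "),
          class = "ecm_parameter_error")
  }
  sol <- ecm_solve(model, spec, seed = config$seed)
  poly <- sol$polytope
  meas <- measured$enzyme_conc[have]

  profile_row <- function(xf, class) {
    x <- stats::setNames(xf, poly$free_ids)
    ec <- enzyme_cost(x, model, spec)
    E <- stats::setNames(ec$breakdown$E_l, ec$breakdown$reaction)
    pm <- prediction_metrics(E[have], meas)
    data.frame(class = class, cost = ec$q, rmse = pm$rmse_log10,
               stringsAsFactors = FALSE)
  }

  rows <- list(profile_row(sol$x_opt[poly$free_ids], "optimum"))
  loc <- sample_metabolite_profiles(poly, sol$x_opt, "local", config)
  for (i in seq_len(nrow(loc))) {
    rows[[length(rows) + 1L]] <- profile_row(loc[i, ], "local")
  }
  cfg_b <- config
  cfg_b$seed <- config$seed + 1L
  br <- sample_metabolite_profiles(poly, mode = "broad", config = cfg_b)
  for (i in seq_len(nrow(br))) {
    rows[[length(rows) + 1L]] <- profile_row(br[i, ], "broad")
  }
  do.call(rbind, rows)
}
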