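# Separable rate-law efficiency factors and the tiered enzyme cost
# functions (EMC0 .. EMC4), with analytic gradients in metabolite log-space.

EMC_VARIANTS <- c("EMC0", "EMC1", "EMC2S", "EMC2SP",
                  "EMC3S", "EMC3SP", "EMC4CM")

#' Specify an enzyme cost function
#'
#' The tiered cost functions trade data requirements against realism:
#' * `EMC0` - sum of fluxes (no kinetic data; constant in metabolite space);
#' * `EMC1` - capacity-based, `sum(h * v/kcat_fwd)` (turnover numbers);
#' * `EMC2S`, `EMC2SP` - reversibility-based, adding the driving-force
#'   factor `1/eta_rev`; the `SP` form also accounts for product occupancy
#'   through the kcat ratio;
#' * `EMC3S`, `EMC3SP` - saturation-based, with simplified denominators
#'   `1+S` and `1+S+P` built from pooled substrate/product mass-action
#'   terms (Michaelis constants required);
#' * `EMC4CM` - full common modular rate law denominator.
#'
#' Each tier is a lower bound on all later tiers at every feasible point.
#'
#' @param variant One of `r paste(EMC_VARIANTS, collapse=", ")`.
#' @param include_regulation Apply noncompetitive-inhibitor prefactors from
#'   the model's modifier table (default TRUE).
#' @param burden_mode How enzyme burdens `h_E` are chosen: `"uniform"` uses
#'   the per-reaction `h_E` stored in the parameters (default 1),
#'   `"protein_mass"` uses molecular masses `m_l` in Da (cost in mg
#'   protein/l), `"chain_length"` uses amino-acid chain length
#'   (approximated as `m_l`/110 Da per residue) divided by its median, and
#'   `"custom"` uses the vector supplied in `burden`.
#' @param burden Named per-reaction burden vector for
#'   `burden_mode = "custom"`.
#' @param burden_fn Optional convex scalar function `h(E)` applied to each
#'   reaction's demand instead of the linear `h_E * E`; supply its
#'   derivative in `burden_fn_grad` for analytic gradients.
#' @param burden_fn_grad Derivative of `burden_fn`.
#' @return An object of class `cost_function_spec`.
#' @export
cost_function_spec <- function(variant = "EMC4CM", include_regulation = TRUE,
                               burden_mode = c("uniform", "protein_mass",
                                               "chain_length", "custom"),
                               burden = NULL, burden_fn = NULL,
                               burden_fn_grad = NULL) {
  variant <- match.arg(variant, EMC_VARIANTS)
  burden_mode <- match.arg(burden_mode)
  if (burden_mode == "custom" && is.null(burden)) {
    stopf("burden_mode = 'custom' requires a burden vector")
  }
  if (!is.null(burden_fn) && is.null(burden_fn_grad)) {
    stopf("burden_fn requires burden_fn_grad for analytic gradients")
  }
  structure(
    list(variant = variant, include_regulation = include_regulation,
         burden_mode = burden_mode, burden = burden,
         burden_fn = burden_fn, burden_fn_grad = burden_fn_grad),
    class = "cost_function_spec"
  )
}

# Per-reaction burden weights for a model under a cost spec.
resolve_burdens <- function(model, spec) {
  par <- model$params
  rxns <- model$network$reaction_ids
  h <- switch(
    spec$burden_mode,
    uniform = par$h_E,
    protein_mass = {
      if (any(is.na(par$m_l[model$flux$active_mask]))) {
        stopf("protein masses m_l required for burden_mode = 'protein_mass'",
              class = "ecm_parameter_error")
      }
      par$m_l
    },
    chain_length = {
      if (any(is.na(par$m_l[model$flux$active_mask]))) {
        stopf("protein masses m_l required for burden_mode = 'chain_length'",
              class = "ecm_parameter_error")
      }
      len <- par$m_l / 110    # ~110 Da per amino-acid residue
      len / stats::median(len[model$flux$active_mask])
    },
    custom = align_named(spec$burden, rxns)
  )
  if (spec$variant == "EMC0") {
    h <- stats::setNames(rep(1, length(rxns)), rxns)
  }
  h
}

# Fail fast if the parameters required by the chosen tier are absent.
validate_cost_inputs <- function(model, spec) {
  par <- model$params
  net <- model$network
  active <- net$reaction_ids[model$flux$active_mask]
  need <- function(x, what) {
    bad <- active[is.na(x[active])]
    if (length(bad) > 0L) {
      stopf("%s required by %s but missing for reaction(s): %s",
            what, spec$variant, paste(bad, collapse = ", "),
            class = "ecm_parameter_error")
    }
  }
  if (spec$variant == "EMC0") return(invisible(TRUE))
  need(par$kcat_fwd, "forward kcat")
  if (spec$variant == "EMC1") return(invisible(TRUE))
  need(par$K_eq, "equilibrium constant")
  if (spec$variant == "EMC2SP") need(par$kcat_rev, "backward kcat")
  if (spec$variant %in% c("EMC3S", "EMC3SP", "EMC4CM")) {
    for (l in active) {
      idx <- net$stoichiometry[, l] != 0
      if (spec$variant == "EMC3S") {
        idx <- net$stoichiometry[, l] < 0
      }
      if (any(is.na(par$K_M[idx, l]))) {
        stopf("Michaelis constants required by %s but missing for reaction '%s'",
              spec$variant, l, class = "ecm_parameter_error")
      }
    }
  }
  invisible(TRUE)
}

#' Reversibility efficiency factor
#'
#' `eta_rev = 1 - exp(-Theta)`: the fraction of the forward flux that
#' survives cancellation by the microscopic backward flux, as a function of
#' the thermodynamic driving force. Values of `Theta <= 0` return 0 (the
#' demand downstream becomes infinite); no error is raised here.
#'
#' @param theta Driving force(s), unitless.
#' @return Value(s) in `[0, 1)`.
#' @export
eta_rev <- function(theta) {
  pmax(0, 1 - exp(-theta))
}

# Saturation/kinetic efficiency factors for the active reactions at a full
# log-concentration vector. Returns a list with eta (named vector) and the
# per-(metabolite, reaction) gradient d ln(eta)/dx as a matrix.
eta_kin_terms <- function(xx, model, variant, reactions = NULL) {
  net <- model$network
  par <- model$params
  S <- net$stoichiometry
  active <- reactions %||% net$reaction_ids[model$flux$active_mask]
  mets <- net$metabolite_ids
  eta <- stats::setNames(rep(1, length(active)), active)
  grad <- matrix(0, length(mets), length(active),
                 dimnames = list(mets, active))
  if (variant %in% c("EMC0", "EMC1", "EMC2S")) {
    return(list(eta = eta, grad = grad))
  }
  if (variant == "EMC2SP") {
    theta <- drop(log(par$K_eq[active]) -
                    crossprod(S[, active, drop = FALSE], xx))
    kappa <- par$kcat_fwd[active] / par$kcat_rev[active]
    z <- kappa * exp(-theta)
    eta[] <- 1 / (1 + z)
    # d ln(eta)/dx_i = -z * n_il / (1 + z)
    for (k in seq_along(active)) {
      grad[, k] <- -z[k] / (1 + z[k]) * S[, active[k]]
    }
    return(list(eta = eta, grad = grad))
  }
  for (k in seq_along(active)) {
    l <- active[k]
    n <- S[, l]
    sub <- which(n < 0)
    prod <- which(n > 0)
    a <- abs(n[sub])
    b <- abs(n[prod])
    km_s <- par$K_M[sub, l]
    km_p <- par$K_M[prod, l]
    lnS <- sum(a * (xx[sub] - log(km_s)))
    Sx <- exp(lnS)
    if (variant == "EMC3S") {
      eta[k] <- Sx / (1 + Sx)
      grad[sub, k] <- a / (1 + Sx)
      next
    }
    lnP <- sum(b * (xx[prod] - log(km_p)))
    Px <- exp(lnP)
    if (variant == "EMC3SP") {
      D <- 1 + Sx + Px
      eta[k] <- Sx / D
      grad[sub, k] <- a - Sx * a / D
      grad[prod, k] <- -Px * b / D
    } else { # EMC4CM: common modular denominator
      rs <- exp(xx[sub]) / km_s
      rp <- exp(xx[prod]) / km_p
      U <- prod((1 + rs)^a)
      V <- prod((1 + rp)^b)
      D <- U + V - 1
      eta[k] <- Sx / D
      dU <- U * a * rs / (1 + rs)
      dV <- V * b * rp / (1 + rp)
      grad[sub, k] <- a - dU / D
      grad[prod, k] <- -dV / D
    }
  }
  list(eta = eta, grad = grad)
}

#' Kinetic (saturation) efficiency factor
#'
#' Evaluates `eta_kin` for each active reaction at a metabolite profile,
#' under the denominator convention of the chosen cost-function tier (see
#' [cost_function_spec()]).
#'
#' @param x Named log-concentration vector (fixed metabolites may be
#'   omitted).
#' @param model An [ecm_model()].
#' @param variant Cost-function tier name.
#' @param reactions Optional subset of reaction identifiers.
#' @return Named vector of efficiencies in `(0, 1]`.
#' @export
eta_kin <- function(x, model, variant = "EMC4CM", reactions = NULL) {
  xx <- full_log_concentrations(x, model)
  eta_kin_terms(xx, model, variant, reactions)$eta
}

# Allosteric regulation prefactors (noncompetitive inhibition):
# eta_reg = prod over inhibitors 1/(1 + c_I/K_I).
eta_reg_terms <- function(xx, model, reactions) {
  mets <- model$network$metabolite_ids
  eta <- stats::setNames(rep(1, length(reactions)), reactions)
  grad <- matrix(0, length(mets), length(reactions),
                 dimnames = list(mets, reactions))
  mods <- model$params$modifiers
  if (nrow(mods) == 0L) return(list(eta = eta, grad = grad))
  for (k in seq_len(nrow(mods))) {
    l <- mods$reaction[k]
    if (!l %in% reactions) next
    cI <- exp(xx[mods$compound[k]])
    z <- cI / mods$K_I[k]
    eta[l] <- eta[l] / (1 + z)
    grad[mods$compound[k], l] <- grad[mods$compound[k], l] - z / (1 + z)
  }
  list(eta = eta, grad = grad)
}

#' Regulation efficiency factor
#'
#' Multiplicative noncompetitive-inhibition prefactor
#' `1/(1 + c_I/K_I)` per inhibitor listed in the model's modifier table.
#'
#' @inheritParams eta_kin
#' @return Named vector of efficiencies in `(0, 1]` over the active
#'   reactions.
#' @export
eta_reg <- function(x, model, reactions = NULL) {
  xx <- full_log_concentrations(x, model)
  active <- reactions %||%
    model$network$reaction_ids[model$flux$active_mask]
  eta_reg_terms(xx, model, active)$eta
}

#' Enzyme demand at a metabolite profile
#'
#' Inverts the separable rate law `v = E * kcat_fwd * eta_rev * eta_kin *
#' eta_reg` to the demand `E = v / (kcat_fwd * eta_rev * eta_kin *
#' eta_reg)` per active reaction. For the capacity tiers the efficiency
#' factors are 1 (`EMC0` additionally sets `kcat_fwd = 1`, so the demand
#' equals the flux).
#'
#' @inheritParams eta_kin
#' @param include_regulation Apply inhibitor prefactors (default TRUE).
#' @return Named vector of enzyme demands in mM.
#' @export
enzyme_demand <- function(x, model, variant = "EMC4CM",
                          include_regulation = TRUE) {
  spec <- cost_function_spec(variant, include_regulation)
  b <- enzyme_cost(x, model, spec)$breakdown
  stats::setNames(b$E_l, b$reaction)
}

#' Enzyme cost, gradient and efficiency breakdown
#'
#' The central objective of enzyme cost minimization: the total burden-
#' weighted enzyme demand `q(x) = sum_l h_l * E_l(x)` as a function of the
#' metabolite log-concentration vector, together with its analytic gradient
#' and the per-reaction multiplicative efficiency breakdown.
#'
#' @param x Named log-concentration vector (`ln(c/1 mM)`); fixed metabolites
#'   may be omitted.
#' @param model An [ecm_model()] (oriented).
#' @param spec A [cost_function_spec()].
#' @return List with `q` (total cost), `gradient` (named over all
#'   metabolites; entries for fixed metabolites are reported but unused by
#'   the optimizer), and `breakdown`, a data frame with one row per active
#'   reaction: flux, kcat, burden, the three efficiency factors, demand
#'   `E_l` (mM) and cost `q_l`.
#' @export
enzyme_cost <- function(x, model, spec) {
  if (!inherits(spec, "cost_function_spec")) {
    spec <- cost_function_spec(spec)
  }
  validate_cost_inputs(model, spec)
  net <- model$network
  par <- model$params
  v <- model$flux$v
  active <- net$reaction_ids[model$flux$active_mask]
  mets <- net$metabolite_ids
  xx <- full_log_concentrations(x, model)
  h <- resolve_burdens(model, spec)[active]

  kf <- if (spec$variant == "EMC0") {
    stats::setNames(rep(1, length(active)), active)
  } else {
    par$kcat_fwd[active]
  }

  use_rev <- !spec$variant %in% c("EMC0", "EMC1")
  if (use_rev) {
    theta <- drop(log(par$K_eq[active]) -
                    crossprod(net$stoichiometry[, active, drop = FALSE], xx))
    bad <- theta <= 0
    if (any(bad)) {
      stopf("metabolite profile is thermodynamically infeasible: driving force <= 0 for reaction(s) %s",
            paste(active[bad], collapse = ", "),
            class = "ecm_infeasible_error")
    }
    e_rev <- 1 - exp(-theta)
  } else {
    theta <- stats::setNames(rep(Inf, length(active)), active)
    e_rev <- stats::setNames(rep(1, length(active)), active)
  }

  kin <- eta_kin_terms(xx, model, spec$variant, active)
  if (spec$include_regulation && use_rev) {
    reg <- eta_reg_terms(xx, model, active)
  } else {
    reg <- list(eta = stats::setNames(rep(1, length(active)), active),
                grad = matrix(0, length(mets), length(active),
                              dimnames = list(mets, active)))
  }

  E <- v[active] / (kf * e_rev * kin$eta * reg$eta)
  if (is.null(spec$burden_fn)) {
    q_l <- h * E
    w <- h
  } else {
    q_l <- vapply(E, spec$burden_fn, numeric(1L))
    w <- vapply(E, spec$burden_fn_grad, numeric(1L))
  }
  if (spec$variant == "EMC0") {
    q_l <- v[active]
    E <- v[active]
    w <- stats::setNames(rep(1, length(active)), active)
  }
  q <- sum(q_l)

  gradient <- stats::setNames(rep(0, length(mets)), mets)
  if (!spec$variant %in% c("EMC0", "EMC1")) {
    # d ln eta_rev / dx_i = -n_il * exp(-theta)/(1-exp(-theta))
    Sa <- net$stoichiometry[, active, drop = FALSE]
    rev_fac <- exp(-theta) / e_rev
    dln_rev <- -sweep(Sa, 2L, rev_fac, `*`)
    dln_total <- dln_rev + kin$grad + reg$grad
    # dE_l/dx_i = -E_l * d ln(eta...)/dx_i  (v, kcat constant)
    gradient <- -drop(dln_total %*% (w * E))
    names(gradient) <- mets
  }

  breakdown <- data.frame(
    reaction = active,
    v = unname(v[active]),
    kcat_fwd = unname(kf),
    h_E = unname(h),
    theta = unname(theta),
    eta_rev = unname(e_rev),
    eta_kin = unname(kin$eta),
    eta_reg = unname(reg$eta),
    E_l = unname(E),
    q_l = unname(q_l),
    stringsAsFactors = FALSE
  )
  list(q = q, gradient = gradient, breakdown = breakdown)
}

#' Flux burdens
#'
#' The enzyme cost per unit flux, `a_v = h_E / (kcat_fwd * eta_rev *
#' eta_kin * eta_reg)`, and its metabolite-independent lower bound
#' `a_cat = h_E / kcat_fwd` (the cost per flux of an ideally working
#' enzyme). The identity `q = sum(a_v * v)` recovers the total cost.
#'
#' @inheritParams enzyme_cost
#' @return Data frame with columns `reaction`, `a_v`, `a_cat`.
#' @export
flux_burden <- function(x, model, spec) {
  if (!inherits(spec, "cost_function_spec")) spec <- cost_function_spec(spec)
  ec <- enzyme_cost(x, model, spec)
  b <- ec$breakdown
  data.frame(
    reaction = b$reaction,
    a_v = b$q_l / b$v,
    a_cat = b$h_E / b$kcat_fwd,
    stringsAsFactors = FALSE
  )
}

#' Pathway specific activity
#'
#' Pathway flux per total enzyme mass. With mass-based burdens
#' (`burden_mode = "protein_mass"`, `h_E = m_l` in Da) the total cost `q` is
#' in mg protein per liter and the activity `A_pw = v_pw / q` is in
#' mmol/s per mg of enzyme.
#'
#' @param flux_pw Pathway flux in mM/s (mmol/l/s).
#' @param q_mass Mass-based total enzyme cost in mg/l.
#' @return Activity in mmol/s per mg enzyme.
#' @export
pathway_specific_activity <- function(flux_pw, q_mass) {
  if (!is.finite(q_mass) || q_mass <= 0) {
    stopf("mass-based enzyme cost must be positive",
          class = "ecm_domain_error")
  }
  if (flux_pw < 0) {
    stopf("pathway flux must be nonnegative", class = "ecm_domain_error")
  }
  flux_pw / q_mass
}

#' Direct evaluation of the reversible modular rate law
#'
#' Computes `v_l = E_l * (kcat_fwd * S - kcat_rev * P) / D` from
#' concentrations, with pooled mass-action terms
#' `S = prod (s_i/K_M)^|n|`, `P = prod (p_j/K_M)^|n|` and denominator `D`
#' either `1 + S + P` (three-state binding) or the common modular form
#' `prod(1+s/K)^|n| + prod(1+p/K)^|n| - 1`. This is the unfactorized form
#' of the rate law; it serves as an independent check of the separable
#' factorization `v = E * kcat_fwd * eta_rev * eta_kin`.
#'
#' @param conc Named metabolite concentrations in mM.
#' @param E Named enzyme concentrations in mM.
#' @param model An [ecm_model()].
#' @param denominator `"1SP"` or `"CM"`.
#' @return Named vector of reaction rates in mM/s.
#' @export
reaction_rate <- function(conc, E, model, denominator = c("1SP", "CM")) {
  denominator <- match.arg(denominator)
  net <- model$network
  par <- model$params
  S <- net$stoichiometry
  out <- stats::setNames(rep(NA_real_, length(net$reaction_ids)),
                         net$reaction_ids)
  for (l in net$reaction_ids) {
    n <- S[, l]
    sub <- which(n < 0); prod_ <- which(n > 0)
    a <- abs(n[sub]); b <- abs(n[prod_])
    rs <- conc[net$metabolite_ids[sub]] / par$K_M[sub, l]
    rp <- conc[net$metabolite_ids[prod_]] / par$K_M[prod_, l]
    Sx <- prod(rs^a)
    Px <- prod(rp^b)
    D <- if (denominator == "1SP") 1 + Sx + Px
    else prod((1 + rs)^a) + prod((1 + rp)^b) - 1
    out[l] <- E[l] * (par$kcat_fwd[l] * Sx - par$kcat_rev[l] * Px) / D
  }
  out
}
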