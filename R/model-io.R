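#' Construct a metabolic network model
#'
#' @param stoichiometry Numeric matrix (metabolites x reactions) of signed
#'   stoichiometric coefficients; substrates carry negative entries. Row
#'   names are metabolite identifiers, column names reaction identifiers.
#' @param fixed_values Named numeric vector of clamped metabolite
#'   concentrations in mM; names must be metabolite identifiers. Metabolites
#'   listed here are treated as fixed (boundary) species.
#' @return An object of class `network_model` with fields `metabolite_ids`,
#'   `reaction_ids`, `stoichiometry`, `fixed_mask`, `fixed_values`.
#' @export
network_model <- function(stoichiometry, fixed_values = NULL) {
  S <- as.matrix(stoichiometry)
  if (is.null(rownames(S)) || is.null(colnames(S))) {
    stopf("stoichiometry must have metabolite row names and reaction column names")
  }
  if (anyDuplicated(rownames(S)) || anyDuplicated(colnames(S))) {
    stopf("metabolite and reaction identifiers must be unique")
  }
  zero_cols <- colSums(S != 0) == 0
  if (any(zero_cols)) {
    stopf("reaction(s) %s have all-zero stoichiometry",
          paste(colnames(S)[zero_cols], collapse = ", "))
  }
  fixed_values <- fixed_values %||% numeric()
  unknown <- setdiff(names(fixed_values), rownames(S))
  if (length(unknown) > 0L) {
    stopf("fixed metabolite(s) %s not present in the network",
          paste(unknown, collapse = ", "), class = "ecm_reference_error")
  }
  assert_positive(fixed_values, "fixed metabolite concentrations")
  fixed_mask <- rownames(S) %in% names(fixed_values)
  names(fixed_mask) <- rownames(S)
  structure(
    list(
      metabolite_ids = rownames(S),
      reaction_ids = colnames(S),
      stoichiometry = S,
      fixed_mask = fixed_mask,
      fixed_values = fixed_values[names(fixed_values)]
    ),
    class = "network_model"
  )
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf(
    "<network_model> %d metabolites (%d fixed), %d reactions\n",
    length(x$metabolite_ids), sum(x$fixed_mask), length(x$reaction_ids)
  ))
  invisible(x)
}

#' Construct a kinetic/thermodynamic parameter set
#'
#' Holds turnover numbers, Michaelis constants, equilibrium constants and
#' enzyme burdens for a network. Equilibrium constants are unitless at the
#' 1 mM standard concentration; `dG0_over_RT = -ln(K_eq)`. Either `K_eq` or
#' `dG0_over_RT` may be given; the other is derived.
#'
#' @param net A [network_model()].
#' @param kcat_fwd,kcat_rev Named per-reaction turnover numbers (1/s).
#'   `kcat_rev` may contain `NA` before balancing.
#' @param K_M Michaelis constants in mM: either a metabolite x reaction
#'   matrix aligned with the stoichiometry (NA for non-reactants) or a data
#'   frame with columns `reaction`, `compound`, `value`.
#' @param K_eq Named per-reaction equilibrium constants (unitless at 1 mM).
#' @param dG0_over_RT Named per-reaction standard reaction Gibbs energies in
#'   RT units.
#' @param h_E Named per-reaction enzyme burdens (cost per mM enzyme);
#'   default 1.
#' @param m_l Named per-reaction protein masses in Da (optional).
#' @param modifiers Optional data frame of noncompetitive inhibitors with
#'   columns `reaction`, `compound`, `K_I` (mM).
#' @param kcat_inf Diffusion-limited catalytic constant (1/s) used in the
#'   optional decomposition `kcat_fwd = kcat_inf * eta_cat`.
#' @param km_filled Logical matrix marking K_M entries filled from the
#'   default prior rather than observed (audit trail for saturation-based
#'   cost functions).
#' @return An object of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(net, kcat_fwd, kcat_rev = NULL, K_M = NULL,
                               K_eq = NULL, dG0_over_RT = NULL, h_E = NULL,
                               m_l = NULL, modifiers = NULL, kcat_inf = 1e8,
                               km_filled = NULL) {
  rxns <- net$reaction_ids
  mets <- net$metabolite_ids
  kcat_fwd <- align_named(kcat_fwd, rxns)
  kcat_rev <- align_named(kcat_rev, rxns)
  h_E <- if (is.null(h_E)) {
    stats::setNames(rep(1, length(rxns)), rxns)
  } else {
    align_named(h_E, rxns)
  }
  m_l <- align_named(m_l, rxns)

  if (is.null(K_eq) && is.null(dG0_over_RT)) {
    K_eq <- align_named(NULL, rxns)
    dG0_over_RT <- align_named(NULL, rxns)
  } else if (is.null(K_eq)) {
    dG0_over_RT <- align_named(dG0_over_RT, rxns)
    K_eq <- exp(-dG0_over_RT)
  } else if (is.null(dG0_over_RT)) {
    K_eq <- align_named(K_eq, rxns)
    dG0_over_RT <- -log(K_eq)
  } else {
    K_eq <- align_named(K_eq, rxns)
    dG0_over_RT <- align_named(dG0_over_RT, rxns)
    both <- !is.na(K_eq) & !is.na(dG0_over_RT)
    if (any(abs(log(K_eq[both]) + dG0_over_RT[both]) > 1e-6)) {
      stopf("K_eq and dG0_over_RT disagree (K_eq must equal exp(-dG0/RT))",
            class = "ecm_conflict_error")
    }
    K_eq[is.na(K_eq)] <- exp(-dG0_over_RT[is.na(K_eq)])
    dG0_over_RT[is.na(dG0_over_RT)] <- -log(K_eq[is.na(dG0_over_RT)])
  }

  KM <- km_dataframe_to_matrix(K_M, net)
  if (is.null(km_filled)) {
    km_filled <- matrix(FALSE, nrow(KM), ncol(KM), dimnames = dimnames(KM))
  }

  if (!is.null(modifiers) && nrow(modifiers) > 0L) {
    need <- c("reaction", "compound", "K_I")
    if (!all(need %in% names(modifiers))) {
      stopf("modifiers must have columns reaction, compound, K_I")
    }
    bad_r <- setdiff(modifiers$reaction, rxns)
    bad_c <- setdiff(modifiers$compound, mets)
    if (length(bad_r) || length(bad_c)) {
      stopf("modifier references unknown identifier(s): %s",
            paste(c(bad_r, bad_c), collapse = ", "),
            class = "ecm_reference_error")
    }
    assert_positive(modifiers$K_I, "inhibition constants K_I")
    if (is.null(modifiers$mechanism)) modifiers$mechanism <- "noncompetitive"
  } else {
    modifiers <- data.frame(reaction = character(), compound = character(),
                            K_I = numeric(), mechanism = character(),
                            stringsAsFactors = FALSE)
  }

  for (v in list(kcat_fwd, kcat_rev, K_eq, h_E)) {
    if (any(!is.na(v) & v <= 0)) {
      stopf("kinetic constants and burdens must be positive",
            class = "ecm_domain_error")
    }
  }

  structure(
    list(
      kcat_fwd = kcat_fwd, kcat_rev = kcat_rev, K_M = KM,
      K_eq = K_eq, dG0_over_RT = dG0_over_RT,
      h_E = h_E, m_l = m_l, modifiers = modifiers,
      kcat_inf = kcat_inf, km_filled = km_filled
    ),
    class = "kinetic_parameters"
  )
}

km_dataframe_to_matrix <- function(K_M, net) {
  S <- net$stoichiometry
  KM <- matrix(NA_real_, nrow(S), ncol(S), dimnames = dimnames(S))
  if (is.null(K_M)) {
    return(KM)
  }
  if (is.matrix(K_M)) {
    if (!identical(dim(K_M), dim(S))) {
      stopf("K_M matrix must be metabolites x reactions, aligned with the stoichiometry")
    }
    KM[] <- K_M
    KM[S == 0] <- NA_real_
    return(KM)
  }
  need <- c("reaction", "compound", "value")
  if (!all(need %in% names(K_M))) {
    stopf("K_M data frame must have columns reaction, compound, value")
  }
  for (k in seq_len(nrow(K_M))) {
    r <- K_M$reaction[k]
    cpd <- K_M$compound[k]
    if (!r %in% colnames(S) || !cpd %in% rownames(S)) {
      stopf("K_M row %d references unknown identifier ('%s', '%s')",
            k, r, cpd, class = "ecm_reference_error")
    }
    if (S[cpd, r] == 0) {
      stopf("K_M given for '%s' which is not a reactant of '%s'", cpd, r,
            class = "ecm_reference_error")
    }
    if (!is.na(KM[cpd, r])) {
      stopf("duplicate K_M for (%s, %s)", r, cpd, class = "ecm_conflict_error")
    }
    KM[cpd, r] <- as.numeric(K_M$value[k])
  }
  assert_positive(KM[!is.na(KM)], "Michaelis constants")
  KM
}

#' Construct a flux profile
#'
#' @param v Named per-reaction fluxes in mM/s. Zero entries mark inactive
#'   reactions; negative entries are legal before orientation.
#' @param sd Optional named standard deviations (mM/s) used by the
#'   sensitivity sampler.
#' @return An object of class `flux_profile` with fields `v`, `active_mask`,
#'   `sd`.
#' @export
flux_profile <- function(v, sd = NULL) {
  if (is.null(names(v))) {
    stopf("fluxes must be named by reaction identifier")
  }
  if (any(!is.finite(v))) {
    stopf("fluxes must be finite")
  }
  structure(
    list(v = v, active_mask = v != 0,
         sd = if (is.null(sd)) NULL else align_named(sd, names(v))),
    class = "flux_profile"
  )
}

#' Construct a measurement set for validation
#'
#' @param metabolite_conc Named metabolite concentrations in mM (optional).
#' @param enzyme_conc Named enzyme concentrations in mM per reaction
#'   (optional).
#' @return An object of class `measurement_set`. Missing entries are simply
#'   absent from the vectors; they are never imputed.
#' @export
measurement_set <- function(metabolite_conc = NULL, enzyme_conc = NULL) {
  check <- function(x, what) {
    if (is.null(x)) return(numeric())
    if (is.null(names(x))) stopf("%s must be named", what)
    x <- x[!is.na(x)]
    if (any(x < 0)) stopf("%s must be nonnegative", what,
                          class = "ecm_domain_error")
    x
  }
  structure(
    list(
      metabolite_conc = check(metabolite_conc, "measured metabolite concentrations"),
      enzyme_conc = check(enzyme_conc, "measured enzyme concentrations")
    ),
    class = "measurement_set"
  )
}

#' Bundle network, parameters, fluxes and bounds into one model object
#'
#' @param network A [network_model()].
#' @param params A [kinetic_parameters()].
#' @param flux A [flux_profile()].
#' @param bounds Named list with numeric vectors `lower` and `upper`
#'   (concentration bounds in mM per metabolite). Fixed metabolites may be
#'   omitted; their bounds collapse onto the fixed value.
#' @param measurements Optional [measurement_set()].
#' @return An object of class `ecm_model`.
#' @export
ecm_model <- function(network, params, flux, bounds, measurements = NULL) {
  stopifnot(inherits(network, "network_model"),
            inherits(params, "kinetic_parameters"),
            inherits(flux, "flux_profile"))
  mets <- network$metabolite_ids
  rxns <- network$reaction_ids
  miss <- setdiff(names(flux$v), rxns)
  if (length(miss) > 0L) {
    stopf("flux profile references unknown reaction(s): %s",
          paste(miss, collapse = ", "), class = "ecm_reference_error")
  }
  v <- align_named(flux$v, rxns, default = 0)
  flux <- flux_profile(v, sd = flux$sd)
  lower <- align_named(bounds$lower, mets)
  upper <- align_named(bounds$upper, mets)
  fx <- network$fixed_mask
  lower[fx] <- network$fixed_values[mets[fx]]
  upper[fx] <- network$fixed_values[mets[fx]]
  if (any(is.na(lower[!fx])) || any(is.na(upper[!fx]))) {
    stopf("concentration bounds must be given for every free metabolite")
  }
  assert_positive(c(lower, upper), "concentration bounds")
  if (any(lower > upper)) {
    stopf("lower concentration bounds exceed upper bounds",
          class = "ecm_domain_error")
  }
  structure(
    list(
      network = network, params = params, flux = flux,
      bounds = list(lower = lower, upper = upper),
      measurements = measurements %||% measurement_set()
    ),
    class = "ecm_model"
  )
}

#' @export
print.ecm_model <- function(x, ...) {
  print(x$network)
  cat(sprintf("  active reactions: %d; fluxes in [%g, %g] mM/s\n",
              sum(x$flux$active_mask), min(x$flux$v), max(x$flux$v)))
  invisible(x)
}

#' Haldane residuals of a parameter set
#'
#' The Haldane relationship couples kinetics and thermodynamics:
#' `K_eq = (kcat_fwd/kcat_rev) * (prod K_M,products^|n| / prod K_M,substrates^|n|)`.
#' The residual reported here is the log-scale discrepancy per reaction;
#' a consistent set has residuals of zero.
#'
#' @param par A [kinetic_parameters()].
#' @param net The corresponding [network_model()].
#' @return Named numeric vector of residuals (NA where the needed constants
#'   are absent).
#' @export
haldane_residuals <- function(par, net) {
  S <- net$stoichiometry
  res <- rep(NA_real_, length(net$reaction_ids))
  names(res) <- net$reaction_ids
  for (l in net$reaction_ids) {
    kf <- par$kcat_fwd[l]; kr <- par$kcat_rev[l]; keq <- par$K_eq[l]
    km <- par$K_M[, l]
    n <- S[, l]
    idx <- n != 0
    if (is.na(kf) || is.na(kr) || is.na(keq) || any(is.na(km[idx]))) next
    res[l] <- log(keq) - (log(kf) - log(kr)) -
      sum(abs(n[n > 0]) * log(km[n > 0])) +
      sum(abs(n[n < 0]) * log(km[n < 0]))
  }
  res
}

#' Orient all reactions along their fluxes
#'
#' Rewrites every reaction carrying a negative flux in the reverse
#' convention so that all active fluxes become positive: the stoichiometry
#' column is negated, forward and backward turnover numbers are swapped, the
#' equilibrium constant is inverted and the standard reaction Gibbs energy
#' negated. Michaelis constants keep their (reaction, compound) assignment;
#' substrate/product roles follow the sign of the stoichiometry. Zero-flux
#' reactions are marked inactive; they contribute neither cost terms nor
#' driving-force constraints.
#'
#' The operation leaves the physical rate law unchanged: the oriented model
#' assigns rate `-v` to the reversed reaction written in the flipped
#' convention.
#'
#' @param model An [ecm_model()].
#' @return The oriented model (class `ecm_model`).
#' @export
orient_reactions <- function(model) {
  net <- model$network
  par <- model$params
  v <- model$flux$v
  flip <- v < 0
  if (any(flip)) {
    ids <- names(v)[flip]
    net$stoichiometry[, ids] <- -net$stoichiometry[, ids]
    tmp <- par$kcat_fwd[ids]
    par$kcat_fwd[ids] <- par$kcat_rev[ids]
    par$kcat_rev[ids] <- tmp
    par$K_eq[ids] <- 1 / par$K_eq[ids]
    par$dG0_over_RT[ids] <- -par$dG0_over_RT[ids]
    v[ids] <- -v[ids]
  }
  model$network <- net
  model$params <- par
  model$flux <- flux_profile(v, sd = model$flux$sd)
  model
}

#' Load a model bundle from SBtab-style tables
#'
#' Reads Reaction, Compound, Parameter and Flux tables (plus optional
#' ConcentrationData / EnzymeData validation tables) and assembles an
#' [ecm_model()]. Units are converted to the internal standard (mM, 1/s,
#' unitless equilibrium constants at 1 mM; Gibbs energies in kJ/mol are
#' divided by RT = 2.4790 kJ/mol). Michaelis constants missing for a
#' reactant are filled with the 0.1 mM default prior and flagged in
#' `params$km_filled`.
#'
#' @param path Path to a multi-table SBtab TSV file or a directory of
#'   tables (see [read_sbtab()]).
#' @return An [ecm_model()].
#' @export
load_model <- function(path) {
  tabs <- read_sbtab(path)
  rt <- tabs$Reaction
  ct <- tabs$Compound
  if (is.null(rt) || nrow(rt) == 0L) {
    stopf("Reaction table is missing or empty", class = "ecm_reference_error")
  }
  if (is.null(ct) || nrow(ct) == 0L) {
    stopf("Compound table is missing or empty", class = "ecm_reference_error")
  }
  mets <- ct$ID
  rxns <- rt$ID
  if (anyDuplicated(mets) || anyDuplicated(rxns)) {
    stopf("duplicate identifiers in Compound or Reaction table",
          class = "ecm_conflict_error")
  }
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (k in seq_along(rxns)) {
    f <- parse_reaction_formula(rt$ReactionFormula[k])
    for (side in c("substrates", "products")) {
      sg <- if (side == "substrates") -1 else 1
      tab <- f[[side]]
      for (j in seq_len(nrow(tab))) {
        if (!tab$id[j] %in% mets) {
          stopf("Reaction table row %d ('%s'): unknown compound '%s'",
                k, rxns[k], tab$id[j], class = "ecm_reference_error")
        }
        S[tab$id[j], rxns[k]] <- S[tab$id[j], rxns[k]] + sg * tab$coef[j]
      }
    }
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  is_const <- tolower(ct$IsConstant %||% rep("false", nrow(ct))) %in%
    c("true", "1", "yes")
  fixed_values <- NULL
  if (any(is_const)) {
    cv <- num(ct$Concentration[is_const])
    if (any(is.na(cv))) {
      stopf("fixed compound(s) lack a !Concentration value")
    }
    fixed_values <- stats::setNames(cv, mets[is_const])
  }
  net <- network_model(S, fixed_values = fixed_values)

  lower <- stats::setNames(num(ct$`Concentration:Min`), mets)
  upper <- stats::setNames(num(ct$`Concentration:Max`), mets)

  par <- parameters_from_table(tabs$Parameter, net)

  ft <- tabs$Flux
  if (is.null(ft) || nrow(ft) == 0L) {
    stopf("Flux table is missing or empty", class = "ecm_reference_error")
  }
  bad <- setdiff(ft$Reaction, rxns)
  if (length(bad) > 0L) {
    stopf("Flux table references unknown reaction(s): %s",
          paste(bad, collapse = ", "), class = "ecm_reference_error")
  }
  v <- stats::setNames(num(ft$Value), ft$Reaction)
  fsd <- if (!is.null(ft$StdDev)) stats::setNames(num(ft$StdDev), ft$Reaction)
  flux <- flux_profile(align_named(v, rxns, default = 0),
                       sd = if (!is.null(fsd)) align_named(fsd, rxns))

  active <- flux$active_mask
  no_kcat <- active & is.na(par$kcat_fwd)
  if (any(no_kcat)) {
    stopf("missing forward kcat for active reaction(s): %s",
          paste(rxns[no_kcat], collapse = ", "),
          class = "ecm_parameter_error")
  }

  meas <- measurement_set(
    metabolite_conc = table_to_named(tabs$ConcentrationData, "Compound", mets,
                                     "ConcentrationData"),
    enzyme_conc = table_to_named(tabs$EnzymeData, "Reaction", rxns,
                                 "EnzymeData")
  )

  ecm_model(net, par, flux, bounds = list(lower = lower, upper = upper),
            measurements = meas)
}

table_to_named <- function(tab, key, ids, table_name) {
  if (is.null(tab) || nrow(tab) == 0L) return(NULL)
  bad <- setdiff(tab[[key]], ids)
  if (length(bad) > 0L) {
    stopf("%s table references unknown identifier(s): %s",
          table_name, paste(bad, collapse = ", "),
          class = "ecm_reference_error")
  }
  stats::setNames(suppressWarnings(as.numeric(tab$Value)), tab[[key]])
}

parameters_from_table <- function(pt, net) {
  rxns <- net$reaction_ids
  mets <- net$metabolite_ids
  kcat_fwd <- kcat_rev <- K_eq <- dG0 <- h_E <- m_l <- NULL
  km_rows <- list()
  mods <- list()
  seen <- character()
  if (!is.null(pt) && nrow(pt) > 0L) {
    for (k in seq_len(nrow(pt))) {
      qt <- tolower(trimws(pt$QuantityType[k]))
      r <- trimws(pt$`Reaction:SBML:reaction:id`[k] %||% "")
      cpd <- trimws(pt$`Compound:SBML:species:id`[k] %||% "")
      if (is.na(r)) r <- ""
      if (is.na(cpd)) cpd <- ""
      val <- suppressWarnings(as.numeric(pt$Value[k]))
      unit <- pt$Unit[k] %||% ""
      if (nzchar(r) && !r %in% rxns) {
        stopf("Parameter table row %d references unknown reaction '%s'",
              k, r, class = "ecm_reference_error")
      }
      if (nzchar(cpd) && !cpd %in% mets) {
        stopf("Parameter table row %d references unknown compound '%s'",
              k, cpd, class = "ecm_reference_error")
      }
      key <- paste(qt, r, cpd, sep = "|")
      if (key %in% seen) {
        stopf("duplicate parameter for (%s, %s, %s)", qt, r, cpd,
              class = "ecm_conflict_error")
      }
      seen <- c(seen, key)
      val <- convert_unit(val, unit, qt)
      if (qt == "substrate catalytic rate constant") {
        kcat_fwd[r] <- val
      } else if (qt == "product catalytic rate constant") {
        kcat_rev[r] <- val
      } else if (qt == "catalytic rate constant geometric mean") {
        attr(kcat_fwd, "geometric_mean") <-
          c(attr(kcat_fwd, "geometric_mean"), stats::setNames(val, r))
      } else if (qt == "michaelis constant") {
        km_rows[[length(km_rows) + 1L]] <-
          data.frame(reaction = r, compound = cpd, value = val)
      } else if (qt == "equilibrium constant") {
        K_eq[r] <- val
      } else if (qt == "reaction gibbs energy") {
        dG0[r] <- val / RT_KJ_PER_MOL
      } else if (qt == "protein molecular mass") {
        m_l[r] <- val
      } else if (qt == "enzyme burden") {
        h_E[r] <- val
      } else if (qt == "inhibition constant") {
        mods[[length(mods) + 1L]] <-
          data.frame(reaction = r, compound = cpd, K_I = val,
                     mechanism = "noncompetitive")
      } else {
        stopf("unknown quantity type '%s' in Parameter table row %d", qt, k)
      }
    }
  }
  if (!is.null(K_eq) && !is.null(dG0)) {
    both <- intersect(names(K_eq), names(dG0))
    if (any(abs(log(K_eq[both]) + dG0[both]) > 1e-6)) {
      stopf("equilibrium constant and reaction gibbs energy disagree for %s",
            paste(both, collapse = ", "), class = "ecm_conflict_error")
    }
  }
  geo <- attr(kcat_fwd, "geometric_mean")

  KM <- km_dataframe_to_matrix(
    if (length(km_rows)) do.call(rbind, km_rows) else NULL, net
  )
  # default prior for missing Michaelis constants: 0.1 mM, flagged
  S <- net$stoichiometry
  km_filled <- matrix(FALSE, nrow(S), ncol(S), dimnames = dimnames(S))
  miss <- S != 0 & is.na(KM)
  KM[miss] <- 0.1
  km_filled[miss] <- TRUE

  # merge dG0-only reactions into K_eq
  keq_full <- align_named(K_eq, rxns)
  if (!is.null(dG0)) {
    d <- align_named(dG0, rxns)
    use <- is.na(keq_full) & !is.na(d)
    keq_full[use] <- exp(-d[use])
  }

  par <- kinetic_parameters(
    net,
    kcat_fwd = strip_attr(kcat_fwd), kcat_rev = kcat_rev, K_M = KM,
    K_eq = if (all(is.na(keq_full))) NULL else keq_full,
    h_E = h_E, m_l = m_l,
    modifiers = if (length(mods)) do.call(rbind, mods) else NULL,
    km_filled = km_filled
  )
  if (!is.null(geo)) attr(par, "kcat_geometric_mean") <- geo
  par
}

strip_attr <- function(x) {
  attr(x, "geometric_mean") <- NULL
  x
}

#' Write a model bundle as SBtab-style tables
#'
#' Inverse of [load_model()]; numeric values are written with full double
#' precision so that a write/read round trip reproduces the model.
#'
#' @param model An [ecm_model()].
#' @param path Output TSV file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  net <- model$network
  par <- model$params
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))
  rxn_formula <- vapply(net$reaction_ids, function(l) {
    n <- net$stoichiometry[, l]
    term <- function(i) {
      if (abs(n[i]) == 1) net$metabolite_ids[i]
      else paste(formatC(abs(n[i]), format = "g"), net$metabolite_ids[i])
    }
    subs <- vapply(which(n < 0), term, character(1L))
    prods <- vapply(which(n > 0), term, character(1L))
    paste(paste(subs, collapse = " + "), "<=>",
          paste(prods, collapse = " + "))
  }, character(1L))

  reaction <- data.frame(ID = net$reaction_ids, ReactionFormula = rxn_formula,
                         check.names = FALSE)
  attr(reaction, "sbtab") <- list(TableName = "Reaction",
                                  TableType = "Reaction")

  fx <- net$fixed_mask
  compound <- data.frame(
    ID = net$metabolite_ids,
    IsConstant = ifelse(fx, "True", "False"),
    `Concentration:Min` = fmt(ifelse(fx, NA, model$bounds$lower)),
    `Concentration:Max` = fmt(ifelse(fx, NA, model$bounds$upper)),
    Concentration = fmt(ifelse(fx, model$bounds$lower, NA)),
    check.names = FALSE
  )
  attr(compound, "sbtab") <- list(TableName = "Compound",
                                  TableType = "Compound")

  prow <- function(qt, r, cpd, val, unit) {
    data.frame(QuantityType = qt, `Reaction:SBML:reaction:id` = r,
               `Compound:SBML:species:id` = cpd, Value = fmt(val),
               Unit = unit, check.names = FALSE)
  }
  rows <- list()
  for (l in net$reaction_ids) {
    if (!is.na(par$kcat_fwd[l])) {
      rows[[length(rows) + 1L]] <-
        prow("substrate catalytic rate constant", l, "", par$kcat_fwd[l], "1/s")
    }
    if (!is.na(par$kcat_rev[l])) {
      rows[[length(rows) + 1L]] <-
        prow("product catalytic rate constant", l, "", par$kcat_rev[l], "1/s")
    }
    if (!is.na(par$K_eq[l])) {
      rows[[length(rows) + 1L]] <-
        prow("equilibrium constant", l, "", par$K_eq[l], "dimensionless")
    }
    if (!is.na(par$h_E[l]) && par$h_E[l] != 1) {
      rows[[length(rows) + 1L]] <-
        prow("enzyme burden", l, "", par$h_E[l], "dimensionless")
    }
    if (!is.na(par$m_l[l])) {
      rows[[length(rows) + 1L]] <-
        prow("protein molecular mass", l, "", par$m_l[l], "Da")
    }
    for (i in which(net$stoichiometry[, l] != 0)) {
      if (!is.na(par$K_M[i, l]) && !par$km_filled[i, l]) {
        rows[[length(rows) + 1L]] <-
          prow("michaelis constant", l, net$metabolite_ids[i],
               par$K_M[i, l], "mM")
      }
    }
  }
  if (nrow(par$modifiers) > 0L) {
    for (k in seq_len(nrow(par$modifiers))) {
      rows[[length(rows) + 1L]] <-
        prow("inhibition constant", par$modifiers$reaction[k],
             par$modifiers$compound[k], par$modifiers$K_I[k], "mM")
    }
  }
  parameter <- do.call(rbind, rows)
  attr(parameter, "sbtab") <- list(TableName = "Parameter",
                                   TableType = "Quantity")

  flux <- data.frame(Reaction = net$reaction_ids,
                     Value = fmt(model$flux$v),
                     StdDev = fmt(model$flux$sd %||%
                                    rep(NA_real_, length(net$reaction_ids))),
                     check.names = FALSE)
  attr(flux, "sbtab") <- list(TableName = "Flux", TableType = "Quantity")

  tabs <- list(Reaction = reaction, Compound = compound,
               Parameter = parameter, Flux = flux)

  if (length(model$measurements$metabolite_conc) > 0L) {
    cd <- data.frame(Compound = names(model$measurements$metabolite_conc),
                     Value = fmt(model$measurements$metabolite_conc),
                     check.names = FALSE)
    attr(cd, "sbtab") <- list(TableName = "ConcentrationData",
                              TableType = "Quantity")
    tabs$ConcentrationData <- cd
  }
  if (length(model$measurements$enzyme_conc) > 0L) {
    ed <- data.frame(Reaction = names(model$measurements$enzyme_conc),
                     Value = fmt(model$measurements$enzyme_conc),
                     check.names = FALSE)
    attr(ed, "sbtab") <- list(TableName = "EnzymeData",
                              TableType = "Quantity")
    tabs$EnzymeData <- ed
  }
  write_sbtab(tabs, path)
}
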