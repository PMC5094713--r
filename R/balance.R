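# Kinetic parameter balancing: project observed log-parameters onto the
# manifold defined by the Haldane relationships (and, implicitly, the
# Wegscheider conditions, which are enforced by parameterizing equilibrium
# constants through per-metabolite formation energies).

#' Balance a kinetic parameter set onto the Haldane manifold
#'
#' Measured kinetic constants collected from different sources are usually
#' thermodynamically inconsistent: the Haldane relationship
#' `K_eq = (kcat_fwd/kcat_rev) * prod(K_M, products)/prod(K_M, substrates)`
#' (with stoichiometric exponents) couples every reaction's constants, and
#' equilibrium constants across the network must satisfy Wegscheider cycle
#' conditions. This function computes the precision-weighted least-squares
#' projection of the observed log-parameters onto the consistent manifold.
#'
#' The free coordinates are per-metabolite formation energies (in RT units),
#' log forward turnover numbers, and log Michaelis constants; `K_eq` and
#' `kcat_rev` are derived from them, so every output satisfies the Haldane
#' relationship exactly. The fit is an ordinary linear least-squares problem
#' in these coordinates and is deterministic; gauge freedom in the formation
#' energies (only differences are observable) is resolved by the
#' minimum-norm solution, which does not affect any derived constant.
#'
#' @param par A [kinetic_parameters()], possibly with missing `kcat_rev`,
#'   `K_eq` or `K_M` entries.
#' @param net The corresponding [network_model()].
#' @param weights Optional list of precision weights (inverse variances on
#'   the natural-log scale) with elements `kcat_fwd`, `kcat_rev`, `K_M`,
#'   `K_eq`, each a scalar or a named per-reaction vector. Default 1.
#' @param km_prior Default prior for missing Michaelis constants, in mM
#'   (default 0.1, the geometric mid-range of typical values).
#' @param km_prior_weight Precision weight of the K_M prior (default 0.01,
#'   i.e. deliberately weak).
#' @return A balanced [kinetic_parameters()] with attribute `"balance"`
#'   carrying the residual sum of squares and per-quantity log deviations.
#' @export
balance_haldane <- function(par, net, weights = NULL, km_prior = 0.1,
                            km_prior_weight = 0.01) {
  S <- net$stoichiometry
  mets <- net$metabolite_ids
  rxns <- net$reaction_ids
  n_met <- length(mets)
  n_rxn <- length(rxns)

  wt <- function(q, l, default = 1) {
    w <- weights[[q]]
    if (is.null(w)) return(default)
    if (length(w) == 1L && is.null(names(w))) return(as.numeric(w))
    out <- w[l]
    if (is.na(out)) default else as.numeric(out)
  }

  # variable layout: [g_1..g_m | lkf_1..lkf_r | lkm_pairs]
  pairs <- which(S != 0, arr.ind = TRUE)
  pair_key <- paste(mets[pairs[, 1L]], rxns[pairs[, 2L]], sep = "|")
  n_pair <- nrow(pairs)
  n_var <- n_met + n_rxn + n_pair
  idx_g <- seq_len(n_met)
  idx_kf <- n_met + seq_len(n_rxn)
  idx_km <- n_met + n_rxn + seq_len(n_pair)

  pair_index <- function(i, l) {
    match(paste(mets[i], rxns[l], sep = "|"), pair_key)
  }

  rows <- list()
  add_row <- function(coef_idx, coef_val, y, w, tag) {
    r <- numeric(n_var)
    r[coef_idx] <- coef_val
    rows[[length(rows) + 1L]] <<- list(x = r, y = y, w = w, tag = tag)
  }

  # design row for ln K_eq(l) = -sum_i n_il g_i
  keq_row <- function(l) {
    li <- match(l, rxns)
    n <- S[, li]
    list(idx = idx_g[n != 0], val = -n[n != 0])
  }
  # design row for ln kcat_rev(l) = lkf_l - ln K_eq_l
  #                                + sum_P |n| ln K_M - sum_S |n| ln K_M
  krev_row <- function(l) {
    li <- match(l, rxns)
    n <- S[, li]
    ridx <- idx_kf[li]
    rval <- 1
    kq <- keq_row(l)
    ridx <- c(ridx, kq$idx); rval <- c(rval, -kq$val)
    for (i in which(n != 0)) {
      ridx <- c(ridx, idx_km[pair_index(i, li)])
      rval <- c(rval, ifelse(n[i] > 0, abs(n[i]), -abs(n[i])))
    }
    list(idx = ridx, val = rval)
  }

  geo <- attr(par, "kcat_geometric_mean")

  for (li in seq_len(n_rxn)) {
    l <- rxns[li]
    if (!is.na(par$kcat_fwd[l])) {
      add_row(idx_kf[li], 1, log(par$kcat_fwd[l]),
              wt("kcat_fwd", l), "kcat_fwd")
    }
    if (!is.na(par$kcat_rev[l])) {
      kr <- krev_row(l)
      add_row(kr$idx, kr$val, log(par$kcat_rev[l]),
              wt("kcat_rev", l), "kcat_rev")
    }
    if (!is.null(geo) && l %in% names(geo)) {
      kr <- krev_row(l)
      # (ln kcat_fwd + ln kcat_rev)/2 observation
      r <- numeric(n_var)
      r[idx_kf[li]] <- 0.5
      r[kr$idx] <- r[kr$idx] + 0.5 * kr$val
      rows[[length(rows) + 1L]] <- list(
        x = r, y = log(geo[[l]]), w = wt("kcat_geo", l), tag = "kcat_geo"
      )
    }
    if (!is.na(par$K_eq[l])) {
      kq <- keq_row(l)
      add_row(kq$idx, kq$val, log(par$K_eq[l]), wt("K_eq", l), "K_eq")
    }
  }
  for (p in seq_len(n_pair)) {
    i <- pairs[p, 1L]; li <- pairs[p, 2L]
    km <- par$K_M[i, li]
    filled <- par$km_filled[i, li]
    if (!is.na(km) && !filled) {
      add_row(idx_km[p], 1, log(km), wt("K_M", rxns[li]), "K_M")
    } else {
      add_row(idx_km[p], 1, log(km_prior), km_prior_weight, "K_M_prior")
    }
  }

  if (length(rows) == 0L) {
    stopf("no kinetic observations to balance", class = "ecm_parameter_error")
  }
  X <- do.call(rbind, lapply(rows, `[[`, "x"))
  y <- vapply(rows, `[[`, numeric(1L), "y")
  w <- vapply(rows, `[[`, numeric(1L), "w")
  tags <- vapply(rows, `[[`, character(1L), "tag")

  sw <- sqrt(w)
  sv <- svd(X * sw, nv = n_var)   # full right basis: the null space matters
  tol <- max(dim(X)) * max(sv$d, 0) * .Machine$double.eps
  pos <- sv$d > tol
  Vr <- sv$v[, seq_along(sv$d), drop = FALSE]
  theta <- Vr[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% (y * sw)) / sv$d[pos])
  theta <- drop(theta)

  # outputs must be identifiable: every derived constant has to lie in the
  # row space of the design, otherwise the data do not pin it down
  null_cols <- c(which(!pos),
                 setdiff(seq_len(n_var), seq_along(sv$d)))
  null_dim <- length(null_cols)
  if (null_dim > 0L) {
    Vnull <- sv$v[, null_cols, drop = FALSE]
    out_rows <- matrix(0, 0, n_var)
    for (li in seq_len(n_rxn)) {
      r1 <- numeric(n_var); r1[idx_kf[li]] <- 1
      kq <- keq_row(rxns[li]); r2 <- numeric(n_var); r2[kq$idx] <- kq$val
      kr <- krev_row(rxns[li]); r3 <- numeric(n_var); r3[kr$idx] <- kr$val
      out_rows <- rbind(out_rows, r1, r2, r3)
    }
    km_rows <- diag(n_var)[idx_km, , drop = FALSE]
    out_rows <- rbind(out_rows, km_rows)
    leak <- max(abs(out_rows %*% Vnull))
    if (leak > 1e-8) {
      stopf(paste("parameter balancing is under-determined: some kinetic",
                  "constants are not pinned down by the observations;",
                  "supply priors (e.g. kcat_fwd or K_eq values) for every",
                  "active reaction"), class = "ecm_parameter_error")
    }
  }

  g <- theta[idx_g]
  lkf <- theta[idx_kf]
  lkm <- theta[idx_km]

  ln_keq <- -drop(crossprod(S, g))
  names(ln_keq) <- rxns
  KM <- par$K_M
  KM[cbind(pairs[, 1L], pairs[, 2L])] <- exp(lkm)
  ln_krev <- lkf - ln_keq
  for (p in seq_len(n_pair)) {
    i <- pairs[p, 1L]; li <- pairs[p, 2L]
    ln_krev[li] <- ln_krev[li] + sign(S[i, li]) * abs(S[i, li]) * lkm[p]
  }

  fitted <- drop(X %*% theta)
  dev <- fitted - y
  out <- kinetic_parameters(
    net,
    kcat_fwd = stats::setNames(exp(lkf), rxns),
    kcat_rev = stats::setNames(exp(ln_krev), rxns),
    K_M = KM,
    K_eq = stats::setNames(exp(ln_keq), rxns),
    h_E = par$h_E, m_l = par$m_l, modifiers = par$modifiers,
    kcat_inf = par$kcat_inf, km_filled = par$km_filled
  )
  attr(out, "balance") <- list(
    rss = sum(w * dev^2),
    deviations = data.frame(quantity = tags, log_deviation = dev),
    formation_energy_RT = stats::setNames(g, mets)
  )
  out
}
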