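# Driving forces, metabolite polytope and MDF baseline.

# Small LP wrapper around boot::simplex:
#   optimize obj'x  subject to  A x <= b,  lb <= x <= ub  (finite bounds).
# Variables are shifted to y = x - lb >= 0; rows with negative rhs are
# rewritten as >= constraints so the simplex tableau stays canonical.
solve_lp <- function(obj, A, b, lb, ub, maximize = FALSE) {
  n <- length(obj)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stopf("LP bounds must be finite")
  }
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  if (is.null(A)) {
    A <- matrix(0, 0, n)
    b <- numeric()
  }
  shift_b <- b - drop(A %*% lb)
  Aall <- rbind(A, diag(n))
  ball <- c(shift_b, ub - lb)
  neg <- ball < 0
  A1 <- Aall[!neg, , drop = FALSE]
  b1 <- ball[!neg]
  A2 <- -Aall[neg, , drop = FALSE]
  b2 <- -ball[neg]
  res <- boot::simplex(
    a = obj,
    A1 = if (nrow(A1)) A1 else NULL, b1 = if (nrow(A1)) b1 else NULL,
    A2 = if (nrow(A2)) A2 else NULL, b2 = if (nrow(A2)) b2 else NULL,
    maxi = maximize, n.iter = 50 * (n + nrow(Aall)), eps = 1e-10
  )
  if (res$solved == -1) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  if (res$solved != 1) {
    return(list(status = "unsolved", x = NULL, value = NA_real_))
  }
  x <- unname(drop(res$soln)) + unname(lb)
  list(status = "optimal", x = x, value = sum(obj * x))
}

#' Thermodynamic driving forces
#'
#' The driving force of a reaction is the negative reaction Gibbs energy in
#' RT units, `Theta = -dG'/RT = ln(K_eq/Q)`, where `Q` is the mass-action
#' ratio at the 1 mM standard concentration. In log-concentration
#' coordinates it is linear: `Theta_l = ln K_eq_l - sum_i n_il x_i`.
#'
#' @param x Named log-concentration vector (`ln(c/1 mM)`). Values for fixed
#'   metabolites may be omitted; they are substituted from the model.
#' @param model An [ecm_model()].
#' @return Named per-reaction vector of driving forces (unitless). Negative
#'   values are legal outputs; feasibility is checked by
#'   [build_polytope()].
#' @export
driving_forces <- function(x, model) {
  net <- model$network
  xx <- full_log_concentrations(x, model)
  drop(log(model$params$K_eq) - crossprod(net$stoichiometry, xx))
}

# Assemble the full named log-concentration vector, substituting clamped
# metabolites from the model's fixed values.
full_log_concentrations <- function(x, model) {
  net <- model$network
  xx <- align_named(x, net$metabolite_ids)
  fx <- net$fixed_mask
  xx[fx] <- log(net$fixed_values[net$metabolite_ids[fx]])
  if (any(is.na(xx))) {
    stopf("log-concentrations missing for metabolite(s): %s",
          paste(net$metabolite_ids[is.na(xx)], collapse = ", "))
  }
  xx
}

#' Build the metabolite polytope
#'
#' The set of feasible log-concentration vectors is a convex polytope with
#' two kinds of faces: P-faces from the physiological concentration bounds,
#' and E-faces from the requirement that every active (oriented) reaction
#' dissipates Gibbs energy, `Theta_l(x) >= epsilon`. On an E-face a reaction
#' sits at equilibrium and its enzyme demand diverges, so the enzyme cost
#' function itself acts as a barrier; `epsilon` only keeps the linear
#' constraints strict.
#'
#' @param model An [ecm_model()]; reactions must already be oriented along
#'   their fluxes (see [orient_reactions()]).
#' @param epsilon Minimal driving force (unitless, default 1e-9) applied to
#'   every active reaction.
#' @param theta_min Optional named per-reaction minimal driving forces that
#'   override `epsilon` (user-chosen force floors).
#' @return An object of class `metabolite_polytope` with the linear
#'   constraint system, an interior witness point (the point of maximal
#'   minimum slack) and bookkeeping fields.
#' @export
build_polytope <- function(model, epsilon = 1e-9, theta_min = NULL) {
  net <- model$network
  par <- model$params
  v <- model$flux$v
  if (any(v < 0)) {
    stopf("reactions must be oriented along their fluxes before building the polytope (see orient_reactions)")
  }
  active <- names(v)[model$flux$active_mask]
  free <- net$metabolite_ids[!net$fixed_mask]
  if (any(is.na(par$K_eq[active]))) {
    stopf("equilibrium constants missing for active reaction(s): %s",
          paste(active[is.na(par$K_eq[active])], collapse = ", "),
          class = "ecm_parameter_error")
  }
  eps <- stats::setNames(rep(epsilon, length(active)), active)
  if (!is.null(theta_min)) {
    known <- intersect(names(theta_min), active)
    eps[known] <- pmax(eps[known], theta_min[known])
  }
  x_fixed <- log(net$fixed_values)
  x_min <- log(model$bounds$lower[free])
  x_max <- log(model$bounds$upper[free])

  S <- net$stoichiometry
  G <- t(S[free, active, drop = FALSE])
  theta0 <- log(par$K_eq[active])
  if (length(x_fixed) > 0L) {
    theta0 <- theta0 -
      drop(crossprod(S[names(x_fixed), active, drop = FALSE], x_fixed))
  }
  names(theta0) <- active

  poly <- structure(
    list(
      free_ids = free, x_min = x_min, x_max = x_max,
      active_ids = active, G = G, theta0 = theta0, eps = eps,
      x_fixed = x_fixed, witness = NULL, max_slack = NA_real_
    ),
    class = "metabolite_polytope"
  )

  if (length(active) == 0L) {
    poly$witness <- (x_min + x_max) / 2
    poly$max_slack <- Inf
    return(poly)
  }

  sl <- maximin_slack(poly)
  if (sl$status != "optimal" || sl$slack <= 0) {
    iis <- infeasible_subset(poly)
    stopf(paste(
      "the provided flux directions are thermodynamically infeasible:",
      "the metabolite polytope is an empty set.",
      "Irreducible infeasible constraint set: driving-force constraints of",
      "reaction(s) %s (within the given concentration bounds)"),
      paste(iis, collapse = ", "), class = "ecm_infeasible_error")
  }
  poly$witness <- sl$x
  poly$max_slack <- sl$slack
  poly
}

# LP: maximize the minimum slack min_l (Theta_l - eps_l) over the box.
maximin_slack <- function(poly, eps = poly$eps) {
  m <- length(poly$free_ids)
  k <- length(poly$active_ids)
  rhs <- poly$theta0 - eps
  # bounds for the auxiliary slack variable t from interval arithmetic
  Gp <- pmax(poly$G, 0); Gn <- pmin(poly$G, 0)
  th_hi <- rhs - drop(Gn %*% poly$x_max + Gp %*% poly$x_min)
  th_lo <- rhs - drop(Gp %*% poly$x_max + Gn %*% poly$x_min)
  t_hi <- max(th_hi); t_lo <- min(th_lo, 0)
  A <- cbind(poly$G, 1)           # G x + t <= theta0 - eps
  res <- solve_lp(
    obj = c(rep(0, m), 1), A = A, b = rhs,
    lb = c(poly$x_min, t_lo), ub = c(poly$x_max, t_hi),
    maximize = TRUE
  )
  if (res$status != "optimal") {
    return(list(status = res$status, x = NULL, slack = NA_real_))
  }
  x <- res$x[seq_len(m)]
  names(x) <- poly$free_ids
  list(status = "optimal", x = x, slack = res$x[m + 1L])
}

# Greedy deletion filter: an irreducible subset of driving-force constraints
# that is infeasible within the concentration box.
infeasible_subset <- function(poly) {
  keep <- poly$active_ids
  feasible_with <- function(ids) {
    if (length(ids) == 0L) return(TRUE)
    sub <- poly
    sub$active_ids <- ids
    sub$G <- poly$G[ids, , drop = FALSE]
    sub$theta0 <- poly$theta0[ids]
    sub$eps <- poly$eps[ids]
    sl <- maximin_slack(sub)
    sl$status == "optimal" && sl$slack > 0
  }
  for (id in poly$active_ids) {
    trial <- setdiff(keep, id)
    if (!feasible_with(trial)) keep <- trial
  }
  keep
}

#' @export
print.metabolite_polytope <- function(x, ...) {
  cat(sprintf(
    "<metabolite_polytope> %d free metabolites, %d driving-force constraints, max slack %.4g\n",
    length(x$free_ids), length(x$active_ids), x$max_slack
  ))
  invisible(x)
}

#' Test whether a point lies in the metabolite polytope
#'
#' @param poly A [build_polytope()] result.
#' @param x Log-concentration vector over the free metabolites (named or in
#'   polytope order).
#' @param tol Numerical slack allowed on each constraint.
#' @return Logical scalar.
#' @export
polytope_contains <- function(poly, x, tol = 1e-9) {
  xf <- if (!is.null(names(x))) x[poly$free_ids] else x
  if (length(xf) != length(poly$free_ids) || any(is.na(xf))) {
    stopf("point must cover every free metabolite")
  }
  if (any(xf < poly$x_min - tol) || any(xf > poly$x_max + tol)) {
    return(FALSE)
  }
  if (length(poly$active_ids) == 0L) return(TRUE)
  theta <- poly$theta0 - drop(poly$G %*% xf)
  all(theta >= poly$eps - tol)
}

#' Max-min driving force (MDF)
#'
#' Solves the linear program `maximize t subject to Theta_l(x) >= t` over
#' the concentration box: the metabolite profile that keeps the least-driven
#' reaction as far from equilibrium as possible. A positive optimum
#' certifies that the metabolite polytope is nonempty; the argmax is used as
#' the interior starting point for cost minimization.
#'
#' @param poly A [build_polytope()] result.
#' @return List with `mdf` (unitless), `x` (full named log-concentration
#'   vector, fixed metabolites substituted), and `theta` (per-reaction
#'   driving forces at the MDF point).
#' @export
max_min_driving_force <- function(poly) {
  m <- length(poly$free_ids)
  if (length(poly$active_ids) == 0L) {
    x <- c(poly$witness, exp_names(poly))
    return(list(mdf = Inf, x = x[order(names(x))], theta = numeric()))
  }
  sl <- maximin_slack(poly, eps = stats::setNames(
    rep(0, length(poly$active_ids)), poly$active_ids
  ))
  if (sl$status != "optimal") {
    stopf(paste(
      "the provided flux directions are thermodynamically infeasible:",
      "the metabolite polytope is an empty set"),
      class = "ecm_infeasible_error")
  }
  theta <- poly$theta0 - drop(poly$G %*% sl$x)
  x_full <- c(sl$x, poly$x_fixed)
  list(mdf = sl$slack, x = x_full, theta = theta)
}

exp_names <- function(poly) poly$x_fixed

#' Extreme points of the metabolite polytope
#'
#' Returns the `2m` points that realize the minimal and maximal value of
#' each free metabolite over the polytope (the anchor points used for broad
#' metabolite-profile sampling).
#'
#' @param poly A [build_polytope()] result.
#' @return Numeric matrix with one row per point (rows named
#'   `"min:<id>"`/`"max:<id>"`) and one column per free metabolite. With no
#'   free metabolites a single empty-row matrix is returned.
#' @export
extreme_points <- function(poly) {
  m <- length(poly$free_ids)
  if (m == 0L) {
    return(matrix(numeric(), nrow = 1L, ncol = 0L))
  }
  A <- poly$G
  b <- poly$theta0 - poly$eps
  out <- matrix(NA_real_, 2L * m, m,
                dimnames = list(
                  paste0(rep(c("min:", "max:"), m),
                         rep(poly$free_ids, each = 2L)),
                  poly$free_ids
                ))
  row <- 1L
  for (j in seq_len(m)) {
    obj <- numeric(m); obj[j] <- 1
    for (maxi in c(FALSE, TRUE)) {
      res <- solve_lp(obj, A = if (length(poly$active_ids)) A else NULL,
                      b = b, lb = poly$x_min, ub = poly$x_max,
                      maximize = maxi)
      if (res$status != "optimal") {
        stopf("LP for extreme point of '%s' failed (%s)",
              poly$free_ids[j], res$status, class = "ecm_infeasible_error")
      }
      out[row, ] <- res$x
      row <- row + 1L
    }
  }
  out
}
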