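# Enzyme cost minimization: convex program over the metabolite polytope,
# plus tolerance ranges of nearly optimal states.

#' Solve the enzyme cost minimization problem
#'
#' Minimizes the total enzyme cost `q(x)` (see [enzyme_cost()]) over the
#' metabolite polytope, optionally with a small quadratic regularizer
#' `lambda * ||x - x_hat||^2` that makes the reported solution unique for
#' tiers whose cost is not strictly convex (`EMC0`, `EMC1`, `EMC2`-type).
#' The optimization runs in the free log-concentration coordinates with the
#' polytope's linear constraints handled by an interior barrier method
#' (`stats::constrOptim`), starting from the max-min driving force point,
#' which by construction has maximal minimum slack.
#'
#' @param model An [ecm_model()]. Reactions are oriented along their fluxes
#'   automatically.
#' @param spec A [cost_function_spec()] or a tier name.
#' @param lambda Regularizer weight; default `1e-6` times the cost at the
#'   MDF point (negligible for the cost, decisive for tie-breaking). Set to
#'   0 to disable.
#' @param x_hat Regularizer anchor in log-concentration space; default is
#'   the midpoint of the log-bounds of each free metabolite.
#' @param epsilon Minimal driving force passed to [build_polytope()].
#' @param theta_min Optional per-reaction driving-force floors.
#' @param seed Integer used only if the deterministic start fails and a
#'   multi-start fallback is triggered.
#' @param control List of optimizer settings: `outer_iterations`,
#'   `outer_eps`, `maxit`, `reltol`, `mu`.
#' @return An object of class `ecm_solution`: optimal log-concentrations
#'   `x_opt`, concentrations `c_opt` (mM), enzyme levels `E_opt` (mM),
#'   total cost `q_opt`, the per-reaction `breakdown`, the polytope, the
#'   regularizer actually used, and solver `diagnostics`.
#' @export
ecm_solve <- function(model, spec = "EMC4CM", lambda = NULL, x_hat = NULL,
                      epsilon = 1e-9, theta_min = NULL, seed = 1L,
                      control = list()) {
  if (!inherits(spec, "cost_function_spec")) spec <- cost_function_spec(spec)
  model <- orient_reactions(model)
  validate_cost_inputs(model, spec)
  poly <- build_polytope(model, epsilon = epsilon, theta_min = theta_min)
  mdf <- max_min_driving_force(poly)

  free <- poly$free_ids
  m <- length(free)
  ctl <- utils::modifyList(
    list(outer_iterations = 60L, outer_eps = 1e-10, maxit = 1000L,
         reltol = 1e-14, mu = 1e-8),
    control
  )

  if (is.null(x_hat)) {
    x_hat <- (poly$x_min + poly$x_max) / 2
  } else {
    x_hat <- align_named(x_hat, free)
    if (any(is.na(x_hat))) {
      stopf("x_hat must cover every free metabolite")
    }
  }

  q_mdf <- enzyme_cost(mdf$x, model, spec)$q
  if (is.null(lambda)) lambda <- 1e-6 * max(q_mdf, .Machine$double.eps)

  objective <- function(xf) {
    names(xf) <- free
    if (!polytope_contains(poly, xf, tol = 0)) return(Inf)
    ec <- try(enzyme_cost(xf, model, spec), silent = TRUE)
    if (inherits(ec, "try-error")) return(Inf)
    ec$q + lambda * sum((xf - x_hat)^2)
  }
  gradient <- function(xf) {
    names(xf) <- free
    ec <- enzyme_cost(xf, model, spec)
    ec$gradient[free] + 2 * lambda * (xf - x_hat)
  }

  if (m == 0L) {
    x_opt <- poly$x_fixed[model$network$metabolite_ids]
    ec <- enzyme_cost(x_opt, model, spec)
    return(new_ecm_solution(x_opt, ec, model, poly, lambda, x_hat,
                            list(converged = TRUE, outer = 0L,
                                 start = "fixed", value = ec$q)))
  }

  # linear constraints ui %*% x - ci >= 0: box faces and driving forces
  ui <- rbind(diag(m), -diag(m),
              if (length(poly$active_ids)) -poly$G)
  ci <- c(poly$x_min, -poly$x_max,
          if (length(poly$active_ids)) poly$eps - poly$theta0)

  run_from <- function(x0) {
    stats::constrOptim(
      theta = x0, f = objective, grad = gradient, ui = ui, ci = ci,
      mu = ctl$mu, method = "BFGS",
      outer.iterations = ctl$outer_iterations, outer.eps = ctl$outer_eps,
      control = list(maxit = ctl$maxit, reltol = ctl$reltol)
    )
  }

  x0 <- mdf$x[free]
  fit <- try(run_from(x0), silent = TRUE)
  start_used <- "mdf"
  if (inherits(fit, "try-error") || fit$convergence != 0) {
    # multi-start fallback: random interior mixtures of witness and
    # extreme points
    ep <- extreme_points(poly)
    set.seed(seed)
    best <- if (inherits(fit, "try-error")) NULL else fit
    for (k in seq_len(5L)) {
      wgt <- stats::runif(nrow(ep) + 1L)
      wgt <- wgt / sum(wgt)
      x0k <- drop(wgt %*% rbind(ep, poly$witness[free]))
      x0k <- 0.5 * x0k + 0.5 * poly$witness[free]
      fit_k <- try(run_from(x0k), silent = TRUE)
      if (!inherits(fit_k, "try-error") &&
          (is.null(best) || fit_k$value < best$value)) {
        best <- fit_k
        start_used <- sprintf("multistart_%d", k)
      }
    }
    if (is.null(best)) {
      stopf("enzyme cost minimization failed to converge from any start point",
            class = "ecm_error")
    }
    fit <- best
  }

  x_free <- stats::setNames(fit$par, free)
  x_opt <- c(x_free, poly$x_fixed)[model$network$metabolite_ids]
  ec <- enzyme_cost(x_opt, model, spec)
  g <- ec$gradient[free] + 2 * lambda * (x_free - x_hat)
  diag_info <- list(
    converged = fit$convergence == 0,
    outer = fit$outer.iterations,
    barrier = fit$barrier.value,
    start = start_used,
    value = fit$value,
    projected_gradient_norm = projected_gradient_norm(x_free, g, poly),
    active_bounds = active_bound_set(x_free, poly)
  )
  new_ecm_solution(x_opt, ec, model, poly, lambda, x_hat, diag_info)
}

projected_gradient_norm <- function(x, g, poly, tol = 1e-7) {
  # zero out gradient components pushing into an active box face
  at_lo <- x <= poly$x_min + tol
  at_hi <- x >= poly$x_max - tol
  g[at_lo & g > 0] <- 0
  g[at_hi & g < 0] <- 0
  sqrt(sum(g^2))
}

active_bound_set <- function(x, poly, tol = 1e-7) {
  lo <- poly$free_ids[x <= poly$x_min + tol]
  hi <- poly$free_ids[x >= poly$x_max - tol]
  list(lower = lo, upper = hi)
}

new_ecm_solution <- function(x_opt, ec, model, poly, lambda, x_hat,
                             diagnostics) {
  E <- stats::setNames(ec$breakdown$E_l, ec$breakdown$reaction)
  structure(
    list(
      x_opt = x_opt,
      c_opt = exp(x_opt),
      E_opt = E,
      q_opt = ec$q,
      breakdown = ec$breakdown,
      polytope = poly,
      regularizer = list(lambda = lambda, x_hat = x_hat),
      diagnostics = diagnostics
    ),
    class = "ecm_solution"
  )
}

#' @export
print.ecm_solution <- function(x, ...) {
  cat(sprintf("<ecm_solution> total cost q = %.6g (%s)\n", x$q_opt,
              if (x$diagnostics$converged) "converged" else "NOT converged"))
  cat("  enzyme levels (mM):\n")
  print(round(x$E_opt, 6))
  cat("  metabolite levels (mM):\n")
  print(round(x$c_opt, 6))
  invisible(x)
}

#' Tolerance ranges of nearly optimal solutions
#'
#' Relaxes the optimality assumption: with a tolerable cost
#' `q_tol = (1 + alpha) * q_opt`, the nearly optimal set
#' `{x in P : q(x) <= q_tol}` is convex, and each metabolite's tolerance
#' range is the exact min/max of its coordinate over that set (computed by
#' root-finding on the coordinate with convex inner minimizations). Enzyme
#' lower ranges are exact minima of the convex demand over the same set;
#' enzyme upper ranges are a heuristic (maximum over the metabolite-range
#' endpoint solutions, refined by a penalized local ascent) and are tagged
#' as such.
#'
#' @param sol An [ecm_solve()] result.
#' @param model The same model (it is re-oriented internally).
#' @param spec The cost specification used for `sol`.
#' @param alpha Allowed relative cost increase (default 0.01, i.e. one
#'   percent above the optimum).
#' @return An object of class `tolerance_ranges` with data frames
#'   `metabolites` (log and mM bounds) and `enzymes` (mM bounds plus a
#'   `method` tag per upper bound).
#' @export
tolerance_ranges <- function(sol, model, spec = "EMC4CM", alpha = 0.01) {
  if (alpha < 0) {
    stopf("alpha must be nonnegative", class = "ecm_domain_error")
  }
  if (!inherits(spec, "cost_function_spec")) spec <- cost_function_spec(spec)
  model <- orient_reactions(model)
  poly <- sol$polytope
  free <- poly$free_ids
  m <- length(free)
  q_opt <- sol$q_opt
  q_tol <- (1 + alpha) * q_opt
  x_opt_free <- sol$x_opt[free]

  met <- data.frame(
    metabolite = free,
    x_lo = x_opt_free, x_hi = x_opt_free,
    stringsAsFactors = FALSE
  )
  endpoint_solutions <- list()

  if (alpha > 0 && m > 0L) {
    for (j in seq_len(m)) {
      for (side in c("lo", "hi")) {
        r <- coordinate_range_endpoint(j, side, poly, model, spec,
                                       q_tol, x_opt_free)
        met[j, paste0("x_", side)] <- r$a
        endpoint_solutions[[length(endpoint_solutions) + 1L]] <- r$x
      }
    }
  }
  met$c_lo <- exp(met$x_lo)
  met$c_hi <- exp(met$x_hi)

  active <- model$network$reaction_ids[model$flux$active_mask]
  E_opt <- sol$E_opt[active]
  enz <- data.frame(
    reaction = active,
    E_lo = unname(E_opt), E_hi = unname(E_opt),
    method = rep("exact", length(active)),
    stringsAsFactors = FALSE
  )
  if (alpha > 0 && m > 0L) {
    cand <- c(endpoint_solutions, list(x_opt_free))
    for (k in seq_along(active)) {
      l <- active[k]
      demand_l <- function(xf) {
        names(xf) <- free
        b <- enzyme_cost(xf, model, spec)$breakdown
        b$E_l[b$reaction == l]
      }
      enz$E_lo[k] <- penalized_extremum(demand_l, poly, model, spec, q_tol,
                                        start = x_opt_free,
                                        maximize = FALSE)$value
      best <- max(vapply(cand, demand_l, numeric(1L)))
      asc <- penalized_extremum(demand_l, poly, model, spec, q_tol,
                                start = cand[[which.max(
                                  vapply(cand, demand_l, numeric(1L)))]],
                                maximize = TRUE)
      enz$E_hi[k] <- max(best, asc$value)
      enz$method[k] <- "heuristic"
      # lower bound is an exact convex minimum; only the upper is heuristic
    }
  }
  structure(
    list(alpha = alpha, q_opt = q_opt, q_tol = q_tol,
         metabolites = met, enzymes = enz),
    class = "tolerance_ranges"
  )
}

# Exact endpoint of one metabolite's tolerance range: the outermost value a
# of coordinate j such that min{ q(x) : x in P, x_j = a } <= q_tol.
# m(a) is convex in a and minimal at the optimum, so the endpoint is the
# root of m(a) - q_tol on [x_opt_j, box edge].
coordinate_range_endpoint <- function(j, side, poly, model, spec, q_tol,
                                      x_opt_free) {
  free <- poly$free_ids
  edge_lp <- solve_lp(
    obj = replace(numeric(length(free)), j, 1),
    A = if (length(poly$active_ids)) poly$G else NULL,
    b = poly$theta0 - poly$eps,
    lb = poly$x_min, ub = poly$x_max,
    maximize = side == "hi"
  )
  edge <- edge_lp$x[j]
  last_x <- x_opt_free
  m_of <- function(a) {
    r <- constrained_cost_min(j, a, poly, model, spec, start = last_x)
    last_x <<- r$x
    r$q
  }
  if (abs(edge - x_opt_free[j]) < 1e-10) {
    return(list(a = edge, x = edge_lp$x))
  }
  q_edge <- m_of(edge)
  if (q_edge <= q_tol) {
    return(list(a = edge, x = last_x))
  }
  f <- function(a) m_of(a) - q_tol
  root <- stats::uniroot(f, lower = min(edge, x_opt_free[j]),
                         upper = max(edge, x_opt_free[j]),
                         tol = 1e-10)
  # ensure returned point reflects the root
  m_of(root$root)
  list(a = root$root, x = last_x)
}

# min q(x) over the polytope slice {x_j = a}; the coordinate is eliminated.
constrained_cost_min <- function(j, a, poly, model, spec, start) {
  free <- poly$free_ids
  m <- length(free)
  rest <- setdiff(seq_len(m), j)
  make_full <- function(xr) {
    xf <- numeric(m)
    xf[j] <- a
    xf[rest] <- xr
    names(xf) <- free
    xf
  }
  if (length(rest) == 0L) {
    xf <- make_full(numeric(0))
    q <- tryCatch(enzyme_cost(xf, model, spec)$q, error = function(e) Inf)
    return(list(q = q, x = xf))
  }
  G <- if (length(poly$active_ids)) poly$G else matrix(0, 0, m)
  b <- poly$theta0 - poly$eps - (if (nrow(G)) G[, j] * a else numeric(0))
  Gr <- G[, rest, drop = FALSE]
  ui <- rbind(diag(length(rest)), -diag(length(rest)),
              if (nrow(Gr)) -Gr)
  ci <- c(poly$x_min[rest], -poly$x_max[rest],
          if (nrow(Gr)) -b)
  # interior start: pull the warm start toward the slice's analytic center
  x0 <- start[rest]
  x0 <- find_interior(x0, ui, ci, fallback = slice_center(j, a, poly, rest))
  if (is.null(x0)) {
    return(list(q = Inf, x = make_full(start[rest])))
  }
  f <- function(xr) {
    xf <- make_full(xr)
    if (!polytope_contains(poly, xf, tol = 1e-12)) return(Inf)
    tryCatch(enzyme_cost(xf, model, spec)$q, error = function(e) Inf)
  }
  g <- function(xr) {
    xf <- make_full(xr)
    enzyme_cost(xf, model, spec)$gradient[free][rest]
  }
  fit <- try(stats::constrOptim(
    theta = x0, f = f, grad = g, ui = ui, ci = ci, mu = 1e-8,
    method = "BFGS", outer.iterations = 50L, outer.eps = 1e-10,
    control = list(maxit = 500L, reltol = 1e-13)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(q = f(x0), x = make_full(x0)))
  }
  list(q = fit$value, x = make_full(fit$par))
}

# maximin-slack point of the slice {x_j = a} (LP), used as interior start.
slice_center <- function(j, a, poly, rest) {
  m <- length(poly$free_ids)
  G <- if (length(poly$active_ids)) poly$G else matrix(0, 0, m)
  rhs <- poly$theta0 - poly$eps - (if (nrow(G)) G[, j] * a else numeric(0))
  Gr <- G[, rest, drop = FALSE]
  k <- length(rest)
  A <- rbind(cbind(Gr, 1))
  span <- max(poly$x_max[rest] - poly$x_min[rest], 1)
  res <- solve_lp(
    obj = c(numeric(k), 1),
    A = if (nrow(Gr)) A else NULL,
    b = if (nrow(Gr)) rhs else numeric(0),
    lb = c(poly$x_min[rest], -1e3 * span),
    ub = c(poly$x_max[rest], 1e3 * span),
    maximize = TRUE
  )
  if (res$status != "optimal" || res$x[k + 1L] <= 0) return(NULL)
  res$x[seq_len(k)]
}

find_interior <- function(x0, ui, ci, fallback) {
  ok <- function(x) all(ui %*% x - ci > 0)
  if (ok(x0)) return(x0)
  if (is.null(fallback)) return(NULL)
  if (!ok(fallback)) return(NULL)
  for (w in c(0.5, 0.8, 0.95, 1)) {
    x <- (1 - w) * x0 + w * fallback
    if (ok(x)) return(x)
  }
  fallback
}

# Extremize a convex (or -concave) scalar function of x over
# {x in P : q(x) <= q_tol} by an increasing-penalty method inside P.
penalized_extremum <- function(fn, poly, model, spec, q_tol, start,
                               maximize = FALSE) {
  free <- poly$free_ids
  m <- length(free)
  sgn <- if (maximize) -1 else 1
  ui <- rbind(diag(m), -diag(m),
              if (length(poly$active_ids)) -poly$G)
  ci <- c(poly$x_min, -poly$x_max,
          if (length(poly$active_ids)) poly$eps - poly$theta0)
  x <- find_interior(start, ui, ci, fallback = poly$witness[free])
  if (is.null(x)) x <- poly$witness[free]
  best <- NULL
  for (mu in 10^seq(2, 8, by = 2)) {
    obj <- function(xf) {
      names(xf) <- free
      q <- tryCatch(enzyme_cost(xf, model, spec)$q, error = function(e) Inf)
      if (!is.finite(q)) return(Inf)
      sgn * fn(xf) + mu * max(0, q - q_tol)^2 / max(q_tol, 1)^2 * max(q_tol, 1)
    }
    fit <- try(stats::constrOptim(
      theta = x, f = obj, grad = NULL, ui = ui, ci = ci, mu = 1e-8,
      outer.iterations = 30L, outer.eps = 1e-9,
      control = list(maxit = 400L, reltol = 1e-12)
    ), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      x <- fit$par
      best <- fit
    }
  }
  if (is.null(best)) {
    return(list(value = fn(start), x = start))
  }
  xf <- stats::setNames(best$par, free)
  # report the raw extremum value at a point satisfying the cost budget
  q_here <- enzyme_cost(xf, model, spec)$q
  if (q_here > q_tol * (1 + 1e-6)) {
    # walk back toward the optimum until the budget holds
    for (w in seq(0.95, 0, by = -0.05)) {
      xt <- w * xf + (1 - w) * start
      names(xt) <- free
      if (enzyme_cost(xt, model, spec)$q <= q_tol) {
        xf <- xt
        break
      }
    }
  }
  list(value = fn(xf), x = xf)
}
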