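# Internal helpers shared across modules.

# Gas constant times temperature at 25 degrees C, in kJ/mol. Used to convert
# reaction Gibbs energies given in kJ/mol to unitless dG0/RT.
RT_KJ_PER_MOL <- 2.4790

# Standard concentration: all log-concentrations are ln(c / 1 mM).
STANDARD_CONC_MM <- 1

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = character()) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "ecm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

# Condition subclasses:
#   ecm_reference_error  dangling identifier in an input table
#   ecm_conflict_error   duplicate parameter definition
#   ecm_parameter_error  required kinetic parameter absent
#   ecm_infeasible_error thermodynamically empty metabolite polytope
#   ecm_domain_error     argument outside its mathematical domain

assert_positive <- function(x, what) {
  if (any(!is.finite(x) | x <= 0)) {
    stopf("%s must be finite and positive", what, class = "ecm_domain_error")
  }
  invisible(x)
}

# Named numeric vector aligned to `ids`, NA-filled where absent.
align_named <- function(x, ids, default = NA_real_) {
  out <- rep(default, length(ids))
  names(out) <- ids
  if (!is.null(x)) {
    known <- intersect(names(x), ids)
    out[known] <- x[known]
  }
  out
}
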