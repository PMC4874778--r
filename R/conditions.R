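# Structured error conditions.  All package errors carry class
# "fgnupfield_error"; more specific classes distinguish invalid inputs
# (domain), physically infeasible states (a layer too thin to hold its
# monomers), missing coexistence, and solver breakdown.

fg_stop <- function(msg, class, data = list()) {
  cond <- structure(
    class = c(class, "fgnupfield_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), data)
  )
  stop(cond)
}

fg_domain_error <- function(msg, data = list()) {
  fg_stop(msg, "fgnupfield_domain_error", data)
}

fg_infeasible_error <- function(msg, data = list()) {
  fg_stop(msg, "fgnupfield_infeasible_error", data)
}

fg_no_coexistence_error <- function(msg, data = list()) {
  fg_stop(msg, "fgnupfield_no_coexistence_error", data)
}

fg_solver_error <- function(msg, data = list()) {
  fg_stop(msg, "fgnupfield_solver_error", data)
}
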