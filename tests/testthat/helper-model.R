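# Shared fixtures, built in code.

baseline_matrix <- function() {
  build_transition_matrix(default_parameters(), "no_promotion")
}

# a tiny hand-made valid parameter table for error-path tests
minimal_param_table <- function() {
  default_parameters()$table
}

# distributional rows of the shipped parameter set
distributional_params <- function() {
  ps <- default_parameters()
  ps$params[vapply(ps$params, function(p) p$family != "fixed", logical(1))]
}
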