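# shared fixtures: small schedules and parameter sets built in code

p_dna <- simulation_params()

# single-segment schedule at stage-2 resolution
seg2 <- function(n, params = p_dna) {
  data.frame(n_links = n, link_length = params$l2, delta_i = 1L)
}

# canonical two-stage schedule (bp-resolution first segment)
two_stage <- function(N1, N2, params = p_dna) {
  data.frame(n_links = c(N1, N2),
             link_length = c(params$l1, params$l2),
             delta_i = c(params$delta_i_stage1, 1L))
}

# random unit vector
runit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}
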