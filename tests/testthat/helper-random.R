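# shared generators for property-style tests

random_prob_vector <- function(d) {
  g <- rgamma(d, 1)
  g / sum(g)
}

random_stochastic_matrix <- function(nrow, ncol = nrow) {
  M <- matrix(rgamma(nrow * ncol, 1), nrow, ncol)
  sweep(M, 2, colSums(M), "/")
}

# a random contiguous scale on [0, Inf) with d options
random_contiguous_scale <- function(d, max_cut = 10) {
  cuts <- sort(runif(d - 1, 0.2, max_cut))
  interval_scale(c(0, cuts), c(cuts, Inf), version_id = "rand")
}

q97 <- ltpa_scale_1997()
q98 <- ltpa_scale_1998()
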