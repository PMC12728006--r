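# Shared small fixtures built in code.

toy_chain <- function() {
  # A -> B -> C with unit weights
  net <- interaction_network(data.frame(source = c("A", "B"),
                                        target = c("B", "C")))
  list(network = net, solution = model_solution(net, c(1, 1)))
}

toy_two_node <- function(w = 1) {
  net <- interaction_network(data.frame(source = "A", target = "B"))
  list(network = net, solution = model_solution(net, w))
}

# characterization with a handful of effectors over two motives
toy_chars <- function() {
  disease_characterization(data.frame(
    protein = c("E1", "E2", "E3", "E2"),
    motive = c(1L, 1L, 2L, 2L),
    disease_sign = c(1L, -1L, 1L, 1L)))
}

# deterministic activity profile over given proteins
profile_of <- function(...) {
  v <- c(...)
  activity_profile(v)
}
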