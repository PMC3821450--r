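# Independent oracles and random-case generators shared across tests.
# Oracles are deliberately naive (enumeration, choose()-arithmetic) and
# never call the implementation they check.

# Binomial upper/lower tail by direct choose() summation.
oracle_binom_tail <- function(k, n, p0, side) {
  j <- if (side == "greater") k:n else 0:k
  sum(choose(n, j) * p0^j * (1 - p0)^(n - j))
}

# Random binary mark matrix for agreement-index checks.
random_marks <- function(J, B) {
  matrix(sample(0:1, J * B, replace = TRUE), nrow = J, ncol = B)
}

# Random coded stream over the four lanes, with random causal links.
random_stream <- function(S, seed) {
  set.seed(seed)
  scheme <- scheme_lanes4()
  entries <- lapply(seq_len(S), function(i) {
    k <- sample(1:2, 1)
    cats <- sample(scheme$codes, k)
    list(index = i,
         contents = data.frame(label = paste0("c", i, "_", seq_len(k)),
                               category = cats, stringsAsFactors = FALSE),
         causes_next = if (i < S) sample(c(TRUE, FALSE), 1) else NA)
  })
  coded_stream(entries, scheme, text_id = paste0("rand", seed))
}

# Episode partition via connected components of the chain graph (igraph).
oracle_episodes_igraph <- function(S, arcs) {
  g <- igraph::make_empty_graph(n = S, directed = FALSE)
  if (length(arcs)) {
    g <- igraph::add_edges(g, rbind(arcs, arcs + 1L))
  }
  comp <- igraph::components(g)$membership
  split(seq_len(S), comp)
}
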