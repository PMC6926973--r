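# Shared fixtures and small constructors used across the suite.

# single binary node with an arbitrary prior
single_node_net <- function(p = c(no = 0.7, yes = 0.3)) {
  dbn(list(X = names(p)),
      NULL,
      list(cpt("X", character(0), array(unname(p), 2, dimnames = list(names(p))))))
}

# A -> B -> C chain over binary states, hand-set CPTs
chain3_net <- function() {
  v <- list(A = c("f", "t"), B = c("f", "t"), C = c("f", "t"))
  dbn(v, list(c("A", "B"), c("B", "C")), list(
    cpt("A", character(0), array(c(0.6, 0.4), 2, dimnames = list(v$A))),
    cpt("B", "A", array(c(0.8, 0.2, 0.3, 0.7), c(2, 2),
                        dimnames = list(v$B, v$A))),
    cpt("C", "B", array(c(0.9, 0.1, 0.25, 0.75), c(2, 2),
                        dimnames = list(v$C, v$B)))
  ))
}

# network whose CPTs are all 0/1: every sample is the same forced assignment
deterministic_net <- function() {
  v <- list(A = c("a1", "a2"), B = c("b1", "b2"))
  dbn(v, list(c("A", "B")), list(
    cpt("A", character(0), array(c(1, 0), 2, dimnames = list(v$A))),
    cpt("B", "A", array(c(0, 1, 1, 0), c(2, 2), dimnames = list(v$B, v$A)))
  ))
}

# two disconnected binary nodes (independence fixture)
disconnected_net <- function() {
  v <- list(X = c("x1", "x2"), Y = c("y1", "y2"))
  dbn(v, NULL, list(
    cpt("X", character(0), array(c(0.3, 0.7), 2, dimnames = list(v$X))),
    cpt("Y", character(0), array(c(0.55, 0.45), 2, dimnames = list(v$Y)))
  ))
}

expect_prob_vector <- function(p, tol = 1e-9) {
  expect_true(all(p >= -tol))
  expect_equal(sum(p), 1, tolerance = tol)
}
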