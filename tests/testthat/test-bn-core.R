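test_that("joint probability is the chain-rule product of CPT entries", {
  net <- toy3_network()
  expect_equal(
    joint_probability(net, c(Wealth = "Low", Pocket_Money = "Med",
                             Obesity = "Obese")),
    0.4 * 0.4 * 0.4)
  # degenerate single-node case
  expect_equal(joint_probability(single_node_net(c(no = 0, yes = 1)),
                                 c(X = "yes")), 1.0)
  # a zero CPT entry annihilates the product
  expect_equal(joint_probability(deterministic_net(), c(A = "a1", B = "b1")), 0)
})

test_that("joint probability rejects incomplete or illegal assignments", {
  net <- toy3_network()
  expect_error(joint_probability(net, c(Wealth = "Low")),
               class = "gbn_incomplete_assignment")
  expect_error(joint_probability(net, c(Wealth = "Low", Pocket_Money = "Med",
                                        Obesity = "Chubby")),
               class = "gbn_unknown_state")
})

test_that("posterior inference reproduces the hand-enumerated toy values", {
  net <- toy3_network()
  # P(PM) = (0.32, 0.40, 0.28); P(Obese) = .32*.1 + .40*.4 + .28*.15 = 0.234
  expect_equal(unname(infer_posterior(net, "Pocket_Money")),
               c(0.32, 0.40, 0.28))
  expect_equal(infer_posterior(net, "Obesity")[["Obese"]], 0.234)
  # Obesity depends only on Pocket_Money: posterior reads off the CPT
  expect_equal(infer_posterior(net, "Obesity",
                               c(Pocket_Money = "Med"))[["Obese"]], 0.4)
  expect_prob_vector(infer_posterior(net, "Wealth", c(Obesity = "Obese")))
})

test_that("inference errors are typed", {
  net <- toy3_network()
  expect_error(infer_posterior(net, "Obesity", c(Obesity = "Obese")),
               class = "gbn_invalid_query")
  expect_error(infer_posterior(net, "Nope"), class = "gbn_unknown_node")
  expect_error(infer_posterior(deterministic_net(), "B", c(A = "a2")),
               class = "gbn_inconsistent_evidence")
  expect_error(brute_force_posterior(deterministic_net(), "B", c(A = "a2")),
               class = "gbn_inconsistent_evidence")
})

test_that("brute-force enumeration agrees with itself and guards size", {
  net <- toy3_network()
  expect_equal(brute_force_posterior(net, "Obesity")[["Obese"]], 0.234)
  expect_equal(unname(brute_force_posterior(single_node_net(), "X")),
               c(0.7, 0.3))
  big <- random_network(30, max_states = 3, edge_prob = 0.1, seed = 1)
  expect_error(brute_force_posterior(big, "V1"), class = "gbn_too_large")
})

test_that("variable elimination matches enumeration on random networks", {
  for (i in 1:40) {
    net <- random_network(sample(2:8, 1), max_states = 3,
                          edge_prob = 0.4, seed = 1000 + i)
    nodes <- names(net$variables)
    q <- sample(nodes, 1)
    # random evidence on a random subset (possibly empty)
    rest <- setdiff(nodes, q)
    k <- sample(0:min(2, length(rest)), 1)
    ev <- NULL
    if (k > 0) {
      evn <- sample(rest, k)
      ev <- vapply(evn, function(v) sample(net$variables[[v]], 1), "")
    }
    ve <- try(infer_posterior(net, q, ev), silent = TRUE)
    bf <- try(brute_force_posterior(net, q, ev), silent = TRUE)
    if (inherits(ve, "try-error") || inherits(bf, "try-error")) {
      # both routes must agree the evidence is inconsistent
      expect_true(inherits(ve, "try-error") && inherits(bf, "try-error"))
    } else {
      expect_equal(ve, bf, tolerance = 1e-10)
    }
  }
})

test_that("the Bayes identity holds when assembled from separate calls", {
  net <- chain3_net()
  pa <- infer_posterior(net, "A")
  pc <- infer_posterior(net, "C")
  for (b in c("f", "t")) {
    lhs <- infer_posterior(net, "A", c(C = b))
    # P(A | C=b) = P(C=b | A) P(A) / P(C=b)
    rhs <- vapply(c("f", "t"), function(a) {
      infer_posterior(net, "C", c(A = a))[[b]] * pa[[a]] / pc[[b]]
    }, 1.0)
    expect_equal(unname(lhs), unname(rhs), tolerance = 1e-12)
  }
})

test_that("states with prior zero keep posterior zero under evidence", {
  net <- deterministic_net()
  post <- infer_posterior(net, "A", c(B = "b2"))
  expect_equal(post[["a2"]], 0)
})

test_that("evidence-free posterior equals the joint-probability marginal", {
  net <- chain3_net()
  states <- expand.grid(A = c("f", "t"), B = c("f", "t"), C = c("f", "t"),
                        stringsAsFactors = FALSE)
  for (b in c("f", "t")) {
    rows <- states[states$B == b, ]
    m <- sum(vapply(seq_len(nrow(rows)), function(i)
      joint_probability(net, unlist(rows[i, ])), 1.0))
    expect_equal(infer_posterior(net, "B")[[b]], m, tolerance = 1e-12)
  }
})

test_that("ancestral sampling is deterministic and converges", {
  net <- toy3_network()
  a <- ancestral_sample(net, 500, seed = 31)
  b <- ancestral_sample(net, 500, seed = 31)
  expect_identical(a, b)
  expect_false(identical(a, ancestral_sample(net, 500, seed = 32)))

  big <- ancestral_sample(net, 100000, seed = 8)
  se <- sqrt(0.234 * 0.766 / 100000)
  expect_lt(abs(mean(big$Obesity == "Obese") - 0.234), 3 * se)

  det <- ancestral_sample(deterministic_net(), 50, seed = 1)
  expect_true(all(det$A == "a1") && all(det$B == "b2"))
  expect_error(ancestral_sample(net, 0, seed = 1), class = "gbn_invalid_size")
})

test_that("network invariants are enforced at construction", {
  v <- list(A = c("f", "t"), B = c("f", "t"))
  ok_a <- cpt("A", character(0), array(c(0.5, 0.5), 2, dimnames = list(v$A)))
  # cycle
  expect_error(dag(c("A", "B"), list(c("A", "B"), c("B", "A"))),
               class = "gbn_invalid_network")
  # CPT rows must sum to one
  expect_error(cpt("B", "A", array(c(0.5, 0.4, 0.2, 0.8), c(2, 2),
                                   dimnames = list(v$B, v$A))),
               class = "gbn_invalid_network")
  # CPT parents must match the structure
  ok_b_noparent <- cpt("B", character(0),
                       array(c(0.5, 0.5), 2, dimnames = list(v$B)))
  expect_error(dbn(v, list(c("A", "B")), list(ok_a, ok_b_noparent)),
               class = "gbn_invalid_network")
  # fewer than two states
  expect_error(dbn(list(A = "only"), NULL, list(ok_a)),
               class = "gbn_invalid_network")
})

test_that("JSON round-trip preserves the network exactly", {
  for (net in list(toy3_network(),
                   random_network(6, max_states = 3, edge_prob = 0.5, seed = 4))) {
    path <- withr::local_tempfile(fileext = ".json")
    write_dbn_json(net, path)
    back <- read_dbn_json(path)
    expect_identical(names(back$variables), names(net$variables))
    expect_equal(back$structure$edges, net$structure$edges)
    for (v in names(net$variables)) {
      expect_equal(back$cpts[[v]]$prob, net$cpts[[v]]$prob, tolerance = 1e-12)
    }
    # determinism contract: identical write twice
    path2 <- withr::local_tempfile(fileext = ".json")
    write_dbn_json(net, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("XMLBIF export writes one definition per node", {
  skip_if_not_installed("xml2")
  net <- toy3_network()
  path <- withr::local_tempfile(fileext = ".xml")
  write_dbn_xmlbif(net, path)
  doc <- xml2::read_xml(path)
  expect_length(xml2::xml_find_all(doc, "//VARIABLE"), 3)
  expect_length(xml2::xml_find_all(doc, "//DEFINITION"), 3)
})
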