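test_that("CPT estimation applies Laplace smoothing as stated", {
  d <- data.frame(A = c("p", "p", "p", "p"),
                  B = c("u", "u", "u", "v"),
                  stringsAsFactors = FALSE)
  d$A <- factor(d$A, levels = c("p", "q"))
  g <- dag(c("A", "B"), list(c("A", "B")))
  net <- estimate_cpts(g, d, smoothing_alpha = 1)
  # counts (3, 1) with alpha = 1 -> (4/6, 2/6)
  expect_equal(unname(net$cpts$B$prob[, "p"]), c(4 / 6, 2 / 6))
  # unseen parent state q: uniform under alpha = 1 too (0+1)/(0+2)
  expect_equal(unname(net$cpts$B$prob[, "q"]), c(0.5, 0.5))
  # alpha = 0: ML for seen rows, uniform fallback for the empty row
  ml <- estimate_cpts(g, d, smoothing_alpha = 0)
  expect_equal(unname(ml$cpts$B$prob[, "p"]), c(0.75, 0.25))
  expect_equal(unname(ml$cpts$B$prob[, "q"]), c(0.5, 0.5))
})

test_that("estimated CPTs converge to the truth in total variation", {
  net <- toy3_network()
  d <- ancestral_sample(net, 100000, seed = 77)
  fit <- estimate_cpts(net$structure, d, smoothing_alpha = 0,
                       variables = net$variables)
  for (v in names(net$variables)) {
    rt <- matrix(net$cpts[[v]]$prob, nrow = length(net$variables[[v]]))
    rf <- matrix(fit$cpts[[v]]$prob, nrow = length(net$variables[[v]]))
    tv <- apply(abs(rt - rf), 2, sum) / 2
    expect_lt(max(tv), 0.01)
  }
})

test_that("CPT recovery error shrinks as the sample grows", {
  net <- toy3_network()
  tv_at <- vapply(c(500, 5000, 50000), function(n) {
    d <- ancestral_sample(net, n, seed = 123)
    fit <- estimate_cpts(net$structure, d, smoothing_alpha = 0,
                         variables = net$variables)
    max(vapply(names(net$variables), function(v) {
      rt <- matrix(net$cpts[[v]]$prob, nrow = length(net$variables[[v]]))
      rf <- matrix(fit$cpts[[v]]$prob, nrow = length(net$variables[[v]]))
      max(apply(abs(rt - rf), 2, sum) / 2)
    }, 1.0))
  }, 1.0)
  # monotone within simulation error: allow tiny slack between stages
  expect_lt(tv_at[2], tv_at[1] + 0.01)
  expect_lt(tv_at[3], tv_at[2] + 0.01)
})

test_that("learners refuse unclean data", {
  d <- data.frame(A = c("p", NA), B = c("u", "v"), stringsAsFactors = FALSE)
  expect_error(estimate_cpts(dag(c("A", "B")), d),
               class = "gbn_unclean_data")
  expect_error(learn_structure(d), class = "gbn_unclean_data")
  expect_error(learn_structure(data.frame(A = c("p", "q"))),
               class = "gbn_degenerate_input")
})

test_that("network scores decompose over families and ignore row order", {
  net <- build_fixture("survey11", seed = 2)
  d <- ancestral_sample(net, 2000, seed = 5)
  g <- net$structure
  cfg <- learner_config(score = "bic")
  total <- network_score(g, d, cfg)
  # family term for v recovered independently as score(v + parents, edges
  # into v) minus the parents' own root-family terms
  fams <- vapply(g$nodes, function(v) {
    pa <- g$edges$parent[g$edges$child == v]
    sub <- dag(c(v, pa), if (length(pa))
      data.frame(parent = pa, child = v) else NULL)
    s <- network_score(sub, d[, c(v, pa), drop = FALSE], cfg)
    if (length(pa) > 0) {
      s <- s - network_score(dag(pa), d[, pa, drop = FALSE], cfg)
    }
    s
  }, 1.0)
  expect_equal(total, sum(fams), tolerance = 1e-8)
  shuffled <- d[rev(seq_len(nrow(d))), , drop = FALSE]
  expect_equal(network_score(g, shuffled, cfg), total, tolerance = 1e-9)
  expect_equal(network_score(g, shuffled, learner_config(score = "bdeu")),
               network_score(g, d, learner_config(score = "bdeu")),
               tolerance = 1e-9)
})

test_that("BIC penalises edges from independent noise at large n", {
  base <- disconnected_net()
  d <- ancestral_sample(base, 5000, seed = 9)
  empty <- dag(c("X", "Y"))
  with_edge <- dag(c("X", "Y"), list(c("X", "Y")))
  cfg <- learner_config(score = "bic")
  expect_gt(network_score(empty, d, cfg), network_score(with_edge, d, cfg))
  # and hill climbing on independent columns returns the empty graph
  fit <- learn_structure(d, learner_config(score = "bic"))
  expect_equal(nrow(fit$structure$edges), 0)
})

test_that("hill climbing recovers a known chain and is seed-deterministic", {
  net <- chain3_net()
  d <- ancestral_sample(net, 20000, seed = 21)
  fit1 <- learn_structure(d, learner_config(seed = 3, restarts = 2))
  fit2 <- learn_structure(d, learner_config(seed = 3, restarts = 2))
  expect_identical(fit1$structure$edges, fit2$structure$edges)
  r <- recovery_report(net, fit1)
  expect_gte(r$skeleton_f1, 0.8)
})

test_that("accepted hill-climbing moves never lower the score", {
  # final structure must score at least as high as the empty start
  net <- build_fixture("survey11", seed = 3)
  d <- ancestral_sample(net, 3000, seed = 13)
  cfg <- learner_config()
  fit <- learn_structure(d, cfg)
  empty_score <- network_score(dag(names(d)), d, cfg)
  expect_gte(network_score(fit$structure, d, cfg), empty_score)
})

test_that("markov blanket follows the parents/children/co-parents rule", {
  chain <- dag(c("A", "B", "C"), list(c("A", "B"), c("B", "C")))
  expect_identical(markov_blanket(chain, "B")$blanket, c("A", "C"))
  collider <- dag(c("A", "B", "C"), list(c("A", "C"), c("B", "C")))
  expect_identical(markov_blanket(collider, "A")$blanket, c("B", "C"))
  star <- dag(c("K", "F1", "F2", "F3"),
              list(c("K", "F1"), c("K", "F2"), c("K", "F3")))
  expect_identical(markov_blanket(star, "K")$blanket, c("F1", "F2", "F3"))
  expect_error(markov_blanket(star, "nope"), class = "gbn_unknown_node")
  sel <- markov_blanket(collider, "A")
  expect_identical(sort(c(sel$target, sel$blanket, sel$discarded)),
                   sort(collider$nodes))
})

test_that("blanket evidence screens off everything else", {
  # with the ground-truth network, adding non-blanket evidence on top of
  # full-blanket evidence leaves the class posterior unchanged
  for (i in 1:20) {
    net <- random_network(sample(4:8, 1), max_states = 3, edge_prob = 0.35,
                          seed = 400 + i)
    nodes <- names(net$variables)
    target <- sample(nodes, 1)
    sel <- markov_blanket(net, target)
    if (length(sel$blanket) == 0 || length(sel$discarded) == 0) next
    smp <- ancestral_sample(net, 1, seed = 500 + i)
    ev_mb <- unlist(smp[1, sel$blanket, drop = FALSE])
    extra <- sample(sel$discarded, 1)
    ev_plus <- c(ev_mb, unlist(smp[1, extra, drop = FALSE]))
    p1 <- infer_posterior(net, target, ev_mb)
    p2 <- infer_posterior(net, target, ev_plus)
    expect_equal(p1, p2, tolerance = 1e-10)
  }
})

test_that("the blanket-restricted classifier discards noise columns", {
  net <- build_fixture("naive4", seed = 6)
  d <- ancestral_sample(net, 10000, seed = 61)
  d$Noise1 <- withr::with_seed(62, sample(c("a", "b", "c"), 10000, TRUE))
  d$Noise2 <- withr::with_seed(63, sample(c("u", "v"), 10000, TRUE))
  fit <- gbn_mb_classifier(d, "Class", learner_config(seed = 2))
  expect_true(all(c("Noise1", "Noise2") %in% fit$selection$discarded))
  expect_true(all(fit$selection$blanket %in% paste0("F", 1:4)))
  # blanket of the class inside the restricted net stays within the original
  inner <- markov_blanket(fit$net, "Class")
  expect_true(all(inner$blanket %in% fit$selection$blanket))
})

test_that("restricted and full models agree given full-blanket evidence", {
  net <- build_fixture("naive4", seed = 8)
  d <- ancestral_sample(net, 8000, seed = 81)
  fit <- gbn_mb_classifier(d, "Class", learner_config(seed = 4))
  skip_if(length(fit$selection$blanket) == 0)
  row <- ancestral_sample(net, 1, seed = 82)
  ev <- unlist(row[1, fit$selection$blanket, drop = FALSE])
  restricted <- classify_instance(fit$net, "Class", ev)
  full <- classify_instance(fit$full_net, "Class",
                            unlist(row[1, setdiff(names(d), "Class"),
                                       drop = FALSE]))
  # same evidence information: the two posteriors agree up to estimation
  # noise in families outside the blanket
  expect_equal(unname(restricted), unname(full[names(restricted)]),
               tolerance = 0.05)
  # and exactly against the oracle on the restricted model itself
  expect_equal(restricted, brute_force_posterior(fit$net, "Class", ev),
               tolerance = 1e-10)
})
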