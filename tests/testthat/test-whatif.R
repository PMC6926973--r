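test_that("expected target probabilities come from exact inference", {
  net <- toy3_network()
  expect_equal(expected_target(net, c("Obesity", "Obese")), 0.234)
  expect_equal(expected_target(net, c("Obesity", "Obese"),
                               c(Pocket_Money = "Med")), 0.4)
  expect_error(expected_target(net, c("Obesity", "Obese"),
                               c(Obesity = "Obese")),
               class = "gbn_invalid_query")
  # multi-state scores: expectation of an ordinal encoding
  sc <- c(Obese = 1, Not_Obese = 0)
  expect_equal(expected_target(net, "Obesity", scores = sc), 0.234)
})

test_that("scenario application reports the arrow quantities", {
  net <- toy3_network()
  scn <- scenario("medium pocket money", c(Pocket_Money = "Med"),
                  c("Obesity", "Obese"))
  rep_ <- apply_scenario(net, scn)
  expect_equal(unname(rep_$headline), c(0.234, 0.400))
  # evidence node's posterior is the indicator
  expect_equal(unname(rep_$posterior$Pocket_Money), c(0, 1, 0))
  # headline delta equals the expected-target difference exactly
  expect_equal(rep_$headline[["posterior"]] - rep_$headline[["baseline"]],
               expected_target(net, c("Obesity", "Obese"),
                               c(Pocket_Money = "Med")) -
                 expected_target(net, c("Obesity", "Obese")))
  out <- capture.output(print(rep_))
  expect_true(any(grepl("23.4% -> 40.0%", out, fixed = TRUE)))
})

test_that("empty-ish scenarios and directives behave", {
  net <- toy3_network()
  # max/min directives resolve against the state order
  scn <- scenario("extremes", c(Pocket_Money = "max"), c("Obesity", "Obese"))
  rep_ <- apply_scenario(net, scn)
  expect_equal(rep_$evidence[["Pocket_Money"]], "High")
  expect_equal(rep_$headline[["posterior"]], 0.15)
  scn2 <- scenario("low", c(Pocket_Money = "min"), c("Obesity", "Obese"))
  expect_equal(apply_scenario(net, scn2)$headline[["posterior"]], 0.1)
  # inconsistent evidence is surfaced, not swallowed
  det <- deterministic_net()
  expect_error(
    apply_scenario(det, scenario("impossible", c(A = "a2"), c("B", "b1"))),
    class = "gbn_inconsistent_evidence")
})

test_that("single-variable decomposition telescopes", {
  net <- toy3_network()
  d <- whatif_decomposition(net, c("Obesity", "Obese"),
                            c(Pocket_Money = "Med"), max_order = 1)
  expect_equal(d$terms$z, 0.4 - 0.234)
  expect_equal(d$remainder, 0, tolerance = 1e-12)
  expect_equal(d$baseline + sum(d$terms$z) + d$remainder, d$conditional)
})

test_that("full-order decomposition reconstructs the conditional exactly", {
  net <- toy3_network()
  d <- whatif_decomposition(net, c("Obesity", "Obese"),
                            c(Wealth = "Low", Pocket_Money = "Med"),
                            max_order = 2)
  expect_equal(d$conditional, 0.4)
  expect_equal(d$remainder, 0, tolerance = 1e-12)
  z <- setNames(d$terms$z, d$terms$vars)
  expect_equal(z[["Pocket_Money"]], 0.166, tolerance = 1e-12)
  # pairwise term is what is left after both main effects
  expect_equal(z[["Pocket_Money+Wealth"]],
               0.4 - 0.234 - z[["Pocket_Money"]] - z[["Wealth"]],
               tolerance = 1e-12)

  # and on random fixtures, at every d and max_order = d
  for (i in 1:10) {
    net2 <- random_network(sample(4:7, 1), max_states = 3, edge_prob = 0.4,
                           seed = 900 + i)
    nodes <- names(net2$variables)
    target_var <- nodes[length(nodes)]
    tstate <- net2$variables[[target_var]][1]
    pool <- setdiff(nodes, target_var)
    dsize <- sample(2:min(3, length(pool)), 1)
    row <- ancestral_sample(net2, 1, seed = 950 + i)
    ev <- unlist(row[1, sample(pool, dsize), drop = FALSE])
    dec <- whatif_decomposition(net2, c(target_var, tstate), ev,
                                max_order = length(ev))
    expect_lt(abs(dec$remainder), 1e-12)
    expect_equal(dec$baseline + sum(dec$terms$z) + dec$remainder,
                 dec$conditional, tolerance = 1e-12)
  }
})

test_that("truncated decompositions fold higher structure into the remainder", {
  net <- chain3_net()
  row <- c(A = "t", B = "f")
  d1 <- whatif_decomposition(net, c("C", "t"), row, max_order = 1)
  d2 <- whatif_decomposition(net, c("C", "t"), row, max_order = 2)
  expect_equal(d1$conditional, d2$conditional)
  expect_equal(d1$baseline + sum(d1$terms$z) + d1$remainder, d1$conditional,
               tolerance = 1e-14)
  expect_equal(d2$remainder, 0, tolerance = 1e-12)
  # the order-1 remainder equals the pairwise term of the full expansion
  expect_equal(d1$remainder, d2$terms$z[d2$terms$order == 2],
               tolerance = 1e-12)
})

test_that("main effects have weighted mean zero and vanish under d-separation", {
  for (i in 1:6) {
    net <- random_network(5, max_states = 3, edge_prob = 0.4, seed = 330 + i)
    nodes <- names(net$variables)
    tv <- nodes[1]
    ts <- net$variables[[tv]][1]
    for (v in setdiff(nodes, tv)) {
      prof <- main_effect_profile(net, c(tv, ts), v)
      expect_lt(abs(sum(prof$weight * prof$z)), 1e-12)
    }
  }
  # disconnected pair: all main effects identically zero
  prof <- main_effect_profile(disconnected_net(), c("X", "x1"), "Y")
  expect_equal(prof$z, c(0, 0))
})

test_that("scenario YAML files round-trip through the engine", {
  net <- toy3_network()
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(
    "- name: medium pocket money\n  evidence:\n    Pocket_Money: Med\n  target: Obesity=Obese\n- name: rich\n  evidence:\n    Wealth: max\n  target: Obesity=Obese",
    path)
  scns <- read_scenarios(path)
  expect_length(scns, 2)
  rep_ <- apply_scenario(net, scns[[1]])
  expect_equal(rep_$headline[["posterior"]], 0.4)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_scenario_json(rep_, jpath)
  back <- jsonlite::read_json(jpath)
  expect_equal(back$headline$posterior, 0.4, tolerance = 1e-12)
  expect_error(read_scenarios("no/such/file.yaml"), class = "gbn_config")
})
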