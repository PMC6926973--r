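# Synthetic survey generator: fixture networks with known ground truth over
# the analysis variable roster (family wealth, pocket money, smartphone use,
# study time, pressure, sleep quality, parental education, academic
# performance, and a four-state obesity level), plus corruption injection so
# the preprocessing stage can be exercised round-trip.

dirichlet_row <- function(k, concentration = 1) {
  g <- stats::rgamma(k, shape = concentration)
  if (sum(g) <= 0) g <- rep(1, k)
  g / sum(g)
}

random_cpt <- function(child, parents, variables, concentration = 1) {
  r <- length(variables[[child]])
  q <- if (length(parents) == 0) 1L else
    prod(vapply(variables[parents], length, 1L))
  m <- vapply(seq_len(q), function(j) dirichlet_row(r, concentration),
              numeric(r))
  arr <- array(as.vector(m), dim = c(r, vapply(variables[parents], length, 1L)),
               dimnames = c(stats::setNames(list(variables[[child]]), child),
                            variables[parents]))
  cpt(child, parents, arr)
}

#' The three-node teaching network
#'
#' Wealth -> Pocket_Money -> Obesity with fixed, hand-written CPTs:
#' `P(Wealth = Low) = 0.4`; `P(Pocket_Money | Wealth)` equal to
#' (0.5, 0.4, 0.1) for Low wealth and (0.2, 0.4, 0.4) for High over states
#' (Low, Med, High); `P(Obesity = Obese | Pocket_Money)` equal to
#' (0.1, 0.4, 0.15). Its prior obesity probability is 0.234, a convenient
#' hand-checkable anchor used across the test suite.
#'
#' @return a [dbn()] network.
#' @export
toy3_network <- function() {
  variables <- list(
    Wealth = c("Low", "High"),
    Pocket_Money = c("Low", "Med", "High"),
    Obesity = c("Obese", "Not_Obese")
  )
  w <- cpt("Wealth", character(0),
           array(c(0.4, 0.6), 2, dimnames = list(variables$Wealth)))
  pm <- cpt("Pocket_Money", "Wealth",
            array(c(0.5, 0.4, 0.1,
                    0.2, 0.4, 0.4), dim = c(3, 2),
                  dimnames = list(variables$Pocket_Money, variables$Wealth)))
  ob <- cpt("Obesity", "Pocket_Money",
            array(c(0.1, 0.9,
                    0.4, 0.6,
                    0.15, 0.85), dim = c(2, 3),
                  dimnames = list(variables$Obesity, variables$Pocket_Money)))
  dbn(variables, list(c("Wealth", "Pocket_Money"),
                      c("Pocket_Money", "Obesity")),
      list(w, pm, ob))
}

survey11_roster <- function() {
  list(
    Education_Father = c("HighSchool", "College"),
    Education_Mother = c("HighSchool", "College"),
    Wealth = c("Low", "High"),
    Pocket_Money = c("Low", "Mid", "High"),
    Obesity_Level = c("underweight", "normal", "overweight", "obese"),
    Academic_Performance = c("Low", "High"),
    Smartphone_Service = c("Entertainment", "Study", "Social"),
    Smartphone_Time = c("Short", "Medium", "Long"),
    Sitting_Time_Study = c("Short", "Medium", "Long"),
    Pressure = c("Low", "High"),
    Sleeping_Quality = c("Good", "Average", "Poor")
  )
}

survey11_edges <- function() {
  list(
    c("Education_Father", "Wealth"),
    c("Education_Mother", "Wealth"),
    c("Wealth", "Pocket_Money"),
    c("Wealth", "Academic_Performance"),
    c("Wealth", "Smartphone_Service"),
    c("Smartphone_Service", "Smartphone_Time"),
    c("Smartphone_Time", "Sitting_Time_Study"),
    c("Sitting_Time_Study", "Pressure"),
    c("Pressure", "Sleeping_Quality"),
    c("Pocket_Money", "Obesity_Level")
  )
}

# Acceptance conditions for a survey11 CPT draw (checked exactly on the full
# joint, which has only ~31k cells):
#   * every family's parent-configuration probability is at least 0.135, so
#     each CPT row is estimable from O(10^4) survey rows;
#   * the obesity node's marginal entropy lies in [1.5, 2.0] bits, the
#     belief-geometry regime of a four-state survey outcome;
#   * pocket money has the strictly largest mutual information with the
#     obesity node among all other variables.
survey11_ok <- function(net) {
  g <- net$structure
  for (v in g$nodes) {
    pa <- dag_parents(g, v)
    if (length(pa) == 0) next
    # parent sets in this graph are either singletons or independent roots,
    # so the config probability is the product of marginals (exact here)
    probs <- Reduce(function(a, b) as.vector(outer(a, b)),
                    lapply(pa, function(p_) infer_posterior(net, p_)))
    if (min(probs) < 0.135) return(FALSE)
  }
  H <- node_entropy(net, "Obesity_Level")
  if (H < 1.5 || H > 2.0) return(FALSE)
  others <- setdiff(g$nodes, "Obesity_Level")
  mi <- vapply(others, function(v)
    mutual_information(net, "Obesity_Level", v), 1.0)
  names(mi) <- others
  top <- sort(mi, decreasing = TRUE)
  names(top)[1] == "Pocket_Money" && top[1] > top[2] + 1e-9
}

build_survey11 <- function(seed, concentration = 1, max_tries = 5000L) {
  variables <- survey11_roster()
  edges <- survey11_edges()
  g <- dag(names(variables), edges)
  for (try in seq_len(max_tries)) {
    net <- with_seed(derive_seed(seed, try), {
      cpts <- lapply(names(variables), function(v)
        random_cpt(v, dag_parents(g, v), variables, concentration))
      dbn(variables, edges, cpts)
    })
    if (survey11_ok(net)) return(net)
  }
  gbn_abort("internal_consistency",
            "survey11: no acceptable CPT draw within the retry budget")
}

#' Fixture specification
#'
#' @param name fixture label.
#' @param variables named list of state vectors.
#' @param edges list of (parent, child) pairs.
#' @param cpt_source `"random-dirichlet"` (rows drawn per seed) or
#'   `"explicit"` (supply `cpts`).
#' @param concentration Dirichlet concentration for random CPT rows.
#' @param seed integer seed.
#' @param cpts list of [cpt()] objects when `cpt_source = "explicit"`.
#' @return an object of class `gbn_fixture_spec`.
#' @export
fixture_spec <- function(name, variables, edges,
                         cpt_source = c("random-dirichlet", "explicit"),
                         concentration = 1, seed = 1L, cpts = NULL) {
  cpt_source <- match.arg(cpt_source)
  structure(list(name = name, variables = variables, edges = edges,
                 cpt_source = cpt_source, concentration = concentration,
                 seed = as.integer(seed), cpts = cpts),
            class = "gbn_fixture_spec")
}

#' Build a fixture network
#'
#' Shipped named fixtures:
#' * `toy3` — the fixed three-node teaching network ([toy3_network()]).
#' * `survey11` — the eleven analysis variables (obesity level with four
#'   growth-chart states, pocket money, wealth, parental education,
#'   smartphone service/time, study sitting time, academic performance,
#'   pressure, sleeping quality) with random-Dirichlet CPTs per seed,
#'   rejection-tuned so the obesity node's marginal entropy lies in
#'   [1.5, 2] bits, pocket money carries the largest mutual information
#'   with it, and every CPT row stays estimable at survey scale.
#' * `naive4` — a class with four feature children, random-Dirichlet CPTs,
#'   class prior kept away from degeneracy.
#'
#' A [fixture_spec()] may be passed instead of a name for custom fixtures.
#'
#' @param spec fixture name (`"toy3"`, `"survey11"`, `"naive4"`) or a
#'   [fixture_spec()].
#' @param seed integer seed (ignored by the fully explicit `toy3`).
#' @return a [dbn()] network.
#' @export
build_fixture <- function(spec, seed = 1L) {
  if (is_string(spec)) {
    return(switch(spec,
      toy3 = toy3_network(),
      survey11 = build_survey11(seed),
      naive4 = build_naive4(seed),
      gbn_abort("config", paste0("unknown fixture: ", spec))))
  }
  gbn_assert(inherits(spec, "gbn_fixture_spec"), "config",
             "spec must be a fixture name or fixture_spec()")
  g <- dag(names(spec$variables), spec$edges)
  if (spec$cpt_source == "explicit") {
    return(dbn(spec$variables, spec$edges, spec$cpts))
  }
  with_seed(spec$seed, {
    cpts <- lapply(names(spec$variables), function(v)
      random_cpt(v, dag_parents(g, v), spec$variables, spec$concentration))
    dbn(spec$variables, spec$edges, cpts)
  })
}

build_naive4 <- function(seed, n_feature_states = 3L) {
  variables <- c(list(Class = c("c1", "c2", "c3")),
                 stats::setNames(rep(list(paste0("s", seq_len(n_feature_states))), 4),
                                 paste0("F", 1:4)))
  edges <- lapply(paste0("F", 1:4), function(f) c("Class", f))
  g <- dag(names(variables), edges)
  for (try in seq_len(1000L)) {
    net <- with_seed(derive_seed(seed, try), {
      cpts <- lapply(names(variables), function(v)
        random_cpt(v, dag_parents(g, v), variables, 1))
      dbn(variables, edges, cpts)
    })
    if (min(infer_posterior(net, "Class")) >= 0.15) return(net)
  }
  gbn_abort("internal_consistency",
            "naive4: no acceptable class prior within the retry budget")
}

#' Random network for property testing
#'
#' A DAG drawn over a random topological order (each forward pair is an edge
#' with probability `edge_prob`, subject to `max_parents`), with state counts
#' drawn in `2..max_states` and Dirichlet(1) CPT rows.
#'
#' @param n_nodes number of nodes.
#' @param max_states maximum states per node (minimum 2).
#' @param edge_prob forward-pair edge probability.
#' @param max_parents per-node parent cap.
#' @param seed integer seed.
#' @return a [dbn()] network with nodes `V1..Vn`.
#' @export
random_network <- function(n_nodes, max_states = 3L, edge_prob = 0.3,
                           max_parents = 3L, seed = 1L) {
  gbn_assert(n_nodes >= 1, "invalid_size", "n_nodes must be >= 1")
  with_seed(seed, {
    nodes <- paste0("V", seq_len(n_nodes))
    ord <- sample(nodes)
    variables <- stats::setNames(lapply(nodes, function(v) {
      k <- sample(2:max(2, max_states), 1)
      paste0("s", seq_len(k))
    }), nodes)
    edges <- list()
    npar <- stats::setNames(integer(n_nodes), nodes)
    for (i in seq_len(n_nodes)) {
      for (j in seq_len(n_nodes)) {
        if (i >= j) next
        if (npar[[ord[j]]] >= max_parents) next
        if (stats::runif(1) < edge_prob) {
          edges[[length(edges) + 1]] <- c(ord[i], ord[j])
          npar[[ord[j]]] <- npar[[ord[j]]] + 1L
        }
      }
    }
    g <- dag(nodes, edges)
    cpts <- lapply(nodes, function(v)
      random_cpt(v, dag_parents(g, v), variables, 1))
    dbn(variables, if (length(edges)) edges else NULL, cpts)
  })
}

#' Corruption specification for generated surveys
#'
#' Disjoint random row sets get, respectively, one cell blanked to a missing
#' marker, the usage column set to the never-user token, and the usage column
#' set to the "don't know" token. Rates must sum below 1.
#'
#' @param missing_rate,nonuser_rate,dontknow_rate fractions in `[0, 1)`.
#' @param missing_marker,nonuser_token,dontknow_token marker strings written
#'   into the data (defaults match [filter_rows()]'s defaults).
#' @param seed integer seed.
#' @return an object of class `gbn_corruption_spec`.
#' @export
corruption_spec <- function(missing_rate = 0, nonuser_rate = 0,
                            dontknow_rate = 0, missing_marker = "-9",
                            nonuser_token = "never_used",
                            dontknow_token = "dont_know", seed = 1L) {
  rates <- c(missing_rate, nonuser_rate, dontknow_rate)
  gbn_assert(all(rates >= 0) && all(rates < 1) && sum(rates) < 1,
             "invalid_corruption", "corruption rates must lie in [0,1) and sum below 1")
  structure(list(missing_rate = missing_rate, nonuser_rate = nonuser_rate,
                 dontknow_rate = dontknow_rate,
                 missing_marker = missing_marker,
                 nonuser_token = nonuser_token,
                 dontknow_token = dontknow_token, seed = as.integer(seed)),
            class = "gbn_corruption_spec")
}

#' Generate a survey-like dataset with logged corruption
#'
#' Ancestral samples from `net`, then injects missingness, never-user and
#' "don't know" answers on disjoint random row sets per the corruption spec.
#' The injection log records exactly which rows were touched and how, so a
#' downstream [filter_rows()] pass can be reconciled against it exactly.
#'
#' @param net a [dbn()] network.
#' @param n number of rows.
#' @param corruption a [corruption_spec()]; the default injects nothing.
#' @param seed integer seed for the ancestral sampling.
#' @param usage_col column receiving the never-user / "don't know" tokens;
#'   defaults to `"Smartphone_Time"` when present, else the first column.
#' @return list with `data` (the corrupted survey), `log` (list:
#'   `missing_rows`, `missing_cols`, `nonuser_rows`, `dontknow_rows`,
#'   `usage_col`, counts) and `clean` (the uncorrupted sample).
#' @export
generate_survey <- function(net, n, corruption = corruption_spec(),
                            seed = 1L, usage_col = NULL) {
  gbn_assert(inherits(corruption, "gbn_corruption_spec"), "invalid_corruption",
             "corruption must be a corruption_spec()")
  clean <- ancestral_sample(net, n, seed)
  data <- clean
  usage_col <- usage_col %||%
    (if ("Smartphone_Time" %in% names(data)) "Smartphone_Time" else names(data)[1])
  n_miss <- round(corruption$missing_rate * n)
  n_nonu <- round(corruption$nonuser_rate * n)
  n_dk <- round(corruption$dontknow_rate * n)
  log <- with_seed(corruption$seed, {
    pick <- sample(n, n_miss + n_nonu + n_dk)
    miss_rows <- pick[seq_len(n_miss)]
    nonu_rows <- pick[n_miss + seq_len(n_nonu)]
    dk_rows <- pick[n_miss + n_nonu + seq_len(n_dk)]
    miss_cols <- sample(names(data), n_miss, replace = TRUE)
    list(missing_rows = sort(miss_rows),
         missing_cols = miss_cols[order(miss_rows)],
         nonuser_rows = sort(nonu_rows),
         dontknow_rows = sort(dk_rows),
         usage_col = usage_col,
         counts = list(missing = n_miss, nonuser = n_nonu, dontknow = n_dk))
  })
  for (i in seq_along(log$missing_rows)) {
    data[log$missing_rows[i], log$missing_cols[i]] <- corruption$missing_marker
  }
  data[log$nonuser_rows, usage_col] <- corruption$nonuser_token
  data[log$dontknow_rows, usage_col] <- corruption$dontknow_token
  list(data = data, log = log, clean = clean)
}

skeleton_pairs <- function(g) {
  if (nrow(g$edges) == 0) return(character(0))
  unique(vapply(seq_len(nrow(g$edges)), function(i) {
    paste(sort(c(g$edges$parent[i], g$edges$child[i])), collapse = "~")
  }, ""))
}

#' Structure/parameter recovery metrics
#'
#' Compares a learned network against the generating truth on the same
#' variable roster: skeleton (undirected edge) precision, recall and F1; the
#' maximum and mean total-variation distance between matched CPT rows (taken
#' over nodes whose learned parent set equals the true parent set); and the
#' absolute error of each node's marginal, reported as its maximum and as the
#' target node's value when `target` is given.
#'
#' @param truth,learned [dbn()] networks over the same variables.
#' @param target optional node whose marginal error is reported separately.
#' @return list of class `gbn_recovery_report` with elements
#'   `skeleton_precision`, `skeleton_recall`, `skeleton_f1`, `cpt_tv_max`,
#'   `cpt_tv_mean`, `n_matched_rows`, `marginal_abs_error_max`, and
#'   optionally `target_marginal_abs_error`.
#' @export
recovery_report <- function(truth, learned, target = NULL) {
  gbn_assert(setequal(names(truth$variables), names(learned$variables)),
             "incomparable_networks", "networks have different variable rosters")
  for (v in names(truth$variables)) {
    gbn_assert(setequal(truth$variables[[v]], learned$variables[[v]]),
               "incomparable_networks",
               paste0("state roster mismatch for ", v))
  }
  st <- skeleton_pairs(truth$structure)
  sl <- skeleton_pairs(learned$structure)
  tp <- length(intersect(st, sl))
  precision <- if (length(sl) == 0) ifelse(length(st) == 0, 1, 0) else tp / length(sl)
  recall <- if (length(st) == 0) 1 else tp / length(st)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tvs <- numeric(0)
  for (v in names(truth$variables)) {
    pt <- truth$cpts[[v]]$parents
    pl <- learned$cpts[[v]]$parents
    if (!setequal(pt, pl)) next
    rt <- cpt_rows(align_cpt(truth$cpts[[v]], truth$variables))
    rl <- cpt_rows(align_cpt(learned$cpts[[v]], truth$variables))
    tvs <- c(tvs, apply(abs(rt - rl), 1, sum) / 2)
  }
  marg <- vapply(names(truth$variables), function(v) {
    mt <- infer_posterior(truth, v)
    ml <- infer_posterior(learned, v)[names(mt)]
    max(abs(mt - ml))
  }, 1.0)
  out <- list(skeleton_precision = precision, skeleton_recall = recall,
              skeleton_f1 = f1,
              cpt_tv_max = if (length(tvs)) max(tvs) else NA_real_,
              cpt_tv_mean = if (length(tvs)) mean(tvs) else NA_real_,
              n_matched_rows = length(tvs),
              marginal_abs_error_max = max(marg))
  if (!is.null(target)) {
    out$target_marginal_abs_error <- marg[[target]]
  }
  structure(out, class = "gbn_recovery_report")
}

# Re-express a CPT with parents sorted and states in the reference roster
# order, so truth/learned tables line up row-for-row.
align_cpt <- function(ct, ref_variables) {
  parents <- sort(ct$parents)
  prob <- ct$prob
  if (length(ct$parents) > 0) {
    perm <- c(1, 1 + match(parents, ct$parents))
    prob <- aperm(prob, perm)
  }
  dn <- dimnames(prob)
  idx <- c(list(match(ref_variables[[ct$child]], dn[[1]])),
           lapply(seq_along(parents), function(i)
             match(ref_variables[[parents[i]]], dn[[i + 1]])))
  prob <- do.call(`[`, c(list(prob), idx, list(drop = FALSE)))
  dimnames(prob) <- c(stats::setNames(list(ref_variables[[ct$child]]), ct$child),
                      ref_variables[parents])
  cpt(ct$child, parents, prob)
}
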