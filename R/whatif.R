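# What-if scenario engine: apply evidence, propagate exactly, report the
# induced posterior shifts, and decompose the change in a target expectation
# into main effects and interaction terms.

check_target <- function(net, target) {
  gbn_assert(is.list(target) || (is.character(target) && length(target) == 2),
             "invalid_query", "target must be a (variable, state) pair")
  tv <- if (is.list(target)) target[[1]] else target[1]
  ts <- if (is.list(target)) target[[2]] else target[2]
  check_node(net, tv)
  gbn_assert(ts %in% net$variables[[tv]], "unknown_state",
             paste0("state '", ts, "' is not legal for variable ", tv))
  list(var = tv, state = ts)
}

#' Expected target indicator given evidence
#'
#' The target is the indicator of a single state of one variable, so its
#' conditional expectation is the posterior probability
#' `P(target_var = target_state | evidence)`. A multi-state expectation over
#' user-supplied state scores is available via `scores`.
#'
#' @param net a [dbn()] network.
#' @param target `c(variable, state)` (or a 2-element list) naming the
#'   indicator; with `scores`, just the variable name.
#' @param evidence named character vector of observed states (must not
#'   mention the target variable).
#' @param scores optional named numeric vector over the target variable's
#'   states; when supplied the expectation `sum_s scores[s] P(s | evidence)`
#'   is returned instead of an indicator probability.
#' @return `E(Y | evidence)`.
#' @examples
#' net <- toy3_network()
#' expected_target(net, c("Obesity", "Obese"))                       # 0.234
#' expected_target(net, c("Obesity", "Obese"), c(Pocket_Money = "Med"))  # 0.4
#' @export
expected_target <- function(net, target, evidence = NULL, scores = NULL) {
  if (!is.null(scores)) {
    tv <- if (is.list(target)) target[[1]] else target[1]
    check_node(net, tv)
    gbn_assert(setequal(names(scores), net$variables[[tv]]), "invalid_query",
               "scores must name every state of the target variable")
    ev <- check_evidence(net, evidence)
    gbn_assert(!(tv %in% names(ev)), "invalid_query",
               "evidence must not mention the target variable")
    post <- infer_posterior(net, tv, ev)
    return(sum(scores[names(post)] * post))
  }
  tg <- check_target(net, target)
  ev <- check_evidence(net, evidence)
  gbn_assert(!(tg$var %in% names(ev)), "invalid_query",
             "evidence must not mention the target variable")
  unname(infer_posterior(net, tg$var, ev)[tg$state])
}

#' Define a what-if scenario
#'
#' @param name scenario label.
#' @param evidence named character vector `variable -> state`; the special
#'   values `"max"` and `"min"` are resolved against the network at apply
#'   time to the variable's highest/lowest ordinal state (state order as
#'   declared in the roster) and the resolution is recorded in the report.
#' @param target `c(variable, state)` whose probability the scenario tracks;
#'   the variable must not appear in the evidence.
#' @return an object of class `gbn_scenario`.
#' @export
scenario <- function(name, evidence, target) {
  gbn_assert(is_string(name), "config", "scenario name must be a string")
  gbn_assert(length(evidence) >= 1 && !is.null(names(evidence)),
             "config", "scenario evidence must be a named mapping")
  structure(list(name = name, evidence = unlist(evidence),
                 target = target), class = "gbn_scenario")
}

resolve_directives <- function(net, evidence) {
  out <- evidence
  for (v in names(out)) {
    if (identical(out[[v]], "max")) {
      out[[v]] <- utils::tail(net$variables[[v]], 1)
    } else if (identical(out[[v]], "min")) {
      out[[v]] <- net$variables[[v]][1]
    }
  }
  out
}

#' Apply a scenario and report posterior shifts
#'
#' Propagates the scenario evidence through the network and reports, for
#' every node, the no-evidence baseline marginal, the evidence-conditioned
#' posterior, and their difference. The headline quantity is the target
#' state's baseline -> posterior move (the "a -> b" arrow of a scenario
#' table). Evidence nodes get degenerate posteriors.
#'
#' @param net a [dbn()] network.
#' @param scn a [scenario()].
#' @return an object of class `gbn_posterior_report`: list with `scenario`,
#'   `evidence` (after max/min resolution), `baseline`, `posterior`, `deltas`
#'   (named lists of probability vectors / differences) and `headline`
#'   (`c(baseline, posterior)` for the target state).
#' @export
apply_scenario <- function(net, scn) {
  gbn_assert(inherits(scn, "gbn_scenario"), "config",
             "scn must be a scenario()")
  tg <- check_target(net, scn$target)
  ev <- resolve_directives(net, scn$evidence)
  ev <- check_evidence(net, ev)
  gbn_assert(!(tg$var %in% names(ev)), "invalid_query",
             "scenario target variable must not be in the evidence")
  nodes <- names(net$variables)
  baseline <- lapply(stats::setNames(nodes, nodes),
                     function(v) infer_posterior(net, v))
  posterior <- lapply(stats::setNames(nodes, nodes), function(v) {
    if (v %in% names(ev)) {
      p <- stats::setNames(as.numeric(net$variables[[v]] == ev[[v]]),
                           net$variables[[v]])
      p
    } else {
      infer_posterior(net, v, ev)
    }
  })
  deltas <- lapply(stats::setNames(nodes, nodes),
                   function(v) posterior[[v]] - baseline[[v]])
  headline <- c(baseline = unname(baseline[[tg$var]][tg$state]),
                posterior = unname(posterior[[tg$var]][tg$state]))
  structure(list(scenario = scn$name, target = tg, evidence = ev,
                 baseline = baseline, posterior = posterior, deltas = deltas,
                 headline = headline),
            class = "gbn_posterior_report")
}

#' @export
print.gbn_posterior_report <- function(x, digits = 1, ...) {
  cat("Scenario:", x$scenario, "\n")
  cat("Evidence:", paste(names(x$evidence), x$evidence, sep = " = ",
                         collapse = "; "), "\n")
  cat(sprintf("%s = %s: %.*f%% -> %.*f%%\n", x$target$var, x$target$state,
              digits, 100 * x$headline[["baseline"]],
              digits, 100 * x$headline[["posterior"]]))
  cat("Per-node shifts (largest first):\n")
  mag <- vapply(x$deltas, function(d) max(abs(d)), 1.0)
  for (v in names(sort(mag, decreasing = TRUE))) {
    if (v %in% names(x$evidence)) next
    i <- which.max(abs(x$deltas[[v]]))
    cat(sprintf("  %s = %s: %.*f%% -> %.*f%%\n", v,
                names(x$deltas[[v]])[i],
                digits, 100 * x$baseline[[v]][i],
                digits, 100 * x$posterior[[v]][i]))
  }
  invisible(x)
}

# z-term for one evidence subset, by inclusion-exclusion over its proper
# non-empty subsets (reduces to the familiar first/second/third-order forms).
subset_key <- function(vars) paste(sort(vars), collapse = "+")

#' Functional decomposition of a scenario's target expectation
#'
#' Decomposes the conditional expectation of the target indicator under the
#' full scenario evidence into a baseline `E(Y)`, main effects
#' `z_i = E(Y | x_i) - E(Y)`, and interaction terms
#' `z_S = E(Y | x_S) - sum over proper non-empty subsets T of S of z_T - E(Y)`
#' computed at the observed states, up to `max_order`. Whatever higher-order
#' structure is not captured by the retained terms lands in the remainder
#' `E(Y | full evidence) - E(Y) - sum(terms)`; at `max_order = d` the
#' reconstruction is exact and the remainder vanishes.
#'
#' @param net a [dbn()] network.
#' @param target `c(variable, state)` indicator definition.
#' @param evidence named character vector of observed states (the scenario),
#'   all with positive joint probability.
#' @param max_order largest subset size to expand (1 <= max_order <= d).
#' @return an object of class `gbn_whatif_decomposition`: list with
#'   `baseline`, `terms` (data frame: `vars`, `states`, `order`, `z`),
#'   `remainder`, `conditional` (`E(Y | full evidence)`) and `max_order`.
#' @examples
#' net <- toy3_network()
#' d <- whatif_decomposition(net, c("Obesity", "Obese"),
#'                           c(Wealth = "Low", Pocket_Money = "Med"),
#'                           max_order = 2)
#' d$baseline + sum(d$terms$z) + d$remainder  # = E(Y | full evidence)
#' @export
whatif_decomposition <- function(net, target, evidence, max_order = 2L) {
  tg <- check_target(net, target)
  ev <- check_evidence(net, evidence)
  d <- length(ev)
  gbn_assert(d >= 1, "invalid_query", "decomposition needs evidence")
  gbn_assert(!(tg$var %in% names(ev)), "invalid_query",
             "evidence must not mention the target variable")
  gbn_assert(max_order >= 1 && max_order <= d, "invalid_query",
             "max_order must be between 1 and the number of evidence variables")
  baseline <- expected_target(net, target)
  vars <- names(ev)
  z <- list()
  rows <- list()
  for (ord in seq_len(max_order)) {
    for (sel in utils::combn(vars, ord, simplify = FALSE)) {
      sub_ev <- ev[sel]
      e_sub <- tryCatch(
        expected_target(net, target, sub_ev),
        gbn_inconsistent_evidence = function(c_) {
          gbn_abort("inconsistent_evidence",
                    paste0("evidence subset {", paste(sel, collapse = ", "),
                           "} has probability zero"))
        })
      zval <- e_sub - baseline
      if (ord > 1) {
        for (k in seq_len(ord - 1)) {
          for (sub in utils::combn(sel, k, simplify = FALSE)) {
            zval <- zval - z[[subset_key(sub)]]
          }
        }
      }
      z[[subset_key(sel)]] <- zval
      rows[[length(rows) + 1]] <- data.frame(
        vars = subset_key(sel),
        states = paste(sub_ev[sort(sel)], collapse = "+"),
        order = ord, z = zval, stringsAsFactors = FALSE)
    }
  }
  terms <- do.call(rbind, rows)
  conditional <- expected_target(net, target, ev)
  remainder <- conditional - baseline - sum(terms$z)
  structure(list(target = tg, evidence = ev, baseline = baseline,
                 terms = terms, remainder = remainder,
                 conditional = conditional, max_order = as.integer(max_order)),
            class = "gbn_whatif_decomposition")
}

#' @export
print.gbn_whatif_decomposition <- function(x, ...) {
  cat(sprintf("What-if decomposition of P(%s = %s)\n", x$target$var,
              x$target$state))
  cat(sprintf("  baseline E(Y)        = %.6f\n", x$baseline))
  for (i in seq_len(nrow(x$terms))) {
    cat(sprintf("  z[%s = %s]  = %+.6f\n", x$terms$vars[i], x$terms$states[i],
                x$terms$z[i]))
  }
  cat(sprintf("  remainder            = %+.3g\n", x$remainder))
  cat(sprintf("  E(Y | full evidence) = %.6f\n", x$conditional))
  invisible(x)
}

#' Main-effect profile of one variable (full tabulation)
#'
#' Tabulates the first-order term `z_i(x) = E(Y | X_i = x) - E(Y)` over every
#' state of `var`, together with the marginal weights `P(X_i = x)`. Because
#' `E[E(Y | X_i)] = E(Y)`, the weighted mean of the profile is zero.
#'
#' @param net a [dbn()] network.
#' @param target `c(variable, state)` indicator definition.
#' @param var variable to profile (not the target variable).
#' @return data frame with columns `state`, `weight`, `z`.
#' @export
main_effect_profile <- function(net, target, var) {
  tg <- check_target(net, target)
  check_node(net, var)
  gbn_assert(var != tg$var, "invalid_query",
             "cannot profile the target variable against itself")
  baseline <- expected_target(net, target)
  w <- infer_posterior(net, var)
  zs <- vapply(net$variables[[var]], function(s) {
    if (w[[s]] <= 0) return(0)
    expected_target(net, target, stats::setNames(s, var)) - baseline
  }, 1.0)
  data.frame(state = net$variables[[var]], weight = as.numeric(w),
             z = as.numeric(zs), stringsAsFactors = FALSE)
}

#' Read scenarios from a YAML file
#'
#' Each document entry has `name`, `evidence` (mapping, values may be the
#' `"max"`/`"min"` directives) and `target` (`"Var=state"`).
#'
#' @param path YAML file path.
#' @return list of [scenario()] objects.
#' @export
read_scenarios <- function(path) {
  gbn_assert(file.exists(path), "config",
             paste0("scenario file not found: ", path))
  raw <- yaml::read_yaml(path)
  lapply(raw, function(s) {
    tg <- strsplit(s$target, "=", fixed = TRUE)[[1]]
    gbn_assert(length(tg) == 2, "config",
               "scenario target must be 'Variable=state'")
    scenario(s$name, unlist(s$evidence), trimws(tg))
  })
}

#' Write a scenario report as JSON
#'
#' Baseline/posterior/delta per node plus the headline arrow, mirroring the
#' human-readable print method.
#'
#' @param report an [apply_scenario()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_json <- function(report, path) {
  obj <- list(
    scenario = report$scenario,
    target = list(variable = report$target$var, state = report$target$state),
    evidence = as.list(report$evidence),
    headline = list(baseline = report$headline[["baseline"]],
                    posterior = report$headline[["posterior"]]),
    nodes = lapply(names(report$baseline), function(v) {
      list(node = v,
           baseline = as.list(report$baseline[[v]]),
           posterior = as.list(report$posterior[[v]]),
           delta = as.list(report$deltas[[v]]))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
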