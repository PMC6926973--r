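#' Joint probability of a complete assignment
#'
#' Chain-rule factorisation: the product over nodes of the CPT entry selected
#' by the assignment.
#'
#' @param net a [dbn()] network.
#' @param assignment named character vector (or named list) giving one legal
#'   state for every node.
#' @return a probability in `[0, 1]`.
#' @examples
#' net <- toy3_network()
#' joint_probability(net, c(Wealth = "Low", Pocket_Money = "Med",
#'                          Obesity = "Obese"))  # 0.4 * 0.4 * 0.4
#' @export
joint_probability <- function(net, assignment) {
  a <- unlist(assignment)
  nms <- names(a)
  missing <- setdiff(names(net$variables), nms)
  gbn_assert(length(missing) == 0, "incomplete_assignment",
             paste("assignment misses node(s):", paste(missing, collapse = ", ")))
  for (v in names(net$variables)) {
    gbn_assert(a[[v]] %in% net$variables[[v]], "unknown_state",
               paste0("state '", a[[v]], "' is not legal for variable ", v))
  }
  p <- 1
  for (v in names(net$variables)) {
    ct <- net$cpts[[v]]
    idx <- c(match(a[[v]], net$variables[[v]]),
             vapply(ct$parents, function(pa) match(a[[pa]], net$variables[[pa]]), 1L))
    p <- p * unname(do.call(`[`, c(list(ct$prob), as.list(idx))))
    if (p == 0) return(0)
  }
  unname(p)
}

# Min-degree elimination order on the moralised interaction graph of the
# given factors, restricted to `elim`; ties broken lexicographically.
elimination_order <- function(factor_vars, elim) {
  if (length(elim) == 0) return(character(0))
  allv <- sort(unique(unlist(factor_vars)))
  adj <- stats::setNames(lapply(allv, function(v) character(0)), allv)
  for (fv in factor_vars) {
    for (v in fv) adj[[v]] <- union(adj[[v]], setdiff(fv, v))
  }
  remaining <- sort(elim)
  order_out <- character(0)
  active <- allv
  while (length(remaining) > 0) {
    deg <- vapply(remaining, function(v) length(intersect(adj[[v]], active)), 1L)
    v <- remaining[order(deg, remaining)][1]
    nb <- intersect(adj[[v]], active)
    for (u in nb) adj[[u]] <- union(adj[[u]], setdiff(nb, u))
    active <- setdiff(active, v)
    remaining <- setdiff(remaining, v)
    order_out <- c(order_out, v)
  }
  order_out
}

#' Exact posterior by variable elimination
#'
#' Computes `P(query | evidence)` exactly. Non-query, non-evidence variables
#' are summed out along a min-degree order on the moralised graph (ties broken
#' lexicographically); the result is renormalised, with drift beyond 1e-9 in
#' the evidence-free normaliser treated as an internal consistency failure.
#'
#' @param net a [dbn()] network.
#' @param query name of the query variable (must not appear in the evidence).
#' @param evidence named character vector `variable -> observed state`;
#'   `NULL` or empty for the prior marginal.
#' @return named probability vector over the query's states.
#' @examples
#' net <- toy3_network()
#' infer_posterior(net, "Obesity")                               # prior: 0.234
#' infer_posterior(net, "Obesity", c(Pocket_Money = "Med"))      # 0.400
#' @export
infer_posterior <- function(net, query, evidence = NULL) {
  check_node(net, query)
  ev <- check_evidence(net, evidence)
  gbn_assert(!(query %in% names(ev)), "invalid_query",
             "query variable appears in the evidence")
  factors <- lapply(net$cpts, factor_from_cpt)
  for (v in names(ev)) {
    factors <- lapply(factors, factor_reduce, var = v, state = ev[[v]])
  }
  elim <- setdiff(names(net$variables), c(query, names(ev)))
  ord <- elimination_order(lapply(factors, `[[`, "vars"), elim)
  for (v in ord) {
    has <- vapply(factors, function(f) v %in% f$vars, TRUE)
    if (!any(has)) next
    prod_f <- Reduce(factor_product, factors[has])
    factors <- c(factors[!has], list(factor_marginalize(prod_f, v)))
  }
  res <- Reduce(factor_product, factors)
  gbn_assert(identical(res$vars, query) ||
               (length(res$vars) == 1 && res$vars == query),
             "internal_consistency", "elimination left an unexpected factor scope")
  vec <- as.numeric(res$tab)
  z <- sum(vec)
  if (z <= 0) {
    gbn_abort("inconsistent_evidence",
              paste0("evidence has probability zero: {",
                     paste(names(ev), ev, sep = "=", collapse = ", "), "}"))
  }
  if (length(ev) == 0) {
    gbn_assert(abs(z - 1) <= 1e-9, "internal_consistency",
               sprintf("evidence-free normaliser drifted from 1 by %.3g", z - 1))
  }
  stats::setNames(vec / z, net$variables[[query]])
}

#' Posterior by brute-force joint enumeration
#'
#' Reference oracle: tabulates the full joint distribution and marginalises.
#' Same contract as [infer_posterior()], but guarded to networks whose joint
#' state space does not exceed `10^7` cells.
#'
#' @inheritParams infer_posterior
#' @return named probability vector over the query's states.
#' @export
brute_force_posterior <- function(net, query, evidence = NULL) {
  check_node(net, query)
  ev <- check_evidence(net, evidence)
  gbn_assert(!(query %in% names(ev)), "invalid_query",
             "query variable appears in the evidence")
  cells <- prod(vapply(net$variables, length, 1L))
  gbn_assert(cells <= 1e7, "too_large",
             sprintf("joint has %.3g cells; enumeration guard is 1e7", cells))
  jt <- joint_table(net)
  keep <- rep(TRUE, nrow(jt$grid))
  for (v in names(ev)) keep <- keep & (jt$grid[[v]] == ev[[v]])
  p <- jt$prob[keep]
  z <- sum(p)
  if (z <= 0) {
    gbn_abort("inconsistent_evidence",
              paste0("evidence has probability zero: {",
                     paste(names(ev), ev, sep = "=", collapse = ", "), "}"))
  }
  g <- jt$grid[[query]][keep]
  vec <- vapply(net$variables[[query]], function(s) sum(p[g == s]), 1.0)
  stats::setNames(vec / z, net$variables[[query]])
}

# Full joint as (grid of state labels, probability vector); internal helper
# shared by the enumeration oracle and the pairwise-joint routines.
joint_table <- function(net) {
  vars <- names(net$variables)
  grid <- expand.grid(net$variables, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  logp <- numeric(n)
  p <- rep(1, n)
  for (v in vars) {
    ct <- net$cpts[[v]]
    ci <- match(grid[[v]], net$variables[[v]])
    lin <- ci
    stride <- length(net$variables[[v]])
    for (pa in ct$parents) {
      lin <- lin + (match(grid[[pa]], net$variables[[pa]]) - 1L) * stride
      stride <- stride * length(net$variables[[pa]])
    }
    p <- p * as.vector(ct$prob)[lin]
  }
  list(grid = grid, prob = p)
}

#' Draw ancestral samples from a network
#'
#' Samples `n` rows in topological order (each node drawn from its CPT row
#' given the already-sampled parents). Deterministic for a fixed seed; the
#' global RNG stream is left untouched.
#'
#' @param net a [dbn()] network.
#' @param n number of rows (>= 1).
#' @param seed integer seed.
#' @return data frame of character state labels, one column per variable in
#'   roster order.
#' @export
ancestral_sample <- function(net, n, seed) {
  gbn_assert(is.numeric(n) && length(n) == 1 && n >= 1, "invalid_size",
             "n must be a positive integer")
  n <- as.integer(n)
  ord <- topological_order(net$structure)
  out <- vector("list", length(net$variables))
  names(out) <- names(net$variables)
  with_seed(seed, {
    idx <- list()
    for (v in ord) {
      ct <- net$cpts[[v]]
      r <- n_states(net, v)
      pm <- matrix(as.vector(ct$prob), nrow = r)  # columns: parent configs, p1 fastest
      cfg <- rep(1L, n)
      stride <- 1L
      for (pa in ct$parents) {
        cfg <- cfg + (idx[[pa]] - 1L) * stride
        stride <- stride * n_states(net, pa)
      }
      cm <- apply(pm, 2, cumsum)            # r x q cumulative
      u <- stats::runif(n)
      M <- t(cm)[cfg, , drop = FALSE]       # n x r
      st <- 1L + as.integer(rowSums(u > M[, -r, drop = FALSE]))
      idx[[v]] <- st
    }
    for (v in names(net$variables)) out[[v]] <- net$variables[[v]][idx[[v]]]
  })
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}
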