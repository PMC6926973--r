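#' Structure-learning configuration
#'
#' Settings for score-based search and CPT estimation. Defaults follow the
#' conventions of discrete-network toolkits: BDeu score with equivalent sample
#' size 1, at most 3 parents per node, greedy search from the empty graph
#' (no random restarts), Laplace smoothing with `alpha = 1`.
#'
#' @param score `"bdeu"` (Dirichlet-equivalent marginal likelihood) or
#'   `"bic"`.
#' @param equivalent_sample_size BDeu prior strength (> 0).
#' @param max_parents per-node parent limit (>= 1).
#' @param restarts number of additional random-DAG restarts (>= 0).
#' @param seed integer seed governing the random restarts.
#' @param smoothing_alpha Laplace pseudo-count used when estimating CPTs
#'   (>= 0; 0 gives maximum likelihood with a uniform fallback for unseen
#'   parent configurations).
#' @return an object of class `gbn_learner_config`.
#' @export
learner_config <- function(score = c("bdeu", "bic"),
                           equivalent_sample_size = 1.0,
                           max_parents = 3L,
                           restarts = 0L,
                           seed = 1L,
                           smoothing_alpha = 1.0) {
  score <- match.arg(score)
  gbn_assert(equivalent_sample_size > 0, "config",
             "equivalent_sample_size must be > 0")
  gbn_assert(max_parents >= 1, "config", "max_parents must be >= 1")
  gbn_assert(restarts >= 0, "config", "restarts must be >= 0")
  gbn_assert(smoothing_alpha >= 0, "config", "smoothing_alpha must be >= 0")
  structure(list(score = score,
                 equivalent_sample_size = as.numeric(equivalent_sample_size),
                 max_parents = as.integer(max_parents),
                 restarts = as.integer(restarts),
                 seed = as.integer(seed),
                 smoothing_alpha = as.numeric(smoothing_alpha)),
            class = "gbn_learner_config")
}

as_learner_config <- function(x) {
  if (inherits(x, "gbn_learner_config")) return(x)
  do.call(learner_config, x %||% list())
}

# Integer-encode a categorical data frame against a state roster; refuses
# missing values (cleaning is a preprocessing responsibility, not a learner
# one).
encode_data <- function(data, variables) {
  gbn_assert(nrow(data) >= 1, "degenerate_input", "data has no rows")
  x <- matrix(0L, nrow = nrow(data), ncol = length(variables),
              dimnames = list(NULL, names(variables)))
  for (v in names(variables)) {
    col <- as.character(data[[v]])
    if (anyNA(col) || any(col == "")) {
      gbn_abort("unclean_data",
                paste0("column ", v, " contains missing values; ",
                       "run filter_rows() first"))
    }
    m <- match(col, variables[[v]])
    gbn_assert(!anyNA(m), "unknown_state",
               paste0("column ", v, " contains states outside its roster"))
    x[, v] <- m
  }
  x
}

check_data_clean <- function(data) {
  for (v in names(data)) {
    col <- data[[v]]
    if (anyNA(col) || any(as.character(col) == "", na.rm = TRUE)) {
      gbn_abort("unclean_data",
                paste0("column ", v, " contains missing values; ",
                       "run filter_rows() first"))
    }
  }
  invisible(TRUE)
}

# Count matrix N (r x q) for child given parents: columns are parent
# configurations with the FIRST parent varying fastest (matching the internal
# CPT array layout).
family_counts <- function(xmat, child, parents, arities) {
  r <- arities[[child]]
  cfg <- rep(1L, nrow(xmat))
  stride <- 1L
  for (pa in parents) {
    cfg <- cfg + (xmat[, pa] - 1L) * stride
    stride <- stride * arities[[pa]]
  }
  q <- stride
  counts <- tabulate(xmat[, child] + (cfg - 1L) * r, nbins = r * q)
  matrix(counts, nrow = r, ncol = q)
}

#' Estimate CPTs for a fixed structure
#'
#' Per parent configuration, the child distribution is estimated as
#' `(count + alpha) / (total + alpha * r)` where `r` is the number of child
#' states. With `alpha = 0` this is maximum likelihood; parent configurations
#' never seen in the data fall back to the uniform distribution.
#'
#' @param structure a `gbn_dag` (or a [dbn()], whose structure is used).
#' @param data categorical data frame covering every node, no missing values.
#' @param smoothing_alpha Laplace pseudo-count (>= 0).
#' @param variables optional named list of state rosters; defaults to the
#'   sorted unique values observed per column (factor levels are honoured).
#' @return a [dbn()] network with the given structure and estimated CPTs.
#' @export
estimate_cpts <- function(structure, data, smoothing_alpha = 1.0,
                          variables = NULL) {
  g <- as_dag(structure)
  gbn_assert(all(g$nodes %in% names(data)), "degenerate_input",
             "data columns must cover all structure nodes")
  gbn_assert(smoothing_alpha >= 0, "config", "smoothing_alpha must be >= 0")
  check_data_clean(data[g$nodes])
  if (is.null(variables)) {
    variables <- states_from_data(data[g$nodes])
  } else {
    variables <- variables[g$nodes]
  }
  xmat <- encode_data(data, variables)
  arities <- vapply(variables, length, 1L)
  cpts <- lapply(g$nodes, function(v) {
    parents <- dag_parents(g, v)
    N <- family_counts(xmat, v, parents, arities)
    r <- nrow(N)
    tot <- colSums(N)
    P <- sweep(N + smoothing_alpha, 2, tot + smoothing_alpha * r, "/")
    if (smoothing_alpha == 0 && any(tot == 0)) {
      P[, tot == 0] <- 1 / r
    }
    dims <- c(r, arities[parents])
    arr <- array(as.vector(P), dim = dims,
                 dimnames = c(list(variables[[v]]), variables[parents]))
    cpt(v, parents, arr)
  })
  dbn(variables, if (nrow(g$edges)) g$edges else NULL, cpts)
}

# Per-family decomposable score terms ---------------------------------------

family_score <- function(N, config, n_rows) {
  r <- nrow(N)
  q <- ncol(N)
  if (config$score == "bdeu") {
    ess <- config$equivalent_sample_size
    aj <- ess / q
    ajk <- ess / (r * q)
    Nj <- colSums(N)
    sum(lgamma(aj) - lgamma(aj + Nj)) +
      sum(lgamma(ajk + N) - lgamma(ajk))
  } else {
    Nj <- rep(colSums(N), each = r)
    ll <- sum(ifelse(N > 0, N * log(N / Nj), 0))
    ll - 0.5 * log(n_rows) * q * (r - 1)
  }
}

#' Decomposable network score
#'
#' Sum over nodes of the per-family BDeu or BIC term for the structure's
#' parent sets, computed from the data counts.
#'
#' @inheritParams estimate_cpts
#' @param config a [learner_config()] (or a list of its arguments).
#' @return a single numeric score (higher is better).
#' @export
network_score <- function(structure, data, config = learner_config()) {
  g <- as_dag(structure)
  config <- as_learner_config(config)
  check_data_clean(data[g$nodes])
  variables <- states_from_data(data[g$nodes])
  xmat <- encode_data(data, variables)
  arities <- vapply(variables, length, 1L)
  sum(vapply(g$nodes, function(v) {
    N <- family_counts(xmat, v, dag_parents(g, v), arities)
    family_score(N, config, nrow(xmat))
  }, 1.0))
}

# ---- greedy hill climbing --------------------------------------------------

# Internal search state: parent sets as a named list of character vectors.

hc_has_path <- function(parent_sets, from, to) {
  # TRUE if `to` is reachable from `from` following child -> parent? No:
  # we need path from -> ... -> to along directed edges parent -> child.
  # parent_sets maps child -> parents, so children of v are nodes having v
  # as parent.
  stack <- from
  seen <- character(0)
  nodes <- names(parent_sets)
  while (length(stack) > 0) {
    v <- stack[[1]]
    stack <- stack[-1]
    if (v %in% seen) next
    seen <- c(seen, v)
    if (v == to) return(TRUE)
    ch <- nodes[vapply(parent_sets, function(p) v %in% p, TRUE)]
    stack <- c(stack, setdiff(ch, seen))
  }
  FALSE
}

hc_score_family <- function(cache, xmat, arities, config, child, parents) {
  key <- paste0(child, "|", paste(sort(parents), collapse = ","))
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- family_score(family_counts(xmat, child, parents, arities),
                      config, nrow(xmat))
  cache[[key]] <- val
  val
}

hc_search <- function(xmat, arities, config, init_parent_sets, cache) {
  nodes <- colnames(xmat)
  ps <- init_parent_sets
  fam <- vapply(nodes, function(v)
    hc_score_family(cache, xmat, arities, config, v, ps[[v]]), 1.0)
  eps <- 1e-10
  repeat {
    improved <- FALSE
    # moves in fixed lexicographic order of (from, to); for each existing
    # edge: delete, reverse; otherwise: add. First improvement is taken.
    for (a in nodes) {
      for (b in nodes) {
        if (a == b) next
        if (a %in% ps[[b]]) {
          # delete a -> b
          new_pb <- setdiff(ps[[b]], a)
          d <- hc_score_family(cache, xmat, arities, config, b, new_pb) - fam[[b]]
          if (d > eps) {
            ps[[b]] <- new_pb
            fam[[b]] <- fam[[b]] + d
            improved <- TRUE
            break
          }
          # reverse a -> b  (b -> a): b gains parent? a gains parent b
          if (length(ps[[a]]) < config$max_parents) {
            ps_tmp <- ps
            ps_tmp[[b]] <- new_pb
            if (!hc_has_path(ps_tmp, a, b)) {
              # after removing a->b, adding b->a must not create a cycle:
              # cycle would need a path a ~> b
              new_pa <- sort(c(ps[[a]], b))
              d2 <- (hc_score_family(cache, xmat, arities, config, b, new_pb) - fam[[b]]) +
                (hc_score_family(cache, xmat, arities, config, a, new_pa) - fam[[a]])
              if (d2 > eps) {
                ps[[b]] <- new_pb
                ps[[a]] <- new_pa
                fam[[b]] <- hc_score_family(cache, xmat, arities, config, b, new_pb)
                fam[[a]] <- hc_score_family(cache, xmat, arities, config, a, new_pa)
                improved <- TRUE
                break
              }
            }
          }
        } else if (!(b %in% ps[[a]])) {
          # add a -> b
          if (length(ps[[b]]) >= config$max_parents) next
          if (hc_has_path(ps, b, a)) next  # would create a cycle
          new_pb <- sort(c(ps[[b]], a))
          d <- hc_score_family(cache, xmat, arities, config, b, new_pb) - fam[[b]]
          if (d > eps) {
            ps[[b]] <- new_pb
            fam[[b]] <- fam[[b]] + d
            improved <- TRUE
            break
          }
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  list(parent_sets = ps, score = sum(fam))
}

random_parent_sets <- function(nodes, max_parents) {
  ord <- sample(nodes)
  ps <- stats::setNames(lapply(nodes, function(v) character(0)), nodes)
  for (i in seq_along(ord)) {
    if (i == 1) next
    pool <- ord[seq_len(i - 1)]
    k <- min(length(pool), max_parents)
    npar <- sample(0:k, 1)
    if (npar > 0) ps[[ord[i]]] <- sort(sample(pool, npar))
  }
  ps
}

#' Learn a network structure from data
#'
#' Greedy hill climbing over add/delete/reverse single-edge moves, respecting
#' acyclicity and the parent limit, scanning moves in lexicographic order and
#' taking the first improving move. Optional random-DAG restarts (seeded) are
#' compared on the final score; the best-scoring run wins, with the
#' deterministic empty-graph run first in tie-breaks. CPTs of the winning
#' structure are estimated with the configured smoothing.
#'
#' @param data categorical data frame (>= 2 columns, no missing values).
#' @param config a [learner_config()] or argument list.
#' @return a [dbn()] network.
#' @export
learn_structure <- function(data, config = learner_config()) {
  config <- as_learner_config(config)
  gbn_assert(ncol(data) >= 2, "degenerate_input",
             "structure learning needs at least two columns")
  check_data_clean(data)
  variables <- states_from_data(data)
  xmat <- encode_data(data, variables)
  arities <- vapply(variables, length, 1L)
  nodes <- colnames(xmat)
  cache <- new.env(parent = emptyenv())
  empty <- stats::setNames(lapply(nodes, function(v) character(0)), nodes)
  best <- hc_search(xmat, arities, config, empty, cache)
  if (config$restarts > 0) {
    for (k in seq_len(config$restarts)) {
      init <- with_seed(derive_seed(config$seed, k),
                        random_parent_sets(nodes, config$max_parents))
      cand <- hc_search(xmat, arities, config, init, cache)
      if (cand$score > best$score + 1e-10) best <- cand
    }
  }
  edges <- do.call(rbind, lapply(nodes, function(v) {
    if (length(best$parent_sets[[v]]) == 0) return(NULL)
    data.frame(parent = best$parent_sets[[v]], child = v,
               stringsAsFactors = FALSE)
  }))
  g <- dag(nodes, edges)
  estimate_cpts(g, data, smoothing_alpha = config$smoothing_alpha,
                variables = variables)
}

#' Markov-blanket-restricted classifier (GBN-MB)
#'
#' Learns a full network, extracts the Markov blanket of the class node, and
#' relearns the network restricted to the class plus its blanket — the
#' blanket-membership reading of feature selection. Prediction then uses only
#' blanket evidence. An empty blanket falls back to a prior-only classifier
#' with a warning.
#'
#' @param data categorical training data frame.
#' @param class_var name of the class column.
#' @param config a [learner_config()] or argument list.
#' @return list of class `gbn_mb_classifier` with elements `net` (restricted
#'   network), `selection` (a `gbn_mb_selection`), and `full_net`.
#' @export
gbn_mb_classifier <- function(data, class_var, config = learner_config()) {
  gbn_assert(class_var %in% names(data), "unknown_node",
             paste0("class variable ", class_var, " not in data"))
  full <- learn_structure(data, config)
  sel <- markov_blanket(full, class_var)
  if (length(sel$blanket) == 0) {
    warning("empty Markov blanket for ", class_var,
            "; falling back to a prior-only classifier")
    variables <- states_from_data(data[class_var])
    net <- estimate_cpts(dag(class_var), data[class_var],
                         smoothing_alpha = config$smoothing_alpha %||% 1,
                         variables = variables)
  } else {
    config <- as_learner_config(config)
    net <- learn_structure(data[c(class_var, sel$blanket)], config)
  }
  structure(list(net = net, selection = sel, full_net = full,
                 class_var = class_var),
            class = "gbn_mb_classifier")
}
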