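#' Directed acyclic graph over named variables
#'
#' Light container for a DAG: a character vector of node names plus a
#' parent/child edge table. Checked for duplicate nodes, undeclared edge
#' endpoints, duplicate edges, and cycles.
#'
#' @param nodes character vector of node names (unique).
#' @param edges two-column object (parent, child); a data frame, matrix, or
#'   list of length-2 vectors. `NULL` means no edges.
#' @return an object of class `gbn_dag` with elements `nodes` and `edges`
#'   (a data frame with columns `parent`, `child`).
#' @examples
#' g <- dag(c("A", "B", "C"), list(c("A", "B"), c("B", "C")))
#' topological_order(g)
#' @export
dag <- function(nodes, edges = NULL) {
  gbn_assert(is.character(nodes) && length(nodes) >= 1 && !anyNA(nodes),
             "invalid_network", "nodes must be a character vector")
  gbn_assert(!anyDuplicated(nodes), "invalid_network", "duplicate node names")
  ed <- normalize_edges(edges)
  bad <- setdiff(unique(c(ed$parent, ed$child)), nodes)
  gbn_assert(length(bad) == 0, "invalid_network",
             paste("edge endpoint not a declared node:", paste(bad, collapse = ", ")))
  gbn_assert(!anyDuplicated(paste(ed$parent, ed$child, sep = "\r")),
             "invalid_network", "duplicate edges")
  gbn_assert(!any(ed$parent == ed$child), "invalid_network", "self-loop edge")
  g <- structure(list(nodes = nodes, edges = ed), class = "gbn_dag")
  topological_order(g)  # errors on cycles
  g
}

normalize_edges <- function(edges) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0) ||
      (!is.data.frame(edges) && length(edges) == 0)) {
    return(data.frame(parent = character(0), child = character(0),
                      stringsAsFactors = FALSE))
  }
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.data.frame(edges)) {
    gbn_assert(ncol(edges) == 2, "invalid_network", "edges must have two columns")
    out <- data.frame(parent = as.character(edges[[1]]),
                      child = as.character(edges[[2]]),
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (is.list(edges)) {
    gbn_assert(all(vapply(edges, length, 1L) == 2), "invalid_network",
               "each edge must be a (parent, child) pair")
    return(data.frame(parent = vapply(edges, function(e) as.character(e[[1]]), ""),
                      child = vapply(edges, function(e) as.character(e[[2]]), ""),
                      stringsAsFactors = FALSE))
  }
  gbn_abort("invalid_network", "cannot interpret edges")
}

#' Topological order of a DAG
#'
#' Kahn's algorithm with lexicographic tie-breaking, so the order is a pure
#' function of the graph (used for reproducible sampling and elimination).
#'
#' @param x a `gbn_dag` or [dbn()] object.
#' @return character vector of node names, parents before children.
#' @export
topological_order <- function(x) {
  g <- as_dag(x)
  nodes <- sort(g$nodes)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(g$edges$child)
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  avail <- sort(names(indeg)[indeg == 0])
  while (length(avail) > 0) {
    v <- avail[1]
    avail <- avail[-1]
    out <- c(out, v)
    ch <- g$edges$child[g$edges$parent == v]
    for (c_ in ch) {
      indeg[c_] <- indeg[c_] - 1L
      if (indeg[c_] == 0L) avail <- sort(c(avail, c_))
    }
  }
  gbn_assert(length(out) == length(nodes), "invalid_network",
             "graph contains a cycle")
  out
}

as_dag <- function(x) {
  if (inherits(x, "gbn_dag")) return(x)
  if (inherits(x, "gbn_dbn")) return(x$structure)
  gbn_abort("invalid_network", "expected a gbn_dag or gbn_dbn")
}

dag_parents <- function(g, node) sort(g$edges$parent[g$edges$child == node])
dag_children <- function(g, node) sort(g$edges$child[g$edges$parent == node])

#' Conditional probability table
#'
#' The table is stored as a numeric array whose first dimension indexes the
#' child's states and whose remaining dimensions index the parents' states in
#' the declared parent order. Each parent-configuration column must be a
#' probability vector (non-negative, summing to 1 within 1e-9).
#'
#' @param child child variable name.
#' @param parents character vector of parent names (possibly empty).
#' @param prob numeric array, `dim = c(r_child, r_p1, ..., r_pk)`, with
#'   complete dimnames giving the state labels; for a parentless node a named
#'   numeric vector is accepted.
#' @return an object of class `gbn_cpt`.
#' @export
cpt <- function(child, parents, prob) {
  gbn_assert(is_string(child), "invalid_network", "child must be a single name")
  parents <- as.character(parents %||% character(0))
  if (is.null(dim(prob))) {
    gbn_assert(length(parents) == 0, "invalid_network",
               "vector probabilities only allowed for parentless nodes")
    prob <- array(as.numeric(prob), dim = length(prob),
                  dimnames = list(names(prob)))
  }
  dn <- dimnames(prob)
  gbn_assert(!is.null(dn) && !any(vapply(dn, is.null, TRUE)),
             "invalid_network", "prob array must carry complete dimnames")
  gbn_assert(length(dim(prob)) == 1 + length(parents), "invalid_network",
             "prob array rank must be 1 + number of parents")
  dn <- dimnames(prob)
  d <- unname(dim(prob))
  dim(prob) <- d  # normalise: no names on the dim vector itself
  dimnames(prob) <- stats::setNames(lapply(dn, as.character), c(child, parents))
  check_cpt_rows(prob, child)
  structure(list(child = child, parents = parents, prob = prob),
            class = "gbn_cpt")
}

check_cpt_rows <- function(prob, child) {
  gbn_assert(all(prob >= -1e-12), "invalid_network",
             paste0("negative probability in CPT for ", child))
  r <- dim(prob)[1]
  m <- matrix(prob, nrow = r)
  s <- colSums(m)
  gbn_assert(all(abs(s - 1) <= 1e-9), "invalid_network",
             paste0("CPT rows for ", child, " must sum to 1 within 1e-9"))
  invisible(TRUE)
}

#' Discrete Bayesian network
#'
#' Bundles a variable roster (named list of state-label vectors), a DAG, and
#' one conditional probability table per node. Invariants checked: unique
#' variable names, at least two unique states per variable, CPT parent sets
#' exactly matching the graph's incoming edges, and acyclicity.
#'
#' @param variables named list: variable name -> character vector of states.
#' @param edges edge specification as in [dag()].
#' @param cpts list of [cpt()] objects (any order), one per variable.
#' @return an object of class `gbn_dbn` with elements `variables`,
#'   `structure` (a `gbn_dag`) and `cpts` (named list, one per node).
#' @examples
#' net <- dbn(
#'   variables = list(X = c("no", "yes")),
#'   edges = NULL,
#'   cpts = list(cpt("X", character(0),
#'                   array(c(0.7, 0.3), 2, dimnames = list(c("no", "yes")))))
#' )
#' @export
dbn <- function(variables, edges = NULL, cpts) {
  gbn_assert(is.list(variables) && !is.null(names(variables)) &&
               all(nzchar(names(variables))),
             "invalid_network", "variables must be a named list of state vectors")
  nodes <- names(variables)
  gbn_assert(!anyDuplicated(nodes), "invalid_network", "duplicate variable names")
  for (v in nodes) {
    st <- variables[[v]]
    gbn_assert(is.character(st) && length(st) >= 2 && !anyDuplicated(st) &&
                 !anyNA(st),
               "invalid_network",
               paste0("variable ", v, " needs >= 2 unique state labels"))
  }
  g <- dag(nodes, edges)
  if (inherits(cpts, "gbn_cpt")) cpts <- list(cpts)
  names(cpts) <- vapply(cpts, function(x) x$child, "")
  gbn_assert(setequal(names(cpts), nodes) && length(cpts) == length(nodes),
             "invalid_network", "need exactly one CPT per node")
  cpts <- cpts[nodes]
  for (v in nodes) {
    ct <- cpts[[v]]
    gbn_assert(setequal(ct$parents, dag_parents(g, v)),
               "invalid_network",
               paste0("CPT parents for ", v, " do not match the structure"))
    dn <- dimnames(ct$prob)
    gbn_assert(identical(dn[[1]], variables[[v]]), "invalid_network",
               paste0("CPT child states for ", v, " must match the roster"))
    for (i in seq_along(ct$parents)) {
      gbn_assert(identical(dn[[i + 1]], variables[[ct$parents[i]]]),
                 "invalid_network",
                 paste0("CPT parent states for ", v, "/", ct$parents[i],
                        " must match the roster"))
    }
  }
  structure(list(variables = variables, structure = g, cpts = cpts),
            class = "gbn_dbn")
}

#' @export
print.gbn_dbn <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$variables), "nodes,",
      nrow(x$structure$edges), "edges\n")
  for (v in names(x$variables)) {
    pa <- x$cpts[[v]]$parents
    cat("  ", v, " [", length(x$variables[[v]]), " states]",
        if (length(pa)) paste0(" <- ", paste(pa, collapse = ", ")) else "",
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.gbn_dag <- function(x, ...) {
  cat("DAG:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges) > 0)
    cat(paste0("  ", x$edges$parent, " -> ", x$edges$child, collapse = "\n"), "\n")
  invisible(x)
}

n_states <- function(net, v) length(net$variables[[v]])

check_node <- function(net, node) {
  gbn_assert(is_string(node) && node %in% names(net$variables),
             "unknown_node", paste0("unknown node: ", node))
  invisible(TRUE)
}

# Validate an evidence assignment (named character vector or named list).
check_evidence <- function(net, evidence) {
  if (is.null(evidence) || length(evidence) == 0) {
    return(stats::setNames(character(0), character(0)))
  }
  ev <- unlist(evidence)
  nms <- names(ev)
  gbn_assert(!is.null(nms) && all(nzchar(nms)), "unknown_node",
             "evidence must be a named variable -> state mapping")
  gbn_assert(!anyDuplicated(nms), "invalid_query",
             "a variable appears more than once in the evidence")
  for (v in nms) {
    check_node(net, v)
    gbn_assert(ev[[v]] %in% net$variables[[v]], "unknown_state",
               paste0("state '", ev[[v]], "' is not legal for variable ", v))
  }
  stats::setNames(as.character(ev), nms)
}

#' Markov blanket of a node
#'
#' Parents, children, and the children's other parents of `node`, per the
#' standard graphical definition. Conditioning on the blanket renders the node
#' independent of every other variable.
#'
#' @param x a `gbn_dag` or `gbn_dbn`.
#' @param node node name.
#' @return an object of class `gbn_mb_selection`: list with `target`,
#'   `blanket` (sorted character vector) and `discarded` (all remaining
#'   variables).
#' @examples
#' g <- dag(c("A", "B", "C"), list(c("A", "C"), c("B", "C")))
#' markov_blanket(g, "A")$blanket  # co-parent rule: B and C
#' @export
markov_blanket <- function(x, node) {
  g <- as_dag(x)
  gbn_assert(is_string(node) && node %in% g$nodes, "unknown_node",
             paste0("unknown node: ", node))
  pa <- dag_parents(g, node)
  ch <- dag_children(g, node)
  co <- unlist(lapply(ch, function(c_) dag_parents(g, c_)))
  blanket <- sort(setdiff(unique(c(pa, ch, co)), node))
  structure(list(target = node, blanket = blanket,
                 discarded = sort(setdiff(g$nodes, c(node, blanket)))),
            class = "gbn_mb_selection")
}

#' @export
print.gbn_mb_selection <- function(x, ...) {
  cat("Markov blanket of", x$target, "\n")
  cat("  kept:     ", paste(x$blanket, collapse = ", "), "\n")
  cat("  discarded:", paste(x$discarded, collapse = ", "), "\n")
  invisible(x)
}

# ---- CPT row-major (odometer) layout helpers -------------------------------
# External row layout: one row per parent-state combination, combinations
# enumerated in odometer order with the LAST parent varying fastest; each row
# is the probability vector over child states. Internally the array is stored
# column-major with the child index fastest, so the conversion permutes the
# parent dimensions into reverse order.

cpt_rows <- function(ct) {
  k <- length(ct$parents)
  r <- dim(ct$prob)[1]
  if (k == 0) return(matrix(as.numeric(ct$prob), nrow = 1))
  flat <- aperm(ct$prob, rev(seq_len(k + 1)))  # child last, parents reversed
  # flat dims: (p_k, ..., p_1, child) column-major => p_k fastest
  m <- matrix(as.vector(flat), ncol = r)
  m
}

cpt_from_rows <- function(child, parents, child_states, parent_states, rows) {
  rows <- as.matrix(rows)
  k <- length(parents)
  r <- length(child_states)
  q <- if (k == 0) 1L else prod(vapply(parent_states, length, 1L))
  gbn_assert(nrow(rows) == q && ncol(rows) == r, "invalid_network",
             paste0("CPT for ", child, ": expected ", q, " x ", r, " rows"))
  if (k == 0) {
    return(cpt(child, character(0),
               array(as.numeric(rows[1, ]), r, dimnames = list(child_states))))
  }
  dims_rev <- c(rev(vapply(parent_states, length, 1L)), r)
  arr <- array(as.vector(rows), dim = dims_rev)  # (p_k, ..., p_1, child)
  arr <- aperm(arr, c(k + 1, seq(k, 1)))         # (child, p_1, ..., p_k)
  dimnames(arr) <- c(list(child_states), parent_states)
  cpt(child, parents, arr)
}
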