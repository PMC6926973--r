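# Sensitivity-to-findings: how much observing each node would inform a
# target, measured three ways (mutual information in bits, percent of the
# target's entropy removed, and the variance of beliefs). Pairwise joints are
# obtained by exact inference per (target, node) pair, keeping memory bounded.

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Marginal Shannon entropy of a node
#'
#' Base-2 entropy of the node's no-evidence marginal, with `0 log 0 := 0`.
#'
#' @param net a [dbn()] network.
#' @param node node name.
#' @return entropy in bits.
#' @export
node_entropy <- function(net, node) {
  check_node(net, node)
  entropy_bits(infer_posterior(net, node))
}

# Exact pairwise joint P(target, node) as a matrix (target states x node
# states), assembled from P(node) and P(target | node = f) per state.
pair_joint <- function(net, target, node) {
  ts <- net$variables[[target]]
  ns <- net$variables[[node]]
  if (target == node) {
    p <- infer_posterior(net, target)
    return(diag(p, nrow = length(ts)))
  }
  pn <- infer_posterior(net, node)
  J <- matrix(0, nrow = length(ts), ncol = length(ns),
              dimnames = list(ts, ns))
  for (j in seq_along(ns)) {
    if (pn[j] > 0) {
      ev <- stats::setNames(ns[j], node)
      J[, j] <- infer_posterior(net, target, ev) * pn[j]
    }
  }
  J
}

#' Mutual information between the target and another node
#'
#' `I(target; node)` in bits, computed from the exact pairwise joint. The
#' self-pair returns the target's entropy (`I(X; X) = H(X)`).
#'
#' @param net a [dbn()] network.
#' @param target,node node names.
#' @return mutual information in bits.
#' @export
mutual_information <- function(net, target, node) {
  check_node(net, target)
  check_node(net, node)
  if (target == node) return(node_entropy(net, target))
  J <- pair_joint(net, target, node)
  pi_ <- rowSums(J)
  qj <- colSums(J)
  pos <- J > 0
  sum(J[pos] * log2(J[pos] / (outer(pi_, qj)[pos])))
}

#' Variance of beliefs
#'
#' Expected squared change of the target's belief vector upon observing the
#' node, weighted by the posterior belief:
#' `sum_f P(f) sum_s P(s | f) (P(s | f) - P(s))^2`.
#' For the self-pair this reduces to the closed form `sum_s p_s (1 - p_s)^2`.
#'
#' @inheritParams mutual_information
#' @return a non-negative real.
#' @export
variance_of_beliefs <- function(net, target, node) {
  check_node(net, target)
  check_node(net, node)
  if (target == node) {
    p <- infer_posterior(net, target)
    return(sum(p * (1 - p)^2))
  }
  J <- pair_joint(net, target, node)
  ps <- rowSums(J)          # P(target = s)
  pf <- colSums(J)          # P(node = f)
  v <- 0
  for (j in seq_along(pf)) {
    if (pf[j] > 0) {
      post <- J[, j] / pf[j]
      v <- v + pf[j] * sum(post * (post - ps)^2)
    }
  }
  unname(v)
}

#' Sensitivity of a target to findings at every node
#'
#' One row per node: mutual information with the target (bits), the
#' percentage of the target's entropy that observing the node removes
#' (`100 * MI / H(target)`), and the variance of beliefs. The target's
#' self-row comes first (its entropy percentage is exactly 100); the
#' remaining rows are sorted by mutual information, descending, ties broken
#' lexicographically by node name.
#'
#' @param net a [dbn()] network.
#' @param target target node name (must have positive marginal entropy).
#' @return data frame of class `gbn_sensitivity` with columns `node`,
#'   `mutual_information`, `entropy_percent`, `variance_of_beliefs`.
#' @export
sensitivity_to_findings <- function(net, target) {
  check_node(net, target)
  H <- node_entropy(net, target)
  gbn_assert(H > 0, "degenerate_target",
             "target has zero marginal entropy; entropy percentages undefined")
  nodes <- names(net$variables)
  rows <- lapply(nodes, function(v) {
    mi <- mutual_information(net, target, v)
    data.frame(node = v,
               mutual_information = mi,
               entropy_percent = 100 * mi / H,
               variance_of_beliefs = variance_of_beliefs(net, target, v),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  self <- df$node == target
  rest <- df[!self, , drop = FALSE]
  rest <- rest[order(-rest$mutual_information, rest$node), , drop = FALSE]
  out <- rbind(df[self, , drop = FALSE], rest)
  rownames(out) <- NULL
  class(out) <- c("gbn_sensitivity", "data.frame")
  out
}

#' Write a sensitivity report as TSV
#'
#' Four tab-separated columns (`node`, `mutual_information`,
#' `entropy_percent`, `variance_of_beliefs`), self-row first.
#'
#' @param x a [sensitivity_to_findings()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
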