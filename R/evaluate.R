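# Cross-validated classifier comparison: accuracy, class-frequency-weighted
# F-measure, and class-frequency-weighted one-vs-rest AUC (midrank ties),
# for the full network classifier, its Markov-blanket restriction, and a
# naive-Bayes baseline.

#' Stratified k-fold partition
#'
#' Rows are shuffled within each class and dealt cyclically across folds in
#' one continuous pass, so fold sizes differ by at most one row overall and
#' per-class proportions are within one row of the global proportions.
#' Deterministic for a fixed seed.
#'
#' @param data data frame.
#' @param class_var name of the class column used for stratification.
#' @param k number of folds (2 <= k <= nrow(data)).
#' @param seed integer seed.
#' @return list of `k` elements, each `list(train = <row indices>,
#'   test = <row indices>)`.
#' @export
stratified_kfold <- function(data, class_var, k, seed) {
  n <- nrow(data)
  gbn_assert(k >= 2 && k <= n, "stratification",
             "k must be between 2 and the number of rows")
  y <- as.character(data[[class_var]])
  counts <- table(y)
  if (any(counts < k)) {
    warning("stratified_kfold: class(es) ",
            paste(names(counts)[counts < k], collapse = ", "),
            " have fewer than k rows; their rows cover only some folds")
  }
  idx <- with_seed(seed, {
    unlist(lapply(sort(unique(y)), function(cl) sample(which(y == cl))),
           use.names = FALSE)
  })
  fold_of <- rep_len(seq_len(k), n)
  lapply(seq_len(k), function(f) {
    test <- idx[fold_of == f]
    list(train = sort(setdiff(idx, test)), test = sort(test))
  })
}

#' Posterior prediction for one instance
#'
#' Posterior of the class variable given the instance's values on the
#' variables the model uses (for a blanket-restricted model, only blanket
#' columns are read). If the evidence has probability zero under the model,
#' prediction falls back to the same network with Laplace-smoothed (alpha =
#' 1) uniform mixing, i.e. the posterior is recomputed after mixing each CPT
#' row with a uniform pseudo-count.
#'
#' @param net a [dbn()] network (the classifier).
#' @param class_var class variable name.
#' @param row single-row data frame (or named character vector) of evidence.
#' @return named probability vector over the class states.
#' @export
classify_instance <- function(net, class_var, row) {
  check_node(net, class_var)
  use <- setdiff(names(net$variables), class_var)
  rowv <- unlist(row)
  ev <- rowv[intersect(use, names(rowv))]
  tryCatch(
    infer_posterior(net, class_var, ev),
    gbn_inconsistent_evidence = function(c_) {
      infer_posterior(smooth_network(net), class_var, ev)
    })
}

# Mix every CPT row with a uniform pseudo-count (Laplace alpha on the
# probability scale, behaving like alpha = 1 at unit row weight); used only
# as a zero-probability-evidence fallback at prediction time.
smooth_network <- function(net, eps = 1e-3) {
  cpts <- lapply(net$cpts, function(ct) {
    r <- dim(ct$prob)[1]
    prob <- (ct$prob + eps) / (1 + r * eps)
    cpt(ct$child, ct$parents, prob)
  })
  dbn(net$variables,
      if (nrow(net$structure$edges)) net$structure$edges else NULL, cpts)
}

# Vectorised batch prediction when every non-class model variable is
# observed: the class posterior is proportional to the joint, a product of
# CPT entries, accumulated in log space per row.
classify_dataset <- function(net, class_var, data) {
  vars <- names(net$variables)
  use <- setdiff(vars, class_var)
  gbn_assert(all(use %in% names(data)), "degenerate_input",
             "data must provide every model variable except the class")
  n <- nrow(data)
  states <- net$variables[[class_var]]
  idx <- lapply(stats::setNames(vars, vars), function(v) {
    if (v == class_var) return(rep(NA_integer_, n))
    m <- match(as.character(data[[v]]), net$variables[[v]])
    gbn_assert(!anyNA(m), "unknown_state",
               paste0("column ", v, " contains states outside the model roster"))
    m
  })
  logp <- matrix(0, nrow = n, ncol = length(states))
  for (s in seq_along(states)) {
    idx[[class_var]] <- rep(s, n)
    acc <- numeric(n)
    for (v in vars) {
      ct <- net$cpts[[v]]
      lin <- idx[[v]]
      stride <- n_states(net, v)
      for (pa in ct$parents) {
        lin <- lin + (idx[[pa]] - 1L) * stride
        stride <- stride * n_states(net, pa)
      }
      acc <- acc + log(as.vector(ct$prob)[lin])
    }
    logp[, s] <- acc
  }
  bad <- !is.finite(apply(logp, 1, max))
  post <- matrix(0, nrow = n, ncol = length(states),
                 dimnames = list(NULL, states))
  ok <- which(!bad)
  if (length(ok) > 0) {
    mx <- apply(logp[ok, , drop = FALSE], 1, max)
    w <- exp(logp[ok, , drop = FALSE] - mx)
    post[ok, ] <- w / rowSums(w)
  }
  if (any(bad)) {
    sm <- smooth_network(net)
    for (i in which(bad)) {
      post[i, ] <- classify_instance(sm, class_var, data[i, use, drop = FALSE])
    }
  }
  post
}

#' Bundle predictions with their ground truth
#'
#' @param truth character vector of true class states.
#' @param prob numeric matrix, one row per record, columns named by class
#'   state, each row summing to 1 within 1e-9.
#' @return an object of class `gbn_prediction_records`.
#' @export
prediction_records <- function(truth, prob) {
  prob <- as.matrix(prob)
  gbn_assert(length(truth) == nrow(prob), "degenerate_input",
             "truth length must match the number of probability rows")
  gbn_assert(!is.null(colnames(prob)), "degenerate_input",
             "probability columns must be named by class state")
  gbn_assert(all(abs(rowSums(prob) - 1) <= 1e-9), "degenerate_input",
             "each probability row must sum to 1 within 1e-9")
  structure(list(truth = as.character(truth), prob = prob,
                 states = colnames(prob)),
            class = "gbn_prediction_records")
}

#' Classification metrics from pooled prediction records
#'
#' Accuracy is the percentage of records whose argmax state equals the truth
#' (ties resolved to the lexicographically first tied state). F-measure is
#' the class-frequency-weighted mean of per-class F1 (`macro = TRUE` gives
#' the unweighted mean). AUC is the one-vs-rest ranking AUC per class with
#' midrank tie handling, averaged with the same weights.
#'
#' @param records a [prediction_records()] object.
#' @param macro use unweighted (macro) averaging instead of
#'   class-frequency weighting.
#' @return list with `accuracy` (percent), `f_measure`, `auc`.
#' @export
compute_metrics <- function(records, macro = FALSE) {
  gbn_assert(inherits(records, "gbn_prediction_records"), "degenerate_input",
             "records must be prediction_records()")
  truth <- records$truth
  prob <- records$prob
  states <- records$states
  n <- length(truth)
  gbn_assert(n >= 1, "degenerate_input", "need at least one record")
  pred <- vapply(seq_len(n), function(i) {
    p <- prob[i, ]
    sort(states[p == max(p)])[1]
  }, "")
  accuracy <- 100 * mean(pred == truth)
  observed <- sort(unique(truth))
  wts <- vapply(observed, function(cl) mean(truth == cl), 1.0)
  if (macro) wts <- rep(1 / length(observed), length(observed))
  f1s <- vapply(observed, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 1.0)
  f_measure <- sum(wts * f1s)
  gbn_assert(length(observed) >= 2, "degenerate_input",
             "AUC undefined with a single observed class")
  aucs <- vapply(observed, function(cl) {
    score <- prob[, cl]
    pos <- truth == cl
    n1 <- sum(pos)
    n0 <- n - n1
    r <- rank(score, ties.method = "average")
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, 1.0)
  auc <- sum(wts * aucs)
  list(accuracy = accuracy, f_measure = f_measure, auc = auc)
}

train_model <- function(model, data, class_var, config) {
  config <- as_learner_config(config)
  if (model == "gbn") {
    learn_structure(data, config)
  } else if (model == "gbn-mb") {
    gbn_mb_classifier(data, class_var, config)
  } else if (model == "nb") {
    feats <- setdiff(names(data), class_var)
    g <- dag(c(class_var, feats),
             data.frame(parent = class_var, child = feats,
                        stringsAsFactors = FALSE))
    estimate_cpts(g, data, smoothing_alpha = config$smoothing_alpha,
                  variables = states_from_data(data))
  } else {
    gbn_abort("config", paste0("unknown model: ", model))
  }
}

predict_model <- function(fit, class_var, data) {
  net <- if (inherits(fit, "gbn_mb_classifier")) fit$net else fit
  use <- setdiff(names(net$variables), class_var)
  classify_dataset(net, class_var, data[, c(use), drop = FALSE])
}

#' Cross-validated model comparison
#'
#' For each requested model: train on every fold's training split, score the
#' held-out split, pool all held-out predictions, and compute the metrics
#' once on the pooled records. Class rosters are fixed from the full dataset
#' so every fold predicts over the same states. Deterministic for a fixed
#' seed.
#'
#' @param data categorical data frame (clean).
#' @param class_var class column name.
#' @param models subset of `c("gbn", "gbn-mb", "nb")`.
#' @param k number of folds.
#' @param seed integer seed (drives the fold partition and any restarts).
#' @param config a [learner_config()] or argument list.
#' @param macro passed to [compute_metrics()].
#' @return data frame of class `gbn_evaluation` with one row per model:
#'   `model`, `accuracy`, `f_measure`, `auc`, `folds`, `seed`. The pooled
#'   prediction records are attached as `attr(x, "records")`.
#' @export
evaluate_models <- function(data, class_var, models = c("gbn", "gbn-mb", "nb"),
                            k = 10L, seed = 1L, config = learner_config(),
                            macro = FALSE) {
  check_data_clean(data)
  gbn_assert(class_var %in% names(data), "unknown_node",
             paste0("class variable ", class_var, " not in data"))
  config <- as_learner_config(config)
  # fix every column's state roster from the full dataset, so fold models
  # share one state space even when a fold's training split misses a state
  rosters <- states_from_data(data)
  for (v in names(data)) data[[v]] <- factor(as.character(data[[v]]),
                                             levels = rosters[[v]])
  folds <- stratified_kfold(data, class_var, k, seed)
  states <- rosters[[class_var]]
  all_records <- list()
  rows <- lapply(models, function(model) {
    prob <- matrix(NA_real_, nrow = nrow(data), ncol = length(states),
                   dimnames = list(NULL, states))
    for (f in folds) {
      fit <- train_model(model, data[f$train, , drop = FALSE], class_var, config)
      p <- predict_model(fit, class_var, data[f$test, , drop = FALSE])
      prob[f$test, colnames(p)] <- p
    }
    gbn_assert(!anyNA(prob), "internal_consistency",
               "cross-validation did not cover every row exactly once")
    rec <- prediction_records(as.character(data[[class_var]]), prob)
    all_records[[model]] <<- rec
    m <- compute_metrics(rec, macro = macro)
    data.frame(model = model, accuracy = m$accuracy, f_measure = m$f_measure,
               auc = m$auc, folds = as.integer(k), seed = as.integer(seed),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gbn_evaluation", "data.frame")
  attr(out, "records") <- all_records
  out
}

#' Write an evaluation table as TSV
#'
#' @param x an [evaluate_models()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_evaluation_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
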