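# Internal factor algebra for variable elimination. A factor is a list with
#   vars   character vector of variable names (possibly empty)
#   states named list of state labels, one entry per var
#   tab    numeric array with dim = lengths of states (a plain scalar when
#          vars is empty)
# Tables are kept as dense arrays; at the network sizes this package targets
# (tens of nodes, a handful of states each, small parent sets) that is both
# the simplest and the fastest representation in R.

new_factor <- function(vars, states, tab) {
  if (length(vars) == 0) {
    return(list(vars = character(0), states = list(), tab = as.numeric(tab)[1]))
  }
  dims <- vapply(states, length, 1L)
  tab <- array(as.numeric(tab), dim = dims)
  list(vars = vars, states = states, tab = tab)
}

factor_from_cpt <- function(ct) {
  dn <- dimnames(ct$prob)
  new_factor(c(ct$child, ct$parents), stats::setNames(dn, c(ct$child, ct$parents)),
             ct$prob)
}

# Condition on var = state; the variable's dimension is dropped.
factor_reduce <- function(f, var, state) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  k <- match(state, f$states[[i]])
  idx <- rep(list(TRUE), length(f$vars))
  idx[[i]] <- k
  sub <- do.call(`[`, c(list(f$tab), idx, list(drop = FALSE)))
  new_factor(f$vars[-i], f$states[-i], sub)
}

# Sum out one variable.
factor_marginalize <- function(f, var) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  n <- length(f$vars)
  if (n == 1) return(new_factor(character(0), list(), sum(f$tab)))
  ord <- c(seq_len(n)[-i], i)
  tab <- aperm(f$tab, ord)
  d <- dim(f$tab)
  tab <- matrix(tab, ncol = d[i])
  new_factor(f$vars[-i], f$states[-i], rowSums(tab))
}

# Pointwise product, aligning and broadcasting dimensions.
factor_product <- function(a, b) {
  if (length(a$vars) == 0) {
    out <- b
    out$tab <- out$tab * a$tab
    return(out)
  }
  if (length(b$vars) == 0) {
    out <- a
    out$tab <- out$tab * b$tab
    return(out)
  }
  allv <- union(a$vars, b$vars)
  states <- c(a$states, b$states[setdiff(b$vars, a$vars)])
  states <- states[allv]
  ta <- expand_factor_tab(a, allv, states)
  tb <- expand_factor_tab(b, allv, states)
  new_factor(allv, states, ta * tb)
}

expand_factor_tab <- function(f, allv, states) {
  miss <- setdiff(allv, f$vars)
  tab <- f$tab
  vars2 <- f$vars
  if (length(miss) > 0) {
    dm <- vapply(states[miss], length, 1L)
    tab <- array(rep(as.vector(tab), times = prod(dm)), dim = c(dim(f$tab), dm))
    vars2 <- c(f$vars, miss)
  }
  perm <- match(allv, vars2)
  if (length(perm) > 1) tab <- aperm(tab, perm)
  tab
}
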