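# Typed error conditions. Every user-facing failure mode raises a condition of
# class "gbn_<kind>" so callers (and the pipeline driver) can branch on the kind
# rather than matching message strings.

gbn_abort <- function(kind, msg, ...) {
  cnd <- errorCondition(msg, ..., class = c(paste0("gbn_", kind), "gbn_error"))
  stop(cnd)
}

gbn_assert <- function(ok, kind, msg, ...) {
  if (!isTRUE(ok)) gbn_abort(kind, msg, ...)
  invisible(TRUE)
}
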