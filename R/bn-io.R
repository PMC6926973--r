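# Network serialization.
#
# JSON schema:
#   {
#     "variables": [{"name": "...", "states": ["...", ...]}, ...],
#     "edges":     [{"parent": "...", "child": "..."}, ...],
#     "cpts":      [{"child": "...", "parents": [...],
#                    "table": [[p, ...], ...]}, ...]
#   }
# Each CPT "table" is row-major: one row per parent-state combination, the
# combinations enumerated in odometer order with the LAST parent varying
# fastest, and each row a probability vector over the child's states.

#' Write a network to JSON
#'
#' @param net a [dbn()] network.
#' @param path file path; `.json` conventional.
#' @return `path`, invisibly.
#' @seealso [read_dbn_json()], [write_dbn_xmlbif()]
#' @export
write_dbn_json <- function(net, path) {
  obj <- list(
    variables = lapply(names(net$variables), function(v) {
      list(name = v, states = net$variables[[v]])
    }),
    edges = lapply(seq_len(nrow(net$structure$edges)), function(i) {
      list(parent = net$structure$edges$parent[i],
           child = net$structure$edges$child[i])
    }),
    cpts = lapply(names(net$cpts), function(v) {
      ct <- net$cpts[[v]]
      rows <- cpt_rows(ct)
      list(child = v, parents = as.list(ct$parents),
           table = lapply(seq_len(nrow(rows)), function(i) as.numeric(rows[i, ])))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a network from JSON
#'
#' Inverse of [write_dbn_json()]; all structural invariants are re-validated
#' on construction.
#'
#' @param path file path to a JSON file in the package's network schema.
#' @return a [dbn()] network.
#' @export
read_dbn_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  variables <- stats::setNames(
    lapply(obj$variables, function(v) unlist(v$states)),
    vapply(obj$variables, function(v) v$name, "")
  )
  edges <- if (length(obj$edges) == 0) NULL else
    data.frame(parent = vapply(obj$edges, function(e) e$parent, ""),
               child = vapply(obj$edges, function(e) e$child, ""),
               stringsAsFactors = FALSE)
  cpts <- lapply(obj$cpts, function(ce) {
    parents <- as.character(unlist(ce$parents) %||% character(0))
    rows <- do.call(rbind, lapply(ce$table, unlist))
    cpt_from_rows(ce$child, parents, variables[[ce$child]],
                  stats::setNames(variables[parents], parents), rows)
  })
  dbn(variables, edges, cpts)
}

#' Export a network to XMLBIF
#'
#' Interchange format readable by common Bayesian-network GUIs. Requires the
#' suggested `xml2` package.
#'
#' @param net a [dbn()] network.
#' @param path output file path.
#' @param name network name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_dbn_xmlbif <- function(net, path, name = "network") {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    gbn_abort("missing_dependency", "xml2 is required for XMLBIF export")
  }
  doc <- xml2::xml_new_root("BIF", VERSION = "0.3")
  nw <- xml2::xml_add_child(doc, "NETWORK")
  xml2::xml_add_child(nw, "NAME", name)
  for (v in names(net$variables)) {
    var <- xml2::xml_add_child(nw, "VARIABLE", TYPE = "nature")
    xml2::xml_add_child(var, "NAME", v)
    for (s in net$variables[[v]]) xml2::xml_add_child(var, "OUTCOME", s)
  }
  for (v in names(net$cpts)) {
    ct <- net$cpts[[v]]
    def <- xml2::xml_add_child(nw, "DEFINITION")
    xml2::xml_add_child(def, "FOR", v)
    for (pa in ct$parents) xml2::xml_add_child(def, "GIVEN", pa)
    rows <- cpt_rows(ct)
    xml2::xml_add_child(def, "TABLE",
                        paste(apply(rows, 1, paste, collapse = " "),
                              collapse = " "))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
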