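#' Serialize an epsilon machine
#'
#' JSON schema: `{states: [{id, suffixes, pi}], transitions: [{from,
#' symbol, to, prob}], Cmu}`.
#'
#' @param m an `epsilon_machine`.
#' @return a JSON string (class `json`).
#' @export
machine_json <- function(m) {
  stopifnot(inherits(m, "epsilon_machine"))
  pi <- if (is.null(m$pi)) rep(NA_real_, length(m$states)) else m$pi
  states <- lapply(seq_along(m$states), function(i) {
    s <- m$states[[i]]
    list(id = s$id, suffixes = I(s$suffixes), pi = unname(pi[i]))
  })
  jsonlite::toJSON(list(states = states, transitions = m$trans,
                        Cmu = statistical_complexity(m)),
                   auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @rdname machine_json
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_machine_json <- function(m, path) {
  writeLines(machine_json(m), path)
  invisible(path)
}

#' GraphViz DOT export of an epsilon machine
#'
#' Writes the machine as a directed graph with edges labeled
#' `"symbol | prob"`, ready for `dot -Tpdf` rendering of state diagrams.
#'
#' @param m an `epsilon_machine`.
#' @param path output file path.
#' @param name graph name.
#' @return `path`, invisibly.
#' @export
write_machine_dot <- function(m, path, name = "epsilon_machine") {
  stopifnot(inherits(m, "epsilon_machine"))
  ids <- vapply(m$states, `[[`, integer(1), "id")
  lines <- c(sprintf("digraph %s {", name),
             "  rankdir=LR;",
             "  node [shape=circle];",
             sprintf("  \"%d\";", ids),
             sprintf("  \"%d\" -> \"%d\" [label=\"%d | %.3f\"];",
                     m$trans$from, m$trans$to, m$trans$symbol, m$trans$prob),
             "}")
  writeLines(lines, path)
  invisible(path)
}
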