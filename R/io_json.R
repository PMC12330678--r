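#' Read a traced root system from its JSON representation
#'
#' The JSON schema is a flat lossless encoding of the traced arborescence:
#' ```
#' {"metadata": {...}, "scale": float|null,
#'  "nodes": [{"id": int, "x": float, "y": float,
#'             "parent": int|null, "order": int}, ...]}
#' ```
#' Exactly one node has `"parent": null` (the hypocotyl base). Unknown
#' metadata keys are passed through uninterpreted.
#'
#' @param path path to a `.json` file.
#' @return A validated [root_graph()].
#' @seealso [write_root_json()], [read_rsml()]
#' @export
read_root_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyMatrix = FALSE)
  if (is.null(obj$nodes) || NROW(obj$nodes) == 0L) {
    stop("root graph schema: no nodes in ", path, call. = FALSE)
  }
  nodes <- as.data.frame(obj$nodes)
  need <- c("id", "x", "y", "parent", "order")
  miss <- setdiff(need, names(nodes))
  if (length(miss) > 0L) {
    stop("root graph schema: nodes lack field(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (fld in c("x", "y")) {
    v <- nodes[[fld]]
    if (!is.numeric(v) || anyNA(suppressWarnings(as.numeric(v)))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1L]
      stop("root graph schema: non-numeric coordinates at node ",
           nodes$id[bad], call. = FALSE)
    }
  }
  meta <- obj$metadata %||% list()
  root_graph(nodes, scale = obj$scale %||% 1, metadata = as.list(meta))
}

#' Write a traced root system to JSON
#'
#' Emits the schema documented in [read_root_json()] with full-precision
#' coordinates, so that a write/read round trip reproduces the graph exactly
#' (ids, coordinates, orders, scale and metadata).
#'
#' @param graph a [root_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_root_json <- function(graph, path) {
  validate_root_graph(graph)
  obj <- list(
    metadata = graph$metadata,
    scale = graph$scale,
    nodes = graph$nodes
  )
  json <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null", null = "null",
                           pretty = FALSE)
  ok <- tryCatch({ writeLines(json, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write ", path, call. = FALSE)
  invisible(path)
}
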