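#' Construct a speech graph
#'
#' A speech graph is a directed, simple (no self-loops, no parallel edges),
#' positive-integer-weighted graph over string-labeled nodes. Repetition of a
#' relation is encoded in the edge weight: the first occurrence weighs 1 and
#' each repetition adds 1.
#'
#' @param edges Data frame with columns `from`, `to`, `weight` (or zero rows).
#' @param nodes Character vector of node labels (superset of edge endpoints;
#'   isolated nodes allowed).
#' @param graph_type `"structural"` or `"semantic"`.
#' @param provenance Optional named list (participant/task/prompt/window ids).
#' @return An object of class `speech_graph`.
#' @export
speech_graph <- function(edges, nodes, graph_type, provenance = NULL) {
  graph_type <- match.arg(graph_type, c("structural", "semantic"))
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        weight = integer(), stringsAsFactors = FALSE)
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.integer(edges$weight)
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  if (any(edges$weight < 1L)) stop("edge weights must be >= 1")
  if (anyDuplicated(paste0(edges$from, "\r", edges$to))) {
    stop("parallel edges are not allowed; encode repetition in weight")
  }
  nodes <- unique(as.character(nodes))
  missing <- setdiff(c(edges$from, edges$to), nodes)
  if (length(missing)) stop("edge endpoints missing from node set: ",
                            paste(missing, collapse = ", "))
  structure(list(graph_type = graph_type, nodes = nodes, edges = edges,
                 provenance = provenance),
            class = "speech_graph")
}

#' @export
print.speech_graph <- function(x, ...) {
  cat("<speech_graph> ", x$graph_type, ": ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges (total weight ", sum(x$edges$weight), ")\n",
      sep = "")
  invisible(x)
}

# Tally ordered pairs into a weighted simple edge table.
.tally_edges <- function(from, to) {
  keep <- from != to  # self-loop skip
  from <- from[keep]; to <- to[keep]
  if (!length(from)) {
    return(data.frame(from = character(), to = character(),
                      weight = integer(), stringsAsFactors = FALSE))
  }
  key <- paste0(from, "\r", to)
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  data.frame(from = vapply(parts, `[[`, character(1), 1L),
             to = vapply(parts, `[[`, character(1), 2L),
             weight = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Build a structural (sequential) speech graph
#'
#' Connects each content lemma to the next one in spoken order, across
#' utterance boundaries: nodes are the distinct lemmas, and each ordered
#' adjacency contributes 1 to the weight of its edge. Identical consecutive
#' lemmas (would-be self-loops, e.g. disfluent repetitions) are skipped.
#'
#' @param lemmas Character vector, typically from [content_lemmas()] or a
#'   moving window over it.
#' @param provenance Optional provenance list.
#' @return A `structural` [speech_graph()].
#' @export
build_structural <- function(lemmas, provenance = NULL) {
  lemmas <- as.character(lemmas)
  n <- length(lemmas)
  edges <- if (n >= 2L) .tally_edges(lemmas[-n], lemmas[-1L]) else NULL
  speech_graph(edges, nodes = unique(lemmas), graph_type = "structural",
               provenance = provenance)
}

#' Build a semantic (action-predication) speech graph
#'
#' For every SRL frame in every utterance, emits predication edges from the
#' predicate lemma to each present core argument label (A0, A1, A2), and
#' action edges from the actor label (A0) to each undergoer label (A1, A2)
#' when both endpoints are present. Edges are formed only within an
#' utterance; repeated relations anywhere in the scope accumulate edge
#' weight. Nodes are all predicate and argument labels used. Relations whose
#' two endpoints carry the same label are skipped (self-loop rule).
#'
#' @param utterances List of [speech_utterance()] objects (a whole response
#'   or a moving window of utterances).
#' @param provenance Optional provenance list.
#' @param stoplist Lexical exclusion list passed to [argument_label()].
#' @return A `semantic` [speech_graph()].
#' @export
build_semantic <- function(utterances, provenance = NULL,
                           stoplist = filled_pauses()) {
  rel <- lapply(utterances, .semantic_relations, stoplist = stoplist)
  .semantic_from_relations(rel, provenance)
}

# Relation instances (ordered endpoint pairs) and node labels contributed by
# one utterance's frames. Factored out so moving windows can pool
# per-utterance relation multisets without re-deriving argument labels.
.semantic_relations <- function(u, stoplist = filled_pauses()) {
  from <- character(); to <- character(); nodes <- character()
  for (fr in u$frames) {
    pred <- tolower(fr$predicate_lemma)
    labs <- vapply(fr$args, argument_label, character(1),
                   utterance = u, stoplist = stoplist)
    nodes <- c(nodes, pred, unname(labs))
    for (lab in labs) {            # predication: predicate -> argument
      from <- c(from, pred); to <- c(to, lab)
    }
    if ("A0" %in% names(labs)) {   # action: actor -> undergoer(s)
      for (ug in intersect(c("A1", "A2"), names(labs))) {
        from <- c(from, labs[["A0"]]); to <- c(to, labs[[ug]])
      }
    }
  }
  list(from = from, to = to, nodes = nodes)
}

.semantic_from_relations <- function(relations, provenance = NULL) {
  from <- unlist(lapply(relations, `[[`, "from"), use.names = FALSE)
  to <- unlist(lapply(relations, `[[`, "to"), use.names = FALSE)
  nodes <- unlist(lapply(relations, `[[`, "nodes"), use.names = FALSE)
  speech_graph(.tally_edges(as.character(from), as.character(to)),
               nodes = unique(as.character(nodes)),
               graph_type = "semantic", provenance = provenance)
}

#' Convert a speech graph to an igraph object
#'
#' Edge weights become the `weight` edge attribute; `graph_type` and any
#' provenance entries become graph attributes.
#'
#' @param graph A [speech_graph()].
#' @return An `igraph` directed graph.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "speech_graph"))
  g <- igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                     vertices = data.frame(name = graph$nodes))
  g <- igraph::set_graph_attr(g, "graph_type", graph$graph_type)
  for (nm in names(graph$provenance)) {
    g <- igraph::set_graph_attr(g, nm, as.character(graph$provenance[[nm]]))
  }
  g
}

.sorted_edges <- function(edges) {
  edges[order(edges$from, edges$to), , drop = FALSE]
}

#' Export a speech graph to disk
#'
#' Supported formats: GraphML (with integer `weight` edge attribute and
#' `graph_type` graph attribute) and a weighted edge-list TSV with columns
#' `source`, `target`, `weight` (plus a commented node list so isolated
#' nodes round-trip). [import_graph()] inverts either format exactly.
#'
#' @param graph A [speech_graph()].
#' @param path Output path.
#' @param format `"graphml"` or `"tsv"`.
#' @return Invisibly `path`.
#' @export
export_graph <- function(graph, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(graph), path, format = "graphml")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# graph_type=", graph$graph_type), con)
    writeLines(paste0("# nodes=", paste(graph$nodes, collapse = "\t")), con)
    writeLines("source\ttarget\tweight", con)
    e <- .sorted_edges(graph$edges)
    if (nrow(e)) {
      writeLines(paste(e$from, e$to, e$weight, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Import a speech graph written by [export_graph()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"tsv"`.
#' @return A [speech_graph()].
#' @export
import_graph <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(from = el$from, to = el$to,
                        weight = as.integer(el$weight),
                        stringsAsFactors = FALSE)
    gt <- igraph::graph_attr(g, "graph_type")
    speech_graph(edges, nodes = igraph::V(g)$name,
                 graph_type = if (is.null(gt)) "structural" else gt)
  } else {
    lines <- readLines(path, warn = FALSE)
    gt <- sub("^# graph_type=", "", lines[1])
    nodes_line <- sub("^# nodes=", "", lines[2])
    nodes <- if (nzchar(nodes_line)) {
      strsplit(nodes_line, "\t", fixed = TRUE)[[1]]
    } else character()
    body <- lines[-(1:3)]
    edges <- if (length(body)) {
      parts <- strsplit(body, "\t", fixed = TRUE)
      data.frame(from = vapply(parts, `[[`, character(1), 1L),
                 to = vapply(parts, `[[`, character(1), 2L),
                 weight = as.integer(vapply(parts, `[[`, character(1), 3L)),
                 stringsAsFactors = FALSE)
    } else NULL
    speech_graph(edges, nodes = nodes, graph_type = gt)
  }
}
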