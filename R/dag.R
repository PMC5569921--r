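# Workflow DAG: nodes are task sections, edges are IO-connections (data
# flow) plus forced dependencies (ordering without data flow). The planner
# partitions the DAG into stages by longest-path depth, so every stage can
# run with maximal concurrency while all edges are respected.

new_workflow_graph <- function(nodes, edges, payload) {
  structure(list(nodes = nodes, edges = edges, payload = payload),
            class = "workflow_graph")
}

#' Build the workflow DAG from a concrete configuration
#'
#' Nodes are exactly the task sections; edges are every IO-connection
#' (kind `"io"`) plus every forced dependency (kind `"forced"`). Both kinds
#' constrain scheduling identically; the kind is kept for reporting.
#' Replacing one task section in the configuration changes only the edges
#' incident to that node.
#'
#' @param config a concrete (sample-expanded) `workflow_config` that passes
#'   [validate_config()].
#' @param registry named list of `component_definition`s covering every
#'   component the config references.
#' @return a `workflow_graph` with fields `nodes` (task names), `edges`
#'   (data frame `from`/`to`/`kind`) and `payload` (task name ->
#'   list(task, component)).
#' @export
build_graph <- function(config, registry) {
  stopifnot(inherits(config, "workflow_config"))
  nodes <- names(config$tasks)
  edges <- unique(config_edges(config))
  bad <- edges[!(edges$from %in% nodes & edges$to %in% nodes), , drop = FALSE]
  if (nrow(bad)) {
    abort_validation(sprintf("dangling dependency edge(s): %s",
                             paste(sprintf("%s -> %s", bad$from, bad$to), collapse = ", ")))
  }
  cyc <- find_cycle(nodes, edges)
  if (!is.null(cyc)) {
    abort_validation(sprintf("workflow is not acyclic; cycle: %s",
                             paste(cyc, collapse = " -> ")))
  }
  payload <- lapply(nodes, function(tn) {
    task <- config$tasks[[tn]]
    comp <- registry[[task$component_name]]
    if (is.null(comp)) {
      abort_validation(sprintf("task %s references unknown component '%s'",
                               tn, task$component_name))
    }
    list(task = task, component = comp)
  })
  names(payload) <- nodes
  new_workflow_graph(nodes, edges, payload)
}

#' @export
print.workflow_graph <- function(x, ...) {
  cat(sprintf("<workflow_graph> %d node(s), %d edge(s)\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    cat(sprintf("  %s -> %s [%s]", x$edges$from, x$edges$to, x$edges$kind), sep = "\n")
  }
  invisible(x)
}

# first cycle reachable in DFS order, as a task-name path c(A, B, ..., A);
# NULL when acyclic
find_cycle <- function(nodes, edges) {
  adj <- split(edges$to, factor(edges$from, levels = nodes))
  color <- stats::setNames(rep("white", length(nodes)), nodes)
  stack <- character()
  result <- NULL
  visit <- function(v) {
    if (!is.null(result)) return()
    color[v] <<- "grey"
    stack <<- c(stack, v)
    for (w in sort(adj[[v]])) {
      if (!is.null(result)) break
      if (color[w] == "grey") {
        i <- which(stack == w)[1]
        result <<- c(stack[i:length(stack)], w)
      } else if (color[w] == "white") {
        visit(w)
      }
    }
    stack <<- stack[-length(stack)]
    color[v] <<- "black"
  }
  for (v in nodes) if (color[v] == "white") visit(v)
  result
}

predecessors <- function(graph, task, kind = NULL) {
  e <- graph$edges
  if (!is.null(kind)) e <- e[e$kind %in% kind, , drop = FALSE]
  unique(e$from[e$to == task])
}

successors <- function(graph, task) unique(graph$edges$to[graph$edges$from == task])

#' Descendant set of a task in the workflow DAG
#'
#' @param graph a `workflow_graph`.
#' @param task a node name.
#' @return character vector of all tasks reachable from `task` (excluding
#'   `task` itself), in lexicographic order.
#' @export
descendants <- function(graph, task) {
  seen <- character()
  frontier <- successors(graph, task)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(lapply(frontier, successors, graph = graph))), seen)
  }
  sort(seen)
}

#' Partition a workflow DAG into concurrent execution stages
#'
#' Kahn-style level partition: stage k holds the tasks whose longest
#' incoming path has length k, so every task depends only on earlier stages
#' and tasks within one stage are pairwise non-adjacent — they can all run
#' concurrently. Within each stage, names are sorted lexicographically so
#' plans (and hence logs and run reports) are reproducible across runs and
#' platforms. Forced edges constrain exactly like IO edges.
#'
#' @param graph an acyclic `workflow_graph`.
#' @return an `execution_plan`: list with field `stages`, an ordered list of
#'   character vectors partitioning the nodes. The number of stages is one
#'   plus the length of the longest path.
#' @export
build_plan <- function(graph) {
  stopifnot(inherits(graph, "workflow_graph"))
  nodes <- graph$nodes
  e <- graph$edges
  depth <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  indeg_pending <- stats::setNames(integer(length(nodes)), nodes)
  for (to in e$to) indeg_pending[to] <- indeg_pending[to] + 1L
  queue <- nodes[indeg_pending == 0L]
  depth[queue] <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- e[e$from == v, , drop = FALSE]
    for (w in out$to) {
      depth[w] <- max(depth[w], depth[v] + 1L, na.rm = TRUE)
      indeg_pending[w] <- indeg_pending[w] - 1L
      if (indeg_pending[w] == 0L) queue <- c(queue, w)
    }
  }
  if (anyNA(depth)) {
    abort_validation("graph contains a cycle; cannot plan")  # guarded by build_graph
  }
  stages <- lapply(sort(unique(depth)), function(d) sort(nodes[depth == d]))
  structure(list(stages = stages), class = "execution_plan")
}

#' @export
print.execution_plan <- function(x, ...) {
  for (i in seq_along(x$stages)) {
    cat(sprintf("stage %d: %s\n", i, paste(x$stages[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Stage index of a task in an execution plan
#'
#' @param plan an `execution_plan` from [build_plan()].
#' @param task a task name.
#' @return 1-based stage index, or `NA` if the task is not in the plan.
#' @export
stage_of_task <- function(plan, task) {
  for (i in seq_along(plan$stages)) if (task %in% plan$stages[[i]]) return(i)
  NA_integer_
}

## ---- export ----------------------------------------------------------------

#' Export a workflow DAG as Graphviz DOT
#'
#' IO edges are solid, forced dependencies dashed (ordering without data
#' flow).
#'
#' @param graph a `workflow_graph`.
#' @param name graph name in the DOT output.
#' @return character vector of DOT lines.
#' @export
graph_to_dot <- function(graph, name = "workflow") {
  q <- function(x) sprintf('"%s"', x)
  lines <- c(sprintf("digraph %s {", q(name)),
             "  rankdir=TB;",
             sprintf("  %s [label=%s, shape=box];", q(graph$nodes),
                     q(sprintf("%s\\n(%s)", graph$nodes,
                               vapply(graph$payload[graph$nodes],
                                      function(p) p$task$component_name, "")))))
  if (nrow(graph$edges)) {
    style <- ifelse(graph$edges$kind == "forced", " [style=dashed]", "")
    lines <- c(lines, sprintf("  %s -> %s%s;", q(graph$edges$from),
                              q(graph$edges$to), style))
  }
  c(lines, "}")
}

#' Export an execution plan as JSON
#'
#' @param plan an `execution_plan`.
#' @return a JSON string: array of stages, each an array of task names.
#' @export
plan_to_json <- function(plan) {
  jsonlite::toJSON(plan$stages)
}
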