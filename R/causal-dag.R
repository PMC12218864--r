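## Causal DAGs and back-door covariate selection.
##
## The study's causal assumptions live in a plain-text edge list (see
## `system.file("extdata", "habitat_dag.txt", package = "opuntiacam")`),
## kept editable so the graph can be revised without touching code. Latent
## nodes (unobservable, e.g. diffuse human use of a site) may appear in the
## graph but can never enter an adjustment set.

#' Construct a causal DAG
#'
#' @param edges character vector of edges, each `"A -> B"`, or a two-column
#'   matrix/data frame of (from, to) pairs.
#' @param latent character vector of latent (unobservable) node names.
#' @param exposure,outcome optional default exposure/outcome node names.
#' @return An object of class `causal_dag`: nodes, edges (tibble), latent
#'   flags and the exposure/outcome designation.
#' @export
#' @examples
#' causal_dag(c("Z -> X", "Z -> Y", "X -> Y"), exposure = "X", outcome = "Y")
causal_dag <- function(edges, latent = character(), exposure = NULL, outcome = NULL) {
  if (is.character(edges)) {
    parts <- strsplit(trimws(edges), "\\s*->\\s*")
    bad <- lengths(parts) != 2L
    if (any(bad)) stopf("malformed edge specification: %s", edges[bad][1])
    edges <- tibble::tibble(
      from = vapply(parts, `[`, "", 1L),
      to = vapply(parts, `[`, "", 2L)
    )
  } else {
    edges <- tibble::as_tibble(as.data.frame(edges, stringsAsFactors = FALSE))
    names(edges) <- c("from", "to")
  }
  nodes <- sort(unique(c(edges$from, edges$to, latent, exposure, outcome)))
  if (!all(latent %in% nodes)) stopf("latent node not present in graph")
  dag <- structure(
    list(
      nodes = nodes, edges = edges, latent = latent,
      exposure = exposure, outcome = outcome
    ),
    class = "causal_dag"
  )
  if (dag_has_cycle(dag)) stopf("graph contains a directed cycle; a DAG is required")
  if (!is.null(exposure) && !is.null(outcome) && identical(exposure, outcome)) {
    stopf("exposure and outcome must differ")
  }
  dag
}

#' @export
print.causal_dag <- function(x, ...) {
  cat(sprintf(
    "<causal_dag: %d nodes, %d edges>\n", length(x$nodes), nrow(x$edges)
  ))
  if (length(x$latent)) cat("latent:  ", paste(x$latent, collapse = ", "), "\n")
  if (!is.null(x$exposure)) cat("exposure:", x$exposure, "\n")
  if (!is.null(x$outcome)) cat("outcome: ", x$outcome, "\n")
  cat(paste0("  ", x$edges$from, " -> ", x$edges$to, collapse = "\n"), "\n")
  invisible(x)
}

#' Read a causal DAG from an edge-list file
#'
#' The format is one `A -> B` edge per line, with optional header lines
#' `latent: <node>`, `exposure: <node>`, `outcome: <node>` and `#` comments.
#'
#' @param path file path.
#' @return A [causal_dag()] object.
#' @export
read_dag <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hdr <- function(key) {
    hit <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (!length(hit)) NULL else trimws(sub(paste0("^", key, ":"), "", hit))
  }
  causal_dag(
    edges = grep("->", lines, value = TRUE, fixed = TRUE),
    latent = hdr("latent") %||% character(),
    exposure = hdr("exposure"), outcome = hdr("outcome")
  )
}

#' The bundled habitat-use causal graph
#'
#' Loads the package's transcription of the study's causal assumptions:
#' Opuntia affects habitat use directly and through the native plant
#' community; rivers, roads and livestock confound the exposure; diffuse
#' human use is latent, acting through livestock and roads.
#'
#' @return A [causal_dag()] with exposure `opuntia`, outcome `habitat_use`.
#' @export
habitat_dag <- function() {
  read_dag(system.file("extdata", "habitat_dag.txt", package = "opuntiacam"))
}

## ---- graph primitives ----

dag_children <- function(dag, node) dag$edges$to[dag$edges$from == node]
dag_parents <- function(dag, node) dag$edges$from[dag$edges$to == node]

dag_has_cycle <- function(dag) {
  nodes <- dag$nodes
  indeg <- vapply(nodes, function(n) length(dag_parents(dag, n)), 0L)
  queue <- nodes[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    n <- queue[1L]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (c in dag_children(dag, n)) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  seen < length(nodes)
}

# all descendants of `nodes` (not including the nodes themselves)
dag_descendants <- function(dag, nodes) {
  out <- character()
  frontier <- nodes
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, dag_children, dag = dag)))
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  setdiff(out, nodes)
}

dag_ancestors <- function(dag, nodes) {
  out <- character()
  frontier <- nodes
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, dag_parents, dag = dag)))
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  setdiff(out, nodes)
}

.check_nodes <- function(dag, nms) {
  missing <- setdiff(nms, dag$nodes)
  if (length(missing)) stopf("unknown node(s): %s", paste(missing, collapse = ", "))
}

#' d-separation test
#'
#' Tests whether every path between `x` and `y` is blocked given the
#' conditioning set `z` under the usual d-separation rules (chains and forks
#' blocked by conditioning on the middle node; colliders blocked unless the
#' collider or one of its descendants is conditioned on). Implemented via
#' the moralized-ancestral-graph criterion.
#'
#' @param dag a [causal_dag()].
#' @param x,y node names.
#' @param z character vector of conditioning nodes (may be empty).
#' @return `TRUE` if `x` and `y` are d-separated given `z`.
#' @export
#' @examples
#' d <- causal_dag(c("X -> M", "M -> Y"))
#' d_separated(d, "X", "Y", "M")
d_separated <- function(dag, x, y, z = character()) {
  .check_nodes(dag, c(x, y, z))
  if (x %in% z || y %in% z) stopf("x and y must not be members of z")
  keep <- unique(c(x, y, z, dag_ancestors(dag, c(x, y, z))))
  e <- dag$edges[dag$edges$from %in% keep & dag$edges$to %in% keep, , drop = FALSE]
  # moralize: undirected skeleton + marry parents of every node
  und <- rbind(as.matrix(e), as.matrix(e)[, 2:1, drop = FALSE])
  for (n in keep) {
    pa <- unique(e$from[e$to == n])
    if (length(pa) > 1L) {
      pairs <- t(utils::combn(pa, 2L))
      und <- rbind(und, pairs, pairs[, 2:1, drop = FALSE])
    }
  }
  # delete z, test connectivity x ~ y
  live <- setdiff(keep, z)
  und <- und[und[, 1] %in% live & und[, 2] %in% live, , drop = FALSE]
  frontier <- x
  seen <- x
  while (length(frontier)) {
    nxt <- setdiff(unique(und[und[, 1] %in% frontier, 2]), seen)
    if (y %in% nxt) return(FALSE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  TRUE
}

#' Back-door criterion check
#'
#' `z` satisfies the back-door criterion relative to `(exposure, outcome)`
#' iff (i) no member of `z` is a descendant of the exposure and (ii) `z`
#' blocks every path between exposure and outcome that starts with an edge
#' into the exposure. Clause (ii) is tested as d-separation in the graph
#' with the exposure's outgoing edges removed. Latent nodes in `z` are a
#' design error and raise an error rather than returning `FALSE`.
#'
#' @inheritParams d_separated
#' @param exposure,outcome node names (default: the DAG's designations).
#' @param z proposed adjustment set (observed nodes only).
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_backdoor <- function(dag, z = character(), exposure = dag$exposure,
                              outcome = dag$outcome) {
  .check_nodes(dag, c(exposure, outcome, z))
  bad <- intersect(z, dag$latent)
  if (length(bad)) {
    stopf("adjustment set contains latent node(s): %s", paste(bad, collapse = ", "))
  }
  if (exposure %in% z || outcome %in% z) {
    stopf("exposure/outcome cannot be members of the adjustment set")
  }
  if (any(z %in% dag_descendants(dag, exposure))) return(FALSE)
  # remove edges out of the exposure; remaining x-y connections are back-door
  pruned <- dag
  pruned$edges <- dag$edges[dag$edges$from != exposure, , drop = FALSE]
  d_separated(pruned, exposure, outcome, z)
}

#' Minimal adjustment sets for the total effect
#'
#' Enumerates all subset-minimal sets of observed covariates that satisfy
#' the back-door criterion and contain no node lying on a directed path
#' from exposure to outcome (so the mediated, indirect part of the effect is
#' left open and the estimand is the total effect). Sets are returned in
#' lexicographic order.
#'
#' @inheritParams is_valid_backdoor
#' @return A list of character vectors (possibly containing the empty set);
#'   an empty list means no observed set exists (latent confounding).
#' @export
#' @examples
#' d <- causal_dag(c("Z -> X", "Z -> Y", "X -> Y"), exposure = "X", outcome = "Y")
#' total_effect_sets(d)
total_effect_sets <- function(dag, exposure = dag$exposure, outcome = dag$outcome) {
  .check_nodes(dag, c(exposure, outcome))
  # nodes on a directed exposure -> outcome path
  on_causal_path <- intersect(
    dag_descendants(dag, exposure),
    dag_ancestors(dag, outcome)
  )
  candidates <- setdiff(
    dag$nodes,
    c(exposure, outcome, dag$latent, dag_descendants(dag, exposure), on_causal_path)
  )
  candidates <- sort(candidates)
  valid <- list()
  for (k in 0:length(candidates)) {
    combos <- if (k == 0L) list(character()) else {
      m <- utils::combn(candidates, k)
      lapply(seq_len(ncol(m)), function(j) m[, j])
    }
    for (z in combos) {
      if (any(vapply(valid, function(v) all(v %in% z), TRUE))) next # not minimal
      if (is_valid_backdoor(dag, z, exposure, outcome)) valid <- c(valid, list(z))
    }
  }
  # lexicographic order on the concatenated set labels
  valid[order(vapply(valid, function(v) paste(v, collapse = ","), ""))]
}
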