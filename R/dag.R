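#' Disease directed acyclic graph
#'
#' Constructs a disease DAG from a set of `(child, parent)` edges, the
#' MeSH-style hierarchy underlying disease semantic similarity. A node may
#' have several parents (the hierarchy is a DAG, not a tree). The edge
#' relation is verified to be acyclic at construction; on failure the error
#' message lists one offending cycle.
#'
#' @param edges two-column character matrix or data frame of `(child, parent)`
#'   pairs; may have zero rows.
#' @param nodes optional additional (possibly isolated) node identifiers.
#' @return an object of class `"disease_dag"` with elements `nodes`, `edges`,
#'   `parents` and `children` (named adjacency lists).
#' @examples
#' dag <- disease_dag(rbind(c("B", "A"), c("C", "A")))
#' dag_ancestors(dag, "B")
#' @export
disease_dag <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2) {
    stop("`edges` must have two columns (child, parent)", call. = FALSE)
  }
  storage.mode(edges) <- "character"
  if (nrow(edges)) {
    self <- edges[, 1] == edges[, 2]
    if (any(self)) {
      stop("self-loop on node '", edges[which(self)[1], 1], "'", call. = FALSE)
    }
    edges <- unique(edges)
  }
  all_nodes <- unique(c(as.character(nodes), edges[, 1], edges[, 2]))
  if (!length(all_nodes)) stop("DAG has no nodes", call. = FALSE)
  parents <- split(edges[, 2], factor(edges[, 1], levels = all_nodes))
  children <- split(edges[, 1], factor(edges[, 2], levels = all_nodes))
  dag <- structure(
    list(nodes = all_nodes,
         edges = edges,
         parents = lapply(parents, as.character),
         children = lapply(children, as.character)),
    class = "disease_dag")
  cyc <- find_cycle(dag)
  if (!is.null(cyc)) {
    stop("cycle detected in disease DAG: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }
  dag
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("Disease DAG: %d nodes, %d child->parent edges\n",
              length(x$nodes), nrow(x$edges)))
  roots <- x$nodes[vapply(x$parents[x$nodes], length, integer(1)) == 0L]
  cat("Roots:", paste(utils::head(roots, 5), collapse = ", "),
      if (length(roots) > 5) "..." else "", "\n")
  invisible(x)
}

# Depth-first search over child->parent edges; returns one cycle (as a node
# path) or NULL if the relation is acyclic.
find_cycle <- function(dag) {
  state <- structure(integer(length(dag$nodes)), names = dag$nodes)
  path <- character(0)
  result <- NULL
  visit <- function(v) {
    if (!is.null(result)) return(invisible())
    if (state[[v]] == 1L) {
      i <- match(v, path)
      result <<- c(path[i:length(path)], v)
      return(invisible())
    }
    if (state[[v]] == 2L) return(invisible())
    state[[v]] <<- 1L
    path <<- c(path, v)
    for (p in dag$parents[[v]]) visit(p)
    path <<- path[-length(path)]
    state[[v]] <<- 2L
    invisible()
  }
  for (v in dag$nodes) {
    if (state[[v]] == 0L) visit(v)
    if (!is.null(result)) break
  }
  result
}

#' Ancestor closure of a disease node
#'
#' Returns the node together with all its ancestors reachable over
#' child-to-parent edges — the sub-DAG node set over which semantic
#' contributions are accumulated.
#'
#' @param dag a [disease_dag].
#' @param disease a node identifier.
#' @return character vector of node identifiers (includes `disease`).
#' @export
dag_ancestors <- function(dag, disease) {
  if (!disease %in% dag$nodes) {
    stop("disease '", disease, "' not in DAG", call. = FALSE)
  }
  seen <- disease
  frontier <- disease
  while (length(frontier)) {
    nxt <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Semantic contribution of a disease's ancestors
#'
#' Computes the per-ancestor semantic contribution `D1` for a query disease:
#' the disease itself contributes 1, and every ancestor `d` contributes
#' `delta` times the largest contribution among its children inside the
#' query's ancestor closure. With `delta < 1` the contribution decays with
#' distance from the query disease up the hierarchy.
#'
#' @param dag a [disease_dag].
#' @param disease the query disease identifier.
#' @param delta semantic decay factor in `(0, 1]`; default 0.5.
#' @return named numeric vector over the ancestor closure of `disease`.
#' @export
semantic_contribution <- function(dag, disease, delta = 0.5) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0 || delta > 1) {
    stop("`delta` must be a single value in (0, 1]", call. = FALSE)
  }
  closure <- dag_ancestors(dag, disease)
  memo <- new.env(parent = emptyenv())
  d1 <- function(d) {
    if (exists(d, envir = memo, inherits = FALSE)) {
      return(get(d, envir = memo))
    }
    val <- if (d == disease) {
      1
    } else {
      kids <- intersect(dag$children[[d]], closure)
      delta * max(vapply(kids, d1, numeric(1)))
    }
    assign(d, val, envir = memo)
    val
  }
  out <- vapply(closure, d1, numeric(1))
  names(out) <- closure
  out
}

#' Disease semantic similarity from a DAG
#'
#' Computes pairwise disease semantic similarity: two diseases sharing a large
#' part of their DAG ancestor closures score high. For diseases `i` and `j`
#' the score is the sum of both diseases' semantic contributions over shared
#' ancestors, divided by the sum of their total semantic values
#' (`DV1 = sum of D1` over each closure). Scores lie in `[0, 1]` with unit
#' diagonal; diseases with disjoint closures score 0.
#'
#' @param dag a [disease_dag].
#' @param ids ordered character vector of disease identifiers (all in `dag`).
#' @param delta semantic decay factor in `(0, 1]`; default 0.5.
#' @return symmetric numeric matrix over `ids` with unit diagonal.
#' @examples
#' dag <- disease_dag(rbind(c("B", "A")))
#' semantic_similarity(dag, c("A", "B"))  # off-diagonal 0.6
#' @export
semantic_similarity <- function(dag, ids, delta = 0.5) {
  if (!length(ids)) stop("`ids` must be non-empty", call. = FALSE)
  missing <- setdiff(ids, dag$nodes)
  if (length(missing)) {
    stop("diseases not in DAG: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  contrib <- lapply(ids, function(d) semantic_contribution(dag, d, delta))
  dv1 <- vapply(contrib, sum, numeric(1))
  m <- length(ids)
  S <- diag(1, m)
  dimnames(S) <- list(ids, ids)
  if (m > 1) {
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        shared <- intersect(names(contrib[[i]]), names(contrib[[j]]))
        s <- if (length(shared)) {
          sum(contrib[[i]][shared] + contrib[[j]][shared]) / (dv1[i] + dv1[j])
        } else 0
        S[i, j] <- S[j, i] <- s
      }
    }
  }
  S
}
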