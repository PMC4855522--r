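#' Construct a weighted set-cover instance
#'
#' A cover instance is a universe `X` of element ids (tumor ids in cohort
#' mode), a family `F` of named element sets (one per candidate gene), and a
#' real weight per set.  Weights may take any sign; the cohort pipeline only
#' ever produces hypergeometric tail probabilities in `[0, 1]`.
#'
#' @param sets Named list of character vectors; names are set ids (unique),
#'   values are element ids.
#' @param weights Numeric vector of weights, one per set.  Either named
#'   (matched to `names(sets)`) or positional.
#' @param universe Character vector of element ids.  Defaults to the union of
#'   all set elements; it may be a superset (uncovered elements are allowed).
#' @return An object of class `cover_instance` with fields `universe`, `sets`
#'   and `weights`.
#' @examples
#' inst <- cover_instance(
#'   sets = list(g1 = c("T1", "T2"), g2 = c("T2", "T3", "T4"), g3 = c("T2", "T5")),
#'   weights = c(g1 = 0.10, g2 = 0.02, g3 = 0.30))
#' @export
cover_instance <- function(sets, weights = NULL, universe = NULL) {
  if (is.null(sets)) sets <- list()
  if (length(sets) && is.null(names(sets))) {
    stop("`sets` must be a named list (names are set ids)")
  }
  sets <- lapply(sets, as.character)
  if (is.null(weights)) weights <- rep(0, length(sets))
  weights <- as.numeric(weights)
  if (length(weights) != length(sets)) {
    stop("`weights` must have one entry per set")
  }
  if (!is.null(names(weights)) && length(weights)) {
    if (!setequal(names(weights), names(sets))) {
      stop("names of `weights` do not match names of `sets`")
    }
    weights <- weights[names(sets)]
  } else {
    names(weights) <- names(sets)
  }
  if (any(!is.finite(weights))) stop("weights must be finite numbers")
  if (is.null(universe)) {
    universe <- unique(unlist(sets, use.names = FALSE))
    if (is.null(universe)) universe <- character(0)
  }
  structure(
    list(universe = sort_cstr(unique(as.character(universe))),
         sets = sets, weights = weights),
    class = "cover_instance")
}

#' @export
print.cover_instance <- function(x, ...) {
  cat(sprintf("cover_instance: %d elements, %d sets\n",
              length(x$universe), length(x$sets)))
  invisible(x)
}

#' @export
format.cover_solution <- function(x, ...) {
  sprintf("cover_solution: {%s} coverage=%d weight=%.6g",
          paste(x$chosen, collapse = ", "), x$coverage, x$weight)
}

#' @export
print.cover_solution <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# C-locale (radix) sort so ordering is independent of the session locale.
sort_cstr <- function(x) {
  if (!length(x)) return(character(0))
  sort(unname(x), method = "radix")
}

#' Normalize a cover instance
#'
#' Validates and canonicalizes an instance: duplicate set ids and elements
#' missing from the universe are errors; empty sets are dropped (they cannot
#' change coverage and with a negative weight would degenerately lower the
#' objective); sets and universe are sorted so that the family order is the
#' deterministic tie-break order used everywhere downstream.
#'
#' @param instance A `cover_instance`.
#' @return A new, normalized `cover_instance`.
#' @export
normalize_instance <- function(instance) {
  stopifnot(inherits(instance, "cover_instance"))
  ids <- names(instance$sets)
  if (anyDuplicated(ids)) {
    stop("duplicate set_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sets <- lapply(instance$sets, function(e) sort_cstr(unique(as.character(e))))
  stray <- setdiff(unlist(sets, use.names = FALSE), instance$universe)
  if (length(stray)) {
    stop("element(s) not in universe: ", paste(stray, collapse = ", "))
  }
  keep <- lengths(sets) > 0
  sets <- sets[keep]
  weights <- instance$weights[keep]
  ord <- order(names(sets) %||% character(0), method = "radix")
  cover_instance(sets = sets[ord], weights = weights[ord],
                 universe = instance$universe)
}

#' Build the intersection graph of an instance
#'
#' One node per family member; an edge joins two sets iff they share at least
#' one element.  The maximum degree of this graph drives the solver's
#' branching strategy.
#'
#' @param instance A normalized `cover_instance`.
#' @return An `intersection_graph`: list with `nodes` (sorted set ids),
#'   `adjacency` (named list of sorted neighbor ids) and `degree`.
#' @export
build_intersection_graph <- function(instance) {
  instance <- normalize_instance(instance)
  ids <- names(instance$sets)
  m <- length(ids)
  imat <- intersect_matrix(instance)
  adjacency <- stats::setNames(vector("list", m), ids)
  for (i in seq_len(m)) adjacency[[i]] <- ids[imat[i, ]]
  structure(
    list(nodes = ids, adjacency = adjacency,
         degree = stats::setNames(vapply(adjacency, length, 0L), ids)),
    class = "intersection_graph")
}

# m x m logical matrix: TRUE iff sets i and j (i != j) share an element.
# Computed once per instance; set intersection never changes when other sets
# are removed, so subfamilies reuse submatrices of this.
intersect_matrix <- function(instance) {
  m <- length(instance$sets)
  n <- length(instance$universe)
  if (m == 0) return(matrix(FALSE, 0, 0))
  inc <- matrix(0, m, n)
  for (i in seq_len(m)) {
    inc[i, match(instance$sets[[i]], instance$universe)] <- 1
  }
  imat <- tcrossprod(inc) > 0
  diag(imat) <- FALSE
  imat
}

#' @export
print.intersection_graph <- function(x, ...) {
  cat(sprintf("intersection_graph: %d nodes, %d edges, max degree %d\n",
              length(x$nodes), sum(x$degree) %/% 2L,
              if (length(x$degree)) max(x$degree) else 0L))
  invisible(x)
}

#' Connected components of an intersection graph
#'
#' Solving each component independently and concatenating the per-component
#' optima yields the global optimum, because sets in different components are
#' element-disjoint.
#'
#' @param graph An `intersection_graph`.
#' @return List of character vectors (sorted node ids), ordered by each
#'   component's smallest member id.
#' @export
graph_components <- function(graph) {
  stopifnot(inherits(graph, "intersection_graph"))
  nodes <- graph$nodes
  if (!length(nodes)) return(list())
  seen <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (v in nodes) {
    if (seen[[v]]) next
    queue <- v
    seen[[v]] <- TRUE
    members <- character(0)
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      members <- c(members, u)
      for (w in graph$adjacency[[u]]) {
        if (!seen[[w]]) { seen[[w]] <- TRUE; queue <- c(queue, w) }
      }
    }
    comps[[length(comps) + 1L]] <- sort_cstr(members)
  }
  firsts <- vapply(comps, `[[`, "", 1L)
  comps[order(firsts, method = "radix")]
}

#' Closed neighborhood of a node
#'
#' @param graph An `intersection_graph`.
#' @param s A node (set id).
#' @return Sorted character vector: `s` together with all its neighbors.
#' @export
neighbor_closed <- function(graph, s) {
  stopifnot(inherits(graph, "intersection_graph"))
  if (!s %in% graph$nodes) stop("unknown node: ", s)
  sort_cstr(unique(c(s, graph$adjacency[[s]])))
}

#' Construct a cover solution
#'
#' Validates pairwise disjointness and recomputes coverage and weight from
#' the instance, summing weights in sorted set-id order so floating-point
#' ties are reproducible.
#'
#' @param instance A normalized `cover_instance`.
#' @param chosen Character vector of chosen set ids.
#' @return A `cover_solution`: list with `chosen` (sorted), `coverage`
#'   (number of covered elements) and `weight`.
#' @export
cover_solution <- function(instance, chosen) {
  chosen <- sort_cstr(as.character(chosen))
  if (length(chosen)) {
    missing <- setdiff(chosen, names(instance$sets))
    if (length(missing)) stop("chosen ids not in family: ",
                              paste(missing, collapse = ", "))
    elems <- unlist(instance$sets[chosen], use.names = FALSE)
    if (anyDuplicated(elems)) stop("chosen sets are not pairwise disjoint")
    coverage <- length(elems)
    weight <- sum(instance$weights[chosen])
  } else {
    coverage <- 0L
    weight <- 0
  }
  structure(list(chosen = chosen, coverage = as.integer(coverage),
                 weight = weight),
            class = "cover_solution")
}

#' Compare two cover solutions
#'
#' A solution is better if it covers more elements; among equal coverage the
#' smaller weight wins.  Weight comparison is exact (both sides are sums over
#' sorted set ids of the same weight vector, so genuine ties compare equal in
#' floating point).
#'
#' @param a,b `cover_solution` objects from the same instance.
#' @return `1L` if `a` is better, `-1L` if `b` is better, `0L` on a tie.
#' @export
is_better <- function(a, b) {
  stopifnot(inherits(a, "cover_solution"), inherits(b, "cover_solution"))
  if (a$coverage != b$coverage) return(if (a$coverage > b$coverage) 1L else -1L)
  if (a$weight != b$weight) return(if (a$weight < b$weight) 1L else -1L)
  0L
}

# Lexicographic comparison of two sorted id tuples (C locale); used to
# resolve exact ties deterministically.  Returns TRUE if a <= b.
tuple_le <- function(a, b) {
  k <- min(length(a), length(b))
  if (k > 0) {
    for (i in seq_len(k)) {
      if (a[[i]] != b[[i]]) {
        return(sort(c(a[[i]], b[[i]]), method = "radix")[[1]] == a[[i]])
      }
    }
  }
  length(a) <= length(b)
}
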