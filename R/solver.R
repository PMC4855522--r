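#' Exact solver for weighted mutually exclusive maximum set cover
#'
#' Finds the pairwise-disjoint subfamily that covers the maximum number of
#' universe elements and, among all maximum-coverage subfamilies, has the
#' minimum total weight (remaining ties broken by the lexicographically
#' smallest sorted id tuple).  The search is branch and bound on the
#' intersection graph:
#'
#' * isolated (degree-0) nodes are included directly — a disjoint non-empty
#'   set always raises coverage, which is lexicographically prior to weight;
#' * connected components are solved independently and concatenated;
#' * a component whose maximum degree is at most 2 (a simple path or ring) is
#'   solved by quadratic-time midpoint branching without touching the
#'   exponential search;
#' * a component with maximum degree exactly 3 branches on a degree-3 node
#'   reached by walking from a minimum-degree node (see
#'   [find_branch_node_deg3()]), which isolates cheap path components in the
#'   exclude branch;
#' * otherwise the maximum-degree node is branched on: the include branch
#'   removes the node and all its neighbors, the exclude branch removes the
#'   node alone.
#'
#' The resulting search tree has at most about `1.325^m` leaves, where a leaf
#' is a subinstance resolved without include/exclude branching (empty,
#' all-isolated, or handed to the degree-2 routine); component splits count
#' additively.
#'
#' @param instance A `cover_instance` (normalized internally; normalization
#'   is idempotent).
#' @return List with `solution` (a [cover_solution()]) and `stats`, a
#'   `search_stats` list: `branch_leaves`, `branch_nodes` (include/exclude
#'   branchings performed), `max_depth`, and `cover2_internal_leaves` (leaf
#'   count of the polynomial degree-2 recursion, bounded by `2 m^2` per
#'   component).
#' @examples
#' inst <- cover_instance(
#'   sets = list(g1 = c("T1", "T2"), g2 = c("T2", "T3", "T4"), g3 = c("T2", "T5")),
#'   weights = c(g1 = 0.1, g2 = 0.02, g3 = 0.3))
#' wmem_solve(inst)$solution
#' @export
wmem_solve <- function(instance) {
  inst <- normalize_instance(instance)
  st <- solver_state(inst)
  res <- wmem_rec(st, seq_along(inst$sets), 0L)
  finish_solve(st, res)
}

# Shared mutable search state: instance data, intersection matrix, counters.
solver_state <- function(inst) {
  st <- new.env(parent = emptyenv())
  st$ids <- names(inst$sets)
  st$sizes <- lengths(inst$sets)
  st$weights <- inst$weights
  st$imat <- intersect_matrix(inst)
  st$inst <- inst
  st$branch_nodes <- 0L
  st$max_depth <- 0L
  st$c2_leaves <- 0L
  st
}

finish_solve <- function(st, res) {
  sol <- cover_solution(st$inst, st$ids[res$chosen])
  stats <- structure(
    list(branch_leaves = res$leaves,
         branch_nodes = st$branch_nodes,
         max_depth = st$max_depth,
         cover2_internal_leaves = st$c2_leaves),
    class = "search_stats")
  list(solution = sol, stats = stats)
}

# Compare two partial solutions given as integer index vectors.
# Returns TRUE if `a` is at least as good as `b` (coverage desc, weight asc,
# then lexicographically smallest sorted id tuple).
idx_better_eq <- function(st, a, b) {
  cov_a <- sum(st$sizes[a]); cov_b <- sum(st$sizes[b])
  if (cov_a != cov_b) return(cov_a > cov_b)
  ids_a <- sort_cstr(st$ids[a]); ids_b <- sort_cstr(st$ids[b])
  w_a <- sum(st$weights[ids_a]); w_b <- sum(st$weights[ids_b])
  if (w_a != w_b) return(w_a < w_b)
  tuple_le(ids_a, ids_b)
}

# Recursive solve of a subfamily given by integer indices `alive`.
# Returns list(chosen = indices, leaves = branch-leaf count).
wmem_rec <- function(st, alive, depth) {
  if (depth > st$max_depth) st$max_depth <- depth
  if (!length(alive)) return(list(chosen = integer(0), leaves = 1L))
  sub <- st$imat[alive, alive, drop = FALSE]
  deg <- rowSums(sub)
  iso <- alive[deg == 0]
  rest <- alive[deg > 0]
  if (!length(rest)) return(list(chosen = iso, leaves = 1L))
  comps <- idx_components(st, rest)
  chosen <- iso
  leaves <- 0L
  for (comp in comps) {
    r <- wmem_comp(st, comp, depth)
    chosen <- c(chosen, r$chosen)
    leaves <- leaves + r$leaves
  }
  list(chosen = chosen, leaves = leaves)
}

# Connected components of the subgraph induced by `alive` (all degrees >= 1
# within `alive`), ordered by smallest set id; members in index order.
idx_components <- function(st, alive) {
  m <- length(alive)
  sub <- st$imat[alive, alive, drop = FALSE]
  comp_of <- integer(m)
  ncomp <- 0L
  for (i in seq_len(m)) {
    if (comp_of[i] > 0L) next
    ncomp <- ncomp + 1L
    queue <- i
    comp_of[i] <- ncomp
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      nb <- which(sub[u, ] & comp_of == 0L)
      comp_of[nb] <- ncomp
      queue <- c(queue, nb)
    }
  }
  comps <- split(alive, comp_of)
  firsts <- vapply(comps, function(ix) min(st$ids[ix]), "")
  comps[order(firsts, method = "radix")]
}

# Solve one connected component (indices `comp`, every node degree >= 1).
wmem_comp <- function(st, comp, depth) {
  sub <- st$imat[comp, comp, drop = FALSE]
  deg <- rowSums(sub)
  maxdeg <- max(deg)
  if (maxdeg <= 2) {
    r <- deg2_component(st, comp, sub, deg)
    st$c2_leaves <- st$c2_leaves + r$internal
    return(list(chosen = r$chosen, leaves = 1L))
  }
  if (maxdeg == 3) {
    x_local <- deg3_branch_node(st$ids[comp], sub, deg)
  } else {
    cand <- which(deg == maxdeg)
    x_local <- cand[order(st$ids[comp[cand]], method = "radix")[1L]]
  }
  x <- comp[x_local]
  st$branch_nodes <- st$branch_nodes + 1L
  closed <- comp[c(x_local, which(sub[x_local, ]))]
  r_in <- wmem_rec(st, setdiff(comp, closed), depth + 1L)
  ch_in <- c(x, r_in$chosen)
  r_ex <- wmem_rec(st, setdiff(comp, x), depth + 1L)
  if (idx_better_eq(st, ch_in, r_ex$chosen)) {
    list(chosen = ch_in, leaves = r_in$leaves + r_ex$leaves)
  } else {
    list(chosen = r_ex$chosen, leaves = r_in$leaves + r_ex$leaves)
  }
}

# --- degree <= 2 components: simple path or simple ring ---------------------

# Solve a connected max-degree-<=2 component by midpoint branching.
# Returns list(chosen = indices, internal = leaf count of this recursion).
deg2_component <- function(st, comp, sub, deg) {
  m <- length(comp)
  if (m == 1L) return(list(chosen = comp, internal = 1L))
  if (all(deg == 2)) {
    # simple ring: order the cycle starting at the smallest id, stepping
    # first toward the smaller-id neighbor, then branch on the start node.
    start <- order(st$ids[comp], method = "radix")[1L]
    ord <- ring_order(sub, start)
    x <- comp[ord[1L]]
    inner <- comp[ord[3:(m - 1L)]]          # path left after removing
    r_in <- deg2_path(st, if (m > 3L) inner else integer(0))
    ch_in <- c(x, r_in$chosen)
    r_ex <- deg2_path(st, comp[ord[2:m]])
    internal <- r_in$internal + r_ex$internal
    if (idx_better_eq(st, ch_in, r_ex$chosen)) {
      return(list(chosen = ch_in, internal = internal))
    }
    return(list(chosen = r_ex$chosen, internal = internal))
  }
  # simple path: order from the endpoint with the smaller id.
  ends <- which(deg == 1)
  start <- ends[order(st$ids[comp[ends]], method = "radix")[1L]]
  ord <- path_order(sub, start)
  deg2_path(st, comp[ord])
}

# Path order by walking from `start` (local indices into sub).
path_order <- function(sub, start) {
  m <- nrow(sub)
  ord <- integer(m)
  ord[1L] <- start
  prev <- 0L
  cur <- start
  for (k in seq_len(m - 1L)) {
    nxt <- setdiff(which(sub[cur, ]), prev)
    prev <- cur
    cur <- nxt[1L]
    ord[k + 1L] <- cur
  }
  ord
}

ring_order <- function(sub, start) {
  nbs <- which(sub[start, ])
  # step toward the smaller local index (ids unordered here; caller picked
  # start by id, direction fixed by the smaller neighbor index for
  # determinism via the globally sorted family order)
  ord <- integer(nrow(sub))
  ord[1L] <- start
  prev <- start
  cur <- min(nbs)
  k <- 1L
  while (cur != start) {
    k <- k + 1L
    ord[k] <- cur
    nxt <- setdiff(which(sub[cur, ]), prev)
    prev <- cur
    cur <- nxt[1L]
  }
  ord
}

# Optimal disjoint subfamily of a simple path given in path order
# (consecutive sets intersect, nothing else does).  Branches on the middle
# node; an even path uses the lower-indexed of the two middle nodes.
deg2_path <- function(st, order_idx) {
  m <- length(order_idx)
  if (m == 0L) return(list(chosen = integer(0), internal = 1L))
  if (m == 1L) return(list(chosen = order_idx, internal = 1L))
  xp <- as.integer(ceiling(m / 2))
  x <- order_idx[xp]
  l_in <- if (xp >= 3L) order_idx[1:(xp - 2L)] else integer(0)
  r_in <- if (xp + 2L <= m) order_idx[(xp + 2L):m] else integer(0)
  a <- deg2_path(st, l_in); b <- deg2_path(st, r_in)
  ch_in <- c(x, a$chosen, b$chosen)
  leaves_in <- a$internal + b$internal
  l_ex <- if (xp >= 2L) order_idx[1:(xp - 1L)] else integer(0)
  r_ex <- if (xp + 1L <= m) order_idx[(xp + 1L):m] else integer(0)
  ae <- deg2_path(st, l_ex); be <- deg2_path(st, r_ex)
  ch_ex <- c(ae$chosen, be$chosen)
  internal <- leaves_in + ae$internal + be$internal
  if (idx_better_eq(st, ch_in, ch_ex)) {
    list(chosen = ch_in, internal = internal)
  } else {
    list(chosen = ch_ex, internal = internal)
  }
}

# --- degree-3 branch node selection ----------------------------------------

# Core rule on (ids, adjacency matrix, degrees): if some node has degree < 3,
# walk from the smallest-id minimum-degree node along degree-<=2 nodes
# (smallest-id successor first) until the first degree-3 node; in a 3-regular
# graph return the smallest-id node.  Returns a local index.
deg3_branch_node <- function(ids, sub, deg) {
  if (all(deg == 3)) return(order(ids, method = "radix")[1L])
  dmin <- min(deg)
  cand <- which(deg == dmin)
  cur <- cand[order(ids[cand], method = "radix")[1L]]
  prev <- 0L
  steps <- 0L
  while (deg[cur] < 3) {
    nxt <- setdiff(which(sub[cur, ]), prev)
    if (!length(nxt)) stop("walk dead-ended; component has no degree-3 node")
    nxt <- nxt[order(ids[nxt], method = "radix")[1L]]
    prev <- cur
    cur <- nxt
    steps <- steps + 1L
    if (steps > length(ids)) stop("walk did not terminate; malformed graph")
  }
  cur
}

#' Pick the branch node for a maximum-degree-3 component
#'
#' Starting from the smallest-id node of minimum degree, walk along
#' degree-at-most-2 nodes (taking the smallest-id successor at the single
#' free choice at the start) until the first degree-3 node, and return it.
#' Branching there leaves the walked path as an isolated polynomial-time
#' component in the exclude branch, which is what keeps the search tree below
#' `1.325^m`.  If the graph is 3-regular the smallest-id node is returned
#' (after one branching a low-degree node always exists).
#'
#' @param graph A connected `intersection_graph` with maximum degree exactly 3.
#' @return A set id.
#' @export
find_branch_node_deg3 <- function(graph) {
  stopifnot(inherits(graph, "intersection_graph"))
  if (!length(graph$nodes)) stop("empty graph")
  if (max(graph$degree) != 3) stop("maximum degree is not 3")
  if (length(graph_components(graph)) != 1L) stop("graph is not connected")
  ids <- graph$nodes
  m <- length(ids)
  sub <- matrix(FALSE, m, m, dimnames = list(ids, ids))
  for (v in ids) sub[v, graph$adjacency[[v]]] <- TRUE
  ids[deg3_branch_node(ids, sub, rowSums(sub))]
}

# --- exported component solvers (contract-checked wrappers) -----------------

#' Solve a connected component with maximum degree at most 2
#'
#' A connected intersection graph with maximum degree at most 2 is a simple
#' path or a simple ring; midpoint branching solves it with at most `2 m^2`
#' recursion leaves (reported in `cover2_internal_leaves`).
#'
#' @param instance A `cover_instance` whose intersection graph is connected
#'   with maximum degree at most 2.
#' @return As [wmem_solve()].
#' @export
solve_component_deg2 <- function(instance) {
  inst <- normalize_instance(instance)
  check_component(inst, function(deg) {
    if (length(deg) && max(deg) > 2) stop("contract violation: degree > 2 present")
  })
  wmem_solve(inst)
}

#' Solve a connected component with maximum degree exactly 3
#'
#' Branches on the node returned by [find_branch_node_deg3()]; after each
#' include/exclude reduction the instance is re-decomposed, so degrees drop
#' and components split naturally.
#'
#' @param instance A `cover_instance` whose intersection graph is connected
#'   with maximum degree exactly 3.
#' @return As [wmem_solve()].
#' @export
solve_component_deg3 <- function(instance) {
  inst <- normalize_instance(instance)
  check_component(inst, function(deg) {
    if (!length(deg) || max(deg) != 3) {
      stop("contract violation: no degree-3 node (max degree != 3)")
    }
  })
  wmem_solve(inst)
}

check_component <- function(inst, degree_check) {
  g <- build_intersection_graph(inst)
  degree_check(g$degree)
  if (length(g$nodes) && length(graph_components(g)) != 1L) {
    stop("contract violation: instance is not a single connected component")
  }
  invisible(TRUE)
}

# --- brute force oracle -----------------------------------------------------

#' Brute-force oracle for small instances
#'
#' Enumerates all `2^m` subfamilies, keeps the pairwise-disjoint ones, and
#' returns the best under exactly the same ordering as [wmem_solve()]
#' (maximum coverage, then minimum weight summed in sorted-id order, then
#' lexicographically smallest id tuple).  Exponential by construction; used
#' as the independent correctness oracle.
#'
#' @param instance A `cover_instance`.
#' @param max_m Refuse instances with more than this many sets (default 20).
#' @return A [cover_solution()].
#' @export
brute_force_solve <- function(instance, max_m = 20) {
  inst <- normalize_instance(instance)
  m <- length(inst$sets)
  if (m > max_m) stop("instance has m = ", m, " sets; max_m = ", max_m)
  if (m == 0) return(cover_solution(inst, character(0)))
  imat <- intersect_matrix(inst)
  conflict <- integer(m) # bitmask of sets conflicting with each set
  for (i in seq_len(m)) {
    conflict[i] <- sum(bitwShiftL(1L, which(imat[i, ]) - 1L))
  }
  sizes <- lengths(inst$sets)
  nmask <- bitwShiftL(1L, m)
  feasible <- logical(nmask); feasible[1L] <- TRUE
  coverage <- integer(nmask)
  low_of <- as.integer(log2(bitwAnd(seq_len(nmask - 1L),
                                    -seq_len(nmask - 1L)))) + 1L
  for (mask in seq_len(nmask - 1L)) {
    low <- low_of[mask]
    rest <- mask - bitwShiftL(1L, low - 1L)
    if (feasible[rest + 1L] && bitwAnd(rest, conflict[low]) == 0L) {
      feasible[mask + 1L] <- TRUE
      coverage[mask + 1L] <- coverage[rest + 1L] + sizes[low]
    }
  }
  best_cov <- max(coverage[feasible])
  cand <- which(feasible & coverage == best_cov) - 1L
  best <- NULL
  for (mask in cand) {
    ids <- names(inst$sets)[bitwAnd(bitwShiftL(1L, seq_len(m) - 1L), mask) != 0L]
    sol <- cover_solution(inst, ids)
    if (is.null(best) || is_better(sol, best) == 1L ||
        (is_better(sol, best) == 0L && tuple_le(sol$chosen, best$chosen))) {
      best <- sol
    }
  }
  best
}

#' Maximum set-packing size by exhaustive enumeration
#'
#' Independent oracle for the 3-set-packing correspondence: for a family of
#' equal-size sets, the maximum number of pairwise-disjoint sets.
#'
#' @param instance A `cover_instance`.
#' @param max_m As in [brute_force_solve()].
#' @return Integer: maximum cardinality of a pairwise-disjoint subfamily.
#' @export
brute_force_packing_size <- function(instance, max_m = 20) {
  inst <- normalize_instance(instance)
  m <- length(inst$sets)
  if (m > max_m) stop("instance has m = ", m, " sets; max_m = ", max_m)
  if (m == 0) return(0L)
  imat <- intersect_matrix(inst)
  best <- 0L
  for (mask in 0:(bitwShiftL(1L, m) - 1L)) {
    idx <- which(bitwAnd(bitwShiftL(1L, seq_len(m) - 1L), mask) != 0L)
    if (length(idx) <= best) next
    if (length(idx) < 2L || !any(imat[idx, idx])) best <- length(idx)
  }
  best
}
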