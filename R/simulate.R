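# All generators are pure functions of (parameters, seed): the global RNG
# state is saved and restored around each call.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Random weighted set-cover instance
#'
#' Samples `m` sets over an `n`-element universe; each set's size is
#' binomial(`n`, `density`) forced to at least 1, elements drawn uniformly
#' without replacement, weights uniform on `weight_range`.
#'
#' @param m Number of sets (>= 0).
#' @param n Universe size (>= 1).
#' @param density Expected fraction of the universe per set, in (0, 1].
#' @param weight_range Length-2 numeric, lower and upper weight bound.
#' @param seed Integer seed (required; generators keep no global state).
#' @return A normalized [cover_instance()].
#' @export
random_instance <- function(m, n, density, weight_range = c(-1, 1), seed) {
  if (m < 0 || n < 1) stop("need m >= 0 and n >= 1")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (length(weight_range) != 2 || diff(weight_range) < 0) {
    stop("weight_range must be c(lo, hi) with lo <= hi")
  }
  with_seed(seed, {
    universe <- sprintf("e%03d", seq_len(n))
    sizes <- pmax(1L, stats::rbinom(m, n, density))
    sets <- lapply(sizes, function(s) sample(universe, s))
    names(sets) <- sprintf("S%03d", seq_len(m))
    weights <- stats::runif(m, weight_range[1], weight_range[2])
    normalize_instance(cover_instance(sets, weights, universe))
  })
}

#' Realize a prescribed intersection graph as a set family
#'
#' Every edge contributes one element shared by exactly its two endpoint
#' sets; every node additionally receives `private_elements_per_node` unique
#' elements, so the instance's intersection graph equals the requested graph
#' exactly (same node ids, same edges).
#'
#' @param graph_spec List with `nodes` (character vector) and `edges`
#'   (two-column matrix or data frame of node ids; may have zero rows).
#' @param private_elements_per_node Private elements per set (>= 1 keeps
#'   every set non-empty even for isolated nodes).
#' @param weight_range Optional; with `seed`, uniform weights. Default all 0.
#' @param seed Seed for weights (ignored when `weight_range` is NULL).
#' @return A normalized [cover_instance()].
#' @export
instance_from_graph <- function(graph_spec, private_elements_per_node = 1,
                                weight_range = NULL, seed = NULL) {
  nodes <- as.character(graph_spec$nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids")
  edges <- graph_spec$edges
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- matrix(character(0), 0, 2)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("edges must have two columns")
  }
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
  if (!all(edges %in% nodes)) stop("edge endpoint not among nodes")
  key <- apply(edges, 1, function(e) paste(sort_cstr(e), collapse = "\r"))
  if (anyDuplicated(key)) stop("multigraphs are not allowed")
  if (private_elements_per_node < 1) stop("need >= 1 private element per node")
  sets <- stats::setNames(
    lapply(nodes, function(v) {
      sprintf("priv_%s_%d", v, seq_len(private_elements_per_node))
    }), nodes)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1]; v <- edges[i, 2]
    el <- sprintf("edge_%s", gsub("\r", "_", key[i]))
    sets[[u]] <- c(sets[[u]], el)
    sets[[v]] <- c(sets[[v]], el)
  }
  weights <- if (is.null(weight_range)) {
    rep(0, length(nodes))
  } else {
    if (is.null(seed)) stop("seed required when weight_range is given")
    with_seed(seed, stats::runif(length(nodes), weight_range[1], weight_range[2]))
  }
  normalize_instance(cover_instance(sets, weights))
}

#' Random simple graph with bounded degree
#'
#' Shuffles all node pairs and greedily adds edges while both endpoint
#' degrees stay below `max_degree`, giving dense graphs whose maximum degree
#' equals `max_degree` (almost surely, for n > max_degree).
#'
#' @param n_nodes Number of nodes.
#' @param max_degree Degree bound (default 3).
#' @param seed Integer seed.
#' @return A graph spec as taken by [instance_from_graph()].
#' @export
random_max_degree_graph <- function(n_nodes, max_degree = 3, seed) {
  if (n_nodes < 1) stop("need n_nodes >= 1")
  with_seed(seed, {
    nodes <- sprintf("V%03d", seq_len(n_nodes))
    pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    deg <- integer(n_nodes)
    keep <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      u <- pairs[i, 1]; v <- pairs[i, 2]
      if (deg[u] < max_degree && deg[v] < max_degree) {
        keep[i] <- TRUE
        deg[u] <- deg[u] + 1L
        deg[v] <- deg[v] + 1L
      }
    }
    e <- pairs[keep, , drop = FALSE]
    list(nodes = nodes,
         edges = cbind(nodes[e[, 1]], nodes[e[, 2]]))
  })
}

#' Instance with a planted optimal solution
#'
#' Plants `k` pairwise-disjoint sets of size `set_size` that tile the whole
#' universe and carry near-zero weights, then adds `n_decoys` decoy sets of
#' the same size with substantially larger weights.  Decoy elements are
#' drawn from the universe (concentrated on one planted "home" set with
#' probability `overlap_rate` per element), so every decoy overlaps the
#' planted tiling and the planted family is the unique optimum: it attains
#' full coverage, and any equal-coverage alternative must use a decoy and
#' lose on weight.
#'
#' @param k Number of planted sets.
#' @param set_size Elements per set.
#' @param n_decoys Number of decoy sets.
#' @param overlap_rate Per-element probability that a decoy element comes
#'   from its home planted set, in `[0, 1]`.
#' @param seed Integer seed.
#' @param planted_weight_range,decoy_weight_range Uniform weight ranges
#'   (defaults `c(0, 0.01)` and `c(0.5, 1)`).
#' @return List with `instance` (normalized [cover_instance()]) and `truth`
#'   (planted ids, parameters, seed).
#' @export
planted_instance <- function(k, set_size, n_decoys, overlap_rate, seed,
                             planted_weight_range = c(0, 0.01),
                             decoy_weight_range = c(0.5, 1)) {
  if (k < 1 || set_size < 1) stop("need k >= 1 and set_size >= 1")
  if (overlap_rate < 0 || overlap_rate > 1) stop("overlap_rate must be in [0,1]")
  with_seed(seed, {
    n <- k * set_size
    universe <- sprintf("e%03d", seq_len(n))
    planted <- split(universe, rep(seq_len(k), each = set_size))
    names(planted) <- sprintf("P%02d", seq_len(k))
    decoys <- lapply(seq_len(n_decoys), function(i) {
      home <- planted[[sample.int(k, 1)]]
      els <- character(set_size)
      for (j in seq_len(set_size)) {
        pool <- if (stats::runif(1) < overlap_rate) home else universe
        els[j] <- sample(pool, 1)
      }
      unique(els)
    })
    names(decoys) <- sprintf("D%02d", seq_len(n_decoys))
    weights <- c(stats::runif(k, planted_weight_range[1], planted_weight_range[2]),
                 stats::runif(n_decoys, decoy_weight_range[1], decoy_weight_range[2]))
    inst <- normalize_instance(
      cover_instance(c(planted, decoys), weights, universe))
    list(instance = inst,
         truth = list(planted = names(planted),
                      params = list(k = k, set_size = set_size,
                                    n_decoys = n_decoys,
                                    overlap_rate = overlap_rate),
                      seed = seed))
  })
}

#' Synthetic tumor cohort with planted mutually exclusive drivers
#'
#' Emulates the structural assumptions of signature-based driver discovery:
#' a fraction of tumors is signal-perturbed, each perturbed tumor carries
#' exactly one planted driver SGA (mutual exclusivity by construction) —
#' a non-silent mutation, or a GISTIC +/-2 call whose expression is shifted
#' by 3 background standard deviations so the z-score clears 1.64
#' deterministically; signature genes in perturbed tumors are placed exactly
#' at `fold_effect`-fold relative to the pseudocounted normal median, and
#' exactly at the normal level in unperturbed tumors.  Passenger mutations
#' are sprinkled over the background genes at `passenger_rate` across all
#' tumors.  Driver and background genes carry log-normal biological spread
#' (`bio_sd` on log expression) so the GISTIC-0 background sd is well
#' defined; signature genes are noiseless apart from the global measurement
#' noise `noise_sd`, so with `noise_sd = 0` the pipeline recovers the
#' planted labels exactly.
#'
#' @param n_tumors,n_normals Sample counts (defaults 200 / 20).
#' @param n_genes Total genes including drivers and signature (default 300).
#' @param signature_size Genes in the planted signature (default 10).
#' @param n_drivers Planted driver genes (default 4); perturbed tumors are
#'   assigned to drivers round-robin so each driver gets an ample event count.
#' @param passenger_rate Per-gene, per-tumor passenger mutation probability
#'   on background genes (default 0.05).
#' @param fold_effect Signature fold change in perturbed tumors, measured as
#'   the pipeline measures it (pseudocount `eps`); at least 3 for noiseless
#'   acceptance runs (default 3).
#' @param noise_sd Gaussian sd added on log-expression to every entry
#'   (default 0).
#' @param seed Integer seed.
#' @param perturbed_frac Fraction of tumors that are signal-perturbed
#'   (default 0.5).
#' @param bio_sd Biological log-sd of non-signature genes (default 0.25).
#' @param base_expr Baseline expression level (default 100).
#' @param eps Pseudocount matching [fold_changes()] (default 1).
#' @return List with `cohort` (a [cohort_data()]), `signatures` (list of
#'   one signature: `id`, `description`, `genes`) and `truth` (drivers,
#'   per-tumor assignment and event type, perturbed tumor ids, params, seed).
#' @export
synthetic_cohort <- function(n_tumors = 200, n_normals = 20, n_genes = 300,
                             signature_size = 10, n_drivers = 4,
                             passenger_rate = 0.05, fold_effect = 3,
                             noise_sd = 0, seed, perturbed_frac = 0.5,
                             bio_sd = 0.25, base_expr = 100, eps = 1) {
  if (n_genes < n_drivers + signature_size + 1) {
    stop("n_genes must exceed n_drivers + signature_size")
  }
  if (fold_effect <= 1) stop("fold_effect must exceed 1")
  if (perturbed_frac <= 0 || perturbed_frac >= 1) {
    stop("perturbed_frac must be in (0, 1)")
  }
  n_pert <- floor(perturbed_frac * n_tumors)
  if (n_pert < n_drivers) stop("not enough perturbed tumors for the drivers")
  with_seed(seed, {
    tumors <- sprintf("TUM%04d", seq_len(n_tumors))
    normals <- sprintf("NOR%03d", seq_len(n_normals))
    drivers <- sprintf("DRV%02d", seq_len(n_drivers))
    sig_genes <- sprintf("SIG%03d", seq_len(signature_size))
    n_bg <- n_genes - n_drivers - signature_size
    bg_genes <- sprintf("BG%04d", seq_len(n_bg))
    genes <- c(drivers, sig_genes, bg_genes)
    samples <- c(tumors, normals)

    perturbed <- sort_cstr(sample(tumors, n_pert))
    assignment <- stats::setNames(
      rep(drivers, length.out = n_pert)[sample.int(n_pert)], perturbed)
    event_type <- stats::setNames(
      sample(c("mutation", "amplification", "deletion"), n_pert, replace = TRUE),
      perturbed)

    mutation <- matrix(0L, n_genes, n_tumors, dimnames = list(genes, tumors))
    gistic <- matrix(0L, n_genes, n_tumors, dimnames = list(genes, tumors))
    # biological spread for non-signature genes; signature genes stay flat
    expr <- matrix(base_expr, n_genes, length(samples),
                   dimnames = list(genes, samples))
    nonsig <- c(drivers, bg_genes)
    expr[nonsig, ] <- base_expr *
      exp(matrix(stats::rnorm(length(nonsig) * length(samples), 0, bio_sd),
                 length(nonsig), length(samples)))

    # planted driver events
    for (t in perturbed) {
      g <- assignment[[t]]
      switch(event_type[[t]],
             mutation = { mutation[g, t] <- 1L },
             amplification = { gistic[g, t] <- 2L },
             deletion = { gistic[g, t] <- -2L })
    }
    # CNV concordance: shift expression to z = +/-3 against the GISTIC-0
    # background of the same generated matrix
    for (g in drivers) {
      cnv <- tumors[gistic[g, ] != 0L]
      if (!length(cnv)) next
      bg <- expr[g, tumors[gistic[g, tumors] == 0L]]
      m_g <- mean(bg); d_g <- stats::sd(bg)
      expr[g, cnv] <- m_g + 3 * d_g * sign(gistic[g, cnv])
    }
    # signature genes: exact fold_effect in perturbed tumors, measured with
    # the pipeline's pseudocount against the (deterministic) normal median
    ref <- base_expr
    expr[sig_genes, perturbed] <- fold_effect * (ref + eps) - eps
    # passenger mutations on background genes
    if (passenger_rate > 0 && n_bg > 0) {
      hits <- matrix(stats::runif(n_bg * n_tumors) < passenger_rate,
                     n_bg, n_tumors)
      mutation[bg_genes, ][hits] <- 1L
    }
    if (noise_sd > 0) {
      expr <- expr * exp(matrix(stats::rnorm(length(expr), 0, noise_sd),
                                nrow(expr), ncol(expr)))
    }
    ann <- data.frame(sample = samples,
                      type = rep(c("tumor", "normal"),
                                 c(n_tumors, n_normals)),
                      stringsAsFactors = FALSE)
    cohort <- cohort_data(mutation, gistic, expr, ann)
    list(cohort = cohort,
         signatures = list(list(id = "SIG_MODULE",
                                description = "planted co-regulated signature",
                                genes = sig_genes)),
         truth = list(drivers = drivers,
                      assignment = assignment,
                      event_type = event_type,
                      perturbed = perturbed,
                      unperturbed = setdiff(tumors, perturbed),
                      params = list(n_tumors = n_tumors, n_normals = n_normals,
                                    n_genes = n_genes,
                                    signature_size = signature_size,
                                    n_drivers = n_drivers,
                                    passenger_rate = passenger_rate,
                                    fold_effect = fold_effect,
                                    noise_sd = noise_sd,
                                    perturbed_frac = perturbed_frac,
                                    bio_sd = bio_sd, base_expr = base_expr,
                                    eps = eps),
                      seed = seed))
  })
}

#' Random k-uniform set family
#'
#' Samples `m` sets of exactly `set_size` elements each (uniformly without
#' replacement) over an `n`-element universe.  With `set_size = 3` this
#' generates instances of the maximum 3-set packing correspondence: a
#' pairwise-disjoint subfamily of 3-sets covers exactly three elements per
#' set, so maximum coverage equals three times the maximum packing size.
#'
#' @param m Number of sets.
#' @param n Universe size (must be at least `set_size`).
#' @param set_size Exact set size (default 3).
#' @param weight_range Uniform weight range (default all 0).
#' @param seed Integer seed.
#' @return A normalized [cover_instance()].
#' @export
random_uniform_instance <- function(m, n, set_size = 3,
                                    weight_range = c(0, 0), seed) {
  if (n < set_size) stop("universe smaller than set_size")
  with_seed(seed, {
    universe <- sprintf("e%03d", seq_len(n))
    sets <- lapply(seq_len(m), function(i) sample(universe, set_size))
    names(sets) <- sprintf("U%03d", seq_len(m))
    weights <- stats::runif(m, weight_range[1], weight_range[2])
    normalize_instance(cover_instance(sets, weights, universe))
  })
}
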