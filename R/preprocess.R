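#' Assemble a cohort data object
#'
#' Bundles the three gene-by-sample matrices and the sample annotation that
#' the preprocessing pipeline consumes.  Tumor columns must agree across the
#' mutation, GISTIC and expression matrices; the expression matrix
#' additionally carries the normal samples used as the fold-change reference.
#'
#' @param mutation Gene x tumor 0/1 matrix (1 = non-silent somatic mutation).
#' @param gistic Gene x tumor integer matrix with values in -2..2.
#' @param expression Gene x sample numeric matrix (tumors and normals).
#' @param sample_annotation Data frame with columns `sample` and `type`
#'   (`"tumor"` or `"normal"`).
#' @return A `cohort_data` object.
#' @export
cohort_data <- function(mutation, gistic, expression, sample_annotation) {
  mutation <- as.matrix(mutation)
  gistic <- as.matrix(gistic)
  expression <- as.matrix(expression)
  ann <- as.data.frame(sample_annotation, stringsAsFactors = FALSE)
  if (!all(c("sample", "type") %in% names(ann))) {
    stop("sample_annotation needs columns `sample` and `type`")
  }
  if (!all(ann$type %in% c("tumor", "normal"))) {
    stop("sample types must be 'tumor' or 'normal'")
  }
  tumors <- ann$sample[ann$type == "tumor"]
  normals <- ann$sample[ann$type == "normal"]
  if (!length(normals)) stop("at least one normal sample is required")
  if (!identical(sort_cstr(colnames(mutation)), sort_cstr(tumors)) ||
      !identical(sort_cstr(colnames(gistic)), sort_cstr(tumors))) {
    stop("mutation/gistic columns must be exactly the annotated tumors")
  }
  if (!all(c(tumors, normals) %in% colnames(expression))) {
    stop("expression matrix must cover all annotated samples")
  }
  if (!all(mutation %in% c(0, 1))) stop("mutation matrix must be 0/1")
  if (!all(gistic %in% -2:2)) stop("GISTIC values must be in {-2,-1,0,1,2}")
  structure(list(mutation = mutation, gistic = gistic,
                 expression = expression, sample_annotation = ann,
                 tumors = tumors, normals = normals),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("cohort_data: %d tumors, %d normals; %d mutation genes, %d expression genes\n",
              length(x$tumors), length(x$normals),
              nrow(x$mutation), nrow(x$expression)))
  invisible(x)
}

#' Call valid SGA events per gene and tumor
#'
#' A gene carries a valid somatic-genome-alteration (SGA) event in a tumor if
#' it has a non-silent somatic mutation there, or a high-level copy-number
#' call with concordant expression: GISTIC +2 with expression z-score at
#' least `z_threshold`, or GISTIC -2 with z-score at most `-z_threshold`.
#' The z-score background for each gene is its expression across tumors with
#' GISTIC 0 (mean `m_g`, sd `d_g`); 1.64 corresponds to one-sided p = 0.05.
#'
#' Genes whose background is undefined (fewer than 2 GISTIC-0 tumors, or zero
#' background sd) have their copy-number channel skipped with a warning; the
#' mutation channel is unaffected.
#'
#' @param cohort A [cohort_data()] object.
#' @param z_threshold Inclusive z-score cutoff (default 1.64).
#' @return A `valid_sga` map: named list, gene -> sorted character vector of
#'   tumor ids with a valid event.
#' @export
call_valid_sga <- function(cohort, z_threshold = 1.64) {
  stopifnot(inherits(cohort, "cohort_data"))
  tumors <- cohort$tumors
  genes <- sort_cstr(union(rownames(cohort$mutation), rownames(cohort$gistic)))
  out <- stats::setNames(vector("list", length(genes)), genes)
  skipped <- character(0)
  for (g in genes) {
    valid <- character(0)
    if (g %in% rownames(cohort$mutation)) {
      valid <- tumors[cohort$mutation[g, tumors] == 1]
    }
    if (g %in% rownames(cohort$gistic) && g %in% rownames(cohort$expression)) {
      gi <- cohort$gistic[g, tumors]
      cnv_tumors <- tumors[abs(gi) == 2]
      if (length(cnv_tumors)) {
        bg <- cohort$expression[g, tumors[gi == 0]]
        if (length(bg) < 2 || stats::sd(bg) == 0) {
          skipped <- c(skipped, g)
        } else {
          z <- (cohort$expression[g, cnv_tumors] - mean(bg)) / stats::sd(bg)
          hit <- (gi[cnv_tumors] == 2 & z >= z_threshold) |
                 (gi[cnv_tumors] == -2 & z <= -z_threshold)
          valid <- union(valid, cnv_tumors[hit])
        }
      }
    }
    out[[g]] <- sort_cstr(valid)
  }
  if (length(skipped)) {
    warning("copy-number channel skipped for ", length(skipped),
            " gene(s) with undefined GISTIC-0 background: ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  }
  structure(out[lengths(out) > 0], class = "valid_sga")
}

#' Remove rarely altered genes
#'
#' Genes with valid SGA events in no more than `min_tumors` tumors are
#' removed (default 5, so genes need at least 6 events to survive).
#'
#' @param sga A `valid_sga` map.
#' @param min_tumors Genes with `<= min_tumors` events are dropped.
#' @return Filtered `valid_sga` map.
#' @export
filter_rare_genes <- function(sga, min_tumors = 5) {
  structure(sga[lengths(sga) > min_tumors], class = "valid_sga")
}

#' Per-tumor expression fold changes against the normal reference
#'
#' For each gene the reference is the middle value (median by default) of its
#' expression across normal samples; each tumor's fold change is
#' `(tumor + eps) / (reference + eps)` on a linear scale.  The pseudocount
#' `eps` guards against zero references.  If the input is log2 it is unlogged
#' first.
#'
#' @param expression Gene x sample matrix.
#' @param sample_annotation As in [cohort_data()].
#' @param eps Pseudocount (default 1).
#' @param center `"median"` (default) or `"mean"` of normal expression.
#' @param log2_input If `TRUE`, `expression` holds log2 values.
#' @return Gene x tumor matrix of fold changes (ratios; a value below 1 is a
#'   down-regulation of magnitude `1/fold`).
#' @export
fold_changes <- function(expression, sample_annotation, eps = 1,
                         center = c("median", "mean"), log2_input = FALSE) {
  center <- match.arg(center)
  expression <- as.matrix(expression)
  if (log2_input) expression <- 2^expression
  ann <- as.data.frame(sample_annotation, stringsAsFactors = FALSE)
  normals <- intersect(ann$sample[ann$type == "normal"], colnames(expression))
  tumors <- intersect(ann$sample[ann$type == "tumor"], colnames(expression))
  if (!length(normals)) stop("no normal samples in expression matrix")
  cfun <- if (center == "median") stats::median else mean
  ref <- apply(expression[, normals, drop = FALSE], 1, cfun)
  denom <- ref + eps
  if (any(denom == 0)) stop("zero reference after pseudocount; increase eps")
  folds <- sweep(expression[, tumors, drop = FALSE] + eps, 1, denom, "/")
  folds
}

#' Partition tumors by signature expression status
#'
#' Splits tumors into `S_p` (signature perturbed) and `S_n` (normal-like):
#' a tumor joins `S_p` up-regulated if strictly more than `sp_frac` (75 %) of
#' the signature's genes are at least `up_fold`-fold (3x) up, or `S_p`
#' down-regulated with the mirrored rule; it joins `S_n` if at least
#' `sn_frac` (50 %) of signature genes change by less than `near_fold` (2x)
#' in either direction.  If the smaller of the up/down sub-groups holds fewer
#' than `subgroup_frac` (10 %) of the larger's tumors it is dropped from
#' `S_p`; otherwise the signature is rejected as bidirectionally perturbed.
#' The partition is accepted only when `|S_p| > min_sp` (30).
#'
#' @param signature Character vector of signature gene ids.
#' @param folds Gene x tumor fold-change matrix from [fold_changes()].
#' @param signature_id Identifier carried into the result.
#' @param up_fold,near_fold,sp_frac,sn_frac,subgroup_frac,min_sp Thresholds;
#'   defaults as above.
#' @return A `signature_partition`: list with `signature_id`, `S_p`, `S_n`,
#'   `direction` (named `"up"`/`"down"` per `S_p` tumor), `status`
#'   (`"accepted"` or `"rejected"`) and `reason`.
#' @export
partition_tumors <- function(signature, folds, signature_id = "signature",
                             up_fold = 3, near_fold = 2, sp_frac = 0.75,
                             sn_frac = 0.5, subgroup_frac = 0.1, min_sp = 30) {
  signature <- unique(as.character(signature))
  if (!length(signature)) stop("empty signature")
  present <- intersect(signature, rownames(folds))
  if (length(present) < length(signature)) {
    warning(signature_id, ": ", length(signature) - length(present),
            " signature gene(s) missing from the fold table")
  }
  if (!length(present)) {
    return(new_partition(signature_id, character(0), character(0),
                         character(0), "rejected", "no signature genes in data"))
  }
  f <- folds[present, , drop = FALSE]
  frac_up <- colMeans(f >= up_fold)
  frac_down <- colMeans(f <= 1 / up_fold)
  frac_near <- colMeans(pmax(f, 1 / f) < near_fold)
  tumors <- colnames(f)
  sp_up <- tumors[frac_up > sp_frac]
  sp_down <- tumors[frac_down > sp_frac]
  in_sp <- tumors %in% c(sp_up, sp_down)
  s_n <- tumors[!in_sp & frac_near >= sn_frac]
  direction <- c(stats::setNames(rep("up", length(sp_up)), sp_up),
                 stats::setNames(rep("down", length(sp_down)), sp_down))
  small <- if (length(sp_up) <= length(sp_down)) sp_up else sp_down
  large <- if (length(sp_up) <= length(sp_down)) sp_down else sp_up
  if (length(small) > 0 && length(large) > 0) {
    if (length(small) < subgroup_frac * length(large)) {
      direction <- direction[setdiff(names(direction), small)]
    } else {
      return(new_partition(signature_id, character(0), character(0),
                           character(0), "rejected",
                           "signature both up- and down-regulated in comparable sub-groups"))
    }
  }
  s_p <- sort_cstr(names(direction))
  if (length(s_p) <= min_sp) {
    return(new_partition(signature_id, s_p, sort_cstr(s_n), direction,
                         "rejected",
                         sprintf("|S_p| = %d not greater than %d",
                                 length(s_p), min_sp)))
  }
  new_partition(signature_id, s_p, sort_cstr(s_n), direction, "accepted", NA_character_)
}

new_partition <- function(signature_id, s_p, s_n, direction, status, reason) {
  structure(list(signature_id = signature_id, S_p = s_p, S_n = s_n,
                 direction = direction, status = status, reason = reason),
            class = "signature_partition")
}

#' @export
print.signature_partition <- function(x, ...) {
  cat(sprintf("signature_partition '%s': |S_p| = %d, |S_n| = %d, %s%s\n",
              x$signature_id, length(x$S_p), length(x$S_n), x$status,
              if (is.na(x$reason)) "" else paste0(" (", x$reason, ")")))
  invisible(x)
}

# Upper-tail hypergeometric probability P(X >= k) for X ~ Hypergeom with
# `n` draws from `K` successes among `N`.  Shared by gene weighting and
# module enrichment.  Clamped into (0, 1] so -log2 stays finite.
hyper_upper_tail <- function(k, K, N, n) {
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  min(max(p, .Machine$double.xmin), 1)
}

#' Hypergeometric gene weights against a tumor partition
#'
#' For each gene with at least one valid SGA event among the partitioned
#' tumors, the weight is the upper-tail hypergeometric probability of seeing
#' at least the observed number of events inside `S_p`:
#' `N = |S_p| + |S_n|` tumors, `K = |S_p|` of them perturbed, `n_g` tumors
#' with an event, `k_g` of those in `S_p`.  A smaller weight means the
#' gene's events are more informative about the signature's common signal;
#' tumors in neither subset carry no information and are excluded.
#'
#' @param sga A `valid_sga` map (typically after [filter_rare_genes()]).
#' @param partition An accepted [partition_tumors()] result.
#' @return A data frame (`gene`, `k_p`, `k_n`, `n_g`, `weight`) sorted by
#'   ascending weight, then gene id.
#' @export
compute_weights <- function(sga, partition) {
  stopifnot(inherits(partition, "signature_partition"))
  if (!identical(partition$status, "accepted")) {
    stop("partition is not accepted: ", partition$reason)
  }
  K <- length(partition$S_p)
  N <- K + length(partition$S_n)
  rows <- lapply(names(sga), function(g) {
    k_p <- sum(sga[[g]] %in% partition$S_p)
    k_n <- sum(sga[[g]] %in% partition$S_n)
    n_g <- k_p + k_n
    if (n_g == 0 || N == 0) return(NULL)
    data.frame(gene = g, k_p = k_p, k_n = k_n, n_g = n_g,
               weight = hyper_upper_tail(k_p, K, N, n_g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(gene = character(0), k_p = integer(0), k_n = integer(0),
               n_g = integer(0), weight = numeric(0)))))
  out <- out[order(out$weight, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select candidate driver genes by weight
#'
#' Keeps genes with weight strictly below `max_weight` (0.2), sorted by
#' ascending weight (ties by gene id), truncated to the best `top_k` (200).
#'
#' @param weights Data frame from [compute_weights()].
#' @param top_k Maximum number of candidates (default 200).
#' @param max_weight Strict upper bound on the weight (default 0.2).
#' @return Character vector of candidate gene ids.
#' @export
select_candidates <- function(weights, top_k = 200, max_weight = 0.2) {
  w <- weights[weights$weight < max_weight, , drop = FALSE]
  w <- w[order(w$weight, w$gene, method = "radix"), , drop = FALSE]
  utils::head(w$gene, top_k)
}

#' Build the solver instance for one signature
#'
#' The universe is `S_p`; each candidate gene becomes a weighted set holding
#' its valid-SGA tumors restricted to `S_p` (candidates whose restriction is
#' empty are dropped).
#'
#' @param partition An accepted [partition_tumors()] result.
#' @param sga A `valid_sga` map.
#' @param weights Data frame from [compute_weights()].
#' @param candidates Character vector from [select_candidates()].
#' @return A normalized [cover_instance()].
#' @export
build_cover_instance <- function(partition, sga, weights, candidates) {
  stopifnot(inherits(partition, "signature_partition"))
  if (!identical(partition$status, "accepted")) {
    stop("partition is not accepted: ", partition$reason)
  }
  wmap <- stats::setNames(weights$weight, weights$gene)
  sets <- lapply(candidates, function(g) intersect(sga[[g]], partition$S_p))
  names(sets) <- candidates
  sets <- sets[lengths(sets) > 0]
  inst <- cover_instance(sets = sets, weights = wmap[names(sets)],
                         universe = partition$S_p)
  normalize_instance(inst)
}

#' Run the full preprocessing for one signature
#'
#' Convenience chain: fold changes, tumor partition, gene weights, candidate
#' selection, and instance construction, using the thresholds in `config`
#' (see [default_config()]).
#'
#' @param cohort A [cohort_data()] object.
#' @param signature Character vector of signature genes.
#' @param signature_id Identifier.
#' @param config Threshold list, see [default_config()].
#' @param sga Optional precomputed, rare-filtered `valid_sga` map (saves
#'   recomputation across signatures).
#' @return List with `partition`, `weights`, `candidates`, `instance` (NULL
#'   unless accepted).
#' @export
preprocess_signature <- function(cohort, signature, signature_id = "signature",
                                 config = default_config(), sga = NULL) {
  cfg <- validate_config(config)
  if (is.null(sga)) {
    sga <- filter_rare_genes(call_valid_sga(cohort, cfg$z_threshold),
                             cfg$min_event_tumors)
  }
  folds <- fold_changes(cohort$expression, cohort$sample_annotation,
                        eps = cfg$eps, center = cfg$center,
                        log2_input = cfg$log2_input)
  part <- partition_tumors(signature, folds, signature_id,
                           up_fold = cfg$up_fold, near_fold = cfg$near_fold,
                           sp_frac = cfg$sp_frac, sn_frac = cfg$sn_frac,
                           subgroup_frac = cfg$subgroup_frac,
                           min_sp = cfg$min_sp)
  if (!identical(part$status, "accepted")) {
    return(list(partition = part, weights = NULL, candidates = NULL,
                instance = NULL))
  }
  w <- compute_weights(sga, part)
  cand <- select_candidates(w, top_k = cfg$top_k, max_weight = cfg$max_weight)
  inst <- build_cover_instance(part, sga, w, cand)
  list(partition = part, weights = w, candidates = cand, instance = inst)
}
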