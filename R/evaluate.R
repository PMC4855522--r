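#' Module enrichment p-value against the tumor partition
#'
#' Pooled hypergeometric test of whether the module's SGA events concentrate
#' in `S_p`: among the `N = |S_p| + |S_n|` partitioned tumors, `K = |S_p|`
#' are perturbed; `n` tumors carry at least one valid event in any module
#' gene (a tumor counts once however many genes hit it, matching the
#' mutual-exclusivity framing where each tumor carries at most one module
#' event), `k` of them in `S_p`.  Returns the upper-tail probability
#' `P(X >= k)`.  For a single-gene module this is exactly the gene's
#' [compute_weights()] weight (shared tail implementation).
#'
#' @param genes Non-empty character vector of module gene ids.
#' @param sga A `valid_sga` map.
#' @param partition An accepted [partition_tumors()] result.
#' @return p-value in (0, 1].
#' @export
module_enrichment_pvalue <- function(genes, sga, partition) {
  stopifnot(inherits(partition, "signature_partition"))
  if (!identical(partition$status, "accepted")) {
    stop("partition is not accepted: ", partition$reason)
  }
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("empty module gene list")
  hit <- unique(unlist(sga[intersect(genes, names(sga))], use.names = FALSE))
  K <- length(partition$S_p)
  N <- K + length(partition$S_n)
  n <- sum(c(partition$S_p, partition$S_n) %in% hit)
  if (n == 0) {
    warning("module hits no partitioned tumor; p = 1")
    return(1)
  }
  k <- sum(partition$S_p %in% hit)
  hyper_upper_tail(k, K, N, n)
}

#' Build a module report for a solved signature
#'
#' @param partition An accepted [partition_tumors()] result.
#' @param solution A [cover_solution()] whose chosen ids are gene symbols.
#' @param sga A `valid_sga` map.
#' @return A `module_report`: list with `signature_id`, `genes`, `coverage`,
#'   `weight`, `enrichment_p`, `neg_log2_p`.
#' @export
module_report <- function(partition, solution, sga) {
  p <- if (length(solution$chosen)) {
    module_enrichment_pvalue(solution$chosen, sga, partition)
  } else 1
  structure(list(signature_id = partition$signature_id,
                 genes = solution$chosen,
                 coverage = solution$coverage,
                 weight = solution$weight,
                 enrichment_p = p,
                 neg_log2_p = -log2(p)),
            class = "module_report")
}

#' @export
print.module_report <- function(x, ...) {
  cat(sprintf("module_report '%s': {%s}\n  coverage %d, weight %.4g, enrichment p %.3g (-log2 p = %.2f)\n",
              x$signature_id, paste(x$genes, collapse = ", "),
              x$coverage, x$weight, x$enrichment_p, x$neg_log2_p))
  invisible(x)
}
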