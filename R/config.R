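#' Default pipeline configuration
#'
#' All thresholds of the preprocessing pipeline with their standard values,
#' plus solver options.  Fields:
#' \describe{
#'   \item{z_threshold}{Inclusive expression z-score cutoff for copy-number
#'     concordance (1.64, one-sided p = 0.05).}
#'   \item{min_event_tumors}{Genes with at most this many valid-SGA tumors
#'     are removed (5).}
#'   \item{eps}{Fold-change pseudocount (1).}
#'   \item{center}{Normal-reference middle value, "median" or "mean".}
#'   \item{log2_input}{Whether the expression matrix is log2 (FALSE).}
#'   \item{up_fold}{Significant per-gene regulation fold (3).}
#'   \item{near_fold}{Normal-like per-gene fold bound (2).}
#'   \item{sp_frac}{Strict fraction of signature genes required for S_p
#'     membership (0.75).}
#'   \item{sn_frac}{Inclusive fraction of near-normal genes for S_n (0.5).}
#'   \item{subgroup_frac}{Small up/down sub-group tolerance (0.1).}
#'   \item{min_sp}{S_p must be strictly larger than this (30).}
#'   \item{max_signature_genes}{Signatures with at least 50 genes are
#'     dropped at load time (49 allowed).}
#'   \item{top_k}{Candidate cap (200).}
#'   \item{max_weight}{Strict candidate weight bound (0.2).}
#'   \item{oracle_check}{Cross-check the solver against brute force when
#'     feasible (FALSE).}
#'   \item{max_brute_m}{Brute-force refusal bound (20).}
#' }
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(z_threshold = 1.64,
       min_event_tumors = 5,
       eps = 1,
       center = "median",
       log2_input = FALSE,
       up_fold = 3,
       near_fold = 2,
       sp_frac = 0.75,
       sn_frac = 0.5,
       subgroup_frac = 0.1,
       min_sp = 30,
       max_signature_genes = 49,
       top_k = 200,
       max_weight = 0.2,
       oracle_check = FALSE,
       max_brute_m = 20)
}

#' Validate a configuration list
#'
#' Fills missing fields with defaults, rejects unknown keys, and checks each
#' threshold's domain.
#'
#' @param config Named list (possibly partial).
#' @return Completed, validated configuration list.
#' @export
validate_config <- function(config) {
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(def, config)
  # canonical types, so JSON round-trips compare identical
  for (key in names(def)) {
    cfg[[key]] <- if (is.numeric(def[[key]])) as.numeric(cfg[[key]])
                  else if (is.logical(def[[key]])) as.logical(cfg[[key]])
                  else as.character(cfg[[key]])
  }
  chk <- function(ok, what) if (!ok) stop("config: ", what)
  chk(is.numeric(cfg$z_threshold) && cfg$z_threshold >= 0, "z_threshold must be >= 0")
  chk(cfg$min_event_tumors >= 0, "min_event_tumors must be >= 0")
  chk(is.numeric(cfg$eps) && cfg$eps >= 0, "eps must be >= 0")
  chk(cfg$center %in% c("median", "mean"), "center must be 'median' or 'mean'")
  chk(is.logical(cfg$log2_input), "log2_input must be logical")
  chk(cfg$up_fold > 1, "up_fold must exceed 1")
  chk(cfg$near_fold > 1, "near_fold must exceed 1")
  chk(cfg$sp_frac > 0 && cfg$sp_frac < 1, "sp_frac must be in (0,1)")
  chk(cfg$sn_frac > 0 && cfg$sn_frac <= 1, "sn_frac must be in (0,1]")
  chk(cfg$subgroup_frac >= 0 && cfg$subgroup_frac <= 1, "subgroup_frac must be in [0,1]")
  chk(cfg$min_sp >= 0, "min_sp must be >= 0")
  chk(cfg$max_signature_genes >= 1, "max_signature_genes must be >= 1")
  chk(cfg$top_k >= 1, "top_k must be >= 1")
  chk(cfg$max_weight > 0 && cfg$max_weight <= 1, "max_weight must be in (0,1]")
  chk(is.logical(cfg$oracle_check), "oracle_check must be logical")
  chk(cfg$max_brute_m >= 1, "max_brute_m must be >= 1")
  cfg
}

#' Read or write a configuration file (JSON)
#'
#' Configuration files are JSON objects of the fields in [default_config()];
#' `read_config(write_config(cfg, path))` returns `cfg` unchanged.
#'
#' @param path File path.
#' @return `read_config`: validated config list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_config(cfg)
}

#' @param config Config list.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  cfg <- validate_config(config)
  jsonlite::write_json(cfg[sort_cstr(names(cfg))], path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
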