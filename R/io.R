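# --- instance files ---------------------------------------------------------

#' Read a cover instance from TSV or JSON
#'
#' TSV dialect: one row per set, `set_id<TAB>weight<TAB>elem1,elem2,...`;
#' lines starting with `#` are comments, except that a `#universe:` line
#' lists extra (possibly uncovered) universe elements, comma-separated.
#' JSON dialect: an object with `universe` (array) and `sets` (array of
#' `{id, weight, elements}`).  The parsed instance is validated and
#' normalized.
#'
#' @param path File path.
#' @param format `"tsv"`, `"json"`, or `"auto"` (by file extension).
#' @return A normalized [cover_instance()].
#' @export
read_instance <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") return(read_instance_json(path))
  read_instance_tsv(path)
}

read_instance_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  extra_universe <- character(0)
  sets <- list()
  weights <- numeric(0)
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "#")) {
      if (grepl("^#universe:", line)) {
        spec <- trimws(sub("^#universe:", "", line))
        if (nzchar(spec)) {
          extra_universe <- c(extra_universe,
                              trimws(strsplit(spec, ",")[[1]]))
        }
      }
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 3) {
      stop(sprintf("%s:%d: expected 3 tab-separated fields, got %d",
                   path, i, length(fields)))
    }
    id <- trimws(fields[[1]])
    if (!nzchar(id)) stop(sprintf("%s:%d: empty set_id", path, i))
    if (id %in% names(sets)) {
      stop(sprintf("%s:%d: duplicate set_id '%s'", path, i, id))
    }
    w <- suppressWarnings(as.numeric(fields[[2]]))
    if (is.na(w)) {
      stop(sprintf("%s:%d: non-numeric weight '%s'", path, i, fields[[2]]))
    }
    elems <- trimws(strsplit(fields[[3]], ",", fixed = TRUE)[[1]])
    elems <- elems[nzchar(elems)]
    sets[[id]] <- elems
    weights[[id]] <- w
  }
  universe <- union(unlist(sets, use.names = FALSE), extra_universe)
  normalize_instance(cover_instance(sets, weights, universe))
}

read_instance_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$sets)) stop(path, ": missing 'sets' field")
  sets <- list()
  weights <- numeric(0)
  for (i in seq_along(obj$sets)) {
    s <- obj$sets[[i]]
    if (is.null(s$id) || is.null(s$weight) || is.null(s$elements)) {
      stop(sprintf("%s: set #%d lacks id/weight/elements", path, i))
    }
    id <- as.character(s$id)
    if (id %in% names(sets)) {
      stop(sprintf("%s: duplicate set_id '%s'", path, id))
    }
    w <- suppressWarnings(as.numeric(s$weight))
    if (is.na(w)) stop(sprintf("%s: non-numeric weight for set '%s'", path, id))
    sets[[id]] <- vapply(s$elements, as.character, "")
    weights[[id]] <- w
  }
  universe <- union(unlist(sets, use.names = FALSE),
                    vapply(obj$universe, as.character, ""))
  normalize_instance(cover_instance(sets, weights, universe))
}

#' Write a cover instance to TSV or JSON
#'
#' Deterministic, byte-stable output (sets in sorted id order) that
#' round-trips through [read_instance()].
#'
#' @param instance A [cover_instance()].
#' @param path Output path.
#' @param format `"tsv"`, `"json"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_instance <- function(instance, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  inst <- normalize_instance(instance)
  if (format == "json") {
    obj <- list(
      universe = inst$universe,
      sets = lapply(names(inst$sets), function(id) {
        list(id = id, weight = inst$weights[[id]], elements = inst$sets[[id]])
      }))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    uncovered <- setdiff(inst$universe, unlist(inst$sets, use.names = FALSE))
    lines <- c(
      "# set_id\tweight\telements",
      if (length(uncovered)) paste0("#universe: ",
                                    paste(uncovered, collapse = ",")),
      vapply(names(inst$sets), function(id) {
        sprintf("%s\t%s\t%s", id, format(inst$weights[[id]], digits = 17),
                paste(inst$sets[[id]], collapse = ","))
      }, ""))
    writeLines(lines, path)
  }
  invisible(path)
}

# --- GMT signatures ---------------------------------------------------------

#' Read gene signatures from a GMT file
#'
#' Each line is `signature_id<TAB>description<TAB>gene1<TAB>gene2...`.
#' Signatures with `max_genes + 1` or more genes are dropped with a warning
#' (the pipeline only uses signatures of fewer than 50 genes).
#'
#' @param path GMT file path.
#' @param max_genes Largest retained signature size (default 49).
#' @return List of signatures: `id`, `description`, `genes`.
#' @export
read_gmt <- function(path, max_genes = 49) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  dropped <- character(0)
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("%s:%d: GMT line needs at least 3 tab fields", path, i))
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) > max_genes) {
      dropped <- c(dropped, fields[[1]])
      next
    }
    out[[length(out) + 1L]] <- list(id = fields[[1]],
                                    description = fields[[2]],
                                    genes = genes)
  }
  if (length(dropped)) {
    warning("dropped ", length(dropped), " signature(s) with more than ",
            max_genes, " genes: ", paste(dropped, collapse = ", "))
  }
  out
}

#' @param signatures List of signatures (`id`, `description`, `genes`).
#' @rdname read_gmt
#' @export
write_gmt <- function(signatures, path) {
  lines <- vapply(signatures, function(s) {
    paste(c(s$id, s$description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# --- matrices and tables ----------------------------------------------------

#' Read or write a gene-by-sample TSV matrix
#'
#' UTF-8, tab-delimited, first row sample ids, first column gene ids, no
#' quoting.
#'
#' @param path File path.
#' @return `read_matrix_tsv`: a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1,
                          stringsAsFactors = FALSE)
  as.matrix(df)
}

#' @param mat Matrix with row and column names.
#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write the sample annotation table
#'
#' Two tab-separated columns with header: `sample`, `type` (tumor/normal).
#'
#' @param path File path.
#' @return `read_sample_annotation`: data frame with `sample`, `type`.
#' @export
read_sample_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "type") %in% names(df))) {
    stop(path, ": needs columns 'sample' and 'type'")
  }
  if (!all(df$type %in% c("tumor", "normal"))) {
    stop(path, ": sample type must be 'tumor' or 'normal'")
  }
  df
}

#' @param annotation Data frame with `sample`, `type`.
#' @rdname read_sample_annotation
#' @export
write_sample_annotation <- function(annotation, path) {
  utils::write.table(annotation[, c("sample", "type")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a valid-SGA map as TSV
#'
#' Rows of `gene<TAB>tumor1,tumor2,...`, with a header comment.
#'
#' @param path File path.
#' @return `read_valid_sga`: a `valid_sga` map.
#' @export
read_valid_sga <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2) {
      stop(sprintf("%s:%d: expected 2 tab fields", path, i))
    }
    if (fields[[1]] %in% names(out)) {
      stop(sprintf("%s:%d: duplicate gene '%s'", path, i, fields[[1]]))
    }
    out[[fields[[1]]]] <- sort_cstr(trimws(strsplit(fields[[2]], ",")[[1]]))
  }
  structure(out, class = "valid_sga")
}

#' @param sga A `valid_sga` map.
#' @rdname read_valid_sga
#' @export
write_valid_sga <- function(sga, path) {
  ids <- sort_cstr(names(sga))
  lines <- c("# gene\ttumors",
             vapply(ids, function(g) {
               sprintf("%s\t%s", g, paste(sort_cstr(sga[[g]]), collapse = ","))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a signature partition as TSV
#'
#' Columns `tumor`, `group` (`S_p`/`S_n`) and `direction` (`up`/`down`, empty
#' for `S_n`), preceded by comment lines recording the signature id and
#' status.
#'
#' @param path File path.
#' @return `read_partition`: a `signature_partition`.
#' @export
read_partition <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- list(signature_id = "signature", status = "accepted",
               reason = NA_character_)
  for (key in c("signature_id", "status", "reason")) {
    hit <- grep(sprintf("^#%s:", key), lines, value = TRUE)
    if (length(hit)) {
      val <- trimws(sub(sprintf("^#%s:", key), "", hit[[1]]))
      meta[[key]] <- if (identical(val, "NA")) NA_character_ else val
    }
  }
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  s_p <- character(0); s_n <- character(0); direction <- character(0)
  if (length(body) > 1) {
    for (line in body[-1]) {
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(fields) < 2) stop(path, ": malformed partition row")
      if (fields[[2]] == "S_p") {
        s_p <- c(s_p, fields[[1]])
        direction[[fields[[1]]]] <- fields[[3]]
      } else if (fields[[2]] == "S_n") {
        s_n <- c(s_n, fields[[1]])
      } else stop(path, ": unknown group '", fields[[2]], "'")
    }
  }
  new_partition(meta$signature_id, sort_cstr(s_p), sort_cstr(s_n),
                direction, meta$status, meta$reason)
}

#' @param partition A `signature_partition`.
#' @rdname read_partition
#' @export
write_partition <- function(partition, path) {
  rows <- c(
    sprintf("#signature_id: %s", partition$signature_id),
    sprintf("#status: %s", partition$status),
    sprintf("#reason: %s", if (is.na(partition$reason)) "NA" else partition$reason),
    "tumor\tgroup\tdirection",
    vapply(partition$S_p, function(t) {
      sprintf("%s\tS_p\t%s", t, partition$direction[[t]])
    }, ""),
    vapply(partition$S_n, function(t) sprintf("%s\tS_n\t", t), ""))
  writeLines(rows, path)
  invisible(path)
}

# --- solution / evaluation reports ------------------------------------------

#' Write a solver report as byte-stable JSON
#'
#' The report combines a solution and its search statistics:
#' `{chosen, coverage, weight, stats{...}}`, keys sorted, and round-trips
#' through [read_report()].  NaN or infinite numeric values are refused.
#'
#' @param report List with `chosen`, `coverage`, `weight` and optionally
#'   `stats` (as returned by [wmem_solve()]), or a full `module_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "cover_solution")) {
    report <- list(chosen = report$chosen, coverage = report$coverage,
                   weight = report$weight)
  }
  obj <- sort_keys_deep(unclass(report))
  bad <- any(rapply(obj, function(x) {
    is.numeric(x) && any(!is.finite(x))
  }, how = "unlist"))
  if (bad) stop("report contains non-finite numeric values")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sort_keys_deep <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && all(nzchar(names(x)))) {
      x <- x[sort_cstr(names(x))]
    }
    lapply(x, sort_keys_deep)
  } else x
}

#' @rdname write_report
#' @return `read_report`: the parsed report list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
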