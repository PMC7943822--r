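# Shared domain containers and on-disk formats.
#
# An expression matrix is a plain numeric matrix, genes in rows and samples in
# columns, with unique dimnames -- the convention of the co-expression tool
# family this package belongs to. Validation is centralized here so every
# reader and every pipeline stage enforces the same contract.

#' Validate an expression matrix
#'
#' Checks the container contract used throughout the package: a finite numeric
#' matrix with unique, non-empty gene (row) and sample (column) identifiers.
#'
#' @param expr numeric matrix, genes x samples, with dimnames.
#' @return `expr`, invisibly, if valid; otherwise an error naming the
#'   offending record.
#' @export
validate_expression_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  gene_ids <- rownames(expr)
  sample_ids <- colnames(expr)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("expression matrix must carry gene rownames and sample colnames",
         call. = FALSE)
  }
  .check_unique_ids(gene_ids, "gene")
  .check_unique_ids(sample_ids, "sample")
  if (!all(is.finite(expr))) {
    bad <- which(!is.finite(expr), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 gene_ids[bad[1L]], sample_ids[bad[2L]]), call. = FALSE)
  }
  invisible(expr)
}

.check_unique_ids <- function(ids, what) {
  if (any(!nzchar(ids)) || anyNA(ids)) {
    stop(sprintf("empty %s identifier", what), call. = FALSE)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate %s identifier: '%s'", what, dup[1L]),
         call. = FALSE)
  }
  invisible(ids)
}

.sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers (genes as rows). Files exported with samples as rows are
#' handled with `orientation = "samples_rows"`. Parsing is
#' locale-independent (dot decimal separator).
#'
#' @param path file path; `.csv` implies comma separation, anything else tab.
#' @param orientation `"genes_rows"` (default) or `"samples_rows"`.
#' @return validated numeric matrix, genes x samples.
#' @export
read_expression <- function(path, orientation = c("genes_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  sep <- .sep_for(path)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expression file needs an id column and at least one data column")
  ids <- df[[1L]]
  row_kind <- if (orientation == "genes_rows") "gene" else "sample"
  col_kind <- if (orientation == "genes_rows") "sample" else "gene"
  .check_unique_ids(ids, row_kind)
  .check_unique_ids(colnames(df)[-1L], col_kind)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                 vals[bad[1L], bad[2L]], ids[bad[1L]],
                 colnames(df)[-1L][bad[2L]]), call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(df)[-1L])
  if (orientation == "samples_rows") num <- t(num)
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix to TSV/CSV
#'
#' @param expr validated expression matrix (genes x samples).
#' @param path output path; `.csv` implies comma separation.
#' @param id_column header for the gene-id column.
#' @export
write_expression <- function(expr, path, id_column = "gene_id") {
  validate_expression_matrix(expr)
  df <- data.frame(id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write.table(df, path, sep = .sep_for(path), quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a sample-group table
#'
#' Two-column TSV/CSV (`sample_id`, `group`) assigning each sample to the
#' tumor or normal arm.
#'
#' @param path file path.
#' @return named factor with levels `tumor`, `normal`.
#' @export
read_sample_groups <- function(path) {
  df <- read.delim(path, sep = .sep_for(path), header = TRUE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("sample-group file needs sample_id and group columns")
  .check_unique_ids(as.character(df[[1L]]), "sample")
  sample_groups(setNames(as.character(df[[2L]]), as.character(df[[1L]])))
}

#' Construct and validate sample groups
#'
#' @param groups named character vector (or factor) of `tumor`/`normal`
#'   labels, names are sample identifiers.
#' @return named factor with levels `tumor`, `normal`.
#' @export
sample_groups <- function(groups) {
  labs <- as.character(groups)
  bad <- setdiff(unique(labs), c("tumor", "normal"))
  if (length(bad)) {
    stop(sprintf("unknown group label '%s' (expected tumor/normal)", bad[1L]),
         call. = FALSE)
  }
  if (is.null(names(groups))) stop("sample groups must be named by sample id")
  factor(setNames(labs, names(groups)), levels = c("tumor", "normal"))
}

# samples of `expr` split by group; errors if a required group is absent
.group_samples <- function(expr, groups, require_both = TRUE) {
  missing <- setdiff(colnames(expr), names(groups))
  if (length(missing)) {
    stop(sprintf("sample '%s' has no group label", missing[1L]), call. = FALSE)
  }
  g <- groups[colnames(expr)]
  out <- list(tumor = colnames(expr)[g == "tumor"],
              normal = colnames(expr)[g == "normal"])
  if (require_both && (!length(out$tumor) || !length(out$normal))) {
    stop("both tumor and normal samples are required", call. = FALSE)
  }
  out
}

#' Read gene sets in GMT format
#'
#' One set per line: `term_id <tab> description <tab> gene1 <tab> gene2 ...`.
#' Duplicate genes within a line are deduplicated (first occurrence kept).
#'
#' @param path file path.
#' @return an `annotation_sets` object: a named list of character gene
#'   vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(annotation_sets(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1L]),
         call. = FALSE)
  }
  terms <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  annotation_sets(setNames(sets, terms), setNames(desc, terms))
}

#' Construct annotation sets
#'
#' @param sets named list of character gene-id vectors (one per term).
#' @param descriptions optional named character vector of term descriptions.
#' @return `annotation_sets` object.
#' @export
annotation_sets <- function(sets, descriptions = NULL) {
  if (length(sets)) {
    .check_unique_ids(names(sets), "term")
    if (any(vapply(sets, length, 1L) == 0L)) {
      empty <- names(sets)[vapply(sets, length, 1L) == 0L][1L]
      stop(sprintf("annotation term '%s' has an empty gene set", empty),
           call. = FALSE)
    }
  }
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, descriptions = descriptions, class = "annotation_sets")
}

#' Read a PPI edge list
#'
#' Two or three tab/comma-separated columns: `gene1`, `gene2`, and an
#' optional confidence score in \[0, 1\]. The result is an undirected simple
#' graph: reciprocal duplicates collapse to one edge (keeping the maximum
#' score) and self-loops are dropped with a message reporting the count.
#'
#' @param path file path.
#' @return undirected [igraph::graph] with optional `score` edge attribute.
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, sep = .sep_for(path), header = TRUE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("edge list needs at least two id columns")
  a <- as.character(df[[1L]])
  b <- as.character(df[[2L]])
  score <- if (ncol(df) >= 3L) as.numeric(df[[3L]]) else rep(NA_real_, length(a))
  nodes <- unique(c(a, b))
  loop <- a == b
  if (any(loop)) {
    message(sprintf("dropped %d self-loop(s)", sum(loop)))
    a <- a[!loop]; b <- b[!loop]; score <- score[!loop]
  }
  # canonical orientation so A-B and B-A dedupe together
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  keep <- !duplicated(key)
  if (any(!keep)) {
    score <- tapply(score, factor(key, levels = key[keep]), function(s) {
      if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE)
    })
    score <- as.numeric(score)
  } else {
    score <- score[keep]
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (any(keep)) {
    g <- igraph::add_edges(g, rbind(lo[keep], hi[keep]))
    igraph::E(g)$score <- score
  }
  g
}

#' Read a survival table
#'
#' TSV/CSV with columns `sample_id`, `time`, `event` (1 = event, 0 =
#' censored).
#'
#' @param path file path.
#' @return data.frame with columns `sample_id`, `time`, `event`.
#' @export
read_survival <- function(path) {
  df <- read.delim(path, sep = .sep_for(path), header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(df))) {
    stop("survival file needs columns sample_id, time, event")
  }
  survival_table(df$sample_id, df$time, df$event)
}

#' Construct and validate a survival table
#'
#' @param sample_id character sample identifiers.
#' @param time non-negative follow-up times.
#' @param event event indicators, 1 = event observed, 0 = censored.
#' @return data.frame with columns `sample_id`, `time`, `event`.
#' @export
survival_table <- function(sample_id, time, event) {
  sample_id <- as.character(sample_id)
  .check_unique_ids(sample_id, "sample")
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (any(!is.finite(time)) || any(time < 0)) {
    bad <- sample_id[!is.finite(time) | time < 0][1L]
    stop(sprintf("invalid follow-up time for sample '%s'", bad), call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) {
    bad <- sample_id[!event %in% c(0, 1)][1L]
    stop(sprintf("event indicator for sample '%s' must be 0 or 1", bad),
         call. = FALSE)
  }
  data.frame(sample_id = sample_id, time = time, event = as.integer(event),
             stringsAsFactors = FALSE)
}

# ---- module partitions -----------------------------------------------------

.partition_format <- "gcnakpca-partition/1"

#' Construct a module partition
#'
#' @param labels named integer vector, gene id -> module label in `1..K`.
#' @param eigengenes K x m numeric matrix of module eigengenes (one row per
#'   module, columns are samples); each row has unit Euclidean norm.
#' @return `module_partition` object with elements `labels`, `K`,
#'   `eigengenes`.
#' @export
module_partition <- function(labels, eigengenes = NULL) {
  if (is.null(names(labels))) stop("partition labels must be named by gene id")
  labels <- setNames(as.integer(labels), names(labels))
  k <- length(unique(labels))
  if (k && !setequal(unique(labels), seq_len(k))) {
    stop("module labels must be consecutive integers 1..K", call. = FALSE)
  }
  if (!is.null(eigengenes)) {
    eigengenes <- as.matrix(eigengenes)
    if (nrow(eigengenes) != k) {
      stop(sprintf("eigengene matrix has %d rows but K = %d",
                   nrow(eigengenes), k), call. = FALSE)
    }
    norms <- sqrt(rowSums(eigengenes^2))
    if (any(abs(norms - 1) > 1e-6)) {
      stop("each eigengene must have unit Euclidean norm", call. = FALSE)
    }
  }
  structure(list(labels = labels, K = k, eigengenes = eigengenes),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d genes in %d modules\n",
              length(x$labels), x$K))
  print(table(module = x$labels))
  invisible(x)
}

#' Write a module partition to JSON
#'
#' @param partition `module_partition` object.
#' @param path output path.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "module_partition"))
  payload <- list(
    format = .partition_format,
    K = partition$K,
    labels = as.list(partition$labels),
    eigengenes = if (is.null(partition$eigengenes)) NULL else {
      lapply(seq_len(nrow(partition$eigengenes)),
             function(i) unname(partition$eigengenes[i, ]))
    },
    sample_ids = colnames(partition$eigengenes)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a module partition from JSON
#'
#' @param path file written by [write_partition()].
#' @return `module_partition` object.
#' @export
read_partition <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$format) || !identical(payload$format, .partition_format)) {
    stop(sprintf("unrecognized partition format tag '%s'",
                 as.character(payload$format %||% "<missing>")), call. = FALSE)
  }
  if (is.null(payload$K)) stop("partition file is missing the 'K' field")
  labels <- unlist(payload$labels)
  eig <- NULL
  if (!is.null(payload$eigengenes) && length(payload$eigengenes)) {
    eig <- payload$eigengenes
    if (!is.matrix(eig)) eig <- do.call(rbind, eig)
    dimnames(eig) <- NULL
    if (!is.null(payload$sample_ids)) colnames(eig) <- payload$sample_ids
  }
  p <- module_partition(labels, eig)
  if (p$K != payload$K) {
    stop(sprintf("partition file declares K = %d but labels contain %d modules",
                 payload$K, p$K), call. = FALSE)
  }
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
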