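#' Read a delimited expression table
#'
#' Reads a TSV/CSV expression table into a numeric genes x samples matrix.
#' By default genes are in rows: the first column holds gene identifiers and
#' the header row holds sample identifiers. Duplicate gene identifiers are
#' collapsed to the row with the highest mean expression (the usual
#' microarray convention). Gene identifiers are opaque, case-sensitive
#' strings; no symbol mapping is attempted. Files ending in \code{.gz} are
#' read transparently.
#'
#' @param path path to a delimited text file.
#' @param layout \code{"genes_in_rows"} (default) or \code{"genes_in_columns"}.
#' @param sep field separator; guessed from the extension when \code{NULL}
#'   (\code{","} for \code{.csv}, tab otherwise).
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, layout = c("genes_in_rows", "genes_in_columns"),
                            sep = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty or malformed table: ", path)
  hdr <- colnames(df)[-1L]  # check before [.data.frame repairs duplicates
  if (layout == "genes_in_rows" && anyDuplicated(hdr))
    stop("duplicate sample ids: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1L)))[1L]
    col <- colnames(df)[-1L][bad]
    row <- which(is.na(suppressWarnings(as.numeric(df[[bad + 1L]]))))[1L]
    stop(sprintf("non-numeric cell in column '%s', data row %d of %s",
                 col, if (is.na(row)) 1L else row, path))
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene '%s', sample '%s' in %s",
                 ids[idx[1L]], colnames(m)[idx[2L]], path))
  }
  rownames(m) <- ids
  if (layout == "genes_in_columns") m <- t(m)
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  collapse_duplicate_genes(m)
}

#' Collapse duplicate gene rows to the highest-mean row
#'
#' @param m genes x samples matrix, possibly with duplicated rownames.
#' @return matrix with unique rownames; for each duplicated identifier the
#'   row with the highest mean expression is retained.
#' @export
collapse_duplicate_genes <- function(m) {
  if (!anyDuplicated(rownames(m))) return(m)
  means <- rowMeans(m)
  ord <- order(rownames(m), -means)
  m2 <- m[ord, , drop = FALSE]
  m2 <- m2[!duplicated(rownames(m2)), , drop = FALSE]
  # restore first-appearance order of the surviving identifiers
  m2[unique(rownames(m)), , drop = FALSE]
}

#' Read a clinical table
#'
#' Mandatory columns: \code{sample_id}, \code{os_time} (days, > 0) and
#' \code{os_event} (0/1). Any further columns are kept as covariates.
#' Rows without survival information (missing time or event) are dropped
#' with a message.
#'
#' @param path path to a TSV file.
#' @return data.frame with one row per sample.
#' @export
read_clinical <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  req <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) stop("clinical table lacks columns: ", paste(miss, collapse = ", "))
  drop <- is.na(df$os_time) | is.na(df$os_event)
  if (any(drop)) {
    message(sum(drop), " samples lacking survival information excluded")
    df <- df[!drop, , drop = FALSE]
  }
  validate_clinical(df)
  df
}

validate_clinical <- function(df) {
  miss <- setdiff(c("sample_id", "os_time", "os_event"), colnames(df))
  if (length(miss))
    stop("clinical table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in clinical table")
  if (any(df$os_time <= 0)) stop("os_time must be positive")
  if (!all(df$os_event %in% c(0, 1))) stop("os_event must be 0/1")
  invisible(df)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then tab-separated member genes.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stop("GMT line ", bad[1L], " has no members")
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  if (any(lengths(sets) == 0L)) stop("empty gene set in GMT")
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Load an expression dataset with optional clinical annotations
#'
#' Parses the expression matrix (and clinical table when given) and aligns
#' the two by sample id; samples present in only one of the tables are
#' reported and dropped from the aligned pair.
#'
#' @param expr_path expression table path.
#' @param clinical_path optional clinical TSV path.
#' @param layout orientation of the expression table.
#' @param scale declared scale of the values, \code{"linear"} or \code{"log2"}.
#' @param cohort optional cohort label recorded with the dataset.
#' @return list with \code{expr} (matrix), \code{clinical} (data.frame or
#'   NULL), \code{scale}, \code{cohort}.
#' @export
load_dataset <- function(expr_path, clinical_path = NULL,
                         layout = "genes_in_rows",
                         scale = c("linear", "log2"), cohort = NULL) {
  scale <- match.arg(scale)
  expr <- read_expression(expr_path, layout)
  if (scale == "linear" && any(expr < 0))
    stop("negative values in a matrix declared linear-scale")
  clinical <- NULL
  if (!is.null(clinical_path)) {
    clinical <- read_clinical(clinical_path)
    only_expr <- setdiff(colnames(expr), clinical$sample_id)
    only_clin <- setdiff(clinical$sample_id, colnames(expr))
    if (length(only_expr) || length(only_clin))
      message(length(only_expr), " expression-only and ", length(only_clin),
              " clinical-only samples dropped during alignment")
    shared <- intersect(colnames(expr), clinical$sample_id)
    if (!length(shared)) stop("no samples shared between expression and clinical tables")
    expr <- expr[, shared, drop = FALSE]
    clinical <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
    rownames(clinical) <- NULL
  }
  list(expr = expr, clinical = clinical, scale = scale, cohort = cohort)
}
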