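#' Construct a mixed binary/continuous dataset
#'
#' Bundles an N x n_r binary matrix (entries exactly 0 or 1) and an N x n_e
#' continuous matrix over the same N entities. Either block may be absent
#' (`NULL` or zero columns), which enables expression-only or binary-only
#' clustering, but at least one variable must be present overall.
#'
#' @param R binary matrix (or `NULL`): rows are entities, columns binary
#'   variables such as transcription-factor binding or mutation presence.
#' @param E continuous matrix (or `NULL`): rows are entities, columns
#'   continuous variables such as expression values per time point.
#' @param entity_ids character vector of unique entity labels; defaults to
#'   the row names of `R` (then `E`), or `e1..eN`.
#' @return An object of class `mixed_dataset`: a list with elements
#'   `entity_ids`, `binary_names`, `continuous_names`, `R`, `E`, `n`, `n_r`,
#'   `n_e`.
#' @export
mixed_dataset <- function(R = NULL, E = NULL, entity_ids = NULL) {
  if (is.null(R) && is.null(E)) {
    stop("at least one of R (binary) and E (continuous) must be supplied")
  }
  as_block <- function(M, nrow_hint) {
    if (is.null(M)) {
      return(matrix(numeric(0), nrow = nrow_hint, ncol = 0))
    }
    M <- as.matrix(M)
    storage.mode(M) <- "double"
    M
  }
  n <- if (!is.null(R)) nrow(as.matrix(R)) else nrow(as.matrix(E))
  R <- as_block(R, n)
  E <- as_block(E, n)
  if (nrow(R) != nrow(E)) {
    stop("binary block has ", nrow(R), " rows but continuous block has ",
         nrow(E), " rows")
  }
  if (n < 1L) stop("dataset must contain at least one entity")
  if (ncol(R) + ncol(E) < 1L) stop("dataset must contain at least one variable")
  if (ncol(R) > 0) {
    bad <- which(!(R %in% c(0, 1)))
    if (anyNA(R)) stop("missing values in the binary block are not supported")
    if (length(bad) > 0) {
      ij <- arrayInd(bad[1], dim(R))
      stop("binary block entry at row ", ij[1], ", column ", ij[2],
           " is ", R[bad[1]], "; entries must be exactly 0 or 1")
    }
  }
  if (ncol(E) > 0) {
    if (anyNA(E) || any(!is.finite(E))) {
      stop("continuous block contains missing or non-finite values")
    }
  }
  if (is.null(entity_ids)) {
    entity_ids <- rownames(R)
    if (is.null(entity_ids) || ncol(R) == 0) entity_ids <- rownames(E)
    if (is.null(entity_ids)) entity_ids <- paste0("e", seq_len(n))
  }
  entity_ids <- as.character(entity_ids)
  if (length(entity_ids) != n) stop("entity_ids length does not match row count")
  if (anyDuplicated(entity_ids)) stop("entity_ids must be unique")
  name_seq <- function(prefix, k) {
    if (k == 0) character(0) else paste0(prefix, seq_len(k))
  }
  binary_names <- colnames(R)
  if (is.null(binary_names)) binary_names <- name_seq("b", ncol(R))
  continuous_names <- colnames(E)
  if (is.null(continuous_names)) continuous_names <- name_seq("c", ncol(E))
  dimnames(R) <- list(entity_ids, binary_names)
  dimnames(E) <- list(entity_ids, continuous_names)
  structure(
    list(entity_ids = entity_ids,
         binary_names = binary_names,
         continuous_names = continuous_names,
         R = R, E = E,
         n = n, n_r = ncol(R), n_e = ncol(E)),
    class = "mixed_dataset")
}

#' @export
print.mixed_dataset <- function(x, ...) {
  cat("mixed_dataset:", x$n, "entities,", x$n_r, "binary and",
      x$n_e, "continuous variables\n")
  invisible(x)
}

#' Load a mixed dataset from tab-separated matrix files
#'
#' Each file is a TSV with a header row of variable names and a first column
#' of entity labels. Rows are aligned by entity label; the binary file's row
#' order governs. The binary file may instead hold p-values, binarized on
#' load with `binarize_threshold` (strictly less-than). Either path may be
#' `NULL` for expression-only / binary-only runs.
#'
#' @param binary_path path to the binary (or p-value) matrix TSV, or `NULL`.
#' @param continuous_path path to the continuous matrix TSV, or `NULL`.
#' @param binarize_threshold if non-`NULL`, entries of the binary file are
#'   p-values and are converted to 1 when `p < binarize_threshold`.
#' @param normalize if `TRUE`, rows of the continuous matrix are scaled to
#'   zero mean and unit (sample) standard deviation on load.
#' @return a [mixed_dataset()].
#' @export
load_mixed_dataset <- function(binary_path = NULL, continuous_path = NULL,
                               binarize_threshold = NULL, normalize = FALSE) {
  read_mat <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("file '", path, "' has no variable columns")
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) {
      stop("file '", path, "' has duplicated entity label '",
           ids[anyDuplicated(ids)], "'")
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(as.numeric(m))) & !is.na(m))
      ij <- if (length(bad)) arrayInd(bad[1], dim(m)) else c(NA, NA)
      stop("file '", path, "' has a non-numeric entry at row ", ij[1],
           " (", ids[ij[1]], "), column ", ij[2])
    }
    rownames(m) <- ids
    m
  }
  R <- if (!is.null(binary_path)) read_mat(binary_path) else NULL
  E <- if (!is.null(continuous_path)) read_mat(continuous_path) else NULL
  if (!is.null(R) && anyNA(R)) {
    ij <- arrayInd(which(is.na(R))[1], dim(R))
    stop("file '", binary_path, "' has a missing value at row ", ij[1],
         " (", rownames(R)[ij[1]], "), column ", ij[2],
         " (", colnames(R)[ij[2]], ")")
  }
  if (!is.null(E) && anyNA(E)) {
    ij <- arrayInd(which(is.na(E))[1], dim(E))
    stop("file '", continuous_path, "' has a missing value at row ", ij[1],
         " (", rownames(E)[ij[1]], "), column ", ij[2],
         " (", colnames(E)[ij[2]], ")")
  }
  if (!is.null(R) && !is.null(binarize_threshold)) {
    R <- binarize_binding(R, threshold = binarize_threshold)
  }
  if (!is.null(R) && !is.null(E)) {
    if (!setequal(rownames(R), rownames(E))) {
      missing_in_e <- setdiff(rownames(R), rownames(E))
      missing_in_r <- setdiff(rownames(E), rownames(R))
      stop("entity labels differ between '", binary_path, "' and '",
           continuous_path, "': ",
           if (length(missing_in_e)) paste0("missing from continuous file: ",
             paste(utils::head(missing_in_e, 3), collapse = ", ")) else "",
           if (length(missing_in_r)) paste0(" missing from binary file: ",
             paste(utils::head(missing_in_r, 3), collapse = ", ")) else "")
    }
    E <- E[rownames(R), , drop = FALSE]
  }
  if (!is.null(E) && normalize) E <- normalize_expression(E)
  mixed_dataset(R = R, E = E)
}

#' Write a matrix as a labelled TSV
#'
#' Inverse of the [load_mixed_dataset()] dialect: header row of variable
#' names, first column `id` holding entity labels.
#'
#' @param M matrix with row and column names.
#' @param path output file path.
#' @param id_col name for the label column.
#' @export
write_matrix_tsv <- function(M, path, id_col = "id") {
  df <- data.frame(rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(M))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
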