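#' Binarize a binding p-value matrix
#'
#' An entry becomes 1 exactly when its p-value is strictly below
#' `threshold` (binding called at `p < 0.001` by default).
#'
#' @param P matrix of p-values in \[0, 1\].
#' @param threshold strict upper bound for calling a 1.
#' @return binary matrix with the same dimnames.
#' @export
binarize_binding <- function(P, threshold = 0.001) {
  P <- as.matrix(P)
  if (anyNA(P) || any(P < 0) || any(P > 1)) {
    stop("p-value matrix entries must lie in [0, 1] with no missing values")
  }
  B <- (P < threshold) + 0
  dimnames(B) <- dimnames(P)
  B
}

#' Row-normalise an expression matrix
#'
#' Scales each row (entity) to zero mean and unit sample (n-1) standard
#' deviation; idempotent up to rounding. Constant rows are an error.
#'
#' @param E continuous matrix, each row with at least two distinct values.
#' @return matrix of the same shape.
#' @export
normalize_expression <- function(E) {
  E <- as.matrix(E)
  if (ncol(E) < 2) stop("normalisation needs at least two columns")
  sds <- apply(E, 1, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1]
    lab <- rownames(E)[bad]
    stop("row ", bad, if (!is.null(lab)) paste0(" ('", lab, "')"),
         " has zero variance and cannot be normalised")
  }
  (E - rowMeans(E)) / sds
}

#' Preselect binary variables by expression-correlation enrichment
#'
#' A factor (binary variable, e.g. a transcription factor) is retained if
#' the entities it binds contain more highly correlated expression pairs
#' than random entity sets of the same size. "Highly correlated" means a
#' Pearson correlation above `rho`, the given percentile of correlations
#' over all entity pairs. The empirical p-value uses the add-one rule
#' `(1 + #{random sets with proportion >= observed}) / (1 + n_random)`, so
#' it is never zero. Factors binding fewer than two entities are
#' auto-rejected (their pair proportion is undefined) and reported with
#' `empirical_p = NA`.
#'
#' @param R binary matrix (entities x factors).
#' @param E continuous matrix aligned with `R`.
#' @param percentile percentile (0-100) defining the correlation cutoff.
#' @param n_random number of random same-size entity sets per factor.
#' @param p_threshold retain a factor when `empirical_p < p_threshold`.
#' @param seed integer seed for the random sets.
#' @return a data.frame of class `preselection_report` with columns
#'   `factor`, `n_bound`, `observed_proportion`, `empirical_p`, `retained`,
#'   and attribute `rho` (the correlation cutoff used).
#' @export
preselect_binary_variables <- function(R, E, percentile = 95,
                                       n_random = 1000, p_threshold = 0.1,
                                       seed = 1L) {
  R <- as.matrix(R); E <- as.matrix(E)
  if (nrow(R) != nrow(E)) stop("R and E must have the same rows")
  if (n_random < 1) stop("n_random must be >= 1")
  n <- nrow(R)
  cors <- suppressWarnings(cor(t(E)))
  ut <- cors[upper.tri(cors)]
  rho <- unname(quantile(ut, percentile / 100, na.rm = TRUE))
  high <- cors > rho
  high[is.na(high)] <- FALSE
  prop_high <- function(idx) {
    sub <- high[idx, idx, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }
  factors <- colnames(R)
  if (is.null(factors)) factors <- paste0("f", seq_len(ncol(R)))
  out <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(ncol(R)), function(j) {
      bound <- which(R[, j] == 1)
      nb <- length(bound)
      if (nb < 2) {
        return(data.frame(factor = factors[j], n_bound = nb,
                          observed_proportion = NA_real_,
                          empirical_p = NA_real_, retained = FALSE,
                          stringsAsFactors = FALSE))
      }
      obs <- prop_high(bound)
      rand <- vapply(seq_len(n_random), function(b) {
        prop_high(sample.int(n, nb))
      }, numeric(1))
      emp <- (1 + sum(rand >= obs)) / (1 + n_random)
      data.frame(factor = factors[j], n_bound = nb,
                 observed_proportion = obs, empirical_p = emp,
                 retained = emp < p_threshold, stringsAsFactors = FALSE)
    }))
  })
  attr(out, "rho") <- rho
  class(out) <- c("preselection_report", "data.frame")
  out
}

#' Drop entities bound by no retained factor
#'
#' After restricting the binary matrix to retained factors, keeps exactly
#' the rows with at least one 1, and subsets the aligned continuous matrix
#' to the same rows.
#'
#' @param R binary matrix already restricted to retained factor columns.
#' @param E aligned continuous matrix.
#' @return list with the pruned `R` and `E`.
#' @export
drop_unbound_entities <- function(R, E) {
  R <- as.matrix(R); E <- as.matrix(E)
  if (nrow(R) != nrow(E)) stop("R and E must have the same rows")
  keep <- rowSums(R) >= 1
  if (!any(keep)) stop("no entity is bound by any retained factor")
  list(R = R[keep, , drop = FALSE], E = E[keep, , drop = FALSE])
}

#' Filter a mutation matrix by recurrence
#'
#' First drops mutation columns observed in fewer than `min_recurrence`
#' samples, then drops samples (rows) left with no mutation. The order of
#' the two steps matters and is fixed.
#'
#' @param M binary mutation matrix (samples x genes).
#' @param min_recurrence minimum number of mutated samples per kept gene.
#' @return list with `M` (filtered matrix), `kept_columns`, `kept_rows`
#'   (names if present, else indices).
#' @export
filter_mutations <- function(M, min_recurrence = 2) {
  M <- as.matrix(M)
  keep_col <- colSums(M) >= min_recurrence
  if (!any(keep_col)) stop("no mutation meets the recurrence threshold")
  M2 <- M[, keep_col, drop = FALSE]
  keep_row <- rowSums(M2) > 0
  if (!any(keep_row)) stop("no sample retains a mutation after filtering")
  M2 <- M2[keep_row, , drop = FALSE]
  name_or_idx <- function(nms, keep) if (is.null(nms)) which(keep) else nms[keep]
  list(M = M2,
       kept_columns = name_or_idx(colnames(M), keep_col),
       kept_rows = name_or_idx(rownames(M), keep_row))
}

#' Select the most variable continuous features
#'
#' Ranks features by sample SD and by absolute coefficient of variation
#' (|SD / mean|; features with near-zero mean get the maximal CV rank,
#' since their CV is unstable), averages the two ranks, and returns the
#' top `k` by the combined score. Ties break by SD rank, then by column
#' order.
#'
#' @param E continuous matrix (entities x features).
#' @param k number of features to keep.
#' @return integer (or named) vector of the selected column indices, in
#'   decreasing order of the combined score.
#' @export
select_variable_features <- function(E, k = 500) {
  E <- as.matrix(E)
  nf <- ncol(E)
  if (k > nf) stop("k (", k, ") exceeds the number of features (", nf, ")")
  sds <- apply(E, 2, sd)
  means <- colMeans(E)
  cv <- abs(sds / means)
  cv[abs(means) < 1e-12] <- Inf
  rank_sd <- rank(sds, ties.method = "average")
  rank_cv <- rank(cv, ties.method = "average")
  score <- (rank_sd + rank_cv) / 2
  ord <- order(-score, -rank_sd, seq_len(nf))
  sel <- ord[seq_len(k)]
  if (!is.null(colnames(E))) setNames(sel, colnames(E)[sel]) else sel
}
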