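#' Extract per-cluster reports and flag "clear" clusters
#'
#' A cluster is *clear* when its members' expression vectors have average
#' pairwise Pearson correlation strictly above `r_threshold` and at least
#' one binary variable has fitted probability strictly above `b_threshold`.
#' Singleton clusters are never clear (their average correlation is
#' undefined), and on binary-free data the binding probability columns are
#' `NA` so no cluster can be clear.
#'
#' @param model a [mixture_model()] aligned with the clustering (one
#'   component per cluster).
#' @param assignment integer assignment vector (labels `1..N_m`).
#' @param data the [mixed_dataset()] that was clustered.
#' @param r_threshold average-correlation threshold (strict `>`).
#' @param b_threshold binding-probability threshold (strict `>`).
#' @return data.frame of class `cluster_report` with one row per cluster:
#'   `cluster`, `size`, `member_ids` (list column),
#'   `avg_pairwise_expression_correlation`, `max_binding_probability`,
#'   `high_prob_factors` (list column), `is_clear`.
#' @export
clear_clusters <- function(model, assignment, data,
                           r_threshold = 0.5, b_threshold = 0.5) {
  assignment <- validate_assignment(assignment, data$n)
  m <- max(assignment)
  if (model$n_components != m) {
    stop("model has ", model$n_components, " components but the clustering ",
         "has ", m, " clusters")
  }
  rows <- lapply(seq_len(m), function(k) {
    members <- which(assignment == k)
    size <- length(members)
    avg_cor <- NA_real_
    if (size >= 2 && data$n_e >= 2) {
      cc <- suppressWarnings(cor(t(data$E[members, , drop = FALSE])))
      vals <- cc[upper.tri(cc)]
      avg_cor <- mean(vals[is.finite(vals)])
    }
    max_p <- if (data$n_r > 0) max(model$p[k, ]) else NA_real_
    hi <- if (data$n_r > 0) {
      data$binary_names[model$p[k, ] > b_threshold]
    } else character(0)
    is_clear <- isTRUE(avg_cor > r_threshold) && isTRUE(max_p > b_threshold) &&
      size >= 2
    data.frame(cluster = k, size = size,
               member_ids = I(list(data$entity_ids[members])),
               avg_pairwise_expression_correlation = avg_cor,
               max_binding_probability = max_p,
               high_prob_factors = I(list(hi)),
               is_clear = is_clear,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cluster_report", "data.frame")
  out
}

#' Factor-to-cluster network edges
#'
#' One edge per (factor, clear cluster) pair whose fitted binding
#' probability strictly exceeds `b_threshold`. The set of factors appearing
#' in at least one edge is the set of factors assigned a regulatory role.
#'
#' @param report a `cluster_report` from [clear_clusters()].
#' @param model the matching [mixture_model()].
#' @param binary_names factor labels (columns of the binary block).
#' @param b_threshold probability threshold (strict `>`).
#' @return data.frame with columns `factor`, `cluster`, `probability`.
#' @export
network_edges <- function(report, model, binary_names = NULL,
                          b_threshold = 0.5) {
  if (is.null(binary_names)) {
    binary_names <- colnames(model$p)
    if (is.null(binary_names) && model$n_r > 0) {
      binary_names <- paste0("b", seq_len(model$n_r))
    }
  }
  edges <- list()
  for (k in report$cluster[report$is_clear]) {
    if (model$n_r == 0) next
    j <- which(model$p[k, ] > b_threshold)
    if (length(j)) {
      edges[[length(edges) + 1]] <- data.frame(
        factor = binary_names[j], cluster = k,
        probability = model$p[k, j], stringsAsFactors = FALSE)
    }
  }
  if (length(edges) == 0) {
    return(data.frame(factor = character(0), cluster = integer(0),
                      probability = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}

#' Serialize a mixture model as a parameter table
#'
#' Long-format TSV: one row per component per variable with columns
#' `component`, `variable`, `type` (`bernoulli`, `gaussian` or `mixing`),
#' `param1`, `param2`. Bernoulli rows carry the success probability in
#' `param1`; Gaussian rows carry mean and SD; `mixing` rows (variable
#' `alpha`) carry the component weight so the table round-trips.
#'
#' @param model a [mixture_model()].
#' @param path output path (or `NULL` to return the data.frame).
#' @param binary_names,continuous_names variable labels.
#' @return the table, invisibly when written.
#' @export
write_model_table <- function(model, path = NULL,
                              binary_names = NULL, continuous_names = NULL) {
  m <- model$n_components
  if (is.null(binary_names)) {
    binary_names <- colnames(model$p)
    if (is.null(binary_names)) binary_names <- paste0("b", seq_len(model$n_r))
  }
  if (is.null(continuous_names)) {
    continuous_names <- colnames(model$mu)
    if (is.null(continuous_names)) {
      continuous_names <- paste0("c", seq_len(model$n_e))
    }
  }
  rows <- list()
  for (k in seq_len(m)) {
    rows[[length(rows) + 1]] <- data.frame(
      component = k, variable = "alpha", type = "mixing",
      param1 = model$alpha[k], param2 = NA_real_, stringsAsFactors = FALSE)
    if (model$n_r > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        component = k, variable = binary_names, type = "bernoulli",
        param1 = model$p[k, ], param2 = NA_real_, stringsAsFactors = FALSE)
    }
    if (model$n_e > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        component = k, variable = continuous_names, type = "gaussian",
        param1 = model$mu[k, ], param2 = model$sigma[k, ],
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(path)) {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Read a mixture model from a parameter table
#'
#' Inverse of [write_model_table()].
#'
#' @param path TSV path (or a data.frame in the same layout).
#' @return a [mixture_model()].
#' @export
read_model_table <- function(path) {
  tab <- if (is.data.frame(path)) path else
    read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  comps <- sort(unique(tab$component))
  m <- length(comps)
  get_block <- function(type, col) {
    sub <- tab[tab$type == type, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    vars <- unique(sub$variable)
    M <- matrix(NA_real_, m, length(vars),
                dimnames = list(NULL, vars))
    for (r in seq_len(nrow(sub))) {
      M[match(sub$component[r], comps), sub$variable[r]] <- sub[[col]][r]
    }
    M
  }
  alpha <- tab$param1[tab$type == "mixing"][order(tab$component[tab$type == "mixing"])]
  mixture_model(alpha = alpha,
                p = get_block("bernoulli", "param1"),
                mu = get_block("gaussian", "param1"),
                sigma = get_block("gaussian", "param2"))
}

#' Run the full clustering pipeline and write its artifacts
#'
#' Annealing search, EM refinement, cluster report and network edges, with
#' every artifact written under `out_dir`: `assignments.tsv`,
#' `model_params.tsv`, `responsibilities.tsv`, `cluster_report.tsv`,
#' `network_edges.tsv`, `trace.tsv` and `run_log.txt`. Rerunning with the
#' same inputs and seed reproduces the files byte for byte.
#'
#' @param data a [mixed_dataset()] (or use `binary_path`/`continuous_path`).
#' @param out_dir output directory (created if missing).
#' @param spec a [penalty_spec()].
#' @param schedule an [anneal_schedule()] (its `seed` drives the run).
#' @param k_init,n_restarts passed to [anneal()].
#' @param r_threshold,b_threshold clear-cluster thresholds.
#' @param binary_path,continuous_path,binarize_threshold,normalize
#'   loader options used when `data` is `NULL`; see [load_mixed_dataset()].
#' @return invisibly, a list with the in-memory results (`search`, `em`,
#'   `assignment`, `report`, `edges`) and the artifact paths.
#' @export
run_pipeline <- function(data = NULL, out_dir,
                         spec = penalty_spec("constant", 2),
                         schedule = anneal_schedule(),
                         k_init = NULL, n_restarts = 3,
                         r_threshold = 0.5, b_threshold = 0.5,
                         binary_path = NULL, continuous_path = NULL,
                         binarize_threshold = NULL, normalize = FALSE) {
  if (is.null(data)) {
    data <- load_mixed_dataset(binary_path, continuous_path,
                               binarize_threshold, normalize)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    "mixedclust pipeline run",
    paste0("entities: ", data$n, "  binary: ", data$n_r,
           "  continuous: ", data$n_e),
    paste0("penalty: ", spec$kind,
           if (spec$kind == "constant") paste0(" lambda=", spec$lam) else ""),
    paste0("seed: ", schedule$seed, "  restarts: ", n_restarts))

  search <- anneal(data, spec, schedule, k_init, n_restarts)
  log_lines <- c(log_lines,
    paste0("search: ", search$n_clusters, " clusters, objective ",
           format(search$best_objective, digits = 10)))

  em <- run_em(data, search$model)
  ## align the reported model with the hard assignments: components that
  ## win no entity are removed and the labels compacted
  z_raw <- max.col(em$gamma, ties.method = "first")
  present <- sort(unique(z_raw))
  model_hard <- subset_model(em$model, present)
  assignment <- match(z_raw, present)
  k_em <- em$model$n_components
  obj_em <- penalized_objective(
    em$loglik, count_parameters(k_em, data$n_r, data$n_e), spec, data$n)
  log_lines <- c(log_lines,
    paste0("EM: ", k_em, " components after ", em$n_iter,
           " iterations, mixture log-likelihood ",
           format(em$loglik, digits = 10), ", objective ",
           format(obj_em, digits = 10)))

  report <- clear_clusters(model_hard, assignment, data,
                           r_threshold, b_threshold)
  edges <- network_edges(report, model_hard, data$binary_names, b_threshold)
  log_lines <- c(log_lines,
    paste0("clusters: ", nrow(report), " (", sum(report$is_clear),
           " clear), ", nrow(edges), " network edges"))

  p <- function(f) file.path(out_dir, f)
  write.table(data.frame(entity = data$entity_ids, cluster = assignment),
              p("assignments.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_model_table(model_hard, p("model_params.tsv"),
                    data$binary_names, data$continuous_names)
  write_responsibilities_tsv(em$gamma, p("responsibilities.tsv"),
                             data$entity_ids)
  flat <- report
  flat$member_ids <- vapply(report$member_ids, paste, "", collapse = ",")
  flat$high_prob_factors <- vapply(report$high_prob_factors, paste, "",
                                   collapse = ",")
  write.table(flat, p("cluster_report.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(edges, p("network_edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_trace_tsv(search, p("trace.tsv"))
  writeLines(log_lines, p("run_log.txt"))

  invisible(list(search = search, em = em, assignment = assignment,
                 report = report, edges = edges,
                 paths = vapply(c("assignments.tsv", "model_params.tsv",
                                  "responsibilities.tsv",
                                  "cluster_report.tsv", "network_edges.tsv",
                                  "trace.tsv", "run_log.txt"), p, "")))
}
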