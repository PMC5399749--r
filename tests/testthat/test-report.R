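# Reporting: clear-cluster extraction, network edges, serialization and
# the end-to-end pipeline artifacts.

make_report_fixture <- function() {
  # two clusters: one coherent (identical expression, strong binding), one
  # incoherent, plus a singleton
  E <- rbind(c(1, 2, 3), c(1, 2, 3),            # cluster 1: correlation 1
             c(0, 5, -3), c(4, -2, 1),          # cluster 2: scrambled
             c(2, 2, 1))                        # cluster 3: singleton
  R <- rbind(c(1, 0), c(1, 0), c(0, 0), c(0, 1), c(1, 1))
  d <- mixed_dataset(R = R, E = E,
                     entity_ids = paste0("g", 1:5))
  z <- c(1L, 1L, 2L, 2L, 3L)
  model <- hard_mle_model(d, z)
  list(d = d, z = z, model = model)
}

test_that("clear clusters need correlation, binding and at least two members", {
  fx <- make_report_fixture()
  rep_ <- clear_clusters(fx$model, fx$z, fx$d)
  expect_identical(nrow(rep_), 3L)
  expect_identical(rep_$size, c(2L, 2L, 1L))
  expect_true(rep_$is_clear[1])   # corr 1 > 0.5, p = 0.999 > 0.5
  expect_false(rep_$is_clear[2])  # max p = 0.5 is not > 0.5 (strict)
  expect_equal(rep_$max_binding_probability[2], 0.5)
  expect_false(rep_$is_clear[3])  # singleton, correlation undefined
  expect_true(is.na(rep_$avg_pairwise_expression_correlation[3]))
  expect_identical(rep_$member_ids[[1]], c("g1", "g2"))
})

test_that("network edges come from clear clusters above the strict cutoff", {
  # one clear cluster with exactly three high-probability factors
  E <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  R <- rbind(c(1, 1, 1, 0, 0), c(1, 1, 1, 0, 0), c(1, 1, 1, 1, 0))
  d <- mixed_dataset(R = R, E = E)
  z <- rep(1L, 3)
  model <- hard_mle_model(d, z)
  rep_ <- clear_clusters(model, z, d)
  expect_true(rep_$is_clear[1])
  edges <- network_edges(rep_, model, d$binary_names)
  expect_identical(nrow(edges), 3L)
  expect_identical(sort(edges$factor), c("b1", "b2", "b3"))
  expect_true(all(edges$probability > 0.5))
  # probabilities are clamped below 1, so a threshold of 1 empties the list
  expect_identical(nrow(network_edges(rep_, model, d$binary_names,
                                      b_threshold = 1.0)), 0L)
  # no clear clusters -> no edges
  rep_$is_clear <- FALSE
  expect_identical(nrow(network_edges(rep_, model, d$binary_names)), 0L)
})

test_that("model parameter tables round-trip through TSV", {
  fx <- make_report_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model_table(fx$model, path, fx$d$binary_names, fx$d$continuous_names)
  back <- read_model_table(path)
  expect_equal(back$alpha, fx$model$alpha)
  expect_equal(unname(back$p), unname(fx$model$p))
  expect_equal(unname(back$mu), unname(fx$model$mu))
  expect_equal(unname(back$sigma), unname(fx$model$sigma))
})

test_that("dataset loading aligns rows by label and validates entries", {
  dir <- withr::local_tempdir()
  bpath <- file.path(dir, "bin.tsv")
  cpath <- file.path(dir, "cont.tsv")
  R <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("gA", "gB"), c("f1", "f2")))
  E <- matrix(c(1.5, 2.5, -1, 4), 2, 2,
              dimnames = list(c("gB", "gA"), c("t1", "t2")))  # reversed order
  write_matrix_tsv(R, bpath)
  write_matrix_tsv(E, cpath)
  d <- load_mixed_dataset(bpath, cpath)
  expect_identical(d$entity_ids, c("gA", "gB"))
  expect_equal(d$E["gA", "t1"], 2.5)  # realigned to the binary file order
  # non-binary entry is rejected with a located message
  R2 <- matrix(c(1, 2), 1, 2, dimnames = list("gX", c("f1", "f2")))
  write_matrix_tsv(R2, bpath)
  expect_error(load_mixed_dataset(bpath, NULL), "0 or 1")
  # expression-only mode
  d2 <- load_mixed_dataset(NULL, cpath)
  expect_identical(d2$n_r, 0L)
  expect_identical(d2$n, 2L)
})

test_that("the pipeline writes mutually consistent, reproducible artifacts", {
  sim <- simulate_dataset(sim_config(60, 10, n_r = 8, n_e = 8, seed = 21))
  dir <- withr::local_tempdir()
  res <- run_pipeline(sim$data, out_dir = dir,
                      schedule = anneal_schedule(seed = 5), n_restarts = 1)
  expect_true(all(file.exists(res$paths)))
  asg <- read.delim(file.path(dir, "assignments.tsv"))
  expect_identical(nrow(asg), 60L)
  rep_ <- read.delim(file.path(dir, "cluster_report.tsv"))
  expect_identical(sum(rep_$size), 60L)
  expect_equal(unname(table(asg$cluster)[as.character(rep_$cluster)]),
               rep_$size, ignore_attr = TRUE)
  # determinism: same config and seed give byte-identical assignments
  dir2 <- withr::local_tempdir()
  run_pipeline(sim$data, out_dir = dir2,
               schedule = anneal_schedule(seed = 5), n_restarts = 1)
  expect_identical(readLines(file.path(dir, "assignments.tsv")),
                   readLines(file.path(dir2, "assignments.tsv")))
})

test_that("expression-only runs report NA binding and produce no edges", {
  sim <- simulate_dataset(sim_config(30, 10, n_r = 0, n_e = 6, seed = 9))
  dir <- withr::local_tempdir()
  res <- run_pipeline(sim$data, out_dir = dir,
                      schedule = anneal_schedule(seed = 2), n_restarts = 1)
  expect_true(all(is.na(res$report$max_binding_probability)))
  expect_false(any(res$report$is_clear))
  expect_identical(nrow(res$edges), 0L)
})
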