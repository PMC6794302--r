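# a registry where 10 patients traverse 295 -> 410 -> 428 fully, 5 more stop
# after 295 -> 410, and 3 die after the last step
toy_chain_timelines <- function() {
  full <- lapply(1:10, function(k) {
    make_timelines(rep(sprintf("f%02d", k), 3), c("295", "410", "428"),
                   c(0, 100, 300),
                   death_day = if (k <= 3) 310L else NA_integer_)
  })
  partial <- lapply(1:5, function(k) {
    make_timelines(rep(sprintf("s%02d", k), 2), c("295", "410"), c(0, 150))
  })
  dplyr::bind_rows(full, partial)
}

toy_chain_pairs <- function() {
  tibble::tibble(
    source = c("295", "410"), target = c("410", "428"),
    n_total = c(15L, 10L), n_forward = c(15L, 10L), delta = 1,
    p_value = 1e-5, q_value = 1e-4, interval_mean = 120,
    interval_sd = 30, patient_count = c(15L, 10L)
  )
}

test_that("follower counting requires the full ordered sequence within window", {
  tl <- toy_chain_timelines()
  expect_equal(count_path_followers(tl, c("295", "410"))$n_followers, 15)
  res <- count_path_followers(tl, c("295", "410", "428"))
  expect_equal(res$n_followers, 10)
  expect_equal(res$n_deaths, 3)

  far <- make_timelines(c("x", "x"), c("295", "410"), c(0, 500))
  expect_equal(count_path_followers(far, c("295", "410"))$n_followers, 0)
  expect_error(count_path_followers(tl, "295"),
               class = "trajmine_config_error")
})

test_that("the greedy builder recovers the planted chain with exact counts", {
  tl <- toy_chain_timelines()
  dags <- build_trajectories(toy_chain_pairs(), tl)
  expect_named(dags, c("295", "410"))
  dag <- dags[["295"]]
  expect_equal(dag$paths$path, "295 -> 410 -> 428")
  expect_equal(dag$paths$n_followers, 10)
  expect_equal(dag$paths$n_deaths, 3)
  # counts agree with the independent per-patient oracle
  brute <- brute_path_followers(tl, c("295", "410", "428"))
  expect_equal(dag$paths$n_followers, brute$n_followers)
  expect_equal(dag$paths$n_deaths, brute$n_deaths)
  # node and edge bookkeeping
  expect_setequal(dag$nodes$code, c("295", "410", "428", "DEATH"))
  expect_equal(dag$nodes$patient_count[dag$nodes$code == "295"], 15)
  expect_equal(dag$nodes$patient_count[dag$nodes$code == "410"], 15)
  expect_equal(dag$nodes$patient_count[dag$nodes$code == "428"], 10)
  edges <- dag$edges
  e_death <- dplyr::filter(edges, target == "DEATH")
  expect_equal(e_death$source, "428")
  expect_equal(e_death$patient_count, 3)
  expect_true(all(edges$patient_count <= 15))
})

test_that("a single supported pair yields a minimal two-node trajectory", {
  tl <- make_timelines(rep(c("a", "b"), each = 2), rep(c("295", "410"), 2),
                       c(0, 50, 0, 60))
  pairs <- toy_chain_pairs()[1, ]
  dags <- build_trajectories(pairs, tl)
  expect_length(dags, 1)
  expect_equal(dags[["295"]]$paths$length, 2)
  expect_equal(dags[["295"]]$paths$n_followers, 2)
})

test_that("a forced 2-cycle input raises an acyclicity error", {
  tl <- toy_chain_timelines()
  cyc <- dplyr::bind_rows(
    toy_chain_pairs(),
    dplyr::mutate(toy_chain_pairs()[1, ], source = "410", target = "295")
  )
  expect_error(build_trajectories(cyc, tl), class = "trajmine_cycle_error")
})

test_that("follower counts are monotone under path extension", {
  for (seed in 1:5) {
    tl <- random_small_registry(seed)
    dp <- majority_directed_pairs(tl)
    dags <- build_trajectories(dp, tl)
    for (dag in dags) {
      for (p in strsplit(dag$paths$path, " -> ", fixed = TRUE)) {
        if (length(p) < 3) next
        counts <- vapply(2:length(p), function(k) {
          count_path_followers(tl, p[1:k])$n_followers
        }, integer(1))
        expect_true(all(diff(counts) <= 0))
      }
    }
  }
})

test_that("greedy paths match exhaustive enumeration on small registries", {
  for (seed in 1:5) {
    tl <- random_small_registry(seed, n_patients = 120, n_codes = 5)
    dp <- majority_directed_pairs(tl)
    if (nrow(dp) == 0) next
    dags <- build_trajectories(dp, tl)
    supported <- enumerate_supported_paths(dp, tl)
    for (dag in dags) {
      g <- igraph::graph_from_data_frame(dag$edges[, 1:2])
      expect_true(igraph::is_dag(g))
      for (i in seq_len(nrow(dag$paths))) {
        p <- strsplit(dag$paths$path[i], " -> ", fixed = TRUE)[[1]]
        expect_true(dag$paths$path[i] %in% supported)
        expect_equal(dag$paths$n_followers[i],
                     brute_path_followers(tl, p)$n_followers)
      }
    }
  }
})

test_that("DAG serializations are faithful", {
  dags <- build_trajectories(toy_chain_pairs(), toy_chain_timelines())
  dag <- dags[["295"]]

  json <- export_dag(dag, "json")
  back <- dag_from_json(json)
  expect_equal(back$root, dag$root)
  expect_equal(back$nodes, dag$nodes)
  expect_equal(back$edges, dag$edges)
  expect_equal(back$paths, dag$paths)

  dot <- export_dag(dag, "dot")
  expect_match(dot, "digraph")
  expect_match(dot, '"295" -> "410"')
  expect_match(dot, '"DEATH" \\[shape=box') # death rendered distinctly

  gml <- export_dag(dag, "graphml")
  expect_match(gml, "graphml")
  expect_match(gml, "patient_count")
  parsed <- igraph::read_graph(withr::local_tempfile(
    lines = gml, fileext = ".graphml"), format = "graphml")
  expect_equal(igraph::gorder(parsed), nrow(dag$nodes))

  expect_error(export_dag(dag, "svg"))

  path <- withr::local_tempfile(fileext = ".json")
  export_dag(dag, "json", path = path)
  expect_true(file.exists(path))

  expect_s3_class(glance(dag), "tbl_df")
  expect_equal(tidy(dag), dag$edges)
})
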