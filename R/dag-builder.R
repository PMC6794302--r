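DEATH_NODE <- "DEATH"

# patients whose first-diagnosis days strictly increase along `path` with
# every consecutive gap <= window; returns patient_id + day of the last step
path_follower_table <- function(timelines, path, window_days = 365) {
  tl <- dplyr::select(timelines, "patient_id", "code", "first_day")
  cur <- tl |>
    dplyr::filter(.data$code == path[1]) |>
    dplyr::select("patient_id", last_day = "first_day")
  for (k in seq_along(path)[-1]) {
    nxt <- tl |>
      dplyr::filter(.data$code == path[k]) |>
      dplyr::select("patient_id", day = "first_day")
    cur <- cur |>
      dplyr::inner_join(nxt, by = "patient_id") |>
      dplyr::filter(.data$day > .data$last_day,
                    .data$day - .data$last_day <= window_days) |>
      dplyr::select("patient_id", last_day = "day")
  }
  cur
}

patient_deaths <- function(timelines) {
  dplyr::distinct(timelines, .data$patient_id, .data$death_day)
}

#' Count patients following a full trajectory path
#'
#' A follower is a patient whose first-diagnosis days traverse the entire
#' code sequence in strictly increasing order with every consecutive gap at
#' most `window_days`. Deaths are followers whose in-hospital death occurred
#' on or after the final diagnosis of the path.
#'
#' @param timelines A timeline tibble from [build_timelines()].
#' @param path Character vector of three-digit codes, length >= 2.
#' @param window_days Maximum consecutive-step gap (default 365).
#' @return A list with `n_followers`, `n_deaths` and `patients` (the
#'   follower ids).
#' @export
count_path_followers <- function(timelines, path, window_days = 365) {
  if (length(path) < 2) {
    rlang::abort("a trajectory path needs at least two diagnoses",
                 class = "trajmine_config_error")
  }
  fol <- path_follower_table(timelines, path, window_days)
  died <- fol |>
    dplyr::inner_join(patient_deaths(timelines), by = "patient_id") |>
    dplyr::filter(!is.na(.data$death_day), .data$death_day >= .data$last_day)
  list(
    n_followers = nrow(fol),
    n_deaths = nrow(died),
    patients = fol$patient_id
  )
}

#' Build disease-trajectory DAGs from significant directed pairs
#'
#' Greedy concatenation of temporally oriented disease pairs into directed
#' acyclic graphs. Pairs are sorted by descending patient count (ties broken
#' lexically on source then target, for determinism). For every disease that
#' appears as a source, paths are grown from that root: from a path's
#' terminal disease, every sorted pair whose source matches and whose target
#' is not already on the path is attached provided at least one patient
#' follows the entire extended sequence; a path stops when no extension has
#' a follower. All viable extensions are attached, so nodes may branch; each
#' root-to-terminal path is tracked separately with its own follower count.
#' A distinguished death node is appended after terminals whose followers
#' died in hospital on or after the final diagnosis.
#'
#' @param dpairs Directed-pair tibble from [directed_pairs()].
#' @param timelines A timeline tibble.
#' @param window_days Maximum consecutive-step gap for followers (default
#'   365, the same window used pairwise).
#' @param max_paths Safety cap on tracked paths per root (default 10000);
#'   growth stops with a warning beyond it.
#' @return A named list of `trajectory_dag` objects, one per root disease
#'   with at least one supported edge. Each has tibbles `nodes` (`code`,
#'   `patient_count`, `mean_age`, `death_count`, `is_death`), `edges`
#'   (`source`, `target`, `patient_count`, `interval_mean`) and `paths`
#'   (`path`, `length`, `n_followers`, `n_deaths`), plus the `root` code.
#'   Acyclicity of every DAG is verified; a cyclic pair input aborts.
#' @export
build_trajectories <- function(dpairs, timelines, window_days = 365,
                               max_paths = 10000) {
  if (nrow(dpairs) == 0) return(stats::setNames(list(), character()))
  two_cycle <- dplyr::inner_join(
    dpairs, dpairs,
    by = c(source = "target", target = "source"),
    suffix = c("", ".rev")
  )
  if (nrow(two_cycle) > 0) {
    rlang::abort(
      paste0("directed pairs contain a 2-cycle: ",
             two_cycle$source[1], " <-> ", two_cycle$target[1]),
      class = "trajmine_cycle_error"
    )
  }
  sorted <- dplyr::arrange(dpairs, dplyr::desc(.data$patient_count),
                           .data$source, .data$target)
  deaths <- patient_deaths(timelines)
  tl <- dplyr::select(timelines, "patient_id", "code", "first_day")
  roots <- unique(sorted$source)
  dags <- lapply(roots, function(r) {
    grow_dag(r, sorted, tl, deaths, timelines, window_days, max_paths)
  })
  dags <- dags[!vapply(dags, is.null, logical(1))]
  stats::setNames(dags, vapply(dags, function(d) d$root, character(1)))
}

grow_dag <- function(root, sorted, tl, deaths, timelines, window_days,
                     max_paths) {
  seed <- tl |>
    dplyr::filter(.data$code == root) |>
    dplyr::select("patient_id", last_day = "first_day")
  if (nrow(seed) == 0) return(NULL)

  node_sets <- new.env(parent = emptyenv())
  edge_sets <- new.env(parent = emptyenv())
  add_set <- function(env, key, ids) {
    assign(key, union(if (exists(key, env)) get(key, env) else character(),
                      ids), env)
  }

  # adjacency of the accumulated edge union; pairwise orientation does not
  # guarantee global transitivity, so an extension whose edge would close a
  # cycle in the union graph is skipped to keep the trajectory a DAG
  adj <- new.env(parent = emptyenv())
  reaches <- function(from, to) {
    stack <- from
    seen <- character()
    while (length(stack) > 0) {
      cur <- stack[1]; stack <- stack[-1]
      if (cur == to) return(TRUE)
      if (cur %in% seen) next
      seen <- c(seen, cur)
      if (exists(cur, adj)) stack <- c(get(cur, adj), stack)
    }
    FALSE
  }

  queue <- list(list(path = root, followers = seed))
  finals <- list()
  n_states <- 1L
  capped <- FALSE
  while (length(queue) > 0) {
    st <- queue[[1]]; queue <- queue[-1]
    terminal <- st$path[length(st$path)]
    cand <- sorted$target[sorted$source == terminal &
                            !(sorted$target %in% st$path)]
    extended <- FALSE
    for (tgt in cand) {
      if (n_states >= max_paths) { capped <- TRUE; break }
      edge_new <- !exists(paste(terminal, tgt, sep = "\r"), edge_sets)
      if (edge_new && reaches(tgt, terminal)) next
      nxt <- tl |>
        dplyr::filter(.data$code == tgt) |>
        dplyr::select("patient_id", day = "first_day")
      f2 <- st$followers |>
        dplyr::inner_join(nxt, by = "patient_id") |>
        dplyr::filter(.data$day > .data$last_day,
                      .data$day - .data$last_day <= window_days) |>
        dplyr::select("patient_id", last_day = "day")
      if (nrow(f2) > 0) {
        extended <- TRUE
        n_states <- n_states + 1L
        add_set(node_sets, tgt, f2$patient_id)
        add_set(edge_sets, paste(terminal, tgt, sep = "\r"), f2$patient_id)
        if (edge_new) add_set(adj, terminal, tgt)
        queue <- c(queue, list(list(path = c(st$path, tgt), followers = f2)))
      }
    }
    if (!extended && length(st$path) >= 2) {
      finals <- c(finals, list(st))
    }
  }
  if (capped) {
    rlang::warn(paste0("path growth capped at ", max_paths,
                       " states for root ", root))
  }
  if (length(finals) == 0) return(NULL)
  add_set(node_sets, root, seed$patient_id)

  paths_tbl <- purrr::map_dfr(finals, function(st) {
    died <- st$followers |>
      dplyr::inner_join(deaths, by = "patient_id") |>
      dplyr::filter(!is.na(.data$death_day),
                    .data$death_day >= .data$last_day)
    if (nrow(died) > 0) {
      terminal <- st$path[length(st$path)]
      add_set(node_sets, DEATH_NODE, died$patient_id)
      add_set(edge_sets, paste(terminal, DEATH_NODE, sep = "\r"),
              died$patient_id)
    }
    tibble::tibble(
      path = paste(st$path, collapse = " -> "),
      length = length(st$path),
      n_followers = nrow(st$followers),
      n_deaths = nrow(died)
    )
  })

  nodes <- tibble::tibble(code = ls(node_sets)) |>
    dplyr::mutate(
      patient_count = vapply(.data$code,
                             function(k) length(get(k, node_sets)),
                             integer(1), USE.NAMES = FALSE),
      is_death = .data$code == DEATH_NODE
    )
  node_age <- timelines |>
    dplyr::select("code", "patient_id", "age", "first_day", "death_day")
  nodes <- nodes |>
    dplyr::mutate(
      mean_age = vapply(.data$code, function(k) {
        if (k == DEATH_NODE) return(NA_real_)
        sub <- node_age[node_age$code == k &
                          node_age$patient_id %in% get(k, node_sets), ]
        mean(sub$age)
      }, double(1), USE.NAMES = FALSE),
      death_count = vapply(.data$code, function(k) {
        if (k == DEATH_NODE) return(length(get(k, node_sets)))
        sub <- node_age[node_age$code == k &
                          node_age$patient_id %in% get(k, node_sets), ]
        sum(!is.na(sub$death_day) & sub$death_day >= sub$first_day)
      }, integer(1), USE.NAMES = FALSE)
    )

  edge_keys <- ls(edge_sets)
  edges <- purrr::map_dfr(edge_keys, function(key) {
    uv <- strsplit(key, "\r", fixed = TRUE)[[1]]
    ids <- get(key, edge_sets)
    if (uv[2] == DEATH_NODE) {
      u_days <- node_age[node_age$code == uv[1] &
                           node_age$patient_id %in% ids, ]
      gap <- u_days$death_day - u_days$first_day
    } else {
      u_days <- node_age[node_age$code == uv[1] &
                           node_age$patient_id %in% ids, ]
      v_days <- node_age[node_age$code == uv[2] &
                           node_age$patient_id %in% ids, ]
      gap <- v_days$first_day[match(u_days$patient_id, v_days$patient_id)] -
        u_days$first_day
    }
    tibble::tibble(
      source = uv[1], target = uv[2],
      patient_count = length(ids),
      interval_mean = mean(gap)
    )
  }) |>
    dplyr::arrange(dplyr::desc(.data$patient_count), .data$source,
                   .data$target)

  g <- igraph::graph_from_data_frame(edges[, c("source", "target")])
  if (!igraph::is_dag(g)) {
    rlang::abort(paste0("trajectory graph for root ", root,
                        " contains a cycle"),
                 class = "trajmine_cycle_error")
  }

  structure(
    list(
      root = root,
      nodes = dplyr::arrange(nodes, dplyr::desc(.data$patient_count)),
      edges = edges,
      paths = dplyr::arrange(paths_tbl, dplyr::desc(.data$n_followers),
                             .data$path)
    ),
    class = "trajectory_dag"
  )
}

#' @export
print.trajectory_dag <- function(x, ...) {
  cat("Disease trajectory DAG rooted at", x$root, "\n")
  cat("  nodes:", nrow(x$nodes), " edges:", nrow(x$edges),
      " paths:", nrow(x$paths), "\n")
  root_n <- x$nodes$patient_count[x$nodes$code == x$root]
  cat("  patients at root:", root_n, "\n")
  invisible(x)
}

#' Tidy a trajectory DAG into its edge table
#'
#' @param x A `trajectory_dag`.
#' @param ... Unused.
#' @return The edge tibble (`source`, `target`, `patient_count`,
#'   `interval_mean`).
#' @export
tidy.trajectory_dag <- function(x, ...) x$edges

#' One-row summary of a trajectory DAG
#'
#' @param x A `trajectory_dag`.
#' @param ... Unused.
#' @return Tibble with root, node/edge/path counts, patients at root and
#'   total deaths on the death node.
#' @export
glance.trajectory_dag <- function(x, ...) {
  tibble::tibble(
    root = x$root,
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_paths = nrow(x$paths),
    n_root_patients = x$nodes$patient_count[x$nodes$code == x$root],
    n_deaths = sum(x$nodes$patient_count[x$nodes$is_death], 0L)
  )
}

#' Plot a trajectory DAG
#'
#' Layered layout with node area proportional to patient count, colour by
#' mean patient age, and the death terminal drawn as a square.
#'
#' @param object A `trajectory_dag`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory_dag <- function(object, ...) {
  g <- igraph::graph_from_data_frame(
    object$edges[, c("source", "target")],
    vertices = object$nodes$code
  )
  xy <- igraph::layout_with_sugiyama(g)$layout
  lay <- tibble::tibble(code = igraph::V(g)$name,
                        x = xy[, 1], y = xy[, 2]) |>
    dplyr::left_join(object$nodes, by = "code")
  seg <- object$edges |>
    dplyr::left_join(dplyr::select(lay, "code", "x", "y"),
                     by = c(source = "code")) |>
    dplyr::left_join(dplyr::select(lay, "code", "x", "y"),
                     by = c(target = "code"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$patient_count),
      colour = "grey60", show.legend = FALSE
    ) +
    ggplot2::geom_point(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$patient_count,
                   colour = .data$mean_age,
                   shape = .data$is_death)
    ) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 15),
                                guide = "none") +
    ggplot2::scale_size_area(max_size = 14) +
    ggplot2::geom_text(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$code),
      vjust = -1.6, size = 3
    ) +
    ggplot2::labs(title = paste("Trajectory DAG:", object$root),
                  colour = "mean age", size = "patients") +
    ggplot2::theme_void()
}

#' Serialize a trajectory DAG
#'
#' @param dag A `trajectory_dag`.
#' @param format One of `"json"` (lossless; see [dag_from_json()]), `"dot"`
#'   (Graphviz, death node drawn as a box) or `"graphml"` (node and edge
#'   attributes carried as GraphML keys).
#' @param path Optional file to write the serialization to.
#' @return The serialized text, invisibly when `path` is given.
#' @export
export_dag <- function(dag, format = c("json", "dot", "graphml"),
                       path = NULL) {
  stopifnot(inherits(dag, "trajectory_dag"))
  format <- match.arg(format)
  txt <- switch(
    format,
    json = as.character(jsonlite::toJSON(
      list(root = dag$root, nodes = dag$nodes, edges = dag$edges,
           paths = dag$paths),
      digits = NA, pretty = TRUE
    )),
    dot = dag_to_dot(dag),
    graphml = dag_to_graphml(dag)
  )
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Rebuild a trajectory DAG from its JSON serialization
#'
#' @param txt JSON text produced by `export_dag(dag, "json")`.
#' @return A `trajectory_dag`.
#' @export
dag_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt)
  structure(
    list(
      root = obj$root,
      nodes = tibble::as_tibble(obj$nodes),
      edges = tibble::as_tibble(obj$edges),
      paths = tibble::as_tibble(obj$paths)
    ),
    class = "trajectory_dag"
  )
}

dag_to_dot <- function(dag) {
  q <- function(x) paste0('"', x, '"')
  node_lines <- purrr::pmap_chr(dag$nodes, function(code, patient_count,
                                                    is_death, mean_age,
                                                    death_count, ...) {
    shape <- if (is_death) "box" else "ellipse"
    sprintf('  %s [shape=%s, patients=%d, mean_age="%.1f"];',
            q(code), shape, patient_count,
            if (is.na(mean_age)) -1 else mean_age)
  })
  edge_lines <- purrr::pmap_chr(dag$edges, function(source, target,
                                                    patient_count,
                                                    interval_mean, ...) {
    sprintf('  %s -> %s [label="%d", patients=%d];',
            q(source), q(target), patient_count, patient_count)
  })
  paste(c(sprintf('digraph "%s" {', dag$root), node_lines, edge_lines, "}"),
        collapse = "\n")
}

dag_to_graphml <- function(dag) {
  g <- igraph::graph_from_data_frame(
    dag$edges, vertices = dag$nodes[, c("code", "patient_count", "mean_age",
                                        "death_count", "is_death")]
  )
  tmp <- tempfile(fileext = ".graphml")
  on.exit(unlink(tmp))
  igraph::write_graph(g, tmp, format = "graphml")
  paste(readLines(tmp), collapse = "\n")
}
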