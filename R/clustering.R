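#' Periodic-aware distance between collective-variable vectors
#'
#' Euclidean norm of weighted, wrapped differences: each periodic
#' coordinate difference is mapped to `[0, 180]` degrees before weighting.
#' This is the metric used by [kmedoids()].
#'
#' @param u,v numeric CV vectors (degrees for periodic coordinates).
#' @param periodic logical per coordinate (default all `TRUE`).
#' @param weights positive weight per coordinate (default 1).
#' @return nonnegative scalar.
#' @examples
#' circular_distance(179, -179)  # 2, not 358
#' @export
circular_distance <- function(u, v, periodic = rep(TRUE, length(u)),
                              weights = rep(1, length(u))) {
  if (length(u) != length(v)) stop("CV vectors differ in length")
  if (length(periodic) != length(u) || length(weights) != length(u))
    stop("`periodic` and `weights` must match the CV length")
  if (any(weights <= 0)) stop("weights must be > 0")
  d <- abs(u - v)
  d[periodic] <- d[periodic] %% 360
  wrapidx <- periodic & d > 180
  d[wrapidx] <- 360 - d[wrapidx]
  sqrt(sum((weights * d)^2))
}

cv_matrix <- function(cvs, columns = NULL) {
  df <- as.data.frame(cvs)
  cvcols <- setdiff(names(df), "frame")
  if (!is.null(columns)) cvcols <- columns
  X <- as.matrix(df[, cvcols, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' k-medoids clustering of periodic collective variables
#'
#' Clusters the frames of a CV table with the k-medoids algorithm under the
#' wrapped metric of [circular_distance()].  Seeding is a deterministic
#' greedy PAM-style BUILD (ties break to the lowest frame index), followed
#' by alternating assignment and in-cluster medoid update until the
#' assignment stabilizes; the total cost is non-increasing across
#' iterations.  The result is fully deterministic for a given
#' `(data, k, seed)`; the seed is recorded in the model for provenance.
#'
#' @param cvs a `voa_cvtable` (from [cv_timeseries()] or [read_cv_csv()]),
#'   or a plain data frame / matrix of CV columns.
#' @param k number of clusters (`<=` number of frames).
#' @param seed integer seed recorded in the model.
#' @param max_iter maximum assignment/update sweeps.
#' @param weights per-CV weights (default 1).
#' @param columns CV columns to cluster on (default: all non-`frame`).
#' @return a `voa_kmedoids` object: `k`, `medoids` (frame numbers),
#'   `assignment` (cluster id per frame, 1..k labelled in descending
#'   population), `populations`, `centers` (circular mean per cluster and
#'   CV, degrees), `cost`, `cost_history`, `iterations`, `converged`,
#'   `seed`.
#' @export
kmedoids <- function(cvs, k, seed = 1L, max_iter = 100L,
                     weights = NULL, columns = NULL) {
  X <- cv_matrix(cvs, columns)
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of frames")
  if (anyNA(X))
    stop("undefined CV cells present; filter those frames before clustering")
  periodic <- attr(cvs, "periodic")
  if (is.null(periodic)) periodic <- rep(TRUE, ncol(X))
  periodic <- rep_len(periodic, ncol(X))
  if (is.null(weights)) weights <- rep(1, ncol(X))
  fit <- cpp_kmedoids(X, as.logical(periodic), as.numeric(weights),
                      as.integer(k), as.integer(max_iter))
  assign0 <- fit$assignment + 1L    # 1-based cluster ids, BUILD order
  medoids0 <- fit$medoids + 1L
  pop0 <- tabulate(assign0, nbins = k) / n
  # relabel clusters in descending population (ties: lower medoid frame)
  ord <- order(-pop0, medoids0)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  assignment <- relabel[assign0]
  medoids <- medoids0[ord]
  populations <- pop0[ord]
  centers <- matrix(NA_real_, k, ncol(X),
                    dimnames = list(NULL, colnames(X)))
  for (cl in seq_len(k))
    for (j in seq_len(ncol(X)))
      centers[cl, j] <- if (periodic[j]) circ_mean_deg(X[assignment == cl, j])
                        else mean(X[assignment == cl, j])
  structure(list(k = k, medoids = medoids, assignment = assignment,
                 populations = populations, centers = centers,
                 cost = fit$cost, cost_history = fit$cost_history,
                 iterations = fit$iterations, converged = fit$converged,
                 seed = as.integer(seed), periodic = periodic,
                 weights = weights, columns = colnames(X), n = n),
            class = "voa_kmedoids")
}

#' @export
print.voa_kmedoids <- function(x, ...) {
  cat(sprintf("<voa_kmedoids> k = %d on %d frames (%s), cost %.2f, %s\n",
              x$k, x$n, paste(x$columns, collapse = ", "), x$cost,
              if (x$converged) sprintf("converged in %d iterations", x$iterations)
              else "max_iter reached"))
  print(cluster_table(x))
  invisible(x)
}

#' Cluster population table
#'
#' One row per cluster: population percentage (1 decimal) and the circular
#' mean of each CV, sorted by descending population — the layout of the
#' conformer-population tables this pipeline produces.
#'
#' @param model a `voa_kmedoids`.
#' @param digits decimals for population percent.
#' @return data frame `cluster`, `population_pct`, one column per CV
#'   (degrees).  (Medoid frame numbers live in the model and in the
#'   exported medoid files, not in this table, so the table depends only
#'   on the clustered distribution.)
#' @export
cluster_table <- function(model, digits = 1L) {
  stopifnot(inherits(model, "voa_kmedoids"))
  out <- data.frame(cluster = seq_len(model$k),
                    population_pct = round(100 * model$populations, digits))
  cen <- round(model$centers, 1L)
  for (j in seq_along(model$columns)) out[[model$columns[j]]] <- cen[, j]
  out
}

#' Extract (optionally shell-trimmed) medoid frames
#'
#' Returns one frame per cluster in descending-population order; when
#' `shell_radius` is given, each is reduced to the solute plus its
#' solvation shell via [extract_shell()].
#'
#' @param model a `voa_kmedoids` fitted on CVs aligned with `traj` by frame
#'   number.
#' @param traj the [trajectory()] the CVs came from.
#' @param shell_radius shell radius in Angstrom, or `NULL` for full frames.
#' @param solute solute molecule id(s) (required with `shell_radius`).
#' @return named list of [frame()]s (`cluster_1`, `cluster_2`, ...) with a
#'   `comment` attribute carrying cluster id and population.
#' @export
medoid_frames <- function(model, traj, shell_radius = NULL, solute = NULL) {
  stopifnot(inherits(model, "voa_kmedoids"), inherits(traj, "voa_trajectory"))
  if (model$n != n_frames(traj))
    stop("model and trajectory differ in frame count; index mismatch")
  out <- lapply(seq_len(model$k), function(cl) {
    fr <- get_frame(traj, model$medoids[cl])
    if (!is.null(shell_radius)) {
      if (is.null(solute)) stop("`solute` required when shell_radius is set")
      fr <- extract_shell(fr, solute, shell_radius)
    }
    attr(fr, "comment") <- sprintf("cluster %d population %.1f%% medoid frame %d",
                                   cl, 100 * model$populations[cl],
                                   model$medoids[cl])
    fr
  })
  names(out) <- sprintf("cluster_%d", seq_len(model$k))
  out
}

#' Write cluster artifacts to disk
#'
#' @param model a `voa_kmedoids`.
#' @param dir output directory (created if needed).
#' @param traj optional trajectory for medoid export.
#' @param shell_radius,solute passed to [medoid_frames()].
#' @return invisibly, the paths written.
#' @export
write_cluster_outputs <- function(model, dir, traj = NULL,
                                  shell_radius = NULL, solute = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  tabp <- file.path(dir, "cluster_table.csv")
  utils::write.csv(cluster_table(model), tabp, row.names = FALSE, quote = FALSE)
  paths <- c(paths, tabp)
  asgp <- file.path(dir, "assignments.csv")
  utils::write.csv(data.frame(frame = seq_len(model$n),
                              cluster = model$assignment),
                   asgp, row.names = FALSE, quote = FALSE)
  paths <- c(paths, asgp)
  if (!is.null(traj)) {
    med <- medoid_frames(model, traj, shell_radius, solute)
    for (i in seq_along(med)) {
      mp <- file.path(dir, sprintf("medoid_%02d.xyz", i))
      write_xyz(med[[i]], mp, comments = attr(med[[i]], "comment"))
      paths <- c(paths, mp)
    }
  }
  invisible(paths)
}
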