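#' Redundancy pruning of a selected feature subset
#'
#' Removes `floor(prune_fraction * |subset|)` features from the subset by
#' greedy maximum-redundancy-first elimination: at each step the feature
#' with the highest maximum absolute Pearson correlation to the remaining
#' kept features is dropped, with ties broken by lower visibility, then by
#' lower feature index. A single-feature subset is returned unchanged.
#'
#' @param table a [feature_table()].
#' @param subset integer feature indices to prune.
#' @param prune_fraction fraction to remove, in \[0.15, 0.20\] unless
#'   `override = TRUE`.
#' @param visibility optional per-feature visibility (length d); defaults
#'   to [fisher_visibility()] of the table.
#' @param override allow `prune_fraction` outside the standard range.
#' @return list with sorted `kept` and `pruned` index vectors.
#' @export
prune_redundant <- function(table, subset, prune_fraction = 0.2,
                            visibility = NULL, override = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  subset <- sort(as.integer(subset))
  if (!override && (prune_fraction < 0.15 || prune_fraction > 0.20))
    stop("prune_fraction must lie in [0.15, 0.20] (set override = TRUE to ",
         "deviate)", call. = FALSE)
  if (length(subset) <= 1)
    return(list(kept = subset, pruned = integer(0)))
  if (is.null(visibility)) {
    visibility <- if (length(unique(table$labels)) >= 2)
      fisher_visibility(table) else rep(0, ncol(table$matrix))
  }
  n_remove <- floor(prune_fraction * length(subset))
  cur <- subset
  pruned <- integer(0)
  if (n_remove > 0) {
    C <- suppressWarnings(abs(cor(table$matrix[, cur, drop = FALSE])))
    C[!is.finite(C)] <- 0
    diag(C) <- 0
    for (r in seq_len(n_remove)) {
      red <- apply(C, 1, max)
      cand <- which(red >= max(red) - 1e-12)
      if (length(cand) > 1) {            # ties: lower visibility, lower index
        vis <- visibility[cur[cand]]
        cand <- cand[vis <= min(vis) + 1e-12]
        cand <- cand[which.min(cur[cand])]
      }
      pruned <- c(pruned, cur[cand])
      cur <- cur[-cand]
      C <- C[-cand, -cand, drop = FALSE]
    }
  }
  list(kept = sort(cur), pruned = sort(pruned))
}

#' Run the ant-colony feature selector
#'
#' The full schedule: each iteration, every ant constructs a subset under
#' the pseudo-random-proportional transition rule, subsets are scored by
#' the 1-NN holdout fitness (memoised within the run), the iteration-best
#' subset receives a local pheromone deposit, and a global evaporation pulls
#' all pheromone toward `delta0`. An elitist best-so-far subset is tracked
#' across iterations (default); after the final iteration the elitist
#' subset is reduced by [prune_redundant()] and returned as the kept
#' feature set. Fully reproducible under `cfg$seed`.
#'
#' `aco_select()` is the user-facing fitting interface: it accepts either a
#' [feature_table()] or a plain matrix plus labels.
#'
#' @param table a [feature_table()].
#' @param cfg an [aco_config()].
#' @return an object of class `aco_selection` with components
#'   `kept_indices`, `pruned_indices`, `selected_indices` (the pre-pruning
#'   elitist subset), `best_fitness`, `best_fitness_per_iteration`,
#'   `final_pheromone`, `pheromone_history` (d x n_iterations),
#'   `visibility`, `colony`, `config` and `n_evaluations`.
#' @export
run_aco <- function(table, cfg = aco_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(cfg, "aco_config"))
  ini <- init_state(table, cfg)
  state <- ini$state
  colony <- ini$colony
  k <- .resolve_subset_size(cfg, colony$d)
  holdout <- .fitness_split(table$labels, cfg$fitness_holdout, cfg$seed)
  memo <- new.env(parent = emptyenv())
  n_eval <- 0L
  fitness_of <- function(subset) {
    key <- paste(subset, collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    f <- subset_fitness(table, subset, cfg, holdout = holdout)
    memo[[key]] <- f
    n_eval <<- n_eval + 1L
    f
  }
  best_subset <- NULL
  best_fit <- -Inf
  trace <- numeric(cfg$n_iterations)
  pher_hist <- matrix(NA_real_, colony$d, cfg$n_iterations)
  with_seed(cfg$seed, {
    for (it in seq_len(cfg$n_iterations)) {
      it_best <- NULL
      it_fit <- -Inf
      for (ant in seq_len(colony$Kn)) {
        s <- construct_subset(state, cfg, k)
        f <- fitness_of(s)
        if (f > it_fit) {
          it_fit <- f
          it_best <- s
        }
      }
      state <- local_update(state, it_best, it_fit, cfg)
      state <- global_update(state, cfg)
      state$iteration <- it
      if (it_fit > best_fit) {
        best_fit <- it_fit
        best_subset <- it_best
      }
      trace[it] <- if (cfg$elitist) best_fit else it_fit
      pher_hist[, it] <- state$pheromone
    }
  })
  pr <- prune_redundant(table, best_subset, cfg$prune_fraction,
                        visibility = state$visibility,
                        override = cfg$allow_prune_override)
  structure(list(kept_indices = pr$kept, pruned_indices = pr$pruned,
                 selected_indices = sort(best_subset),
                 best_fitness = best_fit,
                 best_fitness_per_iteration = trace,
                 final_pheromone = state$pheromone,
                 pheromone_history = pher_hist,
                 visibility = state$visibility,
                 colony = colony, config = cfg,
                 subset_size = k, n_evaluations = n_eval),
            class = "aco_selection")
}

#' @rdname run_aco
#' @param x a [feature_table()] or numeric feature matrix.
#' @param y integer/factor labels (required when `x` is a matrix).
#' @param ... arguments forwarded to [aco_config()].
#' @export
aco_select <- function(x, y = NULL, ...) {
  table <- if (inherits(x, "feature_table")) x else {
    stopifnot(!is.null(y))
    y <- as.integer(as.factor(y))
    feature_table(as.matrix(x), y)
  }
  run_aco(table, aco_config(...))
}

#' @export
print.aco_selection <- function(x, ...) {
  cat(sprintf(
    "ACO feature selection: %d kept of %d features (%d selected, %d pruned)\n",
    length(x$kept_indices), x$colony$d, length(x$selected_indices),
    length(x$pruned_indices)))
  cat(sprintf("  best 1-NN holdout fitness: %.4f after %d iterations (%d ants, %d evaluations)\n",
              x$best_fitness, x$config$n_iterations, x$colony$Kn,
              x$n_evaluations))
  invisible(x)
}

#' @export
summary.aco_selection <- function(object, ...) {
  cat("Ant-colony feature selection\n")
  cat(sprintf("  features: %d total -> %d selected -> %d kept after %.0f%% pruning\n",
              object$colony$d, length(object$selected_indices),
              length(object$kept_indices), 100 * object$config$prune_fraction))
  cat(sprintf("  colony: Kn = %d ants, V = %d samples; %d iterations\n",
              object$colony$Kn, object$colony$V, object$config$n_iterations))
  tr <- object$best_fitness_per_iteration
  cat(sprintf("  fitness trace: %.4f (first) -> %.4f (final)\n",
              tr[1], tr[length(tr)]))
  cat(sprintf("  pheromone: min %.4f, max %.4f (delta0 = %g)\n",
              min(object$final_pheromone), max(object$final_pheromone),
              object$config$delta0))
  cat("  kept indices:", paste(object$kept_indices, collapse = " "), "\n")
  invisible(object)
}

#' Reduce a feature table (or matrix) to the kept features
#'
#' @param object an `aco_selection`.
#' @param newdata a [feature_table()] or matrix with the same feature
#'   dimension the selector was fit on.
#' @param ... unused.
#' @return the input restricted to `kept_indices` (same type as
#'   `newdata`).
#' @export
predict.aco_selection <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_table")) {
    stopifnot(ncol(newdata$matrix) == object$colony$d)
    return(subset_features(newdata, object$kept_indices))
  }
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == object$colony$d)
  newdata[, object$kept_indices, drop = FALSE]
}

#' Plot the fitness trace and final pheromone profile
#'
#' @param x an `aco_selection`.
#' @param ... passed to [plot()].
#' @export
plot.aco_selection <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$best_fitness_per_iteration, type = "s", xlab = "iteration",
       ylab = "best 1-NN fitness", main = "elitist fitness trace", ...)
  cols <- ifelse(seq_len(x$colony$d) %in% x$kept_indices, "firebrick", "grey60")
  plot(x$final_pheromone, col = cols, pch = 16, cex = 0.6,
       xlab = "feature index", ylab = "final pheromone",
       main = "pheromone (kept in red)")
  abline(h = x$config$delta0, lty = 3)
  invisible(x)
}

#' Write / read a selection result
#'
#' A small structured JSON text file: kept and pruned indices, a config
#' echo, the colony sizing and the per-iteration best-fitness trace (the
#' full pheromone history is not persisted).
#'
#' @param sel an `aco_selection`.
#' @param path output file.
#' @return `write_selection` returns `path` invisibly; `read_selection`
#'   returns the parsed list.
#' @export
write_selection <- function(sel, path) {
  stopifnot(inherits(sel, "aco_selection"))
  cfg <- sel$config
  cfg$subset_size <- sel$subset_size
  out <- list(kept_indices = sel$kept_indices,
              pruned_indices = sel$pruned_indices,
              selected_indices = sel$selected_indices,
              best_fitness = sel$best_fitness,
              best_fitness_per_iteration = sel$best_fitness_per_iteration,
              final_pheromone = sel$final_pheromone,
              colony = sel$colony,
              config = unclass(cfg))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
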