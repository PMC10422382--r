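#' Configuration of the ant-colony feature selector
#'
#' Houses every tunable of the selector: the iteration budget (100 by
#' default, the reference schedule), colony sizing, the transition-rule
#' exponents on pheromone (`alpha`) and visibility (`beta`), the
#' pseudo-random-proportional exploitation probability `q0`, the local
#' (`mu`) and global (`theta`) pheromone rates, the initial pheromone level
#' `delta0`, and the final redundancy-pruning fraction (constrained to the
#' 15-20\% range unless explicitly overridden).
#'
#' The literal colony-sizing rule is `Kn = V x d` (samples times feature
#' width); `n_ants = "auto"` keeps that rule as a formal cap and bounds the
#' colony at `ants_cap` for tractability. `heuristic_mode = "fisher"` uses
#' the per-feature Fisher class-separability score as visibility;
#' `"paper_literal"` sets visibility equal to the pheromone vector, a
#' degenerate heuristic retained for fidelity experiments.
#'
#' @param n_iterations iteration budget (default 100).
#' @param n_ants `"auto"` (min(V x d, `ants_cap`)) or a positive integer or
#'   `"literal"` for the uncapped V x d rule.
#' @param subset_size features each ant selects; default `NULL` means
#'   `round(0.5 * d)` capped at `subset_cap`.
#' @param alpha exponent on pheromone in the transition rule (default 1).
#' @param beta exponent on visibility (default 1).
#' @param q0 probability of the greedy argmax transition (default 0.3).
#' @param mu local pheromone deposit rate, in (0, 1) (default 0.1).
#' @param theta global evaporation rate toward `delta0`, in (0, 1)
#'   (default 0.05).
#' @param delta0 initial pheromone level, > 0 (default 1).
#' @param prune_fraction fraction of the selected subset removed by
#'   redundancy pruning, in \[0.15, 0.20\] (default 0.20).
#' @param seed integer seed; all randomness of a run flows from it.
#' @param heuristic_mode `"fisher"` (default) or `"paper_literal"`.
#' @param elitist track and return the best-so-far subset (default TRUE).
#' @param ants_cap colony cap under `"auto"` sizing (default 32).
#' @param subset_cap cap on the default subset size (default 512).
#' @param fitness_holdout holdout fraction of the seeded stratified split
#'   used by the 1-NN fitness (default 0.3).
#' @param allow_prune_override permit `prune_fraction` outside
#'   \[0.15, 0.20\] (default FALSE).
#' @return an `aco_config` list.
#' @export
aco_config <- function(n_iterations = 100L, n_ants = "auto",
                       subset_size = NULL, alpha = 1, beta = 1, q0 = 0.3,
                       mu = 0.1, theta = 0.05, delta0 = 1,
                       prune_fraction = 0.2, seed = 1L,
                       heuristic_mode = c("fisher", "paper_literal"),
                       elitist = TRUE, ants_cap = 32L, subset_cap = 512L,
                       fitness_holdout = 0.3, allow_prune_override = FALSE) {
  heuristic_mode <- match.arg(heuristic_mode)
  if (!(mu > 0 && mu < 1)) stop("mu must satisfy 0 < mu < 1", call. = FALSE)
  if (!(theta > 0 && theta < 1)) stop("theta must satisfy 0 < theta < 1", call. = FALSE)
  if (delta0 <= 0) stop("delta0 must be positive", call. = FALSE)
  if (!(q0 >= 0 && q0 <= 1)) stop("q0 must lie in [0, 1]", call. = FALSE)
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  if (!allow_prune_override && (prune_fraction < 0.15 || prune_fraction > 0.20))
    stop("prune_fraction must lie in [0.15, 0.20]; set allow_prune_override ",
         "= TRUE to deviate", call. = FALSE)
  if (is.numeric(n_ants) && n_ants < 1) stop("n_ants must be >= 1", call. = FALSE)
  structure(list(n_iterations = as.integer(n_iterations), n_ants = n_ants,
                 subset_size = if (!is.null(subset_size)) as.integer(subset_size),
                 alpha = alpha, beta = beta, q0 = q0, mu = mu, theta = theta,
                 delta0 = delta0, prune_fraction = prune_fraction,
                 seed = as.integer(seed), heuristic_mode = heuristic_mode,
                 elitist = isTRUE(elitist), ants_cap = as.integer(ants_cap),
                 subset_cap = as.integer(subset_cap),
                 fitness_holdout = fitness_holdout,
                 allow_prune_override = isTRUE(allow_prune_override)),
            class = "aco_config")
}

.resolve_subset_size <- function(cfg, d) {
  k <- cfg$subset_size %||%
    as.integer(min(max(1, round(0.5 * d)), cfg$subset_cap))
  if (k > d) stop("subset_size (", k, ") exceeds feature dimension (", d, ")",
                  call. = FALSE)
  as.integer(k)
}

.resolve_n_ants <- function(cfg, V, d) {
  literal <- as.double(V) * as.double(d)
  if (identical(cfg$n_ants, "literal")) return(as.integer(min(literal, .Machine$integer.max)))
  if (identical(cfg$n_ants, "auto")) return(as.integer(min(literal, cfg$ants_cap)))
  as.integer(cfg$n_ants)
}

#' Per-feature Fisher class-separability score
#'
#' For each feature, the (population) variance of the class means divided
#' by the mean within-class (population) variance. Constant features score
#' 0; features with zero within-class variance but separated means get
#' twice the finite maximum of the remaining scores. Used as the
#' visibility heuristic in the default selector mode.
#'
#' @param table a [feature_table()] with at least two classes present.
#' @return nonnegative numeric vector of length d.
#' @export
fisher_visibility <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  y <- table$labels
  if (length(unique(y)) < 2)
    stop("Fisher visibility needs at least two classes", call. = FALSE)
  X <- table$matrix
  cls <- sort(unique(y))
  nc <- vapply(cls, function(c) sum(y == c), 0L)
  means <- rowsum(X, y) / nc                       # class x feature means
  sq <- rowsum(X^2, y) / nc
  within <- sq - means^2                            # population var per class
  wbar <- colMeans(within)
  between <- colMeans(sweep(means, 2, colMeans(means))^2)
  v <- numeric(ncol(X))
  pos <- wbar > 0
  v[pos] <- between[pos] / wbar[pos]
  degen <- !pos & between > 0                       # perfectly separated
  if (any(degen)) {
    finite_max <- if (any(pos)) max(v[pos]) else 1
    v[degen] <- 2 * max(finite_max, .Machine$double.eps)
  }
  v
}

#' Initialize pheromone state and colony sizing
#'
#' Pheromone starts uniformly at `delta0`; visibility is computed once per
#' `heuristic_mode`. Colony sizing reads `V` (samples) and `d` (features)
#' from the table and applies the `Kn = V x d` rule (capped under
#' `"auto"`).
#'
#' @param table a [feature_table()].
#' @param cfg an [aco_config()].
#' @return list with `state` (pheromone, visibility, iteration) and
#'   `colony` (`Kn`, `V`, `d`).
#' @export
init_state <- function(table, cfg = aco_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(cfg, "aco_config"))
  d <- ncol(table$matrix)
  if (d < 2) stop("need at least 2 features", call. = FALSE)
  if (!all(is.finite(table$matrix)))
    stop("feature table contains non-finite values", call. = FALSE)
  pher <- rep(cfg$delta0, d)
  vis <- switch(cfg$heuristic_mode,
                fisher = fisher_visibility(table),
                paper_literal = pher)
  V <- nrow(table$matrix)
  list(state = list(pheromone = pher, visibility = vis, iteration = 0L),
       colony = list(Kn = .resolve_n_ants(cfg, V, d), V = V, d = d))
}

#' Transition probabilities over features
#'
#' The standard ACO product rule: the probability of stepping onto feature
#' `j` is proportional to `pheromone_j^alpha * visibility_j^beta` over the
#' non-excluded features; excluded entries get exactly 0 and the vector
#' sums to 1. If all remaining products are zero, the distribution is
#' uniform over the remaining features.
#'
#' @param state pheromone state from [init_state()].
#' @param cfg an [aco_config()].
#' @param excluded integer indices already visited (probability 0).
#' @return probability vector of length d.
#' @export
transition_probabilities <- function(state, cfg = aco_config(),
                                     excluded = integer()) {
  d <- length(state$pheromone)
  excluded <- as.integer(excluded)
  stopifnot(all(excluded >= 1 & excluded <= d))
  if (length(excluded) >= d)
    stop("all features are excluded", call. = FALSE)
  w <- state$pheromone^cfg$alpha * state$visibility^cfg$beta
  w[excluded] <- 0
  tot <- sum(w)
  if (tot <= 0) {
    w[] <- 0
    w[-excluded] <- 1
    if (!length(excluded)) w[] <- 1
    tot <- sum(w)
  }
  w / tot
}

#' Construct one ant's feature subset
#'
#' Sequential sampling without replacement of `subset_size` features under
#' the pseudo-random-proportional rule: at each step, with probability
#' `q0` the remaining feature maximizing `pheromone^alpha *
#' visibility^beta` is taken greedily (ties to the lowest index);
#' otherwise a feature is drawn from [transition_probabilities()].
#' Consumes the active RNG stream, so it is deterministic under a seeded
#' caller.
#'
#' @param state pheromone state.
#' @param cfg an [aco_config()].
#' @param subset_size number of features to select.
#' @return sorted integer vector of feature indices.
#' @export
construct_subset <- function(state, cfg = aco_config(),
                             subset_size = .resolve_subset_size(cfg, length(state$pheromone))) {
  d <- length(state$pheromone)
  if (subset_size > d)
    stop("subset_size (", subset_size, ") exceeds feature dimension (", d, ")",
         call. = FALSE)
  score <- state$pheromone^cfg$alpha * state$visibility^cfg$beta
  chosen <- integer(0)
  remaining <- rep(TRUE, d)
  for (step in seq_len(subset_size)) {
    if (runif(1) < cfg$q0) {
      s <- score
      s[!remaining] <- -Inf
      pick <- which.max(s)                          # first max = lowest index
    } else {
      p <- transition_probabilities(state, cfg, excluded = which(!remaining))
      pick <- sample.int(d, 1, prob = p)
    }
    chosen <- c(chosen, pick)
    remaining[pick] <- FALSE
  }
  sort(chosen)
}

# Seeded stratified train/holdout split of sample indices (holdout fraction
# rounded half-up per class); used by the 1-NN fitness so that every subset
# in a run is scored on the same partition.
.fitness_split <- function(labels, holdout_frac, seed) {
  with_seed(seed, {
    test <- logical(length(labels))
    for (c in unique(labels)) {
      idx <- which(labels == c)
      k <- max(1L, as.integer(round_half_up(holdout_frac * length(idx))))
      k <- min(k, length(idx) - 1L)
      test[sample(idx, k)] <- TRUE
    }
    test
  })
}

#' Fitness of a feature subset
#'
#' The ant-quality function: held-out accuracy in `[0, 1]` of a 1-nearest
#' neighbor classifier restricted to the subset's columns, under a seeded
#' stratified train/holdout split (fraction `cfg$fitness_holdout`).
#' Columns are standardized with training-part statistics. Cheap,
#' parameter-free, and deterministic under `cfg$seed`; the downstream
#' benchmark classifiers are deliberately not used here.
#'
#' @param table a [feature_table()].
#' @param subset nonempty integer vector of feature indices.
#' @param cfg an [aco_config()].
#' @param holdout optional precomputed logical holdout mask (internal use,
#'   so one run evaluates every subset on one partition).
#' @return accuracy in `[0, 1]`.
#' @export
subset_fitness <- function(table, subset, cfg = aco_config(), holdout = NULL) {
  stopifnot(inherits(table, "feature_table"), length(subset) >= 1)
  subset <- as.integer(subset)
  d <- ncol(table$matrix)
  if (any(subset < 1 | subset > d))
    stop("subset references out-of-range feature indices", call. = FALSE)
  y <- table$labels
  if (is.null(holdout))
    holdout <- .fitness_split(y, cfg$fitness_holdout, cfg$seed)
  X <- table$matrix[, subset, drop = FALSE]
  Xtr <- X[!holdout, , drop = FALSE]
  Xte <- X[holdout, , drop = FALSE]
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
  Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
  D <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * tcrossprod(Xte, Xtr)
  nn <- max.col(-D, ties.method = "first")
  mean(y[!holdout][nn] == y[holdout])
}

#' Local pheromone update (deposit on the iteration-best subset)
#'
#' For each feature `j` in the best subset, `pheromone_j <- (1 - mu) *
#' pheromone_j + mu * best_fitness`; all other features are untouched. The
#' deposit is the iteration-best subset's fitness, so reinforcement is
#' quality-weighted.
#'
#' @param state pheromone state.
#' @param best_subset integer indices of the iteration-best subset.
#' @param best_fitness its fitness in `[0, 1]`.
#' @param cfg an [aco_config()] (supplies `mu`).
#' @return the updated state.
#' @export
local_update <- function(state, best_subset, best_fitness, cfg = aco_config()) {
  s <- as.integer(best_subset)
  state$pheromone[s] <- (1 - cfg$mu) * state$pheromone[s] +
    cfg$mu * best_fitness
  state
}

#' Global pheromone update (evaporation toward the initial level)
#'
#' Applies `pheromone <- (1 - theta) * pheromone + theta * delta0` to every
#' feature: a convex pull toward `delta0` at geometric rate `1 - theta`,
#' with `delta0` as its fixed point. Keeps all pheromone values strictly
#' positive and prevents premature convergence.
#'
#' @param state pheromone state.
#' @param cfg an [aco_config()] (supplies `theta`, `delta0`).
#' @return the updated state.
#' @export
global_update <- function(state, cfg = aco_config()) {
  state$pheromone <- (1 - cfg$theta) * state$pheromone +
    cfg$theta * cfg$delta0
  state
}
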