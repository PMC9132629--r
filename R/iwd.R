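# Intelligent Water Drops (IWD) wrapper feature selection.
#
# Drops traverse a fully connected graph over feature nodes plus a virtual
# start node. Each edge carries "soil"; a drop prefers low-soil edges,
# gains velocity as it moves, and erodes soil from the edges it uses. The
# iteration-best tour (by wrapper fitness) gets a global soil
# reinforcement, so good feature subsets become progressively more
# probable. Velocity and soil are the dynamic quantities; the a/b/c
# constants and the update rates stay fixed for the whole run.

#' IWD parameter set
#'
#' Static constants and run controls for the water-drop search. The
#' defaults follow the canonical IWD literature; all are configurable.
#'
#' @param a_v,b_v,c_v velocity-update constants: a drop crossing an edge
#'   with soil s gains `a_v / (b_v + c_v * s^2)` velocity. `b_v > 0`.
#' @param a_s,b_s,c_s soil-update constants: the soil removed from an
#'   edge is `a_s / (b_s + c_s * time^2)` with `time = HUD / velocity`.
#'   `b_s > 0`.
#' @param rho_n local soil-update rate in (0, 1).
#' @param rho_iwd global (iteration-best) soil-update rate in (0, 1).
#' @param init_soil initial soil on every edge. The default keeps the
#'   decayed initial soil `(1 - rho_n) * init_soil` on the scale of the
#'   largest erosion `rho_n * a_s / b_s`, so a single traversal already
#'   differentiates edges by their heuristic desirability; a much larger
#'   value makes the first traversals look identical regardless of
#'   guidance.
#' @param init_vel initial drop velocity.
#' @param epsilon_p small positive constant guarding the transition-rule
#'   division.
#' @param n_drops drops per iteration.
#' @param n_iterations iteration budget.
#' @param m subset size: features visited per tour. `NULL` defers to the
#'   selector's default (10% of features, at least 5).
#' @param lambda_penalty subset-size penalty weight in the fitness.
#' @param stagnation_reset iterations without best-fitness improvement
#'   after which the soil table is re-initialized (the best subset is
#'   kept). Strong local erosion makes the first good trail absorbing;
#'   periodic restarts restore exploration, the usual stagnation
#'   handling in trail-laying metaheuristics. Worth enabling on small
#'   feature spaces; disabled (`Inf`) by default, where the budget is
#'   better spent deepening trails on large spaces.
#' @param hud_scale multiplier mapping unit heuristic-undesirability
#'   scores onto traversal times commensurate with the drop velocity.
#'   The default, `10 * init_vel * sqrt(b_s / c_s)`, puts the most
#'   desirable edges deep in the high-erosion regime
#'   (`time << sqrt(b_s/c_s)`) and the least desirable ones well past it,
#'   so label-aware guidance actually modulates soil erosion; with unit
#'   HUD and a velocity of 200 the `c_s * time^2` term would be
#'   numerically invisible against `b_s`.
#' @param seed integer seed for the whole search.
#' @return an object of class `iwd_params`.
#' @export
iwd_params <- function(a_v = 1, b_v = 0.01, c_v = 1,
                       a_s = 1, b_s = 0.01, c_s = 1,
                       rho_n = 0.9, rho_iwd = 0.9,
                       init_soil = 100, init_vel = 200,
                       epsilon_p = 0.01,
                       n_drops = 10L, n_iterations = 100L,
                       m = NULL, lambda_penalty = 0.01,
                       stagnation_reset = Inf, hud_scale = NULL, seed = 1L) {
  fail_if(b_v <= 0 || b_s <= 0, "b_v and b_s must be positive")
  fail_if(epsilon_p <= 0, "epsilon_p must be positive")
  fail_if(!(rho_n > 0 && rho_n < 1), "rho_n must be in (0, 1)")
  fail_if(!(rho_iwd > 0 && rho_iwd < 1), "rho_iwd must be in (0, 1)")
  fail_if(!is.null(m) && m < 1, "subset size m must be >= 1")
  if (is.null(hud_scale)) hud_scale <- 10 * init_vel * sqrt(b_s / c_s)
  fail_if(hud_scale <= 0, "hud_scale must be positive")
  fail_if(!(stagnation_reset >= 1), "stagnation_reset must be >= 1")
  structure(list(a_v = a_v, b_v = b_v, c_v = c_v,
                 a_s = a_s, b_s = b_s, c_s = c_s,
                 rho_n = rho_n, rho_iwd = rho_iwd,
                 init_soil = init_soil, init_vel = init_vel,
                 epsilon_p = epsilon_p,
                 n_drops = as.integer(n_drops),
                 n_iterations = as.integer(n_iterations),
                 m = if (is.null(m)) NULL else as.integer(m),
                 lambda_penalty = lambda_penalty,
                 stagnation_reset = if (is.finite(stagnation_reset))
                   as.integer(stagnation_reset) else Inf,
                 hud_scale = hud_scale,
                 seed = as.integer(seed)),
            class = "iwd_params")
}

#' Initialize the IWD search state
#'
#' The state is a mutable environment holding the symmetric edge-soil
#' table over `n_features` feature nodes plus the virtual start node
#' (index 0), the best subset found so far, and the iteration counter.
#' Every edge starts at `init_soil`.
#'
#' @param n_features number of feature nodes; must be at least the subset
#'   size `m`.
#' @param params an [iwd_params()].
#' @return an environment of class `iwd_state` with fields `soil`
#'   (`(n+1) x (n+1)` matrix; row/column 1 is the start node, feature j
#'   lives at index j + 1), `best_subset`, `best_fitness`, `iteration`.
#' @export
iwd_init_state <- function(n_features, params) {
  m <- if (is.null(params$m))
    min(n_features, max(5L, ceiling(0.1 * n_features))) else params$m
  fail_if(n_features < 1L, "need at least one feature")
  fail_if(n_features < m,
          sprintf("n_features (%d) must be >= subset size m (%d)",
                  n_features, m))
  st <- new.env(parent = emptyenv())
  st$soil <- matrix(params$init_soil, n_features + 1L, n_features + 1L)
  diag(st$soil) <- 0
  st$n_features <- as.integer(n_features)
  st$m <- as.integer(m)
  st$best_subset <- NULL
  st$best_fitness <- -Inf
  st$iteration <- 0L
  class(st) <- "iwd_state"
  st
}

#' Transition probabilities of a drop
#'
#' From node i a drop moves to an unvisited feature j with probability
#' proportional to `f(soil(i, j))` where `f(s) = 1 / (epsilon_p + g(s))`
#' and `g` shifts soils up by the most negative candidate soil (soil may
#' legitimately go negative through erosion). Lower soil means higher
#' probability; the probabilities sum to one.
#'
#' @param current current node: 0 for the start node, otherwise a feature
#'   index in 1..n.
#' @param visited integer vector of already-visited feature indices.
#' @param state an `iwd_state`.
#' @param params an [iwd_params()].
#' @return named numeric vector of probabilities over the unvisited
#'   feature indices.
#' @export
iwd_transition_probs <- function(current, visited, state, params) {
  cand <- setdiff(seq_len(state$n_features), visited)
  fail_if(length(cand) == 0L, "no unvisited features to move to")
  soils <- state$soil[current + 1L, cand + 1L]
  g <- soils - min(0, min(soils))
  f <- 1 / (params$epsilon_p + g)
  stats::setNames(f / sum(f), cand)
}

#' Velocity update across an edge
#'
#' `vel(t+1) = vel(t) + a_v / (b_v + c_v * soil^2)`: low-soil edges speed
#' a drop up the most; the increment vanishes as soil grows, and velocity
#' is strictly increasing whenever `a_v > 0`.
#'
#' @param velocity current velocity.
#' @param soil_edge soil on the edge being crossed.
#' @param params an [iwd_params()].
#' @return the updated velocity.
#' @export
iwd_update_velocity <- function(velocity, soil_edge, params) {
  velocity + params$a_v / (params$b_v + params$c_v * soil_edge^2)
}

#' Soil carried off an edge by a drop
#'
#' The traversal time is `HUD / velocity` (HUD is the edge's heuristic
#' undesirability); the soil removed is `a_s / (b_s + c_s * time^2)`:
#' fast drops on desirable edges erode the most soil.
#'
#' @param hud heuristic undesirability of the edge, positive.
#' @param velocity drop velocity after the move; must be positive.
#' @param params an [iwd_params()].
#' @return the (positive, finite) soil increment carried by the drop.
#' @export
iwd_soil_delta <- function(hud, velocity, params) {
  fail_if(velocity <= 0, "drop velocity must be positive")
  tm <- hud / velocity
  params$a_s / (params$b_s + params$c_s * tm^2)
}

#' Local soil update after a traversal
#'
#' The crossed edge loses soil,
#' `soil <- (1 - rho_n) * soil - rho_n * delta_soil`, and the drop adds
#' `delta_soil` to its carried load. The soil table is symmetric, so both
#' orientations of the edge are updated.
#'
#' @param state an `iwd_state` (mutated in place).
#' @param from,to edge endpoints (0 = start node, features 1..n).
#' @param delta_soil soil removed, from [iwd_soil_delta()].
#' @param params an [iwd_params()].
#' @return the new soil value, invisibly.
#' @export
iwd_local_update <- function(state, from, to, delta_soil, params) {
  i <- from + 1L; j <- to + 1L
  s <- (1 - params$rho_n) * state$soil[i, j] - params$rho_n * delta_soil
  state$soil[i, j] <- s
  state$soil[j, i] <- s
  invisible(s)
}

#' Construct one drop's tour
#'
#' A single drop starts at the virtual start node with the initial
#' velocity and makes `m` probabilistic moves; each move updates the
#' drop's velocity, computes the soil it erodes, applies the local soil
#' update and accumulates carried soil. Uses the current R RNG stream
#' (callers seed it).
#'
#' @param state an `iwd_state` (its soil is mutated).
#' @param params an [iwd_params()].
#' @param hud numeric vector of per-feature heuristic undesirability
#'   scores (destination-based edge costs).
#' @return list with `visited` (ordered feature indices), `velocity`,
#'   `carried_soil`.
#' @export
iwd_construct_solution <- function(state, params, hud) {
  visited <- integer(state$m)
  vel <- params$init_vel
  carried <- 0
  current <- 0L
  for (step in seq_len(state$m)) {
    p <- iwd_transition_probs(current, visited[seq_len(step - 1L)],
                              state, params)
    cand <- as.integer(names(p))
    nxt <- if (length(cand) == 1L) cand else
      cand[sample.int(length(cand), 1L, prob = p)]
    edge_soil <- state$soil[current + 1L, nxt + 1L]
    vel <- iwd_update_velocity(vel, edge_soil, params)
    delta <- iwd_soil_delta(hud[nxt], vel, params)
    iwd_local_update(state, current, nxt, delta, params)
    carried <- carried + delta
    visited[step] <- nxt
    current <- nxt
  }
  list(visited = visited, velocity = vel, carried_soil = carried)
}

#' Heuristic undesirability of each feature
#'
#' A label-aware prior edge cost: for each feature, the one-vs-rest
#' point-biserial correlation with every class indicator is computed, the
#' maximum absolute association is normalized over features to \[0, 1\],
#' and HUD is one minus that (floored at 0.05 so traversal times stay
#' positive). Strongly class-associated features are "desirable" — drops
#' reach them fast and erode their edges hardest.
#'
#' @param x a `feature_matrix`.
#' @return numeric vector of HUD scores in \[0.05, 1\], one per feature.
#' @export
iwd_hud_scores <- function(x) {
  stopifnot(inherits(x, "feature_matrix"))
  K <- length(x$class_names)
  ind <- matrix(0, nrow(x$values), K)
  ind[cbind(seq_len(nrow(x$values)), x$labels + 1L)] <- 1
  suppressWarnings(cc <- stats::cor(x$values, ind))
  cc[is.na(cc)] <- 0
  assoc <- apply(abs(cc), 1L, max)
  mx <- max(assoc)
  if (mx > 0) assoc <- assoc / mx
  pmax(1 - assoc, 0.05)
}

#' Build the wrapper fitness configuration
#'
#' The fitness of a subset is the mean stratified k-fold accuracy of a
#' fast nearest-centroid classifier restricted to the subset's columns,
#' minus `lambda_penalty * |subset| / n_features`. The fold assignment is
#' drawn once under the seed, so the fitness is a deterministic function
#' of the subset for the whole search. Rows with identical feature
#' vectors (the duplicates an oversampled matrix contains) are always
#' placed in the same fold: otherwise the inner cross-validation would
#' reward memorizing duplicated rows rather than class signal.
#'
#' @param x the training `feature_matrix`.
#' @param k number of folds (default 3).
#' @param lambda_penalty subset-size penalty weight.
#' @param seed integer seed for the fold assignment.
#' @return an object of class `iwd_fitness_config`.
#' @export
fitness_config <- function(x, k = 3L, lambda_penalty = 0.01, seed = 1L) {
  stopifnot(inherits(x, "feature_matrix"))
  n <- nrow(x$values)
  key <- apply(x$values, 1L, paste, collapse = ",")
  gid <- match(key, unique(key))
  folds <- integer(n)
  with_seed(seed, {
    for (kk in seq_along(x$class_names) - 1L) {
      cls <- x$labels == kk
      gs <- unique(gid[cls])
      gs <- gs[sample.int(length(gs))]
      fmap <- rep_len(seq_len(k), length(gs))
      for (i in seq_along(gs))
        folds[cls & gid == gs[i]] <- fmap[i]
    }
  })
  structure(list(k = as.integer(k), folds = folds,
                 lambda_penalty = lambda_penalty,
                 n_features = ncol(x$values)),
            class = "iwd_fitness_config")
}

#' Wrapper fitness of a feature subset
#'
#' @param indices integer feature (column) indices, non-empty.
#' @param x the training `feature_matrix`.
#' @param config an [fitness_config()].
#' @return the fitness value (mean fold accuracy minus size penalty).
#' @export
iwd_fitness <- function(indices, x, config) {
  fail_if(length(indices) == 0L, "subset must be non-empty")
  V <- x$values[, indices, drop = FALSE]
  labs <- x$labels
  K <- length(x$class_names)
  accs <- vapply(seq_len(config$k), function(f) {
    tr <- config$folds != f
    te <- !tr
    if (!any(te) || !any(tr)) return(NA_real_)
    present <- which(vapply(seq_len(K), function(kk)
      any(tr & labs == kk - 1L), logical(1)))
    cent <- matrix(0, length(present), ncol(V))
    for (pi in seq_along(present))
      cent[pi, ] <- colMeans(V[tr & labs == present[pi] - 1L, , drop = FALSE])
    Xte <- V[te, , drop = FALSE]
    d2 <- outer(rowSums(Xte^2), rowSums(cent^2), `+`) -
      2 * Xte %*% t(cent)
    # ties broken toward the lowest class index (present is ascending)
    pred <- present[max.col(-d2, ties.method = "first")] - 1L
    mean(pred == labs[te])
  }, numeric(1))
  acc <- mean(accs, na.rm = TRUE)
  if (is.nan(acc)) acc <- 0  # degenerate folds (e.g. one row per class)
  acc - config$lambda_penalty * length(indices) / config$n_features
}

#' Global soil reinforcement along the iteration-best tour
#'
#' Every edge of the iteration-best tour is updated as
#' `soil <- (1 + rho_iwd) * soil - rho_iwd * carried_soil / (m - 1)`
#' (divisor guarded at 1 when m = 1), and the best-so-far subset is
#' replaced only on a strict fitness improvement (ties keep the
#' incumbent), so the recorded best fitness never decreases.
#'
#' @param state an `iwd_state` (mutated).
#' @param tour the iteration-best drop: list with `visited` and
#'   `carried_soil`.
#' @param fitness the tour's fitness.
#' @param params an [iwd_params()].
#' @return invisibly, the state.
#' @export
iwd_global_update <- function(state, tour, fitness, params) {
  m <- length(tour$visited)
  share <- tour$carried_soil / max(1L, m - 1L)
  path <- c(0L, tour$visited)
  for (e in seq_len(m)) {
    i <- path[e] + 1L; j <- path[e + 1L] + 1L
    s <- (1 + params$rho_iwd) * state$soil[i, j] - params$rho_iwd * share
    state$soil[i, j] <- s
    state$soil[j, i] <- s
  }
  if (fitness > state$best_fitness) {
    state$best_fitness <- fitness
    state$best_subset <- sort(tour$visited)
  }
  invisible(state)
}

#' Select a feature subset with the Intelligent Water Drops search
#'
#' Runs `n_iterations` iterations of `n_drops` tours each. Every tour is
#' scored by the wrapper fitness ([iwd_fitness()]; fitness values are
#' cached per subset), the iteration best reinforces its edges globally,
#' and the best subset ever seen is returned. Fully reproducible under
#' `params$seed`.
#'
#' @param x the training `feature_matrix`.
#' @param params an [iwd_params()]. If `params$m` is `NULL` the subset
#'   size defaults to 10% of the features, at least 5 (capped at the
#'   feature count).
#' @param fitness_fn optional replacement fitness: a
#'   `function(indices, x)` returning a scalar; defaults to the built-in
#'   nearest-centroid wrapper. Supplying the trained network instead is
#'   possible but far costlier.
#' @return an object of class `iwd_result`: list with `indices` (sorted
#'   selected columns), `feature_names`, `fitness`, `trace` (data frame
#'   of per-iteration best fitness), `params`, `m`, `n_features`.
#' @examples
#' fm <- feature_matrix(matrix(runif(40), 10), rep(c("a", "b"), 5))
#' iwd_select(fm, iwd_params(m = 2, n_iterations = 5, n_drops = 3))
#' @export
iwd_select <- function(x, params = iwd_params(), fitness_fn = NULL) {
  stopifnot(inherits(x, "feature_matrix"), inherits(params, "iwd_params"))
  n_features <- ncol(x$values)
  fail_if(params$n_iterations < 1L, "n_iterations must be >= 1")
  fail_if(params$n_drops < 1L, "n_drops must be >= 1")
  if (!is.null(params$m))
    fail_if(params$m > n_features, "subset size m exceeds feature count")
  state <- iwd_init_state(n_features, params)
  hud <- params$hud_scale * iwd_hud_scores(x)
  fcfg <- fitness_config(x, lambda_penalty = params$lambda_penalty,
                         seed = stage_seed(params$seed, "iwd_folds"))
  fit_fn <- if (is.null(fitness_fn))
    function(idx) iwd_fitness(idx, x, fcfg) else
    function(idx) fitness_fn(idx, x)
  cache <- new.env(parent = emptyenv())
  cached_fit <- function(idx) {
    key <- paste(sort(idx), collapse = ",")
    v <- cache[[key]]
    if (is.null(v)) { v <- fit_fn(idx); cache[[key]] <- v }
    v
  }
  trace <- numeric(params$n_iterations)
  stall <- 0L
  with_seed(stage_seed(params$seed, "iwd_tours"), {
    for (it in seq_len(params$n_iterations)) {
      best_tour <- NULL; best_fit <- -Inf
      for (dr in seq_len(params$n_drops)) {
        tour <- iwd_construct_solution(state, params, hud)
        f <- cached_fit(tour$visited)
        if (f > best_fit) { best_fit <- f; best_tour <- tour }
      }
      improved <- best_fit > state$best_fitness
      iwd_global_update(state, best_tour, best_fit, params)
      state$iteration <- it
      trace[it] <- state$best_fitness
      stall <- if (improved) 0L else stall + 1L
      if (stall >= params$stagnation_reset) {
        state$soil[] <- params$init_soil
        diag(state$soil) <- 0
        stall <- 0L
      }
    }
  })
  structure(list(indices = state$best_subset,
                 feature_names = x$feature_names[state$best_subset],
                 fitness = state$best_fitness,
                 trace = data.frame(iteration = seq_len(params$n_iterations),
                                    best_fitness = trace),
                 params = params, m = state$m, n_features = n_features),
            class = "iwd_result")
}

#' @export
print.iwd_result <- function(x, ...) {
  cat(sprintf("Intelligent Water Drops feature selection\n"))
  cat(sprintf("  %d of %d features selected, wrapper fitness %.4f\n",
              length(x$indices), x$n_features, x$fitness))
  cat(sprintf("  %d iterations x %d drops\n",
              x$params$n_iterations, x$params$n_drops))
  show <- utils::head(x$feature_names, 10L)
  cat("  features:", paste(show, collapse = ", "),
      if (length(x$indices) > 10L) "..." else "", "\n")
  invisible(x)
}

#' @export
plot.iwd_result <- function(x, ...) {
  graphics::plot(x$trace$iteration, x$trace$best_fitness, type = "s",
       xlab = "iteration", ylab = "best fitness",
       main = "IWD convergence", ...)
  invisible(x)
}

#' Persist an IWD selection result as plain text
#'
#' Writes the selected feature names/indices with the fitness, plus the
#' per-iteration convergence trace as a delimited log.
#'
#' @param x an `iwd_result`.
#' @param stem path stem; `<stem>.subset.tsv` and `<stem>.trace.tsv` are
#'   produced.
#' @return `stem`, invisibly.
#' @export
write_iwd_result <- function(x, stem) {
  stopifnot(inherits(x, "iwd_result"))
  utils::write.table(
    data.frame(index = x$indices, feature = x$feature_names,
               fitness = x$fitness),
    paste0(stem, ".subset.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(x$trace, paste0(stem, ".trace.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(stem)
}
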