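#' Swarm configuration for binary PSO feature selection
#'
#' @param pop_size particles per swarm; default 20 (not fixed by the
#'   published configuration).
#' @param max_iters iterations per run; default 50.
#' @param c1,c2 cognitive/social acceleration constants; default 1.
#' @param seed base seed; repetition `r` reseeds with `seed + r - 1`.
#' @param n_runs independent repetitions; default 10.
#' @param velocity_clamp magnitude bound on velocities; default 6, which
#'   keeps the sigmoid transfer away from hard saturation.
#' @param per_dimension_r draw \eqn{r_1, r_2} per dimension instead of one
#'   scalar pair per particle per iteration (the default reading of the
#'   velocity update).
#' @return a [SwarmConfig-class].
#' @export
swarmConfig <- function(pop_size = 20L, max_iters = 50L, c1 = 1, c2 = 1,
                        seed = 1L, n_runs = 10L, velocity_clamp = 6,
                        per_dimension_r = FALSE) {
  new("SwarmConfig", pop_size = as.integer(pop_size),
      max_iters = as.integer(max_iters), c1 = as.numeric(c1),
      c2 = as.numeric(c2), seed = as.integer(seed),
      n_runs = as.integer(n_runs), velocity_clamp = as.numeric(velocity_clamp),
      per_dimension_r = isTRUE(per_dimension_r))
}

#' Fitness configuration for wrapper feature selection
#'
#' @param full_dim total feature dimension \eqn{|D|}.
#' @param omega weight on the embedded-classifier accuracy; default 0.99.
#' @param k_neighbors KNN neighbour count; default 6.
#' @return a [FitnessConfig-class].
#' @export
fitnessConfig <- function(full_dim, omega = 0.99, k_neighbors = 6L) {
  new("FitnessConfig", omega = as.numeric(omega),
      k_neighbors = as.integer(k_neighbors), full_dim = as.integer(full_dim))
}

#' Linearly decaying inertia weight
#'
#' \eqn{w(t) = 1 - t/T}: the swarm explores early (large inertia) and
#' exploits late (inertia falling to zero at the final iteration).
#'
#' @param t current iteration, `0 <= t <= max_iters`.
#' @param max_iters total iterations `T`.
#' @return the inertia weight, in `[0, 1]`.
#' @export
inertiaWeight <- function(t, max_iters) {
  if (any(t < 0) || any(t > max_iters))
    stop("t must lie in [0, max_iters]")
  1 - t / max_iters
}

#' Sigmoid transfer function
#'
#' Maps a real-valued velocity to a bit-flip probability,
#' \eqn{S(v) = 1 / (1 + e^{-v})}; monotone increasing and saturating at the
#' extremes.
#'
#' @param v numeric velocities.
#' @return values in `(0, 1)`.
#' @export
transferSigmoid <- function(v) 1 / (1 + exp(-v))

#' Stochastic binarisation of velocities
#'
#' A position bit is set to 1 when a uniform draw falls below the sigmoid
#' of its velocity.
#'
#' @param v numeric velocities.
#' @param rand uniform draws in `[0, 1]`; defaults to fresh draws from the
#'   current RNG stream (pass explicitly to pin the outcome).
#' @return integer 0/1 vector.
#' @export
binarizeVelocity <- function(v, rand = runif(length(v))) {
  as.integer(rand < transferSigmoid(v))
}

#' One velocity update of a particle
#'
#' \deqn{v' = w v + C_1 r_1 (pbest - x) + C_2 r_2 (gbest - x)}
#' with the result clamped to `[-clamp, clamp]`. `r1`, `r2` default to
#' fresh scalar U\[0,1\] draws shared across dimensions.
#'
#' @param velocity,position,pbest,gbest equal-length numeric/bit vectors.
#' @param w inertia weight.
#' @param c1,c2 acceleration constants.
#' @param r1,r2 uniform draws (scalar, or one per dimension).
#' @param clamp velocity magnitude bound.
#' @return the updated, clamped velocity vector.
#' @export
updateVelocity <- function(velocity, position, pbest, gbest, w,
                           c1 = 1, c2 = 1, r1 = runif(1), r2 = runif(1),
                           clamp = 6) {
  d <- length(velocity)
  if (length(position) != d || length(pbest) != d || length(gbest) != d)
    stop("velocity, position, pbest and gbest dimensions must agree")
  v <- w * velocity + c1 * r1 * (pbest - position) +
    c2 * r2 * (gbest - position)
  pmin(pmax(v, -clamp), clamp)
}

#' Feature-reduction term
#'
#' \eqn{\Delta = (|D| - |d|) / |D|}: the fraction of the full feature
#' dimension a mask discards.
#'
#' @param n_selected selected feature count \eqn{|d|}.
#' @param full_dim total feature dimension \eqn{|D|}.
#' @return value in `[0, 1]`.
#' @examples
#' reductionTerm(592, 1280)  # 0.5375
#' @export
reductionTerm <- function(n_selected, full_dim) {
  if (any(n_selected < 0) || any(n_selected > full_dim))
    stop("n_selected must lie in [0, full_dim]")
  (full_dim - n_selected) / full_dim
}

# Fast fitness path on bare matrices (used inside the optimiser loops).
.mask_fitness <- function(mask, Xtr, ytr, Xev, yev, omega, k, full_dim) {
  d <- sum(mask)
  if (d == 0L) return(0)  # eta undefined with no features; floor fitness
  sel <- which(mask == 1L)
  eta <- .knn_accuracy(Xtr[, sel, drop = FALSE], ytr,
                       Xev[, sel, drop = FALSE], yev, k)
  omega * eta + (1 - omega) * reductionTerm(d, full_dim)
}

#' Fitness of a candidate feature subset
#'
#' Trains the embedded KNN on the masked training features, scores it on
#' the masked evaluation features (accuracy \eqn{\eta}), and combines
#' accuracy with the reduction term:
#' \eqn{F = \omega \eta + (1 - \omega) \Delta}. The empty mask has fitness
#' 0 and can never become an incumbent.
#'
#' @param mask 0/1 vector of length `config@full_dim`.
#' @param train,eval [FeatureMatrix-class] objects whose width equals
#'   `config@full_dim`. `eval` should be a split held out of `train`.
#' @param config a [FitnessConfig-class].
#' @return the fitness, in `[0, 1]` for `omega` in `[0, 1]`.
#' @export
subsetFitness <- function(mask, train, eval, config) {
  mask <- as.integer(mask)
  if (length(mask) != config@full_dim ||
      featureDim(train) != config@full_dim ||
      featureDim(eval) != config@full_dim)
    stop("mask length, feature widths and full_dim must all agree")
  .mask_fitness(mask, featureValues(train), sampleLabels(train),
                featureValues(eval), sampleLabels(eval),
                config@omega, config@k_neighbors, config@full_dim)
}

# One seeded BPSO run. Positions initialise Bernoulli(0.5), velocities
# U[-1, 1]; iteration 0 evaluates the initial swarm before the loop.
# pbest/gbest only move on strictly greater fitness (ties keep incumbents,
# and the iteration-0 gbest is the first particle achieving the maximum).
.bpso_run <- function(Xtr, ytr, Xev, yev, swarm, fit, seed,
                      init_positions = NULL) {
  P <- swarm@pop_size; D <- fit@full_dim; Tm <- swarm@max_iters
  set.seed(seed)
  X <- matrix(rbinom(P * D, 1L, 0.5), P, D)
  if (!is.null(init_positions)) {
    init_positions <- matrix(as.integer(init_positions), ncol = D)
    X[seq_len(nrow(init_positions)), ] <- init_positions
  }
  V <- matrix(runif(P * D, -1, 1), P, D)
  fits <- vapply(seq_len(P), function(i)
    .mask_fitness(X[i, ], Xtr, ytr, Xev, yev, fit@omega, fit@k_neighbors, D),
    numeric(1))
  pbest <- X; pbest_fit <- fits
  g <- which.max(pbest_fit)
  gbest <- pbest[g, ]; gbest_fit <- pbest_fit[g]
  history <- numeric(Tm + 1L); history[1L] <- gbest_fit
  for (t in seq_len(Tm)) {
    w <- inertiaWeight(t, Tm)
    if (swarm@per_dimension_r) {
      R1 <- matrix(runif(P * D), P, D); R2 <- matrix(runif(P * D), P, D)
    } else {
      R1 <- matrix(runif(P), P, D); R2 <- matrix(runif(P), P, D)
    }
    gbest_mat <- matrix(gbest, P, D, byrow = TRUE)
    V <- w * V + swarm@c1 * R1 * (pbest - X) + swarm@c2 * R2 * (gbest_mat - X)
    V <- pmin(pmax(V, -swarm@velocity_clamp), swarm@velocity_clamp)
    X <- matrix(as.integer(matrix(runif(P * D), P, D) < transferSigmoid(V)),
                P, D)
    for (i in seq_len(P)) {
      f <- .mask_fitness(X[i, ], Xtr, ytr, Xev, yev, fit@omega,
                         fit@k_neighbors, D)
      if (f > pbest_fit[i]) {
        pbest_fit[i] <- f
        pbest[i, ] <- X[i, ]
        if (f > gbest_fit) {
          gbest_fit <- f
          gbest <- X[i, ]
        }
      }
    }
    history[t + 1L] <- gbest_fit
  }
  list(mask = as.integer(gbest), fitness = gbest_fit,
       n_selected = as.integer(sum(gbest)), history = history, seed = seed)
}

#' Binary PSO wrapper feature selection
#'
#' Runs `n_runs` independent seeded repetitions of sigmoid-transfer binary
#' PSO over the fused feature space. Each run initialises positions
#' Bernoulli(0.5) and velocities U\[-1, 1\], evaluates the initial swarm
#' (iteration 0), then iterates: inertia weight \eqn{w = 1 - t/T}, velocity
#' update with attraction to the personal and global bests, sigmoid
#' binarisation, fitness evaluation, and strictly-greater best updates.
#' The reported result is the best run's; all runs are retained in
#' `@runs` so metrics can be averaged across repetitions.
#'
#' Identical configuration and inputs give a bitwise-identical result.
#'
#' @param train,eval aligned [FeatureMatrix-class] objects; `eval` is the
#'   held-out split scored by the embedded KNN (keep the test split out of
#'   the selection loop to avoid leakage).
#' @param swarm a [SwarmConfig-class].
#' @param fit a [FitnessConfig-class]; `full_dim` must equal the feature
#'   width.
#' @param init_positions optional 0/1 matrix whose rows replace the first
#'   particles of every run's initial swarm (e.g. to seed the all-ones
#'   mask).
#' @return an [FSResult-class].
#' @export
runBPSO <- function(train, eval, swarm = swarmConfig(),
                    fit = fitnessConfig(featureDim(train)),
                    init_positions = NULL) {
  validObject(swarm); validObject(fit)
  if (featureDim(train) != fit@full_dim || featureDim(eval) != fit@full_dim)
    stop("feature widths must equal full_dim")
  ytr <- sampleLabels(train)
  if (length(unique(ytr)) < 2L)
    stop("feature selection needs at least two classes in the training split")
  Xtr <- featureValues(train); Xev <- featureValues(eval)
  yev <- sampleLabels(eval)
  runs <- lapply(seq_len(swarm@n_runs), function(r)
    .bpso_run(Xtr, ytr, Xev, yev, swarm, fit, swarm@seed + r - 1L,
              init_positions))
  fitnesses <- vapply(runs, `[[`, numeric(1), "fitness")
  best <- which.max(fitnesses)   # ties -> earliest run
  br <- runs[[best]]
  new("FSResult", mask = br$mask, fitness = br$fitness,
      n_selected = br$n_selected, gbest_history = br$history,
      run_seed = as.integer(br$seed), runs = runs)
}

#' Exhaustive-search oracle for small feature spaces
#'
#' Evaluates every non-empty mask (\eqn{2^{|D|} - 1} candidates) and
#' returns the fitness maximiser; a guard refuses dimensions above 20.
#' Ties are broken toward fewer selected features, then by lexicographic
#' mask order. Used as the ground-truth optimum against which stochastic
#' optimisers are benchmarked.
#'
#' @inheritParams runBPSO
#' @return list with elements `mask` (0/1 integer vector) and `fitness`.
#' @export
exhaustiveSearch <- function(train, eval, fit = fitnessConfig(featureDim(train))) {
  D <- fit@full_dim
  if (featureDim(train) != D || featureDim(eval) != D)
    stop("feature widths must equal full_dim")
  if (D > 20L)
    stop("exhaustiveSearch refuses full_dim > 20 (2^D evaluations)")
  Xtr <- featureValues(train); ytr <- sampleLabels(train)
  Xev <- featureValues(eval); yev <- sampleLabels(eval)
  best_mask <- NULL; best_fit <- -Inf; best_n <- Inf
  for (m in seq_len(2^D - 1L)) {
    mask <- as.integer(bitwAnd(bitwShiftR(m, 0:(D - 1L)), 1L))
    f <- .mask_fitness(mask, Xtr, ytr, Xev, yev, fit@omega, fit@k_neighbors, D)
    n <- sum(mask)
    replace <- f > best_fit ||
      (f == best_fit && (n < best_n ||
        (n == best_n && .lex_before(mask, best_mask))))
    if (replace) {
      best_mask <- mask; best_fit <- f; best_n <- n
    }
  }
  list(mask = best_mask, fitness = best_fit)
}

# TRUE if a comes strictly before b in lexicographic 0/1 order.
.lex_before <- function(a, b) {
  d <- which(a != b)
  length(d) > 0L && a[d[1L]] < b[d[1L]]
}

#' Accessors for feature-selection results
#'
#' `selectionMask()` returns the 0/1 mask of the best run,
#' `bestFitness()` its fitness and `gbestHistory()` the per-iteration
#' global-best trajectory (non-decreasing, starting at the iteration-0
#' evaluation).
#'
#' @param x an [FSResult-class].
#' @rdname FSResult-accessors
#' @export
setMethod("selectionMask", "FSResult", function(x) x@mask)

#' @rdname FSResult-accessors
#' @export
setMethod("bestFitness", "FSResult", function(x) x@fitness)

#' @rdname FSResult-accessors
#' @export
setMethod("gbestHistory", "FSResult", function(x) x@gbest_history)

setMethod("show", "FSResult", function(object) {
  cat(sprintf("FSResult: %d of %d features selected, fitness %.6f (run seed %d, %d runs)\n",
              object@n_selected, length(object@mask), object@fitness,
              object@run_seed, length(object@runs)))
})

#' Serialise an FSResult to JSON
#'
#' Writes the mask as a 0/1 string together with the fitness, selected
#' count, winning seed, global-best history and the per-run summaries.
#'
#' @param x an [FSResult-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeFSResult <- function(x, file) {
  jsonlite::write_json(list(
    mask = paste(x@mask, collapse = ""),
    fitness = x@fitness, n_selected = x@n_selected,
    run_seed = x@run_seed, gbest_history = x@gbest_history,
    runs = lapply(x@runs, function(r)
      list(fitness = r$fitness, n_selected = r$n_selected, seed = r$seed))),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeFSResult
#' @export
readFSResult <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  mask <- as.integer(strsplit(j$mask, "")[[1]])
  new("FSResult", mask = mask, fitness = j$fitness,
      n_selected = as.integer(j$n_selected),
      gbest_history = as.numeric(j$gbest_history),
      run_seed = as.integer(j$run_seed),
      runs = if (is.data.frame(j$runs)) split(j$runs, seq_len(nrow(j$runs)))
             else as.list(j$runs))
}
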