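#' Parameters shared by the swarm-based column selectors
#'
#' The three metaheuristic reduction methods (hybrid bee-colony/PSO, cuckoo
#' search, dragonfly) search over binary masks selecting 100 of the 200
#' per-segment sample positions, driven by the shared wrapper fitness of
#' [mask_fitness()]. Candidate solutions live in a continuous position
#' space; positions are squashed through a sigmoid, thresholded at 0.5 and
#' repaired to exactly the target number of selected columns.
#'
#' @param pop_size Population size (>= 2).
#' @param max_iter Number of generations.
#' @param a_weight,b_weight Convex weights of the wrapper fitness
#'   (accuracy term and parsimony term).
#' @param accel_a,accel_b PSO acceleration coefficients toward the personal
#'   and global best.
#' @param beta_step Levy-flight step-size scale for cuckoo search.
#' @param levy_gamma Power-law exponent of the Levy step distribution,
#'   `1 < levy_gamma <= 3`.
#' @param pa_abandon Fraction of worst nests abandoned per generation in
#'   cuckoo search, in `[0, 1]`.
#' @param s,a,c,f,e,omega Dragonfly weights: separation, alignment,
#'   cohesion, food attraction, enemy distraction, inertia.
#' @param enemy_conventional If `TRUE`, use the conventional enemy offset
#'   `Q- - Q` instead of the printed additive form `Q- + Q`.
#' @param fitness_subsample Cap on the number of rows (stratified,
#'   deterministic) used when evaluating the wrapper fitness; keeps the
#'   selectors tractable on full cohorts.
#' @param seed Integer seed; required for reproducibility.
#' @return An object of class `swarm_params`.
#' @export
swarm_params <- function(pop_size = 20, max_iter = 30,
                         a_weight = 0.8, b_weight = 0.2,
                         accel_a = 0.7, accel_b = 0.7,
                         beta_step = 0.5, levy_gamma = 2.5,
                         pa_abandon = 0.25,
                         s = 0.1, a = 0.1, c = 0.7, f = 1, e = 0.1,
                         omega = 0.9, enemy_conventional = FALSE,
                         fitness_subsample = 512, seed = 1L) {
  stopifnot(pop_size >= 2, max_iter >= 0, levy_gamma > 1, levy_gamma <= 3,
            pa_abandon >= 0, pa_abandon <= 1, fitness_subsample >= 10)
  structure(list(pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter),
                 a_weight = a_weight, b_weight = b_weight,
                 accel_a = accel_a, accel_b = accel_b,
                 beta_step = beta_step, levy_gamma = levy_gamma,
                 pa_abandon = pa_abandon, s = s, a = a, c = c, f = f, e = e,
                 omega = omega, enemy_conventional = enemy_conventional,
                 fitness_subsample = as.integer(fitness_subsample),
                 seed = as.integer(seed)),
            class = "swarm_params")
}

# Per-column class-mean separation score |mean_CVD - mean_NORMAL| / pooled sd.
# With a single class present, falls back to the column standard deviation so
# ranking-based repair stays well defined.
column_separation <- function(x, y) {
  cls <- unique(y)
  if (length(cls) < 2) {
    sds <- apply(x, 2, stats::sd)
    return(sds + 1e-12)
  }
  xa <- x[y == "CVD", , drop = FALSE]
  xb <- x[y == "NORMAL", , drop = FALSE]
  sa <- apply(xa, 2, stats::sd)
  sb <- apply(xb, 2, stats::sd)
  pooled <- sqrt((sa^2 + sb^2) / 2) + 1e-12
  abs(colMeans(xa) - colMeans(xb)) / pooled
}

# Force a logical mask to exactly k selected columns by flipping the
# lowest-impact bits according to a fixed column ranking (higher = keep).
repair_mask <- function(sel, k, ranking) {
  n_sel <- sum(sel)
  if (n_sel > k) {
    on <- which(sel)
    drop <- on[order(ranking[on])][seq_len(n_sel - k)]
    sel[drop] <- FALSE
  } else if (n_sel < k) {
    off <- which(!sel)
    add <- off[order(ranking[off], decreasing = TRUE)][seq_len(k - n_sel)]
    sel[add] <- TRUE
  }
  sel
}

# Deterministic stratified split + nearest-centroid holdout accuracy.
centroid_holdout_accuracy <- function(x, y, cols) {
  cls <- unique(y)
  if (length(cls) < 2) return(NA_real_)
  tr <- logical(nrow(x))
  for (cl in cls) {
    idx <- which(y == cl)
    tr[idx[seq_len(ceiling(0.7 * length(idx)))]] <- TRUE
  }
  xm <- x[, cols, drop = FALSE]
  mu_c <- colMeans(xm[tr & y == "CVD", , drop = FALSE])
  mu_n <- colMeans(xm[tr & y == "NORMAL", , drop = FALSE])
  xt <- xm[!tr, , drop = FALSE]
  d_c <- rowSums(sweep(xt, 2, mu_c)^2)
  d_n <- rowSums(sweep(xt, 2, mu_n)^2)
  pred <- ifelse(d_c <= d_n, "CVD", "NORMAL")
  mean(pred == y[!tr])
}

#' Wrapper fitness of a binary column mask
#'
#' Scores a candidate feature subset as `F = a * phi(k) + b * (T - K) / T`
#' where `T` is the total column count, `K` the number of selected columns,
#' and `phi(k)` the hold-out accuracy (0-1) of a nearest-centroid evaluator
#' restricted to the selected columns (deterministic stratified 70/30
#' split). Higher is better. If the training fold holds a single class,
#' `phi(k) = 0` with a warning.
#'
#' @param mask Logical vector over columns with at least one `TRUE`.
#' @param x Numeric matrix of training rows.
#' @param y Character labels (`"CVD"` / `"NORMAL"`).
#' @param a_weight,b_weight Convex weights (defaults 0.8 / 0.2).
#' @return Scalar fitness.
#' @examples
#' b <- generate_feature_blobs(30, 20, 4, seed = 1)
#' mask_fitness(rep(c(TRUE, FALSE), 10), b$x, b$y)
#' @export
mask_fitness <- function(mask, x, y, a_weight = 0.8, b_weight = 0.2) {
  stopifnot(is.logical(mask), length(mask) == ncol(x), sum(mask) >= 1)
  phi <- centroid_holdout_accuracy(x, y, which(mask))
  if (is.na(phi)) {
    warning("single-class training data; accuracy term set to 0")
    phi <- 0
  }
  T_ <- length(mask)
  K <- sum(mask)
  a_weight * phi + b_weight * (T_ - K) / T_
}

#' Mantegna-sampled Levy-flight steps
#'
#' Draws heavy-tailed random step sizes whose density decays as
#' `|step|^(-levy_gamma)` (so the stability index is `levy_gamma - 1`),
#' using Mantegna's ratio-of-Gaussians construction.
#'
#' @param n Number of draws.
#' @param levy_gamma Power-law exponent, `1 < levy_gamma <= 3`.
#' @return Numeric vector of signed steps.
#' @export
levy_steps <- function(n, levy_gamma = 2.5) {
  stopifnot(levy_gamma > 1, levy_gamma <= 3)
  alpha <- levy_gamma - 1
  if (alpha >= 2) return(stats::rnorm(n))
  sigma_u <- (gamma(1 + alpha) * sin(pi * alpha / 2) /
                (gamma((1 + alpha) / 2) * alpha * 2^((alpha - 1) / 2)))^(1 / alpha)
  u <- stats::rnorm(n, sd = sigma_u)
  v <- stats::rnorm(n)
  u / abs(v)^(1 / alpha)
}

# Shared state for the three selectors: subsampled data, column ranking and
# the position -> fitness map.
selector_context <- function(x, y, params, k_select) {
  x <- check_finite_matrix(x, "feature data")
  stopifnot(length(y) == nrow(x))
  if (k_select >= ncol(x)) stop_ppg("k_select must be < ncol(x)")
  # deterministic stratified subsample for fitness evaluation
  if (nrow(x) > params$fitness_subsample) {
    keep <- integer(0)
    for (cl in unique(y)) {
      idx <- which(y == cl)
      take <- max(2L, round(params$fitness_subsample * length(idx) / nrow(x)))
      keep <- c(keep, idx[unique(round(seq(1, length(idx),
                                           length.out = take)))])
    }
    keep <- sort(keep)
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
  }
  ranking <- column_separation(x, y)
  single <- length(unique(y)) < 2
  warned <- FALSE
  fit_fun <- function(pos) {
    sel <- repair_mask(sigmoid(pos) > 0.5, k_select, ranking)
    phi <- if (single) NA_real_ else
      centroid_holdout_accuracy(x, y, which(sel))
    if (is.na(phi)) {
      if (!warned && !single) warning("degenerate fitness split")
      phi <- 0
    }
    T_ <- length(sel)
    params$a_weight * phi + params$b_weight * (T_ - k_select) / T_
  }
  mask_of <- function(pos) repair_mask(sigmoid(pos) > 0.5, k_select, ranking)
  if (single) {
    warning("single-class data: selector fitness reduces to the parsimony term")
  }
  list(fit = fit_fun, mask_of = mask_of, T_ = ncol(x))
}

# Initial population of continuous mask positions. Each individual gets its
# own additive bias so initial selection counts spread from near-empty to
# near-full masks; the ranking-based repair then concentrates the
# high-count individuals on the strongest columns, giving the search a
# well-spread, informative starting population.
init_positions <- function(pop, T_) {
  bias <- seq(-2.5, 2.5, length.out = pop)
  matrix(stats::runif(pop * T_, -1, 1), pop, T_) + bias
}

finish_mask <- function(pos, fitness, trace, ctx, method, params) {
  structure(list(mask = ctx$mask_of(pos), fitness = fitness, trace = trace,
                 method = method, params = params),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("Binary column mask (%s): %d of %d selected, fitness %.4f\n",
              x$method, sum(x$mask), length(x$mask), x$fitness))
  invisible(x)
}

#' Select feature columns with a hybrid bee-colony / particle-swarm search
#'
#' Searches for the best mask of `k_select` of the input columns under the
#' wrapper fitness of [mask_fitness()]. Employed-bee moves perturb one
#' dimension of a personal-best position against a random neighbour,
#' onlooker moves repeat this with selection proportional to fitness, and
#' the scout phase is replaced by particle-swarm velocity/position updates
#' toward the personal and global best. Continuous positions are squashed
#' through a sigmoid, thresholded and repaired to exactly `k_select`
#' columns. The best-so-far fitness trace is non-decreasing (elitism).
#'
#' @param x Numeric matrix (rows = segments, columns = candidate features).
#' @param y Character class labels per row.
#' @param params A [swarm_params()].
#' @param k_select Number of columns to select (default 100).
#' @return A `binary_mask` object: `mask` (logical), `fitness`, `trace`
#'   (best fitness per generation), `method`, `params`.
#' @export
abc_pso_select <- function(x, y, params = swarm_params(), k_select = 100) {
  ctx <- selector_context(x, y, params, k_select)
  with_seed(params$seed, {
    pop <- params$pop_size
    T_ <- ctx$T_
    X <- init_positions(pop, T_)
    V <- matrix(0, pop, T_)
    pbest <- X
    pbest_fit <- apply(pbest, 1, ctx$fit)
    g <- which.max(pbest_fit)
    gbest <- pbest[g, ]
    gbest_fit <- pbest_fit[g]
    trace <- gbest_fit
    bee_move <- function(m) {
      l <- sample(setdiff(seq_len(pop), m), 1)
      k <- sample.int(T_, 1)
      cand <- pbest[m, ]
      cand[k] <- cand[k] + stats::runif(1, -1, 1) * (cand[k] - pbest[l, k])
      fc <- ctx$fit(cand)
      if (fc > pbest_fit[m]) {
        pbest[m, ] <<- cand
        pbest_fit[m] <<- fc
      }
    }
    iter <- 0
    while (iter < params$max_iter) {
      iter <- iter + 1
      for (m in seq_len(pop)) bee_move(m)              # employed bees
      w <- pbest_fit - min(pbest_fit) + 1e-9           # onlookers
      chosen <- sample.int(pop, pop, replace = TRUE, prob = w)
      for (m in chosen) bee_move(m)
      g <- which.max(pbest_fit)
      gbest <- pbest[g, ]
      gbest_fit <- max(gbest_fit, pbest_fit[g])
      # PSO step in place of scouts
      V <- V + params$accel_a * (pbest - X) +
        params$accel_b * sweep(-X, 2, gbest, `+`)
      V <- pmin(pmax(V, -4), 4)
      X <- pmin(pmax(X + V, -6), 6)
      xfit <- apply(X, 1, ctx$fit)
      better <- xfit > pbest_fit
      pbest[better, ] <- X[better, , drop = FALSE]
      pbest_fit[better] <- xfit[better]
      g <- which.max(pbest_fit)
      if (pbest_fit[g] > gbest_fit) {
        gbest <- pbest[g, ]
        gbest_fit <- pbest_fit[g]
      }
      trace <- c(trace, gbest_fit)
    }
    finish_mask(gbest, gbest_fit, trace, ctx, "ABC_PSO", params)
  })
}

#' Select feature columns with cuckoo search and Levy flights
#'
#' Nests hold continuous mask positions; each generation every cuckoo
#' proposes a Levy-flight move `z + beta_step * levy`, which replaces a
#' random nest if fitter, and the `pa_abandon` fraction of worst nests
#' (never the best) is re-randomized. Binary conversion and elitism as in
#' [abc_pso_select()].
#'
#' @inheritParams abc_pso_select
#' @return A `binary_mask` object.
#' @export
cuckoo_select <- function(x, y, params = swarm_params(), k_select = 100) {
  ctx <- selector_context(x, y, params, k_select)
  with_seed(params$seed, {
    pop <- params$pop_size
    T_ <- ctx$T_
    Z <- init_positions(pop, T_)
    fitZ <- apply(Z, 1, ctx$fit)
    g <- which.max(fitZ)
    gbest <- Z[g, ]
    gbest_fit <- fitZ[g]
    trace <- gbest_fit
    iter <- 0
    while (iter < params$max_iter) {
      iter <- iter + 1
      for (i in seq_len(pop)) {
        cand <- Z[i, ] + params$beta_step * levy_steps(T_, params$levy_gamma)
        cand <- pmin(pmax(cand, -6), 6)
        fc <- ctx$fit(cand)
        j <- sample.int(pop, 1)
        if (fc > fitZ[j]) {
          Z[j, ] <- cand
          fitZ[j] <- fc
        }
      }
      n_ab <- floor(params$pa_abandon * pop)
      if (n_ab > 0) {
        ord <- order(fitZ)                      # worst first
        ab <- setdiff(ord, which.max(fitZ))[seq_len(min(n_ab, pop - 1))]
        Z[ab, ] <- matrix(stats::runif(length(ab) * T_, -1, 1),
                          length(ab), T_)
        fitZ[ab] <- apply(Z[ab, , drop = FALSE], 1, ctx$fit)
      }
      g <- which.max(fitZ)
      if (fitZ[g] > gbest_fit) {
        gbest <- Z[g, ]
        gbest_fit <- fitZ[g]
      }
      trace <- c(trace, gbest_fit)
    }
    finish_mask(gbest, gbest_fit, trace, ctx, "CUCKOO", params)
  })
}

#' Select feature columns with the dragonfly algorithm
#'
#' Each dragonfly carries a position and a step vector; the step combines
#' separation, alignment, cohesion, attraction to the best position (food)
#' and distraction from the worst (enemy), plus inertia. The enemy term is
#' the additive form `Q- + Q` by default, switchable to the conventional
#' `Q- - Q` via `swarm_params(enemy_conventional = TRUE)`. Binary
#' conversion and elitism as in [abc_pso_select()].
#'
#' @inheritParams abc_pso_select
#' @return A `binary_mask` object.
#' @export
dragonfly_select <- function(x, y, params = swarm_params(), k_select = 100) {
  ctx <- selector_context(x, y, params, k_select)
  with_seed(params$seed, {
    pop <- params$pop_size
    T_ <- ctx$T_
    Q <- init_positions(pop, T_)
    dQ <- matrix(0, pop, T_)
    fitQ <- apply(Q, 1, ctx$fit)
    g <- which.max(fitQ)
    gbest <- Q[g, ]
    gbest_fit <- fitQ[g]
    trace <- gbest_fit
    iter <- 0
    while (iter < params$max_iter) {
      iter <- iter + 1
      qsum <- colSums(Q)
      vsum <- colSums(dQ)
      food <- Q[which.max(fitQ), ]
      enemy <- Q[which.min(fitQ), ]
      S <- -(pop * Q - matrix(qsum, pop, T_, byrow = TRUE))
      A <- (matrix(vsum, pop, T_, byrow = TRUE) - dQ) / (pop - 1)
      C <- (matrix(qsum, pop, T_, byrow = TRUE) - Q) / (pop - 1) - Q
      F_ <- matrix(food, pop, T_, byrow = TRUE) - Q
      E <- if (params$enemy_conventional) {
        matrix(enemy, pop, T_, byrow = TRUE) - Q
      } else {
        matrix(enemy, pop, T_, byrow = TRUE) + Q
      }
      dQ <- params$s * S + params$a * A + params$c * C +
        params$f * F_ + params$e * E + params$omega * dQ
      dQ <- pmin(pmax(dQ, -4), 4)
      Q <- pmin(pmax(Q + dQ, -6), 6)
      fitQ <- apply(Q, 1, ctx$fit)
      g <- which.max(fitQ)
      if (fitQ[g] > gbest_fit) {
        gbest <- Q[g, ]
        gbest_fit <- fitQ[g]
      }
      trace <- c(trace, gbest_fit)
    }
    finish_mask(gbest, gbest_fit, trace, ctx, "DRAGONFLY", params)
  })
}

#' Pool per-subject segment matrices into one labeled matrix
#'
#' @param seg_list List of segment matrices from [segment_record()].
#' @return List with `x` (pooled matrix), `y` (labels per row) and
#'   `subject` (subject id per row).
#' @export
pool_segments <- function(seg_list) {
  stopifnot(length(seg_list) >= 1)
  x <- do.call(rbind, lapply(seg_list, `[[`, "segments"))
  y <- unlist(lapply(seg_list, function(s) rep(s$label, nrow(s$segments))))
  subject <- unlist(lapply(seg_list,
                           function(s) rep(s$subject_id, nrow(s$segments))))
  list(x = x, y = y, subject = subject)
}

# Apply a binary mask to one subject's segments.
mask_reduce <- function(seg, mask_obj) {
  feature_matrix(seg$subject_id,
                 seg$segments[, mask_obj$mask, drop = FALSE],
                 seg$label, mask_obj$method,
                 list(fitness = mask_obj$fitness,
                      selected = which(mask_obj$mask)))
}

#' Apply one of the five reduction methods to a cohort of segment matrices
#'
#' `"HT"` and `"NLR"` operate per segment; `"ABC_PSO"`, `"CUCKOO"` and
#' `"DRAGONFLY"` first fit a shared 100-column mask on the pooled labeled
#' segments and then apply it to every subject.
#'
#' @param seg_list List of segment matrices.
#' @param method One of `"HT"`, `"NLR"`, `"ABC_PSO"`, `"CUCKOO"`,
#'   `"DRAGONFLY"`.
#' @param params A [swarm_params()] for the mask-based methods.
#' @param n_kernels Kernel count for `"NLR"`.
#' @return List of feature matrix objects, one per subject.
#' @export
reduce_features <- function(seg_list, method,
                            params = swarm_params(), n_kernels = 4) {
  method <- match.arg(method,
                      c("HT", "NLR", "ABC_PSO", "CUCKOO", "DRAGONFLY"))
  if (method == "HT") return(lapply(seg_list, ht_reduce))
  if (method == "NLR") {
    return(lapply(seg_list, nlr_reduce, n_kernels = n_kernels))
  }
  pooled <- pool_segments(seg_list)
  sel <- switch(method,
                ABC_PSO = abc_pso_select(pooled$x, pooled$y, params),
                CUCKOO = cuckoo_select(pooled$x, pooled$y, params),
                DRAGONFLY = dragonfly_select(pooled$x, pooled$y, params))
  lapply(seg_list, mask_reduce, mask_obj = sel)
}
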