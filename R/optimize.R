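MOVING_LABELS <- c("ur", "ll", "lr")

#' Genetic-algorithm configuration
#'
#' Each generation holds `population_size` candidate solutions; search
#' stops after `stall_generations` consecutive generations whose best cost
#' improved by less than `stall_tolerance` (relative), or at
#' `max_generations`.
#'
#' @param population_size solutions per generation (>= 2).
#' @param stall_generations stall window (>= 1).
#' @param stall_tolerance relative improvement counted as significant.
#' @param max_generations hard cap on generations.
#' @param seed RNG seed (full run is reproducible).
#' @param mutation_prob per-gene Gaussian mutation probability.
#' @param tournament_k tournament selection size.
#' @export
ga_config <- function(population_size = 20, stall_generations = 25,
                      stall_tolerance = 1e-4, max_generations = 500,
                      seed = 1, mutation_prob = 0.3, tournament_k = 3) {
  if (population_size < 2) stop("ga_config: population_size must be >= 2")
  if (stall_generations < 1) stop("ga_config: stall_generations must be >= 1")
  structure(list(population_size = as.integer(population_size),
                 stall_generations = as.integer(stall_generations),
                 stall_tolerance = stall_tolerance,
                 max_generations = as.integer(max_generations),
                 seed = as.integer(seed),
                 mutation_prob = mutation_prob,
                 tournament_k = as.integer(tournament_k)),
            class = "ga_config")
}

#' Minimize a function over a box with an elitist genetic algorithm
#'
#' Tournament selection, uniform blend crossover, multi-scale Gaussian
#' mutation (per-gene standard deviation drawn log-uniformly between 0.3%
#' and 30% of the bound's half-width), offspring clipped to the box; the
#' best individual always survives.
#'
#' @param cost_fn function of a numeric vector returning a finite scalar.
#' @param lower,upper bound vectors (finite, same length).
#' @param cfg a `ga_config`.
#' @param init optional initial solution (clipped into the box; seeded as
#'   the first individual).
#' @param group_move optional coordinated-move operator: a function that
#'   perturbs a solution vector along problem-specific coupled directions
#'   (applied to a quarter of the offspring).  Lets the search escape
#'   valleys where no single-gene change improves the cost.
#' @return list: `par`, `value`, `trace` (best cost per generation),
#'   `generations`.
#' @export
ga_minimize <- function(cost_fn, lower, upper, cfg = ga_config(),
                        init = NULL, group_move = NULL) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper) || any(!is.finite(c(lower, upper))) ||
      any(upper < lower))
    stop("ga_minimize: invalid bounds")
  D <- length(lower)
  half <- (upper - lower) / 2
  set.seed(cfg$seed)
  N <- cfg$population_size
  pop <- matrix(stats::runif(N * D, lower, upper), N, D, byrow = TRUE)
  if (!is.null(init)) {
    init <- pmin(pmax(as.numeric(init), lower), upper)
    # seed the first individual with the initialization and scatter half
    # the population around it so local descent starts immediately
    pop[1, ] <- init
    for (i in 2:max(2, floor(N / 2)))
      pop[i, ] <- pmin(pmax(init + stats::rnorm(D, 0, 0.05 * half),
                            lower), upper)
  }
  cost <- apply(pop, 1, cost_fn)
  if (any(!is.finite(cost)))
    stop("ga_minimize: non-finite cost at solution ",
         paste(signif(pop[which(!is.finite(cost))[1], ], 4), collapse = ", "))

  trace <- numeric(0)
  best_at_improve <- min(cost)
  stall <- 0L
  gen <- 0L
  while (gen < cfg$max_generations) {
    gen <- gen + 1L
    elite <- which.min(cost)
    newpop <- matrix(0, N, D)
    newpop[1, ] <- pop[elite, ]
    for (i in 2:N) {
      pick <- function() {
        cand <- sample.int(N, cfg$tournament_k, replace = TRUE)
        cand[which.min(cost[cand])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      u <- stats::runif(D)
      child <- u * p1 + (1 - u) * p2
      mut <- stats::runif(D) < cfg$mutation_prob
      if (any(mut)) {
        # multi-scale Gaussian mutation: sigma log-uniform between 0.3%
        # and 30% of the half-width, so basin hops and sub-pixel polish
        # coexist in one population
        sd_f <- 10^stats::runif(sum(mut), -2.5, -0.5)
        child[mut] <- child[mut] +
          stats::rnorm(sum(mut), 0, sd_f * pmax(half[mut], 1e-12))
      }
      if (!is.null(group_move) && stats::runif(1) < 0.25)
        child <- group_move(child)
      if (i > N - 2)  # random immigrants keep global exploration alive
        child <- stats::runif(D, lower, upper)
      newpop[i, ] <- pmin(pmax(child, lower), upper)
    }
    pop <- newpop
    cost <- apply(pop, 1, cost_fn)
    if (any(!is.finite(cost)))
      stop("ga_minimize: non-finite cost at solution ",
           paste(signif(pop[which(!is.finite(cost))[1], ], 4),
                 collapse = ", "))
    best <- min(cost)
    trace <- c(trace, best)
    rel <- (best_at_improve - best) / max(abs(best_at_improve), 1e-12)
    if (is.finite(rel) && rel > cfg$stall_tolerance) {
      best_at_improve <- best
      stall <- 0L
    } else stall <- stall + 1L
    if (stall >= cfg$stall_generations) break
  }
  i <- which.min(cost)
  list(par = pop[i, ], value = cost[i], trace = trace, generations = gen)
}

## nine-element solution vector <-> transform set about fixed centers
vec_to_transforms <- function(v, centers) {
  tr <- list(ul = rigid_transform(0, 0, 0, center = centers$ul))
  for (i in seq_along(MOVING_LABELS)) {
    lb <- MOVING_LABELS[i]
    k <- (i - 1) * 3
    tr[[lb]] <- rigid_transform(v[k + 1], v[k + 2], v[k + 3],
                                center = centers[[lb]])
  }
  transform_set(tr, fixed = "ul")
}

transforms_to_vec <- function(ts, centers) {
  unlist(lapply(MOVING_LABELS, function(lb) {
    t <- ts$transforms[[lb]]
    a <- transform_affine(t)
    t2 <- affine_to_rigid(a$R, a$v, centers[[lb]])
    c(t2$tx, t2$ty, t2$theta)
  }), use.names = FALSE)
}

## precompute everything the cost needs at one pyramid level: geometry
## (edge chains, endpoints) stays at base resolution; patch appearance is
## sampled from the level images
build_level_context <- function(base_quads, level_imgs, cfg, factor) {
  p_level <- patch_at_level(cfg$p, factor)
  phi <- phi_for(p_level)
  tau <- tau_for(cfg, factor)
  per_q <- lapply(QUADRANT_LABELS, function(lb) {
    q <- base_quads[[lb]]
    li <- level_imgs[[lb]]
    out <- list()
    for (key in c("h", "v")) {
      e <- q$edges$edges[[key]]
      pm <- edge_patch_matrix(li$image$pixels, li$mask$bits, e$pixels,
                              factor, p_level, cfg$b)
      out[[key]] <- list(xy = pm$xy, V = pm$V, n_empty = pm$n_empty,
                         C_in = e$C_in, C_out = e$C_out)
    }
    out
  })
  names(per_q) <- QUADRANT_LABELS
  list(edges = per_q, phi = phi, tau = tau, factor = factor)
}

eval_cost_ctx <- function(ctx, ts, cfg) {
  d <- m <- numeric(4)
  for (i in seq_along(ADJACENT_PAIRS)) {
    ab <- ADJACENT_PAIRS[[i]]
    key <- facing_edge(ab[1], ab[2])
    ea <- ctx$edges[[ab[1]]][[key]]; eb <- ctx$edges[[ab[2]]][[key]]
    ta <- ts$transforms[[ab[1]]]; tb <- ts$transforms[[ab[2]]]
    pa <- transform_points(ta, ea$xy); pb <- transform_points(tb, eb$xy)
    u <- as.numeric(rotation_matrix(ta$theta) %*% (ea$C_in - ea$C_out))
    nrm <- c(-u[2], u[1]) / sqrt(sum(u^2))
    r <- pair_dissim_core(pa, pb, ea$V, eb$V, ctx$tau, ctx$phi,
                          ea$n_empty + eb$n_empty, nrm, cfg$min_cos)
    d[i] <- r$d_pair
    ca <- transform_points(ta, rbind(ea$C_in, ea$C_out))
    cb <- transform_points(tb, rbind(eb$C_in, eb$C_out))
    m[i] <- cfg$w3 * sqrt(sum((ca[1, ] - cb[1, ])^2)) +
      cfg$w4 * sqrt(sum((ca[2, ] - cb[2, ])^2))
  }
  cfg$w1 * mean(d) + cfg$w2 * mean(m)
}

#' Hierarchical coarse-to-fine stitching
#'
#' The coarsest level is seeded by [initial_align()] and searched inside a
#' wide window (translation 25% of the coarse image size, rotation
#' 20 degrees); each finer level re-centers its search window on the
#' previous level's solution (translation `2 * previous factor` base px,
#' rotation 3 degrees).  All transforms are kept in base-resolution units
#' about each quadrant's base tissue centroid.
#'
#' @param qs a `quadrant_set` (segmented; edge geometry is recomputed per
#'   level).
#' @param cost_cfg a `cost_config`.
#' @param ga_cfg a `ga_config` (per-level seeds derived from `seed`).
#' @param factors pyramid downsample factors, coarsest first, last = 1.
#' @param init optional `transform_set` overriding the automatic
#'   initialization.
#' @return class `stitch_result`: `transforms`, `final_cost`, `cost_trace`
#'   (per level), `initial_transforms`, `levels_used`.
#' @export
hierarchical_stitch <- function(qs, cost_cfg = cost_config(),
                                ga_cfg = ga_config(),
                                factors = c(8, 4, 2, 1), init = NULL) {
  stopifnot(inherits(qs, "quadrant_set"))
  factors <- as.integer(factors)
  pyr <- lapply(QUADRANT_LABELS, function(lb) build_pyramid(qs[[lb]], factors))
  names(pyr) <- QUADRANT_LABELS
  centers <- lapply(QUADRANT_LABELS, function(lb)
    mask_centroid(qs[[lb]]$mask$bits))
  names(centers) <- QUADRANT_LABELS

  ts0 <- if (is.null(init)) initial_align(qs)
         else init
  vec <- transforms_to_vec(ts0, centers)

  qs <- ensure_edges(qs)
  traces <- vector("list", length(factors))
  value <- NA_real_
  for (li in seq_along(factors)) {
    f <- factors[li]
    lvl <- lapply(QUADRANT_LABELS, function(lb) pyr[[lb]][[li]])
    names(lvl) <- QUADRANT_LABELS
    ctx <- build_level_context(qs, lvl, cost_cfg, f)
    cost_fn <- function(v) eval_cost_ctx(ctx, vec_to_transforms(v, centers),
                                         cost_cfg)
    if (li == 1) {
      tw <- 0.25 * max(vapply(QUADRANT_LABELS, function(lb)
        max(dim(lvl[[lb]]$image$pixels)), numeric(1))) * f
      rw <- 20
    } else {
      tw <- 2 * factors[li - 1]
      rw <- 3
    }
    width <- rep(c(tw, tw, rw), times = 3)
    # coordinated move: a small global rigid motion of the three moving
    # quadrants about the section center -- the configuration's softest
    # cost directions are coherent, and escaping a coherently displaced
    # local minimum needs all three poses to change together
    pivot <- (centers$ul + centers$ur + centers$ll + centers$lr) / 4
    group_move <- function(v) {
      s <- 10^stats::runif(1, -1.5, 0)
      G <- rigid_transform(stats::rnorm(1, 0, 0.3 * s * tw),
                           stats::rnorm(1, 0, 0.3 * s * tw),
                           stats::rnorm(1, 0, 0.3 * s * rw),
                           center = pivot)
      for (i in seq_along(MOVING_LABELS)) {
        k <- (i - 1) * 3
        t1 <- rigid_transform(v[k + 1], v[k + 2], v[k + 3],
                              center = centers[[MOVING_LABELS[i]]])
        t2 <- compose_transforms(G, t1, center = t1$center)
        v[k + (1:3)] <- c(t2$tx, t2$ty, t2$theta)
      }
      v
    }
    cfg_l <- ga_cfg
    cfg_l$seed <- ga_cfg$seed + 7L * li
    r <- ga_minimize(cost_fn, vec - width, vec + width, cfg_l, init = vec,
                     group_move = group_move)
    vec <- r$par
    value <- r$value
    traces[[li]] <- r$trace
  }
  structure(list(transforms = vec_to_transforms(vec, centers),
                 final_cost = value, cost_trace = traces,
                 initial_transforms = ts0, levels_used = factors),
            class = "stitch_result")
}

#' @export
print.stitch_result <- function(x, ...) {
  cat(sprintf("<stitch_result> final cost %.5f over %d levels (%s)\n",
              x$final_cost, length(x$levels_used),
              paste(x$levels_used, collapse = ", ")))
  print(x$transforms)
  invisible(x)
}
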