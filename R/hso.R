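# Hybrid swarm optimizer (HSO): a minimizer blending a
# corvid (crow-search-style) memory-following move with a gregarious
# (sparrow-style) best-anchored move carrying a decayed random velocity.
# Every agent keeps the best position it has visited; the global best is
# the best of those memories, so the best-fitness trace is non-increasing
# by construction.

#' HSO configuration
#'
#' @param m Population size (>= 2).
#' @param max_iterations Iteration budget `I_max` (>= 1).
#' @param flight_length Corvid step scale `a` (> 0); constant over the
#'   run.
#' @param awareness_prob `Paw` in \[0, 1\]: probability that a corvid move
#'   follows the mate's memory; with probability `1 - Paw` the agent
#'   relocates uniformly in the box (anti-stagnation escape). The default
#'   0.9 reproduces the classic ~10% relocation rate.
#' @param theta_range Range of the gregarious contraction factor `theta`,
#'   drawn uniformly per move.
#' @param chi_range Range of the worst-repulsion factor `chi`.
#' @param v1 Velocity injection scale.
#' @param omega Velocity inertia (exponential decay) in \[0, 1\].
#' @param hybrid_prob Probability that an agent takes the corvid move in
#'   a given iteration (else the gregarious move).
#' @param seed Integer RNG seed.
#' @return An `hso_config`.
#' @export
hso_config <- function(m = 20L, max_iterations = 200L, flight_length = 2,
                       awareness_prob = 0.9, theta_range = c(0, 1),
                       chi_range = c(-1, 1), v1 = 0.1, omega = 0.7,
                       hybrid_prob = 0.5, seed = 1L) {
  assert_scalar_number(m, "m", 2)
  assert_scalar_number(max_iterations, "max_iterations", 1)
  assert_scalar_number(flight_length, "flight_length", 0, strict = TRUE)
  assert_scalar_number(awareness_prob, "awareness_prob", 0)
  if (awareness_prob > 1) stop("`awareness_prob` must be <= 1", call. = FALSE)
  stopifnot(length(theta_range) == 2L, length(chi_range) == 2L)
  assert_scalar_number(hybrid_prob, "hybrid_prob", 0)
  structure(
    list(m = as.integer(m), max_iterations = as.integer(max_iterations),
         flight_length = flight_length, awareness_prob = awareness_prob,
         theta_range = as.numeric(theta_range),
         chi_range = as.numeric(chi_range),
         v1 = v1, omega = omega, hybrid_prob = hybrid_prob,
         seed = as.integer(seed)),
    class = "hso_config"
  )
}

new_agent <- function(position, fitness) {
  list(position = position, fitness = fitness,
       memory = position, memory_fitness = fitness)
}

swarm_best_worst <- function(agents) {
  mem_fit <- vapply(agents, `[[`, numeric(1), "memory_fitness")
  cur_fit <- vapply(agents, `[[`, numeric(1), "fitness")
  b <- which.min(mem_fit)
  list(best_position = agents[[b]]$memory, best_fitness = mem_fit[b],
       worst_fitness = max(cur_fit),
       worst_position = agents[[which.max(cur_fit)]]$position)
}

#' Initialize an HSO swarm
#'
#' Agents start uniformly distributed in the box; each agent's memory is
#' its initial position.
#'
#' @param objective Function mapping a position vector to a scalar
#'   fitness (minimized).
#' @param d Problem dimension (>= 1).
#' @param config An [hso_config()].
#' @param bounds Length-2 numeric `c(lower, upper)` box, identical in
#'   every dimension. Default `c(0, 1)`.
#' @param init_positions Optional matrix (rows = positions) seeding the
#'   first agents, e.g. known candidate solutions.
#' @return A `swarm`: list with `agents`, `best_position`,
#'   `best_fitness`, `worst_fitness`, `velocity`, `iteration`.
#' @export
init_population <- function(objective, d, config, bounds = c(0, 1),
                            init_positions = NULL) {
  stopifnot(inherits(config, "hso_config"))
  assert_scalar_number(d, "d", 1)
  d <- as.integer(d)
  if (config$m < 2L) stop("population must have m >= 2 agents", call. = FALSE)
  pos <- matrix(stats::runif(config$m * d, bounds[1], bounds[2]),
                config$m, d)
  if (!is.null(init_positions)) {
    init_positions <- matrix(init_positions, ncol = d)
    n_seed <- min(nrow(init_positions), config$m)
    pos[seq_len(n_seed), ] <- clamp(init_positions[seq_len(n_seed), ,
                                                   drop = FALSE],
                                    bounds[1], bounds[2])
  }
  agents <- lapply(seq_len(config$m), function(i) {
    p <- pos[i, ]
    new_agent(p, objective(p))
  })
  bw <- swarm_best_worst(agents)
  structure(
    list(agents = agents, best_position = bw$best_position,
         best_fitness = bw$best_fitness, worst_fitness = bw$worst_fitness,
         worst_position = bw$worst_position,
         velocity = numeric(d), iteration = 0L, bounds = bounds),
    class = "swarm"
  )
}

#' Corvid (crow-search-style) candidate move
#'
#' With probability `Paw` the agent flies toward a flock mate's memory:
#' `J' = J + lambda1 * a * (Z - J)` with `lambda1 ~ U(0, 1)`; otherwise
#' it relocates uniformly in the box. The candidate is clipped to the
#' bounds.
#'
#' @param agent An agent (list with `position`).
#' @param mate_memory Memory position `Z` of a randomly chosen mate.
#' @param config An [hso_config()].
#' @param bounds Box bounds `c(lower, upper)`.
#' @param lambda1 Optional override of the uniform draw (for analysis).
#' @return Candidate position vector.
#' @export
corvid_update <- function(agent, mate_memory, config, bounds = c(0, 1),
                          lambda1 = NULL) {
  d <- length(agent$position)
  if (stats::runif(1) <= config$awareness_prob) {
    l1 <- lambda1 %||% stats::runif(1)
    cand <- agent$position +
      l1 * config$flight_length * (mate_memory - agent$position)
  } else {
    cand <- stats::runif(d, bounds[1], bounds[2])
  }
  clamp(cand, bounds[1], bounds[2])
}

#' Gregarious (sparrow-style) candidate move
#'
#' An agent worse than the global best contracts toward a
#' velocity-augmented best, `J' = Jb' + theta * (J - Jb')` with
#' `Jb' = Jbest * (1 + v1 * omega) + V`; an agent already at the global
#' best is instead pushed away from the worst position,
#' `J' = J + chi * |J - Jworst| / (je - jws + eps)`, with an epsilon
#' guard so a degenerate all-equal-fitness swarm stays finite. Clipped to
#' the bounds.
#'
#' @param agent An agent (list with `position`, `fitness`).
#' @param swarm The current `swarm`.
#' @param config An [hso_config()].
#' @param bounds Box bounds.
#' @param theta,chi Optional overrides of the random draws.
#' @return Candidate position vector.
#' @export
gregarious_update <- function(agent, swarm, config, bounds = c(0, 1),
                              theta = NULL, chi = NULL) {
  eps <- 1e-12
  if (agent$fitness > swarm$best_fitness) {
    th <- theta %||% stats::runif(1, config$theta_range[1], config$theta_range[2])
    jb <- swarm$best_position * (1 + config$v1 * config$omega) + swarm$velocity
    cand <- jb + th * (agent$position - jb)
  } else {
    ch <- chi %||% stats::runif(1, config$chi_range[1], config$chi_range[2])
    denom <- agent$fitness - swarm$worst_fitness + eps
    cand <- agent$position +
      ch * abs(agent$position - swarm$worst_position) / denom
  }
  clamp(cand, bounds[1], bounds[2])
}

#' Greedy position/memory update
#'
#' The agent moves to the candidate and its memory is replaced only on
#' strict fitness improvement (ties keep the old memory).
#'
#' @param agent An agent.
#' @param candidate Candidate position (already within bounds).
#' @param objective Fitness function.
#' @return The updated agent.
#' @export
greedy_memory_update <- function(agent, candidate, objective) {
  fit <- objective(candidate)
  if (!is.finite(fit)) {
    # infeasible candidate: keep the previous position
    return(agent)
  }
  agent$position <- candidate
  agent$fitness <- fit
  if (fit < agent$memory_fitness) {
    agent$memory <- candidate
    agent$memory_fitness <- fit
  }
  agent
}

#' Run the HSO minimizer
#'
#' Each iteration every agent takes the corvid move with probability
#' `hybrid_prob` and the gregarious move otherwise; candidates pass
#' through the greedy memory rule. The swarm velocity evolves as
#' `V <- omega * V + v1 * U(-1, 1)^d` from `V = 0`.
#'
#' @param objective Function from a length-`d` numeric vector to a finite
#'   scalar (minimized).
#' @param d Dimension.
#' @param config An [hso_config()].
#' @param bounds Box bounds, default the unit box.
#' @param init_positions Optional seed positions (see
#'   [init_population()]).
#' @return List with `par` (best position), `value` (best fitness),
#'   `trace` (per-iteration best fitness, non-increasing) and `swarm`.
#' @export
hso_optimize <- function(objective, d, config = hso_config(),
                         bounds = c(0, 1), init_positions = NULL) {
  stopifnot(inherits(config, "hso_config"))
  with_local_seed(config$seed, {
    swarm <- init_population(objective, d, config, bounds, init_positions)
    trace <- numeric(config$max_iterations)
    for (it in seq_len(config$max_iterations)) {
      swarm$velocity <- config$omega * swarm$velocity +
        config$v1 * stats::runif(d, -1, 1)
      for (i in seq_along(swarm$agents)) {
        ag <- swarm$agents[[i]]
        cand <- if (stats::runif(1) < config$hybrid_prob) {
          mate <- sample.int(config$m, 1L)
          corvid_update(ag, swarm$agents[[mate]]$memory, config, bounds)
        } else {
          gregarious_update(ag, swarm, config, bounds)
        }
        swarm$agents[[i]] <- greedy_memory_update(ag, cand, objective)
      }
      bw <- swarm_best_worst(swarm$agents)
      swarm$best_position <- bw$best_position
      swarm$best_fitness <- bw$best_fitness
      swarm$worst_fitness <- bw$worst_fitness
      swarm$worst_position <- bw$worst_position
      swarm$iteration <- it
      trace[it] <- bw$best_fitness
    }
    list(par = swarm$best_position, value = swarm$best_fitness,
         trace = trace, swarm = swarm)
  })
}

#' Tune ensemble fusion weights (and optional feature mask) with HSO
#'
#' Minimizes `1 - validation accuracy` of the fused ensemble over weight
#' vectors in the unit box. The swarm is seeded with the one-hot weight
#' vectors, so the tuned fusion can never fall below the best single
#' member on the validation set. Dimensions beyond the member weights,
#' when requested via `n_mask`, are decoded as a feature mask by
#' thresholding at 0.5.
#'
#' @param member_probs List of validation probability matrices, one per
#'   ensemble member (rows = samples, columns = classes in a shared
#'   order).
#' @param labels Validation labels; values must match the probability
#'   matrices' column names.
#' @param config An [hso_config()].
#' @param n_mask Number of trailing mask dimensions (default 0).
#' @return A [fusion_params()] with the tuned weights (and mask), plus
#'   attribute `"accuracy"` holding the fused validation accuracy.
#' @export
tune_fusion <- function(member_probs, labels, config = hso_config(),
                        n_mask = 0L) {
  if (length(member_probs) < 1L) stop("need >= 1 ensemble member", call. = FALSE)
  if (length(labels) < 1L) stop("empty validation set", call. = FALSE)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    stop("validation set must contain both classes", call. = FALSE)
  }
  classes <- colnames(member_probs[[1]])
  if (is.null(classes)) stop("member probabilities must have class colnames",
                             call. = FALSE)
  M <- length(member_probs)
  acc_of <- function(w) {
    if (all(w == 0)) w[1] <- 1e-9
    fused <- ensemble_fuse(member_probs, fusion_params(clamp(w, 0, 1)))
    pred <- classes[max.col(fused, ties.method = "first")]
    mean(pred == labels)
  }
  objective <- function(x) 1 - acc_of(x[seq_len(M)])
  d <- M + as.integer(n_mask)
  one_hot <- diag(1, M)
  if (n_mask > 0L) one_hot <- cbind(one_hot, matrix(1, M, n_mask))
  res <- hso_optimize(objective, d, config, bounds = c(0, 1),
                      init_positions = one_hot)
  w <- res$par[seq_len(M)]
  if (all(w == 0)) w[which.max(res$par)] <- 1
  mask <- if (n_mask > 0L) {
    mk <- res$par[M + seq_len(n_mask)] >= 0.5
    if (!any(mk)) mk[which.max(res$par[M + seq_len(n_mask)])] <- TRUE
    mk
  } else NULL
  out <- fusion_params(w, mask)
  attr(out, "accuracy") <- 1 - res$value
  out
}
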