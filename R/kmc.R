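#' Kinetic Monte Carlo estimate of the splitting probability
#'
#' Simulates Gillespie trajectories of the chain from TOEHOLD_BOUND until
#' absorption at DISPLACED or DETACHED and returns the fraction displaced
#' with its binomial standard error. Only the embedded jump chain is
#' sampled: the splitting probability depends on jump probabilities alone,
#' so holding times are not drawn. Results are reproducible for a given
#' seed.
#'
#' @param chain a [build_chain()] result
#' @param n_traj number of trajectories (>= 1)
#' @param seed integer RNG seed
#' @return one-row tibble with columns `estimate`, `se`, `n_traj`,
#'   `n_displaced`
#' @export
kmc_splitting <- function(chain, n_traj = 1e4, seed = 1) {
  stopifnot(inherits(chain, "markov_chain"), n_traj >= 1)
  start <- match("TOEHOLD_BOUND", chain$states$state)
  disp <- match("DISPLACED", chain$states$state)
  final <- withr::with_seed(seed, {
    .propagate_jump(chain, rep.int(start, n_traj),
                    stop_states = which(rowSums(chain$rates) == 0))
  })
  n_disp <- sum(final == disp)
  p_hat <- n_disp / n_traj
  tibble::tibble(
    estimate = p_hat,
    se = sqrt(p_hat * (1 - p_hat) / n_traj),
    n_traj = as.integer(n_traj),
    n_displaced = as.integer(n_disp)
  )
}

# Vectorised embedded-jump propagation. Walkers start at `start` (state
# indices) and run until their state index is in `stop_states` (or, when
# `stop_coord` is given, until coord >= stop_coord). Returns final states.
.propagate_jump <- function(chain, start, stop_states, stop_coord = NULL,
                            max_sweeps = 1e6) {
  rates <- chain$rates
  total <- rowSums(rates)
  s <- nrow(rates)
  probs <- rates
  live <- total > 0
  probs[live, ] <- rates[live, , drop = FALSE] / total[live]
  coord <- chain$states$coord

  cur <- start
  done_mask <- function(st) {
    hit <- st %in% stop_states
    if (!is.null(stop_coord)) hit <- hit | coord[st] >= stop_coord
    hit
  }
  active <- which(!done_mask(cur))
  sweeps <- 0L
  while (length(active) > 0) {
    sweeps <- sweeps + 1L
    if (sweeps > max_sweeps) {
      stop("jump-chain propagation exceeded max_sweeps; chain may be trapped",
           call. = FALSE)
    }
    st_active <- cur[active]
    for (s_i in sort(unique(st_active))) {
      sel <- active[st_active == s_i]
      cur[sel] <- sample.int(s, length(sel), replace = TRUE,
                             prob = probs[s_i, ])
    }
    active <- active[!done_mask(cur[active])]
  }
  cur
}

#' Gillespie trajectory with physical time
#'
#' Full stochastic simulation of a single trajectory of the chain,
#' including exponential holding times, used for stationary-occupancy
#' checks on small closed chains.
#'
#' @param chain a [build_chain()] result
#' @param t_max total simulated time, seconds
#' @param seed integer RNG seed
#' @param start starting state name
#' @return tibble with columns `state`, `time_s` (sojourn time per visit)
#' @export
kmc_trajectory <- function(chain, t_max, seed = 1, start = "TOEHOLD_BOUND") {
  stopifnot(inherits(chain, "markov_chain"), t_max > 0)
  rates <- chain$rates
  total <- rowSums(rates)
  cur <- match(start, chain$states$state)
  withr::with_seed(seed, {
    visits <- integer(0)
    sojourn <- numeric(0)
    t <- 0
    while (t < t_max) {
      if (total[cur] == 0) { # absorbed: spend the remaining time here
        visits <- c(visits, cur)
        sojourn <- c(sojourn, t_max - t)
        break
      }
      dt <- stats::rexp(1, total[cur])
      dt <- min(dt, t_max - t)
      visits <- c(visits, cur)
      sojourn <- c(sojourn, dt)
      t <- t + dt
      cur <- sample.int(nrow(rates), 1, prob = rates[cur, ])
    }
    tibble::tibble(state = chain$states$state[visits], time_s = sojourn)
  })
}
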