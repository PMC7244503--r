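#' Landscape-model rate parameters
#'
#' Collects the kinetic parameters of the discrete-state landscape model.
#' `k_bm` is the bare branch-migration attempt frequency; each hop is slowed
#' by the sawtooth barrier `dg_sawtooth`, giving an effective hopping rate
#' `k_bm * exp(-dg_sawtooth)`. `dg_plateau` is the penalty for maintaining
#' the three-stranded junction. `k_toehold` is the bimolecular toehold
#' binding rate constant; all headline outputs are ratios, from which it
#' cancels. Defaults are calibrated so that the mismatch-free 4-nt-toehold
#' reference system reproduces a second-order rate constant of order
#' 1e3 M-1 s-1, in the weak-toehold regime where displacement succeeds only
#' rarely per toehold-binding event.
#'
#' @param k_bm branch-migration attempt frequency, s^-1
#' @param k_toehold bimolecular toehold binding rate constant, M^-1 s^-1
#' @param dg_sawtooth per-step branch-migration barrier, kB*T
#' @param dg_plateau three-strand junction penalty, kB*T
#' @param f_max maximum frayed O.T base pairs in the free-energy profile
#' @param toehold_dg toehold attachment free energy in kB*T, or `NULL` to
#'   derive it from the toehold sequence with [toehold_attachment_dg()]
#' @param nn nearest-neighbour parameter set from [nn_params()]
#' @return a list of class `landscape_params`
#' @export
landscape_params <- function(k_bm = 1e7, k_toehold = 3e6, dg_sawtooth = 7.3,
                             dg_plateau = 2.96, f_max = 1, toehold_dg = NULL,
                             nn = nn_params()) {
  stopifnot(k_bm > 0, k_toehold > 0, f_max >= 0)
  structure(
    list(k_bm = k_bm, k_toehold = k_toehold, dg_sawtooth = dg_sawtooth,
         dg_plateau = dg_plateau, f_max = f_max, toehold_dg = toehold_dg,
         nn = nn),
    class = "landscape_params"
  )
}

#' Build the absorbing Markov chain of a displacement reaction
#'
#' States are DETACHED (absorbing failure), TOEHOLD_BOUND, one BRANCH(n)
#' state per branch-migration macrostate `n = h+1 .. n_max` of the
#' free-energy profile, and DISPLACED (absorbing success, entered
#' irreversibly from BRANCH(n_max)). Transition rates between connected
#' transient states satisfy detailed balance on the profile free energies:
#' `rate(i->j) = k_hop * exp(-(G(j) - G(i)) / 2)` with
#' `k_hop = k_bm * exp(-dg_sawtooth)`. Toehold detachment is set from the
#' toehold attachment free energy and `k_toehold` through detailed balance
#' at the 1 M standard-state concentration.
#'
#' @param profile a [displacement_profile()]
#' @param k_bm branch-migration attempt frequency, s^-1
#' @param k_toehold bimolecular toehold binding rate constant, M^-1 s^-1
#' @param toehold_dg toehold attachment free energy (kB*T); default taken
#'   from the profile's system and parameter set
#' @return object of class `markov_chain`: list with a `states` tibble
#'   (`state`, `type`, `coord`, `G_kBT`), a dense `rates` matrix in s^-1,
#'   and bookkeeping attributes
#' @export
build_chain <- function(profile, k_bm = 1e7, k_toehold = 3e6,
                        toehold_dg = NULL) {
  stopifnot(inherits(profile, "free_energy_profile"))
  if (k_bm <= 0) stop("k_bm must be positive", call. = FALSE)
  if (any(!is.finite(profile$G_kBT))) {
    stop("profile free energies must be finite", call. = FALSE)
  }
  sys <- attr(profile, "system")
  h <- sys$toehold_length
  n_max <- max(profile$n)
  if (is.null(toehold_dg)) toehold_dg <- attr(profile, "toehold_dg_kbt")
  g_prof <- profile$G_kBT
  k_hop <- k_bm * exp(-attr(profile, "dg_sawtooth"))

  branch_n <- seq(h + 1, n_max)
  states <- tibble::tibble(
    state = c("DETACHED", "TOEHOLD_BOUND", paste0("BRANCH_", branch_n),
              "DISPLACED"),
    type = c("absorbing", "toehold", rep("branch", length(branch_n)),
             "absorbing"),
    coord = c(-Inf, h, branch_n, n_max + 1),
    G_kBT = c(g_prof[h] - toehold_dg, g_prof[h], g_prof[branch_n], NA_real_)
  )
  s <- nrow(states)
  rates <- matrix(0, s, s, dimnames = list(states$state, states$state))

  hop <- function(gi, gj) k_hop * exp(-(gj - gi) / 2)
  # toehold detachment: detailed balance against bimolecular binding at 1 M
  rates["TOEHOLD_BOUND", "DETACHED"] <- k_toehold * exp(toehold_dg)
  # toehold <-> first branch state, then the branch-migration ladder
  idx <- match(paste0("BRANCH_", branch_n), states$state)
  prev <- 2L # TOEHOLD_BOUND
  for (j in seq_along(branch_n)) {
    gi <- states$G_kBT[prev]
    gj <- states$G_kBT[idx[j]]
    rates[prev, idx[j]] <- hop(gi, gj)
    rates[idx[j], prev] <- hop(gj, gi)
    prev <- idx[j]
  }
  rates[idx[length(idx)], s] <- k_hop # BRANCH(n_max) -> DISPLACED, irreversible

  structure(
    list(states = states, rates = rates, k_toehold = k_toehold,
         toehold_dg = toehold_dg, h = h, n_max = n_max, k_hop = k_hop,
         system = sys),
    class = "markov_chain"
  )
}

#' Build a chain directly from a free-energy ladder
#'
#' Low-level constructor used for toy landscapes and fixtures: a linear
#' chain DETACHED <- TOEHOLD_BOUND <-> BRANCH(2) <-> ... -> DISPLACED with
#' hopping rates satisfying detailed balance on the supplied free energies.
#' With a flat ladder and `k_off = k_bm` this is the classic symmetric
#' gambler's-ruin walk.
#'
#' @param g_kbt free energies (kB*T) of the transient states, first entry
#'   being TOEHOLD_BOUND
#' @param k_bm hopping attempt frequency, s^-1
#' @param k_off detachment rate from TOEHOLD_BOUND, s^-1
#' @param dg_sawtooth uniform hopping barrier, kB*T
#' @return object of class `markov_chain`
#' @export
chain_from_energies <- function(g_kbt, k_bm = 1, k_off = 1, dg_sawtooth = 0) {
  m <- length(g_kbt)
  stopifnot(m >= 1, all(is.finite(g_kbt)), k_bm > 0, k_off >= 0)
  k_hop <- k_bm * exp(-dg_sawtooth)
  coords <- seq_len(m)
  states <- tibble::tibble(
    state = c("DETACHED", "TOEHOLD_BOUND",
              if (m > 1) paste0("BRANCH_", coords[-1]), "DISPLACED"),
    type = c("absorbing", "toehold", rep("branch", m - 1), "absorbing"),
    coord = c(-Inf, coords, m + 1),
    G_kBT = c(g_kbt[1] - log(ifelse(k_off > 0, k_bm / k_off, 1)),
              g_kbt, NA_real_)
  )
  s <- nrow(states)
  rates <- matrix(0, s, s, dimnames = list(states$state, states$state))
  rates[2, 1] <- k_off
  if (m > 1) {
    for (j in seq_len(m - 1)) {
      gi <- g_kbt[j]; gj <- g_kbt[j + 1]
      rates[j + 1, j + 2] <- k_hop * exp(-(gj - gi) / 2)
      rates[j + 2, j + 1] <- k_hop * exp(-(gi - gj) / 2)
    }
  }
  rates[s - 1, s] <- k_hop
  structure(
    list(states = states, rates = rates, k_toehold = NA_real_,
         toehold_dg = NA_real_, h = 1, n_max = m, k_hop = k_hop,
         system = NULL),
    class = "markov_chain"
  )
}

#' @export
print.markov_chain <- function(x, ...) {
  cat("<markov_chain>", nrow(x$states), "states:",
      sum(x$states$type == "branch"), "branch +",
      sum(x$states$type == "absorbing"), "absorbing\n")
  cat(sprintf("  k_hop = %.3g /s, toehold detachment = %.3g /s\n",
              x$k_hop, x$rates["TOEHOLD_BOUND", "DETACHED"]))
  invisible(x)
}

# generator-restricted linear absorption solve.
# success/fail: character vectors of state names treated as absorbing.
.splitting_solve <- function(chain, success, fail) {
  states <- chain$states$state
  rates <- chain$rates
  absorbing <- union(success, fail)
  transient <- setdiff(states, absorbing)
  if (length(transient) == 0) {
    p <- stats::setNames(as.numeric(states %in% success), states)
    return(p)
  }
  q <- rates[transient, transient, drop = FALSE]
  out_total <- rowSums(rates[transient, , drop = FALSE])
  a <- q - diag(out_total, nrow = length(transient))
  b <- -rowSums(rates[transient, success, drop = FALSE])
  sol <- tryCatch(solve(a, b), error = function(e) {
    stop("absorption system is singular (disconnected chain): ",
         conditionMessage(e), call. = FALSE)
  })
  p <- stats::setNames(numeric(length(states)), states)
  p[transient] <- sol
  p[success] <- 1
  p
}

#' Exact splitting probability of displacement
#'
#' Solves the linear absorption system of the chain for the probability
#' that a toehold-bound complex resolves into displacement (absorption at
#' DISPLACED) rather than abortive detachment (absorption at DETACHED).
#' This is the `p(disp | toehold)` factor of the second-order rate
#' `k = k_toehold * p(disp | toehold)`.
#'
#' @param chain a [build_chain()] result
#' @return probability in `[0, 1]`
#' @export
splitting_probability_exact <- function(chain) {
  stopifnot(inherits(chain, "markov_chain"))
  p <- .splitting_solve(chain, "DISPLACED", "DETACHED")
  unname(min(max(p[["TOEHOLD_BOUND"]], 0), 1))
}

#' Conditional decomposition of the displacement probability
#'
#' For each reference branch-migration position `x` in the displacement
#' domain, computes `p(bp x reached | toehold)` (probability of reaching
#' BRANCH(h+x) before detaching) and `p(disp | bp x reached)` (probability
#' of displacement from BRANCH(h+x)), both by exact absorption solves.
#' Because every displacement trajectory must pass through each branch
#' position in turn, the product of the two factors is independent of `x`
#' and equals the overall splitting probability.
#'
#' @param chain a [build_chain()] result
#' @param x_values integer branch positions (1-based within the domain)
#' @return tibble of class `tmsd_decomposition` with columns `x`, `p_reach`,
#'   `p_disp_given_reach`, `product`; the overall splitting probability is
#'   attached as attribute `p_disp`
#' @export
conditional_probabilities <- function(chain, x_values) {
  stopifnot(inherits(chain, "markov_chain"))
  x_values <- as.integer(x_values)
  x_max <- chain$n_max - chain$h
  if (any(x_values < 1 | x_values > x_max)) {
    stop(sprintf("x_values must lie in 1..%d for this chain", x_max),
         call. = FALSE)
  }
  p_disp <- splitting_probability_exact(chain)
  res <- purrr::map_dfr(x_values, function(x) {
    target <- paste0("BRANCH_", chain$h + x)
    # DISPLACED cannot be reached without passing BRANCH(h+x), but it must be
    # treated as absorbing in the reach solve to keep the system non-singular
    p_reach <- .splitting_solve(chain, target,
                                c("DETACHED", "DISPLACED"))[["TOEHOLD_BOUND"]]
    p_cond <- .splitting_solve(chain, "DISPLACED", "DETACHED")[[target]]
    tibble::tibble(x = x, p_reach = p_reach, p_disp_given_reach = p_cond,
                   product = p_reach * p_cond)
  })
  class(res) <- c("tmsd_decomposition", class(res))
  attr(res, "p_disp") <- p_disp
  res
}

#' Relative displacement rate of a mismatch system
#'
#' Ratio of second-order TMSD rate constants between a (typically
#' mismatch-carrying) system and a mismatch-free reference sharing the same
#' toehold. Because the toehold is identical, the bimolecular binding rate
#' `k_toehold` cancels and the ratio reduces to the ratio of the exact
#' splitting probabilities.
#'
#' @param system,reference [displacement_system()] objects with identical
#'   toeholds
#' @param rate_params a [landscape_params()] list
#' @return one-row tibble of class `tmsd_rate_result` with columns `k`,
#'   `k0` (both M^-1 s^-1), `ratio` and `regime`
#' @export
relative_rate <- function(system, reference,
                          rate_params = landscape_params()) {
  stopifnot(inherits(system, "displacement_system"),
            inherits(reference, "displacement_system"))
  h <- system$toehold_length
  if (h != reference$toehold_length ||
      substr(system$target, 1, h) != substr(reference$target, 1, h)) {
    stop("system and reference must share the same toehold sequence; ",
         "the decomposition k = k_toehold * p(disp|toehold) is otherwise ",
         "invalid", call. = FALSE)
  }
  p_sys <- .system_splitting(system, rate_params)
  p_ref <- .system_splitting(reference, rate_params)
  out <- tibble::tibble(
    k = rate_params$k_toehold * p_sys,
    k0 = rate_params$k_toehold * p_ref,
    ratio = p_sys / p_ref,
    regime = "second-order"
  )
  class(out) <- c("tmsd_rate_result", class(out))
  out
}

.system_chain <- function(system, rp) {
  prof <- displacement_profile(system, rp$nn, f_max = rp$f_max,
                               dg_plateau = rp$dg_plateau,
                               dg_sawtooth = rp$dg_sawtooth)
  build_chain(prof, k_bm = rp$k_bm, k_toehold = rp$k_toehold,
              toehold_dg = rp$toehold_dg)
}

.system_splitting <- function(system, rp) {
  splitting_probability_exact(.system_chain(system, rp))
}

#' Mean first-passage time to displacement
#'
#' Exact mean first-passage time from TOEHOLD_BOUND to DISPLACED with
#' detachment disabled (the first-order, high-concentration limit in which
#' a detached invader is instantly replaced, so DETACHED acts as a
#' reflecting boundary).
#'
#' @param chain a [build_chain()] result
#' @return mean first-passage time in seconds
#' @export
mean_first_passage_time <- function(chain) {
  stopifnot(inherits(chain, "markov_chain"))
  states <- chain$states$state
  rates <- chain$rates
  rates["TOEHOLD_BOUND", "DETACHED"] <- 0 # reflecting/instant-rebind limit
  transient <- setdiff(states, c("DISPLACED", "DETACHED"))
  q <- rates[transient, transient, drop = FALSE]
  out_total <- rowSums(rates[transient, , drop = FALSE])
  if (all(rates[transient, "DISPLACED"] == 0)) {
    stop("DISPLACED is unreachable from the transient states", call. = FALSE)
  }
  a <- q - diag(out_total, nrow = length(transient))
  tau <- solve(a, rep(-1, length(transient)))
  unname(tau[match("TOEHOLD_BOUND", transient)])
}

#' Export a chain as an edge list
#'
#' @param chain a [build_chain()] result
#' @return tibble with columns `state_from`, `state_to`, `rate_s_inv`
#' @export
chain_edge_list <- function(chain) {
  stopifnot(inherits(chain, "markov_chain"))
  idx <- which(chain$rates > 0, arr.ind = TRUE)
  tibble::tibble(
    state_from = rownames(chain$rates)[idx[, 1]],
    state_to = colnames(chain$rates)[idx[, 2]],
    rate_s_inv = chain$rates[idx]
  ) |> dplyr::arrange(.data$state_from, .data$state_to)
}
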