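#' Forward flux sampling configuration
#'
#' Interfaces are thresholds on the reaction coordinate (the number of
#' invader-target base pairs); they must be strictly increasing, start at
#' or beyond the first branch-migration coordinate and end at the
#' displacement-committed coordinate. `interfaces = NULL` requests the
#' default placement: every 2 coordinate units from `h + 1` to `n_max`,
#' plus the committed coordinate.
#'
#' @param interfaces increasing numeric thresholds, or `NULL` for defaults
#' @param trials_per_interface trials launched from each interface
#' @param seed integer RNG seed
#' @return list of class `ffs_config`
#' @export
ffs_config <- function(interfaces = NULL, trials_per_interface = 1000,
                       seed = 1) {
  if (!is.null(interfaces)) {
    if (any(diff(interfaces) <= 0)) {
      stop("interfaces must be strictly increasing", call. = FALSE)
    }
  }
  stopifnot(trials_per_interface >= 1)
  structure(
    list(interfaces = interfaces,
         trials_per_interface = as.integer(trials_per_interface),
         seed = as.integer(seed)),
    class = "ffs_config"
  )
}

#' Default interface placement for a chain
#'
#' @param chain a [build_chain()] result
#' @param spacing coordinate spacing between interfaces
#' @return numeric vector of interface coordinates
#' @export
default_interfaces <- function(chain, spacing = 2) {
  stopifnot(inherits(chain, "markov_chain"))
  c(seq(chain$h + 1, chain$n_max, by = spacing), chain$n_max + 1)
}

#' Run forward flux sampling on a chain
#'
#' Direct FFS over the kinetic Monte Carlo dynamics of the chain: trials
#' are launched from configurations stored at interface `i` and propagated
#' until they cross interface `i + 1` (success; configuration stored) or
#' fall back to the failure boundary DETACHED. The total displacement
#' probability is the product of per-interface crossing probabilities with
#' a propagated binomial standard error. Because the chain is memoryless,
#' storing the state label at an interface is an exact-in-distribution
#' restart.
#'
#' @param chain a [build_chain()] result
#' @param config an [ffs_config()]
#' @return object of class `ffs_result`: list with `per_interface` tibble
#'   (`interface`, `n_trials`, `n_success`, `p`), `p_total`, `se_total`,
#'   `interfaces`, `seed`
#' @export
run_ffs <- function(chain, config = ffs_config()) {
  stopifnot(inherits(chain, "markov_chain"), inherits(config, "ffs_config"))
  lambdas <- config$interfaces
  if (is.null(lambdas)) lambdas <- default_interfaces(chain)
  if (lambdas[1] < chain$h + 1) {
    stop("first interface must be at or beyond the first branch coordinate",
         call. = FALSE)
  }
  coord <- chain$states$coord
  detached <- match("DETACHED", chain$states$state)
  n_trials <- config$trials_per_interface

  withr::with_seed(config$seed, {
    stored <- rep.int(match("TOEHOLD_BOUND", chain$states$state), n_trials)
    per <- vector("list", length(lambdas))
    for (i in seq_along(lambdas)) {
      starts <- stored[sample.int(length(stored), n_trials, replace = TRUE)]
      final <- .propagate_jump(chain, starts, stop_states = detached,
                               stop_coord = lambdas[i])
      success <- final[coord[final] >= lambdas[i]]
      if (length(success) == 0) {
        stop(sprintf(
          "interface starved: zero successful crossings at interface %g",
          lambdas[i]
        ), call. = FALSE)
      }
      per[[i]] <- tibble::tibble(
        interface = lambdas[i], n_trials = n_trials,
        n_success = length(success), p = length(success) / n_trials
      )
      stored <- success
    }
  })
  per <- dplyr::bind_rows(per)
  p_total <- prod(per$p)
  rel_var <- sum((1 - per$p) / (per$p * per$n_trials))
  structure(
    list(per_interface = per, p_total = p_total,
         se_total = p_total * sqrt(rel_var), interfaces = lambdas,
         seed = config$seed),
    class = "ffs_result"
  )
}

#' @export
print.ffs_result <- function(x, ...) {
  cat("<ffs_result>\n")
  print(x$per_interface)
  cat(sprintf("  p_total = %.4g +/- %.2g\n", x$p_total, x$se_total))
  invisible(x)
}

#' Relative displacement rate via forward flux sampling
#'
#' Ratio of FFS displacement probabilities between a system and a
#' mismatch-free reference sharing the same toehold, with propagated
#' binomial uncertainty. Both runs use the same seed, so a system compared
#' against itself gives a ratio of exactly one.
#'
#' @param system,reference [displacement_system()] objects with identical
#'   toeholds
#' @param config an [ffs_config()]
#' @param rate_params a [landscape_params()]
#' @return one-row tibble with columns `ratio`, `se`, `p_system`,
#'   `p_reference`
#' @export
relative_rate_ffs <- function(system, reference, config = ffs_config(),
                              rate_params = landscape_params()) {
  h <- system$toehold_length
  if (h != reference$toehold_length ||
      substr(system$target, 1, h) != substr(reference$target, 1, h)) {
    stop("system and reference must share the same toehold sequence",
         call. = FALSE)
  }
  res_s <- run_ffs(.system_chain(system, rate_params), config)
  res_r <- run_ffs(.system_chain(reference, rate_params), config)
  ratio <- res_s$p_total / res_r$p_total
  rel_var <- (res_s$se_total / res_s$p_total)^2 +
    (res_r$se_total / res_r$p_total)^2
  tibble::tibble(
    ratio = ratio, se = ratio * sqrt(rel_var),
    p_system = res_s$p_total, p_reference = res_r$p_total
  )
}
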