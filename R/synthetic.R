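#' Spectrofluorimeter noise model
#'
#' Parameters of the synthetic acquisition: an affine map from
#' concentration signal to fluorescence units (`scale`, `baseline`),
#' additive Gaussian noise of standard deviation `sigma_abs`, and an
#' optional exponential photobleaching channel.
#'
#' @param sigma_abs additive Gaussian SD (a.u.)
#' @param scale signal gain (a.u. per M of signal species)
#' @param baseline offset (a.u.)
#' @param bleach_rate optional photobleaching rate (s^-1); 0 disables
#' @param seed integer RNG seed
#' @return list of class `noise_model`
#' @export
noise_model <- function(sigma_abs = 0, scale = 1, baseline = 0,
                        bleach_rate = 0, seed = 1) {
  stopifnot(sigma_abs >= 0, scale > 0, bleach_rate >= 0)
  structure(
    list(sigma_abs = sigma_abs, scale = scale, baseline = baseline,
         bleach_rate = bleach_rate, seed = as.integer(seed)),
    class = "noise_model"
  )
}

#' Generate a synthetic fluorimeter trace
#'
#' Solves the network ODEs piecewise across a segment schedule of reagent
#' injections (mirroring the baseline / post-substrate / post-invader
#' protocol of a cuvette experiment), samples the signal on a regular
#' grid (60 s by default, the spectrofluorimeter measurement interval),
#' maps it through the affine gain of the noise model and adds seeded
#' Gaussian noise.
#'
#' @param network a [reaction_network()] with a signal definition
#' @param t_end total duration (s)
#' @param noise a [noise_model()]
#' @param interval sampling interval (s)
#' @param protocol optional tibble with columns `at` (injection time, s)
#'   and `add` (list of named concentration increments, M). Segment
#'   boundaries must be increasing.
#' @return a [tmsd_trace()]; the noiseless signal is attached as column
#'   `noiseless`
#' @export
generate_trace <- function(network, t_end, noise = noise_model(),
                           interval = 60, protocol = NULL) {
  stopifnot(inherits(network, "reaction_network"), t_end > interval)
  times <- seq(0, t_end, by = interval)
  if (is.null(protocol)) {
    sim <- simulate_network(network, times)
    sig <- sim$signal
  } else {
    if (any(diff(protocol$at) <= 0)) {
      stop("protocol injection times must be increasing", call. = FALSE)
    }
    bounds <- c(protocol$at, Inf)
    if (any(protocol$at < 0) || protocol$at[1] > t_end) {
      stop("protocol injection times must lie within the trace", call. = FALSE)
    }
    conc <- network$species
    sig <- numeric(length(times))
    seg_start <- 0
    for (j in seq_along(protocol$at)) {
      seg_end <- protocol$at[j]
      idx <- which(times >= seg_start & times < seg_end)
      if (length(idx) > 0) {
        sim <- .simulate_segment(network, conc, times[idx] - seg_start)
        sig[idx] <- sim$signal
        conc <- sim$final
      } else {
        sim <- .simulate_segment(network, conc, seg_end - seg_start)
        conc <- sim$final
      }
      add <- protocol$add[[j]]
      conc[names(add)] <- conc[names(add)] + unlist(add)
      seg_start <- seg_end
    }
    idx <- which(times >= seg_start)
    if (length(idx) > 0) {
      sim <- .simulate_segment(network, conc, times[idx] - seg_start)
      sig[idx] <- sim$signal
    }
  }
  decay <- exp(-noise$bleach_rate * times)
  noiseless <- (noise$baseline + noise$scale * sig) * decay
  noisy <- withr::with_seed(noise$seed, {
    noiseless + stats::rnorm(length(noiseless), 0, noise$sigma_abs)
  })
  out <- tmsd_trace(time_s = times, signal = noisy)
  out$noiseless <- noiseless
  out
}

# integrate one protocol segment from arbitrary initial concentrations;
# returns the signal at the requested offsets and the final concentrations
.simulate_segment <- function(network, conc, offsets) {
  net <- network
  net$species <- conc
  tt <- sort(unique(c(offsets, max(offsets))))
  if (length(tt) == 1 && tt[1] == 0) {
    df <- tibble::as_tibble(as.list(conc))
    sig <- if (!is.null(net$signal)) net$signal(df) else NA_real_
    return(list(signal = rep(sig, length(offsets)), final = conc))
  }
  pos <- tt > 0
  sim <- simulate_network(net, tt[pos])
  full <- dplyr::bind_rows(
    if (any(!pos)) tibble::as_tibble(c(list(time_s = 0), as.list(conc),
                                       list(signal = net$signal(
                                         tibble::as_tibble(as.list(conc)))))),
    sim
  )
  sig <- full$signal[match(offsets, full$time_s)]
  final <- unlist(full[nrow(full), names(network$species)])
  list(signal = sig, final = final)
}

#' Construct the mismatch-position sequence series
#'
#' Builds one `(target, incumbent, invader)` triple per requested mismatch
#' position, all sharing a toehold and a 3-bp mismatch motif (the
#' mismatched pair and its nearest neighbours). For positions up to 13 the
#' `slide` construction moves the base pair immediately after the motif to
#' the position immediately before it, so that deleting the motif window
#' yields the same string for every position and base content is
#' preserved. Positions deeper than 13 fall inside the domain that doubles
#' as the reporter toehold, where the output strand may not change: there
#' the `point_mutation` construction mutates a single target base (a G
#' with the motif's flanks) to create the mismatch against the unchanged
#' output.
#'
#' @param positions integer mismatch positions (1-based from the
#'   toehold-proximal end of the displacement domain)
#' @param construction `"auto"` (slide for x <= 13, point_mutation above),
#'   `"slide"` or `"point_mutation"`
#' @param motif list with `target` (3-nt target-side motif, mismatched base
#'   in the middle) and `incumbent` (the incumbent base opposite the
#'   middle, forming the mismatch)
#' @param base_domain motif-free displacement-domain sequence (the target
#'   domain with the 3-bp motif window deleted)
#' @param toehold toehold sequence (5' end of the target)
#' @param reference_position canonical motif position defining the
#'   full-length mismatch-free target used by the point-mutation designs
#' @param temperature temperature in degrees Celsius
#' @return tibble with columns `position`, `construction`, `target`,
#'   `incumbent`, `invader`
#' @export
generate_mismatch_series <- function(positions,
                                     construction = c("auto", "slide",
                                                      "point_mutation"),
                                     motif = tmsd_default_motif(),
                                     base_domain = tmsd_default_base_domain(),
                                     toehold = tmsd_default_toehold(),
                                     reference_position = 7,
                                     temperature = 25) {
  construction <- match.arg(construction)
  stopifnot(nchar(motif$target) == 3, nchar(motif$incumbent) == 1)
  base_domain <- .check_dna(base_domain, "base_domain")
  toehold <- .check_dna(toehold, "toehold")
  n_dom <- nchar(base_domain) + 3
  mid <- substr(motif$target, 2, 2)
  if (dna_complement(mid) == motif$incumbent) {
    stop("motif incumbent base is the Watson-Crick complement of the motif ",
         "centre; no mismatch would be formed", call. = FALSE)
  }
  rows <- lapply(as.integer(positions), function(x) {
    mode <- if (construction == "auto") {
      if (x <= 13) "slide" else "point_mutation"
    } else construction
    if (x < 2 || x > n_dom - 1) {
      stop(sprintf(
        "mismatch position %d would place the motif outside the domain ",
        x), "(or overlapping the toehold)", call. = FALSE)
    }
    if (mode == "slide") {
      if (x > 13) {
        stop(sprintf(
          "position %d overlaps the reporter-toehold region; the output ",
          x), "sequence may not change there - use point_mutation ",
          "(allowed where the target carries a G in the motif environment)",
          call. = FALSE)
      }
      domain <- paste0(substr(base_domain, 1, x - 2), motif$target,
                       substr(base_domain, x - 1, nchar(base_domain)))
      target <- paste0(toehold, domain)
      incumbent <- .incumbent_with_mismatch(domain, x, motif$incumbent)
    } else {
      base_target <- .series_reference_domain(base_domain, motif,
                                              reference_position)
      ctx <- substr(base_target, x - 1, x + 1)
      want <- paste0(substr(motif$target, 1, 1), "G",
                     substr(motif$target, 3, 3))
      if (ctx != want) {
        stop(sprintf(
          paste0("point_mutation requires target context %s at positions ",
                 "%d-%d (a G opposite an output cytosine in the motif ",
                 "environment); found %s"),
          want, x - 1, x + 1, ctx), call. = FALSE)
      }
      domain <- paste0(substr(base_target, 1, x - 1), mid,
                       substr(base_target, x + 1, nchar(base_target)))
      target <- paste0(toehold, domain)
      # output unchanged: complement of the unmutated reference domain
      incumbent <- dna_reverse_complement(base_target)
    }
    tibble::tibble(position = x, construction = mode, target = target,
                   incumbent = incumbent,
                   invader = dna_reverse_complement(target))
  })
  dplyr::bind_rows(rows)
}

.incumbent_with_mismatch <- function(domain, x, mm_base) {
  inc <- dna_reverse_complement(domain)
  i <- nchar(domain) + 1 - x
  paste0(substr(inc, 1, i - 1), mm_base, substr(inc, i + 1, nchar(inc)))
}

# full-length mismatch-free target domain with the motif's perfect-match
# version at the canonical position
.series_reference_domain <- function(base_domain, motif, reference_position) {
  x <- reference_position
  paste0(substr(base_domain, 1, x - 2), motif$target,
         substr(base_domain, x - 1, nchar(base_domain)))
}

#' Default study sequences
#'
#' The experimental mismatch-motif and flanking sequences live in a
#' supplementary table that is not part of this package; these defaults are
#' a documented synthetic stand-in with the same architecture: a 4-nt
#' toehold, a 20-bp displacement domain, a C.C mismatch (the most
#' destabilising pairing under the nearest-neighbour model) inside a
#' conserved 3-bp motif, and G bases in the reporter-toehold region at
#' domain positions 15 and 17 whose point mutation recreates the motif
#' environment. All motif-dependent behaviour is parameterised so the true
#' sequences can be dropped in.
#'
#' @return the default motif (list), base domain and toehold (strings)
#' @name tmsd-default-sequences
NULL

#' @rdname tmsd-default-sequences
#' @export
tmsd_default_motif <- function() list(target = "TCT", incumbent = "C")

#' @rdname tmsd-default-sequences
#' @export
tmsd_default_base_domain <- function() "CATGACTGAGTGTGTCA"

#' @rdname tmsd-default-sequences
#' @export
tmsd_default_toehold <- function() "ACTC"

#' Displacement system for a mismatch position of the default series
#'
#' Convenience wrapper: builds the [displacement_system()] for one mismatch
#' position of [generate_mismatch_series()], or the mismatch-free reference
#' system when `position` is `NULL`.
#'
#' @param position mismatch position, or `NULL` for the reference
#' @inheritParams generate_mismatch_series
#' @return a [displacement_system()]
#' @export
design_system <- function(position = NULL, motif = tmsd_default_motif(),
                          base_domain = tmsd_default_base_domain(),
                          toehold = tmsd_default_toehold(),
                          reference_position = 7, temperature = 25) {
  if (is.null(position)) {
    dom <- .series_reference_domain(base_domain, motif, reference_position)
    target <- paste0(toehold, dom)
    return(displacement_system(
      target, dna_reverse_complement(dom),
      toehold_length = nchar(toehold), mismatch_position = NULL,
      temperature = temperature
    ))
  }
  row <- generate_mismatch_series(position, motif = motif,
                                  base_domain = base_domain,
                                  toehold = toehold,
                                  reference_position = reference_position)
  displacement_system(row$target, row$incumbent, row$invader,
                      toehold_length = nchar(toehold),
                      mismatch_position = position,
                      temperature = temperature)
}

#' Named fixture bundle of synthetic traces
#'
#' Emits the preset networks, noiseless-by-default traces and generating
#' truth values used across the test-suite: rate-assay traces at the three
#' experimentally reported rate constants, a catalytic run with and
#' without catalyst, and a pulse run at the 4:2:1 concentration ratios.
#'
#' @param seed integer seed for the noise streams
#' @param sigma_abs Gaussian noise SD passed to the noise models
#' @return named list of fixtures, each a list with elements `network`,
#'   `trace` and `truth`
#' @export
trace_fixture_suite <- function(seed = 1, sigma_abs = 0) {
  ks <- c(rate_assay_k0 = 2.6e3, rate_assay_pos3 = 1.8e5,
          rate_assay_pos15 = 1.7e3)
  fixtures <- lapply(seq_along(ks), function(i) {
    k <- ks[[i]]
    net <- build_rate_assay_model(k)
    trace <- generate_trace(net, t_end = 500 * 60,
                            noise = noise_model(sigma_abs = sigma_abs,
                                                seed = seed + i))
    list(network = net, trace = trace, truth = c(k_disp = k))
  })
  names(fixtures) <- names(ks)

  cat_net <- build_catalytic_model()
  cat_net0 <- build_catalytic_model(
    concentrations = catalytic_concentrations(a = 0))
  fixtures$catalytic <- list(
    network = cat_net,
    trace = generate_trace(cat_net, t_end = 500 * 60,
                           noise = noise_model(sigma_abs = sigma_abs,
                                               seed = seed + 11)),
    truth = c(k1 = cat_net$reactions$k[1]),
    network_no_catalyst = cat_net0
  )

  pulse_net <- build_pulse_model()
  pulse_sim <- simulate_network(pulse_net, seq(60, 500 * 60, by = 60))
  fixtures$pulse <- list(
    network = pulse_net,
    trace = tmsd_trace(time_s = pulse_sim$time_s, cy3 = pulse_sim$I3T,
                       cy5 = pulse_sim$I5T),
    truth = c(k3 = pulse_net$reactions$k[1], k5 = pulse_net$reactions$k[3])
  )
  fixtures
}
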