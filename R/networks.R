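#' Mass-action reaction network
#'
#' A reaction network is a set of named species with initial concentrations
#' (mol/L) and a list of elementary reactions with at most bimolecular
#' stoichiometry. Reversible reactions are stored as two irreversible
#' reactions. An optional strand-composition matrix records how many copies
#' of each named strand every species contains, which defines the
#' conservation totals checked after simulation.
#'
#' @param species named numeric vector of initial concentrations (M)
#' @param reactions tibble with list-columns `reactants`, `products`
#'   (character vectors of species names, repeated for stoichiometry) and a
#'   numeric column `k` (M^-1 s^-1 for bimolecular, s^-1 for unimolecular)
#' @param signal function mapping the simulated concentration tibble to a
#'   numeric signal vector, or `NULL`
#' @param composition numeric matrix (species x strands) of strand counts,
#'   or `NULL`
#' @param model_id identifier string carried through to fits
#' @return object of class `reaction_network`
#' @export
reaction_network <- function(species, reactions, signal = NULL,
                             composition = NULL, model_id = "custom") {
  stopifnot(is.numeric(species), !is.null(names(species)))
  if (any(species < 0)) stop("initial concentrations must be >= 0",
                             call. = FALSE)
  if (any(reactions$k < 0)) stop("rate constants must be >= 0", call. = FALSE)
  used <- unique(unlist(c(reactions$reactants, reactions$products)))
  unknown <- setdiff(used, names(species))
  if (length(unknown) > 0) {
    stop("reaction references undeclared species: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(lengths(reactions$reactants) > 2)) {
    stop("at most bimolecular reactions are supported", call. = FALSE)
  }
  if (!is.null(composition)) {
    stopifnot(is.matrix(composition),
              setequal(rownames(composition), names(species)))
  }
  structure(
    list(species = species, reactions = reactions, signal = signal,
         composition = composition, model_id = model_id),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network>", x$model_id, "-", length(x$species), "species,",
      nrow(x$reactions), "reactions\n")
  fmt <- function(v) paste(v, collapse = " + ")
  for (i in seq_len(nrow(x$reactions))) {
    cat(sprintf("  %s -> %s   k = %.3g\n", fmt(x$reactions$reactants[[i]]),
                fmt(x$reactions$products[[i]]), x$reactions$k[i]))
  }
  invisible(x)
}

# stoichiometry matrices (reactions x species): reactant counts and net change
.stoich <- function(network) {
  sp <- names(network$species)
  nr <- nrow(network$reactions)
  count <- function(lst) {
    m <- matrix(0, nr, length(sp), dimnames = list(NULL, sp))
    for (i in seq_len(nr)) {
      tab <- table(lst[[i]])
      m[i, names(tab)] <- as.numeric(tab)
    }
    m
  }
  r <- count(network$reactions$reactants)
  p <- count(network$reactions$products)
  list(reactants = r, net = p - r)
}

#' Simulate a reaction network
#'
#' Deterministic mass-action ODE integration with `deSolve::lsoda`.
#'
#' @param network a [reaction_network()]
#' @param times increasing vector of output times (s); a leading 0 is added
#'   if absent
#' @param rtol,atol solver tolerances
#' @return tibble with column `time_s` and one column per species (M); if
#'   the network defines a signal, a `signal` column is appended
#' @export
simulate_network <- function(network, times, rtol = 1e-10, atol = 1e-16) {
  stopifnot(inherits(network, "reaction_network"))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  prepend0 <- times[1] > 0
  tt <- if (prepend0) c(0, times) else times
  st <- .stoich(network)
  kvec <- network$reactions$k
  deriv <- function(t, y, parms) {
    y <- pmax(y, 0)
    v <- kvec * apply(st$reactants, 1, function(r) prod(y^r))
    list(as.numeric(crossprod(st$net, v)))
  }
  sol <- deSolve::lsoda(network$species, tt, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE solver failed to converge for model '", network$model_id,
         "' (istate = ", attr(sol, "istate")[1], ")", call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out)[1] <- "time_s"
  if (prepend0) out <- out[-1, ]
  if (!is.null(network$signal)) out$signal <- network$signal(out)
  out
}

#' Strand-conservation totals of a simulated trajectory
#'
#' @param network a [reaction_network()] with a composition matrix
#' @param trajectory output of [simulate_network()]
#' @return tibble with `time_s` and one total-concentration column per strand
#' @export
conservation_totals <- function(network, trajectory) {
  stopifnot(!is.null(network$composition))
  comp <- network$composition[names(network$species), , drop = FALSE]
  conc <- as.matrix(trajectory[, names(network$species)])
  totals <- conc %*% comp
  dplyr::bind_cols(tibble::tibble(time_s = trajectory$time_s),
                   tibble::as_tibble(totals))
}

#' Rate-assay concentrations from the reported mixing volumes
#'
#' 2.4 uL of 10 uM substrate duplex and invader into a 1.92 mL cuvette give
#' 12.5 nM each; 2.4 uL of 20 uM reporter complex gives 25 nM.
#'
#' @return named numeric vector of concentrations (M)
#' @export
rate_assay_concentrations <- function() {
  c(OT = 2.4e-6 * 10e-6 / 1.92e-3, # = 12.5 nM
    I = 2.4e-6 * 10e-6 / 1.92e-3,
    Rep = 2.4e-6 * 20e-6 / 1.92e-3) # = 25 nM
}

#' Build the rate-assay network
#'
#' The displacement reaction `I + O.T -> I.T + O` followed by a reporter
#' that converts released output `O` into fluorescence. With
#' `reporter = "instantaneous"` the reporter is treated as an infinitely
#' fast sink and the signal is the cumulative released output (equal to
#' the `I.T` formed); with `reporter = "explicit"` the secondary
#' displacement `O + Rep -> F + W` is integrated with rate constant
#' `k_rep` and the signal is `[F]`.
#'
#' @param k_disp displacement rate constant, M^-1 s^-1
#' @param reporter `"instantaneous"` or `"explicit"`
#' @param k_rep reporter displacement rate constant (explicit mode)
#' @param concentrations named vector with entries `OT`, `I`, `Rep` (M)
#' @return a [reaction_network()]
#' @export
build_rate_assay_model <- function(k_disp,
                                   reporter = c("instantaneous", "explicit"),
                                   k_rep = 1e6,
                                   concentrations = rate_assay_concentrations()) {
  stopifnot(k_disp > 0)
  reporter <- match.arg(reporter)
  ot0 <- concentrations[["OT"]]
  if (reporter == "instantaneous") {
    species <- c(I = concentrations[["I"]], OT = ot0, IT = 0, O = 0)
    reactions <- tibble::tibble(
      reactants = list(c("I", "OT")), products = list(c("IT", "O")),
      k = k_disp
    )
    comp <- rbind(I = c(1, 0, 0), OT = c(0, 1, 1), IT = c(1, 0, 1),
                  O = c(0, 1, 0))
    colnames(comp) <- c("invader", "output", "target")
    # cumulative released output O == I.T formed (robust across injections)
    signal <- function(df) df$IT
  } else {
    species <- c(I = concentrations[["I"]], OT = ot0, IT = 0, O = 0,
                 Rep = concentrations[["Rep"]], F = 0, W = 0)
    reactions <- tibble::tibble(
      reactants = list(c("I", "OT"), c("O", "Rep")),
      products = list(c("IT", "O"), c("F", "W")),
      k = c(k_disp, k_rep)
    )
    comp <- rbind(I = c(1, 0, 0, 0, 0), OT = c(0, 1, 1, 0, 0),
                  IT = c(1, 0, 1, 0, 0), O = c(0, 1, 0, 0, 0),
                  Rep = c(0, 0, 0, 1, 1), F = c(0, 0, 0, 1, 0),
                  W = c(0, 1, 0, 0, 1))
    colnames(comp) <- c("invader", "output", "target", "rep_fluor",
                        "rep_quench")
    signal <- function(df) df$F
  }
  reaction_network(species, reactions, signal = signal, composition = comp,
                   model_id = paste0("rate_assay_", reporter))
}

#' Concentrations of the catalytic toehold-exchange experiment
#'
#' @param a catalyst concentration (M); 0 for the leak experiment
#' @return named numeric vector of concentrations (M)
#' @export
catalytic_concentrations <- function(a = 5e-9) {
  c(BD = 40e-9, C = 200e-9, A = a, Rep = 250e-9)
}

#' Build the catalytic toehold-exchange network
#'
#' The two-step exchange `A + B.D <-> B + A.D`, `C + A.D <-> A + C.D`
#' through which catalyst `A` interconverts `B.D` and `C.D`, plus the
#' direct (uncatalysed) leak channel `C + B.D <-> B + C.D` and a reporter
#' sink `B + Rep -> F + W`. By default the reverse leak constant is set by
#' thermodynamic cycle closure, `K_leak = K1 * K2`, so that catalysis
#' changes only the route to equilibrium, never its position. Raising
#' `k2 / k2r` emulates mismatch elimination in `C.D` (hidden thermodynamic
#' drive); raising `k_leak` emulates the extended fuel strand `C2` whose
#' extra toehold base pairs accelerate the leak.
#'
#' @param k1,k1r forward/reverse constants of `A + B.D <-> B + A.D`
#' @param k2,k2r forward/reverse constants of `C + A.D <-> A + C.D`
#' @param k_rep reporter rate constant (set 0 to disable the sink)
#' @param k_leak direct `C + B.D` leak rate constant
#' @param k_leak_r reverse leak constant; `NULL` applies cycle closure
#' @param concentrations named vector with entries `BD`, `C`, `A`, `Rep`
#' @return a [reaction_network()]
#' @export
build_catalytic_model <- function(k1 = 1e5, k1r = 1e5, k2 = 1e5, k2r = 1e5,
                                  k_rep = 1e6, k_leak = 10, k_leak_r = NULL,
                                  concentrations = catalytic_concentrations()) {
  stopifnot(all(c(k1, k1r, k2, k2r, k_rep, k_leak) >= 0))
  if (is.null(k_leak_r)) {
    k_leak_r <- if (k1 > 0 && k2 > 0) k_leak * (k1r * k2r) / (k1 * k2) else 0
  }
  species <- c(A = concentrations[["A"]], BD = concentrations[["BD"]],
               B = 0, AD = 0, C = concentrations[["C"]], CD = 0,
               Rep = concentrations[["Rep"]], F = 0, W = 0)
  reactions <- tibble::tibble(
    reactants = list(c("A", "BD"), c("B", "AD"), c("C", "AD"), c("A", "CD"),
                     c("C", "BD"), c("B", "CD"), c("B", "Rep")),
    products = list(c("B", "AD"), c("A", "BD"), c("A", "CD"), c("C", "AD"),
                    c("B", "CD"), c("C", "BD"), c("F", "W")),
    k = c(k1, k1r, k2, k2r, k_leak, k_leak_r, k_rep)
  )
  strands <- c("A", "B", "C", "D", "rep_fluor", "rep_quench")
  comp <- rbind(A = c(1, 0, 0, 0, 0, 0), BD = c(0, 1, 0, 1, 0, 0),
                B = c(0, 1, 0, 0, 0, 0), AD = c(1, 0, 0, 1, 0, 0),
                C = c(0, 0, 1, 0, 0, 0), CD = c(0, 0, 1, 1, 0, 0),
                Rep = c(0, 0, 0, 0, 1, 1), F = c(0, 0, 0, 0, 1, 0),
                W = c(0, 1, 0, 0, 0, 1))
  colnames(comp) <- strands
  reaction_network(species, reactions, signal = function(df) df$F,
                   composition = comp, model_id = "catalytic")
}

#' Concentrations of the pulse-generator experiment (4:2:1)
#'
#' @param ot substrate duplex concentration (M)
#' @return named numeric vector with `[I5]:[I3]:[OT] = 4:2:1`
#' @export
pulse_concentrations <- function(ot = 12.5e-9) {
  c(OT = ot, I3 = 2 * ot, I5 = 4 * ot)
}

#' Build the two-toehold pulse-generator network
#'
#' Two invaders compete for the substrate duplex `O.T` from opposite
#' toeholds: `I3 + O.T <-> I3.T + O`, `I5 + O.T <-> I5.T + O`, and the
#' toehold-exchange relaxation `I5 + I3.T <-> I5.T + I3`. The three
#' equilibrium constants form a thermodynamic cycle,
#' `K_ex = K5 / K3`; reverse constants left `NULL` are filled in from the
#' forward constants and the equilibrium constants `K3`, `K5`. A supplied
#' inconsistent set triggers a warning with the cycle residual. The Cy3
#' channel reports `[I3.T]`, the Cy5 channel `[I5.T]`; the inferred output
#' curve is their sum.
#'
#' @param k3,k5 forward invasion rate constants (M^-1 s^-1); the mismatch
#'   three base pairs from the 3' toehold makes `k3` much larger than `k5`
#' @param k3r,k5r reverse constants, or `NULL` for `k3 / K3`, `k5 / K5`
#' @param k_ex forward toehold-exchange constant
#' @param k_exr reverse exchange constant, or `NULL` for cycle closure
#' @param K3,K5 equilibrium constants of the two invasions
#' @param concentrations named vector with entries `OT`, `I3`, `I5`
#' @return a [reaction_network()]
#' @export
build_pulse_model <- function(k3 = 2e5, k5 = 1e4, k3r = NULL, k5r = NULL,
                              k_ex = 1e4, k_exr = NULL, K3 = 5e3, K5 = 5e3,
                              concentrations = pulse_concentrations()) {
  if (is.null(k3r)) k3r <- k3 / K3
  if (is.null(k5r)) k5r <- k5 / K5
  if (is.null(k_exr)) k_exr <- k_ex / ((k5 / k5r) / (k3 / k3r))
  stopifnot(all(c(k3, k3r, k5, k5r, k_ex, k_exr) >= 0))
  residual <- log((k_ex / k_exr) * (k3 / k3r) / (k5 / k5r))
  if (abs(residual) > 1e-8) {
    warning(sprintf(
      "rate constants violate thermodynamic cycle closure: log residual %.3g",
      residual
    ), call. = FALSE)
  }
  species <- c(OT = concentrations[["OT"]], I3 = concentrations[["I3"]],
               I5 = concentrations[["I5"]], I3T = 0, I5T = 0, O = 0)
  reactions <- tibble::tibble(
    reactants = list(c("I3", "OT"), c("I3T", "O"), c("I5", "OT"),
                     c("I5T", "O"), c("I5", "I3T"), c("I5T", "I3")),
    products = list(c("I3T", "O"), c("I3", "OT"), c("I5T", "O"),
                    c("I5", "OT"), c("I5T", "I3"), c("I5", "I3T")),
    k = c(k3, k3r, k5, k5r, k_ex, k_exr)
  )
  comp <- rbind(OT = c(1, 0, 0, 1), I3 = c(0, 1, 0, 0), I5 = c(0, 0, 1, 0),
                I3T = c(0, 1, 0, 1), I5T = c(0, 0, 1, 1), O = c(1, 0, 0, 0))
  colnames(comp) <- c("output", "invader3", "invader5", "target")
  reaction_network(species, reactions,
                   signal = function(df) df$I3T + df$I5T,
                   composition = comp, model_id = "pulse")
}
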