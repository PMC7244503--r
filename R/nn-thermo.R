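#' Duplex free energy under the nearest-neighbour model
#'
#' Computes the standard free energy of duplex formation for two opposed
#' strands as the sum of temperature-adjusted dinucleotide stack terms
#' (`dH - T*dS`), per-end initiation terms and an optional monovalent
#' salt correction. Internal single mismatches are scored with the published
#' internal-mismatch stack parameters; terminal mismatches are rejected
#' (terminal opening is handled by the fraying microstates of
#' [displacement_profile()]).
#'
#' @param top top strand, 5'->3'
#' @param bottom bottom strand, 5'->3'; `bottom` is aligned antiparallel so
#'   that its last base pairs with the first base of `top`
#' @param params parameter set from [nn_params()]
#' @param temperature temperature in degrees Celsius
#' @return duplex formation free energy in kcal/mol (more negative = more
#'   stable)
#' @examples
#' p <- nn_params(salt = NULL)
#' duplex_free_energy("ACGT", dna_reverse_complement("ACGT"), p, 37)
#' @export
duplex_free_energy <- function(top, bottom, params = nn_params(),
                               temperature = 25) {
  top <- .check_dna(top, "top strand")
  bottom <- .check_dna(bottom, "bottom strand")
  if (nchar(top) != nchar(bottom)) {
    stop("top and bottom strands must have equal length", call. = FALSE)
  }
  t_chr <- strsplit(top, "")[[1]]
  # bottom read 3'->5' left to right, aligned under the top strand
  b_chr <- rev(strsplit(bottom, "")[[1]])
  n <- length(t_chr)
  wc <- .is_wc_pair(t_chr, b_chr)
  if (!wc[1] || !wc[n]) {
    stop("terminal mismatches are not supported by duplex_free_energy(); ",
         "terminal opening is modelled as fraying in displacement_profile()",
         call. = FALSE)
  }
  t_k <- celsius_to_kelvin(temperature)
  lut <- .nn_lookup_table(params)
  dh <- 0
  ds <- 0
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      if (!wc[i] && !wc[i + 1]) {
        stop(sprintf(
          "tandem mismatch at dinucleotide step %s%s/%s%s is not supported",
          t_chr[i], t_chr[i + 1], b_chr[i], b_chr[i + 1]
        ), call. = FALSE)
      }
      key <- paste0(t_chr[i], t_chr[i + 1], "/", b_chr[i], b_chr[i + 1])
      flip <- paste0(b_chr[i + 1], b_chr[i], "/", t_chr[i + 1], t_chr[i])
      idx <- match(key, lut$step)
      if (is.na(idx)) idx <- match(flip, lut$step)
      if (is.na(idx)) {
        stop(sprintf("no nearest-neighbour parameters for dinucleotide step %s",
                     key), call. = FALSE)
      }
      dh <- dh + lut$dh[idx]
      ds <- ds + lut$ds[idx]
    }
  }
  # per-end initiation (terminal pairs are WC by the check above)
  for (end_pair in c(t_chr[1], t_chr[n])) {
    term <- if (end_pair %in% c("G", "C")) "init_G/C" else "init_A/T"
    idx <- match(term, params$initiation_terms$term)
    dh <- dh + params$initiation_terms$dh[idx]
    ds <- ds + params$initiation_terms$ds[idx]
  }
  # self-complementary symmetry correction
  if (top == bottom && top == dna_reverse_complement(top)) ds <- ds - 1.4
  if (!is.null(params$salt_model) && n >= 2) {
    ds <- ds + 0.368 * (n - 1) * log(params$salt_model$na_equivalent)
  }
  dh - t_k * ds / 1000
}

.nn_lookup_table <- function(params) {
  dplyr::bind_rows(params$watson_crick_stacks, params$internal_mismatch_stacks)
}

#' Specify a mismatch-elimination displacement system
#'
#' A displacement system is the designed reaction `I + O.T -> I.T + O`: a
#' target strand `T` carrying a 5' single-stranded toehold and an N-bp
#' displacement domain, an incumbent (output) strand `O` complementary to
#' the domain except at an optional single mismatch position, and an
#' invader `I` fully complementary to toehold plus domain. The mismatch
#' position is 1-based, counted from the toehold-proximal end of the
#' displacement domain.
#'
#' @param target target strand `T`, 5'->3' (toehold first, then domain)
#' @param incumbent incumbent/output strand `O`, 5'->3', length `N`
#' @param invader invader strand `I`, 5'->3'; defaults to the full reverse
#'   complement of `target`
#' @param toehold_length toehold length h in nucleotides (default 4)
#' @param mismatch_position 1-based domain position of the mismatch, or
#'   `NULL` for a mismatch-free system
#' @param temperature temperature in degrees Celsius (default 25)
#' @return object of class `displacement_system`
#' @export
displacement_system <- function(target, incumbent,
                                invader = dna_reverse_complement(target),
                                toehold_length = 4,
                                mismatch_position = NULL,
                                temperature = 25) {
  target <- .check_dna(target, "target")
  incumbent <- .check_dna(incumbent, "incumbent")
  invader <- .check_dna(invader, "invader")
  h <- as.integer(toehold_length)
  n_dom <- nchar(target) - h
  if (h < 1 || n_dom < 2) {
    stop("need toehold_length >= 1 and a displacement domain of >= 2 bp",
         call. = FALSE)
  }
  if (nchar(incumbent) != n_dom) {
    stop("incumbent length must equal the displacement-domain length",
         call. = FALSE)
  }
  if (invader != dna_reverse_complement(target)) {
    stop("invader must be fully complementary to the target over toehold ",
         "and displacement domain", call. = FALSE)
  }
  domain <- substr(target, h + 1, h + n_dom)
  x <- if (is.null(mismatch_position)) NULL else as.integer(mismatch_position)
  # incumbent base opposite domain position i sits at incumbent index N+1-i
  dom_chr <- strsplit(domain, "")[[1]]
  inc_chr <- rev(strsplit(incumbent, "")[[1]])
  mismatched <- which(inc_chr != dna_complement(dom_chr))
  if (is.null(x)) {
    if (length(mismatched) > 0) {
      stop("incumbent is not complementary to the displacement domain but no ",
           "mismatch_position was declared (offending position(s): ",
           paste(mismatched, collapse = ", "), ")", call. = FALSE)
    }
    mm_type <- NULL
  } else {
    if (x < 1 || x > n_dom) {
      stop(sprintf("mismatch_position must lie in 1..%d", n_dom), call. = FALSE)
    }
    if (!identical(mismatched, x)) {
      stop("incumbent must be complementary to the displacement domain ",
           "except at the declared mismatch_position", call. = FALSE)
    }
    mm_type <- c(target = dom_chr[x], incumbent = inc_chr[x])
  }
  structure(
    list(
      target = target, incumbent = incumbent, invader = invader,
      toehold_length = h, domain_length = n_dom, domain = domain,
      mismatch_position = x, mismatch_type = mm_type,
      temperature = temperature
    ),
    class = "displacement_system"
  )
}

#' @export
print.displacement_system <- function(x, ...) {
  cat("<displacement_system>\n")
  cat(sprintf("  toehold %d nt + domain %d bp, T = %g C\n",
              x$toehold_length, x$domain_length, x$temperature))
  if (is.null(x$mismatch_position)) {
    cat("  mismatch: none\n")
  } else {
    cat(sprintf("  mismatch: %s.%s at domain position %d\n",
                x$mismatch_type[["target"]], x$mismatch_type[["incumbent"]],
                x$mismatch_position))
  }
  cat("  target:   5'-", x$target, "-3'\n", sep = "")
  cat("  incumbent:5'-", x$incumbent, "-3'\n", sep = "")
  invisible(x)
}

#' Free energy of the displacement reaction
#'
#' Returns `dG(I.T + O) - dG(O.T + I)`, the standard free-energy change of
#' the strand-displacement reaction, with single strands assigned zero
#' structural free energy. A mismatch in `O.T` destabilises the reactant and
#' therefore makes the reaction free energy more negative; the difference
#' with respect to the mismatch-free system is the hidden thermodynamic
#' drive contributed by mismatch elimination.
#'
#' @param system a [displacement_system()]
#' @param params parameter set from [nn_params()]
#' @return reaction free energy in kcal/mol
#' @export
reaction_delta_g <- function(system, params = nn_params()) {
  stopifnot(inherits(system, "displacement_system"))
  d_it <- duplex_free_energy(system$target, system$invader, params,
                             system$temperature)
  d_ot <- .ot_duplex_energy(system, params)
  d_it - d_ot
}

# O.T duplex energy, handling a terminal mismatch (x = 1 or x = N) by
# scoring the terminal mismatched pair as open (documented extrapolation;
# the underlying study never places a mismatch at the duplex ends).
.ot_duplex_energy <- function(system, params) {
  x <- system$mismatch_position
  n_dom <- system$domain_length
  if (!is.null(x) && (x == 1 || x == n_dom)) {
    keep <- if (x == 1) c(2, n_dom) else c(1, n_dom - 1)
    dom <- substr(system$domain, keep[1], keep[2])
    inc_keep <- c(n_dom + 1 - keep[2], n_dom + 1 - keep[1])
    inc <- substr(system$incumbent, inc_keep[1], inc_keep[2])
    return(duplex_free_energy(dom, inc, params, system$temperature))
  }
  duplex_free_energy(system$domain, system$incumbent, params,
                     system$temperature)
}

# lumped mismatch destabilisation of the full O.T duplex, kcal/mol:
# dG(O.T with mismatch) - dG(same region perfectly paired)
.mismatch_ddg <- function(system, params) {
  if (is.null(system$mismatch_position)) return(0)
  perfect <- dna_reverse_complement(system$domain)
  d_mm <- .ot_duplex_energy(system, params)
  d_wc <- duplex_free_energy(system$domain, perfect, params,
                             system$temperature)
  d_mm - d_wc
}

#' Free-energy profile of displacement intermediates
#'
#' Assigns macrostates by the number `n` of invader-target base pairs
#' (toehold base pairs included) and computes `G(n)` in kB*T as a partition
#' sum over microstates that differ in the number `f = 0..f_max` of frayed
#' `O.T` base pairs immediately ahead of the branch point. Microstate
#' energies are nearest-neighbour duplex energies of the intact `I.T` and
#' `O.T` segments; the mismatch enters as a lumped destabilisation applied
#' only while it is enclosed in the intact `O.T` duplex. Fraying lets the
#' duplex trade the cost of enclosing a mismatch near its end for the
#' smaller cost of opening terminal base pairs, which is what makes a
#' position-2 mismatch a weaker thermodynamic driver than deeper ones.
#'
#' `G(1) = 0` anchors the profile at the first invader-target base pair.
#' Branch-migration macrostates (`n > h` with the incumbent still attached)
#' carry the plateau penalty `dg_plateau`; the sawtooth barrier
#' `dg_sawtooth` does not shift macrostate free energies but is stored and
#' used by [build_chain()] to set the branch-migration hopping rate.
#'
#' @param system a [displacement_system()]
#' @param params parameter set from [nn_params()]
#' @param f_max maximum number of frayed O.T base pairs summed over
#' @param dg_plateau free-energy penalty (kB*T) for branch-migration
#'   intermediates with an active three-strand junction
#' @param dg_sawtooth per-step branch-migration barrier (kB*T)
#' @return a tibble of class `free_energy_profile` with columns `n`,
#'   `G_kBT`; attributes carry the system and model settings
#' @export
displacement_profile <- function(system, params = nn_params(), f_max = 1,
                                 dg_plateau = 2.96, dg_sawtooth = 7.3) {
  stopifnot(inherits(system, "displacement_system"), f_max >= 0)
  h <- system$toehold_length
  n_dom <- system$domain_length
  x <- system$mismatch_position
  n_max <- h + n_dom - !is.null(x)
  if (n_max < 2) stop("degenerate system: n_max < 2", call. = FALSE)
  kbt <- kcal_per_kbt(system$temperature)
  ddg <- .mismatch_ddg(system, params)

  # invader.target subduplex energies over bps 1..n (perfect complement)
  d_it <- vapply(seq_len(n_max), function(n) {
    s <- substr(system$target, 1, n)
    duplex_free_energy(s, dna_reverse_complement(s), params,
                       system$temperature)
  }, numeric(1))

  # perfectly paired O.T subduplex energy over domain positions p0..pend
  de_wc <- function(p0, pend) {
    if (p0 > pend) return(0)
    s <- substr(system$domain, p0, pend)
    duplex_free_energy(s, dna_reverse_complement(s), params,
                       system$temperature)
  }

  e_ot <- function(m, f) {
    p0 <- m + f + 1
    if (p0 > n_dom) return(0)
    pend <- n_dom
    add_mm <- 0
    if (!is.null(x) && x > m) {
      enclosed <- (x < pend) && (x > p0 || (x == p0 && f == 0))
      if (enclosed) {
        add_mm <- ddg
      } else if (x >= p0) {
        # terminal mismatch: score the mismatched pair as open
        if (x == p0) p0 <- x + 1 else if (x == pend) pend <- x - 1
      }
    }
    de_wc(p0, pend) + add_mm
  }

  g <- vapply(seq_len(n_max), function(n) {
    m <- max(n - h, 0L)
    fs <- 0:min(f_max, n_dom - m)
    e_kbt <- vapply(fs, function(f) (d_it[n] + e_ot(m, f)) / kbt, numeric(1))
    plateau <- if (m >= 1 && m <= n_dom - 1) dg_plateau else 0
    plateau - .logsumexp(-e_kbt)
  }, numeric(1))
  g <- g - g[1]

  out <- tibble::tibble(n = seq_len(n_max), G_kBT = g)
  class(out) <- c("free_energy_profile", class(out))
  attr(out, "system") <- system
  attr(out, "f_max") <- f_max
  attr(out, "dg_plateau") <- dg_plateau
  attr(out, "dg_sawtooth") <- dg_sawtooth
  attr(out, "ddg_mismatch_kcal") <- ddg
  attr(out, "toehold_dg_kbt") <- toehold_attachment_dg(system, params)
  out
}

# numerically stable log(sum(exp(x)))
.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Toehold attachment free energy
#'
#' Free energy (kB*T) of the fully toehold-bound state relative to the
#' detached state at the 1 M standard state: the nearest-neighbour duplex
#' energy of the toehold subduplex, including initiation.
#'
#' @inheritParams reaction_delta_g
#' @return free energy in kB*T (negative = stable binding)
#' @export
toehold_attachment_dg <- function(system, params = nn_params()) {
  stopifnot(inherits(system, "displacement_system"))
  s <- substr(system$target, 1, system$toehold_length)
  kcal_to_kbt(
    duplex_free_energy(s, dna_reverse_complement(s), params,
                       system$temperature),
    system$temperature
  )
}
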