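# Nearest-neighbour thermodynamics: duplex energies, reaction free energy,
# free-energy profiles with fraying.

test_that("a 1-bp duplex carries initiation terms only", {
  # G paired with C: two duplex ends closed by the same G.C pair
  expect_equal(duplex_free_energy("G", "C", nn_ref, 37),
               2 * dg37(0.1, -2.8), tolerance = 1e-12)
  expect_equal(duplex_free_energy("A", "T", nn_ref, 37),
               2 * dg37(2.3, 4.1), tolerance = 1e-12)
})

test_that("a short duplex reproduces the hand-summed stack entries", {
  # ACGG/CCGT: stacks AC (= GT/CA read from the other strand), CG, GG;
  # ends closed by A.T and G.C. Entries looked up by hand in the published
  # unified table before implementation.
  hand <- dg37(-8.4, -22.4) + dg37(-10.6, -27.2) + dg37(-8.0, -19.9) +
    dg37(2.3, 4.1) + dg37(0.1, -2.8)
  expect_equal(duplex_free_energy("ACGG", "CCGT", nn_ref, 37), hand,
               tolerance = 1e-12)
  # same duplex at 25 C through dH - T*dS
  hand25 <- dg25(-8.4, -22.4) + dg25(-10.6, -27.2) + dg25(-8.0, -19.9) +
    dg25(2.3, 4.1) + dg25(0.1, -2.8)
  expect_equal(duplex_free_energy("ACGG", "CCGT", nn_ref, 25), hand25,
               tolerance = 1e-12)
})

test_that("C.C is the most destabilising internal mismatch in a fixed context", {
  score <- function(x, y) {
    top <- paste0("GA", x, "AG")
    bot <- dna_reverse_complement(top)
    substr(bot, 3, 3) <- y
    duplex_free_energy(top, bot, nn_ref, 37)
  }
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(x = bases, y = bases, stringsAsFactors = FALSE)
  combos <- combos[dna_complement(combos$x) != combos$y, ]
  dgs <- mapply(score, combos$x, combos$y)
  names(dgs) <- paste0(combos$x, ".", combos$y)
  expect_equal(names(which.max(dgs)), "C.C")
  expect_true(all(dgs[["C.C"]] >= dgs))
})

test_that("duplex energy is invariant under reverse-complement relabelling", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      n <- sample(4:12, 1)
      top <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                   collapse = "")
      bot <- dna_reverse_complement(top)
      if (rep > 5) { # introduce an internal mismatch
        i <- sample(2:(n - 1), 1)
        j <- n + 1 - i
        top_i <- substr(top, i, i)
        new <- sample(setdiff(c("A", "C", "G", "T"),
                              c(substr(bot, j, j), dna_complement(top_i))), 1)
        substr(bot, j, j) <- new
      }
      expect_equal(duplex_free_energy(top, bot, nn_buf, 25),
                   duplex_free_energy(bot, top, nn_buf, 25),
                   tolerance = 1e-12)
    }
  })
})

test_that("unsupported inputs raise named errors", {
  expect_error(duplex_free_energy("ACNT", "ANGT", nn_ref), "unsupported base")
  expect_error(duplex_free_energy("ACGT", "ACGA", nn_ref),
               "terminal mismatch")
  # tandem mismatch names the dinucleotide step
  expect_error(duplex_free_energy("GAAG", "CGGC", nn_ref), "AA/GG",
               fixed = TRUE)
})

test_that("reaction free energy is the I.T vs O.T duplex difference", {
  dg <- reaction_delta_g(ref_system, nn_buf)
  d_it <- duplex_free_energy(ref_system$target, ref_system$invader, nn_buf, 25)
  d_ot <- duplex_free_energy(ref_system$domain, ref_system$incumbent,
                             nn_buf, 25)
  expect_equal(dg, d_it - d_ot, tolerance = 1e-12)
  # the displacement domain cancels: what remains is the free energy of
  # forming the toehold duplex (plus its junction step), always favourable
  expect_lt(dg, 0)
})

test_that("the mismatch contribution matches hand-computed NN arithmetic", {
  # C.C mismatch in the T(C.C)T motif at 25 C, salt-free: the two mismatch
  # stacks TC/AC and AC/TC (read 5'->3' on each strand) replace the two
  # Watson-Crick stacks TC/AG and CT/GA
  mm_hand <- (dg25(6.1, 16.4) + dg25(0.0, -4.4)) -
    (dg25(-8.2, -22.2) + dg25(-7.8, -21.0))
  sys <- design_system(7)
  ref <- design_system(NULL)
  nn0 <- nn_params(salt = NULL)
  ddg <- reaction_delta_g(sys, nn0) - reaction_delta_g(ref, nn0)
  expect_equal(ddg, -mm_hand, tolerance = 1e-9)
  # salt correction cancels in the difference
  ddg_salt <- reaction_delta_g(sys, nn_buf) - reaction_delta_g(ref, nn_buf)
  expect_equal(ddg_salt, ddg, tolerance = 1e-9)
})

test_that("uniform-sequence branch-migration plateau is flat", {
  n_dom <- 20
  target <- paste(rep("A", 24), collapse = "")
  sys <- displacement_system(target, paste(rep("T", n_dom), collapse = ""),
                             toehold_length = 4)
  prof <- displacement_profile(sys, nn_ref, f_max = 0, dg_plateau = 0,
                               dg_sawtooth = 0)
  g <- prof$G_kBT
  steps <- diff(g)[5:(length(g) - 2)] # interior branch-migration steps
  expect_lt(max(abs(steps)), 1e-9)
})

test_that("profile endpoints agree with independent duplex energies", {
  kbt <- kcal_per_kbt(25)
  for (sys in list(ref_system, sys_x7)) {
    prof <- displacement_profile(sys, nn_buf, f_max = 0, dg_plateau = 0)
    n_max <- max(prof$n)
    d_it_full <- duplex_free_energy(substr(sys$target, 1, n_max),
                                    dna_reverse_complement(
                                      substr(sys$target, 1, n_max)),
                                    nn_buf, 25)
    d_it_1 <- duplex_free_energy(substr(sys$target, 1, 1),
                                 dna_complement(substr(sys$target, 1, 1)),
                                 nn_buf, 25)
    d_ot_full <- duplex_free_energy(sys$domain, sys$incumbent, nn_buf, 25)
    # remaining O.T at the top state: nothing (mismatch-free) or the final bp
    m_top <- n_max - sys$toehold_length
    d_ot_rem <- if (m_top >= sys$domain_length) 0 else {
      s <- substr(sys$domain, m_top + 1, sys$domain_length)
      duplex_free_energy(s, dna_reverse_complement(s), nn_buf, 25)
    }
    oracle <- (d_it_full + d_ot_rem - d_it_1 - d_ot_full) / kbt
    expect_equal(prof$G_kBT[n_max], oracle, tolerance = 1e-9)
  }
})

test_that("a position-2 mismatch gives a smaller overall drop than deeper ones", {
  drops <- vapply(c(2, 3, 5, 7, 10, 13, 15, 17), function(x) {
    prof <- displacement_profile(design_system(x), nn_buf, f_max = 1)
    prof$G_kBT[nrow(prof)]
  }, numeric(1))
  expect_true(all(abs(drops[1]) < abs(drops[-1])))
})

test_that("the mismatch drop starts at enclosure without fraying, earlier with", {
  x <- 7
  sys <- design_system(x)
  # same sequences with the mismatch removed (fully complementary incumbent)
  sys0 <- displacement_system(sys$target,
                              dna_reverse_complement(sys$domain),
                              toehold_length = sys$toehold_length)
  h <- sys$toehold_length
  for (fm in c(0, 1)) {
    p_mm <- displacement_profile(sys, nn_buf, f_max = fm)
    p_0 <- displacement_profile(sys0, nn_buf, f_max = fm)
    dev <- p_mm$G_kBT - p_0$G_kBT[seq_len(nrow(p_mm))]
    first <- min(which(abs(dev) > 1e-6))
    if (fm == 0) expect_equal(first, h + x) else expect_lt(first, h + x)
  }
})

test_that("removing the mismatch reproduces the mismatch-free profile bit-identically", {
  sys0 <- displacement_system(ref_system$target, ref_system$incumbent,
                              toehold_length = 4, mismatch_position = NULL)
  p1 <- displacement_profile(ref_system, nn_buf)
  p2 <- displacement_profile(sys0, nn_buf)
  expect_identical(p1$G_kBT, p2$G_kBT)
})

test_that("degenerate and invalid systems are rejected", {
  expect_error(displacement_system("ACTCA", "T", toehold_length = 4),
               "domain of >= 2")
  expect_error(displacement_system("ACTCCA", "TG", toehold_length = 4,
                                   mismatch_position = 5),
               "must lie in 1..2")
  expect_error(
    displacement_system(ref_system$target,
                        sub("T", "G", ref_system$incumbent)),
    "no mismatch_position was declared"
  )
})
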