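# Mass-action networks: simulation against closed forms, circuit builders,
# normalization and least-squares fitting.

test_that("an irreversible bimolecular reaction matches the closed form", {
  a0 <- 1e-8; b0 <- 2.5e-8; k <- 1e5
  net <- reaction_network(
    c(A = a0, B = b0, C = 0),
    tibble::tibble(reactants = list(c("A", "B")), products = list("C"),
                   k = k)
  )
  tt <- seq(60, 36000, by = 300)
  sim <- simulate_network(net, tt)
  # textbook second-order solution for unequal initial concentrations
  x <- a0 * b0 * (1 - exp(-(b0 - a0) * k * tt)) /
    (b0 - a0 * exp(-(b0 - a0) * k * tt))
  expect_lt(max(abs(sim$C - x) / a0), 1e-8)
})

test_that("zero rate constants freeze the trajectories", {
  net <- reaction_network(
    c(A = 1e-8, B = 2e-8, C = 0),
    tibble::tibble(reactants = list(c("A", "B")), products = list("C"),
                   k = 0)
  )
  sim <- simulate_network(net, c(60, 600, 6000))
  expect_true(all(sim$A == 1e-8 & sim$B == 2e-8 & sim$C == 0))
})

test_that("a reversible reaction relaxes to detailed balance", {
  kf <- 1e6; kr <- 1e-3
  net <- reaction_network(
    c(A = 2e-8, B = 5e-8, C = 0),
    tibble::tibble(reactants = list(c("A", "B"), "C"),
                   products = list("C", c("A", "B")), k = c(kf, kr))
  )
  eq <- simulate_network(net, c(1, 1e7))
  last <- eq[nrow(eq), ]
  expect_equal(last$C / (last$A * last$B), kf / kr, tolerance = 1e-3)
})

test_that("network validation rejects malformed inputs", {
  expect_error(reaction_network(
    c(A = 1e-9),
    tibble::tibble(reactants = list("A"), products = list("Z"), k = 1)),
    "undeclared species")
  expect_error(reaction_network(
    c(A = 1e-9, B = 1e-9),
    tibble::tibble(reactants = list(c("A", "A", "B")), products = list("B"),
                   k = 1)), "bimolecular")
  expect_error(reaction_network(
    c(A = 1e-9), tibble::tibble(reactants = list("A"), products = list("A"),
                                k = -1)), ">= 0")
})

test_that("strand totals are conserved in every preset circuit", {
  tt <- seq(60, 3e4, by = 600)
  nets <- list(build_rate_assay_model(2.6e3, "explicit"),
               build_catalytic_model(), build_pulse_model())
  for (net in nets) {
    sim <- simulate_network(net, tt)
    totals <- conservation_totals(net, sim)
    drift <- sweep(as.matrix(totals[, -1]), 2,
                   as.matrix(totals[1, -1]), "/") - 1
    expect_lt(max(abs(drift)), 1e-9)
  }
})

test_that("rate-assay presets come from the reported mixing volumes", {
  cc <- rate_assay_concentrations()
  # 2.4 uL of 10 uM into 1.92 mL; 2.4 uL of 20 uM into 1.92 mL
  expect_equal(unname(cc["OT"]), 12.5e-9, tolerance = 1e-12)
  expect_equal(unname(cc["I"]), 12.5e-9, tolerance = 1e-12)
  expect_equal(unname(cc["Rep"]), 25e-9, tolerance = 1e-12)
})

test_that("a fast explicit reporter reproduces the instantaneous limit", {
  tt <- seq(60, 500 * 60, by = 60)
  s_inst <- simulate_network(build_rate_assay_model(2.6e3), tt)$signal
  s_expl <- simulate_network(
    build_rate_assay_model(2.6e3, "explicit", k_rep = 1e6), tt)$signal
  expect_lt(max(abs(s_expl - s_inst)) / max(s_inst), 0.02)
  # no substrate, no signal
  cc <- rate_assay_concentrations(); cc["OT"] <- 0
  s0 <- simulate_network(build_rate_assay_model(2.6e3, concentrations = cc),
                         tt)$signal
  expect_true(all(s0 == 0))
})

test_that("catalytic circuit shows catalysis, leak control and completion", {
  tt <- seq(60, 500 * 60, by = 60)
  sig <- function(net) simulate_network(net, tt)$signal
  bd0 <- catalytic_concentrations()[["BD"]]
  no_path <- sig(build_catalytic_model(
    k_leak = 0, concentrations = catalytic_concentrations(a = 0)))
  expect_true(all(no_path == 0)) # no catalyst, no leak: no route to product
  leak <- sig(build_catalytic_model(
    concentrations = catalytic_concentrations(a = 0)))
  c2 <- sig(build_catalytic_model(
    k_leak = 3e3, concentrations = catalytic_concentrations(a = 0)))
  expect_true(all(c2 > leak)) # extra toehold base pairs boost the leak
  catalysed <- sig(build_catalytic_model())
  expect_gt(catalysed[length(tt)], leak[length(tt)])
  # symmetric exchange with the reporter sink drives conversion to completion
  expect_gt(catalysed[length(tt)] / bd0, 0.99)
  # hidden drive: biasing the second exchange step raises catalysed yield
  driven <- sig(build_catalytic_model(k2r = 10))
  expect_gt(driven[length(tt)], catalysed[length(tt)])
})

test_that("the pulse circuit peaks and relaxes to a rescaling-invariant equilibrium", {
  tt <- seq(60, 3e5, by = 120)
  sim <- simulate_network(build_pulse_model(), tt)
  i_peak <- which.max(sim$I3T)
  expect_gt(i_peak, 1)
  expect_lt(i_peak, nrow(sim)) # strict interior maximum
  expect_lt(sim$I3T[nrow(sim)], max(sim$I3T)) # decays below the peak
  expect_gt(sim$I5T[nrow(sim)], sim$I3T[nrow(sim)]) # I5.T-biased equilibrium
  # uniform 10x rescaling leaves the equilibrium unchanged
  sim10 <- simulate_network(
    build_pulse_model(k3 = 2e6, k5 = 1e5, k_ex = 1e5), tt)
  expect_equal(sim10$I3T[nrow(sim10)], sim$I3T[nrow(sim)],
               tolerance = 1e-6)
  # fully symmetric rates and equal invader concentrations: equal channels
  conc <- c(OT = 12.5e-9, I3 = 25e-9, I5 = 25e-9)
  sym <- simulate_network(
    build_pulse_model(k3 = 1e5, k5 = 1e5, k_ex = 1e4, K3 = 5e3, K5 = 5e3,
                      concentrations = conc), tt)
  expect_lt(max(abs(sym$I3T - sym$I5T)) / max(sym$I3T), 1e-8)
  # inconsistent reverse rates trigger a cycle-closure warning
  expect_warning(build_pulse_model(k_exr = 5), "cycle closure")
})

test_that("normalization follows the fractional-recovery definition", {
  tr <- tmsd_trace(time_s = seq(0, 600, 60),
                   signal = c(1, 1, 1, 2, 5, 8, 9, 10, 10, 10, 10))
  nt <- normalize_trace(tr, baseline_window = c(0, 120),
                        max_window = c(480, 600))
  expect_equal(nt$signal[1], 0)
  expect_true(all(abs(nt$signal[8:11] - 1) < 1e-12))
  # affine invariance
  tr2 <- tr; tr2$signal <- 3.7 * tr$signal - 12
  nt2 <- normalize_trace(tr2, c(0, 120), c(480, 600))
  expect_equal(nt2$signal, nt$signal, tolerance = 1e-12)
  flat <- tmsd_trace(time_s = seq(0, 600, 60), signal = rep(4, 11))
  expect_error(normalize_trace(flat, c(0, 120), c(480, 600)),
               "Fmax equals Fmin")
})

test_that("normalized catalytic signal tracks the fractional conversion of B", {
  tt <- seq(60, 500 * 60, by = 60)
  net <- build_catalytic_model()
  sim <- simulate_network(net, tt)
  tr <- tmsd_trace(time_s = tt, signal = sim$signal)
  nt <- normalize_trace(tr, baseline_window = c(60, 60),
                        max_window = c(tt[length(tt)], tt[length(tt)]))
  conv <- (sim$F - sim$F[1]) / (sim$F[length(tt)] - sim$F[1])
  expect_lt(max(abs(nt$signal - conv)), 1e-9)
})

test_that("the fitter recovers known constants and is deterministic", {
  k_true <- 1.8e5
  net <- build_rate_assay_model(k_true)
  tr <- generate_trace(net, t_end = 150 * 60, noise = noise_model())
  tr$signal <- tr$noiseless
  fit <- fit_rate_constant(tr, build_rate_assay_model,
                           free_parameters = c(k_disp = 1e4),
                           model_id = "rate_assay")
  expect_true(fit$converged)
  expect_lt(abs(tidy(fit)$estimate - k_true) / k_true, 0.01)
  # bit-identical repeat
  fit2 <- fit_rate_constant(tr, build_rate_assay_model,
                            free_parameters = c(k_disp = 1e4),
                            model_id = "rate_assay")
  expect_identical(tidy(fit), tidy(fit2))
  expect_equal(glance(fit)$n_obs, nrow(tr))
  expect_error(
    fit_rate_constant(tr[1:2, ], build_rate_assay_model,
                      free_parameters = c(k_disp = 1e4)),
    "at least as many data points")
})

test_that("fitted constants show no systematic bias under 2% Gaussian noise", {
  k_true <- 1.8e5
  net <- build_rate_assay_model(k_true)
  full_scale <- rate_assay_concentrations()[["OT"]]
  ests <- vapply(1:50, function(s) {
    tr <- generate_trace(net, t_end = 150 * 60,
                         noise = noise_model(sigma_abs = 0.02 * full_scale,
                                             seed = s))
    fit <- fit_rate_constant(tr, build_rate_assay_model,
                             free_parameters = c(k_disp = 3e5),
                             multi_start = 1)
    tidy(fit)$estimate
  }, numeric(1))
  se_mean <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - k_true), 2 * se_mean)
})
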