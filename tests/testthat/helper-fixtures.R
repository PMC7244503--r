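# shared fixtures: parameter sets, study systems and chains.
# built once per test run; everything is generated in code.

nn_ref <- nn_params(salt = NULL) # 1 M NaCl reference, used for hand sums
nn_buf <- nn_params()            # default fluorometry-buffer salt model

ref_system <- design_system(NULL)
sys_x2 <- design_system(2)
sys_x3 <- design_system(3)
sys_x7 <- design_system(7)
sys_x15 <- design_system(15)

default_rp <- landscape_params()

fixture_chains <- function() {
  rp <- default_rp
  list(
    reference = tmsd:::.system_chain(ref_system, rp),
    mismatch_x3 = tmsd:::.system_chain(sys_x3, rp),
    mismatch_x7 = tmsd:::.system_chain(sys_x7, rp),
    mismatch_x15 = tmsd:::.system_chain(sys_x15, rp),
    ruin_flat = chain_from_energies(rep(0, 8), k_bm = 1, k_off = 1)
  )
}

# 25 C free-energy of a tabulated (dh, ds) entry
dg25 <- function(dh, ds) dh - 298.15 * ds / 1000
dg37 <- function(dh, ds) dh - 310.15 * ds / 1000
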