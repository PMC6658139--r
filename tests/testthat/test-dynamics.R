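test_that("Monod rate: half-saturation, zero, and null-affinity behavior", {
  expect_equal(monod_rate(1, 0.3, 1), 0.15)          # R = K
  expect_equal(monod_rate(0, 0.3, 5), 0)
  expect_equal(monod_rate(1, 0.25, 1), 0.125)        # ancestral H at R = K
  expect_equal(monod_rate(10, 0.3, 0), 0)            # null affinity, K -> Inf
  expect_error(monod_rate(-1, 0.3, 1), "negative")
})

test_that("Mankad-Bungay rate: half-max crossing, Monod limit, zeros", {
  g <- 0.7
  # R_M = B_M = 1 gives gmax/2 (the feature distinguishing it from
  # multiplicative double-Monod, which would give gmax/4)
  expect_equal(mankad_bungay_rate(1, 1, g, 1, 1), g / 2)
  # saturating Byproduct recovers Monod kinetics in R
  RM <- 0.37
  expect_equal(mankad_bungay_rate(RM, 1e9, g, 1, 1), g * RM / (RM + 1),
               tolerance = 1e-6)
  expect_equal(mankad_bungay_rate(0, 1, g, 3, 0.03), 0)
  expect_equal(mankad_bungay_rate(1, 0, g, 3, 0.03), 0)
  expect_equal(mankad_bungay_rate(1, 1, g, 0, 0.03), 0)  # null affinity
  expect_error(mankad_bungay_rate(1, -1, g, 1, 1), "negative")
})

test_that("Mankad-Bungay rate: monotone where substrates are balanced or
           limiting, non-monotone past the anomaly point", {
  # more of the scarcer substrate never hurts: monotone while the varied
  # scaled substrate stays below the co-substrate's level
  for (BM in c(1.5, 6)) {
    R_grid <- seq(0, BM / 3, length.out = 40)  # R_M = 3 R <= B_M
    r <- mankad_bungay_rate(R_grid, BM / 0.03, 0.7, 3, 0.03)
    expect_true(all(diff(r) >= -1e-12))
  }
  for (RM in c(1.5, 6)) {
    B_grid <- seq(0, RM / 0.03, length.out = 40) # B_M <= R_M
    r <- mankad_bungay_rate(RM / 3, B_grid, 0.7, 3, 0.03)
    expect_true(all(diff(r) >= -1e-12))
  }
  # but when the other substrate is scarce the rate peaks and then falls
  # (the same structure as the affinity anomaly below)
  r_anom <- mankad_bungay_rate(seq(0.1, 40, by = 0.1), 0.3, 0.7, 3, 0.03)
  expect_lt(which.max(r_anom), length(r_anom))
})

test_that("affinity anomaly: dg/dK_MR changes sign with substrate balance", {
  # finite differences in K_MR at fixed R and B
  g_at <- function(KMR, R, B) {
    mankad_bungay_rate(R, B, g_max = 0.7, aff_MR = 1 / KMR, aff_MB = 1)
  }
  h <- 1e-6
  # R_M = 100 >> 1 >> B_M = 0.01: lower affinity (bigger K) grows faster
  d1 <- (g_at(1 + h, 100, 0.01) - g_at(1 - h, 100, 0.01)) / (2 * h)
  expect_gt(d1, 0)
  # R_M = 0.01 << 1 << B_M = 100: the familiar case, affinity helps
  d2 <- (g_at(1 + h, 0.01, 100) - g_at(1 - h, 0.01, 100)) / (2 * h)
  expect_lt(d2, 0)
})

test_that("Byproduct inhibition factor", {
  expect_equal(h_inhibition_factor(0, 100), 1)
  expect_equal(h_inhibition_factor(100, 100), exp(-1))
  expect_equal(h_inhibition_factor(c(0, 50, 1e6)), c(1, 1, 1)) # commensal
  expect_error(h_inhibition_factor(1, -2), "positive")
})

test_that("chemical step: empty community leaves chemicals unchanged", {
  grp <- data.frame(species = integer(), gmax = numeric(), affR = numeric(),
                    affB = numeric(), biomass = numeric())
  res <- integrate_chem_step(c(R = 0.7, B = 3, P = 5), grp, 0.05, pre)
  expect_equal(res$chem, c(R = 0.7, B = 3, P = 5))
  expect_length(res$integrals, 0)
})

test_that("chemical step matches a fine-step Euler oracle (H only)", {
  grp <- data.frame(species = 1L, gmax = 0.3, affR = 5, affB = 0,
                    biomass = 500)
  res <- integrate_chem_step(c(R = 0.5, B = 0.2, P = 0), grp, 0.05, pre)
  # independent oracle: explicit Euler at dt = 1e-6
  R <- 0.5; B <- 0.2; I <- 0; dt <- 1e-6
  for (i in seq_len(5e4)) {
    g <- 0.3 * R * 5 / (R * 5 + 1)
    R <- R - pre$cRH * g * 500 * dt
    B <- B + g * 500 * dt
    I <- I + g * dt
  }
  expect_equal(res$chem[["R"]], R, tolerance = 1e-6)
  expect_equal(res$chem[["B"]], B, tolerance = 1e-6)
  expect_equal(res$integrals, I, tolerance = 1e-6)
  # with M absent, Byproduct release balances Resource drawdown exactly
  expect_equal(res$chem[["B"]] - 0.2, (0.5 - res$chem[["R"]]) / pre$cRH,
               tolerance = 1e-8)
})

test_that("chemical step converges under tolerance refinement", {
  grp <- data.frame(species = c(1L, 2L), gmax = c(0.3, 0.7),
                    affR = c(5, 3), affB = c(0, 0.03),
                    biomass = c(1500, 2500))
  a <- integrate_chem_step(c(R = 0.3, B = 6, P = 0), grp, 0.05, pre,
                           rtol = 1e-6, atol = 1e-9)
  b <- integrate_chem_step(c(R = 0.3, B = 6, P = 0), grp, 0.05, pre,
                           rtol = 1e-7, atol = 1e-10)
  expect_equal(a$chem, b$chem, tolerance = 1e-5)
  expect_equal(a$integrals, b$integrals, tolerance = 1e-5)
})

test_that("deterministic trajectory: no cost, no Product; states stay >= 0", {
  tr <- deterministic_trajectory(40, 60, pre, fP = 0, T = 17,
                                 times = seq(0, 17, by = 1))
  expect_equal(max(tr[, "P"]), 0)
  expect_true(all(tr[, -1] >= 0))
  expect_true(all(diff(tr[, "P"]) >= 0))
})

test_that("deterministic trajectory obeys conservation identities at
           zero death", {
  fP <- 0.25
  tr <- deterministic_trajectory(40, 60, no_death, fP = fP, T = 17)
  fin <- tr[nrow(tr), ]
  dH <- fin[["H"]] - 40
  dM <- fin[["M"]] - 60
  # Resource budget: consumption tracks potential (not realized) growth
  expect_equal(1 - fin[["R"]],
               no_death$cRH * dH + no_death$cRM * dM / (1 - fP),
               tolerance = 1e-5)
  # Byproduct budget
  expect_equal(fin[["B"]], dH - no_death$cBM * dM / (1 - fP),
               tolerance = 1e-4)
})

test_that("compiled RHS agrees with a plain-R implementation of the same
           equations", {
  rhs_r <- function(t, y, pr) {
    H <- y[1]; M <- y[2]; R <- max(y[3], 0); B <- max(y[4], 0)
    gH <- monod_rate(R, pr$gHmax, pr$affHR)
    gM <- mankad_bungay_rate(R, B, pr$gMmax, pr$affMR, pr$affMB)
    fP <- 0.3
    list(c(gH * H - pr$deltaH * H, (1 - fP) * gM * M - pr$deltaM * M,
           -pr$cRM * gM * M - pr$cRH * gH * H, gH * H - pr$cBM * gM * M,
           fP * gM * M))
  }
  ref <- deSolve::lsoda(c(H = 40, M = 60, R = 1, B = 0, P = 0), c(0, 17),
                        rhs_r, pre, rtol = 1e-8, atol = 1e-10)
  tr <- deterministic_trajectory(40, 60, pre, fP = 0.3, T = 17)
  expect_equal(unname(tr[2, -1]), unname(ref[2, -1]), tolerance = 1e-5)
})

test_that("mutualistic model: Byproduct inhibition slows H", {
  com <- deterministic_trajectory(40, 60, pre, fP = 0.13, T = 17)
  mut_p <- hm_params(B0 = 2 * 100 / 3) # B0 = 2 K_MB
  mu <- deterministic_trajectory(40, 60, mut_p, fP = 0.13, T = 17)
  expect_lt(mu[nrow(mu), "H"], com[nrow(com), "H"])
})
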