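test_that("growth step: closed-form length and Product updates", {
  cells <- rbind(
    data.frame(species = 1L, L = 1, gmax = 0.3, affR = 5, affB = NA_real_,
               fP = NA_real_),
    data.frame(species = 2L, L = 1, gmax = 0.7, affR = 3, affB = 0.03,
               fP = 0.5),
    data.frame(species = 2L, L = 1.4, gmax = 0.7, affR = 3, affB = 0.03,
               fP = 0))
  comm <- community(cells, chem = c(R = 1, B = 1, P = 0))
  # groups: one H, one M (both M cells share growth parameters)
  out <- apply_growth(comm, integrals = c(log(2), 0.2), c(1L, 2L, 2L))
  expect_equal(out$cells$L[1], 2)                       # exp(ln 2)
  expect_equal(out$cells$L[2], exp(0.1))                # (1 - fP) int g
  expect_equal(out$cells$L[3], 1.4 * exp(0.2))          # fP = 0, full growth
  expect_equal(out$chem[["P"]], 1 * (exp(0.1) - 1))     # only the fP=0.5 cell
})

test_that("growth step: fP = 1 limit makes Product, not biomass", {
  cells <- data.frame(species = 2L, L = 1.3, gmax = 0.7, affR = 3,
                      affB = 0.03, fP = 1)
  comm <- community(cells, chem = c(R = 1, B = 1, P = 0))
  out <- apply_growth(comm, integrals = 0.25, 1L)
  expect_equal(out$cells$L, 1.3)
  expect_equal(out$chem[["P"]], 1.3 * 0.25)
})

test_that("death step: boundary probabilities and binomial counts", {
  comm <- unit_adult(0, 1e5)
  expect_identical(apply_death(comm, 0.05, no_death)$cells, comm$cells)
  all_die <- hm_params(deltaM = 20, deltaH = 20) # delta * dtau = 1
  dead <- apply_death(comm, 0.05, all_die)
  expect_equal(nrow(dead$cells), 0L)
  expect_true(dead$extinct)
  # delta_M dtau = 1.75e-4: deaths within 5 binomial SDs of the mean
  set.seed(5)
  n_dead <- 1e5 - nrow(apply_death(comm, 0.05, pre)$cells)
  mu <- 1e5 * pre$deltaM * 0.05
  expect_lt(abs(n_dead - mu), 5 * sqrt(mu * (1 - pre$deltaM * 0.05)))
})

test_that("division: halving, threshold, conservation, daughter placement", {
  cells <- rbind(
    data.frame(species = 1L, L = 2.2, gmax = 0.3, affR = 5, affB = NA_real_,
               fP = NA_real_),
    data.frame(species = 2L, L = 1.9, gmax = 0.7, affR = 3, affB = 0.03,
               fP = 0.13))
  comm <- community(cells, chem = c(R = 1, B = 0, P = 0))
  dv <- apply_division(comm)
  expect_equal(nrow(dv$comm$cells), 3L)
  expect_equal(dv$comm$cells$L, c(1.1, 1.1, 1.9))
  expect_equal(dv$divided, c(1L, 2L))      # mother then daughter
  expect_equal(sum(dv$comm$cells$L), sum(cells$L))  # biomass conserved
})

test_that("maturation: T = 0 is the identity and replay is bit-identical", {
  nb <- make_fixture("monomorphic_newborn")
  a0 <- mature(nb, pre, mut_off, T = 0, seed = 3)
  expect_equal(a0$cells, nb$cells)
  expect_equal(a0$chem, nb$chem)
  m <- mutation_model(P_mut = 0.05, mutable = c("gMmax", "fP"))
  a1 <- mature(nb, pre, m, T = 5, seed = 11)
  a2 <- mature(nb, pre, m, T = 5, seed = 11)
  expect_identical(a1$cells, a2$cells)
  expect_identical(a1$chem, a2$chem)
})

test_that("maturation tracks the coupled ODE within 1% (operator-splitting
           discrepancy only)", {
  nb <- make_fixture("monomorphic_newborn")
  # with death disabled the comparison is exact up to splitting error
  tr <- deterministic_trajectory(40, 60, no_death, fP = 0.13, T = 17)
  fin <- tr[nrow(tr), ]
  ad <- mature(nb, no_death, mut_off, T = 17, seed = 1)
  expect_equal(biomass(ad), fin[["H"]] + fin[["M"]], tolerance = 0.01)
  expect_equal(ad$chem[["P"]], fin[["P"]], tolerance = 0.01)
  # full preadapted scenario, stochastic death on
  tr2 <- deterministic_trajectory(40, 60, pre, fP = 0.13, T = 17)
  fin2 <- tr2[nrow(tr2), ]
  ad2 <- mature(nb, pre, mut_off, T = 17, seed = 2)
  expect_equal(biomass(ad2), fin2[["H"]] + fin2[["M"]], tolerance = 0.01)
  expect_equal(ad2$chem[["P"]], fin2[["P"]], tolerance = 0.01)
  expect_equal(phi_M(ad2), fin2[["M"]] / (fin2[["H"]] + fin2[["M"]]),
               tolerance = 0.01)
})

test_that("with death off, Product equals the per-cell fP/(1-fP) biomass
           ledger", {
  nb <- make_fixture("monomorphic_newborn")
  ad <- mature(nb, no_death, mut_off, T = 17, seed = 1)
  M0 <- 60
  MT <- sum(ad$cells$L[ad$cells$species == 2L])
  expect_equal(ad$chem[["P"]], 0.13 / 0.87 * (MT - M0), tolerance = 1e-6)
})

test_that("compiled maturation equals the R-composed step pipeline,
           draw for draw", {
  nb <- make_fixture("two_phenotype_newborn")
  m <- mutation_model(P_mut = 0.2,
                      mutable = c("gHmax", "gMmax", "affMB", "fP"))
  a_cpp <- mature(nb, pre, m, T = 3, seed = 17)
  a_r <- commsel:::mature_r(nb, pre, m, T = 3, seed = 17)
  expect_equal(nrow(a_cpp$cells), nrow(a_r$cells))
  expect_equal(a_cpp$cells$L, a_r$cells$L, tolerance = 1e-12)
  expect_equal(a_cpp$cells$fP, a_r$cells$fP, tolerance = 1e-12)
  expect_equal(a_cpp$cells$gmax, a_r$cells$gmax, tolerance = 1e-12)
  expect_equal(a_cpp$chem, a_r$chem, tolerance = 1e-12)
})

test_that("extinct community is flagged and chemicals persist", {
  nb <- founder_community(hm_params(deltaM = 20, deltaH = 20), 5, 5, R0 = 1)
  ad <- mature(nb, hm_params(deltaM = 20, deltaH = 20), mut_off, T = 1,
               seed = 1)
  expect_true(ad$extinct)
  expect_equal(nrow(ad$cells), 0L)
  expect_gt(ad$chem[["R"]], 0.99) # nearly untouched after one step's growth
})

test_that("Adult with zero cost everywhere accumulates no Product", {
  nb <- founder_community(pre, 40, 60, R0 = 1, fP = 0)
  ad <- mature(nb, pre, mut_off, T = 17, seed = 4)
  expect_equal(ad$chem[["P"]], 0)
})
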