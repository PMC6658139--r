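test_that("community function definitions and edge cases", {
  nb <- founder_community(pre, 40, 60, R0 = 1, fP = 0)
  ad0 <- mature(nb, pre, mut_off, T = 17, seed = 1)
  expect_equal(community_function(ad0, "total_product"), 0)
  # per-M-biomass function approaches fP/(1-fP) once M(T) >> M(0)
  nb2 <- make_fixture("monomorphic_newborn")
  ad <- mature(nb2, no_death, mut_off, T = 17, seed = 2)
  expect_equal(community_function(ad, "product_per_M"), 0.13 / 0.87,
               tolerance = 0.02)
  # extinct M: undefined score
  exm <- make_fixture("extinct_M")
  exm$chem[["P"]] <- 5
  expect_true(is.na(community_function(exm, "product_per_M")))
  expect_equal(community_function(exm, "total_product"), 5)
})

test_that("measurement noise: identity at zero, calibrated moments", {
  expect_identical(add_measurement_noise(3.2, 0, 800), 3.2)
  set.seed(20)
  x <- add_measurement_noise(rep(100, 1e5), 0.05, 800)
  expect_lt(abs(mean(x) - 100), 5 * 0.05 * 800 / sqrt(1e5))
  expect_equal(sd(x), 0.05 * 800, tolerance = 0.02)
})

test_that("top-dog allocation: greedy fill, trimming, ties by index", {
  cfg <- selection_config(n_tot = 3, n_cycles = 1)
  plan <- choose_and_allocate(c(5, 3, 1), capacity = c(2, 2, 2), cfg)
  expect_equal(plan$adult, c(1L, 2L))
  expect_equal(plan$quota, c(2L, 1L))   # third Adult contributes nothing
  # tie broken toward the lower community index
  plan2 <- choose_and_allocate(c(4, 4, 1), capacity = c(2, 2, 2), cfg)
  expect_equal(plan2$adult[1], 1L)
  expect_error(choose_and_allocate(c(5, 3), capacity = c(1, 1), cfg),
               class = "commsel_extinction")
})

test_that("top-tier allocation: equal quotas; full-population tier means
           one Newborn each", {
  cfg <- selection_config(n_tot = 100, n_chosen = 10, strategy = "top_tier")
  plan <- choose_and_allocate(runif(100), capacity = rep(70, 100), cfg)
  expect_equal(nrow(plan), 10L)
  expect_true(all(plan$quota == 10))
  cfg2 <- selection_config(n_tot = 20, n_chosen = 20, strategy = "top_tier")
  plan2 <- choose_and_allocate(runif(20), capacity = rep(70, 20), cfg2)
  expect_true(all(plan2$quota == 1))
  expect_equal(sort(plan2$adult), 1:20)
})

test_that("selection runs are reproducible and respect n_cycles = 0", {
  cfg <- selection_config(n_tot = 4, n_cycles = 2, master_seed = 5)
  r1 <- run_selection(cfg)
  r2 <- run_selection(cfg)
  expect_identical(r1$records, r2$records)
  expect_equal(nrow(r1$records[r1$records$cycle == 1, ]) >= 1, TRUE)
  cfg0 <- selection_config(n_tot = 4, n_cycles = 0)
  expect_equal(nrow(run_selection(cfg0)$records), 0L)
})

test_that("aggregates are recomputable from the per-Adult rows", {
  cfg <- selection_config(n_tot = 4, n_cycles = 2, master_seed = 6)
  run <- run_selection(cfg)
  agg <- aggregate(cbind(P_T, mean_fP) ~ cycle, run$records, mean)
  expect_equal(run$aggregates$Pbar_T, agg$P_T)
  expect_equal(run$aggregates$fPbar_T, agg$mean_fP)
})

test_that("pregrowth: no conversions at zero probability; population size
           and ordering of variants", {
  set.seed(30)
  p0 <- pregrow_founder(p_conv = 0)
  expect_equal(p0$nulls, 0)
  expect_equal(p0$contributors, 2^23)
  # total population ~ 2^23 within branching fluctuation
  set.seed(31)
  p1 <- pregrow_founder()
  expect_equal(p1$contributors + p1$nulls, 2^23, tolerance = 0.2)
  # mother+daughter conversion loads about twice the null mass
  set.seed(32)
  fr_d <- mean(replicate(200, pregrow_founder()$null_fraction))
  set.seed(32)
  fr_b <- mean(replicate(200,
                         pregrow_founder(convert = "both")$null_fraction))
  expect_gt(fr_b, fr_d)
})

test_that("pregrowth-founded runs carry null M cells into cycle 1", {
  cfg <- selection_config(n_tot = 6, n_cycles = 1, master_seed = 9,
                          pregrowth = TRUE)
  run <- run_selection(cfg)
  expect_s3_class(run, "commsel_run")
  expect_equal(nrow(run$aggregates), 1L)
})

test_that("monoculture group selection: flat trajectory without mutation", {
  cfg <- selection_config(n_tot = 5, n_cycles = 3, master_seed = 7,
                          mut = mut_off, monoculture = TRUE)
  run <- run_group_selection(cfg)
  expect_true(all(abs(run$aggregates$fPbar_T - 0.13) < 1e-12))
  # groups grow: Product accumulates in every cycle
  expect_true(all(run$aggregates$Pbar_T > 0))
})

test_that("monoculture group selection drives growth parameters toward
           their evolutionary upper bounds", {
  cfg <- selection_config(n_tot = 15, n_cycles = 25, master_seed = 11,
                          params = hm_params("ancestral"),
                          mut = mutation_model(mutable = c("gMmax",
                                                           "affMR")),
                          monoculture = TRUE)
  r <- run_group_selection(cfg)
  last <- r$records[r$records$cycle == 25, ]
  expect_gt(mean(last$mean_gMmax), 0.65)  # from the ancestral 0.58
  expect_lte(max(last$mean_gMmax), 0.7)   # never beyond the bound
  expect_gt(mean(last$mean_affMR), 1.05)  # affinity rising from 1
  # cost untouched: fP is not in the mutable set
  expect_true(all(last$mean_fP == 0.1))
})
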