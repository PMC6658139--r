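#' Community function of a matured Adult
#'
#' `"total_product"` scores the total Product accumulated by time `T`,
#' `P(T)`; `"product_per_M"` scores `P(T)/M(T)` and is undefined (`NA`,
#' ranked below every defined score) when M is extinct.
#'
#' @param adult a matured `community`.
#' @param def `"total_product"` or `"product_per_M"`.
#' @return A numeric score (possibly `NA`).
#' @export
community_function <- function(adult, def = c("total_product",
                                              "product_per_M")) {
  def <- match.arg(def)
  P <- adult$chem[["P"]]
  if (def == "total_product") return(P)
  M <- sum(adult$cells$L[adult$cells$species == 2L])
  if (M <= 0) return(NA_real_)
  P / M
}

#' Add measurement noise to a community-function score
#'
#' Gaussian noise with zero mean and standard deviation
#' `noise_sd_frac * P_ancestral`, where `P_ancestral` is the deterministic
#' `P(T)` of the run's founding configuration (computed once per run). The
#' noisy score may be negative.
#'
#' @param score clean score(s).
#' @param noise_sd_frac noise level (0 returns the input unchanged).
#' @param P_ancestral ancestral community function setting the noise scale.
#' @return Noisy score(s).
#' @export
add_measurement_noise <- function(score, noise_sd_frac, P_ancestral) {
  if (noise_sd_frac == 0) return(score)
  score + stats::rnorm(length(score), 0, noise_sd_frac * P_ancestral)
}

#' Rank Adults and allocate Newborn quotas
#'
#' Implements the intercommunity selection strategies. `top_dog`: the
#' highest-scoring Adult contributes all the Newborns it can
#' (`floor(BM/BM_target)`, or the fixed fold), then the runner-up, until
#' `n_tot` is reached; the final Adult's batch is trimmed (a uniform random
#' subset is taken from it at partition time). `top_tier`: the best
#' `n_chosen` Adults contribute exactly `n_tot / n_chosen` each.
#' `random_control`: as top-dog but with Adults in uniform random order.
#' Ties are broken by lower community index; `NA` scores rank last.
#'
#' @param scores numeric scores, one per Adult (`NA` allowed).
#' @param capacity Newborns each Adult can produce.
#' @param config a [selection_config()].
#' @return Data frame with columns `adult` (index) and `quota`, quotas
#'   summing to `n_tot`; errors with class `commsel_extinction` if the
#'   available Newborns cannot reach `n_tot`.
#' @export
choose_and_allocate <- function(scores, capacity, config) {
  n <- length(scores)
  ord <- switch(config$strategy,
    random_control = sample.int(n),
    order(-scores, seq_len(n), na.last = TRUE))
  if (config$strategy == "top_tier") {
    quota <- config$n_tot %/% config$n_chosen
    chosen <- ord[seq_len(config$n_chosen)]
    if (any(capacity[chosen] < quota))
      stop_extinction("a top-tier Adult cannot fill its Newborn quota")
    return(data.frame(adult = chosen, quota = quota))
  }
  take <- integer(0)
  quota <- integer(0)
  left <- config$n_tot
  for (i in ord) {
    if (left <= 0) break
    q <- min(capacity[i], left)
    if (q > 0) {
      take <- c(take, i)
      quota <- c(quota, q)
      left <- left - q
    }
  }
  if (left > 0)
    stop_extinction("all Adults together cannot produce n_tot Newborns")
  data.frame(adult = take, quota = quota)
}

stop_extinction <- function(msg) {
  stop(structure(class = c("commsel_extinction", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# counter-based seed stream: every stochastic stage of a run gets its own
# deterministic seed derived from the master seed, so results do not depend
# on execution order and any community can be replayed in isolation
derive_seed <- function(master, cycle, j, purpose) {
  as.integer((master + 100003 * cycle + 613 * j + 7919 * purpose) %%
               2147483629)
}

make_newborns <- function(config) {
  p <- config$params
  if (config$monoculture) {
    return(lapply(seq_len(config$n_tot), function(j)
      found_monoculture(p$fP, p, R0 = config$R0)))
  }
  base <- founder_community(p, config$init_nH, config$init_nM, config$R0)
  if (!config$pregrowth)
    return(lapply(seq_len(config$n_tot), function(j) base))
  pool <- NULL
  lapply(seq_len(config$n_tot), function(j) {
    if (is.null(pool) || !config$pregrowth_shared_pool)
      pool <<- pregrow_founder()
    nb <- base
    im <- which(nb$cells$species == 2L)
    nulls <- stats::rbinom(1, length(im), pool$null_fraction)
    if (nulls > 0) nb$cells$fP[sample(im, nulls)] <- 0
    nb
  })
}

partition_adult <- function(adult, n_newborns, config) {
  rs <- config$reproduction
  R0 <- config$R0
  nb <- switch(rs$method,
    pipetting = partition_pipetting(adult, rs$BM_target, R0),
    fixed_fold = partition_fixed_fold(adult, rs$fixed_fold_nD, R0),
    sort_biomass = partition_sort_biomass(adult, n_newborns, rs$BM_target,
                                          R0 = R0),
    sort_cellnumber = partition_sort_cellnumber(adult, n_newborns,
                                                rs$BM_target,
                                                mean_cell_length =
                                                  rs$mean_cell_length,
                                                R0 = R0),
    fix_BM_only = partition_fix_single_determinant(adult, "BM_only",
                                                   n_newborns, rs$BM_target,
                                                   R0),
    fix_phiM_only = partition_fix_single_determinant(adult, "phiM_only",
                                                     BM_target =
                                                       rs$BM_target,
                                                     R0 = R0))
  if (length(nb) > n_newborns) nb <- nb[sample.int(length(nb), n_newborns)]
  nb
}

adult_capacity <- function(adult, config) {
  rs <- config$reproduction
  if (config$monoculture) return(nrow(adult$cells))
  nD <- floor(biomass(adult) / rs$BM_target)
  switch(rs$method,
    fixed_fold = rs$fixed_fold_nD,
    pipetting = nD,
    fix_phiM_only = nD,
    # sorting wastes a little biomass per Newborn (each species window can
    # fall short by < 2); keep one fold in reserve
    sort_biomass = max(0, nD - 1),
    fix_BM_only = max(0, nD - 1),
    sort_cellnumber = {
      vphi <- varphi_M(adult)
      nM <- floor(rs$BM_target * vphi / rs$mean_cell_length)
      nH <- floor(rs$BM_target * (1 - vphi) / rs$mean_cell_length)
      availM <- sum(adult$cells$species == 2L)
      availH <- sum(adult$cells$species == 1L)
      min(if (nM) floor(availM / nM) else Inf,
          if (nH) floor(availH / nH) else Inf)
    })
}

adult_record <- function(adult, cycle, j, quota, score) {
  cells <- adult$cells
  isH <- cells$species == 1L
  isM <- !isH
  data.frame(cycle = cycle, community = j, quota = quota, score = score,
             P_T = adult$chem[["P"]], BM_T = sum(cells$L),
             phiM_T = phi_M(adult),
             mean_fP = if (any(isM)) mean(cells$fP[isM]) else NA_real_,
             mean_gHmax = if (any(isH)) mean(cells$gmax[isH]) else NA_real_,
             mean_gMmax = if (any(isM)) mean(cells$gmax[isM]) else NA_real_,
             mean_affHR = if (any(isH)) mean(cells$affR[isH]) else NA_real_,
             mean_affMR = if (any(isM)) mean(cells$affR[isM]) else NA_real_,
             mean_affMB = if (any(isM)) mean(cells$affB[isM]) else NA_real_,
             seed = adult$seed)
}

#' Run cycles of artificial community selection
#'
#' The full protocol: initialize `n_tot` identical Newborns (or
#' pregrowth-founded, or monoculture groups), then per cycle (i) mature
#' every community under its own logged seed, (ii) score the Adults
#' (optionally with measurement noise), (iii) choose who reproduces
#' ([choose_and_allocate()]), (iv) partition the chosen Adults into exactly
#' `n_tot` Newborns under the configured reproduction scheme. Fully
#' reproducible from `master_seed`.
#'
#' @param config a [selection_config()].
#' @return An object of class `commsel_run`: list with `header` (config,
#'   ancestral `P(T)`, master seed), `records` (one row per chosen Adult
#'   per cycle), and `aggregates` (per-cycle means of `P(T)` and of the
#'   within-Adult mean `fP` across chosen Adults). A run cut short by
#'   extinction carries the partial records and an `extinction` flag.
#' @export
run_selection <- function(config) {
  run_selection_core(config)
}

run_selection_core <- function(config, capture = NULL) {
  validate_selection_config(config)
  p <- config$params
  traj <- deterministic_trajectory(
    if (config$monoculture) 0 else config$init_nH,
    if (config$monoculture) 1 else config$init_nM,
    p, fP = p$fP, T = config$T, R0 = config$R0,
    excessB = config$monoculture)
  P_anc <- unname(traj[nrow(traj), "P"])

  set.seed(derive_seed(config$master_seed, 0, 0, 4))
  newborns <- make_newborns(config)

  records <- list()
  extinct_run <- FALSE
  for (cycle in seq_len(config$n_cycles)) {
    adults <- vector("list", config$n_tot)
    for (j in seq_len(config$n_tot)) {
      sd_j <- derive_seed(config$master_seed, cycle, j, 1)
      if (!is.null(capture) && identical(capture, c(cycle, j)))
        return(list(newborn = newborns[[j]], seed = sd_j))
      adults[[j]] <- mature(newborns[[j]], p, config$mut, config$T,
                            config$dtau, seed = sd_j,
                            excessB = config$monoculture)
    }
    scores <- vapply(adults, community_function, numeric(1),
                     def = config$function_def)
    set.seed(derive_seed(config$master_seed, cycle, 0, 3))
    scores <- add_measurement_noise(scores, config$noise_sd_frac, P_anc)
    capacity <- vapply(adults, adult_capacity, numeric(1), config = config)

    set.seed(derive_seed(config$master_seed, cycle, 0, 2))
    plan <- tryCatch(choose_and_allocate(scores, capacity, config),
                     commsel_extinction = function(e) e)
    if (inherits(plan, "commsel_extinction")) {
      extinct_run <- TRUE
      break
    }
    nxt <- list()
    for (r in seq_len(nrow(plan))) {
      i <- plan$adult[r]
      adults[[i]]$lineage <- i
      rec <- adult_record(adults[[i]], cycle, i, plan$quota[r], scores[i])
      records[[length(records) + 1L]] <- rec
      nxt <- c(nxt,
               if (config$monoculture)
                 refound_groups(adults[[i]], plan$quota[r], config)
               else partition_adult(adults[[i]], plan$quota[r], config))
    }
    # sorting methods can occasionally deliver one Newborn fewer than the
    # conservative capacity promised; top up from the next-ranked Adults
    if (length(nxt) < config$n_tot) {
      rest <- setdiff(order(-scores, seq_len(length(scores)),
                            na.last = TRUE), plan$adult)
      for (i in rest) {
        need <- config$n_tot - length(nxt)
        if (need <= 0) break
        q <- min(adult_capacity(adults[[i]], config), need)
        if (q <= 0) next
        adults[[i]]$lineage <- i
        records[[length(records) + 1L]] <-
          adult_record(adults[[i]], cycle, i, q, scores[i])
        nxt <- c(nxt,
                 if (config$monoculture)
                   refound_groups(adults[[i]], q, config)
                 else partition_adult(adults[[i]], q, config))
      }
      if (length(nxt) < config$n_tot) {
        extinct_run <- TRUE
        break
      }
    }
    newborns <- nxt
  }

  records <- if (length(records)) do.call(rbind, records) else
    adult_record(founder_community(p, 0, 0), 0, 0, 0, NA)[0, ]
  agg <- if (nrow(records)) {
    data.frame(cycle = sort(unique(records$cycle)),
               Pbar_T = as.numeric(tapply(records$P_T, records$cycle, mean)),
               fPbar_T = as.numeric(tapply(records$mean_fP, records$cycle,
                                           mean)))
  } else {
    data.frame(cycle = integer(), Pbar_T = numeric(), fPbar_T = numeric())
  }
  structure(list(header = list(config = config, P_ancestral = P_anc,
                               master_seed = config$master_seed,
                               extinction = extinct_run),
                 records = records, aggregates = agg),
            class = "commsel_run")
}

refound_groups <- function(adult, n_newborns, config) {
  cells <- adult$cells
  take <- sample.int(nrow(cells), min(n_newborns, nrow(cells)))
  lapply(take, function(i)
    found_monoculture(cells$fP[i], config$params, gmax = cells$gmax[i],
                      affR = cells$affR[i], affB = cells$affB[i],
                      R0 = config$R0))
}

#' Run artificial selection on Manufacturer monoculture groups
#'
#' Group selection on M alone: every Newborn group is founded by a single M
#' cell (length 1) supplied with fresh Resource and excess Byproduct; the
#' highest-Product Adult group's cells found the next cycle's groups.
#'
#' @param config a [selection_config()]; its `monoculture` flag is forced
#'   on.
#' @return A `commsel_run` (see [run_selection()]).
#' @export
run_group_selection <- function(config) {
  config$monoculture <- TRUE
  run_selection_core(config)
}

#' Pregrow a founder Manufacturer monoculture
#'
#' Two-type branching growth from a single contributor cell (cost
#' `fP = 0.13`, growth rate `rel_growth = 0.87` relative to a null cell).
#' Contributors divide synchronously; at each division a conversion to null
#' (`fP = 0`) is drawn per offspring cell with probability `p_conv`
#' (`convert = "daughter"`: the newborn daughter only, the reading
#' consistent with the reported ~3% null load; `convert = "both"`: mother
#' and daughter independently). Null cohorts double every `rel_growth`
#' contributor generations (completed divisions, exact synchronized-cohort
#' bookkeeping at population-count cost).
#'
#' @param doublings contributor generations (23 gives ~1e7 cells).
#' @param p_conv null-conversion probability per division (1e-3).
#' @param rel_growth contributor growth rate relative to null (0.87).
#' @param fP cost of contributor cells.
#' @param convert which offspring can convert at a division.
#' @return List with `contributors`, `nulls` (cell counts),
#'   `null_fraction`, and the cohort table.
#' @export
pregrow_founder <- function(doublings = 23, p_conv = 1e-3,
                            rel_growth = 0.87, fP = 0.13,
                            convert = c("daughter", "both")) {
  convert <- match.arg(convert)
  C <- 1
  born <- integer(doublings)
  for (k in seq_len(doublings)) {
    offspring <- 2 * C
    draws <- if (convert == "both") offspring else C
    mut <- stats::rbinom(1, draws, p_conv)
    born[k] <- mut
    C <- offspring - mut
  }
  growth <- 2^floor((doublings - seq_len(doublings)) / rel_growth)
  N <- sum(born * growth)
  list(contributors = C, nulls = N, null_fraction = N / (N + C),
       cohorts = data.frame(generation = seq_len(doublings), born = born,
                            final = born * growth))
}

#' @export
print.commsel_run <- function(x, ...) {
  cfg <- x$header$config
  cat(sprintf(
    "<commsel_run> %d cycles x %d communities | %s + %s | seed %d\n",
    cfg$n_cycles, cfg$n_tot, cfg$strategy, cfg$reproduction$method,
    x$header$master_seed))
  cat(sprintf("  ancestral P(T) = %.4g%s\n", x$header$P_ancestral,
              if (isTRUE(x$header$extinction)) " [terminated: extinction]"
              else ""))
  if (nrow(x$aggregates)) {
    last <- x$aggregates[nrow(x$aggregates), ]
    cat(sprintf("  final cycle %d: Pbar(T) = %.4g, fPbar(T) = %.4g\n",
                last$cycle, last$Pbar_T, last$fPbar_T))
  }
  invisible(x)
}
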