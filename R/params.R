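#' Species and community parameters of the Helper-Manufacturer model
#'
#' Assembles the heritable growth phenotypes of Helper (H) and Manufacturer
#' (M), the cost fraction `fP`, and the parameters held fixed through
#' evolution (consumption coefficients, death rates, optional Byproduct
#' inhibition of H), all in the scaled units of the model: Resource in units
#' of the amount supplied to one Newborn, Byproduct in units of the amount
#' released per H biomass grown, Product in units of the amount made at the
#' cost of one M biomass.
#'
#' Nutrient affinities are stored as `1/K` so that a null mutation ("zero
#' affinity") is representable as 0; every growth law is finite at zero
#' affinity.
#'
#' Two named sets are built in. `"preadapted"` puts every growth parameter at
#' its evolutionary upper bound with `fP = 0.13` (the monoculture-optimal
#' cost, the starting point of most selection runs); `"ancestral"` uses the
#' pre-evolution phenotypes (`gHmax = 0.25`, `gMmax = 0.58`, all affinities
#' at 1x, `fP = 0.1`).
#'
#' @param set `"preadapted"` or `"ancestral"` starting phenotypes.
#' @param gHmax,gMmax maximal biomass growth rates (1/time).
#' @param affHR H's affinity for Resource, `1/K_HR`.
#' @param affMR M's affinity for Resource, `1/K_MR`.
#' @param affMB M's affinity for Byproduct, `1/K_MB`.
#' @param fP fraction of M's potential growth diverted to Product, in `[0,1]`.
#' @param cRM,cRH Resource consumed per potential M / H biomass grown.
#' @param cBM Byproduct consumed per potential M biomass grown.
#' @param deltaH,deltaM death rates (1/time).
#' @param B0 Byproduct concentration at which H growth is reduced e-fold
#'   (mutualistic model); `NULL` for the commensal model.
#' @param gHmax_bound evolutionary upper bound for `gHmax`; the default 0.3
#'   is the standard scenario, 0.8 the fast-Helper scenario (which pairs
#'   with `R0 = 10`).
#'
#' @return An object of class `hm_params`: a list of the above plus a
#'   `bounds` list with the evolutionary upper bounds for the five growth
#'   parameters and `fP`.
#' @export
hm_params <- function(set = c("preadapted", "ancestral"),
                      gHmax = NULL, gMmax = NULL, affHR = NULL, affMR = NULL,
                      affMB = NULL, fP = NULL,
                      cRM = 1e-4, cRH = 1e-4, cBM = 1 / 3,
                      deltaH = 1.5e-3, deltaM = 3.5e-3,
                      B0 = NULL, gHmax_bound = 0.3) {
  set <- match.arg(set)
  def <- if (set == "preadapted") {
    list(gHmax = 0.3, gMmax = 0.7, affHR = 5, affMR = 3, affMB = 0.03,
         fP = 0.13)
  } else {
    list(gHmax = 0.25, gMmax = 0.58, affHR = 1, affMR = 1, affMB = 0.006,
         fP = 0.1)
  }
  p <- list(
    gHmax = gHmax %||% def$gHmax, gMmax = gMmax %||% def$gMmax,
    affHR = affHR %||% def$affHR, affMR = affMR %||% def$affMR,
    affMB = affMB %||% def$affMB, fP = fP %||% def$fP,
    cRM = cRM, cRH = cRH, cBM = cBM, deltaH = deltaH, deltaM = deltaM,
    B0 = B0,
    bounds = list(gHmax = gHmax_bound, gMmax = 0.7, affHR = 5, affMR = 3,
                  affMB = 0.03, fP = 1)
  )
  num <- unlist(p[c("gHmax", "gMmax", "affHR", "affMR", "affMB", "fP", "cRM",
                    "cRH", "cBM", "deltaH", "deltaM")])
  if (any(!is.finite(num)) || any(num < 0))
    stop("all hm_params values must be finite and non-negative")
  if (p$fP > 1) stop("fP must lie in [0, 1]")
  if (!is.null(B0) && B0 <= 0) stop("B0 must be positive (or NULL)")
  structure(p, class = "hm_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mutation model for phenotype-altering mutations
#'
#' Each freshly divided cell mutates each of its mutable phenotypes
#' independently with probability `P_mut`. A mutation is null (sets the
#' phenotype to 0) with probability `p_null`; otherwise the phenotype is
#' multiplied by `1 + delta`, with `delta` drawn from a bilateral exponential
#' distribution (mean `s_plus` on the enhancing side, mean `s_minus` in
#' magnitude on the diminishing side, truncated at `delta = -1`). Results
#' are clamped to the evolutionary bounds.
#'
#' With `epistasis_g > 0`, diminishing-returns epistasis acts on `fP`
#' mutations only: at current cost `fP`, the enhancing mean becomes
#' `s_plus / (1 + g (fP/fP_init - 1))` and the diminishing mean
#' `s_minus * (1 + g (fP/fP_init - 1))`.
#'
#' @param P_mut probability of a phenotype-altering mutation per cell per
#'   division per phenotype (default `2e-3`).
#' @param p_null probability a mutation is null (default 0.5; set 0 for the
#'   no-null variant).
#' @param s_plus,s_minus mean relative effects of enhancing / diminishing
#'   mutations (defaults 0.050 and 0.067; the alternative small-effect
#'   configuration uses `s_plus = s_minus = 0.02`).
#' @param epistasis_g diminishing-returns factor in `[0, 1)`; 0 disables
#'   epistasis.
#' @param fP_init reference cost for the epistasis model.
#' @param mutable character vector naming the mutable phenotypes, a subset of
#'   `c("gHmax", "affHR", "gMmax", "affMR", "affMB", "fP")`.
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(P_mut = 2e-3, p_null = 0.5, s_plus = 0.050,
                           s_minus = 0.067, epistasis_g = 0, fP_init = 0.13,
                           mutable = "fP") {
  all_ph <- c("gHmax", "affHR", "gMmax", "affMR", "affMB", "fP")
  bad <- setdiff(mutable, all_ph)
  if (length(bad))
    stop("unknown mutable phenotypes: ", paste(bad, collapse = ", "))
  if (P_mut < 0 || P_mut > 1) stop("P_mut must lie in [0, 1]")
  if (p_null < 0 || p_null > 1) stop("p_null must lie in [0, 1]")
  if (s_plus <= 0 || s_minus <= 0) stop("s_plus and s_minus must be positive")
  if (epistasis_g < 0 || epistasis_g >= 1)
    stop("epistasis_g must lie in [0, 1)")
  structure(list(P_mut = P_mut, p_null = p_null, s_plus = s_plus,
                 s_minus = s_minus, epistasis_g = epistasis_g,
                 fP_init = fP_init, mutable = mutable,
                 mutable_flags = all_ph %in% mutable),
            class = "mutation_model")
}

#' Reproduction scheme for splitting a chosen Adult into Newborns
#'
#' @param method one of `"pipetting"` (volumetric random partition into
#'   `floor(BM/BM_target)` Newborns), `"sort_biomass"` (cell sorter fixing
#'   both Newborn total biomass and species biomass fraction),
#'   `"sort_cellnumber"` (sorter fixing species cell numbers),
#'   `"fix_BM_only"` (fixed total biomass, fluctuating composition),
#'   `"fix_phiM_only"` (fixed composition, fluctuating total biomass), or
#'   `"fixed_fold"` (constant dilution fold regardless of Adult biomass).
#' @param BM_target target Newborn total biomass (default 100).
#' @param fixed_fold_nD dilution fold for `method = "fixed_fold"`.
#' @param mean_cell_length assumed mean cell biomass for the cell-number
#'   variants (1.5).
#' @return An object of class `reproduction_spec`.
#' @export
reproduction_spec <- function(method = c("pipetting", "sort_biomass",
                                         "sort_cellnumber", "fix_BM_only",
                                         "fix_phiM_only", "fixed_fold"),
                              BM_target = 100, fixed_fold_nD = 100,
                              mean_cell_length = 1.5) {
  method <- match.arg(method)
  if (BM_target <= 0) stop("BM_target must be positive")
  if (fixed_fold_nD < 1) stop("fixed_fold_nD must be >= 1")
  structure(list(method = method, BM_target = BM_target,
                 fixed_fold_nD = as.integer(fixed_fold_nD),
                 mean_cell_length = mean_cell_length),
            class = "reproduction_spec")
}

#' Configuration of a community-selection run
#'
#' Bundles everything one selection experiment needs: the species parameters,
#' the mutation model, the reproduction scheme, the intercommunity selection
#' strategy, and the culture conditions. Defaults reproduce the baseline
#' regimen: 100 communities, Newborns of 40 H + 60 M cells of biomass 1,
#' Resource supporting 1e4 biomass, maturation `T = 17` in steps of 0.05,
#' top-dog choice on total Product, reproduction by pipetting, only `fP`
#' mutable.
#'
#' @param n_tot communities per cycle.
#' @param n_chosen Adults chosen under the top-tier strategy (`n_tot` must be
#'   divisible by `n_chosen`).
#' @param strategy `"top_dog"`, `"top_tier"`, or `"random_control"`.
#' @param function_def community function: `"total_product"` is `P(T)`;
#'   `"product_per_M"` is `P(T)/M(T)` (undefined and ranked last if M is
#'   extinct).
#' @param noise_sd_frac sd of Gaussian measurement noise on the score, as a
#'   fraction of the ancestral `P(T)` (0, 0.05, 0.10).
#' @param T maturation time; `dtau` the agent time step.
#' @param R0 Resource supplied to each Newborn (units of the Newborn supply;
#'   10 for the fast-Helper scenario).
#' @param init_nH,init_nM founding cell numbers per Newborn (biomass 1 each).
#' @param n_cycles number of selection cycles.
#' @param master_seed integer seed from which every per-community and
#'   per-reproduction seed is derived (counter-based).
#' @param params an [hm_params()] object.
#' @param mut a [mutation_model()] object.
#' @param reproduction a [reproduction_spec()] object.
#' @param monoculture simulate M-only group selection (excess Byproduct).
#' @param pregrowth found the first cycle's M cells from a pregrown
#'   monoculture ([pregrow_founder()]) instead of identical contributors.
#' @param pregrowth_shared_pool one pregrowth pool shared by all Newborns
#'   (`TRUE`) or an independent pool per Newborn (`FALSE`).
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(n_tot = 100, n_chosen = 10,
                             strategy = c("top_dog", "top_tier",
                                          "random_control"),
                             function_def = c("total_product",
                                              "product_per_M"),
                             noise_sd_frac = 0, T = 17, dtau = 0.05, R0 = 1,
                             init_nH = 40, init_nM = 60, n_cycles = 10,
                             master_seed = 1, params = hm_params(),
                             mut = mutation_model(),
                             reproduction = reproduction_spec(),
                             monoculture = FALSE, pregrowth = FALSE,
                             pregrowth_shared_pool = TRUE) {
  strategy <- match.arg(strategy)
  function_def <- match.arg(function_def)
  cfg <- structure(list(n_tot = as.integer(n_tot),
                        n_chosen = as.integer(n_chosen), strategy = strategy,
                        function_def = function_def,
                        noise_sd_frac = noise_sd_frac, T = T, dtau = dtau,
                        R0 = R0, init_nH = as.integer(init_nH),
                        init_nM = as.integer(init_nM),
                        n_cycles = as.integer(n_cycles),
                        master_seed = as.integer(master_seed),
                        params = params, mut = mut,
                        reproduction = reproduction,
                        monoculture = monoculture, pregrowth = pregrowth,
                        pregrowth_shared_pool = pregrowth_shared_pool),
                   class = "selection_config")
  validate_selection_config(cfg)
  cfg
}

validate_selection_config <- function(cfg) {
  errs <- character()
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(cfg$n_tot >= 1, "n_tot must be >= 1")
  chk(cfg$n_cycles >= 0, "n_cycles must be >= 0")
  chk(cfg$noise_sd_frac >= 0, "noise_sd_frac must be >= 0")
  chk(cfg$T >= 0, "T must be >= 0")
  chk(cfg$dtau > 0, "dtau must be positive")
  chk(abs(cfg$T / cfg$dtau - round(cfg$T / cfg$dtau)) < 1e-8,
      "T must be an integer multiple of dtau")
  chk(cfg$R0 > 0, "R0 must be positive")
  if (cfg$strategy == "top_tier") {
    chk(cfg$n_chosen >= 1 && cfg$n_tot %% cfg$n_chosen == 0,
        sprintf("n_tot (%d) must be divisible by n_chosen (%d) for top_tier",
                cfg$n_tot, cfg$n_chosen))
  }
  chk(cfg$init_nH >= 0 && cfg$init_nM >= 0,
      "founding cell numbers must be non-negative")
  chk(inherits(cfg$params, "hm_params"), "params must be an hm_params object")
  chk(inherits(cfg$mut, "mutation_model"),
      "mut must be a mutation_model object")
  chk(inherits(cfg$reproduction, "reproduction_spec"),
      "reproduction must be a reproduction_spec object")
  if (length(errs))
    stop("invalid selection_config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  invisible(cfg)
}

# parameter vector for the compiled deSolve right-hand side
ode_parms <- function(params, fP, excessB = FALSE) {
  c(params$gHmax, params$gMmax, params$affHR, params$affMR, params$affMB,
    params$cRM, params$cRH, params$cBM, params$deltaH, params$deltaM,
    fP, if (is.null(params$B0)) 0 else 1 / params$B0,
    as.numeric(excessB))
}

# fixed-parameter list consumed by the C++ chemical solver
fixed_list <- function(params, excessB = FALSE) {
  list(cRM = params$cRM, cRH = params$cRH, cBM = params$cBM,
       B0inv = if (is.null(params$B0)) 0 else 1 / params$B0,
       excessB = excessB)
}
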