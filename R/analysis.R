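#' Community-function landscape over cost and composition
#'
#' Deterministic `P(T)` (coupled ODEs, death included, uniform `fP`) over
#' the grid `fP = res*i`, `phiM0 = res*j` for `i, j` in `1..(1/res - 1)`,
#' from Newborn total biomass `BM0`. With `prescan = TRUE` a 0.05-resolution
#' scan locates the optimum first and only a local window is refined at
#' `res`, returning the same argmax at a fraction of the cost (the full
#' grid is still the reference).
#'
#' @param params an [hm_params()] object (typically preadapted).
#' @param BM0 Newborn total biomass (100).
#' @param R0 Resource supplied (1).
#' @param T maturation time (17).
#' @param res grid resolution (0.01).
#' @param prescan coarse-then-refine instead of the full grid.
#' @return Object of class `landscape_result`: list with the `P` matrix
#'   (rows fP, columns phiM0; `NA` where not evaluated under `prescan`),
#'   the grid values, and the argmax (`fP_opt`, `phiM_opt`, `P_opt`).
#' @export
community_function_landscape <- function(params = hm_params(), BM0 = 100,
                                         R0 = 1, T = 17, res = 0.01,
                                         prescan = FALSE) {
  grid <- seq(res, 1 - res, by = res)
  n <- length(grid)
  P <- matrix(NA_real_, n, n, dimnames = list(fP = grid, phiM0 = grid))
  eval_cell <- function(f, phi) {
    tr <- tryCatch(
      deterministic_trajectory(BM0 * (1 - phi), BM0 * phi, params, fP = f,
                               T = T, R0 = R0),
      error = function(e) stop(sprintf(
        "landscape solver failure at fP=%.3f, phiM0=%.3f: %s", f, phi,
        conditionMessage(e)), call. = FALSE))
    tr[nrow(tr), "P"]
  }
  cells <- if (prescan) {
    coarse <- seq(0.05, 0.95, by = 0.05)
    cP <- outer(coarse, coarse, Vectorize(eval_cell))
    top <- which(cP == max(cP), arr.ind = TRUE)[1, ]
    wf <- grid[abs(grid - coarse[top[1]]) <= 0.05 + 1e-9]
    wp <- grid[abs(grid - coarse[top[2]]) <= 0.05 + 1e-9]
    expand.grid(f = wf, phi = wp)
  } else {
    expand.grid(f = grid, phi = grid)
  }
  for (r in seq_len(nrow(cells))) {
    f <- cells$f[r]
    phi <- cells$phi[r]
    P[match(f, grid), match(phi, grid)] <- eval_cell(f, phi)
  }
  top <- which(P == max(P, na.rm = TRUE), arr.ind = TRUE)[1, ]
  structure(list(P = P, fP = grid, phiM0 = grid,
                 fP_opt = grid[top[1]], phiM_opt = grid[top[2]],
                 P_opt = P[top[1], top[2]]),
            class = "landscape_result")
}

#' @export
print.landscape_result <- function(x, ...) {
  cat(sprintf(
    "<landscape_result> optimum P(T) = %.4g at fP = %.2f, phiM(0) = %.2f\n",
    x$P_opt, x$fP_opt, x$phiM_opt))
  invisible(x)
}

#' Closed-form steady-state fraction of M biomass
#'
#' When Byproduct is depleted by the end of each cycle (valid for
#' `fP < ~0.4`), the within-cycle steady-state composition is
#' `phiM_SS = (1 - fP) / (1 - fP + c_BM)`.
#'
#' @param fP cost fraction.
#' @param c_BM Byproduct consumed per potential M biomass (1/3).
#' @return Steady-state M biomass fraction.
#' @export
steady_state_phiM <- function(fP, c_BM = 1 / 3) {
  (1 - fP) / (1 - fP + c_BM)
}

#' Iterated cycle map of the M biomass fraction
#'
#' Deterministic serial-batch map: each cycle integrates the coupled ODEs
#' for time `T`, then resets total biomass to `BM_target` and the chemicals
#' to the Newborn condition while keeping the species fraction. M is
#' declared extinct when its fraction falls below `1/BM_target`.
#'
#' @param fP uniform cost.
#' @param params an [hm_params()] object.
#' @param phi0 starting M biomass fraction.
#' @param n_cycles number of cycles to iterate.
#' @param BM_target Newborn total biomass.
#' @param R0,T culture conditions.
#' @return Numeric vector of end-of-cycle `phi_M(T)` values (stops early on
#'   extinction, attribute `extinct` set).
#' @export
cycle_map_phiM <- function(fP, params = hm_params(), phi0 = 0.6,
                           n_cycles = 30, BM_target = 100, R0 = 1, T = 17) {
  phi <- phi0
  out <- numeric(0)
  extinct <- FALSE
  for (k in seq_len(n_cycles)) {
    tr <- deterministic_trajectory(BM_target * (1 - phi), BM_target * phi,
                                   params, fP = fP, T = T, R0 = R0)
    fin <- tr[nrow(tr), ]
    phi <- fin[["M"]] / (fin[["M"]] + fin[["H"]])
    out <- c(out, phi)
    if (phi < 1 / BM_target) {
      extinct <- TRUE
      break
    }
  }
  attr(out, "extinct") <- extinct
  out
}

#' Optimal cost for a Manufacturer monoculture
#'
#' Grid search over `fP` of the deterministic `P(T)` of an M group founded
#' by a single cell (biomass 1) in excess Byproduct (growth reduces to
#' Monod on Resource) with the community's Resource supply.
#'
#' @param params an [hm_params()] object (growth parameters at bounds).
#' @param R0,T culture conditions.
#' @param fP_grid costs to scan.
#' @return List with `fP_opt`, `P_opt`, and the scanned `P` values.
#' @export
monoculture_optimum <- function(params = hm_params(), R0 = 1, T = 17,
                                fP_grid = seq(0.01, 0.99, by = 0.01)) {
  P <- vapply(fP_grid, function(f) {
    tr <- deterministic_trajectory(0, 1, params, fP = f, T = T, R0 = R0,
                                   excessB = TRUE)
    tr[nrow(tr), "P"]
  }, numeric(1))
  i <- which.max(P)
  list(fP_opt = fP_grid[i], P_opt = P[i], fP = fP_grid, P = P)
}

#' Analytic approximation of the optimal cost
#'
#' For `int g_M dt >> 1` the cost maximizing `P(T)` satisfies
#' `fP (1 - fP) = 1 / int g_M dt`, whose small-`fP` root is approximately
#' `1 / int g_M dt`.
#'
#' @param gM_integral total potential M growth `int g_M dt` over
#'   maturation (> 0).
#' @return Approximate optimal `fP`.
#' @export
optimal_fP_approx <- function(gM_integral) {
  if (any(gM_integral <= 0)) stop("gM_integral must be positive")
  1 / gM_integral
}

#' Newborn composition fluctuations under pipetting
#'
#' Poissonian cell-count statistics of volumetric partitioning: Newborn
#' total biomass fluctuates around `BM_target` with standard deviation
#' `sqrt(BM_target * Lbar)`, and the species biomass ratio `M(0)/H(0)`
#' fluctuates with variance `phiM / (1 - phiM)^3 * Lbar / BM_target`.
#'
#' @param BM_target target Newborn biomass.
#' @param phiM parent Adult's M biomass fraction (strictly inside (0,1)
#'   for the ratio variance).
#' @param Lbar mean cell biomass (1.5).
#' @return Named vector `c(sd_BM =, var_ratio =)`.
#' @export
newborn_fluctuation_stats <- function(BM_target = 100, phiM = 0.6,
                                      Lbar = 1.5) {
  if (phiM <= 0 || phiM >= 1)
    stop("ratio variance undefined at phiM = 0 or 1")
  c(sd_BM = sqrt(BM_target * Lbar),
    var_ratio = phiM / (1 - phiM)^3 * Lbar / BM_target)
}
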