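#' Monod growth rate
#'
#' `g = g_max * R / (R + K)` written in affinity form `aff = 1/K`:
#' `g_max * R*aff / (R*aff + 1)`. A null affinity (`aff = 0`, i.e.
#' `K -> Inf`) gives rate 0, as does `R = 0`.
#'
#' @param R Resource amount (scaled, >= 0).
#' @param g_max maximal growth rate (>= 0).
#' @param aff affinity `1/K` (>= 0).
#' @return Growth rate (vectorized over any argument).
#' @export
monod_rate <- function(R, g_max, aff) {
  if (any(R < 0) || any(g_max < 0) || any(aff < 0))
    stop("monod_rate: negative input")
  x <- R * aff
  ifelse(x > 0, g_max * x / (x + 1), 0)
}

#' Mankad-Bungay dual-substrate growth rate
#'
#' With `R_M = R * aff_MR` and `B_M = B * aff_MB`,
#' `g = g_max * R_M B_M / (R_M + B_M) * (1/(R_M+1) + 1/(B_M+1))`.
#' When either substrate (or its affinity) is zero the rate is zero; when
#' one substrate saturates (`B_M >> 1`) the rate reduces to monosubstrate
#' Monod kinetics in the other.
#'
#' @param R,B Resource and Byproduct amounts (scaled, >= 0).
#' @param g_max maximal growth rate.
#' @param aff_MR,aff_MB affinities `1/K_MR`, `1/K_MB`.
#' @return Growth rate (vectorized).
#' @export
mankad_bungay_rate <- function(R, B, g_max, aff_MR, aff_MB) {
  if (any(R < 0) || any(B < 0) || any(g_max < 0) || any(aff_MR < 0) ||
      any(aff_MB < 0))
    stop("mankad_bungay_rate: negative input")
  RM <- R * aff_MR
  BM <- B * aff_MB
  ifelse(RM > 0 & BM > 0,
         g_max * RM * BM / (RM + BM) * (1 / (RM + 1) + 1 / (BM + 1)),
         0)
}

#' Byproduct inhibition factor on Helper growth
#'
#' In the mutualistic variant of the community, Byproduct inhibits H growth
#' by `exp(-B/B0)`; the commensal model (`B0 = NULL`) applies no inhibition.
#'
#' @param B Byproduct amount (>= 0).
#' @param B0 inhibition scale (> 0), or `NULL` for the commensal model.
#' @return Multiplier in `(0, 1]` (vectorized over `B`).
#' @export
h_inhibition_factor <- function(B, B0 = NULL) {
  if (is.null(B0)) return(rep(1, length(B)))
  if (B0 <= 0) stop("B0 must be positive")
  exp(-B / B0)
}

# exact phenotype grouping of a community's cells: cells sharing the same
# (species, gmax, affR, affB) are one chemical group (fP does not enter the
# chemical equations because Resource/Byproduct consumption follows potential
# growth). Returns the group table plus each cell's group index.
group_cells <- function(cells) {
  affB <- ifelse(is.na(cells$affB), 0, cells$affB)
  key <- paste(cells$species, sprintf("%.17g", cells$gmax),
               sprintf("%.17g", cells$affR), sprintf("%.17g", affB),
               sep = "|")
  idx <- match(key, unique(key))
  first <- !duplicated(key)
  groups <- data.frame(species = cells$species[first],
                       gmax = cells$gmax[first], affR = cells$affR[first],
                       affB = affB[first],
                       biomass = as.numeric(
                         rowsum(cells$L, idx)[as.character(sort(unique(idx))),
                                              1]))
  list(groups = groups, index = idx)
}

#' Integrate the chemical state over one agent time step
#'
#' Solves the within-step chemical equations with cell biomasses frozen at
#' their start-of-step values: `dR/dt = -sum_M cRM g_M M_k - sum_H cRH g_H
#' H_k`, `dB/dt = sum_H g_H H_k - sum_M cBM g_M M_k` (with `g_H` carrying
#' the Byproduct-inhibition factor in the mutualistic model), together with
#' one cumulative growth integral `int g dt` per phenotype group, solved as
#' augmented ODE states by an adaptive Dormand-Prince RK45. Product is not
#' touched here; it is updated from realized biomass deltas by
#' [apply_growth()].
#'
#' @param chem named vector `c(R=, B=, P=)`.
#' @param groups data frame with columns `species`, `gmax`, `affR`, `affB`,
#'   `biomass` (one row per phenotype group), e.g. from the `groups`
#'   element of a community grouping.
#' @param dtau step duration (> 0).
#' @param params an [hm_params()] object (consumption coefficients, `B0`).
#' @param excessB treat Byproduct as saturating (monoculture scenario).
#' @param rtol,atol solver tolerances.
#' @return List with the end-of-step `chem` and the per-group `integrals`.
#' @export
integrate_chem_step <- function(chem, groups, dtau, params,
                                excessB = FALSE, rtol = 1e-6, atol = 1e-9) {
  if (dtau <= 0) stop("dtau must be positive")
  res <- chem_step_cpp(chem[["R"]], chem[["B"]], as.integer(groups$species),
                       groups$gmax, groups$affR, groups$affB, groups$biomass,
                       dtau, fixed_list(params, excessB), rtol, atol)
  list(chem = c(R = res$R, B = res$B, P = chem[["P"]]),
       integrals = res$integrals)
}

#' Deterministic community trajectory (coupled continuous-biomass ODEs)
#'
#' Integrates the fully coupled scaled equations for `H`, `M`, `R`, `B`,
#' `P` over `[0, T]` with uniform cost `fP` across M, death included, via
#' `deSolve::lsoda` with a compiled right-hand side. This is the
#' deterministic engine behind the landscape, cycle-map, and monoculture
#' analyses, and the independent oracle the agent-based simulation is tested
#' against.
#'
#' @param H0,M0 founding biomasses.
#' @param params an [hm_params()] object.
#' @param fP uniform cost fraction (defaults to `params$fP`).
#' @param T maturation time.
#' @param R0,B0,P0 initial chemical amounts.
#' @param excessB Byproduct saturating (M grows Monod on R; B frozen).
#' @param times output times (default `c(0, T)`; pass a vector for a full
#'   time series).
#' @param rtol,atol solver tolerances.
#' @return Matrix with columns `time, H, M, R, B, P` (states clamped at 0).
#' @export
deterministic_trajectory <- function(H0, M0, params = hm_params(),
                                     fP = params$fP, T = 17, R0 = 1, B0 = 0,
                                     P0 = 0, excessB = FALSE, times = NULL,
                                     rtol = 1e-6, atol = 1e-9) {
  if (is.null(times)) times <- c(0, T)
  y0 <- c(H = H0, M = M0, R = R0, B = B0, P = P0)
  out <- deSolve::lsoda(y = y0, times = times, func = "hm_derivs",
                        parms = ode_parms(params, fP, excessB),
                        dllname = "commsel", initfunc = "hm_initmod",
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("deterministic_trajectory: solver failure (istate = ",
         attr(out, "istate")[1], ")")
  out <- unclass(out)
  out[, -1][out[, -1] < 0] <- 0
  colnames(out) <- c("time", "H", "M", "R", "B", "P")
  out
}
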