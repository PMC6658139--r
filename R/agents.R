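#' Apply one step's growth integrals to individual cells
#'
#' Each H cell grows as `L <- L * exp(int g_H dt)`; each M cell as
#' `L <- L * exp((1 - fP) int g_M dt)`, and Product accrues per M cell as
#' `fP/(1-fP) * dL`. For `fP = 1` the analytic limit applies: the cell does
#' not grow and contributes `L * int g_M dt` to Product. Death is handled
#' separately, so Product from a cell that later dies in the same step is
#' retained (Product is extracellular).
#'
#' @param comm a `community`.
#' @param integrals per-group `int g dt` from [integrate_chem_step()].
#' @param group_index group index per cell (from the same grouping the
#'   integrals were computed with).
#' @return The community with grown cells and updated Product.
#' @export
apply_growth <- function(comm, integrals, group_index) {
  cells <- comm$cells
  I <- integrals[group_index]
  isH <- cells$species == 1L
  cells$L[isH] <- cells$L[isH] * exp(I[isH])
  isM <- !isH
  if (any(isM)) {
    f <- cells$fP[isM]
    L <- cells$L[isM]
    Im <- I[isM]
    lim <- f >= 1
    Ln <- ifelse(lim, L, L * exp((1 - f) * Im))
    dP <- ifelse(lim, L * Im, f / (1 - f) * (Ln - L))
    cells$L[isM] <- Ln
    comm$chem[["P"]] <- comm$chem[["P"]] + sum(dP)
  }
  comm$cells <- cells
  comm
}

#' Stochastic death over one step
#'
#' Each cell independently dies with probability `delta * dtau` for its
#' species (one uniform draw per cell, in cell order).
#'
#' @param comm a `community`.
#' @param dtau step duration.
#' @param params an [hm_params()] object (death rates).
#' @return The community containing only survivors (order preserved).
#' @export
apply_death <- function(comm, dtau, params) {
  p <- ifelse(comm$cells$species == 1L, params$deltaH, params$deltaM) * dtau
  if (any(p < 0 | p > 1)) stop("death probability per step must be in [0,1]")
  survive <- stats::runif(nrow(comm$cells)) >= p
  comm$cells <- comm$cells[survive, , drop = FALSE]
  rownames(comm$cells) <- NULL
  comm$extinct <- nrow(comm$cells) == 0L
  comm
}

#' Division of cells that reached length 2
#'
#' Every cell with `L >= 2` is replaced by two cells of half its length and
#' identical phenotype; the daughter is inserted immediately after the
#' mother. Total biomass is conserved exactly.
#'
#' @param comm a `community`.
#' @return List with the updated `community` and `divided`, the row indices
#'   of the freshly divided cells (mother/daughter pairs, consecutive).
#' @export
apply_division <- function(comm) {
  cells <- comm$cells
  div <- cells$L >= 2
  if (!any(div)) return(list(comm = comm, divided = integer()))
  reps <- ifelse(div, 2L, 1L)
  idx <- rep(seq_len(nrow(cells)), times = reps)
  cells <- cells[idx, , drop = FALSE]
  grew <- rep(div, times = reps)
  cells$L[grew] <- cells$L[grew] / 2
  rownames(cells) <- NULL
  comm$cells <- cells
  list(comm = comm, divided = which(grew))
}

#' Mature a Newborn into an Adult
#'
#' Advances one community from time 0 to `T` in steps of `dtau`; within each
#' step, in order: (1) chemical integration with frozen biomasses, (2)
#' biomass growth and Product bookkeeping, (3) stochastic death, (4)
#' division at length 2, (5) independent mutation of every mutable phenotype
#' of every freshly divided cell. If the community goes extinct the
#' remaining steps change nothing (no cells, no chemistry) and the Adult is
#' flagged. The whole loop runs in compiled code; with `seed` set the
#' maturation is exactly replayable.
#'
#' @param newborn a `community`.
#' @param params an [hm_params()] object.
#' @param mut a [mutation_model()] object.
#' @param T maturation time (integer multiple of `dtau`).
#' @param dtau agent time step (default 0.05).
#' @param seed optional integer seed (recorded in the Adult).
#' @param excessB Byproduct saturating (monoculture scenario).
#' @return The Adult `community` with attributes `deaths` and `divisions`.
#' @export
mature <- function(newborn, params = hm_params(), mut = mutation_model(),
                   T = 17, dtau = 0.05, seed = NULL, excessB = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  cells <- newborn$cells
  res <- mature_cpp(cells$species, cells$L, cells$gmax, cells$affR,
                    cells$affB, cells$fP,
                    newborn$chem[["R"]], newborn$chem[["B"]],
                    newborn$chem[["P"]], T, dtau,
                    fixed_list(params, excessB), unclass(mut),
                    params$bounds, params$deltaH, params$deltaM)
  adult <- community(cell_df(res$species, res$L, res$gmax, res$affR,
                             res$affB, res$fP),
                     chem = c(R = res$R, B = res$B, P = res$P),
                     seed = if (is.null(seed)) newborn$seed else seed,
                     lineage = newborn$lineage)
  adult$extinct <- res$extinct
  attr(adult, "deaths") <- res$deaths
  attr(adult, "divisions") <- res$divisions
  adult
}

# pure-R composition of the per-step operations; used in tests to pin the
# compiled maturation loop to the documented operation ordering and RNG
# stream (draw-for-draw identical to mature_cpp)
mature_r <- function(newborn, params = hm_params(), mut = mutation_model(),
                     T = 17, dtau = 0.05, seed = NULL, excessB = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  comm <- newborn
  nsteps <- round(T / dtau)
  for (step in seq_len(nsteps)) {
    if (!nrow(comm$cells)) break
    grp <- group_cells(comm$cells)
    st <- integrate_chem_step(comm$chem, grp$groups, dtau, params, excessB)
    comm$chem <- st$chem
    comm <- apply_growth(comm, st$integrals, grp$index)
    comm <- apply_death(comm, dtau, params)
    dv <- apply_division(comm)
    comm <- dv$comm
    for (i in dv$divided) {
      r <- comm$cells[i, ]
      m <- mutate_cell_cpp(r$species, r$gmax, r$affR, r$affB, r$fP,
                           unclass(mut), params$bounds)
      comm$cells$gmax[i] <- m$gmax
      comm$cells$affR[i] <- m$affR
      comm$cells$affB[i] <- m$affB
      comm$cells$fP[i] <- m$fP
    }
  }
  comm$extinct <- nrow(comm$cells) == 0L
  comm
}
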