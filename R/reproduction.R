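#' Dilution fold of an Adult
#'
#' `n_D = floor(adult_biomass / BM_target)`. An Adult smaller than
#' `BM_target` cannot contribute Newborns.
#'
#' @param adult_BM total Adult biomass (>= 0).
#' @param BM_target target Newborn biomass.
#' @return Integer fold; errors with class `commsel_adult_too_small` when
#'   the fold would be 0.
#' @export
dilution_fold <- function(adult_BM, BM_target = 100) {
  if (adult_BM < 0) stop("adult_BM must be non-negative")
  nD <- floor(adult_BM / BM_target)
  if (nD < 1)
    stop(structure(class = c("commsel_adult_too_small", "error",
                             "condition"),
                   list(message = sprintf(
                     "Adult biomass %.6g below BM_target %g", adult_BM,
                     BM_target), call = sys.call(-1))))
  as.integer(nD)
}

newborn_chem <- function(R0) c(R = R0, B = 0, P = 0)

split_community <- function(adult, assign, nD, R0) {
  lapply(seq_len(nD), function(k) {
    community(adult$cells[assign == k, , drop = FALSE],
              chem = newborn_chem(R0), lineage = adult$lineage)
  })
}

#' Partition an Adult by volumetric pipetting
#'
#' Every cell is assigned an independent uniform random integer in
#' `1..n_D`; cells sharing an integer form one Newborn. The multiset of
#' cells is conserved exactly; Newborn biomass and composition fluctuate as
#' they would under pipetting. Chemicals reset to `R = R0, B = 0, P = 0`.
#' Empty Newborns (possible in principle) are retained.
#'
#' @param adult a matured `community`.
#' @param BM_target target Newborn biomass (sets the fold).
#' @param R0 Resource supplied to each Newborn.
#' @return List of `n_D` Newborn communities.
#' @export
partition_pipetting <- function(adult, BM_target = 100, R0 = 1) {
  nD <- dilution_fold(biomass(adult), BM_target)
  assign <- sample.int(nD, nrow(adult$cells), replace = TRUE)
  split_community(adult, assign, nD, R0)
}

#' Partition an Adult by a fixed dilution fold
#'
#' As [partition_pipetting()] but with the fold fixed at `n_D_fixed`
#' regardless of Adult biomass, so expected Newborn biomass is
#' `adult_BM / n_D_fixed` rather than `BM_target` (the failure mode under
#' excess Resource: selection then favors big Newborns).
#'
#' @param adult a matured `community`.
#' @param n_D_fixed constant fold.
#' @param R0 Resource supplied to each Newborn.
#' @return List of `n_D_fixed` Newborns.
#' @export
partition_fixed_fold <- function(adult, n_D_fixed = 100, R0 = 1) {
  assign <- sample.int(n_D_fixed, nrow(adult$cells), replace = TRUE)
  split_community(adult, assign, as.integer(n_D_fixed), R0)
}

# greedy closest-without-exceeding fill: walk candidates (already permuted),
# take any cell that still fits under the cap, skip the rest. Returns the
# indices taken. Cells are 1 <= L < 2, so the filled biomass lands in
# (cap - 2, cap].
fill_to_cap <- function(L, cap) {
  taken <- logical(length(L))
  tot <- 0
  for (i in seq_along(L)) {
    if (tot + L[i] <= cap) {
      taken[i] <- TRUE
      tot <- tot + L[i]
      if (cap - tot < 1) break # no cell is shorter than 1
    }
  }
  which(taken)
}

#' Partition by biomass sorting (fixed BM and fixed phi_M)
#'
#' Emulates a cell sorter: each Newborn receives M cells filled as close to
#' `BM_target * phiM_target` as possible without exceeding it, and H cells
#' likewise to `BM_target * (1 - phiM_target)` (cells that would overshoot
#' are skipped and stay available for later Newborns). Repeated draws are
#' disjoint until the Adult is exhausted.
#'
#' @param adult a matured `community`.
#' @param n_newborns how many Newborns to sort.
#' @param BM_target target Newborn biomass.
#' @param phiM_target target M biomass fraction (defaults to the Adult's
#'   `phi_M`).
#' @param R0 Resource supplied to each Newborn.
#' @return List of Newborns; attribute `exhausted` flags an early stop with
#'   fewer Newborns than requested.
#' @export
partition_sort_biomass <- function(adult, n_newborns, BM_target = 100,
                                   phiM_target = phi_M(adult), R0 = 1) {
  cells <- adult$cells
  pool_M <- sample(which(cells$species == 2L))
  pool_H <- sample(which(cells$species == 1L))
  capM <- BM_target * phiM_target
  capH <- BM_target * (1 - phiM_target)
  out <- list()
  exhausted <- FALSE
  for (k in seq_len(n_newborns)) {
    iM <- fill_to_cap(cells$L[pool_M], capM)
    iH <- fill_to_cap(cells$L[pool_H], capH)
    bmM <- sum(cells$L[pool_M[iM]])
    bmH <- sum(cells$L[pool_H[iH]])
    if ((capM > 0 && bmM <= capM - 2) || (capH > 0 && bmH <= capH - 2)) {
      exhausted <- TRUE # Adult cannot fill the window any more
      break
    }
    rows <- c(pool_M[iM], pool_H[iH])
    out[[k]] <- community(cells[rows, , drop = FALSE],
                          chem = newborn_chem(R0), lineage = adult$lineage)
    if (length(iM)) pool_M <- pool_M[-iM]
    if (length(iH)) pool_H <- pool_H[-iH]
  }
  attr(out, "exhausted") <- exhausted
  out
}

#' Partition by cell-number sorting
#'
#' Fixed integer cell counts per species:
#' `floor(BM_target * varphi_M / mean_cell_length)` M cells and
#' `floor(BM_target * (1 - varphi_M) / mean_cell_length)` H cells, where
#' `varphi_M` is the Adult's cell-number M fraction, drawn uniformly
#' without replacement; counts are independent of individual cell lengths.
#'
#' @inheritParams partition_sort_biomass
#' @param phiM_cells target M cell-number fraction (defaults to the
#'   Adult's).
#' @param mean_cell_length assumed mean cell biomass (1.5).
#' @return List of Newborns (attribute `exhausted` as above).
#' @export
partition_sort_cellnumber <- function(adult, n_newborns, BM_target = 100,
                                      phiM_cells = varphi_M(adult),
                                      mean_cell_length = 1.5, R0 = 1) {
  cells <- adult$cells
  nM <- floor(BM_target * phiM_cells / mean_cell_length)
  nH <- floor(BM_target * (1 - phiM_cells) / mean_cell_length)
  pool_M <- sample(which(cells$species == 2L))
  pool_H <- sample(which(cells$species == 1L))
  out <- list()
  exhausted <- FALSE
  for (k in seq_len(n_newborns)) {
    if (length(pool_M) < nM || length(pool_H) < nH) {
      exhausted <- TRUE
      break
    }
    rows <- c(pool_M[seq_len(nM)], pool_H[seq_len(nH)])
    out[[k]] <- community(cells[rows, , drop = FALSE],
                          chem = newborn_chem(R0), lineage = adult$lineage)
    if (nM) pool_M <- pool_M[-seq_len(nM)]
    if (nH) pool_H <- pool_H[-seq_len(nH)]
  }
  attr(out, "exhausted") <- exhausted
  out
}

#' Partition fixing only one determinant of Newborn composition
#'
#' `which = "BM_only"`: mixed cells are filled closest-without-exceeding to
#' `BM_target`, letting the species fraction fluctuate. `which =
#' "phiM_only"`: M cells are pipetted by random integers over the dilution
#' fold, then each Newborn's H biomass is filled closest-without-exceeding
#' to `M(0) (1 - phiM_T) / phiM_T`, letting total biomass fluctuate.
#'
#' @inheritParams partition_sort_biomass
#' @param which `"BM_only"` or `"phiM_only"`.
#' @return List of Newborns (attribute `exhausted` as above).
#' @export
partition_fix_single_determinant <- function(adult, which = c("BM_only",
                                                              "phiM_only"),
                                             n_newborns = NULL,
                                             BM_target = 100, R0 = 1) {
  which <- match.arg(which)
  cells <- adult$cells
  if (which == "BM_only") {
    if (is.null(n_newborns))
      n_newborns <- dilution_fold(biomass(adult), BM_target)
    pool <- sample(nrow(cells))
    out <- list()
    exhausted <- FALSE
    for (k in seq_len(n_newborns)) {
      i <- fill_to_cap(cells$L[pool], BM_target)
      if (sum(cells$L[pool[i]]) <= BM_target - 2) {
        exhausted <- TRUE
        break
      }
      out[[k]] <- community(cells[pool[i], , drop = FALSE],
                            chem = newborn_chem(R0),
                            lineage = adult$lineage)
      if (length(i)) pool <- pool[-i]
    }
    attr(out, "exhausted") <- exhausted
    return(out)
  }
  # phiM_only: pipette M, then fill H to match the Adult's composition
  nD <- dilution_fold(biomass(adult), BM_target)
  phiM_T <- phi_M(adult)
  iM <- which(cells$species == 2L)
  assignM <- sample.int(nD, length(iM), replace = TRUE)
  pool_H <- sample(which(cells$species == 1L))
  out <- vector("list", nD)
  exhausted <- FALSE
  for (k in seq_len(nD)) {
    rowsM <- iM[assignM == k]
    M0 <- sum(cells$L[rowsM])
    capH <- if (phiM_T > 0) M0 * (1 - phiM_T) / phiM_T else 0
    iH <- fill_to_cap(cells$L[pool_H], capH)
    if (capH >= 2 && sum(cells$L[pool_H[iH]]) <= capH - 2) exhausted <- TRUE
    out[[k]] <- community(cells[c(rowsM, pool_H[iH]), , drop = FALSE],
                          chem = newborn_chem(R0), lineage = adult$lineage)
    if (length(iH)) pool_H <- pool_H[-iH]
  }
  attr(out, "exhausted") <- exhausted
  out
}

#' Found a monoculture Newborn from a single Manufacturer
#'
#' One M cell of length 1 carrying the given phenotype, supplied with fresh
#' Resource; Byproduct is treated as saturating in the monoculture
#' scenario (growth reduces to Monod on Resource), so the Newborn's `B` is
#' only a placeholder.
#'
#' @param fP cost fraction of the founder (copied exactly).
#' @param params an [hm_params()] object for the growth phenotypes.
#' @param gmax,affR,affB founder phenotypes (default from `params`).
#' @param R0 Resource supplied.
#' @return A single-cell `community`.
#' @export
found_monoculture <- function(fP, params = hm_params(), gmax = params$gMmax,
                              affR = params$affMR, affB = params$affMB,
                              R0 = 1) {
  community(cell_df(2L, 1, gmax, affR, affB, fP),
            chem = c(R = R0, B = 0, P = 0))
}
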