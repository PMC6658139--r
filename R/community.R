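#' Construct a community
#'
#' A community is one culture: a table of individual cells plus the amounts
#' of Resource, Byproduct, and Product it contains, and the seed its
#' maturation was (or will be) run under.
#'
#' @param cells data frame with columns `species` (1 = Helper, 2 =
#'   Manufacturer), `L` (cell biomass/length), `gmax`, `affR`, `affB`
#'   (`NA` for H), `fP` (`NA` for H).
#' @param chem named numeric vector `c(R=, B=, P=)`.
#' @param seed RNG seed recorded for replay (`NA` until maturation).
#' @param lineage identifier of the parent Adult (`NA` for founders).
#' @return An object of class `community`.
#' @export
community <- function(cells, chem = c(R = 1, B = 0, P = 0),
                      seed = NA_integer_, lineage = NA_integer_) {
  stopifnot(is.data.frame(cells),
            all(c("species", "L", "gmax", "affR", "affB", "fP") %in%
                  names(cells)))
  if (any(chem < 0)) stop("chemical amounts must be non-negative")
  if (nrow(cells) && any(cells$L <= 0)) stop("cell lengths must be positive")
  structure(list(cells = cells, chem = chem[c("R", "B", "P")], seed = seed,
                 lineage = lineage, extinct = nrow(cells) == 0L),
            class = "community")
}

cell_df <- function(species = integer(), L = numeric(), gmax = numeric(),
                    affR = numeric(), affB = numeric(), fP = numeric()) {
  data.frame(species = as.integer(species), L = L, gmax = gmax, affR = affR,
             affB = affB, fP = fP)
}

#' Found a Newborn community of identical cells
#'
#' Builds the canonical founding configuration: `nH` Helper and `nM`
#' Manufacturer cells, each of biomass 1, all carrying the phenotypes in
#' `params`, with Resource `R0`, no Byproduct, no Product.
#'
#' @param params an [hm_params()] object supplying the phenotypes.
#' @param nH,nM founding cell numbers.
#' @param R0 Resource supplied.
#' @param fP cost carried by the M cells (defaults to `params$fP`).
#' @return A `community`.
#' @export
founder_community <- function(params = hm_params(), nH = 40, nM = 60, R0 = 1,
                              fP = params$fP) {
  cells <- rbind(
    cell_df(rep(1L, nH), rep(1, nH), rep(params$gHmax, nH),
            rep(params$affHR, nH), rep(NA_real_, nH), rep(NA_real_, nH)),
    cell_df(rep(2L, nM), rep(1, nM), rep(params$gMmax, nM),
            rep(params$affMR, nM), rep(params$affMB, nM), rep(fP, nM)))
  community(cells, chem = c(R = R0, B = 0, P = 0))
}

#' Total biomass of a community
#' @param comm a `community`.
#' @return Sum of cell lengths.
#' @export
biomass <- function(comm) sum(comm$cells$L)

#' Fraction of Manufacturer biomass
#' @param comm a `community`.
#' @return `M/(M+H)` by biomass, or `NaN` for an empty community.
#' @export
phi_M <- function(comm) {
  bm <- comm$cells$L
  if (!length(bm)) return(NaN)
  sum(bm[comm$cells$species == 2L]) / sum(bm)
}

# cell-number fraction of M (used by the cell-number sorter)
varphi_M <- function(comm) {
  n <- nrow(comm$cells)
  if (!n) return(NaN)
  sum(comm$cells$species == 2L) / n
}

#' @export
print.community <- function(x, ...) {
  n <- nrow(x$cells)
  cat(sprintf(
    "<community> %d cells (%d H, %d M), biomass %.4g, phi_M %.3f\n",
    n, sum(x$cells$species == 1L), sum(x$cells$species == 2L),
    biomass(x), phi_M(x)))
  cat(sprintf("  R %.6g  B %.6g  P %.6g  seed %s\n", x$chem["R"],
              x$chem["B"], x$chem["P"], as.character(x$seed)))
  invisible(x)
}

#' Deterministic test communities
#'
#' Fixture generator used throughout the test suite (and handy
#' interactively). All fixtures are built in code; no data files.
#'
#' * `monomorphic_newborn`: the canonical Newborn, 40 H + 60 M of biomass 1,
#'   preadapted phenotypes, `fP = 0.13`.
#' * `two_phenotype_newborn`: as above but half the M cells are null
#'   producers (`fP = 0`).
#' * `adult_7000`: an Adult with total biomass exactly 7000 (1600 H + 2400 M
#'   cells of length 1.75, binary-exact), for dilution arithmetic.
#' * `extinct_M`: Helpers only.
#'
#' @param kind fixture name.
#' @param params an [hm_params()] object.
#' @param R0 Resource in the fixture's chemical state.
#' @return A `community`.
#' @export
make_fixture <- function(kind = c("monomorphic_newborn",
                                  "two_phenotype_newborn", "adult_7000",
                                  "extinct_M"),
                         params = hm_params(), R0 = 1) {
  kind <- match.arg(kind)
  switch(kind,
    monomorphic_newborn = founder_community(params, 40, 60, R0, fP = 0.13),
    two_phenotype_newborn = {
      comm <- founder_community(params, 40, 60, R0, fP = 0.13)
      im <- which(comm$cells$species == 2L)
      comm$cells$fP[im[seq_len(length(im) %/% 2)]] <- 0
      comm
    },
    adult_7000 = {
      nH <- 1600L; nM <- 2400L
      cells <- rbind(
        cell_df(rep(1L, nH), rep(1.75, nH), rep(params$gHmax, nH),
                rep(params$affHR, nH), rep(NA_real_, nH), rep(NA_real_, nH)),
        cell_df(rep(2L, nM), rep(1.75, nM), rep(params$gMmax, nM),
                rep(params$affMR, nM), rep(params$affMB, nM),
                rep(0.13, nM)))
      community(cells, chem = c(R = 0.3, B = 5, P = 800))
    },
    extinct_M = {
      comm <- founder_community(params, 40, 0, R0)
      comm
    })
}
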