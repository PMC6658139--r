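#' Epistasis-adjusted mean mutation effects on fP
#'
#' Under diminishing-returns epistasis the mean enhancing effect shrinks and
#' the mean diminishing effect grows as the current cost rises above the
#' reference `fP_init`: `s_plus_eff = s_plus / (1 + g (fP/fP_init - 1))`,
#' `s_minus_eff = s_minus * (1 + g (fP/fP_init - 1))`.
#'
#' @param fP current cost in `[0, 1]`.
#' @param model a [mutation_model()].
#' @return Named vector `c(s_plus =, s_minus =)`.
#' @export
epistatic_means <- function(fP, model) {
  g <- model$epistasis_g
  fac <- 1 + g * (fP / model$fP_init - 1)
  if (fac <= 0)
    stop("epistasis factor produced a non-positive mean effect")
  c(s_plus = model$s_plus / fac, s_minus = model$s_minus * fac)
}

#' Inverse-CDF sample of a relative mutation effect
#'
#' Maps uniform draws `u2` through the exact inverse of the bilateral
#' exponential CDF (including the `exp(-1/s_minus)` truncation term at the
#' `delta = -1` boundary). Draws with `u2 <= C(0) = s_minus (1 -
#' e^{-1/s_minus}) / (s_plus + s_minus (1 - e^{-1/s_minus}))` fall on the
#' diminishing branch.
#'
#' @param u2 uniform(0,1) draws (strictly inside the interval).
#' @param s_plus,s_minus mean enhancing / diminishing effects.
#' @return Relative effects `delta` in `(-1, Inf)` (vectorized).
#' @export
sample_relative_effect <- function(u2, s_plus = 0.050, s_minus = 0.067) {
  sample_delta_cpp(u2, s_plus, s_minus)
}

#' Mutate a single phenotype value
#'
#' With probability `p_null` the value becomes 0 (null mutation); otherwise
#' it is multiplied by `1 + delta` with `delta` from
#' [sample_relative_effect()] (epistasis-adjusted means when `fP_context`
#' is supplied and epistasis is on). The result is clamped to
#' `[bound_lo, bound_hi]`.
#'
#' @param value current parameter value.
#' @param bound_lo,bound_hi evolutionary bounds.
#' @param model a [mutation_model()].
#' @param fP_context current `fP` when the mutated parameter is `fP` itself
#'   and epistasis is enabled; `NULL` otherwise.
#' @return The mutated value.
#' @export
mutate_phenotype <- function(value, bound_lo = 0, bound_hi, model,
                             fP_context = NULL) {
  u1 <- stats::runif(1)
  if (u1 < model$p_null) return(0)
  s <- c(s_plus = model$s_plus, s_minus = model$s_minus)
  if (!is.null(fP_context) && model$epistasis_g > 0)
    s <- epistatic_means(fP_context, model)
  u2 <- stats::runif(1)
  d <- sample_relative_effect(u2, s[["s_plus"]], s[["s_minus"]])
  min(max(value * (1 + d), bound_lo), bound_hi)
}

#' Mutate a freshly divided mother/daughter pair
#'
#' Each of the two cells, mother first, mutates each of its mutable
#' phenotypes independently with probability `P_mut` (canonical phenotype
#' order: `gmax`, `affR`, then for M cells `affB`, `fP`).
#'
#' @param mother,daughter single-row cell data frames (`species`, `L`,
#'   `gmax`, `affR`, `affB`, `fP`).
#' @param model a [mutation_model()].
#' @param bounds evolutionary upper bounds, e.g. `hm_params()$bounds`.
#' @return List of the two (possibly mutated) cells.
#' @export
mutate_divided_pair <- function(mother, daughter, model,
                                bounds = hm_params()$bounds) {
  out <- lapply(list(mother, daughter), function(cell) {
    m <- mutate_cell_cpp(cell$species, cell$gmax, cell$affR, cell$affB,
                         cell$fP, unclass(model), bounds)
    cell$gmax <- m$gmax
    cell$affR <- m$affR
    cell$affB <- m$affB
    cell$fP <- m$fP
    cell
  })
  names(out) <- c("mother", "daughter")
  out
}

# closed-form CDF of the relative-effect distribution; the independent
# reference the sampler is tested against
relative_effect_cdf <- function(x, s_plus = 0.050, s_minus = 0.067) {
  trunc <- exp(-1 / s_minus)
  D <- s_plus + s_minus * (1 - trunc)
  ifelse(x < 0,
         s_minus / D * (exp(x / s_minus) - trunc),
         1 - s_plus / D * exp(-x / s_plus))
}
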