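# shared fixtures: everything is generated in code at test time

pre <- hm_params()                        # growth parameters at upper bounds
anc <- hm_params("ancestral")
no_death <- hm_params(deltaH = 0, deltaM = 0)
mut_off <- mutation_model(P_mut = 0)

# an Adult-sized community with lengths uniform on [1, 2) (Lbar = 1.5),
# species fractions as asked; deterministic given the seed
random_adult <- function(n_cells = 4000, phiM = 0.6, seed = 99,
                         params = pre, fP = 0.13) {
  set.seed(seed)
  nM <- round(n_cells * phiM)
  nH <- n_cells - nM
  L <- runif(n_cells, 1, 2)
  cells <- rbind(
    data.frame(species = 1L, L = L[seq_len(nH)], gmax = params$gHmax,
               affR = params$affHR, affB = NA_real_, fP = NA_real_),
    data.frame(species = 2L, L = L[nH + seq_len(nM)], gmax = params$gMmax,
               affR = params$affMR, affB = params$affMB, fP = fP))
  community(cells, chem = c(R = 0.2, B = 4, P = 700))
}

# adult whose cells all have length exactly 1 (exact counting tests)
unit_adult <- function(nH = 40, nM = 60, params = pre, fP = 0.13) {
  founder_community(params, nH, nM, R0 = 1, fP = fP)
}
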