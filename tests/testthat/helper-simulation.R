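# Shared fixture builders. Everything is generated in code at test time.

# population with explicit allele matrices (entries +1/-1)
make_pop <- function(a1, a2, female = rep(c(TRUE, FALSE), length.out = nrow(a1)),
                     z = NULL, t = 0L) {
  pop <- population_state(t, a1, a2, female,
                          z = if (is.null(z)) numeric(nrow(a1)) else z)
  if (is.null(z)) pop$z <- genotype_values(pop)
  pop
}

# single-individual population with a given number of positive allele copies
pop_with_copies <- function(n_pos, m = 25) {
  signs <- c(rep(1L, n_pos), rep(-1L, 2 * m - n_pos))
  make_pop(matrix(signs[1:m], 1, m), matrix(signs[(m + 1):(2 * m)], 1, m),
           female = TRUE)
}

# hand-built trajectory for classification tests; vectors are recycled
fake_traj <- function(N, Rbar = rep(1, length(N)), gbar = rep(0, length(N)),
                      sigma_a2 = rep(0.5, length(N)), status = "surviving",
                      theta = 2.8) {
  records <- data.frame(t = seq_along(N) - 1L, N = N, gbar = gbar,
                        zbar = gbar, Wbar = Rbar, Rbar = Rbar,
                        sigma_a2 = sigma_a2, fixed_pos = 0, fixed_neg = 0)
  ext <- which(N <= 1)
  structure(list(records = records, status = status,
                 extinction_gen = if (length(ext)) records$t[ext[1]] else NA_integer_,
                 maladaptation0 = theta - gbar[1],
                 params = sim_params(N0 = max(N[1], 2), theta = theta)),
            class = "rescue_trajectory")
}

default_params <- function(...) sim_params(seed = 99, ...)
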