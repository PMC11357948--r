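# shared fixtures: a default shape, typical parameters and small helpers

sh_default <- qeps_shape()

pars_typical <- qeps_params(Emax = 62.76, Qmax = 98.51, Pmax = 12.92,
                            Etsc = 1, Ptsc = 1, AgeP50 = 11.98)

# a dense, well-spanned visit schedule for fitting tests
ages_dense <- c(0.25, 0.5, 0.75, 1, 1.5, 2, 3:18)

noiseless_series <- function(pars, ages = ages_dense, consts = sh_default) {
  data.frame(age = ages, height = qeps_components(ages, pars, consts)$T)
}

# random in-bounds parameter sets for property loops
random_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    qeps_params(Emax = runif(1, 55, 70), Qmax = runif(1, 80, 115),
                Pmax = runif(1, 2, 22), Etsc = runif(1, 0.8, 1.3),
                Ptsc = runif(1, 0.6, 1.6), AgeP50 = runif(1, 9.5, 14.5)))
}
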