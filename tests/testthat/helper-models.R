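# shared fixtures: the reference dimer/monomer conditions used throughout
# (strong coupling, immobile-fluorophore monomer anisotropy, fully
# depolarized sensitized emission)

dimer_model <- function(coupling = 1)
  oligomer_model(2L, r_mono = 0.35, r_et = 0, coupling = coupling)

monomer_model <- function() oligomer_model(1L, r_mono = 0.35, r_et = 0,
                                           coupling = 0)

default_conditions <- function(n_frames = 50L)
  list(switching = switching_params(p_off_per_frame = 0.08,
                                    n_frames = n_frames),
       camera = camera_model(), optics = optics_config())

# independent textbook OLS oracle: explicit normal equations on the design
# matrix, kept free of the package's ols code path
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  n <- length(x)
  s <- sqrt(sum(resid^2) / (n - 2))
  ss_xx <- sum((x - mean(x))^2)
  list(a = beta[1L], b = beta[2L], s = s, s_beta1 = s / sqrt(ss_xx),
       ss_xx = ss_xx)
}

# brute-force binomial mixture, independent of ensemble_anisotropy's
# vapply/dbinom path
ensemble_oracle <- function(p, model) {
  n <- model$n_subunits
  total <- 0
  for (j in 0:(n - 1L)) {
    w <- choose(n - 1L, j) * p^j * (1 - p)^(n - 1L - j)
    total <- total + w * cluster_anisotropy(j + 1L, model)
  }
  total
}
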