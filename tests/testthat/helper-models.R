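# shared fixtures: Table-1 base models and random model generators

hchop_os <- function() parametric_survival("lognormal", c(meanlog = 3.284, sdlog = 1.938))
hchop_pfs <- function() parametric_survival("lognormal", c(meanlog = 2.998, sdlog = 1.884))
rchop_os <- function() parametric_survival("lognormal", c(meanlog = 2.925, sdlog = 1.843))
rchop_pfs <- function() parametric_survival("lognormal", c(meanlog = 3.007, sdlog = 2.195))

# effectively immortal cohort (exponential with negligible hazard)
const_surv <- function() parametric_survival("exponential", c(rate = 1e-15))

# random plausible lognormal survival model
rand_lnorm <- function() {
  parametric_survival("lognormal",
                      c(meanlog = runif(1, 1, 4), sdlog = runif(1, 0.5, 2.5)))
}

# closed-form lognormal survival, independent of survival_at()
lnorm_surv <- function(t, meanlog, sdlog) {
  ifelse(t <= 0, 1, 1 - pnorm((log(t) - meanlog) / sdlog))
}
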