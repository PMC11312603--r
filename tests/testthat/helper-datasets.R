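# fixtures built in code: small tabular datasets with declared roles

simple_roles <- function(weight = NULL, wave = NULL) {
  variable_roles(outcome = "exam", living_standard = "pce",
                 need = "chronic", control = "education",
                 weight = weight, wave = wave)
}

# random person-level table with a mild pro-rich gradient
simple_table <- function(n, seed = 1) {
  withr::with_seed(seed, {
    pce <- rlnorm(n, 8, 0.8)
    r <- rank(pce) / n
    tibble::tibble(
      exam = rbinom(n, 1, 0.2 + 0.3 * r),
      pce = pce,
      chronic = factor(sample(c("no", "yes"), n, TRUE),
                       levels = c("no", "yes")),
      education = factor(sample(c("low", "high"), n, TRUE),
                         levels = c("low", "high")),
      wave = rep(2011, n)
    )
  })
}

simple_ds <- function(n = 200, seed = 1, ...) {
  analytic_dataset(simple_table(n, seed), simple_roles(...), quiet = TRUE)
}

# nonnegative outcomes from assorted families, for index-bound checks
random_nonneg_outcome <- function(n) {
  switch(sample(4, 1),
         rbinom(n, 1, runif(1, 0.05, 0.95)),
         rpois(n, runif(1, 0.2, 5)),
         rexp(n, 1),
         rlnorm(n, 0, runif(1, 0.2, 1.5)))
}
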