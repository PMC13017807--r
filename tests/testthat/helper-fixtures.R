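# Shared fixtures for the suite. Everything is generated in code; no
# binary data.

default_params <- function(...) species_params(...)

moderate_meteo <- function(Q = 1000, Ta = 30, D = 2, ca = 400, P = 95,
                           ...) {
  meteo_inputs(Q = Q, Ta = Ta, D = D, ca = ca, P = P, ...)
}

# turn a forward() solution + its drivers into a gas-exchange record list
solution_record <- function(meteo, sol) {
  c(as.list(meteo[1, c("Q", "Ta", "Tl", "D", "ca", "P", "day_id")]),
    list(A = sol$A, E = sol$E, gs = sol$gs, ci = sol$ci))
}

# random meteorology draws for property tests (finite, moderate ranges)
draw_meteo <- function(n, seed) {
  with_seed_test(seed, {
    meteo_inputs(Q = stats::runif(n, 100, 2000),
                 Ta = stats::runif(n, 15, 40),
                 D = stats::runif(n, 0.5, 4),
                 ca = stats::runif(n, 350, 450),
                 P = stats::runif(n, 90, 101),
                 day_id = rep_len(1:4, n))
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
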