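# Shared fixtures: tiny phantom cohorts and desk-scale models built in code.

tiny_config <- function(n = 4, seed = 7, ...) {
  phantom_config(n_patients = n, image_size = 48, seed = seed, ...)
}

tiny_cohort <- function(n = 4, seed = 7, ...) {
  simulate_cohort(tiny_config(n = n, seed = seed, ...))
}

tiny_model <- function(seed = 1, d_model = 16, n_heads = 2, n_layers = 2,
                       input = "marker", ...) {
  risk_model(input = input, d_model = d_model, n_heads = n_heads,
             n_layers = n_layers, d_ff = 2 * d_model, seed = seed, ...)
}

# brute-force Harrell concordance: all pairs, ties count one half
brute_cindex <- function(score, time, event) {
  n <- length(score)
  conc <- 0; comp <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- i; b <- j
    if (time[b] < time[a]) { a <- j; b <- i }
    if (time[a] == time[b]) {
      # tied event times are incomparable; death + censored at the same
      # time is comparable with the death failing first
      if (event[a] + event[b] != 1) next
      if (event[b] == 1) { tmp <- a; a <- b; b <- tmp }
    } else if (event[a] != 1) next     # the earlier time must be an event
    comp <- comp + 1
    conc <- conc + if (score[a] > score[b]) 1 else if (score[a] == score[b]) 0.5 else 0
  }
  if (comp == 0) return(NA_real_)
  conc / comp
}

# concordance of a score against an uncensored continuous target
concordance_with <- function(score, target) {
  brute_cindex(score, -target, rep(1, length(target)))
}

random_embedding <- function(n_seq, n_tp, d, seed) {
  withr::with_seed(seed, array(rnorm(n_seq * n_tp * d), c(n_seq, n_tp, d)))
}
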