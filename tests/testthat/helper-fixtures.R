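# shared fixture builders; everything is generated in code at test time

quiet_fit_trend <- function(...) suppressWarnings(fit_trend(...))

# a clean EDA trace with known injected kernels and gentle tonic activity
make_oracle_eda <- function(times, amps, seed, noise_sd = 2e-4,
                            rw_sd = 0, drift = 0.002) {
  generate_eda_trace(data.frame(time = times, amplitude = amps),
                     tonic_params = list(level = 2, drift = drift,
                                         rw_sd = rw_sd),
                     noise_sd = noise_sd, seed = seed)
}

# balanced trial records with known condition means and random intercepts
make_balanced_records <- function(n_participants = 20,
                                  means = c(neutral = 1, amusement = 2,
                                            awe = 4),
                                  intercept_sd = 0.5, noise_sd = 0.1,
                                  seed = 1) {
  set.seed(seed)
  cond <- rep(rep(names(means), each = 2), n_participants)
  pid <- rep(sprintf("p%02d", seq_len(n_participants)), each = 6)
  u <- rnorm(n_participants, 0, intercept_sd)
  y <- means[cond] + u[match(pid, unique(pid))] +
    rnorm(length(cond), 0, noise_sd)
  data.frame(participant = pid, condition = cond, y = as.numeric(y),
             temperature = rep(rnorm(n_participants, 24, 1.5), each = 6),
             humidity = rep(rnorm(n_participants, 50, 8), each = 6),
             stringsAsFactors = FALSE)
}

tiny_session_config <- function(seed = 1, n = 4, duration = 30) {
  synthetic_config(n_participants = n, duration_s = duration, seed = seed)
}
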