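# shared in-code fixtures: gaze trace builders and a small study table

mk_traces <- function(xy_fn, P, n, rate = 60) {
  lapply(seq_len(P), function(p) {
    list(participant = sprintf("p%02d", p), viewing = 1L, trailer = 1L,
         time_ms = (seq_len(n) - 1L) * 1000 / rate,
         xy = xy_fn(p), valid = rep(TRUE, n))
  })
}

uniform_traces <- function(P, n, seed = 1) {
  withr::with_seed(seed, mk_traces(function(p)
    cbind(runif(n, 0, 1024), runif(n, 0, 768)), P, n))
}

# one smooth screen-traversing path followed by everyone, plus jitter
synchronized_traces <- function(P, n, jitter = 5, seed = 1) {
  tt <- (seq_len(n) - 1L) / 60
  path <- cbind(512 + 400 * sin(2 * pi * 0.10 * tt),
                384 + 300 * cos(2 * pi * 0.13 * tt))
  withr::with_seed(seed, mk_traces(function(p)
    path + matrix(rnorm(2 * n, sd = jitter), ncol = 2), P, n))
}

# study table whose metric columns are exactly coupled to the premiere KPI
toy_study <- function(seed = 1) {
  withr::with_seed(seed, {
    n <- 10
    metric <- seq(0.1, 0.9, length.out = n)
    kpi <- data.frame(premiere = 0.3 + 0.8 * metric + rnorm(n, sd = 0.05))
    for (j in 1:8) kpi[[paste0("wknd", j)]] <-
      kpi$premiere * 0.45^j * exp(rnorm(n, sd = 0.1))
    cbind(kpi, asy_v1 = -metric + rnorm(n, sd = 0.05),
          asy_v2 = -metric + rnorm(n, sd = 0.08),
          cogn_40_48 = metric + rnorm(n, sd = 0.05),
          cogn_52_60 = metric + rnorm(n, sd = 0.08),
          cogn_60_70 = metric + rnorm(n, sd = 0.05),
          cogn_52_70 = metric + rnorm(n, sd = 0.04))
  })
}
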