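# shared fixtures: everything is generated in code at test time

default_layout <- build_default_layout()

# small, fast design for pipeline tests (4 trials instead of 20)
small_design <- function(fs = 7.14) make_design(n_trials = 4, fs = fs)

# a minimal group list accepted by analyze_group()
tiny_group <- function(n_subjects = 4, scenario = "null", seed = 1,
                       design = small_design()) {
  simulate_group(n_subjects, default_layout, scenario, seed = seed,
                 design = design)
}

# naive sliding-median oracle with shrinking edge windows
naive_sliding_median <- function(x, window) {
  h <- (window - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - h):min(n, i + h)]
    if (length(w) %% 2 == 0) mean(sort(w)[c(length(w) / 2, length(w) / 2 + 1)])
    else sort(w)[(length(w) + 1) / 2]
  }, numeric(1))
}

# brute-force BH step-up oracle: largest k with p_(k) <= k q / m rejected
naive_bh_flags <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) * q / m)
  flags <- logical(m)
  if (length(ks) > 0) flags[o[seq_len(max(ks))]] <- TRUE
  flags
}

expect_setequal_int <- function(a, b) {
  testthat::expect_setequal(as.integer(a), as.integer(b))
}
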