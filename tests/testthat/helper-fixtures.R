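# Shared fixtures, memoized so expensive simulations are built once per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

model_hr <- function(hr = 60, fs = 250) {
  fixture(sprintf("model_%g_%g", hr, fs),
          template_from_features(default_rest_features(hr), hr, fs))
}

clean_train <- function(hr = 60, dur = 30, fs = 250) {
  fixture(sprintf("clean_%g_%g_%g", hr, dur, fs),
          synthesize_ecg(model_hr(hr, fs), dur, 0))
}

sim_fixture <- function(snr = -5, seed = 11, hr = 60, dur = 60) {
  fixture(sprintf("sim_%g_%d_%g_%g", snr, seed, hr, dur),
          simulate_record(model_hr(hr),
                          contamination_spec(target_snr_in = snr, seed = seed),
                          dur))
}

# exhaustive enumeration of all admissible monotone warp paths; independent
# oracle for the DTW dynamic program
brute_dtw_cost <- function(a, b) {
  m <- length(a); n <- length(b)
  best <- Inf
  rec <- function(x, y, acc) {
    acc <- acc + abs(a[x] - b[y])
    if (acc >= best) return(invisible())
    if (x == m && y == n) { best <<- acc; return(invisible()) }
    if (x < m) rec(x + 1, y, acc)
    if (y < n) rec(x, y + 1, acc)
    if (x < m && y < n) rec(x + 1, y + 1, acc)
  }
  rec(1, 1, 0)
  best
}

# sequences over an alphabet, all lengths 1..maxlen
all_seqs <- function(alphabet, maxlen) {
  out <- list()
  for (len in seq_len(maxlen)) {
    g <- do.call(expand.grid, rep(list(alphabet), len))
    out <- c(out, lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ])))
  }
  out
}
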