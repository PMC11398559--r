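# Independent oracles and tiny fixture builders used across tests.

# Brute-force DTW: recursive minimum accumulated squared cost over all
# monotone warping paths with steps (1,0), (0,1), (1,1) and aligned
# endpoints.  Deliberately naive; no dynamic-programming table.
brute_dtw <- function(x, y) {
  rec <- function(i, j) {
    c0 <- (x[i] - y[j])^2
    if (i == 1L && j == 1L) return(c0)
    best <- Inf
    if (i > 1L && j > 1L) best <- min(best, rec(i - 1L, j - 1L))
    if (i > 1L) best <- min(best, rec(i - 1L, j))
    if (j > 1L) best <- min(best, rec(i, j - 1L))
    c0 + best
  }
  sqrt(rec(length(x), length(y)))
}

# all sequences of length 1..maxlen over the given alphabet
all_sequences <- function(maxlen, values = 0:2) {
  out <- list()
  for (L in seq_len(maxlen)) {
    g <- do.call(expand.grid, rep(list(values), L))
    out <- c(out, lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ])))
  }
  out
}

# two tight, far-separated blocks of 13-day trajectories
two_block_matrix <- function(n_per = 10L, levels = c(2, 12), sd = 0.2,
                             seed = 1L) {
  set.seed(seed)
  m <- rbind(
    matrix(levels[1L] + rnorm(n_per * 13L, 0, sd), n_per, 13L),
    matrix(levels[2L] + rnorm(n_per * 13L, 0, sd), n_per, 13L)
  )
  rownames(m) <- sprintf("p%02d", seq_len(2L * n_per))
  m
}

# small vitals fixture: one patient, samples at given hour offsets
vitals_fixture <- function(values, hours, parameter = "HR",
                           patient_id = "p1",
                           admission = as.POSIXct("2017-03-01 00:00:00", tz = "UTC")) {
  list(
    vitals = data.frame(patient_id = rep(patient_id, length(values)),
                        timestamp = admission + hours * 3600,
                        parameter = rep(parameter, length(values)),
                        value = values,
                        stringsAsFactors = FALSE),
    admissions = data.frame(patient_id = patient_id,
                            admission_time = admission,
                            stringsAsFactors = FALSE)
  )
}

# random valid CFS sub-score targets under the note rule
random_targets <- function() {
  setNames(c(sample(0:3, 4L, replace = TRUE), sample(c(0L, 2L), 2L, replace = TRUE)),
           CFS_CATEGORIES)
}
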