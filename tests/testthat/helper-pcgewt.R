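# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

# default-fs filter bank, reused across tests
test_bank <- function(nfft = 1024L) {
  key <- paste0("bank", nfft)
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- ewt_filter_bank(2000, nfft = nfft)
  .fixtures[[key]]
}

# one preprocessed synthetic participant plus ground truth
test_participant <- function(stenosis = 30, seed = 42, ...) {
  key <- sprintf("part_%s_%s_%s", stenosis, seed, paste(c(...), collapse = "_"))
  if (is.null(.fixtures[[key]])) {
    sim <- simulate_participant(stenosis, n_cycles = 14, params = sim_params(...),
                                seed = seed, participant_id = "TP")
    .fixtures[[key]] <- list(sim = sim, rec = preprocess_pcg(sim$record))
  }
  .fixtures[[key]]
}

# a manifest resembling the default cohort, without simulating any audio
test_manifest <- function(seed = 7) {
  spec <- default_cohort_spec()
  set.seed(seed)
  st <- unlist(lapply(seq_len(nrow(spec)), function(g)
    stats::runif(spec$n[g], spec$lo[g], spec$hi[g])))
  data.frame(participant_id = sprintf("P%03d", seq_along(st)),
             stenosis_pct = st, path = NA_character_,
             label = stenosis_to_class(st), stringsAsFactors = FALSE)
}

# the full default synthetic cohort with extracted features (used by the
# acceptance tests; ~15 s, built once)
test_cohort_features <- function(seed = 11) {
  key <- paste0("cohort", seed)
  if (is.null(.fixtures[[key]])) {
    cohort <- simulate_cohort(seed = seed)
    feats <- extract_cohort_features(cohort)
    .fixtures[[key]] <- list(cohort = cohort, feats = feats)
  }
  .fixtures[[key]]
}

# cleanly separable 3-class feature set grouped by participant
separable_features <- function(n_part_per_class = 8L, rows_per_part = 5L, seed = 3) {
  set.seed(seed)
  classes <- c("mild", "moderate", "severe")
  centers <- rbind(c(-4, 0), c(0, 4), c(4, 0))
  out <- list()
  for (ci in seq_along(classes)) {
    for (p in seq_len(n_part_per_class)) {
      id <- sprintf("%s_%02d", classes[ci], p)
      x <- sweep(matrix(stats::rnorm(rows_per_part * 2, sd = 0.3), ncol = 2),
                 2, centers[ci, ], "+")
      out[[length(out) + 1L]] <- data.frame(participant_id = id,
                                            label = classes[ci],
                                            f1 = x[, 1], f2 = x[, 2])
    }
  }
  do.call(rbind, out)
}
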