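# Synthetic phonocardiogram cohorts with ground-truth event times.
#
# Each cardiac cycle is two Gaussian-enveloped valve sounds (S1, S2). Valve
# closures are mildly broadband, so each burst carries a dominant
# low-frequency tone plus a weaker high-frequency "click" component; the
# click is what survives the 200 Hz high-pass used for S2 detection. The
# stenotic murmur is band-limited Gaussian noise injected into early
# diastole, its amplitude a strictly increasing function of stenosis percent.

#' Simulator parameters
#'
#' Defaults describe a resting adult with a high-SNR chest-wall recording:
#' 75 +/- 5 bpm, S1/S2 tone centers 60/90 Hz with 70/60 ms envelopes plus
#' 220/250 Hz click components, murmur band 150-700 Hz occupying 60-300 ms
#' after the end of S2, and 50 dB broadband SNR. `murmur_amp_30` is the
#' murmur RMS amplitude at 30% stenosis; it was calibrated once, through the
#' full preprocessing + EWT pipeline, so that the cohort-mean band-2 energy
#' e(2) at 30% stenosis lands at ~1e-6 V^2 s.
#'
#' @param ... named overrides of any default.
#' @return list of simulator parameters.
#' @export
sim_params <- function(...) {
  p <- list(
    fs = 2000,
    heart_rate_bpm = c(mean = 75, sd = 5),
    s1_freq = 60, s2_freq = 90,
    s1_click_freq = 220, s2_click_freq = 250,
    click_rel = 0.35,
    s1_dur = 0.070, s2_dur = 0.060,
    s1_amp = 1.0, s2_amp = 0.8,
    systole_fraction = 0.4,
    murmur_band = c(150, 700),
    murmur_amp_30 = 7e-3,     # RMS amplitude at 30% stenosis (calibrated)
    murmur_exp = 1.5,          # amplitude ~ stenosis^1.5
    murmur_start = 0.060,      # s after S2 end
    murmur_end = 0.300,        # s after S2 end
    cycle_gain_sdlog = 0.2,    # lognormal per-cycle murmur jitter
    rumble_amp = 0.015,        # stenosis-independent low-frequency background
    rumble_band = c(15, 80),
    rumble_sdlog = 0.3,        # lognormal per-participant rumble jitter
    noise_snr_db = 50
  )
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  stopifnot(p$s1_dur > 0, p$s2_dur > 0, p$systole_fraction > 0, p$systole_fraction < 1)
  p
}

#' Murmur amplitude for a given stenosis percent
#'
#' Deterministic, strictly increasing power law
#' `murmur_amp_30 * (stenosis_pct / 30)^murmur_exp`, zero at 0%.
#'
#' @param stenosis_pct stenosis percent in `[0, 100]` (vectorized).
#' @param params a [sim_params()] list.
#' @return murmur RMS amplitude (dimensionless signal units).
#' @export
murmur_gain <- function(stenosis_pct, params = sim_params()) {
  if (any(stenosis_pct < 0 | stenosis_pct > 100)) stop("stenosis_pct must lie in [0, 100]")
  params$murmur_amp_30 * (stenosis_pct / 30)^params$murmur_exp
}

tukey_window <- function(n, alpha = 0.25) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  edge <- alpha / 2
  lo <- t < edge
  hi <- t > 1 - edge
  w[lo] <- 0.5 * (1 + cos(pi * (t[lo] / edge - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((t[hi] - 1 + edge) / edge)))
  w
}

# add a Gaussian-enveloped two-component burst in place
add_burst <- function(x, fs, center, amp, f0, f_click, click_rel, dur, phases) {
  sigma <- dur / 6
  i0 <- max(1L, floor((center - 4 * sigma) * fs) + 1L)
  i1 <- min(length(x), ceiling((center + 4 * sigma) * fs) + 1L)
  if (i1 < i0) return(x)
  t <- (seq(i0, i1) - 1) / fs - center
  env <- exp(-t^2 / (2 * sigma^2))
  x[i0:i1] <- x[i0:i1] + amp * env *
    (sin(2 * pi * f0 * t + phases[1]) + click_rel * sin(2 * pi * f_click * t + phases[2]))
  x
}

#' Simulate one participant's heart-sound record
#'
#' @param stenosis_pct stenosis percent in `[0, 100]`.
#' @param n_cycles number of cardiac cycles (>= 1).
#' @param params a [sim_params()] list.
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @param participant_id identifier stored on the record.
#' @return list with `record` (a [pcg_record()]) and `truth`, a `data.frame`
#'   of per-cycle S1 onset, S2 onset and S2 end times (seconds) with the
#'   per-record murmur amplitude as attribute `murmur_amp`.
#' @export
simulate_participant <- function(stenosis_pct, n_cycles = 14, params = sim_params(),
                                 seed = 1L, participant_id = "sim") {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (stenosis_pct < 0 || stenosis_pct > 100) stop("stenosis_pct must lie in [0, 100]")
  fs <- params$fs
  set.seed(as.integer(seed))

  bpm <- pmin(pmax(stats::rnorm(n_cycles, params$heart_rate_bpm[["mean"]],
                                params$heart_rate_bpm[["sd"]]), 40), 150)
  rr <- 60 / bpm
  s1_center <- 0.3 + c(0, cumsum(rr[-n_cycles]))
  s2_center <- s1_center + params$systole_fraction * rr
  sigma2 <- params$s2_dur / 6
  s2_end <- s2_center + sigma2 * sqrt(2 * log(10))  # envelope decays to 10% of peak

  duration <- s2_end[n_cycles] + params$murmur_end + 0.4
  n <- ceiling(duration * fs)
  x <- numeric(n)

  for (i in seq_len(n_cycles)) {
    x <- add_burst(x, fs, s1_center[i], params$s1_amp, params$s1_freq,
                   params$s1_click_freq, params$click_rel, params$s1_dur,
                   stats::runif(2, 0, 2 * pi))
    x <- add_burst(x, fs, s2_center[i], params$s2_amp, params$s2_freq,
                   params$s2_click_freq, params$click_rel, params$s2_dur,
                   stats::runif(2, 0, 2 * pi))
  }

  # unit murmur waveform; the stenosis-dependent gain multiplies it at the
  # end so band energy is exactly monotone in the gain for a fixed seed
  murmur_unit <- numeric(n)
  sdlog <- params$cycle_gain_sdlog
  for (i in seq_len(n_cycles)) {
    j0 <- floor((s2_end[i] + params$murmur_start) * fs) + 1L
    j1 <- min(n, ceiling((s2_end[i] + params$murmur_end) * fs))
    len <- j1 - j0 + 1L
    if (len < 8L) next
    jitter <- stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    seg <- bandlimited_noise(len, fs, params$murmur_band) * tukey_window(len, 0.25)
    murmur_unit[j0:j1] <- murmur_unit[j0:j1] + jitter * seg
  }
  amp <- murmur_gain(stenosis_pct, params)
  x <- x + amp * murmur_unit

  # stenosis-independent low-frequency diastolic background (part of the
  # noise model: it dominates e(1) so band-1 energy carries no stenosis
  # ordering, mirroring clinical behavior)
  if (params$rumble_amp > 0) {
    r_jit <- stats::rlnorm(1, meanlog = -params$rumble_sdlog^2 / 2,
                           sdlog = params$rumble_sdlog)
    x <- x + params$rumble_amp * r_jit *
      bandlimited_noise(n, fs, params$rumble_band, edge_hz = 10)
  }

  if (is.finite(params$noise_snr_db)) {
    p_sig <- mean(x^2)
    noise_sd <- sqrt(p_sig / 10^(params$noise_snr_db / 10))
    x <- x + stats::rnorm(n, 0, noise_sd)
  }

  sigma1 <- params$s1_dur / 6
  truth <- data.frame(
    cycle = seq_len(n_cycles),
    s1_onset = s1_center - 3 * sigma1,
    s2_onset = s2_center - 3 * sigma2,
    s2_end = s2_end
  )
  attr(truth, "murmur_amp") <- amp
  rec <- pcg_record(x, fs, participant_id = participant_id,
                    r_times = s1_center - 3 * sigma1 - 0.03,
                    stenosis_pct = stenosis_pct)
  pcg_log("simulate_participant %s: %d cycles, %d samples", participant_id, n_cycles, n)
  list(record = rec, truth = truth)
}

#' Default cohort composition
#'
#' Seven stenosis groups (sizes 10/10/10/15/10/10/10, 75 participants in
#' total) spanning 0 to 95 percent occlusion, mirroring a clinically graded
#' LAD cohort.
#'
#' @return `data.frame` with columns `name`, `n`, `lo`, `hi`.
#' @export
default_cohort_spec <- function() {
  data.frame(
    name = c("normal", "s30", "s40_50", "s50_60", "s70_75", "s85", "s90_95"),
    n = c(10L, 10L, 10L, 15L, 10L, 10L, 10L),
    lo = c(0, 30, 40, 50, 70, 85, 90),
    hi = c(0, 30, 50, 60, 75, 85, 95)
  )
}

#' Simulate a labeled cohort
#'
#' Per-participant stenosis is drawn uniformly within its group range and
#' per-participant seeds are derived from the master seed, so the whole
#' cohort is reproducible from one integer.
#'
#' @param spec group table as from [default_cohort_spec()].
#' @param n_cycles cycles per participant (default 14, so that 10 valid
#'   diastoles survive extraction).
#' @param params a [sim_params()] list.
#' @param seed master integer seed.
#' @return list with `manifest` (a `cohort_manifest` data.frame), `records`
#'   and `truths` (lists keyed by participant id), and `params`.
#' @export
simulate_cohort <- function(spec = default_cohort_spec(), n_cycles = 14,
                            params = sim_params(), seed = 1L) {
  if (is.null(spec)) stop("empty cohort spec")
  total <- sum(spec$n)
  if (total == 0L) {
    manifest <- data.frame(participant_id = character(), stenosis_pct = numeric(),
                           path = character(), label = character())
    class(manifest) <- c("cohort_manifest", "data.frame")
    return(list(manifest = manifest, records = list(), truths = list(), params = params))
  }
  set.seed(as.integer(seed))
  stenosis <- unlist(lapply(seq_len(nrow(spec)), function(g)
    stats::runif(spec$n[g], spec$lo[g], spec$hi[g])))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, total)
  ids <- sprintf("P%03d", seq_len(total))

  records <- vector("list", total); truths <- vector("list", total)
  for (i in seq_len(total)) {
    sim <- simulate_participant(stenosis[i], n_cycles = n_cycles, params = params,
                                seed = sub_seeds[i], participant_id = ids[i])
    records[[i]] <- sim$record
    truths[[i]] <- sim$truth
  }
  names(records) <- ids; names(truths) <- ids
  manifest <- data.frame(participant_id = ids, stenosis_pct = stenosis,
                         path = NA_character_,
                         label = vapply(stenosis, stenosis_to_class, character(1)),
                         stringsAsFactors = FALSE)
  class(manifest) <- c("cohort_manifest", "data.frame")
  pcg_log("simulate_cohort: %d participants", total)
  list(manifest = manifest, records = records, truths = truths, params = params)
}

#' Write a simulated cohort to disk (WAV + CSV)
#'
#' Writes one float32 WAV per participant, `manifest.csv`, and
#' `ground_truth.csv` (per-cycle event times) under `dir`.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest with `path` filled in, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  truth_rows <- list()
  for (i in seq_len(nrow(man))) {
    id <- man$participant_id[i]
    p <- file.path(dir, paste0(id, ".wav"))
    write_wav(cohort$records[[id]], p, bit_depth = "float32")
    man$path[i] <- p
    tr <- cohort$truths[[id]]
    tr$participant_id <- id
    truth_rows[[i]] <- tr
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, truth_rows), file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(man)
}
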