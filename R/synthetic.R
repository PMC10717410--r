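# Run code under a fixed RNG seed without disturbing the caller's RNG
# stream: the generators are pure functions of (params, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic noisy voltage-clamp sweeps
#'
#' Emulates whole-cell recordings from known ground truth: the model's
#' voltage-clamp currents plus i.i.d. Gaussian noise. With `sd = 0` the
#' output equals [simulate_voltage_clamp()] exactly; identical seeds give
#' identical output.
#'
#' @param params A [cell_params()] object (the ground truth).
#' @param protocol A [voltage_clamp_protocol()].
#' @param sd Noise standard deviation (pA).
#' @param seed Integer RNG seed.
#' @return A [sweep_set()]; each trace's metadata records the generating
#'   `sd` and `seed`.
#' @export
gen_vc_sweeps <- function(params, protocol, sd = 0, seed = 1) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  clean <- simulate_voltage_clamp(params, protocol)
  if (sd == 0) return(clean)
  with_seed(seed, {
    traces <- lapply(clean$traces, function(tr) {
      tr$values <- tr$values + stats::rnorm(length(tr$values), sd = sd)
      tr$metadata$noise_sd <- sd
      tr$metadata$seed <- seed
      tr
    })
    sweep_set(traces, clean$step_mv)
  })
}

#' Synthetic voltage trace with spikes at known times
#'
#' A baseline plus difference-of-exponentials spike waveforms
#' (`exp(-t/decay) - exp(-t/rise)`, scaled to reach `peak_v`), a fixture
#' for spike detection and cycle-length analysis with exact ground truth.
#'
#' @param spike_times Spike onset times (ms); may be empty.
#' @param total_time Trace duration (ms).
#' @param baseline Baseline potential (mV).
#' @param peak_v Spike peak (mV).
#' @param rise,decay Waveform time constants (ms).
#' @param sample_dt Sampling interval (ms).
#' @param sd Gaussian noise standard deviation (mV).
#' @param seed RNG seed (used when `sd > 0`).
#' @return A voltage [new_trace()]; metadata records the ground truth.
#' @export
gen_ap_trace <- function(spike_times, total_time = 1000, baseline = -70,
                         peak_v = 50, rise = 0.5, decay = 2,
                         sample_dt = 0.05, sd = 0, seed = 1) {
  t <- seq(0, total_time, by = sample_dt)
  v <- rep(baseline, length(t))
  if (length(spike_times) > 0) {
    # peak of the unit waveform, for amplitude normalisation
    t_pk <- log(decay / rise) / (1 / rise - 1 / decay)
    unit_pk <- exp(-t_pk / decay) - exp(-t_pk / rise)
    amp <- (peak_v - baseline) / unit_pk
    for (ts in spike_times) {
      rel <- t - ts
      on <- rel >= 0
      v[on] <- v[on] + amp * (exp(-rel[on] / decay) - exp(-rel[on] / rise))
    }
  }
  if (sd > 0) {
    v <- with_seed(seed, v + stats::rnorm(length(v), sd = sd))
  }
  # waveform peaks lag onsets by the rise-decay peak time
  peak_times <- if (length(spike_times)) {
    spike_times + log(decay / rise) / (1 / rise - 1 / decay)
  } else numeric()
  new_trace(t, v, kind = "voltage",
            metadata = list(spike_times = spike_times,
                            peak_times = peak_times,
                            baseline = baseline, peak_v = peak_v,
                            rise = rise, decay = decay, sd = sd,
                            seed = seed))
}

#' Synthetic expression table with a planted passing set
#'
#' Emulates the statistical structure of the CvP/Epi RPKM table: log-normal
#' background expression in both tissues, plus `n_planted_pass` genes that
#' satisfy the screen by construction (CvP above threshold, ratio above
#' threshold). Background genes are constructed to fail the ratio criterion
#' with certainty, so the planted set is exactly the passing set.
#'
#' @param n_genes Total number of genes.
#' @param n_planted_pass Number of planted filter-passing genes
#'   (`<= n_genes`).
#' @param min_cvp,min_ratio The thresholds the planted genes must clear.
#' @param bg_meanlog,bg_sdlog Log-normal parameters of background CvP
#'   expression.
#' @param seed RNG seed.
#' @return Data frame `gene_id, rpkm_cvp, rpkm_epi`, in randomised order,
#'   with the planted ids in `attr(, "planted")`.
#' @export
gen_expression_table <- function(n_genes = 1000, n_planted_pass = 20,
                                 min_cvp = 10, min_ratio = 3,
                                 bg_meanlog = 1, bg_sdlog = 1.5,
                                 seed = 1) {
  stopifnot(n_planted_pass <= n_genes, n_planted_pass >= 0)
  with_seed(seed, {
    n_bg <- n_genes - n_planted_pass
    # background: ratio drawn strictly below the threshold -> never passes
    bg_cvp <- stats::rlnorm(n_bg, bg_meanlog, bg_sdlog)
    bg_ratio <- stats::runif(n_bg, 0.2, min_ratio * 0.999)
    bg_epi <- bg_cvp / bg_ratio
    # planted: clears both strict thresholds by a positive margin
    pl_cvp <- min_cvp * (1.2 + stats::rlnorm(n_planted_pass, 0.5, 0.6))
    pl_ratio <- min_ratio * (1.2 + stats::rexp(n_planted_pass, 1))
    pl_epi <- pl_cvp / pl_ratio
    ids <- sprintf("gene%05d", seq_len(n_genes))
    planted_ids <- if (n_planted_pass > 0) {
      sample(ids, n_planted_pass)
    } else character()
    bg_ids <- setdiff(ids, planted_ids)
    tab <- rbind(
      data.frame(gene_id = bg_ids, rpkm_cvp = bg_cvp, rpkm_epi = bg_epi),
      data.frame(gene_id = planted_ids, rpkm_cvp = pl_cvp,
                 rpkm_epi = pl_epi))
    tab <- tab[sample(nrow(tab)), ]
    rownames(tab) <- NULL
    attr(tab, "planted") <- sort(planted_ids)
    tab
  })
}
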