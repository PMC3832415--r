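#' @title Synthetic RIP-chip and qPCR data generator
#' @name synthetic-data
#' @description
#' Generates probe-level array experiments (and qPCR Ct tables) with the
#' statistical structure the analysis assumes, together with a
#' ground-truth object, so that every pipeline stage is testable without
#' array downloads. The default platform emulates a miRNA 2.0-style
#' design: 1,105 mature miRNA probesets, 1,105 precursor hairpins, 2,334
#' other small RNAs, and 3 spike-in control probesets, 4 probes each; RIP
#' experiments carry triplicate IP arrays and a single input array per
#' cell line.
NULL

#' Simulation configuration
#'
#' Probe intensities are generated as `O = B + E + S`: optical background
#' `B ~ Normal(mu_bg, sigma_bg^2)` truncated to `B >= 0`, a small
#' exponential stray-signal floor `E ~ Exponential(signal_alpha)`
#' (non-specific hybridisation), and specific signal
#' `S = 2^(base_g + probe_offset_p + effect_gs + eps)` with probeset
#' baselines `base_g ~ Normal(signal_mean, signal_sd^2)`, fixed per-probe
#' affinity offsets, and replicate noise `eps ~ Normal(0, noise_sd^2)`.
#' Planted binding adds `effect` log2 units to the IP arrays of the
#' relevant cell line only; planted knockdown effects act on the siYB1
#' group only. Spike-in probesets sit at the 5th percentile of the
#' baseline distribution -- approximately the limit of sensitivity.
#'
#' @param n_mature,n_precursor,n_other,n_spikein Probeset counts (defaults
#'   1105 / 1105 / 2334 / 3).
#' @param probes_per_probeset Probes per probeset (default 4).
#' @param cell_lines Character vector (default MCF7 and MDA-MB-435S).
#' @param n_ip_reps IP replicate arrays per cell line (default 3).
#' @param n_bound Planted bound probesets per cell line (default 20) when
#'   `bound_sets` is NULL.
#' @param bound_effect Log2 IP enrichment of planted probesets (default
#'   2.0, i.e. 4-fold).
#' @param bound_sets Optional explicit list, one element per cell line:
#'   data.frame(probeset_id, effect).
#' @param n_knockdown,knockdown_effect,knockdown_effects Same scheme for
#'   the knockdown experiment (defaults: none -- the null design).
#' @param mu_bg,sigma_bg Background mean and s.d. (intensity units;
#'   defaults 100, 10).
#' @param signal_mean,signal_sd Baseline log2 signal distribution
#'   (defaults 7, 2).
#' @param signal_alpha Rate of the stray-signal exponential (default 0.1,
#'   i.e. mean 10 intensity units).
#' @param noise_sd Replicate log2 noise s.d. (default 0.25).
#' @param probe_sd Per-probe affinity offset s.d. in log2 units (default
#'   0.5).
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the config including this seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_mature = 1105L, n_precursor = 1105L,
                       n_other = 2334L, n_spikein = 3L,
                       probes_per_probeset = 4L,
                       cell_lines = c("MCF7", "MDA-MB-435S"),
                       n_ip_reps = 3L,
                       n_bound = 20L, bound_effect = 2.0,
                       bound_sets = NULL,
                       n_knockdown = 0L, knockdown_effect = 1.0,
                       knockdown_effects = NULL,
                       mu_bg = 100, sigma_bg = 10,
                       signal_mean = 7, signal_sd = 2,
                       signal_alpha = 0.1,
                       noise_sd = 0.25, probe_sd = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_mature = as.integer(n_mature), n_precursor = as.integer(n_precursor),
    n_other = as.integer(n_other), n_spikein = as.integer(n_spikein),
    probes_per_probeset = as.integer(probes_per_probeset),
    cell_lines = as.character(cell_lines),
    n_ip_reps = as.integer(n_ip_reps),
    n_bound = as.integer(n_bound), bound_effect = bound_effect,
    bound_sets = bound_sets,
    n_knockdown = as.integer(n_knockdown),
    knockdown_effect = knockdown_effect,
    knockdown_effects = knockdown_effects,
    mu_bg = mu_bg, sigma_bg = sigma_bg,
    signal_mean = signal_mean, signal_sd = signal_sd,
    signal_alpha = signal_alpha,
    noise_sd = noise_sd, probe_sd = probe_sd,
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(n_mature >= 0, n_precursor >= 0, n_other >= 0,
              n_spikein >= 0, probes_per_probeset >= 1,
              n_ip_reps >= 1, length(cell_lines) >= 1,
              sigma_bg > 0, mu_bg >= 0, signal_alpha > 0,
              noise_sd >= 0, probe_sd >= 0)
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Platform annotation implied by a simulation config
#'
#' Deterministic (no randomness): mature miRNA, precursor hairpin,
#' "other" sncRNA (cycled over snoRNA C/D, H/ACA, scaRNA and a catch-all
#' class), and spike-in control probesets, `probes_per_probeset` probes
#' each.
#'
#' @param config A `"sim_config"`.
#' @return A `probe_annotation`.
#' @export
platform_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  other_classes <- c("snoRNA_CD", "snoRNA_HACA", "scaRNA", "other_sncRNA")
  ps <- c(
    sprintf("syn-mir-%04d_st", seq_len(config$n_mature)),
    sprintf("hp_syn-mir-%04d_st", seq_len(config$n_precursor)),
    sprintf("syn-sno-%04d_st", seq_len(config$n_other)),
    sprintf("spikein_ctrl_%d_st", seq_len(config$n_spikein))
  )
  cls <- c(
    rep("mature_miRNA", config$n_mature),
    rep("precursor_hairpin", config$n_precursor),
    rep_len(other_classes, config$n_other),
    rep("spikein_control", config$n_spikein)
  )
  k <- config$probes_per_probeset
  probe_annotation(
    probe_id = paste0(rep(ps, each = k), "_p", seq_len(k)),
    probeset_id = rep(ps, each = k),
    rna_class = rep(cls, each = k)
  )
}

# Truncated-normal (>= 0) background draws via inverse CDF.
.rbackground <- function(n, mu, sigma) {
  u <- stats::runif(n, stats::pnorm(-mu / sigma), 1)
  mu + sigma * stats::qnorm(u)
}

# Shared latent state: probeset baselines and per-probe affinity offsets.
.sim_latents <- function(config, ann) {
  ps <- unique(ann$probeset_id)
  spike <- spikein_probesets(ann)
  base <- stats::rnorm(length(ps), config$signal_mean, config$signal_sd)
  names(base) <- ps
  base[spike] <- stats::qnorm(0.05, config$signal_mean, config$signal_sd)
  offs <- stats::rnorm(nrow(ann), 0, config$probe_sd)
  names(offs) <- ann$probe_id
  list(base = base, probe_offset = offs, spike = spike)
}

# Sample planted probesets among expressed (above-median baseline)
# non-spike-in probesets: an RNA must be expressed to be pulled down or
# to lose measurable abundance.
.sample_planted <- function(lat, n, effect) {
  pool <- setdiff(names(lat$base), lat$spike)
  expressed <- pool[lat$base[pool] > stats::median(lat$base[pool])]
  data.frame(probeset_id = sample(expressed, n), effect = effect,
             stringsAsFactors = FALSE)
}

# One array: vector of intensities over all probes of ann.
# effect_ps: named per-probeset log2 effect (0 if absent).
.sim_array <- function(config, ann, lat, effect_ps = NULL) {
  n <- nrow(ann)
  expo <- lat$base[ann$probeset_id] + lat$probe_offset
  if (!is.null(effect_ps)) {
    e <- effect_ps[ann$probeset_id]
    e[is.na(e)] <- 0
    expo <- expo + e
  }
  if (config$noise_sd > 0) {
    expo <- expo + stats::rnorm(n, 0, config$noise_sd)
  }
  b <- .rbackground(n, config$mu_bg, config$sigma_bg)
  e <- stats::rexp(n, config$signal_alpha)
  as.numeric(b + e + 2^expo)
}

#' Simulate a RIP-chip experiment
#'
#' For each cell line: one input array and `n_ip_reps` IP arrays; planted
#' bound probesets gain `effect` log2 units on that cell line's IP arrays
#' only. Fully deterministic given the config (one random stream seeded
#' from `config$seed`).
#'
#' @param config A `"sim_config"`.
#' @return List with `intensities` (probes x samples matrix),
#'   `annotation`, `sheet`, and `truth` (class `"synthetic_truth"`:
#'   planted bound sets per cell line, the config echo, and the seed).
#' @export
simulate_rip_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ann <- platform_annotation(config)
  lat <- .sim_latents(config, ann)

  bound <- config$bound_sets
  if (is.null(bound)) {
    bound <- lapply(config$cell_lines, function(cl) {
      .sample_planted(lat, config$n_bound, config$bound_effect)
    })
    names(bound) <- config$cell_lines
  }
  stopifnot(identical(sort(names(bound)), sort(config$cell_lines)))
  for (cl in names(bound)) {
    bad <- setdiff(bound[[cl]]$probeset_id, unique(ann$probeset_id))
    if (length(bad)) stop("bound probeset(s) not on platform: ",
                          paste(bad, collapse = ", "))
  }

  ids <- character(0); cls <- character(0); frac <- character(0)
  rep_ <- integer(0)
  cols <- list()
  for (cl in config$cell_lines) {
    eff <- stats::setNames(bound[[cl]]$effect, bound[[cl]]$probeset_id)
    nm_input <- paste0(cl, "_input")
    cols[[nm_input]] <- .sim_array(config, ann, lat)
    ids <- c(ids, nm_input); cls <- c(cls, cl)
    frac <- c(frac, "input"); rep_ <- c(rep_, 1L)
    for (r in seq_len(config$n_ip_reps)) {
      nm <- paste0(cl, "_IP_", r)
      cols[[nm]] <- .sim_array(config, ann, lat, effect_ps = eff)
      ids <- c(ids, nm); cls <- c(cls, cl)
      frac <- c(frac, "IP"); rep_ <- c(rep_, r)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- ann$probe_id
  sheet <- sample_sheet(ids, cls, frac, treatment = "untransfected",
                        replicate = rep_)
  truth <- structure(
    list(bound = bound, knockdown = NULL, config = config,
         seed = config$seed),
    class = "synthetic_truth"
  )
  list(intensities = m, annotation = ann, sheet = sheet, truth = truth)
}

#' Simulate a knockdown (transfection) experiment
#'
#' Triplicate siYB1, siCtrl and untransfected total-RNA arrays for the
#' first cell line of the config; planted knockdown effects shift the
#' siYB1 group only, all other probesets are null.
#'
#' @param config A `"sim_config"`.
#' @param n_reps Arrays per treatment group (default 3).
#' @return List with `intensities`, `annotation`, `sheet`, `truth`.
#' @export
simulate_knockdown_experiment <- function(config = sim_config(),
                                          n_reps = 3L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ann <- platform_annotation(config)
  lat <- .sim_latents(config, ann)

  kd <- config$knockdown_effects
  if (is.null(kd)) {
    kd <- if (config$n_knockdown > 0) {
      .sample_planted(lat, config$n_knockdown, config$knockdown_effect)
    } else {
      data.frame(probeset_id = character(0), effect = numeric(0),
                 stringsAsFactors = FALSE)
    }
  }
  eff <- stats::setNames(kd$effect, kd$probeset_id)
  cl <- config$cell_lines[1]

  ids <- character(0); trt <- character(0); rep_ <- integer(0)
  cols <- list()
  for (treatment in c("siYB1", "siCtrl", "untransfected")) {
    for (r in seq_len(n_reps)) {
      nm <- paste0(cl, "_", treatment, "_", r)
      e <- if (treatment == "siYB1") eff else NULL
      cols[[nm]] <- .sim_array(config, ann, lat, effect_ps = e)
      ids <- c(ids, nm); trt <- c(trt, treatment); rep_ <- c(rep_, r)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- ann$probe_id
  sheet <- sample_sheet(ids, cell_line = cl, fraction = "input",
                        treatment = trt, replicate = rep_)
  truth <- structure(
    list(bound = NULL, knockdown = kd, config = config,
         seed = config$seed),
    class = "synthetic_truth"
  )
  list(intensities = m, annotation = ann, sheet = sheet, truth = truth)
}

#' Simulate a qPCR Ct table
#'
#' `Ct = intercept(assay) - log2(relative abundance) + sample offset +
#' Normal(0, noise_sd^2)` per replicate. The control sample has abundance
#' 1 for every assay; the treated sample has the given fold change per
#' target and 1 for the reference. The deterministic per-sample offset
#' (pipetting/loading) cancels exactly in ddCt, which is the point of
#' reference normalisation. An 80% knockdown (fold 0.2) yields
#' ddCt = log2(5), about 2.32 cycles.
#'
#' @param fold_changes Named numeric: relative abundance of each target
#'   in the treated sample (e.g. `c(YBX1 = 0.2)`).
#' @param reference Reference assay name (default `"LMNA"`).
#' @param treated,control Sample ids (defaults `"siYB1"`, `"siCtrl"`).
#' @param n_replicates Technical replicates per (sample, assay).
#' @param noise_sd Ct noise s.d. in cycles (default 0.15).
#' @param seed Optional integer seed.
#' @return A `"ct_table"` data frame.
#' @export
simulate_qpcr <- function(fold_changes, reference = "LMNA",
                          treated = "siYB1", control = "siCtrl",
                          n_replicates = 3L, noise_sd = 0.15,
                          seed = NULL) {
  stopifnot(length(fold_changes) >= 1L, !is.null(names(fold_changes)),
            all(fold_changes > 0))
  if (!is.null(seed)) set.seed(seed)
  assays <- c(names(fold_changes), reference)
  intercept <- stats::setNames(
    c(rep(24, length(fold_changes)), 18), assays)
  offset <- stats::setNames(c(0.5, 0), c(treated, control))
  rows <- expand.grid(sample_id = c(treated, control),
                      assay_target = assays,
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  abundance <- ifelse(
    rows$sample_id == treated & rows$assay_target != reference,
    fold_changes[rows$assay_target], 1)
  ct <- intercept[rows$assay_target] - log2(abundance) +
    offset[rows$sample_id]
  if (noise_sd > 0) ct <- ct + stats::rnorm(nrow(rows), 0, noise_sd)
  rows$ct <- as.numeric(ct)
  validate_ct_table(rows[, c("sample_id", "assay_target", "replicate",
                             "ct")])
}

#' Score a selection against planted truth
#'
#' @param selected_ids Character vector of selected probeset ids.
#' @param truth A `"synthetic_truth"`.
#' @param cell_line Cell line whose planted bound set to score against.
#' @return List with `sensitivity` (recall of planted probesets),
#'   `precision` (fraction of selections that are planted), `n_true`,
#'   `n_selected`.
#' @export
score_selection <- function(selected_ids, truth, cell_line) {
  stopifnot(inherits(truth, "synthetic_truth"))
  planted <- truth$bound[[cell_line]]$probeset_id
  if (is.null(planted)) stop("no planted bound set for ", cell_line)
  hits <- length(intersect(selected_ids, planted))
  list(
    sensitivity = if (length(planted)) hits / length(planted) else NA_real_,
    precision = if (length(selected_ids)) hits / length(selected_ids)
                else NA_real_,
    n_true = length(planted),
    n_selected = length(selected_ids)
  )
}

#' Serialise planted truth to TSV
#'
#' One row per planted probeset with its role (`bound` or `knockdown`),
#' cell line (empty for knockdown effects) and log2 effect; the seed in a
#' header comment is avoided -- the config travels separately.
#'
#' @param truth A `"synthetic_truth"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synthetic_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  rows <- list()
  for (cl in names(truth$bound)) {
    b <- truth$bound[[cl]]
    if (nrow(b)) {
      rows[[length(rows) + 1L]] <- data.frame(
        role = "bound", cell_line = cl, probeset_id = b$probeset_id,
        effect = b$effect, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(truth$knockdown) && nrow(truth$knockdown)) {
    rows[[length(rows) + 1L]] <- data.frame(
      role = "knockdown", cell_line = "",
      probeset_id = truth$knockdown$probeset_id,
      effect = truth$knockdown$effect, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(role = character(0), cell_line = character(0),
               probeset_id = character(0), effect = numeric(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
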