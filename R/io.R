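#' Default experiment configuration
#'
#' Full nested configuration with the standard parameter values: network
#' constants, stimulus space, plasticity settings, training schedule,
#' perturbation protocol and metric settings. [load_config()] fills any
#' keys missing from a file with these defaults.
#'
#' @param scale `"full"` (512 Pyr on a 12^3 grid, 500 trials) or
#'   `"reduced"` (64 Pyr on a 4^3 grid, 8 PV, 100 trials); see
#'   [scale_preset()].
#' @return Nested list of class `"ei_config"`.
#' @export
default_config <- function(scale = "full") {
  cfg <- list(
    scale = "full",
    seed = 1L,
    network = list(NE = 512L, NI = 64L, tau_E = 50, tau_I = 25, dt = 1,
                   p = 0.6, J_EE = 2, J_IE = 5, J_EI = 1, J_II = 1,
                   sigma_log = 0.65, I_bg = 5),
    stimulus = list(n_per_dim = 12L, kappa = 1, max_rate = 50),
    plasticity = list(rule = "local", ko = "none", eta_approx = 1e-5,
                      eta_grad = 1e-3, rho0 = 1, delta_EI = 0.1,
                      delta_IE = 0.1, reparam = "exp", normalise = TRUE,
                      adam = list(beta1 = 0.9, beta2 = 0.999,
                                  epsilon = 1e-9)),
    schedule = list(n_trials = 500L, snapshot_every = 10L),
    perturbation = list(delta_I = 10, n_perturbed = 90L),
    metrics = list(threshold = 1e-4, relative_threshold = FALSE,
                   n_sample = 100L, n_resamples = 10000L, n_bins = 10L),
    solver = list(tol = 1e-6, max_steps = 1e5)
  )
  class(cfg) <- c("ei_config", "list")
  if (scale == "reduced") cfg <- scale_preset(cfg, "reduced")
  cfg
}

#' Reduced-scale preset
#'
#' Applies the documented reduced problem size to a configuration: 64 Pyr
#' neurons tiling a 4x4x4 stimulus grid, 8 PV neurons, 100 trials. The
#' local learning rate is set to `1.2e-5`, calibrated so that the reduced
#' protocol reaches the same endpoint as the full-scale one — Pyr rates
#' converged to the homeostatic target — without destabilising the
#' network (much larger rates transiently strip inhibitory control and
#' tip the excitatory recurrence into runaway). The perturbation and
#' resampling analyses are also reduced.
#'
#' @param cfg An `ei_config`.
#' @param scale `"full"` or `"reduced"`.
#' @return The updated configuration.
#' @export
scale_preset <- function(cfg, scale = c("full", "reduced")) {
  scale <- match.arg(scale)
  cfg$scale <- scale
  if (scale == "reduced") {
    cfg$network$NE <- 64L
    cfg$network$NI <- 8L
    cfg$stimulus$n_per_dim <- 4L
    cfg$schedule$n_trials <- 100L
    cfg$plasticity$eta_approx <- 1.2e-5
    cfg$plasticity$eta_grad <- 1e-3
    cfg$perturbation$n_perturbed <- 30L
    cfg$metrics$n_resamples <- 1000L
  }
  cfg
}

# recursively merge user values into defaults, rejecting unknown keys
.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: ", full)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) stop("configuration key ", full, " must be a section")
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

.validate_config <- function(cfg) {
  with(cfg$network, {
    if (NE <= 0 || NI <= 0) stop("config error: population sizes must be positive")
  })
  if (cfg$stimulus$n_per_dim < 1) stop("config error: n_per_dim must be >= 1")
  if (cfg$schedule$n_trials < 1) stop("config error: n_trials must be >= 1")
  if (!cfg$plasticity$rule %in% c("local", "gradient")) {
    stop("config error: plasticity rule must be 'local' or 'gradient'")
  }
  if (!cfg$plasticity$ko %in% c("none", "output", "input")) {
    stop("config error: ko must be 'none', 'output' or 'input'")
  }
  if (!cfg$scale %in% c("full", "reduced")) {
    stop("config error: scale must be 'full' or 'reduced'")
  }
  invisible(cfg)
}

#' Load an experiment configuration from YAML
#'
#' Reads a YAML file, fills missing keys from [default_config()], rejects
#' unknown keys, and validates values. An empty file yields the full
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `ei_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .merge_config(default_config(), user)
  if (!is.null(user$scale) && user$scale == "reduced") {
    # apply the preset first, then re-apply explicit user overrides
    cfg <- scale_preset(default_config(), "reduced")
    cfg <- .merge_config(cfg, user)
  }
  class(cfg) <- c("ei_config", "list")
  .validate_config(cfg)
}

#' Save an experiment configuration to YAML
#'
#' @param cfg An `ei_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# constructors from a config
.network_from_config <- function(cfg, seed) {
  params <- network_params(
    NE = cfg$network$NE, NI = cfg$network$NI, tau_E = cfg$network$tau_E,
    tau_I = cfg$network$tau_I, dt = cfg$network$dt, p = cfg$network$p,
    J_EE = cfg$network$J_EE, J_IE = cfg$network$J_IE,
    J_EI = cfg$network$J_EI, J_II = cfg$network$J_II,
    sigma_log = cfg$network$sigma_log, I_bg = cfg$network$I_bg,
    n_per_dim = cfg$stimulus$n_per_dim, kappa = cfg$stimulus$kappa,
    max_rate = cfg$stimulus$max_rate)
  ei_network(params, seed = seed)
}

.plasticity_from_config <- function(cfg) {
  pl <- cfg$plasticity
  plasticity_config(
    rule = pl$rule, ko = pl$ko,
    eta = if (pl$rule == "local") pl$eta_approx else pl$eta_grad,
    rho0 = pl$rho0, delta_EI = pl$delta_EI, delta_IE = pl$delta_IE,
    beta1 = pl$adam$beta1, beta2 = pl$adam$beta2, epsilon = pl$adam$epsilon,
    reparam = pl$reparam, normalise = pl$normalise)
}

# labelled seed substreams: adding a new label never perturbs existing ones
.derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(master) * 7919 + h) %% 2147483629)
}

#' Run one of the standard experiments end to end
#'
#' Drives the four experiment pipelines: `"fig1"` trains with both rules
#' active and computes the assembly metrics (sampled correlations,
#' selectivity, alignment angles); `"fig2"` is the output knock-out,
#' `"fig3"` the input knock-out (each with the significance-fraction
#' analysis); `"fig4"` trains fully and runs the single-neuron
#' perturbation analysis (influence binned by receptive-field correlation,
#' mean R^2 before/after, outgoing-weight correlation).
#'
#' @param tag One of `"fig1"`, `"fig2"`, `"fig3"`, `"fig4"`.
#' @param scale `"reduced"` (default) or `"full"`.
#' @param seed Master seed; all stochastic steps derive labelled
#'   sub-seeds from it.
#' @param out Optional output path prefix: writes `<out>.rds` (the full
#'   store), `<out>.yaml` (the config) and `<out>.json` (metric summary).
#' @param config Optional `ei_config` overriding the preset.
#' @param verbose Passed to [ei_train()].
#' @return An object of class `"ei_store"`: list with the config, the
#'   network, the fit, response tensors before/after, and a `metrics`
#'   list whose content depends on the tag.
#' @export
reproduce <- function(tag = c("fig1", "fig2", "fig3", "fig4"),
                      scale = c("reduced", "full"), seed = 1L, out = NULL,
                      config = NULL, verbose = FALSE) {
  tag <- match.arg(tag)
  scale <- match.arg(scale)
  cfg <- if (is.null(config)) default_config(scale) else config
  cfg$seed <- as.integer(seed)
  cfg$plasticity$ko <- switch(tag, fig2 = "output", fig3 = "input", "none")
  .validate_config(cfg)

  net <- .network_from_config(cfg, seed = .derive_seed(seed, "network"))
  pcfg <- .plasticity_from_config(cfg)
  fit <- ei_train(net, pcfg, trials = cfg$schedule$n_trials,
                  seed = .derive_seed(seed, "schedule"),
                  snapshot_every = cfg$schedule$snapshot_every,
                  tol = cfg$solver$tol, max_steps = cfg$solver$max_steps,
                  verbose = verbose)
  resp_before <- response_tensor(net)
  resp_after <- response_tensor(net, W = fit$W)

  metrics <- list(
    median_hE = stats::median(
      resp_after$activations[seq_len(net$params$NE), ]),
    mean_dev = fit$history$mean_dev)

  set.seed(.derive_seed(seed, "sampling"))
  sample_after <- sample_reciprocal_pairs(
    fit$W, net$masks, resp_after, n = cfg$metrics$n_sample,
    threshold = cfg$metrics$threshold,
    relative = cfg$metrics$relative_threshold)
  metrics$correlations_after <- sample_correlations(sample_after)
  set.seed(.derive_seed(seed, "sampling_before"))
  sample_before <- sample_reciprocal_pairs(
    net$W, net$masks, resp_before, n = cfg$metrics$n_sample,
    threshold = cfg$metrics$threshold,
    relative = cfg$metrics$relative_threshold)
  metrics$correlations_before <- sample_correlations(sample_before)

  sel <- function(resp) apply(resp$rates, 1L, stimulus_selectivity)
  NE <- net$params$NE
  metrics$selectivity <- list(
    pyr_before = sel(resp_before)[seq_len(NE)],
    pv_before = sel(resp_before)[-seq_len(NE)],
    pyr_after = sel(resp_after)[seq_len(NE)],
    pv_after = sel(resp_after)[-seq_len(NE)])

  if (tag %in% c("fig2", "fig3")) {
    metrics$fractions <- fraction_significant(
      fit$W, net$masks, resp_after,
      n_resamples = cfg$metrics$n_resamples, n = cfg$metrics$n_sample,
      threshold = cfg$metrics$threshold,
      seed = .derive_seed(seed, "fractions"))
  }

  perturb <- NULL
  if (tag == "fig4") {
    perturb <- list(
      after = perturb_influence(fit, delta_I = cfg$perturbation$delta_I,
                                n_perturbed = cfg$perturbation$n_perturbed,
                                seed = .derive_seed(seed, "perturb")),
      before = perturb_influence(net, delta_I = cfg$perturbation$delta_I,
                                 n_perturbed = cfg$perturbation$n_perturbed,
                                 seed = .derive_seed(seed, "perturb")))
    rf_after <- rf_correlation_matrix(resp_after)
    rf_before <- rf_correlation_matrix(resp_before)
    metrics$mean_r2 <- c(before = mean_r2(rf_before),
                         after = mean_r2(rf_after))
    metrics$influence_bins <- list(
      after = bin_influence(perturb$after, rf_after,
                            n_bins = cfg$metrics$n_bins),
      before = bin_influence(perturb$before, rf_before,
                             n_bins = cfg$metrics$n_bins))
    metrics$outgoing <- outgoing_weight_vs_influence(fit$W, perturb$after)
  }

  store <- structure(list(tag = tag, config = cfg, network = net, fit = fit,
                          responses_before = resp_before,
                          responses_after = resp_after,
                          perturbation = perturb, metrics = metrics),
                     class = "ei_store")
  if (!is.null(out)) {
    dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
    saveRDS(store, paste0(out, ".rds"))
    save_config(cfg, paste0(out, ".yaml"))
    summ <- list(tag = tag, scale = scale, seed = seed,
                 median_hE = metrics$median_hE,
                 correlations_after = metrics$correlations_after,
                 correlations_before = metrics$correlations_before,
                 fractions = metrics$fractions,
                 mean_r2 = metrics$mean_r2)
    jsonlite::write_json(summ, paste0(out, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  store
}

#' @export
print.ei_store <- function(x, ...) {
  cat(sprintf("experiment store '%s' (%s scale, seed %d)\n", x$tag,
              x$config$scale, x$config$seed))
  cat(sprintf("median steady-state Pyr activation: %.3f Hz (target %g)\n",
              x$metrics$median_hE, x$config$plasticity$rho0))
  if (!is.null(x$metrics$correlations_after)) {
    cat("sampled correlations after learning:\n")
    print(round(x$metrics$correlations_after, 4))
  }
  invisible(x)
}
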