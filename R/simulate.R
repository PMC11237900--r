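## Synthetic study generator. Emulates the statistical structure the
## downstream analyses assume: two treatment groups (unilateral brain injury
## vs sham), bilateral expression with gene-specific lateralization offsets,
## block-structured gene-gene correlation (positive within each of the two
## networks, negative between), an ipsilesional-dominant injury effect whose
## contralateral log fold change is an attenuated linear function of the
## ipsilesional one, monotone force ramps with limb-specific gain, and
## replicate posture readings around a true signed asymmetry.

#' Default simulated gene panel
#'
#' Twelve genes split into a left-dominant network (positive log2 L/R
#' lateralization offset) and a right-dominant network (negative offset).
#' Half of the genes in each network carry an injury effect.
#'
#' @param lambda magnitude of the lateralization offset, log2 units
#' @param delta injury (ipsilesional) effect, log2 units; negative = lower
#'   expression on the lesion side after injury
#' @return data.frame with columns gene, network, lambda, delta
#' @export
default_gene_panel <- function(lambda = 0.8, delta = -0.8) {
  ldn <- sprintf("Lg%02d", 1:6)
  rdn <- sprintf("Rg%02d", 1:6)
  data.frame(
    gene = c(ldn, rdn),
    network = rep(c("LdN", "RdN"), each = 6L),
    lambda = rep(c(lambda, -lambda), each = 6L),
    delta = rep(c(delta, 0, delta, 0), times = c(3L, 3L, 3L, 3L)),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study. Defaults mirror the
#' study design the analyses were built for: 12 injured and 11 sham rats,
#' left-side lesion, gene panel with +/-0.8 log2 lateralization, block
#' correlation 0.4 within and -0.2 between networks, contralateral
#' attenuation 0.64 of the ipsilesional injury effect, 6 posture replicates
#' around a 3 mm true asymmetry with 0.5 mm replicate SD, and 100 Hz force
#' ramps over 0-10 mm at 5 mm/s with a 1.5 gain on the flexed limb.
#'
#' @param n_ubi,n_sham rats per treatment group
#' @param lesion_side `"left"` or `"right"` (injury group)
#' @param genes data.frame as from [default_gene_panel()]
#' @param regions regions profiled bilaterally
#' @param rho_in within-network correlation, in [0, 1)
#' @param rho_out cross-network correlation, in (-1, 0]
#' @param attenuation contralateral/ipsilesional injury effect ratio, (0, 1]
#' @param sigma_expr log2-scale expression noise SD
#' @param baseline_log2 mean log2 expression level
#' @param mu_pa true signed posture asymmetry after injury, mm
#'   (positive = right flexion; a left lesion flexes the right hindlimb)
#' @param posture_sd replicate posture reading SD, mm
#' @param n_replicates posture replicates per rat and timepoint
#' @param force_gain force ramp slope, g/mm
#' @param force_baseline force at zero stretch, g
#' @param flexed_gain_ratio multiplicative gain of the flexed
#'   (contralesional) limb's ramp
#' @param force_noise_sd additive force noise SD, g
#' @param sampling_hz,ramp_speed,ramp_length force trace sampling rate (Hz),
#'   ramp speed (mm/s) and ramp length (mm)
#' @param seed integer RNG seed; every assay derives its own stream from it
#' @return a `simulation_config` list, validated
#' @export
simulation_config <- function(n_ubi = 12L, n_sham = 11L,
                              lesion_side = "left",
                              genes = default_gene_panel(),
                              regions = c("HPT", "SpC"),
                              rho_in = 0.4, rho_out = -0.2,
                              attenuation = 0.64,
                              sigma_expr = 0.5,
                              baseline_log2 = 5,
                              mu_pa = 3, posture_sd = 0.5,
                              n_replicates = 6L,
                              force_gain = 2, force_baseline = 1,
                              flexed_gain_ratio = 1.5,
                              force_noise_sd = 0.2,
                              sampling_hz = 100, ramp_speed = 5,
                              ramp_length = 10,
                              seed = 1L) {
  cfg <- list(n_ubi = as.integer(n_ubi), n_sham = as.integer(n_sham),
              lesion_side = match.arg(lesion_side, c("left", "right")),
              genes = genes, regions = regions,
              rho_in = rho_in, rho_out = rho_out,
              attenuation = attenuation, sigma_expr = sigma_expr,
              baseline_log2 = baseline_log2,
              mu_pa = mu_pa, posture_sd = posture_sd,
              n_replicates = as.integer(n_replicates),
              force_gain = force_gain, force_baseline = force_baseline,
              flexed_gain_ratio = flexed_gain_ratio,
              force_noise_sd = force_noise_sd,
              sampling_hz = sampling_hz, ramp_speed = ramp_speed,
              ramp_length = ramp_length, seed = as.integer(seed))
  if (cfg$n_ubi < 3L || cfg$n_sham < 3L) stop_config("need at least 3 rats per group")
  if (!(cfg$rho_in >= 0 && cfg$rho_in < 1)) stop_config("rho_in must lie in [0, 1)")
  if (!(cfg$rho_out <= 0 && cfg$rho_out > -1)) stop_config("rho_out must lie in (-1, 0]")
  if (!(cfg$attenuation > 0 && cfg$attenuation <= 1)) stop_config("attenuation must lie in (0, 1]")
  if (cfg$sigma_expr <= 0 || cfg$posture_sd <= 0 || cfg$force_noise_sd <= 0)
    stop_config("all noise SDs must be > 0")
  if (cfg$flexed_gain_ratio <= 0) stop_config("flexed_gain_ratio must be > 0")
  ## check the block correlation matrix is usable before any data is drawn
  tryCatch(chol(block_correlation(cfg$genes$network, cfg$rho_in, cfg$rho_out)),
           error = function(e) stop_config(
             "block correlation matrix from (rho_in, rho_out) is not positive definite"))
  class(cfg) <- "simulation_config"
  cfg
}

## per-assay RNG streams: deterministic children of the master seed so that
## adding one assay never perturbs the draws of another
assay_seed <- function(seed, assay) {
  offset <- c(design = 101L, expression = 211L, posture = 307L, force = 401L)[[assay]]
  (as.integer(seed) * 1009L + offset) %% .Machine$integer.max
}

## correlation matrix: rho_in within each network block, rho_out across
block_correlation <- function(network, rho_in, rho_out) {
  same <- outer(network, network, "==")
  R <- ifelse(same, rho_in, rho_out)
  diag(R) <- 1
  R
}

sim_design <- function(cfg) {
  n <- cfg$n_ubi + cfg$n_sham
  data.frame(
    rat_id = sprintf("rat%02d", seq_len(n)),
    treatment = rep(c(if (cfg$lesion_side == "left") "left_UBI" else "right_UBI",
                      "sham"), c(cfg$n_ubi, cfg$n_sham)),
    lesion_side = rep(c(cfg$lesion_side, "none"), c(cfg$n_ubi, cfg$n_sham)),
    stringsAsFactors = FALSE)
}

#' Simulate a bilateral expression study
#'
#' Per rat, region and side, the log2 expression of gene g is
#' `baseline + side * lambda_g / 2 + injury * delta_g * (1 or attenuation)
#' + correlated noise`, where side is +1 on the left and -1 on the right
#' (so the true log2 L/R asymmetry equals lambda_g), the injury effect is
#' full on the ipsilesional side and attenuated on the contralateral side,
#' and the noise is multivariate normal with the block correlation across
#' (gene, side) measurements within a region. Values are returned on the
#' linear (positive) scale.
#'
#' @param config a [simulation_config()]
#' @return a `synthetic_study` list with `design`, `expression`
#'   (long_table: rat_id, treatment, region, side, gene, value) and
#'   `truth` (the generating parameters)
#' @export
simulate_expression_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  design <- sim_design(config)
  genes <- config$genes
  G <- nrow(genes)
  ## measurement space within a region: genes x sides; network label carries
  ## over to both side measurements of a gene
  meas <- expand.grid(gene_idx = seq_len(G), side = c("left", "right"),
                      stringsAsFactors = FALSE)
  R <- block_correlation(genes$network[meas$gene_idx], config$rho_in, config$rho_out)
  Sigma <- (config$sigma_expr^2) * R
  side_sign <- ifelse(meas$side == "left", 0.5, -0.5)
  lam <- genes$lambda[meas$gene_idx]
  del <- genes$delta[meas$gene_idx]
  ipsi <- as.numeric(meas$side == config$lesion_side)
  injury_mult <- ipsi + (1 - ipsi) * config$attenuation

  set.seed(assay_seed(config$seed, "expression"))
  rows <- vector("list", nrow(design) * length(config$regions))
  k <- 0L
  for (r in seq_len(nrow(design))) {
    injured <- design$treatment[r] != "sham"
    for (region in config$regions) {
      mu <- config$baseline_log2 + side_sign * lam +
        (if (injured) del * injury_mult else 0)
      x <- MASS::mvrnorm(1L, mu = mu, Sigma = Sigma)
      k <- k + 1L
      rows[[k]] <- data.frame(
        rat_id = design$rat_id[r], treatment = design$treatment[r],
        region = region, side = meas$side, gene = genes$gene[meas$gene_idx],
        value = 2^x, stringsAsFactors = FALSE)
    }
  }
  expr <- do.call(rbind, rows)
  expr <- as_long_table(expr[c("rat_id", "region", "side", "gene", "value",
                               "treatment")], builtin_schema("expression"))
  structure(list(design = design, expression = expr,
                 truth = list(lambda = setNames(genes$lambda, genes$gene),
                              delta = setNames(genes$delta, genes$gene),
                              network = setNames(genes$network, genes$gene),
                              attenuation = config$attenuation,
                              rho_in = config$rho_in, rho_out = config$rho_out),
                 config = config),
            class = "synthetic_study")
}

#' Simulate posture readings and stretch-force traces
#'
#' Posture: `n_replicates` readings per rat and timepoint drawn around the
#' group's true signed asymmetry (0 before surgery and for sham, `mu_pa`
#' after injury). Force: both limbs are sampled at `sampling_hz` during a
#' constant-speed ramp; the mean ramp is linear in distance and the flexed
#' (contralesional) limb's ramp is scaled by `flexed_gain_ratio` after
#' injury; Gaussian noise is added pointwise.
#'
#' @param config a [simulation_config()]
#' @param timepoints posture/force timepoints to simulate
#' @return a `synthetic_study` list with `design`, `posture`, `force`
#'   long tables and `truth`
#' @export
simulate_posture_and_force <- function(config, timepoints = c("pre", "post")) {
  stopifnot(inherits(config, "simulation_config"))
  design <- sim_design(config)

  set.seed(assay_seed(config$seed, "posture"))
  pr <- list(); k <- 0L
  for (r in seq_len(nrow(design))) {
    injured <- design$treatment[r] != "sham"
    for (tp in timepoints) {
      ## contralesional flexion: left lesion -> right flexion -> positive PAS
      mu <- if (injured && tp != "pre") {
        if (design$lesion_side[r] == "left") config$mu_pa else -config$mu_pa
      } else 0
      k <- k + 1L
      pr[[k]] <- data.frame(
        rat_id = design$rat_id[r], treatment = design$treatment[r],
        timepoint = tp, replicate = seq_len(config$n_replicates),
        reading_mm = rnorm(config$n_replicates, mu, config$posture_sd),
        stringsAsFactors = FALSE)
    }
  }
  posture <- do.call(rbind, pr)
  posture <- as_long_table(posture[c("rat_id", "timepoint", "replicate",
                                     "reading_mm", "treatment")],
                           builtin_schema("posture"))

  set.seed(assay_seed(config$seed, "force"))
  dt <- 1 / config$sampling_hz
  d <- seq(0, config$ramp_length, by = config$ramp_speed * dt)
  fr <- list(); k <- 0L
  for (r in seq_len(nrow(design))) {
    injured <- design$treatment[r] != "sham"
    flexed <- if (!injured) "none"
      else if (design$lesion_side[r] == "left") "right" else "left"
    for (tp in timepoints) {
      for (limb in c("left", "right")) {
        ## the flexed limb's whole ramp (baseline and slope) is scaled, so
        ## in the noise-free limit the work ratio equals the gain ratio
        mult <- if (tp != "pre" && limb == flexed) config$flexed_gain_ratio else 1
        f <- mult * (config$force_baseline + config$force_gain * d) +
          rnorm(length(d), 0, config$force_noise_sd)
        k <- k + 1L
        fr[[k]] <- data.frame(
          rat_id = design$rat_id[r], treatment = design$treatment[r],
          limb = limb, timepoint = tp, replicate = 1L,
          sample = seq_along(d), distance_mm = d, force_g = f,
          stringsAsFactors = FALSE)
      }
    }
  }
  force <- do.call(rbind, fr)
  force <- as_long_table(force[c("rat_id", "limb", "timepoint", "replicate",
                                 "sample", "distance_mm", "force_g",
                                 "treatment")], builtin_schema("force"))

  structure(list(design = design, posture = posture, force = force,
                 truth = list(mu_pa = config$mu_pa,
                              posture_sd = config$posture_sd,
                              flexed_gain_ratio = config$flexed_gain_ratio),
                 config = config),
            class = "synthetic_study")
}
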