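#' Configuration for the synthetic two-condition study generator
#'
#' The generator emulates a normalized, log-scale two-condition microarray
#' study: Gaussian noise around gene-specific baselines, a planted set of DE
#' targets shifted in the treated condition, and one or more planted
#' regulators that are not DE themselves but are coupled to a block of DE
#' targets with condition-specific strength - the differential-connectivity
#' phenomenon the RIF statistics are built to detect.
#'
#' @param n_genes Total genes.
#' @param n_regulators_planted Number of planted differentially connected
#'   regulators (non-DE by construction).
#' @param n_de_planted Number of planted DE targets.
#' @param n_samples_S,n_samples_C Samples per condition (>= 3).
#' @param de_effect Mean shift of DE targets in the treated condition, in
#'   units of \code{noise_sd}; may be negative (down in treated).
#' @param coupling_S,coupling_C Correlation of each planted regulator to its
#'   target block within the S and C samples; in [-1, 1].
#' @param block_size DE targets coupled to each planted regulator; blocks are
#'   disjoint subsets of the planted DE set.
#' @param noise_sd Residual standard deviation on the log scale.
#' @param baseline_mean_range Interval baseline means are drawn from
#'   (log-scale intensities).
#' @param seed Integer seed; identical seed and config give a bit-identical
#'   study.
#' @return A list of class \code{"SimConfig"}.
#' @export
sim_config <- function(n_genes = 2000, n_regulators_planted = 1,
                       n_de_planted = 200, n_samples_S = 20, n_samples_C = 20,
                       de_effect = 2, coupling_S = 0.8, coupling_C = 0,
                       block_size = 60, noise_sd = 0.5,
                       baseline_mean_range = c(6, 12), seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_regulators_planted = as.integer(n_regulators_planted),
              n_de_planted = as.integer(n_de_planted),
              n_samples_S = as.integer(n_samples_S),
              n_samples_C = as.integer(n_samples_C),
              de_effect = de_effect,
              coupling_S = coupling_S, coupling_C = coupling_C,
              block_size = as.integer(block_size), noise_sd = noise_sd,
              baseline_mean_range = baseline_mean_range,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1L,
            cfg$n_samples_S >= 3L, cfg$n_samples_C >= 3L,
            abs(cfg$coupling_S) <= 1, abs(cfg$coupling_C) <= 1,
            cfg$noise_sd > 0,
            length(cfg$baseline_mean_range) == 2L,
            diff(cfg$baseline_mean_range) >= 0,
            cfg$n_regulators_planted >= 0L, cfg$n_de_planted >= 0L)
  if (cfg$n_de_planted + cfg$n_regulators_planted > cfg$n_genes)
    stop("infeasible config: planted DE targets plus planted regulators ",
         "exceed n_genes")
  if (cfg$n_regulators_planted > 0L &&
      cfg$n_regulators_planted * cfg$block_size > cfg$n_de_planted)
    stop("infeasible config: disjoint target blocks (",
         cfg$n_regulators_planted, " x ", cfg$block_size,
         ") exceed the planted DE set (", cfg$n_de_planted, ")")
  class(cfg) <- "SimConfig"
  cfg
}

#' Full-array-scale simulation preset
#'
#' Same generative model at the dimensions of the motivating study design:
#' 7350 expressed genes, 1279 planted DE targets, 23 + 23 samples.
#'
#' @param ... Overrides passed to \code{\link{sim_config}}.
#' @return A \code{SimConfig}.
#' @export
sim_config_full_scale <- function(...) {
  sim_config(n_genes = 7350, n_de_planted = 1279,
             n_samples_S = 23, n_samples_C = 23, ...)
}

#' Simulate a two-condition expression study with ground truth
#'
#' Construction: every gene gets a baseline mean drawn uniformly from
#' \code{baseline_mean_range} plus i.i.d. Gaussian noise of SD
#' \code{noise_sd}; planted DE targets additionally get
#' \code{de_effect * noise_sd} added to every treated (S) sample; each
#' planted regulator r is pure noise with equal means in both conditions
#' (non-DE by construction), and every target j of its block is rebuilt
#' within each condition as
#' \code{mu_j + noise_sd * (c * z_r + sqrt(1 - c^2) * eps_j)}, where
#' \code{z_r} is the regulator's within-condition standardized profile,
#' \code{eps_j} fresh standard normal noise, and \code{c} the condition's
#' coupling. Coupling through the shared latent profile makes target-target
#' correlations within a block approximately \code{c^2}.
#'
#' @param config A \code{SimConfig}.
#' @return List with elements \code{study} (an \code{ExpressionStudy},
#'   condition labels \code{"S"}/\code{"C"}) and \code{truth}, a list with
#'   \code{de_gene_ids}, \code{dc_regulator_ids}, \code{blocks} (named list
#'   of target-block ids per planted regulator) and \code{realized_couplings}
#'   (per regulator, mean correlation to its block in S and in C).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv))
  }
  set.seed(config$seed)

  n_g <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n_g))
  s_ids <- sprintf("S%02d", seq_len(config$n_samples_S))
  c_ids <- sprintf("C%02d", seq_len(config$n_samples_C))
  sample_ids <- c(s_ids, c_ids)
  n_all <- length(sample_ids)

  mu <- stats::runif(n_g, config$baseline_mean_range[1L],
                     config$baseline_mean_range[2L])
  values <- mu + config$noise_sd * matrix(stats::rnorm(n_g * n_all), n_g, n_all)
  dimnames(values) <- list(gene_ids, sample_ids)

  planted <- sample(gene_ids, config$n_regulators_planted)
  de_ids <- sample(setdiff(gene_ids, planted), config$n_de_planted)
  values[de_ids, s_ids] <- values[de_ids, s_ids] +
    config$de_effect * config$noise_sd

  blocks <- list()
  pool <- de_ids
  for (r in planted) {
    blocks[[r]] <- sample(pool, config$block_size)
    pool <- setdiff(pool, blocks[[r]])
  }

  couple_block <- function(values, r, block, cols, coupling) {
    z <- as.vector(scale(values[r, cols]))
    for (j in block) {
      eps <- stats::rnorm(length(cols))
      values[j, cols] <- mean(values[j, cols]) + config$noise_sd *
        (coupling * z + sqrt(1 - coupling^2) * eps)
    }
    values
  }
  for (r in planted) {
    values <- couple_block(values, r, blocks[[r]], s_ids, config$coupling_S)
    values <- couple_block(values, r, blocks[[r]], c_ids, config$coupling_C)
  }

  study <- expression_study(values,
                            stats::setNames(rep(c("S", "C"),
                                                c(length(s_ids),
                                                  length(c_ids))),
                                            sample_ids),
                            treated_label = "S", control_label = "C")

  realized <- lapply(planted, function(r) {
    block <- blocks[[r]]
    c(S = mean(stats::cor(values[r, s_ids],
                          t(values[block, s_ids, drop = FALSE]))),
      C = mean(stats::cor(values[r, c_ids],
                          t(values[block, c_ids, drop = FALSE]))))
  })
  names(realized) <- planted

  list(study = study,
       truth = list(de_gene_ids = de_ids,
                    dc_regulator_ids = planted,
                    blocks = blocks,
                    realized_couplings = realized))
}
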