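#' Simulation configuration for the synthetic drought experiment
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' The defaults reproduce the study design the pipeline assumes: 8
#' genotypes x 2 treatments x 3 blocks per scenario over two scenarios
#' (96 plants), 2000 genes, and 9 morpho-physiological phenotypes.
#'
#' Planted per-gene ANOVA effect classes cover every cell of the effect
#' cross-tabulation vocabulary (t_o, g_o, g*t_o plus the combination
#' classes g_t, g*t_g, g*t_t, All). A separate pool of trait-coupled genes
#' loads on three sample-level latent factors that also drive the modeled
#' phenotypes; the water-status factor carries a treatment component so
#' that stressed plants shift along it (and OP couples with opposite sign
#' to ITW).
#'
#' @param n_genotypes number of genotypes (default 8).
#' @param n_blocks_per_scenario blocks per scenario (default 3).
#' @param n_genes number of genes (default 2000).
#' @param frac_treatment_genes fraction of genes planted treatment-only.
#' @param frac_genotype_genes fraction planted genotype-only.
#' @param frac_gxt_genes fraction planted interaction-only.
#' @param frac_overlap_genes fraction spread evenly over the four
#'   combination classes (g_t, g*t_g, g*t_t, All).
#' @param effect_size_sd_units planted mean shift in residual-SD units.
#' @param noise_sd residual SD of expression (log2 scale).
#' @param block_sd SD of the per-block nuisance shift.
#' @param genes_per_phenotype trait-coupled genes contributed per modeled
#'   phenotype (the pools are shared within a latent factor).
#' @param phenotype_noise_sd SD of the measurement noise added to each
#'   modeled phenotype, on the scale of the gene-set mean.
#' @param ftsw_threshold_transpiration FTSW below which relative
#'   transpiration declines linearly (two-segment response, default 0.4).
#' @param initial_weight,final_weight calibration pot weights (g); their
#'   difference is TTSW and must be positive.
#' @param base_transpiration full-water daily transpiration (g/day).
#' @param transpiration_cv log-scale SD of genotype transpiration
#'   coefficients (vigour spread).
#' @param transpiration_coefficients optional explicit per-genotype daily
#'   transpiration coefficients (g/day), overriding the random draw.
#' @param treatment_alignment treatment loading of the water-status latent
#'   factor (drives the OP/ITW opposition).
#' @param gene_factor_loading loading of trait-coupled genes on their
#'   latent factor, in residual-SD units.
#' @param n_field_genes size of the synthetic field-derived gene list.
#' @param field_enrichment_factor sampling rate of trait-linked genes in
#'   the field list relative to the background rate.
#' @param max_days simulated days before the harvest rules must trigger.
#' @param seed integer seed for all generator randomness.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_genotypes = 8,
                       n_blocks_per_scenario = 3,
                       n_genes = 2000,
                       frac_treatment_genes = 0.04,
                       frac_genotype_genes = 0.06,
                       frac_gxt_genes = 0.015,
                       frac_overlap_genes = 0.04,
                       effect_size_sd_units = 2.5,
                       noise_sd = 1,
                       block_sd = 0.1,
                       genes_per_phenotype = 15,
                       phenotype_noise_sd = 0.4,
                       ftsw_threshold_transpiration = 0.4,
                       initial_weight = 18000,
                       final_weight = 14000,
                       base_transpiration = 450,
                       transpiration_cv = 0.25,
                       transpiration_coefficients = NULL,
                       treatment_alignment = 0.5,
                       gene_factor_loading = 2,
                       n_field_genes = 156,
                       field_enrichment_factor = 5,
                       max_days = 60,
                       seed = 1) {
  cfg <- as.list(environment())
  fr <- c(frac_treatment_genes, frac_genotype_genes, frac_gxt_genes,
          frac_overlap_genes)
  if (any(fr < 0 | fr > 1)) stop("gene-class fractions must be in [0, 1]")
  if (sum(fr) > 1) stop("gene-class fractions must sum to at most 1")
  if (initial_weight - final_weight <= 0) {
    stop("invalid config: TTSW (initial minus final pot weight) must be positive")
  }
  if (n_genes < 9 * genes_per_phenotype) {
    stop("n_genes must be at least n_phenotypes * genes_per_phenotype")
  }
  if (ftsw_threshold_transpiration <= 0 || ftsw_threshold_transpiration > 1) {
    stop("ftsw_threshold_transpiration must be in (0, 1]")
  }
  if (noise_sd <= 0 || phenotype_noise_sd < 0 || effect_size_sd_units < 0) {
    stop("SDs must be non-negative (noise_sd strictly positive)")
  }
  cfg$phenotype_names <- c("ITW", "E", "OP", "RWC", "LMA", "CID",
                           "PHe", "CoD", "TLA")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' \code{\link{sim_config}}.
#'
#' @param path YAML file with \code{sim_config} fields.
#' @return a \code{sim_config} object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(sim_config, vals)
}

# Derive independent sub-seeds for the generator stages from the master
# seed, keeping every value a valid 32-bit integer.
sim_subseeds <- function(seed) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, 6)
}

sim_genotype_names <- function(n) sprintf("GT%02d", seq_len(n))

sim_gene_ids <- function(n) sprintf("HuCL%05dC001", seq_len(n))

#' Simulate daily pot-weight series under the two drought scenarios
#'
#' Treated plants lose weight daily by a genotype-specific transpiration
#' following a two-segment FTSW response: relative transpiration is 1 above
#' the FTSW threshold and declines linearly to 0 below it. Control plants
#' have the transpired water restored right after weighing, so their weight
#' (and FTSW) stays at field capacity. Harvest days follow the two rules:
#' the fixed-duration blocks are all cut when half of their treated plants
#' drop below FTSW 0.35; each fixed-intensity treated plant is cut when it
#' crosses FTSW 0.1, together with its paired control.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed optional seed overriding \code{config$seed}.
#' @param require_harvest if TRUE (default) a trajectory that never meets
#'   its harvest rule within \code{max_days} is an error; if FALSE such
#'   plants are assigned the last simulated day (useful when probing
#'   degenerate transpiration settings).
#' @return a list with \code{plants} (plant_id, scenario, block, genotype,
#'   treatment, is_control, harvest_day, itw), \code{pot_weights} (long
#'   table: plant_id, day, weight_g, water_added_g), \code{calibration}
#'   (initial/final weight and TTSW) and \code{coefficients} (per-genotype
#'   daily transpiration, g/day).
#' @export
simulate_water_depletion <- function(config, seed = config$seed,
                                     require_harvest = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  G <- config$n_genotypes
  B <- config$n_blocks_per_scenario
  genos <- sim_genotype_names(G)
  ttsw <- compute_ttsw(config$initial_weight, config$final_weight)

  coefs <- config$transpiration_coefficients
  if (is.null(coefs)) {
    coefs <- config$base_transpiration *
      exp(stats::rnorm(G, 0, config$transpiration_cv))
  }
  if (length(coefs) != G) stop("need one transpiration coefficient per genotype")
  names(coefs) <- genos

  plants <- expand.grid(scenario = c("FDS", "FIS"),
                        block_in_scenario = seq_len(B),
                        genotype = genos,
                        treatment = c("control", "stressed"),
                        stringsAsFactors = FALSE)
  plants$block <- ifelse(plants$scenario == "FDS",
                         plants$block_in_scenario,
                         plants$block_in_scenario + B)
  plants$block <- sprintf("B%d", plants$block)
  plants$is_control <- plants$treatment == "control"
  plants <- plants[order(plants$scenario, plants$block,
                         plants$genotype, plants$treatment), ]
  plants$plant_id <- sprintf("P%02d", seq_len(nrow(plants)))
  rownames(plants) <- NULL

  days <- 0:config$max_days
  theta <- config$ftsw_threshold_transpiration
  n_p <- nrow(plants)
  weight <- matrix(NA_real_, length(days), n_p)
  added <- matrix(0, length(days), n_p)
  # per-plant multiplicative variation around the genotype coefficient,
  # plus day-to-day multiplicative noise on the realized transpiration
  plant_mult <- exp(stats::rnorm(n_p, 0, 0.05))
  day_noise <- matrix(exp(stats::rnorm(length(days) * n_p, 0, 0.03)),
                      length(days), n_p)
  weight[1, ] <- config$initial_weight
  for (d in seq_along(days)[-1]) {
    w_prev <- weight[d - 1L, ]
    ftsw_prev <- pmin(pmax((w_prev - config$final_weight) / ttsw, 0), 1)
    ftsw_prev[plants$is_control] <- 1
    td <- coefs[plants$genotype] * plant_mult * day_noise[d, ] *
      pmin(1, ftsw_prev / theta)
    td <- pmin(td, w_prev - config$final_weight) # cannot pass the wilting point
    td <- pmax(td, 0)
    weight[d, ] <- w_prev - td
    # controls are re-watered right after weighing: weight restored,
    # transpired water logged as water_added
    weight[d, plants$is_control] <- config$initial_weight
    added[d, plants$is_control] <- td[plants$is_control]
  }
  ftsw <- pmin(pmax((weight - config$final_weight) / ttsw, 0), 1)
  ftsw[, plants$is_control] <- 1

  # harvest scheduling
  last_day <- as.integer(config$max_days)
  fds_treated <- which(plants$scenario == "FDS" & !plants$is_control)
  fds_day <- tryCatch(schedule_fds_harvest(ftsw[, fds_treated, drop = FALSE]),
                      error = function(e) {
                        if (require_harvest) stop(e)
                        warning(conditionMessage(e)); last_day
                      })
  harvest <- integer(n_p)
  harvest[plants$scenario == "FDS"] <- fds_day
  fis_treated <- which(plants$scenario == "FIS" & !plants$is_control)
  for (j in fis_treated) {
    hd <- tryCatch(schedule_fis_harvest(ftsw[, j]),
                   error = function(e) {
                     if (require_harvest) {
                       stop("plant ", plants$plant_id[j], ": ",
                            conditionMessage(e))
                     }
                     last_day
                   })
    harvest[j] <- hd
    mate <- which(plants$scenario == "FIS" & plants$is_control &
                    plants$genotype == plants$genotype[j] &
                    plants$block == plants$block[j])
    harvest[mate] <- hd
  }
  plants$harvest_day <- harvest

  # ITW: daily sum of (1 - FTSW) from irrigation stop through the day
  # before harvest (controls integrate to 0 by construction)
  plants$itw <- vapply(seq_len(n_p), function(j) {
    if (harvest[j] == 0) return(0)
    compute_itw(ftsw[seq_len(harvest[j]), j])
  }, numeric(1))

  keep <- lapply(seq_len(n_p), function(j) {
    idx <- seq_len(harvest[j] + 1L)
    data.frame(plant_id = plants$plant_id[j], day = days[idx],
               weight_g = weight[idx, j], water_added_g = added[idx, j],
               stringsAsFactors = FALSE)
  })
  pot_weights <- do.call(rbind, keep)
  rownames(pot_weights) <- NULL

  list(plants = plants[, c("plant_id", "scenario", "block", "genotype",
                           "treatment", "is_control", "harvest_day", "itw")],
       pot_weights = pot_weights,
       calibration = list(initial_weight = config$initial_weight,
                          final_weight = config$final_weight, ttsw = ttsw),
       coefficients = coefs)
}

# Latent-factor layout: which modeled phenotypes load on which factor and
# with which sign. ITW is not modeled here (it comes from the water
# simulation); OP opposes the water-status factor so that the OP-ITW
# correlation is negative.
sim_factor_map <- function() {
  data.frame(
    phenotype = c("OP", "E", "RWC", "PHe", "CoD", "TLA", "LMA", "CID"),
    factor = c(1, 1, 1, 2, 2, 2, 3, 3),
    beta_sign = c(-1, 1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Build the truth record for a synthetic dataset
#'
#' Draws the planted per-gene effect classes, the per-gene effect
#' parameters, the trait-coupled gene pools with their signs, and the
#' planted gene-phenotype association list. Everything a recovery test
#' needs is recorded here.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed seed for the truth draw.
#' @return a list of class \code{sim_truth}.
#' @export
make_truth <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  n <- config$n_genes
  G <- config$n_genotypes
  genes <- sim_gene_ids(n)
  d <- config$effect_size_sd_units * config$noise_sd

  fmap <- sim_factor_map()
  pool_sizes <- tapply(rep(config$genes_per_phenotype, nrow(fmap)),
                       fmap$factor, sum)
  n_trait <- sum(pool_sizes)
  trait_idx <- sort(sample.int(n, n_trait))
  factor_of_gene <- rep(NA_integer_, n)
  factor_of_gene[trait_idx] <- rep(as.integer(names(pool_sizes)),
                                   times = pool_sizes)
  gene_sign <- rep(0L, n)
  gene_sign[trait_idx] <- sample(c(-1L, 1L), n_trait, replace = TRUE)

  # planted ANOVA classes on genes outside the trait pools
  n_t  <- round(config$frac_treatment_genes * n)
  n_g  <- round(config$frac_genotype_genes * n)
  n_gt <- round(config$frac_gxt_genes * n)
  n_ov <- 4 * (round(config$frac_overlap_genes * n) %/% 4)
  free <- setdiff(seq_len(n), trait_idx)
  if (n_t + n_g + n_gt + n_ov > length(free)) {
    stop("planted class fractions leave no room next to the trait pools")
  }
  picked <- sample(free, n_t + n_g + n_gt + n_ov)
  class_of <- rep("none", n)
  labs <- c(rep("t_o", n_t), rep("g_o", n_g), rep("g*t_o", n_gt),
            rep(c("g_t", "g*t_g", "g*t_t", "All"), each = n_ov / 4))
  class_of[picked] <- labs

  has_t  <- class_of %in% c("t_o", "g_t", "g*t_t", "All")
  has_g  <- class_of %in% c("g_o", "g_t", "g*t_g", "All")
  has_gt <- class_of %in% c("g*t_o", "g*t_g", "g*t_t", "All")

  # effect parameters: balanced-sign patterns of fixed magnitude so the
  # planted non-centrality is the same for every gene of a class
  half <- c(rep(1, G %/% 2), rep(-1, G - G %/% 2))
  half <- half - mean(half)
  treat_sign <- ifelse(has_t, sample(c(-1, 1), n, replace = TRUE), 0)
  geno_pattern <- matrix(0, n, G)
  gt_pattern <- matrix(0, n, G)
  for (i in which(has_g)) geno_pattern[i, ] <- d * sample(half)
  for (i in which(has_gt)) gt_pattern[i, ] <- 2 * d * sample(half)
  colnames(geno_pattern) <- colnames(gt_pattern) <- sim_genotype_names(G)

  # planted associations: every gene of a factor pool is associated with
  # every phenotype loading on that factor
  assoc <- do.call(rbind, lapply(seq_len(nrow(fmap)), function(r) {
    idx <- which(factor_of_gene == fmap$factor[r])
    if (!length(idx)) return(NULL)
    data.frame(gene = genes[idx], phenotype = fmap$phenotype[r],
               sign = gene_sign[idx] * fmap$beta_sign[r],
               weight = fmap$beta_sign[r] * gene_sign[idx] / length(idx),
               stringsAsFactors = FALSE)
  }))
  if (is.null(assoc)) {
    assoc <- data.frame(gene = character(0), phenotype = character(0),
                        sign = numeric(0), weight = numeric(0),
                        stringsAsFactors = FALSE)
  }
  rownames(assoc) <- NULL

  structure(list(
    genes = genes,
    effect_class = stats::setNames(class_of, genes),
    treat_sign = treat_sign,
    geno_pattern = geno_pattern,
    gt_pattern = gt_pattern,
    factor_of_gene = factor_of_gene,
    gene_sign = gene_sign,
    factor_map = fmap,
    associations = assoc,
    effect_size = d
  ), class = "sim_truth")
}

#' Simulate the log2 expression matrix
#'
#' Every gene is baseline plus Gaussian noise; planted genes add centred
#' treatment / genotype / interaction shifts of fixed magnitude (in
#' residual-SD units) with randomized sign patterns, and trait-coupled
#' genes add their loading on the sample-level latent factors. Block
#' carries a small nuisance shift.
#'
#' @param config a \code{\link{sim_config}}.
#' @param truth a \code{\link{make_truth}} record.
#' @param samples sample sheet: plant_id, scenario, block, genotype,
#'   treatment (one chip per plant).
#' @param seed seed for the expression draw.
#' @return list with \code{expr} (genes x samples matrix, log2 scale) and
#'   \code{factors} (samples x 3 latent factor scores).
#' @export
simulate_expression <- function(config, truth, samples, seed) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(as.integer(seed))
  n <- config$n_genes
  m <- nrow(samples)
  treat_c <- ifelse(samples$treatment == "stressed", 0.5, -0.5)

  factors <- matrix(stats::rnorm(m * 3), m, 3,
                    dimnames = list(samples$plant_id, paste0("F", 1:3)))
  factors[, 1] <- factors[, 1] + config$treatment_alignment * treat_c

  baseline <- stats::rnorm(n, 8, 1.5)
  blocks <- unique(samples$block)
  block_shift <- matrix(stats::rnorm(n * length(blocks), 0, config$block_sd),
                        n, length(blocks), dimnames = list(NULL, blocks))

  expr <- matrix(stats::rnorm(n * m, 0, config$noise_sd), n, m,
                 dimnames = list(truth$genes, samples$plant_id))
  expr <- expr + baseline
  expr <- expr + block_shift[, samples$block]
  d <- truth$effect_size
  expr <- expr + (d * truth$treat_sign) %o% treat_c
  gidx <- match(samples$genotype, colnames(truth$geno_pattern))
  expr <- expr + truth$geno_pattern[, gidx]
  expr <- expr + truth$gt_pattern[, gidx] * rep(treat_c, each = n)
  lam <- config$gene_factor_loading * config$noise_sd
  coupled <- which(!is.na(truth$factor_of_gene))
  if (length(coupled)) {
    expr[coupled, ] <- expr[coupled, ] +
      (lam * truth$gene_sign[coupled]) *
        t(factors[, truth$factor_of_gene[coupled], drop = FALSE])
  }
  list(expr = expr, factors = factors)
}

#' Simulate the per-plant phenotype table
#'
#' Each modeled phenotype is the planted signed linear combination of its
#' gene set's expression plus Gaussian measurement noise, then mapped to a
#' plausible unit scale. ITW is taken from the water simulation, not the
#' linear model; gs is a noisy affine companion of E (a pass-through
#' measurement in the downstream analysis).
#'
#' @param config a \code{\link{sim_config}}.
#' @param truth truth record.
#' @param expr genes x samples expression matrix.
#' @param water result of \code{\link{simulate_water_depletion}}.
#' @param seed seed for the measurement noise.
#' @return data.frame with plant_id and columns ITW, E, gs, OP, RWC, LMA,
#'   CID, PHe, CoD, TLA.
#' @export
simulate_phenotypes <- function(config, truth, expr, water, seed) {
  set.seed(as.integer(seed))
  plants <- water$plants
  stopifnot(identical(colnames(expr), plants$plant_id))
  m <- ncol(expr)
  raw <- matrix(0, m, nrow(truth$factor_map),
                dimnames = list(plants$plant_id, truth$factor_map$phenotype))
  for (p in truth$factor_map$phenotype) {
    a <- truth$associations[truth$associations$phenotype == p, , drop = FALSE]
    if (nrow(a)) {
      raw[, p] <- as.numeric(t(expr[a$gene, , drop = FALSE]) %*% a$weight)
    }
    raw[, p] <- raw[, p] + stats::rnorm(m, 0, config$phenotype_noise_sd)
  }
  units <- list(E = c(4, 1), OP = c(-1.2, 0.15), RWC = c(0.85, 0.02),
                LMA = c(80, 6), CID = c(20, 0.8), PHe = c(60, 8),
                CoD = c(10, 1.2), TLA = c(3000, 300))
  out <- data.frame(plant_id = plants$plant_id, ITW = plants$itw,
                    stringsAsFactors = FALSE)
  for (p in names(units)) {
    out[[p]] <- units[[p]][1] + units[[p]][2] * raw[, p]
  }
  out$RWC <- pmin(pmax(out$RWC, 0.02), 1)
  out$gs <- pmax(0.02 + 0.004 * (out$E - 4) + stats::rnorm(m, 0, 0.003), 1e-4)
  out[, c("plant_id", "ITW", "E", "gs", "OP", "RWC", "LMA", "CID",
          "PHe", "CoD", "TLA")]
}

#' Generate a synthetic field-derived differentially expressed gene list
#'
#' Samples \code{n_field_genes} gene IDs enriched for the planted
#' trait-linked genes: each slot is trait-linked with probability
#' \code{enrichment_factor} times the background rate (capped at 1), the
#' remainder drawn uniformly from non-linked genes.
#'
#' @param truth truth record (provides the trait-linked pool and universe).
#' @param n_field_genes list size (default 156).
#' @param enrichment_factor sampling-rate multiplier (1 = no enrichment).
#' @param seed seed.
#' @return character vector of gene IDs.
#' @export
generate_field_dataset <- function(truth, n_field_genes = 156,
                                   enrichment_factor = 5,
                                   seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  if (n_field_genes == 0) return(character(0))
  if (enrichment_factor <= 0) stop("enrichment_factor must be positive")
  set.seed(as.integer(seed))
  linked <- unique(truth$associations$gene)
  unlinked <- setdiff(truth$genes, linked)
  p_link <- min(1, enrichment_factor * length(linked) / length(truth$genes))
  k <- stats::rbinom(1, n_field_genes, p_link)
  k <- min(k, length(linked))
  if (n_field_genes - k > length(unlinked)) {
    stop("requested field list exceeds the available gene pool")
  }
  out <- c(sample(linked, k), sample(unlinked, n_field_genes - k))
  sample(out) # shuffle so linked genes are not listed first
}

#' Generate a complete synthetic dataset
#'
#' Runs the water, truth, expression, phenotype and field-list generators
#' with sub-seeds derived from the master seed, so identical (config, seed)
#' give identical datasets.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed optional master seed overriding \code{config$seed}.
#' @return list of class \code{sim_dataset}: expr, samples, pot_weights,
#'   phenotypes, water, truth, field_genes, factors.
#' @export
simulate_dataset <- function(config = sim_config(), seed = config$seed) {
  subs <- sim_subseeds(seed)
  water <- simulate_water_depletion(config, seed = subs[1])
  truth <- make_truth(config, seed = subs[2])
  samples <- water$plants[, c("plant_id", "scenario", "block",
                              "genotype", "treatment")]
  ex <- simulate_expression(config, truth, samples, seed = subs[3])
  phen <- simulate_phenotypes(config, truth, ex$expr, water, seed = subs[4])
  field <- generate_field_dataset(truth, config$n_field_genes,
                                  config$field_enrichment_factor,
                                  seed = subs[5])
  structure(list(expr = ex$expr, samples = samples,
                 pot_weights = water$pot_weights, phenotypes = phen,
                 water = water, truth = truth, field_genes = field,
                 factors = ex$factors, config = config, seed = seed),
            class = "sim_dataset")
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits the expression TSV (first column gene ID, header = sample IDs),
#' sample sheet CSV, pot-weight CSV, phenotype CSV, field gene list (one
#' ID per line) and the truth record as JSON.
#'
#' @param dataset a \code{\link{simulate_dataset}} result.
#' @param outdir output directory (created if missing).
#' @return invisibly, the vector of file paths written.
#' @export
write_dataset <- function(dataset, outdir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_expression_tsv(dataset$expr, p("expression.tsv"))
  utils::write.csv(dataset$samples, p("samples.csv"), row.names = FALSE)
  utils::write.csv(dataset$pot_weights, p("pot_weights.csv"), row.names = FALSE)
  utils::write.csv(dataset$phenotypes, p("phenotypes.csv"), row.names = FALSE)
  writeLines(dataset$field_genes, p("field_genes.txt"))
  truth <- dataset$truth
  truth_json <- list(
    effect_class = as.list(truth$effect_class),
    associations = truth$associations,
    transpiration_coefficients = as.list(dataset$water$coefficients),
    harvest_day = stats::setNames(as.list(dataset$water$plants$harvest_day),
                                  dataset$water$plants$plant_id)
  )
  jsonlite::write_json(truth_json, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(vapply(c("expression.tsv", "samples.csv", "pot_weights.csv",
                     "phenotypes.csv", "field_genes.txt", "truth.json"),
                   p, character(1)))
}
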