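# Synthetic paired discovery/validation datasets with planted structure.
#
# The generator emulates the structure the analysis assumes: per-cell-type
# replicate expression on the log2 scale with a background floor near 6,
# planted monotone gene-ephys relationships of configurable strength, gene
# co-expression blocks driven by shared latent factors, article-level ephys
# measurements carrying study metadata with additive condition effects on
# the modeling scale, and a single-cell TPM validation arm with dropout.
# All randomness flows through named substreams of one seed, so enlarging
# the gene panel does not perturb the ephys draws.

# Typical location/spread per property on its modeling scale (log10 for the
# positivity-constrained set). Chosen to mirror commonly reported rodent
# values: e.g. Vrest ~ -65 mV, Rin ~ 160 MOhm, Tau ~ 16 ms, Cm ~ 100 pF.
property_priors <- function() {
  tibble::tribble(
    ~property, ~model_mean, ~model_sd,
    "Vrest",   -65,  6,
    "Rin",     2.2,  0.35,
    "Tau",     1.2,  0.25,
    "Cm",      2.0,  0.25,
    "APamp",   75,   10,
    "APhw",    0.0,  0.25,
    "APthr",   -40,  5,
    "AHPamp",  12,   5,
    "Rheo",    2.0,  0.4,
    "FRmax",   1.8,  0.35,
    "SFA",     0.6,  0.2
  )
}

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the design of the study the package models: 34 cell
#' types with a background expression floor of ~6 log2 units in the
#' discovery arm, and 12 cre-lines of single cells in the TPM validation
#' arm.
#'
#' @param n_cell_types Number of discovery cell types.
#' @param replicates_per_type Expression samples per cell type.
#' @param n_genes Total genes (planted + null).
#' @param background_level Background expression floor, log2 units.
#' @param articles_per_type Integer range (length 2) of articles reporting
#'   each (cell type, property).
#' @param property_missing_rate Probability that a (cell type, property)
#'   has no curated measurement at all.
#' @param replicate_noise_sd Within-type, across-replicate expression noise
#'   (log2 units).
#' @param measurement_noise_frac Article-level ephys noise, as a fraction
#'   of each property's across-type spread on the modeling scale.
#' @param planted_amplitude Across-type expression swing of planted genes
#'   (log2 units, one standard deviation).
#' @param null_bio_sd Across-type biological variation of null genes (log2
#'   units).
#' @param n_lines Cre-lines in the validation arm (taken from the first
#'   `n_lines` discovery cell types, sharing their latent ephys values).
#' @param cells_per_line Single cells per line, transcriptomic arm.
#' @param ephys_cells_per_line Single cells per line, ephys arm (disjoint
#'   cells).
#' @param cell_noise_sd Per-cell expression noise (log2 units).
#' @param cell_ephys_noise_frac Per-cell ephys noise, fraction of the
#'   property's modeling-scale spread.
#' @param dropout_rate Probability an scRNAseq entry is zeroed by dropout.
#' @param seed Integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cell_types = 34L,
                             replicates_per_type = 3L,
                             n_genes = 3000L,
                             background_level = 6.0,
                             articles_per_type = c(3L, 6L),
                             property_missing_rate = 0.15,
                             replicate_noise_sd = 0.5,
                             measurement_noise_frac = 0.35,
                             planted_amplitude = 1.5,
                             null_bio_sd = 0.5,
                             n_lines = 12L,
                             cells_per_line = 30L,
                             ephys_cells_per_line = 30L,
                             cell_noise_sd = 1.0,
                             cell_ephys_noise_frac = 0.5,
                             dropout_rate = 0.3,
                             seed = 1L) {
  stopifnot(
    n_cell_types >= 3, replicates_per_type >= 1, n_genes >= 10,
    length(articles_per_type) == 2, all(articles_per_type >= 1),
    articles_per_type[1] <= articles_per_type[2],
    property_missing_rate >= 0, property_missing_rate < 1,
    replicate_noise_sd >= 0, measurement_noise_frac >= 0,
    planted_amplitude > 0, null_bio_sd >= 0,
    n_lines >= 2, n_lines <= n_cell_types,
    cells_per_line >= 1, ephys_cells_per_line >= 1,
    cell_noise_sd >= 0, cell_ephys_noise_frac >= 0,
    dropout_rate >= 0, dropout_rate < 1
  )
  structure(as.list(environment()), class = "synthetic_config")
}

#' Ground truth for a synthetic dataset
#'
#' @param planted_effects Tibble with columns `gene`, `property`,
#'   `direction` (`"+"` or `"-"`) and `target_abs_spearman` in (0, 1): the
#'   planted monotone gene-ephys relationships.
#' @param lab_effects Tibble with columns `property`, `covariate` (one of
#'   `"age"`, `"temp"`, `"electrode"`, `"jxn"`, `"species"`) and
#'   `magnitude`: additive study-level condition effects on the modeling
#'   scale. Conventions: `temp` is a slope per degree C (centered at 29 C);
#'   `age` a slope per decade of log10(age in days) (centered at log10 30);
#'   `electrode` an offset applied to sharp-electrode articles; `jxn` an
#'   offset applied to junction-potential-uncorrected articles; `species`
#'   an offset applied to rat articles.
#' @param coexpression_blocks List of character vectors of gene ids; each
#'   block shares a latent co-expression factor.
#' @param n_genes Total genes in the generated matrix; genes not planted
#'   are null (independent of every latent ephys value).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(planted_effects = NULL, lab_effects = NULL,
                         coexpression_blocks = list(), n_genes = 3000L) {
  all_genes <- sprintf("G%04d", seq_len(n_genes))
  planted_effects <- if (is.null(planted_effects)) {
    tibble::tibble(gene = character(), property = character(),
                   direction = character(), target_abs_spearman = numeric())
  } else tibble::as_tibble(planted_effects)
  if (nrow(planted_effects) > 0) {
    stopifnot(
      all(planted_effects$direction %in% c("+", "-")),
      all(planted_effects$target_abs_spearman > 0),
      all(planted_effects$target_abs_spearman < 1),
      all(planted_effects$gene %in% all_genes)
    )
    assert_property(planted_effects$property)
    if (anyDuplicated(planted_effects$gene)) {
      stop("Each planted gene may target a single property.", call. = FALSE)
    }
  }
  lab_effects <- if (is.null(lab_effects)) {
    tibble::tibble(property = character(), covariate = character(),
                   magnitude = numeric())
  } else tibble::as_tibble(lab_effects)
  if (nrow(lab_effects) > 0) {
    assert_property(lab_effects$property)
    stopifnot(all(lab_effects$covariate %in%
                    c("age", "temp", "electrode", "jxn", "species")))
  }
  stopifnot(all(unlist(coexpression_blocks) %in% all_genes))
  structure(
    list(
      planted_effects = planted_effects,
      lab_effects = lab_effects,
      coexpression_blocks = coexpression_blocks,
      null_genes = setdiff(all_genes, planted_effects$gene),
      genes = all_genes
    ),
    class = "ground_truth"
  )
}

#' A default ground truth with planted effects spread across properties
#'
#' @param cfg A [synthetic_config()].
#' @param n_planted Number of planted genes, assigned round-robin across
#'   `properties`.
#' @param target_abs_spearman Planted correlation magnitude (recycled).
#' @param properties Properties receiving planted genes.
#' @param lab_effects As in [ground_truth()]; defaults to a +0.5 mV/C
#'   temperature slope on Vrest, a junction-potential offset of +8 mV on
#'   Vrest, and an age slope of -0.25 decades/decade on Rin.
#' @return A `ground_truth`.
#' @export
default_ground_truth <- function(cfg, n_planted = 30L,
                                 target_abs_spearman = 0.8,
                                 properties = ephys_property_codes(),
                                 lab_effects = NULL) {
  stopifnot(n_planted < cfg$n_genes)
  assert_property(properties)
  planted <- tibble::tibble(
    gene = sprintf("G%04d", seq_len(n_planted)),
    property = rep_len(properties, n_planted),
    direction = rep_len(c("+", "-"), n_planted),
    target_abs_spearman = rep_len(target_abs_spearman, n_planted)
  )
  if (is.null(lab_effects)) {
    lab_effects <- tibble::tribble(
      ~property, ~covariate, ~magnitude,
      "Vrest", "temp", 0.5,
      "Vrest", "jxn",  8,
      "Rin",   "age", -0.25
    )
  }
  blocks <- list()
  if (cfg$n_genes >= n_planted + 40) {
    blocks <- list(
      sprintf("G%04d", n_planted + 1:20),
      sprintf("G%04d", n_planted + 21:40)
    )
  }
  ground_truth(planted, lab_effects, blocks, n_genes = cfg$n_genes)
}

# Deterministic shared latent state: cell-type labels and ages, the latent
# ephys value of every (type, property) on the modeling scale, and every
# gene's per-type mean log2 expression. Both generator arms rebuild this
# from the same substreams, which is what ties discovery and validation to
# a common truth.
synth_latents <- function(cfg, truth) {
  priors <- property_priors()
  types <- sprintf("T%02d", seq_len(cfg$n_cell_types))
  ages <- with_substream(cfg$seed, "celltypes", {
    round(10^stats::runif(cfg$n_cell_types, log10(7), log10(90)), 1)
  })
  latent <- with_substream(cfg$seed, "latents", {
    z <- matrix(stats::rnorm(cfg$n_cell_types * nrow(priors)),
                cfg$n_cell_types, nrow(priors),
                dimnames = list(types, priors$property))
    list(z = z,
         model = sweep(sweep(z, 2, priors$model_sd, `*`), 2,
                       priors$model_mean, `+`))
  })
  n_blocks <- length(truth$coexpression_blocks)
  gene_means <- with_substream(cfg$seed, "expression", {
    mu <- matrix(NA_real_, cfg$n_cell_types, cfg$n_genes,
                 dimnames = list(types, truth$genes))
    factors <- if (n_blocks > 0) {
      f <- matrix(stats::rnorm(cfg$n_cell_types * n_blocks), cfg$n_cell_types)
      sweep(f, 2, colMeans(f))   # centered: blocks shift no gene's mean
    } else NULL
    planted <- truth$planted_effects
    amp <- cfg$planted_amplitude
    # Replicate averaging attenuates the planted correlation; compensate so
    # the population Spearman magnitude of summarized expression vs the
    # latent hits the target. Spearman -> Pearson via the bivariate-normal
    # identity r = 2 sin(pi * rho_s / 6).
    atten <- amp / sqrt(amp^2 + cfg$replicate_noise_sd^2 / cfg$replicates_per_type)
    for (i in seq_len(nrow(planted))) {
      r_target <- 2 * sin(pi * planted$target_abs_spearman[i] / 6)
      r_plant <- r_target / atten
      if (r_plant > 0.999) {
        stop("Planted target |r_s| = ", planted$target_abs_spearman[i],
             " for gene ", planted$gene[i], " is infeasible at ",
             "replicate_noise_sd = ", cfg$replicate_noise_sd,
             "; lower the noise or the target.", call. = FALSE)
      }
      zsig <- latent$z[, planted$property[i]] *
        ifelse(planted$direction[i] == "+", 1, -1)
      eps <- stats::rnorm(cfg$n_cell_types)
      base <- stats::runif(1, 8.5, 10)
      mu[, planted$gene[i]] <-
        base + amp * (r_plant * zsig + sqrt(1 - r_plant^2) * eps)
    }
    for (g in truth$null_genes) {
      # per-gene baseline stays within the background band; across-type
      # variation is centered so each null gene's mean sits at its baseline
      base <- cfg$background_level + stats::runif(1, -0.3, 0.3)
      eps <- stats::rnorm(cfg$n_cell_types)
      mu[, g] <- base + cfg$null_bio_sd * (eps - mean(eps))
    }
    if (n_blocks > 0) {
      for (b in seq_len(n_blocks)) {
        for (g in intersect(truth$coexpression_blocks[[b]], truth$null_genes)) {
          mu[, g] <- mu[, g] + 0.8 * factors[, b]
        }
      }
    }
    mu
  })
  list(types = types, ages = ages, z = latent$z,
       latent_model = latent$model, gene_means = gene_means,
       priors = priors)
}

lab_effect_delta <- function(lab_effects, property, rec_temp_C, age_days,
                             electrode, jxn_status, species) {
  delta <- numeric(length(rec_temp_C))
  fx <- lab_effects[lab_effects$property == property, , drop = FALSE]
  for (i in seq_len(nrow(fx))) {
    delta <- delta + switch(
      fx$covariate[i],
      temp = fx$magnitude[i] * (rec_temp_C - 29),
      age = fx$magnitude[i] * (log10(age_days) - log10(30)),
      electrode = fx$magnitude[i] * (electrode == "sharp"),
      jxn = fx$magnitude[i] * (jxn_status == "not_corrected"),
      species = fx$magnitude[i] * (species == "rat")
    )
  }
  delta
}

#' Generate a discovery-style dataset with known ground truth
#'
#' Produces replicate-level log2 expression and article-level curated ephys
#' measurements. Planted genes' per-cell-type mean expression is a linear
#' (hence monotone) function of the latent property value, calibrated so
#' the population Spearman magnitude of summarized expression against the
#' latent matches `target_abs_spearman`. Null genes are independent of all
#' latent ephys values. Article metadata (species, electrode, junction
#' potential, age, temperature) is drawn per article and the configured
#' study-level condition effects are added on the modeling scale.
#'
#' @param cfg A [synthetic_config()].
#' @param truth A [ground_truth()] consistent with `cfg` (same `n_genes`).
#' @return A list with elements `expression` (an [expression_matrix()] on
#'   the log2 intensity scale), `ephys` (a measurement tibble as from
#'   [read_ephys_table()]), and `truth` (the input ground truth augmented
#'   with the realized latent state: `cell_types`, `ages`, `latent_model`,
#'   a cell-type x property matrix on the modeling scale, and `gene_means`).
#' @export
generate_discovery_dataset <- function(cfg, truth = default_ground_truth(cfg)) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(truth, "ground_truth"))
  stopifnot(length(truth$genes) == cfg$n_genes)
  lat <- synth_latents(cfg, truth)

  vals <- with_substream(cfg$seed, "replicates", {
    n_samp <- cfg$n_cell_types * cfg$replicates_per_type
    type_of_sample <- rep(seq_len(cfg$n_cell_types), each = cfg$replicates_per_type)
    v <- t(lat$gene_means[type_of_sample, , drop = FALSE]) +
      matrix(stats::rnorm(cfg$n_genes * n_samp, 0, cfg$replicate_noise_sd),
             cfg$n_genes, n_samp)
    colnames(v) <- sprintf("S_%s_%d", lat$types[type_of_sample],
                           rep(seq_len(cfg$replicates_per_type), cfg$n_cell_types))
    rownames(v) <- truth$genes
    v
  })
  meta <- tibble::tibble(
    sample_id = colnames(vals),
    cell_type_label = rep(lat$types, each = cfg$replicates_per_type),
    age_days = rep(lat$ages, each = cfg$replicates_per_type),
    platform = "synthetic_array"
  )
  expr <- expression_matrix(vals, "log2_intensity", meta)

  ephys <- with_substream(cfg$seed, "ephys", {
    props <- ephys_property_codes()
    grid <- tidyr::crossing(type_idx = seq_len(cfg$n_cell_types),
                            property = props)
    grid <- grid[stats::runif(nrow(grid)) >= cfg$property_missing_rate, ]
    grid$n_art <- sample(seq(cfg$articles_per_type[1], cfg$articles_per_type[2]),
                         nrow(grid), replace = TRUE)
    df <- grid[rep(seq_len(nrow(grid)), grid$n_art), c("type_idx", "property")]
    n <- nrow(df)
    df$article_id <- sprintf("A%05d", seq_len(n))
    df$cell_type_label <- lat$types[df$type_idx]
    df$species <- sample(c("mouse", "rat", "guinea_pig"), n, replace = TRUE,
                         prob = c(0.7, 0.25, 0.05))
    df$electrode <- sample(c("patch", "sharp", "perforated_patch"), n,
                           replace = TRUE, prob = c(0.8, 0.15, 0.05))
    df$jxn_status <- sample(c("not_corrected", "corrected", "unreported"), n,
                            replace = TRUE, prob = c(0.5, 0.3, 0.2))
    df$jxn_offset_mV <- ifelse(df$jxn_status == "corrected",
                               round(stats::runif(n, 8, 15), 1), NA_real_)
    df$rec_temp_C <- round(stats::runif(n, 22, 36), 1)
    # articles characterizing the same cell type span a wide range of
    # animal ages (different labs, protocols); ~+/-35% around the type's
    # typical age keeps age identifiable separately from cell type
    age <- pmax(3, round(lat$ages[df$type_idx] * exp(stats::rnorm(n, 0, 0.3)), 1))
    df$age_lo_days <- age
    df$age_hi_days <- age
    sd_p <- lat$priors$model_sd[match(df$property, lat$priors$property)]
    vm <- lat$latent_model[cbind(df$type_idx, match(df$property, props))] +
      stats::rnorm(n, 0, cfg$measurement_noise_frac * sd_p)
    for (p in unique(df$property)) {
      i <- df$property == p
      vm[i] <- vm[i] + lab_effect_delta(
        truth$lab_effects, p, df$rec_temp_C[i], age[i], df$electrode[i],
        df$jxn_status[i], df$species[i])
    }
    # authors who corrected for the junction potential report the
    # corrected (offset-subtracted) voltage
    revert <- !is.na(df$jxn_offset_mV) & df$property %in% c("Vrest", "APthr")
    vm[revert] <- vm[revert] - df$jxn_offset_mV[revert]
    log10_prop <- df$property %in% ephys_property_codes(log10_only = TRUE)
    df$value <- ifelse(log10_prop, 10^vm, vm)
    df$preparation <- "acute_slice"
    ephys_measurements(df[, c("article_id", "cell_type_label", "property",
                              "value", "species", "preparation", "electrode",
                              "jxn_status", "jxn_offset_mV", "age_lo_days",
                              "age_hi_days", "rec_temp_C")])
  })

  truth$cell_types <- lat$types
  truth$ages <- lat$ages
  truth$latent_model <- lat$latent_model
  truth$gene_means <- lat$gene_means
  list(expression = expr, ephys = ephys, truth = truth)
}

#' Generate a validation-style single-cell dataset sharing the same truth
#'
#' Emulates a cre-line-organized single-cell arm: per line,
#' `cells_per_line` transcriptomic cells whose TPM values are exponentiated
#' from the same latent log2 signal used by the discovery arm (with
#' dropout zeros injected), and a disjoint set of cells carrying per-cell
#' ephys values drawn around the same latent per-line values. Lines are the
#' first `n_lines` discovery cell types, so cross-dataset consistency is
#' testable against the shared ground truth.
#'
#' @inheritParams generate_discovery_dataset
#' @return A list with `expression` (an [expression_matrix()] on the TPM
#'   scale, cells grouped by line), `cell_ephys` (tibble of per-cell
#'   values: `cell_id`, `cell_type_label`, `property`, `value`), `lines`,
#'   and the augmented `truth` (as in [generate_discovery_dataset()]).
#' @export
generate_validation_dataset <- function(cfg, truth = default_ground_truth(cfg)) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(truth, "ground_truth"))
  lat <- synth_latents(cfg, truth)
  lines <- lat$types[seq_len(cfg$n_lines)]

  vals <- with_substream(cfg$seed, "val_cells", {
    n_cells <- cfg$n_lines * cfg$cells_per_line
    line_of_cell <- rep(seq_len(cfg$n_lines), each = cfg$cells_per_line)
    log2_expr <- t(lat$gene_means[line_of_cell, , drop = FALSE]) +
      matrix(stats::rnorm(cfg$n_genes * n_cells, 0, cfg$cell_noise_sd),
             cfg$n_genes, n_cells)
    tpm <- 2^log2_expr
    if (cfg$dropout_rate > 0) {
      drop <- matrix(stats::runif(length(tpm)) < cfg$dropout_rate, nrow(tpm))
      tpm[drop] <- 0
    }
    rownames(tpm) <- truth$genes
    colnames(tpm) <- sprintf("C_%s_%03d", lines[line_of_cell],
                             rep(seq_len(cfg$cells_per_line), cfg$n_lines))
    tpm
  })
  meta <- tibble::tibble(
    sample_id = colnames(vals),
    cell_type_label = rep(lines, each = cfg$cells_per_line),
    age_days = NA_real_,
    platform = "synthetic_scrnaseq"
  )
  expr <- expression_matrix(vals, "tpm", meta)

  cell_ephys <- with_substream(cfg$seed, "val_ephys", {
    priors <- lat$priors
    rows <- lapply(seq_len(cfg$n_lines), function(l) {
      per_prop <- lapply(ephys_property_codes(), function(p) {
        sd_p <- priors$model_sd[priors$property == p]
        vm <- lat$latent_model[lines[l], p] +
          stats::rnorm(cfg$ephys_cells_per_line, 0,
                       cfg$cell_ephys_noise_frac * sd_p)
        tibble::tibble(
          cell_id = sprintf("E_%s_%03d", lines[l],
                            seq_len(cfg$ephys_cells_per_line)),
          cell_type_label = lines[l], property = p,
          value = from_model_scale(vm, p)
        )
      })
      dplyr::bind_rows(per_prop)
    })
    dplyr::bind_rows(rows)
  })

  truth$cell_types <- lat$types
  truth$ages <- lat$ages
  truth$latent_model <- lat$latent_model
  truth$gene_means <- lat$gene_means
  list(expression = expr, cell_ephys = cell_ephys, lines = lines, truth = truth)
}

#' Serialize / read ground truth as JSON
#'
#' Ground truth is written alongside every generated dataset so that
#' downstream checks read the serialized truth, never generator internals.
#'
#' @param truth A `ground_truth` (possibly augmented by a generator).
#' @param path Output / input path.
#' @return `path` invisibly (write); a `ground_truth` (read).
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- unclass(truth)
  for (nm in c("latent_model", "gene_means")) {
    if (!is.null(out[[nm]])) {
      out[[nm]] <- list(rows = rownames(out[[nm]]), cols = colnames(out[[nm]]),
                        values = unname(as.data.frame(out[[nm]])))
    }
  }
  jsonlite::write_json(out, path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- ground_truth(
    planted_effects = if (length(raw$planted_effects) > 0) raw$planted_effects,
    lab_effects = if (length(raw$lab_effects) > 0) raw$lab_effects,
    coexpression_blocks = lapply(raw$coexpression_blocks, as.character),
    n_genes = length(raw$genes)
  )
  for (nm in c("latent_model", "gene_means")) {
    if (!is.null(raw[[nm]])) {
      m <- as.matrix(raw[[nm]]$values)
      dimnames(m) <- list(raw[[nm]]$rows, raw[[nm]]$cols)
      tr[[nm]] <- m
    }
  }
  if (!is.null(raw$cell_types)) tr$cell_types <- raw$cell_types
  if (!is.null(raw$ages)) tr$ages <- raw$ages
  tr
}
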