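FEATURE_COMPARTMENTS <- c("nucleus", "cell", "mitochondria", "vwf",
                          "actin", "junction")

#' Build a latent-factor specification for feature-table simulation
#'
#' Defines the generative model used to simulate single-cell feature
#' tables directly, bypassing image rendering: standardised features
#' arise as `loading %*% factor_scores + noise`, with factor scores
#' drawn around condition-specific means. Each factor is assigned a
#' cellular-compartment tag and loads on its own block of features, so
#' the fraction of variance common to the factors is controlled exactly:
#' with communality `h2` on every feature, `k` factors explain `h2` of
#' the total variance and `k - 1` of them explain `h2 * (k-1)/k`.
#'
#' Condition means encode the same contrasts as [default_phenotype()]:
#' mitochondria-tagged factors carry the DC-vs-HC disease effect and are
#' restored by physiological albumin; junction-, actin- and vWF-tagged
#' factors carry disease effects that albumin does not restore.
#'
#' @param n_factors number of latent factors.
#' @param features_per_factor features loading on each factor.
#' @param communality fraction of each feature's variance explained by
#'   its factor (common variance fraction of the model).
#' @param effect_scale multiplier on the condition factor means.
#' @return list of class `latent_factor_spec` with loading_matrix,
#'   unique_variances, feature_names, compartments, factor_tags and
#'   condition_means (named `group:arm`).
#' @export
default_latent_spec <- function(n_factors = 11, features_per_factor = 6,
                                communality = 0.82, effect_scale = 1) {
  stopifnot(n_factors >= 1, features_per_factor >= 1,
            communality > 0, communality < 1)
  p <- n_factors * features_per_factor
  tags <- rep(FEATURE_COMPARTMENTS, length.out = n_factors)
  loading <- matrix(0, p, n_factors)
  feature_names <- character(p)
  compartments <- character(p)
  for (k in seq_len(n_factors)) {
    rows <- (k - 1) * features_per_factor + seq_len(features_per_factor)
    loading[rows, k] <- sqrt(communality)
    feature_names[rows] <- sprintf("%s_f%02d_%d", tags[k], k,
                                   seq_len(features_per_factor))
    compartments[rows] <- tags[k]
  }
  # factor-mean shift per condition, by the compartment the factor
  # carries; mitochondrial morphology is the dominant disease axis,
  # junction/actin/vWF changes are present but secondary
  shift <- function(tag, group, arm) {
    ph <- default_phenotype(group, arm)
    hc <- default_phenotype("HC", "none")
    switch(tag,
      mitochondria = 2.5 * (ph$mito_fragmentation - hc$mito_fragmentation) /
                       0.65,
      junction = 0.8 * (ph$junction_irregularity -
                          hc$junction_irregularity) / 0.5,
      actin = 0.6 * (ph$actin_stress - hc$actin_stress) / 0.5,
      vwf = 0.5 * (ph$wpb_count_mean - hc$wpb_count_mean) / 3,
      0)                                         # nucleus / cell factors
  }
  conds <- list(c("HC", "none"), c("CC", "none"), c("DC", "none"),
                c("DC", "physiological"), c("HC", "supraphysiological"))
  condition_means <- lapply(conds, function(cd)
    effect_scale * vapply(tags, shift, numeric(1), group = cd[1],
                          arm = cd[2]))
  names(condition_means) <- vapply(conds, paste, character(1),
                                   collapse = ":")
  structure(list(n_factors = n_factors, n_features = p,
                 loading_matrix = loading,
                 unique_variances = rep(1 - communality, p),
                 feature_names = feature_names, compartments = compartments,
                 factor_tags = tags, condition_means = condition_means),
            class = "latent_factor_spec")
}

#' Simulate a single-cell feature table from a latent-factor model
#'
#' For every well in the layout, draws `cells_per_well` cells with
#' factor scores normal around the condition mean (unit variance) and
#' features `loading %*% scores + noise`. Optional per-plate additive
#' offsets emulate plate batch effects that per-plate z-scoring must
#' remove.
#'
#' @param spec a `latent_factor_spec`.
#' @param cells_per_well cells simulated per well.
#' @param layout plate layout data.frame ([generate_plate_layout()]).
#' @param seed integer seed.
#' @param plate_offsets optional named list: plate_id -> numeric vector
#'   (length `n_features`) added to every cell of that plate.
#' @return data.frame: plate_id, well_id, group, albumin_arm,
#'   sample_id, replicate, cell_id, then one column per feature.
#'   Feature->compartment tags are attached as attribute
#'   `compartments`.
#' @export
generate_feature_table <- function(spec, cells_per_well, layout, seed = 1,
                                   plate_offsets = NULL) {
  stopifnot(inherits(spec, "latent_factor_spec"), cells_per_well >= 1)
  L <- spec$loading_matrix
  psi_sd <- sqrt(spec$unique_variances)
  with_seed(seed, {
    blocks <- lapply(seq_len(nrow(layout)), function(i) {
      w <- layout[i, ]
      key <- paste(as.character(w$group), as.character(w$albumin_arm),
                   sep = ":")
      mu <- spec$condition_means[[key]]
      if (is.null(mu)) mu <- numeric(spec$n_factors)
      scores <- matrix(stats::rnorm(cells_per_well * spec$n_factors, mu),
                       nrow = spec$n_factors)     # factors x cells
      noise <- matrix(stats::rnorm(cells_per_well * spec$n_features,
                                   sd = psi_sd),
                      nrow = spec$n_features)
      X <- t(L %*% scores + noise)                # cells x features
      if (!is.null(plate_offsets[[as.character(w$plate_id)]]))
        X <- sweep(X, 2, plate_offsets[[as.character(w$plate_id)]], `+`)
      colnames(X) <- spec$feature_names
      cbind(w[rep(1L, cells_per_well),
              c("plate_id", "well_id", "group", "albumin_arm",
                "sample_id", "replicate")],
            cell_id = seq_len(cells_per_well), as.data.frame(X),
            row.names = NULL)
    })
    out <- do.call(rbind, blocks)
    attr(out, "compartments") <- stats::setNames(spec$compartments,
                                                 spec$feature_names)
    out
  })
}

#' Simulate an extracellular-flux OCR trace
#'
#' Piecewise-constant oxygen consumption over the mito stress test
#' phases (baseline, glucose, oligomycin, FCCP, rotenone/antimycin A)
#' with additive Gaussian noise. Phase boundaries are the injection
#' times.
#'
#' @param phase_levels named numeric vector of OCR levels
#'   (pmol O2/min) — must contain all of baseline, glucose, oligomycin,
#'   fccp, rot_aa.
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_per_phase measurements per phase.
#' @param cell_count cells in the well (attached; used downstream for
#'   normalisation).
#' @param well_id identifier.
#' @param seed integer seed.
#' @param dt_min minutes between measurements.
#' @return data.frame (time_min, phase, ocr, well_id, cell_count) with
#'   attributes `cell_count` and `injections` (phase -> start time).
#' @export
generate_ocr_trace <- function(phase_levels, noise_sd = 2, n_per_phase = 3,
                               cell_count = 6000, well_id = "A01", seed = 1,
                               dt_min = 6.5) {
  missing <- setdiff(OCR_PHASES, names(phase_levels))
  if (length(missing))
    stop("missing phase level(s): ", paste(missing, collapse = ", "))
  if (any(phase_levels < 0)) stop("phase levels must be nonnegative")
  stopifnot(n_per_phase >= 1, cell_count > 0)
  phase <- rep(OCR_PHASES, each = n_per_phase)
  level <- rep(phase_levels[OCR_PHASES], each = n_per_phase)
  n <- length(phase)
  ocr <- level + if (noise_sd > 0)
    with_seed(seed, stats::rnorm(n, sd = noise_sd)) else 0
  trace <- data.frame(time_min = seq_len(n) * dt_min,
                      phase = factor(phase, levels = OCR_PHASES),
                      ocr = as.numeric(ocr), well_id = well_id,
                      cell_count = cell_count, stringsAsFactors = FALSE)
  attr(trace, "cell_count") <- cell_count
  attr(trace, "injections") <- stats::setNames(
    (seq_along(OCR_PHASES) - 1) * n_per_phase * dt_min, OCR_PHASES)
  trace
}

#' Simulate a clinical cohort table
#'
#' One row per patient: group label, Bernoulli categorical flags with
#' per-group probabilities and log-normal continuous variables with
#' per-group location/scale.
#'
#' @param group_sizes named integer vector (group -> n).
#' @param categorical_specs named list: variable -> numeric vector of
#'   per-group probabilities (same order as `group_sizes`).
#' @param continuous_specs named list: variable -> list(meanlog =,
#'   sdlog =) vectors per group.
#' @param seed integer seed.
#' @return data.frame with a `group` column plus the variables.
#' @export
generate_cohort_table <- function(group_sizes, categorical_specs = list(),
                                  continuous_specs = list(), seed = 1) {
  stopifnot(length(group_sizes) >= 1, all(group_sizes >= 1))
  for (v in categorical_specs)
    if (any(v < 0 | v > 1)) stop("categorical probabilities must be in [0,1]")
  groups <- rep(names(group_sizes), group_sizes)
  with_seed(seed, {
    out <- data.frame(group = groups, stringsAsFactors = FALSE)
    for (v in names(categorical_specs)) {
      p <- categorical_specs[[v]][match(groups, names(group_sizes))]
      out[[v]] <- stats::rbinom(length(groups), 1, p)
    }
    for (v in names(continuous_specs)) {
      sp <- continuous_specs[[v]]
      i <- match(groups, names(group_sizes))
      out[[v]] <- stats::rlnorm(length(groups), sp$meanlog[i], sp$sdlog[i])
    }
    out
  })
}
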