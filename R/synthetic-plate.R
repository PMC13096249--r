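GROUPS <- c("HC", "CC", "DC")
ALBUMIN_ARMS <- c("none", "physiological", "supraphysiological")

#' Generate a 96-well plate layout for a plasma-exposure experiment
#'
#' Lays out a plasma-exposure plate following the study design: plasma
#' from healthy controls (HC), compensated cirrhosis (CC) and
#' decompensated cirrhosis (DC) donors, three replicate wells per
#' sample per arm by default. Albumin supplementation arms follow the
#' design: DC samples additionally appear with albumin added to
#' physiological levels, HC samples with albumin added to
#' supraphysiological levels, CC samples only without albumin.
#'
#' @param n_hc,n_cc,n_dc number of plasma samples per group on this
#'   plate (each at least 1... 0 allowed to leave a group off a plate).
#' @param replicates replicate wells per (sample, arm) pair.
#' @param plate_id plate identifier.
#' @param seed integer seed; well positions are shuffled reproducibly.
#' @param sample_offset integer added to sample numbers, so that
#'   multi-plate studies carry globally unique sample ids.
#' @return data.frame with columns plate_id, well_id, group,
#'   albumin_arm, sample_id, replicate.
#' @export
generate_plate_layout <- function(n_hc, n_cc, n_dc, replicates = 3,
                                  plate_id = "P1", seed = 1,
                                  sample_offset = c(HC = 0, CC = 0, DC = 0)) {
  stopifnot(n_hc >= 0, n_cc >= 0, n_dc >= 0, replicates >= 1,
            n_hc + n_cc + n_dc >= 1)
  arms_of <- list(HC = c("none", "supraphysiological"),
                  CC = "none",
                  DC = c("none", "physiological"))
  counts <- c(HC = n_hc, CC = n_cc, DC = n_dc)
  rows <- list()
  for (g in GROUPS) {
    if (counts[[g]] == 0) next
    for (i in seq_len(counts[[g]])) {
      sid <- sprintf("%s%02d", g, i + sample_offset[[g]])
      for (arm in arms_of[[g]])
        for (r in seq_len(replicates))
          rows[[length(rows) + 1L]] <- data.frame(
            plate_id = plate_id, well_id = NA_character_, group = g,
            albumin_arm = arm, sample_id = sid, replicate = r,
            stringsAsFactors = FALSE)
    }
  }
  layout <- do.call(rbind, rows)
  n_wells <- nrow(layout)
  if (n_wells > 96)
    stop("layout requires ", n_wells, " wells; a 96-well plate has 96")
  grid <- as.vector(outer(LETTERS[1:8], sprintf("%02d", 1:12),
                          paste0))                      # A01..H12, row-major
  pos <- with_seed(seed, sample(grid, n_wells))
  layout$well_id <- pos
  layout$group <- factor(layout$group, levels = GROUPS)
  layout$albumin_arm <- factor(layout$albumin_arm, levels = ALBUMIN_ARMS)
  layout[order(layout$well_id), , drop = FALSE]
}

#' Generate the full multi-plate study layout
#'
#' The default study (20 samples per group, 3 replicate wells, the
#' albumin arms of [generate_plate_layout()]) needs 300 wells and is
#' split across plates, keeping all wells of a sample on one plate and
#' balancing groups across plates.
#'
#' @param n_per_group samples per clinical group.
#' @param replicates replicate wells per (sample, arm).
#' @param samples_per_plate samples of each group placed per plate.
#' @param seed integer seed.
#' @return data.frame as in [generate_plate_layout()], several plates.
#' @export
generate_study_layout <- function(n_per_group = 20, replicates = 3,
                                  samples_per_plate = 5, seed = 1) {
  stopifnot(n_per_group >= 1, samples_per_plate >= 1)
  n_plates <- ceiling(n_per_group / samples_per_plate)
  plates <- lapply(seq_len(n_plates), function(p) {
    lo <- (p - 1) * samples_per_plate
    n_here <- min(samples_per_plate, n_per_group - lo)
    generate_plate_layout(n_hc = n_here, n_cc = n_here, n_dc = n_here,
                          replicates = replicates,
                          plate_id = sprintf("P%d", p),
                          seed = seed + p,
                          sample_offset = c(HC = lo, CC = lo, DC = lo))
  })
  do.call(rbind, plates)
}

#' Default phenotype parameters for a clinical group and albumin arm
#'
#' Encodes the qualitative study findings as generator defaults: ECs
#' exposed to DC plasma show fragmented, perinuclear mitochondria and
#' remodelled junctions and cytoskeleton; CC plasma is intermediate; HC
#' plasma is the healthy reference. Albumin supplementation to
#' physiological levels restores the mitochondrial parameters to HC
#' levels while junction irregularity, actin stress and vWF load remain
#' at the disease level; supraphysiological albumin on HC plasma leaves
#' the phenotype unchanged.
#'
#' @param group "HC", "CC" or "DC".
#' @param albumin_arm "none", "physiological" or "supraphysiological".
#' @return list of class `phenotype_params`: mito_fragmentation,
#'   mito_perinuclear, junction_irregularity, actin_stress,
#'   wpb_count_mean, cell_density (cells per field), intensity_snr.
#' @export
default_phenotype <- function(group, albumin_arm = "none") {
  group <- match.arg(group, GROUPS)
  albumin_arm <- match.arg(albumin_arm, ALBUMIN_ARMS)
  base <- switch(group,
    HC = list(mito_fragmentation = 0.15, mito_perinuclear = 0.20,
              junction_irregularity = 0.10, actin_stress = 0.10,
              wpb_count_mean = 3),
    CC = list(mito_fragmentation = 0.45, mito_perinuclear = 0.40,
              junction_irregularity = 0.30, actin_stress = 0.30,
              wpb_count_mean = 4),
    DC = list(mito_fragmentation = 0.80, mito_perinuclear = 0.70,
              junction_irregularity = 0.60, actin_stress = 0.60,
              wpb_count_mean = 6))
  if (albumin_arm == "physiological") {
    hc <- default_phenotype("HC", "none")
    base$mito_fragmentation <- hc$mito_fragmentation
    base$mito_perinuclear <- hc$mito_perinuclear
  }
  # supraphysiological albumin: no phenotype change
  out <- c(base, list(cell_density = 20, intensity_snr = 10))
  validate_phenotype(out)
}

validate_phenotype <- function(p) {
  bounded <- c("mito_fragmentation", "mito_perinuclear",
               "junction_irregularity", "actin_stress")
  for (f in bounded)
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must lie in [0, 1]")
  stopifnot(p$wpb_count_mean >= 0, p$cell_density > 0, p$intensity_snr > 0)
  structure(p, class = "phenotype_params")
}
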