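CHANNEL_TAG <- c(nuclei = "nucleus", ve_cadherin = "junction",
                 f_actin = "actin", mitochondria = "mitochondria",
                 vwf = "vwf")

#' Shape features of a binary object
#'
#' Area, perimeter (boundary edge count), equivalent radius,
#' eccentricity, major and minor axis lengths (from second central
#' moments) and solidity (area over convex hull area). Lengths are in
#' micrometres, areas in square micrometres.
#'
#' @param mask logical matrix containing a single object.
#' @param pixel_size_um physical pixel size.
#' @param prefix feature-name prefix (e.g. "shape_nucleus").
#' @return named numeric vector of 7 features.
#' @export
shape_features <- function(mask, pixel_size_um = 1, prefix = "shape") {
  a_px <- sum(mask)
  nm <- paste(prefix, c("area", "perimeter", "eq_radius", "eccentricity",
                        "major_axis", "minor_axis", "solidity"), sep = "_")
  if (a_px == 0)
    return(stats::setNames(rep(NA_real_, 7), nm))
  pts <- which(mask, arr.ind = TRUE)
  # digital perimeter: foreground/background 4-neighbour edges
  W <- nrow(mask); H <- ncol(mask)
  pad <- matrix(FALSE, W + 2, H + 2); pad[2:(W + 1), 2:(H + 1)] <- mask
  per <- sum(pad[2:(W + 1), 2:(H + 1)] & !pad[1:W, 2:(H + 1)]) +
         sum(pad[2:(W + 1), 2:(H + 1)] & !pad[3:(W + 2), 2:(H + 1)]) +
         sum(pad[2:(W + 1), 2:(H + 1)] & !pad[2:(W + 1), 1:H]) +
         sum(pad[2:(W + 1), 2:(H + 1)] & !pad[2:(W + 1), 3:(H + 2)])
  cv <- stats::cov(pts) * (a_px - 1) / a_px          # population moments
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  ecc <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0
  hull_a <- convex_hull_area(pts)
  c(stats::setNames(c(a_px * pixel_size_um^2, per * pixel_size_um,
                      sqrt(a_px / pi) * pixel_size_um, ecc,
                      major * pixel_size_um, minor * pixel_size_um,
                      min(1, a_px / hull_a)), nm))
}

convex_hull_area <- function(pts) {
  if (nrow(pts) < 3) return(nrow(pts))
  h <- grDevices::chull(pts)
  x <- pts[h, 1]; y <- pts[h, 2]
  n <- length(h)
  # shoelace on pixel centres + half-perimeter correction for pixel extent
  area <- abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
  max(area, nrow(pts))
}

#' Intensity features within a compartment mask
#'
#' @param channel numeric matrix.
#' @param mask logical matrix.
#' @param prefix feature-name prefix.
#' @return mean, sd, mad, q05, q50, q95 and integrated intensity.
#' @export
intensity_features <- function(channel, mask, prefix = "int") {
  v <- channel[mask]
  nm <- paste(prefix, c("mean", "sd", "mad", "q05", "q50", "q95",
                        "integrated"), sep = "_")
  if (!length(v)) return(stats::setNames(rep(NA_real_, 7), nm))
  q <- stats::quantile(v, c(.05, .5, .95), names = FALSE, type = 7)
  stats::setNames(c(mean(v), if (length(v) > 1) stats::sd(v) else 0,
                    stats::mad(v), q[1], q[2], q[3], sum(v)), nm)
}

#' Haralick texture features within a compartment mask
#'
#' Grey-level co-occurrence features (contrast, correlation, entropy,
#' angular second moment) at pixel offsets 1 and 2, each averaged over
#' the four principal directions, on intensities quantised to
#' `n_levels` grey levels within the compartment. A constant
#' compartment has contrast and entropy 0, angular second moment 1,
#' and correlation 0 by convention (it is undefined at zero variance).
#'
#' @param channel numeric matrix.
#' @param mask logical matrix.
#' @param n_levels quantisation levels (default 32).
#' @param offsets pixel distances (default 1 and 2).
#' @param prefix feature-name prefix.
#' @return named numeric vector, 4 features per offset.
#' @export
texture_features <- function(channel, mask, n_levels = 32, offsets = c(1, 2),
                             prefix = "har") {
  v <- channel[mask]
  nms <- as.vector(outer(c("contrast", "correlation", "entropy", "asm"),
                         offsets,
                         function(f, o) paste(prefix, f, paste0("d", o),
                                              sep = "_")))
  if (length(v) < 2) return(stats::setNames(rep(NA_real_, length(nms)), nms))
  rng <- range(v)
  q <- matrix(0L, nrow(mask), ncol(mask))
  q[mask] <- if (rng[1] == rng[2]) 1L else
    pmin(n_levels, 1L + floor((v - rng[1]) / (rng[2] - rng[1]) * n_levels))
  out <- numeric(0)
  for (d in offsets) {
    gl <- glcm(q, d, n_levels)
    out <- c(out, haralick_stats(gl))
  }
  stats::setNames(out, nms)
}

# symmetric co-occurrence matrix summed over 4 directions at distance d
glcm <- function(q, d, n_levels) {
  W <- nrow(q); H <- ncol(q)
  acc <- matrix(0, n_levels, n_levels)
  shifts <- list(c(d, 0), c(0, d), c(d, d), c(d, -d))
  for (s in shifts) {
    dx <- s[1]; dy <- s[2]
    x1 <- max(1, 1 - dx):min(W, W - dx)
    y1 <- max(1, 1 - dy):min(H, H - dy)
    a <- q[x1, y1, drop = FALSE]
    b <- q[x1 + dx, y1 + dy, drop = FALSE]
    ok <- a > 0 & b > 0
    if (!any(ok)) next
    tab <- table(factor(a[ok], levels = 1:n_levels),
                 factor(b[ok], levels = 1:n_levels))
    acc <- acc + tab + t(tab)                       # symmetric
  }
  if (sum(acc) > 0) acc / sum(acc) else acc
}

haralick_stats <- function(p) {
  n <- nrow(p)
  i <- row(p); j <- col(p)
  contrast <- sum(p * (i - j)^2)
  px <- rowSums(p)
  mu <- sum(seq_len(n) * px)
  sig2 <- sum((seq_len(n) - mu)^2 * px)
  corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 0
  ent <- -sum(p[p > 0] * log2(p[p > 0]))
  asm <- sum(p^2)
  c(contrast = contrast, correlation = corr, entropy = ent, asm = asm)
}

#' Radial intensity distribution between nucleus and cell boundary
#'
#' Splits the extranuclear cytoplasm into `n_rings` zones of equal
#' normalised radial width (normalised distance = distance from the
#' nucleus divided by the sum of distances from nucleus and to the cell
#' boundary) and reports each zone's share of the channel's total cell
#' intensity, plus `perinuclear_fraction`: the share inside the annulus
#' from the nucleus boundary to 1.5x the nucleus equivalent radius
#' ([perinuclear_annulus()]). Ring fractions therefore sum to the
#' extranuclear intensity fraction.
#'
#' @param channel numeric matrix.
#' @param cell_mask,nucleus_mask logical matrices.
#' @param n_rings number of zones (default 4).
#' @param prefix feature-name prefix.
#' @return named vector: ring1..ringN fractions and
#'   `perinuclear_fraction`.
#' @export
radial_distribution <- function(channel, cell_mask, nucleus_mask,
                                n_rings = 4, prefix = "rad") {
  nm <- paste(prefix, c(paste0("ring", seq_len(n_rings)),
                        "perinuclear_fraction"), sep = "_")
  total <- sum(channel[cell_mask])
  if (total <= 0 || !any(nucleus_mask))
    return(stats::setNames(rep(NA_real_, n_rings + 1), nm))
  d_nuc <- EBImage::distmap(!nucleus_mask)
  d_bg <- EBImage::distmap(cell_mask)
  cyto <- cell_mask & !nucleus_mask
  r <- d_nuc[cyto] / pmax(d_nuc[cyto] + d_bg[cyto], .Machine$double.eps)
  ring <- pmin(n_rings, 1L + floor(r * n_rings))
  vals <- channel[cyto]
  fr <- vapply(seq_len(n_rings),
               function(k) sum(vals[ring == k]) / total, numeric(1))
  ann <- perinuclear_annulus(cell_mask, nucleus_mask)
  stats::setNames(c(fr, sum(channel[ann]) / total), nm)
}

#' Colocalisation of two channels within a mask
#'
#' Pearson correlation of the raw intensities and Manders overlap
#' coefficients M1/M2 with per-compartment Otsu thresholds on each
#' channel: M1 is the fraction of supra-threshold channel-a intensity
#' found where channel b is also supra-threshold, and conversely for
#' M2.
#'
#' @param channel_a,channel_b numeric matrices.
#' @param mask logical matrix.
#' @param prefix feature-name prefix.
#' @return named vector: pearson, m1, m2.
#' @export
colocalisation <- function(channel_a, channel_b, mask, prefix = "coloc") {
  a <- channel_a[mask]; b <- channel_b[mask]
  nm <- paste(prefix, c("pearson", "m1", "m2"), sep = "_")
  if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0)
    return(stats::setNames(rep(NA_real_, 3), nm))
  ta <- otsu_threshold(a); tb <- otsu_threshold(b)
  am <- a > ta; bm <- b > tb
  m1 <- if (any(am)) sum(a[am & bm]) / sum(a[am]) else 0
  m2 <- if (any(bm)) sum(b[am & bm]) / sum(b[bm]) else 0
  stats::setNames(c(stats::cor(a, b), m1, m2), nm)
}

# histogram Otsu on a numeric vector
otsu_threshold <- function(v, n_bins = 256) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  h <- tabulate(pmin(n_bins, 1L + floor((v - rng[1]) / diff(rng) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  k <- which.max(sb2)
  rng[1] + k / n_bins * diff(rng)
}

#' Mitochondrial morphology features for one cell
#'
#' Thresholds the mitochondria channel within the cell (per-cell Otsu),
#' labels connected components of at least `min_px` pixels and reports
#' object count, mean object area and total mitochondrial area (um^2),
#' the fragmentation index (objects per um^2 of mitochondrial signal),
#' mean object eccentricity, and the perinuclear fraction of the
#' channel intensity (shared annulus definition). When no
#' supra-threshold pixels survive, all features are 0 and `mito_empty`
#' is 1.
#'
#' @param mito_channel numeric matrix.
#' @param cell_mask,nucleus_mask logical matrices.
#' @param pixel_size_um physical pixel size.
#' @param min_px minimum object size in pixels (default 3).
#' @return named vector: mito_object_count, mito_mean_object_area,
#'   mito_total_area, mito_fragmentation_index, mito_mean_eccentricity,
#'   mito_perinuclear_fraction, mito_empty.
#' @export
mito_morphology <- function(mito_channel, cell_mask, nucleus_mask,
                            pixel_size_um = 1, min_px = 3) {
  nm <- c("mito_object_count", "mito_mean_object_area", "mito_total_area",
          "mito_fragmentation_index", "mito_mean_eccentricity",
          "mito_perinuclear_fraction", "mito_empty")
  v <- mito_channel[cell_mask]
  empty <- stats::setNames(c(0, 0, 0, 0, 0, 0, 1), nm)
  if (!length(v) || max(v) <= 0) return(empty)
  thr <- otsu_threshold(v)
  m <- mito_channel > thr & cell_mask
  lab <- EBImage::bwlabel(m)
  lab <- area_filter(lab, min_px, Inf)
  n_obj <- max(lab)
  if (n_obj == 0) return(empty)
  areas <- tabulate(lab, nbins = n_obj)
  eccs <- vapply(seq_len(n_obj), function(k) {
    unname(shape_features(lab == k, pixel_size_um)["shape_eccentricity"])
  }, numeric(1))
  total_um2 <- sum(areas) * pixel_size_um^2
  ann <- perinuclear_annulus(cell_mask, nucleus_mask)
  peri <- if (sum(v) > 0) sum(mito_channel[ann]) / sum(v) else 0
  stats::setNames(c(n_obj, mean(areas) * pixel_size_um^2, total_um2,
                    n_obj / total_um2, mean(eccs), peri, 0), nm)
}

#' Extract the full single-cell feature table from segmented fields
#'
#' Concatenates all feature families (shape, intensity, texture, radial
#' distribution, colocalisation, mitochondrial morphology) for every
#' cell of every field, joins field metadata, and applies the NaN
#' policy: cells with any undefined feature are dropped and counted in
#' the `qc` attribute. Feature-to-compartment tags are attached as
#' attribute `compartments`.
#'
#' @param fields list of `field_image` objects.
#' @param masks list (parallel to `fields`) of lists with elements
#'   `nuclei` and `cells` (`label_mask` objects).
#' @param plate_id plate identifier(s), length 1 or `length(fields)`.
#' @return data.frame: plate_id, well_id, site, cell_id + features.
#' @export
extract_all <- function(fields, masks, plate_id = "P1") {
  stopifnot(length(fields) == length(masks))
  plate_id <- rep_len(plate_id, length(fields))
  rows <- list()
  for (i in seq_along(fields)) {
    fi <- fields[[i]]; mi <- masks[[i]]
    if (!identical(dim(mi$cells$labels), dim(fi$channels[[1]])))
      stop("mask/image shape mismatch for field ", i)
    px <- fi$pixel_size_um
    ch <- lapply(fi$channels, identity)
    for (k in seq_len(max(mi$cells$labels))) {
      cm <- mi$cells$labels == k
      nmk <- mi$nuclei$labels == k
      if (!any(cm) || !any(nmk)) next
      f <- c(
        shape_features(nmk, px, "shape_nucleus"),
        shape_features(cm, px, "shape_cell"),
        unlist(lapply(CHANNELS, function(nm)
          intensity_features(ch[[nm]], cm, paste0("int_", nm, "_cell")))),
        intensity_features(ch$nuclei, nmk, "int_nuclei_nucleus"),
        intensity_features(ch$mitochondria, nmk, "int_mitochondria_nucleus"),
        unlist(lapply(c("ve_cadherin", "f_actin", "mitochondria", "vwf"),
                      function(nm)
          texture_features(ch[[nm]], cm, prefix = paste0("har_", nm)))),
        texture_features(ch$nuclei, nmk, prefix = "har_nuclei_nucleus"),
        unlist(lapply(c("mitochondria", "vwf", "f_actin"), function(nm)
          radial_distribution(ch[[nm]], cm, nmk,
                              prefix = paste0("rad_", nm)))),
        colocalisation(ch$mitochondria, ch$f_actin, cm, "coloc_mito_actin"),
        colocalisation(ch$vwf, ch$ve_cadherin, cm, "coloc_vwf_junction"),
        colocalisation(ch$mitochondria, ch$nuclei, cm, "coloc_mito_nuclei"),
        mito_morphology(ch$mitochondria, cm, nmk, px)
      )
      rows[[length(rows) + 1L]] <- c(
        list(plate_id = plate_id[i], well_id = fi$well_id, site = fi$site,
             cell_id = k), as.list(f))
    }
  }
  if (!length(rows)) stop("no cells to featurise")
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  feat_cols <- setdiff(names(out), c("plate_id", "well_id", "site",
                                     "cell_id"))
  bad <- !stats::complete.cases(out[feat_cols])
  qc <- list(n_cells = nrow(out), n_dropped_nan = sum(bad))
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc") <- qc
  attr(out, "compartments") <- feature_compartment_tags(feat_cols)
  out
}

# compartment tag per feature name, from its family/channel encoding
feature_compartment_tags <- function(feature_names) {
  tag <- function(nm) {
    if (startsWith(nm, "shape_nucleus")) return("nucleus")
    if (startsWith(nm, "shape_cell")) return("cell")
    if (startsWith(nm, "mito_")) return("mitochondria")
    if (startsWith(nm, "coloc_mito")) return("mitochondria")
    if (startsWith(nm, "coloc_vwf")) return("vwf")
    for (chn in names(CHANNEL_TAG))
      if (grepl(chn, nm, fixed = TRUE)) return(unname(CHANNEL_TAG[chn]))
    "cell"
  }
  stats::setNames(vapply(feature_names, tag, character(1)), feature_names)
}
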