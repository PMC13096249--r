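#' Default field geometry
#'
#' 320 x 320 px at 0.33 um/px, typical of 20x / 0.75 NA sampling.
#' @param width_px,height_px field size in pixels (at least 128).
#' @param pixel_size_um physical pixel size.
#' @export
field_geometry <- function(width_px = 320, height_px = 320,
                           pixel_size_um = 0.33) {
  if (width_px * height_px == 0) stop("degenerate geometry: zero area")
  if (width_px < 128 || height_px < 128)
    stop("field must be at least 128x128 px")
  list(width_px = as.integer(width_px), height_px = as.integer(height_px),
       pixel_size_um = pixel_size_um)
}

CHANNELS <- c("nuclei", "ve_cadherin", "f_actin", "mitochondria", "vwf")

#' Render a synthetic multichannel fluorescence field
#'
#' Simulates one imaged site of a confluent endothelial monolayer as a
#' 2D projection. The monolayer is built by Voronoi tessellation of
#' perturbed nucleus seed points; nuclei are drawn as ellipses at the
#' seeds, VE-cadherin along the polygon borders (with gaps and
#' intensity roughness scaled by `junction_irregularity`), F-actin as a
#' cortical rim plus stress fibres scaled by `actin_stress`,
#' mitochondria as random-walk tubules at low `mito_fragmentation`
#' grading into Poisson-placed puncta at high fragmentation (placed in
#' the perinuclear annulus with probability `mito_perinuclear`), and
#' vWF as rod-like Weibel-Palade puncta, Poisson-distributed per cell.
#' Poisson-Gaussian noise is applied at `intensity_snr` (peak-signal
#' SNR; `Inf` disables noise).
#'
#' Ground truth is derived from the rendered, noise-free channels:
#' mitochondrial object counts are connected components of the clean
#' mitochondria mask within each cell, and the perinuclear fraction is
#' integrated clean intensity over the shared annulus definition
#' ([perinuclear_annulus()]).
#'
#' @param phenotype a `phenotype_params` list ([default_phenotype()]).
#' @param geometry a [field_geometry()] list.
#' @param seed integer seed.
#' @param field_id,well_id,site identifiers carried in the result.
#' @return list with `image` (class `field_image`: named 16-bit-scale
#'   channel matrices + metadata) and `truth` (class `ground_truth`:
#'   n_cells, seed centroids, cell and nucleus label matrices, per-cell
#'   mito object count and perinuclear fraction, phenotype).
#' @export
render_field <- function(phenotype, geometry = field_geometry(), seed = 1,
                         field_id = "F1", well_id = "A01", site = 1L) {
  ph <- validate_phenotype(phenotype)
  W <- geometry$width_px; H <- geometry$height_px
  px <- geometry$pixel_size_um
  n_cells <- max(1L, round(ph$cell_density))
  with_seed(seed, {
    seeds <- seed_points(n_cells, W, H)
    labels <- voronoi_labels(seeds, W, H)
    nuc <- render_nuclei(seeds, labels, W, H, px)
    border <- border_mask(labels)
    clean <- list()
    clean$nuclei <- nuc$channel
    clean$ve_cadherin <- render_junctions(border, ph$junction_irregularity,
                                          W, H)
    clean$f_actin <- render_actin(labels, border, ph$actin_stress, W, H)
    mito <- render_mitochondria(labels, nuc$labels, ph, W, H)
    clean$mitochondria <- mito$channel
    clean$vwf <- render_vwf(labels, ph$wpb_count_mean, W, H)
    clean <- lapply(clean, function(ch) pmin(pmax(ch, 0), 1))
    # ground truth from the clean rendering
    truth <- ground_truth_from(clean, labels, nuc$labels, seeds, ph)
    chans <- lapply(clean, apply_noise, snr = ph$intensity_snr)
    chans <- lapply(chans, function(ch) clamp16(ch * 65535))
    image <- structure(list(channels = chans, pixel_size_um = px,
                            field_id = field_id, well_id = well_id,
                            site = site),
                       class = "field_image")
    list(image = image, truth = truth)
  })
}

# --- geometry -----------------------------------------------------------

# jittered-grid seed points: near-regular so nuclei do not touch
seed_points <- function(n, W, H) {
  nx <- max(1L, round(sqrt(n * W / H)))
  ny <- ceiling(n / nx)
  sx <- W / nx; sy <- H / ny
  gx <- rep(seq_len(nx), times = ny); gy <- rep(seq_len(ny), each = nx)
  keep <- sample(length(gx), n)
  x <- (gx[keep] - 0.5) * sx + stats::runif(n, -0.22, 0.22) * sx
  y <- (gy[keep] - 0.5) * sy + stats::runif(n, -0.22, 0.22) * sy
  cbind(x = pmin(pmax(x, 2), W - 1), y = pmin(pmax(y, 2), H - 1))
}

voronoi_labels <- function(seeds, W, H) {
  xs <- seq_len(W); ys <- seq_len(H)
  # squared distance from each pixel to each seed; label = arg min
  best <- matrix(Inf, W, H); lab <- matrix(0L, W, H)
  for (k in seq_len(nrow(seeds))) {
    d2 <- outer((xs - seeds[k, 1])^2, (ys - seeds[k, 2])^2, `+`)
    upd <- d2 < best
    best[upd] <- d2[upd]
    lab[upd] <- k
  }
  lab
}

border_mask <- function(labels) {
  W <- nrow(labels); H <- ncol(labels)
  b <- matrix(FALSE, W, H)
  b[-W, ] <- b[-W, ] | (labels[-W, ] != labels[-1, ])
  b[-1, ] <- b[-1, ] | (labels[-1, ] != labels[-W, ])
  b[, -H] <- b[, -H] | (labels[, -H] != labels[, -1])
  b[, -1] <- b[, -1] | (labels[, -1] != labels[, -H])
  b
}

draw_points <- function(canvas, x, y, value) {
  W <- nrow(canvas); H <- ncol(canvas)
  x <- round(x); y <- round(y)
  ok <- x >= 1 & x <= W & y >= 1 & y <= H
  idx <- cbind(x[ok], y[ok])
  canvas[idx] <- pmax(canvas[idx], value)
  canvas
}

draw_disc <- function(canvas, cx, cy, r, value) {
  W <- nrow(canvas); H <- ncol(canvas)
  xr <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
  yr <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
  d2 <- outer((xr - cx)^2, (yr - cy)^2, `+`)
  sub <- canvas[xr, yr, drop = FALSE]
  sub[d2 <= r^2] <- pmax(sub[d2 <= r^2], value)
  canvas[xr, yr] <- sub
  canvas
}

# --- channels -----------------------------------------------------------

render_nuclei <- function(seeds, labels, W, H, px) {
  channel <- matrix(0, W, H)
  nuc_lab <- matrix(0L, W, H)
  r_um <- stats::rnorm(nrow(seeds), 4.5, 0.35)           # equivalent radius
  theta <- stats::runif(nrow(seeds), 0, pi)
  ecc <- stats::runif(nrow(seeds), 0.1, 0.45)
  for (k in seq_len(nrow(seeds))) {
    r <- max(2.5, r_um[k]) / px
    a <- r * (1 + ecc[k] / 2); b <- r^2 / a                # area-preserving
    cx <- seeds[k, 1]; cy <- seeds[k, 2]
    xr <- max(1, floor(cx - a)):min(W, ceiling(cx + a))
    yr <- max(1, floor(cy - a)):min(H, ceiling(cy + a))
    dx <- outer(xr - cx, rep(1, length(yr)))
    dy <- outer(rep(1, length(xr)), yr - cy)
    u <- dx * cos(theta[k]) + dy * sin(theta[k])
    v <- -dx * sin(theta[k]) + dy * cos(theta[k])
    inside <- (u / a)^2 + (v / b)^2 <= 1
    sub <- channel[xr, yr, drop = FALSE]
    sub[inside] <- pmax(sub[inside],
                        0.85 * (1 - 0.3 * ((u[inside] / a)^2 +
                                           (v[inside] / b)^2)))
    channel[xr, yr] <- sub
    sl <- nuc_lab[xr, yr, drop = FALSE]
    sl[inside] <- k
    nuc_lab[xr, yr] <- sl
  }
  list(channel = EBImage::gblur(channel, sigma = 1), labels = nuc_lab)
}

render_junctions <- function(border, irregularity, W, H) {
  ch <- matrix(0, W, H)
  ch[border] <- 0.9
  ch <- EBImage::dilate(ch, EBImage::makeBrush(3, "disc"))
  if (irregularity > 0) {
    # spatially correlated dropout: gaps grow with irregularity
    field <- EBImage::gblur(matrix(stats::runif(W * H), W, H), sigma = 4)
    cut <- stats::quantile(field, 0.55 * irregularity)
    ch[field < cut] <- 0
    rough <- EBImage::gblur(matrix(stats::runif(W * H), W, H), sigma = 2)
    ch <- ch * (1 - irregularity * 0.5 + irregularity * rough)
  }
  EBImage::gblur(ch, sigma = 0.8)
}

render_actin <- function(labels, border, stress, W, H) {
  ch <- matrix(0.12, W, H)                         # diffuse cytoplasmic pool
  ch[border] <- 0.35                               # cortical rim
  n_fib <- stats::rpois(1, stress * 5 * max(labels))
  if (n_fib > 0) {
    for (i in seq_len(n_fib)) {
      x0 <- stats::runif(1, 1, W); y0 <- stats::runif(1, 1, H)
      ang <- stats::runif(1, 0, pi); len <- stats::runif(1, 15, 45)
      t <- seq(-len / 2, len / 2, by = 0.7)
      ch <- draw_points(ch, x0 + t * cos(ang), y0 + t * sin(ang), 0.7)
    }
  }
  EBImage::gblur(ch, sigma = 0.8)
}

# random-walk tubule constrained to a pixel set (approximately: reflected
# at the bounding box, clipped to the cell by masking afterwards)
walk_tubule <- function(x0, y0, n_steps) {
  ang <- stats::runif(1, 0, 2 * pi)
  dang <- stats::rnorm(n_steps, 0, 0.45)
  angs <- ang + cumsum(dang)
  cbind(x0 + cumsum(cos(angs)), y0 + cumsum(sin(angs)))
}

render_mitochondria <- function(labels, nuc_lab, ph, W, H) {
  ch <- matrix(0, W, H)
  f <- ph$mito_fragmentation
  n_obj_per_cell <- max(1L, round(1 + f * 14))
  total_len <- 110                                  # px of tubule per cell
  for (k in seq_len(max(labels))) {
    cell_mask <- labels == k
    nuc_mask <- nuc_lab == k
    ann <- perinuclear_annulus(cell_mask, nuc_mask)
    cyto <- which(cell_mask & !nuc_mask)
    if (!length(cyto)) next
    ann_idx <- which(ann)
    for (j in seq_len(n_obj_per_cell)) {
      use_ann <- length(ann_idx) > 0 &&
        stats::runif(1) < ph$mito_perinuclear
      start <- if (use_ann) sample(ann_idx, 1) else sample(cyto, 1)
      x0 <- (start - 1) %% W + 1
      y0 <- (start - 1) %/% W + 1
      seg_len <- max(2L, round(total_len / n_obj_per_cell))
      # short fragments are compact puncta; long ones are tubule walks
      pts <- if (seg_len <= 8)
        cbind(x0 + stats::rnorm(seg_len, 0, 1.0),
              y0 + stats::rnorm(seg_len, 0, 1.0))
      else walk_tubule(x0, y0, seg_len)
      keep <- pts[, 1] >= 1 & pts[, 1] <= W & pts[, 2] >= 1 & pts[, 2] <= H
      pts <- pts[keep, , drop = FALSE]
      if (nrow(pts)) {
        inside <- cell_mask[cbind(round(pts[, 1]), round(pts[, 2]))]
        pts <- pts[inside, , drop = FALSE]
      }
      if (nrow(pts)) ch <- draw_points(ch, pts[, 1], pts[, 2], 0.9)
    }
  }
  list(channel = EBImage::gblur(ch, sigma = 0.7))
}

render_vwf <- function(labels, wpb_mean, W, H) {
  ch <- matrix(0, W, H)
  for (k in seq_len(max(labels))) {
    idx <- which(labels == k)
    n_w <- stats::rpois(1, wpb_mean)
    if (n_w == 0) next
    at <- sample(idx, n_w, replace = TRUE)
    for (s in at) {
      x0 <- (s - 1) %% W + 1; y0 <- (s - 1) %/% W + 1
      ang <- stats::runif(1, 0, pi); len <- stats::runif(1, 2.5, 4.5)
      t <- seq(-len / 2, len / 2, by = 0.5)
      ch <- draw_points(ch, x0 + t * cos(ang), y0 + t * sin(ang), 0.85)
    }
  }
  EBImage::gblur(ch, sigma = 0.6)
}

apply_noise <- function(channel, snr) {
  if (!is.finite(snr)) return(channel)
  q <- snr^2                                       # photons at unit signal
  shot <- matrix(stats::rpois(length(channel), channel * q) / q,
                 nrow(channel), ncol(channel))
  pmin(pmax(shot + stats::rnorm(length(channel), 0, 0.15 / snr), 0), 1)
}

ground_truth_from <- function(clean, labels, nuc_lab, seeds, ph) {
  n <- max(labels)
  mito <- clean$mitochondria
  mito_mask <- mito > 0.15
  obj_count <- integer(n)
  perinuc <- numeric(n)
  for (k in seq_len(n)) {
    cm <- labels == k
    m <- mito_mask & cm
    obj_count[k] <- max(EBImage::bwlabel(m))
    tot <- sum(mito[cm])
    if (tot > 0) {
      ann <- perinuclear_annulus(cm, nuc_lab == k)
      perinuc[k] <- sum(mito[ann]) / tot
    }
  }
  structure(list(n_cells = n, centroids = seeds, cell_labels = labels,
                 nucleus_labels = nuc_lab, mito_object_count = obj_count,
                 mito_perinuclear_fraction = perinuc, phenotype = ph),
            class = "ground_truth")
}

#' Write / read a field as multi-page TIFF with a JSON sidecar
#'
#' The five channels are written in the fixed order nuclei,
#' ve_cadherin, f_actin, mitochondria, vwf as 16-bit pages; channel
#' names, pixel size, identifiers are written to `<path>.json`.
#'
#' @param image a `field_image`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field <- function(image, path) {
  arr <- simplify2array(image$channels[CHANNELS]) / 65535
  EBImage::writeImage(EBImage::Image(arr), path, type = "tiff",
                      bits.per.sample = 16L)
  meta <- list(channels = CHANNELS, pixel_size_um = image$pixel_size_um,
               field_id = image$field_id, well_id = image$well_id,
               site = image$site)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_field
#' @param path TIFF path written by [write_field()].
#' @export
read_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- EBImage::imageData(EBImage::readImage(path))
  chans <- lapply(seq_along(meta$channels),
                  function(i) round(arr[, , i] * 65535))
  names(chans) <- meta$channels
  structure(list(channels = chans, pixel_size_um = meta$pixel_size_um,
                 field_id = meta$field_id, well_id = meta$well_id,
                 site = meta$site),
            class = "field_image")
}
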