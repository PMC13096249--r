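#' Segmentation parameters
#'
#' @param nucleus_min_area_um2,nucleus_max_area_um2 nucleus area band
#'   used to filter debris and clumps (defaults 40-400 um^2).
#' @param smoothing_sigma_um Gaussian smoothing applied before
#'   thresholding, in micrometres.
#' @param threshold_method "otsu" or "fixed".
#' @param fixed_threshold threshold on the [0, 1] intensity scale when
#'   `threshold_method = "fixed"`.
#' @param split_touching split touching nuclei by distance-transform
#'   watershed.
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(nucleus_min_area_um2 = 40,
                                nucleus_max_area_um2 = 400,
                                smoothing_sigma_um = 1,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                split_touching = TRUE) {
  stopifnot(nucleus_min_area_um2 > 0,
            nucleus_min_area_um2 < nucleus_max_area_um2)
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && is.null(fixed_threshold))
    stop("fixed_threshold required when threshold_method = 'fixed'")
  structure(list(nucleus_min_area_um2 = nucleus_min_area_um2,
                 nucleus_max_area_um2 = nucleus_max_area_um2,
                 smoothing_sigma_um = smoothing_sigma_um,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 split_touching = split_touching),
            class = "segmentation_params")
}

get_channel <- function(image, name) {
  if (!name %in% names(image$channels))
    stop("channel '", name, "' not present")
  image$channels[[name]] / 65535
}

#' Detect nuclei from the nuclei channel
#'
#' Gaussian smoothing, global threshold (Otsu by default), hole
#' filling, optional distance-transform watershed to split touching
#' nuclei, connected-component labelling, and an area band filter in
#' um^2 to remove debris and clumps. Labels are relabelled consecutively
#' from 1. A blank field yields an empty mask, not an error.
#'
#' @param image a `field_image`.
#' @param params a [segmentation_params()] list.
#' @return list of class `label_mask`: integer `labels` matrix,
#'   `kind = "nuclei"`, `pixel_size_um`.
#' @export
detect_nuclei <- function(image, params = segmentation_params()) {
  x <- get_channel(image, "nuclei")
  px <- image$pixel_size_um
  sigma_px <- max(params$smoothing_sigma_um / px, 0.5)
  xs <- EBImage::gblur(x, sigma = sigma_px)
  thr <- switch(params$threshold_method,
                otsu = EBImage::otsu(EBImage::Image(xs), range = c(0, 1)),
                fixed = params$fixed_threshold)
  fg <- xs > thr
  if (!any(fg))
    return(new_label_mask(matrix(0L, nrow(x), ncol(x)), "nuclei", px))
  fg <- EBImage::fillHull(fg)
  lab <- if (params$split_touching) {
    EBImage::watershed(EBImage::distmap(fg), tolerance = 1.5)
  } else {
    EBImage::bwlabel(fg)
  }
  lab <- area_filter(lab, params$nucleus_min_area_um2 / px^2,
                     params$nucleus_max_area_um2 / px^2)
  new_label_mask(lab, "nuclei", px)
}

area_filter <- function(labels, min_px, max_px) {
  labels <- as_int_matrix(labels)
  if (max(labels) == 0) return(labels)
  areas <- tabulate(labels, nbins = max(labels))
  keep <- which(areas >= min_px & areas <= max_px)
  relabel <- integer(max(labels))
  relabel[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0] <- relabel[labels[labels > 0]]
  out
}

as_int_matrix <- function(x) {
  m <- matrix(as.integer(round(EBImage::imageData(x))),
              nrow = dim(x)[1], ncol = dim(x)[2])
  m
}

new_label_mask <- function(labels, kind, pixel_size_um) {
  structure(list(labels = labels, kind = kind,
                 pixel_size_um = pixel_size_um),
            class = "label_mask")
}

#' Propagate nucleus seeds to cell borders
#'
#' Marker-controlled propagation on the smoothed VE-cadherin intensity
#' landscape (Voronoi-based region growing with an image-driven metric,
#' the CellProfiler-style `propagate` of EBImage), seeded at the
#' detected nuclei and restricted to a foreground mask formed as the
#' closed union of all channels' Otsu foregrounds. For a confluent
#' monolayer the foreground is the whole field and the cells partition
#' it. Cell labels inherit their seed's nucleus label.
#'
#' @param nuclei a `label_mask` of kind "nuclei".
#' @param image the `field_image` the nuclei came from.
#' @param lambda regularisation of the propagate metric: larger values
#'   weight geometric distance over image gradients.
#' @return `label_mask` of kind "cells".
#' @export
propagate_cells <- function(nuclei, image, lambda = 1e-4) {
  stopifnot(inherits(nuclei, "label_mask"), nuclei$kind == "nuclei")
  dims <- dim(image$channels[[1]])
  if (!identical(dim(nuclei$labels), dims))
    stop("nuclei mask shape does not match image")
  if (max(nuclei$labels) == 0)
    return(new_label_mask(matrix(0L, dims[1], dims[2]), "cells",
                          image$pixel_size_um))
  vec <- EBImage::gblur(get_channel(image, "ve_cadherin"), sigma = 1)
  fg <- Reduce(`|`, lapply(names(image$channels), function(nm) {
    ch <- get_channel(image, nm)
    ch > EBImage::otsu(EBImage::Image(ch), range = c(0, 1))
  }))
  fg <- EBImage::closing(fg, EBImage::makeBrush(15, "disc"))
  fg <- EBImage::fillHull(fg) | (nuclei$labels > 0)
  cells <- EBImage::propagate(EBImage::Image(vec),
                              seeds = nuclei$labels,
                              mask = fg, lambda = lambda)
  new_label_mask(as_int_matrix(cells), "cells", image$pixel_size_um)
}

#' Segmentation quality report
#'
#' @param nuclei,cells `label_mask` objects from [detect_nuclei()] and
#'   [propagate_cells()].
#' @return list: counts, area summaries (um^2), border-touching cell
#'   labels and their fraction.
#' @export
segmentation_qc <- function(nuclei, cells) {
  px2 <- nuclei$pixel_size_um^2
  n_areas <- tabulate(nuclei$labels, nbins = max(1, max(nuclei$labels)))
  c_areas <- tabulate(cells$labels, nbins = max(1, max(cells$labels)))
  lb <- cells$labels
  edge <- unique(c(lb[1, ], lb[nrow(lb), ], lb[, 1], lb[, ncol(lb)]))
  edge <- edge[edge > 0]
  n_cells <- max(cells$labels)
  list(n_nuclei = max(nuclei$labels), n_cells = n_cells,
       nucleus_area_um2 = summary(n_areas[n_areas > 0] * px2),
       cell_area_um2 = summary(c_areas[c_areas > 0] * px2),
       border_touching = sort(edge),
       border_touching_fraction = if (n_cells > 0)
         length(edge) / n_cells else 0)
}

#' Mean intersection-over-union against ground-truth cell labels
#'
#' Each ground-truth cell is matched to the predicted cell with the
#' largest overlap; IoU is averaged over ground-truth cells.
#'
#' @param predicted integer label matrix.
#' @param truth integer label matrix of the same shape.
#' @return mean IoU in [0, 1].
#' @export
mean_iou <- function(predicted, truth) {
  stopifnot(identical(dim(predicted), dim(truth)))
  ious <- vapply(seq_len(max(truth)), function(k) {
    tm <- truth == k
    cand <- predicted[tm]
    cand <- cand[cand > 0]
    if (!length(cand)) return(0)
    best <- as.integer(names(which.max(table(cand))))
    pm <- predicted == best
    sum(pm & tm) / sum(pm | tm)
  }, numeric(1))
  mean(ious)
}
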