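#' ecmorph: image-based morphological profiling of endothelial cells
#'
#' Tools for simulating and analysing high-content imaging experiments in
#' which endothelial monolayers are exposed to patient plasma: seeded
#' synthetic data, nucleus-seeded cell segmentation, single-cell feature
#' extraction, factor-analysis / LDA profiling, mito stress test metrics
#' and clinical cohort statistics.
#'
#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state so generators are pure in (config, seed)
# and never disturb the caller's random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Perinuclear annulus mask
#'
#' The annulus runs from the nucleus boundary out to 1.5 times the nucleus
#' equivalent radius (the radius of a disc with the nucleus area), measured
#' from the nucleus centroid, and is clipped to the cell mask. The same
#' definition is used by the synthetic renderer and by the feature
#' extractor so that rendered perinuclear enrichment and the measured
#' `perinuclear_fraction` refer to the same region.
#'
#' @param cell_mask logical matrix, TRUE inside the cell.
#' @param nucleus_mask logical matrix, TRUE inside the nucleus.
#' @param factor outer radius as a multiple of the nucleus equivalent
#'   radius (default 1.5).
#' @return logical matrix, TRUE inside the annulus.
#' @export
perinuclear_annulus <- function(cell_mask, nucleus_mask, factor = 1.5) {
  stopifnot(identical(dim(cell_mask), dim(nucleus_mask)))
  n_area <- sum(nucleus_mask)
  if (n_area == 0) return(array(FALSE, dim(cell_mask)))
  idx <- which(nucleus_mask, arr.ind = TRUE)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  r_eq <- sqrt(n_area / pi)
  nr <- nrow(cell_mask); nc <- ncol(cell_mask)
  d2 <- outer((seq_len(nr) - cx)^2, (seq_len(nc) - cy)^2, `+`)
  (d2 <= (factor * r_eq)^2) & cell_mask & !nucleus_mask
}

# integer-safe %% based channel clamp to the 16-bit scale
clamp16 <- function(x) {
  x[x < 0] <- 0
  x[x > 65535] <- 65535
  round(x)
}
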