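OCR_PHASES <- c("baseline", "glucose", "oligomycin", "fccp", "rot_aa")

#' Mito stress test respiration metrics from an OCR trace
#'
#' Computes the standard extracellular-flux mito stress test metrics
#' from an oxygen-consumption-rate (OCR) trace with sequential injection
#' phases glucose -> oligomycin -> FCCP -> rotenone/antimycin A:
#'
#' * `non_mito`   = mean OCR after rotenone/antimycin A
#' * `basal`      = last OCR of the glucose phase minus `non_mito`
#' * `atp_linked` = last OCR of the glucose phase minus the minimum
#'                  OCR after oligomycin
#' * `maximal`    = maximum OCR after FCCP minus `non_mito`
#' * `spare`      = `maximal` minus `basal`
#'
#' Each metric is also emitted normalised per 1000 cells using the
#' trace's cell count. Pre-glucose baseline measurements, when present,
#' do not enter the metrics: the first injection is glucose, so the
#' glucose phase is the working basal state.
#'
#' @param trace data.frame with columns `time_min`, `phase`
#'   (one of baseline, glucose, oligomycin, fccp, rot_aa, in that
#'   order), `ocr` (pmol O2/min) and a `cell_count` attribute or column.
#' @return list of class `mito_metrics`: raw metrics, `per_1000`
#'   normalised metrics, `cell_count` and a `warning_flags` character
#'   vector (non-empty when a derived metric is negative).
#' @export
mito_stress_metrics <- function(trace) {
  trace <- validate_ocr_trace(trace, require = c("glucose", "oligomycin",
                                                 "fccp", "rot_aa"))
  ocr_in <- function(ph) trace$ocr[trace$phase == ph]
  non_mito <- mean(ocr_in("rot_aa"))
  glu_last <- ocr_in("glucose")[length(ocr_in("glucose"))]
  basal <- glu_last - non_mito
  atp_linked <- glu_last - min(ocr_in("oligomycin"))
  maximal <- max(ocr_in("fccp")) - non_mito
  spare <- maximal - basal
  raw <- c(non_mito = non_mito, basal = basal, atp_linked = atp_linked,
           maximal = maximal, spare = spare)
  flags <- names(raw)[raw < 0]
  if (length(flags))
    warning("negative derived metric(s): ", paste(flags, collapse = ", "))
  cc <- attr(trace, "cell_count")
  structure(list(raw = raw, per_1000 = raw / cc * 1000,
                 cell_count = cc, warning_flags = flags),
            class = "mito_metrics")
}

validate_ocr_trace <- function(trace, require = character()) {
  stopifnot(is.data.frame(trace),
            all(c("time_min", "phase", "ocr") %in% names(trace)))
  if (!all(is.finite(trace$ocr))) stop("non-finite OCR values")
  phases <- unique(as.character(trace$phase))
  if (!all(phases %in% OCR_PHASES)) stop("unknown phase label(s)")
  missing <- setdiff(require, phases)
  if (length(missing))
    stop("missing phase(s): ", paste(missing, collapse = ", "))
  # phases must appear as contiguous blocks in assay order
  ord <- match(as.character(trace$phase), OCR_PHASES)
  if (is.unsorted(ord)) stop("phases out of assay order")
  cc <- attr(trace, "cell_count")
  if (is.null(cc) && "cell_count" %in% names(trace)) cc <- trace$cell_count[1]
  if (is.null(cc) || cc <= 0) stop("positive cell_count required")
  attr(trace, "cell_count") <- cc
  trace
}

#' Normalise mitochondrial superoxide signal to membrane potential
#'
#' The superoxide indicator (MitoSOX) signal scales with both superoxide
#' and mitochondrial mass/potential; dividing by the potential-dependent
#' MitoTracker Red signal gives a per-unit-potential superoxide readout.
#' Records with non-positive MitoTracker Red signal are excluded and
#' counted.
#'
#' @param mitosox,mtred numeric vectors of matched intensities (per cell
#'   or per field).
#' @return list with `ratio` (NA where excluded), `n_excluded`, and
#'   `median` of the retained ratios.
#' @export
mitosox_normalise <- function(mitosox, mtred) {
  stopifnot(length(mitosox) == length(mtred))
  bad <- !(mtred > 0)
  ratio <- ifelse(bad, NA_real_, mitosox / mtred)
  list(ratio = ratio, n_excluded = sum(bad),
       median = stats::median(ratio, na.rm = TRUE))
}

#' Pairwise group comparisons of mito metrics
#'
#' Mann-Whitney U tests between every pair of groups for every metric,
#' with Benjamini-Hochberg correction across all comparisons.
#'
#' @param metrics data.frame with a `group` column and one numeric
#'   column per metric.
#' @return data.frame: metric, group_a, group_b, statistic, p_value,
#'   q_value; one row per metric x group pair.
#' @export
compare_groups <- function(metrics) {
  stopifnot("group" %in% names(metrics))
  g <- factor(metrics$group)
  vars <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  rows <- do.call(rbind, lapply(vars, function(v) {
    do.call(rbind, lapply(pairs, function(pr) {
      tr <- mann_whitney_u(metrics[[v]][g == pr[1]], metrics[[v]][g == pr[2]])
      data.frame(metric = v, group_a = pr[1], group_b = pr[2],
                 statistic = tr$statistic, p_value = tr$p_value,
                 stringsAsFactors = FALSE)
    }))
  }))
  rows$q_value <- stats::p.adjust(rows$p_value, method = "BH")
  rows
}
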