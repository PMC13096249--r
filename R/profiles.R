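META_COLS <- c("plate_id", "well_id", "site", "cell_id", "group",
               "albumin_arm", "sample_id", "replicate", "n_cells")

feature_cols <- function(table) setdiff(names(table), META_COLS)

#' Per-plate z-score normalisation of single-cell features
#'
#' Each feature is centred and scaled to unit variance within each
#' plate separately, removing plate-level batch offsets, after which
#' the plates are concatenated. Features with zero variance on any
#' plate carry no information there and are dropped from the combined
#' table (logged via message).
#'
#' @param table single-cell feature data.frame with a `plate_id`
#'   column.
#' @return the normalised table; dropped features in attribute
#'   `dropped_features`.
#' @export
zscore_per_plate <- function(table) {
  stopifnot("plate_id" %in% names(table))
  feats <- feature_cols(table)
  plates <- split(seq_len(nrow(table)), table$plate_id)
  if (any(vapply(plates, length, integer(1)) < 2))
    stop("each plate needs at least 2 cells")
  drop <- character(0)
  for (idx in plates) {
    sds <- vapply(feats, function(f) stats::sd(table[[f]][idx]), numeric(1))
    drop <- union(drop, feats[sds == 0 | !is.finite(sds)])
  }
  if (length(drop))
    message("dropping ", length(drop), " zero-variance feature(s): ",
            paste(utils::head(drop, 5), collapse = ", "),
            if (length(drop) > 5) ", ...")
  keep <- setdiff(feats, drop)
  for (idx in plates) {
    for (f in keep) {
      v <- table[[f]][idx]
      table[[f]][idx] <- (v - mean(v)) / stats::sd(v)
    }
  }
  out <- table[c(intersect(META_COLS, names(table)), keep)]
  attr(out, "dropped_features") <- drop
  attr(out, "compartments") <- attr(table, "compartments")[keep]
  out
}

#' Maximum-likelihood factor analysis with variance-targeted selection
#'
#' Fits maximum-likelihood factor analysis to the (standardised)
#' feature table, scanning the number of factors upward and selecting
#' the smallest number whose cumulative explained variance (sum of
#' squared loadings over the number of features) reaches
#' `variance_target`. Loadings are varimax-rotated by default:
#' maximum-likelihood loadings are only identified up to an orthogonal
#' rotation, and the rotated solution concentrates each factor on few
#' features, which is what downstream compartment attribution
#' interprets. Rotation does not change the explained-variance scan.
#'
#' @param table normalised feature data.frame ([zscore_per_plate()]).
#' @param variance_target cumulative variance fraction to reach
#'   (default 0.80).
#' @param n_max largest factor count scanned.
#' @param rotation "varimax" (default) or "none".
#' @return list of class `factor_model`: n_factors, loadings,
#'   uniquenesses, explained_variance_ratio, cumulative_variance,
#'   feature_names, feature means/sds for scoring, and
#'   `target_reached` (FALSE with a warning when the scan plateaus
#'   below target, in which case n_factors = n_max).
#' @export
fit_factor_analysis <- function(table, variance_target = 0.80, n_max = 13,
                                rotation = c("varimax", "none")) {
  rotation <- match.arg(rotation)
  stopifnot(variance_target > 0, variance_target <= 1)
  feats <- feature_cols(table)
  X <- as.matrix(table[feats])
  n <- nrow(X); p <- length(feats)
  if (n < 10 * n_max)
    warning("fewer than 10 cells per candidate factor; estimates may be ",
            "unstable")
  mu <- colMeans(X); sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance features present; z-score first")
  R <- stats::cor(X)
  fits <- vector("list", n_max)
  cumvar <- rep(NA_real_, n_max)
  chosen <- NA_integer_
  for (k in seq_len(n_max)) {
    if (factanal_df(p, k) < 0) break
    fit <- tryCatch(
      stats::factanal(covmat = R, factors = k, n.obs = n,
                      rotation = rotation, lower = 0.01),
      error = function(e) e)
    if (inherits(fit, "error")) next
    fits[[k]] <- fit
    cumvar[k] <- sum(fit$loadings^2) / p
    if (cumvar[k] >= variance_target) { chosen <- k; break }
  }
  if (all(vapply(fits, is.null, logical(1))))
    stop("factor analysis failed to converge for any factor count ",
         "(1..", n_max, "); check for collinear features")
  target_reached <- !is.na(chosen)
  if (!target_reached) {
    chosen <- max(which(!vapply(fits, is.null, logical(1))))
    warning("cumulative variance plateaued at ",
            round(max(cumvar, na.rm = TRUE), 3), " below target ",
            variance_target, "; returning n_factors = ", chosen)
  }
  fit <- fits[[chosen]]
  L <- matrix(fit$loadings, p, chosen,
              dimnames = list(feats, paste0("F", seq_len(chosen))))
  per_factor <- colSums(L^2) / p
  structure(list(n_factors = chosen, loadings = L,
                 uniquenesses = fit$uniquenesses,
                 explained_variance_ratio = per_factor,
                 cumulative_variance = sum(per_factor),
                 cumvar_scan = cumvar,
                 feature_names = feats, feature_means = mu,
                 feature_sds = sds, target = variance_target,
                 target_reached = target_reached, rotation = rotation),
            class = "factor_model")
}

factanal_df <- function(p, k) ((p - k)^2 - p - k) / 2

#' Score cells (or wells) on a fitted factor model
#'
#' Thomson regression-method scores: features are standardised with
#' the training means/sds and projected with
#' `solve(L L' + Psi) %*% L`. Deterministic; metadata columns are
#' carried through.
#'
#' @param model a `factor_model`.
#' @param table feature data.frame containing the model's features.
#' @return data.frame of metadata + factor score columns F1..Fk.
#' @export
score_factors <- function(model, table) {
  X <- as.matrix(table[model$feature_names])
  Xs <- sweep(sweep(X, 2, model$feature_means), 2, model$feature_sds, `/`)
  L <- model$loadings
  Sigma <- L %*% t(L) + diag(model$uniquenesses)
  W <- solve(Sigma, L)
  scores <- Xs %*% W
  colnames(scores) <- colnames(L)
  cbind(table[intersect(META_COLS, names(table))], as.data.frame(scores))
}

#' Aggregate single-cell factor scores into well profiles
#'
#' Averages factor scores over the cells of each well, excludes wells
#' with fewer than `min_cells` cells (logged), and scales every factor
#' to zero mean and unit variance across the retained wells.
#'
#' @param scores data.frame from [score_factors()] with well metadata.
#' @param min_cells minimum cells per well (default 50).
#' @return data.frame of well profiles: metadata, `n_cells`, scaled
#'   factor columns.
#' @export
aggregate_wells <- function(scores, min_cells = 50) {
  fcols <- grep("^F\\d+$", names(scores), value = TRUE)
  keycols <- intersect(c("plate_id", "well_id", "group", "albumin_arm",
                         "sample_id", "replicate"), names(scores))
  key <- interaction(scores[keycols], drop = TRUE)
  agg <- lapply(split(seq_len(nrow(scores)), key), function(idx) {
    cbind(scores[idx[1], keycols, drop = FALSE],
          n_cells = length(idx),
          as.data.frame(as.list(colMeans(scores[idx, fcols, drop = FALSE]))))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  low <- out$n_cells < min_cells
  if (any(low))
    message("excluding ", sum(low), " well(s) below min_cells = ", min_cells)
  out <- out[!low, , drop = FALSE]
  if (!nrow(out)) stop("no wells left after min_cells filter")
  for (f in fcols)
    out[[f]] <- as.numeric(scale(out[[f]]))
  out
}

#' Linear discriminant model on well profiles
#'
#' Fits LDA on the training wells (by default the wells without added
#' albumin), maximising between- over within-class scatter of the
#' factor-score profiles. The pooled within-class covariance is
#' shrunk towards a scaled identity with a Ledoit-Wolf intensity by
#' default, which keeps the fit stable when wells are few relative to
#' factors. LD1 is signed so that the HC training mean lies below the
#' DC training mean.
#'
#' @param profiles well-profile data.frame ([aggregate_wells()]).
#' @param label_col class column (default "group").
#' @param train_filter logical vector selecting training wells
#'   (default: `albumin_arm == "none"`).
#' @param n_components 1 or 2 discriminant axes.
#' @param shrinkage shrink the within-class covariance (default TRUE).
#' @return list of class `lda_model`: class_labels, scalings,
#'   grand_mean, class score means, training filter, shrinkage
#'   intensity.
#' @export
fit_lda <- function(profiles, label_col = "group",
                    train_filter = profiles$albumin_arm == "none",
                    n_components = 2, shrinkage = TRUE) {
  stopifnot(n_components %in% 1:2)
  fcols <- grep("^F\\d+$", names(profiles), value = TRUE)
  tr <- profiles[train_filter, , drop = FALSE]
  y <- droplevels(factor(tr[[label_col]]))
  if (nlevels(y) < 2) stop("need at least 2 classes in the training subset")
  X <- as.matrix(tr[fcols])
  p <- ncol(X)
  if (min(table(y)) < p / 2)
    warning("fewer wells per class than half the factor count; ",
            "shrinkage strongly advised")
  grand <- colMeans(X)
  class_means <- t(vapply(levels(y), function(cl)
    colMeans(X[y == cl, , drop = FALSE]), numeric(p)))
  Z <- X - class_means[as.integer(y), , drop = FALSE]
  Sw <- crossprod(Z) / nrow(X)
  gamma <- 0
  if (shrinkage) {
    gamma <- ledoit_wolf_intensity(Z)
    Sw <- (1 - gamma) * Sw + gamma * mean(diag(Sw)) * diag(p)
  }
  if (rcond(Sw) < 1e-12)
    stop("singular within-class scatter; enable shrinkage")
  nB <- table(y)
  Sb <- Reduce(`+`, lapply(levels(y), function(cl) {
    d <- class_means[cl, ] - grand
    nB[[cl]] * tcrossprod(d)
  })) / nrow(X)
  eW <- eigen(Sw, symmetric = TRUE)
  Wi <- eW$vectors %*% diag(1 / sqrt(pmax(eW$values, 1e-12)), p) %*%
    t(eW$vectors)
  M <- Wi %*% Sb %*% Wi
  eM <- eigen(M, symmetric = TRUE)
  ncomp <- min(n_components, nlevels(y) - 1)
  scal <- Wi %*% eM$vectors[, seq_len(ncomp), drop = FALSE]
  colnames(scal) <- paste0("LD", seq_len(ncomp))
  rownames(scal) <- fcols
  # sign convention: mean LD1(HC) < mean LD1(DC) (first vs last class
  # when those labels are absent)
  lo <- if ("HC" %in% levels(y)) "HC" else levels(y)[1]
  hi <- if ("DC" %in% levels(y)) "DC" else levels(y)[nlevels(y)]
  s1 <- drop((class_means[lo, ] - grand) %*% scal[, 1])
  s2 <- drop((class_means[hi, ] - grand) %*% scal[, 1])
  if (s1 > s2) scal[, 1] <- -scal[, 1]
  score_means <- (class_means - matrix(grand, nlevels(y), p,
                                       byrow = TRUE)) %*% scal
  rownames(score_means) <- levels(y)
  structure(list(class_labels = levels(y), scalings = scal,
                 grand_mean = grand, class_score_means = score_means,
                 feature_cols = fcols, n_components = ncomp,
                 shrinkage_gamma = gamma,
                 training_filter = deparse(substitute(train_filter))),
            class = "lda_model")
}

# Ledoit-Wolf shrinkage intensity towards mean(diag(S)) * I,
# computed on (within-class) centred rows
ledoit_wolf_intensity <- function(Z) {
  n <- nrow(Z); p <- ncol(Z)
  S <- crossprod(Z) / n
  m <- mean(diag(S))
  d2 <- sum((S - m * diag(p))^2)
  if (d2 == 0) return(0)
  b2 <- sum(vapply(seq_len(n), function(i)
    sum((tcrossprod(Z[i, ]) - S)^2), numeric(1))) / n^2
  max(0, min(1, b2 / d2))
}

#' Score well profiles with a fitted LDA model
#'
#' Pure projection, no refit: `(X - grand_mean) %*% scalings`. Used to
#' place albumin-supplemented wells in the discriminant space learned
#' from non-supplemented wells.
#'
#' @param model an `lda_model`.
#' @param profiles well-profile data.frame.
#' @return data.frame of metadata + LD columns.
#' @export
score_lda <- function(model, profiles) {
  X <- as.matrix(profiles[model$feature_cols])
  sc <- sweep(X, 2, model$grand_mean) %*% model$scalings
  cbind(profiles[setdiff(names(profiles), model$feature_cols)],
        as.data.frame(sc))
}

#' Compare LD1 between two conditions by Welch t-test
#'
#' @param scores data.frame from [score_lda()].
#' @param cond_a,cond_b logical vectors selecting the two well sets.
#' @return `ecm_test` with the t statistic and p-value.
#' @export
compare_lda_scores <- function(scores, cond_a, cond_b) {
  a <- scores$LD1[cond_a]; b <- scores$LD1[cond_b]
  res <- stats::t.test(a, b)
  new_ecm_test(statistic = unname(res$statistic),
               p_value = res$p.value, method = "Welch t-test on LD1",
               n = c(length(a), length(b)))
}

#' Paired per-factor tests between albumin arms
#'
#' For every factor, compares the two arms with a Wilcoxon signed-rank
#' test, pairing by `sample_id` (replicate wells are first averaged to
#' one profile per sample per arm). The exact null distribution is
#' used up to 25 pairs when no zero or tied differences occur;
#' otherwise the normal approximation with continuity correction.
#' When all paired differences are zero the p-value is 1 by
#' convention. Benjamini-Hochberg q-values are computed across
#' factors.
#'
#' @param profiles well-profile data.frame.
#' @param group restrict to one clinical group (default "DC").
#' @param arms length-2 character: the two albumin arms to pair.
#' @return data.frame: factor, statistic, p_value, q_value, n_pairs.
#' @export
per_factor_tests <- function(profiles, group = "DC",
                             arms = c("none", "physiological")) {
  fcols <- grep("^F\\d+$", names(profiles), value = TRUE)
  sub <- profiles[profiles$group == group &
                    profiles$albumin_arm %in% arms, , drop = FALSE]
  agg <- stats::aggregate(sub[fcols],
                          by = list(sample_id = sub$sample_id,
                                    albumin_arm = as.character(
                                      sub$albumin_arm)),
                          FUN = mean)
  a <- agg[agg$albumin_arm == arms[1], ]
  b <- agg[agg$albumin_arm == arms[2], ]
  missing <- c(setdiff(a$sample_id, b$sample_id),
               setdiff(b$sample_id, a$sample_id))
  if (length(missing))
    stop("unpaired sample(s): ", paste(missing, collapse = ", "))
  b <- b[match(a$sample_id, b$sample_id), ]
  if (nrow(a) < 6) stop("need at least 6 complete pairs")
  rows <- lapply(fcols, function(f) {
    d <- a[[f]] - b[[f]]
    if (all(d == 0)) {
      data.frame(factor = f, statistic = NA_real_, p_value = 1,
                 n_pairs = length(d))
    } else {
      exact <- length(d) <= 25 && !any(d == 0) && !anyDuplicated(abs(d))
      res <- suppressWarnings(
        stats::wilcox.test(a[[f]], b[[f]], paired = TRUE, exact = exact,
                           correct = TRUE))
      data.frame(factor = f, statistic = unname(res$statistic),
                 p_value = res$p.value, n_pairs = length(d))
    }
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Map factors to cellular compartments
#'
#' For every factor, sums absolute loadings by compartment tag and
#' normalises to 1, so the weights say which cellular component a
#' factor mostly encodes. Ties for the dominant compartment are broken
#' alphabetically and flagged.
#'
#' @param model a `factor_model`.
#' @param compartments named character vector feature -> compartment
#'   (e.g. attribute `compartments` of the feature table).
#' @return data.frame: factor, one weight column per compartment,
#'   `dominant`, `tie` flag.
#' @export
factor_component_map <- function(model, compartments) {
  tags <- compartments[model$feature_names]
  if (anyNA(tags)) stop("missing compartment tag(s)")
  lev <- sort(unique(tags))
  out <- lapply(seq_len(model$n_factors), function(k) {
    w <- tapply(abs(model$loadings[, k]), tags, sum)
    w <- w[lev]; w[is.na(w)] <- 0
    w <- w / sum(w)
    top <- max(w)
    dom <- sort(names(w)[w == top])
    c(list(factor = colnames(model$loadings)[k]), as.list(w),
      list(dominant = dom[1], tie = length(dom) > 1))
  })
  do.call(rbind, lapply(out, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

#' PCA model on baseline wells and projection of treated wells
#'
#' `fit_pca` computes principal components on the training wells
#' (profiles are already unit-scaled, so no rescaling); `score_pca`
#' projects any wells; `pca_shift_test` measures the distance between
#' the centroids of a baseline and a treated condition in the leading
#' component space, with a label-permutation p-value.
#'
#' @param profiles well-profile data.frame.
#' @param train_filter logical vector selecting training wells.
#' @param n_components components retained (default 2).
#' @return `fit_pca`: list of class `pca_model` (rotation, center,
#'   feature_cols).
#' @export
fit_pca <- function(profiles, train_filter = rep(TRUE, nrow(profiles)),
                    n_components = 2) {
  fcols <- grep("^F\\d+$", names(profiles), value = TRUE)
  X <- as.matrix(profiles[train_filter, fcols, drop = FALSE])
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  structure(list(rotation = pc$rotation[, seq_len(n_components),
                                        drop = FALSE],
                 center = pc$center, feature_cols = fcols,
                 sdev = pc$sdev),
            class = "pca_model")
}

#' @rdname fit_pca
#' @param model a `pca_model`.
#' @export
score_pca <- function(model, profiles) {
  X <- as.matrix(profiles[model$feature_cols])
  sc <- sweep(X, 2, model$center) %*% model$rotation
  cbind(profiles[setdiff(names(profiles), model$feature_cols)],
        as.data.frame(sc))
}

#' @rdname fit_pca
#' @param scores data.frame from [score_pca()].
#' @param baseline,treated logical vectors selecting the two well sets.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed for the permutation draw.
#' @export
pca_shift_test <- function(scores, baseline, treated, n_perm = 1000,
                           seed = 1) {
  pcols <- grep("^PC\\d+$", names(scores), value = TRUE)
  A <- as.matrix(scores[baseline, pcols, drop = FALSE])
  B <- as.matrix(scores[treated, pcols, drop = FALSE])
  dist0 <- sqrt(sum((colMeans(A) - colMeans(B))^2))
  XX <- rbind(A, B); nA <- nrow(A)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample(nrow(XX), nA)
    sqrt(sum((colMeans(XX[idx, , drop = FALSE]) -
                colMeans(XX[-idx, , drop = FALSE]))^2))
  }, numeric(1)))
  list(distance = dist0,
       p_value = (1 + sum(perm >= dist0)) / (1 + n_perm))
}
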