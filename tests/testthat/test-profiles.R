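small_cohort <- function() cached("profiles_cohort", {
  lay <- generate_study_layout(8, 3, 4, seed = 3)
  spec <- default_latent_spec()
  tab <- generate_feature_table(spec, 60, lay, seed = 3)
  tz <- zscore_per_plate(tab)
  fm <- fit_factor_analysis(tz)
  sc <- score_factors(fm, tz)
  wp <- aggregate_wells(sc, min_cells = 50)
  list(spec = spec, tz = tz, fm = fm, sc = sc, wp = wp)
})

test_that("per-plate z-scoring centres every plate and removes batch offsets", {
  spec <- default_latent_spec(n_factors = 3)
  lay <- rbind(null_layout(6, "P1"), null_layout(6, "P2"))
  offs <- list(P2 = rep(5, spec$n_features))
  tab <- generate_feature_table(spec, 40, lay, seed = 4,
                                plate_offsets = offs)
  f1 <- spec$feature_names[1]
  expect_gt(mean(tab[[f1]][tab$plate_id == "P2"]) -
              mean(tab[[f1]][tab$plate_id == "P1"]), 3)
  tz <- zscore_per_plate(tab)
  for (p in c("P1", "P2")) {
    sub <- as.matrix(tz[tz$plate_id == p, spec$feature_names])
    expect_lt(max(abs(colMeans(sub))), 1e-9)
    expect_lt(max(abs(apply(sub, 2, sd) - 1)), 1e-9)
  }
  # matched generative params: post-op distributions agree across plates
  m1 <- colMeans(as.matrix(tz[tz$plate_id == "P1", spec$feature_names]))
  m2 <- colMeans(as.matrix(tz[tz$plate_id == "P2", spec$feature_names]))
  expect_lt(max(abs(m1 - m2)), 1e-9)
})

test_that("zero-variance features are dropped and tiny plates rejected", {
  spec <- default_latent_spec(n_factors = 3)
  tab <- generate_feature_table(spec, 20, null_layout(2), seed = 5)
  tab$const_feat <- 1
  expect_message(tz <- zscore_per_plate(tab), "zero-variance")
  expect_false("const_feat" %in% names(tz))
  one_cell <- tab[1, ]
  expect_error(zscore_per_plate(one_cell), "2 cells")
})

test_that("factor selection hits the generative factor count at the 0.80 target", {
  cohort <- small_cohort()
  expect_equal(cohort$fm$n_factors, 11)
  expect_gte(cohort$fm$cumulative_variance, 0.80)
  expect_true(cohort$fm$target_reached)
  # one factor short of the truth explains < 0.80
  expect_lt(cohort$fm$cumvar_scan[10], 0.80)
})

test_that("pure isotropic noise plateaus below target with a warning", {
  set.seed(6)
  noise <- as.data.frame(matrix(rnorm(400 * 12), 400, 12))
  names(noise) <- sprintf("n%02d", 1:12)
  noise$plate_id <- "P1"
  expect_warning(fm <- fit_factor_analysis(noise, variance_target = 0.8,
                                           n_max = 5),
                 "plateau")
  expect_false(fm$target_reached)
  expect_equal(fm$n_factors, 5)
})

test_that("variance target 1.0 exhausts the scan", {
  spec <- default_latent_spec(n_factors = 3)
  tab <- generate_feature_table(spec, 80, null_layout(6), seed = 7)
  tz <- zscore_per_plate(tab)
  expect_warning(fm <- fit_factor_analysis(tz, variance_target = 1,
                                           n_max = 4))
  expect_equal(fm$n_factors, 4)
})

test_that("regression scores are deterministic, linear, and mean-consistent", {
  cohort <- small_cohort()
  sc <- cohort$sc
  fcols <- paste0("F", seq_len(cohort$fm$n_factors))
  # averaging scores equals scoring the average (linearity identity)
  X <- cohort$tz[ecmorph:::feature_cols(cohort$tz)]
  mean_row <- cohort$tz[1, ]
  mean_row[names(X)] <- as.list(colMeans(as.matrix(X)))
  sc_mean <- score_factors(cohort$fm, mean_row)
  expect_equal(unlist(sc_mean[fcols]), colMeans(as.matrix(sc[fcols])),
               tolerance = 1e-6, ignore_attr = TRUE)
  # standardised zero vector scores to zero
  zero_row <- mean_row
  zero_row[names(X)] <- as.list(cohort$fm$feature_means)
  expect_equal(unname(unlist(score_factors(cohort$fm, zero_row)[fcols])),
               rep(0, length(fcols)))
  expect_identical(score_factors(cohort$fm, cohort$tz),
                   score_factors(cohort$fm, cohort$tz))
})

test_that("well aggregation averages cells, filters small wells and rescales", {
  cohort <- small_cohort()
  wp <- cohort$wp
  fcols <- paste0("F", seq_len(cohort$fm$n_factors))
  expect_lt(max(abs(colMeans(as.matrix(wp[fcols])))), 1e-9)
  expect_equal(unname(apply(as.matrix(wp[fcols]), 2, sd)),
               rep(1, length(fcols)))
  expect_true(all(wp$n_cells >= 50))
  # dropping a below-threshold well only changes the well count
  sc2 <- cohort$sc[-(1:15), ]                     # cripple the first well
  expect_message(wp2 <- aggregate_wells(sc2, min_cells = 50), "excluding")
  expect_equal(nrow(wp2), nrow(wp) - 1)
})

test_that("LDA separates separated classes and honours the sign convention", {
  set.seed(8)
  prof <- data.frame(group = rep(c("HC", "DC"), each = 15),
                     albumin_arm = "none",
                     sample_id = sprintf("S%02d", 1:30),
                     F1 = c(rnorm(15, 0), rnorm(15, 5)),
                     F2 = rnorm(30))
  mdl <- fit_lda(prof, n_components = 1)
  sc <- score_lda(mdl, prof)
  expect_lt(mean(sc$LD1[sc$group == "HC"]), mean(sc$LD1[sc$group == "DC"]))
  pred <- ifelse(sc$LD1 > mean(sc$LD1), "DC", "HC")
  expect_equal(mean(pred == prof$group), 1)       # full separation
  # scoring training wells reproduces fit-time class means
  expect_equal(mean(sc$LD1[sc$group == "HC"]),
               mdl$class_score_means["HC", 1], ignore_attr = TRUE)
})

test_that("label permutation destroys LDA separation", {
  set.seed(9)
  prof <- data.frame(group = rep(c("HC", "DC"), each = 12),
                     albumin_arm = "none",
                     sample_id = sprintf("S%02d", 1:24),
                     F1 = rnorm(24), F2 = rnorm(24), F3 = rnorm(24))
  ps <- vapply(1:50, function(i) {
    prof$group <- sample(prof$group)
    mdl <- fit_lda(prof, n_components = 1)
    sc <- score_lda(mdl, prof)
    t.test(sc$LD1 ~ prof$group)$p.value
  }, numeric(1))
  # permuted labels: held-out style t-test rarely small; the training
  # optimisation biases p downward, so just require mostly non-tiny
  expect_gte(mean(ps > 0.001), 0.9)
})

test_that("LDA projection is affine in the profiles", {
  cohort <- small_cohort()
  mdl <- fit_lda(cohort$wp)
  fcols <- mdl$feature_cols
  sc <- score_lda(mdl, cohort$wp)
  shifted <- cohort$wp
  shifted[fcols] <- shifted[fcols] + 2
  sc2 <- score_lda(mdl, shifted)
  delta <- sc2$LD1 - sc$LD1
  expect_lt(diff(range(delta)), 1e-9)             # constant shift
  scaled <- cohort$wp
  scaled[fcols] <- scaled[fcols] * 3
  sc3 <- score_lda(mdl, scaled)
  grand_shift <- drop(matrix(2 * mdl$grand_mean, 1) %*% mdl$scalings[, 1])
  expect_equal(sc3$LD1, 3 * sc$LD1 + grand_shift, tolerance = 1e-9)
})

test_that("Welch comparison of LD1 behaves at the identity and under swap", {
  set.seed(10)
  scores <- data.frame(LD1 = c(rnorm(10), rnorm(10, 3)))
  a <- rep(c(TRUE, FALSE), each = 10)
  same <- compare_lda_scores(scores, a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  ab <- compare_lda_scores(scores, a, !a)
  ba <- compare_lda_scores(scores, !a, a)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("per-factor paired Wilcoxon: conventions, closed forms, enumeration", {
  mkprof <- function(delta, n = 6) {
    data.frame(group = "DC",
               albumin_arm = rep(c("none", "physiological"), each = n),
               sample_id = rep(sprintf("S%d", 1:n), 2),
               well_id = sprintf("W%d", 1:(2 * n)), plate_id = "P1",
               replicate = 1,
               F1 = c(delta + 10, rep(10, n)))
  }
  # all differences zero -> p = 1 by convention
  res0 <- per_factor_tests(mkprof(rep(0, 6)))
  expect_equal(res0$p_value, 1)
  # six positive differences -> exact two-sided p = 2 / 2^6
  res <- per_factor_tests(mkprof(c(1, 2, 3, 4, 5, 6) / 10))
  expect_equal(res$p_value, 2 / 64)
  # enumeration oracle on random differences, n = 8
  set.seed(11)
  d <- rnorm(8)
  res8 <- per_factor_tests(mkprof(d, 8))
  expect_equal(res8$p_value, enum_signrank_p(d), tolerance = 1e-12)
  # unpaired input errors with the missing sample named
  broken <- mkprof(rep(1, 6))
  broken <- broken[!(broken$sample_id == "S3" &
                       broken$albumin_arm == "physiological"), ]
  expect_error(per_factor_tests(broken), "S3")
})

test_that("Benjamini-Hochberg q-values follow the step-up arithmetic", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.20), "BH"), c(0.03, 0.03, 0.20))
  cohort <- small_cohort()
  pf <- per_factor_tests(cohort$wp)
  ord <- order(pf$p_value)
  expect_true(all(diff(pf$q_value[ord]) >= -1e-12))
  expect_equal(pf$q_value[ord][nrow(pf)], pf$p_value[ord][nrow(pf)])
})

test_that("factor-component weights normalise and find block-dominant tags", {
  L <- matrix(0, 6, 2, dimnames = list(sprintf("f%d", 1:6), c("F1", "F2")))
  L[1:3, 1] <- 0.9; L[4:6, 2] <- c(0.5, 0.5, 0.5)
  fm <- structure(list(n_factors = 2, loadings = L,
                       feature_names = rownames(L)),
                  class = "factor_model")
  tags <- setNames(c("mitochondria", "mitochondria", "mitochondria",
                     "vwf", "vwf", "actin"), rownames(L))
  cm <- factor_component_map(fm, tags)
  expect_equal(cm$mitochondria[1], 1)
  expect_identical(cm$dominant[1], "mitochondria")
  expect_identical(cm$dominant[2], "vwf")
  # uniform |loadings|: weights proportional to tag counts, tie flagged
  L2 <- L; L2[] <- 1
  fm2 <- structure(list(n_factors = 2, loadings = L2,
                        feature_names = rownames(L)),
                   class = "factor_model")
  cm2 <- factor_component_map(fm2, tags)
  expect_equal(cm2$mitochondria[1], 0.5)
  expect_equal(cm2$vwf[1], 1 / 3)
  expect_equal(cm2$actin[1], 1 / 6)
  tags_tied <- setNames(c("mitochondria", "mitochondria", "mitochondria",
                          "vwf", "vwf", "vwf"), rownames(L))
  cm3 <- factor_component_map(fm2, tags_tied)
  expect_true(all(cm3$tie))
  expect_identical(cm3$dominant[1], "mitochondria")  # alphabetical
})

test_that("PCA scoring centres training wells and the shift test calibrates", {
  cohort <- small_cohort()
  train <- cohort$wp$albumin_arm == "none"
  pca <- fit_pca(cohort$wp, train)
  sc <- score_pca(pca, cohort$wp)
  expect_lt(max(abs(colMeans(as.matrix(sc[train, c("PC1", "PC2")])))), 1e-9)
  # duplicating a held-out well leaves its centroid unchanged
  held <- which(!train)[1:6]
  c1 <- colMeans(as.matrix(sc[held, c("PC1", "PC2")]))
  dup <- score_pca(pca, cohort$wp[c(held, held), ])
  expect_equal(colMeans(as.matrix(dup[c("PC1", "PC2")])), c1)
  # arms generated identically (HC supra vs HC none) -> null shift
  hc_none <- sc$group == "HC" & sc$albumin_arm == "none"
  hc_sup <- sc$group == "HC" & sc$albumin_arm == "supraphysiological"
  ps <- vapply(1:10, function(s)
    pca_shift_test(sc, hc_none, hc_sup, n_perm = 200, seed = s)$p_value,
    numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})
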