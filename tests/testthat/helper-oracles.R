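# Brute-force enumeration oracles, independent of the package's code paths.

# Fisher two-sided p by explicit enumeration of all tables with the
# observed margins, probabilities from choose() ratios.
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  pr <- vapply(support, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1), numeric(1))
  p_obs <- pr[support == tab[1, 1]]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Exact two-sided signed-rank p over all 2^n sign assignments.
enum_signrank_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  lo <- mean(w_all <= w_obs); hi <- mean(w_all >= w_obs)
  min(1, 2 * min(lo, hi))
}

# Exact two-sided Mann-Whitney p over all C(n1+n2, n1) group assignments.
enum_mannwhitney_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  lo <- mean(u_all <= u_obs); hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# single-condition layout whose feature covariance is exactly the
# calibrated latent model (no between-condition variance)
null_layout <- function(n_wells, plate_id = "P1") {
  data.frame(plate_id = plate_id,
             well_id = sprintf("W%02d", seq_len(n_wells)),
             group = "HC", albumin_arm = "none",
             sample_id = sprintf("S%02d", seq_len(n_wells)),
             replicate = 1L, stringsAsFactors = FALSE)
}

# build a field_image from named channel matrices on the 16-bit scale
make_field <- function(channels, pixel_size_um = 0.33, well_id = "A01",
                       site = 1L) {
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 field_id = "Ftest", well_id = well_id, site = site),
            class = "field_image")
}

disc_mask <- function(W, H, cx, cy, r) {
  outer((seq_len(W) - cx)^2, (seq_len(H) - cy)^2, `+`) <= r^2
}

# cache expensive rendered fixtures across tests within a session
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}
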