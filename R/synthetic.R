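# Synthetic multi-view cohort generator: labels first, features conditional
# on labels, so every planted effect is auditable.

#' Configuration for the synthetic cohort generator
#'
#' Describes a two-view cohort: a sparse, skewed, non-negative OTU-style
#' microbial abundance view and a small mixed-type clinical view with
#' missing values. Class-conditional effects are planted in a configurable
#' informative subset of each view; setting every effect to zero gives a
#' pure-noise (null) cohort.
#'
#' @param n_samples number of samples (>= 10).
#' @param positive_fraction positive-class prevalence; exactly
#'   `round(n_samples * positive_fraction)` samples are positive.
#' @param n_microbial number of microbial (OTU) features.
#' @param n_informative_microbial how many microbial features carry signal.
#' @param microbial_effect class-dependent mean shift of informative
#'   microbial features on the log-abundance scale, in units of the
#'   log-scale standard deviation.
#' @param sparsity expected zero fraction of the abundance matrix.
#' @param n_clinical_numeric,n_clinical_categorical clinical view makeup.
#' @param n_informative_clinical how many clinical features carry signal
#'   (numeric features are filled first, then categorical).
#' @param clinical_effect standardized mean shift for informative numeric
#'   clinical features; also scales the level-probability shift of
#'   informative categorical features.
#' @param n_categories levels per categorical clinical feature.
#' @param missing_rate_clinical MCAR missingness rate in the clinical view.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 120, positive_fraction = 0.17,
                             n_microbial = 300, n_informative_microbial = 30,
                             microbial_effect = 2, sparsity = 0.3,
                             n_clinical_numeric = 4, n_clinical_categorical = 3,
                             n_informative_clinical = 2, clinical_effect = 1.5,
                             n_categories = 3,
                             missing_rate_clinical = 0.05, seed = 1) {
  cfg <- list(n_samples = as.integer(n_samples),
              positive_fraction = positive_fraction,
              n_microbial = as.integer(n_microbial),
              n_informative_microbial = as.integer(n_informative_microbial),
              microbial_effect = microbial_effect,
              sparsity = sparsity,
              n_clinical_numeric = as.integer(n_clinical_numeric),
              n_clinical_categorical = as.integer(n_clinical_categorical),
              n_informative_clinical = as.integer(n_informative_clinical),
              clinical_effect = clinical_effect,
              n_categories = as.integer(n_categories),
              missing_rate_clinical = missing_rate_clinical,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_samples >= 10,
              positive_fraction > 0, positive_fraction < 1,
              sparsity >= 0, sparsity <= 1,
              missing_rate_clinical >= 0, missing_rate_clinical <= 1,
              n_informative_microbial <= n_microbial,
              n_informative_clinical <= n_clinical_numeric + n_clinical_categorical)
  })
  structure(cfg, class = "synthetic_config")
}

#' Named cohort presets
#'
#' Presets matching the shapes of the two study cohorts: `"ibd-like"`
#' (535 samples, 17% positive, 6737 microbial and 7 clinical features,
#' heavier clinical missingness) and `"crc-like"` (291 samples, 41%
#' positive, 5982 microbial and 9 clinical features, near-complete
#' clinical data), plus `"-small"` variants (120 samples, 300 microbial
#' features) sized for fast repeated fitting.
#'
#' @param seed integer seed stored in each preset.
#' @return named list of [synthetic_config()] objects.
#' @export
cohort_presets <- function(seed = 1) {
  list(
    "ibd-like" = synthetic_config(
      n_samples = 535, positive_fraction = 0.17,
      n_microbial = 6737, n_informative_microbial = 100,
      n_clinical_numeric = 4, n_clinical_categorical = 3,
      n_informative_clinical = 2,
      missing_rate_clinical = 0.06, seed = seed),
    "crc-like" = synthetic_config(
      n_samples = 291, positive_fraction = 0.41,
      n_microbial = 5982, n_informative_microbial = 100,
      n_clinical_numeric = 5, n_clinical_categorical = 4,
      n_informative_clinical = 2,
      missing_rate_clinical = 0.002, seed = seed),
    "ibd-like-small" = synthetic_config(
      n_samples = 120, positive_fraction = 0.17,
      n_microbial = 300, n_informative_microbial = 30,
      n_clinical_numeric = 4, n_clinical_categorical = 3,
      n_informative_clinical = 2,
      missing_rate_clinical = 0.06, seed = seed),
    "crc-like-small" = synthetic_config(
      n_samples = 120, positive_fraction = 0.41,
      n_microbial = 300, n_informative_microbial = 30,
      n_clinical_numeric = 5, n_clinical_categorical = 4,
      n_informative_clinical = 2,
      missing_rate_clinical = 0.002, seed = seed))
}

#' Generate a synthetic multi-view cohort
#'
#' Labels are drawn first (exact positive count), then features are drawn
#' conditional on the label. Microbial abundances are zero-inflated
#' log-normal counts; the informative subset receives a class-dependent
#' shift of `microbial_effect` on the log scale. Clinical numeric features
#' are Gaussian with a `clinical_effect` shift on informative ones;
#' categorical features get class-dependent level probabilities on
#' informative ones. Missing values are inserted completely at random in
#' the clinical view only.
#'
#' @param config a [synthetic_config()].
#' @return a [multiview_dataset()]. Informative feature names are recorded
#'   in `attr(, "informative")`.
#' @export
generate_multiview <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    n_pos <- round(n * cfg$positive_fraction)
    stopifnot(n_pos >= 1, n_pos <= n - 1)
    labels <- integer(n)
    labels[sample(n, n_pos)] <- 1L

    # Microbial view: zero-inflated log-normal abundances.
    p <- cfg$n_microbial
    info_m <- seq_len(cfg$n_informative_microbial)
    base_mu <- stats::rnorm(p, mean = 1, sd = 0.5)
    logab <- matrix(stats::rnorm(n * p), n, p)
    logab <- sweep(logab, 2, base_mu, "+")
    if (length(info_m) && cfg$microbial_effect != 0) {
      shift <- matrix(0, n, p)
      shift[labels == 1L, info_m] <- cfg$microbial_effect
      logab <- logab + shift
    }
    present <- matrix(stats::runif(n * p) >= cfg$sparsity, n, p)
    micro <- exp(logab) * present
    colnames(micro) <- sprintf("otu_%04d", seq_len(p))

    # Clinical view: numeric then categorical; informative slots are the
    # first numeric columns, then the first categorical columns.
    n_num <- cfg$n_clinical_numeric
    n_cat <- cfg$n_clinical_categorical
    n_info_num <- min(cfg$n_informative_clinical, n_num)
    n_info_cat <- cfg$n_informative_clinical - n_info_num
    clin <- list()
    for (j in seq_len(n_num)) {
      x <- stats::rnorm(n)
      if (j <= n_info_num && cfg$clinical_effect != 0) {
        x <- x + cfg$clinical_effect * labels
      }
      clin[[sprintf("clin_num_%02d", j)]] <- x
    }
    for (j in seq_len(n_cat)) {
      k <- cfg$n_categories
      lv <- paste0("L", seq_len(k))
      p0 <- rep(1 / k, k)
      p1 <- p0
      if (j <= n_info_cat && cfg$clinical_effect != 0) {
        # push positive-class mass onto the first level
        delta <- min(0.9, 0.25 * cfg$clinical_effect)
        p1 <- (1 - delta) * p0
        p1[1] <- p1[1] + delta
      }
      draw <- function(prob) sample(lv, 1, prob = prob)
      vals <- vapply(seq_len(n),
                     function(i) draw(if (labels[i] == 1L) p1 else p0),
                     character(1))
      clin[[sprintf("clin_cat_%02d", j)]] <- factor(vals, levels = lv)
    }
    clin <- as.data.frame(clin)
    if (cfg$missing_rate_clinical > 0 && ncol(clin) > 0) {
      mask <- matrix(stats::runif(n * ncol(clin)) < cfg$missing_rate_clinical,
                     n, ncol(clin))
      for (j in seq_len(ncol(clin))) clin[[j]][mask[, j]] <- NA
    }

    ids <- sprintf("S%04d", seq_len(n))
    meta <- rbind(
      data.frame(feature = names(clin), view = "clinical",
                 kind = ifelse(vapply(clin, is.factor, logical(1)),
                               "categorical", "numeric"),
                 allow_missing = TRUE),
      data.frame(feature = colnames(micro), view = "microbial",
                 kind = "numeric", allow_missing = FALSE))
    ds <- multiview_dataset(list(clinical = clin, microbial = micro),
                            labels, ids, meta)
    attr(ds, "informative") <- list(
      microbial = colnames(micro)[info_m],
      clinical = c(sprintf("clin_num_%02d", seq_len(n_info_num)),
                   if (n_info_cat > 0) sprintf("clin_cat_%02d", seq_len(n_info_cat))))
    ds
  })
}
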