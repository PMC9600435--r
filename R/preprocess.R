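# Training-time feature filtering for the microbial view: zero-variance
# removal, Yeo-Johnson power transform with post-standardization, one-way
# ANOVA F filtering with multiple-test correction, and data-space class
# weights. Everything is fit on training rows only; labels are consulted
# nowhere in the apply path.

#' Remove zero-variance features
#'
#' Drops columns with a single distinct value (constant features carry no
#' class information and break the power transform).
#'
#' @param view numeric matrix (rows = samples), no missing values.
#' @return list with `filtered` (matrix, column order preserved) and
#'   `variance_mask` (named logical; `TRUE` = retained).
#' @export
remove_zero_variance <- function(view) {
  stopifnot(is.matrix(view), is.numeric(view))
  if (anyNA(view)) stop("zero-variance filter expects no missing values", call. = FALSE)
  n_distinct <- apply(view, 2, function(x) length(unique(x)))
  mask <- n_distinct >= 2
  names(mask) <- colnames(view)
  if (!any(mask)) stop("empty view after filtering: all columns constant", call. = FALSE)
  list(filtered = view[, mask, drop = FALSE], variance_mask = mask)
}

# Yeo-Johnson transform of one column at a fixed lambda (via car), and its
# profile log-likelihood under a Gaussian model (normality objective).
yj_loglik <- function(x, lambda) {
  z <- car::yjPower(x, lambda)
  n <- length(x)
  s2 <- stats::var(z) * (n - 1) / n
  if (!is.finite(s2) || s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log(abs(x) + 1))
}

#' Fit a per-column Yeo-Johnson power transform
#'
#' Estimates one Yeo-Johnson exponent per column by maximum likelihood
#' (profile likelihood over lambda in \[-3, 3\]) and records the mean and
#' standard deviation of the transformed column for post-standardization.
#' Yeo-Johnson is used rather than Box-Cox because abundance tables are
#' full of exact zeros.
#'
#' @param view numeric matrix of finite training values, no constant
#'   columns.
#' @return object of class `power_transform` with per-column `lambda`,
#'   `center`, `scale`.
#' @export
fit_power_transform <- function(view) {
  stopifnot(is.matrix(view), all(is.finite(view)))
  sds <- apply(view, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column: remove constant features before transforming",
         call. = FALSE)
  }
  lambda <- vapply(seq_len(ncol(view)), function(j) {
    x <- view[, j]
    stats::optimize(function(l) yj_loglik(x, l), interval = c(-3, 3),
                    maximum = TRUE)$maximum
  }, numeric(1))
  z <- vapply(seq_len(ncol(view)),
              function(j) car::yjPower(view[, j], lambda[j]),
              numeric(nrow(view)))
  ctr <- colMeans(z)
  scl <- apply(z, 2, stats::sd)
  structure(list(features = colnames(view), lambda = lambda,
                 center = ctr, scale = scl),
            class = "power_transform")
}

#' Apply a fitted power transform
#'
#' Deterministic given the fitted parameters; test rows are transformed
#' with training parameters only (no refitting).
#'
#' @param view numeric matrix whose columns match the fitted features.
#' @param params a fitted [fit_power_transform()] object.
#' @return transformed, standardized matrix.
#' @export
apply_power_transform <- function(view, params) {
  stopifnot(inherits(params, "power_transform"))
  view <- view[, params$features, drop = FALSE]
  z <- vapply(seq_len(ncol(view)),
              function(j) car::yjPower(view[, j], params$lambda[j]),
              numeric(nrow(view)))
  if (nrow(view) == 1L) z <- matrix(z, nrow = 1L)
  z <- sweep(z, 2, params$center, "-")
  z <- sweep(z, 2, params$scale, "/")
  colnames(z) <- params$features
  rownames(z) <- rownames(view)
  z
}

# Vectorized two-group one-way ANOVA F statistics (df1 = 1, df2 = n - 2).
anova_f_stats <- function(view, labels) {
  labels <- check_binary_labels(labels)
  n <- nrow(view)
  n1 <- sum(labels == 1L); n0 <- n - n1
  if (n0 < 2 || n1 < 2) stop("each class needs >= 2 samples for ANOVA", call. = FALSE)
  m0 <- colMeans(view[labels == 0L, , drop = FALSE])
  m1 <- colMeans(view[labels == 1L, , drop = FALSE])
  gm <- (n0 * m0 + n1 * m1) / n
  ssb <- n0 * (m0 - gm)^2 + n1 * (m1 - gm)^2
  ssw <- colSums(sweep(view[labels == 0L, , drop = FALSE], 2, m0)^2) +
         colSums(sweep(view[labels == 1L, , drop = FALSE], 2, m1)^2)
  f <- ifelse(ssw > 0, (ssb / 1) / (ssw / (n - 2)), ifelse(ssb > 0, Inf, 0))
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  p[f == 0] <- 1
  list(f = f, p = p)
}

#' ANOVA F-test feature filter with multiple-test correction
#'
#' Scores every (power-transformed) feature with a two-group one-way
#' ANOVA F test and keeps features whose corrected p-value is at or below
#' `alpha`. Benjamini-Hochberg FDR is the default correction; with such
#' wide abundance tables an uncorrected filter admits far too many false
#' discoveries.
#'
#' @param view numeric matrix of transformed training values.
#' @param labels 0/1 training labels (both classes with >= 2 samples).
#' @param alpha significance level in (0, 1) on the adjusted p-value.
#' @param method correction: `"BH"` (default), `"bonferroni"` or `"none"`.
#' @param min_keep if no feature passes, keep the `min_keep` best-ranked
#'   features instead of returning an empty view (flagged in the result).
#' @return object of class `anova_filter` with `kept_features`,
#'   `anova_stats` (feature, F, p, adjusted p, kept), `alpha`, `method`,
#'   `fallback` flag.
#' @export
anova_filter <- function(view, labels, alpha = 0.05,
                         method = c("BH", "bonferroni", "none"),
                         min_keep = 1L) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha <= 1)
  st <- anova_f_stats(view, labels)
  p_adj <- stats::p.adjust(st$p, method = method)
  keep <- p_adj <= alpha & st$f > 0
  fallback <- FALSE
  if (!any(keep) && min_keep > 0) {
    fallback <- TRUE
    keep[order(p_adj, st$p)[seq_len(min(min_keep, length(keep)))]] <- TRUE
  }
  stats_df <- data.frame(feature = colnames(view), f = st$f, p = st$p,
                         p_adj = p_adj, kept = keep, row.names = NULL)
  structure(list(kept_features = colnames(view)[keep],
                 anova_stats = stats_df, alpha = alpha, method = method,
                 fallback = fallback),
            class = "anova_filter")
}

#' Fit the full microbial-view filter
#'
#' Training-only pipeline: zero-variance removal, then Yeo-Johnson power
#' transform with standardization, then the ANOVA/FDR filter on the
#' transformed values. The returned state is everything needed to map new
#' samples into the filtered, transformed feature space.
#'
#' @param view numeric training matrix.
#' @param labels 0/1 training labels.
#' @param alpha,method passed to [anova_filter()].
#' @return object of class `filter_state` with `variance_mask`,
#'   `transform_params`, `anova`, `kept_features`, `alpha`.
#' @export
fit_view_filter <- function(view, labels, alpha = 0.05, method = "BH") {
  zv <- remove_zero_variance(view)
  pt <- fit_power_transform(zv$filtered)
  z <- apply_power_transform(zv$filtered, pt)
  af <- anova_filter(z, labels, alpha = alpha, method = method)
  kept <- af$kept_features
  structure(list(variance_mask = zv$variance_mask,
                 transform_params = pt, anova = af,
                 kept_features = kept, alpha = alpha),
            class = "filter_state")
}

#' Apply a fitted filter state to new samples
#'
#' Selects the surviving features and transforms them with the stored
#' training parameters; never consults labels.
#'
#' @param state a [fit_view_filter()] result.
#' @param view numeric matrix containing at least the fitted features.
#' @return filtered, transformed matrix with columns `state$kept_features`.
#' @export
apply_view_filter <- function(state, view) {
  stopifnot(inherits(state, "filter_state"))
  missing_cols <- setdiff(names(state$variance_mask), colnames(view))
  if (length(missing_cols)) {
    stop(sprintf("view lacks %d fitted feature columns (e.g. '%s')",
                 length(missing_cols), missing_cols[1]), call. = FALSE)
  }
  z <- apply_power_transform(view, state$transform_params)
  z[, state$kept_features, drop = FALSE]
}

#' Serialize a filter state to JSON for audit
#'
#' @param state a [fit_view_filter()] result.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_filter_state <- function(state, path) {
  jsonlite::write_json(
    list(alpha = state$alpha,
         method = state$anova$method,
         fallback = state$anova$fallback,
         n_input = length(state$variance_mask),
         n_nonconstant = sum(state$variance_mask),
         n_kept = length(state$kept_features),
         features = state$anova$anova_stats),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Data-space class weights
#'
#' Balanced weighting `w_c = n / (2 * n_c)`: training mass is re-weighted
#' toward the rare class instead of over- or under-sampling.
#'
#' @param labels 0/1 labels, both classes present.
#' @return object of class `class_weights`: named numeric `c("0" = w0, "1" = w1)`.
#' @export
compute_class_weights <- function(labels) {
  labels <- check_binary_labels(labels)
  n <- length(labels)
  w <- vapply(c(0L, 1L), function(cls) n / (2 * sum(labels == cls)), numeric(1))
  structure(stats::setNames(w, c("0", "1")), class = "class_weights")
}

# Per-sample case weights from class weights.
case_weights <- function(class_weights, labels) {
  unname(unclass(class_weights)[as.character(labels)])
}
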