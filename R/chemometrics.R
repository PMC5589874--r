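#' Principal component analysis of a spectral dataset
#'
#' Column-mean-centred PCA (no extra scaling -- SNV already standardizes each
#' spectrum) with components ordered by explained variance. The sign of each
#' loading vector is fixed deterministically: the largest-magnitude element
#' of every loading is made positive.
#'
#' @param ds a preprocessed [spectral_dataset()] (or plain numeric matrix,
#'   spectra in rows).
#' @param n_components number of components retained (default 3, the factors
#'   with maximum variance contribution).
#' @return A `pca_result` with fields `loadings` (component x wavenumber),
#'   `scores` (spectrum x component), `explained_variance_fraction`,
#'   `center`, `axis`, `labels`, `n_components`.
#' @export
fit_pca <- function(ds, n_components = 3) {
  if (inherits(ds, "spectral_dataset")) {
    X <- ds$matrix; axis <- ds$axis; labels <- ds$labels
  } else {
    X <- as.matrix(ds); axis <- seq_len(ncol(X)); labels <- NULL
  }
  if (nrow(X) < n_components + 1)
    stop("need at least n_components + 1 = ", n_components + 1,
         " spectra, got ", nrow(X), call. = FALSE)
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  rot <- pr$rotation[, k, drop = FALSE]
  sco <- pr$x[, k, drop = FALSE]
  # deterministic sign: largest-magnitude loading element positive
  for (j in k) {
    s <- sign(rot[which.max(abs(rot[, j])), j])
    if (s < 0) { rot[, j] <- -rot[, j]; sco[, j] <- -sco[, j] }
  }
  structure(list(
    loadings = t(rot),
    scores = sco,
    explained_variance_fraction = (pr$sdev^2 / sum(pr$sdev^2))[k],
    center = pr$center,
    axis = axis,
    labels = labels,
    n_components = n_components
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components, explained: %s\n",
              x$n_components,
              paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
                    collapse = ", ")))
  invisible(x)
}

#' 3-D score scatter with separation summary
#'
#' Writes a 3-D scatter of the first three PC scores coloured by group (a
#' lattice cloud plot), and returns the per-group score centroids and
#' spreads together with the mean silhouette coefficient of the 3-PC
#' Euclidean configuration -- the scalar separation summary used in place of
#' a visual judgement of the clusters.
#'
#' @param res a `pca_result` from [fit_pca()] with at least 3 components.
#' @param labels group label per spectrum; defaults to the labels stored in
#'   `res`. At least two distinct groups are required (silhouette is
#'   undefined otherwise).
#' @param file optional PNG path; no figure is written when `NULL`.
#' @return List with `centroids` (data.frame: group, n, PC1..PC3 means and
#'   SDs), `silhouette` (mean silhouette width), `file`.
#' @export
score_scatter_3d <- function(res, labels = NULL, file = NULL) {
  stopifnot(inherits(res, "pca_result"))
  if (res$n_components < 3) stop("need at least 3 components", call. = FALSE)
  if (is.null(labels)) labels <- res$labels
  if (is.null(labels)) stop("group labels are required", call. = FALSE)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("silhouette undefined for a single group", call. = FALSE)
  S <- res$scores[, 1:3, drop = FALSE]
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(S))
  centroids <- do.call(rbind, lapply(unique(labels), function(g) {
    s <- S[labels == g, , drop = FALSE]
    data.frame(group = g, n = nrow(s),
               pc1_mean = mean(s[, 1]), pc2_mean = mean(s[, 2]),
               pc3_mean = mean(s[, 3]),
               pc1_sd = stats::sd(s[, 1]), pc2_sd = stats::sd(s[, 2]),
               pc3_sd = stats::sd(s[, 3]))
  }))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 750)
    on.exit(grDevices::dev.off(), add = TRUE)
    df <- data.frame(PC1 = S[, 1], PC2 = S[, 2], PC3 = S[, 3],
                     group = factor(labels))
    print(lattice::cloud(PC3 ~ PC1 * PC2, data = df, groups = df$group,
                         auto.key = list(space = "right"), pch = 19,
                         main = "PC score scatter"))
  }
  list(centroids = centroids, silhouette = mean(sil[, "sil_width"]),
       file = file)
}

#' Welch two-sample t test
#'
#' Unpaired t test with the Welch correction for unequal variances:
#' unequal-variance t statistic, Welch-Satterthwaite degrees of freedom,
#' two-sided p value.
#'
#' @param a,b numeric samples, each of length at least 2, finite.
#' @param group_pair optional labels of the two groups compared.
#' @return A `welch_result` with `t_statistic`, `degrees_of_freedom`,
#'   `p_value`, `group_pair`.
#' @examples
#' welch_test(c(10, 12, 14), c(20, 22, 24))
#' @export
welch_test <- function(a, b, group_pair = c("a", "b")) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("samples must be finite", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    # identical constant-difference case: t.test errors on zero variance
    res <- list(statistic = 0, parameter = length(a) + length(b) - 2,
                p.value = 1)
  } else {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    res <- list(statistic = unname(ht$statistic),
                parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  structure(list(t_statistic = res$statistic,
                 degrees_of_freedom = res$parameter,
                 p_value = res$p.value,
                 group_pair = group_pair),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("<welch_result> %s vs %s: t = %.4g, df = %.4g, p = %.3g\n",
              x$group_pair[1], x$group_pair[2], x$t_statistic,
              x$degrees_of_freedom, x$p_value))
  invisible(x)
}

#' Welch tests of each exposed group against control
#'
#' @param records data.frame with a `group` column and the value column
#'   named by `value`.
#' @param value name of the numeric column tested.
#' @param control control group label.
#' @param all_pairs if `TRUE`, test every group pair instead of
#'   control-vs-exposed only.
#' @return data.frame with columns `group_a`, `group_b`, `t`, `df`, `p`.
#' @export
welch_vs_control <- function(records, value, control = "control",
                             all_pairs = FALSE) {
  groups <- unique(records$group)
  pairs <- if (all_pairs) utils::combn(groups, 2, simplify = FALSE)
           else lapply(setdiff(groups, control), function(g) c(control, g))
  do.call(rbind, lapply(pairs, function(p) {
    w <- welch_test(records[records$group == p[1], value],
                    records[records$group == p[2], value], p)
    data.frame(group_a = p[1], group_b = p[2], t = w$t_statistic,
               df = w$degrees_of_freedom, p = w$p_value)
  }))
}

#' Background-correct a viability plate table
#'
#' Corrected absorbance per sample well: the 570 nm reading minus the mean
#' 600 nm reading of the blank (reagent-only) wells. Results are grouped by
#' exposure time.
#'
#' @param table a data.frame as produced by [make_viability_table()]
#'   (columns `well_type`, `group`, `exposure_min`, `a570`, `a600`).
#' @return data.frame with one row per exposure time: `group`,
#'   `exposure_min`, `n`, `corrected_mean`, `corrected_sd`.
#' @export
viability_correct <- function(table) {
  blanks <- table[table$well_type == "blank", ]
  if (nrow(blanks) == 0L || all(!is.finite(blanks$a600)))
    stop("no blank wells: cannot background-correct", call. = FALSE)
  bg <- mean(blanks$a600[is.finite(blanks$a600)])
  samples <- table[table$well_type == "sample", ]
  corrected <- samples$a570 - bg
  keys <- unique(samples[, c("group", "exposure_min")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- samples$group == keys$group[i] &
      samples$exposure_min == keys$exposure_min[i]
    data.frame(group = keys$group[i], exposure_min = keys$exposure_min[i],
               n = sum(sel), corrected_mean = mean(corrected[sel]),
               corrected_sd = stats::sd(corrected[sel]))
  }))
  out[order(out$exposure_min), ]
}

#' UV fluence from irradiance and exposure time
#'
#' `fluence = irradiance * minutes * 60 / 1e4` converts W/m^2 and minutes to
#' J/cm^2. With `round_to = 1` the value is reported at one-decimal
#' precision (the precision at which dose tables are usually quoted); with
#' `round_to = NULL` (default) full precision is returned.
#'
#' @param irradiance irradiance, W/m^2, non-negative.
#' @param minutes exposure time, minutes, non-negative.
#' @param round_to decimal places for reporting, or `NULL` for full
#'   precision.
#' @return Fluence, J/cm^2 (vectorized over `minutes`).
#' @examples
#' fluence(1.02, c(50, 100, 200), round_to = 1)  # 0.3 0.6 1.2
#' @export
fluence <- function(irradiance, minutes, round_to = NULL) {
  if (any(irradiance < 0) || any(minutes < 0))
    stop("irradiance and exposure time must be non-negative", call. = FALSE)
  f <- irradiance * minutes * 60 / 1e4
  if (!is.null(round_to)) f <- round(f, round_to)
  f
}
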