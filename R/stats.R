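#' Equivalent sphere diameter of a volume
#'
#' `d = 2 (3V / 4 pi)^(1/3)`; a 1000 um^3 islet corresponds to about 12 um
#' and a 500,000 um^3 islet to about 98 um diameter, assuming sphericity.
#'
#' @param volume_um3 positive volume(s) in um^3.
#' @param rounded also return the nearest-integer diameter.
#' @return numeric diameter(s) in um, or a data.frame when `rounded`.
#' @export
equivalent_sphere_diameter <- function(volume_um3, rounded = FALSE) {
  if (any(!is.finite(volume_um3)) || any(volume_um3 <= 0))
    stop("volume must be positive")
  d <- 2 * (3 * volume_um3 / (4 * pi))^(1 / 3)
  if (rounded) data.frame(diameter_um = d, diameter_um_rounded = round(d))
  else d
}

#' Islet volume distribution over the standard bins
#'
#' Percentage of islets per volume bin with closed-open bins
#' `[0, e1), [e1, e2), [e2, e3), [e3, Inf)` for edges
#' `e = (1000, 50000, 500000)` um^3 by default, plus the median volume.
#'
#' @param volumes_um3 non-empty numeric vector.
#' @param bin_edges increasing interior bin edges.
#' @return list with `percent` (length `length(bin_edges) + 1`, sums to
#'   100), `counts`, `median_um3`, `bin_labels`.
#' @export
volume_distribution <- function(volumes_um3, bin_edges = c(1000, 50000, 500000)) {
  if (length(volumes_um3) == 0L) stop("empty volume vector")
  edges <- c(0, bin_edges, Inf)
  counts <- vapply(seq_len(length(edges) - 1L), function(i)
    sum(volumes_um3 >= edges[i] & volumes_um3 < edges[i + 1L]), 0L)
  labels <- sprintf("[%s, %s)", format(edges[-length(edges)], trim = TRUE,
                                       scientific = FALSE),
                    c(format(bin_edges, trim = TRUE, scientific = FALSE), "Inf"))
  list(percent = 100 * counts / length(volumes_um3),
       counts = counts,
       median_um3 = median(volumes_um3),
       bin_labels = labels)
}

#' Innervated versus non-innervated islet comparison
#'
#' Mean and median islet volume per innervation class, the ratio of mean
#' volumes (innervated / non-innervated; `NA` when a class is absent), and
#' the innervated share of the summed islet volume, overall and per region.
#'
#' @param records islet records from [islet_nerve_distances()].
#' @return data.frame with one row per scope.
#' @export
innervated_comparison <- function(records) {
  if (nrow(records) == 0L) stop("empty islet records")
  one <- function(r, scope) {
    inn <- r$volume_um3[r$innervated]
    non <- r$volume_um3[!r$innervated]
    data.frame(scope = scope,
               n_innervated = length(inn),
               n_not_innervated = length(non),
               mean_volume_innervated_um3 = if (length(inn)) mean(inn) else NA_real_,
               mean_volume_not_innervated_um3 = if (length(non)) mean(non) else NA_real_,
               median_volume_innervated_um3 = if (length(inn)) median(inn) else NA_real_,
               median_volume_not_innervated_um3 = if (length(non)) median(non) else NA_real_,
               mean_volume_ratio = if (length(inn) && length(non))
                 mean(inn) / mean(non) else NA_real_,
               innervated_volume_share_pct = 100 * sum(inn) / sum(r$volume_um3))
  }
  out <- one(records, "total")
  for (rg in c(1L, 2L)) {
    sub <- records[!is.na(records$region) & records$region == rg, , drop = FALSE]
    if (nrow(sub) > 0L)
      out <- rbind(out, one(sub, c("duodenal", "splenic")[rg]))
  }
  rownames(out) <- NULL
  out
}

#' Exact binomial confidence interval for a median
#'
#' Distribution-free order-statistic interval: the widest-possible-coverage
#' pair of order statistics `(x_(j), x_(n-j+1))` such that the binomial
#' coverage `P(j <= B < n - j + 1)`, `B ~ Bin(n, 1/2)`, is at least `conf`.
#'
#' @param x numeric sample.
#' @param conf confidence level.
#' @return list with `median`, `lower`, `upper`, `coverage`.
#' @export
median_ci <- function(x, conf = 0.95) {
  x <- sort(na.omit(x))
  n <- length(x)
  if (n < 3L)
    return(list(median = median(x), lower = NA_real_, upper = NA_real_,
                coverage = NA_real_))
  coverage <- function(j) sum(dbinom(j:(n - j), n, 0.5))
  j <- max(1L, qbinom((1 - conf) / 2, n, 0.5))
  while (j >= 1L && coverage(j) < conf) j <- j - 1L
  if (j < 1L)
    return(list(median = median(x), lower = x[1L], upper = x[n],
                coverage = coverage(1L)))
  list(median = median(x), lower = x[j], upper = x[n - j + 1L],
       coverage = coverage(j))
}

#' Dunn's multiple-comparison test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with tie correction,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups; two-sided p values
#' with a Bonferroni-style family correction by default.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @param p_adjust `"bonferroni"` (default) or `"none"`.
#' @return data.frame of pairwise comparisons.
#' @export
dunn_test <- function(values, groups, p_adjust = c("bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(groups[ok])
  g <- levels(groups)
  if (length(g) < 2L) stop("need at least two groups")
  N <- length(values)
  rk <- rank(values)
  tie_tab <- table(values)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_corr
  mean_rank <- tapply(rk, groups, mean)
  n <- tapply(rk, groups, length)
  pairs <- combn(g, 2L)
  m <- ncol(pairs)
  z <- p <- numeric(m)
  for (k in seq_len(m)) {
    a <- pairs[1L, k]
    b <- pairs[2L, k]
    se <- sqrt(var_base * (1 / n[[a]] + 1 / n[[b]]))
    z[k] <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  if (p_adjust == "bonferroni") p <- pmin(1, p * m)
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
             z = z, p_value = p)
}

#' Normality-gated group comparison
#'
#' Per-group Shapiro-Wilk at `alpha`; when every group is consistent with
#' normality: unpaired two-tailed Student t test (2 groups) or one-way ANOVA
#' with Tukey HSD post hoc (3 or more). When any group departs from
#' normality (or a group is too small to test, n < 3): exact-where-possible
#' Mann-Whitney (2 groups) or Kruskal-Wallis with Dunn post hoc. Only the
#' within-family post hoc correction is applied; no correction is made
#' across metrics.
#'
#' @param data data.frame with the response and a group column.
#' @param metric name of the response column.
#' @param group_col name of the grouping column.
#' @param alpha significance level (default 0.05).
#' @param force optionally force `"parametric"` or `"nonparametric"`.
#' @return a `group_stats_result` list: per-group summaries (n, mean, SEM,
#'   median and its exact 95% CI, Shapiro p), chosen test, statistic,
#'   p value(s), pairwise table where applicable, significance flags.
#' @export
group_compare <- function(data, metric, group_col = "group", alpha = 0.05,
                          force = NULL) {
  stopifnot(metric %in% names(data), group_col %in% names(data))
  values <- data[[metric]]
  groups <- factor(data[[group_col]])
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(groups[ok])
  g <- levels(groups)
  if (length(g) < 2L) stop("need at least two groups")
  n <- tapply(values, groups, length)
  if (any(n < 2L)) stop("every group needs at least two observations")

  per_group <- do.call(rbind, lapply(g, function(gr) {
    x <- values[groups == gr]
    ci <- median_ci(x)
    sw <- if (length(x) >= 3L && sd(x) > 0)
      shapiro.test(x)$p.value else NA_real_
    data.frame(group = gr, n = length(x), mean = mean(x),
               sem = sd(x) / sqrt(length(x)), median = ci$median,
               median_ci_lower = ci$lower, median_ci_upper = ci$upper,
               shapiro_p = sw)
  }))

  normal <- if (!is.null(force)) force == "parametric"
            else all(is.na(per_group$shapiro_p) | per_group$shapiro_p > alpha) &&
                 !any(n < 3L)

  pairwise <- NULL
  if (length(g) == 2L) {
    x <- values[groups == g[1L]]
    y <- values[groups == g[2L]]
    if (normal) {
      tt <- t.test(x, y, var.equal = TRUE)
      test <- "t"
      statistic <- unname(tt$statistic)
      p <- tt$p.value
    } else {
      wt <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
      test <- "MannWhitney"
      statistic <- unname(wt$statistic)
      p <- wt$p.value
    }
  } else {
    if (normal) {
      df <- data.frame(y = values, grp = groups)
      fit <- aov(y ~ grp, data = df)
      an <- summary(fit)[[1L]]
      test <- "ANOVA+Tukey"
      statistic <- an[["F value"]][1L]
      p <- an[["Pr(>F)"]][1L]
      tk <- TukeyHSD(fit)$grp
      nm <- strsplit(rownames(tk), "-", fixed = TRUE)
      pairwise <- data.frame(group1 = vapply(nm, `[`, "", 1L),
                             group2 = vapply(nm, `[`, "", 2L),
                             diff = tk[, "diff"], p_value = tk[, "p adj"],
                             row.names = NULL)
    } else {
      kw <- kruskal.test(values, groups)
      test <- "KruskalWallis+Dunn"
      statistic <- unname(kw$statistic)
      p <- kw$p.value
      pairwise <- dunn_test(values, groups)
    }
  }
  if (!is.null(pairwise)) pairwise$significant <- pairwise$p_value < alpha
  structure(list(metric = metric, groups = g, per_group = per_group,
                 test = test, statistic = statistic, p_value = p,
                 significant = p < alpha, pairwise = pairwise,
                 alpha = alpha, gate = if (normal) "parametric" else
                   "nonparametric"),
            class = "group_stats_result")
}

#' @export
print.group_stats_result <- function(x, ...) {
  cat(sprintf("<group_stats_result> %s: %s, statistic %.4g, p = %.4g%s\n",
              x$metric, x$test, x$statistic, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Normality-gated correlation
#'
#' Pearson when both variables are consistent with normality (Shapiro-Wilk
#' at `alpha`), Spearman otherwise.
#'
#' @param x,y paired finite observations, `n >= 3`.
#' @param alpha gate level.
#' @return list with `method`, `estimate`, `p_value`, `n`, `significant`.
#' @export
correlate <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("mismatched lengths")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  normal <- shapiro.test(x)$p.value > alpha && shapiro.test(y)$p.value > alpha
  method <- if (normal) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(method = method, estimate = unname(ct$estimate),
       p_value = ct$p.value, n = length(x),
       significant = ct$p.value < alpha)
}

#' Regional summary of islet, nerve and tissue metrics
#'
#' Computes, overall and per anatomical region, the headline volumetrics:
#' beta-cell volume as percent of tissue, islet density per mm^3, mean and
#' median islet volume, normalized insulin intensity (mean intensity over
#' islet voxels divided by a reference, by default the mean intensity over
#' the whole tissue), endocrine nerve volume per islet, endocrine and
#' exocrine nerve density (%), the four-bin volume distribution, the
#' innervated/non-innervated comparison and NF200-style intensity per islet
#' volume. Endocrine plus exocrine nerve volume always equals the total
#' nerve volume (conservation).
#'
#' @param islet_records records from [islet_nerve_distances()] (the
#'   intensity sum columns and `intra_islet_nerve_volume_um3` are used).
#' @param nerve_mask logical array of nerve foreground (or `NULL`).
#' @param tissue_mask logical array of tissue.
#' @param voxel_size_um numeric `(z, y, x)` in um.
#' @param region_mask optional integer array (1 duodenal / 2 splenic).
#' @param intensity_channel channel whose intensity is normalized
#'   (default insulin).
#' @param nerve_intensity_channel channel for per-islet-volume intensity
#'   (default nf200); skipped when absent from the records.
#' @param normalization_reference optional scalar reference intensity; when
#'   `NULL` the mean `intensity_channel` value over tissue is required via
#'   `tissue_mean_intensity`.
#' @param tissue_mean_intensity mean intensity of `intensity_channel` over
#'   the tissue (whole-pancreas normalization reference).
#' @param bin_edges islet volume bin edges.
#' @return a data.frame of class `region_summary`, one row per scope.
#' @export
region_summary <- function(islet_records, nerve_mask, tissue_mask,
                           voxel_size_um, region_mask = NULL,
                           intensity_channel = "insulin",
                           nerve_intensity_channel = "nf200",
                           normalization_reference = NULL,
                           tissue_mean_intensity = NULL,
                           bin_edges = c(1000, 50000, 500000)) {
  if (!any(tissue_mask)) stop("tissue volume must be positive")
  vox_vol <- prod(voxel_size_um)
  total_nerve_vol <- if (is.null(nerve_mask)) 0 else {
    stopifnot(identical(dim(nerve_mask), dim(tissue_mask)))
    sum(nerve_mask) * vox_vol
  }

  scope_row <- function(rec, tissue_vox, nerve_vox, scope) {
    tissue_vol <- tissue_vox * vox_vol
    nerve_vol <- nerve_vox * vox_vol
    n <- nrow(rec)
    islet_vol <- sum(rec$volume_um3)
    intra <- sum(rec$intra_islet_nerve_volume_um3)
    sum_col <- paste0("intensity_sum_", intensity_channel)
    mean_islet_int <- if (n > 0L && sum_col %in% names(rec))
      sum(rec[[sum_col]]) / (islet_vol / vox_vol) else NA_real_
    ref <- if (!is.null(normalization_reference)) normalization_reference
           else tissue_mean_intensity
    nf_col <- paste0("intensity_sum_", nerve_intensity_channel)
    vd <- if (n > 0L) volume_distribution(rec$volume_um3, bin_edges)
          else list(percent = rep(NA_real_, length(bin_edges) + 1L),
                    median_um3 = NA_real_)
    inn <- rec$volume_um3[rec$innervated %in% TRUE]
    non <- rec$volume_um3[rec$innervated %in% FALSE]
    exo_tissue <- tissue_vol - islet_vol
    out <- data.frame(
      scope = scope,
      tissue_volume_mm3 = tissue_vol / 1e9,
      n_islets = n,
      beta_volume_percent = 100 * islet_vol / tissue_vol,
      islets_per_mm3 = n / (tissue_vol / 1e9),
      mean_islet_volume_um3 = if (n > 0L) islet_vol / n else NA_real_,
      median_islet_volume_um3 = vd$median_um3,
      normalized_insulin_intensity = if (!is.null(ref) && is.finite(ref) &&
                                         ref > 0) mean_islet_int / ref
                                     else NA_real_,
      endocrine_nerve_volume_per_islet_um3 = if (n > 0L) intra / n else NA_real_,
      endocrine_nerve_volume_um3 = intra,
      exocrine_nerve_volume_um3 = nerve_vol - intra,
      endocrine_nerve_density_percent = if (islet_vol > 0) 100 * intra / islet_vol
                                        else NA_real_,
      exocrine_nerve_density_percent = if (exo_tissue > 0)
        100 * (nerve_vol - intra) / exo_tissue else NA_real_,
      pct_innervated = if (n > 0L) 100 * length(inn) / n else NA_real_,
      mean_volume_innervated_um3 = if (length(inn)) mean(inn) else NA_real_,
      mean_volume_not_innervated_um3 = if (length(non)) mean(non) else NA_real_,
      innervated_volume_share_pct = if (islet_vol > 0)
        100 * sum(inn) / islet_vol else NA_real_,
      nf200_intensity_per_islet_volume = if (n > 0L && nf_col %in% names(rec) &&
                                             islet_vol > 0)
        sum(rec[[nf_col]]) / islet_vol else NA_real_)
    for (i in seq_along(vd$percent))
      out[[paste0("volume_bin_pct_", i)]] <- vd$percent[i]
    out
  }

  rows <- scope_row(islet_records, sum(tissue_mask),
                    if (is.null(nerve_mask)) 0 else sum(nerve_mask), "total")
  if (!is.null(region_mask)) {
    for (rg in c(1L, 2L)) {
      rsel <- region_mask == rg
      if (!any(rsel & tissue_mask)) next
      rec <- islet_records[!is.na(islet_records$region) &
                           islet_records$region == rg, , drop = FALSE]
      nv <- if (is.null(nerve_mask)) 0 else sum(nerve_mask & rsel)
      rows <- rbind(rows, scope_row(rec, sum(tissue_mask & rsel), nv,
                                    c("duodenal", "splenic")[rg]))
    }
  }
  rownames(rows) <- NULL
  # conservation: endocrine + exocrine = total (whole-volume scope)
  stopifnot(abs(rows$endocrine_nerve_volume_um3[1L] +
                rows$exocrine_nerve_volume_um3[1L] - total_nerve_vol) <
              1e-6 * max(1, total_nerve_vol))
  class(rows) <- c("region_summary", "data.frame")
  rows
}
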