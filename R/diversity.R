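#' Shannon diversity per sample
#'
#' Shannon entropy \eqn{H = -\sum p_i \ln p_i} over the nonzero relative
#' abundances of each sample, in nats (natural log, the ecology-toolkit
#' default).
#'
#' @param x a [feature_table()] or count matrix (features x samples).
#' @return A tibble `sample_id`, `shannon`.
#' @export
shannon_index <- function(x) {
  m <- if (inherits(x, "feature_table")) x$counts else x
  if (any(colSums(m) == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "), call. = FALSE)
  }
  h <- vegan::diversity(t(m), index = "shannon")
  tibble::tibble(sample_id = colnames(m), shannon = unname(h))
}

#' Expected richness under rarefaction
#'
#' Expected number of features observed in a random subsample of `depth`
#' individuals drawn without replacement, by the exact hypergeometric
#' formula \eqn{E[S_n] = \sum_i [1 - C(N - N_i, n)/C(N, n)]}
#' (computed in log space by [vegan::rarefy()]).
#'
#' @param counts one sample's count vector.
#' @param depth subsample size, `1 <= depth <= sum(counts)`.
#' @return Expected richness (a single double).
#' @export
rarefaction_richness <- function(counts, depth) {
  n_total <- sum(counts)
  if (n_total == 0) stop("all-zero sample", call. = FALSE)
  if (depth < 1 || depth > n_total) {
    stop("`depth` must lie in [1, ", n_total, "]", call. = FALSE)
  }
  # vegan warns heuristically when no count equals 1; not relevant here
  as.numeric(suppressWarnings(
    vegan::rarefy(matrix(counts, nrow = 1), sample = depth)))
}

#' Rarefaction curves for every sample of a table
#'
#' @param x a [feature_table()] or count matrix.
#' @param depths integer vector of subsample sizes; depths exceeding a
#'   sample's total are skipped for that sample.
#' @return A tibble `sample_id`, `depth`, `richness`.
#' @export
rarefaction_curve <- function(x, depths = NULL) {
  m <- if (inherits(x, "feature_table")) x$counts else x
  if (is.null(depths)) {
    depths <- unique(round(seq(1, min(colSums(m)), length.out = 20)))
  }
  purrr::map_dfr(colnames(m), function(s) {
    tot <- sum(m[, s])
    d <- depths[depths <= tot]
    tibble::tibble(
      sample_id = s, depth = d,
      richness = vapply(d, function(n) rarefaction_richness(m[, s], n),
                        numeric(1))
    )
  })
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}. For a
#' [feature_table()] the dissimilarity is computed on per-sample
#' relative abundances so unequal sequencing depths do not masquerade as
#' community turnover; a plain matrix is used as given.
#'
#' @param x a [feature_table()] or a numeric matrix (features x samples).
#' @return A [stats::dist] object over samples.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "feature_table")) relative_abundance(x) else x
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  zero <- colSums(m) == 0
  if (sum(zero) >= 2) {
    stop("Bray-Curtis undefined between all-zero samples: ",
         paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
  }
  vegan::vegdist(t(m), method = "bray")
}

#' Principal coordinates analysis of a distance matrix
#'
#' Metric ordination by eigendecomposition of the Gower-centered matrix
#' \eqn{B = -\frac{1}{2} J D^2 J}. Coordinates are returned for the
#' positive-eigenvalue axes, each scaled by the square root of its
#' eigenvalue; negative eigenvalues (possible for semi-metric input such
#' as Bray-Curtis) are reported unaltered, with no Cailliez/Lingoes
#' correction. Axis signs are fixed so the largest-magnitude loading on
#' each axis is positive, making runs comparable.
#'
#' @param d a [stats::dist] or symmetric matrix of dissimilarities.
#' @return An object of class `pcoa_ord`: `points` (samples x axes),
#'   `eigenvalues` (all of them, decreasing), `prop_explained`
#'   (per positive axis, relative to the positive-eigenvalue total).
#' @export
pcoa_ordination <- function(d) {
  dm <- as.matrix(d)
  if (nrow(dm) < 3) stop("PCoA needs at least 3 samples", call. = FALSE)
  if (max(abs(dm - t(dm))) > 1e-8) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  fit <- ape::pcoa(stats::as.dist(dm))
  ev <- fit$values$Eigenvalues
  pts <- as.matrix(fit$vectors)
  # deterministic sign: largest-magnitude loading of each axis positive
  for (j in seq_len(ncol(pts))) {
    k <- which.max(abs(pts[, j]))
    if (pts[k, j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("axis", seq_len(ncol(pts)))
  pos <- ev[ev > 0]
  structure(list(
    points = pts,
    eigenvalues = ev,
    prop_explained = pos / sum(pos),
    sample_ids = rownames(dm)
  ), class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat(sprintf("<pcoa_ord> %d samples, %d positive axes", nrow(x$points),
              ncol(x$points)))
  if (any(x$eigenvalues < 0)) {
    cat(sprintf(" (%d negative eigenvalues reported)",
                sum(x$eigenvalues < 0)))
  }
  cat(sprintf("\naxis 1-2 explain %.1f%% + %.1f%%\n",
              100 * x$prop_explained[1], 100 * x$prop_explained[2]))
  invisible(x)
}

#' @export
tidy.pcoa_ord <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(x$points)),
                   tibble::as_tibble(x$points))
}

#' @export
glance.pcoa_ord <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$points),
    n_positive_axes = ncol(x$points),
    n_negative_eigenvalues = sum(x$eigenvalues < 0),
    prop_axis1 = x$prop_explained[1],
    prop_axis2 = x$prop_explained[2]
  )
}

#' @export
autoplot.pcoa_ord <- function(object, metadata = NULL, colour = NULL, ...) {
  df <- tidy.pcoa_ord(object)
  if (!is.null(metadata)) {
    df <- dplyr::left_join(df, metadata, by = "sample_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2))
  if (!is.null(colour) && colour %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(
    x = sprintf("PCo1 (%.1f%%)", 100 * object$prop_explained[1]),
    y = sprintf("PCo2 (%.1f%%)", 100 * object$prop_explained[2])
  ) + ggplot2::theme_minimal()
}

# pseudo-F and R2 from squared distances and a grouping, via the
# sums-of-squares identity SS = sum of squared pairwise distances / n
permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  a <- length(unique(groups))
  ss_among <- ss_total - ss_within
  f <- (ss_among / (a - 1)) / (ss_within / (n - a))
  c(f = f, r2 = ss_among / ss_total)
}

#' PERMANOVA: permutation test of group location on a distance matrix
#'
#' Partitions the total sum of squared dissimilarities into among- and
#' within-group components (the ADONIS decomposition) and assesses the
#' pseudo-F statistic against free permutations of the sample labels:
#' \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})}.
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix.
#' @param groups group label per sample (length = number of samples).
#' @param n_perm number of label permutations (default 999).
#' @param seed optional integer seed for the permutation stream.
#' @return An object of class `permanova` with `f`, `r2`, `p_value`,
#'   `n_perm`, `seed`, `df_among`, `df_within`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  dm <- as.matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(dm)) {
    stop("`groups` length must match the number of samples", call. = FALSE)
  }
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop("group(s) of size 1: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  d2 <- dm^2
  obs <- permanova_f(d2, groups)
  perm_f <- withr::with_seed(
    if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed,
    vapply(seq_len(n_perm), function(i) {
      permanova_f(d2, sample(groups))[["f"]]
    }, numeric(1))
  )
  p <- (1 + sum(perm_f >= obs[["f"]])) / (1 + n_perm)
  structure(list(
    f = obs[["f"]], r2 = obs[["r2"]], p_value = p,
    n_perm = n_perm, seed = seed,
    df_among = length(sizes) - 1, df_within = nrow(dm) - length(sizes)
  ), class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F(%d, %d) = %.3f, R2 = %.3f, p = %.4g (%d perms)\n",
    x$df_among, x$df_within, x$f, x$r2, x$p_value, x$n_perm))
  invisible(x)
}

#' @export
tidy.permanova <- function(x, ...) {
  tibble::tibble(
    term = "groups", df = x$df_among, pseudo_f = x$f, r_squared = x$r2,
    p_value = x$p_value
  )
}

#' @export
glance.permanova <- function(x, ...) {
  tibble::tibble(pseudo_f = x$f, r_squared = x$r2, p_value = x$p_value,
                 n_perm = x$n_perm)
}
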