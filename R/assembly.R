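#' Patristic (cophenetic) distances between tree tips
#'
#' Sum of branch lengths along the path between every pair of tips;
#' the substrate for beta-MNTD.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @return Symmetric matrix of tip-pair distances with zero diagonal.
#' @export
cophenetic_distances <- function(tree) {
  validate_phylogeny(tree)
  ape::cophenetic.phylo(tree)
}

# beta-MNTD between two named abundance vectors (reference form, used
# directly for single pairs and as the oracle target in tests)
beta_mntd_pair <- function(xa, xb, d, weighted = TRUE) {
  ta <- names(xa)[xa > 0]
  tb <- names(xb)[xb > 0]
  if (!length(ta) || !length(tb)) {
    stop("each sample needs at least one taxon present", call. = FALSE)
  }
  missing <- setdiff(c(ta, tb), rownames(d))
  if (length(missing)) {
    stop("taxa missing from the distance matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  dab <- d[ta, tb, drop = FALSE]
  min_a <- apply(dab, 1, min)   # nearest taxon in b for each taxon of a
  min_b <- apply(dab, 2, min)
  if (weighted) {
    f <- xa[ta] / sum(xa[ta])
    g <- xb[tb] / sum(xb[tb])
  } else {
    f <- rep(1 / length(ta), length(ta))
    g <- rep(1 / length(tb), length(tb))
  }
  0.5 * (sum(f * min_a) + sum(g * min_b))
}

# all-pairs beta-MNTD via the identity
#   B[a,b] = 1/2 (G[a,b] + G[b,a]),  G = t(F) %*% M
# where M[i,s] = min distance from taxon i to any taxon present in
# sample s and F holds the (abundance or uniform) weights; avoids the
# per-pair submatrix work inside null-model loops
beta_mntd_matrix <- function(m, d, weighted = TRUE) {
  pres <- m > 0
  if (any(colSums(pres) == 0)) {
    stop("sample(s) with no taxa present: ",
         paste(colnames(m)[colSums(pres) == 0], collapse = ", "),
         call. = FALSE)
  }
  M <- vapply(seq_len(ncol(m)), function(s) {
    cols <- which(pres[, s])
    if (length(cols) == 1L) d[, cols]
    else apply(d[, cols, drop = FALSE], 1, min)
  }, numeric(nrow(m)))
  f <- if (weighted) {
    sweep(m, 2, colSums(m), "/")
  } else {
    sweep(pres + 0, 2, colSums(pres), "/")
  }
  g <- crossprod(f, M)
  b <- 0.5 * (g + t(g))
  dimnames(b) <- list(colnames(m), colnames(m))
  b
}

#' Beta mean nearest taxon distance
#'
#' For a pair of samples, the mean phylogenetic distance from each taxon
#' of one sample to its nearest taxon in the other, averaged over both
#' directions:
#' \eqn{\beta MNTD = \frac{1}{2}[\sum_i f_i \min_j d_{ij} +
#' \sum_j g_j \min_i d_{ij}]}, with weights \eqn{f, g} the relative
#' abundances among present taxa (`weighted = TRUE`, the default) or
#' uniform over present taxa. A taxon present in both samples is its own
#' nearest taxon, contributing distance 0.
#'
#' @param x a [feature_table()] or abundance matrix (taxa x samples),
#'   or a single sample's named abundance vector when `y` is given.
#' @param d tip distance matrix from [cophenetic_distances()], covering
#'   every taxon of `x`.
#' @param weighted abundance-weight the means? Default `TRUE`.
#' @param y optional second named abundance vector.
#' @return A [stats::dist] over samples, or a single number when `x`
#'   and `y` are vectors.
#' @export
beta_mntd <- function(x, d, weighted = TRUE, y = NULL) {
  if (!is.null(y)) return(beta_mntd_pair(x, y, d, weighted))
  m <- if (inherits(x, "feature_table")) x$counts else x
  missing <- setdiff(rownames(m), rownames(d))
  if (length(missing)) {
    stop("taxa missing from the distance matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  d <- d[rownames(m), rownames(m)]
  stats::as.dist(beta_mntd_matrix(m, d, weighted))
}

# all permutations of 1..n in lexicographic order (n small)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Beta nearest taxon index against a tip-shuffle null
#'
#' Standardized effect size of beta-MNTD:
#' \eqn{\beta NTI = (\beta MNTD_{obs} - \overline{\beta MNTD}_{null}) /
#' sd(\beta MNTD_{null})}, where each null replicate shuffles the tip
#' labels of the phylogenetic distance matrix uniformly at random (the
#' canonical "taxa labels" null: it breaks the phylogeny-abundance
#' association while preserving both marginal structures). One shuffle
#' is reused across all sample pairs per replicate. `|betaNTI| > 2` is
#' conventionally read as deterministic selection.
#'
#' `mode = "exhaustive"` enumerates every tip permutation instead of
#' sampling (factorially expensive; allowed up to 8 tips) and returns
#' the exact null mean and standard deviation.
#'
#' @param x a [feature_table()] or abundance matrix (taxa x samples).
#' @param tree an [ape::phylo] whose tips cover the table's features;
#'   table and tree are pruned to their shared taxa with a message.
#' @param reps null replicates (default 999).
#' @param weighted abundance-weighted beta-MNTD? Default `TRUE`.
#' @param seed optional integer seed.
#' @param mode `"sampled"` (default) or `"exhaustive"`.
#' @return An object of class `beta_nti`: matrices `bnti`, `bmntd_obs`,
#'   `null_mean`, `null_sd`, plus `reps`, `weighted`, `mode`, `seed`,
#'   `n_dropped` (features absent from the tree).
#' @export
beta_nti <- function(x, tree, reps = 999, weighted = TRUE, seed = NULL,
                     mode = c("sampled", "exhaustive")) {
  mode <- match.arg(mode)
  if (mode == "sampled" && reps < 2) stop("reps must be >= 2", call. = FALSE)
  m <- if (inherits(x, "feature_table")) x$counts else x
  shared <- intersect(rownames(m), tree$tip.label)
  n_dropped <- nrow(m) - length(shared)
  if (!length(shared)) stop("no shared taxa between table and tree",
                            call. = FALSE)
  if (n_dropped > 0 || length(tree$tip.label) > length(shared)) {
    message(sprintf(
      "beta_nti: dropped %d table feature(s) absent from tree; tree pruned %d -> %d tips",
      n_dropped, length(tree$tip.label), length(shared)))
    tree <- ape::keep.tip(tree, shared)
    m <- m[intersect(rownames(m), shared), , drop = FALSE]
  }
  d <- cophenetic_distances(tree)
  d <- d[rownames(m), rownames(m)]
  obs <- beta_mntd_matrix(m, d, weighted)
  nt <- nrow(d)
  ns <- ncol(m)
  ut <- upper.tri(obs)

  one_null <- function(perm) {
    dp <- d[perm, perm]
    dimnames(dp) <- dimnames(d)
    beta_mntd_matrix(m, dp, weighted)[ut]
  }
  if (mode == "exhaustive") {
    if (nt > 8) stop("exhaustive mode supports at most 8 tips", call. = FALSE)
    perms <- all_permutations(nt)
    nulls <- t(apply(perms, 1, one_null))
    if (sum(ut) == 1) nulls <- matrix(as.numeric(nulls), ncol = 1)
  } else {
    nulls <- withr::with_seed(
      if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed,
      t(vapply(seq_len(reps), function(r) one_null(sample.int(nt)),
               numeric(sum(ut))))
    )
    if (sum(ut) == 1) nulls <- matrix(as.numeric(nulls), ncol = 1)
  }
  mu <- colMeans(nulls)
  # exhaustive enumeration IS the null distribution: population sd;
  # sampled mode estimates it: sample sd
  sdev <- if (mode == "exhaustive") {
    apply(nulls, 2, function(v) sqrt(mean((v - mean(v))^2)))
  } else {
    apply(nulls, 2, stats::sd)
  }
  z <- (obs[ut] - mu) / sdev
  degenerate <- sdev == 0
  if (any(degenerate)) {
    warning(sprintf(
      "beta_nti: %d pair(s) with zero null variance reported as NA",
      sum(degenerate)), call. = FALSE)
    z[degenerate] <- NA_real_
  }
  shape <- function(v) {
    out <- matrix(NA_real_, ns, ns, dimnames = dimnames(obs))
    out[upper.tri(out)] <- v
    out[lower.tri(out)] <- t(out)[lower.tri(out)]
    out
  }
  structure(list(
    bnti = shape(z), bmntd_obs = obs, null_mean = shape(mu),
    null_sd = shape(sdev),
    reps = if (mode == "exhaustive") nrow(nulls) else reps,
    weighted = weighted, mode = mode, seed = seed, n_dropped = n_dropped
  ), class = "beta_nti")
}

#' @export
print.beta_nti <- function(x, ...) {
  v <- x$bnti[upper.tri(x$bnti)]
  cat(sprintf(
    "<beta_nti> %d samples, %d pairs (%s null, %d reps, %s)\n",
    nrow(x$bnti), length(v), x$mode, x$reps,
    if (x$weighted) "abundance-weighted" else "unweighted"))
  ok <- v[!is.na(v)]
  if (length(ok)) {
    cat(sprintf("betaNTI range %.2f .. %.2f; %.1f%% within (-2, 2)\n",
                min(ok), max(ok), 100 * mean(abs(ok) < 2)))
  }
  invisible(x)
}

#' @export
tidy.beta_nti <- function(x, ...) {
  ids <- rownames(x$bnti)
  idx <- which(upper.tri(x$bnti), arr.ind = TRUE)
  tibble::tibble(
    sample_i = ids[idx[, 1]], sample_j = ids[idx[, 2]],
    bmntd_obs = x$bmntd_obs[idx], null_mean = x$null_mean[idx],
    null_sd = x$null_sd[idx], bnti = x$bnti[idx]
  )
}

#' @export
glance.beta_nti <- function(x, ...) {
  v <- x$bnti[upper.tri(x$bnti)]
  ok <- v[!is.na(v)]
  tibble::tibble(
    n_pairs = length(v), n_missing = sum(is.na(v)),
    bnti_min = min(ok), bnti_max = max(ok),
    pct_stochastic = 100 * mean(abs(ok) < 2), reps = x$reps
  )
}

#' Boxplot of betaNTI by stage pairing
#'
#' @param object a `beta_nti` object.
#' @param metadata optional metadata with `sample_id`, `stage`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.beta_nti <- function(object, metadata = NULL, ...) {
  df <- tidy.beta_nti(object)
  df$pairing <- "all"
  if (!is.null(metadata) && "stage" %in% names(metadata)) {
    si <- metadata$stage[match(df$sample_i, metadata$sample_id)]
    sj <- metadata$stage[match(df$sample_j, metadata$sample_id)]
    df$pairing <- ifelse(si == sj, si, "cross")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pairing, y = .data$bnti)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "betaNTI") +
    ggplot2::theme_minimal()
}

# one Raup-Crick null community: keep the sample's richness and total,
# draw identities by occupancy, seed each species with one individual,
# fill up by metacommunity relative abundance; integer taxon ids
rc_null_sample <- function(richness, total, occupancy, abund_w) {
  ids <- sample.int(length(occupancy), richness, prob = occupancy)
  counts <- rep(1, richness)
  extra <- total - richness
  if (extra > 0) {
    counts <- counts + stats::rmultinom(1, extra, prob = abund_w[ids])[, 1]
  }
  list(ids = ids, counts = counts / total)
}

#' Abundance-based Raup-Crick (Bray-Curtis) null deviation
#'
#' For each sample pair, compares the observed Bray-Curtis dissimilarity
#' (on relative abundances) with its distribution under probabilistic
#' assembly from the table-wide species pool: each null community keeps
#' the sample's observed richness and total count, draws species
#' identities without replacement with probability proportional to
#' occupancy (number of samples occupied), seeds each drawn species with
#' one individual and distributes the remaining individuals
#' multinomially in proportion to the species' summed relative abundance
#' across samples. The score
#' \eqn{RC_{bray} = 2[(\#null < obs) + 0.5(\#null = obs)]/reps - 1}
#' lies in \eqn{[-1, 1]}: positive means the pair is more dissimilar
#' than chance assembly predicts (dispersal limitation territory),
#' negative more similar (homogenizing dispersal). Ties on the
#' Bray-Curtis statistic are counted at half weight under exact float
#' equality, not perturbed.
#'
#' @param x a [feature_table()] or count matrix (the species pool is the
#'   table's full feature set).
#' @param reps null replicates (default 999).
#' @param seed optional integer seed.
#' @return A [stats::dist] of RC values over samples.
#' @export
raup_crick <- function(x, reps = 999, seed = NULL) {
  m <- if (inherits(x, "feature_table")) x$counts else x
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(colSums(m) == 0)) {
    stop("sample(s) with zero richness: ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "), call. = FALSE)
  }
  occupancy <- rowSums(m > 0)
  abund_w <- rowSums(relative_abundance(m))
  richness <- colSums(m > 0)
  totals <- colSums(m)
  ns <- ncol(m)
  nt <- nrow(m)
  obs <- as.matrix(bray_curtis(relative_abundance(m)))
  rc <- matrix(0, ns, ns, dimnames = list(colnames(m), colnames(m)))
  scratch_a <- numeric(nt)
  scratch_b <- numeric(nt)
  withr::with_seed(
    if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed,
    for (i in seq_len(ns - 1)) {
      for (j in (i + 1):ns) {
        null_bc <- vapply(seq_len(reps), function(r) {
          a <- rc_null_sample(richness[i], totals[i], occupancy, abund_w)
          b <- rc_null_sample(richness[j], totals[j], occupancy, abund_w)
          scratch_a[a$ids] <- a$counts
          scratch_b[b$ids] <- b$counts
          bc <- sum(abs(scratch_a - scratch_b)) /
            sum(scratch_a + scratch_b)
          scratch_a[a$ids] <- 0
          scratch_b[b$ids] <- 0
          bc
        }, numeric(1))
        score <- (sum(null_bc < obs[i, j]) +
                    0.5 * sum(null_bc == obs[i, j])) / reps
        rc[i, j] <- rc[j, i] <- 2 * score - 1
      }
    }
  )
  stats::as.dist(rc)
}

#' Five-way ecological process classification of sample pairs
#'
#' Applies the standard betaNTI / RC decision rules in order:
#' heterogeneous selection (betaNTI > 2); homogeneous selection
#' (betaNTI < -2); then, within the stochastic band, dispersal
#' limitation (RC > 0.95), homogenizing dispersal (RC < -0.95), and
#' otherwise undominated. All comparisons are strict, so a value exactly
#' at a threshold falls through to the weaker side (a pair at
#' betaNTI = 2 is not called selection; a pair at |RC| = 0.95 is
#' undominated). Pairs with missing betaNTI (degenerate null) get `NA`
#' and are excluded from fractions.
#'
#' @param bnti a `beta_nti` object, or a symmetric matrix of betaNTI
#'   values.
#' @param rc a [stats::dist] or matrix from [raup_crick()].
#' @return A tibble `sample_i`, `sample_j`, `bnti`, `rc_bray`,
#'   `process`.
#' @export
classify_processes <- function(bnti, rc) {
  bm <- if (inherits(bnti, "beta_nti")) bnti$bnti else as.matrix(bnti)
  rm_ <- as.matrix(rc)
  if (!identical(dim(bm), dim(rm_))) {
    stop("betaNTI and RC matrices are not conformable", call. = FALSE)
  }
  rm_ <- rm_[rownames(bm), colnames(bm)]
  idx <- which(upper.tri(bm), arr.ind = TRUE)
  b <- bm[idx]
  r <- rm_[idx]
  process <- dplyr::case_when(
    is.na(b) ~ NA_character_,
    b > 2 ~ "heterogeneous selection",
    b < -2 ~ "homogeneous selection",
    r > 0.95 ~ "dispersal limitation",
    r < -0.95 ~ "homogenizing dispersal",
    .default = "undominated"
  )
  if (anyNA(process)) {
    message(sprintf(
      "classify_processes: %d pair(s) with missing betaNTI excluded",
      sum(is.na(process))))
  }
  tibble::tibble(
    sample_i = rownames(bm)[idx[, 1]],
    sample_j = colnames(bm)[idx[, 2]],
    bnti = b, rc_bray = r, process = process
  )
}

process_levels <- c("heterogeneous selection", "homogeneous selection",
                    "dispersal limitation", "homogenizing dispersal",
                    "undominated")

#' Group-level ecological process fractions
#'
#' Fraction of sample pairs assigned to each of the five processes,
#' within each pairing stratum. With stage metadata, strata are the
#' within-stage pairings (both samples in S1, both in S2, ...) plus
#' `"cross"` for between-stage pairs; an `"all"` stratum over every pair
#' is always emitted, since either view may be the relevant summary.
#' Fractions sum to 1 within each stratum that has pairs.
#'
#' @param processes tibble from [classify_processes()].
#' @param metadata optional sample metadata with `sample_id` and
#'   `stage`.
#' @return A tibble `pairing`, `process`, `n`, `fraction`.
#' @export
process_fractions <- function(processes, metadata = NULL) {
  df <- processes[!is.na(processes$process), ]
  df$pairing <- rep("all", nrow(df))
  if (!is.null(metadata) && "stage" %in% names(metadata) && nrow(df)) {
    si <- metadata$stage[match(df$sample_i, metadata$sample_id)]
    sj <- metadata$stage[match(df$sample_j, metadata$sample_id)]
    staged <- df
    staged$pairing <- as.character(ifelse(si == sj, si, "cross"))
    df <- dplyr::bind_rows(df, staged)
  }
  df$process <- factor(df$process, levels = process_levels)
  out <- df |>
    dplyr::count(.data$pairing, .data$process, .drop = FALSE) |>
    dplyr::group_by(.data$pairing) |>
    dplyr::mutate(fraction = .data$n / max(sum(.data$n), 1L)) |>
    dplyr::ungroup()
  out$process <- as.character(out$process)
  out
}

#' Stacked bar chart of ecological process fractions
#'
#' @param fractions tibble from [process_fractions()].
#' @return A ggplot object.
#' @export
plot_process_fractions <- function(fractions) {
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$pairing, y = .data$fraction,
                               fill = .data$process)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of sample pairs",
                  fill = "assembly process") +
    ggplot2::theme_minimal()
}
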