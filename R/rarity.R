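#' Rarity category of one feature's abundance profile
#'
#' Classifies a feature from its per-sample relative abundances into one
#' of six categories defined by two thresholds, `low` (default 0.01%)
#' and `high` (default 1%):
#'
#' * **AAT** always abundant: above `high` in every sample;
#' * **CAT** conditionally abundant: above `high` in some samples, never
#'   below `low`, not always above `high`;
#' * **CRAT** conditionally rare and abundant: spans both extremes
#'   (above `high` somewhere and below `low` somewhere);
#' * **ART** always rare: below `low` in every sample;
#' * **CRT** conditionally rare: below `low` in some samples, never
#'   above `high`, not always below `low`;
#' * **MT** moderate: strictly between the thresholds in every sample.
#'
#' All comparisons are strict, so a value exactly at a threshold counts
#' as neither "high" nor "low" — it falls in the moderate band. This is
#' the only boundary convention under which the six categories form an
#' exhaustive, mutually exclusive partition.
#'
#' @param p numeric vector of relative abundances in `[0, 1]`.
#' @param low,high rarity thresholds as fractions; `low < high`.
#' @return A single category string.
#' @examples
#' classify_rarity_profile(c(0.02, 0.03, 0.05))   # AAT
#' classify_rarity_profile(c(5e-5, 0.015, 0.002)) # CRAT
#' @export
classify_rarity_profile <- function(p, low = 1e-4, high = 1e-2) {
  if (!length(p)) stop("empty abundance profile", call. = FALSE)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("relative abundances must lie in [0, 1]", call. = FALSE)
  }
  if (low >= high) stop("`low` must be below `high`", call. = FALSE)
  hi <- p > high
  lo <- p < low
  if (all(hi)) return("AAT")
  if (all(lo)) return("ART")
  if (any(hi) && any(lo)) return("CRAT")
  if (any(hi)) return("CAT")
  if (any(lo)) return("CRT")
  "MT"
}

#' Coarse abundance group of a rarity category
#'
#' AAT/CAT/CRAT are the abundant group, ART/CRT the rare group, MT the
#' moderate group.
#'
#' @param category character vector of category codes.
#' @return Character vector in `{"abundant", "rare", "moderate"}`.
#' @export
rarity_group <- function(category) {
  out <- rep(NA_character_, length(category))
  out[category %in% c("AAT", "CAT", "CRAT")] <- "abundant"
  out[category %in% c("ART", "CRT")] <- "rare"
  out[category == "MT"] <- "moderate"
  if (anyNA(out)) {
    stop("unknown category: ",
         paste(unique(category[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Classify every feature of a table into rarity categories
#'
#' @param x a [feature_table()] or a relative-abundance matrix from
#'   [relative_abundance()].
#' @param low,high thresholds as fractions (defaults 0.01% and 1%).
#' @return A tibble with one row per feature: `feature_id`, `category`,
#'   `group`, `min_ra`, `max_ra`, plus the thresholds as attributes
#'   `low` / `high`.
#' @export
classify_rarity <- function(x, low = 1e-4, high = 1e-2) {
  ra <- if (inherits(x, "feature_table")) relative_abundance(x) else x
  cats <- vapply(seq_len(nrow(ra)),
                 function(i) classify_rarity_profile(ra[i, ], low, high),
                 character(1))
  out <- tibble::tibble(
    feature_id = rownames(ra),
    category = cats,
    group = rarity_group(cats),
    min_ra = apply(ra, 1, min),
    max_ra = apply(ra, 1, max)
  )
  attr(out, "low") <- low
  attr(out, "high") <- high
  out
}

#' Per-category feature counts
#'
#' @param assignment tibble from [classify_rarity()].
#' @return A tibble `category`, `n` covering all six categories (zero
#'   rows included).
#' @export
rarity_counts <- function(assignment) {
  lv <- c("AAT", "CAT", "CRAT", "ART", "CRT", "MT")
  tab <- table(factor(assignment$category, levels = lv))
  tibble::tibble(category = lv, n = as.integer(tab))
}

#' Per-sample abundance fractions of the rarity groups
#'
#' For each sample, the summed relative abundance of the abundant, rare
#' and moderate groups; the three fractions sum to 1.
#'
#' @param x a [feature_table()] or relative-abundance matrix.
#' @param assignment tibble from [classify_rarity()] covering every
#'   feature of `x`.
#' @return A long tibble `sample_id`, `group`, `fraction`.
#' @export
group_fractions <- function(x, assignment) {
  ra <- if (inherits(x, "feature_table")) relative_abundance(x) else x
  missing <- setdiff(rownames(ra), assignment$feature_id)
  if (length(missing)) {
    stop("feature(s) without rarity assignment: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  grp <- assignment$group[match(rownames(ra), assignment$feature_id)]
  groups <- c("abundant", "rare", "moderate")
  sums <- rowsum(ra, group = factor(grp, levels = groups))
  # rowsum drops empty levels; rebuild a complete 3 x samples matrix
  full <- matrix(0, nrow = 3, ncol = ncol(ra),
                 dimnames = list(groups, colnames(ra)))
  full[rownames(sums), ] <- sums
  tibble::tibble(
    sample_id = rep(colnames(ra), each = 3),
    group = rep(groups, times = ncol(ra)),
    fraction = as.numeric(full)
  )
}

#' Subset a feature table to one rarity group
#'
#' Convenience used throughout the pipeline: the abundant and rare
#' sub-communities are analyzed separately (diversity, networks,
#' assembly inference).
#'
#' @param x a [feature_table()].
#' @param assignment tibble from [classify_rarity()].
#' @param group one of `"abundant"`, `"rare"`, `"moderate"`, or a vector
#'   of several.
#' @return A [feature_table()] restricted to the group's features.
#' @export
subset_group <- function(x, assignment, group) {
  keep <- assignment$feature_id[assignment$group %in% group]
  subset_table(x, features = intersect(rownames(x$counts), keep))
}

#' Stacked per-sample composition of rarity groups
#'
#' @param fractions tibble from [group_fractions()].
#' @param metadata optional sample metadata with `day`; when present,
#'   samples are ordered by day on the x axis.
#' @return A ggplot object.
#' @export
plot_group_fractions <- function(fractions, metadata = NULL) {
  df <- fractions
  if (!is.null(metadata) && "day" %in% names(metadata)) {
    ord <- metadata$sample_id[order(metadata$day)]
    df$sample_id <- factor(df$sample_id, levels = unique(ord))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative abundance", fill = "group") +
    ggplot2::theme_minimal()
}
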