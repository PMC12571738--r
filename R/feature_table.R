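#' Construct a validated feature count table
#'
#' The central data container of the package: an integer count matrix
#' (features in rows, samples in columns) together with a per-sample
#' metadata tibble. All downstream analyses (rarity classification,
#' diversity, networks, assembly inference) consume this object.
#'
#' @param counts numeric matrix of non-negative integer counts,
#'   features x samples, with unique row and column names.
#' @param metadata optional tibble with one row per sample and at least a
#'   `sample_id` column; typical columns are `day` (integer, fermentation
#'   day), `batch` and `stage`. If `NULL`, a minimal metadata tibble
#'   holding only the sample ids is created.
#' @return An object of class `feature_table` with elements `counts`
#'   (integer matrix) and `metadata` (tibble).
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 3L, 1L, 4L), nrow = 3,
#'             dimnames = list(c("f1", "f2", "f3"), c("s1", "s2")))
#' ft <- feature_table(m)
#' ft
#' @export
feature_table <- function(counts, metadata = NULL) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have feature row names and sample column names",
         call. = FALSE)
  }
  dup_f <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_f)) {
    stop("duplicate feature id(s): ", paste(unique(dup_f), collapse = ", "),
         call. = FALSE)
  }
  dup_s <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_s)) {
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(counts)) stop("`counts` contains missing values", call. = FALSE)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at feature '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]),
         call. = FALSE)
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at feature '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]),
         call. = FALSE)
  }
  storage.mode(counts) <- "integer"

  if (is.null(metadata)) {
    metadata <- tibble::tibble(sample_id = colnames(counts))
  }
  metadata <- tibble::as_tibble(metadata)
  if (!"sample_id" %in% names(metadata)) {
    stop("metadata must contain a `sample_id` column", call. = FALSE)
  }
  missing_meta <- setdiff(colnames(counts), metadata$sample_id)
  if (length(missing_meta)) {
    stop("samples without metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ]

  empty <- colSums(counts) == 0
  if (any(empty)) {
    warning("sample(s) with all-zero counts: ",
            paste(colnames(counts)[empty], collapse = ", "), call. = FALSE)
  }

  structure(list(counts = counts, metadata = metadata),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples (total count %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.double(x$counts)), big.mark = ",")))
  meta_cols <- setdiff(names(x$metadata), "sample_id")
  if (length(meta_cols)) {
    cat("metadata: ", paste(meta_cols, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' Tidy long-format view of a feature table
#'
#' @param x a [feature_table()].
#' @param ... unused.
#' @return A tibble with columns `feature_id`, `sample_id`, `count`,
#'   joined with the sample metadata.
#' @export
as_tibble.feature_table <- function(x, ...) {
  long <- tibble::tibble(
    feature_id = rep(rownames(x$counts), times = ncol(x$counts)),
    sample_id  = rep(colnames(x$counts), each = nrow(x$counts)),
    count      = as.integer(x$counts)
  )
  dplyr::left_join(long, x$metadata, by = "sample_id")
}

#' Read a feature count table from TSV
#'
#' Expects a header row whose first field names the feature-id column
#' (conventionally `feature_id`) followed by sample ids, then one row per
#' feature with integer counts. Input order of features and samples is
#' preserved.
#'
#' @param path path to a tab-separated file.
#' @param metadata optional metadata tibble passed to [feature_table()].
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, metadata = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("feature table needs at least one sample column",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))),
                 arr.ind = TRUE)
    loc <- if (length(bad)) {
      sprintf(" (first offending cell: row '%s', column '%s')",
              ids[bad[1, 1]], colnames(m)[bad[1, 2]])
    } else ""
    stop("non-numeric cell(s) in feature table", loc, call. = FALSE)
  }
  rownames(m) <- ids
  feature_table(m, metadata = metadata)
}

#' Write a feature table to TSV
#'
#' Inverse of [read_feature_table()]: round-tripping is lossless.
#'
#' @param x a [feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  df <- tibble::tibble(feature_id = rownames(x$counts))
  df <- dplyr::bind_cols(df, tibble::as_tibble(x$counts))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a sample metadata table from TSV
#'
#' @param path TSV with columns `sample_id`, `day`, `batch` and
#'   optionally `stage`.
#' @param stage_map optional stage map (see [default_stage_map()]); when
#'   given, a `stage` column is derived from `day`.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path, stage_map = NULL) {
  md <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(md)) {
    stop("metadata must contain a `sample_id` column", call. = FALSE)
  }
  md$sample_id <- as.character(md$sample_id)
  if (!is.null(stage_map)) md <- assign_stages(md, stage_map)
  md
}

#' Default fermentation stage maps
#'
#' Stage boundaries differ between kingdoms: the fungal community
#' restructures within the first two days of fermentation while the
#' bacterial community turns over after day 5. Stages are configuration,
#' not inference; override by passing your own map (a named list of
#' `c(first_day, last_day)` ranges) to [assign_stages()].
#'
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @return Named list of inclusive day ranges.
#' @export
default_stage_map <- function(kingdom = c("bacteria", "fungi")) {
  kingdom <- match.arg(kingdom)
  switch(kingdom,
    bacteria = list(S1 = c(0, 5), S2 = c(7, 14)),
    fungi    = list(S1 = c(0, 1), S2 = c(2, 14))
  )
}

#' Assign fermentation stages to sample metadata from day ranges
#'
#' @param metadata tibble with a `day` column.
#' @param stage_map named list of inclusive `c(first, last)` day ranges.
#' @return `metadata` with a `stage` column.
#' @export
assign_stages <- function(metadata, stage_map) {
  if (!"day" %in% names(metadata)) {
    stop("metadata has no `day` column to derive stages from", call. = FALSE)
  }
  stage <- rep(NA_character_, nrow(metadata))
  for (s in names(stage_map)) {
    rng <- stage_map[[s]]
    hit <- metadata$day >= rng[1] & metadata$day <= rng[2]
    stage[hit & is.na(stage)] <- s
  }
  if (anyNA(stage)) {
    warning("day(s) not covered by the stage map: ",
            paste(unique(metadata$day[is.na(stage)]), collapse = ", "),
            call. = FALSE)
  }
  metadata$stage <- stage
  metadata
}

#' Per-sample relative abundances
#'
#' @param x a [feature_table()] or a non-negative count matrix.
#' @return A numeric matrix with the same dimnames whose columns each sum
#'   to 1.
#' @export
relative_abundance <- function(x) {
  m <- if (inherits(x, "feature_table")) x$counts else x
  tot <- colSums(m)
  if (any(tot == 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(m)[tot == 0], collapse = ", "), call. = FALSE)
  }
  sweep(m, 2, tot, "/")
}

#' Drop features below a global frequency threshold
#'
#' Removes features whose total count over all samples, as a fraction of
#' the table's grand total, falls below `threshold` (strictly below: a
#' feature sitting exactly at the threshold is retained). The default
#' 0.005% mirrors the conventional post-denoising table filter.
#'
#' @param x a [feature_table()].
#' @param threshold fraction of the grand total in `[0, 1)`; default
#'   `5e-5` (i.e. 0.005%).
#' @return A filtered [feature_table()]; a message reports the number of
#'   features removed.
#' @export
filter_min_frequency <- function(x, threshold = 5e-5) {
  stopifnot(inherits(x, "feature_table"))
  if (threshold < 0 || threshold >= 1) {
    stop("`threshold` must be in [0, 1)", call. = FALSE)
  }
  grand <- sum(as.double(x$counts))
  frac <- rowSums(x$counts) / grand
  keep <- frac >= threshold
  message(sprintf("filter_min_frequency: removed %d of %d features below %g",
                  sum(!keep), length(keep), threshold))
  if (!any(keep)) {
    warning("all features removed by frequency filter", call. = FALSE)
  }
  out <- x
  out$counts <- x$counts[keep, , drop = FALSE]
  out
}

#' Subset a feature table
#'
#' @param x a [feature_table()].
#' @param features,samples character vectors of ids (or logical/integer
#'   indices) to keep; `NULL` keeps all.
#' @return A [feature_table()].
#' @export
subset_table <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "feature_table"))
  counts <- x$counts
  if (!is.null(features)) counts <- counts[features, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  md <- x$metadata[x$metadata$sample_id %in% colnames(counts), ]
  suppressWarnings(feature_table(counts, md))
}

#' Read a taxonomy table from TSV
#'
#' Accepts either a `feature_id` column plus one column per rank
#' (kingdom ... species) or a two-column file whose second column is a
#' semicolon-delimited lineage string; the layout is auto-detected.
#' Missing or empty rank labels become `"unclassified"`.
#'
#' @param path TSV path.
#' @return A tibble with `feature_id` and rank columns.
#' @export
read_taxonomy <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  names(df)[1] <- "feature_id"
  df$feature_id <- as.character(df$feature_id)
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  if (ncol(df) == 2 && any(grepl(";", df[[2]], fixed = TRUE))) {
    parts <- strsplit(as.character(df[[2]]), ";", fixed = TRUE)
    mat <- t(vapply(parts, function(p) {
      p <- trimws(p)
      length(p) <- length(ranks)
      p
    }, character(length(ranks))))
    colnames(mat) <- ranks
    df <- dplyr::bind_cols(df["feature_id"], tibble::as_tibble(mat))
  } else {
    names(df) <- tolower(names(df))
  }
  for (r in setdiff(names(df), "feature_id")) {
    v <- as.character(df[[r]])
    v[is.na(v) | v == ""] <- "unclassified"
    df[[r]] <- v
  }
  df
}

#' Aggregate feature counts to a taxonomic rank
#'
#' Sums counts over features sharing a rank label. Features whose label at
#' `rank` is `"unclassified"` are kept apart by suffixing the deepest
#' classified rank above (e.g. `unclassified_Lactobacillaceae`), so
#' unrelated unclassified lineages are never merged. Per-sample totals
#' are conserved.
#'
#' @param x a [feature_table()].
#' @param taxonomy tibble from [read_taxonomy()] covering every feature.
#' @param rank rank column name, e.g. `"genus"`.
#' @return A [feature_table()] with one row per aggregated label.
#' @export
aggregate_by_rank <- function(x, taxonomy, rank = "genus") {
  stopifnot(inherits(x, "feature_table"))
  if (!rank %in% names(taxonomy)) {
    stop("rank '", rank, "' not found in taxonomy", call. = FALSE)
  }
  missing <- setdiff(rownames(x$counts), taxonomy$feature_id)
  if (length(missing)) {
    stop("feature(s) missing from taxonomy: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...", call. = FALSE)
  }
  tax <- taxonomy[match(rownames(x$counts), taxonomy$feature_id), ]
  ranks <- intersect(c("kingdom", "phylum", "class", "order", "family",
                       "genus", "species"), names(tax))
  idx <- match(rank, ranks)
  labels <- vapply(seq_len(nrow(tax)), function(i) {
    lab <- tax[[rank]][i]
    if (!identical(tolower(lab), "unclassified")) return(lab)
    above <- rev(ranks[seq_len(idx - 1)])
    for (r in above) {
      parent <- tax[[r]][i]
      if (!identical(tolower(parent), "unclassified")) {
        return(paste0("unclassified_", parent))
      }
    }
    "unclassified"
  }, character(1))
  agg <- rowsum(x$counts, group = labels, reorder = FALSE)
  feature_table(agg, metadata = x$metadata)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Thin validating wrapper around [ape::read.tree()]: requires unique tip
#' labels and non-negative branch lengths on every edge.
#'
#' @param path Newick file path.
#' @return An [ape::phylo] object.
#' @export
read_phylogeny <- function(path) {
  tree <- ape::read.tree(path)
  validate_phylogeny(tree)
}

#' @rdname read_phylogeny
#' @param tree an [ape::phylo] object to validate in place.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels in tree", call. = FALSE)
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("tree has negative branch lengths", call. = FALSE)
  }
  tree
}
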