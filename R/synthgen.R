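#' Simulate a Yule (pure-birth) phylogeny
#'
#' Exponential waiting times between speciation events (birth rate 1,
#' no extinction); tips are labeled `f0001`, `f0002`, ... so simulated
#' tables and trees share a namespace.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed; the same seed gives an identical tree.
#' @return An [ape::phylo] with positive branch lengths.
#' @export
simulate_tree <- function(n_tips, seed = 1) {
  stopifnot(n_tips >= 2)
  tree <- withr::with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tree$tip.label <- sprintf("f%04d", seq_len(n_tips))
  validate_phylogeny(tree)
}

#' Mock genus-level taxonomy for simulated features
#'
#' Randomly assigns features to `n_genera` mock genera nested in a
#' single mock kingdom/phylum lineage; enough structure to exercise
#' rank aggregation, nothing more.
#'
#' @param feature_ids character vector of feature ids.
#' @param n_genera number of genera to spread the features over.
#' @param seed integer seed.
#' @return A taxonomy tibble compatible with [aggregate_by_rank()].
#' @export
simulate_taxonomy <- function(feature_ids, n_genera = 25, seed = 1) {
  genus <- withr::with_seed(seed, sample(sprintf("g%03d", seq_len(n_genera)),
                                         length(feature_ids),
                                         replace = TRUE))
  tibble::tibble(
    feature_id = feature_ids,
    kingdom = "k1", phylum = "p1", class = "c1", order = "o1",
    family = paste0("fam_", substr(genus, 1, 4)), genus = genus,
    species = "unclassified"
  )
}

#' Parameters of a two-stage succession simulation
#'
#' Describes a solid-state-fermentation-like sampling design: samples
#' at days 0-5, 7, 9, 11 and 14 in two batches, a heavy-tailed
#' (log-normal) community in stage 1, and a takeover set of features
#' whose share ramps to dominance across stage 2, emulating the
#' *Lactobacillus*/*Saccharomyces* sweep typical of grain fermentation.
#'
#' @param n_features community size (default 190, a bacterial-like
#'   table; use ~500 for a fungal-like table).
#' @param days sampling days (default `c(0:5, 7, 9, 11, 14)`).
#' @param n_batches parallel fermentations (default 2).
#' @param depth reads per sample (default 20000).
#' @param stage2_start first day of stage 2 (default 7, the bacterial
#'   stage boundary; use 2 for a fungal-like community).
#' @param base_sdlog log-normal shape of base abundances (default 2.5:
#'   rare features dominate the feature count while a few features carry
#'   most reads).
#' @param n_takeover number of takeover features (default 1).
#' @param takeover_share total relative abundance the takeover set
#'   reaches by the final day (default 0.9).
#' @param stage_shift_sd per-feature log-scale perturbation between the
#'   stage-1 and stage-2 baseline compositions (default 1).
#' @param batch_sd per-batch log-scale noise (default 0.3).
#' @param seed integer seed.
#' @return A list of class `succession_scenario`.
#' @export
succession_scenario <- function(n_features = 190,
                                days = c(0:5, 7, 9, 11, 14),
                                n_batches = 2, depth = 20000,
                                stage2_start = 7, base_sdlog = 2.5,
                                n_takeover = 1, takeover_share = 0.9,
                                stage_shift_sd = 1, batch_sd = 0.3,
                                seed = 1) {
  stopifnot(n_features >= 2, n_batches >= 1, depth >= 1000,
            n_takeover >= 0, n_takeover < n_features,
            takeover_share > 0, takeover_share < 1)
  structure(list(
    n_features = n_features, days = days, n_batches = n_batches,
    depth = depth, stage2_start = stage2_start, base_sdlog = base_sdlog,
    n_takeover = n_takeover, takeover_share = takeover_share,
    stage_shift_sd = stage_shift_sd, batch_sd = batch_sd, seed = seed
  ), class = "succession_scenario")
}

#' Simulate a two-stage succession feature table
#'
#' Per-sample expected compositions are built from a log-normal stage-1
#' baseline, a perturbed stage-2 baseline, and a takeover set whose
#' share interpolates log-linearly from its stage-1 level to
#' `takeover_share` across stage 2; counts are multinomial draws at the
#' configured depth. Ground-truth rarity categories are computed from
#' the expected (not sampled) relative abundances, so sampling noise
#' near a threshold is measurable classifier error rather than label
#' noise.
#'
#' @param scenario a [succession_scenario()].
#' @return A list: `table` (a [feature_table()] with day/batch/stage
#'   metadata), `truth` (tibble `feature_id`, `category`, `group`),
#'   `expected` (expected relative-abundance matrix).
#' @export
simulate_succession <- function(scenario = succession_scenario()) {
  s <- scenario
  withr::with_seed(s$seed, {
    ids <- sprintf("f%04d", seq_len(s$n_features))
    base1 <- stats::rlnorm(s$n_features, meanlog = 0, sdlog = s$base_sdlog)
    base2 <- base1 * exp(stats::rnorm(s$n_features, 0, s$stage_shift_sd))
    takeover <- if (s$n_takeover > 0) {
      # take over from mid-rank: dominant late, unremarkable early
      order(base1, decreasing = TRUE)[ceiling(s$n_features / 4) +
                                        seq_len(s$n_takeover)]
    } else integer(0)
    batch_eff <- matrix(stats::rnorm(s$n_features * s$n_batches, 0,
                                     s$batch_sd),
                        s$n_features, s$n_batches)

    stage2_days <- s$days[s$days >= s$stage2_start]
    expected <- matrix(0, s$n_features, 0)
    sample_ids <- character(0)
    meta <- NULL
    for (b in seq_len(s$n_batches)) {
      for (d in s$days) {
        w <- if (d < s$stage2_start) base1 else base2
        w <- w * exp(batch_eff[, b])
        p <- w / sum(w)
        if (d >= s$stage2_start && length(takeover)) {
          # log-linear ramp of the takeover share across stage 2
          k <- match(d, stage2_days)
          p0 <- max(sum(p[takeover]), 1e-6)
          share <- exp(log(p0) + (log(s$takeover_share) - log(p0)) *
                         k / length(stage2_days))
          p[takeover] <- p[takeover] / sum(p[takeover]) * share
          p[-takeover] <- p[-takeover] / sum(p[-takeover]) * (1 - share)
        }
        expected <- cbind(expected, p)
        sample_ids <- c(sample_ids, sprintf("F%d_b%d", d, b))
        meta <- dplyr::bind_rows(meta, tibble::tibble(
          sample_id = sprintf("F%d_b%d", d, b), day = d,
          batch = paste0("b", b),
          stage = if (d < s$stage2_start) "S1" else "S2"
        ))
      }
    }
    dimnames(expected) <- list(ids, sample_ids)
    counts <- apply(expected, 2, function(p) {
      stats::rmultinom(1, s$depth, p)[, 1]
    })
    rownames(counts) <- ids
    truth <- classify_rarity(expected)
    list(
      table = feature_table(counts, metadata = meta),
      truth = truth[, c("feature_id", "category", "group")],
      expected = expected,
      takeover = ids[takeover]
    )
  })
}

#' Simulate a table with planted correlated feature blocks
#'
#' Features within a block share a latent per-sample log-abundance
#' factor (so their pairwise Spearman correlation approaches 1 as
#' `noise` approaches 0); members with `sign = -1` ride the negated
#' factor. Background features fluctuate independently. Counts are
#' multinomial at `depth`.
#'
#' @param n_features total features including background.
#' @param blocks list of blocks, each `list(size =, sign =)` with
#'   `sign` a vector of +/-1 per member (recycled); blocks occupy the
#'   first feature ids in order.
#' @param n_samples number of samples (default 20).
#' @param depth reads per sample (default 10000).
#' @param noise sd of independent log-noise on block members
#'   (default 0.1); the latent factor has sd `factor_sd`.
#' @param factor_sd sd of the shared latent factor (default 1.5).
#' @param seed integer seed.
#' @return A list: `table` (a [feature_table()]), `truth` (tibble
#'   `feature_id`, `block`, `sign`; block `NA` for background).
#' @export
simulate_correlated_block <- function(n_features, blocks, n_samples = 20,
                                      depth = 10000, noise = 0.1,
                                      factor_sd = 1.5, seed = 1) {
  sizes <- vapply(blocks, function(b) b$size, numeric(1))
  stopifnot(sum(sizes) <= n_features, n_samples >= 4)
  withr::with_seed(seed, {
    ids <- sprintf("f%04d", seq_len(n_features))
    block_id <- rep(NA_integer_, n_features)
    sign_of <- rep(1, n_features)
    at <- 1
    for (k in seq_along(blocks)) {
      members <- at:(at + blocks[[k]]$size - 1)
      block_id[members] <- k
      sgn <- blocks[[k]]$sign %||% 1
      sign_of[members] <- rep_len(sgn, length(members))
      at <- at + blocks[[k]]$size
    }
    # block members ride a higher baseline so anti-phase members never
    # bottom out at zero counts (which would destroy their rank signal)
    base <- stats::rnorm(n_features, mean = ifelse(is.na(block_id), 0, 2),
                         sd = 0.5)
    loga <- matrix(0, n_features, n_samples)
    factors <- matrix(stats::rnorm(length(blocks) * n_samples, 0,
                                   factor_sd),
                      length(blocks), n_samples)
    for (i in seq_len(n_features)) {
      eps <- stats::rnorm(n_samples, 0, if (is.na(block_id[i])) factor_sd
                          else noise)
      fac <- if (is.na(block_id[i])) 0
             else sign_of[i] * factors[block_id[i], ]
      loga[i, ] <- base[i] + fac + eps
    }
    w <- exp(loga)
    counts <- apply(w, 2, function(col) {
      stats::rmultinom(1, depth, col / sum(col))[, 1]
    })
    dimnames(counts) <- list(ids, sprintf("s%02d", seq_len(n_samples)))
    list(
      table = feature_table(counts),
      truth = tibble::tibble(feature_id = ids, block = block_id,
                             sign = ifelse(is.na(block_id), NA, sign_of))
    )
  })
}

#' Parameters of a known-process community assembly simulation
#'
#' Communities assembled under a declared ecological process, for
#' parameter-recovery testing of the betaNTI machinery:
#'
#' * `heterogeneous_selection` — the phylogeny is partitioned into
#'   `n_env` habitat clades (average-linkage clustering of patristic
#'   distances) and each sample is assembled strictly from its own
#'   habitat's clade, round-robin over habitats: different environments
#'   select different lineages, the textbook source of phylogenetic
#'   turnover exceeding the null;
#' * `homogeneous_selection` — every sample is assembled from the same
#'   (largest) habitat clade, so compositional turnover happens among
#'   close relatives only;
#' * `neutral_drift` — every sample is a multinomial draw from one
#'   shared, unfiltered species pool; composition varies by sampling
#'   drift alone.
#'
#' Within the permitted taxon set, expected abundances follow a
#' log-normal baseline shared by all samples; counts are multinomial at
#' `depth`. Strict (zero-outside-habitat) filtering is deliberate: a
#' single stray individual from another sample's clade would provide a
#' zero-distance nearest neighbour and erase the turnover signal the
#' scenario is meant to plant.
#'
#' @param process one of the three process labels above.
#' @param n_taxa pool size (default 30).
#' @param n_samples number of samples (default 8).
#' @param depth reads per sample (default 1000).
#' @param n_env number of habitat clades for heterogeneous selection
#'   (default 3).
#' @param pool_sdlog log-normal shape of baseline abundances
#'   (default 2: a few dominants, a flickering rare tail).
#' @param seed integer seed.
#' @return A list of class `assembly_scenario`.
#' @export
assembly_scenario <- function(process = c("heterogeneous_selection",
                                          "homogeneous_selection",
                                          "neutral_drift"),
                              n_taxa = 30, n_samples = 8, depth = 1000,
                              n_env = 3, pool_sdlog = 2, seed = 1) {
  process <- match.arg(process)
  stopifnot(n_taxa >= 4, n_samples >= 2, depth >= 100, n_env >= 2,
            n_env <= n_taxa / 2)
  structure(list(
    process = process, n_taxa = n_taxa, n_samples = n_samples,
    depth = depth, n_env = n_env, pool_sdlog = pool_sdlog, seed = seed
  ), class = "assembly_scenario")
}

#' Simulate a community assembled under a known process
#'
#' @param scenario an [assembly_scenario()].
#' @return A list: `table` (a [feature_table()]), `tree` (the Yule
#'   phylogeny), `process` (the generating label), `habitat_of_taxon`
#'   (clade membership), `habitat_of_sample` (NA under neutral drift).
#' @export
simulate_assembly <- function(scenario = assembly_scenario()) {
  s <- scenario
  tree <- simulate_tree(s$n_taxa, seed = s$seed)
  d <- cophenetic_distances(tree)
  withr::with_seed(s$seed + 1L, {
    base <- stats::rlnorm(s$n_taxa, meanlog = 0, sdlog = s$pool_sdlog)
    names(base) <- tree$tip.label
    clade <- stats::cutree(stats::hclust(stats::as.dist(d), "average"),
                           k = s$n_env)
    # largest habitats first so round-robin favors well-populated clades
    ranked <- order(tabulate(clade, s$n_env), decreasing = TRUE)
    habitat_of_sample <- switch(s$process,
      heterogeneous_selection = rep_len(ranked, s$n_samples),
      homogeneous_selection = rep(ranked[1], s$n_samples),
      neutral_drift = rep(NA_integer_, s$n_samples)
    )
    sample_ids <- sprintf("s%02d", seq_len(s$n_samples))
    counts <- vapply(seq_len(s$n_samples), function(j) {
      w <- if (s$process == "neutral_drift") base
      else base * (clade == habitat_of_sample[j])
      stats::rmultinom(1, s$depth, w / sum(w))[, 1]
    }, numeric(s$n_taxa))
    dimnames(counts) <- list(tree$tip.label, sample_ids)
    list(
      table = feature_table(counts),
      tree = tree,
      process = s$process,
      habitat_of_taxon = clade,
      habitat_of_sample = habitat_of_sample
    )
  })
}
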