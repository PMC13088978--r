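# Synthetic HTS campaign generator.
#
# Emulates the statistical structure a dual-motif RNA thermal-shift campaign
# presents to the screening loop: a diverse library in fingerprint space;
# rare actives (~0.3% per motif) organized as tight chemotype clusters plus
# isolated singletons; a second motif whose active set overlaps the first
# substantially; delta-Tm magnitudes larger for clustered actives; a small
# fraction of compounds whose melt curves fail QC; and, optionally, raw melt
# curves on the assay's 25-95 degC / 2 degC grid that round-trip through the
# Tm estimator.

#' Configuration of the synthetic campaign generator
#'
#' Defaults define the package's standard desk-scale campaign: 5000
#' compounds at a 0.3% per-motif hit rate (about 15 actives per motif,
#' organized as 3 clusters of 3-6 members plus 3 singletons), 70% overlap
#' between the two motifs' active sets, and 2% invalid measurements.
#'
#' @param n_compounds library size.
#' @param n_bits fingerprint length (256 by default for speed; 1024
#'   optional).
#' @param n_desc number of abstract numeric descriptors.
#' @param n_active_clusters number of active chemotype clusters.
#' @param cluster_size_range inclusive range of cluster sizes.
#' @param n_singleton_actives actives with no structural neighbors.
#' @param base_hit_rate per-motif active fraction of the library.
#' @param motif_overlap_prob probability that a motif-1 active is also
#'   active against motif 2.
#' @param dtm_mu,dtm_sd active Tm shifts are
#'   `threshold + |Normal(dtm_mu, dtm_sd)|` degrees C.
#' @param inactive_sd inactive shifts are `Normal(0, inactive_sd)` truncated
#'   below the threshold.
#' @param cluster_dtm_boost additive shift (degrees C) for clustered
#'   actives, making clustered chemotypes the stronger binders.
#' @param active_threshold active-call cutoff (degrees C).
#' @param invalid_fraction fraction of compounds whose measurements fail QC
#'   (for both motifs).
#' @param bit_density expected fraction of on-bits in background
#'   fingerprints and cluster prototypes.
#' @param flip_prob per-bit probability that a cluster member differs from
#'   its prototype (controls within-cluster Tanimoto distance).
#' @param desc_sd_within descriptor spread of cluster members around their
#'   cluster mean (background compounds are standard normal).
#' @param seed integer seed; the whole campaign is reproducible from it.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_compounds = 5000, n_bits = 256, n_desc = 16,
                         n_active_clusters = 3, cluster_size_range = c(3, 6),
                         n_singleton_actives = 3, base_hit_rate = 0.003,
                         motif_overlap_prob = 0.7, dtm_mu = 2, dtm_sd = 3,
                         inactive_sd = 0.3, cluster_dtm_boost = 1.5,
                         active_threshold = 1, invalid_fraction = 0.02,
                         bit_density = 0.1, flip_prob = 0.02,
                         desc_sd_within = 0.5, seed = 1) {
  assert_that(n_compounds >= 10, "n_compounds must be at least 10")
  assert_that(motif_overlap_prob >= 0 && motif_overlap_prob <= 1,
              "motif_overlap_prob must be a probability")
  assert_that(invalid_fraction >= 0 && invalid_fraction < 1,
              "invalid_fraction must be in [0, 1)")
  assert_that(base_hit_rate > 0 && base_hit_rate < 1,
              "base_hit_rate must be in (0, 1)")
  assert_that(length(cluster_size_range) == 2 &&
                cluster_size_range[1] >= 1 &&
                cluster_size_range[2] >= cluster_size_range[1],
              "cluster_size_range must be an increasing pair")
  cfg <- structure(
    list(n_compounds = as.integer(n_compounds), n_bits = as.integer(n_bits),
         n_desc = as.integer(n_desc),
         n_active_clusters = as.integer(n_active_clusters),
         cluster_size_range = as.integer(cluster_size_range),
         n_singleton_actives = as.integer(n_singleton_actives),
         base_hit_rate = base_hit_rate,
         motif_overlap_prob = motif_overlap_prob,
         dtm_mu = dtm_mu, dtm_sd = dtm_sd, inactive_sd = inactive_sd,
         cluster_dtm_boost = cluster_dtm_boost,
         active_threshold = active_threshold,
         invalid_fraction = invalid_fraction, bit_density = bit_density,
         flip_prob = flip_prob, desc_sd_within = desc_sd_within,
         seed = as.integer(seed)),
    class = "synth_config")
  max_actives <- cfg$n_active_clusters * cfg$cluster_size_range[2] +
    cfg$n_singleton_actives +
    ceiling(cfg$base_hit_rate * cfg$n_compounds)
  if (max_actives > cfg$n_compounds) {
    stop_iterscreen("iterscreen_infeasible_config",
                    "implied active count exceeds the library size")
  }
  cfg
}

# Truncated normal below `upper` via inverse-CDF (exact, no rejection loop).
rnorm_below <- function(n, mean, sd, upper) {
  p <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, 0, p), mean, sd)
}

#' Generate a synthetic screening campaign
#'
#' Builds the full ground-truth package: fingerprints (cluster prototypes
#' with per-bit flip noise for clustered actives, uniform sparse bits for
#' the background, singleton actives placed at Tanimoto distance > 0.6 from
#' every prototype), cluster-structured descriptors, correlated dual-motif
#' active labels, delta-Tm values consistent with the labels, and an
#' invalid-measurement subset. Motif-2 labels are derived from motif 1 via
#' the overlap probability, topped up with independent extra actives so both
#' motifs reach the configured base hit rate.
#'
#' @param config a [synth_config()].
#' @return an object of class `synthetic_campaign`: a list with `config`,
#'   `ids`, `library` ([screen_library()]), `table` ([screen_table()] rows
#'   for motifs 1 and 2), and `truth` (per-active cluster ids, singleton
#'   ids, per-motif active sets) - `truth` is for evaluation only and is
#'   never read by the screening loop.
#' @examples
#' camp <- generate_library(synth_config(n_compounds = 500, seed = 42))
#' camp
#' @export
generate_library <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    n <- config$n_compounds
    b <- config$n_bits
    ids <- sprintf("C%05d", seq_len(n))

    sizes <- sample_from(seq(config$cluster_size_range[1],
                             config$cluster_size_range[2]),
                         config$n_active_clusters, replace = TRUE)
    n_clustered <- sum(sizes)
    n_sing <- config$n_singleton_actives
    n_act1 <- n_clustered + n_sing
    assert_that(n_act1 <= n, "implied actives exceed the library",
                subclass = "iterscreen_infeasible_config")

    act1_idx <- sample.int(n, n_act1)
    clustered_idx <- act1_idx[seq_len(n_clustered)]
    sing_idx <- act1_idx[n_clustered + seq_len(n_sing)]
    cluster_of <- rep(seq_along(sizes), sizes)

    # fingerprints: sparse random background, prototype-plus-flip clusters
    X <- matrix(stats::rbinom(n * b, 1, config$bit_density), n, b)
    protos <- matrix(stats::rbinom(config$n_active_clusters * b, 1,
                                   config$bit_density),
                     config$n_active_clusters, b)
    for (j in seq_len(n_clustered)) {
      flips <- stats::rbinom(b, 1, config$flip_prob)
      X[clustered_idx[j], ] <- as.integer(xor(protos[cluster_of[j], ], flips))
    }
    for (i in sing_idx) {  # keep singletons far from every cluster prototype
      for (tries in 1:100) {
        d <- tanimoto_dist_to_vec(protos, X[i, ])
        if (all(d > 0.6)) break
        X[i, ] <- stats::rbinom(b, 1, config$bit_density)
      }
    }
    rownames(X) <- ids

    # descriptors: cluster members share a cluster mean
    D <- matrix(stats::rnorm(n * config$n_desc), n, config$n_desc)
    cmeans <- matrix(stats::rnorm(config$n_active_clusters * config$n_desc,
                                  0, 1.5),
                     config$n_active_clusters, config$n_desc)
    for (j in seq_len(n_clustered)) {
      D[clustered_idx[j], ] <- cmeans[cluster_of[j], ] +
        stats::rnorm(config$n_desc, 0, config$desc_sd_within)
    }
    rownames(D) <- ids

    # motif-2 labels: carry-over from motif 1 plus independent extras
    carried <- act1_idx[stats::runif(n_act1) < config$motif_overlap_prob]
    target2 <- max(1L, as.integer(round_half_up(config$base_hit_rate * n)))
    extras <- integer(0)
    if (length(carried) < target2) {
      pool <- setdiff(seq_len(n), act1_idx)
      extras <- sample_from(pool, target2 - length(carried))
    }
    act2_idx <- c(carried, extras)

    # delta-Tm per motif, consistent with labels and threshold
    thr <- config$active_threshold
    draw_dtm <- function(active_idx) {
      dtm <- rnorm_below(n, 0, config$inactive_sd, thr)
      k <- length(active_idx)
      dtm[active_idx] <- thr +
        abs(stats::rnorm(k, config$dtm_mu, config$dtm_sd)) +
        config$cluster_dtm_boost * (active_idx %in% clustered_idx)
      dtm
    }
    dtm1 <- draw_dtm(act1_idx)
    dtm2 <- draw_dtm(act2_idx)

    # invalid measurements (per compound, both motifs)
    n_inv <- as.integer(round_half_up(config$invalid_fraction * n))
    inv_idx <- if (n_inv > 0) sample.int(n, n_inv) else integer(0)
    valid <- !(seq_len(n) %in% inv_idx)
    dtm1[!valid] <- NA_real_
    dtm2[!valid] <- NA_real_

    table <- screen_table(
      compound_id = rep(ids, 2),
      motif_id = rep(c(1L, 2L), each = n),
      delta_tm = c(dtm1, dtm2),
      valid = rep(valid, 2),
      threshold = thr
    )

    truth <- list(
      clusters = stats::setNames(cluster_of, ids[clustered_idx]),
      cluster_sizes = sizes,
      singletons = sort_ids(ids[sing_idx]),
      extra_singletons = sort_ids(ids[extras]),
      actives_by_motif = list(`1` = sort_ids(ids[act1_idx]),
                              `2` = sort_ids(ids[act2_idx])),
      invalid = sort_ids(ids[inv_idx])
    )

    structure(
      list(config = config, ids = ids,
           library = screen_library(X, D),
           table = table, truth = truth),
      class = "synthetic_campaign")
  })
}

#' @export
print.synthetic_campaign <- function(x, ...) {
  a1 <- length(x$truth$actives_by_motif[[1]])
  a2 <- length(x$truth$actives_by_motif[[2]])
  both <- length(intersect(x$truth$actives_by_motif[[1]],
                           x$truth$actives_by_motif[[2]]))
  cat(sprintf(
    "<synthetic_campaign> %d compounds (%d fp bits, %d descriptors)\n",
    length(x$ids), ncol(x$library$fingerprints),
    ncol(x$library$descriptors)))
  cat(sprintf(
    "  actives: motif1 %d, motif2 %d, both %d; %d clusters + %d singletons; %d invalid\n",
    a1, a2, both, length(x$truth$cluster_sizes),
    length(x$truth$singletons), length(x$truth$invalid)))
  invisible(x)
}

#' Assay configuration for synthetic melt curves
#'
#' @param grid temperature grid (default 25-95 degrees C in 2 degree steps).
#' @param reference_tm Tm of the compound-free reference (degrees C).
#' @param amplitude,baseline,width logistic curve shape parameters.
#' @param noise_sd additive Gaussian noise on every trace.
#' @param plate_size compounds per plate-equivalent batch; one reference
#'   curve is emitted per plate and motif.
#' @param seed integer seed.
#' @return a list of class `melt_assay_config`.
#' @export
melt_assay_config <- function(grid = default_melt_grid(), reference_tm = 62,
                              amplitude = 1, baseline = 0, width = 2,
                              noise_sd = 0.01, plate_size = 384, seed = 1) {
  structure(list(grid = grid, reference_tm = reference_tm,
                 amplitude = amplitude, baseline = baseline, width = width,
                 noise_sd = noise_sd, plate_size = as.integer(plate_size),
                 seed = as.integer(seed)),
            class = "melt_assay_config")
}

# One deliberately QC-failing trace; kind cycles over the three failure
# modes so a generated set exercises the whole taxonomy.
invalid_curve_fluorescence <- function(kind, assay) {
  g <- assay$grid
  base <- switch(
    kind,
    flat = rep(assay$baseline, length(g)),
    biphasic = assay$baseline +
      0.5 * assay$amplitude / (1 + exp(-(g - 45) / assay$width)) +
      0.5 * assay$amplitude / (1 + exp(-(g - 80) / assay$width)),
    boundary = assay$baseline +
      assay$amplitude / (1 + exp(-(g - (min(g) + 1)) / assay$width))
  )
  base + stats::rnorm(length(g), 0, max(assay$noise_sd, 1e-3))
}

#' Generate raw melt curves for a synthetic campaign
#'
#' Emits one trace per (compound, motif) - each a logistic melt with
#' `Tm = reference_tm + delta_tm` - plus one compound-free reference trace
#' per plate-equivalent batch and motif. Compounds flagged invalid in the
#' campaign get flat, biphasic, or boundary-inflection traces (cycled
#' deterministically) so QC rejects them; for valid compounds the
#' estimate/delta pipeline recovers the campaign's delta-Tm values
#' (round-trip property).
#'
#' @param campaign a `synthetic_campaign` from [generate_library()].
#' @param assay a [melt_assay_config()].
#' @param compounds optional subset of compound ids (default all).
#' @param motifs motif ids to emit (default both).
#' @return a long-format `data.frame` with columns `compound_id`,
#'   `motif_id`, `plate`, `temperature_C`, `fluorescence`, `is_reference`.
#' @export
generate_melt_curves <- function(campaign, assay = melt_assay_config(),
                                 compounds = NULL, motifs = c(1L, 2L)) {
  stopifnot(inherits(campaign, "synthetic_campaign"))
  ids <- compounds %||% campaign$ids
  assert_that(all(ids %in% campaign$ids), "unknown compound ids")
  g <- assay$grid
  ng <- length(g)
  tab <- campaign$table
  invalid_kinds <- c("flat", "biphasic", "boundary")

  with_seed(assay$seed, {
    out <- vector("list", length(motifs))
    for (mi in seq_along(motifs)) {
      motif <- motifs[mi]
      slice <- motif_slice(tab, motif, ids)
      plate <- (match(ids, campaign$ids) - 1L) %/% assay$plate_size + 1L
      plates <- sort(unique(plate))
      ref <- do.call(rbind, lapply(plates, function(p) {
        f <- assay$baseline + assay$amplitude /
          (1 + exp(-(g - assay$reference_tm) / assay$width)) +
          stats::rnorm(ng, 0, assay$noise_sd)
        data.frame(compound_id = sprintf("REF_P%03d", p), motif_id = motif,
                   plate = p, temperature_C = g, fluorescence = f,
                   is_reference = TRUE)
      }))
      cmp <- do.call(rbind, lapply(seq_along(ids), function(k) {
        if (!slice$valid[k]) {
          kind <- invalid_kinds[(match(ids[k], campaign$ids) - 1L) %%
                                  length(invalid_kinds) + 1L]
          f <- invalid_curve_fluorescence(kind, assay)
        } else {
          tm <- assay$reference_tm + slice$delta_tm[k]
          f <- assay$baseline + assay$amplitude /
            (1 + exp(-(g - tm) / assay$width)) +
            stats::rnorm(ng, 0, assay$noise_sd)
        }
        data.frame(compound_id = ids[k], motif_id = motif, plate = plate[k],
                   temperature_C = g, fluorescence = f,
                   is_reference = FALSE)
      }))
      out[[mi]] <- rbind(ref, cmp)
    }
    do.call(rbind, out)
  })
}

#' Analyze a table of raw melt curves into a screening table
#'
#' Runs the Tm estimator over every trace, matches each compound to its
#' plate's reference curve, computes delta-Tm, and calls actives; compounds
#' whose own or whose reference's curve fails QC come out invalid. When the
#' table has no `plate` column a single reference per motif is assumed.
#'
#' @param curves long-format curve table as produced by
#'   [generate_melt_curves()] (or read from CSV with the same columns).
#' @param control a [tm_control()].
#' @param threshold active-call cutoff (degrees C).
#' @return a [screen_table()].
#' @export
analyze_melt_curves <- function(curves, control = tm_control(),
                                threshold = 1) {
  need <- c("compound_id", "motif_id", "temperature_C", "fluorescence",
            "is_reference")
  assert_that(all(need %in% names(curves)),
              paste("curve table needs columns:", paste(need, collapse = ", ")))
  if (!"plate" %in% names(curves)) curves$plate <- 1L

  fit_one <- function(df) {
    estimate_tm(melt_curve(df$temperature_C, df$fluorescence,
                           compound_id = df$compound_id[1],
                           is_reference = df$is_reference[1]),
                control)
  }
  rows <- list()
  for (motif in unique(curves$motif_id)) {
    mc <- curves[curves$motif_id == motif, , drop = FALSE]
    refs <- mc[mc$is_reference, , drop = FALSE]
    ref_fit <- lapply(split(refs, refs$plate), fit_one)
    smp <- mc[!mc$is_reference, , drop = FALSE]
    for (piece in split(smp, smp$compound_id)) {
      fit <- fit_one(piece)
      rf <- ref_fit[[as.character(piece$plate[1])]]
      assert_that(!is.null(rf), sprintf("no reference curve for plate %s",
                                        piece$plate[1]))
      dt <- delta_tm(fit, rf, motif_id = motif)
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = dt$compound_id, motif_id = motif,
        delta_tm = dt$delta_tm %||% NA_real_, valid = dt$valid)
    }
  }
  df <- do.call(rbind, rows)
  screen_table(df$compound_id, df$motif_id, df$delta_tm, df$valid,
               threshold = threshold)
}
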