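# Evaluation statistics for screening campaigns: enrichment factor, hit
# rates, recovery curves, classification metrics, recovered-vs-unrecovered
# delta-Tm summaries, chemotype-cluster recovery, and two-motif overlap.

#' Enrichment factor
#'
#' `EF = (actives_sample / n_sample) / (actives_total / n_total)`: the active
#' rate in a selected sample relative to the active rate in the full valid
#' library (previously tested compounds included in the denominators). EF of
#' the full library is exactly 1; an EF of 20 means all actives were captured
#' in a 5% sample.
#'
#' @param actives_sample,n_sample active count and size of the sample.
#' @param actives_total,n_total active count and size of the full valid
#'   library.
#' @return the enrichment factor (dimensionless), vectorized over its
#'   arguments.
#' @examples
#' enrichment_factor(10, 100, 50, 1000)  # 2
#' @export
enrichment_factor <- function(actives_sample, n_sample, actives_total,
                              n_total) {
  assert_that(all(actives_sample >= 0) && all(actives_total >= 0),
              "counts must be nonnegative")
  assert_that(all(actives_sample <= n_sample) &&
                all(actives_total <= n_total),
              "active counts cannot exceed sample sizes")
  assert_that(all(actives_sample <= actives_total) &&
                all(n_sample <= n_total),
              "sample must be contained in the total")
  if (any(actives_total == 0) || any(n_sample == 0)) {
    stop_iterscreen("iterscreen_undefined_ef",
                    "EF undefined: no actives in the library or empty sample")
  }
  (actives_sample / n_sample) / (actives_total / n_total)
}

#' Hit rate as a percentage of valid data
#'
#' `100 * actives / n_valid`, reported rounded half-up to 2 decimals (the
#' unrounded value is returned alongside).
#'
#' @param actives number of active compounds.
#' @param n_valid number of compounds with valid measurements.
#' @return list with `percent` (rounded, report form) and `raw` (unrounded),
#'   vectorized.
#' @examples
#' hit_rate(216, 71653)$percent  # 0.30
#' @export
hit_rate <- function(actives, n_valid) {
  assert_that(all(n_valid > 0), "n_valid must be positive")
  raw <- 100 * actives / n_valid
  list(percent = round_half_up(raw, 2), raw = raw)
}

#' Recovery curve of a screening trace
#'
#' One point per iteration: cumulative fraction of the valid library
#' screened against cumulative fraction (and count) of valid actives
#' recovered. Invalid-measurement compounds appear in neither numerator nor
#' denominator.
#'
#' @param trace a `screen_trace`.
#' @param table optional [screen_table()]; when supplied, cumulative counts
#'   are recomputed from it (a consistency cross-check), otherwise the
#'   trace's own ledger is used.
#' @return a `data.frame` of class `recovery_curve` with columns `iteration`,
#'   `fraction_screened`, `fraction_recovered`, `n_recovered`.
#' @export
recovery_curve <- function(trace, table = NULL) {
  stopifnot(inherits(trace, "screen_trace"))
  if (!is.null(table)) {
    tab <- motif_slice(table, trace$motif, trace$library_ids)
    valid <- tab$valid
    active <- tab$active
    ids <- trace$library_ids
    tested <- character(0)
    rows <- lapply(trace$iterations, function(r) {
      tested <<- c(tested, r$selected)
      i <- match(tested, ids)
      c(sum(valid[i]), sum(active[i][valid[i]]))
    })
    cum_valid <- vapply(rows, `[[`, numeric(1), 1)
    cum_active <- vapply(rows, `[[`, numeric(1), 2)
    n_valid <- sum(valid)
    actives_total <- sum(active[valid])
  } else {
    cum_valid <- vapply(trace$iterations, `[[`, numeric(1), "cum_valid_tested")
    cum_active <- vapply(trace$iterations, `[[`, numeric(1), "cum_active")
    n_valid <- trace$n_valid
    actives_total <- trace$actives_total
  }
  df <- data.frame(
    iteration = vapply(trace$iterations, `[[`, integer(1), "iteration"),
    fraction_screened = cum_valid / n_valid,
    fraction_recovered = if (actives_total > 0) cum_active / actives_total
                         else rep(NA_real_, length(cum_active)),
    n_recovered = as.integer(cum_active)
  )
  class(df) <- c("recovery_curve", "data.frame")
  df
}

#' @export
plot.recovery_curve <- function(x, ...) {
  graphics::plot(c(0, x$fraction_screened), c(0, x$fraction_recovered),
                 type = "b", pch = 16,
                 xlab = "fraction of library screened",
                 ylab = "fraction of actives recovered", ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Precision, recall and F1 of predicted active calls
#'
#' Precision is the fraction of predicted actives that are truly active,
#' recall the fraction of true actives predicted, and F1 their harmonic
#' mean. Empty denominators yield `NA` (an explicit undefined marker), never
#' a silent 0.
#'
#' @param predicted,truth logical vectors of equal length.
#' @return list with `precision`, `recall`, `f1` and the confusion counts.
#' @examples
#' classification_metrics(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
#'                        c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
#' @export
classification_metrics <- function(predicted, truth) {
  assert_that(length(predicted) == length(truth),
              "predicted and truth must have equal length")
  predicted <- as.logical(predicted)
  truth <- as.logical(truth)
  tp <- sum(predicted & truth)
  fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn)
}

#' Delta-Tm summary of recovered versus unrecovered actives
#'
#' Partitions the actives by whether the screen recovered them and reports
#' mean, median and N of the Tm shifts per group; the workflow's diagnostic
#' for whether it preferentially enriches stronger binders. An optional
#' rank-sum (Wilcoxon) comparison is available; empty groups report `N = 0`
#' with absent statistics.
#'
#' @param delta_tms named numeric vector of Tm shifts for the active
#'   compounds (names = compound ids).
#' @param recovered_ids compound ids recovered by the screen.
#' @param test `"none"` or `"wilcoxon"`.
#' @return list with `recovered` and `unrecovered` summaries (each
#'   `mean`/`median`/`n`) and optionally `p_value`.
#' @export
delta_tm_split_summary <- function(delta_tms, recovered_ids,
                                   test = c("none", "wilcoxon")) {
  test <- match.arg(test)
  assert_that(!is.null(names(delta_tms)) && all(is.finite(delta_tms)),
              "delta_tms must be finite and named by compound id")
  rec <- delta_tms[names(delta_tms) %in% recovered_ids]
  unrec <- delta_tms[!names(delta_tms) %in% recovered_ids]
  grp <- function(v) {
    if (length(v) == 0) list(mean = NA_real_, median = NA_real_, n = 0L)
    else list(mean = mean(v), median = stats::median(v), n = length(v))
  }
  out <- list(recovered = grp(rec), unrecovered = grp(unrec))
  if (test == "wilcoxon" && length(rec) > 0 && length(unrec) > 0) {
    out$p_value <- stats::wilcox.test(rec, unrec, exact = FALSE)$p.value
  }
  out
}

# Classic sphere-exclusion (Butina-style) clustering on a precomputed
# Tanimoto distance matrix. Candidates are processed once, ordered by
# descending neighbor count with ties by smallest id; each centroid absorbs
# its still-unassigned neighbors.
sphere_exclusion <- function(dist_mat, cutoff) {
  ids <- rownames(dist_mat)
  m <- length(ids)
  nb <- lapply(seq_len(m), function(i) {
    which(dist_mat[i, ] <= cutoff & seq_len(m) != i)
  })
  counts <- lengths(nb)
  ord <- order_ids(ids, key = -counts)
  assigned <- integer(m)  # 0 = unassigned
  cluster_id <- 0L
  centroids <- integer(0)
  for (i in ord) {
    if (assigned[i] > 0) next
    cluster_id <- cluster_id + 1L
    members <- c(i, nb[[i]][assigned[nb[[i]]] == 0])
    assigned[members] <- cluster_id
    centroids[cluster_id] <- i
  }
  list(assignment = stats::setNames(assigned, ids),
       centroids = ids[centroids])
}

#' Chemotype-cluster recovery analysis
#'
#' Groups the active compounds by sphere-exclusion (Butina-style) clustering
#' of their fingerprints at a Tanimoto-distance cutoff, then reports the
#' recovered fraction per cluster and for the singletons (clusters of size
#' one). The workflow's diagnostic for whether it preferentially recovers
#' clustered actives - the SAR-tractable chemotypes - over one-off hits.
#'
#' @param fingerprints 0/1 matrix of the ACTIVE compounds only, rownames =
#'   compound ids.
#' @param recovered_ids compound ids recovered by the screen.
#' @param cutoff Tanimoto-distance neighbor cutoff (default 0.4).
#' @return list with `clusters` (data.frame: id, size, centroid,
#'   n_recovered, recovered_fraction), `members` (list of id vectors),
#'   `singletons` (ids), `clustered_recovery` and `singleton_recovery`
#'   (overall recovered fractions, `NA` when the group is empty).
#' @export
cluster_recovery <- function(fingerprints, recovered_ids, cutoff = 0.4) {
  fingerprints <- as.matrix(fingerprints)
  ids <- rownames(fingerprints)
  assert_that(!is.null(ids), "fingerprints must have compound-id rownames")
  d <- tanimoto_dist_matrix(fingerprints)
  cl <- sphere_exclusion(d, cutoff)
  members <- split(names(cl$assignment), cl$assignment)
  names(members) <- NULL
  sizes <- lengths(members)
  rec <- vapply(members, function(v) sum(v %in% recovered_ids), integer(1))
  clusters <- data.frame(
    cluster = seq_along(members), size = sizes,
    centroid = cl$centroids,
    n_recovered = rec,
    recovered_fraction = rec / sizes
  )
  single <- sizes == 1
  singleton_ids <- unlist(members[single], use.names = FALSE)
  clustered_ids <- unlist(members[!single], use.names = FALSE)
  frac <- function(v) {
    if (length(v) == 0) NA_real_ else mean(v %in% recovered_ids)
  }
  list(clusters = clusters, members = members,
       singletons = sort_ids(singleton_ids %||% character(0)),
       clustered_recovery = frac(clustered_ids),
       singleton_recovery = frac(singleton_ids))
}

#' Two-motif overlap and selectivity counts
#'
#' Set cardinalities of active compounds across two RNA motifs: per-motif
#' totals, the intersection (compounds active against both), and the
#' motif-preferential differences; computed for the full active sets and,
#' when given, for the recovered subsets, to check that iterative selection
#' does not distort the selectivity structure of the library.
#'
#' @param actives_by_motif named list of two compound-id vectors (full
#'   active sets per motif).
#' @param recovered_by_motif optional named list of recovered-id vectors.
#' @return a `data.frame` with one row per universe (`full` and, if
#'   supplied, `recovered`): totals per motif, `both`, and per-motif-only
#'   counts.
#' @examples
#' overlap_analysis(list(m1 = c("a", "b", "c"), m2 = c("b", "c", "d")))
#' @export
overlap_analysis <- function(actives_by_motif, recovered_by_motif = NULL) {
  assert_that(length(actives_by_motif) == 2,
              "overlap analysis expects exactly two motifs")
  nms <- names(actives_by_motif) %||% c("motif1", "motif2")
  count_row <- function(sets, universe) {
    a <- unique(sets[[1]])
    b <- unique(sets[[2]])
    data.frame(universe = universe,
               motif_a = nms[1], motif_b = nms[2],
               n_a = length(a), n_b = length(b),
               both = length(intersect(a, b)),
               only_a = length(setdiff(a, b)),
               only_b = length(setdiff(b, a)))
  }
  out <- count_row(actives_by_motif, "full")
  if (!is.null(recovered_by_motif)) {
    out <- rbind(out, count_row(recovered_by_motif, "recovered"))
  }
  out
}
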