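# The iterative-screening engine: diversity-seeded initial subset,
# class-balanced random-forest training, top-fraction batch selection with
# per-iteration retraining, and the matching random-selection baseline.
#
# The screening table acts as the label oracle: the loop only ever reads
# delta-Tm labels for compounds it has already selected, so a simulated
# campaign faithfully reproduces the information flow of a real one.

#' Construct a screening table
#'
#' Per (compound, motif) delta-Tm measurements with validity flags and
#' active calls. Rows whose measurement failed QC are invalid: they carry no
#' delta-Tm or label and are excluded from training and from every
#' numerator/denominator of the recovery statistics (the "valid data"
#' universe).
#'
#' @param compound_id,motif_id,delta_tm,valid vectors of equal length;
#'   `delta_tm` in degrees C (`NA` where invalid), `valid` logical.
#' @param active optional logical; recomputed as `delta_tm > threshold` where
#'   missing.
#' @param threshold active-call cutoff in degrees C (strict).
#' @return a `data.frame` of class `screen_table`.
#' @export
screen_table <- function(compound_id, motif_id, delta_tm, valid = NULL,
                         active = NULL, threshold = 1) {
  n <- length(compound_id)
  delta_tm <- as.numeric(delta_tm)
  if (is.null(valid)) valid <- is.finite(delta_tm)
  assert_that(length(motif_id) == n && length(delta_tm) == n &&
                length(valid) == n, "screen_table columns must align")
  valid <- as.logical(valid)
  valid[!is.finite(delta_tm)] <- FALSE  # delta absent => invalid
  if (is.null(active)) {
    active <- ifelse(valid, delta_tm > threshold, NA)
  }
  active[!valid] <- NA  # active defined only where valid
  df <- data.frame(compound_id = as.character(compound_id),
                   motif_id = motif_id, delta_tm = delta_tm,
                   valid = valid, active = as.logical(active),
                   stringsAsFactors = FALSE)
  assert_that(!anyDuplicated(df[, c("compound_id", "motif_id")]),
              "duplicate (compound_id, motif_id) rows")
  class(df) <- c("screen_table", "data.frame")
  df
}

# Rows of `table` for one motif, aligned to `ids`; errors if coverage is
# incomplete.
motif_slice <- function(table, motif, ids) {
  tab <- table[table$motif_id == motif, , drop = FALSE]
  idx <- match(ids, tab$compound_id)
  assert_that(!anyNA(idx),
              sprintf("screening table does not cover the library for motif %s",
                      motif))
  tab[idx, , drop = FALSE]
}

#' Configuration of the iterative screening loop
#'
#' Defaults follow the workflow's published operating point: a 10% diverse
#' initial subset, 5% batches, and a random forest of 50 trees with maximum
#' depth 20 retrained after every batch.
#'
#' @param initial_fraction fraction of the library in the diversity-picked
#'   initial subset.
#' @param batch_fraction per-iteration batch size as a fraction of the FULL
#'   library (not of the untested remainder); the final batch truncates.
#' @param n_trees,max_depth random-forest hyperparameters, fixed across
#'   iterations.
#' @param balance class-balancing policy for training: `"oversample"`
#'   (default; minority oversampled and majority undersampled to a 1:1 set
#'   the size of the input), `"undersample"` (majority cut to the minority
#'   count), or `"none"`. See [balance_training()].
#' @param stop_fraction stop once this fraction of the library has been
#'   tested (default 0.35); use 1 for an exhaustive screen.
#' @param max_iterations hard cap on model iterations.
#' @param seed_diversity,seed_model seeds for the diversity pick and for
#'   balancing/forest fitting; together with the data they fix the entire
#'   trace bitwise.
#' @param seeds_baseline integer seeds for the independent random-selection
#'   baseline runs (default six).
#' @param threshold active-call cutoff (degrees C) used when tables lack
#'   explicit calls.
#' @param store_scores keep the per-iteration predicted scores in the trace.
#' @return a list of class `screen_config`.
#' @export
screen_config <- function(initial_fraction = 0.10, batch_fraction = 0.05,
                          n_trees = 50, max_depth = 20,
                          balance = c("oversample", "undersample", "none"),
                          stop_fraction = 0.35, max_iterations = 1000,
                          seed_diversity = 1, seed_model = 1,
                          seeds_baseline = 1:6, threshold = 1,
                          store_scores = TRUE) {
  balance <- match.arg(balance)
  assert_that(initial_fraction > 0 && initial_fraction <= 1,
              "initial_fraction must be in (0, 1]")
  assert_that(batch_fraction > 0 && batch_fraction <= 1,
              "batch_fraction must be in (0, 1]")
  assert_that(stop_fraction > 0 && stop_fraction <= 1,
              "stop_fraction must be in (0, 1]")
  assert_that(n_trees >= 1, "n_trees must be >= 1")
  structure(list(initial_fraction = initial_fraction,
                 batch_fraction = batch_fraction,
                 n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 balance = balance, stop_fraction = stop_fraction,
                 max_iterations = max_iterations,
                 seed_diversity = as.integer(seed_diversity),
                 seed_model = as.integer(seed_model),
                 seeds_baseline = as.integer(seeds_baseline),
                 threshold = threshold, store_scores = store_scores),
            class = "screen_config")
}

#' MaxMin diversity pick
#'
#' Greedy diversity selection on Tanimoto distance: the first pick is drawn
#' uniformly at random (seeded); each subsequent pick maximizes its minimum
#' Tanimoto distance to the already-picked set, breaking ties by smallest
#' compound id.
#'
#' @param fingerprints 0/1 matrix with compound ids as rownames.
#' @param k number of compounds to pick, `1 <= k <= nrow`.
#' @param seed integer seed for the first pick.
#' @return character vector of k compound ids in pick order.
#' @export
maxmin_pick <- function(fingerprints, k, seed = 1) {
  fingerprints <- as.matrix(fingerprints)
  n <- nrow(fingerprints)
  ids <- rownames(fingerprints)
  assert_that(!is.null(ids), "fingerprints must have compound-id rownames")
  assert_that(k >= 1 && k <= n, "k must be between 1 and the library size")
  k <- as.integer(k)
  first <- with_seed(seed, sample.int(n, 1))
  picked <- integer(k)
  picked[1] <- first
  if (k > 1) {
    mind <- tanimoto_dist_to_vec(fingerprints, fingerprints[first, ])
    mind[first] <- -Inf
    for (j in 2:k) {
      m <- max(mind)
      cand <- which(mind == m)
      nxt <- if (length(cand) == 1) cand else cand[order_ids(ids[cand])[1]]
      picked[j] <- nxt
      d <- tanimoto_dist_to_vec(fingerprints, fingerprints[nxt, ])
      mind <- pmin(mind, d)
      mind[nxt] <- -Inf
    }
  }
  ids[picked]
}

#' Class-balance a training set
#'
#' Two 1:1 balancing policies, both capped at the original row count
#' ("relative number of rows after balancing = 1") and both leaving labels
#' untouched:
#' * `"undersample"` - the majority class is undersampled (seeded, without
#'   replacement) to the minority count; e.g. 900 inactives / 100 actives
#'   become 100/100.
#' * `"oversample"` - the minority class is oversampled (seeded, with
#'   replacement) and the majority undersampled so that each class holds
#'   half the original row count. This mirrors the class-balancing of
#'   AutoML-style forest training and is the loop's default: at sub-percent
#'   hit rates the minority class in early iterations can be a handful of
#'   compounds, and undersampling the majority down to it discards nearly
#'   all information.
#'
#' Single-class input signals an `iterscreen_degenerate_labels` condition so
#' the caller can fall back to a random batch.
#'
#' @param labels logical vector of active calls for the tested compounds.
#' @param policy `"oversample"` or `"undersample"`.
#' @param seed integer seed for the sampling draws.
#' @return integer indices (into `labels`) of the training rows, in sorted
#'   order, possibly with repeats under `"oversample"`.
#' @export
balance_training <- function(labels, policy = c("oversample", "undersample"),
                             seed = 1) {
  policy <- match.arg(policy)
  labels <- as.logical(labels)
  assert_that(!anyNA(labels), "labels must be non-missing")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop_iterscreen("iterscreen_degenerate_labels",
                    "training labels contain a single class")
  }
  pos <- which(labels)
  neg <- which(!labels)
  keep <- if (policy == "undersample") {
    m <- min(n_pos, n_neg)
    with_seed(seed, {
      c(if (n_pos > m) sample_from(pos, m) else pos,
        if (n_neg > m) sample_from(neg, m) else neg)
    })
  } else {
    m <- max(1L, length(labels) %/% 2L)
    with_seed(seed, {
      c(sample_from(pos, m, replace = n_pos < m),
        sample_from(neg, m, replace = n_neg < m))
    })
  }
  sort(keep)
}

#' Train the batch-selection classifier
#'
#' A probability random forest (50 trees, maximum depth 20 by default) on the
#' balanced training set; returns a model whose score is the predicted
#' probability of activity in \[0, 1\]. Fitting is deterministic given the
#' model seed.
#'
#' @param features numeric feature matrix (rows = compounds).
#' @param labels logical active calls aligned with `features`.
#' @param config a [screen_config()].
#' @param seed integer seed for the forest.
#' @return an object of class `screen_model`.
#' @export
train_classifier <- function(features, labels, config = screen_config(),
                             seed = config$seed_model) {
  assert_that(nrow(features) == length(labels),
              "features and labels must have matching length")
  y <- factor(as.logical(labels), levels = c(FALSE, TRUE))
  fit <- ranger::ranger(x = as.data.frame(features), y = y,
                        num.trees = config$n_trees,
                        max.depth = config$max_depth,
                        probability = TRUE, seed = seed, num.threads = 1)
  structure(list(fit = fit, feature_names = colnames(features)),
            class = "screen_model")
}

#' Score compounds with a trained screen model
#'
#' @param object a `screen_model`.
#' @param newdata numeric feature matrix with the training columns.
#' @param ... unused.
#' @return named numeric vector of probability-of-active scores.
#' @export
predict.screen_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[, object$feature_names, drop = FALSE]
  p <- stats::predict(object$fit, data = newdata, num.threads = 1)$predictions
  scores <- p[, "TRUE"]
  names(scores) <- rownames(newdata)
  scores
}

#' Select the top-scoring fraction of the untested library
#'
#' Batch size is `round_half_up(fraction * n_total)` (a fraction of the full
#' library), capped by the number of untested compounds; the highest scores
#' are taken first, ties broken by smallest compound id.
#'
#' @param scores named numeric vector covering exactly the untested set.
#' @param fraction batch fraction of the full library.
#' @param n_total full library size.
#' @return character vector of selected compound ids.
#' @export
top_fraction <- function(scores, fraction, n_total) {
  assert_that(length(scores) > 0, "no untested compounds left to select from")
  assert_that(!is.null(names(scores)), "scores must be named by compound id")
  size <- min(as.integer(round_half_up(fraction * n_total)), length(scores))
  size <- max(size, 1L)
  ord <- order_ids(names(scores), key = -scores)
  names(scores)[ord[seq_len(size)]]
}

# One iteration record of a trace.
iteration_record <- function(iteration, mode, selected, revealed_active,
                             revealed_valid, cum_tested, cum_valid,
                             cum_active, degenerate = FALSE, scores = NULL) {
  list(iteration = iteration, mode = mode, selected = selected,
       n_selected = length(selected),
       n_active = sum(revealed_active, na.rm = TRUE),
       n_valid = sum(revealed_valid),
       cum_tested = cum_tested, cum_valid_tested = cum_valid,
       cum_active = cum_active, degenerate = degenerate, scores = scores)
}

#' Run a model-guided iterative screen
#'
#' The engine of the workflow. Iteration 0 tests a MaxMin-diverse subset
#' (`initial_fraction` of the library). Each subsequent iteration retrains
#' the class-balanced random forest on every tested-and-valid compound,
#' scores the untested remainder, and selects the top `batch_fraction` of the
#' full library for testing; labels are revealed only for selected
#' compounds. The loop stops at `stop_fraction` of the library (or when
#' nothing is left untested). If the tested labels are single-class the
#' iteration falls back to a seeded random batch and is flagged in the
#' trace.
#'
#' @param library a [screen_library()].
#' @param table a [screen_table()] covering the library for `motif` (the
#'   label oracle).
#' @param motif motif identifier to screen against.
#' @param config a [screen_config()].
#' @return an object of class `screen_trace`; see [summary.screen_trace()],
#'   [plot.screen_trace()], [predict.screen_trace()].
#' @examples
#' camp <- generate_library(synth_config(n_compounds = 400, seed = 3))
#' tr <- iterative_screen(camp$library, camp$table, motif = 1,
#'                        config = screen_config(stop_fraction = 0.3))
#' summary(tr)
#' @export
iterative_screen <- function(library, table, motif,
                             config = screen_config()) {
  stopifnot(inherits(library, "screen_library"))
  ids <- library$ids
  n <- length(ids)
  tab <- motif_slice(table, motif, ids)
  valid <- tab$valid
  active <- tab$active
  n_valid <- sum(valid)
  actives_total <- sum(active[valid])

  n_init <- max(1L, as.integer(round_half_up(config$initial_fraction * n)))
  n_batch <- max(1L, as.integer(round_half_up(config$batch_fraction * n)))
  stop_n <- min(n, as.integer(round_half_up(config$stop_fraction * n)))
  n_init <- min(n_init, stop_n)

  X <- NULL  # combined feature matrix, built on first model iteration
  tested <- logical(n)
  names(tested) <- ids

  sel0 <- maxmin_pick(library$fingerprints, n_init,
                      seed = config$seed_diversity)
  tested[sel0] <- TRUE
  iters <- list(iteration_record(
    0L, "diversity", sel0,
    revealed_active = active[tested][valid[tested]],
    revealed_valid = valid[tested],
    cum_tested = sum(tested),
    cum_valid = sum(tested & valid),
    cum_active = sum(active[tested & valid])
  ))

  model <- NULL
  it <- 0L
  while (sum(tested) < stop_n && any(!tested) &&
         it < config$max_iterations) {
    it <- it + 1L
    untested_ids <- ids[!tested]
    train_ids <- ids[tested & valid]
    train_labels <- active[match(train_ids, ids)]
    batch_cap <- min(n_batch, stop_n - sum(tested))

    degenerate <- length(unique(train_labels)) < 2
    if (!degenerate) {
      if (is.null(X)) X <- combined_features(library, train_ids)
      keep <- if (config$balance == "none") seq_along(train_labels) else {
        balance_training(train_labels, policy = config$balance,
                         seed = derive_seed(config$seed_model, it * 2L))
      }
      model <- train_classifier(X[train_ids[keep], , drop = FALSE],
                                train_labels[keep], config,
                                seed = derive_seed(config$seed_model, it * 2L + 1L))
      scores <- predict(model, X[untested_ids, , drop = FALSE])
      sel <- top_fraction(scores, config$batch_fraction, n)
      sel <- sel[seq_len(min(length(sel), batch_cap))]
      mode <- "model"
    } else {
      sel <- with_seed(derive_seed(config$seed_model, it * 2L), {
        sample_from(untested_ids, min(batch_cap, length(untested_ids)))
      })
      scores <- NULL
      mode <- "random"
    }

    tested[sel] <- TRUE
    iters[[length(iters) + 1L]] <- iteration_record(
      it, mode, sel,
      revealed_active = active[match(sel, ids)][valid[match(sel, ids)]],
      revealed_valid = valid[match(sel, ids)],
      cum_tested = sum(tested),
      cum_valid = sum(tested & valid),
      cum_active = sum(active[tested & valid]),
      degenerate = degenerate,
      scores = if (config$store_scores && !is.null(scores)) scores else NULL
    )
  }

  structure(
    list(motif = motif, selection = "model", config = config,
         n_library = n, n_valid = n_valid, actives_total = actives_total,
         iterations = iters, tested_ids = ids[tested],
         final_model = model, library_ids = ids),
    class = "screen_trace"
  )
}

#' Run random-selection baseline screens
#'
#' The nonprioritized control: the same batch schedule as the model-guided
#' run, with batches drawn uniformly without replacement from the untested
#' remainder. One trace per seed; the default seeds are taken from the
#' configuration (six independent repeats).
#'
#' With `initial = "shared"` (the default) every baseline starts from the
#' same MaxMin-diverse initial subset as the model-guided arm and only the
#' subsequent batches are random - a paired design in which any difference
#' from [iterative_screen()] is attributable to model-guided batch
#' selection alone. `initial = "random"` draws the initial subset uniformly
#' too, giving the fully nonprioritized screen whose expected recovery at
#' screened fraction f is f (hypergeometric sampling).
#'
#' @inheritParams iterative_screen
#' @param seeds integer vector of seeds, one baseline run per seed.
#' @param initial `"shared"` (diversity-picked initial subset, as in the
#'   model arm) or `"random"` (uniform).
#' @return list of `screen_trace` objects (class `screen_baseline`).
#' @export
random_screen <- function(library, table, motif, config = screen_config(),
                          seeds = config$seeds_baseline,
                          initial = c("shared", "random")) {
  initial <- match.arg(initial)
  stopifnot(inherits(library, "screen_library"))
  ids <- library$ids
  n <- length(ids)
  tab <- motif_slice(table, motif, ids)
  valid <- tab$valid
  active <- tab$active

  n_init <- max(1L, as.integer(round_half_up(config$initial_fraction * n)))
  n_batch <- max(1L, as.integer(round_half_up(config$batch_fraction * n)))
  stop_n <- min(n, as.integer(round_half_up(config$stop_fraction * n)))
  n_init <- min(n_init, stop_n)

  shared0 <- if (initial == "shared") {
    maxmin_pick(library$fingerprints, n_init, seed = config$seed_diversity)
  } else NULL

  traces <- lapply(seeds, function(seed) {
    with_seed(seed, {
      tested <- logical(n)
      names(tested) <- ids
      iters <- list()
      it <- 0L
      repeat {
        size <- if (it == 0L) n_init else min(n_batch, stop_n - sum(tested))
        if (size <= 0 || !any(!tested)) break
        sel <- if (it == 0L && !is.null(shared0)) shared0
               else sample_from(ids[!tested], min(size, sum(!tested)))
        tested[sel] <- TRUE
        iters[[length(iters) + 1L]] <- iteration_record(
          it, if (it == 0L && !is.null(shared0)) "diversity" else "random",
          sel,
          revealed_active = active[match(sel, ids)][valid[match(sel, ids)]],
          revealed_valid = valid[match(sel, ids)],
          cum_tested = sum(tested),
          cum_valid = sum(tested & valid),
          cum_active = sum(active[tested & valid])
        )
        if (sum(tested) >= stop_n) break
        it <- it + 1L
      }
      structure(
        list(motif = motif, selection = "random", config = config,
             seed = seed, n_library = n, n_valid = sum(valid),
             actives_total = sum(active[valid]), iterations = iters,
             tested_ids = ids[tested], final_model = NULL,
             library_ids = ids),
        class = "screen_trace"
      )
    })
  })
  structure(traces, class = "screen_baseline")
}

#' @export
print.screen_trace <- function(x, ...) {
  last <- x$iterations[[length(x$iterations)]]
  cat(sprintf(
    "<screen_trace> motif %s, %s selection: %d iterations, %d/%d tested, %d/%d valid actives recovered (%.1f%%)\n",
    x$motif, x$selection, length(x$iterations), last$cum_tested, x$n_library,
    last$cum_active, x$actives_total,
    if (x$actives_total > 0) 100 * last$cum_active / x$actives_total else 0))
  invisible(x)
}

#' Summarize a screening trace
#'
#' One row per iteration: batch size and mode, actives revealed, cumulative
#' counts, fraction of the valid library screened, fraction of valid actives
#' recovered, and the cumulative enrichment factor over the valid universe.
#'
#' @param object a `screen_trace`.
#' @param ... unused.
#' @return a `data.frame`.
#' @export
summary.screen_trace <- function(object, ...) {
  it <- object$iterations
  df <- data.frame(
    iteration = vapply(it, `[[`, integer(1), "iteration"),
    mode = vapply(it, `[[`, character(1), "mode"),
    n_selected = vapply(it, `[[`, integer(1), "n_selected"),
    n_active = vapply(it, function(r) as.integer(r$n_active), integer(1)),
    cum_tested = vapply(it, function(r) as.integer(r$cum_tested), integer(1)),
    cum_valid_tested = vapply(it, function(r) as.integer(r$cum_valid_tested),
                              integer(1)),
    cum_active = vapply(it, function(r) as.integer(r$cum_active), integer(1)),
    degenerate = vapply(it, function(r) isTRUE(r$degenerate), logical(1))
  )
  df$fraction_screened <- df$cum_valid_tested / object$n_valid
  df$fraction_recovered <- if (object$actives_total > 0)
    df$cum_active / object$actives_total else NA_real_
  df$ef_cumulative <- ifelse(
    df$cum_valid_tested > 0 & object$actives_total > 0,
    (df$cum_active / df$cum_valid_tested) /
      (object$actives_total / object$n_valid),
    NA_real_)
  df
}

#' Plot the recovery curve of a screening trace
#'
#' Cumulative fraction of valid actives recovered versus fraction of the
#' valid library screened, optionally against the mean +/- sd band of
#' random-baseline traces and the diagonal expected under uniform sampling.
#'
#' @param x a `screen_trace`.
#' @param baselines optional list of baseline `screen_trace`s (e.g. from
#'   [random_screen()]).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.screen_trace <- function(x, baselines = NULL, ...) {
  s <- summary(x)
  graphics::plot(c(0, s$fraction_screened), c(0, s$fraction_recovered),
                 type = "s", xlab = "fraction of library screened",
                 ylab = "fraction of actives recovered",
                 xlim = c(0, max(s$fraction_screened)), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  if (!is.null(baselines)) {
    rec <- sapply(baselines, function(b) summary(b)$fraction_recovered)
    fr <- summary(baselines[[1]])$fraction_screened
    mu <- rowMeans(rec)
    sdv <- apply(rec, 1, stats::sd)
    graphics::lines(fr, mu, col = "black", lwd = 2)
    graphics::lines(fr, pmin(1, mu + sdv), col = "black", lty = 2)
    graphics::lines(fr, pmax(0, mu - sdv), col = "black", lty = 2)
  }
  graphics::points(s$fraction_screened, s$fraction_recovered, pch = 16)
  invisible(x)
}

#' Score compounds with the final model of a trace
#'
#' Applies the last trained forest of a model-guided trace to new compounds.
#'
#' @param object a `screen_trace` from [iterative_screen()].
#' @param library a [screen_library()] of compounds to score (defaults are
#'   not available: the trace stores only the model, not the library).
#' @param ... unused.
#' @return named numeric vector of probability-of-active scores.
#' @export
predict.screen_trace <- function(object, library, ...) {
  assert_that(!is.null(object$final_model),
              "trace has no trained model (random baseline or degenerate run)")
  predict(object$final_model, combined_features(library))
}
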