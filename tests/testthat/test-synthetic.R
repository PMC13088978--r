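# The synthetic campaign generator: reproducibility, structure, label
# consistency, and melt-curve round trips.

test_that("campaign generation is bitwise reproducible from its seed", {
  a <- generate_library(synth_config(n_compounds = 600, seed = 7))
  b <- generate_library(synth_config(n_compounds = 600, seed = 7))
  expect_identical(a, b)
  c2 <- generate_library(synth_config(n_compounds = 600, seed = 8))
  expect_false(identical(a$library$fingerprints, c2$library$fingerprints))
})

test_that("active counts follow the configured structure (frozen regression)", {
  camp <- generate_library(synth_config(seed = 7))
  a1 <- length(camp$truth$actives_by_motif[[1]])
  a2 <- length(camp$truth$actives_by_motif[[2]])
  # structural bounds: clusters of 3-6 plus singletons; motif 2 topped up to
  # the base rate
  expect_gte(a1, 3 * 3 + 3)
  expect_lte(a1, 3 * 6 + 3)
  expect_gte(a2, round_half_up(0.003 * 5000))
  # frozen exact counts for this seed, checked as a regression
  expect_equal(a1, 17)
  expect_equal(a2, 15)
})

test_that("labels and delta-Tm values are mutually consistent", {
  camp <- generate_library(synth_config(n_compounds = 1000, seed = 11))
  tab <- camp$table
  ok <- tab$valid
  expect_true(all(tab$active[ok] == (tab$delta_tm[ok] > 1)))
  expect_true(all(is.na(tab$delta_tm[!ok])))
  expect_true(all(is.na(tab$active[!ok])))
  # invalid set matches truth
  expect_setequal(unique(tab$compound_id[!ok]), camp$truth$invalid)
})

test_that("full overlap nests motif-1 actives inside motif 2", {
  camp <- generate_library(synth_config(n_compounds = 1000,
                                        motif_overlap_prob = 1, seed = 3))
  a <- camp$truth$actives_by_motif
  expect_true(all(a[[1]] %in% a[[2]]))
})

test_that("clusters are separable: within-cluster distances are far below background", {
  for (seed in 1:5) {
    camp <- generate_library(synth_config(n_compounds = 800, seed = seed))
    fp <- camp$library$fingerprints
    cl <- camp$truth$clusters
    within <- c()
    for (k in unique(cl)) {
      members <- names(cl)[cl == k]
      d <- iterscreen:::tanimoto_dist_matrix(fp[members, , drop = FALSE])
      within <- c(within, d[upper.tri(d)])
    }
    others <- setdiff(rownames(fp), names(cl))[1:50]
    d_between <- iterscreen:::tanimoto_dist_matrix(fp[others, ])
    expect_lt(mean(within), mean(d_between[upper.tri(d_between)]) - 0.3)
  }
})

test_that("singleton actives sit far from every cluster prototype", {
  camp <- generate_library(synth_config(n_compounds = 800, seed = 13))
  fp <- camp$library$fingerprints
  for (s in camp$truth$singletons) {
    for (k in unique(camp$truth$clusters)) {
      members <- names(camp$truth$clusters)[camp$truth$clusters == k]
      d <- min(iterscreen:::tanimoto_dist_to_vec(fp[members, , drop = FALSE],
                                                 fp[s, ]))
      expect_gt(d, 0.5)
    }
  }
})

test_that("clustered actives carry larger delta-Tm shifts on average", {
  shifts <- vapply(1:10, function(seed) {
    camp <- generate_library(synth_config(n_compounds = 800, seed = seed))
    tab <- camp$table[camp$table$motif_id == 1, ]
    d <- setNames(tab$delta_tm, tab$compound_id)
    mean(d[names(camp$truth$clusters)], na.rm = TRUE) -
      mean(d[camp$truth$singletons], na.rm = TRUE)
  }, numeric(1))
  expect_gte(sum(shifts > 0), 8)
})

test_that("melt curves round-trip through the estimator", {
  camp <- generate_library(synth_config(n_compounds = 60, seed = 21,
                                        invalid_fraction = 0.1))
  assay <- melt_assay_config(noise_sd = 0.005, seed = 2)
  curves <- generate_melt_curves(camp, assay, motifs = 1L)
  tab <- analyze_melt_curves(curves)
  truth <- camp$table[camp$table$motif_id == 1, ]
  m <- merge(as.data.frame(tab), as.data.frame(truth), by = "compound_id",
             suffixes = c("_est", "_true"))
  valid_both <- m$valid_est & m$valid_true
  # valid compounds: recovered shift within estimator tolerance
  expect_gt(mean(valid_both[m$valid_true]), 0.95)
  expect_true(all(abs(m$delta_tm_est[valid_both] -
                        m$delta_tm_true[valid_both]) < 0.5))
  # constructed invalid curves are rejected by QC
  expect_true(all(!m$valid_est[!m$valid_true]))
})

test_that("near-noiseless curves recover shifts to within 0.2 degC", {
  camp <- generate_library(synth_config(n_compounds = 40, seed = 31,
                                        invalid_fraction = 0))
  assay <- melt_assay_config(noise_sd = 1e-4, seed = 3)
  curves <- generate_melt_curves(camp, assay, motifs = 2L)
  tab <- analyze_melt_curves(curves)
  truth <- camp$table[camp$table$motif_id == 2, ]
  m <- merge(as.data.frame(tab), as.data.frame(truth), by = "compound_id",
             suffixes = c("_est", "_true"))
  keep <- m$valid_est & m$valid_true
  expect_true(all(abs(m$delta_tm_est[keep] - m$delta_tm_true[keep]) < 0.2))
})

test_that("infeasible configurations are rejected", {
  expect_error(synth_config(n_compounds = 20, n_active_clusters = 5,
                            cluster_size_range = c(4, 6)),
               class = "iterscreen_infeasible_config")
})
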