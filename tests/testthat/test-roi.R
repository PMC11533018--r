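test_that("mu +/- 2 sigma trimming follows the single-pass definition", {
  # 100 copies of 10 plus an outlier at 1000: mu ~ 19.80, sigma ~ 98.0,
  # upper bound ~ 215.9, so only the outlier is dropped
  v <- c(rep(10, 100), 1000)
  tm <- trim_and_mean(v)
  expect_equal(tm$trimmed_mean, 10)
  expect_equal(tm$n_used, 100L)

  tm_eq <- trim_and_mean(rep(7.5, 20))
  expect_equal(tm_eq$trimmed_mean, 7.5)
  expect_equal(tm_eq$n_used, 20L)

  tm_sym <- trim_and_mean(c(-1, 0, 1))
  expect_equal(tm_sym$trimmed_mean, 0)
  expect_equal(tm_sym$n_used, 3L)

  expect_error(trim_and_mean(5), "2 values")
})

test_that("trimming removes at most ~5% of Gaussian samples", {
  set.seed(31)
  for (i in 1:20) {
    v <- stats::rnorm(2000)
    tm <- trim_and_mean(v)
    removed <- 1 - tm$n_used / length(v)
    # expected removal is 4.55%; 0.0595 is a +3 sd binomial envelope
    expect_lt(removed, 0.0595)
  }
})

test_that("roi_table trims contamination and flags unusable regions", {
  g <- small_geometry(48)
  ph <- make_phantom(g)
  lt <- ph$label_table
  mask <- array(TRUE, dim = g$grid_shape)

  map_u <- as_chi_map(ph$chi, mask)
  tab <- roi_table(map_u, ph$labels, lt)
  truth <- sapply(seq_len(nrow(lt)), function(i) mean(ph$chi[ph$labels == lt$code[i]]))
  expect_equal(tab$trimmed_mean, truth, tolerance = 1e-12)
  expect_false(any(tab$flagged))

  # 5% of putamen voxels far above mu + 2 sigma are dropped
  chi_c <- ph$chi
  put_l <- which(ph$labels == lt$code[lt$name == "putamen" & lt$hemisphere == "L"])
  n_bad <- round(0.05 * length(put_l))
  set.seed(4)
  bad <- sample(put_l, n_bad)
  chi_c[bad] <- 1e5
  tab_c <- roi_table(as_chi_map(chi_c, mask), ph$labels, lt)
  row <- tab_c[tab_c$roi_name == "putamen" & tab_c$hemisphere == "L", ]
  clean <- tab[tab$roi_name == "putamen" & tab$hemisphere == "L", ]
  expect_equal(row$n_voxels_used, row$n_voxels_total - n_bad)
  expect_lt(abs(row$trimmed_mean - clean$trimmed_mean) / abs(clean$trimmed_mean), 0.01)

  # reliability mask that blanks an ROI yields a flagged, value-free row
  rel <- mask
  rel[ph$labels == lt$code[1]] <- FALSE
  tab_f <- roi_table(map_u, ph$labels, lt, reliability = rel)
  expect_true(tab_f$flagged[1])
  expect_true(is.na(tab_f$trimmed_mean[1]))

  # invariance to relabelling
  relab <- ph$labels
  relab[ph$labels > 0] <- relab[ph$labels > 0] + 500L
  lt2 <- lt; lt2$code <- lt$code + 500L
  tab_r <- roi_table(map_u, relab, lt2)
  expect_equal(tab_r$trimmed_mean, tab$trimmed_mean)
})

test_that("hemisphere test behaves under symmetry, offset and antisymmetry", {
  mk_table <- function(l_vals, r_vals) {
    n <- length(l_vals)
    rbind(
      data.frame(subject_id = sprintf("S%02d", 1:n), roi_name = "putamen",
                 hemisphere = "L", metric = "qsm_ppb", trimmed_mean = l_vals,
                 n_voxels_used = 10L, n_voxels_total = 10L, flagged = FALSE),
      data.frame(subject_id = sprintf("S%02d", 1:n), roi_name = "putamen",
                 hemisphere = "R", metric = "qsm_ppb", trimmed_mean = r_vals,
                 n_voxels_used = 10L, n_voxels_total = 10L, flagged = FALSE))
  }
  set.seed(8)
  base <- stats::rnorm(20, 30, 5)
  ht_eq <- hemisphere_test(mk_table(base, base))
  expect_equal(ht_eq$p_value, 1)

  ht_off <- hemisphere_test(mk_table(base + 5, base))
  expect_lt(ht_off$p_value, 0.01)

  d <- rep(c(2, -2), 10)
  ht_anti <- hemisphere_test(mk_table(base + d, base))
  expect_gt(ht_anti$p_value, 0.5)
})

test_that("hemisphere merging averages, propagates and flags", {
  tab <- rbind(
    data.frame(subject_id = "S01", roi_name = "caudate", hemisphere = "L",
               metric = "qsm_ppb", trimmed_mean = 10, n_voxels_used = 50L,
               n_voxels_total = 50L, flagged = FALSE),
    data.frame(subject_id = "S01", roi_name = "caudate", hemisphere = "R",
               metric = "qsm_ppb", trimmed_mean = 14, n_voxels_used = 50L,
               n_voxels_total = 50L, flagged = FALSE),
    data.frame(subject_id = "S01", roi_name = "thalamus", hemisphere = "L",
               metric = "qsm_ppb", trimmed_mean = NA_real_, n_voxels_used = 0L,
               n_voxels_total = 40L, flagged = TRUE),
    data.frame(subject_id = "S01", roi_name = "thalamus", hemisphere = "R",
               metric = "qsm_ppb", trimmed_mean = 9, n_voxels_used = 40L,
               n_voxels_total = 40L, flagged = FALSE))
  bi <- merge_hemispheres(tab)
  expect_equal(bi$trimmed_mean[bi$roi_name == "caudate"], 12)
  expect_false(bi$flagged[bi$roi_name == "caudate"])
  expect_equal(bi$trimmed_mean[bi$roi_name == "thalamus"], 9)
  expect_true(bi$flagged[bi$roi_name == "thalamus"])

  # merging a mirror-symmetric phantom reproduces either hemisphere
  g <- small_geometry(48)
  ph <- make_phantom(g)
  tabp <- roi_table(as_chi_map(ph$chi, array(TRUE, dim = g$grid_shape)),
                    ph$labels, ph$label_table)
  bip <- merge_hemispheres(tabp)
  l <- tabp[tabp$hemisphere == "L", ]
  expect_equal(bip$trimmed_mean[match(l$roi_name, bip$roi_name)],
               l$trimmed_mean, tolerance = 1e-12)
})

test_that("volume-metric correlations detect exact dependence and degeneracy", {
  n <- 77
  set.seed(12)
  vols <- data.frame(subject_id = sprintf("S%03d", 1:n), roi_name = "putamen",
                     volume = stats::runif(n, 4000, 6000), tiv = 1.5e6)
  tab_lin <- data.frame(subject_id = vols$subject_id, roi_name = "putamen",
                        hemisphere = "bilateral", metric = "qsm_ppb",
                        trimmed_mean = 0.01 * vols$volume + 3)
  res <- volume_metric_correlation(vols, tab_lin)
  pear <- res[res$method == "pearson" & res$volume_measure == "volume", ]
  expect_equal(pear$estimate, 1, tolerance = 1e-9)

  # independent metric: small correlation across a null simulation
  tab_nul <- tab_lin
  tab_nul$trimmed_mean <- stats::rnorm(n, 30, 5)
  res_n <- volume_metric_correlation(vols, tab_nul)
  expect_true(all(abs(res_n$estimate) < 0.35))

  vols_c <- vols; vols_c$volume <- 5000
  res_c <- volume_metric_correlation(vols_c, tab_nul)
  expect_true(all(res_c$flagged))
  expect_true(all(is.na(res_c$estimate)))
})
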