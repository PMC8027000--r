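test_that("missingness filter reads 'more than 50%' strictly", {
  # planted missing fractions 0.0, 0.4, 0.5, 0.6 at threshold 0.5:
  # exactly-half-missing retained, strictly-more removed
  x <- matrix(stats::rlnorm(40), 10, 4)
  x[1:4, 2] <- NA
  x[1:5, 3] <- NA
  x[1:6, 4] <- NA
  ft <- feature_table(x, data.frame(molecule_id = paste0("m", 1:4),
                                    name = paste0("m", 1:4),
                                    class = "metabolite",
                                    msi_level = 3L))
  out <- filter_missingness(ft, 0.5)
  expect_identical(out$table$molecules$molecule_id, c("m1", "m2", "m3"))
  expect_identical(out$report$molecule_id, "m4")
  expect_equal(out$report$missing_fraction, 0.6)
  # surviving values untouched
  expect_equal(out$table$intensities, x[, 1:3], ignore_attr = TRUE)
})

test_that("missingness filter is an identity on complete tables and errors
           when nothing survives", {
  ft <- toy_table()
  out <- filter_missingness(ft, 0.5)
  expect_identical(out$table$intensities, ft$intensities)
  expect_identical(nrow(out$report), 0L)
  x <- ft$intensities
  x[1:10, ] <- NA
  allna <- feature_table(x, ft$molecules)
  expect_error(filter_missingness(allna, 0.5), "nothing left")
})

test_that("retained set matches a per-column counting oracle on random holes", {
  set.seed(123)
  for (rep in 1:5) {
    x <- matrix(stats::rlnorm(200), 20, 10)
    holes <- which(matrix(stats::runif(200) < 0.35, 20, 10))
    x[holes] <- NA
    ft <- feature_table(x, data.frame(molecule_id = paste0("m", 1:10),
                                      name = paste0("m", 1:10),
                                      class = "metabolite", msi_level = 3L))
    thr <- 0.3
    keep_oracle <- which(apply(x, 2, function(col) sum(is.na(col)) / 20) <= thr)
    out <- filter_missingness(ft, thr)
    expect_identical(out$table$molecules$molecule_id,
                     paste0("m", keep_oracle))
  }
})

test_that("knn imputation: identity, duplicate-neighbour, and oracle
           equivalence", {
  ft <- toy_table()
  expect_identical(knn_impute(ft, k = 3)$table$intensities, ft$intensities)

  # molecule 2 duplicates molecule 1 except where molecule 1 is missing:
  # with k = 1 the imputed value must equal the duplicate's value there
  x <- matrix(stats::rlnorm(30, 3), 10, 3)
  x[, 2] <- x[, 1]
  x[1, 1] <- NA
  ft2 <- feature_table(x, data.frame(molecule_id = paste0("m", 1:3),
                                     name = paste0("m", 1:3),
                                     class = "metabolite", msi_level = 3L))
  imp <- knn_impute(ft2, k = 1)
  expect_equal(imp$table$intensities[1, 1], x[1, 2])
  expect_identical(imp$report$imputed_cell_count, 1L)
  # observed cells never altered
  obs <- !is.na(x)
  expect_identical(imp$table$intensities[obs], x[obs])

  # random 30 x 8 with ~10% holes, k = 3: exhaustive oracle to 1e-10
  set.seed(7)
  y <- matrix(stats::rlnorm(240, 3), 30, 8)
  y[matrix(stats::runif(240) < 0.1, 30, 8)] <- NA
  stopifnot(anyNA(y), all(colSums(!is.na(y)) > 0))
  ft3 <- feature_table(y, data.frame(molecule_id = paste0("m", 1:8),
                                     name = paste0("m", 1:8),
                                     class = "metabolite", msi_level = 3L))
  imp3 <- knn_impute(ft3, k = 3)
  expect_false(anyNA(imp3$table$intensities))
  expect_equal(imp3$table$intensities, knn_oracle(y, 3),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("knn imputation errors and fallbacks are explicit", {
  x <- matrix(stats::rlnorm(20, 3), 10, 2)
  x[, 2] <- NA
  ft <- feature_table(x, data.frame(molecule_id = c("a", "b"),
                                    name = c("a", "b"),
                                    class = "metabolite", msi_level = 3L))
  expect_error(knn_impute(ft, 1), "filter_missingness")

  # both neighbours missing in the target sample -> molecule-mean fallback
  y <- matrix(stats::rlnorm(30, 3), 10, 3)
  y[1, ] <- NA  # whole sample missing
  ft2 <- feature_table(y, data.frame(molecule_id = paste0("m", 1:3),
                                     name = paste0("m", 1:3),
                                     class = "metabolite", msi_level = 3L))
  imp <- knn_impute(ft2, k = 2)
  expect_equal(imp$table$intensities[1, ], colMeans(y, na.rm = TRUE),
               ignore_attr = TRUE)
  expect_identical(nrow(imp$report$fallback_cells), 3L)
})

test_that("sum normalization yields unit block row sums and cancels
           dilution", {
  # single-block arithmetic forced: [2,3,5] -> [0.2,0.3,0.5]
  ft <- feature_table(matrix(c(2, 3, 5), 1, 3),
                      data.frame(molecule_id = paste0("m", 1:3),
                                 name = paste0("m", 1:3),
                                 class = "metabolite", msi_level = 3L))
  expect_equal(as.numeric(sum_normalize(ft)$intensities), c(0.2, 0.3, 0.5))
  # idempotence
  expect_equal(sum_normalize(sum_normalize(ft))$intensities,
               sum_normalize(ft)$intensities)

  # block-wise unit row sums on a mixed-class table
  tt <- toy_table()
  nt <- sum_normalize(tt)
  for (cl in c("chemical", "metabolite")) {
    cols <- tt$molecules$class == cl
    expect_equal(rowSums(nt$intensities[, cols, drop = FALSE]),
                 rep(1, nrow(nt$intensities)), ignore_attr = TRUE)
  }

  # scale invariance: multiplying a sample's block by c > 0 changes nothing
  sc <- tt
  sc$intensities[3, tt$molecules$class == "chemical"] <-
    7.5 * sc$intensities[3, tt$molecules$class == "chemical"]
  expect_equal(sum_normalize(sc)$intensities, nt$intensities)

  # dilution factors drawn by the simulator cancel exactly: two cohorts
  # differing only in dilution_sd give identical normalized tables
  base <- list(n_samples = 50, n_chemicals = 5, n_metabolites = 10,
               n_blocks = 2, chemical_edge_count = 5,
               censoring_quantile = 0, seed = 77)
  t0 <- simulate_cohort(do.call(sim_config, c(base, dilution_sd = 0)))$table
  t1 <- simulate_cohort(do.call(sim_config, c(base, dilution_sd = 0.6)))$table
  expect_false(isTRUE(all.equal(t0$intensities, t1$intensities)))
  expect_equal(sum_normalize(t0)$intensities, sum_normalize(t1)$intensities,
               tolerance = 1e-12)

  bad <- ft
  bad$intensities[1, ] <- 0
  expect_error(sum_normalize(bad), "zero metabolite block total")
})

test_that("glog transform: closed forms, monotonicity, invertibility", {
  expect_equal(glog(0, 1), -1)                       # log2(1/2)
  expect_equal(glog(1e6, 1), log2(1e6), tolerance = 1e-6)
  set.seed(5)
  x1 <- stats::runif(1000, 0, 100)
  x2 <- x1 + stats::runif(1000, 1e-6, 10)
  expect_true(all(glog(x1, 2.5) < glog(x2, 2.5)))
  # bijective on its range
  expect_equal(glog_inverse(glog(x1, 0.7), 0.7), x1, tolerance = 1e-9)

  tt <- sum_normalize(toy_table())
  gl <- glog_transform(tt)
  offs <- attr(gl, "glog_offset")
  expect_true(all(offs > 0))
  # default offset is each block's minimum positive value
  for (cl in c("chemical", "metabolite")) {
    blk <- tt$intensities[, tt$molecules$class == cl]
    expect_equal(unname(offs[cl]), min(blk[blk > 0]))
  }
  expect_error(glog_transform(tt, offset = -1), "positive")
})

test_that("block split and merge round-trip with chemicals first", {
  tt <- toy_table()
  # scramble column order so the merge has to restore chemicals-first
  sc <- subset_table(tt, molecules = c(3, 1, 5, 2, 4))
  blocks <- split_blocks(sc)
  merged <- merge_blocks(blocks$chemicals, blocks$metabolites)
  expect_identical(merged$molecules$class,
                   c("chemical", "chemical", "metabolite", "metabolite",
                     "metabolite"))
  expect_identical(ncol(merged$intensities),
                   ncol(blocks$chemicals$intensities) +
                     ncol(blocks$metabolites$intensities))
  # merge-then-split round-trips
  again <- split_blocks(merged)
  expect_identical(again$chemicals$intensities, blocks$chemicals$intensities)
  expect_identical(again$metabolites$intensities,
                   blocks$metabolites$intensities)
  # sample mismatch
  shifted <- blocks$metabolites
  rownames(shifted$intensities) <- rev(rownames(shifted$intensities))
  expect_error(merge_blocks(blocks$chemicals, shifted), "sample ids differ")
})

test_that("the full preprocessing chain orders stages correctly and
           reports what it did", {
  cfg <- sim_config(n_samples = 60, n_chemicals = 6, n_metabolites = 12,
                    n_blocks = 3, chemical_edge_count = 6,
                    censoring_quantile = 0.15, seed = 21)
  tab <- simulate_cohort(cfg)$table
  out <- preprocess(tab, max_missing_fraction = 0.5, k = 5)
  expect_false(anyNA(out$table$intensities))
  expect_identical(out$table$molecules$class,
                   c(rep("chemical", 6), rep("metabolite", 12)))
  expect_identical(out$report$imputed_cell_count,
                   sum(is.na(tab$intensities)))
  expect_identical(out$report$k, 5)
  rp <- tempfile(fileext = ".txt")
  write_preprocess_report(out$report, rp)
  lines <- readLines(rp)
  expect_true(any(grepl("^imputed_cell_count: ", lines)))
  expect_true(any(grepl("^glog_offset: ", lines)))
})

test_that("feature tables round-trip through delimited text with missing
           cells", {
  tt <- toy_table(missing = list(c(1, 2), c(4, 5)))
  f <- tempfile(fileext = ".tsv")
  write_feature_table(tt, f)
  back <- read_feature_table(f)
  expect_equal(back$intensities, tt$intensities)
  expect_identical(back$molecules$molecule_id, tt$molecules$molecule_id)
  expect_identical(back$molecules$class, tt$molecules$class)
})
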