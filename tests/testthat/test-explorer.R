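write_group_folder <- function(dir, group, reps, n = 10, version = "v0.1.7",
                               shift = 0) {
  g <- file.path(dir, group)
  dir.create(g, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_len(reps)) {
    rec <- data.frame(id = seq_len(n),
                      cilia_length_um = round(rnorm(n, 3 + shift, 0.5), 3),
                      volume_um3 = round(rnorm(n, 1, 0.2), 3))
    tab <- cilia_table(rec, metadata = if (!is.null(version))
      run_metadata(version) else NULL,
      group_label = group, replicate_id = paste0("rep", r))
    write_cilia_table(tab, file.path(g, sprintf("rep%d.tsv", r)))
  }
  g
}

test_that("pooling tags records with folder-derived identity and conserves counts", {
  td <- withr::local_tempdir()
  set.seed(1)
  g1 <- write_group_folder(td, "24h_starved", 3)
  g2 <- write_group_folder(td, "72h_starved", 3)
  ds <- pool_groups(c(g1, g2))
  expect_equal(nrow(ds$records), 60L)
  expect_setequal(unique(ds$records$group), c("24h_starved", "72h_starved"))
  expect_equal(length(unique(ds$records$replicate)), 3L)

  expect_error(pool_groups(c(g1, g1)), "duplicate group")
  empty <- file.path(td, "empty"); dir.create(empty)
  expect_error(pool_groups(empty), "no tables")
})

test_that("tool-version consistency is checked across pooled tables", {
  td <- withr::local_tempdir()
  set.seed(2)
  g1 <- write_group_folder(td, "a", 2)
  g2 <- write_group_folder(td, "b", 2)
  ds <- pool_groups(c(g1, g2))
  vc <- check_version_consistency(ds)
  expect_true(vc$consistent)

  td2 <- withr::local_tempdir()
  g1 <- write_group_folder(td2, "a", 1, version = "v0.1.7")
  g2 <- write_group_folder(td2, "b", 1, version = "v0.1.6")
  ds2 <- pool_groups(c(g1, g2))
  expect_warning(vc2 <- check_version_consistency(ds2), "mismatch")
  expect_false(vc2$consistent)
  expect_match(vc2$message, "v0.1.6")
  expect_match(vc2$message, "v0.1.7")

  td3 <- withr::local_tempdir()
  g1 <- write_group_folder(td3, "a", 1, version = "v0.1.7")
  g2 <- write_group_folder(td3, "b", 1, version = NULL)
  ds3 <- pool_groups(c(g1, g2))
  expect_warning(vc3 <- check_version_consistency(ds3), "unknown")
  expect_true(vc3$consistent)
})

test_that("the QC screen flags fences, branching and zero lengths, advisory only", {
  mk <- function(len, branches = 1) {
    rec <- data.frame(id = seq_along(len), cilia_length_um = len,
                      volume_um3 = rep(1, length(len)),
                      max_span_um = rep(2, length(len)),
                      intensity_mean = rep(100, length(len)),
                      intensity_sd = rep(5, length(len)),
                      n_branches = branches)
    cilia_table(rec, metadata = run_metadata("v0.1.7"),
                group_label = "g", replicate_id = "r1")
  }
  # identical values everywhere: zero flags
  ds <- grouped_dataset(list(mk(rep(3, 10))))
  qc <- qc_screen(ds)
  expect_equal(nrow(qc$flags), 0L)

  # planted 10x-median outlier flagged for length
  ds2 <- grouped_dataset(list(mk(c(rep(3, 12), 30))))
  qc2 <- qc_screen(ds2)
  expect_true(any(qc2$flags$measurement == "cilia_length_um" &
                  qc2$flags$reason == "outlier"))

  # a 15-branch record is flagged as highly branched
  ds3 <- grouped_dataset(list(mk(rep(3, 8), branches = c(rep(1, 7), 15))))
  qc3 <- qc_screen(ds3)
  expect_true(any(qc3$flags$reason == "highly-branched"))

  # zero-length records are informational flags
  ds4 <- grouped_dataset(list(mk(c(rep(3, 6), 0))))
  qc4 <- qc_screen(ds4)
  expect_true(any(grepl("zero-length", qc4$flags$reason)))

  # tiny group: fences skipped with a notice, no error
  ds5 <- grouped_dataset(list(mk(c(1, 50))))
  qc5 <- qc_screen(ds5)
  expect_true(any(grepl("skipped", qc5$notices)))
})

test_that("feature selection excludes exactly the segmentation-property columns", {
  rec <- data.frame(id = 1:20, x = runif(20), y = runif(20), z = runif(20),
                    volume_voxels = sample(50:100, 20),
                    volume_um3 = runif(20),
                    threshold_value = rep(300, 20),
                    cilia_length_um = rnorm(20, 3),
                    surface_um2 = rnorm(20, 5),
                    constant_col = rep(1, 20))
  out <- select_features(rec)
  expect_setequal(colnames(out$features),
                  c("volume_um3", "cilia_length_um", "surface_um2"))
  expect_setequal(
    out$excluded$column[out$excluded$reason %in%
                        c("id", "coordinate", "threshold",
                          "voxel-duplicate", "zero-variance")],
    c("id", "x", "y", "z", "threshold_value", "volume_voxels",
      "constant_col"))
  # standardized to zero mean, unit variance
  expect_equal(unname(colMeans(out$features)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(out$features, 2, sd)), rep(1, 3),
               tolerance = 1e-12)

  expect_error(select_features(data.frame(id = 1:5, x = 1:5)),
               "fewer than two")
})

test_that("PCA separates planted groups and is deterministic up to fixed signs", {
  set.seed(9)
  n <- 60
  f <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  f[1:30, 1:3] <- f[1:30, 1:3] + 5      # 5-sd offset on 3 features
  f <- scale(f)
  e1 <- embed_cilia(f, "pca")
  e2 <- embed_cilia(f, "pca")
  expect_identical(e1$coords, e2$coords)
  cen1 <- colMeans(e1$coords[1:30, ])
  cen2 <- colMeans(e1$coords[31:60, ])
  spread <- max(apply(e1$coords[1:30, ], 2, sd),
                apply(e1$coords[31:60, ], 2, sd))
  expect_gt(sqrt(sum((cen1 - cen2)^2)), spread)

  ident <- matrix(1, 10, 3)
  expect_error(embed_cilia(scale(ident, scale = FALSE), "pca"),
               "identical")
})

test_that("UMAP embedding is reproducible for a fixed seed", {
  set.seed(10)
  f <- scale(matrix(rnorm(40 * 4), 40, 4))
  u1 <- embed_cilia(f, "umap", seed = 42)
  u2 <- embed_cilia(f, "umap", seed = 42)
  expect_identical(u1$coords, u2$coords)
  expect_equal(dim(u1$coords), c(40L, 2L))
  expect_warning(embed_cilia(f[1:8, ], "umap", seed = 1, n_neighbors = 15),
                 "n_neighbors")
})

test_that("LDA ranks the planted-effect feature first", {
  set.seed(12)
  n <- 80
  f <- cbind(cilia_length_um = rnorm(n), volume_um3 = rnorm(n),
             surface_um2 = rnorm(n))
  g <- rep(c("a", "b"), each = n / 2)
  f[g == "b", "cilia_length_um"] <- f[g == "b", "cilia_length_um"] + 3
  out <- discriminate(scale(f), g)
  expect_identical(out$ranking$feature[1], "cilia_length_um")
  expect_equal(ncol(out$coefficients), 1L)

  # two near-identical groups: near-zero separation
  f0 <- scale(cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n)))
  out0 <- discriminate(f0, g)
  expect_lt(max(abs(colMeans(f0[g == "a", , drop = FALSE]) %*%
                    out0$coefficients -
                    colMeans(f0[g == "b", , drop = FALSE]) %*%
                    out0$coefficients)), 1)

  # 3 groups: 2 discriminant axes
  g3 <- rep(c("a", "b", "c"), length.out = n)
  out3 <- discriminate(f0, g3)
  expect_equal(ncol(out3$coefficients), 2L)
  expect_error(discriminate(f0, rep("a", n)), "two groups")
})

test_that("the decision tree picks tests from normality and homogeneity", {
  set.seed(20)
  # two lognormal groups: Mann-Whitney U
  ds <- make_two_group_dataset(rlnorm(60, 1, 0.8), rlnorm(60, 1.2, 0.8))
  expect_identical(choose_test(ds, "cilia_length_um")$test, "Mann-Whitney U")

  # two normal equal-variance groups: Student's t
  ds <- make_two_group_dataset(rnorm(60, 3, 0.5), rnorm(60, 3.3, 0.5))
  expect_identical(choose_test(ds, "cilia_length_um")$test, "Student's t")

  # normal but strongly heteroscedastic: Welch's t
  ds <- make_two_group_dataset(rnorm(80, 3, 0.2), rnorm(80, 3.2, 2))
  expect_identical(choose_test(ds, "cilia_length_um")$test, "Welch's t")

  # one group: no statistical analysis
  rec <- data.frame(id = 1:10, cilia_length_um = rnorm(10, 3))
  one <- grouped_dataset(list(cilia_table(rec,
    metadata = run_metadata("v0.1.7"), group_label = "only",
    replicate_id = "r1")))
  expect_identical(choose_test(one, "cilia_length_um")$test, "none")

  # fewer than 3 records in a group: no test run
  tiny <- make_two_group_dataset(c(1, 2), rnorm(10, 3))
  expect_identical(choose_test(tiny, "cilia_length_um")$test,
                   "insufficient n")

  # the trace records every intermediate p-value
  ds <- make_two_group_dataset(rnorm(30, 3, 0.5), rnorm(30, 3, 0.5))
  tr <- choose_test(ds, "cilia_length_um")$trace
  expect_equal(sum(tr$check == "shapiro"), 2L)
  expect_equal(sum(tr$check == "levene"), 1L)
})

test_that("three-group branches select ANOVA, Welch ANOVA or Kruskal-Wallis", {
  mk3 <- function(x1, x2, x3) {
    tabs <- Map(function(x, g) {
      rec <- data.frame(id = seq_along(x), m = x)
      cilia_table(rec, metadata = run_metadata("v0.1.7"),
                  group_label = g, replicate_id = "r1")
    }, list(x1, x2, x3), c("a", "b", "c"))
    grouped_dataset(tabs)
  }
  set.seed(30)
  ds <- mk3(rnorm(50, 1, 1), rnorm(50, 1.5, 1), rnorm(50, 2, 1))
  ch <- choose_test(ds, "m")
  expect_identical(ch$test, "one-way ANOVA")
  expect_identical(ch$posthoc, "Tukey HSD")
  st <- run_stats(ds, "m")
  expect_s3_class(st$m$posthoc, "data.frame")
  expect_equal(nrow(st$m$posthoc), 3L)

  ds <- mk3(rnorm(60, 1, 0.2), rnorm(60, 1.5, 1.5), rnorm(60, 2, 3))
  ch <- choose_test(ds, "m")
  expect_identical(ch$test, "Welch ANOVA")
  expect_identical(ch$posthoc, "Games-Howell")

  ds <- mk3(rlnorm(60, 0, 1), rlnorm(60, 0.3, 1), rlnorm(60, 0.6, 1))
  ch <- choose_test(ds, "m")
  expect_identical(ch$test, "Kruskal-Wallis")
  expect_identical(ch$posthoc, "Dunn (Holm)")
  st <- run_stats(ds, "m")
  expect_true(all(c("group1", "group2", "p_value") %in%
                  names(st$m$posthoc)))
})

test_that("stars map p-values at the exact boundaries", {
  expect_identical(significance_stars(c(0.0009, 0.001, 0.0011, 0.01,
                                        0.011, 0.05, 0.051, NA)),
                   c("***", "***", "**", "**", "*", "*", "ns", "ns"))
})

test_that("run_stats executes the chosen test and writes coherent results", {
  set.seed(31)
  ds <- make_two_group_dataset(rnorm(100, 3, 0.5), rnorm(100, 5, 0.5))
  st <- run_stats(ds, "cilia_length_um")
  expect_identical(st$cilia_length_um$stars, "***")
  expect_lt(st$cilia_length_um$p_value, 0.001)

  # no-stats mode skips testing entirely
  st0 <- run_stats(ds, "cilia_length_um", no_stats = TRUE)
  expect_true(is.na(st0$cilia_length_um$p_value))

  # integer-valued measurements warn as ordinal
  rec1 <- data.frame(id = 1:30, n_branches = rpois(30, 2) + 1L)
  rec2 <- data.frame(id = 1:30, n_branches = rpois(30, 4) + 1L)
  ds2 <- grouped_dataset(list(
    cilia_table(rec1, metadata = run_metadata("v0.1.7"),
                group_label = "a", replicate_id = "r1"),
    cilia_table(rec2, metadata = run_metadata("v0.1.7"),
                group_label = "b", replicate_id = "r1")))
  expect_warning(run_stats(ds2, "n_branches"), "ordinal")
})

test_that("superplots overlay correct replicate means and quantiles", {
  td <- withr::local_tempdir()
  set.seed(33)
  g1 <- write_group_folder(td, "ctrl", 3, n = 15)
  g2 <- write_group_folder(td, "trt", 3, n = 15, shift = 1)
  ds <- pool_groups(c(g1, g2))
  p <- make_superplot(ds, "cilia_length_um")
  means <- attr(p, "replicate_means")
  direct <- aggregate(cilia_length_um ~ group + replicate, ds$records, mean)
  m <- merge(means, direct, by.x = c("group", "replicate"),
             by.y = c("group", "replicate"))
  expect_equal(m$value, m$cilia_length_um)
  expect_s3_class(p, "ggplot")

  # single replicate renders without a replicate legend
  ds1 <- grouped_dataset(list(cilia_table(
    data.frame(id = 1:10, cilia_length_um = rnorm(10, 3)),
    metadata = run_metadata("v0.1.7"), group_label = "only",
    replicate_id = "r1")))
  p1 <- make_superplot(ds1, "cilia_length_um")
  expect_s3_class(p1, "ggplot")
})

test_that("the output tree is complete, conservative and reproducible", {
  td <- withr::local_tempdir()
  set.seed(34)
  g1 <- write_group_folder(td, "ctrl", 2, n = 12)
  g2 <- write_group_folder(td, "trt", 2, n = 12, shift = 1)
  ds <- pool_groups(c(g1, g2))
  qc <- qc_screen(ds)
  st <- run_stats(ds, c("cilia_length_um", "volume_um3"))
  files <- write_outputs(ds, qc, st, first_group_path = g1,
                         annotations = c(objective = "63x oil"))
  root <- file.path(g1, "Analysis")
  expect_true(dir.exists(file.path(root, "Data")))
  expect_true(dir.exists(file.path(root, "Plots")))
  # conservation: output record count equals pooled input count
  pooled <- read.csv(file.path(root, "Data", "pooled_records.csv"))
  expect_equal(nrow(pooled), nrow(ds$records))
  # metafile annotations echoed into the summary
  expect_true(any(grepl("63x oil", readLines(file.path(root,
                                                       "summary.txt")))))
  # qc file lists exactly the QC flags
  qc_lines <- readLines(file.path(root, "qc.txt"))
  expect_true(any(grepl(sprintf("flags: %d", nrow(qc$flags)), qc_lines)))
  # raster and vector format for every superplot
  pls <- list.files(file.path(root, "Plots"))
  expect_true(all(c("superplot_cilia_length_um.png",
                    "superplot_cilia_length_um.svg") %in% pls))
  # rerun: byte-identical Data tables
  before <- readBin(file.path(root, "Data", "pooled_records.csv"),
                    "raw", 1e6)
  write_outputs(ds, qc, st, first_group_path = g1,
                annotations = c(objective = "63x oil"))
  after <- readBin(file.path(root, "Data", "pooled_records.csv"),
                   "raw", 1e6)
  expect_identical(before, after)
})
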