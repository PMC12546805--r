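# Explorer stage: pool per-condition folders of cilium tables, run quality
# control, select and execute the statistics decision tree, run
# dimensionality reduction with the feature-exclusion rules, and emit
# superplots and report files.

#' Pooled, replicate-aware dataset of cilium tables
#'
#' @param tables list of [cilia_table()] with group/replicate labels set.
#' @param provenance character vector of source folder paths.
#' @return an object of class `grouped_dataset` with the pooled `records`
#'   data.frame (columns `group`, `replicate`, then the measurements) and the
#'   set of tool versions seen.
#' @export
grouped_dataset <- function(tables, provenance = character(0)) {
  stopifnot(length(tables) >= 1L)
  recs <- lapply(tables, function(t) {
    if (is.na(t$group_label) || !nzchar(t$group_label))
      stop("pooled tables must carry a group label")
    if (is.na(t$replicate_id) || !nzchar(t$replicate_id))
      stop("pooled tables must carry a replicate id")
    cbind(data.frame(group = t$group_label, replicate = t$replicate_id,
                     stringsAsFactors = FALSE), t$records)
  })
  common <- Reduce(intersect, lapply(recs, names))
  records <- do.call(rbind, lapply(recs, function(r) r[common]))
  rownames(records) <- NULL
  versions <- vapply(tables, function(t)
    if (!is.null(t$metadata)) t$metadata$tool_version else NA_character_, "")
  groups <- split(tables, vapply(tables, function(t) t$group_label, ""))
  structure(list(groups = groups, records = records,
                 versions_seen = versions, provenance = provenance),
            class = "grouped_dataset")
}

#' @export
print.grouped_dataset <- function(x, ...) {
  cat(sprintf("<grouped_dataset> %d cilia, %d group(s): %s\n",
              nrow(x$records), length(x$groups),
              paste(names(x$groups), collapse = ", ")))
  invisible(x)
}

#' Pool per-condition folders of cilium tables
#'
#' Each folder is one experimental condition; its name becomes the group
#' label in all outputs, and every table file inside becomes one replicate.
#' An empty folder or an unreadable table raises (no silent skips); listing
#' the same folder twice is a duplicate-group error.
#'
#' @param folders character vector of folder paths.
#' @return a [grouped_dataset()].
#' @export
pool_groups <- function(folders) {
  if (!length(folders)) stop("need at least one group folder")
  labels <- basename(normalizePath(folders, mustWork = TRUE))
  if (anyDuplicated(labels))
    stop("duplicate group folder(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  tables <- list()
  for (i in seq_along(folders)) {
    files <- sort(list.files(folders[i], pattern = "\\.(tsv|txt)$",
                             full.names = TRUE))
    files <- files[!grepl("_meta\\.txt$", files)]
    if (!length(files))
      stop("group folder contains no tables: ", folders[i])
    for (f in files) {
      tab <- read_cilia_table(f, group_label = labels[i],
                              replicate_id = tools::file_path_sans_ext(
                                basename(f)))
      tables[[length(tables) + 1L]] <- tab
    }
  }
  grouped_dataset(tables, provenance = folders)
}

#' Check tool-version consistency across a pooled dataset
#'
#' Comparing data analyzed with different tool versions can introduce a
#' batch-dependent bias, so pooled data is checked by default: consistent iff
#' all non-missing version strings are identical. A mismatch produces a
#' prominent warning listing the versions; missing versions produce an
#' "unknown version" warning but do not fail the check.
#'
#' @param dataset a [grouped_dataset()].
#' @return list: `consistent` flag, `versions` seen, `message`.
#' @export
check_version_consistency <- function(dataset) {
  v <- dataset$versions_seen
  known <- unique(v[!is.na(v)])
  consistent <- length(known) <= 1L
  msg <- if (!consistent) {
    m <- paste0("tool version mismatch across pooled tables: {",
                paste(known, collapse = ", "),
                "}; comparing data from different tool versions might ",
                "introduce a batch-dependent bias")
    warning(m)
    m
  } else if (any(is.na(v))) {
    m <- "unknown tool version in at least one table"
    warning(m)
    m
  } else sprintf("all tables from version %s", known)
  list(consistent = consistent, versions = v, message = msg)
}

qc_default_measurements <- function(records) {
  intersect(c("cilia_length_um", "volume_um3", "max_span_um",
              "intensity_mean", "intensity_sd"), names(records))
}

#' Advisory quality-control screen
#'
#' Flags, per group, values of the QC measurements (cilium length, volume,
#' maximum span, mean marker intensity and its standard deviation) outside
#' the Tukey fences `[Q1 - k*IQR, Q3 + k*IQR]`, records with more than
#' `branch_limit` skeleton branches (a clean cilium has one), and
#' zero-length records (often spherical objects; informational). QC is
#' advisory: flags never remove records from the analysis.
#'
#' @param dataset a [grouped_dataset()].
#' @param fence_multiplier Tukey fence multiplier k (default 1.5).
#' @param branch_limit flag records with `n_branches` above this (default 1).
#' @return an object of class `qc_report`: `flags` data.frame (`group`,
#'   `replicate`, `id`, `measurement`, `reason`, `value`), `notices`,
#'   `version_consistent`, `per_group_counts`.
#' @export
qc_screen <- function(dataset, fence_multiplier = 1.5, branch_limit = 1L) {
  stopifnot(inherits(dataset, "grouped_dataset"))
  rec <- dataset$records
  if (!nrow(rec)) stop("empty dataset")
  flags <- list()
  notices <- character(0)
  add_flag <- function(rows, measurement, reason) {
    if (!nrow(rows)) return()
    flags[[length(flags) + 1L]] <<- data.frame(
      group = rows$group, replicate = rows$replicate, id = rows$id,
      measurement = measurement, reason = reason,
      value = rows[[measurement]], stringsAsFactors = FALSE)
  }
  for (g in unique(rec$group)) {
    sub <- rec[rec$group == g, , drop = FALSE]
    if (nrow(sub) < 4L) {
      notices <- c(notices, sprintf(
        "group '%s' has %d record(s): outlier fences skipped", g, nrow(sub)))
    } else {
      for (m in qc_default_measurements(rec)) {
        v <- sub[[m]]
        q <- quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
        iqr <- q[2] - q[1]
        out <- !is.na(v) & (v < q[1] - fence_multiplier * iqr |
                            v > q[2] + fence_multiplier * iqr)
        add_flag(sub[out, , drop = FALSE], m, "outlier")
      }
    }
    if ("n_branches" %in% names(sub)) {
      hb <- !is.na(sub$n_branches) & sub$n_branches > branch_limit
      add_flag(sub[hb, , drop = FALSE], "n_branches", "highly-branched")
    }
    if ("cilia_length_um" %in% names(sub)) {
      zl <- !is.na(sub$cilia_length_um) & sub$cilia_length_um == 0
      add_flag(sub[zl, , drop = FALSE], "cilia_length_um",
               "zero-length (informational; often spherical objects)")
    }
  }
  vc <- withCallingHandlers(check_version_consistency(dataset),
                            warning = function(w) {
                              notices <<- c(notices, conditionMessage(w))
                              invokeRestart("muffleWarning")
                            })
  flags_df <- if (length(flags)) do.call(rbind, flags) else
    data.frame(group = character(0), replicate = character(0),
               id = numeric(0), measurement = character(0),
               reason = character(0), value = numeric(0))
  structure(list(flags = flags_df, notices = notices,
                 version_consistent = vc$consistent,
                 per_group_counts = table(rec$group)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d flag(s), version %s\n", nrow(x$flags),
              if (x$version_consistent) "consistent" else "INCONSISTENT"))
  for (n in x$notices) cat("  note:", n, "\n")
  invisible(x)
}

qc_report_lines <- function(qc) {
  c("quality control report",
    sprintf("version consistent: %s", qc$version_consistent),
    sprintf("records per group: %s",
            paste(names(qc$per_group_counts), qc$per_group_counts,
                  sep = "=", collapse = ", ")),
    if (length(qc$notices)) paste("note:", qc$notices),
    sprintf("flags: %d", nrow(qc$flags)),
    if (nrow(qc$flags))
      sprintf("  %s/%s cilium %s: %s %s (value %.3f)", qc$flags$group,
              qc$flags$replicate, format(qc$flags$id), qc$flags$measurement,
              qc$flags$reason, qc$flags$value))
}

#' Select and standardize the feature matrix for dimensionality reduction
#'
#' Excludes columns that encode segmentation rather than ciliary properties:
#' the cilium id, spatial coordinates (x/y/z centroids), intensity-threshold
#' columns, voxel-unit duplicates of micrometer-unit columns (kept once, in
#' physical units, to avoid double weighting), non-numeric columns and
#' zero-variance columns. Retained columns are standardized to zero mean and
#' unit variance.
#'
#' @param dataset a [grouped_dataset()] or a records data.frame.
#' @return list: `features` (standardized matrix), `excluded` data.frame
#'   (`column`, `reason`), `center`, `scale`.
#' @export
select_features <- function(dataset) {
  rec <- if (inherits(dataset, "grouped_dataset")) dataset$records
         else dataset
  cols <- setdiff(names(rec), c("group", "replicate"))
  excluded <- data.frame(column = character(0), reason = character(0))
  drop <- function(cs, reason) {
    if (!length(cs)) return()
    excluded <<- rbind(excluded, data.frame(column = cs, reason = reason))
    cols <<- setdiff(cols, cs)
  }
  drop(intersect(cols, c("id", "cilium_id")), "id")
  drop(cols[grepl("^(centroid_)?[xyz](_um)?$", cols) |
            grepl("^centroid_[xyz]_um$", cols)], "coordinate")
  drop(cols[grepl("threshold", cols, ignore.case = TRUE)], "threshold")
  vox <- cols[grepl("_voxels?$", cols)]
  vox_dup <- vox[vapply(vox, function(v) {
    stem <- sub("_voxels?$", "", v)
    any(grepl(paste0("^", stem, "_um[0-9]?$"), cols))
  }, TRUE)]
  drop(vox_dup, "voxel-duplicate")
  nonnum <- cols[!vapply(rec[cols], is.numeric, TRUE)]
  drop(nonnum, "non-numeric")
  allna <- cols[vapply(rec[cols], function(v) all(is.na(v)), TRUE)]
  drop(allna, "all-missing")
  zv <- cols[vapply(rec[cols], function(v) var(v, na.rm = TRUE) == 0 ||
                      is.na(var(v, na.rm = TRUE)), TRUE)]
  drop(zv, "zero-variance")
  if (length(cols) < 2L)
    stop("fewer than two features remain after exclusion")
  x <- as.matrix(rec[cols])
  x[is.na(x)] <- matrix(rep(colMeans(x, na.rm = TRUE), each = nrow(x)),
                        nrow(x))[is.na(x)]
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  feats <- scale(x, center = ctr, scale = scl)
  list(features = feats, excluded = excluded, center = ctr, scale = scl)
}

#' 2D embedding of the feature matrix
#'
#' PCA is deterministic up to sign; the sign convention makes the
#' largest-magnitude loading of each component positive. UMAP runs the
#' reference umap-learn implementation through the python interpreter with a
#' fixed seed, so repeated runs with the same seed give identical
#' coordinates.
#'
#' @param features standardized feature matrix (rows = cilia).
#' @param method `"pca"` or `"umap"`.
#' @param seed integer seed (UMAP).
#' @param n_neighbors,min_dist UMAP parameters; `n_neighbors` is reduced
#'   with a warning when it exceeds the record count.
#' @return list: `coords` (n x 2), `method`, and for PCA
#'   `explained_variance` (proportions) and `rotation`.
#' @export
embed_cilia <- function(features, method = c("pca", "umap"), seed = 42L,
                        n_neighbors = 15L, min_dist = 0.1) {
  method <- match.arg(method)
  if (nrow(features) <= 2L) stop("need more than two records to embed")
  if (method == "pca") {
    if (all(apply(features, 2, sd) == 0))
      stop("explained variance undefined: all records identical")
    p <- prcomp(features, center = FALSE, scale. = FALSE)
    for (j in 1:2) {
      i <- which.max(abs(p$rotation[, j]))
      if (p$rotation[i, j] < 0) {
        p$rotation[, j] <- -p$rotation[, j]
        p$x[, j] <- -p$x[, j]
      }
    }
    ev <- p$sdev^2 / sum(p$sdev^2)
    list(coords = p$x[, 1:2, drop = FALSE], method = "pca",
         explained_variance = ev[1:2], rotation = p$rotation[, 1:2])
  } else {
    if (n_neighbors >= nrow(features)) {
      n_neighbors <- max(2L, nrow(features) - 1L)
      warning("n_neighbors reduced to ", n_neighbors,
              " (exceeds record count)")
    }
    umap_embed(features, seed, n_neighbors, min_dist)
  }
}

umap_embed <- function(features, seed, n_neighbors, min_dist) {
  py <- Sys.which("python")
  if (!nzchar(py)) stop("python interpreter not found for UMAP embedding")
  script <- system.file("python", "umap_embed.py", package = "ciliometry")
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)))
  utils::write.table(features, fin, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  status <- system2(py, c(script, fin, fout, as.integer(seed),
                          as.integer(n_neighbors), min_dist),
                    stdout = FALSE, stderr = "")
  if (status != 0 || !file.exists(fout))
    stop("UMAP embedding failed (python exit status ", status, ")")
  coords <- as.matrix(utils::read.csv(fout, header = FALSE))
  colnames(coords) <- c("UMAP1", "UMAP2")
  list(coords = coords, method = "umap", seed = seed,
       n_neighbors = n_neighbors, min_dist = min_dist)
}

#' Per-feature discrimination weights (LDA)
#'
#' Linear Discriminant Analysis on the standardized feature matrix,
#' returning the absolute discriminant coefficients per measurement, ranked;
#' the top-ranked feature is the one contributing most to class separation.
#' With g groups the coefficient table has `min(g - 1, p)` axes.
#'
#' @param features standardized feature matrix.
#' @param groups group labels (>= 2 distinct).
#' @return list: `coefficients` (p x axes matrix), `ranking` data.frame
#'   (`feature`, `score`) sorted decreasing.
#' @export
discriminate <- function(features, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L)
    stop("LDA needs at least two groups")
  fit <- MASS::lda(features, grouping = groups)
  coefs <- fit$scaling
  prop <- fit$svd^2 / sum(fit$svd^2)
  score <- as.numeric(abs(coefs) %*% prop[seq_len(ncol(coefs))])
  ranking <- data.frame(feature = rownames(coefs), score = score)
  ranking <- ranking[order(-ranking$score), ]
  rownames(ranking) <- NULL
  list(coefficients = coefs, ranking = ranking)
}

#' Choose a statistical test through the decision tree
#'
#' One condition: no test. Otherwise every group is Shapiro-tested for
#' normality and the groups are Levene-tested (median-centered) for variance
#' homogeneity, both at `alpha`. All normal and homogeneous: Student's t
#' (2 groups) or one-way ANOVA with Tukey post-hoc (> 2). Normal but
#' heterogeneous: Welch's t or Welch ANOVA with Games-Howell. Any group
#' non-normal: Mann-Whitney U or Kruskal-Wallis with Dunn (Holm-corrected).
#' Each group needs at least 3 records, otherwise no test is run. For group
#' sizes above 5000 the Shapiro test is applied to a seeded subsample of
#' 5000 (the test's validity limit).
#'
#' @param dataset a [grouped_dataset()] (or records data.frame with `group`).
#' @param measurement measurement column name.
#' @param alpha decision significance level.
#' @return list: `test` (name or "none"/"insufficient n"), `posthoc`,
#'   `trace` data.frame recording every intermediate check and p-value.
#' @export
choose_test <- function(dataset, measurement, alpha = 0.05) {
  rec <- if (inherits(dataset, "grouped_dataset")) dataset$records
         else dataset
  if (!measurement %in% names(rec)) stop("unknown measurement ", measurement)
  v <- rec[[measurement]]
  g <- as.factor(rec$group)
  ok <- !is.na(v)
  v <- v[ok]; g <- droplevels(g[ok])
  k <- nlevels(g)
  trace <- data.frame(check = character(0), detail = character(0),
                      p = numeric(0))
  note <- function(check, detail, p = NA_real_)
    trace <<- rbind(trace, data.frame(check = check, detail = detail, p = p))
  if (k == 1L) {
    note("group count", "1 condition: no statistical analysis")
    return(list(test = "none", posthoc = NULL, trace = trace))
  }
  n <- tapply(v, g, length)
  if (any(n < 3L)) {
    note("sample size", paste0("group(s) with fewer than 3 cilia: ",
                               paste(names(n)[n < 3], collapse = ", ")))
    return(list(test = "insufficient n", posthoc = NULL, trace = trace))
  }
  normal <- TRUE
  for (lv in levels(g)) {
    x <- v[g == lv]
    if (length(x) > 5000L) {
      x <- with_seed(42L, sample(x, 5000L))
      note("shapiro subsample", sprintf("group %s subsampled to 5000", lv))
    }
    p <- if (length(unique(x)) == 1L) 0 else shapiro.test(x)$p.value
    note("shapiro", lv, p)
    if (p < alpha) normal <- FALSE
  }
  homogeneous <- NA
  if (normal) {
    lv <- car::leveneTest(v ~ g, center = stats::median)
    p_lev <- lv[["Pr(>F)"]][1]
    note("levene", "median-centered", p_lev)
    homogeneous <- p_lev >= alpha
  }
  if (!normal) {
    test <- if (k == 2L) "Mann-Whitney U" else "Kruskal-Wallis"
    posthoc <- if (k > 2L) "Dunn (Holm)" else NULL
  } else if (homogeneous) {
    test <- if (k == 2L) "Student's t" else "one-way ANOVA"
    posthoc <- if (k > 2L) "Tukey HSD" else NULL
  } else {
    test <- if (k == 2L) "Welch's t" else "Welch ANOVA"
    posthoc <- if (k > 2L) "Games-Howell" else NULL
  }
  note("decision", sprintf("%d groups, %s, %s", k,
                           if (normal) "all normal" else "non-normal",
                           if (is.na(homogeneous)) "homogeneity not tested"
                           else if (homogeneous) "homogeneous variances"
                           else "heterogeneous variances"))
  list(test = test, posthoc = posthoc, trace = trace)
}

execute_test <- function(test, v, g) {
  g <- droplevels(as.factor(g))
  switch(test,
    "Student's t" = {
      r <- t.test(v ~ g, var.equal = TRUE)
      list(statistic = unname(r$statistic), p_value = r$p.value)
    },
    "Welch's t" = {
      r <- t.test(v ~ g, var.equal = FALSE)
      list(statistic = unname(r$statistic), p_value = r$p.value)
    },
    "Mann-Whitney U" = {
      r <- wilcox.test(v ~ g, exact = FALSE, correct = TRUE)
      list(statistic = unname(r$statistic), p_value = r$p.value)
    },
    "one-way ANOVA" = {
      r <- summary(aov(v ~ g))[[1]]
      list(statistic = r[["F value"]][1], p_value = r[["Pr(>F)"]][1])
    },
    "Welch ANOVA" = {
      r <- oneway.test(v ~ g, var.equal = FALSE)
      list(statistic = unname(r$statistic), p_value = r$p.value)
    },
    "Kruskal-Wallis" = {
      r <- kruskal.test(v, g)
      list(statistic = unname(r$statistic), p_value = r$p.value)
    },
    stop("unknown test ", test))
}

execute_posthoc <- function(posthoc, v, g) {
  g <- droplevels(as.factor(g))
  switch(posthoc,
    "Tukey HSD" = {
      t <- TukeyHSD(aov(v ~ g))$g
      pairs <- strsplit(rownames(t), "-", fixed = TRUE)
      data.frame(group1 = vapply(pairs, `[`, "", 1L),
                 group2 = vapply(pairs, `[`, "", 2L),
                 statistic = t[, "diff"], p_value = t[, "p adj"],
                 row.names = NULL)
    },
    "Games-Howell" = games_howell(v, g),
    "Dunn (Holm)" = dunn_test(v, g, "holm"),
    stop("unknown post-hoc ", posthoc))
}

#' Run the statistics stage
#'
#' Chooses (via [choose_test()]) and executes the test per measurement,
#' computes significance stars at the fixed thresholds, runs the post-hoc
#' pairwise table where applicable, and collects everything into
#' `stats_result` objects. With `no_stats = TRUE` all testing is skipped
#' (summary tables are still produced by [write_outputs()]). Integer-valued
#' measurements are labeled ordinal in the output and still tested with the
#' same tree, with a warning that such results need care.
#'
#' @param dataset a [grouped_dataset()].
#' @param measurements measurement column names (default: all numeric
#'   measurement columns).
#' @param alpha significance level.
#' @param no_stats skip hypothesis testing entirely.
#' @return named list of per-measurement results: `test`, `statistic`,
#'   `p_value`, `stars`, `posthoc` table, `trace`, `ordinal`.
#' @export
run_stats <- function(dataset, measurements = NULL, alpha = 0.05,
                      no_stats = FALSE) {
  rec <- dataset$records
  if (is.null(measurements)) {
    measurements <- setdiff(names(rec)[vapply(rec, is.numeric, TRUE)],
                            c("id"))
  }
  res <- list()
  for (m in measurements) {
    v <- rec[[m]]
    ordinal <- is.numeric(v) && all(v == round(v), na.rm = TRUE)
    if (no_stats) {
      res[[m]] <- list(test = "none (no statistics requested)",
                       statistic = NA_real_, p_value = NA_real_,
                       stars = NA_character_, posthoc = NULL,
                       trace = NULL, ordinal = ordinal)
      next
    }
    ch <- choose_test(dataset, m, alpha = alpha)
    if (ch$test %in% c("none", "insufficient n")) {
      res[[m]] <- list(test = ch$test, statistic = NA_real_,
                       p_value = NA_real_, stars = NA_character_,
                       posthoc = NULL, trace = ch$trace, ordinal = ordinal)
      next
    }
    ok <- !is.na(v)
    ex <- execute_test(ch$test, v[ok], rec$group[ok])
    ph <- if (!is.null(ch$posthoc))
      execute_posthoc(ch$posthoc, v[ok], rec$group[ok]) else NULL
    if (!is.null(ph)) ph$stars <- significance_stars(ph$p_value)
    if (ordinal)
      warning("measurement '", m, "' is integer-valued (ordinal); the ",
              "decision tree is designed for continuous variables - ",
              "interpret with care")
    res[[m]] <- list(test = ch$test, statistic = ex$statistic,
                     p_value = ex$p_value,
                     stars = significance_stars(ex$p_value),
                     posthoc = ph, trace = ch$trace, ordinal = ordinal)
  }
  res
}

stats_report_lines <- function(stats, alpha) {
  out <- c("statistical analysis", sprintf("alpha = %g", alpha), "")
  for (m in names(stats)) {
    s <- stats[[m]]
    out <- c(out, sprintf("measurement: %s%s", m,
                          if (isTRUE(s$ordinal))
                            " [ordinal: integer-valued, interpret with care]"
                          else ""))
    if (is.na(s$p_value)) {
      out <- c(out, sprintf("  test: %s", s$test), "")
      next
    }
    out <- c(out, sprintf("  test: %s | statistic = %.4f | p = %.6g | %s",
                          s$test, s$statistic, s$p_value, s$stars))
    if (!is.null(s$trace))
      out <- c(out, sprintf("  trace: %s [%s]%s", s$trace$check,
                            s$trace$detail,
                            ifelse(is.na(s$trace$p), "",
                                   sprintf(" p = %.6g", s$trace$p))))
    if (!is.null(s$posthoc))
      out <- c(out, "  post-hoc:",
               sprintf("    %s vs %s: statistic = %.4f, p = %.6g %s",
                       s$posthoc$group1, s$posthoc$group2,
                       s$posthoc$statistic, s$posthoc$p_value,
                       s$posthoc$stars))
    out <- c(out, "")
  }
  out
}

#' Replicate-aware superplot
#'
#' Per-cilium points jittered within group with replicate identity encoded
#' by color, replicate means overplotted as large outlined points, a violin
#' with median and quartile lines, and the significance annotation from the
#' statistics stage.
#'
#' @param dataset a [grouped_dataset()].
#' @param measurement measurement column name.
#' @param stats optional [run_stats()] result for the annotation.
#' @return a ggplot object; the per-replicate means are attached as
#'   `attr(, "replicate_means")`.
#' @export
make_superplot <- function(dataset, measurement, stats = NULL) {
  rec <- dataset$records
  if (!measurement %in% names(rec)) stop("unknown measurement ", measurement)
  df <- data.frame(group = factor(rec$group), replicate = rec$replicate,
                   value = rec[[measurement]])
  df <- df[!is.na(df$value), ]
  means <- aggregate(value ~ group + replicate, df, mean)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_violin(draw_quantiles = c(0.25, 0.5, 0.75),
                         fill = "grey92", color = "grey40") +
    ggplot2::geom_jitter(ggplot2::aes(color = .data$replicate),
                         width = 0.15, size = 0.8, alpha = 0.6) +
    ggplot2::geom_point(data = means,
                        ggplot2::aes(fill = .data$replicate),
                        shape = 21, size = 3.2, color = "black") +
    ggplot2::labs(x = NULL, y = measurement) +
    ggplot2::theme_classic()
  if (length(unique(df$replicate)) == 1L)
    p <- p + ggplot2::guides(color = "none", fill = "none")
  if (!is.null(stats) && !is.null(stats[[measurement]]) &&
      !is.na(stats[[measurement]]$p_value)) {
    lab <- stats[[measurement]]$stars
    ytop <- max(df$value) + 0.06 * diff(range(df$value, finite = TRUE) + c(0, 1e-9))
    p <- p + ggplot2::annotate("text", x = mean(seq_len(nlevels(df$group))),
                               y = ytop, label = lab, size = 5)
  }
  attr(p, "replicate_means") <- means
  p
}

save_plot <- function(plot, path_base, formats = c("png", "svg")) {
  paths <- character(0)
  for (fmt in unique(c(formats, "svg"))) {   # vector format always included
    path <- paste0(path_base, ".", fmt)
    if (fmt == "png") {
      grDevices::png(path, width = 1600, height = 1200, res = 200)
    } else {
      grDevices::svg(path, width = 8, height = 6)
    }
    print(plot)
    grDevices::dev.off()
    paths <- c(paths, path)
  }
  paths
}

embedding_plot <- function(emb, rec, title) {
  df <- data.frame(d1 = emb$coords[, 1], d2 = emb$coords[, 2],
                   group = factor(rec$group), replicate = rec$replicate)
  labs <- if (emb$method == "pca")
    sprintf("PC%d (%.1f%%)", 1:2, 100 * emb$explained_variance)
  else c("UMAP1", "UMAP2")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d1, y = .data$d2,
                                   color = .data$group,
                                   shape = .data$replicate)) +
    ggplot2::geom_point(size = 1.6, alpha = 0.8) +
    ggplot2::scale_shape_manual(
      values = rep(c(16, 17, 15, 3, 7, 8, 5, 6),
                   length.out = max(1L, length(unique(df$replicate))))) +
    ggplot2::labs(x = labs[1], y = labs[2], title = title) +
    ggplot2::theme_classic()
}

#' Write the full analysis output tree
#'
#' Creates `Analysis/Data` (comma-separated summary tables) and
#' `Analysis/Plots` (every figure as raster plus vector format) under
#' `first_group_path`, plus `qc.txt`, `statistics.txt` and `summary.txt` at
#' the top level. Metafile annotations are echoed into the summary. The
#' output directory must be writable before any file is produced.
#'
#' @param dataset a [grouped_dataset()].
#' @param qc a [qc_screen()] report.
#' @param stats a [run_stats()] result (may be `NULL`).
#' @param first_group_path directory to create `Analysis/` in.
#' @param measurements measurements to superplot (default: the QC set plus
#'   any tested measurement).
#' @param embeddings optional named list of [embed_cilia()] results to plot.
#' @param annotations optional named character vector from [read_metafile()].
#' @param alpha significance level (echoed in reports).
#' @param plot_formats raster/vector formats; a vector format is always
#'   included.
#' @return (invisibly) character vector of all files written.
#' @export
write_outputs <- function(dataset, qc, stats = NULL, first_group_path,
                          measurements = NULL, embeddings = NULL,
                          annotations = NULL, alpha = 0.05,
                          plot_formats = c("png", "svg")) {
  root <- file.path(first_group_path, "Analysis")
  data_dir <- file.path(root, "Data")
  plot_dir <- file.path(root, "Plots")
  ok <- dir.create(data_dir, recursive = TRUE, showWarnings = FALSE) ||
    dir.exists(data_dir)
  ok <- ok && (dir.create(plot_dir, recursive = TRUE,
                          showWarnings = FALSE) || dir.exists(plot_dir))
  if (!ok || file.access(root, 2L) != 0L)
    stop("output path not writable: ", root)
  written <- character(0)
  rec <- dataset$records
  if (is.null(measurements))
    measurements <- if (!is.null(stats)) names(stats)
                    else qc_default_measurements(rec)
  # Data: pooled records + per-group summaries (CSV)
  f <- file.path(data_dir, "pooled_records.csv")
  utils::write.csv(rec, f, row.names = FALSE)
  written <- c(written, f)
  summ <- do.call(rbind, lapply(measurements, function(m) {
    v <- rec[[m]]
    agg <- aggregate(v ~ rec$group, FUN = function(x)
      c(n = length(x), mean = mean(x), sd = sd(x), median = median(x)))
    data.frame(measurement = m, group = agg[[1]],
               n = agg$v[, "n"], mean = agg$v[, "mean"],
               sd = agg$v[, "sd"], median = agg$v[, "median"])
  }))
  f <- file.path(data_dir, "group_summaries.csv")
  utils::write.csv(summ, f, row.names = FALSE)
  written <- c(written, f)
  # top-level text reports
  f <- file.path(root, "qc.txt")
  writeLines(qc_report_lines(qc), f)
  written <- c(written, f)
  sum_lines <- c("analysis summary",
                 sprintf("groups: %s", paste(names(dataset$groups),
                                             collapse = ", ")),
                 sprintf("total records: %d", nrow(rec)),
                 sprintf("records per group: %s",
                         paste(names(qc$per_group_counts),
                               qc$per_group_counts, sep = "=",
                               collapse = ", ")))
  if (length(annotations))
    sum_lines <- c(sum_lines, "", "experimental metadata:",
                   sprintf("  %s: %s", names(annotations), annotations))
  f <- file.path(root, "summary.txt")
  writeLines(sum_lines, f)
  written <- c(written, f)
  if (!is.null(stats)) {
    f <- file.path(root, "statistics.txt")
    writeLines(stats_report_lines(stats, alpha), f)
    written <- c(written, f)
  }
  for (m in measurements) {
    sp <- make_superplot(dataset, m, stats)
    written <- c(written, save_plot(sp, file.path(plot_dir,
                                                  paste0("superplot_", m)),
                                    plot_formats))
  }
  for (nm in names(embeddings)) {
    pl <- embedding_plot(embeddings[[nm]], rec, toupper(nm))
    written <- c(written, save_plot(pl, file.path(plot_dir,
                                                  paste0(nm, "_embedding")),
                                    plot_formats))
  }
  invisible(written)
}

#' @importFrom ggplot2 .data
NULL
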