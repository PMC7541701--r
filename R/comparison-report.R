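INDEX_COLS <- c("redundancy", "fpr", "nsq", "coupon", "rep_gap")

#' Per-cell summaries of the 2x2 design
#'
#' Mean and sample standard deviation of every randomness index in each
#' expertise-by-task cell, the descriptive backbone of the group
#' comparison. Cells absent from the input are reported with
#' `n_sequences = 0` and `NA` summaries, never fabricated.
#'
#' @param profiles Output of [randomness_profile()] carrying `group` and
#'   `task` labels.
#' @return A tibble with columns `group`, `task`, `index`, `mean`, `sd`,
#'   `n_sequences`.
#' @export
summarize_cells <- function(profiles) {
  if (!all(c("group", "task") %in% names(profiles))) {
    stop_input("`profiles` must carry group and task labels.")
  }
  long <- tidyr::pivot_longer(
    profiles[, c("group", "task", intersect(INDEX_COLS, names(profiles)))],
    dplyr::all_of(intersect(INDEX_COLS, names(profiles))),
    names_to = "index", values_to = "value"
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$group, .data$task, .data$index),
    mean = mean(.data$value, na.rm = TRUE),
    sd = sd(.data$value, na.rm = TRUE),
    n_sequences = sum(!is.na(.data$value)),
    .groups = "drop"
  )
  full <- tidyr::expand_grid(group = GROUPS, task = TASKS,
                             index = intersect(INDEX_COLS, names(profiles)))
  out <- dplyr::left_join(full, out, by = c("group", "task", "index"))
  out$n_sequences[is.na(out$n_sequences)] <- 0L
  out$mean[out$n_sequences == 0] <- NA_real_
  as_tibble(out)
}

#' Distribution overlap index (OV)
#'
#' Non-parametric effect size: the integral of the pointwise minimum of two
#' Gaussian kernel density estimates (Silverman's rule-of-thumb bandwidth
#' per sample, a common grid of `n_grid` points spanning the pooled range
#' plus three bandwidths, trapezoidal integration). 1 means identical
#' distributions, 0 disjoint ones; values below 0.20 correspond to roughly
#' Cohen's d > 2. If either sample has zero variance the KDE is degenerate
#' and the function falls back to discrete mass overlap (flagged in the
#' `method` attribute, with a warning).
#'
#' @param sample_1,sample_2 Numeric vectors, each of length >= 2.
#' @param n_grid Grid resolution (default 512).
#' @return A number in (0, 1) with attribute `method` (`"kde"` or
#'   `"discrete"`).
#' @export
#' @examples
#' set.seed(1)
#' overlap_index(rnorm(500), rnorm(500, mean = 2))  # ~ 2 * pnorm(-1)
overlap_index <- function(sample_1, sample_2, n_grid = 512L) {
  if (!is.numeric(sample_1) || !is.numeric(sample_2) ||
      length(sample_1) < 2 || length(sample_2) < 2 ||
      anyNA(sample_1) || anyNA(sample_2)) {
    stop_input("Both samples must be numeric, length >= 2, without missing values.")
  }
  if (sd(sample_1) == 0 || sd(sample_2) == 0) {
    warn("Zero-variance sample: falling back to discrete mass overlap.")
    vals <- sort(unique(c(sample_1, sample_2)))
    p1 <- tabulate(match(sample_1, vals), length(vals)) / length(sample_1)
    p2 <- tabulate(match(sample_2, vals), length(vals)) / length(sample_2)
    ov <- sum(pmin(p1, p2))
    attr(ov, "method") <- "discrete"
    return(ov)
  }
  bw1 <- stats::bw.nrd0(sample_1)
  bw2 <- stats::bw.nrd0(sample_2)
  pad <- 3 * max(bw1, bw2)
  lo <- min(sample_1, sample_2) - pad
  hi <- max(sample_1, sample_2) + pad
  d1 <- density(sample_1, bw = bw1, from = lo, to = hi, n = n_grid)
  d2 <- density(sample_2, bw = bw2, from = lo, to = hi, n = n_grid)
  f <- pmin(d1$y, d2$y)
  ov <- sum((f[-1] + f[-length(f)]) / 2 * diff(d1$x))
  ov <- min(max(ov, 0), 1)
  attr(ov, "method") <- "kde"
  ov
}

#' Permutation contrast on the mean difference
#'
#' A two-sided label-permutation test of the difference in means between
#' two samples: `p = (1 + #{|perm diff| >= |observed|}) / (n_perm + 1)`,
#' the add-one form that is valid (conservative) under exchangeability.
#'
#' @param sample_1,sample_2 Numeric vectors, each of length >= 2.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed, or `NULL`.
#' @return A one-row tibble: `observed_diff` (mean_1 - mean_2), `p_value`,
#'   `n_perm`.
#' @export
permutation_contrast <- function(sample_1, sample_2, n_perm = 999L, seed = NULL) {
  if (!is.numeric(sample_1) || !is.numeric(sample_2) ||
      length(sample_1) < 2 || length(sample_2) < 2 ||
      anyNA(sample_1) || anyNA(sample_2)) {
    stop_input("Both samples must be numeric, length >= 2, without missing values.")
  }
  n_perm <- check_count(n_perm, "n_perm", min = 99L)
  obs <- mean(sample_1) - mean(sample_2)
  pooled <- c(sample_1, sample_2)
  n1 <- length(sample_1)
  with_seed_if(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(length(pooled), n1)
      d <- mean(pooled[idx]) - mean(pooled[-idx])
      if (abs(d) >= abs(obs)) exceed <- exceed + 1L
    }
    tibble(observed_diff = obs, p_value = (1 + exceed) / (n_perm + 1),
           n_perm = n_perm)
  })
}

#' Pairwise correlations among the randomness indices
#'
#' Product-moment (or rank) correlations between every pair of the five
#' indices across sequences; a constant index column yields `NA` for its
#' pairs, with a warning. The mean absolute correlation is attached as the
#' `mean_abs_r` attribute.
#'
#' @param profiles Output of [randomness_profile()] (>= 3 rows).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A tibble with columns `index_1`, `index_2`, `r` (one row per
#'   unordered pair), carrying attributes `matrix` and `mean_abs_r`.
#' @export
metric_correlations <- function(profiles, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  cols <- intersect(INDEX_COLS, names(profiles))
  if (nrow(profiles) < 3) stop_input("Need at least 3 profiles.")
  m <- as.matrix(profiles[, cols])
  const <- apply(m, 2, function(v) sd(v, na.rm = TRUE) == 0 || all(is.na(v)))
  if (any(const)) {
    warn(sprintf("Constant index column(s): %s; correlations undefined there.",
                 paste(cols[const], collapse = ", ")))
  }
  cm <- suppressWarnings(cor(m, method = method, use = "pairwise.complete.obs"))
  cm[const, ] <- NA_real_
  cm[, const] <- NA_real_
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  out <- tibble(index_1 = cols[pairs[, 1]], index_2 = cols[pairs[, 2]],
                r = cm[pairs])
  attr(out, "matrix") <- cm
  attr(out, "mean_abs_r") <- mean(abs(out$r), na.rm = TRUE)
  out
}

report_contrasts <- function() {
  tibble(
    contrast = c("morra: beginner vs expert", "rngt: beginner vs expert",
                 "beginner: morra vs rngt", "expert: morra vs rngt"),
    type = c("between", "between", "within", "within"),
    g1 = c("beginner", "beginner", "beginner", "expert"),
    t1 = c("morra", "rngt", "morra", "morra"),
    g2 = c("expert", "expert", "beginner", "expert"),
    t2 = c("morra", "rngt", "rngt", "rngt")
  )
}

#' Build the full comparison report
#'
#' Bundles the descriptive 2x2 analysis of a set of randomness profiles:
#' per-cell means and SDs, the four study contrasts (beginner vs expert
#' within each task; game vs isolated task within each group) with the
#' overlap index and a permutation p-value per index, and the pairwise
#' index correlations. All settings and seeds are echoed so the report is
#' reproducible; re-running with the same inputs gives identical output.
#'
#' @param profiles Output of [randomness_profile()] with `group` and `task`
#'   labels.
#' @param n_perm Permutations per contrast (default 999).
#' @param seed Integer seed driving all permutation draws.
#' @param cor_method Correlation type, `"pearson"` or `"spearman"`.
#' @return An object of class `morra_report`: a list with `cells`,
#'   `contrasts`, `correlations` and `settings`.
#' @export
#' @examples
#' profiles <- study_design(seed = 7) |>
#'   generate_study() |>
#'   standardize() |>
#'   randomness_profile()
#' rep <- build_report(profiles, n_perm = 199, seed = 7)
#' rep
build_report <- function(profiles, n_perm = 999L, seed = 1L,
                         cor_method = "pearson") {
  cells <- summarize_cells(profiles)
  plan <- report_contrasts()
  idx_cols <- intersect(INDEX_COLS, names(profiles))
  rows <- list()
  j <- 0L
  for (i in seq_len(nrow(plan))) {
    for (idx in idx_cols) {
      j <- j + 1L
      s1 <- profiles[[idx]][profiles$group == plan$g1[i] & profiles$task == plan$t1[i]]
      s2 <- profiles[[idx]][profiles$group == plan$g2[i] & profiles$task == plan$t2[i]]
      s1 <- s1[!is.na(s1)]
      s2 <- s2[!is.na(s2)]
      if (length(s1) < 2 || length(s2) < 2) {
        rows[[j]] <- dplyr::bind_cols(plan[i, ], tibble(
          index = idx, ov = NA_real_, ov_method = "missing cell",
          observed_diff = NA_real_, p_value = NA_real_))
        next
      }
      ov <- overlap_index(s1, s2)
      pc <- permutation_contrast(s1, s2, n_perm = n_perm,
                                 seed = sub_seed(seed, j))
      rows[[j]] <- dplyr::bind_cols(plan[i, ], tibble(
        index = idx, ov = as.numeric(ov), ov_method = attr(ov, "method"),
        observed_diff = pc$observed_diff, p_value = pc$p_value))
    }
  }
  structure(list(
    cells = cells,
    contrasts = dplyr::bind_rows(rows),
    correlations = metric_correlations(profiles, method = cor_method),
    settings = list(n_perm = as.integer(n_perm), seed = as.integer(seed),
                    cor_method = cor_method,
                    n_sequences = nrow(profiles), indices = idx_cols)
  ), class = "morra_report")
}

#' @export
print.morra_report <- function(x, digits = 3, ...) {
  cat("Randomness comparison report\n")
  cat(sprintf("  %d sequences; %d permutations per contrast (seed %d)\n\n",
              x$settings$n_sequences, x$settings$n_perm, x$settings$seed))
  cat("Cell means (SD) by expertise and task:\n")
  wide <- tidyr::pivot_wider(
    dplyr::mutate(x$cells,
                  cell = paste(.data$group, .data$task, sep = "/"),
                  value = ifelse(is.na(.data$mean), "missing cell",
                                 sprintf("%.*f (%.*f)", digits, .data$mean,
                                         digits, .data$sd))),
    id_cols = "index", names_from = "cell", values_from = "value"
  )
  print(as.data.frame(wide), row.names = FALSE)
  cat("\nContrasts (overlap index OV; permutation p):\n")
  ct <- dplyr::mutate(x$contrasts,
                      ov = round(.data$ov, digits),
                      p_value = round(.data$p_value, digits),
                      observed_diff = round(.data$observed_diff, digits))
  print(as.data.frame(ct[, c("contrast", "index", "ov", "observed_diff", "p_value")]),
        row.names = FALSE)
  cat(sprintf("\nMean |r| among indices: %.3f\n",
              attr(x$correlations, "mean_abs_r")))
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Writes `<path>.txt` (the human-readable rendering), `<path>.json` (every
#' number plus all settings and seeds, machine readable) and `<path>_cells.csv`
#' / `<path>_contrasts.csv` (delimited tables). Output is byte-identical
#' across re-runs with the same inputs.
#'
#' @param report A `morra_report`.
#' @param path Output path prefix.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "morra_report")) stop_input("`report` must be a morra_report.")
  txt <- utils::capture.output(print(report))
  writeLines(txt, paste0(path, ".txt"))
  jsonlite::write_json(list(
    cells = report$cells,
    contrasts = report$contrasts,
    correlations = as.data.frame(report$correlations),
    mean_abs_r = attr(report$correlations, "mean_abs_r"),
    settings = report$settings
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  readr::write_csv(report$cells, paste0(path, "_cells.csv"))
  readr::write_csv(report$contrasts, paste0(path, "_contrasts.csv"))
  invisible(path)
}

#' @export
tidy.morra_report <- function(x, ...) x$contrasts

#' @export
glance.morra_report <- function(x, ...) {
  tibble(
    n_sequences = x$settings$n_sequences,
    n_contrasts = nrow(x$contrasts),
    mean_abs_r = attr(x$correlations, "mean_abs_r"),
    min_ov = min(x$contrasts$ov, na.rm = TRUE),
    max_ov = max(x$contrasts$ov, na.rm = TRUE),
    n_perm = x$settings$n_perm,
    seed = x$settings$seed
  )
}

#' Plot the cell summaries of a comparison report
#'
#' @param object A `morra_report`.
#' @param ... Unused.
#' @return A ggplot: cell means with +/- 1 SD bars, one facet per index.
#' @exportS3Method ggplot2::autoplot
autoplot.morra_report <- function(object, ...) {
  cells <- object$cells
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$task, y = .data$mean,
                                      colour = .data$group, group = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.15,
                           position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "Task", y = "Index value", colour = "Group") +
    ggplot2::theme_minimal()
}
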