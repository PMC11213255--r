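#' One- or two-way fixed-effects ANOVA on per-plant bin means
#'
#' One factor gives a one-way ANOVA (`stats::aov`); two factors give a
#' two-way model with interaction, tested with Type II sums of squares
#' (`car::Anova`) — the conventional choice for the unbalanced designs these
#' experiments produce (group sizes routinely differ between treatments).
#'
#' @param data A data frame with one row per experimental unit (plant).
#' @param response Name of the numeric response column.
#' @param factor1 Name of the primary grouping column (e.g. treatment).
#' @param factor2 Optional name of a second factor (e.g. genotype).
#' @return An object of class `leaf_anova`; see [tidy()] and [glance()].
#' @export
#' @examples
#' d <- data.frame(y = rnorm(30), g = rep(c("a", "b", "c"), 10))
#' tidy(leaf_anova(d, "y", "g"))
leaf_anova <- function(data, response, factor1, factor2 = NULL) {
  stopifnot(response %in% names(data), factor1 %in% names(data))
  data <- data[stats::complete.cases(data[, c(response, factor1, factor2)]), ]
  f1 <- factor(data[[factor1]])
  if (nlevels(f1) < 2) stop("need at least 2 groups in ", factor1, call. = FALSE)
  check_n <- function(f, name) {
    tab <- table(f)
    small <- names(tab)[tab < 2]
    if (length(small) > 0) {
      stop("groups with fewer than 2 observations in ", name, ": ",
           paste(small, collapse = ", "), call. = FALSE)
    }
  }
  check_n(f1, factor1)
  y <- data[[response]]

  if (is.null(factor2)) {
    fit <- stats::aov(y ~ f1)
    sm <- summary(fit)[[1]]
    table <- tibble::tibble(
      effect = factor1,
      F = sm[1, "F value"],
      df1 = sm[1, "Df"],
      df2 = sm[nrow(sm), "Df"],
      p = sm[1, "Pr(>F)"]
    )
  } else {
    f2 <- factor(data[[factor2]])
    if (nlevels(f2) < 2) stop("need at least 2 groups in ", factor2, call. = FALSE)
    check_n(f2, factor2)
    fit <- stats::lm(y ~ f1 * f2)
    a2 <- car::Anova(fit, type = 2)
    df_res <- a2["Residuals", "Df"]
    eff_names <- c(factor1, factor2, paste0(factor1, ":", factor2))
    rows <- c("f1", "f2", "f1:f2")
    table <- tibble::tibble(
      effect = eff_names,
      F = a2[rows, "F value"],
      df1 = a2[rows, "Df"],
      df2 = df_res,
      p = a2[rows, "Pr(>F)"]
    )
  }
  out <- list(table = table, fit = fit, nobs = length(y),
              response = response, factors = c(factor1, factor2))
  class(out) <- "leaf_anova"
  out
}

#' @export
print.leaf_anova <- function(x, ...) {
  cat("<leaf_anova> ", x$response, " ~ ", paste(x$factors, collapse = " * "),
      " (n = ", x$nobs, ")\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @export
tidy.leaf_anova <- function(x, ...) x$table

#' @export
glance.leaf_anova <- function(x, ...) {
  tibble::tibble(nobs = x$nobs, df_residual = stats::df.residual(x$fit))
}

#' Tukey honest-significant-difference pairwise comparisons
#'
#' Runs a one-way ANOVA on the grouping factor and returns the studentized
#' range ("Tukey") adjusted p-value for every pair of groups as a symmetric
#' matrix with unit diagonal — the input format of
#' [compact_letter_display()].
#'
#' @inheritParams leaf_anova
#' @param group Name of the grouping column.
#' @return An object of class `leaf_tukey` with elements `p` (symmetric
#'   adjusted p matrix), `diff` (pairwise mean differences), `means` (named
#'   group means).
#' @export
tukey_hsd <- function(data, response, group) {
  stopifnot(response %in% names(data), group %in% names(data))
  data <- data[stats::complete.cases(data[, c(response, group)]), ]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  tab <- table(g)
  if (any(tab < 2)) {
    stop("groups with fewer than 2 observations: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  y <- data[[response]]
  fit <- stats::aov(y ~ g)
  th <- stats::TukeyHSD(fit)$g

  lev <- levels(g)
  k <- length(lev)
  p <- matrix(1, k, k, dimnames = list(lev, lev))
  d <- matrix(0, k, k, dimnames = list(lev, lev))
  pairs <- strsplit(rownames(th), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    p[a, b] <- p[b, a] <- th[i, "p adj"]
    d[a, b] <- th[i, "diff"]
    d[b, a] <- -th[i, "diff"]
  }
  out <- list(p = p, diff = d, means = tapply(y, g, mean))
  class(out) <- "leaf_tukey"
  out
}

#' @export
tidy.leaf_tukey <- function(x, ...) {
  lev <- rownames(x$p)
  idx <- which(upper.tri(x$p), arr.ind = TRUE)
  tibble::tibble(
    group1 = lev[idx[, 1]], group2 = lev[idx[, 2]],
    estimate = x$diff[idx[, c(2, 1), drop = FALSE]],
    adj_p = x$p[idx]
  )
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Assigns significance letters by insert-and-absorb: all groups start in
#' one letter column; every significant pair splits each column containing
#' both groups into two (one without each member), and columns contained in
#' another are absorbed. The result guarantees that two groups share a
#' letter exactly when their adjusted p-value is at least `alpha`. Letters
#' are ordered by descending group mean when means are supplied (so "a"
#' labels the highest group, as in published panels), otherwise by input
#' order.
#'
#' @param p Symmetric pairwise adjusted p-value matrix with unit diagonal,
#'   or a `leaf_tukey` object.
#' @param alpha Significance level.
#' @param means Optional named group means used only for letter ordering.
#' @return Named character vector of letter strings, one per group, in the
#'   input order.
#' @export
#' @examples
#' p <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
#' p["a", "c"] <- p["c", "a"] <- 0.001
#' compact_letter_display(p)
compact_letter_display <- function(p, alpha = 0.05, means = NULL) {
  if (inherits(p, "leaf_tukey")) {
    if (is.null(means)) means <- p$means
    p <- p$p
  }
  if (!is.matrix(p) || nrow(p) != ncol(p) || !isTRUE(all.equal(p, t(p)))) {
    stop("p must be a symmetric matrix", call. = FALSE)
  }
  k <- nrow(p)
  groups <- rownames(p)
  if (is.null(groups)) groups <- as.character(seq_len(k))
  ord <- if (!is.null(means)) order(-as.numeric(means[groups])) else seq_len(k)

  po <- p[ord, ord, drop = FALSE]
  cols <- list(rep(TRUE, k))  # letter columns over ordered groups
  sig <- which(upper.tri(po) & po < alpha, arr.ind = TRUE)
  if (nrow(sig) > 0) {
    sig <- sig[order(sig[, 1], sig[, 2]), , drop = FALSE]
    for (s in seq_len(nrow(sig))) {
      i <- sig[s, 1]; j <- sig[s, 2]
      new_cols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          c1 <- col; c1[j] <- FALSE
          c2 <- col; c2[i] <- FALSE
          new_cols <- c(new_cols, list(c1, c2))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb columns that are subsets of another column
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[a] &&
              all(new_cols[[a]] <= new_cols[[b]]) &&
              (any(new_cols[[a]] != new_cols[[b]]) || b < a)) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  # order columns by their first (highest-mean) member for stable lettering
  first <- vapply(cols, function(cl) which(cl)[1], integer(1))
  cols <- cols[order(first)]
  alphabet <- c(letters, as.vector(outer(letters, letters, paste0)))
  lets <- rep("", k)
  for (ci in seq_along(cols)) {
    lets[cols[[ci]]] <- paste0(lets[cols[[ci]]], alphabet[ci])
  }
  out <- character(k)
  out[ord] <- lets
  names(out) <- groups
  out
}

#' Group means with standard errors at each timepoint
#'
#' Pointwise mean and SEM (sd / sqrt(n)) over plants, per group, at every
#' common time — the quantity plotted as "mean +/- SEM" kinetics. A group
#' with a single plant at a timepoint reports its value with a missing SEM.
#'
#' @param series A synced kinetics tibble with `zt_h`, metric columns and a
#'   grouping column.
#' @param group Name of the grouping column.
#' @return A long tibble: group, `zt_h`, `metric`, `mean`, `sem`, `n`.
#' @export
summarize_groups <- function(series, group = "treatment") {
  stopifnot(group %in% names(series), "zt_h" %in% names(series))
  cols <- metric_columns(series)
  series |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "metric",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group, "zt_h", "metric")))) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = ifelse(dplyr::n() > 1, stats::sd(.data$value) / sqrt(dplyr::n()), NA_real_),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Per-bin group statistics with significance letters
#'
#' For every metric and 2-h bin: group means and SEMs over plants, the
#' ANOVA table (one-way on `group`, or two-way with `factor2`), Tukey
#' pairwise adjusted p-values, and compact-letter-display letters at level
#' `alpha`. Bins where the test is not estimable (fewer than two groups
#' with two plants each) are reported with missing letters. Each bin is
#' tested independently, with no multiplicity correction across bins —
#' matching how such kinetics panels are conventionally annotated; treat
#' isolated significant bins with care.
#'
#' @param binned Output of [bin_series()].
#' @param group Grouping column name (default `"treatment"`).
#' @param factor2 Optional second factor for a two-way ANOVA.
#' @param alpha Significance level for the letters.
#' @param reliable_only Drop per-plant bin means marked unreliable?
#' @return An object of class `binned_stats`: list with `summary` (tibble
#'   `metric, bin_start_zt_h, group, mean, sem, n, letter`) and `anova`
#'   (tibble `metric, bin_start_zt_h, effect, F, df1, df2, p`).
#' @export
binned_stats <- function(binned, group = "treatment", factor2 = NULL,
                         alpha = 0.05, reliable_only = TRUE) {
  stopifnot(all(c("plant_id", "metric", "bin_start_zt_h", "mean") %in% names(binned)),
            group %in% names(binned))
  dat <- binned
  if (reliable_only && "reliable" %in% names(dat)) {
    dat <- dat[dat$reliable & !is.na(dat$mean), ]
  }
  tukey_group <- if (is.null(factor2)) group else "interaction_group"
  if (!is.null(factor2)) {
    dat$interaction_group <- paste(dat[[group]], dat[[factor2]], sep = ":")
  }

  cells <- dat |> dplyr::distinct(.data$metric, .data$bin_start_zt_h)
  sum_rows <- list(); an_rows <- list()
  for (r in seq_len(nrow(cells))) {
    cell <- dat[dat$metric == cells$metric[r] &
                  dat$bin_start_zt_h == cells$bin_start_zt_h[r], ]
    gs <- cell |>
      dplyr::group_by(dplyr::across(dplyr::all_of(tukey_group))) |>
      dplyr::summarise(
        gmean = mean(.data$mean),
        sem = ifelse(dplyr::n() > 1, stats::sd(.data$mean) / sqrt(dplyr::n()), NA_real_),
        n = dplyr::n(), .groups = "drop"
      )
    testable <- sum(gs$n >= 2) >= 2 && nrow(gs) >= 2 && all(gs$n >= 2)
    letters_out <- stats::setNames(rep(NA_character_, nrow(gs)), gs[[tukey_group]])
    if (testable) {
      av <- leaf_anova(cell, "mean", group, factor2 = factor2)
      an_rows[[length(an_rows) + 1]] <- dplyr::mutate(
        av$table, metric = cells$metric[r],
        bin_start_zt_h = cells$bin_start_zt_h[r], .before = 1
      )
      tk <- tukey_hsd(cell, "mean", tukey_group)
      letters_out <- compact_letter_display(tk, alpha = alpha)
    }
    gs$letter <- unname(letters_out[gs[[tukey_group]]])
    gs$metric <- cells$metric[r]
    gs$bin_start_zt_h <- cells$bin_start_zt_h[r]
    sum_rows[[length(sum_rows) + 1]] <- gs
  }
  summary <- dplyr::bind_rows(sum_rows) |>
    dplyr::rename(group = dplyr::all_of(tukey_group), mean = "gmean") |>
    dplyr::select("metric", "bin_start_zt_h", "group", "mean", "sem", "n", "letter") |>
    dplyr::arrange(.data$metric, .data$bin_start_zt_h, .data$group)
  anova_tbl <- if (length(an_rows) > 0) {
    dplyr::bind_rows(an_rows) |>
      dplyr::arrange(.data$metric, .data$bin_start_zt_h)
  } else {
    tibble::tibble(metric = character(), bin_start_zt_h = numeric(),
                   effect = character(), F = numeric(), df1 = numeric(),
                   df2 = numeric(), p = numeric())
  }
  out <- list(summary = summary, anova = anova_tbl, alpha = alpha,
              group = group, factor2 = factor2)
  class(out) <- "binned_stats"
  out
}

#' @export
print.binned_stats <- function(x, ...) {
  cat(sprintf("<binned_stats> %d metric(s), %d bin(s), alpha = %g\n",
              length(unique(x$summary$metric)),
              length(unique(x$summary$bin_start_zt_h)), x$alpha))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.binned_stats <- function(x, ...) x$summary

#' @export
glance.binned_stats <- function(x, ...) {
  tibble::tibble(
    n_metrics = length(unique(x$summary$metric)),
    n_bins = length(unique(x$summary$bin_start_zt_h)),
    alpha = x$alpha
  )
}

#' Write binned statistics to per-metric CSV files
#'
#' Writes `stats_<metric>.csv` (`bin_start_zt_h, group, mean, sem, n,
#' letter`) and `anova_<metric>.csv` (`bin_start_zt_h, effect, F, df1, df2,
#' p`) into `dir`.
#'
#' @param bs A [binned_stats()] object.
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_binned_stats <- function(bs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (m in unique(bs$summary$metric)) {
    p1 <- file.path(dir, paste0("stats_", m, ".csv"))
    readr::write_csv(
      bs$summary[bs$summary$metric == m,
                 c("bin_start_zt_h", "group", "mean", "sem", "n", "letter")], p1)
    p2 <- file.path(dir, paste0("anova_", m, ".csv"))
    readr::write_csv(
      bs$anova[bs$anova$metric == m,
               c("bin_start_zt_h", "effect", "F", "df1", "df2", "p")], p2)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}
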