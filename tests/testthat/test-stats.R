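group_data <- function(means, sd = 1, n = 10, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    y = stats::rnorm(n * length(means), rep(means, each = n), sd),
    g = rep(paste0("g", seq_along(means)), each = n)
  )
}

test_that("one-way F equals the squared pooled t statistic at k = 2", {
  d <- group_data(c(0, 1), seed = 4)
  av <- leaf_anova(d, "y", "g")
  tt <- stats::t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(av$table$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(av$table$p, tt$p.value, tolerance = 1e-9)
  expect_equal(glance(av)$nobs, 20)
})

test_that("identically-drawn groups rarely reject; huge effects always do", {
  pvals <- vapply(1:100, function(s) {
    leaf_anova(group_data(c(0, 0), seed = s), "y", "g")$table$p
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)

  d <- group_data(c(0, 10), seed = 2)
  expect_lt(leaf_anova(d, "y", "g")$table$p, 1e-6)
})

test_that("anova errors name groups that are too small", {
  d <- group_data(c(0, 1))
  d <- d[-(1:9), ]  # leave one observation in g1
  expect_error(leaf_anova(d, "y", "g"), "g1")
})

test_that("two-way ANOVA returns Type II tests for both factors", {
  d <- group_data(c(0, 0, 5, 5), n = 8, seed = 6)
  d$treatment <- rep(c("WL", "FRw"), each = 16)
  d$genotype <- rep(rep(c("Col", "pif"), each = 8), 2)
  av <- leaf_anova(d, "y", "treatment", "genotype")
  expect_equal(av$table$effect,
               c("treatment", "genotype", "treatment:genotype"))
  expect_lt(av$table$p[1], 1e-6)
  expect_gt(av$table$p[2], 0.05)

  # with a null balanced second factor, the first factor's F stays close to
  # the one-way value
  f1 <- leaf_anova(d, "y", "treatment")$table$F
  expect_equal(av$table$F[1], f1, tolerance = 0.15 * f1)
})

test_that("Tukey reduces to the pooled t-test at k = 2", {
  d <- group_data(c(0, 0.8), seed = 7)
  tk <- tukey_hsd(d, "y", "g")
  tt <- stats::t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(tk$p["g1", "g2"], tt$p.value, tolerance = 1e-6)
  expect_true(isSymmetric(tk$p))
  expect_equal(diag(tk$p), c(g1 = 1, g2 = 1))
})

test_that("Tukey separates distant groups and not identical ones", {
  d <- group_data(c(0, 0, 10), seed = 8)
  tk <- tukey_hsd(d, "y", "g")
  expect_gt(tk$p["g1", "g2"], 0.05)
  expect_lt(tk$p["g1", "g3"], 0.001)
  expect_lt(tk$p["g2", "g3"], 0.001)

  same <- tibble::tibble(y = rep(c(1, 2, 3), 3),
                         g = rep(c("a", "b", "c"), each = 3))
  expect_true(all(tukey_hsd(same, "y", "g")$p >= 0.99))
})

test_that("letter display handles the degenerate patterns", {
  p_ns <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(compact_letter_display(p_ns)), c("a", "a", "a"))

  p_all <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(p_all) <- 1
  lets <- compact_letter_display(p_all)
  expect_setequal(unname(lets), c("a", "b", "c"))

  expect_error(compact_letter_display(matrix(c(1, 0.2, 0.4, 1), 2, 2)),
               "symmetric")
})

test_that("chain structure yields letters matching the matrix, minimally", {
  # 1~2, 2~3, 3~4 non-significant; 1-3, 1-4, 2-4 significant
  p <- matrix(0.01, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  diag(p) <- 1
  for (pr in list(c(1, 2), c(2, 3), c(3, 4))) {
    p[pr[1], pr[2]] <- p[pr[2], pr[1]] <- 0.5
  }
  lets <- compact_letter_display(p)
  expect_true(letters_match_pmatrix(lets, p))
  n_letters <- length(unique(unlist(strsplit(lets, ""))))
  expect_equal(n_letters, min_clique_cover(p >= 0.05))
})

test_that("letters reproduce random 6-group significance structures", {
  for (s in 1:50) {
    p <- random_pmatrix(6, seed = s)
    lets <- compact_letter_display(p, alpha = 0.5)  # dense significance mix
    expect_true(letters_match_pmatrix(lets, p, alpha = 0.5), label = paste("seed", s))
    lets2 <- compact_letter_display(p, alpha = 0.05)
    expect_true(letters_match_pmatrix(lets2, p, alpha = 0.05), label = paste("seed", s))
  }
})

test_that("letters are ordered by descending group mean", {
  p <- matrix(0.01, 3, 3, dimnames = list(c("lo", "mid", "hi"), c("lo", "mid", "hi")))
  diag(p) <- 1
  lets <- compact_letter_display(p, means = c(lo = 1, mid = 5, hi = 9))
  expect_equal(lets[["hi"]], "a")
  expect_equal(lets[["lo"]], "c")
})

test_that("group summaries report mean and sd/sqrt(n)", {
  s <- tibble::tibble(
    plant_id = rep(c("p1", "p2"), each = 2),
    treatment = "WL",
    zt_h = rep(c(0, 1), 2),
    petiole_angle_deg = c(1, 2, 3, 6)
  )
  sg <- summarize_groups(s)
  expect_equal(sg$mean, c(2, 4))
  expect_equal(sg$sem, c(1, 2))  # sd(c(1,3))/sqrt(2) = 1.0 etc.

  solo <- summarize_groups(s[1:2, ])
  expect_true(all(is.na(solo$sem)))
  expect_equal(solo$mean, c(1, 2))

  set.seed(9)
  vals <- stats::rnorm(10)
  many <- tibble::tibble(plant_id = paste0("p", 1:10), treatment = "WL",
                         zt_h = 0, petiole_angle_deg = vals)
  sg10 <- summarize_groups(many)
  expect_equal(sg10$sem, stats::sd(vals) / sqrt(10), tolerance = 1e-12)
})

test_that("binned_stats assembles letters consistent with its own Tukey", {
  set.seed(10)
  plants <- expand.grid(plant_id = paste0("p", 1:8),
                        treatment = c("WL", "FRw"), stringsAsFactors = FALSE)
  plants$plant_id <- paste0(plants$plant_id, "_", plants$treatment)
  rows <- lapply(seq_len(nrow(plants)), function(i) {
    shift <- if (plants$treatment[i] == "FRw") 10 else 0
    tibble::tibble(
      plant_id = plants$plant_id[i], treatment = plants$treatment[i],
      zt_h = (0:239) / 60,
      petiole_angle_deg = stats::rnorm(240, shift)
    )
  })
  series <- dplyr::bind_rows(rows)
  b <- bin_series(series)
  bs <- binned_stats(b)
  expect_s3_class(bs, "binned_stats")
  expect_equal(sort(unique(bs$summary$group)), c("FRw", "WL"))
  # a 10-sd separation must earn distinct letters in every bin
  for (bin in unique(bs$summary$bin_start_zt_h)) {
    sub <- bs$summary[bs$summary$bin_start_zt_h == bin, ]
    expect_false(sub$letter[sub$group == "WL"] ==
                   sub$letter[sub$group == "FRw"])
  }
  expect_true(all(bs$anova$p < 1e-6))
  expect_equal(glance(bs)$n_bins, 2)
  td <- tidy(bs)
  expect_named(td, c("metric", "bin_start_zt_h", "group", "mean", "sem",
                     "n", "letter"))
})
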