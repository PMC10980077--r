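# small helper: minimal attribute table with prescribed total_score values
mini_table <- function(total_scores, base_pdb = "p1") {
  n <- length(total_scores)
  t <- data.frame(base_pdb = base_pdb,
                  variant = paste0("A", seq_len(n) - 1L, "G"),
                  total_score = total_scores,
                  fa_atr = seq_len(n) / 10)
  class(t) <- c("attribute_table", "data.frame")
  t
}

test_that("the modified z-score filter reproduces the hand-worked example", {
  # group {1,2,3,4,5,100}: median 3.5, MAD 1.5, s(100) = 96.5/1.5 ~ 64.33
  t <- mini_table(c(1, 2, 3, 4, 5, 100))
  res <- clean_attribute_table(t, seed = 1)
  g <- res$report$groups[["p1"]]
  expect_equal(g$median, 3.5)
  expect_equal(g$mad, 1.5)
  expect_equal(max(g$z), 96.5 / 1.5, tolerance = 1e-12)
  expect_gt(max(g$z), 6.5)
  expect_equal(nrow(res$table), 5L)
  expect_equal(res$report$removed$outlier, 6L)
  expect_false(100 %in% res$table$total_score)
})

test_that("cleaning drops NaNs, deduplicates with one survivor, and reports", {
  t <- mini_table(c(1, 2, 3, 4))
  t$variant[2] <- t$variant[1]
  t$variant[3] <- t$variant[1]          # variant appears 3x
  t$fa_atr[4] <- NaN
  # a single surviving row gives MAD = 0, which warns by design
  expect_warning(res <- clean_attribute_table(t, seed = 5), "MAD = 0")
  expect_equal(sum(res$table$variant == t$variant[1]), 1L)
  expect_equal(length(res$report$removed$nan), 1L)
  expect_equal(length(res$report$removed$duplicate), 2L)
  # removal counts by cause account for every lost row
  expect_equal(sum(lengths(res$report$removed)),
               res$report$n_in - res$report$n_out)
  # all-equal group (MAD = 0): no outlier removal, with a warning
  t2 <- mini_table(rep(7, 6))
  expect_warning(res2 <- clean_attribute_table(t2, seed = 1), "MAD = 0")
  expect_equal(nrow(res2$table), 6L)
})

test_that("cleaning is idempotent and recovers injected outliers", {
  s <- make_toy_structure(12, seed = 3)
  p <- sim_params(seed = 4)
  vars <- sample_subvariants(s$sequence, 2000, max_subs = 3, seed = 5)
  tab <- score_variants(s, p, vars, noise = TRUE, seed = 6)
  fj <- inject_faults(tab, r_out = 0.02, out_magnitude = 50, seed = 7)
  res1 <- clean_attribute_table(fj$table, seed = 8)
  # >= 95% of the injected outliers removed
  expect_gte(length(intersect(res1$report$removed$outlier,
                              fj$outlier_rows)),
             ceiling(0.95 * length(fj$outlier_rows)))
  # <= 1% of clean rows removed
  clean_rows <- setdiff(seq_len(nrow(tab)), fj$outlier_rows)
  expect_lte(length(intersect(res1$report$removed$outlier, clean_rows)),
             0.01 * length(clean_rows))
  # idempotence
  res2 <- clean_attribute_table(res1$table, seed = 8)
  expect_equal(nrow(res2$table), nrow(res1$table))
  expect_identical(res2$table$variant, res1$table$variant)
})

test_that("term exclusion leaves 55 terms and never touches binding columns", {
  s <- make_toy_structure(8, seed = 1)
  p <- sim_params(seed = 1, interface = 0:2)
  vars <- enumerate_variants(s$sequence, 1)[1:10]
  tab <- score_variants(s, p, vars, noise = FALSE)
  out <- drop_excluded_terms(tab)
  expect_length(setdiff(names(out), c("base_pdb", "variant")), 55L)
  expect_false(any(excluded_terms() %in% names(out)))

  tb <- score_variants(s, p, vars, with_binding = TRUE, noise = FALSE)
  outb <- drop_excluded_terms(tb)
  expect_length(setdiff(names(outb), c("base_pdb", "variant")), 72L)
  expect_true(all(binding_terms() %in% names(outb)))

  # already-absent column: the other four go, with a warning
  t2 <- tab[, names(tab) != "dslf_fa13"]
  expect_warning(out2 <- drop_excluded_terms(t2), "dslf_fa13")
  expect_length(setdiff(names(out2), c("base_pdb", "variant")), 55L)
})

test_that("standardization uses train-only statistics per group and term", {
  s <- make_toy_structure(10, seed = 2)
  p <- sim_params(seed = 3)
  tab <- score_variants(s, p, enumerate_variants(s$sequence, 1),
                        noise = TRUE, seed = 1)
  tab2 <- score_variants(make_toy_structure(10, seed = 9), p,
                         enumerate_variants(s$sequence, 1),
                         noise = TRUE, seed = 2)
  both <- rbind(tab, tab2)
  class(both) <- c("attribute_table", "data.frame")
  train <- c(1:120, 191:310)
  res <- standardize_attributes(both, train)
  for (g in unique(both$base_pdb)) {
    rows <- intersect(which(both$base_pdb == g), train)
    expect_lt(abs(mean(res$table$total_score[rows])), 1e-9)
    expect_lt(abs(sd(res$table$total_score[rows]) - 1), 1e-9)
  }
  # held-out rows use train stats, not their own
  ho <- setdiff(which(both$base_pdb == both$base_pdb[1]), train)
  st <- res$stats[[both$base_pdb[1]]]
  expect_equal(res$table$fa_atr[ho],
               (both$fa_atr[ho] - st$mean[["fa_atr"]]) / st$sd[["fa_atr"]])
  # constant columns are centered only
  expect_equal(unique(res$table$res_count_all), 0)
  expect_equal(st$sd[["res_count_all"]], 1)
  # a group without training rows is an error
  expect_error(standardize_attributes(both, 1:120), "no training rows")
})

test_that("experimental normalization drops stops, rebases and rounds", {
  raw <- data.frame(variant = c("", "A2G", "V5*", "A2G,L7M"),
                    score = c(2.3, 2.4234567891, 9, 1.1))
  out <- normalize_experimental_dataset(raw)
  expect_equal(nrow(out), 3L)        # stop variant removed
  expect_equal(out$score[1], 0)      # wild type exactly 0
  expect_equal(out$score[2], round(2.4234567891 - 2.3, 7))
  # explicit wt_score and 1-based conversion
  raw2 <- data.frame(variant = "A2G", score = 2.3)
  out2 <- normalize_experimental_dataset(raw2, wt_score = 2.3, offset = 1)
  expect_identical(out2$variant, "A1G")
  expect_equal(out2$score, 0)
  # no wild-type row and no wt_score: error
  expect_error(normalize_experimental_dataset(raw2), "wt_score")
})
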