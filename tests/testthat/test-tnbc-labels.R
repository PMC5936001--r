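test_that("HER2 precedence: determinate FISH overrides IHC status", {
  clin <- rbind(
    # ER+, PR-, IHC '1+'/negative, FISH positive -> non-TNBC via FISH
    clin_row("LL-A5YP", er = "positive", pr = "negative",
             level = "1+", ihc = "negative", fish = "positive"),
    # ER-, PR-, IHC status positive, FISH negative -> TNBC via FISH
    clin_row("A2-A0EQ", er = "negative", pr = "negative",
             level = "3+", ihc = "positive", fish = "negative"),
    # all three negative, no FISH -> TNBC via IHC status
    clin_row("S3", ihc = "negative"),
    # equivocal FISH falls back to IHC status
    clin_row("S4", ihc = "negative", fish = "equivocal")
  )
  res <- build_tnbc_labels(clin)
  lab <- res$labels
  expect_equal(lab$y[lab$sample_id == "LL-A5YP"], 0L)
  expect_equal(lab$her2_source[lab$sample_id == "LL-A5YP"], "fish")
  expect_equal(lab$y[lab$sample_id == "A2-A0EQ"], 1L)
  expect_equal(lab$her2_source[lab$sample_id == "A2-A0EQ"], "fish")
  expect_equal(lab$y[lab$sample_id == "S3"], 1L)
  expect_equal(lab$her2_source[lab$sample_id == "S3"], "ihc_status")
  expect_equal(lab$y[lab$sample_id == "S4"], 1L)
  expect_equal(lab$her2_source[lab$sample_id == "S4"], "ihc_status")
  expect_equal(nrow(res$excluded), 0L)
})

test_that("unresolvable samples are excluded and listed, any positive gives y=0", {
  clin <- rbind(
    clin_row("POS", er = "positive"),                 # ER+ decides alone
    clin_row("UNRES", er = "negative", pr = "negative")  # HER2 missing
  )
  res <- build_tnbc_labels(clin)
  expect_equal(res$labels$y[res$labels$sample_id == "POS"], 0L)
  expect_equal(res$excluded$sample_id, "UNRES")
  expect_match(res$excluded$reason, "unresolved")
})

test_that("y = 1 iff (ER, PR, HER2 call) all negative, by exhaustive enumeration", {
  codes <- c("positive", "negative", "missing")
  her2 <- c("positive", "negative", "equivocal", "indeterminate", "missing")
  grid <- expand.grid(er = codes, pr = codes, ihc = her2, fish = her2,
                      stringsAsFactors = FALSE)
  clin <- data.frame(sample_id = sprintf("c%03d", seq_len(nrow(grid))),
                     er_status = grid$er, pr_status = grid$pr,
                     her2_ihc_level = "missing",
                     her2_ihc_status = grid$ihc, her2_fish = grid$fish,
                     stringsAsFactors = FALSE)
  res <- build_tnbc_labels(clin)
  # oracle: resolve the HER2 call independently
  call <- ifelse(grid$fish %in% c("positive", "negative"), grid$fish,
                 ifelse(grid$ihc %in% c("positive", "negative"), grid$ihc,
                        "missing"))
  y_star <- ifelse(grid$er == "negative" & grid$pr == "negative" &
                     call == "negative", 1L,
                   ifelse(grid$er == "positive" | grid$pr == "positive" |
                            call == "positive", 0L, NA_integer_))
  m <- match(clin$sample_id, res$labels$sample_id)
  expect_equal(res$labels$y[m[!is.na(y_star)]], y_star[!is.na(y_star)])
  expect_setequal(res$excluded$sample_id, clin$sample_id[is.na(y_star)])
  # determinism / idempotence
  expect_identical(res, build_tnbc_labels(clin))
})

test_that("suspect flags: level-vs-status and IHC-vs-FISH discordance", {
  clin <- rbind(
    clin_row("LL-A73Y", level = "3+", ihc = "negative"),          # level vs status
    clin_row("BH-A18T", ihc = "positive", fish = "negative"),     # ihc vs fish
    clin_row("OK1", level = "1+", ihc = "negative"),              # concordant
    clin_row("OK2", level = "2+", ihc = "positive")               # 2+ indeterminate
  )
  fl <- flag_suspect_individuals(clin)
  expect_setequal(fl$sample_id, c("LL-A73Y", "BH-A18T"))
  expect_equal(fl$kind[fl$sample_id == "LL-A73Y"], "level_vs_status")
  expect_equal(fl$kind[fl$sample_id == "BH-A18T"], "ihc_vs_fish")
})

test_that("confounder screening: Fisher exact, logistic Wald, degenerate cases", {
  # perfectly associated 2x2 table: p = 2 / choose(20, 10)
  y <- rep(c(0, 1), each = 10)
  cov1 <- factor(rep(c("a", "b"), each = 10))
  res <- screen_confounders(data.frame(grp = cov1), y)
  expect_equal(res$test, "fisher_exact")
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(res$significant)

  # balanced table [[5,5],[5,5]]: two-sided p = 1
  y2 <- rep(c(0, 1), 10)
  cov2 <- factor(rep(c("a", "a", "b", "b"), 5))
  res2 <- screen_confounders(data.frame(grp = cov2), y2)
  expect_equal(res2$p_value, 1)

  # oracle: two-sided Fisher p equals point-probability summation
  tab <- matrix(c(7, 3, 2, 8), 2)
  probs <- dhyper(0:10, 10, 10, 9)
  obs <- dhyper(7, 10, 10, 9)
  expect_equal(fisher.test(tab)$p.value,
               sum(probs[probs <= obs * (1 + 1e-7)]), tolerance = 1e-9)

  # continuous covariate equal to y: separation noted, small p or flag
  res3 <- suppressWarnings(
    screen_confounders(data.frame(age = as.numeric(y)), y))
  expect_true(res3$note == "possible separation" || res3$significant)

  # constant covariate: p = 1 with warning
  expect_warning(res4 <- screen_confounders(data.frame(k = rep(1, 20)), y),
                 "constant")
  expect_equal(res4$p_value, 1)
})
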