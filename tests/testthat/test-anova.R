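anova_row <- function(av, src) av[av$source == src, ]

test_that("the Box-Behnken selectivity ANOVA matches the published decomposition", {
  fit <- fit_surface(bbd3(), "selectivity", scale = "fraction")
  av <- surface_anova(fit, order = c("T", "P", "G"))

  expect_equal(anova_row(av, "Total")$df, 14L)
  expect_equal(anova_row(av, "Regression")$df, 9L)
  expect_equal(anova_row(av, "Residual error")$df, 5L)
  expect_equal(anova_row(av, "Pure error")$df, 2L)
  expect_equal(anova_row(av, "Lack-of-fit")$df, 3L)

  # pure error from the three centre replicates 0.0183/0.0211/0.0217
  ctr <- c(0.0183, 0.0211, 0.0217)
  expect_equal(anova_row(av, "Pure error")$seq_ss, sum((ctr - mean(ctr))^2),
               tolerance = 1e-12)
  expect_equal(round(anova_row(av, "Pure error")$seq_ss, 6), 7e-06)

  # published F statistics reproduce to the precision the 2-dp responses allow
  expect_equal(round(anova_row(av, "Regression")$statistic, 2), 5.79)
  expect_rel_equal(anova_row(av, "T*G")$statistic, 7.47, 0.01)
  expect_rel_equal(anova_row(av, "P*G")$statistic, 12.79, 0.01)
  expect_rel_equal(anova_row(av, "Lack-of-fit")$statistic, 4.18, 0.01)
  expect_rel_equal(anova_row(av, "Total")$seq_ss, 0.000549, 0.01)

  # sequential pattern unique to the uncoded fit: T explains most first, little adjusted
  expect_gt(anova_row(av, "T")$seq_ss, 2e-4)
  expect_lt(anova_row(av, "T")$adj_ss, 1e-6)
})

test_that("sums of squares are additive", {
  fit <- fit_surface(bbd3(), "selectivity", scale = "fraction")
  av <- surface_anova(fit, order = c("T", "P", "G"))
  total <- anova_row(av, "Total")$seq_ss
  reg <- anova_row(av, "Regression")$seq_ss
  res <- anova_row(av, "Residual error")$seq_ss
  expect_rel_equal(reg + res, total, 1e-10)
  # single-term sequential SS sum to the regression SS
  singles <- av$seq_ss[av$source %in% c("T", "P", "G", "T*T", "P*P", "G*G",
                                        "T*P", "T*G", "P*G")]
  expect_rel_equal(sum(singles), reg, 1e-10)
  # block rows sum their members
  expect_rel_equal(anova_row(av, "Linear")$seq_ss,
                   sum(av$seq_ss[av$source %in% c("T", "P", "G")]), 1e-10)
  # lack-of-fit + pure error = residual
  expect_rel_equal(
    anova_row(av, "Lack-of-fit")$seq_ss + anova_row(av, "Pure error")$seq_ss,
    res, 1e-10
  )
  expect_true(all(av$seq_ss >= 0))
})

test_that("term order changes sequential but not adjusted SS or F", {
  fit <- fit_surface(bbd3(), "selectivity", scale = "fraction")
  av1 <- surface_anova(fit, order = c("T", "P", "G"))
  av2 <- surface_anova(fit, order = c("G", "P", "T"))
  # sequential SS of the square terms depend strongly on their position
  # (G*G first vs last differs several-fold in this non-orthogonal basis)
  expect_gt(anova_row(av1, "G*G")$seq_ss / anova_row(av2, "G*G")$seq_ss, 2)
  # adjusted SS and F are order-invariant (interaction rows are labelled by
  # the permutation, so match them as unordered pairs)
  pair_of <- function(src) paste(sort(strsplit(src, "*", fixed = TRUE)[[1]]),
                                 collapse = "*")
  for (src1 in c("T", "P", "G", "T*T", "P*P", "G*G", "T*P", "T*G", "P*G")) {
    src2 <- av2$source[vapply(av2$source, pair_of, "") == pair_of(src1)]
    expect_rel_equal(anova_row(av2, src2)$adj_ss, anova_row(av1, src1)$adj_ss, 1e-10)
    expect_rel_equal(anova_row(av2, src2)$statistic,
                     anova_row(av1, src1)$statistic, 1e-10)
  }
  expect_rel_equal(attr(av2, "r_squared"), attr(av1, "r_squared"), 1e-12)
})

test_that("adjusted SS agree with an independent Type III computation", {
  skip_if_not_installed("car")
  fit <- fit_surface(bbd3(), "selectivity", scale = "fraction")
  av <- surface_anova(fit, order = c("T", "P", "G"))
  mod <- lm(selectivity ~ T + P + G + I(T^2) + I(P^2) + I(G^2) +
              T:P + T:G + P:G,
            data = convert_response_scale(bbd3(), "selectivity", "fraction"))
  a3 <- car::Anova(mod, type = 3)
  map <- c(T = "T", P = "P", G = "G", `T*T` = "I(T^2)", `P*P` = "I(P^2)",
           `G*G` = "I(G^2)", `T*P` = "T:P", `T*G` = "T:G", `P*G` = "P:G")
  for (src in names(map)) {
    expect_rel_equal(anova_row(av, src)$adj_ss,
                     a3[map[[src]], "Sum Sq"], 1e-8)
  }
})

test_that("F ratios and p-values are invariant under response rescaling", {
  fit <- fit_surface(bbd3(), "selectivity", scale = "percent")
  av_f <- surface_anova(fit, order = c("T", "P", "G"), scale = "fraction")
  av_p <- surface_anova(fit, order = c("T", "P", "G"), scale = "percent")
  model_rows <- !av_f$source %in% c("Residual error", "Pure error", "Total")
  expect_equal(av_p$statistic[model_rows], av_f$statistic[model_rows],
               tolerance = 1e-10)
  expect_equal(av_p$p.value[model_rows], av_f$p.value[model_rows],
               tolerance = 1e-10)
  # SS scale by exactly 100^2
  expect_equal(av_p$seq_ss / av_f$seq_ss, rep(1e4, nrow(av_f)), tolerance = 1e-10)
})

test_that("designs without replicates omit the residual split with a warning", {
  ks <- known_surface()
  design <- ks$design[1:13, ] # drop two of the three centre replicates
  design <- design_table(tibble::as_tibble(design),
                         attr(ks$design, "factors"), attr(ks$design, "responses"))
  design$y <- design$y + seq(0.001, 0.013, by = 0.001) # avoid a perfect fit
  fit <- fit_surface(design, "y")
  expect_warning(av <- surface_anova(fit), "no replicated runs")
  expect_false(any(av$source %in% c("Lack-of-fit", "Pure error")))
  expect_equal(attr(av, "warnings"), "no replicated runs: lack-of-fit and pure-error rows omitted")
})
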