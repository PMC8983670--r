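test_that("missing-value filter keeps peptides complete enough in one condition", {
  cond <- rep(c("ctrl", "stress"), each = 4)
  m <- matrix(rnorm(40), 5, 8,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:8)))
  m[2, 1:3] <- NA            # 3 missing in ctrl, 0 in stress -> kept
  m[3, c(1:3, 5:7)] <- NA    # 3 missing in both -> dropped
  m[4, 5:8] <- NA            # complete in ctrl -> kept
  out <- suppressMessages(filter_missing(m, cond, thr = 2))
  expect_setequal(rownames(out), c("p1", "p2", "p4", "p5"))
  expect_error(filter_missing(m, cond, thr = -1), "thr")
  expect_error(filter_missing(m, rep("a", 8)), "conditions")
})

test_that("filter matches a brute-force set evaluation on random masks", {
  set.seed(7)
  cond <- rep(c("a", "b", "c"), each = 5)
  for (i in 1:10) {
    m <- matrix(rnorm(50 * 15), 50, 15,
                dimnames = list(paste0("p", 1:50), paste0("s", 1:15)))
    m[matrix(runif(length(m)) < 0.35, nrow = 50)] <- NA
    keep_bf <- vapply(seq_len(50), function(r) {
      any(vapply(unique(cond), function(l) {
        sum(is.na(m[r, cond == l])) <= 2
      }, logical(1)))
    }, logical(1))
    out <- suppressMessages(filter_missing(m, cond, thr = 2))
    expect_identical(rownames(out), rownames(m)[keep_bf])
  }
})

test_that("MinProb imputation draws near the detection floor, reproducibly", {
  set.seed(8)
  m <- matrix(rnorm(500 * 10, 20, 2), 500, 10,
              dimnames = list(paste0("p", 1:500), paste0("s", 1:10)))
  complete <- impute_minprob(m)
  expect_identical(complete, m)  # nothing to impute

  m[matrix(runif(length(m)) < 0.2, nrow = 500)] <- NA
  i1 <- impute_minprob(m, seed = 5)
  i2 <- impute_minprob(m, seed = 5)
  expect_identical(i1, i2)
  expect_false(anyNA(i1))
  # observed cells never touched
  expect_identical(i1[!is.na(m)], m[!is.na(m)])
  # imputed values sit below the per-sample observed median
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss))
      expect_lt(mean(i1[miss, j]), median(m[!miss, j]))
  }
  m_bad <- m; m_bad[, 1] <- NA
  expect_error(impute_minprob(m_bad), "zero observed")
})

test_that("unmoderated limit of the moderated test equals the two-sample t-test", {
  set.seed(9)
  m <- matrix(rnorm(50 * 12), 50, 12, dimnames = list(paste0("p", 1:50), NULL))
  g <- rep(c("stress", "control"), each = 6)
  res <- moderated_diff(m, g, c("stress", "control"), moderate = FALSE)
  for (r in c(1, 17, 50)) {
    tt <- t.test(m[r, g == "stress"], m[r, g == "control"], var.equal = TRUE)
    expect_equal(res$p_value[r], tt$p.value, tolerance = 1e-8)
    expect_equal(res$log2fc[r], unname(diff(rev(tt$estimate))), tolerance = 1e-8)
  }
})

test_that("moderated test agrees closely with an independent shrinkage implementation", {
  skip_if_not_installed("limma")
  set.seed(10)
  m <- matrix(rnorm(300 * 10, 20, 1), 300, 10,
              dimnames = list(paste0("p", 1:300), NULL))
  m[1:30, 1:5] <- m[1:30, 1:5] + 1
  g <- rep(c("stress", "control"), times = c(5, 5))
  mine <- moderated_diff(m, g, c("stress", "control"))
  design <- model.matrix(~factor(g, levels = c("control", "stress")))
  lf <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(mine$log2fc, unname(lf$coefficients[, 2]), tolerance = 1e-8)
  expect_gt(cor(-log10(mine$p_value), -log10(lf$p.value[, 2])), 0.999)
})

test_that("null p-values are uniform and planted effects are recovered with power", {
  set.seed(11)
  m0 <- matrix(rnorm(5000 * 12, 20, 1), 5000, 12)
  g <- rep(c("a", "b"), each = 6)
  p0 <- moderated_diff(m0, g, c("a", "b"))$p_value
  expect_gt(ks.test(p0, "punif")$p.value, 0.01)

  hits <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    m <- matrix(rnorm(60 * 12, 20, 0.3), 60, 12)
    m[1, g == "a"] <- m[1, g == "a"] + 1  # planted log2FC = 1
    res <- moderated_diff(m, g, c("a", "b"))
    res$fdr[1] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("blocking absorbs block shifts", {
  set.seed(12)
  g <- rep(c("a", "b"), each = 6)
  block <- rep(c("x", "y"), 6)
  m <- matrix(rnorm(100 * 12, 0, 0.5), 100, 12)
  m[, block == "y"] <- m[, block == "y"] + 5  # large block effect
  res_b <- moderated_diff(m, g, c("a", "b"), blocks = block)
  res_nb <- moderated_diff(m, g, c("a", "b"))
  # with the block absorbed, residual variance drops by ~the block variance
  expect_lt(median(attr(res_b, "prior")["var_prior"]),
            median(attr(res_nb, "prior")["var_prior"]))
  expect_gt(ks.test(res_b$p_value, "punif")$p.value, 0.01)
})

test_that("BH step-up reproduces hand-computed adjustments", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  # hand step-up: p_(i) * n / i, cumulative minimum from the top
  hand <- rev(cummin(rev(p * 10 / 1:10)))
  expect_equal(bh_fdr(p), hand)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("phospho enrichment reproduces the printed percentages and Fisher stats", {
  frac <- function(num, den, total_phospho, total) {
    is_ph <- rep(c(TRUE, FALSE), c(total_phospho, total - total_phospho))
    sig <- logical(total)
    sig[seq_len(num)] <- TRUE                      # phospho & significant
    sig[total_phospho + seq_len(den - num)] <- TRUE # non-phospho significant
    enrichment_stats(is_ph, sig)$fraction_phospho_sig
  }
  expect_equal(frac(10132, 16302, 10132, 16302), 62)  # all quantified
  expect_equal(frac(253, 269, 10132, 16302), 94)
  expect_equal(frac(188, 206, 10132, 16302), 91)
  expect_equal(frac(86, 94, 10132, 16302), 91)

  balanced <- enrichment_stats(rep(c(TRUE, FALSE), each = 20),
                               rep(c(TRUE, FALSE), times = 20))
  expect_equal(balanced$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(balanced$fisher_p, 1)
  expect_warning(enrichment_stats(c(TRUE, FALSE), c(FALSE, FALSE)),
                 "no significant")
})

test_that("two-way interaction test is calibrated and detects crossover", {
  f1 <- rep(c("ctrl", "stress"), each = 8)
  f2 <- rep(rep(c("m", "f"), each = 4), 2)
  set.seed(13)
  # additive truth: main effects only, no interaction
  m <- matrix(rnorm(3000 * 16), 3000, 16)
  m[, f1 == "stress"] <- m[, f1 == "stress"] + 2.5
  m[, f2 == "f"] <- m[, f2 == "f"] + 1
  res <- interaction_anova(m, f1, f2)
  expect_gt(ks.test(res$p_interaction, "punif")$p.value, 0.01)
  expect_lt(median(res$p_f1), 0.01)
  expect_lt(median(res$p_f2), 0.15)

  # perfect crossover, tiny noise
  mx <- matrix(rnorm(5 * 16, 0, 1e-4), 5, 16)
  shift <- ifelse(f1 == "stress", 1, -1) * ifelse(f2 == "f", 1, -1)
  mx <- sweep(mx, 2, shift, "+")
  resx <- interaction_anova(mx, f1, f2)
  expect_true(all(resx$p_interaction < 1e-12))
  expect_true(all(resx$p_f1 > 0.5))  # balanced crossover has no main effect

  expect_error(interaction_anova(m, rep("a", 16), f2), "two levels")
  expect_error(interaction_anova(m[, 1:8], f1[1:8], rep("m", 8)), "two levels")
})

test_that("filter-impute-test pipeline is deterministic given the seed", {
  sp <- phospho_sim_spec(n_peptides = 400, seed = 77)
  ph <- simulate_phospho(sp)
  run <- function() {
    f <- suppressMessages(filter_missing(ph$matrix, ph$samples$condition))
    i <- impute_minprob(f, seed = 3)
    moderated_diff(i, ph$samples$condition, c("t0.1", "control"))
  }
  expect_identical(run(), run())
})
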