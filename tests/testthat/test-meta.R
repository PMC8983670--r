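planted_profiles <- function(n_per, centers, noise = 0.05, seed = 1) {
  set.seed(seed)
  m <- do.call(rbind, lapply(seq_along(centers), function(i) {
    matrix(rep(centers[[i]], each = n_per), n_per) +
      matrix(rnorm(n_per * length(centers[[i]]), 0, noise), n_per)
  }))
  rownames(m) <- sprintf("f%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("c%d", seq_along(centers[[1]]))
  list(m = m, truth = rep(seq_along(centers), each = n_per))
}

test_that("k-means recovers planted temporal waves exactly at low noise", {
  early <- c(2, 1, 0.3, 0, 0); late <- c(0, 0.3, 1, 2, 1)
  pp <- planted_profiles(30, list(early, late), seed = 61)
  cl <- kmeans_profiles(pp$m, k = 2, min_size = 15, seed = 62)
  expect_equal(adjusted_rand(cl$assignment, pp$truth), 1)
  expect_equal(sort(cl$sizes), c(30, 30))
  expect_length(cl$excluded, 0)
  # reproducible under the same seed
  cl2 <- kmeans_profiles(pp$m, k = 2, min_size = 15, seed = 62)
  expect_identical(cl$assignment, cl2$assignment)
})

test_that("small clusters are excluded from the report but never dropped", {
  big1 <- c(2, 0, 0); big2 <- c(0, 0, 2)
  pp <- planted_profiles(20, list(big1, big2), noise = 0.02, seed = 63)
  outlier <- matrix(c(-5, -5, -5, -5.01, -5, -5), 2, 3, byrow = TRUE,
                    dimnames = list(c("o1", "o2"), colnames(pp$m)))
  m <- rbind(pp$m, outlier)
  cl <- kmeans_profiles(m, k = 3, min_size = 15, seed = 64)
  expect_equal(cl$sizes, c(20, 20, 2))
  expect_equal(cl$excluded, 3)          # smallest cluster label
  expect_equal(cl$included, c(1, 2))
  expect_length(cl$assignment, 42)      # everything still assigned

  # min_size larger than n: every cluster excluded, reported empty
  cl_all <- kmeans_profiles(pp$m, k = 2, min_size = 100, seed = 65)
  expect_length(cl_all$included, 0)
  expect_equal(length(cl_all$excluded), 2)
})

test_that("cluster summaries recompute exactly from the assignments", {
  pp <- planted_profiles(25, list(c(1, 0, -1), c(-1, 0, 1)), seed = 66)
  cl <- kmeans_profiles(pp$m, k = 2, min_size = 5, seed = 67)
  for (l in seq_along(cl$sizes)) {
    sub <- pp$m[cl$assignment == l, , drop = FALSE]
    expect_equal(cl$summary[[l]]$mean, unname(colMeans(sub)))
    expect_equal(cl$summary[[l]]$sd, unname(apply(sub, 2, sd)))
    expect_equal(cl$summary[[l]]$sem,
                 unname(apply(sub, 2, sd)) / sqrt(nrow(sub)))
  }
})

test_that("degenerate all-zero profiles are split without error", {
  m <- matrix(0, 20, 4, dimnames = list(sprintf("f%02d", 1:20), NULL))
  cl <- kmeans_profiles(m, k = 2, min_size = 1, seed = 68)
  expect_equal(cl$tot_withinss, 0)
  expect_length(cl$assignment, 20)
  expect_error(kmeans_profiles(m, k = 1), "k must")
  expect_error(kmeans_profiles(m[1, , drop = FALSE], k = 2), "at least k")
})

test_that("elbow diagnostics peak at the planted number of clusters", {
  pp <- planted_profiles(15, list(c(3, 0, 0), c(0, 3, 0), c(0, 0, 3)),
                         noise = 0.1, seed = 69)
  rep_k <- elbow_report(pp$m, k_range = 2:6, seed = 70)
  expect_equal(rep_k$k[which.max(rep_k$mean_silhouette)], 3)
  expect_true(all(diff(rep_k$inertia) <= 1e-8))  # monotone decrease
  expect_error(elbow_report(pp$m[1, , drop = FALSE], 2), "features")
  expect_error(elbow_report(pp$m, k_range = c(2, 45)), "k_range")
})

test_that("surrogate variables are null-calibrated, recover batches, and stay orthogonal", {
  set.seed(71)
  design <- data.frame(condition = rep(c("ctrl", "stress"), each = 8))
  # no hidden structure: usually no SVs
  zeros <- 0L
  for (seed in 1:15) {
    set.seed(900 + seed)
    counts <- matrix(rnbinom(300 * 16, mu = 100, size = 10), 300, 16,
                     dimnames = list(NULL, paste0("s", 1:16)))
    sv <- estimate_svs(counts, design, n_perm = 50, seed = seed)
    zeros <- zeros + (sv$n_sv == 0)
  }
  expect_gte(zeros, 13)

  # planted gene-specific batch effects on half the samples
  set.seed(72)
  batch <- rep(c(0, 1), times = 8)
  delta <- rnorm(400, 0, 0.5)
  mu <- 100 * exp(outer(delta, batch))
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 10), 400,
                   dimnames = list(NULL, paste0("s", 1:16)))
  sv <- estimate_svs(counts, design, n_perm = 50, seed = 73)
  expect_gte(sv$n_sv, 1)
  expect_gte(abs(cor(sv$sv[, 1], batch)), 0.9)
  X <- model.matrix(~., design)
  expect_lt(max(abs(crossprod(X, sv$sv))) / nrow(X), 1e-8)
})

test_that("meta_fit reduces to the ordinary linear model for one dataset, no SVs", {
  set.seed(74)
  counts <- matrix(rnbinom(100 * 10, mu = 200, size = 5), 100, 10,
                   dimnames = list(paste0("g", 1:100), paste0("s", 1:10)))
  cond <- rep(c("ctrl", "stress"), each = 5)
  res <- meta_fit(counts, cond, dataset = rep("d1", 10))
  v <- logcpm(counts)
  for (g in c(3, 50, 97)) {
    fit <- summary(lm(v[g, ] ~ factor(cond)))
    expect_equal(res$p_condition[g], fit$coefficients[2, 4],
                 tolerance = 1e-10)
    expect_equal(res$logfc[g], fit$coefficients[2, 1], tolerance = 1e-10)
  }
})

test_that("interactive mode detects dataset-specific effects and flags aliasing", {
  set.seed(75)
  n <- 24
  dataset <- rep(c("d1", "d2"), each = 12)
  cond <- rep(rep(c("ctrl", "stress"), each = 6), 2)
  # balanced planting (10 up, 10 down) keeps library sizes stable so the
  # remaining genes are genuinely null after CPM normalization
  mu <- matrix(200, 300, n)
  d2s <- dataset == "d2" & cond == "stress"
  mu[1:10, d2s] <- 200 * 3   # d2-only effects
  mu[11:20, d2s] <- 200 / 3
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 20), 300,
                   dimnames = list(paste0("g", 1:300), paste0("s", 1:n)))
  res <- meta_fit(counts, cond, dataset, mode = "interactive")
  expect_gte(mean(res$fdr_interaction[1:20] < 0.05), 0.8)
  # null genes: interaction p-values not anti-conservative
  expect_lt(mean(res$p_interaction[21:300] < 0.05), 0.1)
  expect_gt(median(res$p_interaction[21:300]), 0.35)

  # shared effect across datasets: additive test powered, interaction null
  mu2 <- matrix(200, 300, n)
  mu2[1:10, cond == "stress"] <- 400
  mu2[11:20, cond == "stress"] <- 100
  counts2 <- matrix(rnbinom(length(mu2), mu = mu2, size = 20), 300,
                    dimnames = dimnames(counts))
  res2 <- meta_fit(counts2, cond, dataset, mode = "interactive")
  expect_gte(mean(res2$fdr_condition[1:20] < 0.05), 0.9)
  expect_gt(ks.test(res2$p_interaction[1:20], "punif")$p.value, 0.001)

  confounded <- rep(c("ctrl", "stress"), each = 12)
  expect_error(meta_fit(counts, confounded, dataset, mode = "interactive"),
               "confounded")
})

test_that("surrogate variables rescue a batch-confounded meta-analysis", {
  set.seed(76)
  n <- 24
  dataset <- rep(c("d1", "d2"), each = 12)
  cond <- rep(rep(c("ctrl", "stress"), each = 6), 2)
  delta <- rnorm(300, 0, 0.5)  # gene-specific dataset effects
  mu <- 150 * exp(outer(delta, as.numeric(dataset == "d2")))
  mu[1:30, cond == "stress"] <- mu[1:30, cond == "stress"] * 2
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 20), 300,
                   dimnames = list(paste0("g", 1:300), paste0("s", 1:n)))
  sv <- estimate_svs(counts, data.frame(condition = cond), n_perm = 50,
                     seed = 77)
  res <- meta_fit(counts, cond, dataset, svs = sv$sv)
  expect_gte(mean(res$fdr_condition[1:30] < 0.05), 0.8)
})
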