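random_table <- function(n_rows, n_met = 6L, seed = 1) {
  set.seed(seed)
  tb <- tibble::as_tibble(matrix(stats::runif(n_rows * n_met, 1, 100),
                                 nrow = n_rows,
                                 dimnames = list(NULL, sprintf("m%02d", seq_len(n_met)))))
  dplyr::bind_cols(tibble::tibble(line_id = sprintf("l%02d", seq_len(n_rows)),
                                  replicate = 1L), tb)
}

test_that("PCA scores respect duplication and rank-1 structure", {
  tb <- random_table(5, 6, seed = 2)
  dup <- dplyr::bind_rows(tb, tb)
  pca <- fit_pca(dup)
  sc <- as.matrix(tidy(pca)[, c("PC1", "PC2")])
  expect_equal(sc[1:5, ], sc[6:10, ], ignore_attr = TRUE)

  # two perfectly correlated columns: PC1 carries all the variance
  x <- stats::runif(10, 1, 50)
  tb2 <- tibble::tibble(line_id = sprintf("l%d", 1:10), m01 = x, m02 = 2 * x + 5)
  pca2 <- fit_pca(tb2)
  expect_equal(pca2$explained[1], 1, tolerance = 1e-12)
})

test_that("truncated reconstruction error equals the eigendecomposition oracle", {
  tb <- random_table(12, 8, seed = 5)
  k <- 2L
  pca <- fit_pca(tb, k = k)
  x <- scale(as.matrix(tb[, sprintf("m%02d", 1:8)]))
  # oracle: full eigendecomposition of the correlation matrix, truncate to k
  eig <- eigen(stats::cov(x), symmetric = TRUE)
  vk <- eig$vectors[, seq_len(k), drop = FALSE]
  recon_oracle <- x %*% vk %*% t(vk)
  err_oracle <- sum((x - recon_oracle)^2)
  rot <- pca$fit$rotation[, seq_len(k), drop = FALSE]
  recon_fit <- pca$fit$x[, seq_len(k), drop = FALSE] %*% t(rot)
  expect_equal(sum((x - recon_fit)^2), err_oracle, tolerance = 1e-8)
  # explained variance is non-increasing and sums below 1
  expect_true(all(diff(pca$explained) <= 1e-12))
  expect_lte(sum(pca$explained), 1 + 1e-12)
})

test_that("PCA drops zero-variance metabolites and rejects constant tables", {
  tb <- random_table(6, 4, seed = 3)
  tb$m03 <- 5
  expect_warning(pca <- fit_pca(tb), "zero-variance")
  expect_equal(pca$dropped, "m03")
  tb_const <- tb
  tb_const[sprintf("m%02d", 1:4)] <- 1
  expect_error(suppressWarnings(fit_pca(tb_const)))
})

test_that("scores are invariant to row order and to global rescaling", {
  tb <- random_table(9, 6, seed = 8)
  pca <- fit_pca(tb)
  perm <- sample(nrow(tb))
  pca_perm <- fit_pca(tb[perm, ])
  sc <- tidy(pca); scp <- tidy(pca_perm)
  a <- as.matrix(sc[, c("PC1", "PC2")])
  b <- as.matrix(scp[order(match(scp$line_id, sc$line_id)), c("PC1", "PC2")])
  # principal axes are defined up to sign; align before comparing
  for (j in 1:2) b[, j] <- b[, j] * sign(sum(a[, j] * b[, j]))
  expect_equal(b, a, tolerance = 1e-9, ignore_attr = TRUE)
  # global rescaling of raw areas changes nothing after autoscaling
  tb_scaled <- tb
  tb_scaled[sprintf("m%02d", 1:6)] <- tb_scaled[sprintf("m%02d", 1:6)] * 7.3
  expect_equal(as.matrix(tidy(fit_pca(tb_scaled))[, c("PC1", "PC2")]),
               as.matrix(sc[, c("PC1", "PC2")]), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("nearest-centroid assignment handles exact hits, ties and novelty", {
  refs <- tibble::tibble(
    line_id = rep(c("rA", "rB"), each = 3),
    class = rep(c("sad1", "sad3"), each = 3),
    PC1 = c(0, 0.1, -0.1, 5, 5.1, 4.9),
    PC2 = c(0, 0.1, -0.1, 0, 0.1, -0.1)
  )
  q <- tibble::tibble(line_id = c("q1", "q2", "q3"),
                      PC1 = c(0, 5, 100), PC2 = c(0, 0, 100))
  asn <- assign_chemotype(q, refs)
  expect_equal(asn$assigned, c("sad1", "sad3", "novel"))
  expect_equal(asn$distance[1], 0)
  # no references: everything is novel
  asn2 <- assign_chemotype(q, refs[0, ])
  expect_true(all(asn2$assigned == "novel"))
  # under-replicated reference class is rejected
  expect_error(assign_chemotype(q, refs[c(1, 4:6), ]), "2 replicates")
})

test_that("a line with a chemotype absent from the references is called novel", {
  classes <- setdiff(names(chemotype_profiles()), "cyp94d65")
  cfg <- sim_config(seed = 31)
  asg <- c(stats::setNames(classes, paste0("ref_", classes)),
           q_unknown = "cyp94d65")
  tb <- simulate_peak_table(cfg, asg, n_replicates = 3)
  asn <- classify_lines(tb)
  expect_equal(asn$assigned[asn$line_id == "q_unknown"], "novel")
})

test_that("marker ranking orders by |Welch t| and matches a recomputation oracle", {
  set.seed(12)
  n <- 5L
  tb <- dplyr::bind_rows(
    dplyr::mutate(random_table(n, 8, seed = 13), class = "WT"),
    dplyr::mutate(random_table(n, 8, seed = 14), class = "mut")
  )
  tb$m01 <- rep(c(10, 10), each = n) + stats::rnorm(2 * n, 0, 0.01)  # near-constant
  tb$m02[tb$class == "mut"] <- tb$m02[tb$class == "mut"] + 500       # 10+ SD shift
  mk <- rank_markers(tb, "WT", "mut", top_n = 8)
  expect_equal(mk$metabolite[1], "m02")
  expect_equal(mk$metabolite[8], "m01")
  # direct recomputation oracle
  for (i in seq_len(nrow(mk))) {
    m <- mk$metabolite[i]
    tt <- stats::t.test(tb[[m]][tb$class == "mut"], tb[[m]][tb$class == "WT"])
    expect_equal(mk$t[i], unname(tt$statistic), tolerance = 1e-12)
  }
  expect_true(all(diff(abs(mk$t)) <= 1e-12))
  expect_warning(rank_markers(tb, "WT", "mut", top_n = 240), "exceeds")
})

test_that("group comparison reproduces the textbook pooled-variance t test", {
  tb <- tibble::tibble(
    line_id = "l", replicate = 1:6,
    class = rep(c("a", "b"), each = 3),
    m01 = c(10, 12, 11, 4, 5, 6),
    m02 = c(1, 2, 3, 1, 2, 3)
  )
  res <- compare_groups(tb, "m01", "a", "b")
  # hand computation: pooled sd with n1 = n2 = 3, s1 = s2 = 1
  sp <- sqrt(((3 - 1) * 1 + (3 - 1) * 1) / 4)
  t_hand <- (11 - 5) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * stats::pt(-abs(t_hand), df = 4), tolerance = 1e-12)
  expect_equal(res$fold_change, 5 / 11, tolerance = 1e-12)

  ident <- compare_groups(tb, "m02", "a", "b")
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_equal(ident$fold_change, 1)

  # zero variance in both groups with equal means
  tb$m03 <- 7
  flat <- compare_groups(tb, "m03", "a", "b")
  expect_equal(flat$p, 1)
})

test_that("segregation chi-square matches hand formulas", {
  exact <- segregation_test(c(48, 96, 48))
  expect_equal(exact$statistic, 0)
  expect_equal(exact$p_value, 1)
  expect_equal(exact$df, 2)

  # 40:100:52 against 1:2:1, expected 48:96:48:
  # X2 = 64/48 + 16/96 + 16/48; 2-df survival = exp(-x/2)
  res <- segregation_test(c(40, 100, 52))
  x2_hand <- 64 / 48 + 16 / 96 + 16 / 48
  expect_equal(res$statistic, x2_hand, tolerance = 1e-12)
  expect_equal(res$p_value, exp(-x2_hand / 2), tolerance = 1e-12)

  expect_lt(segregation_test(c(192, 0, 0))$p_value, 1e-10)
  expect_error(segregation_test(c(10, 20), ratio = c(1, 2, 1)), "same number")
})
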