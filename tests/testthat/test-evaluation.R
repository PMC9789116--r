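test_that("rle_matrix centers rows on their medians", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  colnames(m) <- paste0("s", 1:3)
  r <- rle_matrix(m)
  expect_equal(r["a", ], c(s1 = -1, s2 = 0, s3 = 1))
  expect_equal(unname(r["b", ]), c(0, 0, 0))
  set.seed(1)
  m2 <- matrix(rnorm(50), 10, 5)
  expect_true(all(abs(apply(rle_matrix(m2), 1, median)) < 1e-12))
})

test_that("rle_quality computes grouped variances and omega", {
  # identical duplicated samples per group: variances 0, omega capped
  base <- matrix(rnorm(30), 10, 3)
  m <- cbind(base[, 1], base[, 1], base[, 2], base[, 2])
  colnames(m) <- paste0("s", 1:4)
  rs <- rle_quality(rle_matrix(m), c("g1", "g1", "g2", "g2"))
  expect_equal(rs$V_med, 0)
  expect_equal(rs$omega, 1e9)
  expect_true(rs$capped)

  # injected variance: omega = -ln(V_med + V_iqr)
  set.seed(2)
  delta <- rnorm(4, 0, 0.3)
  m2 <- sweep(cbind(base[, 1], base[, 1], base[, 2], base[, 2]), 2, delta, "+")
  colnames(m2) <- paste0("s", 1:4)
  rs2 <- rle_quality(rle_matrix(m2), c("g1", "g1", "g2", "g2"))
  expect_false(rs2$capped)
  expect_equal(rs2$omega, -log(rs2$V_med + rs2$V_iqr))
  # shifts move medians, not IQRs
  expect_gt(rs2$V_med, 0)
  expect_lt(rs2$V_iqr, rs2$V_med)

  expect_error(rle_quality(rle_matrix(m), paste0("g", 1:4)), "singleton")
})

test_that("omega equals -ln 0.02 on a constructed summary", {
  # construct groups whose median variance + iqr variance is exactly 0.02
  expect_equal(-log(0.02), 3.912, tolerance = 1e-3)
  base <- matrix(rep(seq(-2, 2, length.out = 11), 4), 11, 4)
  delta <- c(-0.1, 0.1, -0.1, 0.1)       # within-group var of medians = 0.02
  m <- sweep(base, 2, delta, "+")
  colnames(m) <- paste0("s", 1:4)
  rs <- rle_quality(rle_matrix(m), c("g1", "g1", "g2", "g2"))
  expect_equal(rs$V_med, 0.02, tolerance = 1e-12)
  expect_equal(rs$V_iqr, 0, tolerance = 1e-12)
  expect_equal(rs$omega, -log(0.02), tolerance = 1e-9)
})

test_that("rle_ncc detects and acquits batch association", {
  set.seed(3)
  N <- 200
  md <- data.frame(sample_id = paste0("s", 1:N),
                   replicate_group = rep(c("a", "b"), N / 2),
                   batch = sample(rep(c("x", "y"), N / 2)))
  # independent summaries: NCC high
  S <- cbind(median = rnorm(N), iqr = rnorm(N))
  rownames(S) <- md$sample_id
  expect_gte(rle_ncc(S, md, "batch"), 0.7)
  # summaries equal to the batch dummy: NCC 0
  S2 <- cbind(median = as.numeric(md$batch == "y"), iqr = rnorm(N))
  rownames(S2) <- md$sample_id
  expect_lt(rle_ncc(S2, md, "batch"), 1e-6)
})

test_that("single-pair NCC reduces to 1 - |Pearson r|", {
  set.seed(4)
  N <- 60
  x <- rnorm(N)
  md <- data.frame(sample_id = paste0("s", 1:N),
                   replicate_group = "g",
                   num2 = ifelse(x + rnorm(N, 0, 0.5) > 0, "hi", "lo"))
  S <- cbind(median = x)
  rownames(S) <- md$sample_id
  d <- as.numeric(md$num2 == "lo")
  expect_equal(rle_ncc(S, md, "num2"), 1 - abs(cor(x, d)), tolerance = 1e-9)
})

test_that("pca_scores follow SVD geometry", {
  # rank-1 data: PC1 explains everything
  set.seed(5)
  v <- rnorm(12)
  t_ <- rnorm(8)
  m <- outer(t_, v)                      # taxa x samples, exact rank 1
  dimnames(m) <- list(paste0("t", 1:8), paste0("s", 1:12))
  p <- pca_scores(m, 4)
  expect_gt(p$explained[1], 0.999)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-12)

  # duplicated sample gives identical score rows
  m2 <- matrix(rnorm(80), 8, 10,
               dimnames = list(paste0("t", 1:8), paste0("s", 1:10)))
  m2[, 10] <- m2[, 1]
  p2 <- pca_scores(m2, 3)
  expect_equal(p2$scores[1, ], p2$scores[10, ], tolerance = 1e-9)

  expect_warning(p3 <- pca_scores(matrix(3, 5, 8,
                                         dimnames = list(paste0("t", 1:5),
                                                         paste0("s", 1:8))), 2),
                 "constant")
  expect_true(all(p3$scores == 0))
})

test_that("silhouette matches a brute-force reimplementation exactly", {
  brute_sil <- function(scores, labels) {
    D <- as.matrix(dist(scores))
    n <- nrow(D)
    s <- numeric(n)
    for (i in seq_len(n)) {
      own <- labels == labels[i]
      if (sum(own) == 1) { s[i] <- 0; next }
      a <- mean(D[i, own & seq_len(n) != i])
      b <- min(vapply(setdiff(unique(labels), labels[i]),
                      function(l) mean(D[i, labels == l]), 0))
      s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
    }
    mean(s)
  }
  set.seed(6)
  scores <- matrix(rnorm(60 * 3), 60, 3)
  labels <- sample(c("a", "b", "c"), 60, replace = TRUE)
  expect_equal(silhouette_by_label(scores, labels),
               brute_sil(scores, labels), tolerance = 1e-12)
})

test_that("silhouette separates tight clusters and is ~0 under shuffling", {
  set.seed(7)
  scores <- rbind(matrix(rnorm(100, 0, 0.1), 50, 2),
                  matrix(rnorm(100, 10, 0.1), 50, 2))
  labels <- rep(c("a", "b"), each = 50)
  expect_gte(silhouette_by_label(scores, labels), 0.9)
  expect_lt(abs(silhouette_by_label(scores, sample(labels))), 0.1)
  expect_error(silhouette_by_label(scores, rep("a", 100)), "2 labels")
})

test_that("factor_correlation scores numeric and categorical covariates", {
  set.seed(8)
  N <- 200
  lgm <- rnorm(N)
  batch <- sample(rep(c("x", "y"), N / 2))
  md <- data.frame(sample_id = paste0("s", 1:N), replicate_group = "g",
                   batch = batch)
  W <- cbind(W1 = lgm,                            # = log geometric mean
             W2 = as.numeric(batch == "y") + rnorm(N, 0, 0.2),
             W3 = rnorm(N))
  rownames(W) <- md$sample_id
  fc <- factor_correlation(W, md, numeric_covariates = list(lgm = lgm))
  get <- function(w, cov) fc$correlation[fc$w_column == w & fc$covariate == cov]
  expect_equal(get("W1", "lgm"), 1, tolerance = 1e-12)
  expect_gte(get("W2", "batch"), 0.8)
  expect_lt(get("W3", "batch"), 0.25)
  expect_lt(get("W3", "lgm"), 0.25)
})

test_that("evaluation metrics are invariant to sample permutation and relabeling", {
  sim <- small_scenario(seed = 41)
  md <- sim$metadata
  logm <- clr_transform(sim$counts)
  perm <- sample(ncol(logm))
  r1 <- rle_quality(rle_matrix(logm), md$replicate_group)
  r2 <- rle_quality(rle_matrix(logm[, perm]), md$replicate_group[perm])
  expect_equal(r1$omega, r2$omega, tolerance = 1e-9)

  n1 <- rle_ncc(r1, md, "storage")
  md2 <- md
  md2$storage <- ifelse(md$storage == "A", "level_Z", "level_Q")
  n2 <- rle_ncc(r1, md2, "storage")
  expect_equal(n1, n2, tolerance = 1e-9)
})

test_that("control_cpm_ratio reproduces constructed ratios", {
  md <- data.frame(sample_id = paste0("s", 1:4), replicate_group = "g",
                   spiked = c(TRUE, TRUE, FALSE, FALSE))
  m <- rbind(spike = c(92L, 92L, 2L, 2L),
             bg = c(908L, 908L, 998L, 998L),
             absent = c(0L, 0L, 0L, 0L))
  colnames(m) <- md$sample_id
  r <- control_cpm_ratio(m, md, c("spike", "absent", "bg"))
  expect_equal(r$ratio[r$taxon_id == "spike"], 46, tolerance = 1e-12)
  expect_true(is.nan(r$ratio[r$taxon_id == "absent"]))
  expect_true(r$flagged[r$taxon_id == "absent"])
  expect_equal(r$ratio[r$taxon_id == "bg"], 908 / 998, tolerance = 1e-9)

  md$spiked <- NULL
  expect_error(control_cpm_ratio(m, md, "spike"), "spiked")
})
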