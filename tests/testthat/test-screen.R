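test_that("correlation p-values match the t-distribution oracle", {
  expect_equal(correlation_pvalue(0, 10), 1)
  expect_equal(correlation_pvalue(1, 10), 0)
  expect_equal(correlation_pvalue(-1, 5), 0)
  # hand value from the t CDF at r = 0.9, n = 12
  expect_equal(correlation_pvalue(0.9, 12),
               2 * pt(-0.9 * sqrt(10 / 0.19), 10), tolerance = 1e-12)
  # independent route: cor.test on random data
  set.seed(5)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    a <- rnorm(n); b <- rnorm(n)
    expect_equal(correlation_pvalue(cor(a, b), n),
                 cor.test(a, b)$p.value, tolerance = 1e-10)
  }
  expect_error(correlation_pvalue(0.5, 2), "at least 3")
})

test_that("BH adjustment matches a hand-written step-up oracle", {
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(6)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))^2
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  # order invariance up to reordering
  p <- runif(20)
  ord <- sample(20)
  expect_equal(bh_fdr(p)[ord], bh_fdr(p[ord]))
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("delays classify into the three-way partition", {
  expect_identical(classify_delay(c(0L, 3L, -2L, NA)),
                   c("none", "positive", "negative", NA))
})

test_that("a screen flags exactly the planted noise-free shifted copies", {
  set.seed(8)
  T <- 14
  ref <- rbind(ref1 = cosine_traj(T))
  true_shift <- rep_len(c(-2, -1, 0, 1, 2), 20)
  queries <- matrix(rnorm(100 * T), 100, T)
  for (i in 1:20) queries[i, ] <- cosine_traj(T, shift = true_shift[i])
  rownames(queries) <- sprintf("q%03d", 1:100)
  res <- screen_associations(ref, queries)
  expect_s3_class(res, "dynomics_screen")
  expect_identical(nrow(res), 100L)
  expect_identical(which(res$associated), 1:20)
  expect_identical(res$delay[1:20], as.integer(true_shift))
  expect_identical(res$delay_class[res$delay == 0 & res$associated],
                   rep("none", sum(true_shift == 0)))
})

test_that("the sign filter separates inhibitory from concordant pairs", {
  T <- 12
  ref <- rbind(r1 = cosine_traj(T))
  qry <- rbind(q1 = -cosine_traj(T))       # the 180-degree case
  neg <- screen_associations(ref, qry, sign_filter = "negative")
  pos <- screen_associations(ref, qry, sign_filter = "positive")
  expect_true(neg$associated)
  expect_false(pos$associated)
  expect_identical(neg$delay, 0L)
})

test_that("raising the correlation threshold only removes associations", {
  set.seed(13)
  T <- 10
  refs <- matrix(rnorm(5 * T), 5, T, dimnames = list(paste0("r", 1:5), NULL))
  queries <- matrix(rnorm(8 * T), 8, T, dimnames = list(paste0("q", 1:8), NULL))
  lo <- screen_associations(refs, queries, corr_threshold = 0.5)
  hi <- screen_associations(refs, queries, corr_threshold = 0.8)
  expect_true(all(which(hi$associated) %in% which(lo$associated)))
  none <- screen_associations(refs, queries, corr_threshold = 1.0)
  expect_false(any(none$associated))
})

test_that("zero-variance trajectories are flagged, never dropped", {
  T <- 10
  refs <- rbind(r1 = cosine_traj(T), r2 = rep(2, T))
  queries <- rbind(q1 = cosine_traj(T))
  res <- screen_associations(refs, queries)
  expect_identical(nrow(res), 2L)
  flat <- res[res$reference_id == "r2", ]
  expect_identical(flat$status, "zero_variance")
  expect_false(flat$associated)
  expect_true(is.na(flat$correlation))
})

test_that("a pair list restricts the screen and unknown ids error", {
  T <- 10
  refs <- rbind(r1 = cosine_traj(T), r2 = cosine_traj(T, K = 2))
  queries <- rbind(q1 = cosine_traj(T), q2 = rnorm(T))
  pl <- data.frame(reference_id = c("r1", "r2"), query_id = c("q1", "q1"))
  res <- screen_associations(refs, queries, pairs = pl)
  expect_identical(nrow(res), 2L)
  expect_identical(res$query_id, c("q1", "q1"))
  expect_error(
    screen_associations(refs, queries,
                        pairs = data.frame(reference_id = "r9",
                                           query_id = "q1")),
    "r9")
})

test_that("screening is deterministic and independent of pair order", {
  set.seed(17)
  T <- 10
  refs <- matrix(rnorm(3 * T), 3, T, dimnames = list(paste0("r", 1:3), NULL))
  queries <- matrix(rnorm(4 * T), 4, T, dimnames = list(paste0("q", 1:4), NULL))
  a <- screen_associations(refs, queries)
  b <- screen_associations(refs, queries)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # shuffled inputs give the same per-pair records
  perm <- c(3, 1, 2)
  c_ <- screen_associations(refs[perm, ], queries)
  key <- function(d) d[order(d$reference_id, d$query_id),
                       setdiff(names(d), c())]
  rownames_null <- function(d) { rownames(d) <- NULL; d }
  expect_equal(rownames_null(key(as.data.frame(a))),
               rownames_null(key(as.data.frame(c_))))
})

test_that("mismatched time grids are rejected", {
  expect_error(screen_associations(matrix(rnorm(10), 1),
                                   matrix(rnorm(12), 1)),
               "same number of")
})
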