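# Independent Kruskal-Wallis oracle: H = 12/(N(N+1)) * sum R_i^2/n_i - 3(N+1)
# (no ties in the inputs used here).
kw_oracle <- function(values, labels) {
  r <- rank(values)
  N <- length(values)
  Rs <- tapply(r, labels, sum)
  ns <- tapply(r, labels, length)
  12 / (N * (N + 1)) * sum(Rs^2 / ns) - 3 * (N + 1)
}

test_that("Kruskal-Wallis H matches the rank-formula oracle", {
  v1 <- c(1, 2, 3, 4, 5, 6)
  g1 <- rep(1:2, each = 3)
  expect_equal(kw_oracle(v1, g1), 3.857142857, tolerance = 1e-9)
  expect_equal(kw_test(v1, g1)$H, kw_oracle(v1, g1), tolerance = 1e-9)
  v2 <- c(1:5, 11:15)
  g2 <- rep(1:2, each = 5)
  expect_equal(kw_oracle(v2, g2), 6.818181818, tolerance = 1e-9)
  expect_equal(kw_test(v2, g2)$H, kw_oracle(v2, g2), tolerance = 1e-9)
  # all identical values: no rank variation
  expect_equal(kw_test(rep(2, 6), g1)$H, 0)
  expect_equal(kw_test(rep(2, 6), g1)$p, 1)
  expect_error(kw_test(1:5, rep(1, 5)), "2 groups")
})

test_that("H and p are invariant under cluster-label permutation", {
  set.seed(3)
  v <- runif(30)
  g <- sample(1:3, 30, replace = TRUE)
  a <- kw_test(v, g)
  b <- kw_test(v, c(3, 1, 2)[g])
  expect_equal(a$H, b$H)
  expect_equal(a$p, b$p)
})

test_that("cluster tree separates well-separated blobs at the top", {
  set.seed(5)
  J <- rbind(matrix(rnorm(40, 0, 0.02), ncol = 2),
             matrix(rnorm(40, 1, 0.02), ncol = 2))
  tree <- cluster_tree(J)
  lab <- cutree(tree, 2)
  expect_equal(length(unique(lab[1:20])), 1)
  expect_equal(length(unique(lab[21:40])), 1)
  expect_false(lab[1] == lab[21])
  # duplicated points merge at height zero
  Jd <- rbind(c(0, 0), c(0, 0), c(1, 1))
  expect_equal(min(cluster_tree(Jd)$height), 0)
  expect_error(cluster_tree(J[1, , drop = FALSE]), "2 solutions")
})

test_that("4-point linkage matches the Lance-Williams median oracle", {
  # points spanning [0,1] in both coordinates so normalization is identity
  X <- rbind(c(0, 0), c(0.1, 0.9), c(0.55, 0.45), c(1, 1))
  tree <- cluster_tree(X)
  # brute-force WPGMC agglomeration on squared Euclidean distances
  d <- as.matrix(dist(X))^2
  active <- as.list(1:4)
  merges <- list()
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (i >= j) next
      if (d[i, j] < best[1]) best <- c(d[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    merges[[length(merges) + 1]] <- sort(c(active[[i]], active[[j]]))
    nd <- sapply(seq_along(active), function(k)
      if (k %in% c(i, j)) NA else
        d[i, k] / 2 + d[j, k] / 2 - d[i, j] / 4)
    keep <- setdiff(seq_along(active), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], nd[keep]),
               c(nd[keep], 0))
    active <- c(active[keep],
                list(sort(c(active[[i]], active[[j]]))))
  }
  expect_equal(tree$height, heights, tolerance = 1e-12)
  # leaves merged at each step agree with the oracle
  got <- list()
  for (s in seq_len(nrow(tree$merge))) {
    members <- function(v) {
      out <- integer(0)
      for (m in v) out <- c(out, if (m < 0) -m else got[[m]])
      sort(out)
    }
    got[[s]] <- members(tree$merge[s, ])
    expect_equal(got[[s]], merges[[s]])
  }
})

test_that("planted clusters are recovered by k-selection", {
  recovered <- 0
  k2 <- 0
  for (s in 1:40) {
    fx <- make_fixture(fixture_spec("planted_clusters", size = 60,
                                    effect = 0.5, seed = s))
    cl <- select_k(cluster_tree(fx$J), fx$theta)
    sig <- subset(cl$kw, k == cl$k & p < 0.05)$parameter
    if (all(fx$shifted %in% sig)) recovered <- recovered + 1
    if (cl$k == 2) k2 <- k2 + 1
  }
  expect_gte(recovered / 40, 0.95)
  expect_gte(k2 / 40, 0.5)   # modal choice is the true blob count
})

test_that("iid parameters give no significant association and k = 2 tie", {
  set.seed(8)
  n <- 24
  # objectives on a clean line (no cluster structure beyond geometry)
  J <- cbind(seq(0, 1, length.out = n), seq(1, 0, length.out = n))
  theta <- matrix(rep(seq_len(n), 3), n, 3)  # monotone but identical split
  theta[] <- runif(length(theta))
  cl <- select_k(cluster_tree(J + matrix(rnorm(2 * n, 0, 1e-3), n, 2)),
                 theta, alpha = 1e-6)
  expect_equal(cl$k, 2)           # zero counts everywhere: tie -> smallest
  expect_true(all(cl$counts == 0))
})

test_that("monotone effect: stronger shifts never recover fewer parameters", {
  n_sig <- sapply(c(0.1, 0.4, 0.7), function(eff) {
    mean(sapply(1:10, function(s) {
      fx <- make_fixture(fixture_spec("planted_clusters", size = 60,
                                      effect = eff, seed = s))
      cl <- select_k(cluster_tree(fx$J), fx$theta)
      sum(fx$shifted %in% subset(cl$kw, k == cl$k & p < 0.05)$parameter)
    }))
  })
  expect_true(all(diff(n_sig) >= 0))
})

test_that("guideline classes follow significance and range shrinkage", {
  fx <- make_fixture(fixture_spec("planted_clusters", size = 60,
                                  effect = 0.6, seed = 2))
  cl <- select_k(cluster_tree(fx$J), fx$theta)
  gl <- extract_guidelines(cl, fx$theta, bounds = fx$bounds)
  expect_s3_class(gl, "guideline_report")
  # planted parameters are cluster-specific knobs
  planted <- gl$class[match(fx$shifted, gl$parameter)]
  expect_true(all(planted == "cluster-specific"))
  # ranges always inside the initial bounds
  expect_true(all(gl$overall_lo >= gl$lower0 - 1e-9))
  expect_true(all(gl$overall_hi <= gl$upper0 + 1e-9))
  cr <- attr(gl, "cluster_ranges")
  expect_true(all(cr$lo >= gl$lower0 - 1e-9))
  expect_true(all(cr$hi <= gl$upper0 + 1e-9))
  # a parameter spanning its full bounds in all clusters is unconstrained
  noise <- setdiff(gl$parameter, fx$shifted)
  expect_true(any(gl$class[gl$parameter %in% noise] %in%
                    c("unconstrained", "general")))
  # flattened table mirrors the report
  tab <- format_guidelines(gl)
  expect_equal(nrow(tab), 10)
  expect_true(all(c("initial_range", "general_guideline",
                    "cluster1") %in% names(tab)))
})

test_that("report is invariant under label permutation", {
  fx <- make_fixture(fixture_spec("planted_clusters", size = 40,
                                  effect = 0.6, seed = 3))
  cl <- select_k(cluster_tree(fx$J), fx$theta)
  gl1 <- extract_guidelines(cl, fx$theta, bounds = fx$bounds)
  cl2 <- cl
  perm <- rev(seq_len(cl$k))
  cl2$labels <- perm[cl$labels]
  gl2 <- extract_guidelines(cl2, fx$theta, bounds = fx$bounds)
  expect_equal(gl1$class, gl2$class)
  expect_equal(gl1$p, gl2$p)
  expect_equal(gl1$overall_lo, gl2$overall_lo)
})
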