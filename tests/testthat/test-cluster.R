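toy_delta <- data.frame(
  ase_id = rep(c("a1", "a2"), each = 4),
  cell_line = rep(rep(c("L1", "L2"), each = 2), 2),
  sirna = rep(c("siRNA1", "siRNA2"), 4),
  batch_day = 1L,
  delta_psi = c(10, 14, 9, 11, 2, 1, -12, -10))
toy_calls <- call_changes(toy_delta)

test_that("the delta-psi matrix holds per-siRNA means for changed ASEs only", {
  m <- build_dpsi_matrix(toy_delta, toy_calls)
  expect_equal(sort(rownames(m)), c("a1", "a2"))
  expect_equal(m["a1", "L1"], mean(c(10, 14)))   # +12
  expect_equal(m["a1", "L2"], 10)
  expect_equal(m["a2", "L2"], -11)
  expect_equal(m["a2", "L1"], 1.5)  # representative value even where unchanged
  # an ASE never changed anywhere contributes no row
  quiet <- toy_delta
  quiet$delta_psi[quiet$ase_id == "a2"] <- 0
  m2 <- build_dpsi_matrix(quiet, call_changes(quiet))
  expect_equal(rownames(m2), "a1")
  # gene labels prefix row names when a catalog is supplied
  cat_ <- data.frame(ase_id = c("a1", "a2"), gene = c("G1", "G2"),
                     size_inclusion_bp = 300L, size_exclusion_bp = 250L,
                     inclusion_is_long = TRUE)
  expect_equal(rownames(build_dpsi_matrix(toy_delta, toy_calls, cat_)),
               c("G1|a1", "G2|a2"))
})

test_that("identical rows merge at height zero; tiny trees need >= 2 rows", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  tree <- hierarchical_cluster(m, linkage = "average")
  expect_equal(min(tree$rows$height), 0)
  expect_error(hierarchical_cluster(m[1, , drop = FALSE]), ">= 2 rows")
})

test_that("well-separated planted groups merge within-group first", {
  m <- rbind(i1 = c(20, 22, 21), i2 = c(21, 20, 22),
             e1 = c(-20, -21, -22), e2 = c(-22, -20, -21))
  for (lk in c("average", "ward")) {
    tree <- hierarchical_cluster(m, linkage = lk)
    first_two <- tree$rows$merge[1:2, ]
    # both first merges join two singletons from the same planted group
    pairs <- apply(first_two, 1, function(r) sort(rownames(m)[-r]))
    expect_true(all(substr(pairs[1, ], 1, 1) == substr(pairs[2, ], 1, 1)))
    cl <- cut_k(tree, 2)
    expect_equal(cl[["i1"]], cl[["i2"]])
    expect_equal(cl[["e1"]], cl[["e2"]])
    expect_false(cl[["i1"]] == cl[["e1"]])
  }
})

test_that("average linkage heights match a hand-computed agglomeration", {
  # rows on a line: 0, 1, 5 -> merge (a,b) at 1; then c joins at mean(5, 4) = 4.5
  m <- cbind(c(0, 1, 5))
  rownames(m) <- c("a", "b", "c")
  tree <- hierarchical_cluster(m, linkage = "average")
  expect_equal(tree$rows$height, c(1, 4.5))
})

test_that("linkage heights agree with a Lance-Williams recursion up to 8 rows", {
  set.seed(77)
  for (rep in 1:6) {
    n <- sample(4:8, 1)
    m <- matrix(rnorm(n * 5, sd = 10), nrow = n)
    rownames(m) <- paste0("r", seq_len(n))
    d <- stats::dist(m)
    for (lk in c("average", "ward")) {
      tree <- hierarchical_cluster(m, linkage = lk)
      oracle <- lance_williams_heights(d, if (lk == "ward") "ward.D" else "average")
      expect_equal(sort(tree$rows$height), sort(oracle), tolerance = 1e-8)
    }
  }
})

test_that("missing entries impute to zero by default, pairwise mode available", {
  m <- rbind(a = c(10, NA), b = c(10, 0), c = c(-10, -10))
  tree <- hierarchical_cluster(m)
  expect_equal(unname(tree$matrix["a", 2]), 0)
  expect_equal(min(tree$rows$height), 0)  # a and b identical after imputation
  tree2 <- hierarchical_cluster(m, impute = "pairwise")
  expect_true(all(is.finite(tree2$rows$height)))
})

test_that("cluster memberships are invariant to row permutation", {
  set.seed(5)
  m <- matrix(rnorm(7 * 4), nrow = 7, dimnames = list(paste0("r", 1:7), NULL))
  cl <- cut_k(hierarchical_cluster(m, linkage = "ward"), 3)
  perm <- sample(7)
  cl_p <- cut_k(hierarchical_cluster(m[perm, ], linkage = "ward"), 3)[rownames(m)]
  # same partition up to label renaming
  tab <- table(cl, cl_p)
  expect_equal(sum(tab > 0), 3)
})

test_that("cut_k validates k and handles the trivial cuts", {
  m <- matrix(rnorm(12), nrow = 4, dimnames = list(letters[1:4], NULL))
  tree <- hierarchical_cluster(m)
  expect_equal(unname(cut_k(tree, 1)), rep(1L, 4))
  expect_equal(sort(unique(cut_k(tree, 4))), 1:4)
  expect_error(cut_k(tree, 0), "k")
  expect_error(cut_k(tree, 5), "k")
})

test_that("heatmap export writes the dendrogram-reordered matrix", {
  m <- build_dpsi_matrix(toy_delta, toy_calls)
  tree <- hierarchical_cluster(m)
  path <- tempfile(fileext = ".tsv")
  exported <- export_heatmap_tsv(tree, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(back$row, rownames(exported))
  expect_equal(as.matrix(back[, -1]), exported, ignore_attr = TRUE)
})
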