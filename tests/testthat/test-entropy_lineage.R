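make_partitioning <- function(labels, cells = names(labels)) {
  structure(list(labels = stats::setNames(as.integer(labels), cells),
                 resolution = 1, modularity = 0),
            class = "partitioning")
}

make_dpg <- function(nodes, sse, from, to, w) {
  structure(list(nodes = nodes, sse = stats::setNames(sse, nodes),
                 edges = data.frame(from = from, to = to, weight = w,
                                    stringsAsFactors = FALSE)),
            class = "directed_partition_graph")
}

test_that("functional-group entropy matches closed forms", {
  # 3 groups of 2 genes each; activation pattern set by hand
  m <- expr_mat(0, 3, 6)
  groups <- data.frame(gene = colnames(m), group = rep(c("f1", "f2", "f3"),
                                                       each = 2))
  m[1, 1:2] <- 5                      # single active group -> 0
  m[2, ] <- 5                         # all groups uniformly active -> ln 3
  m[3, 1:4] <- 5                      # a = (1, 1, 0) -> ln 2
  ent <- cell_entropy(m, groups, threshold = 1)
  expect_equal(unname(ent), c(0, log(3), log(2)))
  # per-gene groups reduce to log expressed-gene count
  ent2 <- cell_entropy(m, threshold = 1)
  expect_equal(unname(ent2), log(c(2, 6, 4)))
  # zero activation warns and yields 0
  m[1, ] <- 0
  expect_warning(e0 <- cell_entropy(m, groups, threshold = 1), "zero")
  expect_equal(unname(e0[1]), 0)
})

test_that("entropy is invariant to gene order and consistent scaling", {
  syn <- generate_lineage(60, 80, 1, 0.1, seed = 3)
  m <- syn$matrix
  e1 <- cell_entropy(m, threshold = 1)
  perm <- sample(ncol(m))
  expect_equal(cell_entropy(m[, perm], threshold = 1), e1)
  expect_equal(cell_entropy(m * 10, threshold = 10), e1)
})

test_that("stable-state entropy averages the lowest-entropy core", {
  ent <- stats::setNames(c(4, 3, 2, 1), sprintf("c%d", 1:4))
  part <- make_partitioning(rep(0L, 4), names(ent))
  expect_equal(as.numeric(stable_state_entropy(ent, part, 0.25)), 1)
  expect_equal(as.numeric(stable_state_entropy(ent, part, 1)), 2.5)
  # partition of size one returns that cell's entropy
  part2 <- make_partitioning(c(0L, 0L, 0L, 1L), names(ent))
  sse <- stable_state_entropy(ent, part2, 0.25)
  expect_equal(unname(sse["1"]), 1)
  # core size is ceil(fraction * n) and never empty
  cores <- attr(stable_state_entropy(ent, part2, 0.25), "core_cells")
  expect_identical(lengths(cores), stats::setNames(c(1L, 1L), c("0", "1")))
})

test_that("edges point from high to low stable-state entropy", {
  pg <- structure(list(
    sizes = stats::setNames(c(2L, 2L), c("0", "1")),
    theta = matrix(c(0, 0.8, 0.8, 0), 2, 2,
                   dimnames = list(c("0", "1"), c("0", "1")))),
    class = "partition_graph")
  dg <- orient_partition_graph(pg, c("0" = 2.0, "1" = 1.0))
  expect_identical(dg$edges$from, "0")
  expect_identical(dg$edges$to, "1")
  expect_equal(dg$edges$weight, 0.8)
  # tie: lower id points to higher
  dg2 <- orient_partition_graph(pg, c("0" = 1.5, "1" = 1.5))
  expect_identical(dg2$edges$from, "0")
  # no edges in, none out
  pg0 <- pg; pg0$theta[] <- 0
  expect_identical(nrow(orient_partition_graph(pg0, c("0" = 1, "1" = 2))$edges),
                   0L)
})

test_that("forced star arborescence keeps both edges", {
  dg <- make_dpg(c("0", "1", "2"), c(3, 2, 1),
                 from = c("0", "0"), to = c("1", "2"), w = c(0.9, 0.8))
  tree <- max_arborescence(dg)
  expect_identical(tree$roots, "0")
  expect_identical(sort(tree$edges$child), c("1", "2"))
  expect_equal(sum(tree$edges$weight), 1.7)
})

test_that("chu-liu matches exhaustive enumeration on random digraphs", {
  set.seed(123)
  for (rep in 1:20) {
    n <- sample(4:6, 1)
    g <- random_rooted_digraph(n, root = 1L)
    oracle <- arborescence_exhaustive(g$n, g$from, g$to, g$w, 1L)
    sse <- stats::setNames(c(n + 1, stats::runif(n - 1)),
                           as.character(seq_len(n) - 1))
    dg <- make_dpg(as.character(seq_len(n) - 1), sse,
                   from = as.character(g$from - 1),
                   to = as.character(g$to - 1), w = g$w)
    tree <- max_arborescence(dg)
    expect_identical(tree$roots, "0")
    expect_identical(nrow(tree$edges), n - 1L)
    expect_equal(sum(tree$edges$weight), oracle$weight, tolerance = 1e-12)
    # every non-root node has exactly one parent
    expect_identical(sort(tree$edges$child),
                     sort(as.character(seq_len(n - 1))))
  }
})

test_that("on entropy-oriented DAGs the arborescence is the in-edge argmax", {
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    sse <- sort(stats::runif(n, 1, 5), decreasing = TRUE)
    nodes <- as.character(seq_len(n) - 1)
    # random connected undirected support, oriented by strict sse order
    from <- character(0); to <- character(0); w <- numeric(0)
    for (j in 2:n) {
      ups <- sample(seq_len(j - 1), sample(seq_len(j - 1), 1))
      from <- c(from, nodes[ups])
      to <- c(to, rep(nodes[j], length(ups)))
      w <- c(w, round(stats::runif(length(ups), 0.01, 1), 3))
    }
    dg <- make_dpg(nodes, stats::setNames(sse, nodes), from, to, w)
    tree <- max_arborescence(dg)
    # independent per-node best in-edge selection (no cycles can form when
    # edges strictly decrease in sse)
    for (v in nodes[-1]) {
      ine <- which(to == v)
      pick <- ine[which.max(w[ine])]
      row <- tree$edges[tree$edges$child == v, ]
      expect_identical(row$parent, from[pick])
      expect_equal(row$weight, w[pick])
    }
    # edge directions follow non-increasing stable-state entropy
    expect_true(all(dg$sse[tree$edges$parent] >= dg$sse[tree$edges$child]))
  }
})

test_that("unreachable high-entropy nodes become orphan roots", {
  # both 0 and 2 point into 1; 2 cannot be reached from the root 0
  dg <- make_dpg(c("0", "1", "2"), c(3, 1, 2),
                 from = c("0", "2"), to = c("1", "1"), w = c(0.5, 0.6))
  expect_warning(tree <- max_arborescence(dg), "orphan")
  expect_identical(sort(tree$roots), c("0", "2"))
  # node 1 is claimed by the primary root's arborescence; the orphan root 2
  # keeps no children
  expect_identical(tree$edges$parent, "0")
  expect_identical(tree$edges$child, "1")
})
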