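# fixture: 20 cells in 2 groups, 3 ligand-receptor pairs, one pair with an
# absent ligand gene
make_cci_fixture <- function(seed = 11) {
  set.seed(seed)
  n <- 20
  genes <- c("L1", "R1", "L2", "R2", "R3", "F1", "F2")
  m <- matrix(stats::runif(n * length(genes), 0, 4), n, length(genes),
              dimnames = list(sprintf("cell%02d", 1:n), genes))
  groups <- rep(c(1L, 2L), each = 10)
  lr <- data.frame(ligand = c("L1", "L2", "LX"),
                   receptor = c("R1", "R2", "R3"),
                   pair_id = c("p1", "p2", "p3"),
                   stringsAsFactors = FALSE)
  list(m = m, groups = groups, lr = lr)
}

test_that("group assignment honours provided labels and the Gap rule", {
  fx <- make_cci_fixture()
  expect_identical(unname(assign_groups(fx$m, labels = fx$groups)),
                   fx$groups)
  blobs <- make_blobs(rbind(c(0, 0, 0, 0, 0), c(10, 0, 0, 0, 0),
                            c(0, 10, 0, 0, 0)), 20, 0.1)
  g3 <- assign_groups(blobs, k_max = 6, seed = 1)
  expect_identical(length(unique(g3)), 3L)
  # recovered clusters coincide with the planted blobs
  expect_true(all(colSums(table(g3, rep(1:3, each = 20)) > 0) == 1))
  blob1 <- make_blobs(rbind(c(0, 0, 0, 0, 0)), 40, 0.1)
  expect_identical(length(unique(assign_groups(blob1, k_max = 6, seed = 1))),
                   1L)
  # deterministic under a fixed seed
  expect_identical(g3, assign_groups(blobs, k_max = 6, seed = 1))
})

test_that("communication score saturates by the Hill form", {
  # two single-cell groups with unit means
  m <- expr_mat(1, 2, 2, genes = c("L1", "R1"))
  lr <- data.frame(ligand = "L1", receptor = "R1", pair_id = "p1")
  comm <- cluster_communication(m, c(1L, 2L), lr, kh = 0.5)
  expect_equal(comm$C["1", "2", "p1"], 2 / 3)
  # zero ligand mean gives zero probability
  m0 <- m; m0[1, "L1"] <- 0
  comm0 <- cluster_communication(m0, c(1L, 2L), lr, kh = 0.5)
  expect_equal(comm0$C["1", "2", "p1"], 0)
  # absent gene scores zero everywhere
  lrx <- data.frame(ligand = "NOPE", receptor = "R1", pair_id = "px")
  commx <- cluster_communication(m, c(1L, 2L), lrx, kh = 0.5)
  expect_true(all(commx$C == 0))
  # entries always in [0, 1)
  fx <- make_cci_fixture()
  cc <- cluster_communication(fx$m, fx$groups, fx$lr)
  expect_true(all(cc$C >= 0 & cc$C < 1))
})

test_that("communication is invariant to cell order within groups", {
  fx <- make_cci_fixture()
  cc <- cluster_communication(fx$m, fx$groups, fx$lr)
  perm <- sample(nrow(fx$m))
  cc2 <- cluster_communication(fx$m[perm, ], fx$groups[perm], fx$lr)
  expect_equal(cc$C, cc2$C)
})

test_that("single-cell CCI matrix matches hand-computed sums", {
  # hand fixture: one pair with known C, validity gating by threshold
  m <- expr_mat(0, 2, 2, genes = c("L1", "R1"))
  m["cell01", "L1"] <- 2
  m["cell02", "R1"] <- 2
  lr <- data.frame(ligand = "L1", receptor = "R1", pair_id = "p1")
  comm <- structure(list(
    C = array(0.4, dim = c(2, 2, 1),
              dimnames = list(c("1", "2"), c("1", "2"), "p1")),
    group_levels = c(1L, 2L), pairs = lr, kh = 0.5),
    class = "cluster_communication")
  P <- build_cci_matrix(m, c(1L, 2L), comm, expr_threshold = 1)
  expect_equal(P["cell01", "cell02"], 0.4)
  # ligand expressed exactly at the threshold is not valid (strict >)
  m2 <- m; m2["cell01", "L1"] <- 1
  expect_equal(build_cci_matrix(m2, c(1L, 2L), comm)["cell01", "cell02"], 0)
  # two valid pairs sum
  m3 <- expr_mat(2, 2, 4, genes = c("L1", "R1", "L2", "R2"))
  lr2 <- data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R2"),
                    pair_id = c("p1", "p2"))
  comm2 <- structure(list(
    C = array(rep(c(0.2, 0.3), each = 4), dim = c(2, 2, 2),
              dimnames = list(c("1", "2"), c("1", "2"), c("p1", "p2"))),
    group_levels = c(1L, 2L), pairs = lr2, kh = 0.5),
    class = "cluster_communication")
  P3 <- build_cci_matrix(m3, c(1L, 2L), comm2)
  expect_equal(P3["cell01", "cell02"], 0.5)
  expect_equal(unname(diag(P3)), c(0, 0))
})

test_that("single-cell CCI matrix equals the triple-loop oracle", {
  fx <- make_cci_fixture()
  comm <- cluster_communication(fx$m, fx$groups, fx$lr)
  P <- build_cci_matrix(fx$m, fx$groups, comm, expr_threshold = 1)
  expect_equal(P, cci_triple_loop(fx$m, fx$groups, comm, 1))
  # monotone in the validity threshold
  P0 <- build_cci_matrix(fx$m, fx$groups, comm, expr_threshold = 0)
  expect_true(all(P <= P0 + 1e-12))
  # bounded by the total pair mass between the two groups
  total <- apply(comm$C, c(1, 2), sum)
  gi <- as.character(fx$groups)
  expect_true(all(P <= total[cbind(rep(gi, times = 20),
                                   rep(gi, each = 20))] + 1e-12))
})

test_that("symmetrization averages directions and scales by the maximum", {
  P <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  P["a", "b"] <- 0.4
  S <- symmetrize_cci(P, scale = FALSE)
  expect_equal(S["a", "b"], 0.2)
  expect_equal(S, t(S))
  expect_equal(symmetrize_cci(P * 0), P * 0)   # degenerate max: no scaling
  sym <- (P + t(P)) / 2
  expect_equal(symmetrize_cci(P, scale = FALSE), sym)
  expect_equal(max(symmetrize_cci(P, scale = TRUE)), 1)
})
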