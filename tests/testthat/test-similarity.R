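# Hand-built association matrix helper: symmetric, unit diagonal.
hand_R <- function(genes, ...) {
  R <- diag(length(genes))
  dimnames(R) <- list(genes, genes)
  for (e in list(...)) {
    R[e[[1]], e[[2]]] <- R[e[[2]], e[[1]]] <- as.numeric(e[[3]])
  }
  R
}

test_that("soft difference matches hand evaluation and the identity case", {
  R <- hand_R(c("a", "b"), list("a", "b", 0.5))
  expect_identical(soft_difference("a", "b", hand_R(c("a", "b"))), 1)
  expect_equal(soft_difference("a", "b", R), 0.5)
  # identical sets give exactly zero under the unit-diagonal convention
  expect_identical(soft_difference(c("a", "b"), c("a", "b"), R), 0)
  # genes absent from the matrix associate only with themselves
  expect_identical(soft_difference("zz", "b", R), 1)
  expect_identical(soft_difference("zz", "zz", R), 0)
  expect_error(soft_difference(character(0), "b", R), "nonempty")
  bad <- hand_R(c("a", "b"), list("a", "b", 1.5))
  expect_error(soft_difference("a", "b", bad), "outside")
})

test_that("soft difference agrees with a literal-formula oracle", {
  withr::local_seed(42)
  genes <- sprintf("g%d", 1:8)
  for (rep in 1:10) {
    R <- matrix(runif(64), 8, 8, dimnames = list(genes, genes))
    R <- (R + t(R)) / 2
    diag(R) <- 1
    G1 <- sample(genes, sample(1:5, 1))
    G2 <- sample(genes, sample(1:5, 1))
    expect_equal(soft_difference(G1, G2, R),
                 brute_soft_difference(G1, G2, R), tolerance = 1e-12)
  }
})

test_that("sim_net covers the identical, disjoint and hand-derived cases", {
  w <- worked_example()
  diff <- iterate_ranking(w$network)
  expect_identical(sim_net("TA:0000004", "TB:0000002", w$ann, diff), 1)
  # fully disconnected disjoint singletons: (2 - 1 - 1) / 2 = 0
  R0 <- hand_R(c("a", "b"))
  expect_identical(unname((2 - soft_difference("a", "b", R0) -
                             soft_difference("b", "a", R0)) / 2), 0)
  # singleton pair with r = 0.5: (2 - 0.5 - 0.5) / 2 = 0.5
  Rh <- hand_R(c("a", "b"), list("a", "b", 0.5))
  d <- soft_difference("a", "b", Rh)
  expect_equal((2 - 2 * d) / 2, 0.5, tolerance = 1e-15)
})

test_that("sim_net reduces to the crisp overlap formula when R is the identity", {
  withr::local_seed(7)
  genes <- sprintf("g%d", 1:12)
  R <- diag(12); dimnames(R) <- list(genes, genes)
  pf <- function(p) data.frame(parent = p, relation = rep("is_a", length(p)))
  dag <- ontology_dag(c("r1", "t1", "r2", "t2"),
                      c(r1 = "c1", t1 = "c1", r2 = "c2", t2 = "c2"),
                      list(r1 = pf(character(0)), t1 = pf("r1"),
                           r2 = pf(character(0)), t2 = pf("r2")))
  for (rep in 1:10) {
    G1 <- sample(genes, sample(2:8, 1))
    G2 <- sample(genes, sample(2:8, 1))
    ann <- propagate(annotation_map(
      list(t1 = G1, r1 = "pad1", t2 = G2, r2 = "pad2"), dag), dag)
    crisp <- (length(union(G1, G2)) - length(setdiff(G1, G2)) -
                length(setdiff(G2, G1))) / length(union(G1, G2))
    expect_equal(sim_net("t1", "t2", ann, R), crisp, tolerance = 1e-12)
  }
})

test_that("raising a cross-set association never decreases sim_net", {
  genes <- c("a1", "a2", "b1", "b2")
  vals <- seq(0, 1, by = 0.25)
  sims <- vapply(vals, function(v) {
    R <- hand_R(genes, list("a1", "b1", v), list("a2", "b2", 0.3))
    u <- 4
    (u - soft_difference(c("a1", "a2"), c("b1", "b2"), R) -
        soft_difference(c("b1", "b2"), c("a1", "a2"), R)) / u
  }, numeric(1))
  expect_true(all(diff(sims) >= -1e-12))
})

test_that("sim_go is the geometric mean of the depth factors", {
  w <- worked_example()
  # category roots annotate the whole universe -> weight 0
  expect_identical(sim_go("TA:0000001", "TB:0000001", w$ann), 0)
  # |G1| = |G2| = 2 in universes of 4 -> sqrt(0.5 * 0.5) = 0.5
  expect_equal(sim_go("TA:0000003", "TB:0000003", w$ann), 0.5)
  # hand case |G|/|U| = 10/100 and 20/200 -> 0.9
  pf <- function(p) data.frame(parent = p, relation = rep("is_a", length(p)))
  dag <- ontology_dag(c("r1", "t1", "r2", "t2"),
                      c(r1 = "c1", t1 = "c1", r2 = "c2", t2 = "c2"),
                      list(r1 = pf(character(0)), t1 = pf("r1"),
                           r2 = pf(character(0)), t2 = pf("r2")))
  ann <- propagate(annotation_map(
    list(t1 = sprintf("x%03d", 1:10), r1 = sprintf("x%03d", 1:100),
         t2 = sprintf("y%03d", 1:20), r2 = sprintf("y%03d", 1:200)),
    dag), dag)
  expect_equal(sim_go("t1", "t2", ann), 0.9, tolerance = 1e-12)
})

test_that("score_pair multiplies the two factors, is symmetric, cross-category only", {
  w <- worked_example()
  diff <- iterate_ranking(w$network)
  s <- score_pair("TA:0000003", "TB:0000003", w$ann, diff)
  expect_equal(s$sim, s$sim_net * s$sim_go, tolerance = 1e-12)
  s_rev <- score_pair("TB:0000003", "TA:0000003", w$ann, diff)
  expect_equal(s$sim, s_rev$sim, tolerance = 1e-15)
  expect_equal(s$n_genes_1, 2L)
  # root pair scores 0 regardless of its network similarity
  expect_identical(score_pair("TA:0000001", "TB:0000001", w$ann, diff)$sim, 0)
  expect_error(score_pair("TA:0000003", "TA:0000004", w$ann, diff),
               "cross-category")
})

test_that("shallow near-root pairs score below specific pairs at equal sim_net", {
  # same gene sets at two depths: the specific pair has the larger sim
  pf <- function(p) data.frame(parent = p, relation = rep("is_a", length(p)))
  dag <- ontology_dag(
    c("r1", "l1", "r2", "l2"),
    c(r1 = "c1", l1 = "c1", r2 = "c2", l2 = "c2"),
    list(r1 = pf(character(0)), l1 = pf("r1"),
         r2 = pf(character(0)), l2 = pf("r2")))
  # both pairs have identical propagated sets, hence equal sim_net (= 1);
  # only the depth differs
  ann <- propagate(annotation_map(
    list(l1 = c("g1", "g2"), r1 = "g3",
         l2 = c("g1", "g2"), r2 = "g3"), dag), dag)
  R <- diag(3); dimnames(R) <- list(sprintf("g%d", 1:3), sprintf("g%d", 1:3))
  shallow <- score_pair("r1", "r2", ann, R)
  specific <- score_pair("l1", "l2", ann, R)
  expect_identical(shallow$sim_net, specific$sim_net)
  expect_gt(specific$sim, shallow$sim)
})
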