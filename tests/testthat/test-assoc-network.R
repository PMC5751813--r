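# A small two-category fixture reused across the association-network tests.
assoc_fixture <- function() {
  w <- worked_example()
  diff <- iterate_ranking(w$network)
  list(w = w, diff = diff)
}

test_that("score_all_pairs enumerates every cross-category pair once, in order", {
  f <- assoc_fixture()
  sc <- score_all_pairs(f$w$ann, f$w$dag, f$diff, "category_a", "category_b",
                        verbose = FALSE)
  # 4 annotated category_a terms x 3 category_b terms
  expect_equal(nrow(sc), 12L)
  expect_false(any(duplicated(paste(sc$t1, sc$t2))))
  expect_identical(sc, sc[order(sc$t1, sc$t2), ])
  expect_true(all(startsWith(sc$t1, "TA:")) && all(startsWith(sc$t2, "TB:")))
  expect_error(score_all_pairs(f$w$ann, f$w$dag, f$diff,
                               "category_a", "category_a"), "differ")
})

test_that("empirical p-values follow the rank counting formula", {
  f <- assoc_fixture()
  sc <- score_all_pairs(f$w$ann, f$w$dag, f$diff, "category_a", "category_b",
                        verbose = FALSE)
  out <- empirical_fdr(sc, f$w$ann, f$w$dag, f$diff, n_null = 999, seed = 3)
  expect_true(all(out$p_value >= 1 / 1000 & out$p_value <= 1))
  expect_equal(out$q_value, stats::p.adjust(out$p_value, "BH"))
  # determinism under the same seed, different under another
  out2 <- empirical_fdr(sc, f$w$ann, f$w$dag, f$diff, n_null = 999, seed = 3)
  expect_identical(out, out2)
  expect_error(empirical_fdr(sc, f$w$ann, f$w$dag, f$diff, n_null = 50),
               "at least 100")
})

test_that("the rank counting formula hits its boundary cases", {
  f <- assoc_fixture()
  sc <- score_all_pairs(f$w$ann, f$w$dag, f$diff, "category_a", "category_b",
                        verbose = FALSE)
  # a score above every achievable similarity beats all 999 null samples
  sc$sim[1] <- 2
  # a score below every achievable similarity is beaten by all of them
  sc$sim[2] <- -1
  out <- empirical_fdr(sc, f$w$ann, f$w$dag, f$diff, n_null = 999, seed = 7)
  expect_identical(out$p_value[1], 1 / 1000)
  expect_identical(out$p_value[2], 1)
})

test_that("a single planted pair with no background is the unique top scorer", {
  spec <- synthetic_spec(n_terms_per_category = 13, n_genes = 100,
                         genes_per_leaf = 3, n_planted_pairs = 1,
                         within_module_edge_prob = 1,
                         background_edge_prob = 0, seed = 11)
  b <- synthetic_bundle(spec)
  diff <- iterate_ranking(b$network)
  sc <- score_all_pairs(b$ann, b$dag, diff, "category_a", "category_b",
                        verbose = FALSE)
  sc <- sc[order(-sc$sim), ]
  expect_identical(paste(sc$t1[1], sc$t2[1]),
                   paste(b$planted$term1, b$planted$term2))
  expect_gt(sc$sim[1], sc$sim[2])
})

test_that("the direction rule keeps edges to the most specific terms", {
  pf <- function(p) data.frame(parent = p, relation = rep("is_a", length(p)))
  dag <- ontology_dag(
    c("x", "p", "c", "q", "u1", "u2"),
    c(x = "c1", p = "c2", c = "c2", q = "c2", u1 = "c2", u2 = "c1"),
    list(x = pf(character(0)), p = pf(character(0)), c = pf("p"),
         q = pf("c"), u1 = pf(character(0)), u2 = pf(character(0))))
  mk <- function(t1, t2) data.frame(t1 = t1, t2 = t2, sim = 0.5,
                                    q_value = 0.01)
  # parent and child both linked to x: edge x->parent removed, x->child kept
  net1 <- assign_directions(rbind(mk("x", "p"), mk("x", "c")), dag)
  expect_identical(sort(paste(net1$edges$source, net1$edges$target)),
                   sort(c("x c", "p x", "c x")))
  # chain p <- c <- q: only the most specific target survives from x
  net2 <- assign_directions(rbind(mk("x", "p"), mk("x", "c"), mk("x", "q")),
                            dag)
  out_x <- net2$edges$target[net2$edges$source == "x"]
  expect_identical(out_x, "q")
  # unrelated targets: both kept
  net3 <- assign_directions(rbind(mk("x", "p"), mk("x", "u1")), dag)
  expect_setequal(net3$edges$target[net3$edges$source == "x"], c("p", "u1"))
  expect_error(assign_directions(mk("x", "nope"), dag), "absent")
})

test_that("no exported edge points at an ancestor of another target (audit)", {
  spec <- synthetic_spec(n_terms_per_category = 13, n_genes = 120,
                         genes_per_leaf = 3, n_planted_pairs = 3, seed = 5)
  b <- synthetic_bundle(spec)
  net <- suppressMessages(build_assoc_network(
    b$dag, b$ann, b$network, "category_a", "category_b",
    sim_threshold = 0.2, n_null = 200, seed = 5))
  expect_gt(nrow(net$edges), 0L)
  for (s in unique(net$edges$source)) {
    targets <- net$edges$target[net$edges$source == s]
    for (t in targets) {
      expect_false(any(setdiff(targets, t) %in% descendants(b$dag, t)),
                   label = sprintf("edge %s -> %s survives the rule", s, t))
    }
  }
  # every edge crosses categories and carries its provenance
  cat_of <- b$dag$category
  expect_true(all(cat_of[net$edges$source] != cat_of[net$edges$target]))
  expect_equal(net$provenance$alpha, 0.1)
})

test_that("export and reimport round-trip the edge multiset", {
  f <- assoc_fixture()
  sc <- score_all_pairs(f$w$ann, f$w$dag, f$diff, "category_a", "category_b",
                        verbose = FALSE)
  sc$q_value <- 0.01
  net <- assign_directions(sc[sc$sim > 0.2, ], f$w$dag,
                           provenance = list(alpha = 0.1, fdr = 0.05))
  tsv <- tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  back <- import_network_tsv(tsv)
  expect_setequal(paste(back$source, back$target), paste(net$edges$source, net$edges$target))
  expect_equal(back$sim[order(back$source, back$target)],
               net$edges$sim[order(net$edges$source, net$edges$target)],
               tolerance = 1e-12)
  # sif and graphml write without error; empty networks export header-only
  sif <- tempfile(fileext = ".sif"); export_network(net, sif, "sif")
  expect_equal(length(readLines(sif)), nrow(net$edges))
  gml <- tempfile(fileext = ".graphml"); export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net$edges))
  empty <- assign_directions(sc[0, ], f$w$dag)
  etsv <- tempfile(fileext = ".tsv")
  export_network(empty, etsv, "tsv")
  expect_equal(nrow(import_network_tsv(etsv)), 0L)
  expect_error(export_network(net, tsv, "bogus"))
})

test_that("the full pipeline is deterministic given identical inputs and seed", {
  spec <- synthetic_spec(n_terms_per_category = 13, n_genes = 120,
                         genes_per_leaf = 3, n_planted_pairs = 2, seed = 8)
  b <- synthetic_bundle(spec)
  run <- function() {
    out <- tempfile(fileext = ".tsv")
    net <- suppressMessages(build_assoc_network(
      b$dag, b$ann, b$network, "category_a", "category_b",
      sim_threshold = 0.15, n_null = 150, seed = 4))
    export_network(net, out, "tsv")
    readLines(out)
  }
  expect_identical(run(), run())
})
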