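test_that("hypergeometric upper tail matches exact rational-arithmetic values", {
  # values computed once with exact rational arithmetic (integer binomials)
  frozen <- list(
    list(5, 5, 10, 20, 0.016253869969040248),
    list(3, 8, 12, 40, 0.45151033386327505),
    list(0, 5, 10, 20, 1.0),
    list(2, 3, 4, 10, 1 / 3),
    list(7, 15, 20, 60, 0.17094196522113697),
    list(1, 30, 30, 60, 1.0),
    list(10, 10, 10, 60, 1.3263650083219113e-11),
    list(4, 12, 6, 25, 0.2813664596273292),
    list(6, 20, 15, 50, 0.6201811947337587),
    list(2, 2, 2, 4, 1 / 6))
  for (f in frozen) {
    expect_equal(hypergeom_upper_tail(f[[1]], f[[2]], f[[3]], f[[4]]), f[[5]],
                 tolerance = 1e-12)
  }
  expect_equal(hypergeom_upper_tail(0, 7, 3, 30), 1.0)
  expect_error(hypergeom_upper_tail(6, 5, 10, 20), "k")
  expect_error(hypergeom_upper_tail(1, 25, 10, 20), "N")
})

test_that("log-space tail agrees with direct summation over the full small-N grid", {
  worst <- 0
  for (N in c(5, 12, 23, 37, 48, 60)) {
    for (K in 0:N) {
      for (n in seq(0, N, by = 3)) {
        for (k in 0:min(K, n)) {
          p <- hypergeom_upper_tail(k, K, n, N)
          q <- direct_hyper_tail(k, K, n, N)
          worst <- max(worst, abs(p - q) / q)
        }
      }
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("tail is non-increasing in k and cross-checks against phyper", {
  for (par in list(c(10, 15, 30), c(5, 20, 40))) {
    K <- par[1]; n <- par[2]; N <- par[3]
    p <- vapply(0:min(K, n), function(k) hypergeom_upper_tail(k, K, n, N), 1.0)
    expect_true(all(diff(p) <= 1e-15))
    ref <- vapply(0:min(K, n), function(k)
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE), 1.0)
    expect_equal(p, ref, tolerance = 1e-12)
  }
})

test_that("term enrichment fills counts from set intersections", {
  terms <- read_gmt(fixture_path("mirna_sets.gmt"))
  expect_equal(terms$TAM_onco$members, c("miR-24", "miR-27a", "miR-146b"))

  universe <- unique(unlist(lapply(terms, `[[`, "members")))
  universe <- union(universe, c("miR-100", "miR-200b", "miR-335", "miR-451"))
  query <- c("miR-24", "miR-27a", "miR-146b")
  res <- term_enrichment(query, universe, terms)
  onco <- res[res$term_id == "TAM_onco", ]
  expect_equal(onco$k, 3L)                      # full onco-miRNA set recovered
  expect_equal(onco$K, 3L)
  expect_equal(onco$p_value,
               direct_hyper_tail(3, 3, 3, length(universe)), tolerance = 1e-12)
  expect_equal(res$p_value, sort(res$p_value))  # sorted ascending

  # query = universe: every term has p = 1
  res_all <- term_enrichment(universe, universe, terms)
  expect_true(all(res_all$p_value == 1))

  expect_error(term_enrichment(character(), universe, terms), "empty")
  expect_error(term_enrichment(c("miR-24", "nope"), universe, terms), "universe")
})

test_that("enrichment p-values agree with a permutation null on a small instance", {
  set.seed(70)
  universe <- sprintf("g%02d", 1:20)
  members <- universe[1:6]
  query <- universe[c(1:4, 10, 15)]
  k_obs <- length(intersect(query, members))
  p <- hypergeom_upper_tail(k_obs, 6, 6, 20)
  draws <- replicate(1e5, length(intersect(sample(universe, 6), members)) >= k_obs)
  p_hat <- mean(draws)
  expect_lt(abs(p - p_hat), 4 * sqrt(p * (1 - p) / 1e5))
})

test_that("kappa similarity matches the closed-form contingency formula", {
  expect_equal(kappa_similarity(c(1, 0, 1), c(1, 0, 1)), 1.0)
  expect_equal(kappa_similarity(rep(TRUE, 4), rep(TRUE, 4)), 1.0)  # p_e = 1 case
  # hand contingency a=3 (both), b=1, c=1, d=5: kappa = (0.8-0.52)/0.48
  a <- c(rep(1, 3), rep(1, 1), rep(0, 1), rep(0, 5))
  b <- c(rep(1, 3), rep(0, 1), rep(1, 1), rep(0, 5))
  expect_equal(kappa_similarity(a, b), (0.8 - 0.52) / (1 - 0.52), tolerance = 1e-12)
  # independent random vectors: kappa near 0
  set.seed(71)
  x <- runif(1e4) < 0.3; y <- runif(1e4) < 0.5
  expect_lt(abs(kappa_similarity(x, y)), 0.05)
  expect_error(kappa_similarity(c(1, 0), c(1)), "length")
})

test_that("annotation clustering applies the representative-term rule", {
  memberships <- list(
    A1 = c("g1", "g2", "g3"), A2 = c("g1", "g2", "g3", "g4"),
    B1 = c("g7", "g8"), C1 = c("g9", "g10"))
  records <- data.frame(
    term_id = c("A1", "A2", "B1", "C1"),
    p_value = c(0.04, 0.01, 0.02, 0.06), stringsAsFactors = FALSE)
  cl <- cluster_annotations(records, memberships, kappa_threshold = 0.5)
  # A1+A2 cluster: representative is the lower-p member
  a <- cl[cl$member_term_ids == "A1,A2", ]
  expect_equal(nrow(a), 1L)
  expect_equal(a$representative_term_id, "A2")
  # disjoint-membership terms stay singletons; C1 (min p 0.06) is dropped
  expect_true("B1" %in% cl$representative_term_id)
  expect_false(any(grepl("C1", cl$member_term_ids)))

  # tie on p broken lexicographically by term id
  records_tie <- transform(records, p_value = c(0.01, 0.01, 0.5, 0.5))
  cl_tie <- cluster_annotations(records_tie, memberships)
  expect_equal(cl_tie$representative_term_id, "A1")

  # invariant to record input order
  cl_rev <- cluster_annotations(records[4:1, ], memberships)
  expect_equal(cl, cl_rev)
})
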