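three_doc_corpus <- function() {
  list(P1 = toy_protein("P1", "kinase alpha", "Homo sapiens"),
       P2 = toy_protein("P2", "kinase beta gamma", "Mus musculus"),
       P3 = toy_protein("P3", "transport channel", "Homo sapiens"))
}

test_that("BM25 index ranks exact name matches first and zeros out OOV queries", {
  corpus <- three_doc_corpus()
  idx <- build_index(corpus)
  s <- bm25_scores(idx, "transport channel")
  expect_equal(names(which.max(s)), "P3")
  expect_true(all(bm25_scores(idx, "xyzzy qwerty") == 0))
  expect_true(all(s >= 0))
  expect_error(build_index(list()), "empty")
})

test_that("BM25 scores equal an independent hand computation of the Okapi formula", {
  corpus <- three_doc_corpus()
  idx <- build_index(corpus, k1 = 1.5, b = 0.75)
  got <- bm25_scores(idx, "kinase")
  # direct Okapi arithmetic, written independently of the index internals:
  # docs (name + species): lengths 4, 5, 4; avgdl 13/3; "kinase" df = 2, tf =
  # 1 in P1 and P2
  N <- 3; df <- 2; k1 <- 1.5; b <- 0.75; avgdl <- 13 / 3
  idf <- log((N - df + 0.5) / (df + 0.5) + 1)
  expect_tf <- function(tf, dl) idf * tf * (k1 + 1) / (tf + k1 * (1 - b + b * dl / avgdl))
  expect_equal(unname(got["P1"]), expect_tf(1, 4))
  expect_equal(unname(got["P2"]), expect_tf(1, 5))
  expect_equal(unname(got["P3"]), 0)
})

test_that("BM25 is non-decreasing in query-term frequency at fixed length", {
  corpus <- list(A = toy_protein("A", "kinase kinase kinase pump", ""),
                 B = toy_protein("B", "kinase pump pump pump", ""),
                 C = toy_protein("C", "channel gate lock seal", ""))
  idx <- build_index(corpus)
  s <- bm25_scores(idx, "kinase")
  expect_true(s[["A"]] > s[["B"]])
})

test_that("query_neighbors excludes self, truncates to pool size, breaks ties lexicographically", {
  corpus <- three_doc_corpus()
  idx <- build_index(corpus)
  nbs <- query_neighbors(idx, corpus$P1, k = 5)
  expect_equal(nrow(nbs), 2)
  expect_false("P1" %in% nbs$accession)

  # two identical documents tie; lexicographic accession decides
  twins <- list(Z9 = toy_protein("Z9", "pump protein", "Homo sapiens"),
                A1 = toy_protein("A1", "pump protein", "Homo sapiens"),
                Q5 = toy_protein("Q5", "pump protein", "Homo sapiens"))
  nbt <- query_neighbors(build_index(twins),
                         toy_protein("X0", "pump protein", "Homo sapiens"), k = 3)
  expect_equal(nbt$accession, c("A1", "Q5", "Z9"))

  restricted <- query_neighbors(idx, corpus$P1, k = 3, eligible = "P3")
  expect_equal(restricted$accession, "P3")
})

test_that("collect_candidates unions neighbor annotations with provenance, excluding the root", {
  onto <- parse_obo(write_toy_obo(list(
    "GO:0000001" = character(0), "GO:0000002" = "GO:0000001",
    "GO:0000003" = "GO:0000001", "GO:0000004" = "GO:0000002")))
  annots <- propagate_annotations(onto, list(N1 = c("GO:0000002", "GO:0000004"),
                                             N2 = c("GO:0000002", "GO:0000003")))
  nbs <- structure(data.frame(accession = c("N1", "N2"), score = c(2, 1)),
                   query = "QX", k = 2, class = c("neighbor_set", "data.frame"))
  cands <- collect_candidates(nbs, annots, onto, "BPO")
  expect_setequal(cands$terms, c("GO:0000002", "GO:0000003", "GO:0000004"))
  expect_setequal(cands$provenance[["GO:0000002"]], c("N1", "N2"))
  expect_equal(cands$provenance[["GO:0000003"]], "N2")
  expect_false("GO:0000001" %in% cands$terms)

  none <- collect_candidates(nbs, list(), onto, "BPO")
  expect_length(none$terms, 0)
})

test_that("knn_score is the weighted vote fraction with the documented edge cases", {
  expect_equal(knn_score(c(TRUE, FALSE), c(100, 50)), 100 / 150)
  expect_equal(knn_score(TRUE, 7), 1)
  expect_equal(knn_score(c(FALSE, FALSE), c(10, 20)), 0)
  expect_error(knn_score(c(TRUE, FALSE), c(0, 0)), "zero")
  expect_error(knn_score(TRUE, -1), "non-negative")
})

test_that("knn_score is scale invariant and reduces to plain vote under equal weights", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    has <- sample(c(TRUE, FALSE), n, replace = TRUE)
    w <- stats::runif(n, 0.1, 10)
    s <- knn_score(has, w)
    expect_true(s >= 0 && s <= 1)
    expect_equal(knn_score(has, w * 37.5), s)
    expect_equal(knn_score(has, rep(2, n)), mean(has))
  }
})

test_that("score_candidates_knn agrees with brute-force re-evaluation of the vote", {
  set.seed(5)
  onto <- parse_obo(write_toy_obo(c(list("GO:0000001" = character(0)),
    stats::setNames(rep("GO:0000001", 9), sprintf("GO:%07d", 2:10)))))
  for (rep in 1:5) {
    nb_acc <- paste0("N", 1:4)
    annots <- lapply(stats::setNames(nb_acc, nb_acc), function(a)
      c("GO:0000001", sample(sprintf("GO:%07d", 2:10), sample(1:5, 1))))
    nbs <- structure(data.frame(accession = nb_acc, score = stats::runif(4, 0.5, 3)),
                     query = "QX", k = 4, class = c("neighbor_set", "data.frame"))
    cands <- collect_candidates(nbs, annots, onto, "BPO")
    got <- score_candidates_knn(cands, nbs, annots)
    for (i in seq_len(nrow(got))) {
      t <- got$term[i]
      manual <- sum(nbs$score * vapply(nb_acc, function(a) t %in% annots[[a]],
                                       logical(1))) / sum(nbs$score)
      expect_equal(got$score[i], manual)
    }
    expect_false(is.unsorted(rev(got$score)))
  }
})

test_that("two equal-weight neighbors give 0.5 for a term carried by one", {
  onto <- toy_chain_onto()
  annots <- list(N1 = c("GO:0000001", "GO:0000002", "GO:0000003"),
                 N2 = c("GO:0000001", "GO:0000002"))
  nbs <- structure(data.frame(accession = c("N1", "N2"), score = c(1, 1)),
                   query = "QX", k = 2, class = c("neighbor_set", "data.frame"))
  cands <- collect_candidates(nbs, annots, onto, "BPO")
  got <- score_candidates_knn(cands, nbs, annots)
  expect_equal(got$score[got$term == "GO:0000002"], 1.0)
  expect_equal(got$score[got$term == "GO:0000003"], 0.5)
})

test_that("cap_candidates keeps the top terms per protein by score then id", {
  df <- data.frame(protein = rep(c("P1", "P2"), c(4, 2)),
                   term = sprintf("GO:%07d", c(4, 2, 3, 1, 9, 8)),
                   score = c(0.9, 0.8, 0.8, 0.1, 0.5, 0.6))
  capped <- cap_candidates(df, cap = 2)
  expect_equal(sort(capped$term[capped$protein == "P1"]),
               c("GO:0000002", "GO:0000004"))  # tie 0.8 broken by term id
  expect_equal(nrow(capped[capped$protein == "P2", ]), 2)
})
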