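toy_candidates <- function() {
  structure(list(
    query = "P1", branch = "BPO",
    terms = sprintf("GO:%07d", 2:4),
    definition = stats::setNames(c("alpha beta gamma", "delta epsilon",
                                   "zeta eta theta"), sprintf("GO:%07d", 2:4)),
    provenance = NULL), class = "candidate_set")
}

test_that("query construction is byte-stable and emits sentences in rank order", {
  prot <- toy_protein("P1", "IF3-2")
  inf <- data.frame(text = c("Binds ribosome.", "Initiates translation."),
                    relevance = c(0.9, 0.5))
  expect_identical(build_query(prot, inf),
                   "The protein is IF3-2 The description is Binds ribosome. Initiates translation.")
  # unsorted input: the high-relevance sentence is emitted first
  expect_identical(build_query(prot, inf[2:1, ]),
                   "The protein is IF3-2 The description is Binds ribosome. Initiates translation.")
  expect_identical(build_query(prot, NULL),
                   "The protein is IF3-2 The description is ")
  expect_error(build_query(toy_protein("P1", "")), "non-empty")
})

test_that("build_pairs yields one pair per defined candidate, query side shared", {
  pairs <- build_pairs("QTEXT", toy_candidates())
  expect_equal(nrow(pairs), 3)
  expect_equal(unique(pairs$query), "QTEXT")
  expect_equal(pairs$doc[pairs$term == "GO:0000003"], "delta epsilon")

  cands <- toy_candidates()
  cands$definition["GO:0000003"] <- ""
  expect_warning(p2 <- build_pairs("QTEXT", cands), "without a definition")
  expect_equal(nrow(p2), 2)

  empty <- toy_candidates(); empty$terms <- character(0)
  empty$definition <- stats::setNames(character(0), character(0))
  expect_equal(nrow(build_pairs("QTEXT", empty)), 0)
})

test_that("score_candidates sorts by score with term-id ties and enforces [0,1]", {
  pairs <- build_pairs("QTEXT", toy_candidates())
  mock <- structure(list(), class = c("mock_scorer", "pair_scorer"))
  assign("pair_score.mock_scorer",
         function(scorer, query, doc) ifelse(grepl("delta", doc), 1, 0),
         envir = globalenv())
  on.exit(rm("pair_score.mock_scorer", envir = globalenv()), add = TRUE)
  out <- score_candidates(pairs, mock, protein = "P1", branch = "BPO")
  expect_equal(out$term[1], "GO:0000003")

  const <- structure(list(), class = c("const_scorer", "pair_scorer"))
  assign("pair_score.const_scorer", function(scorer, query, doc) rep(0.5, length(doc)),
         envir = globalenv())
  on.exit(rm("pair_score.const_scorer", envir = globalenv()), add = TRUE)
  out2 <- score_candidates(pairs, const)
  expect_equal(out2$term, sort(out2$term))  # tie rule: term-id order

  bad <- structure(list(), class = c("bad_scorer", "pair_scorer"))
  assign("pair_score.bad_scorer", function(scorer, query, doc) rep(1.5, length(doc)),
         envir = globalenv())
  on.exit(rm("pair_score.bad_scorer", envir = globalenv()), add = TRUE)
  expect_error(score_candidates(pairs, bad), "contract")
})

test_that("the lexical pair scorer measures definition coverage", {
  sc <- lexical_pair_scorer()
  expect_equal(pair_score(sc, "the protein binds alpha beta", "alpha beta"), 1)
  expect_equal(pair_score(sc, "the protein binds alpha beta", "gamma delta"), 0)
  expect_equal(pair_score(sc, "alpha with noise words", "alpha beta"), 0.5)
  expect_equal(pair_score(sc, "anything", ""), 0)
})

test_that("negative sampling is 1:1, capped by availability, seed-reproducible", {
  cands <- toy_candidates()
  cands$terms <- sprintf("GO:%07d", 2:14)
  pos3 <- sprintf("GO:%07d", 2:4)
  neg <- sample_negatives(pos3, cands, seed = 9)
  expect_length(neg, 3)
  expect_true(all(neg %in% setdiff(cands$terms, pos3)))
  expect_identical(neg, sample_negatives(pos3, cands, seed = 9))
  expect_false(identical(neg, sample_negatives(pos3, cands, seed = 10)))

  pos_many <- sprintf("GO:%07d", 2:12)  # only 2 negatives remain
  expect_length(sample_negatives(pos_many, cands, seed = 1), 2)
  expect_warning(none <- sample_negatives(cands$terms, cands, seed = 1),
                 "no negative")
  expect_length(none, 0)
})

test_that("pair_loss is summed cross-entropy with the documented values", {
  eps <- 1e-7
  expect_lt(pair_loss(rep(1 - eps, 3), rep(eps, 3)), 1e-5)
  expect_equal(pair_loss(0.5, 0.5), -2 * log(0.5))
  l1 <- pair_loss(c(0.6, 0.5), 0.3)
  l2 <- pair_loss(c(0.7, 0.5), 0.3)
  expect_lt(l2, l1)  # raising a positive's score lowers the loss
  expect_gte(pair_loss(0.99, 0.01), 0)
})

test_that("the bag-of-words backend trains, reduces loss, and is deterministic", {
  set.seed(21)
  pos_docs <- sprintf("alpha beta signal%d", 1:20)
  neg_docs <- sprintf("noise other%d", 1:20)
  pairs <- data.frame(
    query = "the protein is x the description is alpha beta",
    doc = c(pos_docs, neg_docs),
    label = rep(c(1, 0), each = 20), stringsAsFactors = FALSE)
  fit1 <- pair_fit(bow_pair_scorer(), pairs, list(epochs = 100))
  losses <- attr(fit1, "loss")
  expect_lt(losses[length(losses)], losses[1])
  fit2 <- pair_fit(bow_pair_scorer(), pairs, list(epochs = 100))
  expect_identical(fit1$weights, fit2$weights)
  s <- pair_score(fit1, pairs$query[1], c(pos_docs[1], neg_docs[1]))
  expect_true(s[1] > s[2])
})

test_that("bow scorer parameters round-trip through JSON", {
  sc <- bow_pair_scorer(16)
  sc$weights <- seq_along(sc$weights) / 10
  path <- tempfile(fileext = ".json")
  write_bow_pair_scorer(sc, path)
  back <- read_bow_pair_scorer(path)
  expect_equal(back$weights, sc$weights)
  expect_equal(back$dim, sc$dim)
})

test_that("assemble_predictions max-propagates, drops roots, respects the cap", {
  onto <- toy_chain_onto()
  scored <- data.frame(protein = "P1", term = c("GO:0000003", "GO:0000002"),
                       branch = "BPO", score = c(0.9, 0.4))
  prop <- assemble_predictions(scored, onto, propagate = TRUE)
  expect_equal(prop$score[prop$term == "GO:0000002"], 0.9)  # parent lifted
  expect_false("GO:0000001" %in% prop$term)                 # root removed

  flat <- assemble_predictions(scored, onto, propagate = FALSE)
  expect_equal(flat$score[flat$term == "GO:0000002"], 0.4)

  rooted <- rbind(scored, data.frame(protein = "P1", term = "GO:0000001",
                                     branch = "BPO", score = 1))
  expect_false("GO:0000001" %in% assemble_predictions(rooted, onto)$term)

  capped <- assemble_predictions(scored, onto, cap = 1)
  expect_equal(nrow(capped), 1)
  expect_equal(capped$term, "GO:0000003")
})
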