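test_that("weighted precision/recall handle perfect and partial predictions", {
  truth <- list(P1 = c("GO:0000002", "GO:0000003"))
  ic <- c("GO:0000002" = 1, "GO:0000003" = 1, "GO:0000004" = 1)
  perfect <- data.frame(protein = "P1", term = c("GO:0000002", "GO:0000003"),
                        score = 1)
  pr <- weighted_pr_rc(perfect, truth, ic, tau = 0.5)
  expect_equal(unname(pr[c("wpr", "wrc")]), c(1, 1))
  expect_error(weighted_pr_rc(perfect, truth, ic, tau = 1.5), "tau")
})

test_that("with uniform IC the weighted metrics reduce to set arithmetic", {
  set.seed(13)
  terms <- sprintf("GO:%07d", 1:12)
  ic <- stats::setNames(rep(1, 12), terms)
  for (rep in 1:10) {
    truth <- lapply(stats::setNames(1:3, paste0("P", 1:3)),
                    function(i) sample(terms, sample(2:6, 1)))
    preds <- data.frame(protein = sample(paste0("P", 1:3), 15, replace = TRUE),
                        term = sample(terms, 15, replace = TRUE),
                        score = sample(seq(0.1, 1, 0.1), 15, replace = TRUE))
    preds <- preds[!duplicated(preds[c("protein", "term")]), ]
    tau <- 0.5
    got <- weighted_pr_rc(preds, truth, ic, tau)
    # direct set arithmetic
    m <- 0; pr <- 0; rc <- 0
    for (p in names(truth)) {
      call <- preds$term[preds$protein == p & preds$score >= tau]
      if (length(call)) { m <- m + 1; pr <- pr + length(intersect(call, truth[[p]])) / length(call) }
      rc <- rc + length(intersect(call, truth[[p]])) / length(truth[[p]])
    }
    expect_equal(unname(got["wpr"]), if (m > 0) pr / m else 0)
    expect_equal(unname(got["wrc"]), rc / 3)
  }
})

test_that("proteins without calls count in recall averaging but not precision", {
  truth <- list(P1 = "GO:0000002", P2 = "GO:0000003")
  ic <- c("GO:0000002" = 1, "GO:0000003" = 1)
  preds <- data.frame(protein = "P1", term = "GO:0000002", score = 0.9)
  pr <- weighted_pr_rc(preds, truth, ic, tau = 0.5)
  expect_equal(unname(pr["wpr"]), 1)    # only P1 has a call
  expect_equal(unname(pr["wrc"]), 0.5)  # averaged over both proteins
  expect_equal(unname(pr["m"]), 1)
})

test_that("wfmax reproduces the enumerated two-term example", {
  truth <- list(P1 = c("GO:0000002", "GO:0000003"))
  ic <- c("GO:0000002" = 1, "GO:0000003" = 1, "GO:0000004" = 1)
  preds <- data.frame(protein = "P1", term = c("GO:0000002", "GO:0000004"),
                      score = c(0.8, 0.4))
  res <- wfmax(preds, truth, ic)
  expect_equal(res$wfmax, 2 / 3)          # precision 1, recall 1/2 above 0.4
  expect_true(res$tau > 0.4 && res$tau <= 0.8)
  expect_equal(nrow(res$curve), 100)
})

test_that("wfmax of empty predictions is 0 with a warning", {
  truth <- list(P1 = "GO:0000002")
  ic <- c("GO:0000002" = 1)
  expect_warning(res <- wfmax(data.frame(protein = character(0),
                                         term = character(0),
                                         score = numeric(0)), truth, ic),
                 "no predictions")
  expect_equal(res$wfmax, 0)
})

test_that("wfmax is invariant to uniform IC rescaling and matches the sweep oracle", {
  set.seed(17)
  terms <- sprintf("GO:%07d", 1:10)
  for (rep in 1:8) {
    ic <- stats::setNames(stats::runif(10, 0.2, 3), terms)
    truth <- lapply(stats::setNames(1:4, paste0("P", 1:4)),
                    function(i) sample(terms, sample(2:5, 1)))
    preds <- data.frame(protein = sample(names(truth), 20, replace = TRUE),
                        term = sample(terms, 20, replace = TRUE),
                        score = sample(seq(0.01, 1, 0.01), 20, replace = TRUE))
    preds <- preds[!duplicated(preds[c("protein", "term")]), ]
    res <- wfmax(preds, truth, ic)
    expect_equal(res$wfmax, oracle_wfmax(preds, truth, ic))
    expect_equal(wfmax(preds, truth, ic * 2)$wfmax, res$wfmax)
  }
})

test_that("with uniform IC and one protein wFmax equals classical Fmax", {
  terms <- sprintf("GO:%07d", 1:8)
  ic <- stats::setNames(rep(1, 8), terms)
  truth <- list(P1 = terms[1:4])
  preds <- data.frame(protein = "P1", term = terms[c(1, 2, 5, 6, 7)],
                      score = c(0.9, 0.7, 0.6, 0.3, 0.2))
  res <- wfmax(preds, truth, ic)
  # enumerate thresholds by hand: best is calls {1,2,5} or {1,2}
  f_at <- function(call) {
    pr <- length(intersect(call, truth$P1)) / length(call)
    rc <- length(intersect(call, truth$P1)) / 4
    2 * pr * rc / (pr + rc)
  }
  best <- max(f_at(terms[c(1, 2, 5)]), f_at(terms[1:2]), f_at(terms[1]),
              f_at(terms[c(1, 2, 5, 6)]), f_at(terms[c(1, 2, 5, 6, 7)]))
  expect_equal(res$wfmax, best)
})

test_that("F1 from confusion counts follows 2TP/(2TP+FP+FN)", {
  expect_equal(f1_from_counts(4, 14, 10), 0.250)
  expect_equal(f1_from_counts(11, 8, 3), 0.667)
  expect_equal(f1_from_counts(0, 0, 5), 0)
  expect_error(f1_from_counts(0, 0, 0), "undefined")
})

test_that("candidate-set F1 covers agreement, disjointness and the empty case", {
  expect_equal(candidate_set_f1(c("a", "b"), c("a", "b")), 1)
  expect_equal(candidate_set_f1(c("a", "b"), c("c", "d")), 0)
  expect_equal(candidate_set_f1(c("a", "b", "c"), c("a", "b")), 0.8)
  expect_warning(z <- candidate_set_f1(character(0), character(0)), "empty")
  expect_equal(z, 0)
})

test_that("macro averages and relative improvements round as displayed", {
  expect_equal(macro_average(0.5), 0.5)
  expect_equal(macro_average(c(0.1, 0.2, 0.6)), 0.3)
  expect_error(macro_average(numeric(0)), "empty")
  expect_equal(relative_improvement(0.6, 0.6), 0)
  expect_equal(relative_improvement(0.66, 0.6), 10)
  expect_error(relative_improvement(0.5, 0), "positive")
})
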