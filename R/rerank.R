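#' Build the protein-side query text for reranking
#'
#' Fixed template joining the recommended name and the informative literature
#' sentences: `"The protein is <name> The description is <s1 s2 ...>"`.
#' Sentences are emitted in decreasing relevance order (the input is
#' re-sorted if a `relevance` column is present); single spaces separate all
#' pieces. A protein without literature keeps the template with an empty
#' description clause so downstream scorers still receive a well-formed
#' query.
#'
#' @param protein a `protein_record` (or any list with `$name`).
#' @param informative data.frame with `text` (and optionally `relevance`)
#'   from [select_informative()], or a character vector.
#' @return A single query string.
#' @export
build_query <- function(protein, informative = NULL) {
  if (!nzchar(protein$name)) stop("protein name must be non-empty")
  if (is.null(informative)) {
    texts <- character(0)
  } else if (is.character(informative)) {
    texts <- informative
  } else {
    if (!is.null(informative$relevance)) {
      ord <- order(-informative$relevance, method = "radix")
      informative <- informative[ord, , drop = FALSE]
    }
    texts <- informative$text
  }
  paste0("The protein is ", protein$name,
         " The description is ", paste(texts, collapse = " "))
}

#' Build (query, definition) rerank pairs for a candidate set
#'
#' One pair per candidate term, all sharing the same protein-side query text;
#' the document side is the term's GO definition, kept verbatim. Candidates
#' without a definition are skipped with a warning.
#'
#' @param query_text from [build_query()].
#' @param cands a `candidate_set`.
#' @return data.frame `term`, `query`, `doc`.
#' @export
build_pairs <- function(query_text, cands) {
  terms <- cands$terms
  defs <- cands$definition[terms]
  ok <- !is.na(defs) & nzchar(defs)
  if (any(!ok))
    warning(sprintf("skipped %d candidate(s) without a definition", sum(!ok)))
  data.frame(term = terms[ok], query = rep_len(query_text, sum(ok)),
             doc = unname(defs[ok]), stringsAsFactors = FALSE)
}

# ---- pair-scorer contract -------------------------------------------------

#' Score (query, document) pairs
#'
#' Generic for the pair-scorer contract: implementations map a protein-side
#' query string and a GO-definition string to a relevance score in `[0, 1]`,
#' deterministically for fixed parameters. Trainable backends additionally
#' implement [pair_fit()].
#'
#' @param scorer a pair scorer.
#' @param query,doc character vectors of equal length (or one recycled).
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
pair_score <- function(scorer, query, doc) UseMethod("pair_score")

#' Fit a trainable pair scorer
#'
#' @param scorer a trainable pair scorer.
#' @param pairs data.frame with `query`, `doc`, `label` (1 = positive,
#'   0 = negative).
#' @param config list of training options; see the backend's documentation.
#' @return The fitted scorer (with a `loss` attribute tracing training).
#' @export
pair_fit <- function(scorer, pairs, config = list()) UseMethod("pair_fit")

#' Deterministic lexical pair scorer
#'
#' Inference-only backend: the fraction of the definition's distinct tokens
#' that occur in the protein-side query (definition coverage), which lies in
#' `[0, 1]` by construction. A definition whose content words all appear in
#' the protein's literature scores 1; one sharing nothing scores 0. Useful as
#' an offline fallback where no trained semantic model is attached; it is
#' asymmetric on purpose — the query pools many sentences, so coverage of the
#' short definition is the informative direction.
#'
#' @return A pair scorer object.
#' @export
lexical_pair_scorer <- function() {
  structure(list(), class = c("lexical_pair_scorer", "pair_scorer"))
}

#' @export
pair_score.lexical_pair_scorer <- function(scorer, query, doc) {
  n <- max(length(query), length(doc))
  query <- rep_len(query, n); doc <- rep_len(doc, n)
  vapply(seq_len(n), function(i) {
    d <- unique(tokenize(doc[i])[[1]])
    if (!length(d)) return(0)
    q <- unique(tokenize(query[i])[[1]])
    length(intersect(d, q)) / length(d)
  }, numeric(1))
}

#' Trainable bag-of-words logistic pair scorer
#'
#' A compact trainable backend standing behind the same contract as
#' transformer cross-encoders: the (query, definition) interaction is
#' featurized as hashed counts of tokens occurring in *both* sides (dimension
#' `dim`) plus two overlap statistics and an intercept, and scored through a
#' logistic layer trained by full-batch gradient descent on the summed binary
#' cross-entropy of positive and negative pairs.
#'
#' @param dim hashing dimension for shared-token counts.
#' @return An (unfitted) pair scorer object.
#' @export
bow_pair_scorer <- function(dim = 64L) {
  structure(list(dim = as.integer(dim),
                 weights = numeric(dim + 3L)),  # + overlap, coverage, intercept
            class = c("bow_pair_scorer", "pair_scorer"))
}

bow_features <- function(scorer, query, doc) {
  q <- tokenize(query)[[1]]; d <- tokenize(doc)[[1]]
  x <- numeric(scorer$dim + 3L)
  shared <- intersect(q, d)
  if (length(shared)) {
    dt <- table(d)
    for (tok in shared) {
      j <- string_bucket(tok, scorer$dim)
      x[j] <- x[j] + as.numeric(dt[[tok]])
    }
  }
  x[scorer$dim + 1L] <- if (length(d)) length(shared) / length(unique(d)) else 0
  x[scorer$dim + 2L] <- if (length(q)) length(shared) / length(unique(q)) else 0
  x[scorer$dim + 3L] <- 1  # intercept
  x
}

bow_design <- function(scorer, query, doc) {
  n <- max(length(query), length(doc))
  query <- rep_len(query, n); doc <- rep_len(doc, n)
  t(vapply(seq_len(n), function(i) bow_features(scorer, query[i], doc[i]),
           numeric(scorer$dim + 3L)))
}

#' @export
pair_score.bow_pair_scorer <- function(scorer, query, doc) {
  X <- bow_design(scorer, query, doc)
  as.numeric(stats::plogis(X %*% scorer$weights))
}

#' @export
pair_fit.bow_pair_scorer <- function(scorer, pairs, config = list()) {
  stopifnot(nrow(pairs) > 0, all(pairs$label %in% c(0, 1)))
  epochs <- config$epochs %||% 200L
  lr <- config$lr %||% 0.5
  X <- bow_design(scorer, pairs$query, pairs$doc)
  y <- pairs$label
  w <- scorer$weights
  losses <- numeric(epochs + 1L)
  nll <- function(w) {
    p <- pmin(pmax(stats::plogis(X %*% w), 1e-7), 1 - 1e-7)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  losses[1L] <- nll(w)
  for (e in seq_len(epochs)) {
    p <- as.numeric(stats::plogis(X %*% w))
    grad <- as.numeric(t(X) %*% (p - y))
    w <- w - lr * grad / nrow(X)
    losses[e + 1L] <- nll(w)
  }
  scorer$weights <- w
  attr(scorer, "loss") <- losses
  scorer
}

#' Serialize / restore bag-of-words scorer parameters as JSON text
#'
#' @param scorer a fitted `bow_pair_scorer`.
#' @param path output (input) path.
#' @return `path` invisibly; `read_bow_pair_scorer` returns the scorer.
#' @export
write_bow_pair_scorer <- function(scorer, path) {
  jsonlite::write_json(list(backend = "bow", dim = scorer$dim,
                            weights = scorer$weights),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bow_pair_scorer
#' @export
read_bow_pair_scorer <- function(path) {
  obj <- jsonlite::fromJSON(path)
  sc <- bow_pair_scorer(obj$dim)
  sc$weights <- as.numeric(obj$weights)
  sc
}

# ---- scoring, negative sampling, training ---------------------------------

#' Rerank candidate pairs with a pair scorer
#'
#' Scores every pair, validates the `[0, 1]` contract, and returns
#' predictions sorted by decreasing score with ties broken by term id.
#'
#' @param pairs data.frame from [build_pairs()].
#' @param scorer a pair scorer.
#' @param protein,branch carried through into the output.
#' @return data.frame `protein`, `term`, `branch`, `score`.
#' @export
score_candidates <- function(pairs, scorer, protein = NA_character_,
                             branch = NA_character_) {
  if (!nrow(pairs))
    return(data.frame(protein = character(0), term = character(0),
                      branch = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  s <- pair_score(scorer, pairs$query, pairs$doc)
  if (any(s < 0 | s > 1))
    stop("pair scorer violated its contract: scores outside [0, 1]")
  out <- data.frame(protein = protein, term = pairs$term, branch = branch,
                    score = s, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$term, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample negative terms for training at a 1:1 ratio
#'
#' Negatives are drawn uniformly without replacement from the candidate terms
#' that are not in the protein's true set; exactly
#' `min(n_positive, n_available)` are returned. Reproducible under the seed.
#'
#' @param positives character vector of true term ids.
#' @param candidates a `candidate_set` (or character vector of terms).
#' @param seed integer seed.
#' @return Character vector of sampled negative term ids.
#' @export
sample_negatives <- function(positives, candidates, seed) {
  terms <- if (inherits(candidates, "candidate_set")) candidates$terms else candidates
  pool <- sort(setdiff(terms, positives))
  n <- min(length(positives), length(pool))
  if (n == 0L) {
    warning("no negative candidates available")
    return(character(0))
  }
  with_seed(seed, sample(pool, n))
}

#' Summed binary cross-entropy of positive and negative pair scores
#'
#' `-(sum(log p+) + sum(log(1 - p-)))` with scores epsilon-clipped away from
#' 0 and 1 before the logs (natural log).
#'
#' @param scores_pos,scores_neg numeric vectors of scores in `[0, 1]`.
#' @param eps clipping epsilon.
#' @return Non-negative scalar loss.
#' @export
pair_loss <- function(scores_pos, scores_neg, eps = 1e-7) {
  p <- pmin(pmax(scores_pos, eps), 1 - eps)
  q <- pmin(pmax(scores_neg, eps), 1 - eps)
  -(sum(log(p)) + sum(log(1 - q)))
}

#' Train a pair scorer for one GO branch
#'
#' Builds branch-specific training pairs — for each training protein:
#' BM25 neighbors (self excluded), candidate terms, positives = candidates in
#' the protein's propagated truth, negatives sampled 1:1 from the remaining
#' candidates — splits off a validation fraction (default 10%), fits the
#' scorer on the training portion and reports validation loss before and
#' after fitting.
#'
#' @param corpus list of `protein_record`s (training proteins).
#' @param annots propagated annotation list.
#' @param onto a `gene_ontology`.
#' @param branch `MFO`, `BPO` or `CCO`.
#' @param scorer a trainable pair scorer, e.g. [bow_pair_scorer()].
#' @param config list: `k` (retrieval depth, default 3), `fraction`
#'   (informative-sentence fraction, default 0.5), `val_fraction` (default
#'   0.1), `seed` (default 1), plus backend options passed to [pair_fit()].
#' @return The fitted scorer, with attributes `val_loss_init`,
#'   `val_loss_final`, `n_pairs`.
#' @export
train_scorer <- function(corpus, annots, onto, branch, scorer = bow_pair_scorer(),
                         config = list()) {
  k <- config$k %||% 3L
  fraction <- config$fraction %||% 0.5
  val_fraction <- config$val_fraction %||% 0.1
  seed <- config$seed %||% 1L
  branch_annots <- filter_branch(annots, onto, branch)
  if (!length(branch_annots)) stop("no training annotations in branch ", branch)
  index <- build_index(corpus)
  sent_scorer <- config$sentence_scorer %||% make_lexical_scorer()
  eligible <- names(branch_annots)

  rows <- list()
  for (i in seq_along(corpus)) {
    rec <- corpus[[i]]
    truth <- branch_annots[[rec$accession]] %||% character(0)
    truth <- setdiff(truth, onto$roots)
    if (!length(truth)) next
    nbs <- query_neighbors(index, rec, k, eligible = eligible)
    if (!nrow(nbs)) next
    cands <- collect_candidates(nbs, annots, onto, branch)
    if (!length(cands$terms)) next
    pos <- intersect(cands$terms, truth)
    if (!length(pos)) next
    neg <- suppressWarnings(sample_negatives(pos, cands, seed + i))
    inf <- informative_sentences(rec, branch, sent_scorer, fraction)
    qtext <- build_query(rec, inf)
    sel <- c(pos, neg)
    defs <- cands$definition[sel]
    rows[[length(rows) + 1L]] <-
      data.frame(query = qtext, doc = unname(defs), term = sel,
                 label = c(rep(1, length(pos)), rep(0, length(neg))),
                 protein = rec$accession, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || !nrow(pairs)) stop("empty training set for branch ", branch)

  n <- nrow(pairs)
  n_val <- max(1L, floor(val_fraction * n))
  val_idx <- with_seed(seed, sample(n, n_val))
  val <- pairs[val_idx, , drop = FALSE]
  trn <- pairs[-val_idx, , drop = FALSE]
  if (!nrow(trn)) trn <- val

  val_loss <- function(sc) {
    s <- pair_score(sc, val$query, val$doc)
    pair_loss(s[val$label == 1], s[val$label == 0])
  }
  loss0 <- val_loss(scorer)
  fitted <- pair_fit(scorer, trn, config)
  loss1 <- val_loss(fitted)
  attr(fitted, "val_loss_init") <- loss0
  attr(fitted, "val_loss_final") <- loss1
  attr(fitted, "n_pairs") <- n
  fitted
}

#' Post-process scored predictions
#'
#' Drops branch roots and obsolete terms, optionally enforces ancestor
#' consistency by max-propagation (every ancestor of a predicted term
#' receives at least the maximum score among its predicted descendants), and
#' caps the number of terms kept per protein.
#'
#' @param scored data.frame `protein`, `term`, `branch`, `score`.
#' @param onto a `gene_ontology`.
#' @param propagate apply ancestor max-propagation.
#' @param cap per-protein term cap (default unlimited).
#' @return data.frame of the same shape, sorted by protein then decreasing
#'   score.
#' @export
assemble_predictions <- function(scored, onto, propagate = FALSE, cap = Inf) {
  live <- onto$terms$id[!onto$terms$obsolete]
  scored <- scored[scored$term %in% setdiff(live, onto$roots), , drop = FALSE]
  if (propagate && nrow(scored)) {
    parts <- lapply(split(scored, scored$protein), function(sub) {
      env <- new.env(parent = emptyenv())
      for (i in seq_len(nrow(sub))) {
        ids <- c(sub$term[i], ancestors(onto, sub$term[i]))
        for (id in ids) {
          cur <- env[[id]] %||% -Inf
          if (sub$score[i] > cur) env[[id]] <- sub$score[i]
        }
      }
      ids <- setdiff(ls(env), onto$roots)
      data.frame(protein = sub$protein[1],
                 term = ids,
                 branch = term_branch(onto, ids),
                 score = vapply(ids, function(id) env[[id]], numeric(1)),
                 stringsAsFactors = FALSE)
    })
    scored <- do.call(rbind, parts)
  }
  if (!nrow(scored)) { rownames(scored) <- NULL; return(scored) }
  keep <- unlist(lapply(split(seq_len(nrow(scored)), scored$protein), function(idx) {
    ord <- idx[order(-scored$score[idx], scored$term[idx], method = "radix")]
    utils::head(ord, cap)
  }), use.names = FALSE)
  out <- scored[keep, , drop = FALSE]
  out <- out[order(out$protein, -out$score, out$term, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
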