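#' Okapi BM25 index over protein descriptions
#'
#' Each document is the tokenized concatenation of a protein's recommended
#' name and species. Tokenization lowercases and splits on non-alphanumeric
#' characters; no stemming, no stop-list, so scores are exactly reproducible.
#' The IDF uses the standard `log((N - df + 0.5)/(df + 0.5) + 1)` form, which
#' is strictly positive, so all scores are >= 0 and a document sharing no
#' token with the query scores exactly 0.
#'
#' @param corpus list of `protein_record` objects.
#' @param k1,b Okapi parameters (term-frequency saturation and length
#'   normalization).
#' @return A `bm25_index` object.
#' @export
build_index <- function(corpus, k1 = 1.5, b = 0.75) {
  if (!length(corpus)) stop("cannot build a BM25 index from an empty corpus")
  texts <- vapply(corpus, function(r) paste(r$name, r$species), character(1))
  toks <- tokenize(texts)
  counts <- lapply(toks, function(t) table(t))
  doclen <- vapply(toks, length, numeric(1))
  df_env <- new.env(parent = emptyenv())
  for (ct in counts) for (tok in names(ct))
    assign(tok, (df_env[[tok]] %||% 0L) + 1L, envir = df_env)
  structure(list(
    accessions = vapply(corpus, `[[`, character(1), "accession"),
    counts = counts,
    doclen = doclen,
    avgdl = mean(doclen),
    n_docs = length(corpus),
    df = df_env,
    k1 = k1, b = b
  ), class = "bm25_index")
}

#' @export
print.bm25_index <- function(x, ...) {
  cat(sprintf("<bm25_index> %d documents, avg length %.2f tokens (k1=%g, b=%g)\n",
              x$n_docs, x$avgdl, x$k1, x$b))
  invisible(x)
}

#' BM25 scores of every indexed document against a query string
#'
#' @param index a `bm25_index`.
#' @param query_text free text; tokenized like the documents.
#' @return Named numeric vector of scores (one per indexed accession).
#' @export
bm25_scores <- function(index, query_text) {
  q <- unique(tokenize(query_text)[[1]])
  scores <- stats::setNames(numeric(index$n_docs), index$accessions)
  if (!length(q)) return(scores)
  N <- index$n_docs
  for (tok in q) {
    dfreq <- index$df[[tok]]
    if (is.null(dfreq)) next
    idf <- log((N - dfreq + 0.5) / (dfreq + 0.5) + 1)
    for (i in seq_len(N)) {
      f <- index$counts[[i]][tok]
      if (is.na(f)) next
      f <- as.numeric(f)
      denom <- f + index$k1 * (1 - index$b + index$b * index$doclen[i] / index$avgdl)
      scores[i] <- scores[i] + idf * f * (index$k1 + 1) / denom
    }
  }
  scores
}

#' Retrieve the nearest annotated neighbors of a protein
#'
#' Ranks indexed proteins by BM25 similarity between the query protein's
#' name + species and theirs, excludes the query protein itself (same
#' accession), optionally restricts to an eligible pool (typically training
#' proteins with at least one annotation in the queried branch), and returns
#' the top k. Ties at any rank are broken by lexicographic accession so
#' retrieval is fully reproducible.
#'
#' @param index a `bm25_index`.
#' @param query a `protein_record`.
#' @param k retrieval depth (>= 1).
#' @param eligible optional character vector of accessions allowed as
#'   neighbors.
#' @return A `neighbor_set`: data.frame with columns `accession`, `score`,
#'   plus attributes `query` and `k`; at most k rows, sorted by decreasing
#'   score.
#' @export
query_neighbors <- function(index, query, k, eligible = NULL) {
  stopifnot(k >= 1)
  scores <- bm25_scores(index, paste(query$name, query$species))
  pool <- names(scores)
  pool <- pool[pool != query$accession]
  if (!is.null(eligible)) pool <- pool[pool %in% eligible]
  scores <- scores[pool]
  ord <- order(-scores, pool, method = "radix")
  top <- utils::head(ord, k)
  out <- data.frame(accession = pool[top], score = unname(scores[top]),
                    stringsAsFactors = FALSE)
  attr(out, "query") <- query$accession
  attr(out, "k") <- k
  class(out) <- c("neighbor_set", "data.frame")
  out
}

#' Collect candidate GO terms from a neighbor set
#'
#' The candidate set is the union of the neighbors' (propagated) annotations
#' restricted to one branch, with branch roots excluded and the contributing
#' neighbors recorded per term.
#'
#' @param neighbors a `neighbor_set` from [query_neighbors()].
#' @param annots named list protein -> term ids (ancestor-propagated).
#' @param onto a `gene_ontology`.
#' @param branch `MFO`, `BPO` or `CCO`.
#' @return A `candidate_set`: list with `query`, `branch`, `terms` (character
#'   vector), `definition` (named), `provenance` (named list term ->
#'   contributing neighbor accessions).
#' @export
collect_candidates <- function(neighbors, annots, onto, branch) {
  prov <- list()
  for (nb in neighbors$accession) {
    ts <- annots[[nb]] %||% character(0)
    ts <- ts[term_branch(onto, ts) %in% branch]
    ts <- setdiff(ts, onto$roots)
    for (t in ts) prov[[t]] <- c(prov[[t]], nb)
  }
  terms <- sort(names(prov) %||% character(0))
  defs <- stats::setNames(onto$terms[terms, "def"], terms)
  structure(list(query = attr(neighbors, "query"), branch = branch,
                 terms = terms, definition = defs,
                 provenance = prov[terms]),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %s [%s]: %d candidate term(s)\n",
              x$query, x$branch, length(x$terms)))
  invisible(x)
}

#' Weighted nearest-neighbor vote for one term
#'
#' The shared kernel of the BLAST-KNN, Net-KNN and BM25-KNN scorers: the
#' weighted fraction of neighbors carrying the term,
#' `sum(w[has]) / sum(w)`. Weights are BLAST bit scores, PPI edge weights, or
#' BM25 relevance scores depending on the generator.
#'
#' @param has_term logical vector: does each neighbor carry the term?
#' @param weights non-negative neighbor weights, not all zero.
#' @return Score in `[0, 1]`.
#' @export
knn_score <- function(has_term, weights) {
  stopifnot(length(has_term) == length(weights))
  if (any(weights < 0)) stop("neighbor weights must be non-negative")
  total <- sum(weights)
  if (total == 0) stop("all neighbor weights are zero")
  sum(weights[has_term]) / total
}

#' Score a candidate set by the BM25-weighted neighbor vote
#'
#' Applies [knn_score()] to every candidate term with the retrieval scores as
#' weights; this is the retrieval-only predictor (stage 1 without reranking).
#'
#' @param cands a `candidate_set`.
#' @param neighbors the `neighbor_set` the candidates came from.
#' @param annots named list protein -> term ids (propagated), used to test
#'   term membership per neighbor.
#' @return data.frame `protein`, `term`, `branch`, `score`, sorted by
#'   decreasing score then term id.
#' @export
score_candidates_knn <- function(cands, neighbors, annots) {
  if (!length(cands$terms))
    return(data.frame(protein = character(0), term = character(0),
                      branch = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  w <- neighbors$score
  nb_terms <- lapply(neighbors$accession, function(a) annots[[a]] %||% character(0))
  score <- vapply(cands$terms, function(t) {
    has <- vapply(nb_terms, function(ts) t %in% ts, logical(1))
    knn_score(has, w)
  }, numeric(1))
  out <- data.frame(protein = cands$query, term = cands$terms,
                    branch = cands$branch, score = unname(score),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$term, method = "radix"), , drop = FALSE]
}

#' Cap an externally generated candidate list
#'
#' When candidates come from an external predictor (sequence- or
#' embedding-based), only the top `cap` terms per protein (by the external
#' score, ties by term id) are kept for reranking.
#'
#' @param df data.frame with columns `protein`, `term`, `score`.
#' @param cap maximum candidates per protein (default 100).
#' @return Filtered data.frame.
#' @export
cap_candidates <- function(df, cap = 100) {
  if (!nrow(df)) return(df)
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$protein), function(idx) {
    ord <- idx[order(-df$score[idx], df$term[idx], method = "radix")]
    utils::head(ord, cap)
  }), use.names = FALSE)
  out <- df[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
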