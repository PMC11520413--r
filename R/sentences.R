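#' Branch-conditioned relevance query
#'
#' Renders the fixed question template used to rank literature sentences for
#' one GO branch: `"What is the <branch description> of protein <name>?"`,
#' where the branch description is "Molecular Function", "Biological Process"
#' or "Cellular Component". Only the recommended protein name is interpolated
#' (full description lines add noise).
#'
#' @param branch `MFO`, `BPO` or `CCO`.
#' @param protein_name recommended protein name; must be non-empty.
#' @return A `branch_query`: list with `branch`, `name`, `text`.
#' @export
build_branch_query <- function(branch, protein_name) {
  desc <- c(MFO = "Molecular Function", BPO = "Biological Process",
            CCO = "Cellular Component")
  branch <- match.arg(branch, names(desc))
  if (!nzchar(protein_name)) stop("protein name must be non-empty")
  structure(list(branch = branch, name = protein_name,
                 text = sprintf("What is the %s of protein %s?",
                                desc[[branch]], protein_name)),
            class = "branch_query")
}

#' Deterministic lexical sentence scorer
#'
#' A model-free stand-in for seq2seq relevance scoring: the IDF-weighted
#' cosine similarity between the token bags of the query and the sentence.
#' Pure function of its inputs, so sentence ranking is exactly reproducible.
#' An empty sentence scores 0.
#'
#' @param idf optional named numeric vector of token IDF weights; tokens not
#'   listed get weight 1.
#' @return A scorer `function(query_text, sentence_text) -> numeric`.
#' @export
make_lexical_scorer <- function(idf = NULL) {
  weight <- function(tok) {
    if (is.null(idf)) return(rep(1, length(tok)))
    w <- idf[tok]
    w[is.na(w)] <- 1
    unname(w)
  }
  function(query_text, sentence_text) {
    q <- tokenize(query_text)[[1]]
    s <- tokenize(sentence_text)[[1]]
    if (!length(q) || !length(s)) return(0)
    qt <- table(q); st <- table(s)
    shared <- intersect(names(qt), names(st))
    if (!length(shared)) return(0)
    wq <- as.numeric(qt) * weight(names(qt))
    ws <- as.numeric(st) * weight(names(st))
    num <- sum((as.numeric(qt[shared]) * weight(shared)) *
               (as.numeric(st[shared]) * weight(shared)))
    num / (sqrt(sum(wq^2)) * sqrt(sum(ws^2)))
  }
}

#' Select the informative sentences for one branch
#'
#' Scores every sentence against the branch query with the supplied scorer,
#' sorts by decreasing relevance (stable, so ties keep their input order) and
#' keeps the top `ceiling(fraction * n)` sentences — at least one whenever any
#' sentence exists. The default fraction of one half matches the convention
#' of keeping the top 50% of sentences as informative.
#'
#' @param sentences character vector of sentences, or a data.frame with
#'   columns `text` and optionally `pmid`.
#' @param scorer a `function(query_text, sentence_text) -> numeric`; see
#'   [make_lexical_scorer()].
#' @param query a `branch_query` from [build_branch_query()].
#' @param fraction fraction of sentences to keep, in (0, 1].
#' @return data.frame `text`, `pmid`, `relevance`, sorted by decreasing
#'   relevance.
#' @export
select_informative <- function(sentences, scorer, query, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  if (is.character(sentences))
    sentences <- data.frame(text = sentences,
                            pmid = rep(NA_character_, length(sentences)),
                            stringsAsFactors = FALSE)
  if (!nrow(sentences))
    return(data.frame(text = character(0), pmid = character(0),
                      relevance = numeric(0), stringsAsFactors = FALSE))
  if (is.null(sentences$pmid)) sentences$pmid <- NA_character_
  rel <- vapply(sentences$text, function(s) scorer(query$text, s), numeric(1),
                USE.NAMES = FALSE)
  ord <- order(-rel, method = "radix")  # radix sort is stable
  n_keep <- max(1L, ceiling(fraction * nrow(sentences)))
  keep <- utils::head(ord, n_keep)
  out <- data.frame(text = sentences$text[keep], pmid = sentences$pmid[keep],
                    relevance = rel[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pool and rank a protein's literature sentences for one branch
#'
#' Convenience wrapper: splits every document of the protein into sentences
#' (titles included), pools them across documents, and applies
#' [select_informative()] with the branch query built from the protein's
#' recommended name.
#'
#' @param protein a `protein_record`.
#' @param branch `MFO`, `BPO` or `CCO`.
#' @param scorer sentence scorer.
#' @param fraction fraction to keep.
#' @return data.frame as from [select_informative()]; zero rows if the
#'   protein has no literature.
#' @export
informative_sentences <- function(protein, branch, scorer, fraction = 0.5) {
  if (!nrow(protein$docs))
    return(data.frame(text = character(0), pmid = character(0),
                      relevance = numeric(0), stringsAsFactors = FALSE))
  pieces <- lapply(seq_len(nrow(protein$docs)), function(i) {
    sents <- split_sentences(protein$docs[i, , drop = FALSE])
    if (!length(sents)) return(NULL)
    data.frame(text = sents, pmid = protein$docs$pmid[i], stringsAsFactors = FALSE)
  })
  pooled <- do.call(rbind, pieces)
  if (is.null(pooled) || !nrow(pooled))
    return(data.frame(text = character(0), pmid = character(0),
                      relevance = numeric(0), stringsAsFactors = FALSE))
  query <- build_branch_query(branch, protein$name)
  select_informative(pooled, scorer, query, fraction)
}
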