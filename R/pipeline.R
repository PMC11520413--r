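#' Pipeline configuration
#'
#' Collects every tunable of the two-stage pipeline with the standard
#' defaults: retrieval depth k = 3 for MFO and BPO and k = 2 for CCO (CCO
#' carries fewer annotated terms), informative-sentence fraction 0.5,
#' external-candidate cap 100, threshold grid 0.01..1.00 in 0.01 steps.
#' `read_pipeline_config()` loads a YAML file and merges it over the
#' defaults; unknown keys are an error so typos fail loudly.
#'
#' @param ... overrides of the defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    ontology = NULL, corpus = NULL, annotations = NULL, targets = NULL,
    k = c(MFO = 3L, BPO = 3L, CCO = 2L),
    fraction = 0.5,
    cap = 100L,
    backend = "lexical",
    scorer_params = NULL,
    tau_grid = seq(0.01, 1, by = 0.01),
    seed = 1L,
    propagate = FALSE,
    branches = c("MFO", "BPO", "CCO"),
    digits = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  if (any(cfg$k < 1)) stop("retrieval depth k must be >= 1")
  if (cfg$fraction <= 0 || cfg$fraction > 1) stop("fraction must be in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file of overrides.
#' @export
read_pipeline_config <- function(path) {
  over <- yaml::read_yaml(path)
  if (!is.null(over$k)) over$k <- unlist(over$k)
  do.call(pipeline_config, over)
}

pick_scorer <- function(config) {
  switch(config$backend,
         lexical = lexical_pair_scorer(),
         bow = {
           if (!is.null(config$scorer_params)) read_bow_pair_scorer(config$scorer_params)
           else bow_pair_scorer()
         },
         stop("unknown scorer backend '", config$backend,
              "'; available backends: lexical, bow"))
}

#' Stage 1 for a set of target proteins
#'
#' For every target protein and branch: BM25 neighbors among annotated
#' training proteins (self excluded), candidate aggregation, and the
#' BM25-weighted neighbor vote. Targets whose neighbors all score zero yield
#' no candidates for that branch.
#'
#' @param corpus training corpus (list of `protein_record`s) used to build
#'   the index.
#' @param annots propagated annotation list for the training proteins.
#' @param onto a `gene_ontology`.
#' @param targets list of `protein_record`s to annotate.
#' @param config a [pipeline_config()].
#' @return data.frame `protein`, `branch`, `term`, `score`, `neighbors`
#'   (comma-joined contributing accessions).
#' @export
retrieve_candidates <- function(corpus, annots, onto, targets, config = pipeline_config()) {
  index <- build_index(corpus)
  rows <- list()
  for (branch in config$branches) {
    branch_annots <- filter_branch(annots, onto, branch)
    eligible <- names(branch_annots)
    k <- config$k[[branch]]
    for (rec in targets) {
      nbs <- query_neighbors(index, rec, k, eligible = eligible)
      if (!nrow(nbs) || sum(nbs$score) == 0) next
      cands <- collect_candidates(nbs, annots, onto, branch)
      if (!length(cands$terms)) next
      scored <- score_candidates_knn(cands, nbs, annots)
      scored$neighbors <- vapply(scored$term, function(t)
        paste(cands$provenance[[t]], collapse = ","), character(1))
      rows[[length(rows) + 1L]] <- scored
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein = character(0), term = character(0),
                      branch = character(0), score = numeric(0),
                      neighbors = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[, c("protein", "branch", "term", "score", "neighbors")]
}

#' Stage 2: rerank candidate terms by query/definition matching
#'
#' Builds the protein-side query (name + informative sentences per branch),
#' pairs it with every candidate term's definition and rescores with the
#' configured pair-scorer backend. Externally generated candidate lists are
#' capped to the top `config$cap` terms per protein first. Candidates beyond
#' the cap keep their stage-1 ordering, rescaled strictly below the smallest
#' reranked score so the output remains a total order.
#'
#' @param candidates data.frame `protein`, `branch`, `term`, `score` (stage-1
#'   scores).
#' @param corpus list of `protein_record`s covering the candidate proteins.
#' @param onto a `gene_ontology`.
#' @param config a [pipeline_config()].
#' @param scorer optional pair scorer (defaults to the configured backend).
#' @param external is `candidates` from an external generator (applies the
#'   per-protein cap)?
#' @return data.frame `protein`, `term`, `branch`, `score`.
#' @export
rerank_candidates <- function(candidates, corpus, onto, config = pipeline_config(),
                              scorer = NULL, external = FALSE) {
  scorer <- scorer %||% pick_scorer(config)
  sent_scorer <- make_lexical_scorer()
  kept <- if (external) cap_candidates(candidates, config$cap) else candidates
  rows <- list()
  for (key in unique(paste(kept$protein, kept$branch))) {
    sub <- kept[paste(kept$protein, kept$branch) == key, , drop = FALSE]
    prot <- sub$protein[1]; branch <- sub$branch[1]
    rec <- corpus[[prot]]
    if (is.null(rec)) next
    inf <- informative_sentences(rec, branch, sent_scorer, config$fraction)
    qtext <- build_query(rec, inf)
    cands <- structure(list(query = prot, branch = branch, terms = sub$term,
                            definition = stats::setNames(
                              onto$terms[sub$term, "def"], sub$term),
                            provenance = NULL),
                       class = "candidate_set")
    pairs <- build_pairs(qtext, cands)
    res <- score_candidates(pairs, scorer, protein = prot, branch = branch)
    rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(protein = character(0), term = character(0),
                      branch = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))

  # candidates dropped by the cap re-enter below the minimum reranked score
  if (external && nrow(candidates) > nrow(kept)) {
    dropped <- candidates[!paste(candidates$protein, candidates$term) %in%
                            paste(kept$protein, kept$term), , drop = FALSE]
    min_rr <- if (nrow(out)) min(out$score) else 1
    max_s1 <- max(dropped$score, 1e-12)
    dropped <- data.frame(protein = dropped$protein, term = dropped$term,
                          branch = dropped$branch,
                          score = 0.99 * min_rr * dropped$score / max_s1,
                          stringsAsFactors = FALSE)
    out <- rbind(out, dropped)
  }
  out <- assemble_predictions(out, onto, propagate = config$propagate)
  rownames(out) <- NULL
  out
}

# ---- command-line entry points --------------------------------------------

#' Pipeline commands
#'
#' Thin file-to-file wrappers tying the stages together; these back the
#' `inst/cli/gorank` script. All are deterministic given config + seed.
#'
#' `cmd_retrieve` writes a candidate TSV (protein, branch, term, stage-1
#' score, contributing neighbors). `cmd_rerank` reads such a file (or an
#' external candidate file with columns protein, term, score), reranks and
#' writes a CAFA-style prediction TSV (protein, term, score). `cmd_evaluate`
#' compares predictions with a GAF truth file and writes a JSON report with
#' per-branch wFmax, optimal thresholds and the macro average. `cmd_train`
#' fits the trainable backend per branch and writes JSON parameter files.
#'
#' @param config a [pipeline_config()] with `ontology`, `corpus`,
#'   `annotations` (and for retrieve/rerank, `targets`: a file listing
#'   accessions to annotate, or NULL for all corpus proteins not in training).
#' @param out output path.
#' @name cli
NULL

load_inputs <- function(config) {
  onto <- parse_obo(config$ontology)
  corpus <- read_corpus(config$corpus)
  annots <- read_gaf(config$annotations, onto)
  propagated <- propagate_annotations(onto, annots)
  targets <- if (!is.null(config$targets)) {
    accs <- readLines(config$targets, warn = FALSE)
    corpus[accs[accs %in% names(corpus)]]
  } else corpus
  list(onto = onto, corpus = corpus, annots = annots,
       propagated = propagated, targets = targets)
}

#' @rdname cli
#' @export
cmd_retrieve <- function(config, out) {
  inp <- load_inputs(config)
  message(sprintf("corpus: %d proteins, %d annotated",
                  length(inp$corpus), length(inp$annots)))
  cands <- retrieve_candidates(inp$corpus, inp$propagated, inp$onto,
                               inp$targets, config)
  for (br in config$branches)
    message(sprintf("branch %s: %d candidate rows", br, sum(cands$branch == br)))
  utils::write.table(cands, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' @rdname cli
#' @param candidates candidate TSV (from [cmd_retrieve()] or an external
#'   generator).
#' @param external treat the candidate file as externally generated (cap
#'   applies).
#' @param rerank set to `FALSE` to pass stage-1 scores through
#'   (retrieval-only mode).
#' @export
cmd_rerank <- function(config, candidates, out, external = FALSE, rerank = TRUE) {
  onto <- parse_obo(config$ontology)
  corpus <- read_corpus(config$corpus)
  cand <- utils::read.delim(candidates, colClasses = "character",
                            stringsAsFactors = FALSE)
  cand$score <- as.numeric(cand$score)
  if (is.null(cand$branch)) cand$branch <- term_branch(onto, cand$term)
  preds <- if (rerank) {
    rerank_candidates(cand, corpus, onto, config, external = external)
  } else {
    assemble_predictions(cand[, c("protein", "term", "branch", "score")],
                         onto, propagate = config$propagate)
  }
  fmt <- if (!is.null(config$digits)) round(preds$score, config$digits) else preds$score
  utils::write.table(
    data.frame(protein = preds$protein, term = preds$term, score = fmt),
    out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' @rdname cli
#' @param predictions prediction TSV from [cmd_rerank()].
#' @export
cmd_evaluate <- function(config, predictions, out) {
  onto <- parse_obo(config$ontology)
  annots <- read_gaf(config$annotations, onto)
  propagated <- propagate_annotations(onto, annots)
  ic <- information_content(onto, propagated)
  preds <- utils::read.delim(predictions, stringsAsFactors = FALSE,
                             colClasses = c("character", "character", "numeric"))
  report <- list()
  scores <- numeric(0)
  for (br in config$branches) {
    truth <- lapply(filter_branch(propagated, onto, br),
                    function(ts) setdiff(ts, onto$roots))
    sub <- preds[term_branch(onto, preds$term) %in% br, , drop = FALSE]
    res <- suppressWarnings(wfmax(sub, truth, ic, config$tau_grid))
    report[[br]] <- list(wfmax = res$wfmax, tau = res$tau, n = res$n_e)
    scores[[br]] <- res$wfmax
    message(sprintf("%s: wFmax %.3f at tau %.2f (n=%d)", br, res$wfmax,
                    res$tau, res$n_e))
  }
  report$macro_wfmax <- macro_average(scores)
  message(sprintf("macro average wFmax: %.3f", report$macro_wfmax))
  jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' @rdname cli
#' @param out_dir directory for per-branch parameter files.
#' @export
cmd_train <- function(config, out_dir) {
  if (config$backend != "bow")
    stop("backend '", config$backend, "' is not trainable; use backend = 'bow'")
  inp <- load_inputs(config)
  paths <- character(0)
  for (br in config$branches) {
    fitted <- train_scorer(inp$corpus, inp$propagated, inp$onto, br,
                           bow_pair_scorer(),
                           config = list(k = config$k[[br]],
                                         fraction = config$fraction,
                                         seed = config$seed))
    message(sprintf("%s: validation loss %.3f -> %.3f (%d pairs)", br,
                    attr(fitted, "val_loss_init"), attr(fitted, "val_loss_final"),
                    attr(fitted, "n_pairs")))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(out_dir, paste0("scorer_", br, ".json"))
    write_bow_pair_scorer(fitted, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
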