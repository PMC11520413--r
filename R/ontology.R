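#' Gene Ontology container
#'
#' A `gene_ontology` object holds the parsed GO DAG: one row per non-obsolete
#' term (id, name, namespace, definition) plus the direct-parent relation used
#' for ancestry queries. The three namespaces are coded with the CAFA branch
#' abbreviations `MFO` (molecular function), `BPO` (biological process) and
#' `CCO` (cellular component). Obsolete terms are retained for bookkeeping but
#' excluded from every graph query, candidate set and prediction.
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`, `def`,
#'   `obsolete`.
#' @param parents named list mapping a term id to its direct parent ids.
#' @param roots named character vector mapping branch code to its root term id.
#' @return An object of class `gene_ontology`.
#' @keywords internal
new_gene_ontology <- function(terms, parents, roots) {
  stopifnot(is.data.frame(terms), is.list(parents))
  obj <- list(
    terms = terms,
    parents = parents,
    roots = roots,
    .anc_cache = new.env(parent = emptyenv())
  )
  class(obj) <- "gene_ontology"
  obj
}

#' @export
print.gene_ontology <- function(x, ...) {
  tab <- table(x$terms$namespace[!x$terms$obsolete])
  cat("<gene_ontology> ", sum(!x$terms$obsolete), " terms (",
      paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
      "), ", sum(x$terms$obsolete), " obsolete\n", sep = "")
  invisible(x)
}

GO_BRANCHES <- c(MFO = "molecular_function",
                 BPO = "biological_process",
                 CCO = "cellular_component")

normalize_namespace <- function(ns) {
  if (ns %in% names(GO_BRANCHES)) return(ns)
  hit <- names(GO_BRANCHES)[match(ns, GO_BRANCHES)]
  if (is.na(hit)) NA_character_ else hit
}

#' Parse a Gene Ontology OBO file
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas (id, name, namespace, def, is_a,
#' relationship, is_obsolete). Ancestry edges are taken from `is_a` plus any
#' relationship types in `relations` (default `part_of`, following GO
#' annotation-propagation practice). Terms missing a namespace and edges that
#' cross namespaces or point at obsolete/unknown terms are dropped with a
#' warning; a cyclic parent relation is a hard error.
#'
#' @param path path to an OBO file.
#' @param relations relationship types (besides `is_a`) contributing ancestry
#'   edges.
#' @return A [new_gene_ontology()] object.
#' @export
parse_obo <- function(path, relations = "part_of") {
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas found in OBO file: ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  keep <- lines[starts] == "[Term]"

  ids <- character(0); nms <- character(0); nss <- character(0)
  defs <- character(0); obs <- logical(0); pars <- list()
  n_dropped_ns <- 0L

  for (i in which(keep)) {
    block <- lines[starts[i]:ends[i]]
    field <- function(key) {
      v <- sub(paste0("^", key, ": *"), "", grep(paste0("^", key, ":"), block, value = TRUE))
      trimws(sub(" *!.*$", "", v))
    }
    first <- function(v, default = "") if (length(v) && !is.na(v[1])) v[1] else default
    id <- first(field("id"), NA_character_)
    if (is.na(id)) next
    ns <- normalize_namespace(first(field("namespace"), NA_character_))
    if (is.na(ns)) { n_dropped_ns <- n_dropped_ns + 1L; next }
    def_raw <- first(field("def"))
    def <- {
      m <- regmatches(def_raw, regexpr('"[^"]*"', def_raw))
      if (length(m)) substr(m, 2, nchar(m) - 1L) else def_raw
    }
    is_a <- field("is_a")
    rel_lines <- field("relationship")
    rel_par <- character(0)
    if (length(rel_lines)) {
      sp <- strsplit(trimws(rel_lines), "[ \t]+")
      rel_par <- vapply(sp[vapply(sp, function(s) length(s) >= 2 && s[1] %in% relations, logical(1))],
                        `[[`, character(1), 2L)
    }
    ids <- c(ids, id); nms <- c(nms, first(field("name")))
    nss <- c(nss, ns); defs <- c(defs, def)
    obs <- c(obs, tolower(first(field("is_obsolete"), "false")) == "true")
    pars[[id]] <- unique(c(is_a, rel_par))
  }
  if (n_dropped_ns > 0)
    warning(sprintf("dropped %d term(s) without a recognizable namespace", n_dropped_ns))

  terms <- data.frame(id = ids, name = nms, namespace = nss, def = defs,
                      obsolete = obs, stringsAsFactors = FALSE)
  dup <- duplicated(terms$id)
  if (any(dup)) terms <- terms[!dup, , drop = FALSE]
  rownames(terms) <- terms$id

  live <- terms$id[!terms$obsolete]
  ns_of <- stats::setNames(terms$namespace, terms$id)
  n_cross <- 0L
  pars <- lapply(stats::setNames(terms$id, terms$id), function(id) {
    p <- pars[[id]] %||% character(0)
    p <- p[p %in% live]
    same <- ns_of[p] == ns_of[[id]]
    n_cross <<- n_cross + sum(!same)
    unname(p[same])
  })
  if (n_cross > 0)
    warning(sprintf("dropped %d cross-namespace parent edge(s)", n_cross))

  # acyclicity check by iterative leaf stripping (Kahn)
  indeg <- new.env(parent = emptyenv())
  nchild <- stats::setNames(integer(length(live)), live)
  for (id in live) for (p in pars[[id]]) nchild[[p]] <- nchild[[p]] + 1L
  queue <- live[nchild[live] == 0L]
  seen <- 0L
  npar <- stats::setNames(vapply(pars[live], length, integer(1)), live)
  # strip from leaves toward roots
  remaining <- nchild
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (p in pars[[v]]) {
      remaining[[p]] <- remaining[[p]] - 1L
      if (remaining[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen != length(live)) stop("cyclic is_a/relationship graph in OBO file: ", path)

  live_terms <- terms[!terms$obsolete, , drop = FALSE]
  root_ids <- live_terms$id[vapply(pars[live_terms$id], length, integer(1)) == 0L]
  roots <- stats::setNames(root_ids, live_terms[root_ids, "namespace"])

  new_gene_ontology(terms, pars, roots)
}

#' Ancestor terms
#'
#' Transitive closure of the direct-parent relation, excluding the query term
#' itself. Obsolete or unknown ids are errors.
#'
#' @param onto a `gene_ontology`.
#' @param id a term id.
#' @return Character vector of ancestor term ids (unordered).
#' @export
ancestors <- function(onto, id) {
  stopifnot(inherits(onto, "gene_ontology"))
  if (!id %in% onto$terms$id) stop("unknown term id: ", id)
  if (onto$terms[id, "obsolete"]) stop("obsolete term id: ", id)
  cache <- onto$.anc_cache
  key <- id
  if (!is.null(cache[[key]])) return(cache[[key]])
  out <- character(0)
  stack <- onto$parents[[id]]
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v %in% out) next
    out <- c(out, v)
    cached <- cache[[v]]
    if (!is.null(cached)) {
      out <- union(out, cached)
    } else {
      stack <- c(stack, onto$parents[[v]])
    }
  }
  cache[[key]] <- out
  out
}

#' Branch of a term
#' @param onto a `gene_ontology`.
#' @param ids term ids.
#' @return Character vector of branch codes (`MFO`/`BPO`/`CCO`).
#' @export
term_branch <- function(onto, ids) {
  unname(stats::setNames(onto$terms$namespace, onto$terms$id)[ids])
}

#' True-path propagation of annotations
#'
#' Closes every protein's term set under [ancestors()] (the true-path rule: a
#' protein annotated with a term is implicitly annotated with all the term's
#' ancestors). Idempotent.
#'
#' @param onto a `gene_ontology`.
#' @param annots named list mapping protein accession to a character vector of
#'   term ids.
#' @return Named list of the same shape, each set closed under ancestry.
#' @export
propagate_annotations <- function(onto, annots) {
  lapply(annots, function(terms) {
    if (!length(terms)) return(character(0))
    anc <- unlist(lapply(terms, ancestors, onto = onto), use.names = FALSE)
    sort(unique(c(terms, anc)))
  })
}

#' Information content of GO terms
#'
#' For each non-obsolete term v, `IC(v) = -log2 Pr(v | Pa(v))`, where the
#' conditional probability is estimated from an ancestor-propagated annotation
#' corpus as the number of proteins annotated with v divided by the number of
#' proteins annotated with *all* direct parents of v. Branch roots have IC 0.
#' The probability is clamped to `[1/(N+1), 1]` (N = corpus size) so terms
#' never seen in the corpus get a large finite IC rather than infinity.
#'
#' @param onto a `gene_ontology`.
#' @param propagated_annots named list protein -> term ids, already closed
#'   under ancestry (see [propagate_annotations()]).
#' @return Named numeric vector of IC values in bits, one per non-obsolete
#'   term; all values are >= 0.
#' @export
information_content <- function(onto, propagated_annots) {
  live <- onto$terms$id[!onto$terms$obsolete]
  n_prot <- length(propagated_annots)
  counts <- stats::setNames(integer(length(live)), live)
  for (terms in propagated_annots) {
    terms <- terms[terms %in% live]
    counts[terms] <- counts[terms] + 1L
  }
  floor_p <- 1 / (n_prot + 1)
  ic <- stats::setNames(numeric(length(live)), live)
  for (id in live) {
    pars <- onto$parents[[id]]
    if (!length(pars)) { ic[[id]] <- 0; next }
    # propagated sets are ancestor-closed, so proteins carrying the term also
    # carry every parent; the joint parent count is the size of the
    # intersection of the parents' protein sets
    if (length(pars) == 1L) {
      denom <- counts[[pars]]
    } else {
      denom <- sum(vapply(propagated_annots, function(ts) all(pars %in% ts), logical(1)))
    }
    num <- counts[[id]]
    p <- if (denom > 0) num / denom else 0
    p <- min(max(p, floor_p), 1)
    ic[[id]] <- -log2(p)
  }
  ic
}
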