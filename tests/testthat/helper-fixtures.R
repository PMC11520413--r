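# In-code fixture builders shared across the suite.

# Write an OBO file from a parent map. `parents` is a named list
# id -> character vector of is_a parents; `namespace` a single branch long
# name or a named character vector per id.
write_toy_obo <- function(parents, namespace = "biological_process",
                          obsolete = character(0), defs = NULL,
                          path = tempfile(fileext = ".obo")) {
  ids <- names(parents)
  ns <- if (length(namespace) == 1L) stats::setNames(rep(namespace, length(ids)), ids)
        else namespace
  lines <- c("format-version: 1.2", "")
  for (id in ids) {
    def <- if (!is.null(defs) && !is.null(defs[[id]])) defs[[id]]
           else paste("definition of", id)
    lines <- c(lines, "[Term]", paste0("id: ", id), paste0("name: name ", id),
               paste0("namespace: ", ns[[id]]),
               sprintf('def: "%s" [TEST:1]', def),
               if (length(parents[[id]])) paste0("is_a: ", parents[[id]]),
               if (id %in% obsolete) "is_obsolete: true",
               "")
  }
  writeLines(lines, path)
  path
}

# Chain root <- b <- c (c is the deepest term).
toy_chain_onto <- function() {
  parse_obo(write_toy_obo(list(
    "GO:0000001" = character(0),
    "GO:0000002" = "GO:0000001",
    "GO:0000003" = "GO:0000002")))
}

toy_protein <- function(accession = "P1", name = "kinase alpha",
                        species = "Homo sapiens", docs = NULL) {
  rec <- list(accession = accession, name = name, species = species,
              entry = paste0(accession, "_TEST"),
              docs = docs %||% data.frame(pmid = character(0),
                                          title = character(0),
                                          abstract = character(0),
                                          stringsAsFactors = FALSE))
  class(rec) <- "protein_record"
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force ancestor closure (repeated parent expansion),
# used as the oracle against ancestors().
oracle_ancestors <- function(parents, id) {
  out <- character(0)
  frontier <- parents[[id]]
  while (length(frontier)) {
    out <- unique(c(out, frontier))
    frontier <- unique(unlist(parents[frontier], use.names = FALSE))
    frontier <- setdiff(frontier, out)
  }
  out
}

# Independent brute-force weighted Fmax: sweep every distinct prediction
# score as a threshold and take the best harmonic mean of IC-weighted
# precision/recall computed by direct set arithmetic.
oracle_wfmax <- function(preds, truth, ic) {
  taus <- sort(unique(preds$score))
  if (!length(taus)) return(0)
  best <- 0
  for (tau in taus) {
    m <- 0; pr <- 0; rc <- 0
    for (prot in names(truth)) {
      call <- preds$term[preds$protein == prot & preds$score >= tau]
      tt <- truth[[prot]]
      if (length(call)) {
        m <- m + 1
        pr <- pr + sum(ic[intersect(call, tt)]) / sum(ic[call])
      }
      rc <- rc + if (sum(ic[tt]) > 0) sum(ic[intersect(call, tt)]) / sum(ic[tt]) else 0
    }
    wpr <- if (m > 0) pr / m else 0
    wrc <- rc / length(truth)
    f <- if (wpr + wrc > 0) 2 * wpr * wrc / (wpr + wrc) else 0
    best <- max(best, f)
  }
  best
}
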