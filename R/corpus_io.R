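#' Protein text corpus IO
#'
#' The corpus holds, per protein, the UniProt-style description fields used by
#' the retrieval stage (recommended name, species, entry name) and the
#' expert-curated literature (PubMed id, title, abstract) used by sentence
#' extraction. Two on-disk layouts are supported: a TSV with one
#' (protein, pmid) row per line and a JSON-lines file with one record per
#' protein.
#'
#' @name corpus_io
NULL

CORPUS_COLUMNS <- c("accession", "name", "species", "entry", "pmid", "title", "abstract")

new_protein_record <- function(accession, name, species = "", entry = "", docs = NULL) {
  docs <- docs %||% data.frame(pmid = character(0), title = character(0),
                               abstract = character(0), stringsAsFactors = FALSE)
  structure(list(accession = accession, name = name, species = species,
                 entry = entry, docs = docs),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s \"%s\" (%s), %d doc(s)\n",
              x$accession, x$name, x$species, nrow(x$docs)))
  invisible(x)
}

#' Read a protein text corpus
#'
#' TSV layout: header row with columns `accession`, `name`, `species`,
#' `entry`, `pmid`, `title`, `abstract`; one row per (protein, document);
#' proteins without literature leave pmid/title/abstract empty. JSON-lines
#' layout (`format = "jsonl"` or a `.jsonl`/`.ndjson` path): one object per
#' protein with a nested `docs` array. Rows sharing an accession are grouped
#' into one record; duplicate pmids within a protein are dropped; records with
#' an empty name are rejected with a warning.
#'
#' @param path corpus file.
#' @param format `"tsv"`, `"jsonl"`, or `"auto"` (by extension).
#' @return List of `protein_record` objects, named by accession.
#' @export
read_corpus <- function(path, format = c("auto", "tsv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(jsonl|ndjson)$", path)) "jsonl" else "tsv"
  if (format == "jsonl") return(read_corpus_jsonl(path))

  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 && ncol(df) <= 1) return(structure(list(), names = character(0)))
  missing_cols <- setdiff(CORPUS_COLUMNS, names(df))
  if (length(missing_cols))
    stop("corpus file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  build_records(df)
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    for (f in c("accession", "name", "species", "entry"))
      if (is.null(rec[[f]])) {
        if (f %in% c("accession", "name"))
          stop("corpus file is missing mandatory column(s): ", f)
        rec[[f]] <- ""
      }
    docs <- rec$docs
    if (is.null(docs) || (is.data.frame(docs) && !nrow(docs))) {
      data.frame(accession = rec$accession, name = rec$name,
                 species = rec$species, entry = rec$entry,
                 pmid = "", title = "", abstract = "", stringsAsFactors = FALSE)
    } else {
      data.frame(accession = rec$accession, name = rec$name,
                 species = rec$species, entry = rec$entry,
                 pmid = as.character(docs$pmid %||% ""),
                 title = as.character(docs$title %||% ""),
                 abstract = as.character(docs$abstract %||% ""),
                 stringsAsFactors = FALSE)
    }
  })
  build_records(do.call(rbind, rows))
}

build_records <- function(df) {
  bad <- !nzchar(df$name)
  if (any(bad)) {
    warning(sprintf("rejected %d corpus row(s) with empty protein name",
                    sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  accs <- unique(df$accession)
  recs <- lapply(accs, function(acc) {
    sub <- df[df$accession == acc, , drop = FALSE]
    docs <- sub[nzchar(sub$pmid), c("pmid", "title", "abstract"), drop = FALSE]
    docs <- docs[!duplicated(docs$pmid), , drop = FALSE]
    rownames(docs) <- NULL
    new_protein_record(acc, sub$name[1], sub$species[1], sub$entry[1], docs)
  })
  stats::setNames(recs, accs)
}

#' Write a protein text corpus as TSV
#'
#' Inverse of [read_corpus()]: one (protein, document) row per line; proteins
#' without documents get a single row with empty literature fields.
#'
#' @param records list of `protein_record` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(records, path) {
  rows <- lapply(records, function(r) {
    if (nrow(r$docs)) {
      data.frame(accession = r$accession, name = r$name, species = r$species,
                 entry = r$entry, pmid = r$docs$pmid, title = r$docs$title,
                 abstract = r$docs$abstract, stringsAsFactors = FALSE)
    } else {
      data.frame(accession = r$accession, name = r$name, species = r$species,
                 entry = r$entry, pmid = "", title = "", abstract = "",
                 stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) df <- as.data.frame(stats::setNames(
    replicate(length(CORPUS_COLUMNS), character(0), simplify = FALSE), CORPUS_COLUMNS))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Evidence codes accepted by default: experimental, high-throughput,
# traceable author statement, and curator inference.
DEFAULT_EVIDENCE <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP",
                      "HTP", "HDA", "HMP", "HGI", "HEP", "TAS", "IC")

GAF_ASPECT <- c(F = "MFO", P = "BPO", C = "CCO")

#' Read a GAF 2.x annotation file
#'
#' Comment lines start with `!`. Rows with a `NOT` qualifier are dropped, the
#' evidence-code whitelist is applied (default: experimental +
#' high-throughput + TAS + IC), and rows whose GO id is absent from the
#' ontology (or obsolete) are dropped with a warning. Malformed rows (fewer
#' than 15 columns) are skipped and counted.
#'
#' @param path GAF file.
#' @param onto a `gene_ontology`; used to validate term ids and assign
#'   branches.
#' @param evidence evidence-code whitelist.
#' @return An annotation table: named list `protein -> character vector of
#'   term ids`, with attributes `branch_of` (term id -> branch) and
#'   `evidence` (data.frame protein/term/evidence kept as provenance).
#' @export
read_gaf <- function(path, onto, evidence = DEFAULT_EVIDENCE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_bad <- sum(vapply(parts, length, integer(1)) < 15L)
  if (n_bad > 0) warning(sprintf("skipped %d malformed GAF row(s)", n_bad))
  parts <- parts[vapply(parts, length, integer(1)) >= 15L]

  acc <- vapply(parts, `[[`, character(1), 2L)
  qual <- vapply(parts, `[[`, character(1), 4L)
  go <- vapply(parts, `[[`, character(1), 5L)
  ev <- vapply(parts, `[[`, character(1), 7L)

  keep <- !grepl("(^|\\|)NOT($|\\|)", qual) & ev %in% evidence
  acc <- acc[keep]; go <- go[keep]; ev <- ev[keep]

  live <- onto$terms$id[!onto$terms$obsolete]
  known <- go %in% live
  if (any(!known))
    warning(sprintf("dropped %d annotation row(s) with unknown or obsolete terms",
                    sum(!known)))
  acc <- acc[known]; go <- go[known]; ev <- ev[known]

  annots <- lapply(split(go, acc), function(x) sort(unique(x)))
  attr(annots, "branch_of") <- stats::setNames(term_branch(onto, unique(go)), unique(go))
  attr(annots, "evidence") <- data.frame(protein = acc, term = go, evidence = ev,
                                         stringsAsFactors = FALSE)
  annots
}

#' Restrict an annotation list to one GO branch
#'
#' @param annots named list protein -> term ids.
#' @param onto a `gene_ontology`.
#' @param branch `MFO`, `BPO` or `CCO`.
#' @param drop_empty drop proteins with no terms left.
#' @return Named list of the same shape.
#' @export
filter_branch <- function(annots, onto, branch, drop_empty = TRUE) {
  out <- lapply(annots, function(ts) ts[term_branch(onto, ts) %in% branch])
  if (drop_empty) out <- out[vapply(out, length, integer(1)) > 0L]
  out
}

#' Read BLAST tabular (outfmt 6) hits into a similarity table
#'
#' Standard 12-column layout; column 12 is the bit score. Self-hits are
#' removed and only the maximum bit score per (query, subject) pair is kept.
#' Rows with a non-numeric bit score are skipped with a warning.
#'
#' @param path BLAST tabular file.
#' @return data.frame with columns `query`, `subject`, `bitscore`.
#' @export
read_blast_tab <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("expected 12-column BLAST outfmt 6 file: ", path)
  bits <- suppressWarnings(as.numeric(df[[12]]))
  bad <- is.na(bits)
  if (any(bad)) warning(sprintf("skipped %d BLAST row(s) with non-numeric bit score",
                                sum(bad)))
  out <- data.frame(query = df[[1]][!bad], subject = df[[2]][!bad],
                    bitscore = bits[!bad], stringsAsFactors = FALSE)
  out <- out[out$query != out$subject, , drop = FALSE]
  if (nrow(out)) {
    key <- paste(out$query, out$subject, sep = "\r")
    out <- out[order(key, -out$bitscore), , drop = FALSE]
    out <- out[!duplicated(paste(out$query, out$subject, sep = "\r")), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# Abbreviations whose trailing period never ends a sentence.
SENTENCE_ABBREV <- c("e.g.", "i.e.", "cf.", "ca.", "vs.", "et al.", "Fig.",
                     "fig.", "Figs.", "Eq.", "approx.", "spp.", "sp.", "no.")

#' Split a literature document into sentences
#'
#' The title is emitted as its own sentence; the abstract is split on
#' `.`/`!`/`?` followed by whitespace, with a rule-based guard for common
#' abbreviations and single-letter genus initials in species binomials
#' ("E. coli"), so splitting is deterministic and model-free.
#'
#' @param doc a one-row data.frame (or list) with `title` and `abstract`.
#' @return Character vector of sentences.
#' @export
split_sentences <- function(doc) {
  title <- trimws(doc$title %||% "")
  abstract <- trimws(doc$abstract %||% "")
  out <- if (nzchar(title)) title else character(0)
  if (nzchar(abstract)) {
    prot <- abstract
    sentinel <- "\x01"
    for (ab in SENTENCE_ABBREV) {
      ab_prot <- gsub(".", sentinel, ab, fixed = TRUE)
      prot <- gsub(ab, ab_prot, prot, fixed = TRUE)
    }
    # genus initial: single capital letter + period + space + lowercase word
    prot <- gsub("\\b([A-Z])\\.( [a-z])", paste0("\\1", sentinel, "\\2"), prot)
    pieces <- strsplit(prot, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
    pieces <- gsub(sentinel, ".", pieces, fixed = TRUE)
    out <- c(out, trimws(pieces[nzchar(trimws(pieces))]))
  }
  out
}
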