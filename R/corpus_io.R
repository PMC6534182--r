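# ChemProt-format corpus I/O.
#
# The corpus dialect is three headerless, unquoted, UTF-8, tab-separated
# files:
#   abstracts.tsv: doc_id <TAB> title <TAB> abstract
#   entities.tsv:  doc_id <TAB> entity_id <TAB> type <TAB> start <TAB> end <TAB> text
#   relations.tsv: doc_id <TAB> cpr_class <TAB> eval_flag <TAB> relation_name
#                  <TAB> Arg1:<entity_id> <TAB> Arg2:<entity_id>
#
# Character offsets are 0-based, half-open, computed over
#   full_text = title <sep> abstract
# with a single-character separator (default "\t"). This convention is fixed
# here so entity offsets resolve unambiguously across the pipeline.

ENTITY_TYPES <- c("CHEMICAL", "GENE-Y", "GENE-N")

#' Split text into sentence spans
#'
#' Rule-based splitter: a sentence ends at a run of `.`, `?` or `!`
#' followed by whitespace and an uppercase letter or digit, unless the
#' token ending at the period is a known abbreviation. Returns 0-based,
#' half-open character spans into `text`, ordered and non-overlapping;
#' leading/trailing whitespace is excluded from each span.
#'
#' @param text a single string.
#' @return integer matrix with columns `start`, `end` (0-based half-open).
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  n <- nchar(text)
  if (n == 0L) return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  abbrev <- c("e.g.", "i.e.", "et al.", "Fig.", "fig.", "Figs.", "Dr.", "vs.",
              "cf.", "No.", "approx.", "ca.", "St.", "al.")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  ends <- integer(0)  # 1-based index of last char of each sentence
  i <- 1L
  while (i <= n) {
    if (chars[i] %in% c(".", "?", "!")) {
      # extend over a punctuation run
      j <- i
      while (j < n && chars[j + 1L] %in% c(".", "?", "!")) j <- j + 1L
      k <- j + 1L
      while (k <= n && chars[k] %in% c(" ", "\t", "\n")) k <- k + 1L
      boundary <- (k > n) || grepl("[[:upper:][:digit:]]", chars[k])
      if (boundary && chars[i] == ".") {
        # abbreviation guard: look at the word ending at this period
        ws <- max(gregexpr("[ \t\n]", substr(text, 1L, i))[[1]])
        word <- substr(text, if (ws < 1L) 1L else ws + 1L, j)
        word2 <- if (ws >= 1L) {
          ws2 <- max(c(0L, gregexpr("[ \t\n]", substr(text, 1L, ws - 1L))[[1]]))
          substr(text, ws2 + 1L, j)
        } else word
        if (word %in% abbrev || word2 %in% abbrev ||
            grepl("^[[:upper:]]\\.$", word) || grepl("^[0-9][0-9.]*$", word)) {
          boundary <- FALSE
        }
      }
      if (boundary) {
        ends <- c(ends, j)
        i <- j + 1L
        next
      }
      i <- j + 1L
      next
    }
    i <- i + 1L
  }
  if (length(ends) == 0L || ends[length(ends)] < n) ends <- c(ends, n)
  starts <- c(1L, ends[-length(ends)] + 1L)
  spans <- matrix(0L, nrow = length(ends), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  keep <- logical(length(ends))
  for (s in seq_along(ends)) {
    a <- starts[s]; b <- ends[s]
    while (a <= b && grepl("[ \t\n]", substr(text, a, a))) a <- a + 1L
    while (b >= a && grepl("[ \t\n]", substr(text, b, b))) b <- b - 1L
    keep[s] <- a <= b
    spans[s, ] <- c(a - 1L, b)  # to 0-based half-open
  }
  spans[keep, , drop = FALSE]
}

#' Construct a document record
#'
#' Builds the document's `full_text` as `title`, a single separator
#' character, then `abstract`, and computes sentence spans over it: the
#' title is always its own sentence, and the abstract is split with
#' `splitter`.
#'
#' @param doc_id document identifier (PMID-like string).
#' @param title,abstract title and abstract text (must not contain tabs or
#'   newlines, which are dialect delimiters).
#' @param sep single separator character between title and abstract.
#' @param splitter function mapping text to a 0-based half-open span matrix.
#' @return A `cpie_document` list with fields `doc_id`, `title`,
#'   `abstract`, `full_text`, `sentence_spans`.
#' @export
make_document <- function(doc_id, title, abstract, sep = "\t",
                          splitter = split_sentences) {
  stopifnot(nchar(sep) == 1L)
  full_text <- paste0(title, sep, abstract)
  off <- nchar(title) + 1L
  abs_spans <- splitter(abstract)
  spans <- rbind(
    if (nchar(title) > 0L) matrix(c(0L, nchar(title)), ncol = 2L) else NULL,
    abs_spans + off
  )
  colnames(spans) <- c("start", "end")
  structure(list(doc_id = as.character(doc_id), title = title,
                 abstract = abstract, sep = sep, full_text = full_text,
                 sentence_spans = spans),
            class = "cpie_document")
}

#' @export
print.cpie_document <- function(x, ...) {
  cat("<cpie_document>", x$doc_id, "-", nrow(x$sentence_spans), "sentences,",
      nchar(x$full_text), "chars\n")
  invisible(x)
}

read_tsv_lines <- function(path, n_fields, what) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(list(fields = vector("list", 0L), lines = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) != n_fields)
  if (length(bad) > 0L) {
    stop(sprintf("malformed %s line(s) in %s (expected %d tab-separated fields): line %s",
                 what, path, n_fields, paste(bad, collapse = ", ")))
  }
  list(fields = fields, lines = lines)
}

#' Read a ChemProt-format corpus
#'
#' Parses the three-file TSV dialect, reconstructs each document's
#' `full_text`, splits sentences, and validates every entity mention
#' (its `full_text` slice must equal its surface string) and every relation
#' (both arguments must resolve, the CPR class must be known, and the
#' evaluation flag must equal "Y" exactly for the five evaluated classes).
#'
#' @param abstracts_path,entities_path,relations_path file paths.
#' @param sep separator character used between title and abstract when
#'   reconstructing `full_text` (default tab, matching the dialect).
#' @param splitter sentence splitter, see [split_sentences()].
#' @return A `cpie_corpus` list with `documents` (named list of
#'   `cpie_document`), `entities` and `relations` data frames.
#' @export
read_corpus <- function(abstracts_path, entities_path, relations_path,
                        sep = "\t", splitter = split_sentences) {
  ab <- read_tsv_lines(abstracts_path, 3L, "abstract")
  docs <- list()
  for (f in ab$fields) {
    d <- make_document(f[1], f[2], f[3], sep = sep, splitter = splitter)
    docs[[d$doc_id]] <- d
  }

  en <- read_tsv_lines(entities_path, 6L, "entity")
  entities <- if (length(en$fields) == 0L) {
    data.frame(doc_id = character(0), entity_id = character(0),
               type = character(0), start = integer(0), end = integer(0),
               text = character(0), stringsAsFactors = FALSE)
  } else {
    m <- do.call(rbind, en$fields)
    data.frame(doc_id = m[, 1], entity_id = m[, 2], type = m[, 3],
               start = as.integer(m[, 4]), end = as.integer(m[, 5]),
               text = m[, 6], stringsAsFactors = FALSE)
  }
  bad_type <- !entities$type %in% ENTITY_TYPES
  if (any(bad_type)) {
    stop("unknown entity type(s): ",
         paste(unique(entities$type[bad_type]), collapse = ", "))
  }
  errs <- character(0)
  for (i in seq_len(nrow(entities))) {
    e <- entities[i, ]
    doc <- docs[[e$doc_id]]
    if (is.null(doc)) {
      errs <- c(errs, sprintf("entity %s refers to unknown doc %s", e$entity_id, e$doc_id))
      next
    }
    if (e$start >= e$end) {
      errs <- c(errs, sprintf("doc %s entity %s: empty/inverted span", e$doc_id, e$entity_id))
      next
    }
    slice <- substr(doc$full_text, e$start + 1L, e$end)
    if (!identical(slice, e$text)) {
      errs <- c(errs, sprintf("doc %s entity %s: offset/surface mismatch ('%s' vs slice '%s')",
                              e$doc_id, e$entity_id, e$text, slice))
    }
  }
  if (length(errs) > 0L) {
    stop("entity validation failed:\n  ", paste(errs, collapse = "\n  "))
  }

  re <- read_tsv_lines(relations_path, 6L, "relation")
  relations <- if (length(re$fields) == 0L) {
    data.frame(doc_id = character(0), cpr_class = character(0),
               evaluated = logical(0), relation_name = character(0),
               arg1 = character(0), arg2 = character(0),
               stringsAsFactors = FALSE)
  } else {
    m <- do.call(rbind, re$fields)
    data.frame(doc_id = m[, 1], cpr_class = m[, 2],
               evaluated = m[, 3] == "Y", relation_name = m[, 4],
               arg1 = sub("^Arg1:", "", m[, 5]),
               arg2 = sub("^Arg2:", "", m[, 6]), stringsAsFactors = FALSE)
  }
  bad_cpr <- !relations$cpr_class %in% ALL_CPR
  if (any(bad_cpr)) {
    stop("unknown CPR class(es): ",
         paste(unique(relations$cpr_class[bad_cpr]), collapse = ", "))
  }
  flag_should <- relations$cpr_class %in% EVALUATED_CPR
  if (any(relations$evaluated != flag_should)) {
    i <- which(relations$evaluated != flag_should)[1]
    stop(sprintf("relation eval flag inconsistent with class %s in doc %s",
                 relations$cpr_class[i], relations$doc_id[i]))
  }
  for (i in seq_len(nrow(relations))) {
    r <- relations[i, ]
    known <- entities$entity_id[entities$doc_id == r$doc_id]
    if (!(r$arg1 %in% known) || !(r$arg2 %in% known)) {
      stop(sprintf("doc %s: relation arguments %s/%s do not resolve to entities",
                   r$doc_id, r$arg1, r$arg2))
    }
  }

  structure(list(documents = docs, entities = entities, relations = relations),
            class = "cpie_corpus")
}

#' @export
print.cpie_corpus <- function(x, ...) {
  cat("<cpie_corpus>", length(x$documents), "documents,",
      nrow(x$entities), "entities,", nrow(x$relations), "relations\n")
  invisible(x)
}

#' Write a corpus in the ChemProt three-file dialect
#'
#' Inverse of [read_corpus()]: `read_corpus()` on the written files
#' reproduces the corpus byte-identically (canonical field order, record
#' order preserved).
#'
#' @param corpus a `cpie_corpus`.
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the three file paths.
#' @export
write_corpus <- function(corpus, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(abstracts = file.path(out_dir, "abstracts.tsv"),
             entities = file.path(out_dir, "entities.tsv"),
             relations = file.path(out_dir, "relations.tsv"))
  ab <- vapply(corpus$documents, function(d)
    paste(d$doc_id, d$title, d$abstract, sep = "\t"), "")
  writeLines(unname(ab), paths["abstracts"], useBytes = TRUE)
  e <- corpus$entities
  writeLines(if (nrow(e)) paste(e$doc_id, e$entity_id, e$type, e$start, e$end,
                                e$text, sep = "\t") else character(0),
             paths["entities"], useBytes = TRUE)
  r <- corpus$relations
  writeLines(if (nrow(r)) paste(r$doc_id, r$cpr_class,
                                ifelse(r$evaluated, "Y", "N"),
                                r$relation_name,
                                paste0("Arg1:", r$arg1),
                                paste0("Arg2:", r$arg2), sep = "\t")
             else character(0),
             paths["relations"], useBytes = TRUE)
  paths
}

# Locate the sentence (row index into doc$sentence_spans) containing a
# 0-based half-open character span; NA if none contains it fully;
# -1L if it straddles a sentence boundary (overlaps a sentence partially).
sentence_of_span <- function(doc, start, end) {
  sp <- doc$sentence_spans
  inside <- which(sp[, "start"] <= start & end <= sp[, "end"])
  if (length(inside) >= 1L) return(inside[1])
  overlap <- which(start < sp[, "end"] & end > sp[, "start"])
  if (length(overlap) > 0L) return(-1L)
  NA_integer_
}

#' Generate labeled candidate instances for one document
#'
#' Enumerates every within-sentence (chemical, gene) mention pair. A pair
#' linked by a gold relation of an evaluated class (CPR:3/4/5/6/9) gets
#' that class as its label -- one instance per distinct (pair, class).
#' Gold relations of non-evaluated classes map to the negative class, as
#' does any unlinked pair. Cross-sentence gold relations are dropped and
#' counted in the `dropped_cross_sentence` attribute; an entity straddling
#' a sentence boundary is skipped with a warning.
#'
#' The chemical argument is normalized into the `chem_id` field regardless
#' of its Arg1/Arg2 position in the relation file.
#'
#' @param doc a `cpie_document`.
#' @param entities,relations corpus data frames (any docs; filtered by id).
#' @return Data frame with columns `doc_id`, `sentence_index` (1-based),
#'   `sent_start`, `sent_end`, `chem_id`, `gene_id`, `label`; attributes
#'   `dropped_cross_sentence` (count) and `skipped_entities` (ids).
#' @export
generate_candidates <- function(doc, entities, relations) {
  ent <- entities[entities$doc_id == doc$doc_id, , drop = FALSE]
  rel <- relations[relations$doc_id == doc$doc_id, , drop = FALSE]
  ent$sentence <- NA_integer_
  skipped <- character(0)
  for (i in seq_len(nrow(ent))) {
    s <- sentence_of_span(doc, ent$start[i], ent$end[i])
    if (identical(s, -1L)) {
      warning(sprintf("doc %s: entity %s spans a sentence boundary; skipped",
                      doc$doc_id, ent$entity_id[i]))
      skipped <- c(skipped, ent$entity_id[i])
      s <- NA_integer_
    }
    ent$sentence[i] <- s
  }
  sent_of <- stats::setNames(ent$sentence, ent$entity_id)
  type_of <- stats::setNames(ent$type, ent$entity_id)

  # gold (chem, gene, class) tuples for evaluated classes, chem normalized
  gold <- list()
  dropped <- 0L
  for (i in seq_len(nrow(rel))) {
    r <- rel[i, ]
    if (!r$cpr_class %in% EVALUATED_CPR) next  # non-evaluated -> NEG
    a1 <- r$arg1; a2 <- r$arg2
    chem <- if (identical(type_of[[a1]], "CHEMICAL")) a1 else a2
    gene <- if (identical(chem, a1)) a2 else a1
    s1 <- sent_of[[chem]]; s2 <- sent_of[[gene]]
    if (is.na(s1) || is.na(s2) || s1 != s2) {
      dropped <- dropped + 1L
      next
    }
    gold[[paste(chem, gene, r$cpr_class, sep = "\r")]] <- TRUE
  }
  gold_keys <- names(gold)

  rows <- list()
  for (s in seq_len(nrow(doc$sentence_spans))) {
    chems <- ent$entity_id[!is.na(ent$sentence) & ent$sentence == s &
                             ent$type == "CHEMICAL"]
    genes <- ent$entity_id[!is.na(ent$sentence) & ent$sentence == s &
                             ent$type %in% c("GENE-Y", "GENE-N")]
    for (ch in chems) for (g in genes) {
      classes <- EVALUATED_CPR[paste(ch, g, EVALUATED_CPR, sep = "\r") %in% gold_keys]
      if (length(classes) == 0L) classes <- "NEG"
      for (cl in classes) {
        rows[[length(rows) + 1L]] <- data.frame(
          doc_id = doc$doc_id, sentence_index = s,
          sent_start = doc$sentence_spans[s, "start"],
          sent_end = doc$sentence_spans[s, "end"],
          chem_id = ch, gene_id = g, label = cl, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(doc_id = character(0), sentence_index = integer(0),
               sent_start = integer(0), sent_end = integer(0),
               chem_id = character(0), gene_id = character(0),
               label = character(0), stringsAsFactors = FALSE)
  attr(out, "dropped_cross_sentence") <- dropped
  attr(out, "skipped_entities") <- skipped
  out
}

#' Generate candidates for every document in a corpus
#'
#' @param corpus a `cpie_corpus`.
#' @return Row-bound candidate data frame (see [generate_candidates()])
#'   with summed `dropped_cross_sentence` attribute.
#' @export
corpus_candidates <- function(corpus) {
  parts <- lapply(corpus$documents, generate_candidates,
                  entities = corpus$entities, relations = corpus$relations)
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- generate_candidates(make_document("x", "t", "a"),
                               data.frame(doc_id = character(0), entity_id = character(0),
                                          type = character(0), start = integer(0),
                                          end = integer(0), text = character(0)),
                               data.frame(doc_id = character(0), cpr_class = character(0),
                                          evaluated = logical(0), relation_name = character(0),
                                          arg1 = character(0), arg2 = character(0)))[0, ]
  }
  attr(out, "dropped_cross_sentence") <-
    sum(vapply(parts, function(p) attr(p, "dropped_cross_sentence") %||% 0L, 0L))
  rownames(out) <- NULL
  out
}

#' Serialize / read candidate instances as JSON lines
#'
#' One JSON object per line with the candidate fields; used as the stable
#' on-disk interchange format between preprocessing and training.
#'
#' @param instances candidate data frame.
#' @param path file path.
#' @return `write_instances`: the path, invisibly. `read_instances`: the
#'   data frame.
#' @export
write_instances <- function(instances, path) {
  lines <- vapply(seq_len(nrow(instances)), function(i) {
    jsonlite::toJSON(as.list(instances[i, , drop = FALSE]), auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_instances
#' @export
read_instances <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) as.data.frame(jsonlite::fromJSON(l),
                                                  stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
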