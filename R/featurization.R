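# Featurization: tokens, POS tags, entity-relative positions, index
# sequences. All character offsets here are 0-based half-open, relative to
# the sentence.

POS_TAGS <- c("NOUN", "VERB", "ADJ", "DET", "PREP", "CONJ", "NUM", "PUNCT", "OTHER")

#' Deterministic coarse part-of-speech tagger
#'
#' A small rule tagger over closed-class word lists and suffix patterns.
#' It exists so the pipeline is self-contained and reproducible; any
#' function mapping a character vector of tokens to a same-length vector
#' of tags from the same tagset can be injected in its place.
#'
#' @param tokens character vector.
#' @return Character vector of tags from `POS_TAGS`.
#' @export
default_pos_tagger <- function(tokens) {
  low <- tolower(tokens)
  tag <- rep("NOUN", length(tokens))
  tag[grepl("^[[:punct:]]+$", tokens)] <- "PUNCT"
  tag[grepl("^[0-9][0-9.,%]*$", tokens)] <- "NUM"
  tag[low %in% c("the", "a", "an", "this", "that", "these", "those", "its")] <- "DET"
  tag[low %in% c("of", "in", "by", "with", "on", "for", "to", "from", "at",
                 "into", "via", "through", "between", "against")] <- "PREP"
  tag[low %in% c("and", "or", "but", "whereas", "while", "although")] <- "CONJ"
  verbish <- grepl("(ed|ing|izes|yzes|ates|ises)$", low) |
    low %in% c("is", "was", "were", "are", "be", "been", "has", "have", "had",
               "shows", "show", "suggests", "catalyzes", "binds", "acts")
  tag[verbish & tag == "NOUN"] <- "VERB"
  tag[grepl("(ive|ous|ant|ent|al|ic)$", low) & tag == "NOUN" & nchar(low) > 4] <- "ADJ"
  tag
}

# Tokenize one plain-text segment (no protected spans inside): whitespace
# split, then peel leading/trailing punctuation into their own tokens.
tokenize_segment <- function(text, offset) {
  out <- list()
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] == -1L) return(out)
  lens <- attr(m, "match.length")
  for (i in seq_along(m)) {
    a <- m[i]; b <- m[i] + lens[i] - 1L  # 1-based inclusive within text
    # leading punctuation
    while (a < b && grepl("^[[:punct:]]$", substr(text, a, a))) {
      out[[length(out) + 1L]] <- c(a, a)
      a <- a + 1L
    }
    # trailing punctuation
    tail_start <- b
    while (tail_start > a && grepl("^[[:punct:]]$", substr(text, tail_start, tail_start))) {
      tail_start <- tail_start - 1L
    }
    out[[length(out) + 1L]] <- c(a, tail_start)
    if (tail_start < b) {
      for (p in (tail_start + 1L):b) out[[length(out) + 1L]] <- c(p, p)
    }
  }
  lapply(out, function(ab) c(start = offset + ab[1] - 1L, end = offset + ab[2]))
}

#' Tokenize a sentence with mention-boundary-aware spans and POS tags
#'
#' Whitespace/punctuation tokenization in which each protected span (a
#' gold entity mention, possibly multi-word) is kept as exactly one token:
#' no token boundary ever falls strictly inside a mention.
#'
#' @param sentence_text sentence string (non-empty).
#' @param mention_spans integer matrix (or NULL) with columns `start`,
#'   `end`: 0-based half-open protected spans relative to the sentence.
#'   Overlapping spans are merged.
#' @param tagger POS tagging function, see [default_pos_tagger()].
#' @return Data frame with columns `text`, `pos_tag`, `start`, `end`
#'   (0-based half-open, ordered, non-overlapping).
#' @export
tokenize_and_tag <- function(sentence_text, mention_spans = NULL,
                             tagger = default_pos_tagger) {
  if (!nzchar(sentence_text)) stop("cannot tokenize an empty sentence")
  n <- nchar(sentence_text)
  prot <- if (is.null(mention_spans) || nrow(mention_spans) == 0L) {
    matrix(integer(0), ncol = 2L)
  } else {
    sp <- mention_spans[order(mention_spans[, 1]), , drop = FALSE]
    merged <- list(sp[1, ])
    for (i in seq_len(nrow(sp))[-1]) {
      last <- merged[[length(merged)]]
      if (sp[i, 1] < last[2]) {
        merged[[length(merged)]] <- c(last[1], max(last[2], sp[i, 2]))
      } else merged[[length(merged) + 1L]] <- sp[i, ]
    }
    do.call(rbind, merged)
  }
  spans <- list()
  cursor <- 0L  # 0-based
  for (i in seq_len(nrow(prot))) {
    a <- prot[i, 1]; b <- prot[i, 2]
    if (a > cursor) {
      seg <- substr(sentence_text, cursor + 1L, a)
      spans <- c(spans, tokenize_segment(seg, cursor))
    }
    spans[[length(spans) + 1L]] <- c(start = a, end = b)
    cursor <- b
  }
  if (cursor < n) {
    seg <- substr(sentence_text, cursor + 1L, n)
    spans <- c(spans, tokenize_segment(seg, cursor))
  }
  if (length(spans) == 0L) stop("sentence contains no tokens")
  sp <- do.call(rbind, spans)
  txt <- substr(rep(sentence_text, nrow(sp)), sp[, 1] + 1L, sp[, 2])
  data.frame(text = txt, pos_tag = tagger(txt),
             start = as.integer(sp[, 1]), end = as.integer(sp[, 2]),
             stringsAsFactors = FALSE)
}

# Map a 0-based half-open character span to the token index range [s, e]
# (1-based) of tokens it overlaps; error if it matches no token.
token_range_of_span <- function(tokens, span) {
  hit <- which(tokens$start < span[2] & tokens$end > span[1])
  if (length(hit) == 0L) stop("entity span matches no token")
  c(min(hit), max(hit))
}

#' Entity-relative token positions
#'
#' Position `i` gets 0 if token `i` lies inside the entity's token range
#' `[s, e]`, `i - s` before it (negative) and `i - e` after it (positive),
#' clipped to `[-D, D]`.
#'
#' @param tokens token data frame from [tokenize_and_tag()], or an integer
#'   count of tokens.
#' @param entity_span length-2 integer: 0-based half-open character span of
#'   the entity (when `tokens` is a data frame), or the 1-based token index
#'   range `c(s, e)` (when `tokens` is a count).
#' @param D clip distance (default 30).
#' @return Integer vector of length `n` in `[-D, D]`.
#' @export
relative_positions <- function(tokens, entity_span, D = 30L) {
  if (is.data.frame(tokens)) {
    n <- nrow(tokens)
    se <- token_range_of_span(tokens, entity_span)
  } else {
    n <- as.integer(tokens)
    se <- as.integer(entity_span)
  }
  i <- seq_len(n)
  out <- integer(n)
  out[i < se[1]] <- i[i < se[1]] - se[1]
  out[i > se[2]] <- i[i > se[2]] - se[2]
  pmax(pmin(out, D), -D)
}

#' Build a token vocabulary
#'
#' Index 0 is reserved for PAD and index 1 for OOV; observed tokens get
#' dense indices from 2 in first-seen order. Tokens are lowercased before
#' indexing. A frozen vocabulary maps unseen tokens to OOV.
#'
#' @param token_lists list of character vectors (or one character vector).
#' @param min_count minimum occurrence count to enter the vocabulary.
#' @return A `cpie_vocab` object.
#' @export
build_vocab <- function(token_lists, min_count = 1L) {
  if (is.character(token_lists)) token_lists <- list(token_lists)
  toks <- tolower(unlist(token_lists, use.names = FALSE))
  counts <- table(factor(toks, levels = unique(toks)))
  keep <- names(counts)[counts >= min_count]
  idx <- stats::setNames(seq_along(keep) + 1L, keep)  # 0-based ids from 2
  structure(list(token_to_index = idx, pad_index = 0L, oov_index = 1L,
                 size = length(idx) + 2L, frozen = TRUE),
            class = "cpie_vocab")
}

#' @export
print.cpie_vocab <- function(x, ...) {
  cat("<cpie_vocab>", x$size, "entries (incl. PAD=0, OOV=1)\n")
  invisible(x)
}

#' Look up token indices in a vocabulary
#'
#' @param vocab a `cpie_vocab`.
#' @param tokens character vector (lowercased internally).
#' @return Integer vector of 0-based indices; unseen tokens map to OOV.
#' @export
vocab_lookup <- function(vocab, tokens) {
  idx <- vocab$token_to_index[tolower(tokens)]
  idx[is.na(idx)] <- vocab$oov_index
  as.integer(idx)
}

#' Invert a vocabulary lookup
#' @param vocab a `cpie_vocab`.
#' @param ids integer vector of 0-based indices.
#' @return Character vector ("<PAD>"/"<OOV>" for the reserved indices).
#' @export
vocab_tokens <- function(vocab, ids) {
  inv <- c("<PAD>", "<OOV>", names(vocab$token_to_index))
  inv[ids + 1L]
}

#' Save / load a vocabulary as JSON
#' @param vocab a `cpie_vocab`.
#' @param path file path.
#' @export
save_vocab <- function(vocab, path) {
  jsonlite::write_json(list(tokens = names(vocab$token_to_index)), path)
  invisible(path)
}

#' @rdname save_vocab
#' @export
load_vocab <- function(path) {
  toks <- jsonlite::fromJSON(path)$tokens
  idx <- stats::setNames(seq_along(toks) + 1L, toks)
  structure(list(token_to_index = idx, pad_index = 0L, oov_index = 1L,
                 size = length(idx) + 2L, frozen = TRUE),
            class = "cpie_vocab")
}

pos_tag_ids <- function(tags) {
  # PAD = 0, tags from 1
  i <- match(tags, POS_TAGS)
  i[is.na(i)] <- match("OTHER", POS_TAGS)
  as.integer(i)
}

# Tokenize one candidate's sentence and apply the anonymization policy.
# Returns tokens data frame plus the token ranges of the two targets.
candidate_tokens <- function(cand, doc, entities,
                             anonymize = c("target", "all", "none"),
                             tagger = default_pos_tagger) {
  anonymize <- match.arg(anonymize)
  sent_text <- substr(doc$full_text, cand$sent_start + 1L, cand$sent_end)
  ent <- entities[entities$doc_id == cand$doc_id &
                    entities$start >= cand$sent_start &
                    entities$end <= cand$sent_end, , drop = FALSE]
  spans <- cbind(start = ent$start - cand$sent_start,
                 end = ent$end - cand$sent_start)
  toks <- tokenize_and_tag(sent_text, spans, tagger = tagger)
  chem <- ent[ent$entity_id == cand$chem_id, ]
  gene <- ent[ent$entity_id == cand$gene_id, ]
  if (nrow(chem) != 1L || nrow(gene) != 1L) {
    stop("candidate's target mentions not found within its sentence")
  }
  chem_range <- token_range_of_span(toks, c(chem$start, chem$end) - cand$sent_start)
  gene_range <- token_range_of_span(toks, c(gene$start, gene$end) - cand$sent_start)
  if (anonymize %in% c("target", "all")) {
    toks$text[chem_range[1]:chem_range[2]] <- "CHEM_ENT"
    toks$text[gene_range[1]:gene_range[2]] <- "GENE_ENT"
  }
  if (anonymize == "all") {
    for (i in seq_len(nrow(ent))) {
      if (ent$entity_id[i] %in% c(cand$chem_id, cand$gene_id)) next
      r <- token_range_of_span(toks, c(ent$start[i], ent$end[i]) - cand$sent_start)
      ph <- if (ent$type[i] == "CHEMICAL") "CHEM_ENT" else "GENE_ENT"
      toks$text[r[1]:r[2]] <- ph
    }
  }
  list(tokens = toks, chem_range = chem_range, gene_range = gene_range)
}

#' Featurize one candidate instance
#'
#' Maps a candidate to aligned index sequences: token ids, POS tag ids and
#' two clipped entity-relative distance channels (stored shifted to
#' `[0, 2D]` so they index embedding rows), plus the 0-based label id under
#' the fixed class order of [cpi_classes()]. Deterministic given
#' (candidate, vocabulary, D).
#'
#' @param cand one-row candidate data frame (see [generate_candidates()]).
#' @param doc the candidate's `cpie_document`.
#' @param entities corpus entity data frame.
#' @param vocab frozen `cpie_vocab`.
#' @param D position clip distance.
#' @param anonymize entity anonymization policy: replace the two target
#'   mentions ("target", default), all mentions ("all"), or none.
#' @param tagger POS tagger function.
#' @return List with `token_ids`, `pos_ids`, `dist_chem`, `dist_gene`
#'   (equal-length integer vectors), `label_id`, `tokens` (character),
#'   `sentence_key` (string key identifying the token sequence).
#' @export
featurize <- function(cand, doc, entities, vocab, D = 30L,
                      anonymize = "target", tagger = default_pos_tagger) {
  if (!cand$label %in% CPI_CLASS_ORDER) stop("label outside the 6-class set: ", cand$label)
  ct <- candidate_tokens(cand, doc, entities, anonymize = anonymize, tagger = tagger)
  toks <- ct$tokens
  n <- nrow(toks)
  list(
    token_ids = vocab_lookup(vocab, toks$text),
    pos_ids = pos_tag_ids(toks$pos_tag),
    dist_chem = relative_positions(n, ct$chem_range, D) + D,
    dist_gene = relative_positions(n, ct$gene_range, D) + D,
    label_id = class_to_id(cand$label),
    tokens = tolower(toks$text),
    sentence_key = paste(vocab_lookup(vocab, toks$text), collapse = ",")
  )
}

#' Featurize every candidate of a corpus
#'
#' @param candidates candidate data frame (see [corpus_candidates()]).
#' @param corpus a `cpie_corpus`.
#' @inheritParams featurize
#' @return List of featurized instances.
#' @export
featurize_corpus <- function(candidates, corpus, vocab, D = 30L,
                             anonymize = "target", tagger = default_pos_tagger) {
  lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, , drop = FALSE]
    featurize(cand, corpus$documents[[cand$doc_id]], corpus$entities,
              vocab, D = D, anonymize = anonymize, tagger = tagger)
  })
}

#' Build the token vocabulary over a corpus' candidate sentences
#'
#' Tokens are collected after anonymization so placeholders are in-vocab.
#'
#' @inheritParams featurize_corpus
#' @param min_count minimum token count.
#' @return A `cpie_vocab`.
#' @export
corpus_vocab <- function(candidates, corpus, anonymize = "target",
                         tagger = default_pos_tagger, min_count = 1L) {
  token_lists <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, , drop = FALSE]
    ct <- candidate_tokens(cand, corpus$documents[[cand$doc_id]],
                           corpus$entities, anonymize = anonymize,
                           tagger = tagger)
    ct$tokens$text
  })
  build_vocab(token_lists, min_count = min_count)
}

#' Pad a list of featurized instances into a rectangular batch
#'
#' All index sequences are right-padded with PAD (0) to the batch maximum
#' length; the returned 0/1 mask marks real tokens. Downstream encoding,
#' attention and pooling ignore padded positions.
#'
#' @param feats list of featurized instances (see [featurize()]).
#' @return List of integer matrices `token_ids`, `pos_ids`, `dist_chem`,
#'   `dist_gene` (batch x max_len), numeric `mask`, integer `lengths`,
#'   `labels` (0-based ids), and the instances' `tokens`.
#' @export
pad_batch <- function(feats) {
  if (length(feats) == 0L) stop("cannot pad an empty batch")
  lens <- vapply(feats, function(f) length(f$token_ids), 1L)
  Tm <- max(lens)
  B <- length(feats)
  pad_mat <- function(field) {
    m <- matrix(0L, B, Tm)
    for (b in seq_len(B)) m[b, seq_len(lens[b])] <- feats[[b]][[field]]
    m
  }
  mask <- matrix(0, B, Tm)
  for (b in seq_len(B)) mask[b, seq_len(lens[b])] <- 1
  list(token_ids = pad_mat("token_ids"), pos_ids = pad_mat("pos_ids"),
       dist_chem = pad_mat("dist_chem"), dist_gene = pad_mat("dist_gene"),
       mask = mask, lengths = lens,
       labels = vapply(feats, function(f) f$label_id, 1L),
       tokens = lapply(feats, function(f) f$tokens))
}
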