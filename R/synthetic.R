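# Synthetic ChemProt-format corpus generator.
#
# Sentences are built from a small set of slot-filling frames (active,
# passive, multi-clause) around one chemical and one gene/protein entity,
# with filler tokens drawn from a Zipf-distributed vocabulary and
# per-class trigger keywords planted between or near the entity pair with
# probability `trigger_strength`. The class trigger lexicons are disjoint,
# so at trigger strength 1 with no distractors a keyword-matching
# classifier is Bayes-optimal (micro-F 1). Entity surfaces are synthetic
# alphanumeric identifiers (CHM####, GEN####); no real lexicon is needed.

DEFAULT_TRIGGERS <- list(
  "CPR:3" = c("expression", "increased", "induced", "activation", "activity"),
  "CPR:4" = c("inhibitor", "inhibition", "inhibitors", "inhibited"),
  "CPR:5" = c("agonist", "agonists", "selective"),
  "CPR:6" = c("antagonist", "antagonists"),
  "CPR:9" = c("metabolism", "catalyzes", "metabolized", "uptake", "enzyme")
)

# Neutral verbs used when no class trigger is planted; disjoint from every
# trigger lexicon.
NEUTRAL_VERBS <- c("examined", "measured", "observed", "assessed", "detected",
                   "cooccurs")

RELATION_NAMES <- c("CPR:3" = "UPREGULATOR", "CPR:4" = "DOWNREGULATOR",
                    "CPR:5" = "AGONIST", "CPR:6" = "ANTAGONIST",
                    "CPR:9" = "SUBSTRATE")

#' Synthetic corpus configuration
#'
#' @param n_docs number of documents.
#' @param sentences_per_doc length-2 integer range (inclusive) of sentences
#'   per document.
#' @param mixture named probability vector over the six classes in
#'   [cpi_classes()]; must sum to 1 and give every positive class mass
#'   only if its trigger lexicon exists.
#' @param triggers per-class trigger lexicons (disjoint lists recommended;
#'   the defaults are disjoint).
#' @param trigger_strength probability that a positive sentence contains
#'   its class trigger (otherwise a neutral verb is used).
#' @param distractor_rate probability a sentence gets an appended
#'   distractor clause containing one extra entity (adds negative
#'   candidate pairs without adding gold relations).
#' @param passive_rate probability a relation sentence uses the passive
#'   frame.
#' @param confound_rate probability a CPR:3 (CPR:4) sentence also carries
#'   a CPR:4 (CPR:3) trigger in a trailing clause, making the two classes
#'   confusable.
#' @param vocab_size number of distinct filler tokens (Zipf-distributed).
#' @param seed integer seed; generation is deterministic given the config.
#' @return A `cpie_synth_config` list.
#' @export
synth_config <- function(n_docs = 100L, sentences_per_doc = c(3L, 6L),
                         mixture = c("NEG" = 0.5, "CPR:3" = 0.1,
                                     "CPR:4" = 0.1, "CPR:5" = 0.1,
                                     "CPR:6" = 0.1, "CPR:9" = 0.1),
                         triggers = DEFAULT_TRIGGERS,
                         trigger_strength = 1.0, distractor_rate = 0,
                         passive_rate = 0.1, confound_rate = 0,
                         vocab_size = 120L, seed = 1L) {
  if (abs(sum(mixture) - 1) > 1e-8) stop("class mixture must sum to 1")
  if (any(mixture < 0)) stop("class mixture must be non-negative")
  if (!all(names(mixture) %in% CPI_CLASS_ORDER)) stop("unknown class in mixture")
  if (sum(mixture > 0) == 0L) stop("degenerate mixture")
  if (trigger_strength < 0 || trigger_strength > 1) {
    stop("trigger_strength must lie in [0, 1]")
  }
  structure(list(n_docs = as.integer(n_docs),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 mixture = mixture, triggers = triggers,
                 trigger_strength = trigger_strength,
                 distractor_rate = distractor_rate,
                 passive_rate = passive_rate, confound_rate = confound_rate,
                 vocab_size = as.integer(vocab_size), seed = as.integer(seed)),
            class = "cpie_synth_config")
}

zipf_weights <- function(V, s = 1.1) {
  w <- 1 / seq_len(V)^s
  w / sum(w)
}

#' Generate a synthetic ChemProt-format corpus
#'
#' Deterministic given the config seed. Returns the in-memory corpus plus
#' a ground-truth instance table; optionally writes the three-file TSV
#' dialect (plus a JSON-lines instance file) to `out_dir`.
#'
#' @param config a [synth_config()].
#' @param out_dir optional output directory.
#' @return List with `corpus` (a `cpie_corpus`), `instances` (data frame
#'   with one row per expected candidate: doc_id, sentence_index, chem_id,
#'   gene_id, label, trigger) and `paths` (when written).
#' @export
generate_corpus <- function(config, out_dir = NULL) {
  fillers <- sprintf("flr%03d", seq_len(config$vocab_size))
  zw <- zipf_weights(config$vocab_size)
  rfill <- function(k) sample(fillers, k, replace = TRUE, prob = zw)
  mix <- config$mixture[config$mixture > 0]
  classes <- names(mix)

  # Structure (document lengths) and one RNG substream seed per sentence
  # are drawn up front, so each sentence's randomness is isolated: a knob
  # that only affects a sentence's tail (e.g. the distractor rate) cannot
  # perturb the labels of other sentences.
  set.seed(config$seed)
  n_sent_per_doc <- sample(config$sentences_per_doc[1]:config$sentences_per_doc[2],
                           config$n_docs, replace = TRUE)
  sent_seeds <- matrix(sample.int(.Machine$integer.max,
                                  config$n_docs * max(n_sent_per_doc),
                                  replace = TRUE),
                       nrow = config$n_docs)

  docs <- list(); ent_rows <- list(); rel_rows <- list(); inst_rows <- list()
  chm_counter <- 0L; gen_counter <- 0L

  for (di in seq_len(config$n_docs)) {
    doc_id <- sprintf("9%06d", di)
    n_sent <- n_sent_per_doc[di]
    sents <- character(n_sent)
    doc_ents <- list()   # per-entity: id, type, tok (surface), sent index,
                         # offset within sentence
    doc_rels <- list()
    tcount <- 0L
    new_ent <- function(type) {
      if (type == "CHEMICAL") {
        chm_counter <<- chm_counter + 1L
        sprintf("CHM%04d", chm_counter)
      } else {
        gen_counter <<- gen_counter + 1L
        sprintf("GEN%04d", gen_counter)
      }
    }
    for (si in seq_len(n_sent)) {
      set.seed(sent_seeds[di, si])
      # decision draws first (fixed count), content draws after
      lab <- sample(classes, 1L, prob = mix)
      u_trig <- stats::runif(1)
      u_passive <- stats::runif(1)
      u_confound <- stats::runif(1)
      u_distract <- stats::runif(1)
      u_swap <- stats::runif(1)
      gene_type <- sample(c("GENE-Y", "GENE-N"), 1L, prob = c(0.8, 0.2))
      chem <- new_ent("CHEMICAL")
      gene <- new_ent(gene_type)
      trig <- NA_character_
      if (lab != "NEG" && u_trig < config$trigger_strength) {
        trig <- sample(config$triggers[[lab]], 1L)
      }
      verb <- if (is.na(trig)) sample(NEUTRAL_VERBS, 1L) else trig
      passive <- u_passive < config$passive_rate
      pre <- rfill(sample(0:2, 1L))
      post <- rfill(sample(1:3, 1L))
      toks <- if (passive) {
        c("The", gene, "was", verb, "by", chem, "in", post, ".")
      } else {
        c(if (length(pre)) c("The", pre) else "The", chem, verb,
          "the", gene, "in", post, ".")
      }
      extra <- NULL
      if (config$confound_rate > 0 && lab %in% c("CPR:3", "CPR:4") &&
          u_confound < config$confound_rate) {
        other <- if (lab == "CPR:3") "CPR:4" else "CPR:3"
        conf_trig <- sample(config$triggers[[other]], 1L)
        toks <- c(toks[-length(toks)], ",", "a", "context", "of", conf_trig,
                  ".")
      }
      if (u_distract < config$distractor_rate) {
        ex_type <- sample(c("CHEMICAL", "GENE-Y"), 1L)
        ex <- new_ent(ex_type)
        toks <- c(toks[-length(toks)], ",", "whereas", ex, "was",
                  sample(NEUTRAL_VERBS, 1L), "with", rfill(1L), ".")
        extra <- list(id = ex, type = ex_type)
      }
      # character offsets of each token within the sentence
      starts <- cumsum(c(0L, nchar(toks[-length(toks)]) + 1L))
      sent <- paste(toks, collapse = " ")
      sents[si] <- sent
      reg <- function(surface, type) {
        tcount <<- tcount + 1L
        pos <- which(toks == surface)[1]
        doc_ents[[length(doc_ents) + 1L]] <<- list(
          tid = sprintf("T%d", tcount), type = type, surface = surface,
          sent = si, off = starts[pos])
        sprintf("T%d", tcount)
      }
      chem_tid <- reg(chem, "CHEMICAL")
      gene_tid <- reg(gene, gene_type)
      extra_pairs <- NULL
      if (!is.null(extra)) {
        ex_tid <- reg(extra$id, extra$type)
        if (extra$type == "CHEMICAL") {
          extra_pairs <- data.frame(chem_id = ex_tid, gene_id = gene_tid)
        } else {
          extra_pairs <- data.frame(chem_id = chem_tid, gene_id = ex_tid)
        }
      }
      if (lab != "NEG") {
        swap <- u_swap < 0.3
        doc_rels[[length(doc_rels) + 1L]] <- list(
          cpr = lab, arg1 = if (swap) gene_tid else chem_tid,
          arg2 = if (swap) chem_tid else gene_tid)
      }
      inst_rows[[length(inst_rows) + 1L]] <- data.frame(
        doc_id = doc_id, sentence_index = si + 1L,  # +1: title is sentence 1
        chem_id = chem_tid, gene_id = gene_tid, label = lab,
        trigger = if (is.na(trig)) NA_character_ else trig,
        text = sent, stringsAsFactors = FALSE)
      if (!is.null(extra_pairs)) {
        for (k in seq_len(nrow(extra_pairs))) {
          inst_rows[[length(inst_rows) + 1L]] <- data.frame(
            doc_id = doc_id, sentence_index = si + 1L,
            chem_id = extra_pairs$chem_id[k], gene_id = extra_pairs$gene_id[k],
            label = "NEG", trigger = NA_character_, text = sent,
            stringsAsFactors = FALSE)
        }
      }
    }
    title <- sprintf("Synthetic abstract %s", doc_id)
    abstract <- paste(sents, collapse = " ")
    doc <- make_document(doc_id, title, abstract)
    docs[[doc_id]] <- doc
    # absolute offsets: title + tab, then sentences joined by single spaces
    sent_abs_start <- nchar(title) + 1L +
      cumsum(c(0L, nchar(sents[-length(sents)]) + 1L))
    for (e in doc_ents) {
      st <- sent_abs_start[e$sent] + e$off
      ent_rows[[length(ent_rows) + 1L]] <- data.frame(
        doc_id = doc_id, entity_id = e$tid, type = e$type, start = st,
        end = st + nchar(e$surface), text = e$surface,
        stringsAsFactors = FALSE)
    }
    for (r in doc_rels) {
      rel_rows[[length(rel_rows) + 1L]] <- data.frame(
        doc_id = doc_id, cpr_class = r$cpr, evaluated = TRUE,
        relation_name = RELATION_NAMES[[r$cpr]], arg1 = r$arg1,
        arg2 = r$arg2, stringsAsFactors = FALSE)
    }
  }
  empty_ent <- data.frame(doc_id = character(0), entity_id = character(0),
                          type = character(0), start = integer(0),
                          end = integer(0), text = character(0),
                          stringsAsFactors = FALSE)
  empty_rel <- data.frame(doc_id = character(0), cpr_class = character(0),
                          evaluated = logical(0), relation_name = character(0),
                          arg1 = character(0), arg2 = character(0),
                          stringsAsFactors = FALSE)
  corpus <- structure(list(
    documents = docs,
    entities = if (length(ent_rows)) do.call(rbind, ent_rows) else empty_ent,
    relations = if (length(rel_rows)) do.call(rbind, rel_rows) else empty_rel),
    class = "cpie_corpus")
  instances <- do.call(rbind, inst_rows)
  rownames(corpus$entities) <- NULL
  rownames(corpus$relations) <- NULL
  rownames(instances) <- NULL
  out <- list(corpus = corpus, instances = instances)
  if (!is.null(out_dir)) {
    paths <- write_corpus(corpus, out_dir)
    gt <- file.path(out_dir, "instances.jsonl")
    write_instances(instances, gt)
    out$paths <- c(paths, instances = gt)
  }
  out
}

#' Generate a deliberately hard synthetic corpus
#'
#' Same engine as [generate_corpus()] with difficulty knobs raised to at
#' least hard-mode levels: frequent passive frames, appended multi-clause
#' distractors, and CPR:3/CPR:4 trigger confounds (a sentence of one class
#' carrying the other class's trigger in a trailing clause). Knobs already
#' set higher in the config are respected.
#'
#' @inheritParams generate_corpus
#' @return See [generate_corpus()].
#' @export
generate_hard_corpus <- function(config, out_dir = NULL) {
  config$passive_rate <- max(config$passive_rate, 0.5)
  config$distractor_rate <- max(config$distractor_rate, 0.5)
  config$confound_rate <- max(config$confound_rate, 0.5)
  generate_corpus(config, out_dir = out_dir)
}

#' Trigger-keyword baseline classifier
#'
#' Predicts the class whose trigger lexicon intersects the token sequence
#' (first match in class order), or NEG when none does. With disjoint
#' lexicons, full trigger strength and no confounds this is the
#' Bayes-optimal rule on the generated corpora.
#'
#' @param tokens_list list of character token vectors (lowercased
#'   internally).
#' @param triggers per-class trigger lexicons.
#' @return Character vector of predicted labels.
#' @export
trigger_baseline_predict <- function(tokens_list, triggers = DEFAULT_TRIGGERS) {
  vapply(tokens_list, function(toks) {
    toks <- tolower(toks)
    for (cl in names(triggers)) {
      if (any(tolower(triggers[[cl]]) %in% toks)) return(cl)
    }
    "NEG"
  }, "")
}
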