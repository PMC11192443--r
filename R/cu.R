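#' Default lexicons for description cleaning and tokenization
#'
#' Plain-text, user-extensible word/phrase lists shipped with the package:
#' a stop-word list of high-frequency function words and three filler
#' lexicons (self-referential, meta-descriptive, confidence/belief-state
#' phrases) removed from descriptions before Content-Unit scoring. The
#' historical lists used in the original survey analysis are not
#' recoverable; these defaults cover the same categories.
#'
#' @return `default_stopwords()`: character vector.
#'   `default_filler_lexicons()`: named list with elements `self_ref`,
#'   `meta`, `confidence`.
#' @export
default_stopwords <- function() {
  readLines(system.file("extdata", "stopwords.txt", package = "natisc"))
}

#' @rdname default_stopwords
#' @export
default_filler_lexicons <- function() {
  rd <- function(f) readLines(system.file("extdata", f, package = "natisc"))
  list(self_ref = rd("lexicon_self_ref.txt"),
       meta = rd("lexicon_meta.txt"),
       confidence = rd("lexicon_confidence.txt"))
}

#' Remove filler phrases from a description
#'
#' Strips self-referential, meta-descriptive and confidence/belief-state
#' phrases (case-insensitively, longest phrase first, at word boundaries)
#' and normalizes whitespace. An empty result is permitted.
#'
#' @param text character string.
#' @param lexicons named list of phrase vectors (default:
#'   [default_filler_lexicons()]).
#' @return cleaned string.
#' @export
clean_description <- function(text, lexicons = default_filler_lexicons()) {
  stopifnot(is.character(text), length(text) == 1)
  phrases <- unlist(lexicons, use.names = FALSE)
  phrases <- phrases[order(-nchar(phrases))]
  out <- text
  for (ph in phrases) {
    pat <- paste0("(?i)(?<![A-Za-z])",
                  gsub("([^A-Za-z0-9 '])", "\\\\\\1", ph),
                  "(?![A-Za-z])")
    out <- gsub(pat, " ", out, perl = TRUE)
  }
  trimws(gsub("\\s+", " ", out))
}

# Irregular lemma table for the rule lemmatizer. Covers common strong
# verbs/nouns; stop words never reach the lemmatizer.
CU_IRREGULAR <- c(
  ran = "run", flew = "fly", sat = "sit", ate = "eat", went = "go",
  saw = "see", took = "take", gave = "give", made = "make", got = "get",
  came = "come", stood = "stand", held = "hold", fell = "fall",
  drove = "drive", rode = "ride", sang = "sing", rang = "ring",
  threw = "throw", drank = "drink", woke = "wake", broke = "break",
  spoke = "speak", found = "find", brought = "bring", bought = "buy",
  caught = "catch", taught = "teach", told = "tell", said = "say",
  men = "man", women = "woman", children = "child", people = "person",
  mice = "mouse", geese = "goose", feet = "foot", teeth = "tooth",
  leaves = "leaf", knives = "knife", wolves = "wolf"
)

# Stems whose final "e" is dropped before -ing/-ed; used to restore it.
CU_E_RESTORE <- c("mak", "tak", "giv", "com", "hav", "writ", "danc", "mov",
                  "smil", "chas", "wav", "rid", "driv", "hid", "shap",
                  "chang", "rais", "clos", "leav", "shar", "us",
                  "wak", "not")

# -ing words that are lexical items, not inflections
CU_ING_NOUNS <- c("morning", "evening", "building", "ceiling", "something",
                  "anything", "nothing", "everything", "painting", "lightning")

lemmatize_word <- function(w) {
  if (w %in% names(CU_IRREGULAR)) return(unname(CU_IRREGULAR[[w]]))
  n <- nchar(w)
  restore_e <- function(stem) {
    if (stem %in% CU_E_RESTORE) return(paste0(stem, "e"))
    # collapse doubled final consonant (running -> run), keep -ll/-ss
    if (nchar(stem) >= 3) {
      last2 <- substr(stem, nchar(stem) - 1, nchar(stem))
      c1 <- substr(last2, 1, 1); c2 <- substr(last2, 2, 2)
      if (c1 == c2 && !c2 %in% c("l", "s", "e") &&
          !c2 %in% c("a", "e", "i", "o", "u")) {
        return(substr(stem, 1, nchar(stem) - 1))
      }
    }
    stem
  }
  if (n > 5 && endsWith(w, "ing") && !w %in% CU_ING_NOUNS) {
    stem <- substr(w, 1, n - 3)
    if (endsWith(stem, "y") || grepl("[aeiou]", stem)) return(restore_e(stem))
  }
  if (n > 4 && endsWith(w, "ed")) {
    stem <- substr(w, 1, n - 2)
    if (endsWith(stem, "i")) return(paste0(substr(stem, 1, nchar(stem) - 1), "y"))
    if (grepl("[aeiouy]", stem)) return(restore_e(stem))
  }
  if (n > 4 && endsWith(w, "sses")) return(substr(w, 1, n - 2))
  if (n > 4 && (endsWith(w, "shes") || endsWith(w, "ches") ||
                endsWith(w, "xes") || endsWith(w, "zes"))) {
    return(substr(w, 1, n - 2))
  }
  if (n > 3 && endsWith(w, "ies")) return(paste0(substr(w, 1, n - 3), "y"))
  if (n > 2 && endsWith(w, "s") && !endsWith(w, "ss") &&
      !endsWith(w, "us") && !endsWith(w, "is")) {
    return(substr(w, 1, n - 1))
  }
  w
}

#' Tokenize a cleaned description into lemma tokens
#'
#' Multiword proper names in `proper_noun_merges` are merged into single
#' tokens first (e.g. `"Mr. Bean"` becomes the single token `"Mr_Bean"`,
#' case preserved);
#' the remainder is lowercased, split on non-letter characters, stripped of
#' stop words, and lemmatized with the package's rule lemmatizer
#' (irregular-form table plus inflectional suffix rules for plural,
#' `-ing` and `-ed` forms).
#'
#' @param text character string (ideally after [clean_description()]).
#' @param stopwords character vector (default [default_stopwords()]).
#' @param proper_noun_merges character vector of multiword names to merge.
#' @return ordered character vector of lemma tokens.
#' @export
extract_lemmas <- function(text, stopwords = default_stopwords(),
                           proper_noun_merges = character(0)) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(trimws(text))) return(character(0))
  for (name in proper_noun_merges) {
    merged <- gsub("[. ]+", "_", trimws(name))
    pat <- paste0("(?i)(?<![A-Za-z])",
                  gsub("([^A-Za-z0-9 '])", "\\\\\\1", name),
                  "(?![A-Za-z])")
    text <- gsub(pat, merged, text, perl = TRUE)
  }
  raw <- strsplit(gsub("[^A-Za-z_']+", " ", text), "\\s+")[[1]]
  raw <- raw[nzchar(raw)]
  out <- character(0)
  for (tok in raw) {
    if (grepl("_", tok)) {          # merged proper name: keep as one CU
      out <- c(out, tok)
      next
    }
    w <- tolower(gsub("'", "", tok))
    if (!nzchar(w) || w %in% stopwords) next
    out <- c(out, lemmatize_word(w))
  }
  out
}

#' Construct a description corpus
#'
#' A long data.frame with one free-text response per (stimulus, subclip,
#' participant). Subclips are integer indices in chronological order; a
#' participant contributes at most one text per subclip.
#'
#' @param df data.frame with columns `stimulus`, `subclip`, `participant`,
#'   `text`.
#' @return a data.frame of class `description_corpus`.
#' @export
description_corpus <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("stimulus", "subclip", "participant", "text") %in% names(df)))
  if (anyDuplicated(df[, c("stimulus", "subclip", "participant")])) {
    stop("at most one text per (stimulus, subclip, participant)")
  }
  df$subclip <- as.integer(df$subclip)
  class(df) <- c("description_corpus", "data.frame")
  df
}

# Clean + tokenize every response of one stimulus; returns the subset of
# the corpus with a `tokens` list-column.
tokenized_stimulus <- function(corpus, stimulus, lexicons, stopwords, merges) {
  sub <- corpus[corpus$stimulus == stimulus, , drop = FALSE]
  sub$tokens <- lapply(sub$text, function(tx) {
    extract_lemmas(clean_description(tx, lexicons), stopwords, merges)
  })
  sub
}

# Lemmas used by >= min_participants distinct participants for a stimulus.
inclusion_lexicon <- function(tok, min_participants) {
  by_part <- tapply(tok$tokens, tok$participant,
                    function(l) unique(unlist(l)), simplify = FALSE)
  usage <- table(unlist(by_part))
  sort(names(usage)[usage >= min_participants])
}

#' Content-Unit counts per participant and subclip
#'
#' Cleans and tokenizes every response for the stimulus, forms the
#' inclusion lexicon (lemmas used by at least `min_participants` distinct
#' participants anywhere in that stimulus's responses), and counts, per
#' response, the TOKENS of included lemmas — repeated words within one
#' response count separately, since the same entity can take part in
#' several events of a subclip.
#'
#' @param corpus a `description_corpus`.
#' @param stimulus stimulus name.
#' @param min_participants inclusion filter (default 3).
#' @param lexicons filler lexicons for [clean_description()].
#' @param stopwords stop-word list for [extract_lemmas()].
#' @param proper_noun_merges multiword names merged to single tokens.
#' @return list with `table` (data.frame: stimulus, subclip, participant,
#'   cu_count) and `included_lexicon` (character).
#' @export
count_cus <- function(corpus, stimulus, min_participants = 3,
                      lexicons = default_filler_lexicons(),
                      stopwords = default_stopwords(),
                      proper_noun_merges = character(0)) {
  stopifnot(is.data.frame(corpus))
  tok <- tokenized_stimulus(corpus, stimulus, lexicons, stopwords,
                            proper_noun_merges)
  if (nrow(tok) == 0) {
    return(list(table = data.frame(stimulus = character(0),
                                   subclip = integer(0),
                                   participant = character(0),
                                   cu_count = integer(0)),
                included_lexicon = character(0)))
  }
  lex <- inclusion_lexicon(tok, min_participants)
  counts <- vapply(tok$tokens, function(tk) sum(tk %in% lex), integer(1))
  list(table = data.frame(stimulus = tok$stimulus, subclip = tok$subclip,
                          participant = tok$participant, cu_count = counts,
                          stringsAsFactors = FALSE),
       included_lexicon = lex)
}

#' Mean pairwise shared Content-Unit count
#'
#' For each subclip, every unordered participant pair contributes the
#' number of included lemma TYPES present in both responses ("shared" is a
#' set notion); the subclip value is the mean over pairs, and the clip
#' value the mean over subclips.
#'
#' @inheritParams count_cus
#' @return list with `per_subclip` (data.frame: subclip, mean_shared) and
#'   `clip_mean`.
#' @export
shared_cu_pairwise <- function(corpus, stimulus, min_participants = 3,
                               lexicons = default_filler_lexicons(),
                               stopwords = default_stopwords(),
                               proper_noun_merges = character(0)) {
  tok <- tokenized_stimulus(corpus, stimulus, lexicons, stopwords,
                            proper_noun_merges)
  if (length(unique(tok$participant)) < 2) {
    stop("pairwise shared CUs need >= 2 participants")
  }
  lex <- inclusion_lexicon(tok, min_participants)
  subclips <- sort(unique(tok$subclip))
  per <- vapply(subclips, function(sc) {
    rows <- tok[tok$subclip == sc, , drop = FALSE]
    types <- lapply(rows$tokens, function(tk) unique(tk[tk %in% lex]))
    n <- length(types)
    if (n < 2) return(NA_real_)
    pairs <- utils::combn(n, 2)
    mean(apply(pairs, 2, function(ij) {
      length(intersect(types[[ij[1]]], types[[ij[2]]]))
    }))
  }, numeric(1))
  list(per_subclip = data.frame(subclip = subclips, mean_shared = per),
       clip_mean = mean(per, na.rm = TRUE))
}

#' Mixed model of subclip CU counts on condition type
#'
#' Response: per-subclip CU count averaged across participants; fixed
#' effect: condition type (dummy coded, reference `"+M/-L"`); random
#' intercept: condition (stimulus).
#'
#' @param cu_table data.frame with columns `stimulus`, `subclip`,
#'   `participant`, `cu_count` (e.g. rbind of [count_cus()] tables).
#' @param manifest data.frame mapping `name` to `condition_type` (e.g.
#'   `design$conditions`).
#' @param reference reference condition type.
#' @param reml REML (default) or ML.
#' @return an `lme_fit`.
#' @export
cu_condition_model <- function(cu_table, manifest, reference = "+M/-L",
                               reml = TRUE) {
  agg <- stats::aggregate(cu_count ~ stimulus + subclip, cu_table, mean)
  agg$condition_type <- manifest$condition_type[match(agg$stimulus, manifest$name)]
  if (anyNA(agg$condition_type)) stop("manifest lacks some stimuli in cu_table")
  if (length(unique(agg$condition_type)) < 2) stop("need >= 2 condition types")
  d <- data.frame(z = agg$cu_count,
                  condition_type = ct_factor(agg$condition_type, reference),
                  condition = agg$stimulus, stringsAsFactors = FALSE)
  fit_lme(d, "condition_type", "condition", "cu_condition",
          reference_level = reference, reml = reml)
}

#' Association between Content-Unit counts and ISC
#'
#' Per stimulus, the CU metric is the subclip mean of participant-averaged
#' `cu_count` (`metric = "mean_cu"`) or the mean pairwise shared count
#' (`metric = "shared_cu"`); the ISC value is the stimulus's mean Fisher z.
#' Three results are returned for the stimuli in `scope`:
#' \itemize{
#'   \item the Pearson correlation between the CU metric and mean ISC
#'     (refused for fewer than 3 stimuli or a constant metric);
#'   \item an LRT comparing the condition-type ISC model against the same
#'     model plus centered CU count as an extra fixed effect (nested, ML);
#'   \item the AIC difference between the condition-type model and a model
#'     with centered CU count replacing condition type (non-nested).
#' }
#'
#' @param cu_values data.frame with columns `stimulus` and `cu` (one row
#'   per stimulus; see [count_cus()] / [shared_cu_pairwise()]), or a raw
#'   `cu_table` (then `metric = "mean_cu"` aggregation is applied).
#' @param isc an `isc_table`.
#' @param metric `"mean_cu"` or `"shared_cu"` (label recorded in output).
#' @param scope character vector of stimuli to include; must be explicit.
#' @return list with `pearson_r`, `p`, `n_stimuli`, `cu_beta` (coefficient
#'   of centered CU in the augmented model), and `model_comparisons`
#'   (`lrt`, `delta_aic`).
#' @export
cu_isc_association <- function(cu_values, isc, metric = c("mean_cu", "shared_cu"),
                               scope) {
  metric <- match.arg(metric)
  if (missing(scope) || is.null(scope)) {
    stop("`scope` (the stimulus subset) must be given explicitly")
  }
  if (all(c("subclip", "cu_count") %in% names(cu_values))) {
    agg <- stats::aggregate(cu_count ~ stimulus + subclip, cu_values, mean)
    cu_values <- stats::aggregate(cu_count ~ stimulus, agg, mean)
    names(cu_values)[2] <- "cu"
  }
  stopifnot(all(c("stimulus", "cu") %in% names(cu_values)))
  scope <- intersect(scope, unique(isc$condition))
  if (length(scope) < 3) stop("correlation refused: scope has < 3 stimuli")
  cu <- cu_values$cu[match(scope, cu_values$stimulus)]
  if (anyNA(cu)) stop("missing CU values for some stimuli in scope")
  if (stats::sd(cu) == 0) stop("CU metric is constant across stimuli; r undefined")
  isc_mean <- tapply(isc$z[isc$condition %in% scope],
                     isc$condition[isc$condition %in% scope], mean)
  isc_mean <- as.numeric(isc_mean[scope])
  ct <- stats::cor.test(cu, isc_mean)

  d <- as.data.frame(isc[isc$condition %in% scope, , drop = FALSE])
  d$cu_centered <- cu[match(d$condition, scope)] - mean(cu)
  d$condition_type <- factor(d$condition_type)
  rf <- intersect(c("froi", "participant", "condition"), names(d))
  multi_type <- length(unique(d$condition_type)) >= 2
  fixed_base <- if (multi_type) "condition_type" else "1"
  orig <- fit_lme(d, fixed_base, rf, "cu_orig", reml = FALSE)
  plus <- fit_lme(d, paste(fixed_base, "+ cu_centered"), rf, "cu_plus",
                  reml = FALSE)
  cuonly <- fit_lme(d, "cu_centered", rf, "cu_only", reml = FALSE)
  lrt <- compare_models(orig, plus, nested = TRUE)
  daic <- compare_models(orig, cuonly, nested = FALSE)
  cu_term <- plus$terms[plus$terms$name == "cu_centered", ]
  list(metric = metric, pearson_r = unname(ct$estimate), p = ct$p.value,
       n_stimuli = length(scope),
       cu_beta = cu_term$beta, cu_se = cu_term$se, cu_p = cu_term$p,
       cu_only_beta = cuonly$terms$beta[cuonly$terms$name == "cu_centered"],
       model_comparisons = list(lrt = lrt, delta_aic = daic$delta_aic))
}

#' Write / read a description corpus as nested JSON
#'
#' JSON layout: stimulus -> subclip -> participant -> text.
#'
#' @param corpus a `description_corpus`.
#' @param path file path.
#' @return `path` (write) or a `description_corpus` (read).
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(is.data.frame(corpus))
  nested <- lapply(split(corpus, corpus$stimulus), function(s) {
    lapply(split(s, s$subclip), function(sc) {
      stats::setNames(as.list(sc$text), sc$participant)
    })
  })
  jsonlite::write_json(nested, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  nested <- jsonlite::read_json(path)
  rows <- list()
  for (stim in names(nested)) {
    for (sc in names(nested[[stim]])) {
      resp <- nested[[stim]][[sc]]
      rows[[length(rows) + 1L]] <- data.frame(
        stimulus = stim, subclip = as.integer(sc),
        participant = names(resp),
        text = unlist(resp, use.names = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  description_corpus(do.call(rbind, rows))
}
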