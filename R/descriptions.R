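# Concept vocabulary for the description generator: lemma -> inflected
# surface forms, so the tokenizer's lemmatizer is genuinely exercised.
cu_vocabulary <- function() {
  list(
    bird = c("bird", "birds"), fly = c("fly", "flies", "flying", "flew"),
    dog = c("dog", "dogs"), run = c("run", "running", "ran"),
    cat = c("cat", "cats"), chase = c("chase", "chased", "chasing"),
    ball = c("ball", "balls"), jump = c("jump", "jumped", "jumping"),
    tree = c("tree", "trees"), house = c("house", "houses"),
    box = c("box", "boxes"), open = c("open", "opened", "opening"),
    door = c("door", "doors"), walk = c("walk", "walked", "walking"),
    shape = c("shape", "shapes"), circle = c("circle", "circles"),
    square = c("square", "squares"), move = c("move", "moved", "moving"),
    cloud = c("cloud", "clouds"), rain = c("rain", "rained", "raining"),
    man = c("man", "men"), woman = c("woman", "women"),
    child = c("child", "children"), sit = c("sit", "sat", "sitting"),
    eat = c("eat", "ate", "eating"), drink = c("drink", "drank", "drinking"),
    car = c("car", "cars"), drive = c("drive", "driving", "drove"),
    music = "music", play = c("play", "played", "playing"),
    sound = c("sound", "sounds"), morning = "morning",
    coffee = "coffee", pour = c("pour", "poured", "pouring"),
    alarm = c("alarm", "alarms"), ring = c("ring", "ringing", "rang"),
    give = c("give", "giving", "gave"), take = c("take", "taking", "took"),
    stand = c("stand", "standing", "stood"), hold = c("hold", "holding", "held"),
    fall = c("fall", "falling", "fell"), throw = c("throw", "throwing", "threw"),
    wave = c("wave", "waved", "waving"), smile = c("smile", "smiled", "smiling"),
    dance = c("dance", "danced", "dancing"), sing = c("sing", "singing", "sang"),
    wake = c("wake", "waking", "woke"), find = c("find", "finding", "found")
  )
}

#' Simulate a free-text description corpus for one stimulus
#'
#' Emulates the survey structure behind Content-Unit scoring: a stimulus
#' cut into subclips, each described by every participant. A fixed set of
#' `core_concepts_per_subclip` concepts is assigned to each subclip from
#' the package vocabulary; each participant mentions each core concept
#' independently with probability `share_prob`, using a randomly chosen
#' inflected surface form. With `filler = TRUE`, self-referential /
#' meta-descriptive / confidence phrases from the default removal lexicons
#' are interleaved; they come from an independent random stream, so the
#' concept content of a seeded run is unchanged by toggling `filler` — and
#' cleaning must remove them completely.
#'
#' @param n_participants number of describers (positive).
#' @param n_subclips subclips per stimulus (positive).
#' @param core_concepts_per_subclip concepts planted per subclip.
#' @param share_prob probability a participant mentions a core concept.
#' @param filler add removable filler phrases.
#' @param seed integer seed.
#' @param stimulus stimulus label.
#' @return a `description_corpus`.
#' @export
simulate_descriptions <- function(n_participants, n_subclips,
                                  core_concepts_per_subclip,
                                  share_prob, filler = FALSE, seed = 1L,
                                  stimulus = "stim") {
  stopifnot(n_participants >= 1, n_subclips >= 1,
            core_concepts_per_subclip >= 1,
            share_prob >= 0, share_prob <= 1)
  vocab <- cu_vocabulary()
  if (core_concepts_per_subclip > length(vocab)) {
    stop("core_concepts_per_subclip exceeds the vocabulary size (",
         length(vocab), ")")
  }
  fill_phrases <- unlist(default_filler_lexicons(), use.names = FALSE)
  parts <- sprintf("d%02d", seq_len(n_participants))

  set.seed(stream_seed(seed, "concept-assignment", stimulus))
  concepts <- lapply(seq_len(n_subclips), function(sc) {
    sample(names(vocab), core_concepts_per_subclip)
  })

  rows <- list()
  for (sc in seq_len(n_subclips)) {
    for (p in parts) {
      set.seed(stream_seed(seed, "mentions", stimulus, sc, p))
      mentioned <- concepts[[sc]][stats::runif(core_concepts_per_subclip) < share_prob]
      words <- vapply(mentioned, function(cn) {
        forms <- vocab[[cn]]
        forms[sample.int(length(forms), 1)]
      }, character(1))
      if (length(words)) words <- sample(words)  # shuffle word order
      if (filler) {
        set.seed(stream_seed(seed, "filler", stimulus, sc, p))
        n_fill <- 1 + stats::rpois(1, 1)
        fills <- sample(fill_phrases, min(n_fill, length(fill_phrases)))
        pos <- sample(length(words) + 1, length(fills), replace = TRUE)
        merged <- character(0)
        for (slot in seq_len(length(words) + 1)) {
          merged <- c(merged, fills[pos == slot])
          if (slot <= length(words)) merged <- c(merged, words[slot])
        }
        words <- merged
      }
      rows[[length(rows) + 1L]] <- data.frame(
        stimulus = stimulus, subclip = sc, participant = p,
        text = paste(words, collapse = " "), stringsAsFactors = FALSE)
    }
  }
  out <- description_corpus(do.call(rbind, rows))
  attr(out, "core_concepts") <- concepts
  out
}

#' Simulate a description corpus for a whole design
#'
#' One [simulate_descriptions()] call per condition, with the number of
#' subclips derived from the stimulus duration (~30 s subclips) and the
#' planted semantic richness depending on condition type: meaningful
#' stimuli (`+M/+L`, `+M/-L`) carry many core concepts per subclip,
#' non-meaningful (`-M/-L`) few — mirroring the expectation that
#' descriptions of a flute piece or a kaleidoscope name far fewer concepts
#' than descriptions of a narrative.
#'
#' @param design a `sim_design`.
#' @param n_participants describers per stimulus (default 20).
#' @param concepts_meaningful,concepts_nonmeaningful core concepts per
#'   subclip by condition type.
#' @param share_prob probability of mentioning a core concept.
#' @param filler add removable filler phrases.
#' @param seed integer seed (defaults to the design's).
#' @return a `description_corpus` covering every condition.
#' @export
simulate_corpus <- function(design, n_participants = 20,
                            concepts_meaningful = 12,
                            concepts_nonmeaningful = 3,
                            share_prob = 0.5, filler = TRUE,
                            seed = design$seed) {
  stopifnot(inherits(design, "sim_design"))
  pieces <- lapply(seq_len(nrow(design$conditions)), function(ci) {
    cond <- design$conditions$name[ci]
    n_sub <- max(2, round((design$conditions$duration_s[ci] - 32) / 30))
    k <- if (design$conditions$condition_type[ci] == "-M/-L") {
      concepts_nonmeaningful
    } else {
      concepts_meaningful
    }
    simulate_descriptions(n_participants, n_sub, k, share_prob,
                          filler = filler, seed = seed, stimulus = cond)
  })
  description_corpus(do.call(rbind, pieces))
}
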