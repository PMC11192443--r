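test_that("filler phrases are stripped case-insensitively and whitespace normalized", {
  expect_equal(clean_description("I think the bird flies"), "the bird flies")
  expect_equal(clean_description("no filler here at all"), "no filler here at all")
  expect_equal(clean_description("I think maybe it seems like"), "")
  expect_equal(clean_description("IN THIS CLIP a dog runs"), "a dog runs")
  # phrase matching respects word boundaries: "thinking" is not "think"
  expect_equal(clean_description("maybelline maybe"), "maybelline")
})

test_that("lemma extraction lowercases, strips stop words, merges proper nouns", {
  expect_equal(extract_lemmas("The birds were flying"), c("bird", "fly"))
  expect_equal(extract_lemmas("Mr. Bean sat", proper_noun_merges = "Mr. Bean"),
               c("Mr_Bean", "sit"))
  expect_equal(extract_lemmas(""), character(0))
  expect_equal(extract_lemmas("the of and was"), character(0))
  expect_equal(extract_lemmas("Elvis Presley sang songs",
                              proper_noun_merges = "Elvis Presley"),
               c("Elvis_Presley", "sing", "song"))
  # inflection coverage used by the generator's vocabulary
  vocab <- natisc:::cu_vocabulary()
  for (lemma in names(vocab)) {
    for (form in vocab[[lemma]]) {
      expect_equal(natisc:::lemmatize_word(form), lemma,
                   label = sprintf("lemmatize(%s)", form))
    }
  }
})

test_that("hand-worked toy corpus reproduces the hand-computed CU quantities", {
  corpus <- read_corpus(system.file("extdata", "toy_corpus.json",
                                    package = "natisc"))
  cc <- count_cus(corpus, "toy")
  # lemmas used by >= 3 participants: ball, cat, dog, eat, sit
  expect_equal(cc$included_lexicon, c("ball", "cat", "dog", "eat", "sit"))
  tab <- cc$table[order(cc$table$subclip, cc$table$participant), ]
  expect_equal(tab$cu_count, c(3L, 2L, 2L, 4L, 4L, 4L))

  sp <- shared_cu_pairwise(corpus, "toy")
  expect_equal(sp$per_subclip$mean_shared, c(2, 4))
  expect_equal(sp$clip_mean, 3)
})

test_that("the repeated-word rule and min-participant filter act jointly", {
  corpus <- description_corpus(data.frame(
    stimulus = "s", subclip = 1,
    participant = c("a", "b", "c"),
    text = c("bird bird", "bird bird", "bird bird"),
    stringsAsFactors = FALSE))
  cc <- count_cus(corpus, "s")
  expect_equal(cc$included_lexicon, "bird")
  expect_equal(cc$table$cu_count, c(2L, 2L, 2L))

  # a lemma used by two participants only is excluded
  corpus2 <- description_corpus(data.frame(
    stimulus = "s", subclip = 1,
    participant = c("a", "b", "c"),
    text = c("bird cat", "bird cat", "bird"),
    stringsAsFactors = FALSE))
  cc2 <- count_cus(corpus2, "s")
  expect_equal(cc2$included_lexicon, "bird")
  expect_equal(cc2$table$cu_count, c(1L, 1L, 1L))
  # min_participants = 1 admits every observed lemma
  cc1 <- count_cus(corpus2, "s", min_participants = 1)
  expect_setequal(cc1$included_lexicon, c("bird", "cat"))
  # raising the filter never increases counts
  expect_true(all(cc2$table$cu_count <= cc1$table$cu_count))
  empty <- count_cus(corpus2, "unseen")
  expect_equal(nrow(empty$table), 0)
})

test_that("cu_count is invariant to word order within a response", {
  base <- description_corpus(data.frame(
    stimulus = "s", subclip = 1, participant = c("a", "b", "c"),
    text = c("dog ball cat", "cat dog ball", "ball cat dog"),
    stringsAsFactors = FALSE))
  cc <- count_cus(base, "s")
  expect_equal(cc$table$cu_count, c(3L, 3L, 3L))
})

test_that("pairwise shared counts are set-valued and bounded by each pair's types", {
  corpus <- description_corpus(data.frame(
    stimulus = "s", subclip = rep(1:2, each = 3),
    participant = rep(c("a", "b", "c"), 2),
    text = c("dog cat bird", "dog cat bird", "dog cat bird",
             "dog dog", "cat", "dog cat"),
    stringsAsFactors = FALSE))
  sp <- shared_cu_pairwise(corpus, "s", min_participants = 2)
  # subclip 1: all share {dog, cat, bird} -> 3 per pair
  expect_equal(sp$per_subclip$mean_shared[1], 3)
  # subclip 2 (lexicon from whole stimulus): sets {dog},{cat},{dog,cat}
  # pairs: (a,b)=0, (a,c)=1, (b,c)=1 -> mean 2/3; repeats don't inflate types
  expect_equal(sp$per_subclip$mean_shared[2], 2 / 3)
  expect_error(shared_cu_pairwise(description_corpus(data.frame(
    stimulus = "s", subclip = 1, participant = "a", text = "dog",
    stringsAsFactors = FALSE)), "s"), ">= 2")

  for (seed in 1:20) {
    corp <- simulate_descriptions(4, 2, 5, 0.7, seed = seed)
    tok <- natisc:::tokenized_stimulus(corp, "stim",
                                       default_filler_lexicons(),
                                       default_stopwords(), character(0))
    lex <- natisc:::inclusion_lexicon(tok, 3)
    sp <- shared_cu_pairwise(corp, "stim")
    for (sc in sp$per_subclip$subclip) {
      rows <- tok[tok$subclip == sc, ]
      sets <- lapply(rows$tokens, function(tk) unique(tk[tk %in% lex]))
      expect_equal(sp$per_subclip$mean_shared[sp$per_subclip$subclip == sc],
                   oracle_shared_pairwise(sets))
    }
  }
})

test_that("CU condition model finds poorer vocabularies in -M stimuli", {
  d <- make_design("small", seed = 10)
  corp <- simulate_corpus(d, n_participants = 8, concepts_meaningful = 10,
                          concepts_nonmeaningful = 2, share_prob = 0.8,
                          filler = FALSE, seed = 10)
  cu_tab <- do.call(rbind, lapply(unique(corp$stimulus), function(s) {
    count_cus(corp, s)$table
  }))
  fit <- cu_condition_model(cu_tab, d$conditions)
  b <- fit$terms
  expect_lt(b$beta[b$name == "condition_type-M/-L"], 0)
  # single stimulus per type: condition random intercept flagged singular
  expect_true(is.logical(fit$singular))
})

test_that("CU-ISC association computes scoped correlations and model comparisons", {
  d <- make_design("small", seed = 20)
  it <- compute_isc_table(preprocess_timecourses(simulate_timecourses(d)))
  cu_vals <- data.frame(stimulus = d$conditions$name, cu = c(8, 7.5, 2))
  res <- cu_isc_association(cu_vals, it, metric = "mean_cu",
                            scope = d$conditions$name)
  expect_equal(res$n_stimuli, 3)
  expect_true(abs(res$pearson_r) <= 1)
  expect_true(all(c("lrt", "delta_aic") %in% names(res$model_comparisons)))
  expect_error(cu_isc_association(cu_vals, it, scope = d$conditions$name[1:2]),
               "< 3 stimuli")
  const <- data.frame(stimulus = d$conditions$name, cu = c(5, 5, 5))
  expect_error(cu_isc_association(const, it, scope = d$conditions$name),
               "constant")
  expect_error(cu_isc_association(cu_vals, it), "scope")
})

test_that("corpus JSON round-trips", {
  corp <- simulate_descriptions(3, 2, 4, 0.5, filler = TRUE, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_corpus(corp, path)
  back <- read_corpus(path)
  m <- merge(as.data.frame(corp)[, 1:4], back,
             by = c("stimulus", "subclip", "participant"))
  expect_equal(m$text.x, m$text.y)
})
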