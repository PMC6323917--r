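# Name recognition, sentence filtering, species/family assignment,
# scoring and ranking.

test_that("sentence splitting handles boundaries, abbreviations, decimals", {
  expect_equal(split_sentences("MiR-21 is overexpressed. It targets PTEN."),
               c("MiR-21 is overexpressed.", "It targets PTEN."))
  one <- split_sentences(
    "As shown in Fig. 2, expression rose 3.5-fold at pH 7.4 levels.")
  expect_length(one, 1L)
  expect_equal(length(split_sentences("Is it real? Yes! It is.")), 3L)
  # name followed by a period at the end of a line still terminates
  expect_length(split_sentences("The gene is miR-21. Expression rose."),
                2L)
  expect_equal(split_sentences(""), character(0))
})

test_that("synthetic paragraphs with known boundaries are split exactly", {
  set.seed(202)
  words <- c("expression", "rose", "in", "muscle", "tissue", "after",
             "induction", "the", "level", "was", "stable", "mir-21",
             "let-7b", "cells", "showed", "marked", "growth")
  for (rep_i in 1:50) {
    n <- sample(2:8, 1L)
    sents <- vapply(seq_len(n), function(i) {
      w <- sample(words, sample(4:12, 1L), replace = TRUE)
      w[1] <- paste0(toupper(substr(w[1], 1, 1)), substr(w[1], 2, 99))
      paste0(paste(w, collapse = " "), sample(c(".", "?", "!"), 1L))
    }, "")
    expect_equal(split_sentences(paste(sents, collapse = " ")), sents)
  }
})

test_that("every name style printed in real top-article tables is found", {
  names_in_tables <- c("MicroRNA-21", "miR-21", "Mir-21", "miRNA-21",
                       "microRNA 21", "let-7a-1", "let-7a-2", "let-7a-3",
                       "mir-214", "mir-221", "mir-222", "mir-328",
                       "mir-451a", "mir-451b", "mir-181b-1", "mir-181b-2",
                       "mir-29b-1", "mir-29b-2", "mir-34a", "mir-9718",
                       "mir-16-1", "mir-16-2", "mir-29a", "let-7",
                       "mir-27b", "mir-130a", "mir-126", "mir-296",
                       "mir-378", "mir-19a", "mir-23b", "mir-26a-1",
                       "mir-26a-2", "mir-122")
  for (nm in names_in_tables) {
    found <- find_mirna_names(paste0("The microRNA gene ", nm,
                                     " was strongly induced."))
    expect_equal(nrow(found), 1L, info = nm)
    expect_equal(found$surface, nm, info = nm)
  }
  expect_equal(find_mirna_names("MicroRNA-21 governs TORC1 activation"
                                )$normalized, "mir-21")
})

test_that("recognition normalises prefixes, arms and typography", {
  got <- find_mirna_names("let-7a and miR-214 cooperate")
  expect_equal(got$normalized, c("let-7a", "mir-214"))
  # no gene number, no mention
  expect_equal(nrow(find_mirna_names("2 miR and 3 microRNAs were studied")),
               0L)
  # arm suffix split off; unicode hyphen and spacing variants normalise
  arm <- find_mirna_names("hsa-miR-499a-5p and miR‑21 and miR 133b")
  expect_equal(arm$normalized, c("mir-499a", "mir-21", "mir-133b"))
  expect_equal(arm$arm, c("5p", "", ""))
  # spans index into the original sentence text
  s <- "We studied miR-21 carefully"
  m <- find_mirna_names(s)
  expect_equal(substr(s, m$start, m$end), m$surface)
  # leftmost-longest: the full suffixed form wins
  long <- find_mirna_names("mir-133a-2 was deleted")
  expect_equal(long$surface, "mir-133a-2")
})

test_that("table-like sentences are eliminated at the printed thresholds", {
  many <- paste(sprintf("miR-%d", 1:26), collapse = ", ")
  some <- paste(sprintf("miR-%d", 1:25), collapse = ", ")
  long200 <- paste(c("miR-21 studied", rep("word", 198)), collapse = " ")
  long201 <- paste(c("miR-21 studied", rep("word", 199)), collapse = " ")
  res <- filter_sentences(c(many, some, long200, long201))
  expect_equal(res$eliminated, c(many, long201))
  expect_equal(res$kept, c(some, long200))
  # repeated mentions of one name count once
  rep_one <- paste(rep("miR-21", 30), collapse = " and ")
  expect_length(filter_sentences(rep_one)$kept, 1L)
  # partition + order preservation + idempotence
  set.seed(5)
  corpus <- sample(c(many, some, long200, long201, rep_one), 20L,
                   replace = TRUE)
  res2 <- filter_sentences(corpus)
  expect_length(c(res2$kept, res2$eliminated), length(corpus))
  expect_equal(corpus[corpus %in% res2$kept], res2$kept[order(seq_along(res2$kept))])
  expect_equal(filter_sentences(res2$kept)$kept, res2$kept)
})

test_that("species assignment follows the exclusion and fallback rules", {
  lex <- read_species_lexicon(system.file("extdata", "species_lexicon.tsv",
                                          package = "mirqc"))
  # names a subset -> only the named species
  expect_equal(assign_species("This was seen in mouse liver",
                              c("hsa", "mmu"), lex), "mmu")
  expect_equal(assign_species("Seen in human and mouse",
                              c("hsa", "mmu"), lex), c("hsa", "mmu"))
  # names none -> all article species
  expect_equal(assign_species("Expression was high in muscle",
                              c("hsa", "mmu"), lex), c("hsa", "mmu"))
  # names only a species absent from the article -> all article species
  expect_equal(assign_species("As reported for zebrafish",
                              c("hsa", "mmu"), lex), c("hsa", "mmu"))
  expect_equal(assign_species("Confirmed in H. sapiens samples",
                              c("hsa"), lex), "hsa")
  # matches are word-bounded: 'humans' is an alias, 'humanized' is not
  expect_equal(assign_species("a humanized antibody construct",
                              c("hsa", "mmu"), lex), c("hsa", "mmu"))
  expect_warning(out <- assign_species("anything", character(0), lex),
                 "no associated species")
  expect_length(out, 0L)
})

test_that("family expansion is exact against the packaged table", {
  tab <- read_family_table(system.file("extdata", "families_synthetic.tsv",
                                       package = "mirqc"))
  # undisambiguated family name -> all 11 human let-7 members
  expect_length(expand_family("let-7", "hsa", tab), 11L)
  # fully specified gene -> exactly one
  expect_equal(expand_family("mir-133a-2", "hsa", tab), "SYNMI00014")
  # lettered group -> all genes of that letter group
  expect_length(expand_family("let-7a", "hsa", tab), 3L)
  expect_length(expand_family("let-7b", "hsa", tab), 1L)
  # absent name -> empty (recorded as unmatched upstream)
  expect_length(expand_family("mir-99999", "hsa", tab), 0L)
  # brute-force cross-check: every expansion is exactly the table rows
  # whose gene name equals, letter-groups or families the query
  for (q in c("let-7", "let-7a", "mir-133", "mir-133a", "mir-29b",
              "mir-21", "bantam")) {
    for (sp in unique(tab$species_code)) {
      got <- sort(expand_family(q, sp, tab))
      rows <- tab[tab$species_code == sp, ]
      want <- if (q %in% rows$gene_name) {
        rows$gene_accession[rows$gene_name == q]
      } else if (any(grepl(paste0("^", q, "-[0-9]+$"), rows$gene_name))) {
        rows$gene_accession[grepl(paste0("^", q, "-[0-9]+$"),
                                  rows$gene_name)]
      } else {
        rows$gene_accession[rows$family_key == q]
      }
      expect_equal(got, sort(want), info = paste(q, sp))
    }
  }
})

test_that("sentence scores count stem hits and add over concatenation", {
  # recounted by hand against the shipped lexicons:
  # targets (target+), regulates (regulat+), proliferation (proliferat+)
  expect_equal(score_sentence("miR-21 targets PTEN and regulates proliferation"),
               3L)
  expect_equal(score_sentence("The moon is far away"), 0L)
  # negative stems: measured (measur+), normalized (normaliz+), qPCR
  expect_equal(score_sentence("Values were measured and normalized by qPCR"),
               -3L)
  s1 <- "miR-21 targets PTEN"
  s2 <- "levels were measured by qPCR"
  expect_equal(score_sentence(paste(s1, s2)),
               score_sentence(s1) + score_sentence(s2))
})

test_that("article ranking equals a brute-force re-aggregation", {
  set.seed(61)
  for (rep_i in 1:10) {
    scored <- data.frame(
      gene_accession = sample(c("G1", "G2"), 40L, replace = TRUE),
      article_id = sample(sprintf("A%02d", 1:6), 40L, replace = TRUE),
      score = sample(-3:5, 40L, replace = TRUE),
      stringsAsFactors = FALSE)
    expect_equal(rank_articles(scored), oracle_rank(scored))
  }
  # tie-breaking: equal sums -> more sentences first, then id
  tie <- data.frame(gene_accession = "G",
                    article_id = c("B", "B", "B", "A", "C", "C"),
                    score = c(2L, 2L, 2L, 6L, 3L, 3L),
                    stringsAsFactors = FALSE)
  r <- rank_articles(tie)
  expect_equal(r$article_id, c("B", "C", "A"))
})

test_that("the corpus pipeline is deterministic and assigns families", {
  lex <- read_species_lexicon(system.file("extdata", "species_lexicon.tsv",
                                          package = "mirqc"))
  tab <- read_family_table(system.file("extdata", "families_synthetic.tsv",
                                       package = "mirqc"))
  corpus <- read_corpus_jsonl(system.file("extdata",
                                          "corpus_example.jsonl",
                                          package = "mirqc"))
  res1 <- mine_corpus(corpus, lex, tab)
  res2 <- mine_corpus(corpus, lex, tab)
  expect_identical(res1, res2)
  # the mouse-only sentence reaches mouse let-7a genes, not human ones
  mouse_rows <- res1$sentences[grepl("In mouse", res1$sentences$text), ]
  expect_setequal(unique(mouse_rows$species_code), "mmu")
  expect_setequal(mouse_rows$gene_accession,
                  c("SYNMI00101", "SYNMI00102"))
  # hsa-mir-21 sentences all land on the single human mir-21 gene
  m21 <- res1$sentences[res1$sentences$gene_accession == "SYNMI00012", ]
  expect_gte(nrow(m21), 2L)
  expect_true(all(m21$article_id == "900001"))
  # ranking is computed per gene over article score sums
  expect_true(all(res1$ranking$n_sentences >= 1L))
})
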