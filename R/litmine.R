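# Literature mining: microRNA gene-name recognition in article text,
# table-like sentence filtering, species and gene-family assignment,
# functional keyword scoring and article ranking.

# Unicode hyphen variants seen in real typography, mapped to '-' (all are
# single characters, so character offsets are preserved).
normalize_hyphens <- function(x) {
  gsub("[‐‑‒–—−­]", "-", x,
       perl = TRUE)
}

DEFAULT_EXCEPTIONAL_NAMES <- c("let-7", "lin-4", "bantam", "lsy-6",
                               "iab-4", "iab-8")

#' Split prose into sentences
#'
#' Deterministic rule-based segmentation: a sentence ends at `.`, `!` or
#' `?` followed by whitespace and a capital letter, digit or opening
#' quote/parenthesis (or end of text). Common abbreviations (`Fig.`,
#' `et al.`, `e.g.`, `i.e.`, `vs.`, initials, ...) and decimal numbers
#' are protected. The splitter is pluggable: any function mapping text to
#' a character vector can replace it downstream.
#'
#' @param section_text Plain prose (one section's text).
#' @param abbreviations Abbreviations (without the dot) never treated as
#'   sentence ends.
#' @return Character vector of sentences, trimmed, empty ones removed.
#' @examples
#' split_sentences("MiR-21 is overexpressed. It targets PTEN.")
#' @export
split_sentences <- function(section_text,
                            abbreviations = c("fig", "figs", "eq", "eqs",
                                              "ref", "refs", "e.g", "i.e",
                                              "vs", "cf", "ca", "al",
                                              "dr", "prof", "st", "no",
                                              "approx")) {
  text <- gsub("[\r\n]+", " ", section_text)
  n <- nchar(text)
  if (n == 0L) return(character(0))
  cand <- gregexpr("[.!?]+", text)[[1L]]
  if (cand[1L] == -1L) {
    out <- trimws(text)
    return(out[nzchar(out)])
  }
  lens <- attr(cand, "match.length")
  bounds <- integer(0)
  for (k in seq_along(cand)) {
    p <- cand[k]; last <- p + lens[k] - 1L
    after <- substr(text, last + 1L, n)
    # must be followed by whitespace + sentence opener, or end of text
    if (!(grepl("^\\s*$", after) ||
          grepl("^\\s+[\"'(“]?[A-Z0-9]", after))) next
    mark <- substr(text, p, p)
    if (mark == ".") {
      before <- substr(text, max(1L, p - 12L), p - 1L)
      word <- tolower(sub(".*?([A-Za-z.]+)$", "\\1", before))
      word <- sub("\\.$", "", word)
      if (word %in% abbreviations) next
      # single capital initial, as in author names ("J. Smith")
      if (grepl("(^|\\s)[A-Z]$", substr(text, max(1L, p - 2L), p - 1L)))
        next
    }
    bounds <- c(bounds, last)
  }
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  out <- trimws(substring(text, starts[seq_along(ends)], ends))
  out[nzchar(out)]
}

mirna_name_regex <- function(exceptional = DEFAULT_EXCEPTIONAL_NAMES) {
  suffix <- "(?:[a-z](?![a-z]))?(?:-\\d+)?(?:-[35]p)?"
  numbered <- paste0("(?:micro[ -]?rna|mirna|mir)[ -]?\\d+", suffix)
  exc <- vapply(exceptional, function(nm) {
    core <- gsub("-", "[ -]", nm, fixed = TRUE)
    if (grepl("^let-7", nm)) paste0(core, suffix) else
      paste0(core, "(?:-[35]p)?")
  }, "")
  paste0("(?i)\\b(?:", paste(c(numbered, exc), collapse = "|"),
         ")(?![a-z0-9])")
}

normalize_mirna_name <- function(surface) {
  s <- tolower(normalize_hyphens(surface))
  s <- gsub("[ ]", "-", s)
  s <- sub("^micro-?rna-?", "mir-", s)
  s <- sub("^mirna-?", "mir-", s)
  s <- sub("^mir-?(?=\\d)", "mir-", s, perl = TRUE)
  arm <- ""
  if (grepl("-[35]p$", s)) {
    arm <- sub("^.*-([35]p)$", "\\1", s)
    s <- sub("-[35]p$", "", s)
  }
  list(normalized = s, arm = arm)
}

#' Recognise microRNA gene names in a sentence
#'
#' Case-insensitive matching of the standard name patterns
#' (`miR-#`, `miRNA-#`, `microRNA-#`, with optional letter, paralogue
#' number and `-5p`/`-3p` arm suffixes, hyphen or space separators and
#' unicode hyphen variants) plus a configurable lexicon of exceptional
#' names (`let-7`, `lin-4`, `bantam`, `lsy-6`, `iab-4`, `iab-8`).
#' Overlapping candidates resolve leftmost-longest. Names are normalised
#' to a canonical lower-case `mir-` form with the arm suffix split into
#' its own field.
#'
#' @param sentence_text The sentence to scan.
#' @param exceptional_names Exceptional (non-numbered) name lexicon.
#' @return A data.frame with one row per mention: `surface`,
#'   `normalized`, `arm`, `start`, `end` (character offsets, 1-based
#'   inclusive).
#' @examples
#' find_mirna_names("MicroRNA-21 governs TORC1 activation")$normalized
#' @export
find_mirna_names <- function(sentence_text,
                             exceptional_names = DEFAULT_EXCEPTIONAL_NAMES) {
  text <- normalize_hyphens(sentence_text)
  rx <- mirna_name_regex(exceptional_names)
  m <- gregexpr(rx, text, perl = TRUE)[[1L]]
  empty <- data.frame(surface = character(), normalized = character(),
                      arm = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (m[1L] == -1L) return(empty)
  lens <- attr(m, "match.length")
  surfaces <- substring(sentence_text, m, m + lens - 1L)
  norm <- lapply(substring(text, m, m + lens - 1L), normalize_mirna_name)
  data.frame(surface = surfaces,
             normalized = vapply(norm, `[[`, "", "normalized"),
             arm = vapply(norm, `[[`, "", "arm"),
             start = as.integer(m), end = as.integer(m + lens - 1L),
             stringsAsFactors = FALSE)
}

#' Count whitespace-delimited words
#'
#' @param text Input string.
#' @return Integer token count.
#' @export
count_words <- function(text) {
  toks <- strsplit(trimws(text), "\\s+")[[1L]]
  sum(nzchar(toks))
}

#' Filter out table-like sentences
#'
#' Separates real prose from extracts of tables and reference lists: a
#' sentence is eliminated iff it contains strictly more than `max_names`
#' distinct normalised microRNA names or strictly more than `max_words`
#' whitespace words. Exactly 25 names or 200 words passes. Distinct
#' names are counted before family expansion. The operation partitions
#' its input and preserves order, so it is idempotent on the kept set.
#'
#' @param sentences Character vector of sentences.
#' @param max_names Maximum distinct names (default 25).
#' @param max_words Maximum words (default 200).
#' @param exceptional_names Passed to [find_mirna_names()].
#' @return List with character vectors `kept` and `eliminated`.
#' @export
filter_sentences <- function(sentences, max_names = 25L, max_words = 200L,
                             exceptional_names = DEFAULT_EXCEPTIONAL_NAMES) {
  if (length(sentences) == 0L) {
    return(list(kept = character(0), eliminated = character(0)))
  }
  drop <- vapply(sentences, function(s) {
    n_names <- length(unique(
      find_mirna_names(s, exceptional_names)$normalized))
    n_names > max_names || count_words(s) > max_words
  }, NA, USE.NAMES = FALSE)
  list(kept = sentences[!drop], eliminated = sentences[drop])
}

#' Read a species lexicon
#'
#' TSV with header columns `species_code` and `alias` (one alias per
#' row: scientific name, common name or abbreviation such as
#' `H. sapiens`).
#'
#' @param path Path to the lexicon TSV.
#' @return Named list mapping species code to a character vector of
#'   aliases.
#' @export
read_species_lexicon <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species_code", "alias") %in% names(df)))
  split(df$alias, df$species_code)
}

#' Assign a sentence to species
#'
#' Species names are a major source of mis-assignment when a paper
#' covers several organisms. Rule: if the sentence names some of the
#' article's species, the sentence is assigned only to those named (a
#' sentence naming other species but not a given one excludes that one);
#' if it names none of the article's species -- including when it only
#' names species absent from the article's list -- it is assigned to all
#' of the article's species, since the mention cannot be attributed.
#'
#' @param sentence_text The sentence.
#' @param article_species Character vector of species codes attached to
#'   the article.
#' @param species_lexicon Named list from [read_species_lexicon()].
#' @return Character vector of assigned species codes (empty, with a
#'   warning, when the article has no species).
#' @export
assign_species <- function(sentence_text, article_species,
                           species_lexicon) {
  if (length(article_species) == 0L) {
    warning("article has no associated species; nothing to assign",
            call. = FALSE)
    return(character(0))
  }
  regex_escape <- function(x) gsub("([^A-Za-z0-9 ])", "\\\\\\1", x)
  named <- vapply(article_species, function(code) {
    aliases <- species_lexicon[[code]]
    if (is.null(aliases)) return(FALSE)
    any(vapply(aliases, function(a) {
      rx <- paste0("(?<![A-Za-z])", regex_escape(a), "(?![A-Za-z])")
      grepl(rx, sentence_text, perl = TRUE, ignore.case = TRUE)
    }, NA))
  }, NA)
  if (any(named)) article_species[named] else article_species
}

#' Read a microRNA family table
#'
#' TSV with header columns `species_code`, `family_key`, `gene_name`,
#' `gene_accession`; one row per gene. `(species_code, family_key,
#' gene_name)` must be unique.
#'
#' @param path Path to the family table.
#' @return The table as a data.frame.
#' @export
read_family_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("species_code", "family_key", "gene_name", "gene_accession")
  stopifnot(all(needed %in% names(df)))
  key <- paste(df$species_code, df$family_key, df$gene_name)
  if (anyDuplicated(key)) {
    stop("duplicate (species, family, gene) rows in family table",
         call. = FALSE)
  }
  df
}

#' Expand a mention to gene family members
#'
#' A fully specified gene name (e.g. `mir-133a-2`) expands to exactly
#' that gene; a lettered group name (`let-7a`) expands to every gene of
#' that letter group (`let-7a-1` ... `let-7a-3`); an undisambiguated
#' family name (`let-7`, `mir-133`) expands to every member whose family
#' key matches. A name absent from the table for that species yields an
#' empty vector (recorded as unmatched by the pipeline).
#'
#' @param normalized_name Normalised mention (arm suffix stripped).
#' @param species_code Species to expand within.
#' @param family_table Data.frame from [read_family_table()].
#' @return Character vector of gene accessions.
#' @examples
#' tab <- read_family_table(system.file("extdata",
#'   "families_synthetic.tsv", package = "mirqc"))
#' expand_family("let-7", "hsa", tab)
#' @export
expand_family <- function(normalized_name, species_code, family_table) {
  sp <- family_table[family_table$species_code == species_code, ,
                     drop = FALSE]
  exact <- sp$gene_name == normalized_name
  if (any(exact)) return(sp$gene_accession[exact])
  group <- grepl(paste0("^", gsub("([.])", "\\\\\\1", normalized_name),
                        "-[0-9]+$"), sp$gene_name)
  if (any(group)) return(sp$gene_accession[group])
  fam <- sp$family_key == normalized_name
  sp$gene_accession[fam]
}

read_stem_list <- function(path) {
  stems <- trimws(readLines(path))
  stems <- stems[nzchar(stems) & !startsWith(stems, "#")]
  tolower(stems)
}

#' Default functional keyword lexicons
#'
#' Positive stems describe microRNA function (expression, targeting,
#' regulation, inhibition and curated extensions); negative stems flag
#' measurements, calculations and experimental procedure. Both ship as
#' editable plain-text stem lists under `inst/extdata` and are matched
#' case-insensitively at word-prefix boundaries, so `regulat` matches
#' `regulates` and `regulation`.
#'
#' @param which `"positive"` or `"negative"`.
#' @return Character vector of stems.
#' @export
default_keywords <- function(which = c("positive", "negative")) {
  which <- match.arg(which)
  read_stem_list(system.file("extdata",
                             paste0(which, "_keywords.txt"),
                             package = "mirqc", mustWork = TRUE))
}

tokenize_words <- function(text) {
  toks <- strsplit(trimws(text), "\\s+")[[1L]]
  toks <- gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", toks)
  tolower(toks[nzchar(toks)])
}

count_stem_hits <- function(tokens, stems) {
  if (length(tokens) == 0L || length(stems) == 0L) return(0L)
  sum(vapply(tokens, function(tok) {
    any(startsWith(tok, stems))
  }, NA, USE.NAMES = FALSE))
}

#' Score a sentence for functional content
#'
#' `score = (# tokens matching a positive stem) - (# tokens matching a
#' negative stem)`; every hit counts, so the score is additive over
#' concatenated sentences. Stems match case-insensitively as token
#' prefixes.
#'
#' @param sentence_text The sentence.
#' @param positive_lexicon,negative_lexicon Character vectors of stems;
#'   default to the shipped lexicons.
#' @return Integer score.
#' @examples
#' score_sentence("miR-21 targets PTEN and regulates proliferation")
#' @export
score_sentence <- function(sentence_text,
                           positive_lexicon = default_keywords("positive"),
                           negative_lexicon = default_keywords("negative")) {
  toks <- tokenize_words(sentence_text)
  count_stem_hits(toks, tolower(positive_lexicon)) -
    count_stem_hits(toks, tolower(negative_lexicon))
}

#' Rank articles for a gene by summed sentence score
#'
#' Per (gene, article) the score is the sum of its sentence scores;
#' articles are ordered by descending summed score, ties broken by
#' descending sentence count then ascending article id (deterministic).
#'
#' @param scored A data.frame with columns `gene_accession`,
#'   `article_id`, `score` (one row per retained sentence assignment).
#' @return A data.frame `gene_accession`, `article_id`, `total_score`,
#'   `n_sentences`, ordered within each gene.
#' @export
rank_articles <- function(scored) {
  if (nrow(scored) == 0L) {
    return(data.frame(gene_accession = character(),
                      article_id = character(), total_score = integer(),
                      n_sentences = integer(), stringsAsFactors = FALSE))
  }
  agg <- aggregate(score ~ gene_accession + article_id, scored,
                   function(x) c(sum(x), length(x)))
  out <- data.frame(gene_accession = agg$gene_accession,
                    article_id = as.character(agg$article_id),
                    total_score = agg$score[, 1L],
                    n_sentences = agg$score[, 2L],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_accession, -out$total_score,
                   -out$n_sentences, out$article_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a JSON-lines article corpus
#'
#' One JSON object per line: `{"id": ..., "sections": {"abstract": ...,
#' "introduction": ..., "results": ..., "discussion": ...},
#' "species": [...]}`. Missing sections are treated as empty.
#'
#' @param path Path to the `.jsonl` file.
#' @return List of articles (lists with `id`, `sections`, `species`).
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    if (is.null(obj$id) || is.null(obj$sections)) {
      stop("corpus record must have 'id' and 'sections'", call. = FALSE)
    }
    list(id = as.character(obj$id),
         sections = lapply(obj$sections, as.character),
         species = as.character(obj$species))
  })
}

ARTICLE_SECTIONS <- c("abstract", "introduction", "results", "discussion")

#' Run the literature-mining pipeline over a corpus
#'
#' For each article: extract the abstract, introduction, results and
#' discussion sections, split them into sentences, recognise microRNA
#' names, eliminate table-like sentences (>25 distinct names or >200
#' words), assign retained sentences to species, expand mentions to gene
#' family members in each assigned species, and score each sentence for
#' functional content.
#'
#' @param corpus List of articles, as from [read_corpus_jsonl()].
#' @param species_lexicon Named list from [read_species_lexicon()].
#' @param family_table Data.frame from [read_family_table()].
#' @param positive_lexicon,negative_lexicon Keyword stem vectors.
#' @param max_names,max_words Sentence-filter thresholds.
#' @param exceptional_names Exceptional-name lexicon for recognition.
#' @return List with `sentences` (data.frame: `gene_accession`,
#'   `species_code`, `article_id`, `score`, `text`), `ranking` (from
#'   [rank_articles()]), and `unmatched` (data.frame of normalised names
#'   that had no family-table entry for an assigned species).
#' @export
mine_corpus <- function(corpus, species_lexicon, family_table,
                        positive_lexicon = default_keywords("positive"),
                        negative_lexicon = default_keywords("negative"),
                        max_names = 25L, max_words = 200L,
                        exceptional_names = DEFAULT_EXCEPTIONAL_NAMES) {
  rows <- list()
  unmatched <- list()
  for (article in corpus) {
    texts <- unlist(lapply(ARTICLE_SECTIONS, function(sec) {
      txt <- article$sections[[sec]]
      if (is.null(txt) || !nzchar(txt)) character(0) else
        split_sentences(txt)
    }), use.names = FALSE)
    if (length(texts) == 0L) next
    with_names <- texts[vapply(texts, function(s) {
      nrow(find_mirna_names(s, exceptional_names)) > 0L
    }, NA, USE.NAMES = FALSE)]
    kept <- filter_sentences(with_names, max_names, max_words,
                             exceptional_names)$kept
    for (sentence in kept) {
      mentions <- find_mirna_names(sentence, exceptional_names)
      sp_codes <- assign_species(sentence, article$species,
                                 species_lexicon)
      s_score <- score_sentence(sentence, positive_lexicon,
                                negative_lexicon)
      for (nm in unique(mentions$normalized)) {
        for (sp in sp_codes) {
          genes <- expand_family(nm, sp, family_table)
          if (length(genes) == 0L) {
            unmatched[[length(unmatched) + 1L]] <-
              data.frame(normalized = nm, species_code = sp,
                         article_id = article$id,
                         stringsAsFactors = FALSE)
            next
          }
          for (g in genes) {
            rows[[length(rows) + 1L]] <-
              data.frame(gene_accession = g, species_code = sp,
                         article_id = article$id, score = s_score,
                         text = sentence, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  sentences <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(gene_accession = character(), species_code = character(),
               article_id = character(), score = integer(),
               text = character(), stringsAsFactors = FALSE)
  # one sentence assigned to a gene through several species still counts
  # once per (gene, article, sentence) for ranking
  dedup <- sentences[!duplicated(sentences[, c("gene_accession",
                                               "article_id", "text")]), ,
                     drop = FALSE]
  ranking <- rank_articles(dedup)
  unmatched <- if (length(unmatched) > 0L) {
    u <- do.call(rbind, unmatched)
    u[!duplicated(u), , drop = FALSE]
  } else {
    data.frame(normalized = character(), species_code = character(),
               article_id = character(), stringsAsFactors = FALSE)
  }
  rownames(sentences) <- NULL
  rownames(unmatched) <- NULL
  list(sentences = sentences, ranking = ranking, unmatched = unmatched)
}
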