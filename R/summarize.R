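# Word-cloud term frequencies over a gene's retained sentences.

#' Default stop lists
#'
#' `"english"` is the standard snowball English stop-word list;
#' `"curated"` removes common scientific terms that obscure functional
#' information (`expressed`, `cell`, `sequence`, `gene`, and curated
#' extensions). Both ship as editable plain-text files under
#' `inst/extdata`.
#'
#' @param which `"english"` or `"curated"`.
#' @return Character vector of lower-case terms.
#' @export
default_stoplist <- function(which = c("english", "curated")) {
  which <- match.arg(which)
  fname <- switch(which, english = "stopwords_english.txt",
                  curated = "stopwords_curated.txt")
  read_stem_list(system.file("extdata", fname, package = "mirqc",
                             mustWork = TRUE))
}

tokenize_terms <- function(text) {
  toks <- regmatches(tolower(text),
                     gregexpr("[[:alnum:]][[:alnum:]-]*", tolower(text)))[[1L]]
  gsub("^-+|-+$", "", toks)
}

#' Term frequencies for a gene's sentences
#'
#' Tokenises to lower-case alphanumeric-plus-hyphen tokens, then drops
#' tokens on either stop list, tokens with no letters (pure numbers) and
#' tokens shorter than 3 characters, and counts the rest. This frequency
#' table is the tested word-cloud contract; rendering is a separate,
#' optional step ([plot.term_frequency_table()]).
#'
#' @param sentences Character vector of (already filtered and assigned)
#'   sentences.
#' @param english_stopwords,curated_stoplist Stop lists; default to the
#'   shipped ones.
#' @param gene_accession Optional accession recorded on the table.
#' @return Object of class `term_frequency_table`: fields
#'   `gene_accession`, `terms` (named integer vector, counts >= 1,
#'   sorted by decreasing count then term) and `n_sentences`.
#' @examples
#' tf <- term_frequencies(c("the gene regulates apoptosis"))
#' tf$terms
#' @export
term_frequencies <- function(sentences,
                             english_stopwords = default_stoplist("english"),
                             curated_stoplist = default_stoplist("curated"),
                             gene_accession = NA_character_) {
  stop_all <- unique(c(tolower(english_stopwords),
                       tolower(curated_stoplist)))
  toks <- unlist(lapply(sentences, tokenize_terms), use.names = FALSE)
  toks <- toks[nchar(toks) >= 3L]
  toks <- toks[grepl("[a-z]", toks)]
  toks <- toks[!toks %in% stop_all]
  counts <- if (length(toks) == 0L) integer(0) else {
    tab <- table(toks)
    setNames(as.integer(tab), names(tab))
  }
  if (length(counts) > 0L) {
    counts <- counts[order(-counts, names(counts))]
  }
  base::structure(
    list(gene_accession = gene_accession, terms = counts,
         n_sentences = length(sentences)),
    class = "term_frequency_table")
}

#' @export
print.term_frequency_table <- function(x, n = 10L, ...) {
  cat(sprintf("<term_frequency_table> %s: %d terms from %d sentences\n",
              ifelse(is.na(x$gene_accession), "(unnamed)",
                     x$gene_accession),
              length(x$terms), x$n_sentences))
  show <- head(x$terms, n)
  if (length(show) > 0L) {
    cat(paste(sprintf("  %s: %d", names(show), show), collapse = "\n"),
        "\n")
  }
  invisible(x)
}

#' Is a gene eligible for a word cloud?
#'
#' Word clouds are only shown for genes with at least `min_sentences`
#' associated sentences (inclusive at the printed value of 10).
#'
#' @param table A `term_frequency_table`.
#' @param min_sentences Minimum sentence count (default 10).
#' @return `TRUE` or `FALSE`.
#' @export
wordcloud_eligible <- function(table, min_sentences = 10L) {
  table$n_sentences >= min_sentences
}

#' Write a term-frequency table as TSV
#'
#' Columns `term`, `count`; decreasing count order.
#'
#' @param table A `term_frequency_table`.
#' @param path Output path.
#' @export
write_term_frequencies <- function(table, path) {
  df <- data.frame(term = names(table$terms),
                   count = unname(table$terms), stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a simple word cloud
#'
#' A base-graphics rendering: terms on a spiral, sized by frequency.
#' Purely cosmetic; the frequency table is the tested contract.
#'
#' @param x A `term_frequency_table`.
#' @param max_terms Terms to draw (most frequent first).
#' @param ... Ignored.
#' @export
plot.term_frequency_table <- function(x, max_terms = 50L, ...) {
  terms <- head(x$terms, max_terms)
  if (length(terms) == 0L) {
    graphics::plot.new()
    graphics::title(main = "no terms")
    return(invisible(x))
  }
  graphics::plot.new()
  graphics::plot.window(xlim = c(-1, 1), ylim = c(-1, 1), asp = 1)
  sizes <- 0.7 + 2.3 * (terms - min(terms)) /
    max(1L, max(terms) - min(terms))
  theta <- seq(0, 6 * pi, length.out = length(terms))
  r <- seq(0, 0.9, length.out = length(terms))
  graphics::text(r * cos(theta), r * sin(theta), names(terms),
                 cex = sizes, col = grDevices::hcl.colors(length(terms)))
  invisible(x)
}
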