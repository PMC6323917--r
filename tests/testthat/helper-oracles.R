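# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately use different algorithms from the package code.

# --- dot-bracket oracle: peel innermost "(...)" spans with regex ----------
oracle_pair_table <- function(db) {
  n <- nchar(db)
  pt <- rep(NA_integer_, n)
  work <- db
  repeat {
    m <- regexpr("\\([.]*\\)", work)
    if (m == -1L) break
    i <- as.integer(m)
    j <- i + attr(m, "match.length") - 1L
    pt[i] <- j
    pt[j] <- i
    substr(work, i, i) <- "."
    substr(work, j, j) <- "."
  }
  pt
}

random_balanced_db <- function(n) {
  gen <- function(n) {
    if (n <= 0L) return("")
    if (n == 1L || runif(1) < 0.4) return(paste0(".", gen(n - 1L)))
    k <- sample.int(n - 1L, 1L) - 1L
    paste0("(", gen(k), ")", gen(n - 2L - k))
  }
  gen(n)
}

# --- profile oracle: expand collapsed entries read by read ----------------
oracle_profile <- function(stack, annotations) {
  arms <- vapply(annotations, `[[`, "", "arm")
  m5 <- if ("5p" %in% arms) annotations[[match("5p", arms)]] else NULL
  m3 <- if ("3p" %in% arms) annotations[[match("3p", arms)]] else NULL
  tally <- list(`5p` = integer(0), `3p` = integer(0))
  unassigned <- 0L
  ent <- stack$entries
  for (i in seq_len(nrow(ent))) {
    for (rep_k in seq_len(ent$count[i])) {
      arm <- assign_read(ent$start[i],
                         ent$start[i] + nchar(ent$read_sequence[i]) - 1L,
                         m5, m3)
      if (arm == "unassigned") {
        unassigned <- unassigned + 1L
      } else {
        key <- as.character(ent$start[i])
        tally[[arm]][key] <- sum(tally[[arm]][key], 1L, na.rm = TRUE)
      }
    }
  }
  list(tally = tally, unassigned = unassigned)
}

# --- term-frequency oracle: per-token loop into an environment ------------
oracle_term_counts <- function(sentences, stop_all) {
  env <- new.env()
  for (s in sentences) {
    raw <- regmatches(tolower(s),
                      gregexpr("[[:alnum:]][[:alnum:]-]*",
                               tolower(s)))[[1L]]
    raw <- gsub("^-+|-+$", "", raw)
    for (tok in raw) {
      if (nchar(tok) < 3L) next
      if (!grepl("[a-z]", tok)) next
      if (tok %in% stop_all) next
      cur <- if (is.null(env[[tok]])) 0L else env[[tok]]
      env[[tok]] <- cur + 1L
    }
  }
  vals <- mget(ls(env), envir = env)
  setNames(as.integer(unlist(vals)), names(vals))
}

# --- article-ranking oracle: explicit loops then a plain sort -------------
oracle_rank <- function(scored) {
  keys <- unique(scored[, c("gene_accession", "article_id")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- scored$gene_accession == keys$gene_accession[i] &
      scored$article_id == keys$article_id[i]
    rows[[i]] <- data.frame(gene_accession = keys$gene_accession[i],
                            article_id = as.character(keys$article_id[i]),
                            total_score = sum(scored$score[sel]),
                            n_sentences = sum(sel),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_accession, -out$total_score, -out$n_sentences,
                   out$article_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- exact-histogram stack builder ----------------------------------------
# counts_5p / counts_3p: named integer vectors, names are 5' start offsets
# relative to the arm's canonical mature start. Reads are exact hairpin
# substrings of the mature length (clipped at the hairpin 3' end).
scatter_stack <- function(locus, counts_5p = NULL, counts_3p = NULL) {
  hp <- locus$hairpin
  rows <- list()
  add_arm <- function(ann, counts) {
    if (is.null(counts) || length(counts) == 0L) return()
    len <- ann$end - ann$start + 1L
    for (k in seq_along(counts)) {
      off <- as.integer(names(counts)[k])
      st <- ann$start + off
      stopifnot(st >= 1L, st + len - 1L <= hp$length)
      rows[[length(rows) + 1L]] <<- data.frame(
        read_sequence = substr(hp$sequence, st, st + len - 1L),
        start = st, count = as.integer(counts[k]),
        stringsAsFactors = FALSE)
    }
  }
  add_arm(locus$annotations[[1L]], counts_5p)
  add_arm(locus$annotations[[2L]], counts_3p)
  read_stack(hp$accession, do.call(rbind, rows), hairpin = hp)
}

# spread `total` reads over the given offsets as evenly as possible
spread_counts <- function(total, offsets) {
  n <- length(offsets)
  base <- total %/% n
  extra <- total %% n
  setNames(as.integer(base + (seq_len(n) <= extra)), offsets)
}

# a locus where every high-confidence rule passes by construction
canonical_locus <- function(seed = 11L) {
  make_locus(sim_params(seed = seed))
}

# identical perfectly processed reads on both arms, `depth` each
perfect_stack <- function(locus, depth) {
  scatter_stack(locus,
                counts_5p = setNames(depth, "0"),
                counts_3p = setNames(depth, "0"))
}

random_stack <- function(locus, n_entries = 30L) {
  hp <- locus$hairpin
  starts <- sample.int(hp$length - 15L, n_entries, replace = TRUE)
  lens <- pmin(sample(16:24, n_entries, replace = TRUE),
               hp$length - starts + 1L)
  read_stack(hp$accession, data.frame(
    read_sequence = substring(hp$sequence, starts, starts + lens - 1L),
    start = starts,
    count = sample.int(50L, n_entries, replace = TRUE),
    stringsAsFactors = FALSE), hairpin = hp)
}
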