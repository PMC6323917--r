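# On-disk representations: hairpin FASTA, dot-bracket structure files,
# mature annotation tables, collapsed small RNA alignments (TSV / SAM).
# All coordinates are 1-based inclusive, matching community file formats.

#' Construct a hairpin precursor record
#'
#' @param name Hairpin name, e.g. `"hsa-mir-21"`. The species code is taken
#'   from the 3-4 letter prefix when present.
#' @param sequence Precursor sequence over A/C/G/U (T is accepted and
#'   normalised to U; case is normalised to upper).
#' @param accession Stable accession; defaults to the name when absent.
#' @return An object of class `hairpin_record` with fields `accession`,
#'   `name`, `species_code`, `sequence` and `length`.
#' @examples
#' hp <- hairpin_record("hsa-mir-21", "ACGUACGUACGU")
#' hp$length
#' @export
hairpin_record <- function(name, sequence, accession = name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- normalize_rna(sequence)
  if (!nzchar(sequence)) {
    stop("hairpin '", name, "' has an empty sequence", call. = FALSE)
  }
  bad <- gsub("[ACGU]", "", sequence)
  if (nzchar(bad)) {
    stop("hairpin '", name, "' contains non-ACGU characters: ",
         substr(bad, 1L, 10L), call. = FALSE)
  }
  species <- ""
  if (grepl("^[A-Za-z]{3,4}-", name)) {
    species <- tolower(sub("^([A-Za-z]{3,4})-.*$", "\\1", name))
  }
  structure(
    list(accession = as.character(accession), name = name,
         species_code = species, sequence = sequence,
         length = nchar(sequence)),
    class = "hairpin_record"
  )
}

#' @export
print.hairpin_record <- function(x, ...) {
  cat(sprintf("<hairpin_record> %s (%s), %d nt\n", x$name, x$accession,
              x$length))
  cat(" ", x$sequence, "\n", sep = "")
  invisible(x)
}

normalize_rna <- function(x) {
  chartr("Tt", "Uu", toupper(trimws(x)))
}

#' Read hairpin precursors from FASTA
#'
#' Headers are parsed as `name accession ...`; when only one token is
#' present the accession falls back to the name. `T` bases are normalised
#' to `U`. Entries with empty sequences are dropped with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A list of [hairpin_record] objects, named by accession.
#' @export
read_hairpin_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  out <- list()
  for (i in seq_along(set)) {
    header <- names(set)[i]
    toks <- strsplit(trimws(header), "\\s+")[[1L]]
    seq <- as.character(set[[i]])
    if (!nzchar(gsub("[^A-Za-z]", "", seq))) {
      warning("entry '", header, "' has an empty sequence; skipped",
              call. = FALSE)
      next
    }
    acc <- if (length(toks) >= 2L) toks[2L] else toks[1L]
    rec <- hairpin_record(name = toks[1L], sequence = seq, accession = acc)
    out[[rec$accession]] <- rec
  }
  out
}

#' Write hairpin precursors to FASTA
#'
#' Inverse of [read_hairpin_fasta()]: headers are `name accession`.
#'
#' @param hairpins List of [hairpin_record] objects.
#' @param path Output path.
#' @export
write_hairpin_fasta <- function(hairpins, path) {
  seqs <- Biostrings::BStringSet(vapply(hairpins, `[[`, "", "sequence"))
  names(seqs) <- vapply(hairpins, function(h) {
    paste(h$name, h$accession)
  }, "")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Construct a mature microRNA annotation
#'
#' An arm's interval on its hairpin, 1-based inclusive.
#'
#' @param mature_name Mature product name, e.g. `"hsa-miR-21-5p"`.
#' @param arm `"5p"` or `"3p"`.
#' @param start,end 1-based inclusive positions on the hairpin.
#' @param sequence The mature sequence; must equal the hairpin subsequence
#'   at `[start, end]` (checked by [validate_annotations()] and on use).
#' @return An object of class `mature_annotation`.
#' @export
mature_annotation <- function(mature_name, arm, start, end, sequence) {
  arm <- match.arg(arm, c("5p", "3p"))
  start <- as.integer(start); end <- as.integer(end)
  if (!(start >= 1L && start <= end)) {
    stop("invalid mature interval [", start, ", ", end, "]", call. = FALSE)
  }
  structure(
    list(mature_name = mature_name, arm = arm, start = start, end = end,
         sequence = normalize_rna(sequence)),
    class = "mature_annotation"
  )
}

#' @export
print.mature_annotation <- function(x, ...) {
  cat(sprintf("<mature_annotation> %s (%s) [%d, %d] %s\n", x$mature_name,
              x$arm, x$start, x$end, x$sequence))
  invisible(x)
}

#' Check a pair of mature annotations against their hairpin
#'
#' Verifies interval bounds, sequence identity with the hairpin
#' subsequence, and that a 5p interval lies entirely before a 3p interval.
#'
#' @param hairpin A [hairpin_record].
#' @param annotations List of [mature_annotation]s (at most one per arm).
#' @return `annotations`, invisibly; errors describe the first violation.
#' @export
validate_annotations <- function(hairpin, annotations) {
  arms <- vapply(annotations, `[[`, "", "arm")
  if (anyDuplicated(arms)) {
    stop("multiple annotations for the same arm", call. = FALSE)
  }
  for (ann in annotations) {
    if (ann$end > hairpin$length) {
      stop(ann$mature_name, ": interval exceeds hairpin length",
           call. = FALSE)
    }
    sub <- substr(hairpin$sequence, ann$start, ann$end)
    if (sub != ann$sequence) {
      stop(ann$mature_name, ": sequence does not match hairpin at [",
           ann$start, ", ", ann$end, "]", call. = FALSE)
    }
  }
  if (all(c("5p", "3p") %in% arms)) {
    a5 <- annotations[[match("5p", arms)]]
    a3 <- annotations[[match("3p", arms)]]
    if (a5$end >= a3$start) {
      stop("5p interval must lie entirely before the 3p interval",
           call. = FALSE)
    }
  }
  invisible(annotations)
}

#' Locate a mature sequence on its hairpin by exact substring match
#'
#' When the mature sequence occurs more than once, `arm_hint`
#' disambiguates: `"5p"` takes the leftmost occurrence, `"3p"` the
#' rightmost. Ambiguity without a hint is an error, as is no occurrence.
#'
#' @param hairpin A [hairpin_record].
#' @param mature_sequence Mature sequence (T normalised to U).
#' @param arm_hint Optional `"5p"`/`"3p"`.
#' @param mature_name Name recorded on the returned annotation.
#' @return A [mature_annotation] with recovered 1-based coordinates.
#' @export
locate_mature <- function(hairpin, mature_sequence, arm_hint = NULL,
                          mature_name = NULL) {
  mature_sequence <- normalize_rna(mature_sequence)
  if (!nzchar(mature_sequence)) {
    stop("mature sequence is empty", call. = FALSE)
  }
  hits <- gregexpr(mature_sequence, hairpin$sequence, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) {
    stop("mature sequence not found on hairpin '", hairpin$name, "'",
         call. = FALSE)
  }
  if (length(hits) > 1L && is.null(arm_hint)) {
    stop("mature sequence occurs ", length(hits), " times on '",
         hairpin$name, "'; supply arm_hint", call. = FALSE)
  }
  arm <- if (is.null(arm_hint)) {
    # single hit: infer the arm from which half of the hairpin it sits in
    if (hits[1L] - 1L + nchar(mature_sequence) / 2 <= hairpin$length / 2)
      "5p" else "3p"
  } else {
    match.arg(arm_hint, c("5p", "3p"))
  }
  start <- if (!is.null(arm_hint) && arm == "3p") {
    hits[length(hits)]
  } else {
    hits[1L]
  }
  if (is.null(mature_name)) {
    mature_name <- paste0(hairpin$name, "-", arm)
  }
  mature_annotation(mature_name, arm, start,
                    start + nchar(mature_sequence) - 1L, mature_sequence)
}

#' Read mature annotations from a TSV table
#'
#' Columns: `hairpin_accession`, `mature_name`, `arm`, `start`, `end`
#' (1-based inclusive), `sequence`. Returns a list (one element per
#' hairpin accession) of lists of [mature_annotation]s.
#'
#' @param path Path to the tab-separated table (with header).
#' @export
read_mature_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("hairpin_accession", "mature_name", "arm", "start", "end",
              "sequence")
  if (!all(needed %in% names(df))) {
    stop("mature table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(df))) {
    ann <- mature_annotation(df$mature_name[i], df$arm[i], df$start[i],
                             df$end[i], df$sequence[i])
    acc <- df$hairpin_accession[i]
    out[[acc]] <- c(out[[acc]], list(ann))
  }
  out
}

#' Write mature annotations to a TSV table
#'
#' @param annotations Named list (by hairpin accession) of lists of
#'   [mature_annotation]s, as returned by [read_mature_tsv()].
#' @param path Output path.
#' @export
write_mature_tsv <- function(annotations, path) {
  rows <- do.call(rbind, unlist(lapply(names(annotations), function(acc) {
    lapply(annotations[[acc]], function(a) {
      data.frame(hairpin_accession = acc, mature_name = a$mature_name,
                 arm = a$arm, start = a$start, end = a$end,
                 sequence = a$sequence, stringsAsFactors = FALSE)
    })
  }), recursive = FALSE))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a collapsed read stack
#'
#' @param hairpin_accession Accession of the hairpin the reads map to.
#' @param entries `data.frame` with columns `read_sequence`, `start`
#'   (1-based position of the read 5' end on the hairpin) and `count`
#'   (positive integer of collapsed identical reads). Duplicate
#'   (sequence, start) rows are summed.
#' @param hairpin Optional [hairpin_record]; when supplied every entry is
#'   checked to match the hairpin subsequence at its start.
#' @return An object of class `read_stack`.
#' @export
read_stack <- function(hairpin_accession, entries, hairpin = NULL) {
  if (is.null(entries) || nrow(entries) == 0L) {
    entries <- data.frame(read_sequence = character(), start = integer(),
                          count = integer(), stringsAsFactors = FALSE)
  } else {
    entries <- data.frame(read_sequence = normalize_rna(entries$read_sequence),
                          start = as.integer(entries$start),
                          count = as.integer(entries$count),
                          stringsAsFactors = FALSE)
    if (any(entries$count < 1L)) stop("counts must be >= 1", call. = FALSE)
    if (any(entries$start < 1L)) stop("starts must be >= 1", call. = FALSE)
    key <- paste(entries$read_sequence, entries$start)
    if (anyDuplicated(key)) {
      agg <- aggregate(count ~ read_sequence + start, entries, sum)
      entries <- agg[, c("read_sequence", "start", "count")]
    }
    entries <- entries[order(entries$start, entries$read_sequence), ,
                       drop = FALSE]
    rownames(entries) <- NULL
  }
  if (!is.null(hairpin)) {
    for (i in seq_len(nrow(entries))) {
      ok <- stack_entry_matches(hairpin, entries$read_sequence[i],
                                entries$start[i])
      if (!ok) {
        stop("read at start ", entries$start[i],
             " does not match hairpin '", hairpin$name, "'", call. = FALSE)
      }
    }
  }
  structure(list(hairpin_accession = hairpin_accession, entries = entries),
            class = "read_stack")
}

stack_entry_matches <- function(hairpin, read_sequence, start) {
  end <- start + nchar(read_sequence) - 1L
  end <= hairpin$length &&
    substr(hairpin$sequence, start, end) == read_sequence
}

#' @export
print.read_stack <- function(x, ...) {
  cat(sprintf("<read_stack> %s: %d distinct entries, %d reads\n",
              x$hairpin_accession, nrow(x$entries), sum(x$entries$count)))
  invisible(x)
}

#' Read collapsed small RNA alignments
#'
#' TSV input has header columns `hairpin_accession`, `read_sequence`,
#' `start` (1-based) and `count`. SAM input is a single-reference-per-read
#' dialect: only flag 0 records are used; flag 16 (reverse strand) records
#' are rejected with a warning because hairpins are single-stranded;
#' other flags are ignored. Collapsed counts may be encoded in the SAM
#' query name as a `_xN` suffix (`count = 1` otherwise).
#'
#' Entries whose sequence does not match the hairpin at their start, and
#' rows with non-positive counts, are dropped and tallied in the
#' `"rejections"` attribute of the result.
#'
#' @param path Path to the alignment file.
#' @param hairpins List of [hairpin_record]s, as from
#'   [read_hairpin_fasta()]; used to validate entries and resolve names.
#' @param format `"tsv"` or `"sam"`.
#' @return A named list of [read_stack]s (one per hairpin with alignments),
#'   with attribute `"rejections"`, a data.frame tallying dropped rows by
#'   reason.
#' @export
read_alignments <- function(path, hairpins, format = c("tsv", "sam")) {
  format <- match.arg(format)
  raw <- switch(format,
                tsv = alignments_from_tsv(path),
                sam = alignments_from_sam(path))
  index <- hairpin_index(hairpins)
  rejected <- c(unmatched_sequence = 0L, unknown_hairpin = 0L,
                bad_count = 0L, reverse_strand = raw$n_reverse)
  keep <- rep(TRUE, nrow(raw$rows))
  acc <- character(nrow(raw$rows))
  for (i in seq_len(nrow(raw$rows))) {
    ref <- raw$rows$hairpin[i]
    hp <- index[[ref]]
    if (is.null(hp)) {
      rejected[["unknown_hairpin"]] <- rejected[["unknown_hairpin"]] + 1L
      keep[i] <- FALSE
      next
    }
    acc[i] <- hp$accession
    if (raw$rows$count[i] < 1L) {
      rejected[["bad_count"]] <- rejected[["bad_count"]] + 1L
      keep[i] <- FALSE
      next
    }
    if (!stack_entry_matches(hp, raw$rows$read_sequence[i],
                             raw$rows$start[i])) {
      rejected[["unmatched_sequence"]] <-
        rejected[["unmatched_sequence"]] + 1L
      keep[i] <- FALSE
    }
  }
  rows <- raw$rows[keep, , drop = FALSE]
  rows$accession <- acc[keep]
  stacks <- lapply(split(rows, rows$accession), function(grp) {
    read_stack(grp$accession[1L],
               data.frame(read_sequence = grp$read_sequence,
                          start = grp$start, count = grp$count,
                          stringsAsFactors = FALSE))
  })
  attr(stacks, "rejections") <-
    data.frame(reason = names(rejected), n = unname(rejected),
               stringsAsFactors = FALSE)
  stacks
}

hairpin_index <- function(hairpins) {
  index <- list()
  for (hp in hairpins) {
    index[[hp$accession]] <- hp
    index[[hp$name]] <- hp
  }
  index
}

alignments_from_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("hairpin_accession", "read_sequence", "start", "count")
  if (!all(needed %in% names(df))) {
    stop("alignment TSV must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  list(rows = data.frame(hairpin = df$hairpin_accession,
                         read_sequence = normalize_rna(df$read_sequence),
                         start = as.integer(df$start),
                         count = as.integer(df$count),
                         stringsAsFactors = FALSE),
       n_reverse = 0L)
}

alignments_from_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  hair <- character(0); seqs <- character(0)
  starts <- integer(0); counts <- integer(0)
  n_reverse <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 10L) stop("malformed SAM record: ", ln, call. = FALSE)
    flag <- as.integer(f[2L])
    if (bitwAnd(flag, 16L) == 16L) {
      n_reverse <- n_reverse + 1L
      next
    }
    if (flag != 0L) next  # unmapped / secondary etc.
    count <- 1L
    if (grepl("_x[0-9]+$", f[1L])) {
      count <- as.integer(sub("^.*_x([0-9]+)$", "\\1", f[1L]))
    }
    hair <- c(hair, f[3L]); seqs <- c(seqs, normalize_rna(f[10L]))
    starts <- c(starts, as.integer(f[4L])); counts <- c(counts, count)
  }
  if (n_reverse > 0L) {
    warning(n_reverse, " reverse-strand SAM record(s) rejected; ",
            "hairpins are single-stranded", call. = FALSE)
  }
  list(rows = data.frame(hairpin = hair, read_sequence = seqs,
                         start = starts, count = counts,
                         stringsAsFactors = FALSE),
       n_reverse = n_reverse)
}

#' Write collapsed alignments as TSV
#'
#' Inverse of [read_alignments()] with `format = "tsv"`.
#'
#' @param stacks Named list of [read_stack]s.
#' @param path Output path.
#' @export
write_alignments_tsv <- function(stacks, path) {
  rows <- do.call(rbind, lapply(stacks, function(st) {
    if (nrow(st$entries) == 0L) return(NULL)
    data.frame(hairpin_accession = st$hairpin_accession,
               read_sequence = st$entries$read_sequence,
               start = st$entries$start, count = st$entries$count,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(hairpin_accession = character(),
                       read_sequence = character(), start = integer(),
                       count = integer())
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write collapsed alignments as SAM
#'
#' Emits flag-0 records with counts in the query name (`_xN` suffix), one
#' `@SQ` header line per hairpin.
#'
#' @param stacks Named list of [read_stack]s.
#' @param hairpins List of [hairpin_record]s (for `@SQ` lengths).
#' @param path Output path.
#' @export
write_alignments_sam <- function(stacks, hairpins, path) {
  index <- hairpin_index(hairpins)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (hp in hairpins) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", hp$accession, hp$length), con)
  }
  i <- 0L
  for (st in stacks) {
    for (k in seq_len(nrow(st$entries))) {
      i <- i + 1L
      seq <- st$entries$read_sequence[k]
      writeLines(sprintf("r%06d_x%d\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                         i, st$entries$count[k], st$hairpin_accession,
                         st$entries$start[k], nchar(seq),
                         chartr("U", "T", seq)), con)
    }
  }
  invisible(path)
}
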