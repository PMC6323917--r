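# Dot-bracket secondary structures and the FASTA-like structure file
# (header line, sequence line, structure line per hairpin).

#' Parse a dot-bracket string into a pair table
#'
#' Stack matching over `(`, `)` and `.`. The pair table is an integer
#' vector `pt` of the given length with `pt[i] == j` when positions `i`
#' and `j` (1-based) are paired, and `NA` for unpaired positions.
#'
#' @param structure_string String over `(`, `)`, `.`.
#' @param length Expected length; must equal `nchar(structure_string)`.
#' @param source `"provided"` (default) or `"folded"`; recorded on the
#'   result.
#' @return An object of class `secondary_structure` with fields
#'   `pair_table`, `dot_bracket`, `length`, `source`.
#' @examples
#' ss <- parse_dot_bracket("((..))", 6)
#' ss$pair_table  # 6 5 NA NA 2 1
#' @export
parse_dot_bracket <- function(structure_string, length,
                              source = c("provided", "folded")) {
  source <- match.arg(source)
  n <- nchar(structure_string)
  if (n != length) {
    stop("structure length ", n, " does not match expected length ",
         length, call. = FALSE)
  }
  chars <- strsplit(structure_string, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad) > 0L) {
    stop("invalid character '", chars[bad[1L]], "' at position ", bad[1L],
         call. = FALSE)
  }
  pt <- rep(NA_integer_, n)
  open <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      open <- c(open, i)
    } else if (chars[i] == ")") {
      if (length(open) == 0L) {
        stop("unbalanced structure: unmatched ')' at position ", i,
             call. = FALSE)
      }
      j <- open[length(open)]
      open <- open[-length(open)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(open) > 0L) {
    stop("unbalanced structure: unmatched '(' at position ", open[1L],
         call. = FALSE)
  }
  structure(list(pair_table = pt, dot_bracket = structure_string,
                 length = n, source = source),
            class = "secondary_structure")
}

#' Render a pair table back to dot-bracket notation
#'
#' Inverse of [parse_dot_bracket()] for non-pseudoknotted tables.
#'
#' @param ss A `secondary_structure`.
#' @return The dot-bracket string.
#' @export
render_dot_bracket <- function(ss) {
  pt <- ss$pair_table
  chars <- rep(".", length(pt))
  paired <- which(!is.na(pt))
  chars[paired[pt[paired] > paired]] <- "("
  chars[paired[pt[paired] < paired]] <- ")"
  paste(chars, collapse = "")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d nt, %d base pairs (%s)\n",
              x$length, sum(!is.na(x$pair_table)) %/% 2L, x$source))
  cat(" ", x$dot_bracket, "\n", sep = "")
  invisible(x)
}

#' Read a structure file
#'
#' FASTA-like records of three lines: `>name accession`, sequence,
#' dot-bracket structure of the same length.
#'
#' @param path Path to the structure file.
#' @return Named list (by accession, falling back to name) of
#'   `secondary_structure` objects; each carries the record's sequence as
#'   attribute `"sequence"`.
#' @export
read_structure_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- which(startsWith(lines, ">"))
  if (length(heads) == 0L) stop("no records in '", path, "'", call. = FALSE)
  out <- list()
  for (h in heads) {
    if (h + 2L > length(lines)) {
      stop("truncated record at line ", h, " of '", path, "'",
           call. = FALSE)
    }
    toks <- strsplit(sub("^>", "", lines[h]), "\\s+")[[1L]]
    key <- if (length(toks) >= 2L) toks[2L] else toks[1L]
    seq <- normalize_rna(lines[h + 1L])
    ss <- parse_dot_bracket(lines[h + 2L], nchar(seq))
    attr(ss, "sequence") <- seq
    out[[key]] <- ss
  }
  out
}

#' Write a structure file
#'
#' @param records Named list (by accession) of lists with elements
#'   `hairpin` ([hairpin_record]) and `structure` (`secondary_structure`),
#'   or the output of [make_locus()].
#' @param path Output path.
#' @export
write_structure_file <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    hp <- rec$hairpin
    writeLines(c(paste0(">", hp$name, " ", hp$accession), hp$sequence,
                 rec$structure$dot_bracket), con)
  }
  invisible(path)
}

#' Fold a sequence by maximum base pairing (fixture helper)
#'
#' A simple Nussinov-style dynamic program maximising Watson-Crick plus
#' G:U pairs with a minimum hairpin loop of 3 nt. This exists only to
#' build synthetic structures for fixtures and is never required for
#' classification, which consumes provided structures.
#'
#' @param sequence RNA sequence.
#' @param min_loop Minimum unpaired loop length (default 3).
#' @return A `secondary_structure` with `source = "folded"`.
#' @export
fold_max_pairing <- function(sequence, min_loop = 3L) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  s <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  can_pair <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  }
  dp <- matrix(0L, n, n)
  for (span in seq_len(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- dp[i, j - 1L]
      for (k in i:(j - min_loop - 1L)) {
        if (k >= i && j - k > min_loop && can_pair(s[k], s[j])) {
          left <- if (k > i) dp[i, k - 1L] else 0L
          cand <- left + 1L + (if (k + 1L <= j - 1L) dp[k + 1L, j - 1L] else 0L)
          if (cand > best) best <- cand
        }
      }
      dp[i, j] <- best
    }
  }
  pt <- rep(NA_integer_, n)
  trace <- function(i, j) {
    while (i < j) {
      if (dp[i, j] == dp[i, j - 1L]) { j <- j - 1L; next }
      for (k in i:(j - min_loop - 1L)) {
        if (can_pair(s[k], s[j]) && j - k > min_loop) {
          left <- if (k > i) dp[i, k - 1L] else 0L
          inner <- if (k + 1L <= j - 1L) dp[k + 1L, j - 1L] else 0L
          if (dp[i, j] == left + 1L + inner) {
            pt[k] <<- j; pt[j] <<- k
            if (k > i) trace(i, k - 1L)
            i <- k + 1L; j <- j - 1L
            break
          }
        }
      }
    }
  }
  if (n > 1L) trace(1L, n)
  db <- rep(".", n)
  db[!is.na(pt) & pt > seq_len(n)] <- "("
  db[!is.na(pt) & pt < seq_len(n)] <- ")"
  parse_dot_bracket(paste(db, collapse = ""), n, source = "folded")
}
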