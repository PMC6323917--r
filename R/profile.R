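# Per-arm read-stack statistics: arm assignment, 5' start histograms,
# modal 5' fractions. These feed the confidence classifiers.

#' Assign a read interval to a hairpin arm
#'
#' A read is assigned to the arm whose mature interval, extended by
#' `extension` nt on each side (tolerating templated 3' trimming/tailing),
#' overlaps it by at least `min_overlap` of the read length. If both arms
#' qualify the larger overlap wins; an exact tie, or neither arm
#' qualifying, yields `"unassigned"`.
#'
#' @param read_start,read_end 1-based inclusive read interval.
#' @param mature_5p,mature_3p [mature_annotation]s or `NULL`.
#' @param extension Interval extension in nt (default 2).
#' @param min_overlap Minimum overlap as a fraction of read length
#'   (default 0.5).
#' @return `"5p"`, `"3p"` or `"unassigned"`.
#' @export
assign_read <- function(read_start, read_end, mature_5p = NULL,
                        mature_3p = NULL, extension = 2L,
                        min_overlap = 0.5) {
  read_len <- read_end - read_start + 1L
  ov <- function(ann) {
    if (is.null(ann)) return(0L)
    lo <- max(read_start, ann$start - extension)
    hi <- min(read_end, ann$end + extension)
    max(0L, hi - lo + 1L)
  }
  ov5 <- ov(mature_5p); ov3 <- ov(mature_3p)
  q5 <- ov5 >= min_overlap * read_len
  q3 <- ov3 >= min_overlap * read_len
  if (q5 && q3) {
    if (ov5 > ov3) "5p" else if (ov3 > ov5) "3p" else "unassigned"
  } else if (q5) "5p" else if (q3) "3p" else "unassigned"
}

#' Modal 5' fraction of an arm profile
#'
#' The fraction of an arm's assigned reads sharing the most frequent
#' (modal) 5' start position. Ties on the mode do not change the
#' fraction. With no assigned reads the statistic is undefined and `NA`
#' is returned; callers must treat the homogeneity criterion as failed
#' for lack of data.
#'
#' @param arm_profile An `arm_profile` (see [build_profile()]).
#' @return Fraction in `[0, 1]`, or `NA` when no reads are assigned.
#' @export
modal_five_prime_fraction <- function(arm_profile) {
  if (arm_profile$assigned_reads == 0L) return(NA_real_)
  max(arm_profile$start_histogram) / arm_profile$assigned_reads
}

make_arm_profile <- function(arm, starts, counts) {
  if (length(starts) == 0L) {
    prof <- structure(
      list(arm = arm, assigned_reads = 0L,
           start_histogram = integer(0), modal_start = NA_integer_,
           modal_fraction = NA_real_),
      class = "arm_profile")
    return(prof)
  }
  hist <- tapply(counts, starts, sum)
  hist <- setNames(as.integer(hist), names(hist))
  pos <- as.integer(names(hist))
  ord <- order(pos)
  hist <- hist[ord]; pos <- pos[ord]
  total <- sum(hist)
  modal <- pos[which.max(hist)]  # smallest position on ties
  structure(
    list(arm = arm, assigned_reads = total, start_histogram = hist,
         modal_start = modal, modal_fraction = max(hist) / total),
    class = "arm_profile")
}

#' Build a per-locus read profile
#'
#' Assigns every collapsed entry to an arm with [assign_read()] and
#' accumulates counts (not distinct sequences) into per-arm 5'-start
#' histograms. Conservation holds by construction:
#' `assigned(5p) + assigned(3p) + unassigned == total_reads`.
#'
#' @param stack A [read_stack].
#' @param annotations List of [mature_annotation]s on the same hairpin.
#' @param extension,min_overlap Passed to [assign_read()].
#' @return An object of class `locus_profile` with fields `accession`,
#'   `total_reads`, `arm_profiles` (named list with `5p`/`3p` entries for
#'   annotated arms), `unassigned_reads`.
#' @export
build_profile <- function(stack, annotations, extension = 2L,
                          min_overlap = 0.5) {
  arms <- vapply(annotations, `[[`, "", "arm")
  m5 <- if ("5p" %in% arms) annotations[[match("5p", arms)]] else NULL
  m3 <- if ("3p" %in% arms) annotations[[match("3p", arms)]] else NULL
  ent <- stack$entries
  n <- nrow(ent)
  assigned <- character(n)
  for (i in seq_len(n)) {
    assigned[i] <- assign_read(ent$start[i],
                               ent$start[i] + nchar(ent$read_sequence[i]) - 1L,
                               m5, m3, extension, min_overlap)
  }
  profs <- list()
  if (!is.null(m5)) {
    sel <- assigned == "5p"
    profs[["5p"]] <- make_arm_profile("5p", ent$start[sel], ent$count[sel])
  }
  if (!is.null(m3)) {
    sel <- assigned == "3p"
    profs[["3p"]] <- make_arm_profile("3p", ent$start[sel], ent$count[sel])
  }
  total <- if (n > 0L) sum(ent$count) else 0L
  unas <- sum(ent$count[assigned == "unassigned"])
  structure(
    list(accession = stack$hairpin_accession, total_reads = total,
         arm_profiles = profs, unassigned_reads = as.integer(unas)),
    class = "locus_profile")
}

#' @export
print.locus_profile <- function(x, ...) {
  cat(sprintf("<locus_profile> %s: %d reads (%d unassigned)\n",
              x$accession, x$total_reads, x$unassigned_reads))
  for (p in x$arm_profiles) {
    cat(sprintf("  %s: %d reads, modal 5' at %s (fraction %s)\n", p$arm,
                p$assigned_reads,
                ifelse(is.na(p$modal_start), "-", p$modal_start),
                ifelse(is.na(p$modal_fraction), "-",
                       sprintf("%.3f", p$modal_fraction))))
  }
  invisible(x)
}

#' Dump a locus profile as a data.frame (TSV-ready)
#'
#' One row per annotated arm plus an `unassigned` row.
#'
#' @param profile A `locus_profile`.
#' @return A data.frame with columns `accession`, `arm`, `assigned_reads`,
#'   `modal_start`, `modal_fraction`.
#' @export
profile_table <- function(profile) {
  rows <- lapply(profile$arm_profiles, function(p) {
    data.frame(accession = profile$accession, arm = p$arm,
               assigned_reads = p$assigned_reads,
               modal_start = ifelse(is.na(p$modal_start), NA_integer_,
                                    p$modal_start),
               modal_fraction = p$modal_fraction,
               stringsAsFactors = FALSE)
  })
  rows <- c(rows, list(data.frame(
    accession = profile$accession, arm = "unassigned",
    assigned_reads = profile$unassigned_reads, modal_start = NA_integer_,
    modal_fraction = NA_real_, stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a locus profile as TSV or JSON
#'
#' @param profile A `locus_profile`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_profile <- function(profile, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(profile_table(profile), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    obj <- list(accession = profile$accession,
                total_reads = profile$total_reads,
                unassigned_reads = profile$unassigned_reads,
                arms = lapply(profile$arm_profiles, function(p) {
                  list(arm = p$arm, assigned_reads = p$assigned_reads,
                       start_histogram = as.list(p$start_histogram),
                       modal_start = p$modal_start,
                       modal_fraction = p$modal_fraction)
                }))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' ASCII rendering of a read stack under its hairpin
#'
#' Mirrors the familiar website view: the hairpin sequence, the
#' dot-bracket structure when available, then one line per collapsed
#' entry (indented to its start) with its count.
#'
#' @param hairpin A [hairpin_record].
#' @param stack A [read_stack] on that hairpin.
#' @param structure Optional `secondary_structure`.
#' @return Character vector of lines, invisibly; printed when
#'   `print = TRUE`.
#' @param print Print the rendering to the console (default `TRUE`).
#' @export
render_read_stack <- function(hairpin, stack, structure = NULL,
                              print = TRUE) {
  lines <- hairpin$sequence
  if (!is.null(structure)) lines <- c(lines, structure$dot_bracket)
  ent <- stack$entries
  ord <- order(ent$start, -ent$count)
  for (i in ord) {
    pad <- strrep(" ", ent$start[i] - 1L)
    lines <- c(lines, sprintf("%s%s x%d", pad, ent$read_sequence[i],
                              ent$count[i]))
  }
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
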