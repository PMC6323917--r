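# High/low-confidence classification of hairpin annotations from read
# patterns and duplex 3'-overhang geometry.

#' Classification parameters with their published defaults
#'
#' Thresholds are read exactly as printed: per-arm depth `>= 20` reads,
#' modal 5' fraction `>= 50%`, duplex 3' overhangs within `[0, 4]` nt
#' (negative, i.e. recessed, ends fail), low-confidence flag requires
#' strictly `> 100` total reads and dominant-arm modal fraction strictly
#' `< 30%`.
#'
#' @param min_reads Minimum assigned reads per arm for high confidence.
#' @param min_frac Minimum modal 5' fraction per arm for high confidence.
#' @param min_overhang,max_overhang Inclusive bounds on both duplex 3'
#'   overhangs.
#' @param low_min_reads Low-confidence flag requires total reads strictly
#'   greater than this.
#' @param low_max_frac Low-confidence flag requires dominant-arm modal
#'   fraction strictly below this.
#' @param overhang_mode `"both"` (default: both duplex ends must be
#'   defined and in range) or `"either"` (one defined in-range end
#'   suffices).
#' @param scan_window How far (nt) from a mature 5' terminus to look for
#'   a paired base when measuring overhangs.
#' @param arm_extension,min_read_overlap Read-to-arm assignment controls;
#'   see [assign_read()].
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_reads = 20L, min_frac = 0.5, min_overhang = 0L,
                      max_overhang = 4L, low_min_reads = 100L,
                      low_max_frac = 0.3,
                      overhang_mode = c("both", "either"),
                      scan_window = 5L, arm_extension = 2L,
                      min_read_overlap = 0.5) {
  structure(
    list(min_reads = as.integer(min_reads), min_frac = min_frac,
         min_overhang = as.integer(min_overhang),
         max_overhang = as.integer(max_overhang),
         low_min_reads = as.integer(low_min_reads),
         low_max_frac = low_max_frac,
         overhang_mode = match.arg(overhang_mode),
         scan_window = as.integer(scan_window),
         arm_extension = as.integer(arm_extension),
         min_read_overlap = min_read_overlap),
    class = "qc_params")
}

#' Measure duplex 3' overhangs from a pair table
#'
#' The 5p:3p mature duplex leaves a 3' overhang at each end: at the
#' hairpin-base (Drosha) end the 3p mature's 3' terminus protrudes past
#' the partner of the 5p mature's 5' terminus, and at the loop (Dicer)
#' end the 5p mature's 3' terminus protrudes past the partner of the 3p
#' mature's 5' terminus. Because mature termini may themselves be
#' unpaired, the first paired base within `scan_window` nt inside each
#' mature 5' end anchors the measurement; the offset is compensated, so
#' the result is exact on locally helical duplexes. Ends with no paired
#' base within the window are reported undefined. Negative values mean a
#' recessed (5'-overhanging or blunt-passed) end.
#'
#' @param structure A `secondary_structure` for the hairpin.
#' @param mature_5p,mature_3p [mature_annotation]s for the two arms.
#' @param scan_window Scan width in nt (default 5).
#' @return Object of class `duplex_geometry`: fields
#'   `overhang_drosha_end`, `overhang_dicer_end` (signed nt, `NA` when
#'   undefined) and `defined` (named logical of length 2).
#' @export
duplex_overhangs <- function(structure, mature_5p, mature_3p,
                             scan_window = 5L) {
  if (mature_5p$end >= mature_3p$start) {
    stop("5p and 3p matures overlap; cannot measure duplex geometry",
         call. = FALSE)
  }
  if (mature_3p$end > structure$length) {
    stop("mature annotation exceeds structure length", call. = FALSE)
  }
  pt <- structure$pair_table
  anchor <- function(start) {
    for (delta in 0:(scan_window - 1L)) {
      pos <- start + delta
      if (pos <= length(pt) && !is.na(pt[pos])) {
        return(c(pos = pos, partner = pt[pos], delta = delta))
      }
    }
    NULL
  }
  a5 <- anchor(mature_5p$start)
  a3 <- anchor(mature_3p$start)
  drosha <- if (is.null(a5)) NA_integer_ else {
    as.integer((mature_3p$end - a5[["partner"]]) - a5[["delta"]])
  }
  dicer <- if (is.null(a3)) NA_integer_ else {
    as.integer((mature_5p$end - a3[["partner"]]) - a3[["delta"]])
  }
  base::structure(
    list(overhang_drosha_end = drosha, overhang_dicer_end = dicer,
         defined = c(drosha = !is.na(drosha), dicer = !is.na(dicer))),
    class = "duplex_geometry")
}

#' @export
print.duplex_geometry <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else paste0(v, " nt")
  cat("<duplex_geometry> 3' overhangs: Drosha end ",
      fmt(x$overhang_drosha_end), ", Dicer end ",
      fmt(x$overhang_dicer_end), "\n", sep = "")
  invisible(x)
}

overhang_in_range <- function(value, params) {
  !is.na(value) && value >= params$min_overhang &&
    value <= params$max_overhang
}

#' Evaluate the high-confidence criteria
#'
#' A locus is high confidence iff (a) mature products are annotated on
#' both arms, (b) the duplex 3' overhangs are within `[0, 4]` nt
#' (by default at both ends; undefined ends fail), (c) each arm has at
#' least 20 assigned reads, and (d) at least 50% of each arm's reads
#' share the modal 5' end.
#'
#' @param profile A `locus_profile` built over `annotations`.
#' @param annotations The mature annotations used for the profile.
#' @param geometry A `duplex_geometry`, or `NULL` when unmeasurable (the
#'   overhang criterion then fails).
#' @param params A [qc_params] object.
#' @return Named logical vector of the six criteria:
#'   `both_arms_annotated`, `overhang_ok`, `depth_ok_5p`, `depth_ok_3p`,
#'   `homogeneity_ok_5p`, `homogeneity_ok_3p`.
#' @export
high_confidence_call <- function(profile, annotations, geometry,
                                 params = qc_params()) {
  arms <- vapply(annotations, `[[`, "", "arm")
  both <- all(c("5p", "3p") %in% arms)
  over_ok <- if (is.null(geometry)) FALSE else {
    dro <- overhang_in_range(geometry$overhang_drosha_end, params)
    dic <- overhang_in_range(geometry$overhang_dicer_end, params)
    if (params$overhang_mode == "both") dro && dic else dro || dic
  }
  arm_stat <- function(arm, what) {
    p <- profile$arm_profiles[[arm]]
    if (is.null(p)) return(if (what == "depth") 0L else NA_real_)
    if (what == "depth") p$assigned_reads else modal_five_prime_fraction(p)
  }
  d5 <- arm_stat("5p", "depth"); d3 <- arm_stat("3p", "depth")
  f5 <- arm_stat("5p", "frac");  f3 <- arm_stat("3p", "frac")
  c(both_arms_annotated = both,
    overhang_ok = over_ok,
    depth_ok_5p = d5 >= params$min_reads,
    depth_ok_3p = d3 >= params$min_reads,
    homogeneity_ok_5p = !is.na(f5) && f5 >= params$min_frac,
    homogeneity_ok_3p = !is.na(f3) && f3 >= params$min_frac)
}

dominant_arm <- function(profile) {
  profs <- profile$arm_profiles
  if (length(profs) == 0L) return(NULL)
  depths <- vapply(profs, `[[`, 0L, "assigned_reads")
  if (all(depths == 0L)) return(NULL)
  profs[[which.max(depths)]]  # ties: first listed arm (5p)
}

#' Evaluate the low-confidence criteria
#'
#' A locus is flagged low confidence iff strictly more than 100 reads map
#' across the hairpin locus AND strictly fewer than 30% of the reads on
#' the more abundant arm share the modal 5' end. Thresholds are strict
#' inequalities, exactly as published.
#'
#' @param profile A `locus_profile`.
#' @param params A [qc_params] object.
#' @return Named logical vector `low_total_reads_gt_threshold`,
#'   `low_homogeneity_lt_threshold`.
#' @export
low_confidence_call <- function(profile, params = qc_params()) {
  dom <- dominant_arm(profile)
  frac <- if (is.null(dom)) NA_real_ else modal_five_prime_fraction(dom)
  c(low_total_reads_gt_threshold =
      profile$total_reads > params$low_min_reads,
    low_homogeneity_lt_threshold =
      !is.na(frac) && frac < params$low_max_frac)
}

#' Classify a hairpin annotation from its read pattern
#'
#' Composes profile construction, duplex geometry and the two
#' classifiers. `call` is `"high"` when all six high-confidence criteria
#' hold, else `"low"` when both low-confidence criteria hold (high takes
#' precedence), else `"undetermined"`. All per-criterion booleans and the
#' underlying metrics are reported so users can see why a locus missed a
#' classification; lack of data alone never condemns an annotation, it
#' simply leaves it undetermined.
#'
#' @param hairpin A [hairpin_record].
#' @param annotations List of [mature_annotation]s on the hairpin.
#' @param structure A `secondary_structure` for the hairpin, or `NULL`.
#' @param stack A [read_stack] of alignments to the hairpin (may be
#'   empty).
#' @param params A [qc_params] object.
#' @return An object of class `confidence_report` with fields
#'   `accession`, `criteria` (the eight named booleans), `call` and
#'   `metrics`.
#' @examples
#' loc <- make_locus(sim_params(seed = 7))
#' st <- simulate_reads(loc, sim_params(seed = 7))
#' classify(loc$hairpin, loc$annotations, loc$structure, st)$call
#' @export
classify <- function(hairpin, annotations, structure, stack,
                     params = qc_params()) {
  validate_annotations(hairpin, annotations)
  if (!is.null(structure) && structure$length != hairpin$length) {
    stop("structure length does not match hairpin length", call. = FALSE)
  }
  arms <- vapply(annotations, `[[`, "", "arm")
  m5 <- if ("5p" %in% arms) annotations[[match("5p", arms)]] else NULL
  m3 <- if ("3p" %in% arms) annotations[[match("3p", arms)]] else NULL
  geometry <- NULL
  if (!is.null(structure) && !is.null(m5) && !is.null(m3)) {
    geometry <- duplex_overhangs(structure, m5, m3, params$scan_window)
  }
  profile <- build_profile(stack, annotations, params$arm_extension,
                           params$min_read_overlap)
  hi <- high_confidence_call(profile, annotations, geometry, params)
  lo <- low_confidence_call(profile, params)
  call <- if (all(hi)) "high" else if (all(lo)) "low" else "undetermined"
  frac_of <- function(arm) {
    p <- profile$arm_profiles[[arm]]
    if (is.null(p)) NA_real_ else modal_five_prime_fraction(p)
  }
  depth_of <- function(arm) {
    p <- profile$arm_profiles[[arm]]
    if (is.null(p)) 0L else p$assigned_reads
  }
  metrics <- list(
    depth_5p = depth_of("5p"), depth_3p = depth_of("3p"),
    modal_fraction_5p = frac_of("5p"), modal_fraction_3p = frac_of("3p"),
    overhang_drosha_end =
      if (is.null(geometry)) NA_integer_ else geometry$overhang_drosha_end,
    overhang_dicer_end =
      if (is.null(geometry)) NA_integer_ else geometry$overhang_dicer_end,
    total_reads = profile$total_reads,
    unassigned_reads = profile$unassigned_reads)
  base::structure(
    list(accession = hairpin$accession, criteria = c(hi, lo), call = call,
         metrics = metrics, profile = profile),
    class = "confidence_report")
}

#' @export
print.confidence_report <- function(x, ...) {
  cat(sprintf("<confidence_report> %s: %s\n", x$accession, x$call))
  crit <- x$criteria
  cat("  criteria:",
      paste(sprintf("%s=%s", names(crit), ifelse(crit, "T", "F")),
            collapse = " "), "\n")
  m <- x$metrics
  cat(sprintf(
    "  depth 5p/3p: %d/%d; modal fraction 5p/3p: %s/%s; overhangs: %s/%s; total %d\n",
    m$depth_5p, m$depth_3p,
    ifelse(is.na(m$modal_fraction_5p), "-",
           sprintf("%.2f", m$modal_fraction_5p)),
    ifelse(is.na(m$modal_fraction_3p), "-",
           sprintf("%.2f", m$modal_fraction_3p)),
    ifelse(is.na(m$overhang_drosha_end), "-", m$overhang_drosha_end),
    ifelse(is.na(m$overhang_dicer_end), "-", m$overhang_dicer_end),
    m$total_reads))
  invisible(x)
}

report_row <- function(report) {
  crit <- as.list(report$criteria)
  m <- report$metrics
  cbind(data.frame(accession = report$accession, call = report$call,
                   stringsAsFactors = FALSE),
        as.data.frame(crit),
        data.frame(depth_5p = m$depth_5p, depth_3p = m$depth_3p,
                   modal_fraction_5p = m$modal_fraction_5p,
                   modal_fraction_3p = m$modal_fraction_3p,
                   overhang_drosha_end = m$overhang_drosha_end,
                   overhang_dicer_end = m$overhang_dicer_end,
                   total_reads = m$total_reads,
                   unassigned_reads = m$unassigned_reads))
}

#' Write confidence reports as TSV or JSON
#'
#' One row (or JSON object) per hairpin, with the call, all eight
#' per-criterion booleans and the underlying metrics.
#'
#' @param reports List of `confidence_report`s.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_confidence_reports <- function(reports, path,
                                     format = c("tsv", "json")) {
  format <- match.arg(format)
  rows <- do.call(rbind, lapply(reports, report_row))
  rownames(rows) <- NULL
  if (format == "tsv") {
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}
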