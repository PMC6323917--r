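# Seeded generator of synthetic hairpin loci and Drosha/Dicer-consistent
# (or deliberately inconsistent) read stacks. The generator is the
# package's ground truth for classifier testing: every printed threshold
# and boundary can be exercised without downloading any data.

#' Simulation parameters
#'
#' Defaults describe a well-processed, well-covered mammalian-style
#' locus: 24-nt perfect-stem arms, an 8-nt loop, 2-nt 3' overhangs at
#' both duplex ends, 1000 reads per arm with 90% 5'-homogeneity, 5'
#' shifts of at most 3 nt and 3' trimming jitter of at most 2 nt.
#'
#' @param arm_length Stem arm length (nt).
#' @param loop_length Unpaired loop length (nt, >= 3).
#' @param flank_length Unpaired flanking sequence on each side of the
#'   stem (nt), mirroring the precursor context around the duplex.
#' @param depth_5p,depth_3p Reads drawn per arm.
#' @param homogeneity_5p,homogeneity_3p Probability that a read starts at
#'   the canonical mature 5' end.
#' @param shift_range Maximum |5' shift| for non-canonical reads (the
#'   shift is never 0).
#' @param trim_range Maximum 3' length jitter (nt).
#' @param overhang_drosha,overhang_dicer Requested duplex 3' overhangs
#'   (nt) realised exactly by construction.
#' @param seed Integer seed; same seed, same locus and reads.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(arm_length = 24L, loop_length = 8L,
                       flank_length = 10L,
                       depth_5p = 1000L, depth_3p = 1000L,
                       homogeneity_5p = 0.9, homogeneity_3p = 0.9,
                       shift_range = 3L, trim_range = 2L,
                       overhang_drosha = 2L, overhang_dicer = 2L,
                       seed = 1L) {
  stopifnot(arm_length >= 8L, loop_length >= 3L, flank_length >= 0L,
            homogeneity_5p >= 0, homogeneity_5p <= 1,
            homogeneity_3p >= 0, homogeneity_3p <= 1,
            shift_range >= 1L, trim_range >= 0L)
  base::structure(
    list(arm_length = as.integer(arm_length),
         loop_length = as.integer(loop_length),
         flank_length = as.integer(flank_length),
         depth_5p = as.integer(depth_5p), depth_3p = as.integer(depth_3p),
         homogeneity_5p = homogeneity_5p,
         homogeneity_3p = homogeneity_3p,
         shift_range = as.integer(shift_range),
         trim_range = as.integer(trim_range),
         overhang_drosha = as.integer(overhang_drosha),
         overhang_dicer = as.integer(overhang_dicer),
         seed = as.integer(seed)),
    class = "sim_params")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

revcomp_rna <- function(x) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

#' Build a synthetic hairpin locus
#'
#' Constructs a perfect-stem hairpin (the 3p stem arm is the reverse
#' complement of the 5p stem arm), an unpaired loop, unpaired flanking
#' sequence on both sides, and mature annotations on both arms positioned
#' so that [duplex_overhangs()] recovers the requested overhangs exactly.
#' The pair table is written analytically, never folded.
#'
#' With arm length `A`, loop `L`, flank `F`, total `N = 2A + L + 2F`,
#' stem position `F + i` pairs with `N - F + 1 - i` for `i = 1..A`.
#' Requested overhangs `d` (Drosha end) and `c` (Dicer end) place the 5p
#' mature at `[F + max(d,0) + 1, F + A]` and the 3p mature at
#' `[N - F + 1 - A + c, N - F - max(d,0) + d]`.
#'
#' @param params A [sim_params] object.
#' @param name Hairpin name for the record.
#' @return A list of class `sim_locus` with elements `hairpin`
#'   ([hairpin_record]), `structure` (`secondary_structure`),
#'   `annotations` (list of two [mature_annotation]s, 5p first) and
#'   `params`.
#' @examples
#' loc <- make_locus(sim_params(overhang_drosha = 2, overhang_dicer = 2))
#' duplex_overhangs(loc$structure, loc$annotations[[1]],
#'                  loc$annotations[[2]])
#' @export
make_locus <- function(params = sim_params(), name = "syn-mir-1") {
  A <- params$arm_length; L <- params$loop_length
  fl <- params$flank_length
  d <- params$overhang_drosha; cc <- params$overhang_dicer
  N <- 2L * A + L + 2L * fl
  s5 <- fl + max(d, 0L) + 1L
  e5 <- fl + A
  m5_len <- e5 - s5 + 1L
  s3 <- N - fl + 1L - A + cc
  e3 <- N - fl - max(d, 0L) + d
  if (m5_len < 2L || e3 - s3 + 1L < 2L) {
    stop("requested overhangs leave no room for mature sequences on a ",
         A, "-nt arm", call. = FALSE)
  }
  if (e3 > N || s3 <= e5 || cc < -(L - 1L)) {
    stop("requested overhangs do not fit this arm/loop geometry",
         call. = FALSE)
  }
  seq <- with_seed(params$seed, {
    arm5 <- random_rna(A)
    loop <- random_rna(L)
    flank5 <- random_rna(fl)
    flank3 <- random_rna(fl)
    paste0(flank5, arm5, loop, revcomp_rna(arm5), flank3)
  })
  hp <- hairpin_record(name, seq, accession = paste0("SYN-", name))
  db <- paste0(strrep(".", fl), strrep("(", A), strrep(".", L),
               strrep(")", A), strrep(".", fl))
  ss <- parse_dot_bracket(db, N)
  ann5 <- mature_annotation(paste0(name, "-5p"), "5p", s5, e5,
                            substr(seq, s5, e5))
  ann3 <- mature_annotation(paste0(name, "-3p"), "3p", s3, e3,
                            substr(seq, s3, e3))
  base::structure(
    list(hairpin = hp, structure = ss, annotations = list(ann5, ann3),
         params = params),
    class = "sim_locus")
}

#' Simulate a collapsed read stack over a synthetic locus
#'
#' For each arm, `depth` reads are drawn independently: the 5' start is
#' the canonical mature 5' end with probability `homogeneity`, otherwise
#' it is shifted by a uniform non-zero offset within `±shift_range`; the
#' read length is the mature length plus uniform jitter within
#' `±trim_range`. Reads are exact substrings of the hairpin (clamped to
#' its bounds) and are returned collapsed by (sequence, start) with
#' counts. Reproducible: the same seed yields the same stack.
#'
#' @param locus A `sim_locus` from [make_locus()].
#' @param params A [sim_params]; defaults to the locus's own.
#' @return A [read_stack].
#' @export
simulate_reads <- function(locus, params = locus$params) {
  hp <- locus$hairpin
  arms <- list(
    list(ann = locus$annotations[[1L]], depth = params$depth_5p,
         h = params$homogeneity_5p),
    list(ann = locus$annotations[[2L]], depth = params$depth_3p,
         h = params$homogeneity_3p))
  with_seed(params$seed + 1L, {
    starts <- integer(0); lens <- integer(0)
    for (arm in arms) {
      if (arm$depth == 0L) next
      canonical <- arm$ann$start
      m_len <- arm$ann$end - arm$ann$start + 1L
      modal <- runif(arm$depth) < arm$h
      shift <- integer(arm$depth)
      if (any(!modal)) {
        mag <- sample(params$shift_range, sum(!modal), replace = TRUE)
        sgn <- sample(c(-1L, 1L), sum(!modal), replace = TRUE)
        shift[!modal] <- mag * sgn
      }
      jitter <- if (params$trim_range > 0L) {
        sample(seq(-params$trim_range, params$trim_range), arm$depth,
               replace = TRUE)
      } else rep(0L, arm$depth)
      st <- pmax(1L, pmin(canonical + shift, hp$length))
      ln <- pmax(10L, m_len + jitter)
      ln <- pmin(ln, hp$length - st + 1L)
      starts <- c(starts, st); lens <- c(lens, ln)
    }
    seqs <- substring(hp$sequence, starts, starts + lens - 1L)
    read_stack(hp$accession,
               data.frame(read_sequence = seqs, start = starts,
                          count = rep(1L, length(starts)),
                          stringsAsFactors = FALSE),
               hairpin = hp)
  })
}

#' Named simulation presets
#'
#' `"high"`: canonical geometry, deep homogeneous coverage — classifies
#' high confidence. `"low"`: deep coverage with maximally scattered 5'
#' ends (homogeneity 0.1, shifts up to 8 nt) — classifies low
#' confidence. `"sparse"`: canonical geometry but only 5 reads per arm —
#' undetermined for lack of data.
#'
#' @param preset `"high"`, `"low"` or `"sparse"`.
#' @param seed Integer seed.
#' @return A [sim_params] object.
#' @export
sim_preset <- function(preset = c("high", "low", "sparse"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
         high = sim_params(seed = seed),
         low = sim_params(homogeneity_5p = 0.1, homogeneity_3p = 0.1,
                          shift_range = 8L, depth_5p = 500L,
                          depth_3p = 500L, seed = seed),
         sparse = sim_params(depth_5p = 5L, depth_3p = 5L, seed = seed))
}

#' Write a simulated locus and its reads to disk
#'
#' Emits the four community-format files consumed by the classifier:
#' `<prefix>.fa` (hairpin FASTA), `<prefix>.str` (structure file),
#' `<prefix>.mature.tsv` (mature annotations) and `<prefix>.aln.tsv`
#' (collapsed alignments).
#'
#' @param locus A `sim_locus`.
#' @param stack A [read_stack] over the locus.
#' @param prefix Output path prefix.
#' @return Named character vector of the four paths, invisibly.
#' @export
write_locus_files <- function(locus, stack, prefix) {
  hp <- locus$hairpin
  paths <- c(fasta = paste0(prefix, ".fa"),
             structure = paste0(prefix, ".str"),
             mature = paste0(prefix, ".mature.tsv"),
             alignments = paste0(prefix, ".aln.tsv"))
  write_hairpin_fasta(list(hp), paths[["fasta"]])
  write_structure_file(list(locus), paths[["structure"]])
  anns <- list(locus$annotations)
  names(anns) <- hp$accession
  write_mature_tsv(anns, paths[["mature"]])
  stacks <- list(stack)
  names(stacks) <- hp$accession
  write_alignments_tsv(stacks, paths[["alignments"]])
  invisible(paths)
}
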