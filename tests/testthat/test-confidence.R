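# Duplex geometry and the high/low-confidence classifiers.

test_that("duplex overhangs are measured exactly on hand-built stems", {
  # 22+22 perfect stem, 8-nt loop: position k pairs with 53-k.
  db <- paste0(strrep("(", 22), strrep(".", 8), strrep(")", 22))
  ss <- parse_dot_bracket(db, 52L)
  dummy <- strrep("A", 52)
  m <- function(arm, s, e) {
    mature_annotation(paste0("m-", arm), arm, s, e, substr(dummy, s, e))
  }
  # matures placed so each 3' end extends 2 nt past its partner
  geo <- duplex_overhangs(ss, m("5p", 3L, 22L), m("3p", 33L, 52L))
  expect_equal(geo$overhang_drosha_end, 2L)
  expect_equal(geo$overhang_dicer_end, 2L)
  # blunt duplex: matures exactly span the stem
  blunt <- duplex_overhangs(ss, m("5p", 1L, 22L), m("3p", 31L, 52L))
  expect_equal(blunt$overhang_drosha_end, 0L)
  expect_equal(blunt$overhang_dicer_end, 0L)
  # fully unpaired: both ends undefined
  open <- parse_dot_bracket(strrep(".", 52), 52L)
  geo2 <- duplex_overhangs(open, m("5p", 3L, 22L), m("3p", 33L, 52L))
  expect_true(is.na(geo2$overhang_drosha_end))
  expect_true(is.na(geo2$overhang_dicer_end))
  expect_false(any(geo2$defined))
  # overlapping matures are rejected
  expect_error(duplex_overhangs(ss, m("5p", 3L, 30L), m("3p", 28L, 52L)),
               "overlap")
})

test_that("unpaired mature termini are compensated within the scan window", {
  # same stem but the 5p mature starts 2 nt before the helix
  db <- paste0("..", strrep("(", 20), strrep(".", 8), strrep(")", 20),
               "..")
  ss <- parse_dot_bracket(db, 52L)
  dummy <- strrep("A", 52)
  m <- function(arm, s, e) {
    mature_annotation(paste0("m-", arm), arm, s, e, substr(dummy, s, e))
  }
  # 5p starts at 1 (unpaired, first pair at 3); geometry equals the
  # helix-anchored construction shifted by the scan compensation
  geo <- duplex_overhangs(ss, m("5p", 1L, 20L), m("3p", 31L, 52L))
  # anchor i=3 pairs with 50; drosha = (52-50)-(3-1) = 0
  expect_equal(geo$overhang_drosha_end, 0L)
  # terminal bases unpaired beyond the scan window -> undefined
  far <- parse_dot_bracket(paste0(strrep(".", 10), strrep("(", 12),
                                  strrep(".", 8), strrep(")", 12),
                                  strrep(".", 10)), 52L)
  geo2 <- duplex_overhangs(far, m("5p", 1L, 20L), m("3p", 33L, 52L))
  expect_true(is.na(geo2$overhang_drosha_end))
})

test_that("high-confidence call requires all four published rules", {
  loc <- canonical_locus()
  deep <- perfect_stack(loc, 25L)
  rep_full <- classify(loc$hairpin, loc$annotations, loc$structure, deep)
  expect_equal(rep_full$call, "high")
  expect_true(all(rep_full$criteria[1:6]))

  # single-arm annotation is never high, whatever the reads
  rep_one <- classify(loc$hairpin, loc$annotations[1L], loc$structure,
                      scatter_stack(loc, counts_5p = c(`0` = 1000L)))
  expect_false(rep_one$criteria[["both_arms_annotated"]])
  expect_false(rep_one$call == "high")

  # depth boundary: 19 reads on one arm fails, 20 passes
  r19 <- classify(loc$hairpin, loc$annotations, loc$structure,
                  scatter_stack(loc, counts_5p = c(`0` = 19L),
                                counts_3p = c(`0` = 25L)))
  r20 <- classify(loc$hairpin, loc$annotations, loc$structure,
                  scatter_stack(loc, counts_5p = c(`0` = 20L),
                                counts_3p = c(`0` = 25L)))
  expect_equal(r19$call, "undetermined")
  expect_false(r19$criteria[["depth_ok_5p"]])
  expect_equal(r20$call, "high")
})

test_that("5' homogeneity boundary is inclusive at 50%", {
  loc <- canonical_locus()
  # remainder spread over 10 positions so the canonical start stays modal
  mk <- function(m) {
    rest <- spread_counts(1000L - m, as.character(1:10))
    scatter_stack(loc, counts_5p = c(setNames(m, "0"), rest),
                  counts_3p = c(`0` = 1000L))
  }
  r499 <- classify(loc$hairpin, loc$annotations, loc$structure, mk(499L))
  r500 <- classify(loc$hairpin, loc$annotations, loc$structure, mk(500L))
  expect_false(r499$criteria[["homogeneity_ok_5p"]])
  expect_false(r499$call == "high")
  expect_true(r500$criteria[["homogeneity_ok_5p"]])
  expect_equal(r500$call, "high")
})

test_that("overhang window is inclusive [0, 4] and fails when undefined", {
  for (oh in 0:4) {
    p <- sim_params(overhang_drosha = oh, overhang_dicer = oh, seed = 2L)
    loc <- make_locus(p)
    rep <- classify(loc$hairpin, loc$annotations, loc$structure,
                    perfect_stack(loc, 25L))
    expect_equal(rep$metrics$overhang_drosha_end, oh)
    expect_equal(rep$call, "high")
  }
  p5 <- sim_params(overhang_drosha = 5L, overhang_dicer = 5L, seed = 2L)
  loc5 <- make_locus(p5)
  rep5 <- classify(loc5$hairpin, loc5$annotations, loc5$structure,
                   perfect_stack(loc5, 25L))
  expect_false(rep5$criteria[["overhang_ok"]])
  expect_equal(rep5$call, "undetermined")

  # recessed (negative) overhang fails the [0, 4] window
  pneg <- sim_params(overhang_drosha = -2L, overhang_dicer = 2L, seed = 2L)
  locn <- make_locus(pneg)
  repn <- classify(locn$hairpin, locn$annotations, locn$structure,
                   perfect_stack(locn, 25L))
  expect_equal(repn$metrics$overhang_drosha_end, -2L)
  expect_false(repn$criteria[["overhang_ok"]])

  # without a structure the overhang criterion fails conservatively
  rep_nostr <- classify(loc5$hairpin, loc5$annotations, NULL,
                        perfect_stack(loc5, 25L))
  expect_false(rep_nostr$criteria[["overhang_ok"]])

  # either-end mode accepts one good end
  mixed <- make_locus(sim_params(overhang_drosha = 2L,
                                 overhang_dicer = 6L, seed = 2L))
  st <- perfect_stack(mixed, 25L)
  strict <- classify(mixed$hairpin, mixed$annotations, mixed$structure,
                     st)
  loose <- classify(mixed$hairpin, mixed$annotations, mixed$structure,
                    st, qc_params(overhang_mode = "either"))
  expect_false(strict$criteria[["overhang_ok"]])
  expect_true(loose$criteria[["overhang_ok"]])
})

test_that("low-confidence call uses strict > 100 reads and < 30% bounds", {
  loc <- canonical_locus()
  scattered <- function(total, modal_frac, dominant_extra = 0L) {
    modal <- as.integer(round(total * modal_frac))
    rest <- spread_counts(total - modal, as.character(c(-9:-1, 1:10)))
    scatter_stack(loc, counts_5p = c(setNames(modal, "0"), rest))
  }
  # total 500, dominant-arm modal fraction 0.25 -> low
  r <- classify(loc$hairpin, loc$annotations, loc$structure,
                scattered(500L, 0.25))
  expect_equal(r$call, "low")
  # exactly 100 reads is not enough ("more than 100")
  r100 <- classify(loc$hairpin, loc$annotations, loc$structure,
                   scattered(100L, 0.05))
  expect_false(r100$criteria[["low_total_reads_gt_threshold"]])
  expect_equal(r100$call, "undetermined")
  # 101 reads with scattered ends is flagged
  r101 <- classify(loc$hairpin, loc$annotations, loc$structure,
                   scattered(101L, 0.05))
  expect_equal(r101$call, "low")
  # modal fraction exactly 0.30 is not low (strict <30%)
  hist30 <- c(setNames(30L, "0"),
              spread_counts(70L, as.character(c(-9:-1, 1:10))))
  st30 <- scatter_stack(loc, counts_5p = hist30,
                        counts_3p = c(`0` = 1L))
  r30 <- classify(loc$hairpin, loc$annotations, loc$structure, st30)
  expect_equal(r30$metrics$modal_fraction_5p, 0.3)
  expect_false(r30$criteria[["low_homogeneity_lt_threshold"]])
  expect_equal(r30$call, "undetermined")
})

test_that("zero reads leave every read criterion false but arms intact", {
  loc <- canonical_locus()
  rep <- classify(loc$hairpin, loc$annotations, loc$structure,
                  read_stack(loc$hairpin$accession, NULL))
  expect_equal(rep$call, "undetermined")
  expect_true(rep$criteria[["both_arms_annotated"]])
  expect_true(rep$criteria[["overhang_ok"]])  # geometry is read-free
  expect_false(any(rep$criteria[c("depth_ok_5p", "depth_ok_3p",
                                  "homogeneity_ok_5p",
                                  "homogeneity_ok_3p")]))
})

test_that("adding modal reads or concentrating mass never flips high away", {
  loc <- canonical_locus()
  base <- c(`0` = 30L, `1` = 10L, `2` = 5L)
  st <- scatter_stack(loc, counts_5p = base, counts_3p = base)
  r0 <- classify(loc$hairpin, loc$annotations, loc$structure, st)
  expect_equal(r0$call, "high")
  # monotonicity in depth at the modal start
  for (extra in c(1L, 10L, 1000L)) {
    more <- base; more[["0"]] <- more[["0"]] + extra
    r <- classify(loc$hairpin, loc$annotations, loc$structure,
                  scatter_stack(loc, counts_5p = more, counts_3p = base))
    expect_equal(r$call, "high")
  }
  # monotonicity in homogeneity: move off-modal mass onto the mode
  conc <- c(`0` = 45L, `1` = 0L, `2` = 0L)
  conc <- conc[conc > 0L]
  r <- classify(loc$hairpin, loc$annotations, loc$structure,
                scatter_stack(loc, counts_5p = conc, counts_3p = base))
  expect_equal(r$call, "high")
})

test_that("no locus is ever both high and low", {
  loc <- canonical_locus()
  set.seed(77)
  for (rep_i in 1:20) {
    st <- random_stack(loc, n_entries = 15L)
    rep <- classify(loc$hairpin, loc$annotations, loc$structure, st)
    hi <- all(rep$criteria[1:6])
    lo <- all(rep$criteria[7:8])
    expect_false(hi && lo)
    expect_equal(rep$call,
                 if (hi) "high" else if (lo) "low" else "undetermined")
  }
})

test_that("confidence reports serialise with criteria and metrics", {
  loc <- canonical_locus()
  reports <- list(classify(loc$hairpin, loc$annotations, loc$structure,
                           perfect_stack(loc, 25L)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_confidence_reports(reports, tsv, format = "tsv")
  write_confidence_reports(reports, jsn, format = "json")
  df <- read.delim(tsv)
  expect_equal(df$call, "high")
  expect_equal(df$depth_5p, 25L)
  expect_true(df$both_arms_annotated)
  back <- jsonlite::fromJSON(jsn)
  expect_equal(back$call, "high")
})
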